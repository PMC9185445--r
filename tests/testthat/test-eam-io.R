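# Voltage-map I/O and preprocessing.

test_that("voltage CSV parsing is verbatim and contract errors are informative", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("X,Y,Z,Uni,Bi",
               "1.5,2.5,3.5,4.25,0.5",
               "-1,0,2,3.75,0.25",
               "0,0,1,2.5,1.5"), path)
  m <- read_voltage_csv(path, patient_id = "p1")
  expect_s3_class(m, "voltage_map")
  expect_equal(n_points(m), 3L)
  expect_false(m$normalized)
  expect_equal(m$points[, "x"], c(1.5, -1, 0))
  expect_equal(m$unipolar, c(4.25, 3.75, 2.5))
  expect_equal(m$bipolar, c(0.5, 0.25, 1.5))
  expect_true(is.na(m$af_type))

  # missing required column is named
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z,unipolar", "1,2,3,4"), path2)
  expect_error(read_voltage_csv(path2), "bipolar")

  # non-numeric cell reports its row
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z,unipolar,bipolar", "1,2,3,4,0.5", "1,2,oops,4,0.5"), path3)
  expect_error(read_voltage_csv(path3), "row 2")

  # empty file
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y,z,unipolar,bipolar", path4)
  expect_error(read_voltage_csv(path4), "empty")
})

test_that("write/read round trip is lossless field by field", {
  m <- tiny_map(n = 20L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_voltage_csv(m, path)
  back <- read_voltage_csv(path, patient_id = m$patient_id)
  expect_identical(back$points[, 1], m$points[, 1])
  expect_identical(back$points[, 2], m$points[, 2])
  expect_identical(back$points[, 3], m$points[, 3])
  expect_identical(back$unipolar, m$unipolar)
  expect_identical(back$bipolar, m$bipolar)
})

test_that("labels travel through the manifest", {
  maps <- list(tiny_map(), {
    m <- tiny_map(seed = 43L)
    m$patient_id <- "tiny2"
    m$af_type <- 0L
    m$recurrence_1y <- 1L
    m
  })
  dir <- withr::local_tempdir()
  write_cohort(maps, dir)
  again <- read_cohort(dir, labels = file.path(dir, "labels.csv"))
  expect_equal(vapply(again, function(m) m$af_type, integer(1)), c(1L, 0L))
  expect_equal(vapply(again, function(m) m$recurrence_1y, integer(1)), c(0L, 1L))
})

test_that("min-max normalization rescales each channel to [0, 1] per map", {
  m <- voltage_map("p", cbind(c(0, 5, 10), c(1, 2, 3), c(-1, 0, 3)),
                   unipolar = c(0, 1, 0.5), bipolar = c(2, 4, 6))
  nm <- minmax_normalize(m)
  expect_equal(nm$points[, 1], c(0, 0.5, 1))
  expect_true(nm$normalized)
  # channel already spanning {0,1} is unchanged
  expect_equal(nm$unipolar, c(0, 1, 0.5))

  # property: random map attains exact 0 and 1 in every channel
  r <- minmax_normalize(tiny_map(n = 50L))
  for (v in list(r$points[, 1], r$points[, 2], r$points[, 3],
                 r$unipolar, r$bipolar)) {
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
  }

  # idempotent up to floating tolerance on its own output
  r2 <- r
  r2$normalized <- FALSE
  expect_equal(minmax_normalize(r2)$unipolar, r$unipolar, tolerance = 1e-12)

  # degenerate inputs
  expect_error(minmax_normalize(voltage_map("p", matrix(1:3, 1), 1, 1)),
               "at least 2")
  const <- voltage_map("p", cbind(c(1, 2), c(1, 2), c(1, 2)),
                       unipolar = c(3, 3), bipolar = c(1, 2))
  expect_warning(cm <- minmax_normalize(const), "unipolar")
  expect_equal(cm$unipolar, c(0, 0))
})

test_that("map filtering keeps exactly the maps at or above the threshold", {
  sizes <- c(50L, 99L, 100L, 406L)
  maps <- lapply(sizes, function(n) {
    voltage_map(paste0("p", n), matrix(rnorm(3 * n), ncol = 3),
                rep(1.5, n), rep(0.5, n))
  })
  kept <- filter_maps(maps, 100L)
  expect_equal(vapply(kept, n_points, integer(1)), c(100L, 406L))
  expect_identical(filter_maps(list(), 100L), list())

  # brute-force count oracle on random sizes
  rnd <- eamreg:::with_seed(11L, sample(20:500, 12L))
  maps2 <- lapply(rnd, function(n) {
    voltage_map(paste0("q", n), matrix(0, n, 3), rep(1, n), rep(1, n))
  })
  expect_equal(length(filter_maps(maps2, 100L)), sum(rnd >= 100L))
  # retained plus rejected partition the input
  expect_equal(length(filter_maps(maps2, 100L)) + sum(rnd < 100L), length(maps2))
})

test_that("resampling draws a seeded subset without replacement", {
  m <- tiny_map(n = 1300L)
  r <- resample_points(m, 406L, seed = 3L)
  expect_equal(n_points(r), 406L)
  # every retained row is literally present in the input, no duplicates
  key <- function(map) paste(map$points[, 1], map$unipolar, map$bipolar)
  expect_true(all(key(r) %in% key(m)))
  expect_equal(anyDuplicated(key(r)), 0L)

  # N == target returns the identical map
  expect_identical(resample_points(r, 406L, seed = 9L), r)
  # determinism / sensitivity
  expect_identical(resample_points(m, 406L, seed = 3L), r)
  expect_false(identical(resample_points(m, 406L, seed = 4L)$unipolar,
                         r$unipolar))
  expect_error(resample_points(tiny_map(n = 10L), 406L, seed = 1L), "fewer")
})

test_that("preprocessing runs filter, normalize, resample in order", {
  maps <- list(tiny_map(n = 80L), tiny_map(n = 500L), tiny_map(n = 450L))
  out <- preprocess_maps(maps, min_points = 100L, n_points = 406L, seed = 1L)
  expect_length(out, 2L)
  for (m in out) {
    expect_equal(n_points(m), 406L)
    expect_true(m$normalized)
    expect_true(all(m$points >= 0 & m$points <= 1))
  }
})
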