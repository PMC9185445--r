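# Synthetic cohort generator: shells, voltage fields, rigid poses, cohorts.

test_that("shells are deterministic, bounded and non-spherical", {
  s <- generate_shell(406L, shape_seed = 5L)
  expect_equal(dim(s), c(406L, 3L))
  expect_identical(generate_shell(406L, shape_seed = 5L), s)
  # bounded: modulation adds at most 1 + 3 * 0.25 of the max semi-axis (39mm)
  expect_true(all(abs(s) < 39 * 1.75))
  # deformed shell: radial spread from the centroid is nonzero
  ctr <- colMeans(s)
  rad <- sqrt(rowSums(sweep(s, 2, ctr, "-")^2))
  expect_gt(stats::sd(rad) / mean(rad), 0.01)
  expect_error(generate_shell(3L, 1L), "at least 4")
})

test_that("voltage fields ignore the label exactly at effect size zero", {
  spec <- cohort_spec(effect_size = 0, seed = 1L)
  pts <- generate_shell(300L, 2L)
  f0 <- generate_voltage_field(pts, label = 0L, spec, seed = 9L)
  f1 <- generate_voltage_field(pts, label = 1L, spec, seed = 9L)
  expect_identical(f0, f1)
  # determinism and positivity
  expect_identical(generate_voltage_field(pts, 0L, spec, seed = 9L), f0)
  expect_true(all(f0$unipolar > 0) && all(f0$bipolar > 0))
})

test_that("larger effect size depresses bipolar voltage in the positive class", {
  spec <- cohort_spec(effect_size = 4, noise_sd = 0.4, seed = 1L)
  pts <- generate_shell(300L, 3L)
  mean_bi <- function(label) {
    vapply(1:25, function(i) {
      mean(generate_voltage_field(pts, label, spec, seed = 100L + i)$bipolar)
    }, numeric(1))
  }
  expect_lt(mean(mean_bi(1L)), mean(mean_bi(0L)))
})

test_that("random rigid poses are exact isometries with exact ground truth", {
  pts <- generate_shell(150L, 4L)
  # zero ranges give the identity
  id <- apply_random_rigid(pts, 0, 0, seed = 1L)
  expect_equal(id$transform, diag(4))
  expect_equal(id$points, pts, tolerance = 1e-12)

  r <- apply_random_rigid(pts, 45, 0.8, seed = 2L)
  expect_true(is_rigid_transform(r$transform))
  # pairwise distances preserved
  expect_equal(as.numeric(dist(r$points)), as.numeric(dist(pts)),
               tolerance = 1e-10)
  # inverting the ground truth recovers the input coordinates
  back <- apply_transform(rigid_inverse(r$transform), r$points)
  expect_equal(back, pts, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cohort generation is deterministic with the requested structure", {
  spec <- cohort_spec(n_patients = 8L, points_per_map_range = c(200L, 600L),
                      class_balance = 0.5, seed = 21L)
  cohort <- generate_cohort(spec)
  expect_length(cohort, 8L)
  af <- vapply(cohort, function(m) m$af_type, integer(1))
  expect_equal(sum(af %in% c(0L, 1L)), 8L)
  expect_equal(sum(af), 4L)  # balance 0.5 on 8 maps
  counts <- vapply(cohort, n_points, integer(1))
  expect_true(all(counts >= 200L & counts <= 600L))
  # byte-identical regeneration
  expect_identical(generate_cohort(spec), cohort)
  # every map carries its ground-truth pose
  expect_true(all(vapply(cohort, function(m) {
    is_rigid_transform(attr(m, "pose"))
  }, logical(1))))
})

test_that("null cohorts show no label-voltage association", {
  # permutation test on mean bipolar voltage at effect size zero; the
  # association should be rejected at alpha = 0.01 only at the nominal rate
  n_cohorts <- 60L
  pvals <- vapply(seq_len(n_cohorts), function(i) {
    spec <- cohort_spec(n_patients = 8L, points_per_map_range = c(150L, 400L),
                        effect_size = 0, seed = 400L + i)
    cohort <- generate_cohort(spec)
    stat <- vapply(cohort, function(m) mean(m$bipolar), numeric(1))
    lab <- vapply(cohort, function(m) m$af_type, integer(1))
    obs <- abs(mean(stat[lab == 1]) - mean(stat[lab == 0]))
    perm <- eamreg:::with_seed(i, vapply(1:200, function(j) {
      pl <- sample(lab)
      abs(mean(stat[pl == 1]) - mean(stat[pl == 0]))
    }, numeric(1)))
    mean(perm >= obs)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("class separation grows with effect size", {
  gap <- function(effect) {
    mean(vapply(1:4, function(s) {
      spec <- cohort_spec(n_patients = 16L, points_per_map_range = c(150L, 300L),
                          effect_size = effect, seed = 70L + s)
      cohort <- generate_cohort(spec)
      stat <- vapply(cohort, function(m) mean(m$bipolar), numeric(1))
      lab <- vapply(cohort, function(m) m$af_type, integer(1))
      mean(stat[lab == 0]) - mean(stat[lab == 1])
    }, numeric(1)))
  }
  gaps <- vapply(c(0, 2, 6), gap, numeric(1))
  expect_true(all(diff(gaps) > 0))
})
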