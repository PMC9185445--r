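# Voltage-map container and preprocessing: CSV input/output, per-map
# min-max normalisation, minimum-point filtering and resampling to a common
# point count.

#' Construct a voltage map
#'
#' A voltage map is one patient's electroanatomical map: an N x 3 matrix of
#' endocardial point coordinates with a unipolar and a bipolar electrogram
#' amplitude bound to each point, plus two binary outcome labels.
#'
#' @param patient_id Character scalar identifier.
#' @param points N x 3 numeric matrix of coordinates (millimetres when raw,
#'   unitless in `[0, 1]` after normalisation).
#' @param unipolar,bipolar Length-N numeric voltage vectors (millivolts when
#'   raw).
#' @param af_type Binary label: 0 = paroxysmal, 1 = persistent AF
#'   (`NA` when unknown).
#' @param recurrence_1y Binary label: 0 = no recurrence within one year of
#'   ablation, 1 = recurrence (`NA` when unknown).
#' @param normalized Logical: have the five channels been min-max normalised?
#' @return An object of class `voltage_map`.
#' @export
voltage_map <- function(patient_id, points, unipolar, bipolar,
                        af_type = NA_integer_, recurrence_1y = NA_integer_,
                        normalized = FALSE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("`points` must have 3 columns", call. = FALSE)
  n <- nrow(points)
  if (n < 1L) stop("a voltage map needs at least one point", call. = FALSE)
  unipolar <- as.numeric(unipolar)
  bipolar <- as.numeric(bipolar)
  if (length(unipolar) != n || length(bipolar) != n) {
    stop("`unipolar` and `bipolar` must match the number of points", call. = FALSE)
  }
  for (lbl in list(af_type, recurrence_1y)) {
    if (!is.na(lbl) && !(lbl %in% c(0, 1))) {
      stop("labels must be 0, 1 or NA", call. = FALSE)
    }
  }
  structure(
    list(patient_id = as.character(patient_id),
         points = points,
         unipolar = unipolar,
         bipolar = bipolar,
         af_type = as.integer(af_type),
         recurrence_1y = as.integer(recurrence_1y),
         normalized = isTRUE(normalized)),
    class = "voltage_map"
  )
}

#' Number of mapped points in a voltage map
#' @param map A `voltage_map`.
#' @return Integer point count.
#' @export
n_points <- function(map) nrow(map$points)

#' @export
print.voltage_map <- function(x, ...) {
  cat(sprintf("<voltage_map> patient %s: %d points (%s)\n",
              x$patient_id, n_points(x),
              if (x$normalized) "normalized" else "raw"))
  cat(sprintf("  unipolar range [%.3g, %.3g], bipolar range [%.3g, %.3g]\n",
              min(x$unipolar), max(x$unipolar),
              min(x$bipolar), max(x$bipolar)))
  cat(sprintf("  af_type = %s, recurrence_1y = %s\n",
              x$af_type, x$recurrence_1y))
  invisible(x)
}

# column-name aliases accepted in voltage CSV headers (lower-cased)
.column_aliases <- list(
  x = c("x"), y = c("y"), z = c("z"),
  unipolar = c("unipolar", "uni"),
  bipolar = c("bipolar", "bi")
)

#' Read a voltage map from a comma-separated-value export
#'
#' Expects a header naming columns for x, y, z, unipolar and bipolar
#' (case-insensitive; `Uni`/`Bi` accepted as aliases), one mapped point per
#' row. Labels are not part of the export; attach them from a manifest with
#' [attach_labels()].
#'
#' @param path Path to the CSV file.
#' @param patient_id Identifier; defaults to the file name without extension.
#' @return A raw (unnormalised) `voltage_map` with row order preserved and
#'   labels unset.
#' @export
read_voltage_csv <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty voltage file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (nrow(df) == 0L) stop("empty voltage file (no data rows): ", path, call. = FALSE)
  lower <- tolower(trimws(names(df)))
  cols <- integer(0)
  for (canon in names(.column_aliases)) {
    hit <- which(lower %in% .column_aliases[[canon]])
    if (length(hit) == 0L) {
      stop(sprintf("voltage file %s is missing required column '%s'", path, canon),
           call. = FALSE)
    }
    cols[[canon]] <- hit[1L]
  }
  parse_col <- function(canon) {
    raw <- df[[cols[[canon]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d of %s",
                   raw[bad[1L]], canon, bad[1L], path), call. = FALSE)
    }
    val
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  voltage_map(
    patient_id = patient_id,
    points = cbind(x = parse_col("x"), y = parse_col("y"), z = parse_col("z")),
    unipolar = parse_col("unipolar"),
    bipolar = parse_col("bipolar")
  )
}

#' Write a voltage map to CSV
#'
#' Writes columns `x,y,z,unipolar,bipolar` at full double precision so that
#' a read/write round trip is lossless.
#'
#' @param map A `voltage_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_voltage_csv <- function(map, path) {
  stopifnot(inherits(map, "voltage_map"))
  fmt <- function(x) sprintf("%.17g", x)
  df <- data.frame(x = fmt(map$points[, 1]), y = fmt(map$points[, 2]),
                   z = fmt(map$points[, 3]), unipolar = fmt(map$unipolar),
                   bipolar = fmt(map$bipolar))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labels manifest
#'
#' CARTO exports carry no outcomes, so labels travel in a separate manifest:
#' a CSV with columns `patient_id`, `af_type`, `recurrence_1y` and values in
#' `{0, 1}`.
#'
#' @param path Manifest path.
#' @return A data frame with one row per patient.
#' @export
read_labels_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  need <- c("patient_id", "af_type", "recurrence_1y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cl in c("af_type", "recurrence_1y")) {
    if (!all(df[[cl]] %in% c(0L, 1L))) {
      stop("manifest column '", cl, "' must contain only 0/1", call. = FALSE)
    }
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Write a labels manifest
#' @param maps List of `voltage_map`s with labels set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_manifest <- function(maps, path) {
  df <- data.frame(
    patient_id = vapply(maps, function(m) m$patient_id, character(1)),
    af_type = vapply(maps, function(m) m$af_type, integer(1)),
    recurrence_1y = vapply(maps, function(m) m$recurrence_1y, integer(1))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach manifest labels to voltage maps
#' @param maps List of `voltage_map`s.
#' @param manifest Data frame from [read_labels_manifest()].
#' @return The maps with `af_type` / `recurrence_1y` filled in.
#' @export
attach_labels <- function(maps, manifest) {
  lapply(maps, function(m) {
    i <- match(m$patient_id, manifest$patient_id)
    if (is.na(i)) {
      warning("no manifest entry for patient ", m$patient_id, call. = FALSE)
      return(m)
    }
    m$af_type <- as.integer(manifest$af_type[i])
    m$recurrence_1y <- as.integer(manifest$recurrence_1y[i])
    m
  })
}

#' Min-max normalise a voltage map
#'
#' Rescales each of the five channels (x, y, z, unipolar, bipolar)
#' independently to `[0, 1]` via `(c - min(c)) / (max(c) - min(c))`,
#' per map — cohort-wide normalisation is deliberately not used, so every
#' map fills the unit cube regardless of atrial size. A constant channel
#' (zero denominator) maps to all zeros with a warning.
#'
#' @param map A raw `voltage_map` with at least two points.
#' @return The normalised `voltage_map` (`normalized = TRUE`).
#' @export
minmax_normalize <- function(map) {
  stopifnot(inherits(map, "voltage_map"))
  if (map$normalized) stop("map is already normalized", call. = FALSE)
  if (n_points(map) < 2L) {
    stop("min-max normalization needs at least 2 points", call. = FALSE)
  }
  scale01 <- function(v, name) {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warning(sprintf("channel '%s' is constant; normalized to all zeros", name),
              call. = FALSE)
      return(rep(0, length(v)))
    }
    (v - rng[1]) / (rng[2] - rng[1])
  }
  map$points <- cbind(x = scale01(map$points[, 1], "x"),
                      y = scale01(map$points[, 2], "y"),
                      z = scale01(map$points[, 3], "z"))
  map$unipolar <- scale01(map$unipolar, "unipolar")
  map$bipolar <- scale01(map$bipolar, "bipolar")
  map$normalized <- TRUE
  map
}

#' Drop maps with too few points
#'
#' Maps whose point count is smaller than `min_points` are removed
#' (the boundary count itself is kept); order is preserved.
#'
#' @param maps List of `voltage_map`s.
#' @param min_points Minimum point count (default 100).
#' @return The retained maps (possibly an empty list).
#' @export
filter_maps <- function(maps, min_points = 100L) {
  maps[vapply(maps, n_points, integer(1)) >= min_points]
}

#' Resample a voltage map to a common point count
#'
#' Draws a uniformly random subset of rows without replacement, keeping each
#' (point, unipolar, bipolar) row intact and preserving the original
#' relative row order. Deterministic given `seed`.
#'
#' @param map A `voltage_map` with at least `n_target` points.
#' @param n_target Common point count (default 406).
#' @param seed Integer seed for the subset draw.
#' @return A `voltage_map` with exactly `n_target` points.
#' @export
resample_points <- function(map, n_target = 406L, seed) {
  stopifnot(inherits(map, "voltage_map"))
  n <- n_points(map)
  if (n < n_target) {
    stop(sprintf("map %s has %d points, fewer than the target %d",
                 map$patient_id, n, n_target), call. = FALSE)
  }
  if (n == n_target) return(map)
  keep <- sort(with_seed(seed, sample.int(n, n_target)))
  map$points <- map$points[keep, , drop = FALSE]
  map$unipolar <- map$unipolar[keep]
  map$bipolar <- map$bipolar[keep]
  map
}

#' Preprocess a cohort of voltage maps
#'
#' Applies the fixed preprocessing order: filter out maps with fewer than
#' `min_points` points, min-max normalise each survivor, then resample each
#' to `n_points` points (per-map seeds derived from `seed`).
#'
#' @param maps List of raw `voltage_map`s.
#' @param min_points Minimum point count (default 100).
#' @param n_points Common resampled count (default 406).
#' @param seed Master integer seed.
#' @return List of normalised, resampled `voltage_map`s.
#' @export
preprocess_maps <- function(maps, min_points = 100L, n_points = 406L, seed) {
  kept <- filter_maps(maps, min_points)
  lapply(seq_along(kept), function(i) {
    m <- minmax_normalize(kept[[i]])
    resample_points(m, n_points, seed = derive_seed(seed, 101L, i))
  })
}

#' Read a directory of voltage CSVs plus a labels manifest
#' @param dir Directory containing `*.csv` voltage exports (the manifest,
#'   if inside `dir`, must be named `labels.csv` and is skipped).
#' @param labels Optional path to the labels manifest.
#' @return List of raw `voltage_map`s.
#' @export
read_cohort <- function(dir, labels = NULL) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "labels.csv"]
  if (length(files) == 0L) stop("no voltage CSV files in ", dir, call. = FALSE)
  maps <- lapply(files, read_voltage_csv)
  if (!is.null(labels)) maps <- attach_labels(maps, read_labels_manifest(labels))
  maps
}

#' Write a cohort of voltage maps plus its labels manifest
#' @param maps List of `voltage_map`s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in maps) {
    write_voltage_csv(m, file.path(dir, paste0(m$patient_id, ".csv")))
  }
  write_labels_manifest(maps, file.path(dir, "labels.csv"))
  invisible(dir)
}
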