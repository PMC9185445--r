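# Canonical voltage reordering: after registration every map lives in the
# template's normalised frame, so sorting points by their L1 distance to the
# origin gives every patient's voltages the same positional meaning.

#' L1 (Manhattan) distance of a point to the origin
#' @param point Numeric length-3 coordinate vector.
#' @return `|x| + |y| + |z|`.
#' @export
l1_distance <- function(point) {
  stopifnot(length(point) == 3L, all(is.finite(point)))
  sum(abs(point))
}

#' Canonically reorder a map's voltages by L1 distance to the origin
#'
#' Computes `d_i = |x_i| + |y_i| + |z_i|` per point, sorts ascending (ties
#' broken stably by original row index), and applies the identical
#' permutation to both voltage channels, yielding fixed-length vectors whose
#' coordinates carry the same spatial meaning across registered patients.
#' The result is invariant to any prior shuffling of the map's rows.
#'
#' @param map A registered `voltage_map` with the common point count.
#' @param n_common Expected common point count (default 406).
#' @return List of two `ordered_voltage_vector`s, `unipolar` and `bipolar`:
#'   numeric vectors with attributes `channel` and `patient_id`.
#' @export
reorder_voltages <- function(map, n_common = 406L) {
  stopifnot(inherits(map, "voltage_map"))
  if (n_points(map) != n_common) {
    stop(sprintf("map %s has %d points; expected the common count %d",
                 map$patient_id, n_points(map), n_common), call. = FALSE)
  }
  d <- rowSums(abs(map$points))
  ord <- order(d)  # radix sort: stable, ties keep original row order
  make_vec <- function(values, channel) {
    structure(values[ord], channel = channel, patient_id = map$patient_id,
              class = "ordered_voltage_vector")
  }
  list(unipolar = make_vec(map$unipolar, "unipolar"),
       bipolar = make_vec(map$bipolar, "bipolar"))
}

#' Write a cohort's reordered voltages to CSV
#'
#' One row per patient: `patient_id`, the two outcome labels, then the
#' canonically ordered unipolar and bipolar voltages (`uni_001` ...,
#' `bi_001` ...), ready for any external classifier.
#'
#' @param maps List of registered `voltage_map`s with the common point count.
#' @param path Output CSV path.
#' @param n_common Common point count (default 406).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(maps, path, n_common = 406L) {
  uni <- build_feature_matrix(maps, "unipolar", n_common)
  bi <- build_feature_matrix(maps, "bipolar", n_common)
  colnames(uni) <- sprintf("uni_%03d", seq_len(n_common))
  colnames(bi) <- sprintf("bi_%03d", seq_len(n_common))
  df <- data.frame(
    patient_id = vapply(maps, function(m) m$patient_id, character(1)),
    af_type = vapply(maps, function(m) m$af_type, integer(1)),
    recurrence_1y = vapply(maps, function(m) m$recurrence_1y, integer(1)),
    uni, bi, check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stack a cohort's reordered voltages into a feature matrix
#'
#' @param maps List of registered `voltage_map`s with the common point count.
#' @param channel `"unipolar"` or `"bipolar"`.
#' @param n_common Common point count (default 406).
#' @return Numeric matrix, one row per patient, `n_common` columns; row
#'   names are patient ids.
#' @export
build_feature_matrix <- function(maps, channel = c("unipolar", "bipolar"),
                                 n_common = 406L) {
  channel <- match.arg(channel)
  rows <- lapply(maps, function(m) {
    as.numeric(reorder_voltages(m, n_common)[[channel]])
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(maps, function(m) m$patient_id, character(1))
  X
}
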