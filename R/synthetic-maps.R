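# Synthetic voltage-map cohorts: deformed-ellipsoid atrial shells, spatially
# correlated voltage fields with class-dependent low-voltage burden, and
# random rigid poses with exact ground truth.

#' Specify a synthetic cohort
#'
#' Bundles the generator parameters for a synthetic left-atrial cohort.
#' Point counts emulate clinical mapping densities (roughly 200-4000 points,
#' mean about 1300); `effect_size` controls how strongly low-voltage burden
#' separates the two classes (0 = labels carry no signal), in units of the
#' additive measurement noise.
#'
#' @param n_patients Number of maps (default 8).
#' @param points_per_map_range Length-2 integer range of raw point counts.
#' @param class_balance Fraction of positive labels in `[0, 1]`.
#' @param effect_size Nonnegative class-separation strength.
#' @param noise_sd Additive voltage noise standard deviation (millivolts).
#' @param correlation_length Spatial correlation length of the baseline
#'   voltage field, as a fraction of the shell diameter.
#' @param seed Master integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 8L,
                        points_per_map_range = c(200L, 4000L),
                        class_balance = 0.5,
                        effect_size = 2,
                        noise_sd = 0.4,
                        correlation_length = 0.3,
                        seed = 1L) {
  stopifnot(n_patients >= 1L,
            length(points_per_map_range) == 2L,
            points_per_map_range[1] >= 1L,
            points_per_map_range[1] <= points_per_map_range[2],
            class_balance >= 0, class_balance <= 1,
            effect_size >= 0, noise_sd >= 0, correlation_length > 0)
  structure(
    list(n_patients = as.integer(n_patients),
         points_per_map_range = as.integer(points_per_map_range),
         class_balance = class_balance,
         effect_size = effect_size,
         noise_sd = noise_sd,
         correlation_length = correlation_length,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Min-max normalise bare coordinates to the unit cube
#'
#' Coordinate-only analogue of [minmax_normalize()] for clouds that carry no
#' voltages (registration training shells).
#'
#' @param points N x 3 matrix.
#' @return N x 3 matrix with each column rescaled to `[0, 1]`.
#' @export
normalize_unit_cube <- function(points) {
  apply(points, 2L, function(v) (v - min(v)) / (max(v) - min(v)))
}

# uniform directions on the unit sphere (n x 3)
runif_sphere <- function(n) {
  m <- matrix(stats::rnorm(3L * n), ncol = 3L)
  m / sqrt(rowSums(m^2))
}

#' Sample a deformed-ellipsoid atrial shell
#'
#' Points are drawn on the surface of a randomly scaled ellipsoid (semi-axes
#' around 30 mm, the order of a left atrium) whose radius is modulated by a
#' few smooth directional bumps, giving closed star-convex shells of varied
#' shape.
#'
#' @param n_points Number of surface points (at least 4).
#' @param shape_seed Integer seed; the same seed reproduces the shell.
#' @return N x 3 coordinate matrix (millimetres), centred near the origin.
#' @export
generate_shell <- function(n_points, shape_seed) {
  if (n_points < 4L) stop("a shell needs at least 4 points", call. = FALSE)
  with_seed(shape_seed, {
    axes <- 30 * stats::runif(3L, 0.7, 1.3)
    n_bumps <- 3L
    bump_dir <- runif_sphere(n_bumps)
    bump_amp <- stats::runif(n_bumps, 0.05, 0.25)
    bump_kappa <- stats::runif(n_bumps, 3, 6)
    dirs <- runif_sphere(n_points)
    mod <- rep(1, n_points)
    for (j in seq_len(n_bumps)) {
      cosang <- dirs %*% bump_dir[j, ]
      mod <- mod + bump_amp[j] * exp(bump_kappa[j] * (cosang - 1))
    }
    pts <- dirs * as.numeric(mod)
    pts <- sweep(pts, 2L, axes, "*")
    colnames(pts) <- c("x", "y", "z")
    pts
  })
}

# multiplicative low-voltage depression field from a set of patches
patch_depression <- function(points, centers, radii, depths) {
  m <- rep(1, nrow(points))
  for (p in seq_along(radii)) {
    d2 <- rowSums(sweep(points, 2L, centers[p, ], "-")^2)
    m <- m * (1 - depths[p] * exp(-d2 / (2 * radii[p]^2)))
  }
  m
}

#' Generate spatially correlated unipolar/bipolar voltage fields
#'
#' Builds a smooth baseline electrogram-amplitude field (Gaussian random
#' bumps with correlation length `spec$correlation_length` of the shell
#' diameter), then carves low-voltage patches into it — the synthetic stand-in
#' for fibrotic substrate. Background patches appear regardless of label;
#' label-linked patches, whose expected count and depth scale with
#' `label * spec$effect_size`, concentrate around a fixed direction of the
#' shell's intrinsic frame, so class signal is carried both by overall
#' low-voltage burden and by its location. The bipolar channel shares the
#' patch geometry with the unipolar channel (lower baseline, stronger
#' relative depression), and independent noise of sd `spec$noise_sd` is
#' added to each channel. All values are clamped positive.
#'
#' @param points N x 3 shell coordinates (intrinsic, pre-pose frame).
#' @param label Binary class label driving the primary patch family.
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @param label2 Optional second binary label driving an independent,
#'   weaker patch family around a different direction (default 0 = absent).
#' @return List with numeric length-N `unipolar` and `bipolar` vectors
#'   (millivolts, positive).
#' @export
generate_voltage_field <- function(points, label, spec, seed, label2 = 0L) {
  stopifnot(nrow(points) >= 1L, label %in% c(0, 1), label2 %in% c(0, 1))
  with_seed(seed, {
    n <- nrow(points)
    ctr <- colMeans(points)
    diam <- 2 * mean(sqrt(rowSums(sweep(points, 2L, ctr, "-")^2)))
    ell <- spec$correlation_length * diam

    # smooth baseline field shared by the two channels
    n_base <- 10L
    base_idx <- sample.int(n, min(n_base, n))
    w <- stats::rnorm(length(base_idx), 0, 0.25)
    g <- rep(0, n)
    for (m in seq_along(base_idx)) {
      d2 <- rowSums(sweep(points, 2L, points[base_idx[m], ], "-")^2)
      g <- g + w[m] * exp(-d2 / (2 * ell^2))
    }

    draw_patches <- function(k, dir_center, concentration) {
      if (k == 0L) {
        return(list(centers = matrix(0, 0, 3), radii = numeric(0),
                    depths = numeric(0)))
      }
      dirs <- runif_sphere(k)
      if (!is.null(dir_center)) {
        dirs <- dirs + concentration * matrix(dir_center, k, 3, byrow = TRUE)
        dirs <- dirs / sqrt(rowSums(dirs^2))
      }
      # anchor each patch at the shell point most aligned with its direction
      rel <- sweep(points, 2L, ctr, "-")
      rel <- rel / sqrt(rowSums(rel^2))
      idx <- apply(dirs %*% t(rel), 1L, which.max)
      list(centers = points[idx, , drop = FALSE],
           radii = stats::runif(k, 0.15, 0.22) * diam,
           depths = stats::runif(k, 0.6, 0.8))
    }

    # Background burden is a shared nuisance (Poisson). Label-linked patch
    # counts are deterministic in label * effect_size: the class signal must
    # shift the burden without inflating its variance, otherwise separation
    # on the per-map normalized scale is not monotone in the effect.
    background <- draw_patches(stats::rpois(1L, 0.8), NULL, 0)
    u_primary <- c(1, 1, 1) / sqrt(3)
    u_secondary <- c(-1, 1, -1) / sqrt(3)
    primary <- draw_patches(round(1.5 * label * spec$effect_size),
                            u_primary, 2.5)
    secondary <- draw_patches(round(1.0 * label2 * spec$effect_size),
                              u_secondary, 2.5)

    centers <- rbind(background$centers, primary$centers, secondary$centers)
    radii <- c(background$radii, primary$radii, secondary$radii)
    depths <- c(background$depths, primary$depths, secondary$depths)
    m_uni <- patch_depression(points, centers, radii, 0.8 * depths)
    m_bi <- patch_depression(points, centers, radii, depths)

    uni <- (3.0 + g) * m_uni + stats::rnorm(n, 0, spec$noise_sd)
    bi <- (1.5 + 0.6 * g) * m_bi + stats::rnorm(n, 0, spec$noise_sd)
    list(unipolar = pmax(uni, 0.02), bipolar = pmax(bi, 0.02))
  })
}

#' Apply a random rigid pose to a point cloud
#'
#' Draws a rotation of angle uniform in `[0, max_rot_deg]` degrees about a
#' uniformly random axis and a translation of magnitude uniform in
#' `[0, max_trans]` along a uniformly random direction, and returns both the
#' transformed cloud and the exact transform used.
#'
#' @param points N x 3 matrix.
#' @param max_rot_deg Maximum rotation angle in degrees (default 45).
#' @param max_trans Maximum translation magnitude (default 0.8).
#' @param seed Integer seed.
#' @return List with `points` (transformed N x 3) and `transform`
#'   (the 4x4 rigid transform `G` with `points = apply_transform(G, input)`).
#' @export
apply_random_rigid <- function(points, max_rot_deg = 45, max_trans = 0.8, seed) {
  stopifnot(is.matrix(points), ncol(points) == 3L, nrow(points) >= 1L)
  with_seed(seed, {
    axis <- as.numeric(runif_sphere(1L))
    angle <- stats::runif(1L, 0, max_rot_deg) * pi / 180
    tdir <- as.numeric(runif_sphere(1L))
    tmag <- stats::runif(1L, 0, max_trans)
    G <- diag(4)
    G[1:3, 1:3] <- rotation_axis_angle(axis, angle)
    G[1:3, 4] <- tmag * tdir
    list(points = apply_transform(G, points), transform = G)
  })
}

#' Generate a synthetic voltage-map cohort
#'
#' For each patient: a deformed-ellipsoid shell, class-dependent voltage
#' fields in the shell's intrinsic frame, then a random rigid pose
#' (rotation up to 10 degrees, translation up to 10 mm). The pose spread
#' emulates clinical exports, which share the mapping system's patient
#' frame and so differ by moderate orientation offsets rather than
#' arbitrary rotations. Labels are
#' assigned as fixed counts per `class_balance` in a seeded random order;
#' `af_type` drives the primary low-voltage patch family and
#' `recurrence_1y` an independent weaker family. Fully deterministic given
#' `spec$seed`.
#'
#' @param spec A `cohort_spec`.
#' @return List of raw `voltage_map`s with labels set and, for registration
#'   benchmarking, the ground-truth pose stored in attribute `"pose"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  rng <- spec$points_per_map_range
  counts <- with_seed(derive_seed(spec$seed, 1L), {
    k <- round(stats::rlnorm(n, meanlog = log(1150), sdlog = 0.45))
    pmin(pmax(k, rng[1]), rng[2])
  })
  pos <- round(spec$class_balance * n)
  af <- with_seed(derive_seed(spec$seed, 2L),
                  sample(c(rep(1L, pos), rep(0L, n - pos))))
  # recurrence is stratified within the AF classes (balanced as closely as
  # the group sizes allow), so the two outcomes are orthogonal by design and
  # neither patch family confounds the other's classification
  rec <- integer(n)
  rec_stream <- derive_seed(spec$seed, 3L)
  for (cls in c(0L, 1L)) {
    idx <- which(af == cls)
    k <- length(idx)
    kp <- round(spec$class_balance * k)
    rec[idx] <- with_seed(derive_seed(rec_stream, cls),
                          sample(c(rep(1L, kp), rep(0L, k - kp))))
  }
  lapply(seq_len(n), function(i) {
    shell <- generate_shell(counts[i], derive_seed(spec$seed, 10L, i))
    volt <- generate_voltage_field(shell, af[i], spec,
                                   derive_seed(spec$seed, 20L, i),
                                   label2 = rec[i])
    posed <- apply_random_rigid(shell, max_rot_deg = 10, max_trans = 10,
                                seed = derive_seed(spec$seed, 30L, i))
    m <- voltage_map(patient_id = sprintf("synth%02d", i),
                     points = posed$points,
                     unipolar = volt$unipolar,
                     bipolar = volt$bipolar,
                     af_type = af[i],
                     recurrence_1y = rec[i])
    attr(m, "pose") <- posed$transform
    m
  })
}

#' Generate labelled synthetic shape classes for encoder pretraining
#'
#' Four elementary closed-surface classes — sphere, anisotropic ellipsoid,
#' box shell and two-lobe (two fused spheres) — each with per-cloud random
#' scale and jitter. These play the role of a generic shape corpus for
#' pretraining the point-cloud encoder.
#'
#' @param n_per_class Clouds per class.
#' @param n_points Points per cloud.
#' @param seed Integer seed.
#' @return List with `clouds` (list of N x 3 matrices) and `labels`
#'   (integer class ids 1..4).
#' @export
generate_shape_classes <- function(n_per_class = 50L, n_points = 406L, seed = 1L) {
  make_one <- function(class_id, s) {
    with_seed(s, {
      dirs <- runif_sphere(n_points)
      pts <- switch(class_id,
        dirs,                                          # sphere
        sweep(dirs, 2L, stats::runif(3L, 0.4, 1.6), "*"),  # ellipsoid
        {                                               # box shell
          cube <- matrix(stats::runif(3L * n_points, -1, 1), ncol = 3L)
          face <- sample.int(3L, n_points, replace = TRUE)
          sgn <- sample(c(-1, 1), n_points, replace = TRUE)
          cube[cbind(seq_len(n_points), face)] <- sgn
          cube
        },
        {                                               # two-lobe
          side <- sample(c(-1, 1), n_points, replace = TRUE)
          dirs * 0.7 + cbind(side * 0.6, 0, 0)
        })
      scale <- stats::runif(1L, 0.8, 1.2)
      pts * scale + matrix(stats::rnorm(3L * n_points, 0, 0.02), ncol = 3L)
    })
  }
  clouds <- list()
  labels <- integer(0)
  for (cls in 1:4) {
    for (j in seq_len(n_per_class)) {
      clouds[[length(clouds) + 1L]] <- make_one(cls, derive_seed(seed, cls, j))
      labels <- c(labels, cls)
    }
  }
  list(clouds = clouds, labels = labels)
}
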