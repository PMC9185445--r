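# Feature-space Lucas-Kanade registration on SE(3).

test_that("the Jacobian is the negative-perturbation finite difference", {
  pts <- unit_shell(5L)
  w <- encoder_init(1L)
  J <- compute_jacobian(pts, w, step = 0.01)
  expect_equal(dim(J), c(1024L, 6L))

  # analytic test double: centroid encoder. For translation generator i,
  # exp(-step e_i) shifts every point by -step along axis i, so the centroid
  # derivative is exactly -e_i.
  centroid_fun <- function(p) colMeans(p)
  Jc <- compute_jacobian(pts, w, step = 0.01, encode_fun = centroid_fun)
  expect_equal(Jc[, 4:6], -diag(3), tolerance = 1e-10)
  # rotation columns: d/dt of R(-t e_i) applied to the centroid
  ctr <- colMeans(pts)
  for (i in 1:3) {
    expect_equal(Jc[, i], as.numeric(eamreg:::skew3(ctr)[, i]),
                 tolerance = 0.01)
  }

  # halving the step changes a smooth encoder's Jacobian by O(step)
  smooth_fun <- function(p) {
    c(sin(colMeans(p)), colMeans(p^2))
  }
  J1 <- compute_jacobian(pts, w, step = 0.02, encode_fun = smooth_fun)
  J2 <- compute_jacobian(pts, w, step = 0.01, encode_fun = smooth_fun)
  J3 <- compute_jacobian(pts, w, step = 0.005, encode_fun = smooth_fun)
  e1 <- max(abs(J1 - J2))
  e2 <- max(abs(J2 - J3))
  expect_lt(e2, e1)  # first-order scheme: difference shrinks with the step

  expect_error(compute_jacobian(pts, w, step = 0), "positive")
})

test_that("registering a map onto itself stays at the identity", {
  m <- small_cohort(seed = 3L, n = 2L)[[1]]
  w <- encoder_init(1L)
  reg <- lk_register(m, m, w)
  expect_lt(max(abs(reg$estimate - diag(4))), 1e-6)
  expect_lte(reg$iterations_run, 2L)
  expect_true(reg$converged)
  expect_length(reg$residual_trace, reg$iterations_run + 1L)
})

test_that("registration respects the iteration cap and point-voltage pairing", {
  cohort <- small_cohort(seed = 5L, n = 2L)
  src <- cohort[[1]]
  tpl <- cohort[[2]]
  w <- encoder_init(1L)
  reg <- lk_register(src, tpl, w, max_iter = 20L)
  expect_lte(reg$iterations_run, 20L)
  expect_length(reg$residual_trace, reg$iterations_run + 1L)
  # voltages ride along unchanged and stay bound to their rows
  expect_identical(reg$aligned$unipolar, src$unipolar)
  expect_identical(reg$aligned$bipolar, src$bipolar)
  # coordinates moved rigidly by the estimate
  expect_equal(reg$aligned$points,
               apply_transform(reg$estimate, src$points),
               tolerance = 1e-8, ignore_attr = TRUE)

  short <- lk_register(src, tpl, w, max_iter = 3L)
  expect_lte(short$iterations_run, 3L)

  expect_error(lk_register(src$points[1:100, ], tpl, w), "same point count")
})

test_that("a trained encoder recovers known rigid perturbations", {
  w <- get_registration_weights()
  res <- recovery_trials(w, n_trials = 10L, max_rot = 10, max_trans = 0.1)
  expect_lt(median(res[, "rot"]), 5)
  expect_lt(median(res[, "trans"]), 0.05)
  # residual is non-increasing over the final iterations on an easy case
  tpl <- unit_shell(31L)
  pert <- apply_random_rigid(tpl, 10, 0.1, seed = 55L)
  reg <- lk_register(pert$points, tpl, w)
  tail_trace <- utils::tail(reg$residual_trace, 3L)
  expect_true(all(diff(tail_trace) <= 1e-8))
})

test_that("registration training contracts hold", {
  shells <- lapply(1:3, function(i) normalize_unit_cube(generate_shell(80L, i)))
  w <- encoder_init(2L)
  expect_identical(train_registration(shells, w, "pretrain", epochs = 0L), w)
  expect_error(train_registration(shells[1], w, "finetune", epochs = 1L),
               "at least 2")

  cohort <- small_cohort(seed = 9L, n = 3L)
  wf <- train_registration(cohort, w, "finetune", epochs = 1L, seed = 4L,
                           max_iter = 1L)
  expect_equal(attr(wf, "rounds_per_epoch"), 3L)
  expect_length(attr(wf, "loss_trace"), 1L)
  # weights actually moved
  expect_gt(max(abs(wf$W3 - w$W3)), 0)
})

test_that("pretraining reduces the recovery loss below its initialization level", {
  w_init <- encoder_init(101L)  # an untrained encoder as the baseline
  w_trained <- get_registration_weights()
  loss_init <- recovery_trials(w_init, n_trials = 10L, max_rot = 45,
                               max_trans = 0.8)[, "loss"]
  loss_trained <- recovery_trials(w_trained, n_trials = 10L, max_rot = 45,
                                  max_trans = 0.8)[, "loss"]
  expect_lt(median(loss_trained), median(loss_init))
})

test_that("recovery error does not improve as perturbations grow", {
  w <- get_registration_weights()
  mean_rot_err <- vapply(c(5, 20, 40), function(mr) {
    mean(recovery_trials(w, n_trials = 10L, max_rot = mr,
                         max_trans = mr / 100)[, "rot"])
  }, numeric(1))
  expect_true(all(diff(mean_rot_err) >= 0))
})
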