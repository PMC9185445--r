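# Encoder weights shared across test files. Training runs once per suite:
# shape-class pretraining followed by ground-truth-twist registration
# pretraining on 200 synthetic shells for 20 epochs (5 unrolled iterations
# per training sample, Adam lr 3e-4), the same schedule the acceptance
# checks use.

.weights_cache <- new.env(parent = emptyenv())

get_registration_weights <- function() {
  if (!is.null(.weights_cache$w)) return(.weights_cache$w)
  shapes <- generate_shape_classes(n_per_class = 25L, n_points = 200L,
                                   seed = 101L)
  w <- pretrain_encoder(shapes, epochs = 5L, batch_size = 16L, seed = 102L)
  shells <- lapply(1:200, function(i) {
    normalize_unit_cube(generate_shell(200L, 9000L + i))
  })
  for (round in 1:4) {
    w <- train_registration(shells, w, mode = "pretrain", epochs = 5L,
                            seed = eamreg:::derive_seed(103L, round),
                            max_iter = 5L, lr = 3e-4)
  }
  .weights_cache$w <- w
  w
}

# registration recovery trials shared by module and acceptance tests
recovery_trials <- function(weights, n_trials = 50L, max_rot = 20,
                            max_trans = 0.2, max_iter = 20L) {
  t(vapply(seq_len(n_trials), function(s) {
    tpl <- unit_shell(300L + (s %% 10L))
    pert <- apply_random_rigid(tpl, max_rot, max_trans, seed = 700L + s)
    G_gt <- rigid_inverse(pert$transform)
    reg <- lk_register(pert$points, tpl, weights, max_iter = max_iter)
    kab <- kabsch_align(pert$points, tpl)
    c(rot = rotation_error_deg(reg$estimate, G_gt),
      trans = translation_error(reg$estimate, G_gt),
      agree = as.numeric(rotation_error_deg(reg$estimate, kab) < 5 &
                           translation_error(reg$estimate, kab) < 0.05),
      iters = reg$iterations_run,
      loss = registration_loss(reg$estimate, G_gt))
  }, numeric(5)))
}
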