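# SE(3) Lucas-Kanade registration through the encoder's feature space.
#
# The template's feature Jacobian is approximated once by finite differences
# of negative twist perturbations (inverse-compositional form). Each
# iteration solves for the twist with the Moore-Penrose pseudoinverse,
# xi = J^+ [phi(P_S) - phi(P_T)], applies DeltaG = exp(xi) to the source
# coordinates (voltages ride along, bound to their points), and recomputes
# the source feature. The final estimate is the left-to-right composition of
# the incremental updates.

# Moore-Penrose pseudoinverse via SVD with a relative singular-value cutoff
pinv <- function(A, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1]
  rank_deficient <- any(!keep)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  list(pinv = sv$v %*% (dinv * t(sv$u)), rank_deficient = rank_deficient)
}

# resolve a voltage map or bare matrix to an N x 3 coordinate matrix
as_points <- function(x) {
  if (inherits(x, "voltage_map")) x$points else as.matrix(x)
}

#' Finite-difference feature Jacobian at the template
#'
#' Column i is `[phi(exp(-step * e_i) . P_T) - phi(P_T)] / step`: the
#' inverse-compositional approximation built from negative twist
#' perturbations of the template, computed once per registration call.
#'
#' @param template A `voltage_map` or N x 3 matrix.
#' @param weights An `encoder_weights` object.
#' @param step Finite-difference step size (default 0.01).
#' @param encode_fun Feature function `f(points)`; defaults to
#'   [encode()] with `weights` (overridable for analytic test doubles).
#' @return A (feature dimension) x 6 Jacobian matrix.
#' @export
compute_jacobian <- function(template, weights, step = 0.01,
                             encode_fun = NULL) {
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  pts <- as_points(template)
  if (is.null(encode_fun)) encode_fun <- function(p) encode(p, weights)
  phi0 <- encode_fun(pts)
  J <- matrix(0, length(phi0), 6L)
  for (i in 1:6) {
    xi <- rep(0, 6)
    xi[i] <- -step
    J[, i] <- (encode_fun(apply_transform(se3_exp(xi), pts)) - phi0) / step
  }
  J
}

#' Register a source voltage map to a template
#'
#' Iterative feature-space Lucas-Kanade alignment on SE(3). Stops when the
#' twist norm falls below `tol` or after `max_iter` applied updates. Only the
#' source's coordinates move; its unipolar/bipolar values stay bound to
#' their points throughout.
#'
#' @param source,template `voltage_map`s (or N x 3 matrices) preprocessed to
#'   the same point count.
#' @param weights An `encoder_weights` object.
#' @param max_iter Maximum applied updates (default 20).
#' @param tol Convergence tolerance on the twist norm (default 1e-7).
#' @param step Jacobian finite-difference step (default 0.01).
#' @param max_step Trust-region bound on the twist norm per iteration
#'   (default `Inf`, the plain Gauss-Newton step). A finite bound keeps the
#'   iterates from wandering when source and template are different shapes
#'   and the feature residual can never vanish.
#' @param keep_internals Keep the terminal forward cache and pseudoinverse
#'   (used by registration training)?
#' @return An object of class `registration_result`: `estimate` (4x4 rigid
#'   transform mapping source coordinates onto the template), `aligned`
#'   (the transformed source), `iterations_run`, `residual_trace` (feature
#'   residual norm, length `iterations_run + 1` including the initial
#'   residual), `converged`, and `rank_deficient` (Jacobian flag).
#' @export
lk_register <- function(source, template, weights, max_iter = 20L,
                        tol = 1e-7, step = 0.01, max_step = Inf,
                        keep_internals = FALSE) {
  src_pts <- as_points(source)
  tpl_pts <- as_points(template)
  if (nrow(src_pts) != nrow(tpl_pts)) {
    stop("source and template must have the same point count", call. = FALSE)
  }
  phi_t <- encode(tpl_pts, weights)
  J <- compute_jacobian(tpl_pts, weights, step = step)
  pv <- pinv(J)
  Jp <- pv$pinv

  G <- diag(4)
  cur <- src_pts
  fw <- encoder_forward(cur, weights)
  trace <- sqrt(sum((fw$phi - phi_t)^2))
  iterations <- 0L
  converged <- FALSE
  xi <- as.numeric(Jp %*% (fw$phi - phi_t))
  repeat {
    if (!all(is.finite(xi))) break
    if (sqrt(sum(xi^2)) < tol) {
      converged <- TRUE
      break
    }
    if (iterations >= max_iter) break
    nx <- sqrt(sum(xi^2))
    if (nx > max_step) xi <- xi * (max_step / nx)
    dG <- se3_exp(xi)
    G <- dG %*% G
    cur <- apply_transform(dG, cur)
    fw <- encoder_forward(cur, weights)
    trace <- c(trace, sqrt(sum((fw$phi - phi_t)^2)))
    iterations <- iterations + 1L
    xi <- as.numeric(Jp %*% (fw$phi - phi_t))
  }

  aligned <- source
  if (inherits(source, "voltage_map")) {
    aligned$points <- cur
    colnames(aligned$points) <- colnames(source$points)
  } else {
    aligned <- cur
  }
  res <- structure(
    list(estimate = G, aligned = aligned, iterations_run = iterations,
         residual_trace = trace, converged = converged,
         rank_deficient = pv$rank_deficient),
    class = "registration_result"
  )
  if (keep_internals) {
    res$internals <- list(phi_t = phi_t, Jp = Jp, fw = fw, xi = xi,
                          points = cur)
  }
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %d iteration(s), %s; residual %.4g -> %.4g\n",
              x$iterations_run,
              if (x$converged) "converged" else "max iterations",
              x$residual_trace[1], x$residual_trace[length(x$residual_trace)]))
  invisible(x)
}

#' Train the encoder through the registration task
#'
#' Two modes. `"pretrain"`: each cloud is perturbed by a random rigid
#' transform (rotation uniform in `[0, max_rot_deg]` degrees, translation
#' magnitude uniform in `[0, max_trans]`); the registration is run and the
#' recovery loss `registration_loss(estimate, ground_truth)` is reduced by
#' gradient steps on the encoder, with exact reverse-mode gradients through
#' the whole unrolled iteration (every feature evaluation, the moving
#' coordinates, the composed exponential maps, the template Jacobian and its
#' pseudoinverse). `"finetune"`: no ground truth exists; each leave-one-out round
#' takes one voltage map as the template and the rest as sources, and the
#' terminal feature residual `||phi(G_est . P_S) - phi(P_T)||^2` is
#' minimised, with an encoder update per template round.
#'
#' @param x For `"pretrain"`: list of N x 3 clouds (or `voltage_map`s). For
#'   `"finetune"`: list of at least two preprocessed `voltage_map`s.
#' @param weights Starting `encoder_weights`.
#' @param mode `"pretrain"` or `"finetune"`.
#' @param epochs Training epochs (0 returns `weights` unchanged).
#' @param seed Integer seed.
#' @param lr Adam learning rate.
#' @param max_iter Registration iterations during training (default 10;
#'   evaluation uses the full 20).
#' @param step Jacobian finite-difference step.
#' @param max_rot_deg,max_trans Pretraining perturbation ranges
#'   (defaults 45 degrees and 0.8).
#' @param max_step Trust-region bound per iteration for the finetuning
#'   registrations (cross-patient; default 0.05).
#' @param verbose Emit per-epoch loss messages?
#' @return Updated `encoder_weights` with attribute `"loss_trace"` (mean
#'   loss per epoch).
#' @export
train_registration <- function(x, weights, mode = c("pretrain", "finetune"),
                               epochs, seed = 1L, lr = 3e-4, max_iter = 10L,
                               step = 0.01, max_rot_deg = 45, max_trans = 0.8,
                               max_step = 0.05, verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "finetune" && length(x) < 2L) {
    stop("finetuning needs at least 2 voltage maps", call. = FALSE)
  }
  if (epochs == 0L) return(weights)
  params <- weights[c("W1", "b1", "W2", "b2", "W3", "b3")]
  opt <- adam_init(params)
  wts <- weights
  loss_trace <- numeric(0)

  set_params <- function() {
    wts[c("W1", "b1", "W2", "b2", "W3", "b3")] <<- params
  }

  for (ep in seq_len(epochs)) {
    ep_losses <- numeric(0)
    if (mode == "pretrain") {
      ord <- with_seed(derive_seed(seed, 41L, ep), sample.int(length(x)))
      for (i in ord) {
        set_params()
        cloud <- as_points(x[[i]])
        pert <- apply_random_rigid(cloud, max_rot_deg, max_trans,
                                   seed = derive_seed(seed, 42L, ep, i))
        G_gt <- rigid_inverse(pert$transform)  # aligns source back onto cloud
        # unrolled registration with exact reverse-mode gradients through
        # every iteration, the moving coordinates, the composed exponential
        # maps, the template Jacobian and its pseudoinverse
        fwd <- lk_forward_unrolled(pert$points, cloud, wts,
                                   n_iter = max_iter, step = step)
        bk <- lk_backward_unrolled(fwd, wts, G_gt)
        ep_losses <- c(ep_losses, bk$loss)
        st <- adam_step(opt, params, bk$grads, lr = lr)
        opt <- st$state
        params <- st$params
      }
    } else {
      n <- length(x)
      for (tpl in seq_len(n)) {
        set_params()
        tpl_map <- x[[tpl]]
        grads <- lapply(params, function(p) p * 0)
        for (src in setdiff(seq_len(n), tpl)) {
          reg <- lk_register(x[[src]], tpl_map, wts, max_iter = max_iter,
                             step = step, max_step = max_step)
          fw_s <- encoder_forward(as_points(reg$aligned), wts)
          fw_t <- encoder_forward(as_points(tpl_map), wts)
          diff <- fw_s$phi - fw_t$phi
          ep_losses <- c(ep_losses, sum(diff^2))
          gs <- encoder_backward(fw_s$cache, wts, 2 * diff)
          gt <- encoder_backward(fw_t$cache, wts, -2 * diff)
          for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + gs[[nm]] + gt[[nm]]
        }
        st <- adam_step(opt, params, grads, lr = lr)
        opt <- st$state
        params <- st$params
      }
    }
    loss_trace <- c(loss_trace, mean(ep_losses))
    if (verbose) {
      message(sprintf("registration %s epoch %d/%d: mean loss %.4f",
                      mode, ep, epochs, mean(ep_losses)))
    }
  }
  set_params()
  attr(wts, "loss_trace") <- loss_trace
  if (mode == "finetune") attr(wts, "rounds_per_epoch") <- length(x)
  wts
}
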