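# Reverse-mode differentiation through the unrolled Lucas-Kanade iteration.
#
# The registration forward pass is a chain
#     phi_T = f(W; P_T),  J from 6 twist perturbations of P_T,  Jp = pinv(J),
#     for k = 0..n-1:  phi_k = f(W; P_k),  xi_k = Jp (phi_k - phi_T),
#                      P_{k+1} = exp(xi_k) P_k,
#     G = exp(xi_{n-1}) ... exp(xi_0),   L = || G^-1 G_gt - I ||_F.
# Training needs dL/dW with the gradient flowing through every iteration's
# feature evaluation, the moving point coordinates, the composed exponential
# maps and (optionally) the pseudoinverse of the template Jacobian. All of
# that is hand-rolled below; the only numerical shortcut is a central finite
# difference for the 6 partials of each 4x4 exponential, which are cheap and
# accurate.

# unrolled forward pass retaining every intermediate needed by the backward
lk_forward_unrolled <- function(source_pts, template_pts, weights,
                                n_iter = 5L, step = 0.01) {
  fw_t <- encoder_forward(template_pts, weights)
  phi_t <- fw_t$phi
  # template Jacobian from negative twist perturbations, caches kept
  pert_caches <- vector("list", 6L)
  J <- matrix(0, length(phi_t), 6L)
  pert_pts <- vector("list", 6L)
  for (i in 1:6) {
    xi <- rep(0, 6)
    xi[i] <- -step
    pp <- apply_transform(se3_exp(xi), template_pts)
    fw_p <- encoder_forward(pp, weights)
    J[, i] <- (fw_p$phi - phi_t) / step
    pert_caches[[i]] <- fw_p
    pert_pts[[i]] <- pp
  }
  pv <- pinv(J)
  Jp <- pv$pinv

  Ps <- vector("list", n_iter + 1L)
  fws <- vector("list", n_iter)
  xis <- vector("list", n_iter)
  Es <- vector("list", n_iter)
  Ps[[1L]] <- source_pts
  G <- diag(4)
  for (k in seq_len(n_iter)) {
    fws[[k]] <- encoder_forward(Ps[[k]], weights)
    xis[[k]] <- as.numeric(Jp %*% (fws[[k]]$phi - phi_t))
    Es[[k]] <- se3_exp(xis[[k]])
    Ps[[k + 1L]] <- apply_transform(Es[[k]], Ps[[k]])
    G <- Es[[k]] %*% G
  }
  list(G = G, Ps = Ps, fws = fws, xis = xis, Es = Es,
       fw_t = fw_t, phi_t = phi_t, J = J, Jp = Jp,
       pert_caches = pert_caches, step = step)
}

# 6 partials of se3_exp at xi (central differences), optionally applied to a
# point matrix: returns list of 4x4 (or N x 3) sensitivities
exp_partials <- function(xi, h = 1e-6) {
  lapply(1:6, function(i) {
    e <- rep(0, 6)
    e[i] <- h
    (se3_exp(xi + e) - se3_exp(xi - e)) / (2 * h)
  })
}

# dL/dG for L = ||G^-1 G_gt - I||_F (zero gradient at exact recovery)
recovery_loss_grad_G <- function(G, G_gt) {
  K <- rigid_inverse(G)
  M <- K %*% G_gt - diag(4)
  L <- sqrt(sum(M^2))
  if (L < 1e-9) return(list(loss = L, dG = matrix(0, 4, 4)))
  list(loss = L, dG = -t(K) %*% (M / L) %*% t(K %*% G_gt))
}

# full reverse pass: returns encoder weight gradients
lk_backward_unrolled <- function(fwd, weights, G_gt,
                                 detach_jacobian = FALSE) {
  n_iter <- length(fwd$xis)
  lg <- recovery_loss_grad_G(fwd$G, G_gt)
  dG <- lg$dG

  zero_like <- function(p) p * 0
  grads <- lapply(weights[c("W1", "b1", "W2", "b2", "W3", "b3")], zero_like)
  acc <- function(g) {
    for (nm in names(grads)) grads[[nm]] <<- grads[[nm]] + g[[nm]]
  }

  # prefix/suffix products for dL/dE_k = suffix^T dG prefix^T
  prefix <- vector("list", n_iter)  # E_{k-1} ... E_0
  cur <- diag(4)
  for (k in seq_len(n_iter)) {
    prefix[[k]] <- cur
    cur <- fwd$Es[[k]] %*% cur
  }
  suffix <- vector("list", n_iter)  # E_{n-1} ... E_{k+1}
  cur <- diag(4)
  for (k in rev(seq_len(n_iter))) {
    suffix[[k]] <- cur
    cur <- cur %*% fwd$Es[[k]]
  }

  dP_next <- matrix(0, nrow(fwd$Ps[[1L]]), 3L)  # adjoint of P_{k+1}
  dphi_t_total <- rep(0, length(fwd$phi_t))
  dJp <- matrix(0, nrow(fwd$Jp), ncol(fwd$Jp))

  for (k in rev(seq_len(n_iter))) {
    xi <- fwd$xis[[k]]
    Pk <- fwd$Ps[[k]]
    dE <- exp_partials(xi)
    # xi adjoint via the composed-estimate path
    dE_k <- t(suffix[[k]]) %*% dG %*% t(prefix[[k]])
    a <- vapply(dE, function(D) sum(D * dE_k), numeric(1))
    # xi adjoint via the moved points P_{k+1} = E_k(xi) P_k
    if (any(dP_next != 0)) {
      a <- a + vapply(dE, function(D) {
        sum(dP_next * (Pk %*% t(D[1:3, 1:3]) +
                         matrix(D[1:3, 4], nrow(Pk), 3L, byrow = TRUE)))
      }, numeric(1))
    }
    # through xi_k = Jp (phi_k - phi_t)
    r_k <- fwd$fws[[k]]$phi - fwd$phi_t
    dphi_k <- as.numeric(crossprod(fwd$Jp, a))
    dphi_t_total <- dphi_t_total - dphi_k
    if (!detach_jacobian) dJp <- dJp + outer(a, r_k)
    # encoder at P_k: weight grads and input grad
    gk <- encoder_backward(fwd$fws[[k]]$cache, weights, dphi_k,
                           input_grad = TRUE)
    dP_k <- gk$points
    gk$points <- NULL
    acc(gk)
    # P_k also feeds P_{k+1} through the rigid map
    dP_k <- dP_k + dP_next %*% fwd$Es[[k]][1:3, 1:3]
    dP_next <- dP_k
  }
  # note: dP_next now holds dL/d(source points); sources are data, dropped

  if (!detach_jacobian) {
    # through Jp = pinv(J), J full column rank:
    #   dL/dJ = -Jp^T Xi Jp^T + (I - J Jp) Xi^T (J^T J)^-1,  Xi = dL/dJp
    J <- fwd$J
    Jp <- fwd$Jp
    JtJ_inv <- solve(crossprod(J))
    term1 <- -t(Jp) %*% dJp %*% t(Jp)
    XiT <- t(dJp)
    term2 <- (XiT - J %*% (Jp %*% XiT)) %*% JtJ_inv
    dJ <- term1 + term2
    # J[, i] = (phi(A_i P_T) - phi_T) / step
    for (i in 1:6) {
      gp <- encoder_backward(fwd$pert_caches[[i]]$cache, weights,
                             dJ[, i] / fwd$step)
      acc(gp)
      dphi_t_total <- dphi_t_total - dJ[, i] / fwd$step
    }
  }
  # template feature used in every residual (and every Jacobian column)
  gt <- encoder_backward(fwd$fw_t$cache, weights, dphi_t_total)
  acc(gt)

  list(grads = grads, loss = lg$loss)
}
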