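#' Refresh the CF prediction targets from the current network support
#'
#' The collaborative-filtering term predicts the union of prior-supported
#' edges and edges currently retained by the sparse expression model:
#' `Theta_ij = ||S_ij||_0 + (1 - ||S_ij||_0) B_ij`. Its per-pair penalty
#' switches to the confirmed-edge weight on the retained support:
#' `Omega_ij = Cbar_ij` where `S_ij != 0`, else `C_ij`.
#'
#' @param S Numeric n-by-m network matrix.
#' @param pen A `grncf_penalties`.
#' @return List with binary matrix `Theta` and positive matrix `Omega`.
#' @export
update_cf_targets <- function(S, pen) {
  supp <- (S != 0) * 1
  Theta <- supp + (1 - supp) * pen$B
  Omega <- ifelse(supp == 1, pen$Cbar, pen$C)
  list(Theta = Theta, Omega = Omega)
}

#' Weighted collaborative-filtering objective
#'
#' `sum_ij Omega_ij (Theta_ij - x_i' y_j)^2`, the confidence-weighted square
#' loss of the latent factorization against the current prediction targets.
#'
#' @param X n-by-h gene feature matrix.
#' @param Y m-by-h TF feature matrix.
#' @param Theta Binary n-by-m target matrix.
#' @param Omega Positive n-by-m weight matrix.
#' @return Scalar objective value.
#' @export
cf_objective <- function(X, Y, Theta, Omega) {
  sum(Omega * (Theta - X %*% t(Y))^2)
}

#' Minimize a quadratic over the unit ball
#'
#' Solves `min_v v' phi v - varphi . v  s.t. ||v||^2 <= 1` for symmetric
#' positive-semidefinite `phi`. If the unconstrained stationary point
#' `phi^{-1} varphi / 2` is feasible it is returned; otherwise the KKT
#' boundary solution `(phi + nu I)^{-1} varphi / 2` is found by monotone
#' scalar root-finding of `||v(nu)|| = 1` in the eigenbasis of `phi`.
#'
#' @param phi Symmetric PSD h-by-h matrix.
#' @param varphi Numeric h-vector (the linear term's coefficient).
#' @return The minimizing h-vector, with norm at most 1 + 1e-8.
#' @export
solve_unit_ball_qp <- function(phi, varphi) {
  if (any(!is.finite(phi)) || any(!is.finite(varphi))) {
    stop("non-finite inputs to unit-ball QP")
  }
  varphi <- as.numeric(varphi)
  h <- length(varphi)
  if (all(varphi == 0)) return(numeric(h))
  es <- eigen((phi + t(phi)) / 2, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  w <- drop(crossprod(es$vectors, varphi)) / 2
  pos <- lam > max(lam[1L], 1e-300) * 1e-12
  # interior candidate exists when varphi lies in the range of phi
  if (all(pos | abs(w) <= max(abs(w)) * 1e-12)) {
    v0 <- ifelse(pos, w / lam, 0)
    if (sum(v0^2) <= 1 + 1e-12) {
      v <- drop(es$vectors %*% v0)
      return(clip_unit(v))
    }
  }
  norm2 <- function(nu) sum((w / (lam + nu))^2)
  hi <- sqrt(sum(w^2))
  lo <- hi * 1e-14
  it <- 0L
  while (norm2(lo) < 1 && it < 60L) { lo <- lo / 4; it <- it + 1L }
  if (norm2(lo) < 1) {  # numerically interior; accept the near-feasible point
    return(clip_unit(drop(es$vectors %*% (w / (lam + lo)))))
  }
  root <- stats::uniroot(function(nu) norm2(nu) - 1, c(lo, hi),
                         tol = 1e-14)$root
  v <- drop(es$vectors %*% (w / (lam + root)))
  clip_unit(v)
}

clip_unit <- function(v, eps = 1e-8) {
  nv <- sqrt(sum(v^2))
  if (nv > 1 + eps) v <- v / nv
  v
}

# lambda * Omega: the quadratic weight each (i, j) pair carries in the CF
# term, with the confirmed-edge penalty on the current support of S.
cf_quad_weights <- function(S, pen, lambda) {
  supp <- (S != 0) * 1
  lambda * (pen$C + (pen$Cbar - pen$C) * supp)
}

#' Proximal update of the gene feature matrix X
#'
#' Each gene row solves a unit-ball-constrained quadratic built from the
#' current targets: `phi = (mu_x/2) I + Y' diag(Abar_i) Y` and
#' `varphi = 2 (Abar_i * Theta_i) Y + mu_x x_i`, where `Abar_i` is the
#' lambda-scaled CF weight row and `mu_x` the per-row prox constant
#' `max(2 ||Y' diag(Abar_i) Y||_F, mu_min)`. Rows are independent.
#'
#' @param X,Y Current factor matrices (n-by-h, m-by-h).
#' @param S Current network (n-by-m), defining support-dependent weights.
#' @param pen A `grncf_penalties`.
#' @param lambda CF/NCA balance (>= 0).
#' @param mu_min Lower guard for the prox constant.
#' @return Updated n-by-h matrix X with all row norms <= 1 + 1e-8.
#' @export
update_X <- function(X, Y, S, pen, lambda, mu_min = 1e-6) {
  targ <- update_cf_targets(S, pen)
  Abar <- cf_quad_weights(S, pen, lambda)
  Xn <- X
  for (i in seq_len(nrow(X))) {
    ai <- Abar[i, ]
    M <- crossprod(Y, ai * Y)
    mu <- max(2 * sqrt(sum(M^2)), mu_min)
    phi <- M + diag(mu / 2, ncol(Y))
    varphi <- 2 * drop(crossprod(Y, ai * targ$Theta[i, ])) + mu * X[i, ]
    Xn[i, ] <- solve_unit_ball_qp(phi, varphi)
  }
  Xn
}

#' Proximal update of the TF feature matrix Y
#'
#' Column-wise analogue of [update_X()]: each TF row `y_j` solves the
#' unit-ball quadratic with `phi = X' diag(Abar_.j) X + (mu_y/2) I` and
#' `varphi = 2 (Abar_.j * Theta_.j) X + mu_y y_j`.
#'
#' @inheritParams update_X
#' @return Updated m-by-h matrix Y with all row norms <= 1 + 1e-8.
#' @export
update_Y <- function(X, Y, S, pen, lambda, mu_min = 1e-6) {
  targ <- update_cf_targets(S, pen)
  Abar <- cf_quad_weights(S, pen, lambda)
  Yn <- Y
  for (j in seq_len(nrow(Y))) {
    aj <- Abar[, j]
    M <- crossprod(X, aj * X)
    mu <- max(2 * sqrt(sum(M^2)), mu_min)
    phi <- M + diag(mu / 2, ncol(X))
    varphi <- 2 * drop(crossprod(X, aj * targ$Theta[, j])) + mu * Y[j, ]
    Yn[j, ] <- solve_unit_ball_qp(phi, varphi)
  }
  Yn
}
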