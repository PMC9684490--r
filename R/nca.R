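#' Smooth part of the sparse NCA objective
#'
#' `H(S, A) = ||E - S A||_F^2 + lambda_A ||A||_F^2 + lambda_S ||S||_F^2`:
#' the squared reconstruction error of expression by the weighted network
#' times the hidden TF activities, plus ridge terms.
#'
#' @param S n-by-m network matrix.
#' @param A m-by-l TF activity matrix.
#' @param E n-by-l expression matrix.
#' @param lambda_A,lambda_S Ridge penalties (>= 0).
#' @return Scalar, finite and >= 0.
#' @export
nca_objective <- function(S, A, E, lambda_A = 0, lambda_S = 0) {
  sum((E - S %*% A)^2) + lambda_A * sum(A^2) + lambda_S * sum(S^2)
}

#' Closed-form proximal update of TF activities
#'
#' Minimizes `H(S, .) + (mu_A/2) ||A - A_prev||_F^2` exactly:
#' `A = (S'S + ((2 lambda_A + mu_A)/2) I)^{-1} (S'E + (mu_A/2) A_prev)`
#' with step constant `mu_A = max(||S'S + lambda_A I||_F, mu_min)`. The
#' system matrix is positive definite because `mu_A > 0`.
#'
#' @param S n-by-m network matrix.
#' @param A_prev m-by-l previous activity matrix (the prox anchor).
#' @param E n-by-l expression matrix.
#' @param lambda_A Ridge penalty on A.
#' @param mu_min Lower guard for `mu_A` (keeps the step defined at S = 0).
#' @return The updated m-by-l activity matrix.
#' @export
update_A <- function(S, A_prev, E, lambda_A = 0, mu_min = 1e-6) {
  m <- ncol(S)
  StS <- crossprod(S)
  mu_A <- max(frob(StS + diag(lambda_A, m)), mu_min)
  lhs <- StS + diag((2 * lambda_A + mu_A) / 2, m)
  rhs <- crossprod(S, E) + (mu_A / 2) * A_prev
  A <- tryCatch(solve(lhs, rhs),
                error = function(e) stop("singular activity update system: ",
                                         conditionMessage(e)))
  A
}

frob <- function(M) sqrt(sum(M^2))

#' Gradient step and threshold radii for the network update
#'
#' Builds the workspace of the prox-linearized S step: the step constant
#' `mu_S = max(||A A' + lambda_S I||_F, mu_min)`, the gradient-step point
#' `U = S - (1/mu_S)(2 (S A - E) A' + 2 lambda_S S)`, and the per-pair
#' hard-threshold radii
#' `c_ij = sqrt((2/mu_S) * (lambda * [Cbar_ij (1 - B_ij)(1 + 2(B_ij - x_i'y_j))
#'  + (Cbar_ij - C_ij)(B_ij - x_i'y_j)^2] + eta_ij))`,
#' the l0 price an edge must pay to stay nonzero. Negative radicands (a
#' negative price, where removing the edge cannot pay) clamp to 0.
#'
#' @param S Current n-by-m network.
#' @param A m-by-l activities (already updated this iteration).
#' @param E n-by-l expression.
#' @param pen A `grncf_penalties`.
#' @param X,Y Current latent factors.
#' @param lambda CF/NCA balance.
#' @param eta Scalar or n-by-m matrix of l0 penalties.
#' @param lambda_S Ridge penalty on S.
#' @param mu_min Lower guard for `mu_S`.
#' @return List with `U`, `cmat`, `mu_S`.
#' @export
compute_S_threshold_inputs <- function(S, A, E, pen, X, Y, lambda, eta,
                                       lambda_S = 0, mu_min = 1e-6) {
  m <- nrow(A)
  mu_S <- max(frob(A %*% t(A) + diag(lambda_S, m)), mu_min)
  grad <- 2 * ((S %*% A - E) %*% t(A)) + 2 * lambda_S * S
  U <- S - grad / mu_S
  G <- X %*% t(Y)
  if (length(eta) == 1L) eta <- matrix(eta, nrow(S), ncol(S))
  bracket <- pen$Cbar * (1 - pen$B) * (1 + 2 * (pen$B - G)) +
    (pen$Cbar - pen$C) * (pen$B - G)^2
  rad <- (2 / mu_S) * (lambda * bracket + eta)
  cmat <- sqrt(pmax(rad, 0))
  list(U = U, cmat = cmat, mu_S = mu_S)
}

#' Elementwise hard-threshold update of the network
#'
#' Solves the separable prox problem exactly: for each pair,
#' `S_ij = U_ij` if `|U_ij| > c_ij`, else 0 (the measure-zero tie
#' `|U_ij| = c_ij` resolves to 0 for a deterministic, sparser result).
#'
#' @param ws Workspace from [compute_S_threshold_inputs()].
#' @return The updated n-by-m network matrix.
#' @export
update_S <- function(ws) {
  ifelse(abs(ws$U) > ws$cmat, ws$U, 0)
}
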