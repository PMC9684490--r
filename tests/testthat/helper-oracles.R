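# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's own code paths: naive loops, dense grid
# search, finite differences, and general-purpose numeric optimization.

# Naive double-loop CF objective.
oracle_cf_objective <- function(X, Y, Theta, Omega) {
  acc <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(Y))) {
      acc <- acc + Omega[i, j] * (Theta[i, j] - sum(X[i, ] * Y[j, ]))^2
    }
  }
  acc
}

# Elementwise NCA objective.
oracle_nca_objective <- function(S, A, E, lambda_A, lambda_S) {
  R <- E - S %*% A
  acc <- 0
  for (v in R) acc <- acc + v^2
  for (v in A) acc <- acc + lambda_A * v^2
  for (v in S) acc <- acc + lambda_S * v^2
  acc
}

# Dense polar grid search over the closed unit disk (h = 2 only).
# Returns the best grid point and its objective value.
oracle_disk_min <- function(phi, varphi, n_r = 400L, n_a = 1600L) {
  r <- seq(0, 1, length.out = n_r)
  a <- seq(0, 2 * pi, length.out = n_a)
  g <- expand.grid(r = r, a = a)
  v1 <- g$r * cos(g$a); v2 <- g$r * sin(g$a)
  obj <- phi[1, 1] * v1^2 + 2 * phi[1, 2] * v1 * v2 + phi[2, 2] * v2^2 -
    varphi[1] * v1 - varphi[2] * v2
  k <- which.min(obj)
  list(v = c(v1[k], v2[k]), value = obj[k])
}

qp_objective <- function(v, phi, varphi) {
  drop(t(v) %*% phi %*% v - sum(varphi * v))
}

# Numeric minimizer of the activity prox objective
# ||E - S A||_F^2 + lambda_A ||A||_F^2 + (mu/2) ||A - A_prev||_F^2
# by BFGS from the anchor point, with mu recomputed independently.
oracle_prox_A <- function(S, A_prev, E, lambda_A, mu_min = 1e-6) {
  m <- ncol(S); l <- ncol(E)
  mu <- max(sqrt(sum((crossprod(S) + diag(lambda_A, m))^2)), mu_min)
  fn <- function(a) {
    A <- matrix(a, m, l)
    sum((E - S %*% A)^2) + lambda_A * sum(A^2) + (mu / 2) * sum((A - A_prev)^2)
  }
  gr <- function(a) {
    A <- matrix(a, m, l)
    G <- -2 * crossprod(S, E - S %*% A) + 2 * lambda_A * A + mu * (A - A_prev)
    as.numeric(G)
  }
  opt <- stats::optim(as.numeric(A_prev), fn, gr, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  matrix(opt$par, m, l)
}

# Exact separable prox of the hard-threshold problem by two-candidate
# enumeration: per element, compare (0 - U)^2 + 0 against c^2 (keeping U).
oracle_threshold <- function(U, cmat) {
  out <- U
  for (i in seq_along(U)) {
    keep_cost <- cmat[i]^2   # (U - U)^2 + c^2 * 1
    drop_cost <- U[i]^2      # (0 - U)^2 + c^2 * 0
    out[i] <- if (keep_cost < drop_cost) U[i] else 0
  }
  out
}

# Central finite differences of H(S, A) = ||E - SA||^2 + lambda_S ||S||^2
# with respect to S.
oracle_grad_S <- function(S, A, E, lambda_S, h = 1e-6) {
  G <- S * 0
  for (k in seq_along(S)) {
    Sp <- S; Sm <- S
    Sp[k] <- Sp[k] + h; Sm[k] <- Sm[k] - h
    G[k] <- (sum((E - Sp %*% A)^2) + lambda_S * sum(Sp^2) -
             sum((E - Sm %*% A)^2) - lambda_S * sum(Sm^2)) / (2 * h)
  }
  G
}

# Naive per-entity average-rank recomputation from an edge ranking.
oracle_gene_ars <- function(prediction, gold_mat) {
  genes <- rownames(gold_mat); tfs <- colnames(gold_mat)
  m <- length(tfs)
  per <- c()
  for (g in genes) {
    gtfs <- tfs[gold_mat[g, ] == 1]
    if (length(gtfs) == 0L) next
    sel <- prediction$gene == g
    sc <- prediction$score[sel]; names(sc) <- prediction$tf[sel]
    rs <- sapply(gtfs, function(tf) {
      if (!tf %in% names(sc)) return(100)
      pos <- rank(-sc, ties.method = "average")[[tf]]
      100 * (pos - 1) / (m - 1)
    })
    per <- c(per, mean(rs))
  }
  mean(per)
}

# Small random PSD matrix.
rand_psd <- function(h, ridge = 0.1) {
  M <- matrix(stats::rnorm(h * h), h, h)
  crossprod(M) / h + diag(ridge, h)
}

# Small random penalties object on an n x m index.
rand_penalties <- function(n, m, a = 60) {
  genes <- sprintf("g%02d", seq_len(n)); tfs <- sprintf("t%02d", seq_len(m))
  Psum <- matrix(stats::runif(n * m) * stats::rbinom(n * m, 1, 0.4), n, m,
                 dimnames = list(genes, tfs))
  structure(list(C = 1 + a * Psum, Cbar = 1 + a * pmax(Psum, 0.5),
                 B = (Psum != 0) * 1, genes = genes, tfs = tfs),
            class = "grncf_penalties")
}
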