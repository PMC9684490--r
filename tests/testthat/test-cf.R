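test_that("CF targets combine network support with prior support", {
  pen <- structure(list(C = matrix(3, 1, 1), Cbar = matrix(7, 1, 1),
                        B = matrix(0, 1, 1)), class = "grncf_penalties")
  # S != 0, B = 0: predicted with confirmed-edge penalty
  t1 <- update_cf_targets(matrix(2, 1, 1), pen)
  expect_equal(t1$Theta[1, 1], 1)
  expect_equal(t1$Omega[1, 1], 7)
  # S = 0, B = 1: predicted with prior penalty
  pen$B[1, 1] <- 1
  t2 <- update_cf_targets(matrix(0, 1, 1), pen)
  expect_equal(t2$Theta[1, 1], 1)
  expect_equal(t2$Omega[1, 1], 3)
  # S = 0, B = 0: not predicted
  pen$B[1, 1] <- 0
  t3 <- update_cf_targets(matrix(0, 1, 1), pen)
  expect_equal(t3$Theta[1, 1], 0)
  expect_equal(t3$Omega[1, 1], 3)
})

test_that("cf_objective equals the naive double-loop oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(2:20, 1); m <- sample(2:20, 1); h <- sample(1:4, 1)
    X <- matrix(rnorm(n * h), n, h); Y <- matrix(rnorm(m * h), m, h)
    Theta <- matrix(rbinom(n * m, 1, 0.5), n, m)
    Omega <- matrix(runif(n * m, 1, 60), n, m)
    expect_equal(cf_objective(X, Y, Theta, Omega),
                 oracle_cf_objective(X, Y, Theta, Omega),
                 tolerance = 1e-10)
  }
  # perfect fit: zero objective
  X <- matrix(c(1, 0), 1, 2); Y <- matrix(c(1, 0), 1, 2)
  expect_equal(cf_objective(X, Y, matrix(1, 1, 1), matrix(10, 1, 1)), 0)
  # zero factors: sum of Omega * Theta^2
  X0 <- matrix(0, 2, 2); Y0 <- matrix(0, 3, 2)
  Theta <- matrix(rbinom(6, 1, 0.5), 2, 3); Omega <- matrix(runif(6, 1, 5), 2, 3)
  expect_equal(cf_objective(X0, Y0, Theta, Omega), sum(Omega * Theta^2))
})

test_that("unit-ball QP returns boundary and interior solutions", {
  v <- solve_unit_ball_qp(diag(2), c(4, 0))
  expect_equal(v, c(1, 0), tolerance = 1e-7)     # boundary: (2,0) infeasible
  v <- solve_unit_ball_qp(diag(2), c(1, 0))
  expect_equal(v, c(0.5, 0), tolerance = 1e-8)   # interior stationary point
  v <- solve_unit_ball_qp(rand_psd(3), c(0, 0, 0))
  expect_equal(v, c(0, 0, 0))                    # zero linear term
  expect_error(solve_unit_ball_qp(diag(2), c(NA, 1)), "non-finite")
})

test_that("unit-ball QP matches dense grid search on random instances", {
  set.seed(17)
  for (rep in 1:20) {
    phi <- rand_psd(2, ridge = runif(1, 0.01, 1))
    varphi <- rnorm(2, sd = 3)
    v <- solve_unit_ball_qp(phi, varphi)
    expect_lte(sum(v^2), 1 + 1e-8)
    g <- oracle_disk_min(phi, varphi)
    expect_lte(qp_objective(v, phi, varphi), g$value + 1e-3)
  }
})

test_that("factor updates are fixed points when the CF term is off", {
  set.seed(31)
  pen <- rand_penalties(4, 3)
  X <- matrix(runif(8, -0.5, 0.5), 4, 2)
  Y <- matrix(runif(6, -0.5, 0.5), 3, 2)
  S <- matrix(rbinom(12, 1, 0.5) * rnorm(12), 4, 3)
  expect_equal(update_X(X, Y, S, pen, lambda = 0), X, tolerance = 1e-9)
  expect_equal(update_Y(X, Y, S, pen, lambda = 0), Y, tolerance = 1e-9)
})

test_that("row updates solve the per-row prox problem (grid oracle)", {
  set.seed(41)
  pen <- rand_penalties(2, 2)
  lambda <- 0.8
  S <- matrix(c(1.2, 0, 0, -0.7), 2, 2)
  X <- matrix(runif(4, -0.5, 0.5), 2, 2)
  Y <- matrix(runif(4, -0.7, 0.7), 2, 2)
  targ <- update_cf_targets(S, pen)
  Abar <- lambda * targ$Omega
  Xn <- update_X(X, Y, S, pen, lambda)
  for (i in 1:2) {
    M <- crossprod(Y, Abar[i, ] * Y)
    mu <- max(2 * sqrt(sum(M^2)), 1e-6)
    # oracle: minimize the lambda-weighted CF row loss plus the prox tether
    row_obj <- function(v1, v2) {
      G <- cbind(v1, v2) %*% t(Y)
      rowSums(sweep((sweep(-G, 2, targ$Theta[i, ], "+"))^2, 2, Abar[i, ], "*")) +
        (mu / 2) * ((v1 - X[i, 1])^2 + (v2 - X[i, 2])^2)
    }
    r <- seq(0, 1, length.out = 300); a <- seq(0, 2 * pi, length.out = 1200)
    gg <- expand.grid(r = r, a = a)
    vals <- row_obj(gg$r * cos(gg$a), gg$r * sin(gg$a))
    expect_lte(row_obj(Xn[i, 1], Xn[i, 2])[1], min(vals) + 1e-3)
    expect_lte(sum(Xn[i, ]^2), 1 + 1e-8)
  }
})

test_that("factor updates never increase the CF objective", {
  set.seed(53)
  for (rep in 1:5) {
    n <- 6; m <- 5; h <- 3
    pen <- rand_penalties(n, m)
    S <- matrix(rbinom(n * m, 1, 0.4) * rnorm(n * m), n, m)
    X <- matrix(runif(n * h, -0.5, 0.5), n, h)
    Y <- matrix(runif(m * h, -0.5, 0.5), m, h)
    targ <- update_cf_targets(S, pen)
    lambda <- 1.5
    f0 <- cf_objective(X, Y, targ$Theta, targ$Omega)
    X2 <- update_X(X, Y, S, pen, lambda)
    f1 <- cf_objective(X2, Y, targ$Theta, targ$Omega)
    expect_lte(f1, f0 + 1e-8 * abs(f0))
    Y2 <- update_Y(X2, Y, S, pen, lambda)
    f2 <- cf_objective(X2, Y2, targ$Theta, targ$Omega)
    expect_lte(f2, f1 + 1e-8 * abs(f1))
    expect_true(all(rowSums(X2^2) <= 1 + 1e-8))
    expect_true(all(rowSums(Y2^2) <= 1 + 1e-8))
  }
})

test_that("CF-only fit recovers masked edges of a modular network", {
  # block-structured observation matrix: three gene modules, each driven by
  # its own TF group; 20% of true edges are masked before fitting
  set.seed(61)
  n <- 30; m <- 9; h <- 3
  genes <- sprintf("g%02d", 1:n); tfs <- sprintf("t%d", 1:m)
  Btrue <- matrix(0, n, m, dimnames = list(genes, tfs))
  for (blk in 0:2) Btrue[blk * 10 + (1:10), blk * 3 + (1:3)] <- 1
  true_idx <- which(Btrue == 1)
  masked <- sample(true_idx, round(0.2 * length(true_idx)))
  Bobs <- Btrue; Bobs[masked] <- 0
  pen <- structure(list(C = 1 + 60 * Bobs, Cbar = 1 + 60 * pmax(Bobs, 0.5),
                        B = Bobs, genes = genes, tfs = tfs),
                   class = "grncf_penalties")
  X <- matrix(runif(n * h, -1 / sqrt(h), 1 / sqrt(h)), n, h)
  Y <- matrix(runif(m * h, -1 / sqrt(h), 1 / sqrt(h)), m, h)
  S0 <- matrix(0, n, m)
  for (sweep in 1:25) {
    X <- update_X(X, Y, S0, pen, lambda = 1)
    Y <- update_Y(X, Y, S0, pen, lambda = 1)
  }
  G <- X %*% t(Y)
  never <- which(Btrue == 0)
  expect_gt(mean(G[masked]), mean(G[never]))
})
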