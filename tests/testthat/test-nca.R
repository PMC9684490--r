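test_that("nca_objective matches elementwise recomputation", {
  set.seed(3)
  E <- matrix(rnorm(12), 4, 3)
  expect_equal(nca_objective(matrix(0, 4, 2), matrix(0, 2, 3), E), sum(E^2))
  S <- matrix(rnorm(8), 4, 2); A <- matrix(rnorm(6), 2, 3)
  expect_equal(nca_objective(S, A, S %*% A), 0)
  expect_equal(nca_objective(S, A, E, 0.3, 0.7),
               oracle_nca_objective(S, A, E, 0.3, 0.7), tolerance = 1e-12)
})

test_that("activity update reproduces the scalar worked example", {
  # n = m = l = 1, E = 1, S = 1, lambda_A = 0, A_prev = 0:
  # mu_A = 1, A = (1 + 1/2)^-1 (1 + 0) = 2/3
  A <- update_A(S = matrix(1), A_prev = matrix(0), E = matrix(1), lambda_A = 0)
  expect_equal(A[1, 1], 2 / 3)
})

test_that("activity update matches a numeric prox minimizer", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 3; m <- 2; l <- 4
    S <- matrix(rnorm(n * m), n, m)
    E <- matrix(rnorm(n * l), n, l)
    A_prev <- matrix(rnorm(m * l), m, l)
    lambda_A <- runif(1, 0, 0.5)
    A <- update_A(S, A_prev, E, lambda_A)
    expect_equal(A, oracle_prox_A(S, A_prev, E, lambda_A), tolerance = 1e-6)
  }
})

test_that("activity update is a local minimum of its prox objective", {
  set.seed(19)
  S <- matrix(rnorm(12), 4, 3); E <- matrix(rnorm(8), 4, 2)
  A_prev <- matrix(rnorm(6), 3, 2)
  lambda_A <- 0.2
  mu <- max(sqrt(sum((crossprod(S) + diag(lambda_A, 3))^2)), 1e-6)
  A <- update_A(S, A_prev, E, lambda_A)
  obj <- function(M) sum((E - S %*% M)^2) + lambda_A * sum(M^2) +
    (mu / 2) * sum((M - A_prev)^2)
  base <- obj(A)
  for (rep in 1:30) {
    D <- matrix(rnorm(6), 3, 2); D <- D / sqrt(sum(D^2))
    expect_gte(obj(A + 1e-4 * D), base - 1e-12)
  }
})

test_that("zero network with no ridge leaves activities at the anchor", {
  A_prev <- matrix(rnorm(6), 2, 3)
  A <- update_A(S = matrix(0, 4, 2), A_prev = A_prev,
                E = matrix(rnorm(12), 4, 3), lambda_A = 0)
  expect_equal(A, A_prev, tolerance = 1e-12)
})

test_that("threshold workspace has zero gradient at an exact fit", {
  set.seed(29)
  S <- matrix(rnorm(12), 4, 3); A <- matrix(rnorm(6), 3, 2)
  pen <- rand_penalties(4, 3)
  X <- matrix(runif(8, -0.5, 0.5), 4, 2); Y <- matrix(runif(6, -0.5, 0.5), 3, 2)
  ws <- compute_S_threshold_inputs(S, A, E = S %*% A, pen, X, Y,
                                   lambda = 1, eta = 0, lambda_S = 0)
  expect_equal(ws$U, S, tolerance = 1e-12)
})

test_that("balanced penalties give prior edges a zero threshold radius", {
  # B = 1, Cbar = C, eta = 0 -> radicand 0 -> c = 0
  pen <- structure(list(C = matrix(61, 1, 1), Cbar = matrix(61, 1, 1),
                        B = matrix(1, 1, 1)), class = "grncf_penalties")
  ws <- compute_S_threshold_inputs(matrix(0.5), matrix(1, 1, 1), matrix(0.7),
                                   pen, matrix(0.3), matrix(0.2),
                                   lambda = 1, eta = 0)
  expect_equal(ws$cmat[1, 1], 0)
})

test_that("negative radicands clamp to zero rather than NaN", {
  pen <- structure(list(C = matrix(61, 1, 1), Cbar = matrix(2, 1, 1),
                        B = matrix(1, 1, 1)), class = "grncf_penalties")
  ws <- compute_S_threshold_inputs(matrix(0.5), matrix(1, 1, 1), matrix(0.7),
                                   pen, matrix(0), matrix(0),
                                   lambda = 1, eta = 0)
  expect_equal(ws$cmat[1, 1], 0)
  expect_false(anyNA(ws$cmat))
})

test_that("network gradient matches central finite differences", {
  set.seed(37)
  S <- matrix(rnorm(12), 4, 3); A <- matrix(rnorm(6), 3, 2)
  E <- matrix(rnorm(8), 4, 2)
  lambda_S <- 0.3
  pen <- rand_penalties(4, 3)
  ws <- compute_S_threshold_inputs(S, A, E, pen, matrix(0, 4, 2),
                                   matrix(0, 3, 2), lambda = 1, eta = 0,
                                   lambda_S = lambda_S)
  grad_impl <- (S - ws$U) * ws$mu_S
  expect_equal(grad_impl, oracle_grad_S(S, A, E, lambda_S), tolerance = 1e-5)
})

test_that("hard threshold follows the three-case rule with tie going to zero", {
  ws <- list(U = matrix(c(2, 0.5, 1, -3), 2, 2),
             cmat = matrix(c(1, 1, 1, 1), 2, 2), mu_S = 1)
  S <- update_S(ws)
  expect_equal(S[1, 1], 2)    # |U| > c: keep U
  expect_equal(S[2, 1], 0)    # |U| < c: drop
  expect_equal(S[1, 2], 0)    # |U| = c: deterministic tie to zero
  expect_equal(S[2, 2], -3)   # sign preserved
})

test_that("threshold update solves the separable prox exactly", {
  set.seed(43)
  for (rep in 1:20) {
    U <- matrix(rnorm(30, sd = 2), 6, 5)
    cmat <- matrix(abs(rnorm(30)), 6, 5)
    got <- update_S(list(U = U, cmat = cmat, mu_S = 1))
    expect_identical(got, oracle_threshold(U, cmat))
  }
})

test_that("support shrinks monotonically as the l0 price rises", {
  set.seed(47)
  S <- matrix(rnorm(40), 8, 5); A <- matrix(rnorm(15), 5, 3)
  E <- matrix(rnorm(24), 8, 3)
  pen <- rand_penalties(8, 5)
  X <- matrix(runif(16, -0.5, 0.5), 8, 2); Y <- matrix(runif(10, -0.5, 0.5), 5, 2)
  prev <- Inf
  for (eta in c(0, 0.5, 2, 10, 50)) {
    ws <- compute_S_threshold_inputs(S, A, E, pen, X, Y, lambda = 1, eta = eta)
    supp <- sum(update_S(ws) != 0)
    expect_lte(supp, prev)
    prev <- supp
  }
})

test_that("with no CF term the radius reduces to the pure sparse-NCA form", {
  set.seed(59)
  S <- matrix(rnorm(12), 4, 3); A <- matrix(rnorm(6), 3, 2)
  E <- matrix(rnorm(8), 4, 2)
  pen <- rand_penalties(4, 3)
  eta <- 3.7
  ws <- compute_S_threshold_inputs(S, A, E, pen, matrix(0, 4, 2),
                                   matrix(0, 3, 2), lambda = 0, eta = eta)
  expect_equal(ws$cmat, matrix(sqrt(2 * eta / ws$mu_S), 4, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
})
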