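# small helper: dataset wrapper around an arbitrary binary matrix
as_dataset <- function(A) {
  dimnames(A) <- list(sprintf("c%02d", seq_len(nrow(A))),
                      sprintf("d%02d", seq_len(ncol(A))))
  structure(list(A = A, circ_ids = rownames(A), disease_ids = colnames(A)),
            class = "circ_dataset")
}

test_that("imc_objective matches its definition", {
  set.seed(1)
  A <- matrix(rbinom(12, 1, 0.5), 3, 4)
  d <- as_dataset(A)
  C <- random_orthonormal(3, 2); D <- random_orthonormal(4, 2)

  # Z = 0: every observed residual is 1
  expect_equal(imc_objective(matrix(0, 2, 2), C, D, d, lambda = 1), 0.5 * sum(A))

  # exact fit, no regularization, full observation
  I3 <- diag(1, 3)
  d3 <- as_dataset(matrix(rbinom(9, 1, 0.5), 3, 3))
  expect_equal(imc_objective(d3$A, I3, I3, d3, lambda = 0,
                             observed = matrix(TRUE, 3, 3)), 0)

  # random instance vs a term-by-term sum
  Z <- matrix(rnorm(4), 2, 2)
  pred <- C %*% Z %*% t(D)
  manual <- sum(svd(Z)$d) * 2
  for (i in 1:3) for (j in 1:4) {
    if (A[i, j] == 1) manual <- manual + 0.5 * (pred[i, j] - 1)^2
  }
  expect_equal(imc_objective(Z, C, D, d, lambda = 2), manual)
  expect_error(imc_objective(Z, C, D[1:2, ], d), "shapes")
})

test_that("imc_gradient passes a finite-difference check", {
  set.seed(2)
  for (rep in 1:3) {
    A <- matrix(rbinom(12, 1, 0.4), 4, 3)
    d <- as_dataset(A)
    C <- random_orthonormal(4, 3); D <- random_orthonormal(3, 2)
    Y <- matrix(rnorm(6), 3, 2)
    G <- imc_gradient(Y, C, D, d)
    dir <- matrix(rnorm(6), 3, 2)
    h <- 1e-6
    f <- function(Z) imc_objective(Z, C, D, d, lambda = 0)
    fd <- (f(Y + h * dir) - f(Y - h * dir)) / (2 * h)
    expect_equal(sum(G * dir), fd, tolerance = 1e-5)
  }
  # empty observed set: zero gradient
  A0 <- matrix(0L, 2, 2)
  expect_equal(imc_gradient(matrix(1, 2, 2), diag(1, 2), diag(1, 2),
                            as_dataset(A0)),
               matrix(0, 2, 2))
})

test_that("svt_prox soft-thresholds the singular values", {
  set.seed(3)
  M <- matrix(rnorm(12), 4, 3)
  expect_equal(svt_prox(M, 0), M)
  expect_equal(svt_prox(M, svd(M)$d[1] + 1), matrix(0, 4, 3))
  expect_equal(svt_prox(diag(c(3, 1)), 2), diag(c(1, 0)))
})

test_that("svt_prox equals the argmin of the nuclear-norm proximal problem", {
  set.seed(4)
  for (rep in 1:20) {
    M <- matrix(rnorm(9), 3, 3)
    t0 <- runif(1, 0.1, 2)
    expect_lt(max(abs(svt_prox(M, t0) - prox_oracle(M, t0))), 1e-4)
  }
})

test_that("solve_imc handles degenerate regularization correctly", {
  set.seed(5)
  A <- matrix(rbinom(20, 1, 0.4), 5, 4)
  d <- as_dataset(A)
  C <- random_orthonormal(5, 3); D <- random_orthonormal(4, 2)

  # lambda beyond the first gradient step kills everything
  big <- svd(imc_gradient(matrix(0, 3, 2), C, D, d))$d[1] + 1
  fit <- solve_imc(C, D, d, lambda = big)
  expect_equal(fit$Z, matrix(0, 3, 2))
  expect_equal(unname(fit$scores), matrix(0, 5, 4))

  # near-unregularized full-observation fit recovers A through identity features
  I5 <- diag(1, 5)
  dimnames(I5) <- NULL
  d5 <- as_dataset(matrix(rbinom(25, 1, 0.5), 5, 5))
  fit5 <- solve_imc(I5, I5, d5, lambda = 1e-6,
                    observed = matrix(TRUE, 5, 5), max_iter = 2000)
  expect_lt(max(abs(fit5$scores - d5$A)), 0.01)
})

test_that("objective trace is non-increasing and the stop rule fires", {
  set.seed(6)
  for (rep in 1:5) {
    A <- matrix(rbinom(30, 1, 0.3), 6, 5)
    if (sum(A) == 0) A[1, 1] <- 1L
    d <- as_dataset(A)
    C <- random_orthonormal(6, 4); D <- random_orthonormal(5, 3)
    fit <- solve_imc(C, D, d, lambda = 1)
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
    expect_true(fit$converged)
    expect_lte(fit$iterations, 500)
    tr <- fit$objective_trace
    n <- length(tr)
    if (n > 1 && tr[n - 1] > 0) {
      expect_lt(1 - tr[n] / tr[n - 1], 1e-5)
    }
  }
})

test_that("lambda = 0 with full observation converges to the least-squares projection", {
  set.seed(7)
  A <- matrix(rbinom(20, 1, 0.5), 5, 4)
  d <- as_dataset(A)
  C <- random_orthonormal(5, 2); D <- random_orthonormal(4, 2)
  fit <- solve_imc(C, D, d, lambda = 0, observed = matrix(TRUE, 5, 4),
                   max_iter = 2000, tol = 1e-12)
  R <- A - fit$scores
  expect_lt(max(abs(crossprod(C, R) %*% D)), 1e-6)
})

test_that("solution is invariant under column sign flips of C and D", {
  set.seed(8)
  A <- matrix(rbinom(20, 1, 0.4), 5, 4)
  d <- as_dataset(A)
  C <- random_orthonormal(5, 3); D <- random_orthonormal(4, 2)
  fit1 <- solve_imc(C, D, d, lambda = 0.5)
  flip_c <- diag(c(-1, 1, -1)); flip_d <- diag(c(1, -1))
  fit2 <- solve_imc(C %*% flip_c, D %*% flip_d, d, lambda = 0.5)
  expect_equal(fit1$scores, fit2$scores, tolerance = 1e-8)
})

test_that("recovery error decreases with more observed entries", {
  set.seed(9)
  C <- random_orthonormal(20, 4); D <- random_orthonormal(8, 4)
  Zstar <- matrix(rnorm(16), 4, 4)
  M <- C %*% Zstar %*% t(D)
  A <- matrix(as.integer(M > quantile(M, 0.7)), 20, 8)
  d <- as_dataset(A)
  errs <- vapply(c(0.2, 0.5, 0.9), function(frac) {
    obs <- matrix(runif(160) < frac, 20, 8)
    fit <- solve_imc(C, D, d, lambda = 0.01, observed = obs, max_iter = 1000)
    sqrt(sum((fit$scores - M)^2)) / sqrt(sum(M^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("score_matrix labels scores and flags known pairs", {
  d <- toy_dataset()
  C <- diag(1, 4); D <- diag(1, 3)
  fit <- solve_imc(C, D, d, lambda = 0.1)
  tab <- score_matrix(fit, d)
  expect_identical(nrow(tab), 12L)
  expect_identical(sum(tab$known), 5L)
  manual <- C %*% fit$Z %*% t(D)
  row <- tab[tab$circ_id == "c2" & tab$disease_id == "d1", ]
  expect_equal(row$score, manual[2, 1])
  # zero latent matrix gives all-zero scores
  fit0 <- solve_imc(C, D, d, lambda = 100)
  expect_true(all(score_matrix(fit0, d)$score == 0))
})
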