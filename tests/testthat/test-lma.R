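test_that("zero binding constants leave all protein free", {
  eq <- solve_lma(c(0.1, 0.2, 0.3, 0.05), matrix(0, 4, 4))
  expect_equal(eq$F, c(0.1, 0.2, 0.3, 0.05))
  expect_true(all(eq$F_pair == 0))
  expect_true(eq$converged)
})

test_that("single self-binding species matches the quadratic closed form", {
  withr::with_seed(1, {
    for (i in 1:40) {
      C <- runif(1, 0.01, 2)
      k <- 10^runif(1, -2, 6)
      eq <- solve_lma(C, matrix(k, 1, 1), rel_tol = 1e-8)
      F_exact <- (-1 + sqrt(1 + 4 * k * C)) / (2 * k)  # root of kF^2 + F - C
      expect_equal(eq$F, F_exact, tolerance = 1e-6)
      expect_equal(eq$F_pair[1, 1], k * eq$F^2 / 2, tolerance = 1e-10)
      # mass conservation with two monomers per homodimer
      expect_lt(abs(eq$F + 2 * eq$F_pair[1, 1] - C) / C, 1e-6)
    }
  })
})

test_that("two heterodimerizing species match the analytic two-species solution", {
  withr::with_seed(2, {
    for (i in 1:60) {
      C1 <- runif(1, 0.01, 1); C2 <- runif(1, 0.01, 1)
      k <- 10^runif(1, -2, 6)
      K <- matrix(c(0, k, k, 0), 2, 2)
      eq <- solve_lma(c(C1, C2), K, rel_tol = 1e-8)
      # dimer D solves k D^2 - (1 + k C1 + k C2) D + k C1 C2 = 0 (smaller root)
      bq <- 1 + k * (C1 + C2)
      D <- (bq - sqrt(bq^2 - 4 * k^2 * C1 * C2)) / (2 * k)
      expect_equal(eq$F_pair[1, 2], D, tolerance = 1e-5)
      expect_equal(eq$F[1], C1 - D, tolerance = 1e-5)
      expect_equal(eq$F[2], C2 - D, tolerance = 1e-5)
    }
  })
})

test_that("mass is conserved on random 4-species instances", {
  withr::with_seed(3, {
    for (i in 1:50) {
      C <- runif(4, 0.01, 0.5)
      K <- matrix(0, 4, 4)
      K[upper.tri(K, diag = TRUE)] <- 10^runif(10, -1, 5)
      K <- K + t(K) - diag(diag(K))
      eq <- solve_lma(C, K, rel_tol = 1e-4)
      expect_true(all(abs(lma_residual(eq, C)) / C < 10 * 1e-4))
      expect_true(all(eq$F >= 0))
    }
  })
})

test_that("solution agrees with an independent Newton root-finder", {
  # independent oracle: full Newton iteration on the residual system
  newton_lma <- function(C, K, iters = 200) {
    n <- length(C)
    f <- C / 2
    for (it in seq_len(iters)) {
      denom <- 1 + as.vector(K %*% f)
      res <- f * denom - C
      J <- diag(denom) + outer(f, rep(1, n)) * K
      step <- solve(J, res)
      f <- f - step
      f[f < 0] <- 1e-12
      if (max(abs(res)) < 1e-14) break
    }
    f
  }
  withr::with_seed(4, {
    for (i in 1:20) {
      C <- runif(4, 0.01, 0.5)
      K <- matrix(0, 4, 4)
      K[upper.tri(K, diag = TRUE)] <- 10^runif(10, -1, 4)
      K <- K + t(K) - diag(diag(K))
      eq <- solve_lma(C, K, rel_tol = 1e-9)
      expect_equal(eq$F, newton_lma(C, K), tolerance = 1e-5)
    }
  })
})

test_that("increasing a binding constant depletes the partners and grows the dimer", {
  withr::with_seed(5, {
    C <- c(0.2, 0.3, 0.1, 0.15)
    K <- matrix(1, 4, 4)
    eq0 <- solve_lma(C, K, rel_tol = 1e-8)
    K2 <- K; K2[1, 2] <- K2[2, 1] <- 50
    eq1 <- solve_lma(C, K2, rel_tol = 1e-8)
    expect_lt(eq1$F[1], eq0$F[1])
    expect_lt(eq1$F[2], eq0$F[2])
    expect_gt(eq1$F_pair[1, 2], eq0$F_pair[1, 2])
  })
})

test_that("the vectorized solver agrees with the scalar solver", {
  withr::with_seed(6, {
    n <- 30
    Cm <- matrix(runif(4 * n, 0.01, 0.4), n, 4)
    Karr <- matrix(10^runif(10 * n, -1, 6), n, 10)
    res <- mutatorsim:::solve_lma_matrix(Cm, Karr, rel_tol = 1e-7)
    for (r in c(1, 13, 30)) {
      K <- matrix(0, 4, 4)
      idx <- mutatorsim:::PAIR_IDX
      K[cbind(idx[, 1], idx[, 2])] <- Karr[r, ]
      K[cbind(idx[, 2], idx[, 1])] <- Karr[r, ]
      eq <- solve_lma(Cm[r, ], K, rel_tol = 1e-7)
      expect_equal(res$F[r, ], eq$F, tolerance = 1e-5)
      expect_equal(res$F_pair[r, 10], eq$F_pair[4, 4], tolerance = 1e-5)
    }
  })
})

test_that("non-convergence raises an error carrying the last state", {
  err <- tryCatch(solve_lma(c(0.5), matrix(1e4, 1, 1), rel_tol = 1e-12,
                            max_iter = 3, plain_iter = 1),
                  mutatorsim_convergence_error = function(e) e)
  expect_s3_class(err, "mutatorsim_convergence_error")
  expect_false(err$state$converged)
  expect_length(err$state$F, 1)
})

test_that("functional complex concentrations are simple products", {
  eq <- solve_lma(c(0.1, 0.1, 0.1, 0.1), matrix(2, 4, 4), rel_tol = 1e-8)
  expect_equal(functional_mmr_concentration(eq, 1, 1), eq$F_pair[4, 4])
  expect_equal(functional_mmr_concentration(eq, 0.5, 0.9),
               eq$F_pair[4, 4] * 0.5 * 0.81)
  fake <- list(F = c(0.3, 0, 0, 0),
               F_pair = matrix(0.02, 4, 4))
  expect_equal(functional_mmr_concentration(fake, 0.5, 0.9), 0.02 * 0.5 * 0.81)
  g <- functional_rcg_concentrations(fake, 1, 1, 1, 1)
  expect_equal(g$G1, 0.3)
  expect_equal(g$G23, 0.02)
  g2 <- functional_rcg_concentrations(fake, 0.9, 0.8, 0.7, 0)
  expect_equal(g2$G23, 0)
  expect_equal(g2$G1, 0.27)
})
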