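make_bilinear <- function(seed = 1, I = 6, J = 40, N = 3) {
  set.seed(seed)
  S <- matrix(runif(J * N), J, N)
  colnames(S) <- paste0("c", seq_len(N))
  C <- matrix(runif(I * N), I, N)
  colnames(C) <- colnames(S)
  list(X = C %*% t(S), C = C, S = S)
}

test_that("c_step solves the unconstrained least squares exactly", {
  b <- make_bilinear()
  C_hat <- c_step(b$X, b$S, constraint_spec(nonneg_C = FALSE, nonneg_S = FALSE))
  expect_equal(C_hat, b$C, tolerance = 1e-10)
  I2 <- diag(2); colnames(I2) <- c("a", "b")
  expect_equal(c_step(diag(2), I2, constraint_spec(FALSE, FALSE)), I2)
  expect_error(c_step(b$X, b$S[1:20, ], constraint_spec()), "differ")
  S0 <- b$S; S0[, 2] <- 0
  expect_error(c_step(b$X, S0, constraint_spec()), "all-zero")
})

test_that("non-negative c_step matches the brute-force grid oracle", {
  # orthonormal two-vector basis; mixture with a negative true coefficient
  v1 <- c(1, 0, 0, 0); v2 <- c(0, 1, 0, 0)
  S <- cbind(a = v1, b = v2)
  x <- v1 - 0.1 * v2
  C_hat <- c_step(matrix(x, 1), S, constraint_spec(nonneg_C = TRUE))
  oracle <- grid_nnls_orthonormal(x, S)
  expect_equal(unname(C_hat[1, ]), oracle, tolerance = 1e-9)
  expect_equal(unname(C_hat[1, ]), c(1, 0))
})

test_that("NNLS never does worse than clipping the unconstrained solution", {
  for (s in 1:25) {
    set.seed(s)
    S <- matrix(abs(rnorm(20)), 10, 2); colnames(S) <- c("a", "b")
    x <- rnorm(10)
    C_nnls <- c_step(matrix(x, 1), S, constraint_spec(nonneg_C = TRUE))
    C_clip <- pmax(c_step(matrix(x, 1), S, constraint_spec(nonneg_C = FALSE)), 0)
    r_nnls <- sum((x - S %*% C_nnls[1, ])^2)
    r_clip <- sum((x - S %*% C_clip[1, ])^2)
    expect_lte(r_nnls, r_clip + 1e-12)
  }
})

test_that("s_step honours known spectra and recovers unknowns", {
  b <- make_bilinear(seed = 4)
  sys_all <- component_system(colnames(b$S), b$S, rep(TRUE, 3))
  expect_identical(s_step(b$X * 2, b$C, sys_all), b$S)

  sys_none <- component_system(colnames(b$S), b$S * 0 + 0.5, rep(FALSE, 3))
  S_hat <- s_step(b$X, b$C, sys_none, constraint_spec(nonneg_S = FALSE))
  expect_equal(S_hat, b$S, tolerance = 1e-10)

  # one known of three: compare to direct LS on the independently deflated matrix
  sys_one <- component_system(colnames(b$S), b$S, c(TRUE, FALSE, FALSE))
  S_hat1 <- s_step(b$X, b$C, sys_one, constraint_spec(nonneg_S = FALSE))
  X_defl <- b$X - b$C[, 1, drop = FALSE] %*% t(b$S[, 1, drop = FALSE])
  S2_ref <- t(qr.solve(b$C[, 2:3], X_defl))
  expect_equal(unname(S_hat1[, 2:3]), unname(S2_ref), tolerance = 1e-8)

  C0 <- b$C; C0[, 2] <- 0
  expect_error(s_step(b$X, C0, sys_one, constraint_spec()), "unidentifiable")
})

test_that("closure rescales rows and flags degenerate ones", {
  C <- rbind(c(0.2, 0.2, 0.6), c(2, 2, 6), c(0, 0, 0))
  colnames(C) <- c("a", "b", "c")
  out <- apply_closure(C, c("a", "b", "c"), 1)
  expect_equal(unname(out[1, ]), c(0.2, 0.2, 0.6))
  expect_equal(unname(out[2, ]), c(0.2, 0.2, 0.6))
  expect_equal(unname(out[3, ]), c(0, 0, 0))
  expect_equal(attr(out, "closure_skipped"), 3L)
  expect_error(apply_closure(C, c("a", "zz"), 1), "not in")
  expect_error(apply_closure(C, "a", -1), "> 0")
})

test_that("lack of fit equals the Frobenius residual ratio", {
  b <- make_bilinear(seed = 9, I = 4, J = 6, N = 2)
  expect_equal(lack_of_fit(b$X, b$C, b$S), 0, tolerance = 1e-12)
  expect_equal(lack_of_fit(b$X, b$C * 0, b$S), 1)
  set.seed(10)
  Cr <- matrix(rnorm(8), 4, 2); Sr <- matrix(rnorm(12), 6, 2)
  direct <- sqrt(sum((b$X - Cr %*% t(Sr))^2)) / sqrt(sum(b$X^2))
  expect_equal(lack_of_fit(b$X, Cr, Sr), direct, tolerance = 1e-12)
  expect_error(lack_of_fit(b$X * 0, Cr, Sr), "all-zero")
})

test_that("fully known systems collapse to a single C-step", {
  b <- make_bilinear(seed = 2)
  sys <- component_system(colnames(b$S), b$S, rep(TRUE, 3))
  cs <- constraint_spec()
  fit <- run_als(b$X, sys, cs)
  expect_identical(fit$iterations, 1L)
  expect_true(fit$converged)
  expect_equal(fit$C_hat, c_step(b$X, b$S, cs), tolerance = 1e-12)

  # scaling consistency: alpha X gives alpha C when all spectra are fixed
  fit2 <- run_als(3 * b$X, sys, cs)
  expect_equal(fit2$C_hat, 3 * fit$C_hat, tolerance = 1e-9)
})

test_that("ALS recovers a perturbed noiseless system and keeps LoF monotone", {
  sim <- small_substance_study(seed = 3)
  X <- spectra_matrix(sim$data)
  S_true <- sim$truth$spectra
  set.seed(7)
  S0 <- S_true
  S0[, 2:3] <- S0[, 2:3] * (1 + 0.05 * matrix(runif(2 * nrow(S0), -1, 1),
                                              ncol = 2))
  sys <- component_system(colnames(S_true), S0, c(TRUE, FALSE, FALSE))
  cs <- constraint_spec(closure = list(components = colnames(S_true),
                                       constant = 1))
  fit <- run_als(X, sys, cs, max_iter = 1000)
  expect_lt(fit$lof, 0.001)
  expect_gt(cosine(fit$S_hat[, "Inter"], S_true[, "Inter"]), 0.999)
  expect_gt(cosine(fit$S_hat[, "Prod"], S_true[, "Prod"]), 0.999)
  expect_true(all(diff(fit$lof_trace) <= 1e-10))
  expect_true(all(fit$C_hat >= -1e-12) && all(fit$S_hat >= -1e-12))
  expect_equal(unname(rowSums(fit$C_hat)), rep(1, nrow(X)), tolerance = 1e-8)
})

test_that("unconstrained ALS agrees with an independent reference implementation", {
  b <- make_bilinear(seed = 6, I = 5, J = 12, N = 2)
  set.seed(8)
  S0 <- b$S * (1 + 0.2 * matrix(runif(length(b$S), -1, 1), nrow = nrow(b$S)))
  noisyX <- b$X + matrix(rnorm(length(b$X), sd = 0.02), nrow = nrow(b$X))
  sys <- component_system(colnames(b$S), S0, c(FALSE, FALSE))
  fit <- run_als(noisyX, sys, constraint_spec(nonneg_C = FALSE, nonneg_S = FALSE),
                 tol = 1e-12, max_iter = 400)
  lof_ref <- ref_als_unconstrained(noisyX, S0, iters = 400)
  expect_equal(fit$lof, lof_ref, tolerance = 1e-6)
})

test_that("fixed and shared-scalar concentration constraints are honoured", {
  set.seed(12)
  J <- 30
  S <- cbind(p = abs(rnorm(J)), q = abs(rnorm(J)), r = abs(rnorm(J)))
  C <- cbind(p = rep(0.7, 5), q = rep(0.33, 5), r = runif(5))
  X <- C %*% t(S)
  cs <- constraint_spec(fixed_C = list(q = 0.33), free_scalar_C = "p")
  C_hat <- c_step(X, S, cs)
  expect_equal(unname(C_hat[, "q"]), rep(0.33, 5))
  expect_equal(sd(C_hat[, "p"]), 0)
  expect_equal(unname(C_hat[, "p"]), rep(0.7, 5), tolerance = 1e-8)
  expect_equal(unname(C_hat[, "r"]), unname(C[, "r"]), tolerance = 1e-8)
  expect_error(constraint_spec(fixed_C = list(p = 1), free_scalar_C = "p"),
               "cannot be both")
})
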