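cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

## a tiny spectral dataset built in code
tiny_spectra <- function(n = 3, wn = c(4000, 4500, 5000, 5500, 6000),
                         seed = 1) {
  set.seed(seed)
  spectra_tbl(
    tibble::tibble(sample_id = sprintf("s%d", seq_len(n)),
                   material_kind = "substance",
                   age_months = seq_len(n) - 1,
                   batch = "B1", replicate = 1L),
    wn, matrix(runif(n * length(wn)), nrow = n)
  )
}

## independent reference MCR-ALS for the unconstrained case: plain
## alternating least squares written from the normal equations, sharing no
## code with the package implementation
ref_als_unconstrained <- function(X, S0, iters = 200) {
  S <- S0
  for (i in seq_len(iters)) {
    C <- X %*% S %*% solve(crossprod(S))
    S <- t(X) %*% C %*% solve(crossprod(C))
  }
  C <- X %*% S %*% solve(crossprod(S))
  sqrt(sum((X - C %*% t(S))^2) / sum(X^2))
}

## brute-force grid oracle for one-row non-negative least squares on an
## orthonormal basis: the residual separates per coefficient
grid_nnls_orthonormal <- function(x, S, step = 1e-3, upper = 2) {
  cand <- seq(0, upper, by = step)
  vapply(seq_len(ncol(S)), function(k) {
    a <- sum(x * S[, k])
    cand[which.min((cand - a)^2)]
  }, numeric(1))
}

## numerical integration oracle for the sequential first-order scheme
ode_two_step <- function(times, k1, k2, c0 = 1) {
  out <- deSolve::ode(
    y = c(A = c0, B = 0, P = 0),
    times = sort(unique(c(0, times))),
    func = function(t, y, p) {
      list(c(-p[1] * y[1], p[1] * y[1] - p[2] * y[2], p[2] * y[2]))
    },
    parms = c(k1, k2), rtol = 1e-10, atol = 1e-12
  )
  out[match(times, out[, "time"]), c("A", "B", "P"), drop = FALSE]
}

## small synthetic three-component study used by several pipeline tests
small_substance_study <- function(seed = 1, noise = 0, jitter = 0,
                                  n = 12, baseline_sd = 0) {
  simulate_substance_dataset(
    n_samples = n, model = two_step_model(0.023, 0.01), noise = noise,
    time_jitter_months = jitter, baseline_sd = baseline_sd,
    replicates = 1, seed = seed
  )
}

preprocess_default <- function(ds, baseline = "none") {
  ds |> select_range(4000, 9000) |> average_replicates() |>
    baseline_correct(baseline)
}
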