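## Synthetic NIR aging data with known ground truth.  Component spectra are
## sums of Gaussian bands on a 4000-9000 cm^-1 grid; concentrations follow
## the two-step first-order scheme; measurement noise is additive iid
## Gaussian plus a per-spectrum constant baseline offset (which the offset
## baseline correction inverts).  Every generator returns both the dataset
## and the truth needed for recovery studies.

#' Default wavenumber grid for simulations
#'
#' 4000-9000 cm^-1 in steps of 4 cm^-1 (1251 points) — the informative NIR
#' range, sampled finely enough that spectral least-squares estimates
#' average over many channels while staying fast on a laptop (the
#' instrument itself records at 2 cm^-1).
#'
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(4000, 9000, by = 4)

#' Default Gaussian band definitions for the six tablet components
#'
#' One tibble of `(center, width, amplitude)` Gaussian bands per component
#' (API, Inter, Prod, MCC, Rest, PVC). Bands overlap substantially (pairwise
#' cosine similarities up to about 0.7) so the unmixing is non-trivial,
#' while each component keeps at least one selective window where the
#' components it must be distinguished from are effectively zero — without
#' such selectivity the soft resolution is rotationally ambiguous and no
#' analysis could pin down the true factors. The intermediate carries a
#' distinct hydroxyl-like band near 5000 cm^-1. All bands sit inside
#' 4200-8700 cm^-1 so the spectra decay to ~0 at the range edges.
#'
#' @return Named list of tibbles with columns `center`, `width`,
#'   `amplitude` (cm^-1, cm^-1, absorbance units).
#' @export
default_peak_specs <- function() {
  pk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble::tibble(center = m[, 1], width = m[, 2], amplitude = m[, 3])
  }
  list(
    API = pk(4420, 100, 0.80, 5320, 150, 1.00, 6010, 200, 0.60, 8320, 180, 0.30),
    Inter = pk(5000, 90, 1.00, 5350, 150, 0.50, 6120, 200, 0.50, 7050, 180, 0.40),
    Prod = pk(4900, 110, 0.70, 5620, 160, 0.90, 6520, 180, 0.50, 7800, 140, 0.35),
    MCC = pk(4760, 140, 0.90, 5210, 180, 0.80, 6930, 300, 0.60, 8350, 170, 0.25),
    Rest = pk(4400, 90, 0.50, 4750, 90, 0.50, 5280, 90, 0.60, 6320, 220, 0.50,
              8100, 130, 0.40),
    PVC = pk(4350, 80, 0.90, 5820, 250, 0.50, 7010, 150, 0.30, 8700, 90, 0.40)
  )
}

#' Build component spectra from Gaussian band definitions
#'
#' Each spectrum is the sum of its Gaussian bands
#' `amplitude * exp(-(nu - center)^2 / (2 width^2))` evaluated on the grid;
#' non-negative by construction.
#'
#' @param peaks Named list of band tables (see [default_peak_specs()]).
#' @param grid Wavenumber grid in cm^-1.
#' @return Matrix, `length(grid)` rows by `length(peaks)` components.
#' @export
make_component_spectra <- function(peaks = default_peak_specs(),
                                   grid = default_grid()) {
  if (!length(peaks)) stop("`peaks` must name at least one component", call. = FALSE)
  S <- vapply(peaks, function(p) {
    p <- tibble::as_tibble(p)
    if (!nrow(p)) stop("empty peak list for a component", call. = FALSE)
    if (any(p$width <= 0) || any(p$amplitude <= 0)) {
      stop("peak widths and amplitudes must be positive", call. = FALSE)
    }
    rowSums(vapply(seq_len(nrow(p)), function(i) {
      p$amplitude[i] * exp(-(grid - p$center[i])^2 / (2 * p$width[i]^2))
    }, numeric(length(grid))))
  }, numeric(length(grid)))
  colnames(S) <- names(peaks)
  S
}

add_measurement_noise <- function(X0, noise, baseline_sd) {
  mean_signal <- mean(abs(X0))
  X <- X0
  if (noise > 0) {
    X <- X + matrix(stats::rnorm(length(X0), sd = noise * mean_signal),
                    nrow = nrow(X0))
  }
  if (baseline_sd > 0) {
    X <- X + stats::rnorm(nrow(X0), sd = baseline_sd * mean_signal)
  }
  X
}

#' Simulate a substance aging dataset
#'
#' Substance samples are a closed API/Inter/Prod system: ages are spread
#' evenly over `age_range`, concentrations follow [two_step_profile()], and
#' spectra are the bilinear product plus Gaussian noise and a per-spectrum
#' baseline offset. Nominal ages (the recorded metadata) are the true ages
#' plus a uniform jitter of up to `time_jitter_months`, emulating production
#' dates known only to within a few months; true ages are kept in the truth.
#'
#' @param n_samples Number of distinct substance samples (>= 4).
#' @param age_range `c(min, max)` age span in months.
#' @param model A [two_step_model()] (ground truth).
#' @param noise Relative sd of iid Gaussian noise (fraction of the mean
#'   absolute signal); >= 0.
#' @param time_jitter_months Half-width of the uniform nominal-age jitter.
#' @param baseline_sd Relative sd of the per-spectrum constant offset.
#' @param replicates Replicate spectra per sample (averaged in
#'   preprocessing).
#' @param seed Integer seed; the dataset is a deterministic function of it.
#' @param grid,peaks Wavenumber grid and band definitions.
#' @return A list with `data` (spectral dataset tibble) and `truth`
#'   (spectra, concentrations, true/nominal ages, model, seed).
#' @export
simulate_substance_dataset <- function(n_samples = 36, age_range = c(0, 120),
                                       model = two_step_model(0.023, 0.01),
                                       noise = 0.01, time_jitter_months = 3,
                                       baseline_sd = 0.01, replicates = 3,
                                       seed = 1, grid = default_grid(),
                                       peaks = default_peak_specs()) {
  if (n_samples < 4) stop("`n_samples` must be at least 4", call. = FALSE)
  if (noise < 0 || baseline_sd < 0) stop("noise levels must be >= 0", call. = FALSE)
  set.seed(seed)
  S <- make_component_spectra(peaks, grid)[, c("API", "Inter", "Prod")]
  ages <- seq(age_range[1], age_range[2], length.out = n_samples)
  C <- profile_matrix(ages, model$k1, model$k2, model$c0)
  nominal <- pmax(0, ages + stats::runif(n_samples, -time_jitter_months,
                                         time_jitter_months))
  idx <- rep(seq_len(n_samples), each = replicates)
  X0 <- C[idx, , drop = FALSE] %*% t(S)
  X <- add_measurement_noise(X0, noise, baseline_sd)
  meta <- tibble::tibble(
    sample_id = sprintf("sub%02d", idx),
    material_kind = "substance",
    age_months = nominal[idx],
    batch = "S1",
    replicate = rep(seq_len(replicates), times = n_samples)
  )
  list(
    data = spectra_tbl(meta, grid, X),
    truth = list(spectra = S, conc = C, model = model, true_ages = ages,
                 nominal_ages = nominal, noise = noise,
                 baseline_sd = baseline_sd, seed = seed, grid = grid)
  )
}

#' Tablet composition from the prescription masses
#'
#' Component masses of a fresh tablet: 100 mg API (Diclofenac sodium),
#' 90 mg microcrystalline cellulose, 85 mg other excipients and coating.
#' Relative fractions are the masses over the total, rounded to two
#' decimals (0.36 / 0.33 / 0.31), and must sum to 1.00 after rounding.
#'
#' @param mass_api,mass_mcc,mass_rest Masses in mg.
#' @return An object of class `tablet_composition` with fractions `c_api`,
#'   `c_mcc`, `c_rest`.
#' @export
tablet_composition <- function(mass_api = 100, mass_mcc = 90, mass_rest = 85) {
  total <- mass_api + mass_mcc + mass_rest
  f <- round(c(mass_api, mass_mcc, mass_rest) / total, 2)
  if (abs(sum(f) - 1) > 1e-12) {
    stop("rounded mass fractions (", paste(sprintf("%.2f", f), collapse = " + "),
         ") do not sum to 1.00", call. = FALSE)
  }
  structure(list(mass_api = mass_api, mass_mcc = mass_mcc, mass_rest = mass_rest,
                 c_api = f[1], c_mcc = f[2], c_rest = f[3]),
            class = "tablet_composition")
}

#' Simulate a blister-packed tablet aging dataset
#'
#' Six-component tablets measured through a PVC blister: the degradation
#' subsystem (API, Inter, Prod) carries `c_api` of the mass and follows
#' [two_step_profile()] scaled by `c_api`; MCC and Rest are constant at
#' `c_mcc` / `c_rest`; the blister contributes `pvc_weight * s_PVC`, a
#' spectral weighting factor rather than a mass fraction. Tablet production
#' dates are reliable, so ages are exact (no jitter).
#'
#' @param batches Number of production batches.
#' @param ages Tablet ages in months; must include 0 (fresh tablets are
#'   needed to estimate the Rest spectrum and the blister weight).
#' @param comp A [tablet_composition()].
#' @param model Ground-truth [two_step_model()].
#' @param pvc_weight Ground-truth blister weighting factor.
#' @param n_per_cell Tablets per batch x age combination.
#' @inheritParams simulate_substance_dataset
#' @return A list with `data` and `truth` (spectra, concentrations, model,
#'   `pvc_weight`, composition, seed).
#' @export
simulate_tablet_dataset <- function(batches = 5, ages = c(0, 9, 18, 76, 79),
                                    comp = tablet_composition(),
                                    model = two_step_model(0.028, 0.003),
                                    pvc_weight = 0.4, n_per_cell = 2,
                                    noise = 0.01, baseline_sd = 0.01,
                                    replicates = 3, seed = 1,
                                    grid = default_grid(),
                                    peaks = default_peak_specs()) {
  if (!any(ages == 0)) stop("`ages` must include 0 (fresh tablets)", call. = FALSE)
  if (noise < 0 || baseline_sd < 0) stop("noise levels must be >= 0", call. = FALSE)
  set.seed(seed + 1L)
  S <- make_component_spectra(peaks, grid)
  design <- expand.grid(tablet = seq_len(n_per_cell), age = ages,
                        batch = seq_len(batches))
  n <- nrow(design)
  deg <- comp$c_api * profile_matrix(design$age, model$k1, model$k2, model$c0)
  C <- cbind(PVC = rep(pvc_weight, n), MCC = rep(comp$c_mcc, n),
             Rest = rep(comp$c_rest, n), deg)
  idx <- rep(seq_len(n), each = replicates)
  X0 <- C[idx, , drop = FALSE] %*% t(S[, colnames(C)])
  X <- add_measurement_noise(X0, noise, baseline_sd)
  meta <- tibble::tibble(
    sample_id = sprintf("tab_b%d_a%03d_t%d", design$batch[idx],
                        design$age[idx], design$tablet[idx]),
    material_kind = "tablet",
    age_months = design$age[idx],
    batch = sprintf("B%d", design$batch[idx]),
    replicate = rep(seq_len(replicates), times = n)
  )
  list(
    data = spectra_tbl(meta, grid, X),
    truth = list(spectra = S, conc = C, model = model, pvc_weight = pvc_weight,
                 comp = comp, ages = design$age, noise = noise,
                 baseline_sd = baseline_sd, seed = seed, grid = grid)
  )
}
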