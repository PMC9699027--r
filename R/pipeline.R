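## The multi-step analysis: Step 1 resolves the substance data (API spectrum
## known, Inter/Prod unknown) and fits the kinetics with age adjustment;
## Step 2.1 resolves fresh tablets (PVC/MCC/API spectra and API/MCC/Rest
## concentrations known) for the Rest spectrum and the blister weight;
## the cleaning step subtracts the time-invariant part and rescales by the
## API mass fraction; Step 2.2 resolves the cleaned aged tablets; Step 3
## stacks cleaned tablets and substances into one resolution and fits the
## joint kinetics with a shared first-stage constant.  Spectra estimated at
## one step initialise the next.

as_spectrum_vector <- function(x, J) {
  if (is.data.frame(x)) x <- spectra_matrix(x)[1, ]
  x <- as.numeric(x)
  if (length(x) != J) {
    stop("spectrum length (", length(x), ") does not match the data grid (",
         J, ")", call. = FALSE)
  }
  x
}

#' Subtract-to-non-negativity deflation
#'
#' Removes from `x` the largest multiple of the reference spectrum `s` that
#' keeps the residual non-negative over the channels where `s` is dominant.
#' The coefficient is the minimum of the channel-wise ratio `x / s` over the
#' dominant channels, with both spectra lightly smoothed first so a single
#' noisy channel cannot drive the minimum down. When `s` has a selective
#' window — contiguous channels where the other constituents of `x` are
#' zero — the coefficient equals the true contribution of `s` and the
#' deflation is exact on noiseless data; this is the purest-channel logic
#' that classic pure-variable initialisations rely on.
#'
#' @param x Numeric spectrum to deflate.
#' @param s Reference spectrum on the same grid.
#' @param dominant Fraction of `max(s)` above which a channel counts as
#'   dominant.
#' @param smooth Width (channels) of the running mean applied before the
#'   ratio; 1 disables smoothing.
#' @return List with `coef` (the removed multiple, >= 0) and `residual`
#'   (clipped at zero).
#' @export
deflate_to_nonneg <- function(x, s, dominant = 0.1, smooth = 9) {
  xs <- x
  ss <- s
  if (smooth > 1) {
    kern <- rep(1 / smooth, smooth)
    xs <- as.numeric(stats::filter(x, kern, sides = 2))
    ss <- as.numeric(stats::filter(s, kern, sides = 2))
  }
  dom <- which(!is.na(ss) & ss >= dominant * max(ss, na.rm = TRUE))
  coef <- max(min(xs[dom] / ss[dom]), 0)
  list(coef = coef, residual = pmax(x - coef * s, 0))
}

## Deterministic data-driven initial approximations for the unknown Inter
## and Prod spectra.  Sequential purest-channel deflation: remove the known
## API spectrum from a young aged sample (mostly API + Inter) and from the
## oldest sample (Inter + Prod rich); then cross-deflate the two residuals —
## removing the old residual from the young one cancels the Prod content
## exactly at Prod-selective channels, and vice versa.
init_degradation_spectra <- function(X, ages, s_api) {
  aged <- which(ages > 0)
  if (!length(aged)) stop("no aged samples to initialise from", call. = FALSE)
  young <- aged[ages[aged] >= 0.05 * max(ages) & ages[aged] <= 0.35 * max(ages)]
  if (!length(young)) young <- aged[which.min(abs(ages[aged] - 0.15 * max(ages)))]
  old <- which(ages >= 0.65 * max(ages))
  ## average the group first, deflate once: the minimum-ratio estimate is
  ## then taken on a sqrt(n)-less-noisy spectrum
  r_young <- deflate_to_nonneg(colMeans(X[young, , drop = FALSE]), s_api)$residual
  r_old <- deflate_to_nonneg(colMeans(X[old, , drop = FALSE]), s_api)$residual
  inter0 <- deflate_to_nonneg(r_young, r_old)$residual
  if (sum(inter0) <= 1e-12 * length(inter0)) inter0 <- r_young
  prod0 <- deflate_to_nonneg(r_old, inter0)$residual
  if (sum(prod0) <= 1e-12 * length(prod0)) prod0 <- r_old
  list(Inter = inter0, Prod = prod0)
}

new_step_result <- function(step, mcr, kinetics = NULL, extras = list()) {
  structure(
    c(list(step = step, mcr = mcr, kinetics = kinetics,
           lof_percent = mcr$lof * 100), extras),
    class = "step_result"
  )
}

#' @export
print.step_result <- function(x, ...) {
  cat("<step_result> ", x$step, ": LoF ", signif(x$lof_percent, 3), "%\n", sep = "")
  if (!is.null(x$kinetics)) print(x$kinetics)
  invisible(x)
}

#' Step 1: resolve and model the substance data
#'
#' Three-component soft MCR (API spectrum known; Inter and Prod spectra
#' unknown) with closure to 1 over \{API, Inter, Prod\} and non-negativity on
#' concentrations and spectra, followed by the kinetic fit with bounded
#' adjustment of the uncertain nominal ages. Unknown spectra are initialised
#' from the data by sequential purest-channel deflation (see
#' [deflate_to_nonneg()]) of a young and the oldest sample; a good
#' initialisation matters because the soft constraints leave a rotational
#' ambiguity whose resolution the alternating least squares inherits from
#' its starting point.
#'
#' @param sub_ds Substance spectral dataset (one row per sample; run
#'   [average_replicates()] first).
#' @param api_spectrum Known API spectrum on the dataset grid (numeric
#'   vector or one-row spectral tibble).
#' @param bound_months Age-adjustment bound (0 disables adjustment).
#' @param tol,max_iter Passed to [run_als()].
#' @return A `step_result` with the MCR fit, the kinetic fit and the
#'   estimated Inter/Prod spectra.
#' @export
step1_substances <- function(sub_ds, api_spectrum, bound_months = 6,
                             tol = 1e-3, max_iter = 500) {
  meta <- spectra_meta(sub_ds)
  if (!all(meta$material_kind == "substance")) {
    stop("step 1 expects substance samples only", call. = FALSE)
  }
  if (nrow(meta) < 4) {
    stop("at least 4 substance samples are needed to identify the kinetics",
         call. = FALSE)
  }
  X <- spectra_matrix(sub_ds)
  wn <- spectra_wavenumbers(sub_ds)
  s_api <- as_spectrum_vector(api_spectrum, ncol(X))
  ages <- meta$age_months

  init <- init_degradation_spectra(X, ages, s_api)
  S0 <- cbind(API = s_api, Inter = init$Inter, Prod = init$Prod)
  system <- component_system(c("API", "Inter", "Prod"), S0,
                             known = c(TRUE, FALSE, FALSE), wavenumbers = wn)
  cs <- constraint_spec(
    nonneg_C = TRUE, nonneg_S = TRUE,
    closure = list(components = c("API", "Inter", "Prod"), constant = 1)
  )
  mcr <- run_als(X, system, cs, tol = tol, max_iter = max_iter)
  kin <- adjust_time_points(mcr$C_hat, ages, bound_months = bound_months)
  new_step_result("step1_substances", mcr, kin,
                  list(spectra = mcr$S_hat, wavenumbers = wn))
}

#' Step 2.1: resolve fresh tablets for the Rest spectrum and blister weight
#'
#' Four-component MCR of fresh (age 0) tablets in which three spectra (PVC,
#' MCC, API) and three concentrations (API, MCC, Rest — the prescription
#' fractions) are known and constant; the unknowns are the Rest spectrum
#' (non-negative) and the blister pseudo-concentration, one scalar shared
#' by all samples.
#'
#' @param fresh_ds Fresh-tablet spectral dataset (age 0 only).
#' @param known_spectra Named list with numeric spectra `PVC`, `MCC`, `API`
#'   on the dataset grid.
#' @param comp A [tablet_composition()].
#' @inheritParams step1_substances
#' @return A `step_result` with `rest_spectrum` and `pvc_weight`.
#' @export
step2_fresh_tablets <- function(fresh_ds, known_spectra, comp = tablet_composition(),
                                tol = 1e-3, max_iter = 500) {
  meta <- spectra_meta(fresh_ds)
  if (!all(meta$material_kind == "tablet")) {
    stop("step 2.1 expects tablet samples only", call. = FALSE)
  }
  if (any(meta$age_months != 0)) {
    stop("step 2.1 expects fresh (age 0) tablets only", call. = FALSE)
  }
  if (nrow(meta) < 2) stop("at least 2 fresh tablets are required", call. = FALSE)
  if (comp$c_rest <= 0) {
    stop("unidentifiable component: Rest has zero concentration", call. = FALSE)
  }
  X <- spectra_matrix(fresh_ds)
  wn <- spectra_wavenumbers(fresh_ds)
  J <- ncol(X)
  s_known <- cbind(PVC = as_spectrum_vector(known_spectra$PVC, J),
                   MCC = as_spectrum_vector(known_spectra$MCC, J),
                   API = as_spectrum_vector(known_spectra$API, J))
  ## Rest init: subtract the known MCC/API contributions exactly, deflate
  ## the PVC contribution to non-negativity, rescale to the fixed fraction.
  y <- colMeans(X) - comp$c_mcc * s_known[, "MCC"] - comp$c_api * s_known[, "API"]
  rest0 <- deflate_to_nonneg(y, s_known[, "PVC"])$residual / comp$c_rest
  if (sum(rest0) <= 1e-12 * length(rest0)) rest0 <- pmax(y, 0) / comp$c_rest
  system <- component_system(c("PVC", "MCC", "API", "Rest"),
                             cbind(s_known, Rest = rest0),
                             known = c(TRUE, TRUE, TRUE, FALSE),
                             wavenumbers = wn)
  cs <- constraint_spec(
    nonneg_C = TRUE, nonneg_S = TRUE,
    fixed_C = list(MCC = comp$c_mcc, API = comp$c_api, Rest = comp$c_rest),
    free_scalar_C = "PVC"
  )
  mcr <- run_als(X, system, cs, tol = tol, max_iter = max_iter)
  new_step_result("step2_fresh_tablets", mcr, NULL,
                  list(rest_spectrum = mcr$S_hat[, "Rest"],
                       pvc_weight = mean(mcr$C_hat[, "PVC"]),
                       wavenumbers = wn))
}

#' Remove the time-invariant contribution from tablet spectra
#'
#' Subtracts the fixed part `C_fix S_fix^t` (PVC, MCC and Rest at their
#' known concentrations/weights) from the tablet spectra and divides by the
#' prescribed fresh-tablet API fraction, so the cleaned spectra describe
#' the API + degradation-product mixture on the substance concentration
#' scale. Negative residual values are noise around zero and are retained,
#' with their fraction reported in the `"negative_fraction"` attribute.
#'
#' @param tab_ds Tablet spectral dataset.
#' @param fixed_spectra Named list of numeric spectra `PVC`, `MCC`, `Rest`
#'   on the dataset grid.
#' @param fixed_conc Named numeric vector of their concentrations/weights,
#'   e.g. `c(PVC = 0.41, MCC = 0.33, Rest = 0.31)`.
#' @param api_fraction Fresh-tablet API mass fraction used for the
#'   normalisation (default 0.36).
#' @return A spectral dataset tibble of cleaned spectra (metadata
#'   preserved).
#' @export
clean_tablet_spectra <- function(tab_ds, fixed_spectra, fixed_conc,
                                 api_fraction = 0.36) {
  if (api_fraction <= 0) stop("`api_fraction` must be > 0", call. = FALSE)
  X <- spectra_matrix(tab_ds)
  J <- ncol(X)
  nm <- c("PVC", "MCC", "Rest")
  if (!all(nm %in% names(fixed_spectra)) || !all(nm %in% names(fixed_conc))) {
    stop("fixed spectra and concentrations must name PVC, MCC and Rest",
         call. = FALSE)
  }
  S_fix <- vapply(nm, function(n) as_spectrum_vector(fixed_spectra[[n]], J),
                  numeric(J))
  fixed_part <- rep(1, nrow(X)) %*% t(S_fix %*% fixed_conc[nm])
  X_clean <- (X - fixed_part) / api_fraction
  out <- replace_matrix(tab_ds, X_clean)
  attr(out, "negative_fraction") <- mean(X_clean < 0)
  out
}

#' Step 2.2: resolve and model the cleaned aged tablets
#'
#' Same three-component resolution as Step 1, applied to cleaned tablet
#' spectra, with the Inter and Prod spectra estimated in Step 1 as initial
#' approximations. Tablet production dates are reliable, so the kinetic fit
#' uses the exact ages with no adjustment.
#'
#' @param clean_ds Cleaned tablet dataset from [clean_tablet_spectra()].
#' @param init_spectra Named list with numeric `Inter` and `Prod` initial
#'   spectra (typically `step1$mcr$S_hat` columns).
#' @inheritParams step1_substances
#' @return A `step_result` with the MCR and kinetic fits.
#' @export
step2_tablets <- function(clean_ds, init_spectra, api_spectrum,
                          tol = 1e-3, max_iter = 500) {
  if (is.null(init_spectra$Inter) || is.null(init_spectra$Prod)) {
    stop("`init_spectra` must provide Inter and Prod", call. = FALSE)
  }
  meta <- spectra_meta(clean_ds)
  X <- spectra_matrix(clean_ds)
  wn <- spectra_wavenumbers(clean_ds)
  J <- ncol(X)
  S0 <- cbind(API = as_spectrum_vector(api_spectrum, J),
              Inter = as_spectrum_vector(init_spectra$Inter, J),
              Prod = as_spectrum_vector(init_spectra$Prod, J))
  system <- component_system(c("API", "Inter", "Prod"), S0,
                             known = c(TRUE, FALSE, FALSE), wavenumbers = wn)
  cs <- constraint_spec(
    nonneg_C = TRUE, nonneg_S = TRUE,
    closure = list(components = c("API", "Inter", "Prod"), constant = 1)
  )
  mcr <- run_als(X, system, cs, tol = tol, max_iter = max_iter)
  kin <- fit_rate_constants(mcr$C_hat, meta$age_months)
  new_step_result("step2_tablets", mcr, kin,
                  list(spectra = mcr$S_hat, wavenumbers = wn))
}

#' Step 3: combined resolution and joint kinetics
#'
#' Stacks the cleaned tablet spectra and the substance spectra (both
#' describe the same closed API/Inter/Prod system) into one matrix, runs a
#' single soft MCR with shared spectra, and fits the joint kinetic model
#' with one shared first-stage constant and dataset-specific second-stage
#' constants (`k21` tablets, `k22` substances).
#'
#' @param clean_tab_ds Cleaned tablet dataset.
#' @param sub_ds Substance dataset on the same wavenumber grid.
#' @param init_spectra Named list with `Inter` and `Prod` initial spectra
#'   (typically from Step 2.2).
#' @param substance_times Optional ages for the substance samples (e.g. the
#'   adjusted ages from Step 1); defaults to the nominal metadata ages.
#' @inheritParams step1_substances
#' @return A `step_result` whose `kinetics` is the shared-`k1` joint fit.
#' @export
step3_combined <- function(clean_tab_ds, sub_ds, init_spectra, api_spectrum,
                           substance_times = NULL, tol = 1e-3, max_iter = 500) {
  wn_t <- spectra_wavenumbers(clean_tab_ds)
  wn_s <- spectra_wavenumbers(sub_ds)
  if (length(wn_t) != length(wn_s) || any(abs(wn_t - wn_s) > 1e-9)) {
    stop("tablet and substance datasets are on different grids", call. = FALSE)
  }
  X_tab <- spectra_matrix(clean_tab_ds)
  X_sub <- spectra_matrix(sub_ds)
  X <- rbind(X_tab, X_sub)
  J <- ncol(X)
  S0 <- cbind(API = as_spectrum_vector(api_spectrum, J),
              Inter = as_spectrum_vector(init_spectra$Inter, J),
              Prod = as_spectrum_vector(init_spectra$Prod, J))
  system <- component_system(c("API", "Inter", "Prod"), S0,
                             known = c(TRUE, FALSE, FALSE), wavenumbers = wn_t)
  cs <- constraint_spec(
    nonneg_C = TRUE, nonneg_S = TRUE,
    closure = list(components = c("API", "Inter", "Prod"), constant = 1)
  )
  mcr <- run_als(X, system, cs, tol = tol, max_iter = max_iter)
  n_tab <- nrow(X_tab)
  C_tab <- mcr$C_hat[seq_len(n_tab), , drop = FALSE]
  C_sub <- mcr$C_hat[-seq_len(n_tab), , drop = FALSE]
  t_tab <- spectra_meta(clean_tab_ds)$age_months
  t_sub <- substance_times %||% spectra_meta(sub_ds)$age_months
  kin <- fit_joint(C_tab, t_tab, C_sub, t_sub, share_k1 = TRUE)
  new_step_result("step3_combined", mcr, kin,
                  list(spectra = mcr$S_hat, wavenumbers = wn_t,
                       n_tablets = n_tab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration for a full pipeline run
#'
#' Collects the generator settings (or input files) and analysis options of
#' [run_pipeline()]. With `files = NULL` a synthetic study is generated:
#' tablets and substances share the ground-truth first-stage constant
#' `k1` while the second stage differs (`k21` tablets, `k22` substances),
#' matching the mechanism the analysis is designed to detect.
#'
#' @param seed Integer seed controlling every random draw.
#' @param k1,k21,k22 Ground-truth rate constants (month^-1).
#' @param noise,baseline_sd Relative noise levels for the generator.
#' @param pvc_weight Ground-truth blister weighting factor.
#' @param n_substances,substance_age_range,time_jitter_months Substance
#'   study shape.
#' @param batches,tablet_ages,n_per_cell Tablet study shape.
#' @param bound_months Age-adjustment bound for Step 1.
#' @param tol,max_iter ALS convergence settings passed to every resolution
#'   step.
#' @param baseline Baseline-correction method for preprocessing.
#' @param range Informative wavenumber range kept for analysis.
#' @param files Optional named list of paths (`tablets`, `substances`,
#'   `pure`) to read instead of simulating; `pure` must contain rows with
#'   `sample_id` PVC, MCC and API.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, k1 = 0.022, k21 = 0.003, k22 = 0.007,
                            noise = 0.01, baseline_sd = 0.01, pvc_weight = 0.4,
                            n_substances = 36, substance_age_range = c(0, 120),
                            time_jitter_months = 3, batches = 5,
                            tablet_ages = c(0, 9, 18, 76, 79), n_per_cell = 2,
                            bound_months = 6, baseline = "linear",
                            range = c(4000, 9000), tol = 1e-3,
                            max_iter = 500, files = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

preprocess <- function(ds, config) {
  ds |>
    select_range(config$range[1], config$range[2]) |>
    average_replicates() |>
    baseline_correct(config$baseline)
}

#' Run the full multi-step analysis
#'
#' Executes preprocessing (range selection, replicate averaging, baseline
#' correction), Step 1 (substances), Step 2.1 (fresh tablets), cleaning,
#' Step 2.2 (aged tablets) and Step 3 (combined), carrying spectra forward
#' as initial approximations, and collects the per-step lack of fit and the
#' final constants table (`k1` both, `k21` tablets, `k22` substances).
#' Deterministic given the seed in `config`.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_report`; see [tidy.pipeline_report()]
#'   and [write_pipeline_report()].
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.null(config$files)) {
    sub_sim <- simulate_substance_dataset(
      n_samples = config$n_substances, age_range = config$substance_age_range,
      model = two_step_model(config$k1, config$k22),
      noise = config$noise, time_jitter_months = config$time_jitter_months,
      baseline_sd = config$baseline_sd, seed = config$seed
    )
    tab_sim <- simulate_tablet_dataset(
      batches = config$batches, ages = config$tablet_ages,
      model = two_step_model(config$k1, config$k21),
      pvc_weight = config$pvc_weight, n_per_cell = config$n_per_cell,
      noise = config$noise, baseline_sd = config$baseline_sd,
      seed = config$seed
    )
    sub_raw <- sub_sim$data
    tab_raw <- tab_sim$data
    pure <- list(PVC = tab_sim$truth$spectra[, "PVC"],
                 MCC = tab_sim$truth$spectra[, "MCC"],
                 API = tab_sim$truth$spectra[, "API"])
    pure_grid <- tab_sim$truth$grid
    truth <- list(substances = sub_sim$truth, tablets = tab_sim$truth)
  } else {
    sub_raw <- read_spectra(config$files$substances)
    tab_raw <- read_spectra(config$files$tablets)
    pure_ds <- read_spectra(config$files$pure)
    pm <- spectra_matrix(pure_ds)
    pure <- list(PVC = pm[spectra_meta(pure_ds)$sample_id == "PVC", ],
                 MCC = pm[spectra_meta(pure_ds)$sample_id == "MCC", ],
                 API = pm[spectra_meta(pure_ds)$sample_id == "API", ])
    pure_grid <- spectra_wavenumbers(pure_ds)
    truth <- NULL
  }

  sub_ds <- preprocess(sub_raw, config)
  tab_ds <- preprocess(tab_raw, config)
  wn <- spectra_wavenumbers(tab_ds)
  if (length(pure_grid) != length(wn) || any(abs(pure_grid - wn) > 1e-9)) {
    pure_tbl <- spectra_tbl(
      tibble::tibble(sample_id = names(pure), material_kind = "pure_component"),
      pure_grid, do.call(rbind, pure)
    )
    pure_rs <- resample_spectra(pure_tbl, wn)
    m <- spectra_matrix(pure_rs)
    pure <- stats::setNames(lapply(seq_along(pure), function(i) m[i, ]), names(pure))
  }

  s1 <- step1_substances(sub_ds, pure$API, bound_months = config$bound_months,
                         tol = config$tol, max_iter = config$max_iter)

  fresh <- dplyr::filter(tab_ds, .data$age_months == 0)
  s21 <- step2_fresh_tablets(fresh, pure, tablet_composition(),
                             tol = config$tol, max_iter = config$max_iter)

  comp <- tablet_composition()
  clean_ds <- clean_tablet_spectra(
    tab_ds,
    fixed_spectra = list(PVC = pure$PVC, MCC = pure$MCC,
                         Rest = s21$rest_spectrum),
    fixed_conc = c(PVC = s21$pvc_weight, MCC = comp$c_mcc, Rest = comp$c_rest),
    api_fraction = comp$c_api
  )

  s22 <- step2_tablets(clean_ds,
                       init_spectra = list(Inter = s1$mcr$S_hat[, "Inter"],
                                           Prod = s1$mcr$S_hat[, "Prod"]),
                       api_spectrum = pure$API,
                       tol = config$tol, max_iter = config$max_iter)

  s3 <- step3_combined(clean_ds, sub_ds,
                       init_spectra = list(Inter = s22$mcr$S_hat[, "Inter"],
                                           Prod = s22$mcr$S_hat[, "Prod"]),
                       api_spectrum = pure$API,
                       substance_times = s1$kinetics$adjusted_times,
                       tol = config$tol, max_iter = config$max_iter)

  constants <- tibble::tibble(
    name = c("k1", "k21", "k22"),
    value = c(s3$kinetics$k1, s3$kinetics$k21, s3$kinetics$k22),
    scope = c("both", "tablets", "substances")
  )
  lof <- tibble::tibble(
    step = c("step1_substances", "step2_fresh_tablets", "step2_tablets",
             "step3_combined"),
    lof_percent = c(s1$lof_percent, s21$lof_percent, s22$lof_percent,
                    s3$lof_percent)
  )
  structure(
    list(steps = list(step1 = s1, step2_1 = s21, step2_2 = s22, step3 = s3),
         constants = constants, lof = lof, pvc_weight = s21$pvc_weight,
         wavenumbers = wn, seed = config$seed, config = config, truth = truth),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "\n")
  cat("Lack of fit per step (%):\n")
  print(as.data.frame(x$lof), row.names = FALSE)
  cat("Estimated blister weighting factor:", signif(x$pvc_weight, 4), "\n")
  cat("Kinetic constants (month^-1):\n")
  print(as.data.frame(x$constants), row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to delimited text
#'
#' Writes `constants.csv` (name, value_per_month, scope), `lof.csv`
#' (step, percent) and `spectra_estimates.csv` (wavenumber by component,
#' final Step-3 spectra) into `dir`.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$constants, file.path(dir, "constants.csv"))
  readr::write_csv(report$lof, file.path(dir, "lof.csv"))
  S <- report$steps$step3$mcr$S_hat
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(wavenumber = report$wavenumbers),
                     tibble::as_tibble(S)),
    file.path(dir, "spectra_estimates.csv")
  )
  invisible(dir)
}

#' Read back the constants table written by [write_pipeline_report()]
#'
#' @param dir Directory holding `constants.csv`.
#' @return Tibble with columns `name`, `value`, `scope`.
#' @export
read_constants <- function(dir) {
  readr::read_csv(file.path(dir, "constants.csv"), show_col_types = FALSE,
                  progress = FALSE)
}
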