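#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy an MCR fit into a long concentration table
#'
#' @param x An `mcr_fit` from [run_als()].
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `component`, `concentration`.
#' @export
tidy.mcr_fit <- function(x, ...) {
  C <- x$C_hat
  tibble::tibble(
    sample_id = rep(rownames(C) %||% as.character(seq_len(nrow(C))),
                    times = ncol(C)),
    component = rep(colnames(C), each = nrow(C)),
    concentration = as.vector(C)
  )
}

#' One-row summary of an MCR fit
#'
#' @inheritParams tidy.mcr_fit
#' @return Tibble with `lof_percent`, `iterations`, `converged`,
#'   `residual_norm`, `n_samples`, `n_components`.
#' @export
glance.mcr_fit <- function(x, ...) {
  tibble::tibble(
    lof_percent = x$lof * 100,
    iterations = x$iterations,
    converged = x$converged,
    residual_norm = x$residual_norm,
    n_samples = x$n_samples,
    n_components = length(x$components)
  )
}

#' Tidy a kinetic fit into a constants table
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `scope` (and
#'   `std.error` where a covariance approximation is available).
#' @export
tidy.kinetic_fit <- function(x, ...) {
  if (!is.null(x$k21)) {
    return(tibble::tibble(
      term = c("k1", "k21", "k22"),
      estimate = c(x$k1, x$k21, x$k22),
      scope = c(if (x$shared_k1) "both" else "tablets", "tablets", "substances")
    ))
  }
  se <- if (!is.null(x$cov) && !anyNA(x$cov)) sqrt(pmax(diag(x$cov), 0))
        else rep(NA_real_, 2)
  tibble::tibble(term = c("k1", "k2"), estimate = c(x$k1, x$k2),
                 std.error = se, scope = "data")
}

#' One-row summary of a kinetic fit
#'
#' @inheritParams tidy.kinetic_fit
#' @return Tibble with `rss`, `n`, `shared_k1`, `times_adjusted` and, for
#'   joint fits, the split/pooled residuals of the competing hypotheses.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss,
    n = x$n,
    shared_k1 = isTRUE(x$shared_k1),
    times_adjusted = !is.null(x$adjusted_times),
    rss_split = x$rss_split %||% NA_real_,
    rss_shared_all = x$rss_shared_all %||% NA_real_
  )
}

#' Fitted concentration profiles alongside the observations
#'
#' @inheritParams tidy.kinetic_fit
#' @return Long tibble with `time`, `component`, `observed`, `fitted`.
#' @export
augment.kinetic_fit <- function(x, ...) {
  times <- x$adjusted_times %||% x$times
  if (!is.null(x$k21)) {
    n_tab <- x$n_tab
    pred <- rbind(
      profile_matrix(times[seq_len(n_tab)], x$k1, x$k21, x$c0),
      profile_matrix(times[-seq_len(n_tab)],
                     if (x$shared_k1) x$k1 else x$fit_substances$k1,
                     x$k22, x$c0)
    )
    scope <- rep(c("tablets", "substances"),
                 c(n_tab, length(times) - n_tab))
  } else {
    pred <- profile_matrix(times, x$k1, x$k2, x$c0)
    scope <- rep("data", length(times))
  }
  n <- nrow(x$conc)
  tibble::tibble(
    time = rep(times, 3),
    scope = rep(scope, 3),
    component = rep(colnames(x$conc), each = n),
    observed = as.vector(x$conc),
    fitted = as.vector(pred)
  )
}

#' Constants table of a full pipeline run
#'
#' @param x A `pipeline_report` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble with `name`, `value` (month^-1), `scope`.
#' @export
tidy.pipeline_report <- function(x, ...) x$constants

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.pipeline_report
#' @return Tibble with the per-step lack of fit (percent), the blister
#'   weighting factor and the seed.
#' @export
glance.pipeline_report <- function(x, ...) {
  lof <- stats::setNames(as.list(x$lof$lof_percent),
                         paste0("lof_", x$lof$step))
  tibble::as_tibble(c(lof, list(pvc_weight = x$pvc_weight, seed = x$seed)))
}
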