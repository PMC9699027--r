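## Soft MCR-ALS: bilinear model X = C S^t + E, alternating least-squares
## estimation of C (concentrations) and S (pure spectra) under soft
## constraints: non-negativity (solved as true NNLS, not clipping), closure
## (row rescaling of a component subset to a constant sum), fixed known
## spectra (partial-known S-step on the deflated matrix), fixed concentration
## columns, and shared free scalar concentrations (the blister weighting
## factor). Kinetics are never imposed inside ALS; they are fitted afterward.

#' Define a component system for curve resolution
#'
#' A component system names the chemical components of the bilinear model
#' and holds one spectrum per component, flagged as known (held fixed during
#' the alternating least squares) or unknown (the supplied spectrum is the
#' initial approximation, refined at every S-step).
#'
#' @param names Character vector of component labels (length N).
#' @param spectra Numeric matrix, wavenumbers by components (J x N), columns
#'   in the order of `names`. Unknown components may hold any non-negative
#'   initial approximation.
#' @param known Logical vector of length N: is the spectrum known?
#' @param wavenumbers Optional wavenumber grid (length J), carried for grid
#'   checks and plotting.
#' @return An object of class `component_system`.
#' @export
component_system <- function(names, spectra, known, wavenumbers = NULL) {
  spectra <- as.matrix(spectra)
  n <- length(names)
  if (n < 1) stop("at least one component is required", call. = FALSE)
  if (ncol(spectra) != n || length(known) != n) {
    stop("`spectra` columns and `known` must match `names`", call. = FALSE)
  }
  if (any(spectra[, known, drop = FALSE] < 0)) {
    stop("known spectra must be non-negative", call. = FALSE)
  }
  colnames(spectra) <- names
  structure(
    list(names = names, spectra = spectra, known = as.logical(known),
         wavenumbers = wavenumbers),
    class = "component_system"
  )
}

#' @export
print.component_system <- function(x, ...) {
  cat("<component_system> ", length(x$names), " components, ",
      nrow(x$spectra), " wavenumbers\n", sep = "")
  cat("  known:  ", paste(x$names[x$known], collapse = ", "), "\n")
  cat("  unknown:", paste(x$names[!x$known], collapse = ", "), "\n")
  invisible(x)
}

#' Declare the constraint set for an MCR run
#'
#' @param nonneg_C,nonneg_S Enforce non-negativity of concentrations /
#'   spectra (solved as non-negative least squares).
#' @param closure Optional `list(components =, constant =)`: in every sample
#'   the named components' concentrations are rescaled to sum to `constant`
#'   (mass balance in a closed system).
#' @param fixed_C Optional named list: component name -> fixed concentration,
#'   either one scalar shared by all samples or a per-sample vector.
#' @param free_scalar_C Optional character vector of components whose
#'   concentration is a single unknown scalar shared across all samples
#'   (used for the PVC blister weighting factor).
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(nonneg_C = TRUE, nonneg_S = TRUE, closure = NULL,
                            fixed_C = NULL, free_scalar_C = NULL) {
  if (!is.null(closure)) {
    stopifnot(is.list(closure), !is.null(closure$components))
    if (is.null(closure$constant)) closure$constant <- 1
    if (closure$constant <= 0) stop("closure constant must be > 0", call. = FALSE)
  }
  if (length(intersect(names(fixed_C), free_scalar_C))) {
    stop("a component cannot be both fixed and a free shared scalar", call. = FALSE)
  }
  structure(
    list(nonneg_C = nonneg_C, nonneg_S = nonneg_S, closure = closure,
         fixed_C = fixed_C, free_scalar_C = free_scalar_C),
    class = "constraint_spec"
  )
}

## Moore-Penrose pseudo-inverse by SVD, relative singular-value cutoff 1e-10.
pinv_svd <- function(A, rtol = 1e-10, warn = TRUE) {
  sv <- svd(A)
  if (length(sv$d) == 0 || sv$d[1] == 0) {
    if (warn) warning("zero matrix in least-squares step", call. = FALSE)
    return(t(A) * 0)
  }
  keep <- sv$d > rtol * sv$d[1]
  if (!all(keep) && warn) {
    warning("rank-deficient least-squares step; minimum-norm solution used",
            call. = FALSE)
  }
  d_inv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (d_inv * t(sv$u))
}

## Solve min ||A %*% x - b||, x >= 0, for every column b of B.  The
## unconstrained LS solution is the NNLS solution whenever it is already
## feasible, so constrained solving is only needed for offending columns.
## For 1 or 2 unknowns the KKT cases can be enumerated in closed form and
## vectorised across all columns; larger systems fall back to the
## active-set solver.
nnls_cols <- function(A, B, warn = FALSE) {
  X <- pinv_svd(A, warn = warn) %*% B
  bad <- which(apply(X, 2, min) < -1e-12)
  if (!length(bad)) return(X)
  p <- ncol(A)
  if (p == 1) {
    X[1, bad] <- pmax(X[1, bad], 0)
  } else if (p == 2) {
    ## candidates: each single-column solution clipped at zero, and (0, 0);
    ## the unconstrained optimum is infeasible for these columns, so the
    ## NNLS optimum lies on the boundary
    Bb <- B[, bad, drop = FALSE]
    a11 <- sum(A[, 1]^2); a22 <- sum(A[, 2]^2)
    x1 <- pmax(as.vector(crossprod(A[, 1], Bb)) / a11, 0)
    x2 <- pmax(as.vector(crossprod(A[, 2], Bb)) / a22, 0)
    ## residual^2 = ||b||^2 - 2 x (a.b) + x^2 ||a||^2, compare the two edges
    r1 <- -2 * x1 * as.vector(crossprod(A[, 1], Bb)) + x1^2 * a11
    r2 <- -2 * x2 * as.vector(crossprod(A[, 2], Bb)) + x2^2 * a22
    use1 <- r1 <= r2
    X[1, bad] <- ifelse(use1, x1, 0)
    X[2, bad] <- ifelse(use1, 0, x2)
  } else {
    for (k in bad) {
      X[, k] <- pracma::lsqnonneg(A, B[, k])$x
    }
  }
  X
}

#' Apply the closure constraint to a concentration matrix
#'
#' Rescales, within every sample (row), the concentrations of the given
#' component subset so that they sum to `constant`. Rows whose subset sum is
#' numerically zero (<= 1e-15) are left unchanged and flagged in the
#' `"closure_skipped"` attribute of the result.
#'
#' @param C Numeric concentration matrix with component column names.
#' @param components Character vector naming the closed subset.
#' @param constant Positive closure constant.
#' @return The rescaled matrix.
#' @export
apply_closure <- function(C, components, constant = 1) {
  if (constant <= 0) stop("closure constant must be > 0", call. = FALSE)
  idx <- match(components, colnames(C))
  if (anyNA(idx)) stop("closure components not in concentration matrix", call. = FALSE)
  s <- rowSums(C[, idx, drop = FALSE])
  ok <- s > 1e-15
  C[ok, idx] <- C[ok, idx, drop = FALSE] * (constant / s[ok])
  attr(C, "closure_skipped") <- which(!ok)
  C
}

#' Relative lack of fit of a bilinear model
#'
#' `||X - C S^t||_F / ||X||_F`, the standard residual measure for curve
#' resolution, returned as a fraction (multiply by 100 for percent).
#'
#' @param X Data matrix (samples x wavenumbers).
#' @param C Concentration matrix (samples x components).
#' @param S Spectra matrix (wavenumbers x components).
#' @return A single non-negative number.
#' @export
lack_of_fit <- function(X, C, S) {
  nx <- norm(X, "F")
  if (nx == 0) stop("lack of fit undefined for an all-zero data matrix", call. = FALSE)
  norm(X - C %*% t(S), "F") / nx
}

#' Concentration (C-type) step of the alternating least squares
#'
#' Computes the unconstrained least-squares concentrations
#' `C_in = X (S^t)^+` and then applies the constraints in a fixed order:
#' fixed concentration values are substituted, free shared scalars are
#' estimated by one-dimensional least squares over all samples jointly,
#' non-negativity is enforced per sample by non-negative least squares on
#' the remaining free components, and finally closure rescales the closed
#' subset.
#'
#' @param X Data matrix (samples x wavenumbers).
#' @param S_hat Current spectra matrix (wavenumbers x components) with
#'   component column names.
#' @param cs A [constraint_spec()].
#' @return Concentration matrix `C_hat` (samples x components).
#' @export
c_step <- function(X, S_hat, cs = constraint_spec()) {
  X <- as.matrix(X)
  S_hat <- as.matrix(S_hat)
  if (ncol(X) != nrow(S_hat)) {
    stop("X columns (", ncol(X), ") and S rows (", nrow(S_hat), ") differ",
         call. = FALSE)
  }
  if (is.null(colnames(S_hat))) colnames(S_hat) <- paste0("comp", seq_len(ncol(S_hat)))
  if (any(colSums(S_hat^2) == 0)) {
    stop("all-zero spectrum column in S", call. = FALSE)
  }
  comp <- colnames(S_hat)
  n <- length(comp)
  I <- nrow(X)

  ## unconstrained LS:  X = C S^t  =>  C = X (S^t)^+
  C <- X %*% t(pinv_svd(S_hat))
  colnames(C) <- comp

  fixed <- names(cs$fixed_C)
  scal <- cs$free_scalar_C
  free <- setdiff(comp, c(fixed, scal))

  ## 1) substitute fixed concentration values
  for (nm in fixed) {
    C[, nm] <- rep_len(cs$fixed_C[[nm]], I)
  }

  ## 2) free shared scalars: 1-D LS over all samples jointly, other columns
  ##    held at their current values
  for (nm in scal) {
    others <- setdiff(comp, nm)
    R <- X - C[, others, drop = FALSE] %*% t(S_hat[, others, drop = FALSE])
    s <- S_hat[, nm]
    alpha <- sum(R %*% s) / (I * sum(s^2))
    if (cs$nonneg_C) alpha <- max(alpha, 0)
    C[, nm] <- alpha
  }

  ## 3) re-solve the remaining free components against the deflated data,
  ##    with non-negativity if requested
  if (length(free) && length(free) < n) {
    R <- X - C[, c(fixed, scal), drop = FALSE] %*%
      t(S_hat[, c(fixed, scal), drop = FALSE])
    A <- S_hat[, free, drop = FALSE]
    Cf <- if (cs$nonneg_C) t(nnls_cols(A, t(R))) else R %*% t(pinv_svd(A, warn = FALSE))
    C[, free] <- Cf
  } else if (length(free) && cs$nonneg_C) {
    C[, free] <- t(nnls_cols(S_hat[, free, drop = FALSE], t(X)))
  }

  ## 4) closure
  if (!is.null(cs$closure)) {
    C <- apply_closure(C, cs$closure$components, cs$closure$constant)
  }
  C
}

#' Spectral (S-type) step of the alternating least squares
#'
#' Known spectra are returned unchanged; the unknown spectra are solved by
#' least squares from the deflated matrix `X - C1 S1^t` against the
#' concentration columns of the unknown components (`C2`), per wavenumber,
#' with non-negativity enforced as non-negative least squares when
#' requested.
#'
#' @param X Data matrix (samples x wavenumbers).
#' @param C_hat Current concentration matrix with component column names.
#' @param system A [component_system()] (supplies the known spectra).
#' @param cs A [constraint_spec()].
#' @return Spectra matrix `S_hat` (wavenumbers x components).
#' @export
s_step <- function(X, C_hat, system, cs = constraint_spec()) {
  X <- as.matrix(X)
  S <- system$spectra
  known <- system$known
  if (all(known)) return(S)
  C2 <- C_hat[, system$names[!known], drop = FALSE]
  if (any(colSums(C2^2) < 1e-300)) {
    bad <- system$names[!known][colSums(C2^2) < 1e-300]
    stop("unidentifiable component (all-zero concentrations): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Xd <- X
  if (any(known)) {
    C1 <- C_hat[, system$names[known], drop = FALSE]
    Xd <- X - C1 %*% t(S[, known, drop = FALSE])
  }
  ## X_defl = C2 S2^t: one small LS (or NNLS) problem per wavenumber
  S2 <- if (cs$nonneg_S) t(nnls_cols(C2, Xd)) else t(pinv_svd(C2) %*% Xd)
  S[, !known] <- S2
  S
}

#' Run soft MCR-ALS to convergence
#'
#' Alternates [c_step()] and [s_step()] until the relative change of the
#' lack of fit drops below `tol` or `max_iter` is reached. When every
#' spectrum in the system is known, the problem is linear and is solved in
#' a single C-step. Iterations that increase the lack of fit are rejected
#' (the best factors are kept); three consecutive rejections abort the run
#' with a warning.
#'
#' @param X Data matrix (samples x wavenumbers) or a spectral dataset tibble.
#' @param system A [component_system()]; unknown spectra must carry initial
#'   approximations.
#' @param cs A [constraint_spec()].
#' @param tol Relative lack-of-fit change per iteration below which the
#'   run is declared converged. The default follows standard curve-
#'   resolution practice: once an iteration improves the fit by less than
#'   this fraction, further iterations only fit noise, slowly sliding the
#'   factors along rotational-ambiguity directions. Runs that reach an
#'   essentially exact fit (LoF below 1e-10) stop immediately.
#' @param max_iter Iteration cap.
#' @return An object of class `mcr_fit`: concentrations `C_hat`, spectra
#'   `S_hat`, `lof_trace` (fractions, one per accepted iteration),
#'   `iterations`, `converged`, `residual_norm`.
#' @export
run_als <- function(X, system, cs = constraint_spec(), tol = 1e-3,
                    max_iter = 500) {
  if (is.data.frame(X)) {
    if (is.null(system$wavenumbers)) system$wavenumbers <- spectra_wavenumbers(X)
    X <- spectra_matrix(X)
  }
  stopifnot(inherits(system, "component_system"))
  if (!is.null(system$wavenumbers) && length(system$wavenumbers) != ncol(X)) {
    stop("data and component system are on different grids", call. = FALSE)
  }

  S <- system$spectra
  if (all(system$known)) {
    C <- c_step(X, S, cs)
    lof <- lack_of_fit(X, C, S)
    return(new_mcr_fit(C, S, lof_trace = lof, iterations = 1L,
                       converged = TRUE, X = X, system = system))
  }

  ## Closure fixes the concentration scale, so initial spectra supplied only
  ## up to scale must be calibrated first: rescale each unknown column so
  ## the unconstrained concentrations satisfy closure in the LS sense,
  ## otherwise the first closure projection distorts even an exact start.
  if (!is.null(cs$closure)) {
    cl <- match(cs$closure$components, system$names)
    unk <- intersect(which(!system$known), cl)
    if (length(unk)) {
      C0 <- X %*% t(pinv_svd(S, warn = FALSE))
      kn <- setdiff(cl, unk)
      target <- cs$closure$constant -
        if (length(kn)) rowSums(C0[, kn, drop = FALSE]) else 0
      g <- as.vector(pinv_svd(C0[, unk, drop = FALSE], warn = FALSE) %*% target)
      ok <- is.finite(g) & g > 0
      S[, unk[ok]] <- sweep(S[, unk[ok], drop = FALSE], 2, g[ok], "/")
    }
  }

  best <- NULL
  trace <- numeric(0)
  rejects <- 0L
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    C <- c_step(X, S, cs)
    S <- s_step(X, C, system, cs)
    lof <- lack_of_fit(X, C, S)
    if (is.null(best) || lof <= best$lof + 1e-10) {
      prev <- if (is.null(best)) Inf else best$lof
      best <- list(C = C, S = S, lof = lof)
      trace <- c(trace, min(lof, if (length(trace)) trace[length(trace)] else Inf))
      rejects <- 0L
      if (lof < 1e-10 ||
          (is.finite(prev) && abs(prev - lof) <= tol * max(prev, .Machine$double.eps))) {
        converged <- TRUE
        break
      }
    } else {
      rejects <- rejects + 1L
      if (rejects >= 3L) {
        warning("MCR-ALS diverging: lack of fit increased for 3 consecutive ",
                "iterations (best LoF ", signif(best$lof * 100, 4),
                "%); returning the best factors", call. = FALSE)
        break
      }
      ## restart the next iteration from the best spectra
      S <- best$S
    }
  }
  new_mcr_fit(best$C, best$S, lof_trace = trace, iterations = iter,
              converged = converged, X = X, system = system)
}

new_mcr_fit <- function(C, S, lof_trace, iterations, converged, X, system) {
  structure(
    list(
      C_hat = C, S_hat = S,
      lof_trace = lof_trace,
      lof = lof_trace[length(lof_trace)],
      iterations = iterations, converged = converged,
      residual_norm = norm(X - C %*% t(S), "F"),
      wavenumbers = system$wavenumbers,
      known = system$known, components = system$names,
      n_samples = nrow(C)
    ),
    class = "mcr_fit"
  )
}

#' @export
print.mcr_fit <- function(x, ...) {
  cat("<mcr_fit> ", x$n_samples, " samples, ",
      length(x$components), " components (",
      paste(x$components, collapse = ", "), ")\n", sep = "")
  cat("  LoF ", signif(x$lof * 100, 4), "% after ", x$iterations,
      " iteration(s); converged: ", x$converged, "\n", sep = "")
  invisible(x)
}
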