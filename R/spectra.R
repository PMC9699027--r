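#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Spectral datasets are plain tibbles in wide form: a block of metadata
## columns followed by one numeric column per wavenumber (column name = the
## wavenumber in cm^-1). Keeping them as ordinary tibbles means dplyr verbs
## work on them directly; the helpers below extract the two views (metadata
## table, absorbance matrix) that the numerical code needs.

META_COLS <- c("sample_id", "material_kind", "age_months", "batch", "replicate")
MATERIAL_KINDS <- c("tablet", "substance", "pure_component")

#' Assemble a spectral dataset tibble
#'
#' Binds a per-sample metadata table to an absorbance matrix, producing the
#' wide tibble layout used throughout the package: metadata columns
#' (`sample_id`, `material_kind`, `age_months`, `batch`, `replicate`) followed
#' by one column per wavenumber. Wavenumbers are stored in ascending order;
#' if `wavenumbers` is supplied descending (the instrument display
#' convention), columns are permuted consistently.
#'
#' @param meta Data frame with one row per spectrum. Must contain `sample_id`;
#'   missing metadata columns are filled with defaults (`material_kind`
#'   "substance", `age_months` 0, `batch` "B1", `replicate` 1).
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1 (strictly
#'   monotone).
#' @param absorbance Numeric matrix, `nrow(meta)` rows by
#'   `length(wavenumbers)` columns.
#' @return A tibble with `nrow(meta)` rows.
#' @export
#' @examples
#' ds <- spectra_tbl(
#'   data.frame(sample_id = c("a", "b")),
#'   wavenumbers = c(4000, 4500, 5000),
#'   absorbance = matrix(runif(6), nrow = 2)
#' )
spectra_tbl <- function(meta, wavenumbers, absorbance) {
  meta <- tibble::as_tibble(meta)
  if (!"sample_id" %in% names(meta)) {
    stop("`meta` must contain a `sample_id` column", call. = FALSE)
  }
  if (!"material_kind" %in% names(meta)) meta$material_kind <- "substance"
  if (!"age_months" %in% names(meta)) meta$age_months <- 0
  if (!"batch" %in% names(meta)) meta$batch <- "B1"
  meta <- meta[intersect(META_COLS, names(meta))]

  absorbance <- as.matrix(absorbance)
  wavenumbers <- as.numeric(wavenumbers)
  if (nrow(absorbance) != nrow(meta)) {
    stop("absorbance has ", nrow(absorbance), " rows but metadata has ",
         nrow(meta), call. = FALSE)
  }
  if (ncol(absorbance) != length(wavenumbers)) {
    stop("absorbance has ", ncol(absorbance), " columns but ",
         length(wavenumbers), " wavenumbers were given", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("wavenumbers must be strictly monotone", call. = FALSE)
  }
  if (length(d) && all(d < 0)) {
    ord <- rev(seq_along(wavenumbers))
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[, ord, drop = FALSE]
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("absorbance contains missing or non-finite values", call. = FALSE)
  }
  bad <- setdiff(unique(meta$material_kind), MATERIAL_KINDS)
  if (length(bad)) {
    stop("unknown material_kind: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  colnames(absorbance) <- format_wn(wavenumbers)
  dplyr::bind_cols(meta, tibble::as_tibble(absorbance))
}

format_wn <- function(wn) {
  formatC(wn, format = "fg", digits = 12, flag = "")
}

spectral_col_idx <- function(ds) {
  suppressWarnings(v <- as.numeric(names(ds)))
  which(is.finite(v))
}

#' Wavenumber grid of a spectral dataset
#'
#' @param ds Spectral dataset tibble (see [spectra_tbl()]).
#' @return Ascending numeric vector of wavenumbers in cm^-1.
#' @export
spectra_wavenumbers <- function(ds) {
  idx <- spectral_col_idx(ds)
  if (!length(idx)) stop("no spectral columns found", call. = FALSE)
  as.numeric(names(ds)[idx])
}

#' Absorbance matrix of a spectral dataset
#'
#' @inheritParams spectra_wavenumbers
#' @return Numeric matrix, samples by wavenumbers (ascending).
#' @export
spectra_matrix <- function(ds) {
  idx <- spectral_col_idx(ds)
  m <- as.matrix(ds[idx])
  rownames(m) <- if ("sample_id" %in% names(ds)) ds$sample_id else NULL
  m
}

#' Metadata block of a spectral dataset
#'
#' @inheritParams spectra_wavenumbers
#' @return Tibble of the metadata columns only.
#' @export
spectra_meta <- function(ds) {
  ds[setdiff(seq_along(ds), spectral_col_idx(ds))]
}

replace_matrix <- function(ds, m) {
  idx <- spectral_col_idx(ds)
  stopifnot(ncol(m) == length(idx))
  ds[idx] <- tibble::as_tibble(m, .name_repair = "minimal")
  ds
}

#' Read a spectral dataset from delimited text
#'
#' Expects one wide table per file: metadata columns first (`sample_id` is
#' required; `material_kind`, `age_months`, `batch`, `replicate` optional),
#' then one column per wavenumber with the wavenumber as header. The
#' delimiter is auto-detected from the extension (`.csv` comma, `.tsv`/`.txt`
#' tab). Wavenumbers are re-sorted ascending with columns permuted
#' consistently.
#'
#' @param path Path to a CSV/TSV file.
#' @return A validated spectral dataset tibble.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("malformed spectra file ", path, ": row ", probs$row[1],
         " (expected ", probs$expected[1], ", got ", probs$actual[1], ")",
         call. = FALSE)
  }
  if (!"sample_id" %in% names(raw)) {
    stop("malformed header in ", path, ": no `sample_id` column", call. = FALSE)
  }
  suppressWarnings(wn_ok <- is.finite(as.numeric(names(raw))))
  spectral <- which(wn_ok)
  meta_cols <- setdiff(names(raw)[!wn_ok], META_COLS)
  if (length(meta_cols)) {
    stop("malformed header in ", path, ": column(s) ",
         paste(meta_cols, collapse = ", "),
         " are neither known metadata nor numeric wavenumbers", call. = FALSE)
  }
  if (!length(spectral)) stop("no wavenumber columns in ", path, call. = FALSE)
  m <- as.matrix(raw[spectral])
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("missing absorbance values in ", path, " (data row ", bad, ")",
         call. = FALSE)
  }
  spectra_tbl(raw[!wn_ok], as.numeric(names(raw)[spectral]), m)
}

#' Write a spectral dataset to delimited text
#'
#' Inverse of [read_spectra()]; the delimiter follows the file extension.
#'
#' @inheritParams spectra_wavenumbers
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(ds, path, delim = delim)
  invisible(path)
}

#' Restrict a dataset to a wavenumber range
#'
#' Keeps the columns whose wavenumber lies in the closed interval
#' `[lo, hi]`; sample metadata is unchanged. The informative range for the
#' aging analysis is 9000-4000 cm^-1.
#'
#' @inheritParams spectra_wavenumbers
#' @param lo,hi Range bounds in cm^-1, `lo < hi`.
#' @return Spectral dataset tibble on the restricted grid.
#' @export
select_range <- function(ds, lo, hi) {
  if (!(lo < hi)) stop("`lo` must be strictly less than `hi`", call. = FALSE)
  wn <- spectra_wavenumbers(ds)
  keep <- wn >= lo & wn <= hi
  if (!any(keep)) stop("no wavenumbers in [", lo, ", ", hi, "]", call. = FALSE)
  spectra_tbl(spectra_meta(ds), wn[keep], spectra_matrix(ds)[, keep, drop = FALSE])
}

#' Average replicate spectra
#'
#' Collapses replicate measurements of the same object (grouped by
#' `sample_id`) to their arithmetic mean, one row per sample. Replicates of
#' one sample must agree on all other metadata.
#'
#' @inheritParams spectra_wavenumbers
#' @return Spectral dataset tibble with one row per distinct `sample_id` and
#'   no `replicate` column.
#' @export
average_replicates <- function(ds) {
  meta <- spectra_meta(ds)
  chk <- meta |>
    dplyr::select(-dplyr::any_of("replicate")) |>
    dplyr::distinct()
  if (anyDuplicated(chk$sample_id)) {
    bad <- chk$sample_id[duplicated(chk$sample_id)][1]
    stop("replicates of sample ", bad, " disagree on metadata", call. = FALSE)
  }
  ids <- unique(meta$sample_id)
  m <- spectra_matrix(ds)
  avg <- t(vapply(ids, function(id) colMeans(m[meta$sample_id == id, , drop = FALSE]),
                  numeric(ncol(m))))
  meta_out <- chk[match(ids, chk$sample_id), ]
  spectra_tbl(meta_out, spectra_wavenumbers(ds), avg)
}

#' Baseline-correct spectra
#'
#' @inheritParams spectra_wavenumbers
#' @param method `"offset"` subtracts each spectrum's minimum over the
#'   retained range (default; exactly inverts an additive per-spectrum
#'   offset when the underlying spectrum touches zero); `"linear"` subtracts
#'   the straight line through the spectrum's values at the two range
#'   endpoints; `"none"` returns the input unchanged.
#' @return Spectral dataset tibble of the same shape.
#' @export
baseline_correct <- function(ds, method = c("offset", "linear", "none")) {
  method <- match.arg(method)
  if (method == "none") return(ds)
  m <- spectra_matrix(ds)
  wn <- spectra_wavenumbers(ds)
  if (method == "offset") {
    m <- m - apply(m, 1, min)
  } else {
    j <- ncol(m)
    slope <- (m[, j] - m[, 1]) / (wn[j] - wn[1])
    base <- outer(m[, 1], rep(1, j)) + outer(slope, wn - wn[1])
    m <- m - base
  }
  replace_matrix(ds, m)
}

#' Interpolate spectra onto a new wavenumber grid
#'
#' Linear interpolation, used to put pure-component spectra measured on a
#' different grid onto the dataset grid (a shared grid is required by the
#' known-spectrum constraint of the curve-resolution step).
#'
#' @inheritParams spectra_wavenumbers
#' @param wavenumbers Target grid (must lie within the source grid).
#' @return Spectral dataset tibble on the target grid.
#' @export
resample_spectra <- function(ds, wavenumbers) {
  wn <- spectra_wavenumbers(ds)
  if (min(wavenumbers) < min(wn) || max(wavenumbers) > max(wn)) {
    stop("target grid extends beyond the source grid", call. = FALSE)
  }
  m <- spectra_matrix(ds)
  out <- t(apply(m, 1, function(x) stats::approx(wn, x, xout = wavenumbers)$y))
  spectra_tbl(spectra_meta(ds), wavenumbers, out)
}
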