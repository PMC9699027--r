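test_that("write/read round-trips values and metadata", {
  ds <- tiny_spectra()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  back <- read_spectra(path)
  expect_equal(spectra_matrix(back), spectra_matrix(ds), tolerance = 1e-12)
  expect_identical(spectra_meta(back)$sample_id, spectra_meta(ds)$sample_id)
  expect_equal(spectra_meta(back)$age_months, spectra_meta(ds)$age_months)
  expect_equal(spectra_wavenumbers(back), spectra_wavenumbers(ds))
})

test_that("descending wavenumber input is stored ascending, consistently", {
  m <- matrix(1:10, nrow = 2, byrow = TRUE)
  ds <- spectra_tbl(tibble::tibble(sample_id = c("a", "b")),
                    c(6000, 5500, 5000, 4500, 4000), m)
  expect_equal(spectra_wavenumbers(ds), c(4000, 4500, 5000, 5500, 6000))
  expect_equal(unname(spectra_matrix(ds)[1, ]), rev(1:5))
})

test_that("malformed files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,4000,4100", "a,1.0,2.0", "b,1.5"), path)
  expect_error(suppressWarnings(read_spectra(path)), "malformed|missing")
  writeLines(c("sample_id,flux,4100", "a,1.0,2.0"), path)
  expect_error(read_spectra(path), "flux")
  expect_error(read_spectra("no/such/file.csv"), "not found")
  expect_error(spectra_tbl(tibble::tibble(sample_id = "a"),
                           c(4000, 4100), matrix(c(1, NA), 1)),
               "missing")
})

test_that("select_range keeps the closed interval and validates bounds", {
  wn <- seq(4000, 9000, by = 2)
  ds <- spectra_tbl(tibble::tibble(sample_id = "a"), wn,
                    matrix(seq_along(wn), 1))
  expect_equal(ncol(spectra_matrix(select_range(ds, 4000, 9000))), 2501)
  ds2 <- spectra_tbl(tibble::tibble(sample_id = "a"),
                     c(3998, 4000, 9000, 9002), matrix(1:4, 1))
  expect_equal(spectra_wavenumbers(select_range(ds2, 4000, 9000)),
               c(4000, 9000))
  expect_error(select_range(ds, 9000, 4000), "less than")
  expect_error(select_range(ds2, 1000, 2000), "no wavenumbers")
  once <- select_range(ds, 4500, 8000)
  expect_identical(select_range(once, 4500, 8000), once)
})

test_that("average_replicates means within sample_id and checks metadata", {
  wn <- c(4000, 5000)
  meta <- tibble::tibble(sample_id = c("a", "a", "a", "b"),
                         material_kind = "substance",
                         age_months = c(3, 3, 3, 9), batch = "B1",
                         replicate = c(1L, 2L, 3L, 1L))
  m <- rbind(c(0, 1), c(2, 1), c(1, 1), c(5, 5))
  avg <- average_replicates(spectra_tbl(meta, wn, m))
  expect_equal(nrow(avg), 2)
  expect_equal(unname(spectra_matrix(avg)["a", ]), c(1, 1))
  expect_false("replicate" %in% names(avg))

  meta_bad <- meta
  meta_bad$age_months <- c(9, 10, 9, 9)
  expect_error(average_replicates(spectra_tbl(meta_bad, wn, m)), "disagree")
})

test_that("baseline correction behaves per method", {
  wn <- seq(4000, 9000, by = 10)
  bump <- exp(-(wn - 6500)^2 / (2 * 100^2))  # zero at both ends
  ds <- spectra_tbl(tibble::tibble(sample_id = "a"), wn,
                    matrix(bump + 0.5, 1))
  expect_equal(unname(spectra_matrix(baseline_correct(ds, "offset"))[1, ]),
               bump, tolerance = 1e-12)
  expect_identical(baseline_correct(ds, "none"), ds)
  ramp <- 0.2 + 3e-5 * wn
  ds2 <- spectra_tbl(tibble::tibble(sample_id = "a"), wn,
                     matrix(bump + ramp, 1))
  expect_equal(unname(spectra_matrix(baseline_correct(ds2, "linear"))[1, ]),
               bump, tolerance = 1e-10)
  expect_error(baseline_correct(ds, "spliney"))
})

test_that("resampling interpolates linearly onto a coarser grid", {
  wn <- seq(4000, 5000, by = 10)
  ds <- spectra_tbl(tibble::tibble(sample_id = "a"), wn,
                    matrix(2 * wn + 1, 1))
  target <- seq(4005, 4995, by = 10)
  rs <- resample_spectra(ds, target)
  expect_equal(unname(spectra_matrix(rs)[1, ]), 2 * target + 1,
               tolerance = 1e-9)
  expect_error(resample_spectra(ds, c(3000, 4500)), "beyond")
})
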