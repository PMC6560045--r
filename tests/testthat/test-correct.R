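make_vlms <- function(mz, w = 2e-3) {  # wide windows for hand-built examples
  # minimal hand-built vlm_set for correction tests
  structure(list(mz = mz, members = NULL, w = w, mode = "vlm"),
            class = "vlm_set")
}

test_that("two-point interpolation reproduces the hand calculation", {
  vlms <- make_vlms(c(100, 200))
  s <- ms_spectrum(c(99.9, 149.9, 199.9), c(1, 2, 3), id = "x")
  out <- correct_spectrum(s, vlms)
  # a = (200 - 100) / (199.9 - 99.9) = 1, b = 0.1
  expect_equal(out$mz, c(100.0, 150.0, 200.0))
  expect_equal(out$intensity, c(1, 2, 3))
})

test_that("matched peaks already on their lock masses give the identity", {
  vlms <- make_vlms(c(100, 200, 300))
  s <- ms_spectrum(c(100, 150, 200, 250, 300), rep(1, 5), id = "x")
  out <- correct_spectrum(s, vlms)
  expect_identical(out$mz, s$mz)
})

test_that("trim removes peaks outside the outermost matched VLMs", {
  vlms <- make_vlms(c(100, 200))
  s <- ms_spectrum(c(95, 100, 150, 200, 210), rep(1, 5), id = "x")
  trimmed <- correct_spectrum(s, vlms, trim = TRUE)
  expect_equal(trimmed$mz, c(100, 150, 200))
  expect_equal(trimmed$source_index, 2:4)
  kept <- correct_spectrum(s, vlms, trim = FALSE)
  expect_equal(length(kept), 5L)
  expect_equal(kept$mz[c(1, 5)], c(95, 210))  # passed through unmodified
  expect_equal(kept$corrected, c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("unmatched VLMs are bridged over; fewer than 2 matches aborts", {
  vlms <- make_vlms(c(100, 200, 300))
  # no peak near 200: interpolation bridges 100 -> 300
  s <- ms_spectrum(c(99.9, 199.5, 299.7), rep(1, 3), id = "x")
  mt <- match_vlm_peaks(s, vlms)
  expect_equal(mt$alpha, c(1L, NA, 3L))
  expect_equal(mt$n_matched, 2L)
  out <- correct_spectrum(s, vlms)
  expect_equal(out$mz[c(1, 3)], c(100, 300))
  # two peaks inside one window: ambiguous, unmatched
  s2 <- ms_spectrum(c(99.999, 100.001, 200, 300), rep(1, 4), id = "y")
  expect_true(is.na(match_vlm_peaks(s2, vlms)$alpha[1]))
  # a spectrum matching fewer than 2 VLMs cannot be corrected
  s3 <- ms_spectrum(c(100, 500), c(1, 1), id = "z")
  expect_error(correct_spectrum(s3, vlms), "uncorrectable")
})

test_that("correcting a detection set lands member peaks exactly on v_i", {
  sim <- generate_spectra(synthetic_config(m = 8, K_common = 20,
                                           K_variable = 5,
                                           K_noise_per_spectrum = 5),
                          seed = 3)
  vlms <- detect_vlms(sim$spectra, detection_params(w_ppm = 40))
  expect_gte(length(vlms$mz), 3L)
  co <- correct_set(sim$spectra, vlms)
  expect_true(all(co$report$corrected))
  for (i in seq_along(vlms$mz)) {
    mem <- vlms$members[[i]]
    for (k in seq_len(nrow(mem))) {
      sp <- co$spectra[[mem$id[k]]]
      # the member peak, traced by source index, sits exactly on v_i
      j <- match(mem$peak[k], sp$source_index)
      expect_identical(sp$mz[j], vlms$mz[i])
    }
  }
  # intensities of surviving peaks are a conserved multiset
  for (id in names(co$spectra)) {
    orig <- sim$spectra[[id]]
    kept <- co$spectra[[id]]
    expect_identical(sort(kept$intensity),
                     sort(orig$intensity[kept$source_index]))
  }
})

test_that("re-detection and re-correction of a corrected set is the identity", {
  sim <- generate_spectra(synthetic_config(m = 6, K_common = 15,
                                           K_variable = 0,
                                           K_noise_per_spectrum = 3),
                          seed = 9)
  p <- detection_params(w_ppm = 40)
  vlms <- detect_vlms(sim$spectra, p)
  co <- correct_set(sim$spectra, vlms)$spectra
  vlms2 <- detect_vlms(co, p)
  expect_equal(length(vlms2$mz), length(vlms$mz))
  expect_equal(vlms2$mz, vlms$mz, tolerance = 1e-12)
  # zero within-group spread after correction
  spread <- vapply(vlms2$members, function(mm) diff(range(mm$mz)), numeric(1))
  expect_equal(spread, rep(0, length(spread)))
  co2 <- correct_set(co, vlms2)$spectra
  for (id in names(co)) {
    expect_equal(co2[[id]]$mz, co[[id]]$mz, tolerance = 1e-12)
    expect_identical(co2[[id]]$intensity, co[[id]]$intensity)
  }
})

test_that("correction slopes are positive and preserve peak order", {
  sim <- generate_spectra(synthetic_config(m = 5, K_common = 12,
                                           K_noise_per_spectrum = 10),
                          seed = 13)
  vlms <- detect_vlms(sim$spectra, detection_params(w_ppm = 40))
  co <- correct_set(sim$spectra, vlms)$spectra
  for (id in names(co)) {
    expect_false(is.unsorted(co[[id]]$mz))
    expect_false(is.unsorted(co[[id]]$source_index))
  }
})

test_that("correction_rmse matches its closed form and validates input", {
  a <- spectra_set(list(ms_spectrum(c(100, 200, 300, 400), rep(1, 4), id = "s")))
  expect_equal(correction_rmse(a, a), 0)
  # one of four peaks off by exactly 1 ppm: RMSE = sqrt(1/4)
  b <- spectra_set(list(ms_spectrum(c(100 * (1 + 1e-6), 200, 300, 400),
                                    rep(1, 4), id = "s")))
  expect_equal(correction_rmse(b, a), 0.5, tolerance = 1e-9)
  short <- spectra_set(list(ms_spectrum(c(100, 200), c(1, 1), id = "s")))
  expect_error(correction_rmse(short, a), "mismatch")
  # source-based matching pairs the shared peaks only
  short2 <- spectra_set(list(ms_spectrum(c(100, 200), c(1, 1), id = "s",
                                         source_index = c(1L, 2L))))
  expect_equal(correction_rmse(short2, a, match_by = "source"), 0)
})
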