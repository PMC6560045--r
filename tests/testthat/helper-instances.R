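# Fixture builders used across the suite. Everything is generated in code;
# instances emulate centroided spectra: compound masses shared across
# spectra with small relative jitter, plus sparse spurious peaks.

# m identical spectra with peaks at 'masses'
identical_set <- function(masses, m = 3, intensity = 5000) {
  spectra_set(lapply(seq_len(m), function(i) {
    ms_spectrum(masses, rep(intensity, length(masses)), id = paste0("s", i))
  }))
}

# Small random instance in the method's operating regime: shared compound
# masses with jitter well below the window half-width, compounds present
# with high probability, plus a few noise peaks.
random_instance <- function(seed, m = NULL, n_compounds = 8, p_present = 0.8,
                            n_noise = 4, jitter = 1e-5, lo = 100, hi = 1000) {
  set.seed(seed)
  if (is.null(m)) m <- sample(2:5, 1)
  masses <- sort(runif(n_compounds, lo, hi))
  spectra_set(lapply(seq_len(m), function(i) {
    pres <- runif(n_compounds) < p_present
    mz <- c(masses[pres] * (1 + runif(sum(pres), -jitter, jitter)),
            runif(n_noise, lo, hi))
    ms_spectrum(sort(mz), rlnorm(length(mz), log(5e4), 1),
                id = paste0("s", i))
  }))
}

# Set-level equality of two vlm_set objects: same values (relative 1e-12)
# and the same member peaks.
expect_same_vlms <- function(a, b) {
  expect_equal(length(a$mz), length(b$mz))
  if (length(a$mz)) {
    expect_true(all(abs(a$mz - b$mz) <= 1e-12 * b$mz))
    for (i in seq_along(a$mz)) {
      expect_identical(a$members[[i]]$spectrum, b$members[[i]]$spectrum)
      expect_identical(a$members[[i]]$peak, b$members[[i]]$peak)
    }
  }
}

# RMSE (ppm) of compound peaks against their planted true masses,
# traced through source_index so it also applies to corrected spectra.
rmse_to_truth <- function(spectra, sim, common_only = TRUE) {
  truth <- sim$truth
  ids <- names(sim$spectra)
  ss <- 0; n <- 0L
  for (s in seq_along(ids)) {
    sp <- spectra[[ids[s]]]
    if (is.null(sp)) next
    org <- truth$origin[[s]][sp$source_index]
    keep <- org > 0L
    if (common_only) keep <- keep & truth$is_common[pmax(org, 1L)]
    if (!any(keep)) next
    d <- 1e6 * (sp$mz[keep] - truth$true_masses[org[keep]]) /
      truth$true_masses[org[keep]]
    ss <- ss + sum(d^2); n <- n + sum(keep)
  }
  sqrt(ss / n)
}
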