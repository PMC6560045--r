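## Synthetic centroided spectra with planted ground truth.
##
## Emulates a batch of spectra of samples of the same nature (e.g. pooled
## plasma): a set of compound masses shared by every spectrum, further
## compounds present in only some samples, and spurious noise peaks. Each
## spectrum sigma carries a multiplicative mass drift (1 + eps_sigma) --
## the scale error piecewise-linear lock-mass correction removes -- and
## each peak an independent multiplicative jitter (1 + eta). Jitter is
## uniform by default so worst-case deviations are bounded and recovery
## bounds are assertable. Intensities are log-normal. Only the mass axis is
## modelled: no isotope patterns, adducts or intensity drift.

#' Configuration for the synthetic spectra generator
#'
#' @param m number of spectra (default 50).
#' @param K_common compounds present in every spectrum (default 100).
#' @param K_variable compounds present in each spectrum independently with
#'   probability `p_variable` (default 30).
#' @param p_variable presence probability of variable compounds (default
#'   0.5).
#' @param K_noise_per_spectrum spurious peaks per spectrum, uniform over the
#'   mass range (default 20).
#' @param mass_range m/z range in thomson (default `c(50, 1000)`).
#' @param min_separation_ppm minimum relative separation between planted
#'   masses, ppm (default 200).
#' @param drift_ppm per-spectrum multiplicative drift magnitude, ppm;
#'   `eps_sigma` is uniform in +/- this (default 10).
#' @param jitter_ppm per-peak mass jitter magnitude, ppm; uniform in +/-
#'   this by default (default 5).
#' @param jitter_dist `"uniform"` (bounded; default) or `"gaussian"` (the
#'   ppm value is then the standard deviation).
#' @param intensity_logmean,intensity_logsd log-normal intensity parameters
#'   (defaults `log(5e4)` and 0.8, a bright centroid population for which
#'   counts below the usual detection threshold of 1000 are rare).
#' @param sub_ta_fraction fraction of common compounds forced below the
#'   intensity threshold `t_a_ref` in one random spectrum (default 0).
#' @param t_a_ref reference lower intensity threshold used by
#'   `sub_ta_fraction` (default 1000 counts).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(m = 50, K_common = 100, K_variable = 30,
                             p_variable = 0.5, K_noise_per_spectrum = 20,
                             mass_range = c(50, 1000),
                             min_separation_ppm = 200,
                             drift_ppm = 10, jitter_ppm = 5,
                             jitter_dist = c("uniform", "gaussian"),
                             intensity_logmean = log(5e4),
                             intensity_logsd = 0.8,
                             sub_ta_fraction = 0, t_a_ref = 1000) {
  jitter_dist <- match.arg(jitter_dist)
  stopifnot(m >= 1, K_common >= 0, K_variable >= 0,
            K_noise_per_spectrum >= 0, length(mass_range) == 2L,
            mass_range[1] > 0, mass_range[2] > mass_range[1],
            min_separation_ppm > 0, drift_ppm >= 0, jitter_ppm >= 0,
            sub_ta_fraction >= 0, sub_ta_fraction <= 1)
  structure(list(m = as.integer(m), K_common = as.integer(K_common),
                 K_variable = as.integer(K_variable),
                 p_variable = p_variable,
                 K_noise_per_spectrum = as.integer(K_noise_per_spectrum),
                 mass_range = mass_range,
                 min_separation = ppm_to_frac(min_separation_ppm),
                 drift = ppm_to_frac(drift_ppm),
                 jitter = ppm_to_frac(jitter_ppm),
                 jitter_dist = jitter_dist,
                 intensity_logmean = intensity_logmean,
                 intensity_logsd = intensity_logsd,
                 sub_ta_fraction = sub_ta_fraction, t_a_ref = t_a_ref),
            class = "synthetic_config")
}

## Draw K masses in [lo, hi] with pairwise relative separation >= min_sep:
## sorted uniform draws, with too-small gaps pushed forward to the minimum
## separation. Errors when the range cannot hold K masses that far apart.
draw_masses <- function(K, lo, hi, min_sep) {
  if (K == 0L) return(numeric(0))
  mass <- sort(runif(K, lo, hi))
  if (K > 1L) {
    for (i in 2:K) {
      floor_i <- mass[i - 1L] * (1 + min_sep)
      if (mass[i] < floor_i) mass[i] <- floor_i
    }
  }
  if (mass[K] > hi) {
    stop("could not place ", K, " masses in [", lo, ", ", hi,
         "] with relative separation ", min_sep)
  }
  mass
}

#' Generate a synthetic spectra set with known ground truth
#'
#' Observed m/z values are `mass * (1 + eps_sigma) * (1 + eta)` with
#' per-spectrum drift `eps_sigma` uniform in the drift magnitude and
#' per-peak jitter `eta` from the configured jitter distribution.
#' Intensities are log-normal; noise peaks are uniform over the range.
#' Fully reproducible from `seed`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer RNG seed.
#' @return a list with `spectra` (a [spectra_set()]) and `truth`, a list of
#'   `true_masses` (sorted, common compounds flagged in `is_common`),
#'   `presence` (compound x spectrum logical matrix), `drift` (eps_sigma),
#'   and `origin` (per spectrum, the compound index of each peak, 0 for
#'   noise).
#' @export
generate_spectra <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  K <- config$K_common + config$K_variable
  mass <- draw_masses(K, config$mass_range[1], config$mass_range[2],
                      config$min_separation)
  # random assignment of which planted masses are the common ones
  is_common <- rep(FALSE, K)
  if (K > 0L) is_common[sample.int(K, config$K_common)] <- TRUE

  m <- config$m
  presence <- matrix(TRUE, nrow = K, ncol = m)
  if (config$K_variable > 0L) {
    varr <- which(!is_common)
    presence[varr, ] <- matrix(
      rbinom(length(varr) * m, 1L, config$p_variable) == 1L,
      nrow = length(varr))
  }
  drift <- runif(m, -config$drift, config$drift)

  jitter_fun <- switch(config$jitter_dist,
    uniform = function(n) runif(n, -config$jitter, config$jitter),
    gaussian = function(n) stats::rnorm(n, 0, config$jitter))

  # compounds forced under the intensity threshold in one spectrum each
  weak <- integer(0)
  weak_spec <- integer(0)
  if (config$sub_ta_fraction > 0 && config$K_common > 0L) {
    common_idx <- which(is_common)
    n_weak <- floor(config$sub_ta_fraction * length(common_idx))
    weak <- sample(common_idx, n_weak)
    weak_spec <- sample.int(m, n_weak, replace = TRUE)
  }

  spectra <- vector("list", m)
  origin <- vector("list", m)
  for (s in seq_len(m)) {
    comp <- which(presence[, s])
    mz_comp <- mass[comp] * (1 + drift[s]) * (1 + jitter_fun(length(comp)))
    it_comp <- rlnorm(length(comp), config$intensity_logmean,
                      config$intensity_logsd)
    hit <- weak_spec == s
    if (any(hit)) {
      rows <- match(weak[hit], comp)
      it_comp[rows] <- config$t_a_ref * runif(sum(hit), 0.1, 0.9)
    }
    nn <- config$K_noise_per_spectrum
    mz_noise <- runif(nn, config$mass_range[1], config$mass_range[2])
    it_noise <- rlnorm(nn, config$intensity_logmean, config$intensity_logsd)
    mz_all <- c(mz_comp, mz_noise)
    it_all <- c(it_comp, it_noise)
    org <- c(comp, integer(nn))
    o <- order(mz_all)
    spectra[[s]] <- ms_spectrum(mz_all[o], it_all[o],
                                id = sprintf("S%03d", s))
    origin[[s]] <- org[o]
  }
  list(spectra = spectra_set(spectra),
       truth = list(true_masses = mass, is_common = is_common,
                    presence = presence, drift = drift, origin = origin,
                    config = config, seed = seed))
}

#' Score recovery of planted masses
#'
#' Matches each detected m/z value to the nearest true mass; a detection is
#' a hit when the relative distance is within `tol_ppm`. Recall is the
#' fraction of target masses hit; precision the fraction of detections that
#' are hits.
#'
#' @param detected numeric vector of detected m/z values (VLMs or alignment
#'   points), or a `vlm_set`.
#' @param truth the `truth` component of [generate_spectra()].
#' @param tol_ppm matching tolerance in ppm (default 15, the drift + jitter
#'   budget of the default configuration).
#' @param targets which planted masses count for recall: `"common"` (those
#'   present in every spectrum; default) or `"all"`.
#' @return a list with `recall`, `precision`, `n_hit`, `n_detected`,
#'   `n_target`, and `errors_ppm` (signed error of each hit).
#' @export
score_recovery <- function(detected, truth, tol_ppm = 15,
                           targets = c("common", "all")) {
  targets <- match.arg(targets)
  if (inherits(detected, "vlm_set")) detected <- detected$mz
  mass <- truth$true_masses
  target_idx <- if (targets == "common") which(truth$is_common) else
    seq_along(mass)
  tol <- ppm_to_frac(tol_ppm)
  nearest <- vapply(detected, function(v) which.min(abs(mass - v)),
                    integer(1))
  err <- (detected - mass[nearest]) / mass[nearest]
  hit <- abs(err) <= tol
  recalled <- intersect(unique(nearest[hit]), target_idx)
  list(recall = if (length(target_idx)) length(recalled) / length(target_idx)
       else NA_real_,
       precision = if (length(detected)) mean(hit) else NA_real_,
       n_hit = sum(hit), n_detected = length(detected),
       n_target = length(target_idx),
       errors_ppm = frac_to_ppm(err[hit]))
}
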