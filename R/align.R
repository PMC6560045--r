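## From lock-mass correction to spectra alignment.
##
## After correction, peaks of a VLM sit exactly on their v_i, but other
## peaks of the same compound spread over a small window. The alignment
## window theta is chosen from leave-one-out deviations: leaving VLM v_i out
## of the correction and correcting its member peaks with the remaining
## VLMs, theta_i is the largest relative deviation from v_i. The 95th
## percentile (nearest rank) of the interior theta_i is the default theta.
## Alignment points are then detected with the same sweep, relaxed to
## groups of 1..m peaks and without intensity bounds, and each corrected
## spectrum becomes a feature vector of intensities over the points.

#' Leave-one-VLM-out deviations
#'
#' For each interior VLM `v_i` (the outermost two are excluded, having only
#' one neighbour each), all spectra are corrected with the VLM set minus
#' `v_i`; only the two segments adjacent to `v_i` change, so each deviation
#' is found in O(m): the member peak of `v_i` in spectrum sigma is mapped by
#' the bridging segment between `v_(i-1)` and `v_(i+1)`, and
#' `theta_i = max_sigma |mz' - v_i| / v_i`.
#'
#' @param spectra the [spectra_set()] the VLMs were detected on.
#' @param vlms a `vlm_set` with at least 3 VLMs.
#' @param w window half-width (fraction); defaults to the set's `w`.
#' @return numeric vector of `theta_i` (length r - 2), named by VLM m/z.
#' @export
loo_theta <- function(spectra, vlms, w = vlms$w) {
  v <- vlms$mz
  r <- length(v)
  if (r < 3L) stop("leave-one-out deviations require at least 3 VLMs")
  m <- attr(spectra, "m")
  M <- matrix(NA_real_, nrow = m, ncol = r)  # matched peak m/z per spectrum
  for (s in seq_len(m)) {
    mt <- match_vlm_peaks(spectra[[s]], vlms, w)
    if (anyNA(mt$alpha)) {
      stop("spectrum '", spectra[[s]]$id,
           "' does not match every VLM; deviations are defined on the detection set")
    }
    M[s, ] <- spectra[[s]]$mz[mt$alpha]
  }
  idx <- 2:(r - 1L)
  thetas <- vapply(idx, function(i) {
    a <- (v[i + 1L] - v[i - 1L]) / (M[, i + 1L] - M[, i - 1L])
    b <- v[i - 1L] - a * M[, i - 1L]
    corr <- a * M[, i] + b
    max(abs(corr - v[i])) / v[i]
  }, numeric(1))
  names(thetas) <- format(v[idx])
  thetas
}

#' Select the alignment window from leave-one-out deviations
#'
#' Nearest-rank upper percentile: the k-th smallest deviation with
#' `k = ceiling(z/100 * length(thetas))`, i.e. the smallest value covering
#' z% of the entries. The default z = 95 trades a slightly smaller window
#' against covering every VLM (z = 100, the maximum, is an overestimate
#' but available).
#'
#' @param thetas deviations from [loo_theta()].
#' @param percentile z in (0, 100].
#' @return the selected window half-width (fraction).
#' @export
select_theta <- function(thetas, percentile = 95) {
  if (!length(thetas)) stop("'thetas' must be non-empty")
  if (percentile <= 0 || percentile > 100) {
    stop("'percentile' must be in (0, 100]")
  }
  k <- ceiling(percentile / 100 * length(thetas))
  sort(thetas)[[k]]
}

#' Detect isolated alignment points on corrected spectra
#'
#' Runs the detection sweep with the full-membership constraint removed
#' (groups of 1..m peaks from distinct spectra) and no intensity bounds
#' beyond an optional noise floor. Singleton groups are legal output.
#'
#' @param corrected a [spectra_set()] of VLM-corrected spectra.
#' @param theta alignment window half-width (fraction), `0 < theta << w`.
#' @param noise_floor lower intensity threshold (default 0: align every
#'   peak).
#' @param strict_exclusivity see [detection_params()].
#' @return a `vlm_set` with `mode = "alignment"`.
#' @export
detect_alignment_points <- function(corrected, theta, noise_floor = 0,
                                    strict_exclusivity = FALSE) {
  if (!inherits(corrected, "spectra_set")) {
    stop("'corrected' must be a spectra_set")
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("'theta' must be a single positive number")
  }
  params <- detection_params(w = theta, t_a = noise_floor, t_b = Inf,
                             require_full = FALSE,
                             strict_exclusivity = strict_exclusivity)
  detect_vlms(corrected, params)
}

#' Fit an alignment model on corrected spectra
#'
#' Bundles the theta selection and alignment-point detection: leave-one-out
#' deviations from the VLMs, the chosen percentile, and the resulting
#' isolated alignment points.
#'
#' @param corrected [spectra_set()] of corrected spectra.
#' @param vlms the `vlm_set` used for correction.
#' @param spectra_for_loo spectra to compute the deviations on: the
#'   *uncorrected* detection set (the corrected set would give all-zero
#'   deviations, its matched peaks sitting exactly on the VLMs).
#' @param percentile percentile z for [select_theta()] (default 95).
#' @param noise_floor lower intensity threshold for alignment detection.
#' @param w window half-width (fraction); defaults to the set's `w`.
#' @return an object of class `alignment_model` with fields `theta`,
#'   `thetas_i`, `percentile`, `points`, `noise_floor`.
#' @export
alignment_model <- function(corrected, vlms, spectra_for_loo,
                            percentile = 95, noise_floor = 0, w = vlms$w) {
  thetas <- loo_theta(spectra_for_loo, vlms, w)
  theta <- select_theta(thetas, percentile)
  if (theta <= 0) {
    # perfectly reproducible synthetic peaks can give zero deviations;
    # fall back to the smallest positive spacing the doubles can express
    theta <- max(max(thetas), .Machine$double.eps * 8)
  }
  points <- detect_alignment_points(corrected, theta, noise_floor)
  structure(list(theta = theta, thetas_i = thetas, percentile = percentile,
                 points = points, noise_floor = noise_floor, w = w),
            class = "alignment_model")
}

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf(
    "<alignment_model: theta = %.4g ppm (%dth pct of %d deviations), %d alignment points>\n",
    frac_to_ppm(x$theta), x$percentile, length(x$thetas_i),
    length(x$points$mz)))
  invisible(x)
}

#' Write and read an alignment-point table
#'
#' Plain-CSV serialization of a fitted [alignment_model()] (theta and the
#' sorted alignment points), so that the inductive freeze-then-apply
#' workflow is auditable. Reading restores a model usable by [represent()].
#'
#' @param model an [alignment_model()].
#' @param path output path.
#' @export
write_alignment_table <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# theta=%.17g percentile=%g noise_floor=%.17g",
                     model$theta, model$percentile, model$noise_floor), con)
  df <- data.frame(point_mz = model$points$mz,
                   window_lo = model$points$mz * (1 - model$theta),
                   window_hi = model$points$mz * (1 + model$theta),
                   n_members = vapply(model$points$members, nrow, integer(1)))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_alignment_table
#' @export
read_alignment_table <- function(path) {
  header <- readLines(path, n = 1L)
  grab <- function(key) {
    as.numeric(sub(paste0("^.*", key, "=([^ ]+).*$"), "\\1", header))
  }
  df <- read.csv(path, skip = 1L)
  structure(list(theta = grab("theta"), thetas_i = NULL,
                 percentile = grab("percentile"),
                 points = list(mz = df$point_mz,
                               members = NULL, mode = "alignment"),
                 noise_floor = grab("noise_floor"), w = NA_real_),
            class = "alignment_model")
}

#' Feature vector of a corrected spectrum
#'
#' For each alignment point `mu_f`, the feature is the intensity of the
#' spectrum peak inside `[mu_f(1-theta), mu_f(1+theta)]` whose m/z is
#' closest to `mu_f` (ties to the lower m/z), or 0 when the window is
#' empty. Peaks matching no window contribute nothing.
#'
#' @param spectrum a VLM-corrected [ms_spectrum()].
#' @param model an [alignment_model()].
#' @return named numeric vector, one entry per alignment point (names are
#'   the point m/z to 6 decimals).
#' @export
represent <- function(spectrum, model) {
  pts <- model$points$mz
  theta <- model$theta
  mz <- spectrum$mz
  lo <- pts * (1 - theta)
  hi <- pts * (1 + theta)
  first <- findInterval(lo, mz, left.open = TRUE) + 1L
  last <- findInterval(hi, mz)
  vals <- numeric(length(pts))
  nonempty <- which(first <= last)
  for (i in nonempty) {
    idx <- first[i]:last[i]
    best <- idx[which.min(abs(mz[idx] - pts[i]))]  # ties: lower m/z wins
    vals[i] <- spectrum$intensity[best]
  }
  names(vals) <- sprintf("%.6f", pts)
  vals
}

#' Feature matrix for a set of corrected spectra
#'
#' @param corrected a [spectra_set()] of corrected spectra.
#' @param model an [alignment_model()].
#' @return a data frame: `sample_id`, `label`, then one intensity column
#'   per alignment point.
#' @export
represent_set <- function(corrected, model) {
  mat <- t(vapply(corrected, represent, numeric(length(model$points$mz)),
                  model = model))
  df <- data.frame(sample_id = set_ids(corrected),
                   label = set_labels(corrected),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(mat, check.names = FALSE))
}

#' Fixed-width binning baseline
#'
#' Tiles the half-open range `[lo, hi)` with fixed bins and aggregates the
#' intensities of the peaks in each bin (sum by default, max optionally).
#' A peak exactly on a bin edge belongs to the right bin. Bin labels are
#' bin centers.
#'
#' @param spectrum an [ms_spectrum()].
#' @param bin_width bin width in thomson.
#' @param range numeric length-2 `c(lo, hi)` with `lo < hi`.
#' @param agg `"sum"` or `"max"`.
#' @return named numeric vector of bin features.
#' @export
bin_spectrum <- function(spectrum, bin_width, range, agg = c("sum", "max")) {
  agg <- match.arg(agg)
  if (bin_width <= 0) stop("'bin_width' must be positive")
  lo <- range[1L]; hi <- range[2L]
  if (!(lo < hi)) stop("empty m/z range")
  nb <- ceiling((hi - lo) / bin_width)
  idx <- floor((spectrum$mz - lo) / bin_width) + 1L
  inside <- idx >= 1L & idx <= nb & spectrum$mz < hi & spectrum$mz >= lo
  vals <- numeric(nb)
  if (any(inside)) {
    f <- if (agg == "sum") sum else max
    agg_vals <- tapply(spectrum$intensity[inside], idx[inside], f)
    vals[as.integer(names(agg_vals))] <- as.numeric(agg_vals)
  }
  names(vals) <- sprintf("%.6f", lo + (seq_len(nb) - 0.5) * bin_width)
  vals
}

#' @rdname bin_spectrum
#' @param spectra a [spectra_set()].
#' @export
bin_set <- function(spectra, bin_width, range, agg = c("sum", "max")) {
  agg <- match.arg(agg)
  nb <- ceiling((range[2L] - range[1L]) / bin_width)
  mat <- t(vapply(spectra, bin_spectrum, numeric(nb),
                  bin_width = bin_width, range = range, agg = agg))
  df <- data.frame(sample_id = set_ids(spectra), label = set_labels(spectra),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(mat, check.names = FALSE))
}

#' Run the full detection-correction-alignment pipeline
#'
#' Transductive mode pools training and test spectra through detection,
#' correction, theta selection and alignment-point detection, then splits
#' the feature matrix. Inductive mode fits every model on the training
#' spectra only and applies the frozen transformation to the test spectra:
#' unmatched VLMs are bridged over during correction and alignment windows
#' with no peak yield zero features; test spectra are never re-clustered.
#'
#' @param train a [spectra_set()].
#' @param test an optional [spectra_set()] of held-out spectra.
#' @param params a [detection_params()] for VLM detection.
#' @param w_ppm_grid optional grid for [scan_window_sizes()]; when given,
#'   the window maximizing the isolated-VLM count replaces `params$w`.
#' @param percentile theta percentile (default 95; in inductive learning
#'   workflows this is the natural hyperparameter to cross-validate).
#' @param noise_floor lower intensity threshold for alignment detection.
#' @param trim see [correct_spectrum()].
#' @param mode `"transductive"` or `"inductive"`.
#' @return a list with `features_train`, `features_test` (or `NULL`),
#'   `vlms`, `model`, `correction_report`, `w`, `mode`.
#' @export
run_pipeline <- function(train, test = NULL, params = detection_params(),
                         w_ppm_grid = NULL, percentile = 95,
                         noise_floor = 0, trim = TRUE,
                         mode = c("transductive", "inductive")) {
  mode <- match.arg(mode)
  fit_ids <- set_ids(train)
  if (mode == "transductive" && !is.null(test)) {
    fit_set <- spectra_set(c(unclass(train), unclass(test)))
  } else {
    fit_set <- train
  }
  if (!is.null(w_ppm_grid)) {
    params$w <- scan_window_sizes(fit_set, w_ppm_grid, params)$best_w
  }
  vlms <- detect_vlms(fit_set, params)
  corr <- correct_set(fit_set, vlms, trim = trim)
  model <- alignment_model(corr$spectra, vlms, spectra_for_loo = fit_set,
                           percentile = percentile,
                           noise_floor = noise_floor)
  fm <- represent_set(corr$spectra, model)

  if (mode == "transductive") {
    features_train <- fm[fm$sample_id %in% fit_ids, , drop = FALSE]
    features_test <- if (is.null(test)) NULL else {
      fm[fm$sample_id %in% set_ids(test), , drop = FALSE]
    }
    report <- corr$report
  } else {
    features_train <- fm
    report <- corr$report
    features_test <- NULL
    if (!is.null(test)) {
      corr_test <- correct_set(test, vlms, trim = trim)
      features_test <- represent_set(corr_test$spectra, model)
      report <- rbind(report, corr_test$report)
    }
  }
  rownames(features_train) <- NULL
  if (!is.null(features_test)) rownames(features_test) <- NULL
  list(features_train = features_train, features_test = features_test,
       vlms = vlms, model = model, correction_report = report,
       w = params$w, mode = mode)
}
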