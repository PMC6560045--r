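## Recalibration of a spectrum's m/z axis against a set of virtual lock
## masses: each VLM v_i is matched to the unique spectrum peak inside its
## window, and every peak between the first and last matched peak is mapped
## by the piecewise linear function that sends matched peak mu_{alpha_i}
## exactly to v_i. Slopes are a = (v_{i+1} - v_i) / (mu_{alpha_{i+1}} -
## mu_{alpha_i}) and intercepts b = v_i - a * mu_{alpha_i}. Peaks outside
## the outermost matched peaks could only be corrected by extrapolation and
## are trimmed by default. Intensities are never modified.

#' Match VLMs to the peaks of one spectrum
#'
#' For each VLM `v_i`, finds the spectrum peak with m/z inside the closed
#' window `[v_i(1-w), v_i(1+w)]`. For a spectrum of the detection set there
#' is exactly one such peak by construction. For a new spectrum a window may
#' hold zero or two-plus peaks; that VLM is reported unmatched (`NA`) and
#' interpolation later bridges over it.
#'
#' @param spectrum an [ms_spectrum()].
#' @param vlms a `vlm_set`.
#' @param w window half-width (fraction); defaults to the set's own `w`.
#' @return a list with `alpha` (integer peak index per VLM, `NA` when
#'   unmatched) and `n_matched`.
#' @export
match_vlm_peaks <- function(spectrum, vlms, w = vlms$w) {
  v <- vlms$mz
  mz <- spectrum$mz
  lo <- v * (1 - w)
  hi <- v * (1 + w)
  n_le_hi <- findInterval(hi, mz)
  n_lt_lo <- findInterval(lo, mz, left.open = TRUE)
  count <- n_le_hi - n_lt_lo
  alpha <- ifelse(count == 1L, n_lt_lo + 1L, NA_integer_)
  list(alpha = as.integer(alpha), n_matched = sum(count == 1L))
}

#' Correct one spectrum against a VLM set
#'
#' Applies the piecewise linear recalibration through the matched VLM peaks.
#' Matched peaks land exactly on their `v_i`; peaks between two matched VLMs
#' are interpolated; peaks before the first or after the last matched VLM
#' are removed when `trim = TRUE` (the default) or passed through unmodified
#' and flagged in the `corrected` field otherwise. Intensities are
#' unchanged and, since every segment slope is positive, peak order is
#' preserved. Runs in linear time in the peak count.
#'
#' @inheritParams match_vlm_peaks
#' @param trim drop peaks outside the span of the matched VLMs (default
#'   `TRUE`).
#' @return the corrected [ms_spectrum()]. Its `source_index` tracks the
#'   input peaks that survived; with `trim = FALSE` a logical `corrected`
#'   field marks which peaks were actually recalibrated.
#' @export
correct_spectrum <- function(spectrum, vlms, w = vlms$w, trim = TRUE) {
  mt <- match_vlm_peaks(spectrum, vlms, w)
  alpha <- mt$alpha[!is.na(mt$alpha)]
  v <- vlms$mz[!is.na(mt$alpha)]
  if (length(alpha) < 2L) {
    stop("spectrum '", spectrum$id, "' is uncorrectable: only ",
         length(alpha), " of ", length(vlms$mz), " VLMs matched")
  }
  if (is.unsorted(alpha, strictly = TRUE)) {
    stop("matched peak indices are not strictly increasing")
  }
  mu <- spectrum$mz[alpha]
  a <- diff(v) / diff(mu)
  if (any(a <= 0)) stop("non-positive interpolation slope")
  b <- v[-length(v)] - a * mu[-length(mu)]

  mz <- spectrum$mz
  n <- length(mz)
  in_span <- seq_len(n) >= alpha[1L] & seq_len(n) <= alpha[length(alpha)]
  seg <- findInterval(mz[in_span], mu)
  seg <- pmin(pmax(seg, 1L), length(a))
  new_mz <- mz
  new_mz[in_span] <- a[seg] * mz[in_span] + b[seg]
  new_mz[alpha] <- v  # matched peaks sit exactly on their lock mass

  if (trim) {
    keep <- which(in_span)
    out <- ms_spectrum(new_mz[keep], spectrum$intensity[keep],
                       id = spectrum$id, label = spectrum$label,
                       source_index = spectrum$source_index[keep])
  } else {
    out <- ms_spectrum(new_mz, spectrum$intensity, id = spectrum$id,
                       label = spectrum$label,
                       source_index = spectrum$source_index)
    out$corrected <- in_span
  }
  out
}

#' Correct every spectrum of a set
#'
#' @param spectra a [spectra_set()].
#' @param vlms a `vlm_set` (detected on this set, or on a training set of
#'   the same nature).
#' @param w window half-width (fraction); defaults to the set's `w`.
#' @param trim see [correct_spectrum()].
#' @param on_error `"skip"` records uncorrectable spectra in the report and
#'   drops them; `"fail"` stops at the first one.
#' @return a list with `spectra` (the corrected [spectra_set()]) and
#'   `report`, a data frame of (id, n_matched, corrected).
#' @export
correct_set <- function(spectra, vlms, w = vlms$w, trim = TRUE,
                        on_error = c("skip", "fail")) {
  on_error <- match.arg(on_error)
  out <- vector("list", length(spectra))
  report <- data.frame(id = set_ids(spectra),
                       n_matched = NA_integer_, corrected = FALSE)
  for (i in seq_along(spectra)) {
    report$n_matched[i] <- match_vlm_peaks(spectra[[i]], vlms, w)$n_matched
    res <- tryCatch(correct_spectrum(spectra[[i]], vlms, w, trim),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "fail") stop(res)
    } else {
      out[[i]] <- res
      report$corrected[i] <- TRUE
    }
  }
  ok <- !vapply(out, is.null, logical(1))
  if (!any(ok)) stop("no spectrum could be corrected")
  list(spectra = spectra_set(out[ok]), report = report)
}

#' RMSE in ppm between two corrections of the same spectra
#'
#' Both sets must contain the same spectra (same ids). Homologous peaks are
#' paired either by position (requiring identical peak counts) or by the
#' `source_index` carried through correction (intersecting peaks that
#' survived both corrections, e.g. under different trims). The error for a
#' pair is `1e6 * (mzA - mzB) / mzB` ppm; the result is the root mean
#' square over all paired peaks.
#'
#' @param a,b [spectra_set()] objects holding the same samples.
#' @param match_by `"position"` or `"source"`.
#' @return RMSE in ppm (single number).
#' @export
correction_rmse <- function(a, b, match_by = c("position", "source")) {
  match_by <- match.arg(match_by)
  ids <- set_ids(a)
  if (!setequal(ids, set_ids(b))) stop("sets hold different samples")
  ss <- 0
  n <- 0L
  for (id in ids) {
    sa <- a[[id]]
    sb <- b[[id]]
    if (match_by == "position") {
      if (length(sa$mz) != length(sb$mz)) {
        stop("peak-count mismatch for spectrum '", id, "'")
      }
      dppm <- 1e6 * (sa$mz - sb$mz) / sb$mz
    } else {
      common <- intersect(sa$source_index, sb$source_index)
      ia <- match(common, sa$source_index)
      ib <- match(common, sb$source_index)
      dppm <- 1e6 * (sa$mz[ia] - sb$mz[ib]) / sb$mz[ib]
    }
    ss <- ss + sum(dppm^2)
    n <- n + length(dppm)
  }
  if (n == 0L) stop("no homologous peaks to compare")
  sqrt(ss / n)
}
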