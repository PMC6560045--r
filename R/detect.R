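## Virtual-lock-mass detection.
##
## A virtual lock mass (VLM) for a set of m spectra and window half-width w
## is an m/z value v supported by a peak set P such that: (1) P holds exactly
## one peak per spectrum, (2) v is the mean m/z of P, (3) every peak of P
## lies in [v(1-w), v(1+w)], (4) no other peak of the set lies in that
## interval, and (5) every peak of P has intensity within [t_a, t_b].
## Only isolated VLMs -- those whose windows intersect no other VLM's
## window -- are kept. Alignment points relax (1) to "1..m peaks from
## distinct spectra" and drop the intensity bounds, adding instead that no
## further peak can be added without breaking the other properties.

## Per-spectrum arrays concatenated for the C++ sweep.
flatten_set <- function(spectra) {
  ns <- vapply(spectra, function(s) length(s$mz), integer(1))
  list(mz = unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE),
       intensity = unlist(lapply(spectra, `[[`, "intensity"),
                          use.names = FALSE),
       spec0 = rep.int(seq_along(spectra) - 1L, ns),
       offsets = c(0L, cumsum(ns)),
       ns = ns)
}

materialize_vlm_set <- function(means, member_idx, flat, spectra, params,
                                mode, n_candidates, n_removed, ops = NULL) {
  ids <- set_ids(spectra)
  members <- lapply(member_idx, function(g) {
    s <- flat$spec0[g] + 1L
    rho <- g - flat$offsets[s]
    o <- order(flat$mz[g], s)
    # plain-list constructor: detect can emit tens of thousands of groups
    structure(list(spectrum = s[o], peak = as.integer(rho[o]),
                   id = ids[s][o], mz = flat$mz[g][o],
                   intensity = flat$intensity[g][o]),
              class = "data.frame", row.names = seq_along(g))
  })
  o <- order(means)
  structure(list(mz = means[o], members = members[o], w = params$w,
                 mode = mode, params = params, spectrum_ids = ids,
                 n_candidates = n_candidates, n_removed = n_removed,
                 ops = ops),
            class = "vlm_set")
}

#' @export
print.vlm_set <- function(x, ...) {
  what <- if (x$mode == "vlm") "VLMs" else "alignment points"
  cat(sprintf("<vlm_set: %d isolated %s, w = %g ppm (%d candidates, %d overlapping removed)>\n",
              length(x$mz), what, frac_to_ppm(x$w), x$n_candidates,
              x$n_removed))
  invisible(x)
}

#' @export
length.vlm_set <- function(x) length(x$mz)

#' Mark overlapping candidate windows on a sorted sequence
#'
#' Two candidates overlap when their windows `[v(1-w), v(1+w)]` intersect.
#' Both members of an overlapping pair are discarded, so the kept windows are
#' pairwise disjoint; on a sorted sequence checking adjacent neighbours
#' suffices.
#'
#' @param mz sorted candidate m/z values.
#' @param w window half-width (fraction).
#' @return logical vector: `TRUE` for candidates to keep.
#' @examples
#' remove_overlaps(c(100, 100.003, 200), ppm_to_frac(40)) # FALSE FALSE TRUE
#' @export
remove_overlaps <- function(mz, w) {
  n <- length(mz)
  if (n == 0L) return(logical(0))
  if (is.unsorted(mz)) stop("candidates must be sorted")
  keep <- rep(TRUE, n)
  if (n > 1L) {
    ov <- which(mz[-n] * (1 + w) >= mz[-1] * (1 - w))  # i overlaps i+1
    keep[ov] <- FALSE
    keep[ov + 1L] <- FALSE
  }
  keep
}

## Post-hoc re-check of window exclusivity against every peak of the set,
## including those outside the intensity bounds (which the sweep never sees).
strict_exclusivity_keep <- function(means, sizes, all_mz_sorted, w) {
  lo <- means * (1 - w)
  hi <- means * (1 + w)
  n_in <- findInterval(hi, all_mz_sorted) -
    findInterval(lo, all_mz_sorted, left.open = TRUE)
  n_in == sizes
}

#' Detect isolated virtual lock masses
#'
#' Sweeps the pooled, m/z-ordered peaks of a spectra set with a binary
#' min-heap (one pending peak per spectrum) and a growing/shrinking active
#' sequence, collecting every maximal candidate group, then discards
#' candidates whose windows overlap. Peaks with intensity outside
#' `[t_a, t_b]` never enter the sweep. Runs in O(n log m) for n pooled
#' peaks; the heap performs at most 2n + m push/pop operations.
#'
#' @param spectra a [spectra_set()]; each spectrum sorted by m/z.
#' @param params a [detection_params()].
#' @return a `vlm_set`: sorted isolated VLM values `mz`, per-VLM `members`
#'   (data frame of spectrum, peak, id, mz, intensity), the window `w`,
#'   candidate counts, and heap-operation counters in `ops`.
#' @seealso [brute_force_vlms()] for the direct implementation of the
#'   definition, [scan_window_sizes()] for choosing `w`.
#' @export
detect_vlms <- function(spectra, params = detection_params()) {
  if (!inherits(spectra, "spectra_set")) stop("'spectra' must be a spectra_set")
  m <- attr(spectra, "m")
  if (attr(spectra, "n") == 0L) stop("spectra set contains no peaks")
  if (params$require_full && m < 2L) {
    stop("virtual-lock-mass detection requires at least 2 spectra")
  }
  flat <- flatten_set(spectra)
  res <- .vlm_sweep(flat$mz, flat$intensity, flat$spec0, flat$offsets,
                    params$w, params$require_full, params$t_a, params$t_b)
  means <- res$mean
  sizes <- res$sizes
  member_idx <- split(res$members + 1L, rep.int(seq_along(sizes), sizes))
  names(member_idx) <- NULL
  o <- order(means)
  means <- means[o]
  sizes <- sizes[o]
  member_idx <- member_idx[o]
  n_cand <- length(means)

  if (params$strict_exclusivity && n_cand) {
    keep <- strict_exclusivity_keep(means, sizes, sort(flat$mz), params$w)
    means <- means[keep]
    member_idx <- member_idx[keep]
  }
  keep <- remove_overlaps(means, params$w)
  materialize_vlm_set(means[keep], member_idx[keep], flat, spectra, params,
                      mode = if (params$require_full) "vlm" else "alignment",
                      n_candidates = n_cand, n_removed = sum(!keep),
                      ops = list(pushes = res$pushes, pops = res$pops))
}

#' Brute-force reference detection
#'
#' Direct, quadratic-time implementation of the VLM / alignment-point
#' definitions: enumerates every contiguous run of the pooled sorted peaks,
#' checks the defining properties verbatim (distinct spectra, mean value,
#' window containment, window exclusivity, intensity bounds, and in
#' alignment mode maximality), then removes overlapping candidates. Used as
#' an independent oracle for [detect_vlms()] on small instances.
#'
#' @inheritParams detect_vlms
#' @return a `vlm_set` (without heap counters).
#' @export
brute_force_vlms <- function(spectra, params = detection_params()) {
  if (!inherits(spectra, "spectra_set")) stop("'spectra' must be a spectra_set")
  m <- attr(spectra, "m")
  if (params$require_full && m < 2L) {
    stop("virtual-lock-mass detection requires at least 2 spectra")
  }
  flat <- flatten_set(spectra)
  keep_peak <- flat$intensity >= params$t_a & flat$intensity <= params$t_b
  gidx <- which(keep_peak)
  o <- order(flat$mz[gidx], flat$spec0[gidx])
  gidx <- gidx[o]
  mz <- flat$mz[gidx]
  sp <- flat$spec0[gidx] + 1L
  n <- length(mz)
  w <- params$w

  core_valid <- function(i, j) {
    if (i < 1L || j > n) return(FALSE)
    s <- sp[i:j]
    if (anyDuplicated(s)) return(FALSE)
    v <- mean(mz[i:j])
    lo <- v * (1 - w); hi <- v * (1 + w)
    if (mz[i] < lo || mz[j] > hi) return(FALSE)
    if (i > 1L && mz[i - 1L] >= lo) return(FALSE)
    if (j < n && mz[j + 1L] <= hi) return(FALSE)
    TRUE
  }

  means <- numeric(0)
  member_idx <- list()
  if (n > 0L) {
    for (i in seq_len(n)) {
      seen <- logical(m)
      j <- i
      while (j <= n && !seen[sp[j]]) {
        seen[sp[j]] <- TRUE
        k <- j - i + 1L
        ok <- if (params$require_full) {
          k == m && core_valid(i, j)
        } else {
          core_valid(i, j) && !core_valid(i, j + 1L) && !core_valid(i - 1L, j)
        }
        if (ok) {
          means <- c(means, mean(mz[i:j]))
          member_idx <- c(member_idx, list(gidx[i:j]))
        }
        j <- j + 1L
      }
    }
  }
  o <- order(means)
  means <- means[o]
  member_idx <- member_idx[o]
  n_cand <- length(means)
  if (params$strict_exclusivity && n_cand) {
    keep <- strict_exclusivity_keep(means, lengths(member_idx),
                                    sort(flat$mz), w)
    means <- means[keep]
    member_idx <- member_idx[keep]
  }
  keep <- remove_overlaps(means, w)
  materialize_vlm_set(means[keep], member_idx[keep], flat, spectra, params,
                      mode = if (params$require_full) "vlm" else "alignment",
                      n_candidates = n_cand, n_removed = sum(!keep))
}

#' Scan window sizes for the one maximizing the isolated-VLM count
#'
#' The number of isolated VLMs behaves unimodally in `w`: too small and no
#' window spans the peak scatter, too large and candidates overlap and are
#' discarded. The best `w` is the one yielding the most isolated VLMs; ties
#' are broken toward the smallest `w`.
#'
#' @param spectra a [spectra_set()].
#' @param w_ppm_grid increasing vector of window half-widths in ppm; default
#'   a 20-point geometric grid over 1-200 ppm.
#' @param params a [detection_params()]; its `w` is replaced by each grid
#'   value in turn.
#' @return a list with `best_w_ppm`, `best_w` (fraction), and `table`, a
#'   data frame of (w_ppm, n_vlms).
#' @export
scan_window_sizes <- function(spectra, w_ppm_grid = NULL,
                              params = detection_params()) {
  if (is.null(w_ppm_grid)) {
    w_ppm_grid <- exp(seq(log(1), log(200), length.out = 20))
  }
  if (!length(w_ppm_grid) || any(w_ppm_grid <= 0) ||
      is.unsorted(w_ppm_grid, strictly = TRUE)) {
    stop("'w_ppm_grid' must be a non-empty increasing positive vector")
  }
  counts <- vapply(w_ppm_grid, function(wp) {
    p <- params
    p$w <- ppm_to_frac(wp)
    length(detect_vlms(spectra, p)$mz)
  }, integer(1))
  best <- w_ppm_grid[which.max(counts)]  # which.max takes the first maximum
  list(best_w_ppm = best, best_w = ppm_to_frac(best),
       table = data.frame(w_ppm = w_ppm_grid, n_vlms = counts))
}

#' Compare VLMs of a spectra subset to VLMs of the full set
#'
#' A VLM detected on a subset B of the spectra is homologous to a VLM
#' detected on the full set A when its member peaks are a subset of the
#' full-set VLM's member peaks. Peaks are identified by (spectrum id, peak
#' index).
#'
#' @param vlms_sub `vlm_set` detected on a subset of the spectra.
#' @param vlms_full `vlm_set` detected on the full set, with the same `w`.
#' @return a list with the `pairing` data frame (sub_index, full_index),
#'   counts `n_sub`, `n_full`, `n_full_with_homologue`, and
#'   `fraction_full_matched`.
#' @export
compare_homologues <- function(vlms_sub, vlms_full) {
  if (!isTRUE(all.equal(vlms_sub$w, vlms_full$w))) {
    stop("VLM sets were computed with different window sizes")
  }
  key <- function(mem) paste(mem$id, mem$peak, sep = "\r")
  full_map <- new.env(parent = emptyenv())
  for (i in seq_along(vlms_full$members)) {
    for (k in key(vlms_full$members[[i]])) assign(k, i, envir = full_map)
  }
  full_index <- vapply(vlms_sub$members, function(mem) {
    ks <- key(mem)
    hit <- vapply(ks, function(k) {
      if (exists(k, envir = full_map, inherits = FALSE)) {
        get(k, envir = full_map)
      } else NA_integer_
    }, integer(1))
    if (anyNA(hit) || length(unique(hit)) != 1L) NA_integer_ else hit[[1L]]
  }, integer(1))
  pairing <- data.frame(sub_index = seq_along(full_index),
                        full_index = full_index)
  matched <- unique(full_index[!is.na(full_index)])
  list(pairing = pairing,
       n_sub = length(vlms_sub$mz),
       n_full = length(vlms_full$mz),
       n_full_with_homologue = length(matched),
       fraction_full_matched = if (length(vlms_full$mz)) {
         length(matched) / length(vlms_full$mz)
       } else NA_real_)
}

#' Audit a detected set against the defining properties
#'
#' Re-checks every emitted VLM or alignment point independently against the
#' full spectra set: membership (one peak per spectrum in VLM mode; 1..m
#' peaks from distinct spectra in alignment mode), mean value, window
#' containment, window exclusivity, intensity bounds, isolation of
#' consecutive windows, and (alignment mode) maximality.
#'
#' @param vlms a `vlm_set`.
#' @param spectra the [spectra_set()] it was detected on.
#' @return a data frame with one row per point and logical check columns;
#'   attribute `ok` is `TRUE` when every check passed.
#' @export
check_vlm_properties <- function(vlms, spectra) {
  params <- vlms$params
  w <- vlms$w
  m <- attr(spectra, "m")
  full_mode <- params$require_full
  pooled <- pool_peaks(spectra)
  if (params$strict_exclusivity) {
    visible <- pooled
  } else {
    visible <- pooled[pooled$intensity >= params$t_a &
                        pooled$intensity <= params$t_b, , drop = FALSE]
  }
  vm <- visible$mz
  vis_key <- paste(visible$spectrum, visible$peak)
  r <- length(vlms$mz)
  res <- data.frame(
    mz = vlms$mz,
    membership = logical(r), mean_ok = logical(r), containment = logical(r),
    exclusivity = logical(r), intensity_ok = logical(r),
    isolation = logical(r), maximality = logical(r)
  )
  lo_all <- vlms$mz * (1 - w)
  hi_all <- vlms$mz * (1 + w)
  core_ok <- function(mzv, spv) {
    # would this peak multiset satisfy membership/containment/exclusivity?
    if (anyDuplicated(spv)) return(FALSE)
    v <- mean(mzv)
    lo <- v * (1 - w); hi <- v * (1 + w)
    if (any(mzv < lo | mzv > hi)) return(FALSE)
    n_in <- findInterval(hi, vm) - findInterval(lo, vm, left.open = TRUE)
    n_in == length(mzv)
  }
  for (i in seq_len(r)) {
    mem <- vlms$members[[i]]
    v <- vlms$mz[i]
    lo <- lo_all[i]; hi <- hi_all[i]
    res$membership[i] <- if (full_mode) {
      nrow(mem) == m && !anyDuplicated(mem$spectrum)
    } else {
      nrow(mem) >= 1L && nrow(mem) <= m && !anyDuplicated(mem$spectrum)
    }
    res$mean_ok[i] <- abs(v - mean(mem$mz)) <= 1e-9 * v
    res$containment[i] <- all(mem$mz >= lo & mem$mz <= hi)
    n_in <- findInterval(hi, vm) - findInterval(lo, vm, left.open = TRUE)
    res$exclusivity[i] <- n_in == nrow(mem)
    res$intensity_ok[i] <- if (full_mode) {
      all(mem$intensity >= params$t_a & mem$intensity <= params$t_b)
    } else TRUE
    res$isolation[i] <-
      (i == 1L || hi_all[i - 1L] < lo) && (i == r || hi < lo_all[i + 1L])
    if (full_mode) {
      res$maximality[i] <- TRUE  # implied by one-peak-per-spectrum
    } else {
      # try adding the pooled neighbours just outside the member run
      rows <- match(paste(mem$spectrum, mem$peak), vis_key)
      lo_r <- min(rows); hi_r <- max(rows)
      addable <- FALSE
      for (cand in c(lo_r - 1L, hi_r + 1L)) {
        if (cand >= 1L && cand <= nrow(visible)) {
          if (core_ok(c(mem$mz, visible$mz[cand]),
                      c(mem$spectrum, visible$spectrum[cand]))) {
            addable <- TRUE
          }
        }
      }
      res$maximality[i] <- !addable
    }
  }
  attr(res, "ok") <- all(unlist(res[, -1L]))
  res
}
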