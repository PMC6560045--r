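## Domain types and ppm-window arithmetic shared by all modules.
##
## A spectrum is a centroided peak list: parallel numeric vectors of m/z
## (thomson, ascending) and intensity (detector counts), plus a sample id.
## Window sizes are stored internally as dimensionless fractions of m/z;
## user-facing surfaces accept ppm (40 ppm == 4e-5) because ToF mass error
## grows linearly with m/z.

#' Convert between ppm and dimensionless window fractions
#'
#' Window sizes are relative to m/z: a half-width of `w` spans
#' `[mz * (1 - w), mz * (1 + w)]`. These helpers convert the ppm values used
#' on all user-facing surfaces to the internal fractional representation.
#'
#' @param ppm window half-width in parts per million.
#' @param frac window half-width as a dimensionless fraction.
#' @return the converted value.
#' @examples
#' ppm_to_frac(40) # 4e-05
#' @export
ppm_to_frac <- function(ppm) ppm * 1e-6

#' @rdname ppm_to_frac
#' @export
frac_to_ppm <- function(frac) frac * 1e6

#' Relative (ppm-style) window around an m/z value
#'
#' Returns the closed interval `[mz * (1 - w), mz * (1 + w)]` of total width
#' `2 * w * mz`. The width is proportional to m/z, matching the relative mass
#' error of time-of-flight instruments.
#'
#' @param mz m/z value(s), strictly positive.
#' @param w window half-width as a dimensionless fraction (use
#'   [ppm_to_frac()] for ppm input).
#' @return a data frame with columns `lo` and `hi`, one row per `mz`.
#' @examples
#' ppm_window(100, ppm_to_frac(40)) # [99.996, 100.004]
#' @export
ppm_window <- function(mz, w) {
  if (!is.numeric(mz) || any(!is.finite(mz)) || any(mz <= 0)) {
    stop("'mz' must be finite and strictly positive")
  }
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0) {
    stop("'w' must be a single positive number")
  }
  data.frame(lo = mz * (1 - w), hi = mz * (1 + w))
}

#' Construct a centroided spectrum
#'
#' @param mz numeric vector of m/z values (thomson). Sorted ascending on
#'   construction; unsorted input is sorted with a warning.
#' @param intensity numeric vector of intensities (counts), non-negative,
#'   same length as `mz`.
#' @param id sample identifier.
#' @param label optional class label for downstream learning.
#' @param source_index integer identity of each peak, used to track peaks
#'   through correction and trimming. Defaults to `seq_along(mz)`.
#' @return an object of class `ms_spectrum` with fields `id`, `mz`,
#'   `intensity`, `label`, `source_index`.
#' @export
ms_spectrum <- function(mz, intensity, id = "spectrum", label = NULL,
                        source_index = NULL) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("'mz' and 'intensity' must have the same length")
  }
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("all m/z values must be finite and strictly positive")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("all intensities must be finite and non-negative")
  }
  if (is.null(source_index)) source_index <- seq_along(mz)
  if (is.unsorted(mz)) {
    warning("peaks not sorted by m/z; sorting")
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    source_index <- source_index[o]
  }
  structure(
    list(id = as.character(id), mz = mz, intensity = intensity,
         label = label, source_index = as.integer(source_index)),
    class = "ms_spectrum"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum '%s': %d peaks", x$id, length(x$mz)))
  if (length(x$mz)) {
    cat(sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)))
  }
  if (!is.null(x$label)) cat(sprintf(", label '%s'", x$label))
  cat(">\n")
  invisible(x)
}

#' @export
length.ms_spectrum <- function(x) length(x$mz)

#' Construct a set of spectra
#'
#' @param spectra a list of [ms_spectrum()] objects with distinct ids.
#' @return an object of class `spectra_set`: the list of spectra with
#'   attributes `m` (spectrum count) and `n` (total peak count).
#' @export
spectra_set <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 1L) {
    stop("'spectra' must be a non-empty list of ms_spectrum objects")
  }
  ok <- vapply(spectra, inherits, logical(1), "ms_spectrum")
  if (!all(ok)) stop("all elements must be ms_spectrum objects")
  ids <- vapply(spectra, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("spectrum ids must be distinct")
  names(spectra) <- ids
  structure(spectra, class = "spectra_set",
            m = length(spectra),
            n = sum(vapply(spectra, function(s) length(s$mz), integer(1))))
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set: %d spectra, %d peaks>\n",
              attr(x, "m"), attr(x, "n")))
  invisible(x)
}

#' @export
`[.spectra_set` <- function(x, i) {
  spectra_set(unclass(x)[i])
}

set_ids <- function(spectra) {
  unname(vapply(spectra, `[[`, character(1), "id"))
}

set_labels <- function(spectra) {
  unname(vapply(spectra, function(s) {
    if (is.null(s$label)) NA_character_ else as.character(s$label)
  }, character(1)))
}

## Pool all peaks of a set into one table sorted by (m/z, spectrum index).
## The tie-break matches the detection heap so pooled order is the sweep's
## processing order.
pool_peaks <- function(spectra) {
  m <- attr(spectra, "m")
  mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  intensity <- unlist(lapply(spectra, `[[`, "intensity"), use.names = FALSE)
  ns <- vapply(spectra, function(s) length(s$mz), integer(1))
  spectrum <- rep.int(seq_len(m), ns)
  peak <- unlist(lapply(ns, seq_len), use.names = FALSE)
  o <- order(mz, spectrum)
  data.frame(mz = mz[o], intensity = intensity[o],
             spectrum = spectrum[o], peak = peak[o])
}

#' Detection parameters
#'
#' Bundles the tunables of the detection sweep. `w` is stored as a
#' dimensionless fraction; pass ppm through `w_ppm`.
#'
#' @param w_ppm window half-width in ppm (default 40).
#' @param t_a lower intensity threshold in counts (default 1000); peaks below
#'   it never enter the sweep.
#' @param t_b upper intensity threshold in counts (default `Inf`, i.e.
#'   unbounded).
#' @param require_full if `TRUE` (virtual-lock-mass mode) a group must
#'   contain exactly one peak from every spectrum; if `FALSE` (alignment
#'   mode) groups of 1 to m peaks from distinct spectra are allowed.
#' @param strict_exclusivity if `TRUE`, candidate windows are re-checked
#'   post hoc against *all* peaks including sub-threshold ones, so that a
#'   peak below `t_a` can veto a window.
#' @param w window half-width as a fraction; overrides `w_ppm` when given.
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(w_ppm = 40, t_a = 1000, t_b = Inf,
                             require_full = TRUE, strict_exclusivity = FALSE,
                             w = NULL) {
  if (is.null(w)) w <- ppm_to_frac(w_ppm)
  if (!is.numeric(w) || length(w) != 1L || w <= 0) {
    stop("window size must be a single positive number")
  }
  if (t_a < 0) stop("'t_a' must be non-negative")
  if (is.finite(t_b) && t_b <= t_a) stop("'t_b' must exceed 't_a'")
  structure(list(w = w, t_a = t_a, t_b = t_b,
                 require_full = isTRUE(require_full),
                 strict_exclusivity = isTRUE(strict_exclusivity)),
            class = "detection_params")
}

#' Read a centroided peak list
#'
#' Reads one spectrum from a two-column (mz, intensity) CSV/TSV file, or from
#' a centroid-mode mzML file via the mzR package. A non-numeric first row is
#' treated as a header. Unsorted peaks are sorted with a warning;
#' zero-intensity rows are retained.
#'
#' @param path path to the file.
#' @param dialect one of `"csv"`, `"tsv"`, `"mzml"`; defaults to the file
#'   extension.
#' @param id sample identifier; defaults to the file stem.
#' @param label optional class label.
#' @param merge_scans for mzML files with several scans, set `TRUE` to merge
#'   them into one peak list; otherwise multiple scans are an error.
#' @return an [ms_spectrum()].
#' @export
read_peaklist <- function(path, dialect = c("auto", "csv", "tsv", "mzml"),
                          id = NULL, label = NULL, merge_scans = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, tsv = "tsv", txt = "tsv", mzml = "mzml", "csv")
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (dialect == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the 'mzR' package")
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    nscan <- mzR::length(h)
    if (nscan > 1L && !isTRUE(merge_scans)) {
      stop("mzML file has ", nscan, " scans; set merge_scans = TRUE to merge")
    }
    pk <- mzR::peaks(h)
    if (is.list(pk)) pk <- do.call(rbind, pk)
    return(ms_spectrum(pk[, 1], pk[, 2], id = id, label = label))
  }
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(ms_spectrum(numeric(0), numeric(0), id = id, label = label))
  }
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  if (has_header) lines <- lines[-1]
  if (!length(lines)) {
    return(ms_spectrum(numeric(0), numeric(0), id = id, label = label))
  }
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop("unparseable row at line ",
         which(nf < 2L)[1L] + has_header, " of ", path)
  }
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad)) {
    stop("unparseable row at line ", bad[1L] + has_header, " of ", path)
  }
  if (any(mz <= 0)) {
    stop("non-positive m/z at line ", which(mz <= 0)[1L] + has_header,
         " of ", path)
  }
  ms_spectrum(mz, it, id = id, label = label)
}

#' Write a peak list to CSV/TSV
#'
#' @param spectrum an [ms_spectrum()].
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_peaklist <- function(spectrum, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(mz = spectrum$mz, intensity = spectrum$intensity)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a TSV with columns `sample_id`, `path` and optionally
#' `label`. Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest path.
#' @return a data frame with columns `sample_id`, `path`, `label`.
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns 'sample_id' and 'path'")
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df[, c("sample_id", "path", "label")]
}

#' Read all spectra listed in a manifest
#'
#' @param manifest path to a manifest TSV, or a data frame as returned by
#'   [read_manifest()].
#' @param ... passed to [read_peaklist()].
#' @return a [spectra_set()].
#' @export
read_spectra <- function(manifest, ...) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  spectra <- lapply(seq_len(nrow(manifest)), function(i) {
    lab <- manifest$label[i]
    if (is.na(lab)) lab <- NULL
    read_peaklist(manifest$path[i], id = manifest$sample_id[i],
                  label = lab, ...)
  })
  spectra_set(spectra)
}

#' Write and read a virtual-lock-mass table
#'
#' The table has one row per VLM with its mean m/z, window bounds, and the
#' matched member m/z per spectrum id. Round-tripping reproduces the values
#' to full double precision.
#'
#' @param vlms a `vlm_set` as returned by [detect_vlms()].
#' @param path output path.
#' @export
write_vlm_table <- function(vlms, path) {
  w <- vlms$w
  ids <- vlms$spectrum_ids
  r <- length(vlms$mz)
  mat <- matrix(NA_real_, nrow = r, ncol = length(ids),
                dimnames = list(NULL, ids))
  for (i in seq_len(r)) {
    mem <- vlms$members[[i]]
    mat[i, mem$id] <- mem$mz
  }
  df <- data.frame(vlm_mz = vlms$mz,
                   window_lo = vlms$mz * (1 - w),
                   window_hi = vlms$mz * (1 + w))
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# w=%.17g mode=%s", w, vlms$mode), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vlm_table
#' @export
read_vlm_table <- function(path) {
  header <- readLines(path, n = 1L)
  w <- as.numeric(sub("^# w=([^ ]+).*$", "\\1", header))
  mode <- sub("^.* mode=(\\S+).*$", "\\1", header)
  df <- read.csv(path, skip = 1L, check.names = FALSE)
  ids <- setdiff(names(df), c("vlm_mz", "window_lo", "window_hi"))
  members <- lapply(seq_len(nrow(df)), function(i) {
    vals <- as.numeric(df[i, ids])
    keep <- !is.na(vals)
    data.frame(id = ids[keep], mz = vals[keep], stringsAsFactors = FALSE)
  })
  structure(list(mz = df$vlm_mz, members = members, w = w, mode = mode,
                 spectrum_ids = ids),
            class = "vlm_set")
}

#' Write and read a feature matrix
#'
#' One row per sample, one column per alignment point labelled by its mean
#' m/z rounded to 6 decimals, cells holding intensities (0 when the sample
#' has no peak in the point's window), plus `sample_id` and optional `label`
#' columns. Round trips are lossless to double precision.
#'
#' @param fm a feature-matrix data frame as returned by [represent_set()].
#' @param path output path.
#' @export
write_feature_matrix <- function(fm, path) {
  num <- vapply(fm, is.numeric, logical(1))
  out <- fm
  out[num] <- lapply(fm[num], function(x) {
    format(x, digits = 17, trim = TRUE, scientific = FALSE)
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
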