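#' Assemble a sample set from a peak table
#'
#' A sample set bundles the integrated ion peaks of one study with the
#' ordered list of study samples and, optionally, per-sample internal
#' standard (retention time, retention index) calibration pairs.
#'
#' @param peaks data.frame with columns `sample_id`, `mz`, `rt`, `area`
#'   and optionally `peak_id`, `ri`, `ms_level`, `precursor_mz`.
#' @param samples character vector of sample ids; defaults to the unique
#'   sample ids found in `peaks`, in order of first appearance.
#' @param standards optional data.frame with columns `sample_id`, `rt`,
#'   `ri` giving internal-standard calibration points.
#' @return An object of class `ps_sample_set`.
#' @export
sample_set <- function(peaks, samples = NULL, standards = NULL) {
  peaks <- normalize_peaks(peaks)
  errs <- peak_row_errors(peaks)
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  if (is.null(samples)) samples <- unique(peaks$sample_id)
  if (!all(peaks$sample_id %in% samples)) {
    stop("peaks reference sample ids absent from `samples`")
  }
  if (!is.null(standards)) {
    stopifnot(all(c("sample_id", "rt", "ri") %in% names(standards)))
  }
  structure(
    list(samples = as.character(samples), peaks = peaks,
         standards = standards),
    class = "ps_sample_set"
  )
}

# Coerce a raw peak data.frame to the canonical column set and types.
normalize_peaks <- function(peaks) {
  req <- c("sample_id", "mz", "rt", "area")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) {
    stop("peak table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(peaks$peak_id)) {
    peaks$peak_id <- sprintf("P%06d", seq_len(nrow(peaks)))
  }
  n <- nrow(peaks)
  if (is.null(peaks$ri)) peaks$ri <- rep(NA_real_, n)
  if (is.null(peaks$ms_level)) peaks$ms_level <- rep(1L, n)
  peaks$ms_level[is.na(peaks$ms_level)] <- 1L
  if (is.null(peaks$precursor_mz)) peaks$precursor_mz <- rep(NA_real_, n)
  for (col in c("mz", "rt", "ri", "area", "precursor_mz")) {
    v <- peaks[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    # non-numeric tokens become NA here and are reported as row errors
    peaks[[col]] <- suppressWarnings(as.numeric(v))
  }
  peaks$ms_level <- as.integer(peaks$ms_level)
  peaks$sample_id <- as.character(peaks$sample_id)
  peaks$peak_id <- as.character(peaks$peak_id)
  peaks[c("peak_id", "sample_id", "mz", "rt", "ri", "area",
          "ms_level", "precursor_mz")]
}

# Row-numbered invariant violations; returns character(0) when clean.
peak_row_errors <- function(peaks) {
  errs <- character(0)
  bad_row <- function(rows, what) {
    if (length(rows)) {
      sprintf("row %s: %s", paste(rows, collapse = ", "), what)
    } else character(0)
  }
  errs <- c(errs, bad_row(which(!is.finite(peaks$mz) | peaks$mz <= 0),
                          "mz must be a positive number"))
  errs <- c(errs, bad_row(which(!is.finite(peaks$area) | peaks$area <= 0),
                          "area must be a positive number"))
  errs <- c(errs, bad_row(which(!peaks$ms_level %in% c(1L, 2L)),
                          "ms_level must be 1 or 2"))
  errs <- c(errs, bad_row(
    which(peaks$ms_level == 2L & !is.finite(peaks$precursor_mz)),
    "ms_level 2 rows require precursor_mz"))
  errs <- c(errs, bad_row(
    which(peaks$ms_level == 1L & is.finite(peaks$precursor_mz)),
    "precursor_mz only allowed on ms_level 2 rows"))
  if (anyDuplicated(peaks$peak_id)) {
    dup <- unique(peaks$peak_id[duplicated(peaks$peak_id)])
    errs <- c(errs, sprintf("duplicate peak_id: %s",
                            paste(dup, collapse = ", ")))
  }
  errs
}

#' Read a peak table from CSV
#'
#' Expects a UTF-8 CSV with a header row. Required columns (after
#' applying `dialect`): `sample_id`, `mz`, `rt`, `area`; optional:
#' `peak_id`, `ri`, `ms_level`, `precursor_mz`. `ms_level` defaults to 1.
#' Rows violating the peak invariants are rejected with row-numbered
#' error messages.
#'
#' @param path path to the CSV file.
#' @param dialect named character vector mapping canonical column names
#'   to the names used in the file, e.g. `c(mz = "Mass", area = "Area")`,
#'   so third-party peak-picker exports can be ingested unchanged.
#' @return A `ps_sample_set`.
#' @export
read_peak_table <- function(path, dialect = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(df)) {
        stop("dialect column '", src, "' not found in ", path)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  sample_set(df)
}

#' Write a peak table to CSV
#'
#' Numeric fields are written at full precision (15 significant digits)
#' so that a read/write round trip reproduces them exactly.
#'
#' @param x a `ps_sample_set` or a peak data.frame.
#' @param path output path.
#' @export
write_peak_table <- function(x, path) {
  peaks <- if (inherits(x, "ps_sample_set")) x$peaks else x
  out <- peaks
  for (col in c("mz", "rt", "ri", "area", "precursor_mz")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    out[[col]][out[[col]] %in% c("NA", " NA")] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Assign retention indices by internal-standard calibration
#'
#' Converts each peak's retention time to a retention index by
#' piecewise-linear interpolation through that sample's internal
#' standard (rt, ri) pairs. Peaks eluting before the first or after the
#' last standard are linearly extrapolated using the nearest segment's
#' slope rather than dropped, so bin fill fractions are not silently
#' altered at the ends of the gradient.
#'
#' @param x a `ps_sample_set` (uses `x$standards`) or a peak data.frame.
#' @param standards data.frame `sample_id`, `rt`, `ri`; required when
#'   `x` is a data.frame or has no standards attached. At least two
#'   standards per sample, strictly increasing in both rt and ri.
#' @return `x` with the `ri` column populated for every peak.
#' @export
assign_retention_index <- function(x, standards = NULL) {
  is_set <- inherits(x, "ps_sample_set")
  peaks <- if (is_set) x$peaks else x
  if (is.null(standards)) standards <- if (is_set) x$standards else NULL
  if (is.null(standards)) stop("no calibration standards supplied")
  for (s in unique(peaks$sample_id)) {
    std <- standards[standards$sample_id == s, , drop = FALSE]
    if (nrow(std) < 2) {
      stop("sample ", s, ": at least 2 internal standards required")
    }
    std <- std[order(std$rt), , drop = FALSE]
    if (any(diff(std$rt) <= 0) || any(diff(std$ri) <= 0)) {
      stop("sample ", s, ": standards must be strictly increasing in rt and ri")
    }
    sel <- peaks$sample_id == s
    peaks$ri[sel] <- interp_ri(peaks$rt[sel], std$rt, std$ri)
  }
  if (is_set) {
    x$peaks <- peaks
    x
  } else {
    peaks
  }
}

# Piecewise-linear interpolation with end-segment extrapolation.
interp_ri <- function(rt, std_rt, std_ri) {
  n <- length(std_rt)
  ri <- stats::approx(std_rt, std_ri, xout = rt, rule = 1)$y
  lo <- rt < std_rt[1]
  hi <- rt > std_rt[n]
  if (any(lo)) {
    slope <- (std_ri[2] - std_ri[1]) / (std_rt[2] - std_rt[1])
    ri[lo] <- std_ri[1] + slope * (rt[lo] - std_rt[1])
  }
  if (any(hi)) {
    slope <- (std_ri[n] - std_ri[n - 1]) / (std_rt[n] - std_rt[n - 1])
    ri[hi] <- std_ri[n] + slope * (rt[hi] - std_rt[n])
  }
  ri
}

#' @export
print.ps_sample_set <- function(x, ...) {
  cat(sprintf(
    "Sample set: %d samples, %d peaks (%d MS1, %d MS2)%s\n",
    length(x$samples), nrow(x$peaks),
    sum(x$peaks$ms_level == 1L), sum(x$peaks$ms_level == 2L),
    if (is.null(x$standards)) "" else
      sprintf(", %d calibration standards", nrow(x$standards))
  ))
  invisible(x)
}
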