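# Small peak-table builders used across test files.

peak_rows <- function(sample_id, mz, ri, area, rt = ri / 1000,
                      ms_level = 1L, precursor_mz = NA_real_) {
  data.frame(sample_id = sample_id, mz = mz, rt = rt, ri = ri,
             area = area, ms_level = ms_level, precursor_mz = precursor_mz)
}

# n samples, one ion series per column of `areas` (samples x ions) at
# the given masses, all eluting at `ri`.
ion_series <- function(mzs, areas, ri, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(areas)))
  do.call(rbind, lapply(seq_along(mzs), function(k) {
    peak_rows(samples, mzs[k], ri, areas[, k])
  }))
}

# deterministic abundance profile spanning ~e^2 dynamic range
abundance_profile <- function(n) exp(seq(-1, 1, length.out = n))

write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
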