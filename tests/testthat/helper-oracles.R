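# Independent oracles, written with naive loops and no package
# internals, so implementation and check never share code.

# Greedy binning oracle: peaks in descending area order; each peak joins
# the in-window bin minimizing |dmz|/mw + |dri|/rw (earliest bin on
# ties) or opens a new bin centered on itself.
oracle_greedy_bins <- function(peaks, mw, rw) {
  ord <- order(-peaks$area, peaks$mz, peaks$ri, peaks$peak_id)
  cm <- numeric(0)
  cr <- numeric(0)
  assign <- integer(nrow(peaks))
  for (i in ord) {
    best <- 0L
    best_d <- Inf
    for (k in seq_along(cm)) {
      dm <- abs(peaks$mz[i] - cm[k])
      dr <- abs(peaks$ri[i] - cr[k])
      if (dm <= mw && dr <= rw) {
        d <- dm / mw + dr / rw
        if (d < best_d) {
          best_d <- d
          best <- k
        }
      }
    }
    if (best == 0L) {
      cm <- c(cm, peaks$mz[i])
      cr <- c(cr, peaks$ri[i])
      best <- length(cm)
    }
    assign[i] <- best
  }
  assign
}

# Canonical form of a peak partition for comparison: sorted sets of
# peak ids, ordered by their first element.
canon_partition <- function(peak_id, bin) {
  parts <- lapply(split(peak_id, bin), sort)
  unname(parts[order(vapply(parts, `[`, "", 1))])
}

# Brute-force monomer scoring oracle: every (bin, form) proposal taken
# as a cluster anchor collects the scores of all proposals within the
# merge window; the top candidate is the anchor with the maximal total.
# Valid whenever proposal masses are either clearly merged or clearly
# separated, where all merge orders agree.
oracle_monomer_top <- function(bins, forms, window) {
  mono <- c()
  score <- c()
  for (i in seq_len(nrow(bins))) {
    for (f in seq_len(nrow(forms))) {
      m <- (bins$mean_mz[i] - forms$adduct_mz[f]) / forms$n_imer[f]
      if (m <= 0) next
      mono <- c(mono, m)
      score <- c(score, bins$mean_area[i] * forms$probability_pct[f])
    }
  }
  totals <- vapply(seq_along(mono), function(k) {
    sum(score[abs(mono - mono[k]) <= window])
  }, 0)
  best <- which.max(totals)
  list(monomer_mz = mono[best], score = totals[best])
}

# Textbook Pearson formula, independent of stats::cor.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
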