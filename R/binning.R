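#' @section Binning:
#' Ions from all samples of a study are partitioned into cross-sample
#' bins by mass and retention index. Each bin is characterized by a
#' center mass and a center RI; an ion joins a bin when its m/z and RI
#' fall within the mass window and RI window around that center. A
#' sample contributing exactly one ion to a bin is a *singlet* there; a
#' sample contributing more than one is a *multiplet* (a *collision*,
#' indicating co-elution). Bin statistics, grouping correlations and
#' library entries are computed over singlet ions only.
#' @name binning
NULL

# Greedy assignment of peaks to bins, in descending area order. Peaks
# that fit no existing bin open a new bin centered on themselves. When a
# peak fits several bins the bin minimizing the scale-free distance
# |dmz|/mass_window + |dri|/ri_window wins; remaining ties go to the
# earliest-created bin. Returns the assignment plus the augmented center
# list.
greedy_assign <- function(peaks, centers, t) {
  ord <- order(-peaks$area, peaks$mz, peaks$ri, peaks$peak_id)
  cm <- centers$center_mz
  cr <- centers$center_ri
  cid <- centers$bin_id
  next_id <- if (length(cid)) max(cid) + 1L else 1L
  bin_id <- integer(nrow(peaks))
  for (i in ord) {
    dmz <- abs(peaks$mz[i] - cm)
    dri <- abs(peaks$ri[i] - cr)
    ok <- which(dmz <= t$mass_window & dri <= t$ri_window)
    if (length(ok)) {
      d <- dmz[ok] / t$mass_window + dri[ok] / t$ri_window
      bin_id[i] <- cid[ok[which.min(d)]]
    } else {
      bin_id[i] <- next_id
      cm <- c(cm, peaks$mz[i])
      cr <- c(cr, peaks$ri[i])
      cid <- c(cid, next_id)
      next_id <- next_id + 1L
    }
  }
  list(bin_id = bin_id,
       centers = data.frame(bin_id = cid, center_mz = cm, center_ri = cr))
}

# Select the MS1 peaks inside the RI analysis window.
ms1_analysis_peaks <- function(x, t) {
  peaks <- if (inherits(x, "ps_sample_set")) x$peaks else x
  if (any(!is.finite(peaks$ri))) {
    stop("peaks lack retention indices; run assign_retention_index() first")
  }
  peaks[peaks$ms_level == 1L &
          peaks$ri >= t$ri_range[1] & peaks$ri <= t$ri_range[2], ,
        drop = FALSE]
}

#' Seed ion bins from MS1 peaks
#'
#' First binning pass: ions are sorted by area in descending order and
#' ions with smaller areas are binned around ions with larger areas, the
#' larger ions serving as the bin centers.
#'
#' @param x a `ps_sample_set` or peak data.frame with `ri` assigned.
#' @param t a [ps_thresholds()] object.
#' @return A `ps_binning` object: peaks with bin assignments and singlet
#'   flags, a bin table, and a binning report.
#' @export
seed_bins <- function(x, t = ps_thresholds()) {
  peaks <- ms1_analysis_peaks(x, t)
  samples <- if (inherits(x, "ps_sample_set")) x$samples else
    unique(peaks$sample_id)
  empty <- data.frame(bin_id = integer(0), center_mz = numeric(0),
                      center_ri = numeric(0))
  res <- greedy_assign(peaks, empty, t)
  peaks$bin_id <- res$bin_id
  new_binning(peaks, res$centers, samples)
}

new_binning <- function(peaks, centers, samples, report = NULL) {
  peaks <- flag_singlets(peaks)
  b <- structure(
    list(peaks = peaks, bins = centers, samples = samples,
         report = report %||% list(n_bins = nrow(centers),
                                   n_collisions = count_collisions(peaks),
                                   n_iterations = 0L, n_migrated = 0L)),
    class = "ps_binning"
  )
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flag_singlets <- function(peaks) {
  key <- paste(peaks$bin_id, peaks$sample_id, sep = "\r")
  peaks$is_singlet <- !(key %in% key[duplicated(key)])
  peaks
}

count_collisions <- function(peaks) {
  key <- paste(peaks$bin_id, peaks$sample_id, sep = "\r")
  sum(table(key) > 1L)
}

#' Compute per-bin statistics over singlet ions
#'
#' Means and standard deviations of mass, RI, RT and area are computed
#' from the singlet ions of each bin; multiplet ions remain bin members
#' but are excluded from all statistics. The SD of a single-singlet bin
#' is 0. The filled fraction is the share of study samples contributing
#' a singlet. Bins with no singlet ion get `NA` statistics and are
#' removed at the next [recenter_and_prune()].
#'
#' @param b a `ps_binning`.
#' @return `b` with its bin table populated.
#' @export
compute_bin_stats <- function(b) {
  peaks <- b$peaks
  sing <- peaks[peaks$is_singlet, , drop = FALSE]
  ids <- b$bins$bin_id
  grp <- factor(sing$bin_id, levels = ids)
  agg <- function(v, f) as.numeric(tapply(v, grp, f))
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  n_sing <- as.integer(table(grp))
  all_grp <- factor(peaks$bin_id, levels = ids)
  n_total <- as.integer(table(all_grp))
  stats <- data.frame(
    bin_id = ids,
    center_mz = b$bins$center_mz,
    center_ri = b$bins$center_ri,
    mean_mz = agg(sing$mz, mean), sd_mz = agg(sing$mz, sd0),
    mean_ri = agg(sing$ri, mean), sd_ri = agg(sing$ri, sd0),
    mean_rt = agg(sing$rt, mean), sd_rt = agg(sing$rt, sd0),
    mean_area = agg(sing$area, mean), sd_area = agg(sing$area, sd0),
    n_singlets = n_sing,
    n_multiplets = n_total - n_sing,
    filled_fraction = n_sing / length(b$samples)
  )
  b$bins <- stats
  b$report$n_bins <- nrow(stats)
  b
}

#' Recenter bins on their singlet means and drop empty bins
#'
#' Resets each bin's center mass and center RI to its singlet mean mass
#' and mean RI, accounting for the actual ion distribution within the
#' bin, and removes all bins that have no singlet ions.
#'
#' @param b a `ps_binning` with current statistics.
#' @return `b` with updated centers.
#' @export
recenter_and_prune <- function(b) {
  keep <- b$bins$n_singlets > 0
  bins <- b$bins[keep, , drop = FALSE]
  bins$center_mz <- bins$mean_mz
  bins$center_ri <- bins$mean_ri
  b$bins <- bins
  b
}

#' Re-bin all ions against the current bin centers
#'
#' Every ion is re-assigned to the recentered bins; an ion that cannot
#' be binned into any of them opens a new bin with its own mass and RI
#' as the center.
#'
#' @param b a `ps_binning` after [recenter_and_prune()].
#' @param t a [ps_thresholds()] object.
#' @return `b` with fresh assignments.
#' @export
rebin <- function(b, t = ps_thresholds()) {
  centers <- b$bins[c("bin_id", "center_mz", "center_ri")]
  res <- greedy_assign(b$peaks, centers, t)
  peaks <- b$peaks
  peaks$bin_id <- res$bin_id
  new_binning(peaks, res$centers, b$samples, b$report)
}

# Canonical signature of the peak -> bin partition, independent of bin
# ids, for convergence detection.
partition_signature <- function(b) {
  parts <- split(b$peaks$peak_id, b$peaks$bin_id)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, "", 1))])
}

#' Run the full iterative binning procedure
#'
#' Seeds bins in descending area order, then repeats the
#' statistics/recenter/re-bin cycle until the peak-to-bin partition is
#' unchanged or `t$max_iterations` is reached, yielding an optimized
#' binning of all ions.
#'
#' @param x a `ps_sample_set` or peak data.frame with `ri` assigned.
#' @param t a [ps_thresholds()] object.
#' @return A converged `ps_binning` whose report records the number of
#'   bins, collisions (multiplet (sample, bin) pairs) and iterations.
#' @examples
#' sim <- simulate_study(preset_coelution(), sim_config(n_samples = 6))
#' b <- iterate_binning(sim$sample_set)
#' b$report$n_bins
#' @export
iterate_binning <- function(x, t = ps_thresholds()) {
  b <- seed_bins(x, t)
  if (nrow(b$peaks) == 0) return(compute_bin_stats(b))
  sig <- partition_signature(b)
  iters <- 0L
  for (i in seq_len(t$max_iterations)) {
    b <- compute_bin_stats(b)
    b <- recenter_and_prune(b)
    b <- rebin(b, t)
    iters <- iters + 1L
    new_sig <- partition_signature(b)
    if (identical(new_sig, sig)) break
    sig <- new_sig
  }
  b <- compute_bin_stats(b)
  b$report$n_iterations <- iters
  b$report$n_collisions <- count_collisions(b$peaks)
  b
}

#' Recover outlier ions from under-filled bins
#'
#' A bin that is not 100% filled may be missing ions that fell just
#' outside its mass and/or RI window in some samples. Working from the
#' more filled bins to the less filled bins, each missing sample's ions
#' are searched in less filled bins within the extended mass and RI
#' windows of the bin center; a candidate qualifies only if its area
#' lies within `outlier_sd_multiple` standard deviations of the bin's
#' singlet mean area, and the best-matched candidate (smallest combined
#' normalized mass/RI distance) is migrated into the bin. Bins with
#' fewer than 3 singlets are not recovery targets, since their area SD
#' is not meaningful. The total peak count is conserved.
#'
#' @param b a converged `ps_binning` with current statistics.
#' @param t a [ps_thresholds()] object.
#' @return `b` with migrations applied, statistics recomputed, and
#'   `report$n_migrated` set.
#' @export
recover_outlier_ions <- function(b, t = ps_thresholds()) {
  b <- compute_bin_stats(b)
  bins <- b$bins
  peaks <- b$peaks
  fill <- stats::setNames(bins$filled_fraction, bins$bin_id)
  ord <- order(-bins$filled_fraction, -bins$n_singlets, bins$bin_id)
  n_migrated <- 0L
  for (k in ord) {
    tb <- bins[k, ]
    if (tb$n_singlets < 3) next
    if (tb$filled_fraction >= 1) next
    present <- unique(peaks$sample_id[peaks$bin_id == tb$bin_id])
    missing <- setdiff(b$samples, present)
    for (s in missing) {
      cand <- which(
        peaks$sample_id == s &
          peaks$bin_id != tb$bin_id &
          fill[as.character(peaks$bin_id)] < fill[as.character(tb$bin_id)] &
          abs(peaks$mz - tb$center_mz) <= t$extended_mass_window &
          abs(peaks$ri - tb$center_ri) <= t$extended_ri_window &
          abs(peaks$area - tb$mean_area) <=
            t$outlier_sd_multiple * tb$sd_area
      )
      if (!length(cand)) next
      d <- abs(peaks$mz[cand] - tb$center_mz) / t$extended_mass_window +
        abs(peaks$ri[cand] - tb$center_ri) / t$extended_ri_window
      best <- cand[which.min(d)]
      peaks$bin_id[best] <- tb$bin_id
      fill[as.character(tb$bin_id)] <-
        fill[as.character(tb$bin_id)] + 1 / length(b$samples)
      n_migrated <- n_migrated + 1L
    }
  }
  b$peaks <- flag_singlets(peaks)
  # drop bins emptied by migration; bins that merely lost their singlet
  # keep their members and are skipped downstream (no usable statistics)
  b$bins <- b$bins[b$bins$bin_id %in% unique(b$peaks$bin_id), , drop = FALSE]
  b <- compute_bin_stats(b)
  b$report$n_migrated <- b$report$n_migrated + n_migrated
  b$report$n_collisions <- count_collisions(b$peaks)
  b
}

#' Export the bin table
#'
#' @param b a `ps_binning` with statistics.
#' @param path optional CSV output path; when `NULL` the data.frame is
#'   returned invisibly without writing.
#' @return The bin table data.frame.
#' @export
write_bin_table <- function(b, path = NULL) {
  tab <- b$bins
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' @export
print.ps_binning <- function(x, ...) {
  cat(sprintf(
    "Ion binning: %d peaks in %d bins (%d collisions, %d iterations, %d migrated)\n",
    nrow(x$peaks), nrow(x$bins), x$report$n_collisions,
    x$report$n_iterations, x$report$n_migrated))
  invisible(x)
}
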