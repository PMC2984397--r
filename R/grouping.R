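#' @section Grouping:
#' Ions produced from the same metabolite share that metabolite's
#' biological variability across the study samples and therefore
#' correlate, while ions of different chemical origin are largely
#' non-covariant. Bins are sorted by mean area in descending order;
#' using the larger bins as the normalizer, smaller bins are grouped
#' around them when their common-singlet areas correlate above the
#' threshold. Each group is the pseudo-spectrum of one (known or
#' unknown) metabolite.
#' @name grouping
NULL

#' Singlet area matrix of a binning
#'
#' The samples-by-bins matrix of singlet ion areas (`NA` where a sample
#' contributes no singlet to the bin); the basis of every correlation in
#' grouping and rescue.
#'
#' @param b a `ps_binning`.
#' @return numeric matrix, rownames = sample ids, colnames = bin ids.
#' @export
singlet_area_matrix <- function(b) {
  sing <- b$peaks[b$peaks$is_singlet, , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(b$samples), ncol = nrow(b$bins),
              dimnames = list(b$samples, as.character(b$bins$bin_id)))
  m[cbind(match(sing$sample_id, b$samples),
          match(as.character(sing$bin_id), colnames(m)))] <- sing$area
  m
}

#' Paired common-singlet areas of two bins
#'
#' Returns the per-sample area pairs over samples that are singlet in
#' both bins, excluding samples where either area exceeds
#' `max_linear_area` (detector-saturation guard).
#'
#' @param a,b bin ids (or column names of `m`).
#' @param m singlet area matrix from a `ps_binning` (samples x bins).
#' @param t a [ps_thresholds()] object.
#' @return list with `sample_ids`, `areas_a`, `areas_b`.
#' @export
common_singlets <- function(a, b, m, t = ps_thresholds()) {
  va <- m[, as.character(a)]
  vb <- m[, as.character(b)]
  keep <- is.finite(va) & is.finite(vb) &
    va <= t$max_linear_area & vb <= t$max_linear_area
  list(sample_ids = rownames(m)[keep],
       areas_a = unname(va[keep]),
       areas_b = unname(vb[keep]))
}

#' Pearson correlation of paired bin areas
#'
#' Standard Pearson product-moment correlation of the common singlet
#' areas of two bins. Undefined cases (fewer than 2 pairs, or zero
#' variance in either vector, as for compounds with limited biological
#' variability) return `NA` and are treated as "not correlated" by
#' callers.
#'
#' @param pairs output of [common_singlets()].
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
pearson <- function(pairs) {
  x <- pairs$areas_a
  y <- pairs$areas_b
  if (length(x) < 2) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Relative standard deviation of the paired area ratio
#'
#' RSD (percent, 100 * SD / mean) of the per-sample ratios
#' `areas_a / areas_b`. A single pair gives 0%.
#'
#' @param pairs output of [common_singlets()].
#' @return RSD in percent.
#' @export
area_ratio_rsd <- function(pairs) {
  r <- pairs$areas_a / pairs$areas_b
  if (length(r) < 2) return(0)
  100 * stats::sd(r) / mean(r)
}

#' Group correlated bins into per-metabolite pseudo-spectra
#'
#' Bins are processed by mean area in descending order. The largest
#' unassigned bin opens a new group as its normalizer; every remaining
#' unassigned (smaller) bin joins the group when all of the following
#' hold: the difference of mean RIs is at most `max_ri_difference`, the
#' bins share at least `min_correlated_ions` common singlets, the RSD of
#' the common-singlet area ratio is at most `max_rsd_pct`, and the
#' Pearson correlation is at least `min_correlation`. Each bin belongs
#' to exactly one group; bins that attach nowhere become singleton
#' groups.
#'
#' @param b a `ps_binning` with statistics.
#' @param t a [ps_thresholds()] object.
#' @return A `ps_groups` object: the bin table augmented with
#'   `group_id`, `is_normalizer`, `correlation` (with the group's
#'   normalizer), `n_common` and `rescued`; a group table; and the
#'   singlet area matrix used.
#' @examples
#' sim <- simulate_study(preset_coelution(), sim_config(n_samples = 8))
#' g <- group_bins(iterate_binning(sim$sample_set))
#' table(g$bins$group_id)
#' @export
group_bins <- function(b, t = ps_thresholds()) {
  if (length(b$samples) < 2) stop("grouping requires at least 2 samples")
  m <- singlet_area_matrix(b)
  bins <- b$bins
  usable <- which(bins$n_singlets > 0)
  ord <- usable[order(-bins$mean_area[usable], bins$bin_id[usable])]
  group_id <- rep(NA_integer_, nrow(bins))
  correlation <- rep(NA_real_, nrow(bins))
  n_common <- rep(NA_integer_, nrow(bins))
  is_norm <- rep(FALSE, nrow(bins))
  next_gid <- 1L
  for (i in ord) {
    if (!is.na(group_id[i])) next
    gid <- next_gid
    next_gid <- next_gid + 1L
    group_id[i] <- gid
    is_norm[i] <- TRUE
    correlation[i] <- 1
    for (j in ord) {
      if (!is.na(group_id[j])) next
      if (abs(bins$mean_ri[j] - bins$mean_ri[i]) > t$max_ri_difference) next
      pairs <- common_singlets(bins$bin_id[i], bins$bin_id[j], m, t)
      nc <- length(pairs$areas_a)
      if (nc < t$min_correlated_ions) next
      if (area_ratio_rsd(pairs) > t$max_rsd_pct) next
      r <- pearson(pairs)
      if (is.na(r) || r < t$min_correlation) next
      group_id[j] <- gid
      correlation[j] <- r
      n_common[j] <- nc
    }
  }
  bins$group_id <- group_id
  bins$is_normalizer <- is_norm
  bins$correlation <- correlation
  bins$n_common <- n_common
  bins$rescued <- NA_character_
  bins$form_label <- NA_character_
  new_groups(bins, m, b)
}

new_groups <- function(bins, m, binning) {
  gr <- bins[!is.na(bins$group_id), , drop = FALSE]
  norm <- gr[gr$is_normalizer, , drop = FALSE]
  groups <- data.frame(
    group_id = norm$group_id,
    normalizer_bin_id = norm$bin_id,
    group_ri = norm$mean_ri,
    normalizer_area = norm$mean_area,
    n_members = as.integer(table(factor(gr$group_id,
                                        levels = norm$group_id)))
  )
  groups <- groups[order(-groups$normalizer_area), , drop = FALSE]
  rownames(groups) <- NULL
  structure(list(bins = bins, groups = groups, area_matrix = m,
                 binning = binning),
            class = "ps_groups")
}

# Rebuild the group table after membership edits (rescues).
refresh_groups <- function(g) {
  bins <- g$bins
  for (gid in unique(stats::na.omit(bins$group_id))) {
    idx <- which(bins$group_id == gid)
    if (!length(idx)) next
    norm <- idx[which.max(bins$mean_area[idx])]
    bins$is_normalizer[idx] <- FALSE
    bins$is_normalizer[norm] <- TRUE
  }
  g2 <- new_groups(bins, g$area_matrix, g$binning)
  g2$monomers <- g$monomers
  g2
}

#' Export group membership and pseudo-spectra
#'
#' Writes one row per grouped bin (group id, normalizer flag,
#' correlation with the normalizer, mean mass/RI/area, relative area
#' scaled to normalizer = 100, ion form label when annotated).
#'
#' @param g a `ps_groups`.
#' @param path optional CSV output path.
#' @return The export data.frame, invisibly when writing.
#' @export
write_group_table <- function(g, path = NULL) {
  bins <- g$bins[!is.na(g$bins$group_id), , drop = FALSE]
  norm_area <- stats::setNames(g$groups$normalizer_area, g$groups$group_id)
  out <- data.frame(
    group_id = bins$group_id,
    bin_id = bins$bin_id,
    is_normalizer = bins$is_normalizer,
    mean_mz = bins$mean_mz,
    mean_ri = bins$mean_ri,
    mean_rt = bins$mean_rt,
    mean_area = bins$mean_area,
    relative_area_pct = 100 * bins$mean_area /
      norm_area[as.character(bins$group_id)],
    correlation = bins$correlation,
    n_common = bins$n_common,
    rescued = bins$rescued,
    form_label = bins$form_label
  )
  out <- out[order(out$group_id, -out$mean_area), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' @export
print.ps_groups <- function(x, ...) {
  nm <- sum(x$groups$n_members > 1)
  cat(sprintf("Bin groups: %d groups (%d with >1 member) over %d bins\n",
              nrow(x$groups), nm, sum(!is.na(x$bins$group_id))))
  invisible(x)
}
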