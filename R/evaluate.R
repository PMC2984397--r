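#' Score grouping recovery against simulation ground truth
#'
#' Each bin is labeled with the majority compound of its member peaks;
#' each group with the majority label of its bins. Purity is the
#' fraction of bins whose label agrees with their group's majority
#' label; completeness of a compound is the fraction of its bins
#' captured by the single group holding most of them. Both are reported
#' per group / per compound and as overall summaries.
#'
#' @param g a `ps_groups`.
#' @param truth ground-truth data.frame (`peak_id`, `compound`) from
#'   [simulate_study()].
#' @param ri_window optional numeric length-2: restrict scoring to bins
#'   whose mean RI lies in `[lo, hi]` (e.g. the co-elution window).
#' @return list with `purity`, `completeness`, `per_group`,
#'   `per_compound`, `bin_labels`.
#' @export
evaluate_grouping <- function(g, truth, ri_window = NULL) {
  bins <- g$bins[!is.na(g$bins$group_id) & g$bins$n_singlets > 0, ,
                 drop = FALSE]
  if (!is.null(ri_window)) {
    bins <- bins[bins$mean_ri >= ri_window[1] &
                   bins$mean_ri <= ri_window[2], , drop = FALSE]
  }
  peaks <- g$binning$peaks
  lab <- stats::setNames(truth$compound, truth$peak_id)
  majority <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  bins$compound <- vapply(bins$bin_id, function(bid) {
    majority(lab[peaks$peak_id[peaks$bin_id == bid]])
  }, "")
  per_group <- do.call(rbind, lapply(split(bins, bins$group_id),
                                     function(d) {
    maj <- majority(d$compound)
    data.frame(group_id = d$group_id[1], n_bins = nrow(d),
               majority_compound = maj,
               purity = mean(d$compound == maj))
  }))
  rownames(per_group) <- NULL
  group_maj <- stats::setNames(per_group$majority_compound,
                               per_group$group_id)
  correct <- bins$compound == group_maj[as.character(bins$group_id)]
  per_compound <- do.call(rbind, lapply(split(bins, bins$compound),
                                        function(d) {
    best <- max(table(d$group_id))
    data.frame(compound = d$compound[1], n_bins = nrow(d),
               completeness = best / nrow(d))
  }))
  rownames(per_compound) <- NULL
  list(purity = mean(correct),
       completeness = mean(per_compound$completeness),
       per_group = per_group, per_compound = per_compound,
       bin_labels = bins[c("bin_id", "group_id", "compound")])
}

#' Monomer-mass recovery errors
#'
#' For every simulated compound that carries a monomer mass, locates the
#' group holding the majority of the compound's bins and reports the
#' absolute difference between that group's inferred monomer mass and
#' the true one.
#'
#' @param g a `ps_groups` with monomers inferred ([infer_monomers()]).
#' @param truth ground-truth data.frame from [simulate_study()].
#' @param specs the compound specs the simulation was built from.
#' @return data.frame `compound`, `true_monomer`, `inferred_monomer`,
#'   `abs_error`.
#' @export
monomer_errors <- function(g, truth, specs) {
  ev <- evaluate_grouping(g, truth)
  bl <- ev$bin_labels
  do.call(rbind, lapply(specs, function(sp) {
    if (!is.finite(sp$monomer_mz)) return(NULL)
    mine <- bl[bl$compound == sp$name, , drop = FALSE]
    if (nrow(mine) == 0) {
      return(data.frame(compound = sp$name, true_monomer = sp$monomer_mz,
                        inferred_monomer = NA_real_, abs_error = NA_real_))
    }
    gid <- as.integer(names(sort(table(mine$group_id),
                                 decreasing = TRUE))[1])
    inferred <- g$monomers$monomer_mz[g$monomers$group_id == gid]
    if (!length(inferred)) inferred <- NA_real_
    data.frame(compound = sp$name, true_monomer = sp$monomer_mz,
               inferred_monomer = inferred,
               abs_error = abs(inferred - sp$monomer_mz))
  }))
}
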