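#' @section Chemical intelligence:
#' In LC/MS the ions originating from one chemical include in-source
#' fragments, isotopes, adducts (H+, Na+, K+, Cl-, NH4+, formate, water
#' loss, ...) and multimers (2m, 3m, ...). Given a measured ion mass and
#' a hypothesized ion form, the monomer mass is
#' `(measured - adduct) / n_imer`; enumerating forms over all bins of a
#' group and accumulating area-times-probability scores on merged
#' candidate masses yields the most probable monomer mass, which in turn
#' labels each bin with its most probable ion form and drives the rescue
#' of mass-consistent adduct and isotope bins mis-grouped at the strict
#' correlation threshold.
#' @name chem-intel
NULL

# 13C spacing; dominant isotope pattern in biological small molecules.
ISOTOPE_OFFSETS <- c(1.00335, 2.00670)

#' The default adduct and multimer form table
#'
#' Each row is a hypothesized ion form: a label, the adduct mass shift
#' (Th, may be negative for losses), the number of monomer copies in the
#' aggregate, and the prior probability (percent) of observing the form.
#' The shipped table is used as printed in its source configuration; a
#' few rows carry labels that disagree with the sign of their numeric
#' adduct mass (e.g. "3 m-H" with adduct +1.00728, "m + H-H20" with
#' adduct -17.01) — the numeric columns are authoritative, the labels
#' are annotations.
#'
#' @param path optional CSV with columns `label`, `adduct_mz`, `n_imer`,
#'   `probability_pct` to use instead of the shipped table.
#' @param mode optional filter: `"positive"` or `"negative"` restricts
#'   the table to forms whose label matches that ionization mode; the
#'   default keeps the full table.
#' @return data.frame of ion forms.
#' @export
default_adduct_table <- function(path = NULL, mode = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "adduct_forms.csv",
                        package = "pseudospec", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "adduct_mz", "n_imer", "probability_pct")
                %in% names(tab)),
            all(tab$n_imer >= 1),
            all(tab$probability_pct > 0 & tab$probability_pct <= 100))
  if (!is.null(mode)) {
    neg <- grepl("-$|m-H|Cl|Form", tab$label) & !grepl("H20", tab$label)
    tab <- if (mode == "negative") tab[neg, , drop = FALSE]
           else tab[!neg, , drop = FALSE]
  }
  tab
}

#' Monomer mass from a measured ion mass under an ion-form hypothesis
#'
#' The true (monomer) mass is recovered from the measured mass as
#' `(measured - adduct) / n_imer`. Non-positive results mean the form
#' cannot explain the ion and must be rejected by the caller.
#'
#' @param measured_mz measured ion m/z (Th).
#' @param form one row of an adduct table (or any list with `adduct_mz`
#'   and `n_imer`).
#' @return monomer m/z (Th).
#' @examples
#' h <- list(adduct_mz = 1.00728, n_imer = 1)
#' monomer_mass(269.088, h) # protonated molecular ion of inosine
#' @export
monomer_mass <- function(measured_mz, form) {
  (measured_mz - form$adduct_mz) / form$n_imer
}

#' Predicted measured mass of a monomer under an ion form
#'
#' Inverse of [monomer_mass()]: `n_imer * monomer + adduct`.
#'
#' @param monomer_mz monomer m/z (Th).
#' @param form one row of an adduct table.
#' @return predicted measured m/z (Th).
#' @export
predict_measured_mass <- function(monomer_mz, form) {
  form$n_imer * monomer_mz + form$adduct_mz
}

#' Score candidate monomer masses for a group
#'
#' Every (bin, ion form) pair proposes a monomer mass, scored by the
#' product of the bin's mean peak area and the form probability. Bins
#' are visited from large to small peak area and forms from most to
#' least probable; a proposal within `candidate_merge_window` of an
#' existing candidate adds its score to that candidate (the candidate's
#' mass stays at its first contributor's value), otherwise it opens a
#' new candidate. Non-positive monomer masses are skipped.
#'
#' @param group_bins data.frame of the group's bins with `bin_id`,
#'   `mean_mz`, `mean_area`.
#' @param table adduct form table ([default_adduct_table()]).
#' @param t a [ps_thresholds()] object.
#' @return data.frame of candidates (`monomer_mz`, `score`,
#'   `n_contributors`), sorted by score descending, with a
#'   `contributors` attribute listing (bin_id, label) per candidate.
#' @export
score_monomer_candidates <- function(group_bins, table = default_adduct_table(),
                                     t = ps_thresholds()) {
  if (nrow(group_bins) == 0) stop("empty group")
  if (nrow(table) == 0) stop("empty adduct table")
  bins <- group_bins[order(-group_bins$mean_area, group_bins$bin_id), ,
                     drop = FALSE]
  forms <- table[order(-table$probability_pct), , drop = FALSE]
  cand_mz <- numeric(0)
  cand_score <- numeric(0)
  cand_area <- numeric(0)
  contributors <- list()
  for (i in seq_len(nrow(bins))) {
    for (f in seq_len(nrow(forms))) {
      mono <- monomer_mass(bins$mean_mz[i], forms[f, ])
      if (!is.finite(mono) || mono <= 0) next
      score <- bins$mean_area[i] * forms$probability_pct[f]
      hit <- which(abs(cand_mz - mono) <= t$candidate_merge_window)
      if (length(hit)) {
        k <- hit[1]
        cand_score[k] <- cand_score[k] + score
        cand_area[k] <- cand_area[k] + bins$mean_area[i]
        contributors[[k]] <- rbind(
          contributors[[k]],
          data.frame(bin_id = bins$bin_id[i], label = forms$label[f]))
      } else {
        cand_mz <- c(cand_mz, mono)
        cand_score <- c(cand_score, score)
        cand_area <- c(cand_area, bins$mean_area[i])
        contributors[[length(cand_mz)]] <-
          data.frame(bin_id = bins$bin_id[i], label = forms$label[f])
      }
    }
  }
  ord <- order(-cand_score, -cand_area)
  out <- data.frame(monomer_mz = cand_mz[ord], score = cand_score[ord],
                    total_area = cand_area[ord],
                    n_contributors = vapply(contributors[ord], nrow, 0L))
  attr(out, "contributors") <- contributors[ord]
  out
}

#' Most probable monomer mass
#'
#' The candidate with the maximal mass score; ties are broken toward the
#' candidate with the larger total contributing area.
#'
#' @param candidates output of [score_monomer_candidates()].
#' @return one-row data.frame (the top candidate).
#' @export
best_monomer_mass <- function(candidates) {
  candidates[1, , drop = FALSE]
}

#' Annotate each bin of a group with its most probable ion form
#'
#' Each bin is checked against the possible aggregates/adducts of the
#' group's monomer mass: the highest-probability form whose predicted
#' measured mass lies within `candidate_merge_window` of the bin's mean
#' mass labels the bin; bins explained by no form (e.g. in-source
#' fragments) are labeled `"unassigned"`.
#'
#' @param group_bins data.frame with `bin_id`, `mean_mz`.
#' @param monomer_mz the group's inferred monomer mass.
#' @param table adduct form table.
#' @param t a [ps_thresholds()] object.
#' @return character vector of labels aligned to `group_bins` rows.
#' @export
annotate_ion_forms <- function(group_bins, monomer_mz,
                               table = default_adduct_table(),
                               t = ps_thresholds()) {
  forms <- table[order(-table$probability_pct), , drop = FALSE]
  pred <- forms$n_imer * monomer_mz + forms$adduct_mz
  vapply(group_bins$mean_mz, function(mz) {
    hit <- which(abs(pred - mz) <= t$candidate_merge_window)
    if (length(hit)) forms$label[hit[1]] else "unassigned"
  }, "")
}

# shared search-and-migrate core for adduct and isotope rescue.
# expected_fn(group_norm_row, parent_bins) must return a data.frame with
# columns expected_mz, label and optionally max_area.
rescue_bins <- function(g, t, expected_fn, flag) {
  bins <- g$bins
  m <- g$area_matrix
  order_groups <- g$groups$group_id  # already sorted by normalizer area desc
  norm_area <- stats::setNames(g$groups$normalizer_area, g$groups$group_id)
  for (gid in order_groups) {
    norm_bin <- g$groups$normalizer_bin_id[g$groups$group_id == gid]
    ni <- which(bins$bin_id == norm_bin)
    if (!length(ni)) next
    targets <- expected_fn(gid, bins[which(bins$group_id == gid), , drop = FALSE])
    if (is.null(targets) || nrow(targets) == 0) next
    for (k in seq_len(nrow(targets))) {
      cand <- which(
        !is.na(bins$group_id) & bins$group_id != gid &
          norm_area[as.character(bins$group_id)] <
            norm_area[as.character(gid)]
      )
      cand <- cand[abs(bins$mean_mz[cand] - targets$expected_mz[k]) <=
                     t$mass_window &
                   abs(bins$mean_ri[cand] - bins$mean_ri[ni]) <= t$ri_window]
      if (!is.null(targets$max_area)) {
        cand <- cand[bins$mean_area[cand] <= targets$max_area[k]]
      }
      if (!length(cand)) next
      cors <- vapply(cand, function(j) {
        pairs <- common_singlets(bins$bin_id[ni], bins$bin_id[j], m, t)
        r <- pearson(pairs)
        if (is.na(r)) -Inf else r
      }, 0)
      best <- which.max(cors)
      if (cors[best] <= t$rescue_correlation) next
      j <- cand[best]
      bins$group_id[j] <- gid
      bins$correlation[j] <- cors[best]
      bins$rescued[j] <- flag
      bins$is_normalizer[j] <- FALSE
      bins$form_label[j] <- targets$label[k]
      g$bins <- bins
      g <- refresh_groups(g)
      bins <- g$bins
      norm_area <- stats::setNames(g$groups$normalizer_area,
                                   g$groups$group_id)
    }
  }
  g
}

#' Rescue missing adduct/multimer bins into larger groups
#'
#' Adduct and aggregate ions can be more variant across samples than the
#' main ion, so their correlation with the normalizer falls below the
#' grouping threshold and the bin lands in the wrong (smaller) group.
#' For each group, from the largest down: for each possible ion form the
#' expected measured mass is computed from the group's monomer mass;
#' bins currently in smaller groups within the mass window of that mass
#' and the RI window of the group's normalizer are correlated with the
#' normalizer, and the highest-correlating bin is migrated into the
#' group when its correlation exceeds `rescue_correlation`. Migrated
#' bins are flagged `"adduct"`. The total bin count is conserved.
#'
#' @param g a `ps_groups` with monomer masses computed (see
#'   [infer_monomers()]).
#' @param t a [ps_thresholds()] object.
#' @param table adduct form table.
#' @return `g` with migrations applied.
#' @export
recover_missing_adducts <- function(g, t = ps_thresholds(),
                                    table = default_adduct_table()) {
  if (is.null(g$monomers)) g <- infer_monomers(g, table, t)
  forms <- table[order(-table$probability_pct), , drop = FALSE]
  rescue_bins(g, t, function(gid, members) {
    mono <- g$monomers$monomer_mz[g$monomers$group_id == gid]
    if (!length(mono) || is.na(mono)) return(NULL)
    data.frame(expected_mz = forms$n_imer * mono + forms$adduct_mz,
               label = forms$label)
  }, flag = "adduct")
}

#' Rescue isotope bins into larger groups
#'
#' Same search-and-migrate logic as [recover_missing_adducts()], but the
#' expected masses are each grouped bin's mean mass shifted by the 13C
#' isotope spacings (+1.00335 and +2.00670 Th), and a candidate is only
#' eligible when its mean area is at most `isotope_area_fraction`
#' (default one half) of the parent ion's mean area.
#'
#' @param g a `ps_groups`.
#' @param t a [ps_thresholds()] object.
#' @return `g` with isotope migrations applied (flagged `"isotope"`).
#' @export
recover_isotopes <- function(g, t = ps_thresholds()) {
  rescue_bins(g, t, function(gid, members) {
    members <- members[order(-members$mean_area), , drop = FALSE]
    if (nrow(members) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(members)), function(i) {
      data.frame(
        expected_mz = members$mean_mz[i] + ISOTOPE_OFFSETS,
        label = sprintf("isotope %+0.5f of %.4f", ISOTOPE_OFFSETS,
                        members$mean_mz[i]),
        max_area = t$isotope_area_fraction * members$mean_area[i])
    }))
  }, flag = "isotope")
}

#' Infer the monomer mass of every group
#'
#' Runs [score_monomer_candidates()] and [best_monomer_mass()] per group
#' and stores the result on the `ps_groups` object.
#'
#' @param g a `ps_groups`.
#' @param table adduct form table.
#' @param t a [ps_thresholds()] object.
#' @return `g` with a `monomers` data.frame (`group_id`, `monomer_mz`,
#'   `score`).
#' @export
infer_monomers <- function(g, table = default_adduct_table(),
                           t = ps_thresholds()) {
  res <- lapply(g$groups$group_id, function(gid) {
    members <- g$bins[!is.na(g$bins$group_id) & g$bins$group_id == gid, ,
                      drop = FALSE]
    members <- members[is.finite(members$mean_area), , drop = FALSE]
    if (nrow(members) == 0) {
      return(data.frame(group_id = gid, monomer_mz = NA_real_,
                        score = NA_real_))
    }
    top <- best_monomer_mass(
      score_monomer_candidates(members, table, t))
    data.frame(group_id = gid, monomer_mz = top$monomer_mz,
               score = top$score)
  })
  g$monomers <- do.call(rbind, res)
  g
}
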