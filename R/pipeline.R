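#' Run the full deconvolution pipeline on a sample set
#'
#' Assigns retention indices when standards are attached and RIs are
#' missing, runs iterative binning, recovers outlier ions from
#' under-filled bins, groups correlated bins into pseudo-spectra, infers
#' each group's monomer mass, rescues mis-grouped adduct and isotope
#' bins at the relaxed correlation threshold, and annotates every
#' grouped bin with its most probable ion form.
#'
#' @param s a `ps_sample_set`.
#' @param t a [ps_thresholds()] object.
#' @param adducts adduct form table.
#' @param rescue run the adduct/isotope rescue passes (default TRUE).
#' @return A `ps_groups` with monomers, annotations and an updated
#'   report reachable via `$binning$report`.
#' @examples
#' sim <- simulate_study(preset_coelution(), sim_config(n_samples = 8))
#' res <- ps_deconvolute(sim$sample_set)
#' res$groups
#' @export
ps_deconvolute <- function(s, t = ps_thresholds(),
                           adducts = default_adduct_table(),
                           rescue = TRUE) {
  if (any(!is.finite(s$peaks$ri))) {
    if (is.null(s$standards)) {
      stop("peaks lack retention indices and no standards are attached")
    }
    s <- assign_retention_index(s)
  }
  b <- iterate_binning(s, t)
  b <- recover_outlier_ions(b, t)
  g <- group_bins(b, t)
  g <- infer_monomers(g, adducts, t)
  if (rescue) {
    g <- recover_missing_adducts(g, t, adducts)
    g <- recover_isotopes(g, t)
    g <- infer_monomers(g, adducts, t)
  }
  # ion-form labels for every grouped bin (rescued labels are kept)
  for (gid in g$groups$group_id) {
    idx <- which(!is.na(g$bins$group_id) & g$bins$group_id == gid &
                   is.na(g$bins$rescued))
    if (!length(idx)) next
    mono <- g$monomers$monomer_mz[g$monomers$group_id == gid]
    g$bins$form_label[idx] <-
      annotate_ion_forms(g$bins[idx, , drop = FALSE], mono, adducts, t)
  }
  g
}

stage_counts <- function(g) {
  list(n_bins = nrow(g$bins),
       n_collisions = g$binning$report$n_collisions,
       n_iterations = g$binning$report$n_iterations,
       n_migrated = g$binning$report$n_migrated,
       n_groups = nrow(g$groups),
       n_multi_groups = sum(g$groups$n_members > 1),
       n_rescued = sum(!is.na(g$bins$rescued)))
}

write_manifest <- function(out_dir, inputs, t, seed = NULL, counts = list()) {
  manifest <- list(
    tool = "pseudospec",
    version = as.character(utils::packageVersion("pseudospec")),
    inputs = inputs,
    thresholds = unclass(t),
    seed = seed,
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

#' Pipeline commands behind the command-line interface
#'
#' `cmd_simulate()` writes a synthetic peak table and its ground truth;
#' `cmd_deconvolute()` runs the full pipeline on a peak-table CSV and
#' writes the bin table, group table and run manifest;
#' `cmd_library()` builds a library from a deconvolution result or
#' matches one against an existing library, registering unknowns.
#' Every command records a `manifest.json` (inputs, resolved thresholds,
#' seed, per-stage counts) in its output directory; re-running with an
#' identical manifest reproduces identical outputs.
#'
#' @param preset `"coelution"` or `"lc"`, or a list of
#'   [compound_spec()]s.
#' @param out_dir output directory (created if needed).
#' @param cfg a [sim_config()].
#' @return `cmd_simulate`: paths written; `cmd_deconvolute`: the
#'   `ps_groups`; `cmd_library`: the library or match table. All
#'   invisibly.
#' @export
cmd_simulate <- function(preset = "coelution", out_dir, cfg = sim_config()) {
  specs <- if (is.character(preset)) {
    switch(preset, coelution = preset_coelution(), lc = preset_lc_adducts(),
           stop("unknown preset: ", preset))
  } else preset
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_study(specs, cfg)
  peaks_path <- file.path(out_dir, "peaks.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_peak_table(sim$sample_set, peaks_path)
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  write_manifest(out_dir, list(preset = if (is.character(preset)) preset
                               else "custom"),
                 ps_thresholds(), seed = cfg$seed,
                 counts = list(n_peaks = nrow(sim$sample_set$peaks),
                               n_samples = cfg$n_samples))
  invisible(c(peaks = peaks_path, truth = truth_path))
}

#' @rdname cmd_simulate
#' @param peaks_path peak-table CSV.
#' @param t a [ps_thresholds()] object (e.g. from [read_thresholds()]
#'   with CLI overrides applied).
#' @export
cmd_deconvolute <- function(peaks_path, out_dir, t = ps_thresholds()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- read_peak_table(peaks_path)
  if (nrow(s$peaks) == 0) {
    utils::write.csv(data.frame(), file.path(out_dir, "groups.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, list(peaks = peaks_path), t)
    return(invisible(NULL))
  }
  g <- ps_deconvolute(s, t)
  write_bin_table(g$binning, file.path(out_dir, "bins.csv"))
  write_group_table(g, file.path(out_dir, "groups.csv"))
  utils::write.csv(g$monomers, file.path(out_dir, "monomers.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, list(peaks = peaks_path), t,
                 counts = stage_counts(g))
  invisible(g)
}

#' @rdname cmd_simulate
#' @param action `"build"` or `"match"`.
#' @param library_path JSON library file; created by `"build"` when
#'   absent.
#' @param g a `ps_groups` from [cmd_deconvolute()] /
#'   [ps_deconvolute()].
#' @param s optional `ps_sample_set` for MS2 assembly.
#' @export
cmd_library <- function(action, library_path, g, s = NULL,
                        t = ps_thresholds(), out_dir = dirname(library_path)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lib <- if (file.exists(library_path)) read_library(library_path)
         else new_library()
  multi <- g$groups$group_id
  if (action == "build") {
    for (gid in multi) {
      entry <- build_library_entry(g, gid, s, t)
      lib <- add_entry(lib, entry)
    }
    write_library(lib, library_path)
    write_manifest(out_dir, list(library = library_path), t,
                   counts = list(n_entries = length(lib$entries)))
    return(invisible(lib))
  }
  if (action == "match") {
    rows <- lapply(multi, function(gid) {
      entry <- build_library_entry(g, gid, s, t)
      res <- register_unknown(entry, lib, t)
      lib <<- res$library
      top <- if (nrow(res$results)) res$results[1, ] else
        data.frame(entry_id = NA, name = NA, score = 0,
                   matched_ions = 0L, ri_delta = NA)
      data.frame(group_id = gid, best_entry = top$name,
                 score = top$score,
                 registered_as = if (is.null(res$entry)) NA_character_
                                 else res$entry$name)
    })
    report <- do.call(rbind, rows)
    write_library(lib, library_path)
    utils::write.csv(report, file.path(out_dir, "matches.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, list(library = library_path), t,
                   counts = list(n_queries = length(multi),
                                 n_unknown = sum(!is.na(report$registered_as))))
    return(invisible(report))
  }
  stop("unknown library action: ", action)
}

#' Correlation-threshold sensitivity sweep
#'
#' Re-runs grouping over a grid of `min_correlation` values on an
#' existing binning, reporting group counts so the user can pick the
#' threshold by inspection (the usual practice is trial and error
#' between 0.70 and 0.90, judged against known metabolites).
#'
#' @param b a `ps_binning`.
#' @param thresholds numeric vector of correlation thresholds to try.
#' @param t base [ps_thresholds()].
#' @return data.frame `min_correlation`, `n_groups`, `n_multi_groups`,
#'   `n_grouped_bins`.
#' @export
sweep_correlation <- function(b, thresholds = seq(0.70, 0.90, by = 0.05),
                              t = ps_thresholds()) {
  do.call(rbind, lapply(thresholds, function(mc) {
    ti <- t
    ti$min_correlation <- mc
    g <- group_bins(b, ti)
    data.frame(min_correlation = mc, n_groups = nrow(g$groups),
               n_multi_groups = sum(g$groups$n_members > 1),
               n_grouped_bins = sum(g$groups$n_members[g$groups$n_members > 1]))
  }))
}
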