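#' Processing thresholds for binning, grouping and annotation
#'
#' Constructs the full set of tunable thresholds used by the pipeline:
#' the retention-index analysis window, the mass/RI binning windows, the
#' grouping (correlation) thresholds, and the chemical-intelligence and
#' library-matching parameters. All windows are half-widths: a window of
#' 0.4 Th admits ions within center +/- 0.4 Th.
#'
#' @param ri_range numeric length-2, retention-index analysis window
#'   `[lo, hi]`; peaks outside it are excluded before binning.
#' @param mass_window Th, half-width for binning ions together.
#' @param extended_mass_window Th, half-width used when searching
#'   neighboring bins for outlier ions missing from a sample.
#' @param ri_window RI units, half-width for binning ions together.
#' @param extended_ri_window RI units, half-width for the outlier search.
#' @param max_ri_difference RI units, maximal difference between the mean
#'   RIs of two bins for them to be grouped. Defaults to `ri_window`.
#' @param min_correlated_ions minimal number of common singlet ions two
#'   bins must share for a correlation to count.
#' @param max_linear_area area cap: common singlet pairs where either
#'   area exceeds this are excluded from correlation (detector
#'   saturation guard). Default `Inf` includes all ions.
#' @param max_rsd_pct maximal relative standard deviation (percent) of
#'   the per-sample area ratio between two bins for grouping.
#' @param min_correlation minimal Pearson correlation for grouping,
#'   usually between 0.70 and 0.90.
#' @param outlier_sd_multiple area tolerance, in standard deviations of
#'   a bin's singlet areas, for recovering outlier ions.
#' @param rescue_correlation relaxed correlation threshold for rescuing
#'   mass-consistent adduct/isotope bins into a group.
#' @param isotope_area_fraction maximal area of an isotope bin relative
#'   to its parent ion's bin.
#' @param candidate_merge_window Th, half-width within which two
#'   candidate monomer masses are considered the same candidate.
#' @param max_iterations cap on binning refinement iterations.
#' @param min_rel_intensity_pct minimal relative intensity (percent of
#'   the normalize bin) for an MS2 fragment to be kept.
#' @param ri_match_window RI units, gate for library matching.
#' @param match_accept_score minimal match score (0-100) below which a
#'   query group is registered as an unknown.
#'
#' @return An object of class `ps_thresholds` (a validated named list).
#' @examples
#' t <- ps_thresholds(min_correlation = 0.75)
#' t$mass_window
#' @export
ps_thresholds <- function(ri_range = c(-100, 9100),
                          mass_window = 0.4,
                          extended_mass_window = 0.5,
                          ri_window = 25,
                          extended_ri_window = 38,
                          max_ri_difference = ri_window,
                          min_correlated_ions = 3,
                          max_linear_area = Inf,
                          max_rsd_pct = 100,
                          min_correlation = 0.8,
                          outlier_sd_multiple = 4,
                          rescue_correlation = 0.4,
                          isotope_area_fraction = 0.5,
                          candidate_merge_window = 0.3,
                          max_iterations = 10,
                          min_rel_intensity_pct = 1,
                          ri_match_window = 50,
                          match_accept_score = 70) {
  t <- list(
    ri_range = as.numeric(ri_range),
    mass_window = mass_window,
    extended_mass_window = extended_mass_window,
    ri_window = ri_window,
    extended_ri_window = extended_ri_window,
    max_ri_difference = max_ri_difference,
    min_correlated_ions = min_correlated_ions,
    max_linear_area = max_linear_area,
    max_rsd_pct = max_rsd_pct,
    min_correlation = min_correlation,
    outlier_sd_multiple = outlier_sd_multiple,
    rescue_correlation = rescue_correlation,
    isotope_area_fraction = isotope_area_fraction,
    candidate_merge_window = candidate_merge_window,
    max_iterations = max_iterations,
    min_rel_intensity_pct = min_rel_intensity_pct,
    ri_match_window = ri_match_window,
    match_accept_score = match_accept_score
  )
  validate_thresholds(t)
  class(t) <- "ps_thresholds"
  t
}

validate_thresholds <- function(t) {
  stopifnot(
    length(t$ri_range) == 2, t$ri_range[1] < t$ri_range[2],
    t$mass_window > 0, t$extended_mass_window > 0,
    t$ri_window > 0, t$extended_ri_window > 0,
    t$max_ri_difference > 0,
    t$min_correlated_ions >= 1,
    t$max_linear_area > 0,
    t$max_rsd_pct >= 0,
    t$min_correlation >= 0, t$min_correlation <= 1,
    t$outlier_sd_multiple > 0,
    t$rescue_correlation >= 0, t$rescue_correlation <= 1,
    t$isotope_area_fraction > 0, t$isotope_area_fraction <= 1,
    t$candidate_merge_window > 0,
    t$max_iterations >= 1,
    t$min_rel_intensity_pct >= 0,
    t$ri_match_window > 0,
    t$match_accept_score >= 0, t$match_accept_score <= 100
  )
  invisible(t)
}

#' Read thresholds from a JSON configuration file
#'
#' Keys are the snake_case threshold names accepted by [ps_thresholds()];
#' keys absent from the file keep their defaults. Unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path path to a JSON file.
#' @param overrides named list applied on top of the file (e.g. values
#'   from command-line flags); same key rules.
#' @return A `ps_thresholds` object.
#' @export
read_thresholds <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(cfg)) stop("thresholds config must be a JSON object")
  }
  cfg[names(overrides)] <- overrides
  known <- names(formals(ps_thresholds))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown threshold name(s): ", paste(bad, collapse = ", "))
  }
  do.call(ps_thresholds, cfg)
}

#' @export
print.ps_thresholds <- function(x, ...) {
  cat("Processing thresholds:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
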