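#' @section Synthetic studies:
#' The generator emulates the statistical structure the method relies
#' on: every ion of a compound inherits that compound's per-sample
#' biological abundance (log-normal across samples), on top of which
#' each ion carries independent multiplicative measurement noise; ions
#' shared between co-eluting compounds sum their parents' contributions;
#' retention indices jitter around the compound's elution point; and a
#' small dropout rate removes ions from individual samples. Ground truth
#' (peak to compound labels) is emitted alongside the peak table so
#' recovery can be scored at every stage.
#' @name synthetic-studies
NULL

#' Specify a synthetic compound
#'
#' @param name compound name (ground-truth label).
#' @param ri elution point in retention-index units.
#' @param fragments data.frame with `mz` and `rel_int` (relative
#'   intensity in (0, 1]); the in-source fragment/EI ions of the
#'   compound. May be empty if `active_forms` supplies ions.
#' @param monomer_mz neutral monomer m/z; required when `active_forms`
#'   is non-empty.
#' @param active_forms character vector of adduct-form labels (rows of
#'   [default_adduct_table()]); each generates an ion at the predicted
#'   measured mass with relative intensity `probability_pct / 100`.
#' @param log_abundance_mean,log_abundance_sd parameters of the
#'   compound's log-normal biological abundance across samples.
#' @param ms2 optional data.frame `precursor_label`, `mz`, `rel_int`
#'   describing MS2 fragments of one of the compound's primary ions
#'   (`precursor_label` is a form label or `"fragment:<mz>"`).
#' @return A `ps_compound_spec`.
#' @export
compound_spec <- function(name, ri,
                          fragments = data.frame(mz = numeric(0),
                                                 rel_int = numeric(0)),
                          monomer_mz = NA_real_,
                          active_forms = character(0),
                          log_abundance_mean = 0,
                          log_abundance_sd = 0.7,
                          ms2 = NULL) {
  stopifnot(all(fragments$rel_int > 0), all(fragments$rel_int <= 1))
  if (length(active_forms) && !is.finite(monomer_mz)) {
    stop("active_forms require monomer_mz")
  }
  if (nrow(fragments) == 0 && !length(active_forms)) {
    stop("compound must have at least one ion")
  }
  structure(list(name = name, ri = ri, fragments = fragments,
                 monomer_mz = monomer_mz, active_forms = active_forms,
                 log_abundance_mean = log_abundance_mean,
                 log_abundance_sd = log_abundance_sd, ms2 = ms2),
            class = "ps_compound_spec")
}

#' Simulation configuration
#'
#' @param n_samples number of study samples (default 33).
#' @param seed RNG seed; runs are fully reproducible from it.
#' @param noise_sd per-ion multiplicative log-normal measurement noise.
#' @param ri_jitter_sd per-peak retention-index jitter (RI units).
#' @param dropout_rate probability an ion contribution is missing from a
#'   sample.
#' @param saturation_cap optional area ceiling (detector saturation).
#' @param base_area area scale of a relative intensity of 1 at unit
#'   abundance.
#' @return A `ps_sim_config`.
#' @export
sim_config <- function(n_samples = 33, seed = 1, noise_sd = 0.05,
                       ri_jitter_sd = 3, dropout_rate = 0.02,
                       saturation_cap = Inf, base_area = 1e5) {
  stopifnot(n_samples >= 2, noise_sd >= 0, ri_jitter_sd >= 0,
            dropout_rate >= 0, dropout_rate <= 1, base_area > 0)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 noise_sd = noise_sd, ri_jitter_sd = ri_jitter_sd,
                 dropout_rate = dropout_rate, saturation_cap = saturation_cap,
                 base_area = base_area),
            class = "ps_sim_config")
}

# Expand a compound spec into its ion list (mz, rel_int, ms1 row per ion).
compound_ions <- function(spec, adducts) {
  ions <- data.frame(mz = spec$fragments$mz, rel_int = spec$fragments$rel_int,
                     label = if (nrow(spec$fragments)) {
                       sprintf("fragment:%.4f", spec$fragments$mz)
                     } else character(0))
  for (lbl in spec$active_forms) {
    row <- adducts[adducts$label == lbl, ]
    if (nrow(row) != 1) stop("unknown adduct form label: ", lbl)
    ions <- rbind(ions, data.frame(
      mz = predict_measured_mass(spec$monomer_mz, row),
      rel_int = row$probability_pct / 100, label = lbl))
  }
  if (any(duplicated(round(ions$mz, 6)))) {
    stop("compound ", spec$name, ": overlapping fragment masses")
  }
  ions
}

#' Simulate a multi-sample study with ground truth
#'
#' Per sample `s` and compound `c`, the biological abundance is
#' `A_cs = exp(Normal(mean_c, sd_c))`; each of the compound's ions then
#' has area `base_area * A_cs * rel_int * exp(Normal(0, noise_sd))`.
#' Contributions of different compounds to an identical shared mass at
#' an identical elution point are summed into one peak, labeled in the
#' ground truth with the compound contributing the most. Each peak's RI
#' is the compound's elution RI plus `Normal(0, ri_jitter_sd)`; RT is
#' derived from RI via the identity calibration rt = ri / 1000, and
#' matching internal standards are attached so the retention-index
#' calibration path can be exercised end to end. Dropouts are removed
#' and areas clipped at `saturation_cap`.
#'
#' @param specs list of [compound_spec()] objects (a single spec is
#'   accepted too).
#' @param cfg a [sim_config()].
#' @param adducts adduct form table used to realize `active_forms`.
#' @return A `ps_simulation`: `sample_set`, `truth` (data.frame
#'   `peak_id`, `compound`), `specs`, `config`.
#' @examples
#' sim <- simulate_study(preset_coelution(), sim_config(n_samples = 5))
#' head(sim$sample_set$peaks)
#' @export
simulate_study <- function(specs, cfg = sim_config(),
                           adducts = default_adduct_table()) {
  if (inherits(specs, "ps_compound_spec")) specs <- list(specs)
  set.seed(cfg$seed)
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  abn <- vapply(specs, function(sp) {
    exp(stats::rnorm(cfg$n_samples, sp$log_abundance_mean,
                     sp$log_abundance_sd))
  }, numeric(cfg$n_samples))
  # one row per (compound, ion, sample) contribution
  contrib <- do.call(rbind, lapply(seq_along(specs), function(ci) {
    sp <- specs[[ci]]
    ions <- compound_ions(sp, adducts)
    do.call(rbind, lapply(seq_len(nrow(ions)), function(k) {
      area <- cfg$base_area * abn[, ci] * ions$rel_int[k] *
        exp(stats::rnorm(cfg$n_samples, 0, cfg$noise_sd))
      keep <- stats::runif(cfg$n_samples) >= cfg$dropout_rate
      data.frame(sample = samples, compound = sp$name, mz = ions$mz[k],
                 nominal_ri = sp$ri, area = area,
                 ion_label = ions$label[k])[keep, , drop = FALSE]
    }))
  }))
  # merge shared ions: identical mass at identical elution point
  key <- paste(contrib$sample, contrib$mz, contrib$nominal_ri, sep = "\r")
  grp <- match(key, unique(key))
  merged <- data.frame(
    sample = tapply(contrib$sample, grp, `[`, 1),
    mz = as.numeric(tapply(contrib$mz, grp, `[`, 1)),
    nominal_ri = as.numeric(tapply(contrib$nominal_ri, grp, `[`, 1)),
    area = as.numeric(tapply(contrib$area, grp, sum)),
    compound = tapply(seq_along(grp), grp, function(idx) {
      contrib$compound[idx][which.max(contrib$area[idx])]
    })
  )
  merged$ri <- merged$nominal_ri +
    stats::rnorm(nrow(merged), 0, cfg$ri_jitter_sd)
  merged$area <- pmin(merged$area, cfg$saturation_cap)
  peaks <- data.frame(
    peak_id = sprintf("P%06d", seq_len(nrow(merged))),
    sample_id = merged$sample, mz = merged$mz, rt = merged$ri / 1000,
    ri = merged$ri, area = merged$area, ms_level = 1L,
    precursor_mz = NA_real_
  )
  truth <- data.frame(peak_id = peaks$peak_id, compound = merged$compound)
  # MS2 fragments attached to surviving precursor ions
  ms2_rows <- do.call(rbind, lapply(seq_along(specs), function(ci) {
    sp <- specs[[ci]]
    if (is.null(sp$ms2) || nrow(sp$ms2) == 0) return(NULL)
    ions <- compound_ions(sp, adducts)
    do.call(rbind, lapply(unique(sp$ms2$precursor_label), function(pl) {
      prec_mz <- ions$mz[ions$label == pl]
      if (!length(prec_mz)) stop("ms2 precursor_label not an ion: ", pl)
      present <- merged$sample[abs(merged$mz - prec_mz) < 1e-9 &
                                 merged$nominal_ri == sp$ri]
      frag <- sp$ms2[sp$ms2$precursor_label == pl, , drop = FALSE]
      do.call(rbind, lapply(seq_len(nrow(frag)), function(k) {
        idx <- match(present, samples)
        area <- cfg$base_area * abn[idx, ci] * frag$rel_int[k] *
          exp(stats::rnorm(length(present), 0, cfg$noise_sd))
        data.frame(sample_id = present, mz = frag$mz[k],
                   rt = sp$ri / 1000, ri = sp$ri, area = area,
                   ms_level = 2L, precursor_mz = prec_mz,
                   compound = sp$name)
      }))
    }))
  }))
  if (!is.null(ms2_rows) && nrow(ms2_rows)) {
    ms2_rows$peak_id <- sprintf("P2%05d", seq_len(nrow(ms2_rows)))
    peaks <- rbind(peaks,
                   ms2_rows[c("peak_id", "sample_id", "mz", "rt", "ri",
                              "area", "ms_level", "precursor_mz")])
    truth <- rbind(truth, data.frame(peak_id = ms2_rows$peak_id,
                                     compound = ms2_rows$compound))
  }
  standards <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s, rt = 0:10, ri = 1000 * (0:10))
  }))
  ss <- sample_set(peaks, samples = samples, standards = standards)
  structure(list(sample_set = ss, truth = truth, specs = specs,
                 config = cfg),
            class = "ps_simulation")
}

#' Three co-eluting GC/EI compounds with shared fragment masses
#'
#' A phosphate-like, a leucine-like and a glycerol-like compound all
#' eluting at RI 1900, each with 6-7 EI fragment ions and with the
#' masses 73.0 and 147.1 shared by all three (trimethylsilyl-type
#' fragments common to derivatized metabolites), so the shared ions'
#' responses are sums over their parents. Abundance orderings across
#' samples differ because each compound draws its own log-normal
#' abundance (sd 0.7).
#'
#' @return list of three [compound_spec()] objects; the co-elution RI is
#'   attached as attribute `ri`.
#' @export
preset_coelution <- function() {
  specs <- list(
    compound_spec("phosphate_like", ri = 1900, fragments = data.frame(
      mz = c(99.0, 73.0, 299.2, 314.2, 133.1, 211.1, 147.1),
      rel_int = c(1.0, 0.9, 0.6, 0.45, 0.35, 0.25, 0.08))),
    compound_spec("leucine_like", ri = 1900, fragments = data.frame(
      mz = c(158.1, 86.1, 102.1, 130.1, 232.2, 73.0, 147.1),
      rel_int = c(1.0, 0.55, 0.3, 0.2, 0.12, 0.1, 0.07))),
    compound_spec("glycerol_like", ri = 1900, fragments = data.frame(
      mz = c(205.1, 103.1, 147.1, 117.1, 218.2, 73.0),
      rel_int = c(1.0, 0.8, 0.55, 0.35, 0.15, 0.12)))
  )
  attr(specs, "ri") <- 1900
  specs
}

#' LC-style compounds ionizing as adducts and multimers
#'
#' `n` compounds at well-separated retention indices, each observed as
#' the forms m + H, m + Na, 2 m + H and m-H2O of its monomer plus one
#' in-source fragment, for exercising monomer-mass inference and
#' adduct/isotope rescue.
#'
#' @param n number of compounds.
#' @return list of [compound_spec()] objects.
#' @export
preset_lc_adducts <- function(n = 10) {
  lapply(seq_len(n), function(k) {
    mono <- 150.05 + 37.73 * (k - 1)
    compound_spec(
      sprintf("lc_compound_%02d", k), ri = 1000 + 150 * k,
      monomer_mz = mono,
      active_forms = c("m + H", "m + Na", "2 m + H", "m-H2O"),
      fragments = data.frame(mz = mono - 42.75, rel_int = 0.3))
  })
}
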