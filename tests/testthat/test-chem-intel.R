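test_that("monomer mass and predicted measured mass invert each other for every form", {
  tab <- default_adduct_table()
  expect_equal(nrow(tab), 30)
  mH <- tab[tab$label == "m + H", ]
  expect_equal(monomer_mass(269.088, mH), 268.08072)

  # degenerate: measured equal to the adduct mass gives a zero monomer
  expect_equal(monomer_mass(1.00728, mH), 0)

  # hand arithmetic for multimer and loss forms
  na2 <- tab[tab$label == "2 m + Na", ]
  expect_equal(predict_measured_mass(268.081, na2), 2 * 268.081 + 22.98977)
  h2o <- tab[tab$label == "m-H2O", ]
  expect_equal(predict_measured_mass(268.081, h2o), 250.07098)

  # algebraic round trip across the whole table
  for (f in seq_len(nrow(tab))) {
    form <- tab[f, ]
    expect_equal(monomer_mass(predict_measured_mass(268.081, form), form),
                 268.081, tolerance = 1e-9)
  }
})

test_that("monomer candidates merge within the window and accumulate area x probability", {
  t <- ps_thresholds()
  tab <- default_adduct_table()
  grp <- data.frame(bin_id = 1:2, mean_mz = c(269.088, 291.070),
                    mean_area = c(1000, 300))
  cand <- score_monomer_candidates(grp, tab, t)
  top <- best_monomer_mass(cand)
  # m+H on the 269 bin and m+Na on the 291 bin agree on one monomer
  expect_equal(top$monomer_mz, 268.08072)
  expect_equal(top$score, 1000 * 100 + 300 * 90)
  expect_equal(top$n_contributors, 2)

  # single bin, single form
  one <- score_monomer_candidates(
    data.frame(bin_id = 1, mean_mz = 269.088, mean_area = 500),
    tab[tab$label == "m + H", , drop = FALSE], t)
  expect_equal(nrow(one), 1)
  expect_equal(one$score, 500 * 100)

  # bins inconsistent under every form pair stay separate candidates
  forms <- data.frame(label = "m + H", adduct_mz = 1.00728, n_imer = 1,
                      probability_pct = 100)
  two <- score_monomer_candidates(
    data.frame(bin_id = 1:2, mean_mz = c(100.0, 200.0),
               mean_area = c(10, 20)), forms, t)
  expect_equal(nrow(two), 2)
  expect_true(all(two$n_contributors == 1))

  expect_error(score_monomer_candidates(grp[0, ], tab, t), "empty group")
})

test_that("candidate scoring agrees with brute-force enumeration on small groups", {
  t <- ps_thresholds()
  tab <- default_adduct_table()
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(2:5, 1)
    mono <- runif(1, 120, 400)
    forms <- tab[sample(nrow(tab), 6), ]
    grp <- data.frame(bin_id = seq_len(n),
                      mean_mz = forms$n_imer[seq_len(n)] * mono +
                        forms$adduct_mz[seq_len(n)],
                      mean_area = round(runif(n, 50, 2000)))
    cand <- score_monomer_candidates(grp, tab, t)
    oracle <- oracle_monomer_top(grp, tab, t$candidate_merge_window)
    expect_equal(best_monomer_mass(cand)$score, oracle$score)
    expect_lt(abs(best_monomer_mass(cand)$monomer_mz - oracle$monomer_mz),
              t$candidate_merge_window + 1e-9)
  }
})

test_that("ion forms are annotated by probability among mass-consistent forms", {
  t <- ps_thresholds()
  tab <- default_adduct_table()
  mono <- 268.08072
  grp <- data.frame(bin_id = 1:2, mean_mz = c(269.088, 137.046),
                    mean_area = c(1000, 100))
  labels <- annotate_ion_forms(grp, mono, tab, t)
  expect_equal(labels[1], "m + H")
  expect_equal(labels[2], "unassigned")  # in-source fragment, not an adduct

  # the higher-probability form wins when several match the same mass
  custom <- data.frame(label = c("m + K", "rare"),
                       adduct_mz = c(39.954, 39.954),
                       n_imer = c(1, 1), probability_pct = c(10, 1))
  lab <- annotate_ion_forms(
    data.frame(bin_id = 1, mean_mz = mono + 39.954, mean_area = 1),
    mono, custom, t)
  expect_equal(lab, "m + K")
})

# a group of proportional m+H / m+Na ions plus a sodiated dimer whose
# extra variability keeps its correlation between 0.4 and 0.8
rescue_fixture <- function(dimer_areas) {
  a <- abundance_profile(20)
  mono <- 268.08072
  pk <- ion_series(c(mono + 1.00728, mono + 22.98977, 2 * mono + 22.98977),
                   cbind(1000 * a, 900 * a, dimer_areas), ri = 1200)
  sample_set(pk)
}

mid_corr_areas <- function() {
  a <- abundance_profile(20)
  set.seed(7)
  300 * a * exp(rnorm(20, 0, 0.5))
}

low_corr_areas <- function() {
  set.seed(43)
  300 * exp(rnorm(20, 0, 0.7))
}

test_that("mass-consistent adduct bins are rescued at the relaxed threshold", {
  t <- ps_thresholds()
  dimer <- mid_corr_areas()
  r0 <- cor(abundance_profile(20), dimer)
  expect_true(r0 > 0.4 && r0 < 0.8)  # scenario precondition
  g <- group_bins(iterate_binning(rescue_fixture(dimer), t), t)
  expect_equal(nrow(g$groups), 2)    # dimer stranded in its own group
  n_bins_before <- nrow(g$bins)
  g <- recover_missing_adducts(g, t)
  expect_equal(nrow(g$groups), 1)
  rescued <- g$bins[!is.na(g$bins$rescued), ]
  expect_equal(nrow(rescued), 1)
  expect_equal(rescued$rescued, "adduct")
  expect_equal(round(rescued$mean_mz, 3), round(2 * 268.08072 + 22.98977, 3))
  expect_gt(rescued$correlation, t$rescue_correlation)
  expect_equal(nrow(g$bins), n_bins_before)  # bins conserved
})

test_that("bins correlating below the rescue threshold stay where they are", {
  t <- ps_thresholds()
  dimer <- low_corr_areas()
  r0 <- cor(abundance_profile(20), dimer)
  expect_lt(r0, 0.4)
  g <- group_bins(iterate_binning(rescue_fixture(dimer), t), t)
  g2 <- recover_missing_adducts(g, t)
  expect_equal(nrow(g2$groups), 2)
  expect_true(all(is.na(g2$bins$rescued)))

  # and with no mass-consistent bins anywhere, nothing moves at all
  a <- abundance_profile(20)
  pk <- ion_series(c(269.09599, 150.0), cbind(1000 * a, 300 * rev(a)),
                   ri = 1200)
  g3 <- group_bins(iterate_binning(sample_set(pk), t), t)
  g4 <- recover_missing_adducts(g3, t)
  expect_identical(g3$bins$group_id, g4$bins$group_id)
})

test_that("isotope bins are rescued only below half the parent area", {
  t <- ps_thresholds()
  a <- abundance_profile(20)
  iso_ok <- 0.30 * 1000 * a * local({ set.seed(7); exp(rnorm(20, 0, 0.5)) })
  pk <- ion_series(c(250.10, 250.10 + 1.00335), cbind(1000 * a, iso_ok),
                   ri = 1500)
  g <- group_bins(iterate_binning(sample_set(pk), t), t)
  expect_equal(nrow(g$groups), 2)
  g <- recover_isotopes(g, t)
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$bins$rescued[!is.na(g$bins$rescued)], "isotope")

  # area ratio above isotope_area_fraction is rejected
  # above half the parent's mean area, yet still the smaller group
  iso_big <- 0.45 * 1000 * a * local({ set.seed(7); exp(rnorm(20, 0, 0.5)) })
  pk2 <- ion_series(c(250.10, 250.10 + 1.00335), cbind(1000 * a, iso_big),
                    ri = 1500)
  g2 <- recover_isotopes(group_bins(iterate_binning(sample_set(pk2), t), t), t)
  expect_equal(nrow(g2$groups), 2)
  expect_true(all(is.na(g2$bins$rescued)))
})

test_that("proportional isotope partners group directly at the strict threshold", {
  t <- ps_thresholds()
  a <- abundance_profile(15)
  pk <- ion_series(c(158.1, 232.2), cbind(1000 * a, 120 * a), ri = 1900)
  g <- group_bins(iterate_binning(sample_set(pk), t), t)
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$groups$n_members, 2)
})
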