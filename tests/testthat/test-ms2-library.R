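ms2_fixture <- function() {
  a <- abundance_profile(10)
  samples <- sprintf("S%02d", 1:10)
  ms1 <- peak_rows(samples, 269.088, ri = 1200, area = 1000 * a)
  frag <- function(mz, rel, idx) {
    peak_rows(samples[idx], mz, ri = 1200, area = rel * 1000 * a[idx],
              ms_level = 2L, precursor_mz = 269.088)
  }
  pk <- rbind(ms1,
              frag(137.046, 0.8, 1:8),
              frag(110.030, 0.5, 1:6),
              frag(57.000, 0.4, 1),        # below the singlet minimum
              frag(80.000, 0.003, 1:5))    # below 1% relative intensity
  sample_set(pk)
}

test_that("MS2 fragments are binned from singlet samples with count and intensity gates", {
  t <- ps_thresholds()
  s <- ms2_fixture()
  b <- iterate_binning(s, t)
  expect_equal(nrow(b$bins), 1)  # only the MS1 precursor is binned
  sp <- bin_secondary_ions(b$bins$bin_id[1], b, s, t)
  expect_s3_class(sp, "ps_ms2_spectrum")
  expect_equal(sort(round(sp$fragments$mean_mz, 3)), c(110.030, 137.046))
  expect_equal(sum(sp$fragments$relative_intensity_pct == 100), 1)
  expect_true(all(sp$fragments$n_singlets >= t$min_correlated_ions))
  # the larger-mean-intensity fragment is the normalize bin
  expect_equal(sp$fragments$mean_mz[which.max(sp$fragments$mean_intensity)],
               sp$fragments$mean_mz[sp$fragments$relative_intensity_pct == 100])
})

test_that("a study without MS2 data yields an empty, still valid spectrum", {
  t <- ps_thresholds()
  a <- abundance_profile(5)
  s <- sample_set(peak_rows(sprintf("S%d", 1:5), 158.1, 1900, 1000 * a))
  b <- iterate_binning(s, t)
  sp <- bin_secondary_ions(b$bins$bin_id[1], b, s, t)
  expect_equal(nrow(sp$fragments), 0)
})

three_ion_group <- function() {
  a <- abundance_profile(6)
  pk <- ion_series(c(100.0, 150.0, 200.0),
                   cbind(1000 * a, 500 * a, 100 * a), ri = 1500)
  s <- sample_set(pk)
  t <- ps_thresholds()
  g <- infer_monomers(group_bins(iterate_binning(s, t), t))
  list(g = g, s = s, t = t)
}

test_that("library entries normalize member areas to the group normalizer", {
  fx <- three_ion_group()
  expect_equal(nrow(fx$g$groups), 1)
  e <- build_library_entry(fx$g, fx$g$groups$group_id[1], fx$s, fx$t)
  expect_equal(e$ions$relative_area_pct, c(100, 50, 10))
  expect_equal(sum(e$ions$relative_area_pct == 100), 1)

  # singleton group -> one ion at 100%
  a <- abundance_profile(4)
  s1 <- sample_set(peak_rows(sprintf("S%d", 1:4), 300.0, 2000, a))
  t <- ps_thresholds()
  g1 <- group_bins(iterate_binning(s1, t), t)
  e1 <- build_library_entry(g1, g1$groups$group_id[1], s1, t)
  expect_equal(e1$ions$relative_area_pct, 100)
})

test_that("library JSON round trip preserves all entry fields", {
  fx <- three_ion_group()
  e <- build_library_entry(fx$g, fx$g$groups$group_id[1], fx$s, fx$t,
                           name = "test_compound")
  lib <- add_entry(new_library(), e)
  path <- tempfile(fileext = ".json")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(length(back$entries), 1)
  b <- back$entries[[1]]
  expect_equal(b$name, "test_compound")
  expect_equal(b$ions$mean_mz, e$ions$mean_mz)
  expect_equal(b$ions$relative_area_pct, e$ions$relative_area_pct)
  expect_equal(b$monomer_mz, e$monomer_mz)
  expect_equal(b$provenance$n_samples, 6)
})

test_that("MSP round trip keeps ion count, masses to 4 decimals, areas to 2", {
  fx <- three_ion_group()
  e <- build_library_entry(fx$g, fx$g$groups$group_id[1], fx$s, fx$t,
                           name = "msp_compound")
  e$ions$mean_mz <- e$ions$mean_mz + 0.123456  # exercise rounding
  lib <- add_entry(new_library(), e)
  path <- tempfile(fileext = ".msp")
  write_msp(lib, path)
  back <- read_msp(path)
  expect_equal(length(back$entries), 1)
  b <- back$entries[[1]]
  expect_equal(nrow(b$ions), nrow(e$ions))
  expect_equal(b$ions$mean_mz, round(e$ions$mean_mz, 4))
  expect_equal(b$ions$relative_area_pct, round(e$ions$relative_area_pct, 2))
  expect_equal(b$name, "msp_compound")
})

entry_from <- function(mzs, rels, ri, name = NULL) {
  structure(list(
    entry_id = NA_character_, name = name,
    ions = data.frame(mean_mz = mzs, mean_ri = ri, mean_rt = ri / 1000,
                      relative_area_pct = rels,
                      form_label = "unassigned"),
    monomer_mz = NA_real_, ms2 = list(),
    provenance = list(study_id = "test", n_samples = 4, thresholds = NULL)),
    class = "ps_library_entry")
}

test_that("matching scores self-hits at 100, disjoint spectra at 0, and is symmetric", {
  t <- ps_thresholds()
  e <- entry_from(c(100.0, 150.0, 200.0), c(100, 50, 10), 1500, "self")
  lib <- add_entry(new_library(), e)
  res <- match_library(e, lib, t)
  expect_equal(res$score[1], 100)
  expect_equal(res$matched_ions[1], 3)

  far <- entry_from(c(300.0, 350.0), c(100, 40), 1500, "far")
  expect_equal(match_library(far, lib, t)$score, 0)

  # outside the RI gate no candidate is returned at all
  shifted <- entry_from(c(100.0, 150.0, 200.0), c(100, 50, 10), 1700)
  expect_equal(nrow(match_library(shifted, lib, t)), 0)

  # symmetry on equal-length paired spectra
  x <- entry_from(c(100.0, 150.0, 200.0), c(100, 30, 60), 1500, "x")
  y <- entry_from(c(100.0, 150.0, 200.0), c(80, 100, 10), 1500, "y")
  s_xy <- match_library(x, add_entry(new_library(), y), t)$score
  s_yx <- match_library(y, add_entry(new_library(), x), t)$score
  expect_equal(s_xy, s_yx)
})

test_that("unknown registration assigns fresh increasing ids and later self-matches", {
  t <- ps_thresholds()
  lib <- new_library()
  q1 <- entry_from(c(100.0, 150.0), c(100, 40), 1500)
  r1 <- register_unknown(q1, lib, t)
  expect_equal(r1$entry$name, "UNKNOWN-1")
  q2 <- entry_from(c(400.0, 450.0), c(100, 70), 3000)
  r2 <- register_unknown(q2, r1$library, t)
  expect_equal(r2$entry$name, "UNKNOWN-2")
  expect_equal(length(r2$library$entries), 2)

  # the former unknown now matches its own entry at full score
  r3 <- register_unknown(q1, r2$library, t)
  expect_null(r3$entry)
  expect_equal(r3$results$name[1], "UNKNOWN-1")
  expect_equal(r3$results$score[1], 100)
})

test_that("an unknown is identified once an authentic standard entry is added", {
  t <- ps_thresholds()
  # urine-study unknown, registered first against an empty library
  unknown <- entry_from(c(192.1, 119.1, 133.1, 91.1), c(100, 65, 40, 30), 2750)
  r <- register_unknown(unknown, new_library(), t)
  expect_equal(r$entry$name, "UNKNOWN-1")
  # an authentic standard measured later (slightly different averages)
  authentic <- entry_from(c(192.1002, 119.0998, 133.1001, 91.0999),
                          c(98, 67, 41, 29), 2752, "equol_standard")
  lib2 <- add_entry(r$library, authentic)
  res <- match_library(unknown, lib2, t)
  expect_gte(res$score[1], t$match_accept_score)
  expect_true("equol_standard" %in% res$name[res$score >=
                                               t$match_accept_score])
})
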