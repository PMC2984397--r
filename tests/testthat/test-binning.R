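test_that("ions within the mass/RI windows share a bin, others split", {
  t <- ps_thresholds()
  # one ion recurring in 3 samples -> a single bin of 3 singlets
  pk <- peak_rows(c("S1", "S2", "S3"), 158.0, ri = 3000, area = c(10, 12, 9))
  b <- compute_bin_stats(seed_bins(sample_set(pk), t))
  expect_equal(nrow(b$bins), 1)
  expect_equal(b$bins$n_singlets, 3)
  expect_equal(b$bins$filled_fraction, 1)

  # masses separated by more than the window open distinct bins
  pk2 <- rbind(peak_rows("S1", 158.0, 3000, 10),
               peak_rows("S1", 158.9, 3000, 8))
  b2 <- seed_bins(sample_set(pk2), t)
  expect_equal(nrow(b2$bins), 2)

  # two ions of one sample in one bin: multiplet, one collision
  pk3 <- rbind(peak_rows("S1", 158.0, 3000, 10),
               peak_rows("S1", 158.1, 3001, 8),
               peak_rows("S2", 158.0, 3000, 11))
  b3 <- seed_bins(sample_set(pk3), t)
  expect_equal(nrow(b3$bins), 1)
  expect_equal(b3$report$n_collisions, 1)
  expect_equal(sum(!b3$peaks$is_singlet), 2)
})

test_that("bin statistics are computed over singlets only", {
  t <- ps_thresholds()
  pk <- rbind(peak_rows("S1", 100.0, 500, 10),
              peak_rows("S2", 100.0, 500, 20),
              peak_rows("S3", 100.0, 500, 100),   # multiplet pair
              peak_rows("S3", 100.1, 501, 5))
  b <- compute_bin_stats(seed_bins(sample_set(pk), t))
  expect_equal(nrow(b$bins), 1)
  # hand recomputation over the singlet subset {10, 20}
  expect_equal(b$bins$mean_area, mean(c(10, 20)))
  expect_equal(b$bins$sd_area, stats::sd(c(10, 20)))
  expect_equal(b$bins$n_multiplets, 2)

  # degenerate SD of a single-singlet bin is 0
  b1 <- compute_bin_stats(seed_bins(sample_set(peak_rows("S1", 100, 500, 10)), t))
  expect_equal(b1$bins$sd_area, 0)
})

test_that("iterative binning converges quickly on well-separated ions and is order-independent", {
  t <- ps_thresholds()
  prof <- abundance_profile(5)
  pk <- ion_series(c(100.0, 150.0, 200.0), cbind(prof, 2 * prof, 3 * prof),
                   ri = 1000)
  pk$peak_id <- sprintf("P%02d", seq_len(nrow(pk)))
  ss <- sample_set(pk)
  b <- iterate_binning(ss, t)
  expect_equal(nrow(b$bins), 3)
  expect_lte(b$report$n_iterations, 2)

  # permuting input rows leaves the partition unchanged
  set.seed(3)
  ss2 <- sample_set(pk[sample(nrow(pk)), ])
  b2 <- iterate_binning(ss2, t)
  expect_identical(canon_partition(b$peaks$peak_id, b$peaks$bin_id),
                   canon_partition(b2$peaks$peak_id, b2$peaks$bin_id))
})

test_that("greedy binning matches the independent oracle on random ion sets", {
  t <- ps_thresholds()
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    pk <- peak_rows(sample(sprintf("S%d", 1:4), n, replace = TRUE),
                    mz = runif(n, 100, 101.5),
                    ri = runif(n, 1000, 1080),
                    area = runif(n, 10, 1000))
    pk$peak_id <- sprintf("P%02d", seq_len(n))
    ss <- sample_set(pk)
    b <- seed_bins(ss, t)
    oracle <- oracle_greedy_bins(ss$peaks, t$mass_window, t$ri_window)
    expect_identical(canon_partition(b$peaks$peak_id, b$peaks$bin_id),
                     canon_partition(ss$peaks$peak_id, oracle))
  }
})

test_that("every MS1 peak sits in exactly one bin at every stage, and binning is idempotent", {
  t <- ps_thresholds()
  set.seed(9)
  sim <- simulate_study(preset_coelution(), sim_config(n_samples = 12, seed = 9))
  ss <- sim$sample_set
  n_ms1 <- sum(ss$peaks$ms_level == 1L)
  b <- seed_bins(ss, t)
  expect_equal(nrow(b$peaks), n_ms1)
  expect_false(any(is.na(b$peaks$bin_id)))
  b <- iterate_binning(ss, t)
  expect_equal(nrow(b$peaks), n_ms1)
  expect_true(all(b$peaks$bin_id %in% b$bins$bin_id))

  # re-running the whole procedure on its own output changes nothing
  b2 <- iterate_binning(b$peaks[, c("peak_id", "sample_id", "mz", "rt",
                                    "ri", "area", "ms_level",
                                    "precursor_mz")], t)
  expect_identical(canon_partition(b$peaks$peak_id, b$peaks$bin_id),
                   canon_partition(b2$peaks$peak_id, b2$peaks$bin_id))
})

# 30-sample study: a bin filled by 25 samples, sample S26 holding a peak
# just outside the mass window but inside the extended window.
outlier_fixture <- function(cand) {
  filled <- sprintf("S%02d", 1:25)
  pk <- rbind(peak_rows(filled, 100.0, 500, seq(900, 1100, length.out = 25)),
              cand)
  sample_set(pk, samples = sprintf("S%02d", 1:30))
}

test_that("outlier ions within 4 SD migrate into the more filled bin", {
  t <- ps_thresholds()
  cand <- peak_rows("S26", 100.45, 500, 1000)
  b <- recover_outlier_ions(iterate_binning(outlier_fixture(cand), t), t)
  big <- b$bins[which.max(b$bins$n_singlets), ]
  expect_equal(big$n_singlets, 26)
  expect_equal(big$filled_fraction, 26 / 30)
  expect_equal(b$report$n_migrated, 1)
  expect_equal(nrow(b$peaks), 26)  # conservation
})

test_that("candidates outside the 4 SD area window are not migrated", {
  t <- ps_thresholds()
  sd_area <- stats::sd(seq(900, 1100, length.out = 25))
  cand <- peak_rows("S26", 100.45, 500, 1000 + 5 * sd_area)
  b <- recover_outlier_ions(iterate_binning(outlier_fixture(cand), t), t)
  expect_equal(b$report$n_migrated, 0)
  expect_equal(max(b$bins$n_singlets), 25)
  expect_equal(nrow(b$peaks), 26)
})

test_that("with several eligible candidates only the best match migrates", {
  t <- ps_thresholds()
  cand <- rbind(peak_rows("S26", 100.45, 500, 1000),
                peak_rows("S26", 100.48, 500, 995))
  b <- recover_outlier_ions(iterate_binning(outlier_fixture(cand), t), t)
  expect_equal(b$report$n_migrated, 1)
  big_id <- b$bins$bin_id[which.max(b$bins$n_singlets)]
  migrated <- b$peaks[b$peaks$bin_id == big_id & b$peaks$sample_id == "S26", ]
  expect_equal(migrated$mz, 100.45)  # smaller normalized distance wins
  expect_equal(nrow(b$peaks), 27)
})
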