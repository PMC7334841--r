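qf_df <- function(p1, p2, p3, p4) {
  data.frame(chrom = rep("c", length(p1)), pos = seq_along(p1),
             p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}

test_that("pattern sums recover pure ABBA and BABA sites", {
  expect_equal(unname(site_pattern_sums(qf_df(0, 1, 1, 0))), c(1, 0))
  expect_equal(unname(site_pattern_sums(qf_df(1, 0, 1, 0))), c(0, 1))
  expect_equal(unname(site_pattern_sums(qf_df(numeric(0), numeric(0),
                                              numeric(0), numeric(0)))),
               c(0, 0))
})

test_that("frequency-weighted sums equal literal counts on haploid 0/1 data", {
  set.seed(8)
  for (rep in 1:3) {
    b <- replicate(4, sample(0:1, 20, replace = TRUE))
    got <- site_pattern_sums(qf_df(b[, 1], b[, 2], b[, 3], b[, 4]))
    want <- oracle_pattern_counts(b[, 1], b[, 2], b[, 3], b[, 4])
    expect_equal(unname(got), unname(as.numeric(want)))
  }
})

test_that("Patterson's D handles maximal, symmetric and degenerate input", {
  expect_equal(patterson_d(1, 0), 1)
  expect_equal(patterson_d(3.7, 3.7), 0)
  expect_true(is.na(patterson_d(0, 0)))
  expect_true(abs(patterson_d(runif(1, 0, 5), runif(1, 0, 5))) <= 1)
})

test_that("f_d is 1 under complete sharing and 0 with no excess", {
  expect_equal(fd_window(qf_df(rep(0, 5), rep(0.5, 5), rep(0.5, 5),
                               rep(0, 5))), 1)
  expect_equal(fd_window(qf_df(rep(0, 5), rep(0, 5), rep(0.5, 5),
                               rep(0, 5))), 0)
  # negative numerator over a positive denominator clamps to zero
  expect_equal(fd_window(qf_df(c(0, 0.8), c(0.5, 0), c(0.5, 0.5),
                               c(0, 0))), 0)
  expect_true(is.na(fd_window(qf_df(0, 0, 0, 0))))
  # denominator exactly zero is undefined
  expect_true(is.na(fd_window(qf_df(0.9, 0, 0.9, 0))))
})

test_that("jackknife sd is zero for identical blocks and matches the closed form for a mean", {
  x <- rep(1:4, times = 5)  # 20 units, 5 identical blocks of (1,2,3,4)
  jk <- block_jackknife(x, rep(1, 20), n_blocks = 5,
                        statistic = function(sx, sy) sx / sy)
  expect_equal(jk$sd, 0)
  expect_true(is.na(jk$z))
  # linear statistic (plain mean): jackknife sd = sd(block means)/sqrt(m)
  set.seed(4)
  y <- rnorm(100)
  m <- 20L
  jk2 <- block_jackknife(y, rep(1, 100), n_blocks = m,
                         statistic = function(sx, sy) sx / sy)
  bm <- tapply(y, sort(rep_len(1:m, 100)), mean)
  expect_equal(jk2$mean, mean(y), tolerance = 1e-12)
  expect_equal(jk2$sd, sd(bm) / sqrt(m), tolerance = 1e-12)
  expect_error(block_jackknife(y, rep(1, 100), n_blocks = 1), "blocks")
})

test_that("an outlier block inflates the jackknife sd", {
  base <- rep(1, 20)
  with_out <- base; with_out[7] <- 50
  sd_out <- block_jackknife(with_out, rep(1, 20), n_blocks = 20,
                            statistic = function(a, b) a / b)$sd
  sd_flat <- block_jackknife(base, rep(1, 20), n_blocks = 20,
                             statistic = function(a, b) a / b)$sd
  expect_gt(sd_out, sd_flat)
})

test_that("divergence-ratio dating reproduces the printed cortex estimate", {
  r <- divergence_ratio_timing(0.0091, 0.0153)
  expect_equal(r$ratio, 0.0091 / 0.0153)
  expect_equal(round(r$ratio, 3), 0.595)
  r2 <- divergence_ratio_timing(0.4, 0.4, t_div = 2)
  expect_equal(r2$ratio, 1)
  expect_equal(r2$t_intro, 2)
  expect_equal(divergence_ratio_timing(0.5, 1, t_div = 2)$t_intro, 1)
  expect_error(divergence_ratio_timing(0.1, 0), "positive")
})

test_that("peak detection flags spikes and merges across small gaps", {
  v <- c(rnorm(50, 0, 0.01) + 1, 10, rnorm(20, 0, 0.01) + 1)
  pk <- scan_peaks(v, z_threshold = 4)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_idx, 51L)
  expect_equal(pk$n_windows, 1L)
  # nothing above threshold
  expect_equal(nrow(scan_peaks(c(rnorm(30) * 0.01 + 1), 50)), 0L)
  # two flagged windows separated by one unflagged, merge_gap = 1
  v2 <- c(rep(1, 10) + rnorm(10, 0, 0.001), 10, 1, 10,
          rep(1, 10) + rnorm(10, 0, 0.001))
  pk2 <- scan_peaks(v2, z_threshold = 4, merge_gap = 1)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$start_idx, 11L)
  expect_equal(pk2$end_idx, 13L)
  pk3 <- scan_peaks(v2, z_threshold = 4, merge_gap = 0)
  expect_equal(nrow(pk3), 2L)
  expect_error(scan_peaks(c(1, NA, NA)), "defined")
})

test_that("window-mean f_d recovers a known admixture fraction of 0.5", {
  # donor and recipient well diverged relative to N, recent pulse: f_d
  # is then an approximately unbiased estimate of the pulse fraction
  N <- 10000
  model <- demography_quartet(N, t12 = 4 * N, t123 = 8 * N,
                              t_root = 16 * N, pulse_fraction = 0.5,
                              pulse_time = 0.2 * N)
  params <- sim_params(c(P1 = 4L, P2 = 4L, P3 = 4L, O = 4L),
                       mu = 2.5e-8, n_windows = 200,
                       window_length = 10000L, seed = 606L)
  sim <- simulate_dataset(model, params)
  tab <- introgression_scan(sim$matrix, c("P1", "P2", "P3", "O"),
                            sim$popmap, 10000L)
  fd <- tab$fd[!is.na(tab$fd)]
  expect_gte(length(fd), 200L - 5L)
  # f_d is a mildly conservative estimator of the admixture fraction
  # (the per-site max(p2, p3) donor proxy inflates the denominator), so
  # recovery is checked to 0.1 absolute rather than pure sampling error
  expect_lt(abs(mean(fd) - 0.5), 0.1)
  expect_gt(mean(fd), 0.25)
})

test_that("D stays in [-1, 1] and f_d never negative on random scans", {
  toy <- toy_matrix(n_sites = 50, n_per_pop = 2, seed = 13,
                    miss_prob = 0.05)
  pm <- pop_map(toy$popmap$sample,
                rep(c("P1", "P2", "P3", "O"), each = 1))
  tab <- introgression_scan(toy$matrix, c("P1", "P2", "P3", "O"), pm,
                            size = 1000)
  expect_true(all(abs(tab$D) <= 1, na.rm = TRUE))
  expect_true(all(tab$fd >= 0, na.rm = TRUE))
})
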