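test_that("site SNP-index is the variant read proportion", {
  expect_equal(site_snp_index(0, 20), 0)
  expect_equal(site_snp_index(20, 20), 1)
  expect_equal(site_snp_index(7, 20), 0.35)
  expect_true(is.na(site_snp_index(0, 0)))
  expect_error(site_snp_index(21, 20), "exceeds")
  expect_error(site_snp_index(-1, 20), "non-negative")
})

test_that("depth blocks close when both bulks reach the minimum depth", {
  # all sites deep: identity, one block per site
  deep <- data.frame(chrom = "c1", pos = c(10, 20, 30), ref = "A", alt = "T",
                     g_ref = c(20, 25, 35), g_alt = c(5, 5, 5),
                     y_ref = c(20, 25, 35), y_alt = c(5, 5, 5))
  b <- aggregate_blocks(deep, min_block_depth = 20)
  expect_equal(nrow(b), 3)
  expect_equal(b$g_index, deep$g_alt / (deep$g_ref + deep$g_alt))
  expect_true(all(b$complete))

  # hand-aggregated shallow run: sites 1-2 merge, site 3 stands alone
  shallow <- data.frame(chrom = "c1", pos = c(100, 200, 300),
                        ref = "A", alt = "T",
                        g_ref = c(9, 8, 20), g_alt = c(3, 2, 5),
                        y_ref = c(0, 0, 0), y_alt = c(12, 10, 25))
  b <- aggregate_blocks(shallow, min_block_depth = 20)
  expect_equal(b$n_sites, c(2L, 1L))
  expect_equal(b$g_index, c(5 / 22, 0.2))
  expect_equal(b$y_index, c(1, 1))
  expect_equal(b$start, c(100, 300))
  expect_equal(b$end, c(200, 300))

  # trailing block that never reaches depth is flagged incomplete
  tail_open <- data.frame(chrom = "c1", pos = c(10, 20), ref = "A", alt = "T",
                          g_ref = c(30, 3), g_alt = c(5, 1),
                          y_ref = c(30, 3), y_alt = c(5, 1))
  b <- aggregate_blocks(tail_open, min_block_depth = 20)
  expect_equal(b$complete, c(TRUE, FALSE))

  expect_equal(nrow(aggregate_blocks(deep[0, ], 20)), 0)
  expect_error(aggregate_blocks(deep[c(2, 1, 3), ], 20), "sorted")
})

test_that("blocks conserve per-bulk alt and depth totals and never span chromosomes", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:60, 1)
    sites <- data.frame(
      chrom = sort(sample(c("c1", "c2"), n, replace = TRUE)),
      pos = 0, ref = "A", alt = "T",
      g_ref = rpois(n, 6), g_alt = rpois(n, 3),
      y_ref = rpois(n, 6), y_alt = rpois(n, 3))
    sites <- sites[order(sites$chrom), ]
    sites$pos <- ave(seq_len(n), sites$chrom, FUN = seq_along) * 10
    b <- aggregate_blocks(sites, min_block_depth = 15)
    expect_equal(sum(b$g_alt_sum), sum(sites$g_alt))
    expect_equal(sum(b$y_alt_sum), sum(sites$y_alt))
    expect_equal(sum(b$g_depth_sum), sum(sites$g_ref + sites$g_alt))
    expect_equal(sum(b$n_sites), n)
    expect_true(all(stats::na.omit(c(b$g_index, b$y_index)) >= 0))
    expect_true(all(stats::na.omit(c(b$g_index, b$y_index)) <= 1))
    for (ch in unique(sites$chrom))  # blocks partition each chromosome
      expect_equal(sum(b$n_sites[b$chrom == ch]), sum(sites$chrom == ch))
  }
})

test_that("sliding windows enumerate membership by unit start position", {
  one <- data.frame(chrom = "c1", pos = 10, g_index = 0.2, y_index = 0.9)
  prof <- window_profile(one, window_bp = 100, step_bp = 50,
                         chrom_length = 100)
  expect_equal(prof$win_start, c(1, 51))
  expect_equal(prof$win_end, c(100, 100))
  expect_equal(prof$n_units, c(1L, 0L))
  expect_true(all(is.na(prof$g_index_mean)))  # below default min_units = 3
  prof1 <- window_profile(one, window_bp = 100, step_bp = 50,
                          chrom_length = 100, min_units = 1)
  expect_equal(prof1$g_index_mean[1], 0.2)
  expect_equal(prof1$y_index_mean[1], 0.9)

  three <- data.frame(chrom = "c1", pos = c(10, 60, 120),
                      g_index = c(0.2, 0.4, 0.8),
                      y_index = c(0.2, 0.4, 0.8))
  prof <- window_profile(three, window_bp = 100, step_bp = 50,
                         chrom_length = 200, min_units = 1)
  expect_equal(prof$g_index_mean[prof$win_start == 1], 0.3)
  expect_equal(prof$g_index_mean[prof$win_start == 51], 0.6)
  expect_equal(prof$g_index_mean[prof$win_start == 101], 0.8)

  expect_error(window_profile(one, chrom_length = 0), "chrom_length")
  expect_error(window_profile(one, window_bp = 10, step_bp = 20,
                              chrom_length = 100), "window_bp")
})

test_that("constant unit indices give constant window means", {
  units <- data.frame(chrom = "c1", pos = seq(5, 995, by = 10),
                      g_index = 0.37, y_index = 0.37)
  prof <- window_profile(units, window_bp = 100, step_bp = 25,
                         chrom_length = 1000)
  nonmiss <- !is.na(prof$g_index_mean)
  expect_true(any(nonmiss))
  expect_equal(prof$g_index_mean[nonmiss], rep(0.37, sum(nonmiss)))
  expect_equal(prof$y_index_mean[nonmiss], rep(0.37, sum(nonmiss)))
})

test_that("delta is the Y-pool minus G-pool window mean", {
  prof <- data.frame(g_index_mean = c(0.5, 1 / 3, 0.9, NA),
                     y_index_mean = c(0.5, 1, 0.1, 0.5))
  d <- delta_profile(prof)$delta
  expect_equal(d[1], 0)
  expect_equal(d[2], 2 / 3)
  expect_equal(d[3], -0.8)
  expect_true(is.na(d[4]))
})

test_that("null thresholds are symmetric, depth-monotone and vanish asymptotically", {
  expect_lt(abs(null_threshold(40, 40, 30, alpha = 0.5, n_sim = 1e5,
                               seed = 1)), 0.02)
  thr <- vapply(c(10, 20, 50, 100), function(d)
    null_threshold(40, 40, d, alpha = 0.05, n_sim = 1e5, seed = d),
    numeric(1))
  expect_true(all(diff(thr) <= 0.01))   # non-increasing within MC tolerance
  expect_lt(null_threshold(5000, 5000, 5000, alpha = 0.05, n_sim = 2e4,
                           seed = 2), 0.03)
  expect_error(null_threshold(40, 40, 0), "depth")
})

test_that("candidate regions are maximal above-threshold runs", {
  prof <- data.frame(chrom = "c1",
                     win_start = seq(1, 401, by = 100),
                     win_end = seq(100, 500, by = 100),
                     midpoint = seq(50, 450, by = 100),
                     delta = c(0.1, 0.7, 0.72, 0.71, 0.2),
                     threshold = 0.5)
  regs <- call_regions(prof, min_windows = 3)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start, 101)
  expect_equal(regs$end, 400)
  expect_equal(regs$peak_delta, 0.72)
  expect_equal(regs$n_windows, 3L)

  below <- transform(prof, delta = delta - 1)
  expect_equal(nrow(call_regions(below, min_windows = 3)), 0)

  two <- data.frame(chrom = "c1",
                    win_start = seq(1, 701, by = 100),
                    win_end = seq(100, 800, by = 100),
                    midpoint = seq(50, 750, by = 100),
                    delta = c(0.7, 0.7, 0.7, 0.1, 0.7, 0.7, 0.7, 0.1),
                    threshold = 0.5)
  expect_equal(nrow(call_regions(two, min_windows = 3)), 2)

  # missing deltas break runs
  broken <- transform(two, delta = replace(delta, 4, NA))
  expect_equal(nrow(call_regions(broken, min_windows = 3)), 2)
})

test_that("window means and regions match the brute-force reference", {
  set.seed(101)
  for (rep in 1:10) {
    inst <- random_map_instance()
    prof <- window_profile(inst$units, inst$window_bp, inst$step_bp,
                           inst$chrom_length, inst$min_units)
    oracle <- brute_window_profile(inst$units, inst$window_bp, inst$step_bp,
                                   inst$chrom_length, inst$min_units)
    expect_equal(prof$g_index_mean, oracle$g_index_mean)
    expect_equal(prof$y_index_mean, oracle$y_index_mean)
    expect_equal(prof$n_units, oracle$n_units)

    prof <- delta_profile(prof)
    prof$threshold <- inst$threshold
    regs <- call_regions(prof, min_windows = inst$min_windows)
    oracle_regs <- brute_call_regions(prof, min_windows = inst$min_windows)
    if (is.null(oracle_regs)) {
      expect_equal(nrow(regs), 0)
    } else {
      expect_equal(regs$start, oracle_regs$start)
      expect_equal(regs$end, oracle_regs$end)
      expect_equal(regs$peak_delta, oracle_regs$peak_delta)
    }
  }
})

test_that("indices and deltas stay in their theoretical ranges end to end", {
  cfg <- small_config(seed = 5, seq_error = 0.01)
  ds <- simulate_bsa_dataset(cfg)
  m <- map_bsa(ds$counts, chrom_lengths = cfg$chrom_lengths,
               pool_size_g = 30, pool_size_y = 30, seed = 5,
               min_units = 1, n_sim = 2000)
  idx <- stats::na.omit(c(m$blocks$g_index, m$blocks$y_index,
                          m$profile$g_index_mean, m$profile$y_index_mean))
  expect_true(all(idx >= 0 & idx <= 1))
  d <- stats::na.omit(m$profile$delta)
  expect_true(all(d >= -1 & d <= 1))
})
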