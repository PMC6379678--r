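test_that("sliding-window middles match hand arithmetic and boundaries", {
  expect_equal(smooth_profile(rep(0.5, 20), 9, "hmean"), rep(0.5, 12))
  expect_equal(smooth_profile(rep(0.5, 20), 9, "median"), rep(0.5, 12))
  expect_equal(smooth_profile(c(1, 0.5, 0.25), 3, "hmean"), 3 / 7)
  x <- c(0.2, 0.4, 0.9, 0.3)
  # window = L gives the single whole-profile middle
  expect_equal(smooth_profile(x, 4, "gmean"), middle_value(x, "gmean"))
  # profile shorter than the window yields no windows
  expect_length(smooth_profile(x, 5, "hmean"), 0)
  expect_error(smooth_profile(c(0.5, 0), 2), "positive")
})

test_that("smoothing agrees with a brute-force window oracle", {
  set.seed(101)
  for (i in 1:50) {
    L <- sample(5:60, 1)
    w <- sample(1:min(9, L), 1)
    x <- runif(L, 0.05, 1)
    for (m in c("hmean", "gmean", "mean", "median"))
      expect_equal(smooth_profile(x, w, m), naive_smooth(x, w, m),
                   tolerance = 1e-10)
  }
})

test_that("harmonic <= geometric <= arithmetic window means", {
  set.seed(7)
  x <- runif(100, 0.05, 1)
  h <- smooth_profile(x, 9, "hmean")
  g <- smooth_profile(x, 9, "gmean")
  a <- smooth_profile(x, 9, "mean")
  expect_true(all(h <= g + 1e-12))
  expect_true(all(g <= a + 1e-12))
})

test_that("the bottleneck is the 5'-most minimum, with ties reported", {
  expect_equal(find_bottleneck(c(0.5, 0.2, 0.9))$primary, 2)
  b <- find_bottleneck(c(0.2, 0.9, 0.2))
  expect_equal(b$primary, 1)
  expect_equal(b$ties, c(1, 3))
  set.seed(2)
  x <- runif(50)
  expect_equal(find_bottleneck(x)$primary, which.min(x))  # exhaustive scan
  expect_error(find_bottleneck(numeric(0)), "empty")
})

test_that("percent binning follows the 100-equal-parts formula", {
  expect_equal(percent_bin(1, 90), 1L)
  expect_equal(percent_bin(1, 7), 1L)
  expect_equal(percent_bin(9, 100), 9L)          # floor(100*8/100) + 1
  expect_equal(percent_bin(90, 90), 99L)         # floor(100*89/90) + 1
  expect_equal(percent_bin(100, 100), 100L)
  expect_true(all(percent_bin(1:250, 250) %in% 1:100))
})

test_that("outlier cutoff is the largest initial run of outlier bins", {
  expect_equal(consecutive_cutoff(c(1, 2, 3, 5, 7)), 3L)
  expect_equal(consecutive_cutoff(c(2, 3, 4)), 0L)
  expect_equal(consecutive_cutoff(integer(0)), 0L)

  # a flat bottleneck distribution has no Tukey outliers
  flat <- rep(1:100, times = 5)
  expect_equal(infer_outlier_cutoff(flat, mode = "tukey"), 0L)

  # constructed counts: bins 1-5 hold 50 bottlenecks, the rest 1 each;
  # Q3 = 1, IQR = 0, fence = 1, so exactly bins 1-5 are outliers
  bins <- c(rep(1:5, each = 50), 6:100)
  expect_equal(infer_outlier_cutoff(bins, mode = "tukey"), 5L)

  # fixed mode returns the requested cutoff untouched
  expect_equal(infer_outlier_cutoff(bins, mode = "fixed", cutoff = 8), 8L)

  # percentile mode thresholds the bin counts: with bottlenecks only in
  # bins 1-5, the 95th percentile of counts separates them from the rest
  expect_equal(infer_outlier_cutoff(rep(1:5, each = 50),
                                    mode = "percentile", percentile = 95),
               5L)
})

test_that("bottleneck-method ramp calls follow the extension rule", {
  # strictly increasing profile: bottleneck at window 1; with window 3 the
  # whole-gene harmonic mean is first exceeded a few windows in
  profile <- seq(0.1, 1, length.out = 20)
  sm <- smooth_profile(profile, 3, "hmean")
  thr <- middle_value(profile, "hmean")
  e <- which(sm > thr)[1]
  call <- call_ramp(sprintf("C%02d", 1:20), profile, sm, "hmean",
                    cutoff = 100, gene_id = "g")
  expect_equal(call$ramp_length_codons, e - 1L)
  expect_equal(nchar(call$ramp_sequence_nt), 3 * (e - 1L))
  expect_equal(call$bottleneck_window, 1L)

  # bottleneck deep in the gene (bin ~50) with an 8% region: no ramp
  profile2 <- c(runif(100, 0.8, 1), 0.01, runif(100, 0.8, 1))
  sm2 <- smooth_profile(profile2, 9, "hmean")
  expect_null(call_ramp(rep("AAA", 201), profile2, sm2, "hmean", cutoff = 8))

  # constant profile: nothing strictly exceeds the middle -> no ramp
  cp <- rep(0.5, 50)
  expect_null(call_ramp(rep("AAA", 50), cp, smooth_profile(cp, 9, "hmean"),
                        "hmean", cutoff = 100))
})

test_that("standard-deviation ramp calls match a step-by-step scan", {
  set.seed(9)
  profile <- c(runif(12, 0.05, 0.3), runif(28, 0.5, 1))
  codons <- rep("AAA", 40)
  w <- 5
  s <- 0.5
  call <- call_ramp_stddev(codons, profile, window = w, s = s, gene_id = "g")
  # brute-force simulation of the rule
  thr <- mean(profile) - s * sd(profile)
  e <- NA
  for (k in seq_len(length(profile) - w + 1)) {
    if (mean(profile[k:(k + w - 1)]) > thr) { e <- k; break }
  }
  expect_equal(call$ramp_length_codons, e - 1L)

  # enormous s puts the threshold below every window: no ramp
  expect_null(call_ramp_stddev(codons, profile, window = w, s = 100))

  # s near zero reduces to the plain arithmetic-mean threshold
  tiny <- call_ramp_stddev(codons, profile, window = w, s = 1e-12)
  wmeans <- naive_smooth(profile, w, "mean")
  expect_equal(tiny$ramp_length_codons,
               which(wmeans > mean(profile))[1] - 1L)
})

test_that("ramp-length filtering removes tail lengths", {
  mk <- function(lens) data.frame(
    gene_id = paste0("g", seq_along(lens)),
    ramp_length_codons = as.integer(lens),
    ramp_sequence_nt = strrep("AAA", lens),
    bottleneck_window = 1L, bottleneck_percent = 1L,
    stringsAsFactors = FALSE)
  # all equal: sd 0, everything kept
  out <- filter_ramp_lengths(mk(rep(30, 5)), d = 2)
  expect_equal(nrow(out$kept), 5)
  # ten ramps of 30 plus one of 300: the 300 sits beyond 2 sd
  out <- filter_ramp_lengths(mk(c(rep(30, 10), 300)), d = 2)
  expect_equal(out$removed$ramp_length_codons, 300L)
  expect_equal(nrow(out$kept), 10)
  # huge d keeps everything; a single call is kept (sd taken as 0)
  expect_equal(nrow(filter_ramp_lengths(mk(c(rep(30, 10), 300)),
                                        d = 1e6)$kept), 11)
  expect_equal(nrow(filter_ramp_lengths(mk(30), d = 2)$kept), 1)
})

test_that("consensus profiles average position-wise then smooth", {
  p <- c(0.2, 0.4, 0.6, 0.8)
  # identical genes: consensus equals the single smoothed profile
  expect_equal(consensus_profile(list(p, p, p), window = 2),
               naive_smooth(p, 2, "mean"))
  # different lengths: tail positions average over the longer gene only
  q <- c(0.1, 0.3)
  expect_equal(consensus_profile(list(p, q), window = 1),
               c(mean(c(0.2, 0.1)), mean(c(0.4, 0.3)), 0.6, 0.8))
  # window 1 is the identity on the positional means
  expect_equal(consensus_profile(list(p), window = 1), p)
})

test_that("enlarging the outlier region never loses ramps", {
  g <- make_genome(n_genes = 80, seed = 13)
  n_prev <- -1
  for (cutoff in c(2, 5, 10, 25, 60)) {
    res <- run_ramp_extraction(g$records, table = g$table,
                               config = ramp_config(outlier_mode = "fixed",
                                                    cutoff = cutoff))
    expect_gte(nrow(res$ramps), n_prev)
    n_prev <- nrow(res$ramps)
  }
})

test_that("the pipeline is deterministic and thread-independent", {
  expect_equal(nrow(run_ramp_extraction(list(), table = flat_table())$ramps),
               0)
  g <- make_genome(n_genes = 60, seed = 21)
  cfg1 <- ramp_config(outlier_mode = "fixed", cutoff = 8, threads = 1)
  cfg2 <- ramp_config(outlier_mode = "fixed", cutoff = 8, threads = 2)
  r1 <- run_ramp_extraction(g$records, table = g$table, config = cfg1)
  r2 <- run_ramp_extraction(g$records, table = g$table, config = cfg2)
  expect_identical(r1$ramps, r2$ramps)
  expect_identical(r1$no_ramp_ids, r2$no_ramp_ids)
  # ramp calls come back in input order
  expect_equal(r1$ramps$gene_id,
               intersect(vapply(g$records, `[[`, "", "id"),
                         r1$ramps$gene_id))
})

test_that("ramp sequences contain exactly the called codons", {
  g <- make_genome(n_genes = 40, seed = 31)
  res <- run_ramp_extraction(g$records, table = g$table,
                             config = ramp_config(outlier_mode = "fixed",
                                                  cutoff = 8))
  expect_gt(nrow(res$ramps), 0)
  expect_equal(nchar(res$ramps$ramp_sequence_nt),
               3L * res$ramps$ramp_length_codons)
  # the emitted sequence is the 5' prefix of the trimmed gene
  by_id <- setNames(g$records, vapply(g$records, `[[`, "", "id"))
  for (i in seq_len(nrow(res$ramps))) {
    row <- res$ramps[i, ]
    trimmed <- trim_terminal_codons(by_id[[row$gene_id]])
    expect_equal(row$ramp_sequence_nt,
                 paste(trimmed[seq_len(row$ramp_length_codons)],
                       collapse = ""))
  }
})

test_that("profiles shorter than the window are reported as no-ramp", {
  short <- interior_gene("tiny", rep("AAA", 4))   # 4 trimmed codons < 9
  res <- run_ramp_extraction(list(short), table = flat_table(),
                             config = ramp_config(min_length_nt = 3,
                                                  outlier_mode = "fixed"))
  expect_equal(res$no_ramp_ids, "tiny")
  expect_equal(nrow(res$ramps), 0)
})
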