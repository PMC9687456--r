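test_that("fisher_one_sided matches direct hypergeometric enumeration", {
  expect_equal(fisher_one_sided(0, 100, 5, 95), 1.0)
  expect_equal(fisher_one_sided(10, 990, 1, 999),
               hyper_tail_oracle(10, 990, 1, 999), tolerance = 1e-12)
  # equal proportions: the greater-tail p exceeds 0.5
  expect_gt(fisher_one_sided(10, 90, 10, 90), 0.5)
  set.seed(3)
  for (i in 1:50) {
    m <- sample(1:150, 1); n <- sample(1:150, 1)
    k <- sample(1:(m + n), 1)
    as <- max(0, k - n):min(k, m)
    a <- as[sample.int(length(as), 1)]
    p <- fisher_one_sided(a, m - a, k - a, n - (k - a))
    expect_equal(p, hyper_tail_oracle(a, m - a, k - a, n - (k - a)),
                 tolerance = 1e-10)
    # independent cross-check against stats::fisher.test
    ft <- fisher.test(matrix(c(a, m - a, k - a, n - (k - a)), 2,
                             byrow = TRUE), alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-7)
  }
})

test_that("fisher_one_sided is monotone in a with margins fixed", {
  m <- 100; n <- 120; k <- 40
  as <- max(0, k - n):min(k, m)
  ps <- fisher_one_sided(as, m - as, k - as, n - (k - as))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("negative or impossible tables are input errors", {
  expect_error(fisher_one_sided(5, -1, 2, 3), "non-negative")
})

test_that("count_windows splits a read over every touched window", {
  r <- tibble::tibble(seqname = "chr1", start = 0L, end = 100L,
                      strand = "+", library = "IP")
  w <- count_windows(r, window = 20)
  expect_equal(nrow(w), 5L)
  expect_equal(w$start, seq(0L, 80L, 20L))
  expect_true(all(w$ip_count == 1L))
  # no reads: empty sparse stream
  expect_equal(nrow(count_windows(r[0, ])), 0L)
})

test_that("window counts equal a quadratic overlap oracle on simulated reads", {
  sim <- tiny_sim(seed = 23)
  reads <- dplyr::filter(sim$reads, condition == "coarse")[1:1000, ]
  w <- count_windows(reads, window = 20)
  oracle <- window_count_oracle(reads, 20L)
  for (i in sample(nrow(w), 200)) {
    for (lib in c("IP", "Input")) {
      key <- paste(w$seqname[i], w$strand[i], w$start[i], lib, sep = "|")
      got <- if (lib == "IP") w$ip_count[i] else w$input_count[i]
      expect_equal(got, oracle[[key]] %||% 0L, info = key)
    }
  }
  # conservation: total incidences match the per-read window spans
  spans <- (reads$end - 1L) %/% 20L - reads$start %/% 20L + 1L
  expect_equal(sum(w$ip_count + w$input_count), sum(spans))
})

test_that("out-of-bounds reads are rejected with a message", {
  r <- tibble::tibble(seqname = "chr1", start = c(0L, 990L), end = c(100L, 1090L),
                      strand = "+", library = "IP")
  expect_message(w <- count_windows(r, seqlengths = c(chr1 = 1000L)),
                 "rejected 1")
  expect_equal(sum(w$ip_count), 5L)
})

test_that("window significance needs coverage, alpha and IP excess", {
  totals <- list(ip = 10000L, input = 10000L)
  w <- tibble::tibble(seqname = "chr1", start = c(0L, 20L, 40L),
                      end = c(20L, 40L, 60L), strand = "+",
                      ip_count = c(0L, 40L, 3L), input_count = c(50L, 5L, 2L))
  out <- call_significant_windows(w, totals)
  expect_false(out$significant[1]) # ip = 0 can never be enriched
  expect_true(out$significant[2])  # planted 8-fold at good depth
  expect_false(out$tested[3])      # below min_cov
  expect_error(call_significant_windows(
    dplyr::mutate(w, ip_count = 20000L), totals), "exceed")
})

test_that("merging adjacent windows follows a run-length oracle", {
  totals <- list(ip = 1000L, input = 1000L)
  mkwin <- function(sig) {
    n <- length(sig)
    tibble::tibble(seqname = "chr1", start = seq(0L, by = 20L, length.out = n),
                   end = seq(20L, by = 20L, length.out = n), strand = "+",
                   ip_count = 10L, input_count = 1L,
                   p_value = ifelse(sig, 0.01, 0.5), tested = TRUE,
                   significant = sig)
  }
  # two adjacent significant windows become one peak
  p <- merge_adjacent(mkwin(c(FALSE, TRUE, TRUE, FALSE)), totals)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end), c(20L, 60L))
  expect_equal(p$n_windows, 2L)
  # a one-window gap splits peaks at max_gap = 0 and joins at max_gap = 1
  gap <- mkwin(c(TRUE, FALSE, TRUE))
  expect_equal(nrow(merge_adjacent(gap, totals)), 2L)
  expect_equal(nrow(merge_adjacent(gap, totals, max_gap = 1)), 1L)

  set.seed(9)
  for (rep in 1:10) {
    sig <- runif(60) < 0.3
    w <- mkwin(sig)
    got <- merge_adjacent(w, totals)
    want <- run_length_peaks_oracle(w$start, sig, 20L)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, vapply(want, `[[`, numeric(1), "start"))
      expect_equal(got$end, vapply(want, `[[`, numeric(1), "end"))
      expect_equal(got$n_windows,
                   as.integer(vapply(want, `[[`, numeric(1), "n")))
    }
    # merging conserves the summed counts of significant windows
    expect_equal(sum(got$ip_count), sum(w$ip_count[sig]))
  }
})

test_that("planted peaks are recovered by the full caller", {
  cfg <- simulation_config(n_genes = 20, depth_per_library = 20000, seed = 19)
  g <- simulate_genome(cfg)
  r <- simulate_reads(g, emit_fastq = FALSE, conditions = "coarse")
  pk <- call_peaks(r$reads)
  peaks <- tidy(pk)
  tp <- dplyr::filter(g$truth_peaks, condition %in% c("both", "coarse"))
  sens <- mean(vapply(seq_len(nrow(tp)), function(i)
    expect_overlap_any(tp[i, ], peaks), logical(1)))
  expect_gte(sens, 0.9)
  # peak-level invariants
  expect_true(all(peaks$end - peaks$start >= pk$params$window))
  expect_true(all(peaks$p_value > 0 & peaks$p_value <= 1))
})

test_that("reads in one library only is an error", {
  r <- tibble::tibble(seqname = "chr1", start = 0L, end = 100L,
                      strand = "+", library = "IP")
  expect_error(call_peaks(r), "both")
})
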