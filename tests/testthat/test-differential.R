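mkpeaks <- function(starts, ends, strand = "+", p = 1e-6) {
  tibble::tibble(seqname = "chr1", start = starts, end = ends,
                 strand = strand, n_windows = 1L, ip_count = 50L,
                 input_count = 5L, p_value = p, enrichment = 10)
}

test_that("identical peak lists all match; disjoint lists are all specific", {
  a <- mkpeaks(c(100L, 500L), c(200L, 600L))
  m <- match_peaks(a, a)
  expect_true(all(m$status == "matched"))

  b <- mkpeaks(c(1000L, 2000L), c(1100L, 2100L))
  m2 <- match_peaks(a, b)
  expect_setequal(m2$status, c("coarse_specific", "fine_specific"))
  expect_equal(sum(m2$status == "coarse_specific"), 2L)
  expect_equal(sum(m2$status == "fine_specific"), 2L)
})

test_that("random interval matching equals a quadratic overlap oracle", {
  set.seed(41)
  for (rep in 1:5) {
    a <- mkpeaks(starts <- sort(sample(seq(0L, 5000L, 50L), 8)),
                 starts + sample(40:120, 8, TRUE))
    b <- mkpeaks(starts2 <- sort(sample(seq(0L, 5000L, 50L), 8)),
                 starts2 + sample(40:120, 8, TRUE))
    m <- match_peaks(a, b)
    # oracle: a coarse peak is matched iff it overlaps any fine peak
    for (i in seq_len(nrow(a))) {
      touches <- any(b$start < a$end[i] & b$end > a$start[i])
      region <- m[m$start <= a$start[i] & m$end >= a$end[i], ]
      expect_true(nrow(region) >= 1)
      if (touches) {
        expect_true(any(region$status == "matched"))
      }
    }
    # every union interval contains at least one input peak
    expect_true(all(vapply(seq_len(nrow(m)), function(i) {
      expect_overlap_any(m[i, ], dplyr::bind_rows(a, b))
    }, logical(1))))
  }
})

diff_reads <- function(coarse_ip_n, fine_ip_n, at = 100L, width = 100L,
                       bg = 2000L) {
  mk <- function(n, cond, lib, s) {
    if (n == 0) return(NULL)
    tibble::tibble(seqname = "chr1", start = rep(s, n),
                   end = rep(s + width, n), strand = "+",
                   library = lib, condition = cond)
  }
  dplyr::bind_rows(
    mk(coarse_ip_n, "coarse", "IP", at), mk(bg, "coarse", "IP", 5000L),
    mk(fine_ip_n, "fine", "IP", at), mk(bg, "fine", "IP", 5000L),
    mk(50L, "coarse", "Input", at), mk(bg, "coarse", "Input", 5000L),
    mk(50L, "fine", "Input", at), mk(bg, "fine", "Input", 5000L))
}

test_that("equal normalized counts give ns with ratio near zero", {
  reads <- diff_reads(60L, 60L)
  m <- tibble::tibble(seqname = "chr1", start = 100L, end = 200L,
                      strand = "+", status = "matched")
  rec <- test_differential(m, reads)
  expect_equal(rec$class, "ns")
  expect_equal(rec$log2_methylation_ratio, 0, tolerance = 1e-9)
})

test_that("the two-sided p equals exhaustive enumeration and classes follow the ratio", {
  reads <- diff_reads(40L, 5L, bg = 5000L)
  m <- tibble::tibble(seqname = "chr1", start = 100L, end = 200L,
                      strand = "+", status = "matched")
  rec <- test_differential(m, reads)
  tot <- library_totals(reads)
  expect_equal(rec$p_value,
               fisher_two_sided_oracle(40, tot$coarse_ip - 40,
                                       5, tot$fine_ip - 5),
               tolerance = 1e-9)
  expect_equal(rec$class, "up")
})

test_that("zero library totals are an input error", {
  reads <- diff_reads(40L, 5L)
  m <- tibble::tibble(seqname = "chr1", start = 100L, end = 200L,
                      strand = "+", status = "matched")
  expect_error(
    test_differential(m, dplyr::filter(reads, condition == "coarse")),
    "positive")
})

test_that("swapping condition labels swaps up/down and the specific labels", {
  sim <- tiny_sim(seed = 29)
  pkc <- call_peaks(dplyr::filter(sim$reads, condition == "coarse"),
                    min_cov = 5)
  pkf <- call_peaks(dplyr::filter(sim$reads, condition == "fine"),
                    min_cov = 5)
  dm <- diff_m6a(pkc, pkf, sim$reads)
  swapped_reads <- dplyr::mutate(sim$reads, condition = dplyr::recode(
    condition, coarse = "fine", fine = "coarse"))
  dm2 <- diff_m6a(pkf, pkc, swapped_reads)
  flip <- c(up = "down", down = "up", coarse_specific = "fine_specific",
            fine_specific = "coarse_specific", ns = "ns")
  r1 <- dplyr::arrange(tidy(dm), seqname, start)
  r2 <- dplyr::arrange(tidy(dm2), seqname, start)
  expect_equal(r1$start, r2$start)
  expect_equal(unname(flip[r1$class]), r2$class)
  expect_equal(r1$log2_methylation_ratio, -r2$log2_methylation_ratio,
               tolerance = 1e-9)
})

test_that("matched p-values are null-calibrated without planted differences", {
  cfg <- simulation_config(n_genes = 40, depth_per_library = 40000,
                           peak_specific_fraction = 0, de_fraction = 0,
                           seed = 37)
  sim <- simulate_merip(cfg, emit_fastq = FALSE)
  pkc <- call_peaks(dplyr::filter(sim$reads, condition == "coarse"))
  pkf <- call_peaks(dplyr::filter(sim$reads, condition == "fine"))
  dm <- diff_m6a(pkc, pkf, sim$reads)
  rec <- dplyr::filter(tidy(dm), status == "matched")
  frac <- mean(rec$p_value < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(rec)))
})

test_that("gene collapse counts each gene once, by its most significant peak", {
  rec <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g3", "g3", NA),
    class = c("up", "up", "down", "down", "up", "up"),
    p_value = c(0.01, 0.001, 0.01, 0.02, 0.02, 0.001))
  out <- summarize_differential(rec)
  expect_equal(nrow(out$genes), 3L)
  expect_equal(out$genes$class[out$genes$gene_id == "g1"], "up")
  expect_equal(out$genes$class[out$genes$gene_id == "g2"], "up")
  # exact tie between up and down resolves to up
  expect_equal(out$genes$class[out$genes$gene_id == "g3"], "up")
  # recount oracle on the summary
  expect_equal(out$summary$n_genes[out$summary$class == "up"], 3L)
})
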