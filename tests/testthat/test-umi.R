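test_that("cluster_by_umi partitions reads by exact UMI", {
  r <- tibble::tibble(read_id = c("a", "b", "c"),
                      sequence = c("AAAAGGGGCCCC", "AAAATTTTCCCC",
                                   "CCCCGGGGAAAA"))
  cl <- cluster_by_umi(r, umi_length = 4)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$n_reads, c(2L, 1L))
  expect_equal(sum(cl$n_reads), 3L)
  # empty input
  expect_equal(nrow(cluster_by_umi(r[0, ], umi_length = 4)), 0L)
})

test_that("cluster count equals the number of distinct UMIs (brute force)", {
  set.seed(31)
  umis <- replicate(120, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                               collapse = ""))
  picks <- sample(umis, 1000, replace = TRUE)
  r <- tibble::tibble(read_id = sprintf("r%04d", 1:1000),
                      sequence = paste0(picks, strrep("ACGT", 10)))
  cl <- cluster_by_umi(r, umi_length = 6)
  expect_equal(nrow(cl), length(unique(picks)))
})

test_that("malformed UMIs are rejected and counted", {
  r <- tibble::tibble(read_id = c("a", "b"),
                      sequence = c("AAAAGGGG", "ANAAGGGG"))
  expect_message(cl <- cluster_by_umi(r, umi_length = 4), "rejected 1")
  expect_equal(sum(cl$n_reads), 1L)
})

test_that("pairwise identity matches an exhaustive alignment DP oracle", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(pairwise_identity("ACGT", "TGCA"),
               nw_identity_oracle("ACGT", "TGCA"))
  set.seed(7)
  for (i in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE),
               collapse = "")
    expect_equal(pairwise_identity(a, b), nw_identity_oracle(a, b),
                 info = paste(a, b))
    # symmetry
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("one substitution in a 100-mer gives identity 0.99", {
  set.seed(5)
  a <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  b <- a
  substr(b, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(a, 50, 50))[1]
  expect_equal(pairwise_identity(a, b), 0.99)
})

test_that("empty sequences are rejected", {
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
  expect_error(pairwise_identity("ACGT", ""), "non-empty")
})

test_that("subcluster splits below-threshold members and keeps the partition", {
  same <- tibble::tibble(read_id = c("a", "b", "c"),
                         sequence = rep("ACGTACGTACGT", 3))
  expect_equal(length(unique(subcluster(same)$subcluster)), 1L)

  far <- tibble::tibble(read_id = c("a", "b"),
                        sequence = c("AAAAAAAACCCCCCCC", "AAAAAAAAGGGGGGGG"))
  expect_equal(length(unique(subcluster(far)$subcluster)), 2L)
})

test_that("two templates at ~80% identity separate into two sub-clusters", {
  set.seed(13)
  t1 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  x <- strsplit(t1, "")[[1]]
  flip <- sample(100, 20)
  x[flip] <- vapply(x[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  t2 <- paste(x, collapse = "")
  mutate1 <- function(s) {
    if (runif(1) > 0.5) return(s)
    p <- sample(nchar(s), 1)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, p, p)), 1)
    s
  }
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:20),
    sequence = c(vapply(rep(t1, 10), mutate1, character(1)),
                 vapply(rep(t2, 10), mutate1, character(1))),
    template = rep(c(1, 2), each = 10))
  sc <- subcluster(reads)
  expect_equal(length(unique(sc$subcluster)), 2L)
  expect_true(all(table(sc$template, sc$subcluster) %in% c(0L, 10L)))
  # partition: every read assigned exactly once
  expect_equal(sort(sc$read_id), sort(reads$read_id))
})

test_that("consensus recovers the template by majority vote", {
  one <- tibble::tibble(read_id = "a", sequence = "ACGTACGT",
                        quality = "IIIIIIII")
  expect_equal(consensus(one)$sequence, "ACGTACGT")

  five <- tibble::tibble(read_id = letters[1:5],
                         sequence = rep("ACGTACGTACGT", 5))
  expect_equal(consensus(five)$sequence, "ACGTACGTACGT")

  set.seed(21)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  mutate_pct <- function(s) {
    x <- strsplit(s, "")[[1]]
    hit <- runif(100) < 0.01
    x[hit] <- vapply(x[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(x, collapse = "")
  }
  reads <- tibble::tibble(read_id = sprintf("r%d", 1:9),
                          sequence = vapply(rep(tmpl, 9), mutate_pct,
                                            character(1)))
  sc <- subcluster(reads)
  expect_equal(consensus(sc)$sequence, tmpl)
})

test_that("deduplicate recovers the exact molecule count without errors", {
  cfg <- simulation_config(n_genes = 4, depth_per_library = 250,
                           pcr_duplication_rate = 2, seq_error_rate = 0,
                           seed = 17)
  sim <- simulate_merip(cfg, conditions = "coarse")
  fq <- dplyr::filter(sim$fastq, library == "Input")
  dd <- deduplicate(fq, umi_length = cfg$umi_length)
  truth <- dplyr::filter(sim$truth$true_molecules,
                         condition == "coarse", library == "Input")
  expect_equal(nrow(dd), truth$molecules)
  rep <- attr(dd, "report")
  expect_equal(rep$reads_out, nrow(dd))
  expect_equal(rep$reads_in, nrow(fq))
})

test_that("deduplication is idempotent on unique-UMI sets and preserves singletons", {
  r <- tibble::tibble(
    read_id = c("a", "b", "c"),
    sequence = c("AAAACCCCGGGGTTTT", "CCCCAAAAGGGGTTTT", "GGGGACGTACGTACGT"))
  dd <- deduplicate(r, umi_length = 4)
  expect_equal(nrow(dd), 3L)
  expect_setequal(dd$sequence, substring(r$sequence, 5))
  dd2 <- deduplicate(dd)
  expect_setequal(dd2$sequence, dd$sequence)
  # empty input
  expect_equal(nrow(deduplicate(r[0, ], umi_length = 4)), 0L)
})
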