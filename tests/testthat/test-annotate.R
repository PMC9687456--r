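test_that("interval classification follows maximal overlap with fixed priority", {
  g <- simulate_genome(simulation_config(n_genes = 10, seed = 43))
  ann <- g$annotation
  cds <- dplyr::filter(ann$features, feature == "CDS")[1, ]
  q <- tibble::tibble(seqname = cds$seqname, start = cds$start + 10L,
                      end = cds$start + 60L, strand = cds$strand)
  expect_equal(classify_intervals(q, ann)$region, "CDS")
  # intergenic gap before the first gene
  q2 <- tibble::tibble(seqname = "chr1", start = 0L, end = 50L, strand = "+")
  expect_equal(classify_intervals(q2, ann)$region, "intergenic")
  expect_error(classify_intervals(
    tibble::tibble(seqname = "chrX", start = 0L, end = 10L), ann),
    "unknown seqname")
})

test_that("random intervals agree with a per-base majority oracle", {
  g <- simulate_genome(simulation_config(n_genes = 15, n_exons = 2,
                                         noncoding_fraction = 0.3,
                                         seed = 47))
  ann <- g$annotation
  set.seed(48)
  n <- 200
  q <- tibble::tibble(
    seqname = "chr1",
    start = sample.int(ann$seqlengths[["chr1"]] - 300L, n),
    strand = sample(c("+", "-", "*"), n, TRUE))
  q$end <- q$start + sample(20:250, n, TRUE)
  got <- classify_intervals(q, ann)
  for (i in seq_len(n)) {
    want <- region_label_oracle(q$seqname[i], q$start[i], q$end[i],
                                q$strand[i], ann$features)
    expect_equal(got$region[i], want, info = paste("interval", i))
  }
  # determinism and order invariance
  perm <- sample(n)
  got2 <- classify_intervals(q[perm, ], ann)
  expect_equal(got2$region, got$region[perm])
})

test_that("region distributions tally to one and respect construction", {
  g <- simulate_genome(simulation_config(n_genes = 10, seed = 51))
  ann <- g$annotation
  cds <- dplyr::filter(ann$features, feature == "CDS")
  q <- tibble::tibble(seqname = cds$seqname[1:3],
                      start = cds$start[1:3] + 5L,
                      end = cds$start[1:3] + 40L,
                      strand = cds$strand[1:3])
  rd <- region_distribution(q, ann)
  expect_equal(rd$fraction[rd$region == "CDS"], 1.0)
  expect_equal(sum(rd$n), nrow(q))
  expect_equal(sum(rd$fraction), 1, tolerance = 1e-9)
  expect_warning(empty <- region_distribution(q[0, ], ann), "empty")
  expect_true(all(empty$n == 0L))
})

test_that("peaks planted with full stop-codon bias are modally 3'UTR", {
  g <- simulate_genome(simulation_config(n_genes = 25, stop_codon_bias = 1,
                                         seed = 53))
  rd <- region_distribution(g$truth_peaks, g$annotation)
  expect_equal(rd$region[which.max(rd$n)], "three_prime_utr")
})

test_that("metagene rows are anchored, strand-oriented and conserve incidences", {
  g <- simulate_genome(simulation_config(n_genes = 6, seed = 57))
  ann <- g$annotation
  plus <- ann$genes[ann$genes$strand == "+", ][1, ]
  minus <- ann$genes[ann$genes$strand == "-", ][1, ]
  # one read starting exactly at the + strand TSS
  r <- tibble::tibble(seqname = "chr1", start = plus$tss,
                      end = plus$tss + 100L, strand = "+",
                      library = "IP", condition = "coarse")
  mg <- metagene_matrix(r, ann, anchor = "TSS", flank = 1000, bins = 50)
  row <- mg$matrix[plus$gene_id, ]
  # the read covers the bins just 3' of the anchor (bins 26-28 of 50)
  expect_equal(which(row > 0), 26:28)
  # mirrored read on a - strand gene gives the mirrored profile
  r2 <- tibble::tibble(seqname = "chr1", start = minus$tss - 99L,
                       end = minus$tss + 1L, strand = "-",
                       library = "IP", condition = "coarse")
  mg2 <- metagene_matrix(r2, ann, anchor = "TSS", flank = 1000, bins = 50)
  expect_equal(which(mg2$matrix[minus$gene_id, ] > 0), 26:28)

  # conservation: matrix total equals read-bin incidences
  sim <- tiny_sim(seed = 58)
  rr <- dplyr::filter(sim$reads, condition == "coarse", library == "Input")
  mg3 <- metagene_matrix(rr, sim$annotation, anchor = "stop_codon",
                         flank = 400, bins = 20)
  gr_reads <- GenomicRanges::GRanges(
    rr$seqname, IRanges::IRanges(rr$start + 1L, rr$end))
  total <- 0L
  genes <- sim$annotation$genes[!is.na(sim$annotation$genes$stop_codon), ]
  for (i in seq_len(nrow(genes))) {
    for (b in 1:20) {
      off <- -400 + (b - 1) * 40 # transcript-offset bin start
      lo <- if (genes$strand[i] == "+") genes$stop_codon[i] + off
            else genes$stop_codon[i] - off - 40L + 1L
      gr_bin <- GenomicRanges::GRanges(
        genes$seqname[i], IRanges::IRanges(lo + 1L, lo + 40L))
      total <- total + sum(GenomicRanges::countOverlaps(gr_bin, gr_reads))
    }
  }
  expect_equal(sum(mg3$matrix), total)
})

test_that("near-uniform coverage yields a flat metagene profile", {
  # hand-built uniform coverage over one long gene
  g <- simulate_genome(simulation_config(
    n_genes = 1, gene_length_range = c(4000L, 4000L),
    noncoding_fraction = 0, seed = 59))
  ann <- g$annotation
  gene <- ann$genes[1, ]
  set.seed(60)
  starts <- sample(seq(gene$start, gene$end - 100L), 5000, replace = TRUE)
  r <- tibble::tibble(seqname = "chr1", start = starts, end = starts + 100L,
                      strand = gene$strand, library = "Input",
                      condition = "coarse")
  mg <- metagene_matrix(r, ann, anchor = "stop_codon", flank = 400,
                        bins = 20)
  prof <- colMeans(mg$matrix)
  expect_lt(sd(prof) / mean(prof), 0.1)
})

test_that("a GTF round trip preserves genes, features and the exon map", {
  g <- simulate_genome(simulation_config(n_genes = 12, n_exons = 2,
                                         noncoding_fraction = 0.25,
                                         seed = 61))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(g$annotation, path)
  back <- read_annotation_gtf(path)
  a <- g$annotation
  expect_setequal(back$genes$gene_id, a$genes$gene_id)
  ord <- match(a$genes$gene_id, back$genes$gene_id)
  expect_equal(back$genes$start[ord], a$genes$start)
  expect_equal(back$genes$end[ord], a$genes$end)
  expect_equal(back$genes$strand[ord], a$genes$strand)
  expect_equal(back$genes$coding[ord], a$genes$coding)
  expect_equal(back$genes$tss[ord], a$genes$tss)
  expect_equal(back$genes$stop_codon[ord], a$genes$stop_codon)
  key <- function(f) {
    f <- dplyr::arrange(f, gene_id, feature, start)
    paste(f$gene_id, f$feature, f$start, f$end, f$strand)
  }
  expect_equal(key(back$features), key(a$features))
  # reads classified identically under both annotations
  sim <- simulate_reads(g, emit_fastq = FALSE, conditions = "coarse")
  q <- sim$reads[1:100, ]
  expect_equal(classify_intervals(q, back)$region,
               classify_intervals(q, a)$region)
})

test_that("a corrupted GTF is a parse error", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\tx\tgene\tnot_a_number\t10\t.\t+\t.\tgene_id \"g\";",
               "garbage line"), path)
  expect_error(read_annotation_gtf(path), "parse|GTF")
})
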