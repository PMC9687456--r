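#' Simulation parameters for a synthetic MeRIP-seq experiment
#'
#' Builds the configuration object consumed by [simulate_genome()] and
#' [simulate_reads()]. The defaults describe the desk-scale experiment the
#' package is validated against: two conditions (coarse/fine) times two
#' stranded libraries (IP/Input), UMI-tagged PCR duplicate families, true
#' m6A peaks biased toward the stop codon and carrying a planted GGACT
#' (DNA alphabet for GGACU) motif, and a subset of differentially
#' expressed genes.
#'
#' @param n_genes number of genes to simulate.
#' @param gene_length_range integer pair, min/max mRNA (exonic) length in bp.
#' @param n_exons exons per gene; introns are inserted between exons.
#' @param intron_length_range integer pair, intron length range in bp.
#' @param noncoding_fraction fraction of genes that are non-protein-coding
#'   (annotated as `NP_exon`, no CDS/UTRs).
#' @param intergenic_gap bp of intergenic sequence between consecutive genes.
#' @param peak_fraction fraction of genes given a true m6A peak.
#' @param peak_enrichment IP:Input read-rate ratio inside true peaks (>= 1).
#' @param peak_width width of a true peak in bp.
#' @param peak_specific_fraction fraction of true peaks present in only one
#'   condition (split evenly between coarse-specific and fine-specific).
#' @param motif k-mer planted at every true peak centre, DNA alphabet.
#' @param stop_codon_bias probability a true peak is placed immediately
#'   3' of the stop codon (inside the 3'UTR); otherwise placed uniformly
#'   along the transcript.
#' @param depth_per_library expected number of unique molecules in each
#'   Input library. IP libraries carry the same per-base background rate
#'   plus the planted enrichment mass, so their totals exceed this value
#'   when `peak_enrichment > 1`.
#' @param read_length read (fragment) length in bp.
#' @param umi_length UMI length in bases.
#' @param pcr_duplication_rate mean number of PCR duplicates per molecule
#'   (Poisson); 0 means every UMI family is a singleton.
#' @param seq_error_rate per-base substitution probability applied to each
#'   sequenced copy (the UMI itself is copied faithfully).
#' @param de_fraction fraction of genes differentially expressed between
#'   conditions (half up, half down in coarse).
#' @param de_fold true expression fold change of differentially expressed
#'   genes (coarse relative to fine).
#' @param stranded if `FALSE`, read strands are randomised to emulate an
#'   unstranded protocol.
#' @param seed integer random seed; a fixed seed gives byte-identical output.
#'
#' @return A list of class `merip_sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 5, depth_per_library = 500)
#' cfg$peak_enrichment
simulation_config <- function(n_genes = 100,
                              gene_length_range = c(1200L, 3000L),
                              n_exons = 1L,
                              intron_length_range = c(100L, 400L),
                              noncoding_fraction = 0.1,
                              intergenic_gap = 300L,
                              peak_fraction = 0.5,
                              peak_enrichment = 8,
                              peak_width = 150L,
                              peak_specific_fraction = 0.2,
                              motif = "GGACT",
                              stop_codon_bias = 0.8,
                              depth_per_library = 200000L,
                              read_length = 100L,
                              umi_length = 8L,
                              pcr_duplication_rate = 1,
                              seq_error_rate = 0.001,
                              de_fraction = 0.2,
                              de_fold = 4,
                              stranded = TRUE,
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_exons = as.integer(n_exons),
    intron_length_range = as.integer(intron_length_range),
    noncoding_fraction = noncoding_fraction,
    intergenic_gap = as.integer(intergenic_gap),
    peak_fraction = peak_fraction,
    peak_enrichment = peak_enrichment,
    peak_width = as.integer(peak_width),
    peak_specific_fraction = peak_specific_fraction,
    motif = toupper(motif),
    stop_codon_bias = stop_codon_bias,
    depth_per_library = as.integer(depth_per_library),
    read_length = as.integer(read_length),
    umi_length = as.integer(umi_length),
    pcr_duplication_rate = pcr_duplication_rate,
    seq_error_rate = seq_error_rate,
    de_fraction = de_fraction,
    de_fold = de_fold,
    stranded = isTRUE(stranded),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "merip_sim_config")
}

validate_sim_config <- function(cfg) {
  check_number(cfg$n_genes, "n_genes", min = 1)
  check_number(cfg$peak_enrichment, "peak_enrichment", min = 1)
  for (p in c("noncoding_fraction", "peak_fraction", "peak_specific_fraction",
              "stop_codon_bias", "seq_error_rate", "de_fraction")) {
    check_number(cfg[[p]], p, min = 0, max = 1)
  }
  check_number(cfg$depth_per_library, "depth_per_library", min = 0)
  check_number(cfg$pcr_duplication_rate, "pcr_duplication_rate", min = 0)
  check_number(cfg$de_fold, "de_fold", min = 0)
  if (length(cfg$gene_length_range) != 2L ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2]) {
    abort("`gene_length_range` must be an increasing pair")
  }
  # every exon must be able to hold a read and the minimal UTR/CDS split
  min_needed <- max(400L, cfg$n_exons * (cfg$read_length + 20L))
  if (cfg$gene_length_range[1] < min_needed) {
    abort(sprintf(
      "gene length %d is shorter than the minimal exon structure (need >= %d bp)",
      cfg$gene_length_range[1], min_needed))
  }
  if (!grepl("^[ACGT]+$", cfg$motif)) abort("`motif` must be a DNA k-mer")
  invisible(cfg)
}

# split `total` into `k` integer parts, each >= min_part, randomly
split_lengths <- function(total, k, min_part) {
  if (k == 1L) return(total)
  extra <- total - k * min_part
  as.integer(rmultinom(1L, extra, rep(1 / k, k))[, 1] + min_part)
}

# map an mRNA-coordinate interval [m0, m1) onto genomic intervals through
# the gene's exon table (columns mstart/mend/gstart/gend, strand-aware)
map_mrna_interval <- function(exons, m0, m1) {
  hit <- exons[exons$mstart < m1 & exons$mend > m0, , drop = FALSE]
  if (nrow(hit) == 0L) return(tibble(start = integer(), end = integer()))
  a <- pmax(hit$mstart, m0)
  b <- pmin(hit$mend, m1)
  if (hit$strand[1] == "+") {
    tibble(start = hit$gstart + (a - hit$mstart),
           end = hit$gstart + (b - hit$mstart))
  } else {
    tibble(start = hit$gend - (b - hit$mstart),
           end = hit$gend - (a - hit$mstart))
  }
}

# genomic 0-based position of a single mRNA coordinate
map_mrna_point <- function(exons, m) {
  iv <- map_mrna_interval(exons, m, m + 1L)
  iv$start[1]
}

#' Simulate a toy genome and gene annotation
#'
#' Lays `n_genes` genes along a single synthetic chromosome with
#' intergenic gaps, assigns each a strand, an exon/intron structure and
#' (for coding genes) a 5'UTR/CDS/3'UTR partition of the mRNA; a
#' configurable fraction are non-protein-coding (`NP_exon` only). True m6A
#' peaks are chosen on a subset of coding genes — biased to start at the
#' stop codon — and the configured motif is written into the genome
#' sequence at each peak centre, in transcript orientation.
#'
#' @param config a [simulation_config()] object.
#' @return A list of class `merip_genome` with elements
#'   `genome` (named [Biostrings::DNAStringSet-class]),
#'   `annotation` (a `merip_annotation`: `$genes`, `$features`, `$exons`,
#'   `$seqlengths`), `truth_peaks` (tibble of planted peaks with their
#'   condition), and `config`.
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "merip_sim_config"))
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  n <- cfg$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n))
  coding <- runif(n) >= cfg$noncoding_fraction
  mrna_len <- as.integer(round(runif(n, cfg$gene_length_range[1],
                                     cfg$gene_length_range[2])))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  genes <- vector("list", n)
  feats <- vector("list", n)
  exon_tabs <- vector("list", n)
  cursor <- cfg$intergenic_gap
  min_exon <- cfg$read_length + 20L

  for (i in seq_len(n)) {
    ex_len <- split_lengths(mrna_len[i], cfg$n_exons, min_exon)
    n_int <- cfg$n_exons - 1L
    int_len <- if (n_int > 0) {
      as.integer(round(runif(n_int, cfg$intron_length_range[1],
                             cfg$intron_length_range[2])))
    } else integer()
    span <- sum(ex_len) + sum(int_len)
    gstart <- cursor
    gend <- gstart + span
    cursor <- gend + cfg$intergenic_gap

    # genomic exon layout, left to right
    g_off <- gstart + cumsum(c(0L, head(ex_len, -1) + int_len))
    ex_g <- tibble(gstart = as.integer(g_off),
                   gend = as.integer(g_off + ex_len))
    # mRNA order follows transcription: reverse genomic order on "-"
    ord <- if (strand[i] == "+") seq_len(cfg$n_exons) else rev(seq_len(cfg$n_exons))
    ex_m <- ex_g[ord, , drop = FALSE]
    w <- ex_m$gend - ex_m$gstart
    ex_m$mstart <- as.integer(cumsum(c(0L, head(w, -1))))
    ex_m$mend <- as.integer(ex_m$mstart + w)
    ex_m$strand <- strand[i]
    ex_m$gene_id <- gene_ids[i]
    exon_tabs[[i]] <- ex_m

    if (coding[i]) {
      u5 <- max(100L, as.integer(round(0.15 * mrna_len[i])))
      cds <- as.integer(round(0.60 * mrna_len[i]))
      segs <- tibble(
        feature = c("five_prime_utr", "CDS", "three_prime_utr"),
        m0 = c(0L, u5, u5 + cds),
        m1 = c(u5, u5 + cds, mrna_len[i])
      )
    } else {
      segs <- tibble(feature = "NP_exon", m0 = 0L, m1 = mrna_len[i])
    }
    lab <- purrr::pmap_dfr(segs, function(feature, m0, m1) {
      iv <- map_mrna_interval(ex_m, m0, m1)
      iv$feature <- feature
      iv
    })
    if (n_int > 0) {
      int_start <- ex_g$gend[-cfg$n_exons]
      int_end <- ex_g$gstart[-1]
      lab <- bind_rows(lab, tibble(start = int_start, end = int_end,
                                   feature = "intron"))
    }
    lab$gene_id <- gene_ids[i]
    lab$seqname <- "chr1"
    lab$strand <- strand[i]
    feats[[i]] <- lab

    sc_m <- if (coding[i]) u5 + cds else NA_integer_
    tss_i <- if (strand[i] == "+") gstart else gend - 1L
    sc_g <- if (coding[i]) map_mrna_point(ex_m, sc_m) else NA_integer_
    genes[[i]] <- tibble(
      gene_id = gene_ids[i], seqname = "chr1", strand = strand[i],
      start = gstart, end = gend, coding = coding[i],
      mrna_length = mrna_len[i],
      tss = tss_i, stop_codon = sc_g, stop_codon_mrna = sc_m
    )
  }

  genes <- bind_rows(genes)
  features <- bind_rows(feats) %>%
    select("gene_id", "seqname", "strand", "feature", "start", "end") %>%
    arrange(.data$start)
  exons <- bind_rows(exon_tabs)

  chr_len <- max(genes$end) + cfg$intergenic_gap
  seq_chars <- sample(c("A", "C", "G", "T"), chr_len, replace = TRUE)

  # plant true peaks on a subset of coding genes
  coding_ids <- genes$gene_id[genes$coding]
  n_peaks <- min(as.integer(round(cfg$peak_fraction * n)), length(coding_ids))
  peak_genes <- sort(sample(coding_ids, n_peaks))
  truth_peaks <- purrr::map_dfr(peak_genes, function(gid) {
    g <- genes[genes$gene_id == gid, ]
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    if (runif(1) < cfg$stop_codon_bias) {
      p0 <- g$stop_codon_mrna
    } else {
      p0 <- as.integer(floor(runif(1, 0, g$mrna_length - cfg$peak_width)))
    }
    # keep the peak inside one exon so it maps to a single genomic interval
    host <- ex[ex$mstart <= p0 & p0 < ex$mend, , drop = FALSE][1, ]
    wd <- min(cfg$peak_width, host$mend - host$mstart)
    p0 <- min(max(p0, host$mstart), host$mend - wd)
    iv <- map_mrna_interval(ex, p0, p0 + wd)
    tibble(gene_id = gid, seqname = g$seqname, start = iv$start[1],
           end = iv$end[1], strand = g$strand,
           mrna_start = p0, mrna_end = p0 + wd)
  })
  cond <- sample(c("both", "coarse", "fine"), nrow(truth_peaks), replace = TRUE,
                 prob = c(1 - cfg$peak_specific_fraction,
                          cfg$peak_specific_fraction / 2,
                          cfg$peak_specific_fraction / 2))
  truth_peaks$condition <- cond

  # write the motif at each peak centre, in transcript orientation
  motif <- strsplit(cfg$motif, "")[[1]]
  for (j in seq_len(nrow(truth_peaks))) {
    ctr <- truth_peaks$start[j] +
      ((truth_peaks$end[j] - truth_peaks$start[j]) - length(motif)) %/% 2L
    m <- if (truth_peaks$strand[j] == "+") motif else rev(chartr_vec(motif))
    seq_chars[(ctr + 1L):(ctr + length(motif))] <- m
  }

  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "chr1"

  annotation <- structure(
    list(genes = genes, features = features, exons = exons,
         seqlengths = c(chr1 = chr_len)),
    class = "merip_annotation")

  new_merip_result(
    list(genome = genome, annotation = annotation,
         truth_peaks = truth_peaks, config = cfg),
    "merip_genome")
}

# complement of a DNA character vector (elementwise)
chartr_vec <- function(x) chartr("ACGT", "TGCA", x)

#' Simulate IP and Input read libraries with ground truth
#'
#' Draws stranded read placements for the four libraries (coarse/fine x
#' IP/Input). Input coverage is proportional to per-gene expression; IP
#' coverage carries the same per-base background rate plus a
#' `peak_enrichment`-fold elevated rate for fragments overlapping a true
#' peak present in that condition, so the expected within-peak IP:Input
#' count ratio equals `peak_enrichment`. Optionally emits FASTQ-style
#' sequenced copies: each molecule gets a UMI, `1 + Poisson(rate)` PCR
#' copies sharing that UMI, and per-base substitution errors on the
#' fragment.
#'
#' @param sim a `merip_genome` from [simulate_genome()].
#' @param config a [simulation_config()]; defaults to the one stored in `sim`.
#' @param emit_fastq also generate the UMI-tagged sequenced copies
#'   (slower at high depth); set `FALSE` when only aligned placements are
#'   needed.
#' @param conditions which conditions to simulate.
#' @return A list of class `merip_sim_reads` with `reads` (tibble of
#'   aligned placements, 0-based half-open), `fastq` (tibble of sequenced
#'   copies or `NULL`), and `truth` (`$true_peaks`, `$true_de`,
#'   `$true_molecules`).
#' @export
simulate_reads <- function(sim, config = sim$config, emit_fastq = TRUE,
                           conditions = c("coarse", "fine")) {
  stopifnot(inherits(sim, "merip_genome"))
  validate_sim_config(config)
  withr::with_seed(
    derive_seed(config$seed, 1L),
    simulate_reads_impl(sim, config, emit_fastq, match.arg(conditions,
      c("coarse", "fine"), several.ok = TRUE)))
}

simulate_reads_impl <- function(sim, cfg, emit_fastq, conditions) {
  ann <- sim$annotation
  genes <- ann$genes
  n <- nrow(genes)
  rl <- cfg$read_length

  if (cfg$depth_per_library == 0L) {
    warn("depth_per_library is 0: emitting empty libraries")
  }

  # per-gene expression and differential-expression truth
  base_expr <- rlnorm(n, meanlog = 0, sdlog = 0.5)
  n_de <- as.integer(round(cfg$de_fraction * n))
  de_genes <- sort(sample(genes$gene_id, n_de))
  de_class <- rep("ns", n)
  fold <- rep(1, n)
  if (n_de > 0) {
    up <- de_genes[seq_len(ceiling(n_de / 2))]
    down <- setdiff(de_genes, up)
    fold[genes$gene_id %in% up] <- cfg$de_fold
    fold[genes$gene_id %in% down] <- 1 / cfg$de_fold
    de_class[genes$gene_id %in% up] <- "up"
    de_class[genes$gene_id %in% down] <- "down"
  }
  true_de <- tibble(gene_id = genes$gene_id, fold_change = fold,
                    de_class = de_class)

  # per-gene fragment-start geometry in mRNA coordinates
  geom <- purrr::map(genes$gene_id, function(gid) {
    ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    ok <- ex[ex$mend - ex$mstart >= rl, , drop = FALSE]
    allowed <- cbind(ok$mstart, ok$mend - rl) # inclusive start ranges
    pk <- sim$truth_peaks[sim$truth_peaks$gene_id == gid, , drop = FALSE]
    list(exons = ex, allowed = allowed,
         A = sum(allowed[, 2] - allowed[, 1] + 1L),
         peak = if (nrow(pk)) pk else NULL)
  })
  names(geom) <- genes$gene_id

  # inclusive range intersection helpers over the allowed-start ranges
  range_positions <- function(ranges) {
    unlist(lapply(seq_len(nrow(ranges)), function(i)
      seq.int(ranges[i, 1], ranges[i, 2])), use.names = FALSE)
  }

  all_reads <- list()
  all_fastq <- list()
  mol_counts <- list()
  mol_counter <- 0L

  for (cond in conditions) {
    mult <- if (cond == "coarse") fold else rep(1, n)
    w <- base_expr * mult * genes$mrna_length

    # enrichment factor per gene for this condition's IP library
    S <- numeric(n)
    for (i in seq_len(n)) {
      g <- geom[[i]]
      if (!is.null(g$peak) &&
          g$peak$condition[1] %in% c("both", cond)) {
        lo <- g$peak$mrna_start[1] - rl + 1L
        hi <- g$peak$mrna_end[1] - 1L
        s <- 0L
        for (r in seq_len(nrow(g$allowed))) {
          a <- max(g$allowed[r, 1], lo)
          b <- min(g$allowed[r, 2], hi)
          if (b >= a) s <- s + (b - a + 1L)
        }
        S[i] <- s
      }
    }
    A <- vapply(geom, function(g) as.numeric(g$A), numeric(1))
    E <- cfg$peak_enrichment
    f <- (A - S + E * S) / A

    for (lib in c("IP", "Input")) {
      lam <- cfg$depth_per_library * (w / sum(w)) * (if (lib == "IP") f else 1)
      total <- as.integer(round(sum(lam)))
      counts <- if (total > 0) {
        rmultinom(1L, total, lam / sum(lam))[, 1]
      } else rep(0L, n)

      lib_reads <- vector("list", n)
      for (i in seq_len(n)) {
        m <- counts[i]
        if (m == 0L) next
        g <- geom[[i]]
        if (lib == "IP" && S[i] > 0) {
          p_peak <- E * S[i] / (A[i] - S[i] + E * S[i])
          in_peak <- runif(m) < p_peak
        } else {
          in_peak <- rep(FALSE, m)
        }
        pos <- integer(m)
        lo <- if (!is.null(g$peak)) g$peak$mrna_start[1] - rl + 1L else NA
        hi <- if (!is.null(g$peak)) g$peak$mrna_end[1] - 1L else NA
        if (any(in_peak)) {
          pk_ranges <- do.call(rbind, lapply(seq_len(nrow(g$allowed)), function(r) {
            a <- max(g$allowed[r, 1], lo); b <- min(g$allowed[r, 2], hi)
            if (b >= a) c(a, b) else NULL
          }))
          pk_pos <- range_positions(pk_ranges)
          pos[in_peak] <- pk_pos[sample.int(length(pk_pos), sum(in_peak),
                                            replace = TRUE)]
        }
        if (any(!in_peak)) {
          if (lib == "IP" && S[i] > 0) {
            bg_ranges <- do.call(rbind, lapply(seq_len(nrow(g$allowed)), function(r) {
              a <- g$allowed[r, 1]; b <- g$allowed[r, 2]
              pieces <- list()
              if (is.na(lo) || b < lo || a > hi) return(matrix(c(a, b), 1))
              if (a < lo) pieces <- c(pieces, list(c(a, lo - 1L)))
              if (b > hi) pieces <- c(pieces, list(c(hi + 1L, b)))
              if (length(pieces)) do.call(rbind, pieces) else NULL
            }))
            bg_pos <- range_positions(bg_ranges)
          } else {
            bg_pos <- range_positions(g$allowed)
          }
          pos[!in_peak] <- bg_pos[sample.int(length(bg_pos), sum(!in_peak),
                                             replace = TRUE)]
        }
        # map mRNA starts to genomic intervals (fragments stay in one exon)
        ex <- g$exons
        idx <- findInterval(pos, ex$mstart)
        gs <- if (ex$strand[1] == "+") {
          ex$gstart[idx] + (pos - ex$mstart[idx])
        } else {
          ex$gend[idx] - (pos - ex$mstart[idx]) - rl
        }
        strnd <- if (cfg$stranded) rep(ex$strand[1], m)
                 else sample(c("+", "-"), m, replace = TRUE)
        lib_reads[[i]] <- tibble(
          seqname = genes$seqname[i],
          start = as.integer(gs), end = as.integer(gs + rl),
          strand = strnd, library = lib, condition = cond,
          gene_id = genes$gene_id[i])
      }
      lib_tbl <- bind_rows(lib_reads)
      if (nrow(lib_tbl)) {
        lib_tbl$molecule_id <- mol_counter + seq_len(nrow(lib_tbl))
        mol_counter <- mol_counter + nrow(lib_tbl)
      } else {
        lib_tbl$molecule_id <- integer()
      }
      all_reads[[paste(cond, lib, sep = "_")]] <- lib_tbl
      mol_counts[[paste(cond, lib, sep = "_")]] <-
        tibble(condition = cond, library = lib, molecules = nrow(lib_tbl))
    }
  }

  reads <- bind_rows(all_reads)
  fastq <- NULL
  if (emit_fastq && nrow(reads) > 0) {
    fastq <- make_fastq_copies(reads, sim$genome, cfg)
  } else if (emit_fastq) {
    fastq <- tibble(read_id = character(), umi = character(),
                    sequence = character(), quality = character(),
                    molecule_id = integer(), library = character(),
                    condition = character())
  }

  new_merip_result(
    list(reads = reads, fastq = fastq,
         truth = list(true_peaks = sim$truth_peaks, true_de = true_de,
                      true_molecules = bind_rows(mol_counts)),
         config = cfg),
    "merip_sim_reads")
}

# expand molecules into UMI-tagged PCR copies with substitution errors
make_fastq_copies <- function(reads, genome, cfg) {
  chr <- as.character(genome[["chr1"]])
  template <- substring(chr, reads$start + 1L, reads$end)
  neg <- reads$strand == "-"
  if (any(neg)) template[neg] <- revcomp(template[neg])

  bases <- c("A", "C", "G", "T")
  umis <- vapply(seq_len(nrow(reads)), function(i)
    paste(sample(bases, cfg$umi_length, replace = TRUE), collapse = ""),
    character(1))
  n_copies <- 1L + rpois(nrow(reads), cfg$pcr_duplication_rate)

  idx <- rep.int(seq_len(nrow(reads)), n_copies)
  copy_no <- sequence(n_copies)
  seqs <- template[idx]

  if (cfg$seq_error_rate > 0) {
    rl <- nchar(seqs[1])
    n_err <- rbinom(length(seqs), rl, cfg$seq_error_rate)
    hit <- which(n_err > 0)
    for (j in hit) {
      p <- sample.int(rl, n_err[j])
      s <- strsplit(seqs[j], "")[[1]]
      s[p] <- vapply(s[p], function(b) sample(setdiff(bases, b), 1),
                     character(1))
      seqs[j] <- paste(s, collapse = "")
    }
  }

  tibble(
    read_id = sprintf("%s_%s:%d:%d_%s",
                      reads$condition[idx], reads$library[idx],
                      reads$molecule_id[idx], copy_no, umis[idx]),
    umi = umis[idx],
    sequence = paste0(umis[idx], seqs),
    quality = strrep("I", cfg$umi_length + nchar(seqs)),
    molecule_id = reads$molecule_id[idx],
    library = reads$library[idx],
    condition = reads$condition[idx])
}

#' Run the full synthetic generator in one call
#'
#' Convenience wrapper around [simulate_genome()] and [simulate_reads()].
#'
#' @inheritParams simulate_reads
#' @param config a [simulation_config()].
#' @return A list of class `merip_simulation` combining the `merip_genome`
#'   elements with `reads`, `fastq` and `truth`.
#' @export
#' @examples
#' sim <- simulate_merip(simulation_config(n_genes = 10,
#'                                         depth_per_library = 2000,
#'                                         seed = 7))
#' dplyr::count(sim$reads, condition, library)
simulate_merip <- function(config = simulation_config(), emit_fastq = TRUE,
                           conditions = c("coarse", "fine")) {
  g <- simulate_genome(config)
  r <- simulate_reads(g, config, emit_fastq = emit_fastq,
                      conditions = conditions)
  new_merip_result(
    list(genome = g$genome, annotation = g$annotation,
         truth_peaks = g$truth_peaks, reads = r$reads, fastq = r$fastq,
         truth = r$truth, config = config),
    "merip_simulation")
}
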