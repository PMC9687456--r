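# Readers and writers for the standard formats around the pipeline.
# Internal tables are 0-based half-open; GTF is read/written 1-based
# closed, BED 0-based half-open.

#' Write a simulated genome to FASTA
#'
#' @param genome a named [Biostrings::DNAStringSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet-class].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a gene annotation to GTF
#'
#' Emits gene, transcript, exon and (for coding genes) CDS,
#' five_prime_utr and three_prime_utr records, 1-based closed per the GTF
#' convention. Non-protein-coding transcripts are written with exon
#' records only.
#'
#' @param annotation a `merip_annotation` (see [simulate_genome()] or
#'   [read_annotation_gtf()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  genes <- annotation$genes
  feats <- annotation$features
  exons <- annotation$exons

  rows <- list()
  add <- function(type, gid, start, end, strand, seqname) {
    tibble(seqname = seqname, type = type, start = start, end = end,
           strand = strand, gene_id = gid)
  }
  rows[[1]] <- add("gene", genes$gene_id, genes$start, genes$end,
                   genes$strand, genes$seqname)
  rows[[2]] <- add("transcript", genes$gene_id, genes$start, genes$end,
                   genes$strand, genes$seqname)
  ex <- exons %>%
    left_join(genes[, c("gene_id", "seqname")], by = "gene_id")
  rows[[3]] <- add("exon", ex$gene_id, ex$gstart, ex$gend, ex$strand,
                   ex$seqname)
  cod <- feats[feats$feature %in% c("CDS", "five_prime_utr", "three_prime_utr"), ]
  if (nrow(cod)) {
    rows[[4]] <- add(cod$feature, cod$gene_id, cod$start, cod$end,
                     cod$strand, cod$seqname)
  }
  tab <- bind_rows(rows)

  # GTF phase for CDS pieces, in transcript order per gene
  tab$phase <- NA_integer_
  is_cds <- tab$type == "CDS"
  for (gid in unique(tab$gene_id[is_cds])) {
    idx <- which(is_cds & tab$gene_id == gid)
    idx <- idx[order(tab$start[idx],
                     decreasing = tab$strand[idx[1]] == "-")]
    w <- tab$end[idx] - tab$start[idx]
    tab$phase[idx] <- (3L - as.integer(cumsum(c(0L, head(w, -1)))) %% 3L) %% 3L
  }

  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqname,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$gene_id <- tab$gene_id
  S4Vectors::mcols(gr)$transcript_id <- paste0(tab$gene_id, ".t1")
  S4Vectors::mcols(gr)$source <- "meripkit"
  S4Vectors::mcols(gr)$phase <- tab$phase
  rtracklayer::export(sort(gr), path, format = "gtf")
  # drop the run-date header line so identical annotations give
  # byte-identical files regardless of when they are written
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

#' Read a GTF gene annotation
#'
#' Converts a GTF (1-based closed) into the package's annotation object
#' (0-based half-open). Exons of transcripts lacking any CDS record are
#' labeled `NP_exon` ("non-protein exon"); introns are derived as the
#' transcript span minus its exons.
#'
#' @param path GTF file.
#' @return A `merip_annotation` list: `$genes`, `$features`, `$exons`,
#'   `$seqlengths`.
#' @export
read_annotation_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) {
                   abort(sprintf("failed to parse GTF '%s': %s", path,
                                 conditionMessage(e)))
                 })
  df <- as_tibble(as.data.frame(gr))
  check_columns(df, c("type", "gene_id"), "GTF")
  if (!nrow(df)) abort(sprintf("GTF '%s' contains no records", path))
  df <- df %>%
    mutate(start = .data$start - 1L, # back to 0-based half-open
           seqname = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           type = as.character(.data$type))

  ex <- df %>% filter(.data$type == "exon")
  if (!nrow(ex)) abort(sprintf("GTF '%s' has no exon records", path))
  cds <- df %>% filter(.data$type == "CDS")
  utr5 <- df %>% filter(.data$type %in% c("five_prime_utr", "5UTR"))
  utr3 <- df %>% filter(.data$type %in% c("three_prime_utr", "3UTR"))
  coding_ids <- unique(cds$gene_id)

  genes <- ex %>%
    group_by(.data$gene_id) %>%
    summarise(seqname = .data$seqname[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end),
              mrna_length = sum(.data$end - .data$start), .groups = "drop") %>%
    mutate(coding = .data$gene_id %in% coding_ids,
           tss = if_else(.data$strand == "+", .data$start, .data$end - 1L))

  # stop codon = first base of the 3'UTR in genomic coordinates
  sc <- cds %>%
    group_by(.data$gene_id) %>%
    summarise(cds_start = min(.data$start), cds_end = max(.data$end),
              strand = .data$strand[1], .groups = "drop") %>%
    mutate(stop_codon = if_else(.data$strand == "+", .data$cds_end,
                                .data$cds_start - 1L)) %>%
    select("gene_id", "stop_codon")
  genes <- genes %>% left_join(sc, by = "gene_id")

  pick <- c("gene_id", "seqname", "strand", "start", "end")
  labeled <- bind_rows(
    cds %>% select(dplyr::all_of(pick)) %>% mutate(feature = "CDS"),
    utr5 %>% select(dplyr::all_of(pick)) %>% mutate(feature = "five_prime_utr"),
    utr3 %>% select(dplyr::all_of(pick)) %>% mutate(feature = "three_prime_utr"),
    ex %>% filter(!(.data$gene_id %in% coding_ids)) %>%
      select(dplyr::all_of(pick)) %>% mutate(feature = "NP_exon")
  )

  # introns: per gene, transcript span minus exons
  introns <- ex %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$start), ]
      if (nrow(d) < 2) {
        return(tibble(seqname = character(), strand = character(),
                      start = integer(), end = integer()))
      }
      tibble(seqname = d$seqname[1], strand = d$strand[1],
             start = d$end[-nrow(d)], end = d$start[-1])
    }) %>%
    ungroup() %>%
    filter(.data$end > .data$start) %>%
    mutate(feature = "intron")

  features <- bind_rows(labeled, introns) %>%
    select("gene_id", "seqname", "strand", "feature", "start", "end") %>%
    arrange(.data$seqname, .data$start)

  # exon map in transcript coordinates (mRNA order follows strand)
  exons <- ex %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$start, decreasing = d$strand[1] == "-"), ]
      w <- d$end - d$start
      tibble(gstart = d$start, gend = d$end,
             mstart = as.integer(cumsum(c(0L, head(w, -1)))),
             mend = as.integer(cumsum(w)), strand = d$strand[1])
    }) %>%
    ungroup()

  seqlen <- tapply(df$end, df$seqname, max)
  structure(list(genes = genes, features = features, exons = exons,
                 seqlengths = setNames(as.integer(seqlen), names(seqlen))),
            class = "merip_annotation")
}

#' Write aligned read placements to BED6
#'
#' @param reads tibble with `seqname`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param path output file.
#' @param name optional name column to use for the BED name field.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path, name = NULL) {
  check_columns(reads, c("seqname", "start", "end", "strand"), "reads")
  nm <- if (!is.null(name) && name %in% names(reads)) reads[[name]]
        else sprintf("read%06d", seq_len(nrow(reads)))
  readr::write_tsv(
    tibble(reads$seqname, reads$start, reads$end, nm, 0L, reads$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Read aligned read placements from BED6
#'
#' @param path BED file (0-based half-open).
#' @param library,condition optional labels attached to every read.
#' @return tibble of reads.
#' @export
read_reads_bed <- function(path, library = NA_character_,
                           condition = NA_character_) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(seqname = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         library = library, condition = condition,
         read_id = if (!is.null(gr$name)) as.character(gr$name)
                   else sprintf("read%06d", seq_along(gr)))
}

#' Write called peaks to BED6+3
#'
#' Columns: chrom, start, end, name, -log10(p) as score, strand,
#' ip_count, input_count, enrichment.
#'
#' @param peaks peak tibble (from [call_peaks()] / [tidy()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  check_columns(peaks, c("seqname", "start", "end", "strand", "p_value",
                         "ip_count", "input_count", "enrichment"), "peaks")
  readr::write_tsv(
    tibble(peaks$seqname, peaks$start, peaks$end,
           sprintf("peak%05d", seq_len(nrow(peaks))),
           round(-log10(pmax(peaks$p_value, 1e-300)), 4),
           peaks$strand, peaks$ip_count, peaks$input_count,
           round(peaks$enrichment, 4)),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6+3 peak file written by [write_peaks_bed()]
#'
#' @param path peak BED file.
#' @return tibble of peaks.
#' @export
read_peaks_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c(
    "seqname", "start", "end", "name", "score", "strand",
    "ip_count", "input_count", "enrichment"),
    col_types = "ciicdciid", progress = FALSE)
  df %>% mutate(p_value = 10^(-.data$score)) %>%
    select("seqname", "start", "end", "strand", "ip_count",
           "input_count", "enrichment", "p_value")
}

#' Write sequenced reads to FASTQ
#'
#' @param fastq tibble with `read_id`, `sequence`, `quality`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(fastq, path) {
  check_columns(fastq, c("read_id", "sequence", "quality"), "fastq")
  x <- Biostrings::BStringSet(fastq$sequence)
  names(x) <- fastq$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(fastq$quality))
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' If read names carry the UMI after the last underscore (the simulator's
#' convention), it is parsed into a `umi` column.
#'
#' @param path FASTQ file.
#' @return tibble with `read_id`, `sequence`, `quality` and, when
#'   recoverable from the names, `umi`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- names(x)
  out <- tibble(read_id = ids,
                sequence = unname(as.character(x)),
                quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
  umi <- stringr::str_match(ids, "_([ACGTN]+)$")[, 2]
  if (!all(is.na(umi))) out$umi <- umi
  out
}
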