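# Assignment of reads and peaks to gene functional regions (5'UTR, CDS,
# 3'UTR, NP_exon, intron, intergenic) and metagene coverage profiles.

region_levels <- c("CDS", "three_prime_utr", "five_prime_utr", "NP_exon",
                   "intron", "intergenic")

#' Classify intervals by gene functional region
#'
#' Each query interval is labeled by the feature class it overlaps with
#' the most bases; ties are resolved by the fixed priority CDS >
#' 3'UTR > 5'UTR > NP_exon > intron > intergenic. Features on the
#' opposite strand are ignored for stranded queries (`+`/`-`); queries
#' with strand `*` match features on either strand. Intervals touching no
#' annotated feature are `intergenic`. The overlapping gene with maximal
#' exonic+intronic overlap is also reported (ties broken by alphabetical
#' gene id).
#'
#' @param query tibble of intervals: `seqname`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @param annotation a `merip_annotation`.
#' @return `query` with `region` and `gene_id` columns added.
#' @export
classify_intervals <- function(query, annotation) {
  check_columns(query, c("seqname", "start", "end"), "query")
  stopifnot(inherits(annotation, "merip_annotation"))
  if (!"strand" %in% names(query)) query$strand <- "*"
  unknown <- setdiff(unique(query$seqname), names(annotation$seqlengths))
  if (length(unknown)) {
    abort(sprintf("unknown seqname(s) in query: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (nrow(query) == 0L) {
    query$region <- character()
    query$gene_id <- character()
    return(query)
  }
  feats <- annotation$features
  gr_q <- as_granges0(query)
  gr_f <- as_granges0(feats)
  hits <- GenomicRanges::findOverlaps(gr_q, gr_f)
  # strand filter: "*" queries match all; stranded queries need same strand
  qs <- query$strand[S4Vectors::queryHits(hits)]
  fs <- feats$strand[S4Vectors::subjectHits(hits)]
  keep <- qs == "*" | qs == fs
  hits <- hits[keep]
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gr_q)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(gr_f)[S4Vectors::subjectHits(hits)]))

  hit_tbl <- tibble(
    q = S4Vectors::queryHits(hits),
    feature = feats$feature[S4Vectors::subjectHits(hits)],
    gene_id = feats$gene_id[S4Vectors::subjectHits(hits)],
    ov = ov)

  by_label <- hit_tbl %>%
    group_by(.data$q, .data$feature) %>%
    summarise(ov = sum(.data$ov), .groups = "drop") %>%
    mutate(.prio = match(.data$feature, region_levels)) %>%
    arrange(.data$q, desc(.data$ov), .data$.prio) %>%
    group_by(.data$q) %>%
    dplyr::slice(1) %>%
    ungroup()

  by_gene <- hit_tbl %>%
    group_by(.data$q, .data$gene_id) %>%
    summarise(ov = sum(.data$ov), .groups = "drop") %>%
    arrange(.data$q, desc(.data$ov), .data$gene_id) %>%
    group_by(.data$q) %>%
    dplyr::slice(1) %>%
    ungroup()

  query$region <- "intergenic"
  query$region[by_label$q] <- by_label$feature
  query$gene_id <- NA_character_
  query$gene_id[by_gene$q] <- by_gene$gene_id
  query
}

#' Assign peaks to genes
#'
#' Thin wrapper over [classify_intervals()] keeping the maximal-overlap
#' gene assignment (ties alphabetical by gene id).
#'
#' @param peaks peak tibble or `merip_peaks`.
#' @param annotation a `merip_annotation`.
#' @return peak tibble with `gene_id` and `region` columns.
#' @export
assign_peaks_to_genes <- function(peaks, annotation) {
  classify_intervals(peaks_table(peaks), annotation)
}

#' Distribution of intervals across gene functional regions
#'
#' Tallies [classify_intervals()] labels over an interval set.
#'
#' @param items interval tibble (reads, peaks, ...).
#' @param annotation a `merip_annotation`.
#' @return tibble of class `merip_regions`: `region`, `n`, `fraction`
#'   (fractions sum to 1 for non-empty input). An empty input warns and
#'   returns all-zero counts.
#' @export
region_distribution <- function(items, annotation) {
  if (nrow(items) == 0L) {
    warn("region_distribution: empty interval set")
    out <- tibble(region = region_levels, n = 0L, fraction = 0)
  } else {
    cls <- classify_intervals(items, annotation)
    out <- tibble(region = factor(cls$region, levels = region_levels)) %>%
      count(.data$region, .drop = FALSE) %>%
      mutate(region = as.character(.data$region),
             fraction = .data$n / sum(.data$n))
  }
  class(out) <- c("merip_regions", class(out))
  out
}

#' Metagene coverage matrix around an anchor point
#'
#' Per-gene binned read coverage in a strand-oriented window of
#' `2 * flank` bp around the anchor (transcription start site or stop
#' codon). Bin 1 is the most 5' bin of the transcript regardless of
#' genomic strand; a read increments every bin it overlaps. Genes whose
#' window extends past the sequence edge keep zero counts in the missing
#' part and are flagged.
#'
#' @param reads aligned read tibble.
#' @param annotation a `merip_annotation`.
#' @param anchor `"TSS"` or `"stop_codon"` (coding genes only for the
#'   latter).
#' @param flank half-window in bp (> 0).
#' @param bins number of equal-width bins (> 0).
#' @return An object of class `merip_metagene`: list with `matrix`
#'   (genes x bins incidence counts), `anchor`, `flank`, `bins`,
#'   `clipped` (gene ids with clipped windows).
#' @export
metagene_matrix <- function(reads, annotation, anchor = c("TSS", "stop_codon"),
                            flank = 1000L, bins = 50L) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(annotation, "merip_annotation"))
  check_number(flank, "flank", min = 1)
  check_number(bins, "bins", min = 1)
  genes <- annotation$genes
  pos <- if (anchor == "TSS") genes$tss else genes$stop_codon
  keep <- !is.na(pos)
  genes <- genes[keep, , drop = FALSE]
  pos <- pos[keep]

  bw <- 2 * flank / bins
  edges_lo <- vapply(seq_len(bins), function(b)
    -flank + (b - 1) * bw, numeric(1))
  mat <- matrix(0L, nrow = nrow(genes), ncol = bins,
                dimnames = list(genes$gene_id, NULL))
  clipped <- character()

  gr_reads <- if (nrow(reads)) as_granges0(reads, use_strand = FALSE) else NULL
  for (i in seq_len(nrow(genes))) {
    # bins follow transcript orientation: bin b covers transcript offsets
    # [edges_lo[b], edges_lo[b] + bw), with offset = g - anchor on "+"
    # and anchor - g on "-" genes
    if (genes$strand[i] == "+") {
      lo <- floor(pos[i] + edges_lo)
      hi <- floor(pos[i] + edges_lo + bw)
    } else {
      lo <- floor(pos[i] - (edges_lo + bw)) + 1
      hi <- floor(pos[i] - edges_lo) + 1
    }
    lim <- annotation$seqlengths[[genes$seqname[i]]]
    if (any(lo < 0) || any(hi > lim)) clipped <- c(clipped, genes$gene_id[i])
    ok <- lo < lim & hi > 0
    if (!any(ok) || is.null(gr_reads)) next
    gr_bins <- GenomicRanges::GRanges(
      genes$seqname[i],
      IRanges::IRanges(start = pmax(lo[ok], 0) + 1L, end = pmin(hi[ok], lim)))
    cnt <- GenomicRanges::countOverlaps(
      gr_bins, gr_reads[as.character(GenomicRanges::seqnames(gr_reads)) ==
                          genes$seqname[i]],
      ignore.strand = TRUE)
    row <- integer(bins)
    row[which(ok)] <- cnt
    mat[i, ] <- row
  }
  new_merip_result(
    list(matrix = mat, anchor = anchor, flank = flank, bins = bins,
         clipped = clipped),
    "merip_metagene")
}

#' Mean metagene profiles per library
#'
#' Convenience wrapper computing one [metagene_matrix()] per
#' condition-library combination present in `reads` and averaging over
#' genes.
#'
#' @inheritParams metagene_matrix
#' @return tibble: `condition`, `library`, `bin`, `offset` (bp of bin
#'   centre relative to the anchor, 5' to 3'), `mean_count`.
#' @export
metagene_profile <- function(reads, annotation, anchor = c("TSS", "stop_codon"),
                             flank = 1000L, bins = 50L) {
  anchor <- match.arg(anchor)
  groups <- reads %>% distinct(.data$condition, .data$library)
  bw <- 2 * flank / bins
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    sub <- reads %>%
      filter(.data$condition == groups$condition[i],
             .data$library == groups$library[i])
    mg <- metagene_matrix(sub, annotation, anchor = anchor, flank = flank,
                          bins = bins)
    tibble(condition = groups$condition[i], library = groups$library[i],
           bin = seq_len(bins),
           offset = -flank + (seq_len(bins) - 0.5) * bw,
           mean_count = colMeans(mg$matrix))
  })
}
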