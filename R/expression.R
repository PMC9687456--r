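# Expression quantification (RPKM), fold-change differential expression,
# alignment summaries, methylation-expression overlap analysis and a
# generic hypergeometric over-representation test.

#' Reads per kilobase of exon model per million mapped reads
#'
#' `rpkm = C * 1e9 / (N * L)` for count `C`, library size `N` and exon
#' length `L` in bp. Vectorised.
#'
#' @param count reads assigned to the gene.
#' @param library_size total mapped reads of the library (> 0).
#' @param exon_length summed exon length in bp (> 0).
#' @return RPKM values.
#' @export
#' @examples
#' rpkm(1000, 1e6, 1000) # 1000
rpkm <- function(count, library_size, exon_length) {
  if (any(!is.finite(library_size)) || any(library_size <= 0)) {
    abort("`library_size` must be positive")
  }
  if (any(!is.finite(exon_length)) || any(exon_length <= 0)) {
    abort("`exon_length` must be positive")
  }
  count * 1e9 / (library_size * exon_length)
}

#' Quantify per-gene expression from Input libraries
#'
#' Counts Input reads per gene (a read counts for the gene whose exons
#' it overlaps the most, ties alphabetical), computes RPKM per condition
#' and the coarse/fine fold change with a pseudocount on both RPKM
#' values.
#'
#' @param reads aligned reads; only `library == "Input"` rows are used
#'   (the Input library plays the RNA-seq role).
#' @param annotation a `merip_annotation`.
#' @param pseudocount added to both RPKM values before the ratio
#'   (default 0.5).
#' @return tibble of class `merip_expression`: `gene_id`, `exon_length`,
#'   `count_coarse`, `count_fine`, `rpkm_coarse`, `rpkm_fine`,
#'   `fold_change` plus the `library_sizes` attribute. Run [call_de()]
#'   to classify.
#' @export
quantify_expression <- function(reads, annotation, pseudocount = 0.5) {
  check_columns(reads, c("seqname", "start", "end", "condition", "library"),
                "reads")
  stopifnot(inherits(annotation, "merip_annotation"))
  input <- reads %>% filter(.data$library == "Input")
  exon_len <- annotation$exons %>%
    group_by(.data$gene_id) %>%
    summarise(exon_length = sum(.data$gend - .data$gstart), .groups = "drop")

  count_cond <- function(cond) {
    sub <- input %>% filter(.data$condition == cond)
    if (nrow(sub) == 0L) {
      return(tibble(gene_id = character(), n = integer()))
    }
    cls <- classify_intervals(sub, annotation)
    cls %>% filter(!is.na(.data$gene_id)) %>% count(.data$gene_id)
  }
  cc <- count_cond("coarse") %>% rename(count_coarse = "n")
  cf <- count_cond("fine") %>% rename(count_fine = "n")
  n_coarse <- sum(input$condition == "coarse")
  n_fine <- sum(input$condition == "fine")

  out <- exon_len %>%
    left_join(cc, by = "gene_id") %>%
    left_join(cf, by = "gene_id") %>%
    mutate(count_coarse = dplyr::coalesce(.data$count_coarse, 0L),
           count_fine = dplyr::coalesce(.data$count_fine, 0L),
           rpkm_coarse = rpkm(.data$count_coarse, max(n_coarse, 1L),
                              .data$exon_length),
           rpkm_fine = rpkm(.data$count_fine, max(n_fine, 1L),
                            .data$exon_length),
           fold_change = (.data$rpkm_coarse + pseudocount) /
             (.data$rpkm_fine + pseudocount))
  attr(out, "library_sizes") <- c(coarse = n_coarse, fine = n_fine)
  class(out) <- c("merip_expression", class(out))
  out
}

#' Classify genes as differentially expressed by fold change
#'
#' `up` iff `fold_change > up_threshold`, `down` iff
#' `fold_change < down_threshold`, `ns` otherwise — strict inequalities,
#' so boundary values are `ns`.
#'
#' @param records tibble with a `fold_change` column (e.g. from
#'   [quantify_expression()]).
#' @param up_threshold,down_threshold fold-change thresholds
#'   (defaults 2 and 0.5).
#' @return `records` with a `de_class` column.
#' @export
#' @examples
#' call_de(tibble::tibble(fold_change = c(3, 0.4, 1, 2)))$de_class
call_de <- function(records, up_threshold = 2, down_threshold = 0.5) {
  check_columns(records, "fold_change", "records")
  records$de_class <- dplyr::case_when(
    records$fold_change > up_threshold ~ "up",
    records$fold_change < down_threshold ~ "down",
    TRUE ~ "ns")
  records
}

#' Alignment summary with mapping percentages
#'
#' Computes, per sample, total/mapped/unique/non-unique read counts and
#' the three percentages as printed in standard mapping reports: mapped%
#' of total reads, unique% and non-unique% of total mapped reads, each
#' rounded to 2 decimals.
#'
#' Accepts either per-read flags (columns `sample`, `mapped`, `unique`,
#' one row per read) or pre-tallied counts (columns `sample`,
#' `total_reads`, `total_mapped`, `unique_mapped`).
#'
#' @param x a data frame in one of the two layouts above.
#' @return tibble: `sample`, `total_reads`, `total_mapped`,
#'   `unique_mapped`, `non_unique_mapped`, `mapped_pct`, `unique_pct`,
#'   `non_unique_pct`.
#' @export
#' @examples
#' alignment_summary(tibble::tibble(
#'   sample = "Coarse_IP", total_reads = 52622230,
#'   total_mapped = 50790053, unique_mapped = 47142268))
alignment_summary <- function(x) {
  if (all(c("total_reads", "total_mapped", "unique_mapped") %in% names(x))) {
    counts <- as_tibble(x)
    if (!"sample" %in% names(counts)) {
      counts$sample <- sprintf("sample%d", seq_len(nrow(counts)))
    }
  } else {
    check_columns(x, c("mapped", "unique"), "alignment flags")
    if (!"sample" %in% names(x)) x$sample <- "sample1"
    counts <- x %>%
      group_by(.data$sample) %>%
      summarise(total_reads = n(),
                total_mapped = sum(.data$mapped),
                unique_mapped = sum(.data$mapped & .data$unique),
                .groups = "drop")
  }
  counts %>%
    mutate(non_unique_mapped = .data$total_mapped - .data$unique_mapped,
           mapped_pct = round(100 * .data$total_mapped / .data$total_reads, 2),
           unique_pct = round(100 * .data$unique_mapped / .data$total_mapped, 2),
           non_unique_pct = round(100 * .data$non_unique_mapped /
                                    .data$total_mapped, 2)) %>%
    select("sample", "total_reads", "total_mapped", "unique_mapped",
           "non_unique_mapped", "mapped_pct", "unique_pct", "non_unique_pct")
}

#' Overlap analysis of methylation and expression gene sets
#'
#' Cardinalities of the pairwise and triple intersections between
#' up-methylated genes, condition-specific methylated genes and up- or
#' down-expressed genes (the two three-way comparisons of a
#' methylation-expression integration).
#'
#' @param up_m6a,specific_m6a,de_up,de_down character vectors of gene
#'   ids.
#' @return tibble of class `merip_overlap` with `comparison`, `sets`,
#'   `n` columns; set sizes and memberships are carried in the
#'   `sets` attribute.
#' @export
overlap_analysis <- function(up_m6a, specific_m6a, de_up, de_down) {
  gene_sets <- list(up_m6a = unique(up_m6a),
                    specific_m6a = unique(specific_m6a),
                    de_up = unique(de_up), de_down = unique(de_down))
  inter <- function(...) length(Reduce(intersect, list(...)))
  out <- tibble(
    comparison = c(rep("vs_up_expressed", 3), rep("vs_down_expressed", 3)),
    sets = c("up_m6a&de_up", "specific_m6a&de_up", "up_m6a&specific_m6a&de_up",
             "up_m6a&de_down", "specific_m6a&de_down",
             "up_m6a&specific_m6a&de_down"),
    n = c(inter(gene_sets$up_m6a, gene_sets$de_up),
          inter(gene_sets$specific_m6a, gene_sets$de_up),
          inter(gene_sets$up_m6a, gene_sets$specific_m6a, gene_sets$de_up),
          inter(gene_sets$up_m6a, gene_sets$de_down),
          inter(gene_sets$specific_m6a, gene_sets$de_down),
          inter(gene_sets$up_m6a, gene_sets$specific_m6a,
                gene_sets$de_down)))
  attr(out, "sets") <- gene_sets
  class(out) <- c("merip_overlap", class(out))
  out
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided hypergeometric tail probability of the observed overlap
#' between a study set and each category, Benjamini-Hochberg adjusted. A
#' generic replacement for database-backed GO/KEGG enrichment: the
#' category map is user-supplied.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of background gene ids.
#' @param category_map data frame with columns `gene_id` and `category`.
#' @return tibble: `category`, `n_category`, `n_overlap`, `p_value`,
#'   `q_value`, sorted by p-value.
#' @export
gene_set_enrichment <- function(study, population, category_map) {
  check_columns(category_map, c("gene_id", "category"), "category_map")
  study <- unique(study)
  population <- unique(population)
  outside <- setdiff(study, population)
  if (length(outside)) {
    abort(sprintf("study gene(s) outside the population: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  cm <- category_map %>%
    filter(.data$gene_id %in% population) %>%
    distinct(.data$gene_id, .data$category)
  cm %>%
    group_by(.data$category) %>%
    summarise(n_category = n(),
              n_overlap = sum(.data$gene_id %in% study),
              .groups = "drop") %>%
    mutate(p_value = phyper(.data$n_overlap - 1, .data$n_category,
                            length(population) - .data$n_category,
                            length(study), lower.tail = FALSE),
           q_value = p.adjust(.data$p_value, method = "BH")) %>%
    arrange(.data$p_value, .data$category)
}
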