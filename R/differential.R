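# Two-condition comparison of m6A peaks: peaks from the coarse and fine
# conditions are matched by >= 1 bp same-strand overlap into union
# intervals; matched records are tested with a two-sided Fisher exact
# test and classified up/down by the normalized methylation ratio;
# unmatched peaks are condition-specific.

#' Match peaks called in two conditions
#'
#' Overlapping peaks (>= 1 bp, same strand) are merged transitively into
#' a union interval; an interval covered by peaks from both conditions is
#' `matched`, otherwise it is flagged `coarse_specific` or
#' `fine_specific`.
#'
#' @param coarse_peaks,fine_peaks peak tibbles (or `merip_peaks`
#'   objects) from the two conditions.
#' @return tibble of union intervals: `seqname`, `start`, `end`,
#'   `strand`, `status`, `coarse_p`, `fine_p` (minimum contributing peak
#'   p-value per condition, `NA` when absent).
#' @export
match_peaks <- function(coarse_peaks, fine_peaks) {
  cp <- peaks_table(coarse_peaks)
  fp <- peaks_table(fine_peaks)
  if (nrow(cp) + nrow(fp) == 0L) {
    return(tibble(seqname = character(), start = integer(), end = integer(),
                  strand = character(), status = character(),
                  coarse_p = double(), fine_p = double()))
  }
  all_pk <- bind_rows(mutate(cp, .cond = "coarse"),
                      mutate(fp, .cond = "fine"))
  gr <- as_granges0(all_pk)
  red <- GenomicRanges::reduce(gr) # same-strand transitive union
  hit <- GenomicRanges::findOverlaps(red, gr)
  by_region <- split(S4Vectors::subjectHits(hit), S4Vectors::queryHits(hit))

  purrr::map_dfr(seq_along(red), function(i) {
    members <- all_pk[by_region[[as.character(i)]], , drop = FALSE]
    conds <- unique(members$.cond)
    status <- if (length(conds) == 2L) "matched"
              else paste0(conds, "_specific")
    pmin_of <- function(cond) {
      p <- members$p_value[members$.cond == cond]
      if (length(p)) min(p) else NA_real_
    }
    tibble(seqname = as.character(GenomicRanges::seqnames(red[i])),
           start = GenomicRanges::start(red[i]) - 1L,
           end = GenomicRanges::end(red[i]),
           strand = as.character(GenomicRanges::strand(red[i])),
           status = status,
           coarse_p = pmin_of("coarse"), fine_p = pmin_of("fine"))
  }) %>%
    arrange(.data$seqname, .data$start)
}

peaks_table <- function(x) {
  if (inherits(x, "merip_peaks")) x$peaks else as_tibble(x)
}

# reads overlapping each interval (>= 1 bp), per condition x library
count_in_intervals <- function(intervals, reads) {
  gr_iv <- as_granges0(intervals, use_strand = FALSE)
  out <- intervals
  for (cond in c("coarse", "fine")) {
    for (lib in c("IP", "Input")) {
      sub <- reads[reads$condition == cond & reads$library == lib, ,
                   drop = FALSE]
      col <- paste0(cond, "_", tolower(lib))
      if (nrow(sub) == 0L) {
        out[[col]] <- 0L
        next
      }
      gr_rd <- as_granges0(sub, use_strand = FALSE)
      out[[col]] <- GenomicRanges::countOverlaps(gr_iv, gr_rd,
                                                 ignore.strand = TRUE)
    }
  }
  out
}

#' Test matched peaks for differential methylation
#'
#' For every union interval the IP (and Input) reads of both conditions
#' are counted; matched records get a two-sided Fisher exact p-value and
#' a log2 methylation ratio of the reads-per-million-normalized IP/Input
#' ratios (pseudocount 0.5). Classes: `up` (p < alpha, ratio > 0), `down`
#' (p < alpha, ratio < 0), `ns` otherwise; unmatched intervals keep their
#' `coarse_specific`/`fine_specific` status.
#'
#' The default test contrasts the IP counts of the two conditions against
#' their IP library totals (`mode = "ip_vs_total"`); Input enters through
#' the ratio only. `mode = "ip_vs_input"` instead tests the 2x2 table of
#' IP and Input counts of the two conditions.
#'
#' @param matched union-interval tibble from [match_peaks()].
#' @param reads aligned reads of all four libraries, with `condition`
#'   and `library` columns.
#' @param totals named list of library totals
#'   (`coarse_ip`, `coarse_input`, `fine_ip`, `fine_input`); computed
#'   from `reads` when `NULL`.
#' @param alpha two-sided significance threshold (default 0.05).
#' @param mode contingency-table construction, see Details.
#' @param pseudocount added to normalized counts in the ratio.
#' @return tibble of differential peak records with counts, `p_value`,
#'   `log2_methylation_ratio` and `class`.
#' @export
test_differential <- function(matched, reads, totals = NULL, alpha = 0.05,
                              mode = c("ip_vs_total", "ip_vs_input"),
                              pseudocount = 0.5) {
  mode <- match.arg(mode)
  check_columns(matched, c("seqname", "start", "end", "strand", "status"),
                "matched")
  if (is.null(totals)) totals <- library_totals(reads)
  for (nm in c("coarse_ip", "coarse_input", "fine_ip", "fine_input")) {
    if (is.null(totals[[nm]]) || totals[[nm]] <= 0) {
      abort(sprintf("library total `%s` must be positive", nm))
    }
  }
  rec <- count_in_intervals(matched, reads)
  rpm <- function(x, n) 1e6 * x / n
  rec$log2_methylation_ratio <- log2(
    ((rpm(rec$coarse_ip, totals$coarse_ip) + pseudocount) /
       (rpm(rec$coarse_input, totals$coarse_input) + pseudocount)) /
      ((rpm(rec$fine_ip, totals$fine_ip) + pseudocount) /
         (rpm(rec$fine_input, totals$fine_input) + pseudocount)))

  rec$p_value <- NA_real_
  is_m <- rec$status == "matched"
  if (any(is_m)) {
    rec$p_value[is_m] <- vapply(which(is_m), function(i) {
      tab <- if (mode == "ip_vs_total") {
        matrix(c(rec$coarse_ip[i], totals$coarse_ip - rec$coarse_ip[i],
                 rec$fine_ip[i], totals$fine_ip - rec$fine_ip[i]),
               nrow = 2, byrow = TRUE)
      } else {
        matrix(c(rec$coarse_ip[i], rec$coarse_input[i],
                 rec$fine_ip[i], rec$fine_input[i]),
               nrow = 2, byrow = TRUE)
      }
      fisher.test(tab)$p.value
    }, numeric(1))
  }
  rec$class <- dplyr::case_when(
    rec$status == "coarse_specific" ~ "coarse_specific",
    rec$status == "fine_specific" ~ "fine_specific",
    is_m & rec$p_value < alpha & rec$log2_methylation_ratio > 0 ~ "up",
    is_m & rec$p_value < alpha & rec$log2_methylation_ratio < 0 ~ "down",
    TRUE ~ "ns")
  # condition-specific records inherit their originating peak's p-value
  if ("coarse_p" %in% names(rec)) {
    sp <- rec$status == "coarse_specific"
    rec$p_value[sp] <- rec$coarse_p[sp]
    sp <- rec$status == "fine_specific"
    rec$p_value[sp] <- rec$fine_p[sp]
  }
  rec
}

#' Library totals per condition and library
#'
#' @param reads aligned read tibble with `condition` and `library`.
#' @return named list: `coarse_ip`, `coarse_input`, `fine_ip`,
#'   `fine_input`.
#' @export
library_totals <- function(reads) {
  check_columns(reads, c("condition", "library"), "reads")
  list(
    coarse_ip = sum(reads$condition == "coarse" & reads$library == "IP"),
    coarse_input = sum(reads$condition == "coarse" & reads$library == "Input"),
    fine_ip = sum(reads$condition == "fine" & reads$library == "IP"),
    fine_input = sum(reads$condition == "fine" & reads$library == "Input"))
}

#' Differential m6A analysis between two conditions
#'
#' Composition of [match_peaks()] and [test_differential()], returning a
#' tidy-able result object.
#'
#' @inheritParams test_differential
#' @param coarse_peaks,fine_peaks `merip_peaks` objects or peak tibbles.
#' @param reads aligned reads of all four libraries.
#' @return An object of class `merip_diff`: list with `records`, `totals`
#'   and `params`. [tidy()] returns the records, [glance()] class
#'   totals, [autoplot()] a ratio-versus-significance plot.
#' @export
diff_m6a <- function(coarse_peaks, fine_peaks, reads, totals = NULL,
                     alpha = 0.05, mode = c("ip_vs_total", "ip_vs_input"),
                     pseudocount = 0.5) {
  mode <- match.arg(mode)
  if (is.null(totals)) totals <- library_totals(reads)
  matched <- match_peaks(coarse_peaks, fine_peaks)
  records <- test_differential(matched, reads, totals = totals,
                               alpha = alpha, mode = mode,
                               pseudocount = pseudocount)
  new_merip_result(
    list(records = records, totals = totals,
         params = list(alpha = alpha, mode = mode,
                       pseudocount = pseudocount)),
    "merip_diff")
}

#' Collapse differential peak records to genes and tally classes
#'
#' Each gene is counted once, classed by its most significant peak
#' (smallest p-value); on exact ties between an up and a down peak the
#' gene counts as `up`. Records must carry a `gene_id` column (see
#' [assign_peaks_to_genes()]).
#'
#' @param records differential peak records with `gene_id`, `class`,
#'   `p_value`.
#' @return list with `genes` (one row per gene: `gene_id`, `class`,
#'   `p_value`) and `summary` (tibble of gene counts per class).
#' @export
summarize_differential <- function(records) {
  check_columns(records, c("gene_id", "class", "p_value"), "records")
  prio <- c(up = 1L, down = 2L, coarse_specific = 3L, fine_specific = 4L,
            ns = 5L)
  genes <- records %>%
    filter(!is.na(.data$gene_id)) %>%
    mutate(.prio = prio[.data$class]) %>%
    arrange(.data$gene_id, .data$p_value, .data$.prio) %>%
    group_by(.data$gene_id) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select("gene_id", "class", "p_value")
  summary <- genes %>% count(.data$class, name = "n_genes")
  list(genes = genes, summary = summary)
}
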