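# Window-based m6A peak calling: the genome is cut into fixed 20-bp
# windows, IP vs Input read counts per window are tested against the
# library totals with a one-sided Fisher exact test, and adjacent
# significant windows are merged into peaks.

#' One-sided Fisher exact test (first row greater)
#'
#' Exact hypergeometric tail probability for the 2x2 table
#' \code{[[a, b], [c, d]]}, testing whether the first-row proportion
#' `a / (a + b)` exceeds the second-row proportion. In peak calling,
#' `a` is the window's IP count, `b` the remaining IP library,
#' `c` the window's Input count and `d` the remaining Input library.
#' Vectorised over the four arguments.
#'
#' @param a,b,c,d non-negative counts of the contingency table.
#' @return p-values in (0, 1].
#' @export
#' @examples
#' fisher_one_sided(10, 990, 1, 999)
#' fisher_one_sided(0, 100, 5, 95) # a = 0 gives p = 1
fisher_one_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(!is.finite(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    abort("fisher_one_sided() requires non-negative finite counts (is a window count larger than its library total?)")
  }
  # P(X >= a), X ~ Hypergeometric(m = a + b, n = c + d, k = a + c)
  phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

#' Count reads in fixed genomic windows
#'
#' Divides each sequence into non-overlapping windows of `window` bp
#' anchored at coordinate 0 and counts, per window, the IP and Input
#' reads overlapping it by at least 1 bp (a read therefore increments
#' every window it touches). Only windows with at least one read are
#' emitted (sparse mode). With `stranded = TRUE` windows are counted
#' separately per strand.
#'
#' @param reads tibble of aligned reads with `seqname`, `start`, `end`
#'   (0-based half-open), `strand` and `library` (`"IP"`/`"Input"`).
#' @param seqlengths optional named vector of sequence lengths; reads
#'   extending beyond them are rejected with a message.
#' @param window window width in bp (default 20).
#' @param stranded count per strand (default) or collapse strands.
#' @return tibble: `seqname`, `start`, `end`, `strand`, `ip_count`,
#'   `input_count`.
#' @export
count_windows <- function(reads, seqlengths = NULL, window = 20L,
                          stranded = TRUE) {
  check_columns(reads, c("seqname", "start", "end", "library"), "reads")
  window <- as.integer(window)
  if (window < 1L) abort("`window` must be a positive width in bp")
  if (!is.null(seqlengths)) {
    lim <- seqlengths[reads$seqname]
    bad <- is.na(lim) | reads$start < 0L | reads$end > lim
    if (any(bad)) {
      inform(sprintf("count_windows: rejected %d read(s) outside sequence bounds",
                     sum(bad)))
      reads <- reads[!bad, , drop = FALSE]
    }
  }
  if (nrow(reads) == 0L) {
    return(tibble(seqname = character(), start = integer(), end = integer(),
                  strand = character(), ip_count = integer(),
                  input_count = integer()))
  }
  strand <- if (stranded && "strand" %in% names(reads)) reads$strand
            else rep("*", nrow(reads))

  w0 <- reads$start %/% window
  w1 <- (reads$end - 1L) %/% window
  nwin <- w1 - w0 + 1L
  idx <- rep.int(seq_len(nrow(reads)), nwin)
  win <- w0[idx] + (sequence(nwin) - 1L)

  wd <- tibble(seqname = reads$seqname[idx],
               strand = strand[idx],
               start = win * window,
               library = reads$library[idx]) %>%
    count(.data$seqname, .data$strand, .data$start, .data$library) %>%
    tidyr::pivot_wider(names_from = "library", values_from = "n",
                       values_fill = 0L)
  if (!"IP" %in% names(wd)) wd$IP <- 0L
  if (!"Input" %in% names(wd)) wd$Input <- 0L
  wd %>%
    mutate(ip_count = .data$IP, input_count = .data$Input,
           end = .data$start + window) %>%
    select("seqname", "start", "end", "strand", "ip_count", "input_count") %>%
    arrange(.data$seqname, .data$strand, .data$start)
}

#' Flag windows where IP is significantly higher than Input
#'
#' Applies [fisher_one_sided()] per window against the library totals: a
#' window is significant iff its combined coverage reaches `min_cov` and
#' its (optionally BH-adjusted) one-sided p-value is below `alpha`.
#'
#' @param windows window count tibble from [count_windows()].
#' @param totals named list or vector with `ip` and `input` library
#'   totals (total reads per library, not window sums).
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param min_cov minimum combined IP + Input reads for a window to be
#'   tested (default 10; untested windows are never significant).
#' @param p_adjust `"none"` (default, raw p < alpha) or `"BH"` for
#'   Benjamini-Hochberg correction across tested windows.
#' @return `windows` with `p_value`, `tested` and `significant` columns.
#' @export
call_significant_windows <- function(windows, totals, alpha = 0.05,
                                     min_cov = 10L,
                                     p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  check_columns(windows, c("ip_count", "input_count"), "windows")
  totals <- as.list(totals)
  n_ip <- totals$ip; n_input <- totals$input
  if (is.null(n_ip) || is.null(n_input)) {
    abort("`totals` must provide `ip` and `input` library totals")
  }
  if (any(windows$ip_count > n_ip) || any(windows$input_count > n_input)) {
    abort("window counts exceed the library totals")
  }
  windows$tested <- (windows$ip_count + windows$input_count) >= min_cov
  windows$p_value <- NA_real_
  if (any(windows$tested)) {
    wt <- windows[windows$tested, ]
    windows$p_value[windows$tested] <- fisher_one_sided(
      wt$ip_count, n_ip - wt$ip_count,
      wt$input_count, n_input - wt$input_count)
  }
  crit <- windows$p_value
  if (p_adjust == "BH" && any(windows$tested)) {
    crit[windows$tested] <- p.adjust(windows$p_value[windows$tested],
                                     method = "BH")
  }
  windows$significant <- windows$tested & !is.na(crit) & crit < alpha
  windows
}

#' Merge adjacent significant windows into peaks
#'
#' Maximal runs of significant windows on the same sequence and strand,
#' separated by at most `max_gap` non-significant windows, become one
#' peak. Counts are summed over the run's significant windows and the
#' peak p-value is the minimum member p-value.
#'
#' @param windows flagged window tibble from [call_significant_windows()],
#'   position-sorted.
#' @param totals `ip`/`input` library totals, used for the enrichment
#'   column (reads-per-library ratio with a pseudocount).
#' @param max_gap maximum run interruption, in windows (default 0:
#'   strictly adjacent).
#' @param pseudocount added to summed counts in the enrichment ratio.
#' @return peak tibble: `seqname`, `start`, `end`, `strand`, `n_windows`,
#'   `ip_count`, `input_count`, `p_value`, `enrichment`.
#' @export
merge_adjacent <- function(windows, totals, max_gap = 0L, pseudocount = 0.5) {
  check_columns(windows, c("seqname", "start", "end", "strand",
                           "significant"), "windows")
  totals <- as.list(totals)
  sig <- windows %>%
    filter(.data$significant) %>%
    arrange(.data$seqname, .data$strand, .data$start)
  if (nrow(sig) == 0L) {
    return(tibble(seqname = character(), start = integer(), end = integer(),
                  strand = character(), n_windows = integer(),
                  ip_count = integer(), input_count = integer(),
                  p_value = double(), enrichment = double()))
  }
  w <- sig$end[1] - sig$start[1]
  gap_bp <- (max_gap + 1L) * w
  new_run <- c(TRUE,
               sig$seqname[-1] != sig$seqname[-nrow(sig)] |
               sig$strand[-1] != sig$strand[-nrow(sig)] |
               (sig$start[-1] - sig$end[-nrow(sig)]) > (gap_bp - w))
  sig$run <- cumsum(new_run)
  sig %>%
    group_by(.data$run) %>%
    summarise(seqname = .data$seqname[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end),
              n_windows = n(),
              ip_count = sum(.data$ip_count),
              input_count = sum(.data$input_count),
              p_value = min(.data$p_value), .groups = "drop") %>%
    mutate(enrichment = ((.data$ip_count + pseudocount) / totals$ip) /
             ((.data$input_count + pseudocount) / totals$input)) %>%
    select("seqname", "start", "end", "strand", "n_windows", "ip_count",
           "input_count", "p_value", "enrichment") %>%
    arrange(.data$seqname, .data$strand, .data$start)
}

#' Call m6A peaks from IP and Input reads
#'
#' End-to-end peak calling: count reads in fixed windows
#' ([count_windows()]), test each covered window with the one-sided
#' Fisher exact test against library totals
#' ([call_significant_windows()]), and merge adjacent significant windows
#' ([merge_adjacent()]).
#'
#' @inheritParams count_windows
#' @inheritParams call_significant_windows
#' @inheritParams merge_adjacent
#' @param reads tibble containing both libraries, distinguished by the
#'   `library` column (`"IP"`/`"Input"`).
#' @param min_windows minimum significant windows a peak must span
#'   (default 1).
#' @param totals optional `ip`/`input` totals; by default the number of
#'   reads per library in `reads`.
#' @return An object of class `merip_peaks`: list with `peaks`,
#'   `windows`, `totals` and `params`. Use [tidy()] for the peak table,
#'   [glance()] for a one-row summary, [autoplot()] for a window/peak
#'   overview.
#' @export
#' @examples
#' sim <- simulate_merip(simulation_config(n_genes = 10,
#'                                         depth_per_library = 4000,
#'                                         seed = 3),
#'                       emit_fastq = FALSE, conditions = "coarse")
#' pk <- call_peaks(dplyr::filter(sim$reads, condition == "coarse"))
#' glance(pk)
call_peaks <- function(reads, seqlengths = NULL, window = 20L, alpha = 0.05,
                       min_cov = 10L, max_gap = 0L, min_windows = 1L,
                       stranded = TRUE, p_adjust = c("none", "BH"),
                       totals = NULL, pseudocount = 0.5) {
  check_columns(reads, c("seqname", "start", "end", "library"), "reads")
  p_adjust <- match.arg(p_adjust)
  if (is.null(totals)) {
    totals <- list(ip = sum(reads$library == "IP"),
                   input = sum(reads$library == "Input"))
  }
  if (totals$ip == 0L || totals$input == 0L) {
    abort("call_peaks() needs reads in both the IP and the Input library")
  }
  wins <- count_windows(reads, seqlengths = seqlengths, window = window,
                        stranded = stranded)
  wins <- call_significant_windows(wins, totals, alpha = alpha,
                                   min_cov = min_cov, p_adjust = p_adjust)
  peaks <- merge_adjacent(wins, totals, max_gap = max_gap,
                          pseudocount = pseudocount)
  peaks <- peaks[peaks$n_windows >= min_windows, , drop = FALSE]
  new_merip_result(
    list(peaks = peaks, windows = wins, totals = totals,
         params = list(window = window, alpha = alpha, min_cov = min_cov,
                       max_gap = max_gap, min_windows = min_windows,
                       stranded = stranded, p_adjust = p_adjust,
                       pseudocount = pseudocount)),
    "merip_peaks")
}
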