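# print / tidy / glance / autoplot methods for the result objects.

#' @export
print.merip_sim_config <- function(x, ...) {
  cat("<merip_sim_config>\n")
  cat(sprintf("  %d genes, depth %d/library, peak enrichment %gx (%d%% of genes)\n",
              x$n_genes, x$depth_per_library, x$peak_enrichment,
              round(100 * x$peak_fraction)))
  cat(sprintf("  motif %s, UMI %d bp, PCR dup rate %g, error rate %g, seed %d\n",
              x$motif, x$umi_length, x$pcr_duplication_rate,
              x$seq_error_rate, x$seed))
  invisible(x)
}

#' @export
print.merip_peaks <- function(x, ...) {
  cat(sprintf("<merip_peaks> %d peak(s) from %d tested window(s) (alpha = %g)\n",
              nrow(x$peaks), sum(x$windows$tested), x$params$alpha))
  print(x$peaks, n = 5)
  invisible(x)
}

#' @export
print.merip_diff <- function(x, ...) {
  cat(sprintf("<merip_diff> %d record(s): %s\n", nrow(x$records),
              paste(sprintf("%s=%d", names(table(x$records$class)),
                            table(x$records$class)), collapse = ", ")))
  invisible(x)
}

#' Tidy a peak-calling result
#'
#' @param x a `merip_peaks` object.
#' @param ... unused.
#' @return the peak tibble.
#' @export
tidy.merip_peaks <- function(x, ...) x$peaks

#' One-row summary of a peak-calling result
#'
#' @param x a `merip_peaks` object.
#' @param ... unused.
#' @return tibble with peak, window and significance tallies.
#' @export
glance.merip_peaks <- function(x, ...) {
  tibble(n_peaks = nrow(x$peaks),
         n_windows = nrow(x$windows),
         n_tested = sum(x$windows$tested),
         n_significant = sum(x$windows$significant),
         frac_significant = ifelse(sum(x$windows$tested) > 0,
                                   sum(x$windows$significant) /
                                     sum(x$windows$tested), NA_real_),
         ip_total = x$totals$ip, input_total = x$totals$input,
         alpha = x$params$alpha, window = x$params$window)
}

#' Window significance overview plot
#'
#' -log10 window p-values along the genome with called peaks underlined.
#'
#' @param object a `merip_peaks` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.merip_peaks <- function(object, ...) {
  w <- object$windows %>% filter(.data$tested)
  ggplot(w, aes(x = (.data$start + .data$end) / 2,
                y = -log10(pmax(.data$p_value, 1e-300)))) +
    geom_point(aes(colour = .data$significant), size = 0.4) +
    geom_segment(data = object$peaks,
                 aes(x = .data$start, xend = .data$end, y = 0, yend = 0),
                 colour = "red", linewidth = 2, inherit.aes = FALSE) +
    facet_wrap(~seqname, scales = "free_x") +
    labs(x = "position (bp)", y = expression(-log[10]~p),
         colour = "significant") +
    theme_bw()
}

#' Tidy a differential methylation result
#'
#' @param x a `merip_diff` object.
#' @param ... unused.
#' @return the differential record tibble.
#' @export
tidy.merip_diff <- function(x, ...) x$records

#' One-row class summary of a differential methylation result
#'
#' @param x a `merip_diff` object.
#' @param ... unused.
#' @return tibble of class counts.
#' @export
glance.merip_diff <- function(x, ...) {
  cls <- x$records$class
  tibble(n_records = length(cls),
         n_up = sum(cls == "up"), n_down = sum(cls == "down"),
         n_coarse_specific = sum(cls == "coarse_specific"),
         n_fine_specific = sum(cls == "fine_specific"),
         n_ns = sum(cls == "ns"), alpha = x$params$alpha)
}

#' Methylation ratio versus significance plot
#'
#' @param object a `merip_diff` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.merip_diff <- function(object, ...) {
  rec <- object$records %>% filter(.data$status == "matched")
  ggplot(rec, aes(x = .data$log2_methylation_ratio,
                  y = -log10(pmax(.data$p_value, 1e-300)),
                  colour = .data$class)) +
    geom_point(size = 0.8) +
    labs(x = expression(log[2]~"methylation ratio (coarse/fine)"),
         y = expression(-log[10]~p), colour = "class") +
    theme_bw()
}

#' Top enriched k-mers plot
#'
#' @param object a `merip_motifs` result.
#' @param top number of top-ranked k-mers to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.merip_motifs <- function(object, top = 10, ...) {
  d <- as_tibble(object) %>% arrange(.data$rank) %>% head(top)
  ggplot(d, aes(x = stats::reorder(.data$kmer, -.data$rank),
                y = -log10(pmax(.data$q_value, 1e-300)))) +
    geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = expression(-log[10]~q)) +
    theme_bw()
}

#' Region distribution bar plot
#'
#' @param object a `merip_regions` tibble from [region_distribution()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.merip_regions <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(.data$region, levels = .data$region),
             y = .data$fraction)) +
    geom_col(fill = "darkorange") +
    labs(x = NULL, y = "fraction of intervals") +
    theme_bw()
}

#' Metagene profile plot
#'
#' @param object a `merip_metagene` object.
#' @param ... unused.
#' @return a ggplot of the gene-averaged profile.
#' @export
autoplot.merip_metagene <- function(object, ...) {
  bw <- 2 * object$flank / object$bins
  d <- tibble(offset = -object$flank + (seq_len(object$bins) - 0.5) * bw,
              mean_count = colMeans(object$matrix))
  ggplot(d, aes(x = .data$offset, y = .data$mean_count)) +
    geom_line(colour = "steelblue") +
    labs(x = sprintf("distance from %s (bp)", object$anchor),
         y = "mean reads per bin") +
    theme_bw()
}
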