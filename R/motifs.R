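# k-mer motif enrichment in peak sequences versus a background set,
# with RRACH (the degenerate m6A consensus, R = A/G, H = A/C/T in DNA
# alphabet) verification. Counting is presence/absence per sequence; the
# default background preserves each target's dinucleotide composition.

#' Extract strand-oriented peak sequences from a genome
#'
#' Returns the genomic sequence of each peak, reverse-complemented for
#' minus-strand peaks so sequences read in transcript orientation.
#' Out-of-bounds peaks are rejected with a message.
#'
#' @param peaks peak tibble or `merip_peaks` with `seqname`, `start`,
#'   `end`, `strand`.
#' @param genome named [Biostrings::DNAStringSet-class].
#' @return named character vector of sequences.
#' @export
extract_peak_sequences <- function(peaks, genome) {
  pk <- peaks_table(peaks)
  check_columns(pk, c("seqname", "start", "end"), "peaks")
  if (!"strand" %in% names(pk)) pk$strand <- "+"
  lens <- setNames(Biostrings::width(genome), names(genome))
  ok <- pk$seqname %in% names(genome) & pk$start >= 0L &
    pk$end <= lens[pk$seqname] & pk$end > pk$start
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    inform(sprintf("extract_peak_sequences: rejected %d out-of-bounds peak(s)",
                   sum(!ok)))
    pk <- pk[ok, , drop = FALSE]
  }
  if (nrow(pk) == 0L) return(setNames(character(), character()))
  seqs <- vapply(seq_len(nrow(pk)), function(i) {
    as.character(Biostrings::subseq(genome[[pk$seqname[i]]],
                                    start = pk$start[i] + 1L,
                                    end = pk$end[i]))
  }, character(1))
  neg <- pk$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  names(seqs) <- sprintf("peak%05d", seq_len(nrow(pk)))
  seqs
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: each sequence is rewritten as a random
#' Eulerian walk over its dinucleotide multigraph, preserving the exact
#' dinucleotide (and hence mononucleotide) composition as well as the
#' first and last base.
#'
#' @param sequences character vector of sequences.
#' @param seed integer seed for reproducibility.
#' @return character vector of shuffled sequences.
#' @export
shuffle_dinucleotide <- function(sequences, seed = 1L) {
  withr::with_seed(seed, vapply(sequences, shuffle_one, character(1),
                                USE.NAMES = FALSE))
}

shuffle_one <- function(s) {
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  if (n < 3L) return(s)
  verts <- unique(x)
  from <- x[-n]
  to <- x[-1]
  out_edges <- split(to, factor(from, levels = verts))
  last_char <- x[n]

  repeat {
    # pick a random terminal edge for every vertex except the final one
    last_edge <- lapply(out_edges, function(e) {
      if (length(e)) e[sample.int(length(e), 1L)] else NA_character_
    })
    # the terminal edges must lead every used vertex to the final vertex
    ok <- TRUE
    for (v in verts) {
      if (v == last_char || !length(out_edges[[v]])) next
      seen <- character()
      cur <- v
      while (cur != last_char && !(cur %in% seen)) {
        seen <- c(seen, cur)
        nxt <- last_edge[[cur]]
        if (is.na(nxt)) break
        cur <- nxt
      }
      if (cur != last_char) { ok <- FALSE; break }
    }
    if (ok) break
  }

  ordered <- lapply(verts, function(v) {
    e <- out_edges[[v]]
    if (!length(e)) return(e)
    if (v == last_char) {
      e[sample.int(length(e))]
    } else {
      le <- last_edge[[v]]
      rest <- e[-match(le, e)]
      c(if (length(rest)) rest[sample.int(length(rest))], le)
    }
  })
  names(ordered) <- verts

  # walk the graph consuming edges in their shuffled order
  used <- setNames(integer(length(verts)), verts)
  res <- character(n)
  res[1] <- x[1]
  cur <- x[1]
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- ordered[[cur]][used[cur]]
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' k-mer enrichment in target versus background sequences
#'
#' Every k-mer occurring in at least one target sequence is scored by a
#' one-sided Fisher exact test on the presence/absence contingency table
#' (targets containing it vs not, background containing it vs not),
#' reusing [fisher_one_sided()]; Benjamini-Hochberg q-values are reported
#' across all tested k-mers. Results are ranked by p-value, ties broken
#' alphabetically.
#'
#' @param target character vector of (peak) sequences.
#' @param background background sequences; by default a
#'   dinucleotide-preserving shuffle of the targets
#'   ([shuffle_dinucleotide()]).
#' @param k k-mer length (default 5, the RRACH width; 4-8 supported).
#' @param shuffle_seed seed for the default background.
#' @return An object of class `merip_motifs`: tibble with `kmer`,
#'   `target_hits`, `target_fraction`, `background_hits`,
#'   `background_fraction`, `p_value`, `q_value`, `rank`.
#' @export
#' @examples
#' tgt <- c("AAGGACTTT", "CCGGACTAA", "TTGGACTCC")
#' head(kmer_enrichment(tgt, k = 5))
kmer_enrichment <- function(target, background = NULL, k = 5L,
                            shuffle_seed = 1L) {
  k <- as.integer(k)
  if (k < 4L || k > 8L) abort("`k` must be between 4 and 8")
  if (!length(target)) abort("`target` must be a non-empty sequence set")
  if (is.null(background)) {
    background <- shuffle_dinucleotide(target, seed = shuffle_seed)
  }
  if (!length(background)) abort("`background` must be non-empty")
  if (min(nchar(c(target, background))) < k) {
    abort("`k` is longer than the shortest sequence")
  }
  hit_counts <- function(seqs) {
    m <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                              width = k)
    colSums(m > 0)
  }
  th <- hit_counts(target)
  bh <- hit_counts(background)
  kmers <- names(th)[th > 0]
  n_t <- length(target)
  n_b <- length(background)
  res <- tibble(
    kmer = kmers,
    target_hits = as.integer(th[kmers]),
    target_fraction = th[kmers] / n_t,
    background_hits = as.integer(bh[kmers]),
    background_fraction = bh[kmers] / n_b,
    p_value = fisher_one_sided(th[kmers], n_t - th[kmers],
                               bh[kmers], n_b - bh[kmers])) %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) %>%
    arrange(.data$p_value, .data$kmer) %>%
    mutate(rank = row_number())
  attr(res, "n_target") <- n_t
  attr(res, "n_background") <- n_b
  attr(res, "k") <- k
  class(res) <- c("merip_motifs", class(res))
  res
}

#' Fraction of sequences containing an RRACH match
#'
#' Scans each sequence (already in transcript orientation) for the
#' degenerate m6A consensus RRACH (R = A/G, H = A/C/T in the DNA
#' alphabet) and returns the fraction of sequences with at least one
#' match.
#'
#' @param sequences character vector of sequences.
#' @return fraction in \[0, 1\] (0 for an empty set).
#' @export
#' @examples
#' rrach_match_fraction(c("GGACT", "TTTTT")) # 0.5
rrach_match_fraction <- function(sequences) {
  if (!length(sequences)) return(0)
  hits <- Biostrings::vcountPattern(
    "RRACH", Biostrings::DNAStringSet(sequences), fixed = FALSE)
  mean(hits > 0)
}
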