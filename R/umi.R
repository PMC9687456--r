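# UMI-based consensus deduplication.
#
# PCR duplicate families are recovered in three passes: exact grouping on
# the UMI, greedy sub-clustering within each UMI family at a strict
# sequence-identity threshold (> 95% by default, global alignment), and a
# per-sub-cluster consensus by column-wise majority over a star alignment
# to the sub-cluster seed.

#' Group reads into UMI clusters
#'
#' Partitions reads by their exact UMI string. When the table has no
#' `umi` column, the UMI is taken as the first `umi_length` bases of the
#' sequence and stripped from sequence and quality. Reads whose UMI is
#' shorter than expected or contains non-ACGT characters are rejected;
#' the rejection count is reported via the `n_rejected` attribute and a
#' message.
#'
#' @param reads tibble with `read_id`, `sequence` and optionally
#'   `quality` and `umi`.
#' @param umi_length UMI length in bases, required when `umi` is absent.
#' @return A nested tibble with one row per cluster: `umi`, `n_reads`,
#'   `reads` (list column of member read tibbles).
#' @export
#' @examples
#' r <- tibble::tibble(read_id = c("a", "b", "c"),
#'                     sequence = c("AAAAGGGG", "AAAACCCC", "CCCCGGGG"))
#' cluster_by_umi(r, umi_length = 4)
cluster_by_umi <- function(reads, umi_length = NULL) {
  check_columns(reads, c("read_id", "sequence"), "reads")
  if (!"quality" %in% names(reads)) {
    reads$quality <- strrep("I", nchar(reads$sequence))
  }
  if (!is.null(umi_length)) {
    # UMI is carried as the first umi_length bases of the read: extract
    # (or overwrite) the umi column and strip it from sequence/quality
    reads$umi <- substr(reads$sequence, 1L, umi_length)
    reads$sequence <- substr(reads$sequence, umi_length + 1L,
                             nchar(reads$sequence))
    reads$quality <- substr(reads$quality, umi_length + 1L,
                            nchar(reads$quality))
  } else if (!"umi" %in% names(reads)) {
    abort("reads have no `umi` column: supply `umi_length` to extract it")
  }
  expected_len <- umi_length %||%
    (if (nrow(reads)) max(nchar(reads$umi)) else 0L)
  ok <- nchar(reads$umi) == expected_len & grepl("^[ACGT]*$", reads$umi) &
    nchar(reads$sequence) > 0L
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    inform(sprintf("cluster_by_umi: rejected %d read(s) with missing or malformed UMI",
                   n_rejected))
  }
  reads <- reads[ok, , drop = FALSE]
  out <- reads %>%
    select("umi", "read_id", "sequence", "quality") %>%
    tidyr::nest(reads = c("read_id", "sequence", "quality")) %>%
    mutate(n_reads = vapply(.data$reads, nrow, integer(1))) %>%
    select("umi", "n_reads", "reads") %>%
    arrange(.data$umi)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Pairwise global-alignment identity of two sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1,
#' gap -2; identity is the fraction of alignment columns that match, so
#' the value is symmetric in its arguments and lies in \[0, 1\].
#'
#' @param a a single sequence.
#' @param b one or more sequences; the result is vectorised over `b`.
#' @return numeric vector of identities in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT") # 1
#' pairwise_identity("ACGT", "TGCA")
pairwise_identity <- function(a, b) {
  if (length(a) != 1L || is.na(a) || !nzchar(a) || any(is.na(b)) ||
      !all(nzchar(b))) {
    abort("pairwise_identity() requires non-empty sequences")
  }
  idx_same <- b == a
  out <- numeric(length(b))
  out[idx_same] <- 1
  if (any(!idx_same)) {
    aln <- align_to_seed(b[!idx_same], a)
    m <- Biostrings::nmatch(aln)
    x <- Biostrings::nmismatch(aln)
    # under +1/-1/-2 scoring, score = m - x - 2 * gap columns, so the
    # alignment length m + x + gaps follows from the score directly
    gaps <- (m - x - Biostrings::score(aln)) / 2
    out[!idx_same] <- m / (m + x + gaps)
  }
  out
}

# one global alignment call for many patterns against a seed, with the
# +1/-1/-2 scoring scheme (substitution matrix cached across calls)
align_to_seed <- local({
  submat <- NULL
  function(patterns, seed) {
    if (is.null(submat)) {
      submat <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1)
    }
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(patterns), Biostrings::DNAString(seed),
      type = "global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2)
  }
})

#' Split a UMI cluster into sub-clusters at a sequence-identity threshold
#'
#' Greedy partition: the most abundant sequence (ties broken
#' lexicographically) seeds a sub-cluster; every remaining read with
#' global-alignment identity strictly greater than `identity_threshold`
#' to the seed joins it; the process repeats on the remainder. Every read
#' ends up in exactly one sub-cluster.
#'
#' @param cluster_reads tibble of one UMI cluster's members (`read_id`,
#'   `sequence`, optionally `quality`).
#' @param identity_threshold identity above which a read joins the seed's
#'   sub-cluster (strict inequality; the default 0.95 mirrors the
#'   "identity over 95%" rule).
#' @return the input tibble with `subcluster` (integer id) and
#'   `seed_sequence` columns added.
#' @export
subcluster <- function(cluster_reads, identity_threshold = 0.95) {
  check_columns(cluster_reads, c("read_id", "sequence"), "cluster_reads")
  if (nrow(cluster_reads) == 0L) abort("subcluster() needs a non-empty cluster")
  if (!"quality" %in% names(cluster_reads)) {
    cluster_reads$quality <- strrep("I", nchar(cluster_reads$sequence))
  }
  remaining <- cluster_reads
  remaining$.row <- seq_len(nrow(remaining))
  assign_sc <- integer(nrow(cluster_reads))
  assign_seed <- character(nrow(cluster_reads))
  sc <- 0L
  while (nrow(remaining) > 0L) {
    sc <- sc + 1L
    tab <- table(remaining$sequence)
    seed_seq <- names(tab)[tab == max(tab)]
    seed_seq <- sort(seed_seq)[1]
    uniq <- unique(remaining$sequence)
    ident <- pairwise_identity(seed_seq, uniq)
    keep_seq <- uniq[ident > identity_threshold | uniq == seed_seq]
    member <- remaining$sequence %in% keep_seq
    assign_sc[remaining$.row[member]] <- sc
    assign_seed[remaining$.row[member]] <- seed_seq
    remaining <- remaining[!member, , drop = FALSE]
  }
  cluster_reads$subcluster <- assign_sc
  cluster_reads$seed_sequence <- assign_seed
  cluster_reads
}

#' Consensus sequence of a sub-cluster
#'
#' Star alignment: each member is globally aligned to the sub-cluster
#' seed and projected onto seed coordinates (member insertions relative
#' to the seed are dropped); the consensus takes the majority symbol per
#' column, with ties broken by the highest summed base quality and then
#' alphabetically, preferring a base over a deletion. The consensus
#' quality is the maximum member quality per column.
#'
#' @param sub_reads tibble of one sub-cluster's members (`read_id`,
#'   `sequence`, `quality`, `seed_sequence`).
#' @return one-row tibble with `sequence`, `quality`, `n_members`.
#' @export
consensus <- function(sub_reads) {
  check_columns(sub_reads, c("sequence"), "sub_reads")
  if (nrow(sub_reads) == 0L) abort("consensus() needs a non-empty sub-cluster")
  if (!"quality" %in% names(sub_reads)) {
    sub_reads$quality <- strrep("I", nchar(sub_reads$sequence))
  }
  seqs <- sub_reads$sequence
  if (length(unique(seqs)) == 1L) {
    qual <- consensus_quality(sub_reads$quality)
    return(tibble(sequence = seqs[1], quality = qual,
                  n_members = nrow(sub_reads)))
  }
  seed <- if ("seed_sequence" %in% names(sub_reads)) {
    sub_reads$seed_sequence[1]
  } else {
    tab <- table(seqs)
    sort(names(tab)[tab == max(tab)])[1]
  }
  L <- nchar(seed)

  # project every member onto seed coordinates; members with the same
  # sequence share one alignment (computed in a single batched call)
  uniq <- unique(seqs[seqs != seed])
  proj_map <- list()
  if (length(uniq)) {
    aln <- align_to_seed(uniq, seed)
    # aligned() projects each pattern onto seed coordinates (member
    # insertions dropped) cheaply; quality indices follow directly
    # unless the alignment has insertions, where the dropped bases
    # shift them and the explicit gapped strings are needed
    projs <- as.character(Biostrings::aligned(aln))
    n_ins <- Biostrings::insertion(Biostrings::nindel(aln))[, "Length"]
    for (u in seq_along(uniq)) {
      chars <- strsplit(projs[u], "")[[1]]
      if (n_ins[u] == 0L) {
        qidx <- cumsum(chars != "-")
      } else {
        pat <- strsplit(as.character(Biostrings::alignedPattern(aln[u])),
                        "")[[1]]
        sub <- strsplit(as.character(Biostrings::alignedSubject(aln[u])),
                        "")[[1]]
        qi <- cumsum(pat != "-")
        keep <- sub != "-"
        chars <- pat[keep]
        qidx <- qi[keep]
      }
      proj_map[[uniq[u]]] <- list(chars = chars, qidx = qidx)
    }
  }
  proj_seq <- character(nrow(sub_reads))
  proj_qual <- character(nrow(sub_reads))
  for (i in seq_len(nrow(sub_reads))) {
    if (seqs[i] == seed) {
      proj_seq[i] <- seqs[i]
      proj_qual[i] <- sub_reads$quality[i]
      next
    }
    pr <- proj_map[[seqs[i]]]
    qual <- strsplit(sub_reads$quality[i], "")[[1]]
    pq <- ifelse(pr$chars == "-", " ", qual[pmax(pr$qidx, 1L)])
    proj_seq[i] <- paste(pr$chars, collapse = "")
    proj_qual[i] <- paste(pq, collapse = "")
  }

  mat <- matrix(unlist(strsplit(proj_seq, "")), nrow = length(proj_seq),
                byrow = TRUE)
  qmat <- matrix(utf8ToInt(paste(proj_qual, collapse = "")) - 33L,
                 nrow = length(proj_qual), byrow = TRUE)
  symbols <- c("A", "C", "G", "T", "-")
  votes <- vapply(symbols, function(s) colSums(mat == s),
                  numeric(L)) # L x 5
  if (L == 1L) votes <- matrix(votes, nrow = 1, dimnames = list(NULL, symbols))
  best <- max.col(votes, ties.method = "first")
  cons <- symbols[best]
  tie <- rowSums(votes == votes[cbind(seq_len(L), best)]) > 1L
  for (j in which(tie)) {
    cand <- symbols[votes[j, ] == max(votes[j, ])]
    qsum <- vapply(cand, function(s)
      if (s == "-") 0 else sum(qmat[mat[, j] == s, j]), numeric(1))
    # quality tie-break, then base over gap, then alphabetical
    cons[j] <- cand[order(-qsum, cand == "-", cand)][1]
  }
  consq <- character(L)
  nz <- cons != "-"
  for (j in which(nz)) {
    consq[j] <- intToUtf8(max(qmat[mat[, j] == cons[j], j]) + 33L)
  }
  tibble(sequence = paste(cons[nz], collapse = ""),
         quality = paste(consq[nz], collapse = ""),
         n_members = nrow(sub_reads))
}

# column-wise max quality over identical-length quality strings
consensus_quality <- function(quals) {
  if (length(quals) == 1L) return(quals)
  q <- matrix(utf8ToInt(paste(quals, collapse = "")), nrow = length(quals),
              byrow = TRUE)
  intToUtf8(apply(q, 2, max))
}

#' Deduplicate reads by UMI consensus
#'
#' Full composition of the deduplication: [cluster_by_umi()] then
#' [subcluster()] then [consensus()]; the output has exactly one
#' consensus read per sub-cluster.
#'
#' @inheritParams cluster_by_umi
#' @inheritParams subcluster
#' @return tibble of consensus reads: `read_id`, `umi`, `subcluster`,
#'   `sequence`, `quality`, `n_members`. The `report` attribute carries a
#'   one-row tibble with reads in/out, cluster and sub-cluster counts and
#'   the number of rejected reads.
#' @export
#' @examples
#' r <- tibble::tibble(
#'   read_id = c("a", "b", "c"),
#'   sequence = c("AAAAGGGGCCCC", "AAAAGGGGCCCC", "CCCCGGGGTTTT"))
#' deduplicate(r, umi_length = 4)
deduplicate <- function(reads, umi_length = NULL, identity_threshold = 0.95) {
  clusters <- cluster_by_umi(reads, umi_length = umi_length)
  n_in <- sum(clusters$n_reads)
  # bulk fast path: clusters whose members are all identical need no
  # alignment — the consensus is the member sequence itself
  uniform <- vapply(clusters$reads, function(r)
    length(unique(r$sequence)) == 1L, logical(1))
  fast <- if (any(uniform)) {
    tibble(
      umi = clusters$umi[uniform],
      subcluster = 1L,
      sequence = vapply(clusters$reads[uniform],
                        function(r) r$sequence[1], character(1)),
      quality = vapply(clusters$reads[uniform],
                       function(r) consensus_quality(r$quality),
                       character(1)),
      n_members = clusters$n_reads[uniform])
  } else NULL
  slow <- purrr::map_dfr(which(!uniform), function(i) {
    cl <- subcluster(clusters$reads[[i]], identity_threshold)
    purrr::map_dfr(sort(unique(cl$subcluster)), function(s) {
      cons <- consensus(cl[cl$subcluster == s, , drop = FALSE])
      cons$umi <- clusters$umi[i]
      cons$subcluster <- s
      cons
    })
  })
  out <- bind_rows(fast, slow)
  if (nrow(out)) out <- arrange(out, .data$umi, .data$subcluster)
  if (nrow(out)) {
    out$read_id <- sprintf("consensus_%s_%d", out$umi, out$subcluster)
    out <- out[, c("read_id", "umi", "subcluster", "sequence", "quality",
                   "n_members")]
  } else {
    out <- tibble(read_id = character(), umi = character(),
                  subcluster = integer(), sequence = character(),
                  quality = character(), n_members = integer())
  }
  attr(out, "report") <- tibble(
    reads_in = n_in, reads_out = nrow(out),
    n_umi_clusters = nrow(clusters),
    n_subclusters = nrow(out),
    n_rejected = attr(clusters, "n_rejected") %||% 0L)
  out
}
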