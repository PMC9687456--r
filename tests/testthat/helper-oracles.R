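# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the code paths (and, where possible, the
# libraries) used by the package itself.

# --- global alignment identity by explicit dynamic programming ---------
# match +1, mismatch -1, gap -2; identity = matches / alignment columns
# of a score-optimal end-to-end alignment (traceback preferring the
# diagonal, which maximises matches among co-optimal paths).
nw_identity_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * -2
  S[1, ] <- (0:m) * -2
  for (i in 1:n) {
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(
        S[i, j] + ifelse(x[i] == y[j], 1, -1),
        S[i, j + 1] - 2,
        S[i + 1, j] - 2)
    }
  }
  # traceback counting matches and columns
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(x[i] == y[j], 1, -1)) {
      if (x[i] == y[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  matches / cols
}

# --- one-sided hypergeometric tail by direct enumeration ---------------
hyper_tail_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- a:min(k, m)
  xs <- xs[k - xs <= n]
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# --- two-sided Fisher by enumeration of all tables ---------------------
fisher_two_sided_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# --- quadratic interval-overlap counting -------------------------------
window_count_oracle <- function(reads, window) {
  res <- list()
  for (i in seq_len(nrow(reads))) {
    w0 <- reads$start[i] %/% window
    w1 <- (reads$end[i] - 1L) %/% window
    for (w in w0:w1) {
      key <- paste(reads$seqname[i], reads$strand[i], w * window,
                   reads$library[i], sep = "|")
      res[[key]] <- (res[[key]] %||% 0L) + 1L
    }
  }
  res
}

# --- run-length scan over significance flags ---------------------------
run_length_peaks_oracle <- function(starts, flags, window, max_gap = 0) {
  peaks <- list()
  cur <- NULL
  last_sig <- -Inf
  for (i in seq_along(starts)) {
    if (!flags[i]) next
    if (!is.null(cur) &&
        (starts[i] - last_sig) / window - 1 <= max_gap) {
      cur$end <- starts[i] + window
      cur$n <- cur$n + 1
    } else {
      if (!is.null(cur)) peaks[[length(peaks) + 1]] <- cur
      cur <- list(start = starts[i], end = starts[i] + window, n = 1)
    }
    last_sig <- starts[i]
  }
  if (!is.null(cur)) peaks[[length(peaks) + 1]] <- cur
  peaks
}

# --- per-base majority region classification ---------------------------
region_label_oracle <- function(seqname, start, end, strand, features) {
  prio <- c("CDS", "three_prime_utr", "five_prime_utr", "NP_exon",
            "intron", "intergenic")
  best <- "intergenic"; best_ov <- 0
  for (lab in setdiff(prio, "intergenic")) {
    f <- features[features$feature == lab & features$seqname == seqname, ]
    if (strand %in% c("+", "-")) f <- f[f$strand == strand, ]
    ov <- 0
    for (j in seq_len(nrow(f))) {
      ov <- ov + max(0, min(end, f$end[j]) - max(start, f$start[j]))
    }
    if (ov > best_ov) { best <- lab; best_ov <- ov }
  }
  best
}

# --- sliding-window RRACH scan without regex/Biostrings ----------------
rrach_scan_oracle <- function(s) {
  x <- strsplit(s, "")[[1]]
  if (length(x) < 5) return(FALSE)
  for (i in 1:(length(x) - 4)) {
    w <- x[i:(i + 4)]
    if (w[1] %in% c("A", "G") && w[2] %in% c("A", "G") && w[3] == "A" &&
        w[4] == "C" && w[5] %in% c("A", "C", "T")) return(TRUE)
  }
  FALSE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulation shared by several tests
tiny_sim <- function(seed = 1, ...) {
  simulate_merip(simulation_config(n_genes = 10, depth_per_library = 3000,
                                   seed = seed, ...),
                 emit_fastq = FALSE)
}

expect_overlap_any <- function(a_row, b) {
  any(b$seqname == a_row$seqname & b$start < a_row$end &
        b$end > a_row$start)
}
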