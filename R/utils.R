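# Internal helpers shared across modules.
#
# All interval tables in meripkit use 0-based half-open coordinates
# ([start, end), BED convention). GRanges objects are built transiently
# (1-based closed) for overlap machinery and converted back on exit.

# tibble with seqname/start/end(/strand) -> GRanges (1-based closed)
as_granges0 <- function(df, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$seqname,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# 0-based half-open overlap test helpers on plain vectors
overlaps0 <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# derive a child seed from a base seed, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(min), format(max)))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# reverse complement for plain character vectors (DNA alphabet)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

new_merip_result <- function(x, class) {
  structure(x, class = c(class, "list"))
}
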