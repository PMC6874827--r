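#' Assembly summary statistics
#'
#' Computes the standard scaffold-level summary of a genome assembly: scaffold
#' counts and lengths, N50/L50, per-base composition, and gap accounting under
#' the convention that a run of 20 or more consecutive Ns is a scaffolding gap
#' that breaks the scaffold into contigs (shorter N runs are treated as
#' ordinary ambiguity and do not break contigs).
#'
#' N50 is the length of the scaffold at which the cumulative length, taken in
#' descending length order, first reaches half of the total assembly size;
#' L50 is that scaffold's rank. Ties in length are broken by input order.
#'
#' @param sequences Named character vector or `DNAStringSet` of scaffolds.
#'   Alphabet is ACGTN (case-insensitive); any other character is an error.
#' @param gap_min_n Minimum N-run length that counts as a gap (default 20).
#' @return An object of class `assembly_stats`: a list with elements
#'   `n_scaffolds`, `total_bp`, `longest_bp`, `shortest_bp`, `n50_bp`, `l50`,
#'   `base_fractions` (named fractions of A/C/G/T/N), `gc_fraction` (GC among
#'   called bases), `n_gap_runs`, `contig_count`, `mean_gap_bp`.
#' @examples
#' compute_assembly_stats(c(chr1 = "ACGTACGT", chr2 = "ACGT"))
#' @export
compute_assembly_stats <- function(sequences, gap_min_n = 20L) {
  chars <- if (is.character(sequences)) sequences
           else as.character(as_dss(sequences))
  if (length(chars) == 0L) stop("empty sequence set")
  if (is.null(names(chars))) names(chars) <- paste0("seq", seq_along(chars))
  chars <- toupper(chars)
  bad <- regexpr("[^ACGTN]", chars)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                 substr(chars[i], bad[i], bad[i]), names(chars)[i], bad[i]))
  }
  seqs <- Biostrings::DNAStringSet(chars)

  lens <- unname(nchar(chars))
  total <- sum(lens)
  ord <- order(lens, decreasing = TRUE)
  cum <- cumsum(lens[ord])
  l50 <- which(cum >= total / 2)[1L]
  n50 <- lens[ord][l50]

  counts <- colSums(Biostrings::letterFrequency(seqs,
                                                letters = c("A", "C", "G", "T", "N")))
  base_fractions <- counts / total
  acgt <- sum(counts[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) sum(counts[c("C", "G")]) / acgt else NA_real_

  gap_pat <- sprintf("N{%d,}", gap_min_n)
  gaps <- gregexpr(gap_pat, chars)
  gap_lens <- unlist(lapply(gaps, function(m) {
    if (m[1L] == -1L) integer(0) else attr(m, "match.length")
  }))
  n_gap_runs <- length(gap_lens)

  out <- list(
    n_scaffolds = length(seqs),
    total_bp = total,
    longest_bp = max(lens),
    shortest_bp = min(lens),
    n50_bp = n50,
    l50 = l50,
    base_fractions = base_fractions,
    gc_fraction = gc,
    n_gap_runs = n_gap_runs,
    contig_count = length(seqs) + n_gap_runs,
    mean_gap_bp = if (n_gap_runs > 0) mean(gap_lens) else 0
  )
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  Number of scaffolds        %d\n", x$n_scaffolds))
  cat(sprintf("  Total size of scaffolds    %d bp\n", x$total_bp))
  cat(sprintf("  Longest / shortest         %d / %d bp\n", x$longest_bp, x$shortest_bp))
  cat(sprintf("  N50 scaffold length        %d bp (L50 = %d)\n", x$n50_bp, x$l50))
  cat(sprintf("  GC content                 %.1f%%\n", 100 * x$gc_fraction))
  cat(sprintf("  Gap runs (>=20 N)          %d (mean %.0f bp)\n",
              x$n_gap_runs, x$mean_gap_bp))
  cat(sprintf("  Contigs after gap split    %d\n", x$contig_count))
  invisible(x)
}

#' @export
as.data.frame.assembly_stats <- function(x, ...) {
  data.frame(
    metric = c("n_scaffolds", "total_bp", "longest_bp", "shortest_bp",
               "n50_bp", "l50", "pct_A", "pct_C", "pct_G", "pct_T", "pct_N",
               "n_gap_runs", "contig_count", "mean_gap_bp"),
    value = c(x$n_scaffolds, x$total_bp, x$longest_bp, x$shortest_bp,
              x$n50_bp, x$l50, round_half_up(100 * x$base_fractions, 2),
              x$n_gap_runs, x$contig_count, x$mean_gap_bp),
    stringsAsFactors = FALSE
  )
}
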