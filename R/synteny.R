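# Majority-rule orthology calls from synteny-block files and block-size
# correlation.

validate_blocks <- function(blocks) {
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")
  stopifnot(all(need %in% names(blocks)))
  if (nrow(blocks) == 0L) stop("empty synteny block list")
  if (any(blocks$start_a >= blocks$end_a) || any(blocks$start_b >= blocks$end_b))
    stop("zero- or negative-length synteny block (start must be < end)")
  if (!is.null(blocks$n_gene_pairs) && any(blocks$n_gene_pairs < 1L))
    stop("blocks must contain at least one gene pair")
  invisible(blocks)
}

#' Majority-rule orthologous chromosome calls from synteny blocks
#'
#' For each query chromosome, syntenic bp per partner chromosome is the
#' total of its block lengths on the query side, with overlapping blocks on
#' the query side merged first to avoid double counting. A partner holding
#' strictly more than half of the query chromosome's syntenic bp is its
#' ortholog; otherwise the chromosome's synteny is split.
#'
#' @param blocks Data frame of synteny blocks (`chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, optional `n_gene_pairs`, `orientation`).
#' @return A data frame of class `orthology_calls` with one row per query
#'   chromosome: `chrom_a`, `best_partner`, `fraction`, `syntenic_bp`,
#'   `status` (`ortholog` when fraction > 0.5, else `split`); the full
#'   fraction table is in `attr(, "fractions")`.
#' @export
call_orthologs <- function(blocks) {
  validate_blocks(blocks)
  rows <- list()
  fracs <- list()
  for (ca in sort(unique(blocks$chrom_a))) {
    b <- blocks[blocks$chrom_a == ca, , drop = FALSE]
    bp <- vapply(split(b, b$chrom_b), function(bb) {
      r <- IRanges::reduce(IRanges::IRanges(bb$start_a, bb$end_a))
      sum(IRanges::width(r))
    }, numeric(1))
    frac <- bp / sum(bp)
    best <- which.max(bp)
    rows[[ca]] <- data.frame(
      chrom_a = ca,
      best_partner = names(bp)[best],
      fraction = unname(frac[best]),
      syntenic_bp = unname(bp[best]),
      status = if (frac[best] > 0.5) "ortholog" else "split",
      stringsAsFactors = FALSE)
    fracs[[ca]] <- data.frame(chrom_a = ca, chrom_b = names(bp),
                              syntenic_bp = unname(bp),
                              fraction = unname(frac),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fractions") <- do.call(rbind, fracs)
  class(out) <- c("orthology_calls", "data.frame")
  out
}

#' @export
print.orthology_calls <- function(x, ...) {
  cat("Majority-rule (> 50% syntenic bp) orthology calls\n")
  print.data.frame(x)
  invisible(x)
}

#' Squared correlation of syntenic block sizes
#'
#' Pearson correlation between block lengths on the two sides, squared —
#' large, tightly correlated blocks indicate close ancestry.
#'
#' @param blocks Synteny block data frame (>= 2 blocks).
#' @return The squared correlation, with attribute `degenerate = TRUE` (and
#'   value 0) when either side has constant block sizes.
#' @export
block_size_correlation <- function(blocks) {
  validate_blocks(blocks)
  if (nrow(blocks) < 2L) stop("need at least two blocks")
  la <- blocks$end_a - blocks$start_a
  lb <- blocks$end_b - blocks$start_b
  if (stats::sd(la) == 0 || stats::sd(lb) == 0)
    return(structure(0, degenerate = TRUE))
  structure(unname(stats::cor(la, lb)^2), degenerate = FALSE)
}

#' Read synteny blocks
#'
#' Two dialects are supported. `format = "blocks"` is a per-block TSV with
#' columns `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b`,
#' `n_gene_pairs`, `orientation`. `format = "dagchainer"` is the
#' DAGchainer-style layout: a `## alignment` header line per block followed
#' by one tab-separated row per gene pair
#' (`chrom_a  gene_a  start_a  end_a  chrom_b  gene_b  start_b  end_b  score`);
#' block coordinates are the min/max over its gene pairs and the pair count
#' is the row count.
#'
#' @param path File path.
#' @param format `"blocks"` or `"dagchainer"`.
#' @return Synteny block data frame.
#' @export
read_synteny_blocks <- function(path, format = c("blocks", "dagchainer")) {
  format <- match.arg(format)
  if (format == "blocks") {
    out <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    return(out)
  }
  lines <- readLines(path)
  blocks <- list()
  cur <- list()
  orientation <- "+"
  flush <- function() {
    if (length(cur) == 0L) return()
    m <- do.call(rbind, cur)
    blocks[[length(blocks) + 1L]] <<- data.frame(
      chrom_a = m$chrom_a[1L],
      start_a = min(m$start_a), end_a = max(m$end_a),
      chrom_b = m$chrom_b[1L],
      start_b = min(m$start_b), end_b = max(m$end_b),
      n_gene_pairs = nrow(m), orientation = orientation,
      stringsAsFactors = FALSE)
    cur <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, "## alignment")) {
      flush()
      orientation <- if (grepl("\\(reverse\\)", ln)) "-" else "+"
    } else if (!startsWith(ln, "#") && nzchar(trimws(ln))) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      cur[[length(cur) + 1L]] <- data.frame(
        chrom_a = f[1L], start_a = as.numeric(f[3L]), end_a = as.numeric(f[4L]),
        chrom_b = f[5L], start_b = as.numeric(f[7L]), end_b = as.numeric(f[8L]),
        stringsAsFactors = FALSE)
    }
  }
  flush()
  if (length(blocks) == 0L)
    return(data.frame(chrom_a = character(0), start_a = numeric(0),
                      end_a = numeric(0), chrom_b = character(0),
                      start_b = numeric(0), end_b = numeric(0),
                      n_gene_pairs = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Write synteny blocks in the per-block TSV dialect
#'
#' @param blocks Synteny block data frame.
#' @param path Output path.
#' @export
write_synteny_blocks <- function(blocks, path) {
  write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive synteny blocks from a synthetic bundle
#'
#' Groups the collinear gene pairs shared by two genomes of a
#' [simulate_truth_set()] bundle into blocks of `genes_per_block` consecutive
#' genes, giving a ground-truth one-to-one chromosome mapping for testing the
#' majority-rule caller.
#'
#' @param bundle A `synthetic_bundle`.
#' @param genome_a,genome_b Genome labels (`"A"`, `"D"`, `"C"`).
#' @param genes_per_block Consecutive gene pairs per block.
#' @return Synteny block data frame.
#' @export
bundle_synteny_blocks <- function(bundle, genome_a = "A", genome_b = "C",
                                  genes_per_block = 5L) {
  ann_a <- bundle$annotations[[genome_a]]
  ann_b <- bundle$annotations[[genome_b]]
  stopifnot(nrow(ann_a) == nrow(ann_b), nrow(ann_a) > 0L)
  rows <- list()
  for (ch in unique(ann_a$chromosome)) {
    ia <- which(ann_a$chromosome == ch)
    grp <- split(ia, (seq_along(ia) - 1L) %/% genes_per_block)
    for (g in grp) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom_a = ch,
        start_a = min(ann_a$start[g]), end_a = max(ann_a$end[g]),
        chrom_b = ann_b$chromosome[g[1L]],
        start_b = min(ann_b$start[g]), end_b = max(ann_b$end[g]),
        n_gene_pairs = length(g), orientation = "+",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
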