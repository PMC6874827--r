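# Perfect-identity marker placement, linkage-group assignment of scaffolds,
# collinearity-based arm merging, and gene-interval queries.

#' Place tag markers on an assembly at perfect identity
#'
#' A tag is placed if and only if it occurs exactly once genome-wide,
#' counting both strands, with zero mismatches (the perfect-unique-identity
#' filter that guards against the highly repetitive background). Tags with
#' no hit or with multiple hits are rejected with a reason.
#'
#' @param markers Data frame with columns `marker_id` and `sequence`
#'   (ACGT tags of any common length).
#' @param sequences Reference assembly: named character vector or
#'   `DNAStringSet`.
#' @return A list of class `marker_placements`: `placements` (marker_id,
#'   chromosome, position as 0-based start, strand, n_hits_genomewide = 1)
#'   and `rejects` (marker_id, reason in {no_hit, multi_hit}, n_hits).
#' @export
place_markers <- function(markers, sequences) {
  seqs <- as_dss(sequences)
  empty_pl <- data.frame(marker_id = character(0), chromosome = character(0),
                         position = integer(0), strand = character(0),
                         n_hits_genomewide = integer(0),
                         stringsAsFactors = FALSE)
  empty_rj <- data.frame(marker_id = character(0), reason = character(0),
                         n_hits = integer(0), stringsAsFactors = FALSE)
  if (nrow(markers) == 0L) {
    out <- list(placements = empty_pl, rejects = empty_rj)
    class(out) <- "marker_placements"
    return(out)
  }
  tags <- toupper(markers$sequence)
  if (any(grepl("[^ACGT]", tags)))
    stop("marker sequences must be over ACGT")
  widths <- nchar(tags)
  n <- length(tags)
  hit_n <- integer(n)
  hit_chrom <- character(n)
  hit_pos <- integer(n)
  hit_strand <- character(n)

  scan <- function(tagset, strand) {
    # constant-width tag sets go through PDict; mixed widths fall back to a
    # per-tag matchPattern loop
    if (length(unique(nchar(tagset))) == 1L) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(tagset))
      for (ci in seq_along(seqs)) {
        m <- Biostrings::matchPDict(pd, seqs[[ci]])
        st <- Biostrings::startIndex(m)
        for (i in seq_len(n)) {
          s <- st[[i]]
          if (is.null(s) || length(s) == 0L) next
          hit_n[i] <<- hit_n[i] + length(s)
          hit_chrom[i] <<- names(seqs)[ci]
          hit_pos[i] <<- s[1L] - 1L
          hit_strand[i] <<- strand
        }
      }
    } else {
      for (i in seq_len(n)) {
        for (ci in seq_along(seqs)) {
          m <- Biostrings::matchPattern(tagset[i], seqs[[ci]])
          if (length(m) == 0L) next
          hit_n[i] <<- hit_n[i] + length(m)
          hit_chrom[i] <<- names(seqs)[ci]
          hit_pos[i] <<- Biostrings::start(m)[1L] - 1L
          hit_strand[i] <<- strand
        }
      }
    }
  }
  scan(tags, "+")
  scan(revcomp(tags), "-")

  placed <- hit_n == 1L
  placements <- data.frame(marker_id = markers$marker_id[placed],
                           chromosome = hit_chrom[placed],
                           position = hit_pos[placed],
                           strand = hit_strand[placed],
                           n_hits_genomewide = hit_n[placed],
                           stringsAsFactors = FALSE)
  rejects <- data.frame(marker_id = markers$marker_id[!placed],
                        reason = ifelse(hit_n[!placed] == 0L,
                                        "no_hit", "multi_hit"),
                        n_hits = hit_n[!placed],
                        stringsAsFactors = FALSE)
  out <- list(placements = placements, rejects = rejects)
  class(out) <- "marker_placements"
  out
}

#' @export
print.marker_placements <- function(x, ...) {
  cat(sprintf("Marker placements: %d placed, %d rejected (%d no_hit, %d multi_hit)\n",
              nrow(x$placements), nrow(x$rejects),
              sum(x$rejects$reason == "no_hit"),
              sum(x$rejects$reason == "multi_hit")))
  invisible(x)
}

#' Assign scaffolds to linkage groups by marker plurality
#'
#' Tallies placed markers per scaffold by their linkage group of origin and
#' assigns each scaffold to the plurality LG; everything not from the
#' plurality LG is a mismatch. Percentages are rounded half-up to one
#' decimal. An exact tie is broken toward the lexicographically smallest LG
#' id and flagged. Scaffolds with no placements are omitted (with a message).
#'
#' @param placements `placements` data frame from [place_markers()] (or the
#'   `marker_placements` object itself).
#' @param marker_map Data frame with `marker_id` and `lg` (and optionally
#'   `cM`).
#' @return An object of class `lg_assignment`: a data frame with one row per
#'   scaffold (`scaffold`, `total_placed`, `plurality_lg`, `plurality_count`,
#'   `mismatch_count`, `mismatch_pct`, `match_pct`, `tie`), with the full
#'   LG-by-scaffold count matrix in `attr(, "counts")` and pooled/mean
#'   mismatch summaries in `attr(, "totals")`.
#' @export
assign_linkage_groups <- function(placements, marker_map) {
  if (inherits(placements, "marker_placements"))
    placements <- placements$placements
  lg <- marker_map$lg[match(placements$marker_id, marker_map$marker_id)]
  if (anyNA(lg))
    stop("placed markers missing from the marker map: ",
         paste(head(placements$marker_id[is.na(lg)], 3), collapse = ", "))
  if (nrow(placements) == 0L) {
    out <- data.frame(scaffold = character(0), total_placed = integer(0),
                      plurality_lg = character(0), plurality_count = integer(0),
                      mismatch_count = integer(0), mismatch_pct = numeric(0),
                      match_pct = numeric(0), tie = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("lg_assignment", "data.frame")
    return(out)
  }
  counts <- table(lg, scaffold = placements$chromosome)
  scaffolds <- colnames(counts)
  rows <- lapply(scaffolds, function(sc) {
    v <- setNames(counts[, sc], rownames(counts))
    total <- sum(v)
    mx <- max(v)
    winners <- sort(names(v)[v == mx])
    plur <- winners[1L]
    mism <- total - mx
    data.frame(scaffold = sc, total_placed = total,
               plurality_lg = plur, plurality_count = mx,
               mismatch_count = mism,
               mismatch_pct = round_half_up(100 * mism / total, 1),
               match_pct = round_half_up(100 * mx / total, 1),
               tie = length(winners) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- unclass(counts)
  attr(out, "totals") <- list(
    pooled_mismatch_pct = round_half_up(
      100 * sum(out$mismatch_count) / sum(out$total_placed), 1),
    mean_of_rows_mismatch_pct = round_half_up(mean(out$mismatch_pct), 1)
  )
  class(out) <- c("lg_assignment", "data.frame")
  out
}

#' @export
print.lg_assignment <- function(x, ...) {
  cat("Linkage-group assignment of scaffolds\n")
  print.data.frame(x)
  t <- attr(x, "totals")
  if (!is.null(t))
    cat(sprintf("Total mismatch: %.1f%% (pooled), %.1f%% (mean of rows)\n",
                t$pooled_mismatch_pct, t$mean_of_rows_mismatch_pct))
  invisible(x)
}

#' Infer a chromosome-arm merge plan from marker collinearity
#'
#' For every linkage group claimed by two or more scaffolds (each supported
#' by at least `min_markers` placements), orders the scaffolds by the
#' midpoint of their cM spans and orients each by the sign of the Spearman
#' correlation between cM and physical position (negative correlation means
#' the scaffold must be reverse-complemented before joining head-to-tail).
#' Scaffolds whose cM spans overlap by more than `overlap_tol_cm` raise a
#' conflict error.
#'
#' @param table An [assign_linkage_groups()] result.
#' @param placements Placements data frame (or `marker_placements`).
#' @param marker_map Marker map with `marker_id`, `lg`, `cM`.
#' @param gap_n Number of Ns inserted between joined arms (default 1000).
#' @param min_markers Minimum placements per scaffold for an orientation
#'   estimate; below this the orientation defaults to `+` and the entry is
#'   flagged `low_evidence`.
#' @param overlap_tol_cm Tolerated cM overlap between consecutive spans.
#' @return An object of class `merge_plan`: list with `gap_n` and `plans`, a
#'   named list (one entry per merged LG) of data frames (`scaffold`,
#'   `orientation`, `cm_min`, `cm_max`, `rho`, `low_evidence`).
#' @export
infer_merge_plan <- function(table, placements, marker_map, gap_n = 1000L,
                             min_markers = 3L, overlap_tol_cm = 1) {
  if (inherits(placements, "marker_placements"))
    placements <- placements$placements
  stopifnot(inherits(table, "lg_assignment"))
  pl <- placements
  pl$lg <- marker_map$lg[match(pl$marker_id, marker_map$marker_id)]
  pl$cM <- marker_map$cM[match(pl$marker_id, marker_map$marker_id)]
  plans <- list()
  for (lg in unique(table$plurality_lg)) {
    scf <- table$scaffold[table$plurality_lg == lg &
                            table$total_placed >= min_markers]
    if (length(scf) < 2L) next
    ev <- lapply(scf, function(sc) {
      p <- pl[pl$chromosome == sc & pl$lg == lg, ]
      rho <- if (nrow(p) >= min_markers)
        suppressWarnings(stats::cor(p$cM, p$position, method = "spearman"))
      else NA_real_
      data.frame(scaffold = sc,
                 orientation = if (!is.na(rho) && rho < 0) "-" else "+",
                 cm_min = min(p$cM), cm_max = max(p$cM),
                 cm_mid = (min(p$cM) + max(p$cM)) / 2,
                 rho = rho,
                 low_evidence = is.na(rho),
                 stringsAsFactors = FALSE)
    })
    plan <- do.call(rbind, ev)
    plan <- plan[order(plan$cm_mid), , drop = FALSE]
    for (i in seq_len(nrow(plan) - 1L)) {
      overlap <- plan$cm_max[i] - plan$cm_min[i + 1L]
      if (overlap > overlap_tol_cm)
        stop(sprintf(paste0("cM spans conflict on %s: %s spans %.1f-%.1f, ",
                            "%s spans %.1f-%.1f"),
                     lg, plan$scaffold[i], plan$cm_min[i], plan$cm_max[i],
                     plan$scaffold[i + 1L], plan$cm_min[i + 1L],
                     plan$cm_max[i + 1L]))
    }
    rownames(plan) <- NULL
    plans[[lg]] <- plan[, c("scaffold", "orientation", "cm_min", "cm_max",
                            "rho", "low_evidence")]
  }
  out <- list(gap_n = as.integer(gap_n), plans = plans)
  class(out) <- "merge_plan"
  out
}

#' @export
print.merge_plan <- function(x, ...) {
  if (length(x$plans) == 0L) {
    cat("Merge plan: nothing to merge\n")
    return(invisible(x))
  }
  cat(sprintf("Merge plan (%d-N joins):\n", x$gap_n))
  for (lg in names(x$plans)) {
    p <- x$plans[[lg]]
    cat(sprintf("  %s: %s\n", lg,
                paste(sprintf("%s(%s)", p$scaffold, p$orientation),
                      collapse = " -> ")))
  }
  invisible(x)
}

#' Apply a merge plan to an assembly
#'
#' Joins each plan's scaffolds head-to-tail in plan order, separated by runs
#' of `gap_n` Ns, reverse-complementing scaffolds with `-` orientation. The
#' merged sequence is named after its linkage group; constituent scaffolds
#' are removed from the output set.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param plan A [infer_merge_plan()] result.
#' @return A `DNAStringSet` with merged pseudo-chromosomes.
#' @export
apply_merge <- function(sequences, plan) {
  stopifnot(inherits(plan, "merge_plan"))
  seqs <- as_dss(sequences)
  if (length(plan$plans) == 0L) return(seqs)
  chars <- as.character(seqs)
  merged <- character(0)
  used <- character(0)
  for (lg in names(plan$plans)) {
    p <- plan$plans[[lg]]
    missing <- setdiff(p$scaffold, names(chars))
    if (length(missing) > 0L)
      stop("unknown scaffold id: ", paste(missing, collapse = ", "))
    parts <- vapply(seq_len(nrow(p)), function(i) {
      s <- chars[[p$scaffold[i]]]
      if (p$orientation[i] == "-") revcomp(s) else s
    }, character(1))
    merged[lg] <- paste(parts, collapse = strrep("N", plan$gap_n))
    used <- c(used, p$scaffold)
  }
  keep <- chars[setdiff(names(chars), used)]
  out <- Biostrings::DNAStringSet(c(keep, merged))
  out
}

#' Genes overlapping a genomic interval
#'
#' Returns the annotated genes overlapping a 1-based closed query interval by
#' at least one bp, sorted by start — the lookup used to pull candidate genes
#' out of a QTL interval.
#'
#' @param annotations Data frame with `chromosome`, `start`, `end` (1-based
#'   closed), `strand`, `gene_id`.
#' @param chromosome Chromosome name.
#' @param start,end Query interval, 1-based closed, `start <= end`.
#' @return The overlapping annotation rows, sorted by start.
#' @export
genes_in_interval <- function(annotations, chromosome, start, end) {
  stopifnot(start <= end)
  if (!chromosome %in% annotations$chromosome)
    stop(sprintf("unknown chromosome '%s'", chromosome))
  gr <- GenomicRanges::GRanges(
    annotations$chromosome,
    IRanges::IRanges(annotations$start, annotations$end)
  )
  q <- GenomicRanges::GRanges(chromosome, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, gr, minoverlap = 1L)
  res <- annotations[S4Vectors::subjectHits(hits), , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
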