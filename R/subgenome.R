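# Deconvolution of hexaploid linkage groups into A/C/D subgenome origins
# from dual-reference marker placements, homoeolog pairing, and
# translocation detection.

#' Linkage-group by chromosome contingency matrix
#'
#' Tallies placed markers by (linkage group, chromosome) for one reference
#' genome — the engine behind subgenome designation tables.
#'
#' @param placements Placements data frame from [place_markers()] (or the
#'   `marker_placements` object) against one reference.
#' @param marker_map Data frame with `marker_id` and `lg`.
#' @param reference_id Label for the reference genome (e.g. `"A"` or `"C"`).
#' @return An object of class `contingency_matrix`: list with `reference`,
#'   `counts` (LG x chromosome matrix), `row_totals`, `col_totals`,
#'   `lg_sizes` (markers per LG in the map, placed or not), and `rejects`
#'   (markers without an LG label).
#' @export
build_contingency <- function(placements, marker_map, reference_id) {
  if (inherits(placements, "marker_placements"))
    placements <- placements$placements
  lg <- marker_map$lg[match(placements$marker_id, marker_map$marker_id)]
  rejects <- placements$marker_id[is.na(lg)]
  ok <- !is.na(lg)
  counts <- if (any(ok))
    unclass(table(lg = lg[ok], chromosome = placements$chromosome[ok]))
  else matrix(0L, 0L, 0L)
  lg_sizes <- table(marker_map$lg)
  out <- list(reference = reference_id,
              counts = counts,
              row_totals = if (length(counts)) rowSums(counts) else integer(0),
              col_totals = if (length(counts)) colSums(counts) else integer(0),
              lg_sizes = setNames(as.integer(lg_sizes), names(lg_sizes)),
              rejects = rejects)
  class(out) <- "contingency_matrix"
  out
}

#' @export
print.contingency_matrix <- function(x, ...) {
  cat(sprintf("Placement contingency vs reference %s\n", x$reference))
  print(x$counts)
  if (length(x$rejects))
    cat(sprintf("  (%d markers without LG label rejected)\n",
                length(x$rejects)))
  invisible(x)
}

cm_count <- function(m, lg) {
  if (is.null(m) || length(m$counts) == 0L || !(lg %in% rownames(m$counts)))
    return(0L)
  sum(m$counts[lg, ])
}

cm_primary <- function(m, lg) {
  if (is.null(m) || length(m$counts) == 0L || !(lg %in% rownames(m$counts)))
    return(NA_character_)
  v <- m$counts[lg, ]
  if (sum(v) == 0L) return(NA_character_)
  names(v)[which.max(v)]
}

#' Assign subgenome origins to hexaploid linkage groups
#'
#' Classifies each linkage group from its placement counts against the two
#' diploid references. An LG whose C-reference count exceeds its A-reference
#' count by at least `c_ratio` is C-derived. The remaining LGs are grouped by
#' the A-reference chromosome attracting most of their placements; two LGs
#' sharing a primary A chromosome are homoeologs, and within the pair the LG
#' with more perfect A-reference placements is labeled A, the other D (the
#' close A/D relationship means A-derived tags place at a higher perfect-match
#' rate). LGs with substantial counts on both references receive slash labels
#' (e.g. A/C), larger segment first — the signature of an intergenomic
#' translocation.
#'
#' @param matrix_A,matrix_C [build_contingency()] results against the A and C
#'   references.
#' @param c_ratio Minimum C:A count ratio for a C call (default 2, mirroring
#'   the roughly two-fold placement asymmetry expected between references).
#' @param slash_ratio Minimum secondary:primary count ratio for a slash
#'   label (default 0.5).
#' @param prior_labels Optional named character vector of LG -> label that
#'   overrides the data-driven A/D ordering within homoeolog pairs.
#' @return An object of class `subgenome_assignment`: data frame with one
#'   row per LG (`lg`, `label`, `a_count`, `c_count`, `primary_chr_A`,
#'   `primary_chr_C`, `homoeolog_partner`).
#' @export
call_subgenomes <- function(matrix_A, matrix_C, c_ratio = 2,
                            slash_ratio = 0.5, prior_labels = NULL) {
  lgs <- sort(union(rownames(matrix_A$counts), rownames(matrix_C$counts)))
  n <- length(lgs)
  a_n <- vapply(lgs, function(l) cm_count(matrix_A, l), integer(1))
  c_n <- vapply(lgs, function(l) cm_count(matrix_C, l), integer(1))
  chrA <- vapply(lgs, function(l) cm_primary(matrix_A, l), character(1))
  chrC <- vapply(lgs, function(l) cm_primary(matrix_C, l), character(1))
  label <- rep("unassigned", n)
  partner <- rep(NA_character_, n)
  names(label) <- names(partner) <- lgs

  is_c <- (a_n + c_n > 0L) & (c_n >= c_ratio * pmax(a_n, 1L)) &
    (c_n > a_n)
  label[is_c] <- "C"

  # perfect-match rate on the A reference among markers not explained by the
  # C reference: robust to translocations that move part of an LG's panel to
  # the other subgenome (equals count ordering on clean LGs)
  sizes <- matrix_A$lg_sizes
  denom <- pmax(if (is.null(sizes)) a_n + c_n else
    unname(sizes[lgs]) - c_n, 1L)
  a_rate <- a_n / denom
  names(a_rate) <- lgs
  pool <- lgs[!is_c & (a_n > 0L)]
  for (chrom in unique(chrA[pool])) {
    grp <- pool[chrA[pool] == chrom]
    grp <- grp[order(-a_rate[grp], -a_n[grp])]
    if (length(grp) >= 2L) {
      label[grp[1L]] <- "A"
      label[grp[2L]] <- "D"
      partner[grp[1L]] <- grp[2L]
      partner[grp[2L]] <- grp[1L]
    } else if (length(grp) == 1L) {
      label[grp[1L]] <- "A"
    }
  }

  if (!is.null(prior_labels)) {
    hit <- intersect(names(prior_labels), lgs)
    label[hit] <- prior_labels[hit]
  }

  # slash labels for LGs with substantial mapping on both references,
  # larger segment first
  for (i in seq_len(n)) {
    l <- lgs[i]
    if (label[l] %in% c("A", "D") && c_n[i] >= slash_ratio * a_n[i] &&
        c_n[i] > 0L) {
      label[l] <- if (a_n[i] >= c_n[i]) paste0(label[l], "/C")
                  else paste0("C/", label[l])
    } else if (label[l] == "C" && a_n[i] >= slash_ratio * c_n[i] &&
               a_n[i] > 0L) {
      label[l] <- if (c_n[i] >= a_n[i]) "C/A" else "A/C"
    }
  }

  out <- data.frame(lg = lgs, label = unname(label),
                    a_count = unname(a_n), c_count = unname(c_n),
                    primary_chr_A = unname(chrA), primary_chr_C = unname(chrC),
                    homoeolog_partner = unname(partner),
                    stringsAsFactors = FALSE)
  class(out) <- c("subgenome_assignment", "data.frame")
  out
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  cat("Subgenome assignment of linkage groups\n")
  print.data.frame(x)
  invisible(x)
}

#' Detect intergenomic and intragenomic translocations
#'
#' Scans each linkage group in cM order over the chromosome-of-placement
#' sequence (combining placements against both references). Isolated runs
#' shorter than `min_segment_markers` are discarded as strays; every
#' remaining switch between chromosomes yields a call whose breakpoint
#' interval is the open cM interval between the last marker before and the
#' first marker after the switch. A switch between references is
#' intergenomic; within one reference, intragenomic.
#'
#' @param placements_A,placements_C Placements against the A and C references
#'   ([place_markers()] results or data frames).
#' @param marker_map Data frame with `marker_id`, `lg`, `cM`.
#' @param min_segment_markers Minimum markers supporting a segment
#'   (default 5).
#' @return A data frame of class `translocation_calls`: one row per call
#'   (`lg`, `chrom_1`, `ref_1`, `cm_min_1`, `cm_max_1`, `n_markers_1`,
#'   `chrom_2`, `ref_2`, `cm_min_2`, `cm_max_2`, `n_markers_2`,
#'   `breakpoint_lo`, `breakpoint_hi`, `kind`).
#' @export
detect_translocations <- function(placements_A, placements_C, marker_map,
                                  min_segment_markers = 5L) {
  if (inherits(placements_A, "marker_placements"))
    placements_A <- placements_A$placements
  if (inherits(placements_C, "marker_placements"))
    placements_C <- placements_C$placements
  pa <- placements_A
  pc <- placements_C
  if (nrow(pa)) pa$ref <- "A"
  if (nrow(pc)) pc$ref <- "C"
  both <- intersect(pa$marker_id, pc$marker_id)
  pa <- pa[!pa$marker_id %in% both, , drop = FALSE]  # ambiguous between refs
  pc <- pc[!pc$marker_id %in% both, , drop = FALSE]
  pl <- rbind(pa, pc)
  calls <- list()
  if (nrow(pl) > 0L) {
    pl$lg <- marker_map$lg[match(pl$marker_id, marker_map$marker_id)]
    pl$cM <- marker_map$cM[match(pl$marker_id, marker_map$marker_id)]
    pl <- pl[!is.na(pl$lg), , drop = FALSE]
    for (lg in unique(pl$lg)) {
      p <- pl[pl$lg == lg, , drop = FALSE]
      p <- p[order(p$cM), , drop = FALSE]
      lab <- paste(p$ref, p$chromosome, sep = ":")
      runs <- rle_runs(lab)
      runs <- runs[runs$length >= min_segment_markers, , drop = FALSE]
      if (nrow(runs) >= 2L) {
        # merge adjacent kept runs with the same label (strays removed)
        keep <- c(TRUE, runs$value[-1L] != runs$value[-nrow(runs)])
        grp <- cumsum(keep)
        runs <- do.call(rbind, lapply(split(runs, grp), function(r)
          data.frame(value = r$value[1L], start = min(r$start),
                     end = max(r$end), length = sum(r$length),
                     stringsAsFactors = FALSE)))
      }
      if (nrow(runs) < 2L) next
      for (i in seq_len(nrow(runs) - 1L)) {
        r1 <- runs[i, ]
        r2 <- runs[i + 1L, ]
        ref1 <- sub(":.*", "", r1$value)
        ref2 <- sub(":.*", "", r2$value)
        calls[[length(calls) + 1L]] <- data.frame(
          lg = lg,
          chrom_1 = sub("^[^:]*:", "", r1$value), ref_1 = ref1,
          cm_min_1 = p$cM[r1$start], cm_max_1 = p$cM[r1$end],
          n_markers_1 = r1$length,
          chrom_2 = sub("^[^:]*:", "", r2$value), ref_2 = ref2,
          cm_min_2 = p$cM[r2$start], cm_max_2 = p$cM[r2$end],
          n_markers_2 = r2$length,
          breakpoint_lo = p$cM[r1$end], breakpoint_hi = p$cM[r2$start],
          kind = if (ref1 != ref2) "intergenomic" else "intragenomic",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(lg = character(0), chrom_1 = character(0), ref_1 = character(0),
               cm_min_1 = numeric(0), cm_max_1 = numeric(0),
               n_markers_1 = integer(0), chrom_2 = character(0),
               ref_2 = character(0), cm_min_2 = numeric(0),
               cm_max_2 = numeric(0), n_markers_2 = integer(0),
               breakpoint_lo = numeric(0), breakpoint_hi = numeric(0),
               kind = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("translocation_calls", "data.frame")
  out
}
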