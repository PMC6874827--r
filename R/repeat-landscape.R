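# Tandem-repeat discovery (the most-common-repeat centromere heuristic),
# monomer density tracks, centromere/telomere calls with chromosome
# morphology, and microsatellite scanning.

seq_to_codes <- function(s) {
  r <- utf8ToInt(toupper(s))
  codes <- match(r, utf8ToInt("ACGT"))  # N and others -> NA
  codes
}

# Rolling k-mer hash over integer codes; positions containing NA get NA.
rolling_hash <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  h <- numeric(m)
  ok <- rep(TRUE, m)
  for (j in 0:(k - 1L)) {
    v <- codes[(1L + j):(m + j)]
    ok <- ok & !is.na(v)
    v[is.na(v)] <- 0L
    h <- h + (v - 1L) * 4^j
  }
  h[!ok] <- NA_real_
  h
}

# Candidate tandem periods from repeated k-mers: distances between
# consecutive occurrences of identical k-mers, tallied.
candidate_periods <- function(h, min_len, max_len, min_votes) {
  idx <- which(!is.na(h))
  if (length(idx) < 2L) return(integer(0))
  ord <- idx[order(h[idx], idx)]
  same <- h[ord[-1L]] == h[ord[-length(ord)]]
  gaps <- diff(ord)[same]
  gaps <- gaps[gaps >= min_len & gaps <= max_len]
  if (length(gaps) == 0L) return(integer(0))
  tab <- table(gaps)
  periods <- as.integer(names(tab)[tab >= min_votes])
  votes <- as.integer(tab[tab >= min_votes])
  periods[order(periods)]
}

# Maximal arrays with period p: positions where s[i] == s[i+p] score +1,
# mismatches score -(1-d)/d (d = max_divergence), and maximal
# positive-scoring segments are extracted with a Kadane-style scan over the
# run-length encoding — random background (25% chance matches) scores
# negative, while arrays within the divergence budget score positive.
arrays_for_period <- function(codes, p, min_copies, max_divergence) {
  n <- length(codes)
  if (n < 2L * p) return(NULL)
  m <- codes[1:(n - p)] == codes[(p + 1L):n]
  m[is.na(m)] <- FALSE
  r <- rle(m)
  vals <- r$values
  lens <- r$lengths
  penalty <- max(1, (1 - max_divergence) / max(max_divergence, 1e-9))
  score <- ifelse(vals, as.numeric(lens), -penalty * lens)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  segs <- list()
  cur <- 0
  seg_start <- NA_integer_
  best <- 0
  best_end <- NA_integer_
  # a real array must accumulate at least one full period of net match;
  # this also keeps the segment list short on random background
  min_score <- p
  flush <- function() {
    if (!is.na(seg_start) && !is.na(best_end) && best >= min_score)
      segs[[length(segs) + 1L]] <<- c(starts[seg_start], ends[best_end])
  }
  for (i in seq_along(score)) {
    if (cur <= 0) {
      if (score[i] > 0) {
        flush()
        seg_start <- i
        cur <- score[i]
        best <- cur
        best_end <- i
      }
    } else {
      cur <- cur + score[i]
      if (cur > best) {
        best <- cur
        best_end <- i
      }
      if (cur <= 0) {
        flush()
        seg_start <- NA_integer_
        best_end <- NA_integer_
        cur <- 0
      }
    }
  }
  flush()
  if (length(segs) == 0L) return(NULL)
  out <- list()
  for (s in segs) {
    span <- s[2L] + p - s[1L] + 1L
    copies <- span %/% p
    ri <- which(starts >= s[1L] & ends <= s[2L])
    matched <- sum(ifelse(vals[ri], lens[ri], 0L))
    mismatch_frac <- 1 - matched / (s[2L] - s[1L] + 1L)
    if (copies >= min_copies && mismatch_frac <= max_divergence)
      out[[length(out) + 1L]] <- data.frame(start = s[1L],
                                            end = s[1L] + span - 1L,
                                            copies = copies)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Discover the dominant tandem-repeat monomers of a genome
#'
#' Detects maximal tandem arrays by period self-match (a position matching
#' the position one period downstream), seeding candidate periods from
#' repeated k-mer spacings. Monomers are reduced to their primitive unit and
#' canonicalized by the lexicographically minimal rotation over both strands,
#' then ranked by total array bp (copies x monomer length). The top-ranked
#' monomer of a whole-genome scan is the putative centromeric repeat — in
#' repeat-dominated plant genomes the centromeric satellite is the most
#' common repeat in the assembly.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param min_len,max_len Monomer length bounds in bp (defaults 50 and 2000).
#' @param min_copies Minimum tandem copies per array (default 5).
#' @param max_divergence Maximum mismatch fraction tolerated inside an array
#'   (default 0.2).
#' @param k Seed k-mer length for period discovery (default 13).
#' @return A data frame of class `tandem_monomers`, ranked by total array
#'   bp: `monomer` (canonical), `length`, `total_copies`, `n_arrays`,
#'   `total_bp`; array coordinates (chromosome, start, end, 1-based closed)
#'   in `attr(, "spans")`.
#' @export
find_tandem_monomers <- function(sequences, min_len = 50L, max_len = 2000L,
                                 min_copies = 5L, max_divergence = 0.2,
                                 k = 13L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  seqs <- as_dss(sequences)
  chars <- toupper(as.character(seqs))
  if (any(grepl("[^ACGTN]", chars))) stop("alphabet must be ACGTN")
  spans <- list()
  min_votes <- max(2L, (min_copies - 1L) * k)
  for (ci in seq_along(chars)) {
    codes <- seq_to_codes(chars[ci])
    h <- rolling_hash(codes, k)
    periods <- candidate_periods(h, min_len, max_len, min_votes)
    claimed_start <- integer(0)
    claimed_end <- integer(0)
    for (p in periods) {
      arr <- arrays_for_period(codes, p, min_copies, max_divergence)
      if (is.null(arr)) next
      for (j in seq_len(nrow(arr))) {
        st <- arr$start[j]
        en <- arr$end[j]
        # skip arrays already explained by a shorter period
        if (length(claimed_start) &&
            any(pmin(claimed_end, en) - pmax(claimed_start, st) + 1L >
                  0.5 * (en - st + 1L))) next
        unit <- substr(chars[ci], st, st + p - 1L)
        prim <- primitive_unit(unit)
        if (nchar(prim) < min_len) next
        copies <- (en - st + 1L) %/% nchar(prim)
        spans[[length(spans) + 1L]] <- data.frame(
          chromosome = names(seqs)[ci], start = st, end = en,
          monomer = canonical_monomer(prim), length = nchar(prim),
          copies = copies, stringsAsFactors = FALSE)
        claimed_start <- c(claimed_start, st)
        claimed_end <- c(claimed_end, en)
      }
    }
  }
  if (length(spans) == 0L) {
    out <- data.frame(monomer = character(0), length = integer(0),
                      total_copies = integer(0), n_arrays = integer(0),
                      total_bp = numeric(0), stringsAsFactors = FALSE)
    attr(out, "spans") <- data.frame(chromosome = character(0),
                                     start = integer(0), end = integer(0),
                                     monomer = character(0),
                                     stringsAsFactors = FALSE)
    class(out) <- c("tandem_monomers", "data.frame")
    return(out)
  }
  sp <- do.call(rbind, spans)
  agg <- do.call(rbind, lapply(split(sp, sp$monomer), function(g)
    data.frame(monomer = g$monomer[1L], length = g$length[1L],
               total_copies = sum(g$copies), n_arrays = nrow(g),
               total_bp = sum(g$copies) * as.numeric(g$length[1L]),
               stringsAsFactors = FALSE)))
  agg <- agg[order(-agg$total_bp), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "spans") <- sp[, c("chromosome", "start", "end", "monomer")]
  class(agg) <- c("tandem_monomers", "data.frame")
  agg
}

#' @export
print.tandem_monomers <- function(x, ...) {
  cat(sprintf("Tandem monomers (%d found, ranked by total array bp)\n",
              nrow(x)))
  print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Windowed density of a repeat monomer along chromosomes
#'
#' Counts non-overlapping occurrences of the monomer (both strands, within a
#' Hamming-distance budget), greedily left to right; each occurrence is
#' assigned to the window containing its start. The result is bedGraph-ready.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param monomer Monomer sequence.
#' @param window_bp Window size (default 1,000,000).
#' @param max_mismatch_fraction Hamming budget as a fraction of monomer
#'   length (default 0.1).
#' @return A data frame of class `density_track`: `chromosome`, `window`
#'   (0-based index), `start`, `end` (0-based half-open window bounds),
#'   `count`.
#' @export
density_track <- function(sequences, monomer, window_bp = 1000000L,
                          max_mismatch_fraction = 0.1) {
  seqs <- as_dss(sequences)
  monomer <- toupper(as.character(monomer))
  if (nchar(monomer) == 0L) stop("monomer must be non-empty")
  if (window_bp < nchar(monomer))
    stop("window_bp must be at least the monomer length")
  mm <- floor(max_mismatch_fraction * nchar(monomer))
  rc <- revcomp(monomer)
  rows <- list()
  for (ci in seq_along(seqs)) {
    L <- Biostrings::width(seqs)[ci]
    n_win <- max(1L, ceiling(L / window_bp))
    counts <- integer(n_win)
    starts <- sort(unique(c(
      Biostrings::start(Biostrings::matchPattern(monomer, seqs[[ci]],
                                                 max.mismatch = mm)),
      Biostrings::start(Biostrings::matchPattern(rc, seqs[[ci]],
                                                 max.mismatch = mm)))))
    last_end <- 0L
    w <- nchar(monomer)
    for (st in starts) {
      if (st <= last_end) next
      win <- (st - 1L) %/% window_bp + 1L
      counts[win] <- counts[win] + 1L
      last_end <- st + w - 1L
    }
    rows[[ci]] <- data.frame(
      chromosome = names(seqs)[ci],
      window = seq_len(n_win) - 1L,
      start = (seq_len(n_win) - 1L) * window_bp,
      end = pmin(seq_len(n_win) * window_bp, L),
      count = counts, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("density_track", "data.frame")
  out
}

#' Call centromeres, chromosome morphology and telomere placement
#'
#' The centromere of each chromosome is the weighted centroid of the
#' contiguous run of non-empty windows around the global maximum of the
#' centromeric-repeat density track. Arms are measured from that midpoint and
#' the chromosome is classified by its long/short arm ratio using the Levan
#' convention: metacentric below `meta`, submetacentric up to `submeta`,
#' sub-telocentric up to `subtelo`, telocentric beyond. Telomeric-repeat
#' clusters are labeled `terminal` when their centroid lies within
#' `terminal_fraction` of either chromosome end, else `interstitial`.
#'
#' @param cen_track,tel_track [density_track()] results for the centromeric
#'   and telomeric monomers.
#' @param chromosome_lengths Named vector of chromosome lengths.
#' @param terminal_fraction Distal cutoff for terminal telomere arrays
#'   (default 0.05).
#' @param thresholds Arm-ratio cutoffs `c(meta = 1.7, submeta = 3, subtelo = 7)`.
#' @return A list of class `centromere_calls`: `centromeres` (chromosome,
#'   midpoint, short_arm, long_arm, arm_ratio, morphology; chromosomes with
#'   an empty track are listed with `NA` and flagged), `telomeres`
#'   (chromosome, position, status).
#' @export
call_centromeres_telomeres <- function(cen_track, tel_track,
                                       chromosome_lengths,
                                       terminal_fraction = 0.05,
                                       thresholds = c(meta = 1.7,
                                                      submeta = 3,
                                                      subtelo = 7)) {
  cen_rows <- list()
  tel_rows <- list()
  for (ch in names(chromosome_lengths)) {
    L <- chromosome_lengths[[ch]]
    tr <- cen_track[cen_track$chromosome == ch, , drop = FALSE]
    if (nrow(tr) == 0L || all(tr$count == 0L)) {
      cen_rows[[ch]] <- data.frame(chromosome = ch, midpoint = NA_real_,
                                   short_arm = NA_real_, long_arm = NA_real_,
                                   arm_ratio = NA_real_,
                                   morphology = "no_call",
                                   stringsAsFactors = FALSE)
    } else {
      imax <- which.max(tr$count)
      lo <- imax
      while (lo > 1L && tr$count[lo - 1L] > 0L) lo <- lo - 1L
      hi <- imax
      while (hi < nrow(tr) && tr$count[hi + 1L] > 0L) hi <- hi + 1L
      run <- tr[lo:hi, , drop = FALSE]
      mids <- (run$start + run$end) / 2
      centroid <- sum(mids * run$count) / sum(run$count)
      short_arm <- min(centroid, L - centroid)
      long_arm <- max(centroid, L - centroid)
      ratio <- if (short_arm > 0) long_arm / short_arm else Inf
      morph <- if (ratio < thresholds[["meta"]]) "metacentric"
      else if (ratio <= thresholds[["submeta"]]) "submetacentric"
      else if (ratio <= thresholds[["subtelo"]]) "sub-telocentric"
      else "telocentric"
      cen_rows[[ch]] <- data.frame(chromosome = ch, midpoint = centroid,
                                   short_arm = short_arm, long_arm = long_arm,
                                   arm_ratio = ratio, morphology = morph,
                                   stringsAsFactors = FALSE)
    }
    tt <- tel_track[tel_track$chromosome == ch & tel_track$count > 0L, ,
                    drop = FALSE]
    if (nrow(tt) > 0L) {
      grp <- cumsum(c(1L, diff(tt$window) != 1L))
      for (g in split(tt, grp)) {
        mids <- (g$start + g$end) / 2
        pos <- sum(mids * g$count) / sum(g$count)
        status <- if (pos <= terminal_fraction * L ||
                        pos >= (1 - terminal_fraction) * L) "terminal"
                  else "interstitial"
        tel_rows[[length(tel_rows) + 1L]] <-
          data.frame(chromosome = ch, position = pos, status = status,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(
    centromeres = do.call(rbind, c(cen_rows, list(make.row.names = FALSE))),
    telomeres = if (length(tel_rows))
      do.call(rbind, c(tel_rows, list(make.row.names = FALSE)))
    else data.frame(chromosome = character(0), position = numeric(0),
                    status = character(0), stringsAsFactors = FALSE)
  )
  class(out) <- "centromere_calls"
  out
}

#' @export
print.centromere_calls <- function(x, ...) {
  cat("Centromere calls and chromosome morphology\n")
  print.data.frame(x$centromeres)
  cat(sprintf("Telomere clusters: %d terminal, %d interstitial\n",
              sum(x$telomeres$status == "terminal"),
              sum(x$telomeres$status == "interstitial")))
  invisible(x)
}

#' Scan for perfect microsatellites (SSRs)
#'
#' Finds maximal perfect tandem runs of primitive 2-4 bp units meeting
#' per-unit-length minimum copy numbers. Motifs are canonicalized by minimal
#' rotation over both strands, so (TA)n and (AT)n report the same motif.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param unit_lengths Unit lengths to scan (default 2:4).
#' @param min_copies Named minimum copies per unit length
#'   (default `c("2" = 6, "3" = 5, "4" = 5)`).
#' @return A data frame of class `ssr_table`: `chromosome`, `start`
#'   (1-based), `motif` (canonical), `unit_length`, `copies`.
#' @export
scan_ssrs <- function(sequences, unit_lengths = c(2L, 3L, 4L),
                      min_copies = c("2" = 6L, "3" = 5L, "4" = 5L)) {
  seqs <- as_dss(sequences)
  chars <- toupper(as.character(seqs))
  if (any(grepl("[^ACGTN]", chars))) stop("alphabet must be ACGTN")
  rows <- list()
  for (ci in seq_along(chars)) {
    codes <- seq_to_codes(chars[ci])
    n <- length(codes)
    for (u in unit_lengths) {
      if (n < 2L * u) next
      need <- min_copies[[as.character(u)]]
      m <- codes[1:(n - u)] == codes[(u + 1L):n]
      m[is.na(m)] <- FALSE
      runs <- rle_runs(m)
      runs <- runs[runs$value == "TRUE" & runs$length >= (need - 1L) * u, ,
                   drop = FALSE]
      for (j in seq_len(nrow(runs))) {
        st <- runs$start[j]
        span <- runs$length[j] + u
        unit <- substr(chars[ci], st, st + u - 1L)
        if (grepl("N", unit)) next
        if (nchar(primitive_unit(unit)) != u) next
        copies <- span %/% u
        if (copies < need) next
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = names(seqs)[ci], start = st,
          motif = canonical_monomer(unit), unit_length = u,
          copies = copies, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(0), start = integer(0),
               motif = character(0), unit_length = integer(0),
               copies = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ssr_table", "data.frame")
  out
}

#' Write a density track as bedGraph
#'
#' @param track A [density_track()] result.
#' @param path Output path.
#' @param name Track name for the header line.
#' @export
write_bedgraph <- function(track, path, name = "repeat_density") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  write.table(track[, c("chromosome", "start", "end", "count")], con,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
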