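# Nei-Gojobori (1986) synonymous divergence with Jukes-Cantor correction,
# plus the molecular-clock arithmetic built on it.

#' Externally sourced core-eukaryote synonymous substitution rate
#'
#' A commonly used clock constant of 8.1e-9 synonymous substitutions per
#' synonymous site per year, shipped as a named constant so clock dating can
#' be run against either a lineage-calibrated rate or this generic rate.
#' @export
EUKARYOTIC_SYNONYMOUS_RATE <- 8.1e-9

.ng86_cache <- new.env(parent = emptyenv())

# Per-codon synonymous site count: for each of the three positions, the
# fraction of the three possible single-nucleotide changes that are
# synonymous. Changes creating a stop codon are counted as nonsynonymous
# (weight zero), keeping the three-change denominator.
codon_syn_sites <- function(codon) {
  tab <- syn_sites_table()
  s <- tab[codon]
  if (is.na(s))
    stop(sprintf("internal stop codon or invalid codon '%s'", codon))
  unname(s)
}

syn_sites_table <- function() {
  if (!is.null(.ng86_cache$syn_sites)) return(.ng86_cache$syn_sites)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  tab <- setNames(rep(NA_real_, length(codons)), codons)
  for (codon in codons) {
    aa <- gc[[codon]]
    if (aa == "*") next
    s <- 0
    for (pos in 1:3) {
      for (b in BASES) {
        if (b == substr(codon, pos, pos)) next
        alt <- codon
        substr(alt, pos, pos) <- b
        alt_aa <- gc[[alt]]
        if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
      }
    }
    tab[codon] <- s
  }
  .ng86_cache$syn_sites <- tab
  tab
}

# Synonymous/nonsynonymous differences between two codons, averaged over all
# minimal substitution pathways (orderings of the differing positions).
# Pathways passing through a stop codon are excluded; if every pathway is
# blocked, all pathways are used (standard fallback for rare codon pairs).
codon_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- codon_diffs_uncached(c1, c2)
  assign(key, out, envir = .ng86_cache)
  out
}

codon_diffs_uncached <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(diff_pos)
  path_counts <- list()
  blocked_counts <- list()
  for (ord in perms) {
    cur <- c1
    sd <- 0
    ndf <- 0
    blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      aa1 <- gc[[cur]]
      aa2 <- gc[[nxt]]
      if (is.na(aa2) || aa2 == "*") blocked <- TRUE
      if (identical(aa1, aa2)) sd <- sd + 1 else ndf <- ndf + 1
      cur <- nxt
    }
    rec <- c(sd = sd, nd = ndf)
    if (blocked) blocked_counts[[length(blocked_counts) + 1L]] <- rec
    else path_counts[[length(path_counts) + 1L]] <- rec
  }
  use <- if (length(path_counts)) path_counts else blocked_counts
  m <- do.call(rbind, use)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

split_codons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

# 64 x 64 lookup matrices of pathway-averaged synonymous/nonsynonymous
# differences, built once from codon_diffs(); rows/cols follow
# names(GENETIC_CODE). Entries involving stop codons are NA.
diff_tables <- function() {
  if (!is.null(.ng86_cache$SD)) return(list(SD = .ng86_cache$SD,
                                            ND = .ng86_cache$ND))
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  n <- length(codons)
  SD <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  ND <- SD
  for (i in seq_len(n)) {
    if (gc[[codons[i]]] == "*") next
    for (j in seq_len(n)) {
      if (gc[[codons[j]]] == "*") next
      if (i == j) {
        SD[i, j] <- 0
        ND[i, j] <- 0
      } else {
        d <- codon_diffs(codons[i], codons[j])
        SD[i, j] <- d[["sd"]]
        ND[i, j] <- d[["nd"]]
      }
    }
  }
  .ng86_cache$SD <- SD
  .ng86_cache$ND <- ND
  list(SD = SD, ND = ND)
}

#' Synonymous divergence of a codon-aligned pair (Nei-Gojobori 1986)
#'
#' Counts synonymous sites (S) as the per-position fraction of synonymous
#' single-nucleotide changes, averaged over the two sequences, and synonymous
#' differences (Sd) by averaging over all minimal substitution pathways for
#' multi-difference codons (pathways through stop codons excluded). The
#' proportion pS = Sd/S is corrected for multiple hits with the Jukes-Cantor
#' formula Ks = -(3/4) ln(1 - (4/3) pS). Codons containing a gap or ambiguity
#' character in either sequence are dropped before counting.
#'
#' @param seq1,seq2 Codon-aligned DNA strings of equal length divisible by 3,
#'   with no internal stop codons.
#' @return An object of class `ks_estimate`: list with `s_sites`, `n_sites`,
#'   `s_diffs`, `n_diffs`, `p_s`, `p_n`, `ks`, `ka`, `saturated` (TRUE when
#'   pS >= 3/4 makes Ks undefined), `n_codons`.
#' @examples
#' ks_ng86("GTTGTT", "GTCGTT")  # S = 2, Sd = 1, Ks = 0.824
#' @export
ks_ng86 <- function(seq1, seq2) {
  seq1 <- toupper(as.character(seq1))
  seq2 <- toupper(as.character(seq2))
  if (nchar(seq1) != nchar(seq2))
    stop("sequences must be codon-aligned to equal lengths")
  if (nchar(seq1) %% 3L != 0L)
    stop("alignment length not divisible by 3")
  cod1 <- split_codons(seq1)
  cod2 <- split_codons(seq2)
  clean <- grepl("^[ACGT]{3}$", cod1) & grepl("^[ACGT]{3}$", cod2)
  cod1 <- cod1[clean]
  cod2 <- cod2[clean]
  if (length(cod1) == 0L) stop("no ungapped codons to compare")

  codons <- names(Biostrings::GENETIC_CODE)
  i1 <- match(cod1, codons)
  i2 <- match(cod2, codons)
  tab <- unname(syn_sites_table())
  v1 <- tab[i1]
  v2 <- tab[i2]
  if (anyNA(v1) || anyNA(v2)) {
    bad <- which(is.na(v1) | is.na(v2))[1L]
    stop(sprintf("internal stop codon at codon %d", bad))
  }
  S <- (sum(v1) + sum(v2)) / 2
  N <- 3 * length(cod1) - S

  dt <- diff_tables()
  sd_tot <- sum(dt$SD[cbind(i1, i2)])
  nd_tot <- sum(dt$ND[cbind(i1, i2)])
  # S can be zero (e.g. pure Met/Trp codons); pS is then undefined
  p_s <- if (S > 0) sd_tot / S else NaN
  p_n <- if (N > 0) nd_tot / N else NaN
  saturated <- isTRUE(p_s >= 0.75)
  jc <- function(p) {
    if (is.nan(p) || p >= 0.75) NA_real_
    else -0.75 * log(1 - 4 * p / 3)
  }
  out <- list(s_sites = S, n_sites = N, s_diffs = sd_tot, n_diffs = nd_tot,
              p_s = p_s, p_n = p_n,
              ks = if (saturated) NA_real_ else jc(p_s),
              ka = jc(p_n),
              saturated = saturated, n_codons = length(cod1))
  class(out) <- "ks_estimate"
  out
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("NG86: S = %.2f, N = %.2f, Sd = %.2f, pS = %.4f, Ks = %s\n",
              x$s_sites, x$n_sites, x$s_diffs, x$p_s,
              if (x$saturated) "saturated" else sprintf("%.4f", x$ks)))
  invisible(x)
}

#' Mode of a Ks distribution by fixed-width histogram
#'
#' Bins values into fixed-width bins centred on integer multiples of
#' `bin_width` and returns the centre of the fullest bin; ties go to the
#' smallest centre. A deterministic, seed-free peak estimate.
#'
#' @param values Numeric Ks values (non-finite values dropped).
#' @param bin_width Bin width (default 0.005).
#' @return The peak estimate (bin centre).
#' @export
ks_peak <- function(values, bin_width = 0.005) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite Ks values")
  idx <- floor(values / bin_width + 0.5)
  tab <- table(idx)
  best <- as.integer(names(tab)[tab == max(tab)])
  min(best) * bin_width
}

#' Calibrate a lineage substitution rate from a dated node
#'
#' Under a strict molecular clock the synonymous divergence between two
#' lineages that split T years ago is Ks = 2 r T, so a known node age
#' calibrates the rate as r = Ks / (2 T).
#'
#' @param ks Synonymous divergence at the calibration node.
#' @param node_age Age of the node in years.
#' @return Rate in substitutions per site per year.
#' @examples
#' calibrate_rate(0.3, 44.3e6)  # ~3.39e-9, a Pooideae-type rate
#' @export
calibrate_rate <- function(ks, node_age) {
  if (node_age <= 0) stop("node_age must be positive")
  ks / (2 * node_age)
}

#' Date a divergence from Ks and a substitution rate
#'
#' Inverts the clock relation: T = Ks / (2 r).
#'
#' @param ks Synonymous divergence.
#' @param rate Substitution rate per site per year.
#' @return Divergence time in years.
#' @examples
#' divergence_time(0.0875, 3.39e-9) / 1e6  # ~12.9 Ma
#' @export
divergence_time <- function(ks, rate) {
  if (rate <= 0) stop("rate must be positive")
  ks / (2 * rate)
}
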