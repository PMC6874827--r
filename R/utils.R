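#' @importFrom methods is
#' @importFrom stats setNames rnorm runif
#' @importFrom utils head tail write.table read.table modifyList
NULL

# Coerce character vector / DNAStringSet to a named DNAStringSet.
as_dss <- function(sequences) {
  if (is(sequences, "DNAStringSet")) return(sequences)
  if (is.character(sequences)) {
    if (is.null(names(sequences)))
      names(sequences) <- paste0("seq", seq_along(sequences))
    return(Biostrings::DNAStringSet(sequences))
  }
  stop("`sequences` must be a character vector or a DNAStringSet")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Round half away from zero (base round() is banker's rounding, which
# turns 0.05-type boundary percentages the wrong way for table display).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Canonical form of a tandem-repeat monomer
#'
#' The canonical form is the lexicographically smallest string among all
#' rotations of the monomer and all rotations of its reverse complement, so
#' that the same satellite reported from either strand or any phase of the
#' array collapses to one identifier.
#'
#' @param monomer A single DNA string (ACGT).
#' @return A single character string, the canonical rotation.
#' @examples
#' canonical_monomer("TAT")  # == canonical_monomer("ATT")
#' @export
canonical_monomer <- function(monomer) {
  monomer <- toupper(as.character(monomer))
  stopifnot(length(monomer) == 1L, nchar(monomer) >= 1L)
  rots <- function(s) {
    n <- nchar(s)
    d <- paste0(s, s)
    vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
  }
  min(c(rots(monomer), rots(revcomp(monomer))))
}

# Smallest period d (d | n) such that the monomer is (unit)^k; returns the
# primitive unit.
primitive_unit <- function(monomer) {
  n <- nchar(monomer)
  for (d in seq_len(n)) {
    if (n %% d != 0L) next
    unit <- substr(monomer, 1L, d)
    if (paste(rep(unit, n %/% d), collapse = "") == monomer) return(unit)
  }
  monomer
}

# Deterministic per-stage seed fan-out: hashing the stage name means adding a
# stage never perturbs the random stream of another.
stage_seed <- function(global_seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (ch in codes) h <- (h * 131 + ch) %% 2147483647
  as.integer((global_seed + h) %% 2147483647)
}

# Run length encoding on an arbitrary vector, returning a data.frame of
# value/start/end indices.
rle_runs <- function(x) {
  r <- rle(as.character(x))
  ends <- cumsum(r$lengths)
  data.frame(value = r$values,
             start = ends - r$lengths + 1L,
             end = ends,
             length = r$lengths,
             stringsAsFactors = FALSE)
}
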