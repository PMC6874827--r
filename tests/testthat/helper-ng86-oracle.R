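# Independent brute-force oracle for NG86: explicit neighbor enumeration for
# site counts and explicit depth-first pathway enumeration for differences.

GC_TABLE <- Biostrings::GENETIC_CODE

oracle_sites <- function(codon) {
  aa <- GC_TABLE[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == b) next
      mut <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      if (GC_TABLE[[mut]] != "*" && GC_TABLE[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

oracle_paths <- function(c1, c2) {
  # returns list of c(sd, nd, blocked) over every ordering of the
  # differing positions
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  walk <- function(cur, remaining, sd, nd, blocked) {
    if (length(remaining) == 0)
      return(list(c(sd = sd, nd = nd, blocked = as.numeric(blocked))))
    out <- list()
    for (pos in remaining) {
      nxt <- paste0(substr(cur, 1, pos - 1), substr(c2, pos, pos),
                    substr(cur, pos + 1, 3))
      syn <- GC_TABLE[[cur]] == GC_TABLE[[nxt]]
      out <- c(out, walk(nxt, setdiff(remaining, pos),
                         sd + syn, nd + !syn,
                         blocked || GC_TABLE[[nxt]] == "*"))
    }
    out
  }
  walk(c1, dpos, 0, 0, FALSE)
}

oracle_ng86 <- function(s1, s2) {
  c1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  c2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  S <- (sum(vapply(c1, oracle_sites, 0)) + sum(vapply(c2, oracle_sites, 0))) / 2
  sd <- 0
  nd <- 0
  for (i in seq_along(c1)) {
    if (c1[i] == c2[i]) next
    paths <- do.call(rbind, oracle_paths(c1[i], c2[i]))
    ok <- paths[, "blocked"] == 0
    if (!any(ok)) ok <- rep(TRUE, nrow(paths))
    sd <- sd + mean(paths[ok, "sd"])
    nd <- nd + mean(paths[ok, "nd"])
  }
  p_s <- if (S > 0) sd / S else NaN
  list(S = S, sd = sd, p_s = p_s,
       ks = if (!is.nan(p_s) && p_s < 0.75) -0.75 * log(1 - 4 * p_s / 3)
            else NA_real_)
}

sense_codons <- names(GC_TABLE)[GC_TABLE != "*"]
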