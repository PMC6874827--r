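# Synthetic-data generators. Every generator derives its random stream from
# a stage-specific seed so that adding or reordering stages never perturbs
# another stage's output, and identical configs give byte-identical
# artifacts.

BASES <- c("A", "C", "G", "T")

random_sequence <- function(n, gc = 0.44) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(sample(utf8ToInt("ACGT") + 0L, n, replace = TRUE, prob = p))
}

# Substitution-only mutation at per-site probability p; returns the mutated
# string. Each hit is replaced by one of the three other bases.
mutate_sequence <- function(s, p) {
  n <- nchar(s)
  if (p <= 0 || n == 0L) return(s)
  idx <- which(runif(n) < p)
  if (length(idx) == 0L) return(s)
  r <- utf8ToInt(s)
  codes <- utf8ToInt("ACGT")
  cur <- match(r[idx], codes)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  r[idx] <- codes[((cur - 1L + shift) %% 4L) + 1L]
  intToUtf8(r)
}

splice_in <- function(s, start, replacement) {
  # 1-based start; replacement overwrites in place
  end <- start + nchar(replacement) - 1L
  stopifnot(start >= 1L, end <= nchar(s))
  paste0(substr(s, 1L, start - 1L), replacement,
         substr(s, end + 1L, nchar(s)))
}

#' Simulate a truth set of three related genomes
#'
#' Builds the `A` genome from i.i.d. background sequence at the configured GC
#' content, plants centromeric and telomeric tandem arrays and non-overlapping
#' gene intervals, then derives the `D` and `C` genomes by per-site
#' substitution at the configured A-to-D and A-to-C divergences (D close, C
#' distant). Each derived genome receives its own satellite monomers
#' (re-planted as exact tandem copies at the same truth positions). All planted
#' features are recorded in truth tables so downstream modules can be scored
#' without re-simulation.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_bundle`: a list with `genomes`
#'   (named list `A`, `D`, `C` of `DNAStringSet`), `annotations` (per-genome
#'   data frames of 1-based closed gene intervals), `truth_arrays` (genome,
#'   chromosome, start, end, monomer, role), `monomers` (per-genome named
#'   character vectors), `centromere_bp` (per-chromosome centromere midpoints)
#'   and the `config`.
#' @export
simulate_truth_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "truth_set"))
  L <- config$chromosome_length
  nc <- config$n_chromosomes
  cen_frac <- rep_len(config$centromere_position_fraction, nc)

  cen_len <- config$centromere_monomer_length *
    as.integer(config$array_copy_numbers[["centromere"]])
  tel_len <- config$telomere_monomer_length *
    as.integer(config$array_copy_numbers[["telomere"]])
  genes_per_chrom <- split_count(config$n_genes, nc)
  need <- cen_len + 2L * tel_len + 4000L +
    max(genes_per_chrom) * (config$gene_length + 2L)
  if (need > L)
    stop(sprintf(paste0("chromosome too short (%d bp) to host the requested",
                        " arrays and genes (need >= %d bp)"), L, need))

  genome_names <- c("A", "D", "C")
  monomers <- list()
  for (g in genome_names) {
    monomers[[g]] <- c(
      centromere = random_sequence(config$centromere_monomer_length, 0.5),
      telomere = random_sequence(config$telomere_monomer_length, 0.5)
    )
  }

  chroms_A <- character(nc)
  arrays <- list()
  annots <- list()
  cen_mid <- numeric(nc)
  for (i in seq_len(nc)) {
    s <- random_sequence(L, config$gc)
    cen_start <- as.integer(round(cen_frac[i] * L - cen_len / 2))
    cen_start <- max(1L + tel_len + 2000L,
                     min(cen_start, L - tel_len - 2000L - cen_len))
    tel1_start <- 1000L
    tel2_start <- L - 1000L - tel_len + 1L
    spans <- data.frame(
      chromosome = paste0("A", i),
      start = c(cen_start, tel1_start, tel2_start),
      end = c(cen_start + cen_len - 1L, tel1_start + tel_len - 1L,
              tel2_start + tel_len - 1L),
      role = c("centromere", "telomere", "telomere"),
      stringsAsFactors = FALSE
    )
    arrays[[i]] <- spans
    cen_mid[i] <- cen_start + cen_len / 2
    # gene intervals, non-overlapping, outside arrays
    occupied <- spans[, c("start", "end")]
    gene_rows <- list()
    ng <- genes_per_chrom[i]
    tries <- 0L
    while (length(gene_rows) < ng) {
      tries <- tries + 1L
      if (tries > 10000L) stop("chromosome too short to place genes")
      st <- sample.int(L - config$gene_length, 1L)
      en <- st + config$gene_length - 1L
      if (any(st <= occupied$end & en >= occupied$start)) next
      occupied <- rbind(occupied, data.frame(start = st, end = en))
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(chromosome = paste0("A", i), start = st, end = en,
                   strand = sample(c("+", "-"), 1L),
                   stringsAsFactors = FALSE)
    }
    ann <- if (ng > 0L) do.call(rbind, gene_rows) else
      data.frame(chromosome = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 stringsAsFactors = FALSE)
    ann <- ann[order(ann$start), , drop = FALSE]
    annots[[i]] <- ann
    chroms_A[i] <- s
  }
  annotations_A <- do.call(rbind, annots)
  rownames(annotations_A) <- NULL
  if (nrow(annotations_A) > 0L)
    annotations_A$gene_id <- sprintf("gene%04d", seq_len(nrow(annotations_A)))
  else annotations_A$gene_id <- character(0)
  truth_arrays_A <- do.call(rbind, arrays)

  plant <- function(s, spans, mono) {
    for (j in seq_len(nrow(spans))) {
      unit <- mono[[spans$role[j]]]
      n_cop <- (spans$end[j] - spans$start[j] + 1L) %/% nchar(unit)
      s <- splice_in(s, spans$start[j], strrep(unit, n_cop))
    }
    s
  }

  genomes <- list()
  truth_arrays <- list()
  annotations <- list()
  for (g in genome_names) {
    p <- switch(g, A = 0,
                D = config$subgenome_divergence[["AD"]],
                C = config$subgenome_divergence[["AC"]])
    chroms <- character(nc)
    sp_all <- list()
    for (i in seq_len(nc)) {
      s <- if (p > 0) mutate_sequence(chroms_A[i], p) else chroms_A[i]
      spans <- arrays[[i]]
      spans$chromosome <- paste0(g, i)
      spans$genome <- g
      spans$monomer <- unname(monomers[[g]][spans$role])
      s <- plant(s, spans, monomers[[g]])
      chroms[i] <- s
      sp_all[[i]] <- spans
    }
    dss <- Biostrings::DNAStringSet(chroms)
    names(dss) <- paste0(g, seq_len(nc))
    genomes[[g]] <- dss
    truth_arrays[[g]] <- do.call(rbind, sp_all)
    ann <- annotations_A
    if (nrow(ann) > 0L)
      ann$chromosome <- sub("^A", g, ann$chromosome)
    annotations[[g]] <- ann
  }
  truth_arrays <- do.call(rbind, truth_arrays)
  rownames(truth_arrays) <- NULL
  truth_arrays <- truth_arrays[, c("genome", "chromosome", "start", "end",
                                   "role", "monomer")]

  out <- list(genomes = genomes,
              annotations = annotations,
              truth_arrays = truth_arrays,
              monomers = monomers,
              centromere_bp = setNames(cen_mid, paste0("A", seq_len(nc))),
              config = config)
  class(out) <- "synthetic_bundle"
  out
}

split_count <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("Synthetic bundle: %d chromosomes x %d bp per genome (A, D, C)\n",
              x$config$n_chromosomes, x$config$chromosome_length))
  cat(sprintf("  %d genes, %d planted arrays, seed %d\n",
              nrow(x$annotations$A), nrow(x$truth_arrays), x$config$seed))
  invisible(x)
}

# Sample marker start positions (1-based) on one chromosome, outside planted
# arrays, at least marker_length from the end.
sample_marker_starts <- function(n, chrom_length, marker_length, spans) {
  if (n == 0L) return(integer(0))
  lim <- chrom_length - marker_length + 1L
  if (lim < 1L) stop("marker_length exceeds chromosome_length")
  got <- integer(0)
  tries <- 0L
  while (length(got) < n) {
    tries <- tries + 1L
    if (tries > 200L) stop("unable to place markers outside arrays")
    cand <- sample.int(lim, n * 2L, replace = FALSE)
    bad <- rep(FALSE, length(cand))
    for (j in seq_len(nrow(spans))) {
      bad <- bad | (cand <= spans$end[j] &
                      (cand + marker_length - 1L) >= spans$start[j])
    }
    got <- unique(c(got, cand[!bad]))
  }
  sort(got[seq_len(n)])
}

#' Simulate a diploid linkage-map marker panel
#'
#' Draws tag markers as exact substrings (or reverse complements) of the `A`
#' genome, with cM positions from a cumulative recombination map whose density
#' is suppressed inside the pericentromeric third of each chromosome. One
#' linkage group per chromosome.
#'
#' @param bundle A [simulate_truth_set()] bundle.
#' @param config A [sim_config()]; defaults to the bundle's own.
#' @return A list of class `linkage_panel` with `markers` (marker_id,
#'   sequence, lg, cM) and `truth` (marker_id, subgenome, chromosome,
#'   position as 0-based start, strand, lg, cM).
#' @export
simulate_linkage_panel <- function(bundle, config = bundle$config) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  set.seed(stage_seed(config$seed, "linkage_panel"))
  nc <- config$n_chromosomes
  cen_frac <- rep_len(config$centromere_position_fraction, nc)
  mlen <- config$marker_length
  rows <- list()
  for (i in seq_len(nc)) {
    n <- config$n_markers_per_lg
    if (n == 0L) next
    chrom <- paste0("A", i)
    s <- as.character(bundle$genomes$A[[chrom]])
    spans <- bundle$truth_arrays[bundle$truth_arrays$chromosome == chrom, ]
    starts <- sample_marker_starts(n, nchar(s), mlen, spans)
    tags <- substring(s, starts, starts + mlen - 1L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tags[strand == "-"] <- revcomp(tags[strand == "-"])
    cm <- cm_of_position(starts, nchar(s), cen_frac[i],
                         config$map_length_cm, config$recomb_suppression)
    rows[[i]] <- data.frame(
      marker_id = sprintf("LG%d_m%03d", i, seq_len(n)),
      sequence = tags,
      lg = paste0("LG", i),
      cM = round(cm, 3),
      subgenome = "A",
      chromosome = chrom,
      position = starts - 1L,
      strand = strand,
      stringsAsFactors = FALSE
    )
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker_id = character(0), sequence = character(0),
               lg = character(0), cM = numeric(0), subgenome = character(0),
               chromosome = character(0), position = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  out <- list(markers = tab[, c("marker_id", "sequence", "lg", "cM")],
              truth = tab[, c("marker_id", "subgenome", "chromosome",
                              "position", "strand", "lg", "cM")])
  class(out) <- "linkage_panel"
  out
}

#' Simulate a hexaploid marker panel over three subgenomes
#'
#' Emulates a hexaploid (AACCDD) consensus-map marker panel: each chromosome
#' contributes three linkage groups, one per subgenome, whose markers are
#' exact substrings of the corresponding `A`, `D` or `C` genome. Because the
#' D genome diverged little from A, a large fraction of D-derived tags still
#' match the A reference perfectly, while C-derived tags almost never do —
#' the asymmetry the subgenome caller exploits. An optional translocation
#' replaces the markers of one linkage group beyond a cM breakpoint with tags
#' drawn from a donor chromosome of another subgenome.
#'
#' @param config A [sim_config()].
#' @param bundle Optional pre-built [simulate_truth_set()] bundle.
#' @return A list of class `hexaploid_panel` with `markers` (marker_id,
#'   sequence, lg, cM), `truth` (per-marker subgenome/chromosome/position)
#'   and `lg_truth` (per-LG dominant subgenome and source chromosome,
#'   `translocated` flag).
#' @export
simulate_hexaploid_panel <- function(config, bundle = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(bundle)) bundle <- simulate_truth_set(config)
  set.seed(stage_seed(config$seed, "hexaploid_panel"))
  nc <- config$n_chromosomes
  cen_frac <- rep_len(config$centromere_position_fraction, nc)
  mlen <- config$marker_length
  subs <- c("A", "D", "C")
  n_lg <- nc * 3L
  lg_ids <- sprintf("Mrg%02d", sample.int(n_lg))
  k <- 0L
  rows <- list()
  lg_truth <- list()
  for (i in seq_len(nc)) {
    for (g in subs) {
      k <- k + 1L
      lg <- lg_ids[k]
      chrom <- paste0(g, i)
      s <- as.character(bundle$genomes[[g]][[chrom]])
      spans <- bundle$truth_arrays[bundle$truth_arrays$chromosome == chrom, ]
      n <- config$n_markers_per_lg
      if (n == 0L) next
      starts <- sample_marker_starts(n, nchar(s), mlen, spans)
      tags <- substring(s, starts, starts + mlen - 1L)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      tags[strand == "-"] <- revcomp(tags[strand == "-"])
      cm <- cm_of_position(starts, nchar(s), cen_frac[i],
                           config$map_length_cm, config$recomb_suppression)
      df <- data.frame(
        marker_id = sprintf("%s_m%03d", lg, seq_len(n)),
        sequence = tags, lg = lg, cM = round(cm, 3),
        subgenome = g, chromosome = chrom, position = starts - 1L,
        strand = strand, stringsAsFactors = FALSE
      )
      translocated <- FALSE
      ts <- config$translocation_spec
      if (!is.null(ts) && ts$lg_subgenome == g && ts$lg_chromosome == i) {
        if (ts$breakpoint_cm <= 0 || ts$breakpoint_cm >= config$map_length_cm)
          stop("translocation breakpoint outside the LG cM range")
        sel <- df$cM > ts$breakpoint_cm
        if (any(sel)) {
          dg <- ts$donor_subgenome
          dchrom <- paste0(dg, ts$donor_chromosome)
          ds <- as.character(bundle$genomes[[dg]][[dchrom]])
          dspans <- bundle$truth_arrays[
            bundle$truth_arrays$chromosome == dchrom, ]
          dstarts <- sample_marker_starts(sum(sel), nchar(ds), mlen, dspans)
          dcm <- cm_of_position(dstarts, nchar(ds),
                                rep_len(cen_frac, nc)[ts$donor_chromosome],
                                config$map_length_cm,
                                config$recomb_suppression)
          # keep donor markers in the translocated cM range, ordered
          dcm <- ts$breakpoint_cm +
            (config$map_length_cm - ts$breakpoint_cm) *
            (rank(dcm, ties.method = "first") / (sum(sel) + 1))
          dtags <- substring(ds, dstarts, dstarts + mlen - 1L)
          dstrand <- sample(c("+", "-"), sum(sel), replace = TRUE)
          dtags[dstrand == "-"] <- revcomp(dtags[dstrand == "-"])
          df$sequence[sel] <- dtags
          df$cM[sel] <- round(dcm, 3)
          df$subgenome[sel] <- dg
          df$chromosome[sel] <- dchrom
          df$position[sel] <- dstarts - 1L
          df$strand[sel] <- dstrand
          translocated <- TRUE
        }
      }
      df <- df[order(df$cM), , drop = FALSE]
      rows[[length(rows) + 1L]] <- df
      lg_truth[[length(lg_truth) + 1L]] <-
        data.frame(lg = lg, subgenome = g, chromosome = chrom,
                   translocated = translocated, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker_id = character(0), sequence = character(0),
               lg = character(0), cM = numeric(0), subgenome = character(0),
               chromosome = character(0), position = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  lgt <- if (length(lg_truth)) do.call(rbind, lg_truth) else
    data.frame(lg = character(0), subgenome = character(0),
               chromosome = character(0), translocated = logical(0))
  out <- list(markers = tab[, c("marker_id", "sequence", "lg", "cM")],
              truth = tab[, c("marker_id", "lg", "subgenome", "chromosome",
                              "position", "strand", "cM")],
              lg_truth = lgt,
              bundle = bundle)
  class(out) <- "hexaploid_panel"
  out
}

# Codon families whose third position is fully synonymous and whose first two
# positions are always nonsynonymous (Val, Ala, Gly, Thr, Pro, Ser4): every
# codon contributes exactly one synonymous site under NG86.
FOURFOLD_PREFIXES <- c("GT", "GC", "GG", "AC", "CC", "TC")

#' Simulate codon-aligned gene pairs with a targeted Ks distribution
#'
#' Builds gap-free codon alignments from fourfold-degenerate codon families
#' and applies synonymous third-position substitutions so that the realized
#' Nei-Gojobori Ks distribution is unimodal at the configured peak. Each
#' pair's target Ks is drawn from a truncated normal
#' `N(ks_peak, ks_dispersion)`; the number of synonymous substitutions applied
#' is `round(pS * S)` with `pS = 3/4 (1 - exp(-4 Ks / 3))`, so the truth
#' bookkeeping is exact.
#'
#' @param config A [sim_config()].
#' @return A list of class `ks_pair_set` with `pairs` (pair_id, seq1, seq2)
#'   and `truth` (pair_id, ks_target, s_sites, s_diffs_applied, p_s_applied,
#'   ks_applied).
#' @export
simulate_ks_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "ks_pairs"))
  n <- config$n_gene_pairs
  S <- config$pair_codons
  if (n == 0L) {
    out <- list(pairs = data.frame(pair_id = character(0),
                                   seq1 = character(0), seq2 = character(0),
                                   stringsAsFactors = FALSE),
                truth = data.frame(pair_id = character(0),
                                   ks_target = numeric(0),
                                   s_sites = numeric(0),
                                   s_diffs_applied = integer(0),
                                   p_s_applied = numeric(0),
                                   ks_applied = numeric(0)))
    class(out) <- "ks_pair_set"
    return(out)
  }
  pair_id <- sprintf("pair%05d", seq_len(n))
  ks_target <- if (config$ks_peak == 0) rep(0, n) else
    pmax(0, rnorm(n, config$ks_peak, config$ks_dispersion))
  p_s <- pmin(0.75 * (1 - exp(-4 * ks_target / 3)), 0.7499)
  nd <- as.integer(round(p_s * S))
  seq1 <- character(n)
  seq2 <- character(n)
  for (i in seq_len(n)) {
    pref <- sample(FOURFOLD_PREFIXES, S, replace = TRUE)
    third <- sample(BASES, S, replace = TRUE)
    codons <- paste0(pref, third)
    s1 <- paste(codons, collapse = "")
    third2 <- third
    if (nd[i] > 0L) {
      hit <- sample.int(S, nd[i])
      shift <- sample.int(3L, nd[i], replace = TRUE)
      third2[hit] <- BASES[((match(third[hit], BASES) - 1L + shift) %% 4L) + 1L]
    }
    s2 <- paste(paste0(pref, third2), collapse = "")
    seq1[i] <- s1
    seq2[i] <- s2
  }
  p_applied <- nd / S
  out <- list(
    pairs = data.frame(pair_id = pair_id, seq1 = seq1, seq2 = seq2,
                       stringsAsFactors = FALSE),
    truth = data.frame(pair_id = pair_id, ks_target = ks_target,
                       s_sites = S, s_diffs_applied = nd,
                       p_s_applied = p_applied,
                       ks_applied = ifelse(p_applied < 0.75,
                                           -0.75 * log(1 - 4 * p_applied / 3),
                                           NA_real_))
  )
  class(out) <- "ks_pair_set"
  out
}

#' Simulate a clade-structured genotype panel
#'
#' Generates mostly homozygous biallelic calls for a panel of accessions that
#' segregate along a simple rooted tree: each site's derived allele is
#' assigned either to one clade's stem branch (shared by all members) or to a
#' single accession's terminal branch, with probabilities proportional to the
#' configured branch lengths. Optional site-wise Bernoulli contamination
#' injects heterozygous and missing calls for filter testing.
#'
#' @param config A [sim_config()].
#' @return A list of class `genotype_panel` with `genotypes` (a
#'   [genotype_matrix()]) and `truth_tree` (rooted `ape::phylo`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  cs <- config$clade_structure
  accs <- unlist(cs$clades, use.names = FALSE)
  n_acc <- length(accs)
  n_sites <- config$n_sites
  clade_names <- names(cs$clades)
  n_branches <- length(clade_names) + n_acc
  if (n_sites < n_branches)
    stop(sprintf("n_sites (%d) below the %d branches needing support",
                 n_sites, n_branches))

  branch_names <- c(clade_names, accs)
  weights <- c(cs$divergence[clade_names],
               rep(cs$private_divergence, n_acc))
  branch <- sample(branch_names, n_sites, replace = TRUE,
                   prob = weights / sum(weights))

  calls <- matrix(0L, nrow = n_sites, ncol = n_acc,
                  dimnames = list(NULL, accs))
  for (cl in clade_names) {
    sel <- branch == cl
    calls[sel, cs$clades[[cl]]] <- 2L
  }
  priv <- branch %in% accs
  if (any(priv)) {
    ij <- cbind(which(priv), match(branch[priv], accs))
    calls[ij] <- 2L
  }

  if (config$het_rate > 0) {
    hit <- which(runif(length(calls)) < config$het_rate)
    calls[hit] <- 1L
  }
  if (config$missing_rate > 0) {
    hit <- which(runif(length(calls)) < config$missing_rate)
    calls[hit] <- NA_integer_
  }

  # site coordinates on the A-genome chromosomes, strictly increasing
  nc <- config$n_chromosomes
  per_chrom <- split_count(n_sites, nc)
  sites <- do.call(rbind, lapply(seq_len(nc), function(i) {
    pos <- sort(sample.int(config$chromosome_length, per_chrom[i]))
    data.frame(chromosome = paste0("A", i), position = pos,
               stringsAsFactors = FALSE)
  }))
  alleles <- t(vapply(seq_len(n_sites), function(i)
    sample(BASES, 2L), character(2)))
  sites$ref <- alleles[, 1]
  sites$alt <- alleles[, 2]

  gm <- genotype_matrix(accessions = accs, sites = sites, calls = calls)

  tip_len <- cs$private_divergence
  clade_newick <- vapply(clade_names, function(cl) {
    members <- cs$clades[[cl]]
    inner <- paste(sprintf("%s:%g", members, tip_len), collapse = ",")
    if (length(members) == 1L)
      sprintf("%s:%g", members, tip_len + cs$divergence[[cl]])
    else
      sprintf("(%s):%g", inner, cs$divergence[[cl]])
  }, character(1))
  tree <- ape::read.tree(text = paste0("(", paste(clade_newick, collapse = ","),
                                       ");"))
  tree <- ape::root(tree, outgroup = cs$outgroup, resolve.root = TRUE)

  out <- list(genotypes = gm, truth_tree = tree)
  class(out) <- "genotype_panel"
  out
}
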