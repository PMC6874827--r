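#' Simulation configuration
#'
#' Builds the configuration object consumed by every `simulate_*` generator.
#' Defaults describe a desk-scale diploid oat-like system: three chromosomes
#' of 2 Mb at 44% GC, a genome-wide 159-bp centromeric satellite and a 665-bp
#' telomeric satellite planted as tandem arrays, 64-bp tag-level haplotype
#' markers on one linkage group per chromosome, three subgenomes with the
#' A/D pair closely related (1% divergence) and the C genome distant (10%),
#' a synonymous-divergence (Ks) peak at 0.0875, and a clade-structured,
#' mostly homozygous resequencing panel.
#'
#' @param seed Integer seed; identical configurations give byte-identical
#'   artifacts.
#' @param n_chromosomes Number of chromosomes per genome.
#' @param chromosome_length Chromosome length in bp.
#' @param n_genes Total gene count per genome (split evenly over
#'   chromosomes).
#' @param gene_length Gene length in bp.
#' @param centromere_position_fraction Fractional position of the centromere
#'   on each chromosome (recycled); the default mixes metacentric (0.5),
#'   submetacentric (0.3) and sub-telocentric (0.15) placements.
#' @param centromere_monomer_length,telomere_monomer_length Satellite monomer
#'   lengths in bp (159 and 665 by default, the sizes typical of grass
#'   centromeric repeats and of the oat telomeric sub-repeat).
#' @param array_copy_numbers Named vector with elements `centromere` and
#'   `telomere`: tandem copies planted per array.
#' @param n_markers_per_lg Markers simulated per linkage group.
#' @param marker_length Tag length in bp (64, the tag-level haplotype size).
#' @param subgenome_divergence Named per-site substitution probabilities
#'   `c(AD = , AC = )` applied when deriving the D and C genomes from A;
#'   AD must be smaller than AC.
#' @param translocation_spec `NULL`, or a list with fields `lg_subgenome`,
#'   `lg_chromosome`, `breakpoint_cm`, `donor_subgenome`, `donor_chromosome`
#'   describing an intergenomic translocation planted into the hexaploid
#'   panel: markers past the cM breakpoint are drawn from the donor
#'   chromosome.
#' @param ks_peak Target mode of the synonymous-divergence distribution.
#' @param ks_dispersion Standard deviation of the per-pair Ks draw.
#' @param n_gene_pairs Number of codon-aligned pairs to simulate.
#' @param pair_codons Codons per simulated pair.
#' @param n_accessions Accessions in the genotype panel.
#' @param clade_structure `NULL` for the default two-clade-plus-outgroup
#'   partition, or a list with `clades` (named list of accession-id vectors),
#'   `divergence` (named per-clade branch lengths, expected substitutions per
#'   site), `private_divergence` (per-accession terminal branch length) and
#'   `outgroup` (accession id).
#' @param n_sites Segregating sites in the genotype panel.
#' @param het_rate,missing_rate Site-wise Bernoulli contamination rates used
#'   to exercise the heterozygosity and missing-data filters (0 by default).
#' @param map_length_cm Genetic length of each linkage group.
#' @param recomb_suppression Fold reduction of recombination density inside
#'   the pericentromeric third of the chromosome.
#' @param gc GC fraction of the background sequence.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 42, chromosome_length = 1e5, n_genes = 9)
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chromosome_length = 2e6,
                       n_genes = 60L,
                       gene_length = 1500L,
                       centromere_position_fraction = c(0.5, 0.3, 0.15),
                       centromere_monomer_length = 159L,
                       telomere_monomer_length = 665L,
                       array_copy_numbers = c(centromere = 400L, telomere = 30L),
                       n_markers_per_lg = 60L,
                       marker_length = 64L,
                       subgenome_divergence = c(AD = 0.01, AC = 0.10),
                       translocation_spec = NULL,
                       ks_peak = 0.0875,
                       ks_dispersion = 0.01,
                       n_gene_pairs = 2000L,
                       pair_codons = 400L,
                       n_accessions = 24L,
                       clade_structure = NULL,
                       n_sites = 2000L,
                       het_rate = 0,
                       missing_rate = 0,
                       map_length_cm = 120,
                       recomb_suppression = 10,
                       gc = 0.44) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              centromere_position_fraction = centromere_position_fraction,
              centromere_monomer_length = as.integer(centromere_monomer_length),
              telomere_monomer_length = as.integer(telomere_monomer_length),
              array_copy_numbers = array_copy_numbers,
              n_markers_per_lg = as.integer(n_markers_per_lg),
              marker_length = as.integer(marker_length),
              subgenome_divergence = subgenome_divergence,
              translocation_spec = translocation_spec,
              ks_peak = ks_peak,
              ks_dispersion = ks_dispersion,
              n_gene_pairs = as.integer(n_gene_pairs),
              pair_codons = as.integer(pair_codons),
              n_accessions = as.integer(n_accessions),
              clade_structure = clade_structure,
              n_sites = as.integer(n_sites),
              het_rate = het_rate,
              missing_rate = missing_rate,
              map_length_cm = map_length_cm,
              recomb_suppression = recomb_suppression,
              gc = gc)
  if (is.null(cfg$clade_structure))
    cfg$clade_structure <- default_clade_structure(cfg$n_accessions)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

default_clade_structure <- function(n_accessions) {
  if (n_accessions < 3L)
    stop("need at least 3 accessions (two clades plus an outgroup)")
  n_a <- ceiling((n_accessions - 1L) * 0.6)
  n_c <- n_accessions - 1L - n_a
  list(
    clades = list(
      cladeA = sprintf("A%02d", seq_len(n_a)),
      cladeC = sprintf("C%02d", seq_len(n_c)),
      outgroup = "OUT1"
    ),
    divergence = c(cladeA = 0.02, cladeC = 0.05, outgroup = 0.15),
    private_divergence = 0.005,
    outgroup = "OUT1"
  )
}

validate_sim_config <- function(cfg) {
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$n_chromosomes >= 1L,
    cfg$chromosome_length >= 1L,
    cfg$n_genes >= 0L, cfg$gene_length >= 1L,
    frac_ok(cfg$centromere_position_fraction),
    cfg$centromere_monomer_length >= 1L,
    cfg$telomere_monomer_length >= 1L,
    all(cfg$array_copy_numbers >= 1),
    all(c("centromere", "telomere") %in% names(cfg$array_copy_numbers)),
    cfg$n_markers_per_lg >= 0L,
    cfg$marker_length >= 1L,
    all(c("AD", "AC") %in% names(cfg$subgenome_divergence)),
    frac_ok(cfg$subgenome_divergence),
    cfg$ks_peak >= 0, cfg$ks_dispersion >= 0,
    cfg$n_gene_pairs >= 0L, cfg$pair_codons >= 1L,
    cfg$n_accessions >= 3L, cfg$n_sites >= 1L,
    frac_ok(c(cfg$het_rate, cfg$missing_rate, cfg$gc)),
    cfg$map_length_cm > 0, cfg$recomb_suppression >= 1
  )
  if (cfg$subgenome_divergence[["AD"]] >= cfg$subgenome_divergence[["AC"]])
    stop("subgenome_divergence: A->D probability must be below A->C ",
         "(the A and D subgenomes are the close pair)")
  cs <- cfg$clade_structure
  accs <- unlist(cs$clades, use.names = FALSE)
  if (anyDuplicated(accs) || length(accs) != cfg$n_accessions)
    stop("clade_structure must partition all accessions exactly once")
  if (!cs$outgroup %in% accs)
    stop("clade_structure outgroup must be one of the accessions")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d chromosomes x %d bp, seed %d\n",
              x$n_chromosomes, x$chromosome_length, x$seed))
  cat(sprintf("  satellites: %d-bp centromeric, %d-bp telomeric\n",
              x$centromere_monomer_length, x$telomere_monomer_length))
  cat(sprintf("  divergence: A->D %.3f, A->C %.3f; Ks peak %.4f\n",
              x$subgenome_divergence[["AD"]], x$subgenome_divergence[["AC"]],
              x$ks_peak))
  cat(sprintf("  panel: %d accessions, %d sites\n", x$n_accessions, x$n_sites))
  invisible(x)
}

# Genetic map: cumulative recombination density along a chromosome, with a
# `suppression`-fold reduced density inside the third of the chromosome
# centred on the centromere (pericentromeric recombination suppression).
cm_of_position <- function(pos, chrom_length, centromere_frac,
                           map_length_cm = 120, suppression = 10) {
  L <- chrom_length
  cen <- centromere_frac * L
  lo <- max(0, cen - L / 6)
  hi <- min(L, cen + L / 6)
  integral <- function(p) {
    inside <- pmax(0, pmin(p, hi) - lo)
    (p - inside) + inside / suppression
  }
  map_length_cm * integral(pos) / integral(L)
}
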