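#' Genotype matrix container
#'
#' Holds biallelic SNP calls for a panel of accessions. Calls are coded as
#' alternate-allele dosage: 0 (homozygous reference), 2 (homozygous
#' alternate), 1 (heterozygous), `NA` (missing).
#'
#' @param accessions Ordered accession ids.
#' @param sites Data frame with columns `chromosome`, `position` (1-based),
#'   `ref`, `alt`. Positions must be strictly increasing within chromosome.
#' @param calls Integer matrix, sites x accessions, values in {0, 1, 2, NA}.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(accessions, sites, calls) {
  accessions <- as.character(accessions)
  stopifnot(is.matrix(calls),
            nrow(calls) == nrow(sites),
            ncol(calls) == length(accessions),
            all(calls %in% c(0L, 1L, 2L) | is.na(calls)),
            all(c("chromosome", "position", "ref", "alt") %in% names(sites)))
  if (any(sites$ref == sites$alt))
    stop("sites must be biallelic (ref != alt)")
  for (ch in unique(sites$chromosome)) {
    p <- sites$position[sites$chromosome == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on %s", ch))
  }
  colnames(calls) <- accessions
  out <- list(accessions = accessions, sites = sites, calls = calls)
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d sites x %d accessions\n",
              nrow(x$sites), length(x$accessions)))
  n <- length(x$calls)
  cat(sprintf("  het %.2f%%, missing %.2f%%\n",
              100 * sum(x$calls == 1L, na.rm = TRUE) / n,
              100 * sum(is.na(x$calls)) / n))
  invisible(x)
}

subset_sites <- function(gm, keep) {
  genotype_matrix(gm$accessions,
                  gm$sites[keep, , drop = FALSE],
                  gm$calls[keep, , drop = FALSE])
}

#' Filter SNP sites on missingness, heterozygosity and allele frequency
#'
#' Applies the three panel-level site filters in fixed order, attributing
#' each removal to the first failing rule: (1) any missing call removes the
#' site (0% missing data policy); (2) a heterozygous-call fraction strictly
#' above `max_het_fraction` removes it (spurious-mapping heuristic for a
#' cleistogamous, highly inbred panel); (3) minor allele frequency below
#' `min_maf` removes it, with heterozygotes contributing half a dose. Sites
#' on an unplaced chromosome (`NA` or `"."`) are removed first.
#'
#' @param gm A [genotype_matrix()].
#' @param max_het_fraction Maximum tolerated heterozygous fraction
#'   (default 0.05; the rule is strict, i.e. a site at exactly 5% is kept).
#' @param min_maf Minimum minor allele frequency (default 0.1; sites with
#'   MAF < 0.1 are removed).
#' @return A list of class `filter_result`: `genotypes` (filtered matrix) and
#'   `report` (class `filter_report` with input/removed/output counts).
#' @export
filter_sites <- function(gm, max_het_fraction = 0.05, min_maf = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_in <- nrow(gm$sites)
  n_acc <- length(gm$accessions)
  unplaced <- is.na(gm$sites$chromosome) | gm$sites$chromosome == "."
  n_miss_calls <- rowSums(is.na(gm$calls))
  het_frac <- rowSums(gm$calls == 1L, na.rm = TRUE) / n_acc
  alt_freq <- rowSums(gm$calls, na.rm = TRUE) / (2 * (n_acc - n_miss_calls))
  maf <- pmin(alt_freq, 1 - alt_freq)

  reason <- rep("kept", n_in)
  reason[maf < min_maf] <- "maf"
  reason[het_frac > max_het_fraction] <- "het"
  reason[n_miss_calls > 0L] <- "missing"
  reason[unplaced] <- "unplaced"

  keep <- reason == "kept"
  report <- list(input_sites = n_in,
                 removed_unplaced = sum(reason == "unplaced"),
                 removed_missing = sum(reason == "missing"),
                 removed_het = sum(reason == "het"),
                 removed_maf = sum(reason == "maf"),
                 output_sites = sum(keep))
  class(report) <- "filter_report"
  out <- list(genotypes = subset_sites(gm, keep), report = report)
  class(out) <- "filter_result"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP site filter report\n")
  cat(sprintf("  input sites       %d\n", x$input_sites))
  cat(sprintf("  removed unplaced  %d\n", x$removed_unplaced))
  cat(sprintf("  removed missing   %d\n", x$removed_missing))
  cat(sprintf("  removed het       %d\n", x$removed_het))
  cat(sprintf("  removed MAF       %d\n", x$removed_maf))
  cat(sprintf("  output sites      %d\n", x$output_sites))
  invisible(x)
}

#' @export
print.filter_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Sliding-window LD pruning
#'
#' Greedy left-to-right thinning of linked sites, the scheme used to reduce
#' SNP oversampling before tree building: scanning each chromosome in
#' position order, a site is dropped if its squared allelic correlation (r2,
#' computed on allele dosages across accessions) with any already-retained
#' site within `window_bp` upstream exceeds `r2_threshold`. Monomorphic
#' sites (zero variance) are dropped with reason `monomorphic`. After
#' pruning, no retained pair within a window has r2 above the threshold.
#'
#' @param gm A [genotype_matrix()] with no missing calls (filter first).
#' @param window_bp Window size in bp (default 500,000).
#' @param r2_threshold Maximum tolerated r2 (default 0.1).
#' @return A list of class `ld_prune_result`: `genotypes` (pruned matrix) and
#'   `report` (data frame of dropped sites with reasons).
#' @export
ld_prune <- function(gm, window_bp = 500000, r2_threshold = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (anyNA(gm$calls))
    stop("ld_prune requires a matrix with no missing calls; run filter_sites")
  n <- nrow(gm$sites)
  keep <- logical(n)
  reason <- rep(NA_character_, n)
  dosage <- gm$calls / 2
  for (ch in unique(gm$sites$chromosome)) {
    idx <- which(gm$sites$chromosome == ch)
    retained <- integer(0)
    for (i in idx) {
      x <- dosage[i, ]
      if (stats::var(x) == 0) {
        reason[i] <- "monomorphic"
        next
      }
      pos <- gm$sites$position[i]
      inwin <- retained[gm$sites$position[retained] >= pos - window_bp]
      linked <- FALSE
      for (j in rev(inwin)) {
        r2 <- suppressWarnings(stats::cor(x, dosage[j, ]))^2
        if (!is.na(r2) && r2 > r2_threshold) {
          linked <- TRUE
          break
        }
      }
      if (linked) {
        reason[i] <- "linked"
      } else {
        keep[i] <- TRUE
        retained <- c(retained, i)
      }
    }
  }
  dropped <- data.frame(chromosome = gm$sites$chromosome[!keep],
                        position = gm$sites$position[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- list(genotypes = subset_sites(gm, keep), report = dropped)
  class(out) <- "ld_prune_result"
  out
}

#' @export
print.ld_prune_result <- function(x, ...) {
  cat(sprintf("LD pruning: %d sites retained, %d dropped (%d linked, %d monomorphic)\n",
              nrow(x$genotypes$sites), nrow(x$report),
              sum(x$report$reason == "linked"),
              sum(x$report$reason == "monomorphic")))
  invisible(x)
}

# Pairwise p-distance on allele dosage (het = 0.5), pairwise-complete.
p_distance <- function(gm) {
  dosage <- gm$calls / 2
  n_acc <- length(gm$accessions)
  d <- matrix(0, n_acc, n_acc, dimnames = list(gm$accessions, gm$accessions))
  for (i in seq_len(n_acc - 1L)) {
    for (j in (i + 1L):n_acc) {
      diffs <- abs(dosage[, i] - dosage[, j])
      d[i, j] <- d[j, i] <- mean(diffs, na.rm = TRUE)
    }
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around the neighbor-joining engine used by [build_tree()],
#' exposed so that distance matrices from any source can be run through the
#' same code path. On an exactly additive distance matrix the result
#' reproduces the generating tree metric.
#'
#' @param d A `dist` object or symmetric matrix.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_from_distances <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  ape::nj(d)
}

#' Bootstrapped neighbor-joining phylogeny from a genotype matrix
#'
#' Computes pairwise p-distances on allele dosage, builds a neighbor-joining
#' tree, roots it on the designated outgroup, and attaches internal-node
#' bootstrap support from site resampling: each replicate redraws sites with
#' replacement (by site index, so the result is invariant to accession
#' order), rebuilds the NJ tree, and support is the percentage of replicates
#' containing each clade.
#'
#' @param gm A [genotype_matrix()] (filtered and pruned).
#' @param outgroup_id Accession id used to root the tree.
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @return An object of class `snp_tree`: list with `tree` (rooted
#'   `ape::phylo`, node labels = bootstrap percentages), `n_bootstrap`, and
#'   `newick` (serialized tree).
#' @export
build_tree <- function(gm, outgroup_id, n_bootstrap = 1000, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$accessions) < 3L)
    stop("need at least 3 accessions to build a tree")
  if (!outgroup_id %in% gm$accessions)
    stop(sprintf("outgroup '%s' not among the accessions", outgroup_id))
  d <- p_distance(gm)
  main <- nj_from_distances(d)
  rooted <- ape::root(main, outgroup = outgroup_id, resolve.root = TRUE)

  n_sites <- nrow(gm$sites)
  set.seed(stage_seed(seed, "bootstrap"))
  boots <- vector("list", n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n_sites, n_sites, replace = TRUE)
    gb <- gm
    gb$calls <- gm$calls[idx, , drop = FALSE]
    boots[[b]] <- nj_from_distances(p_distance(gb))
  }
  counts <- ape::prop.clades(rooted, boots, rooted = FALSE)
  support <- round(100 * counts / n_bootstrap)
  support[is.na(support)] <- 0
  rooted$node.label <- as.character(support)
  out <- list(tree = rooted, n_bootstrap = n_bootstrap,
              newick = ape::write.tree(rooted))
  class(out) <- "snp_tree"
  out
}

#' @export
print.snp_tree <- function(x, ...) {
  cat(sprintf("Rooted NJ tree over %d accessions (%d bootstrap replicates)\n",
              length(x$tree$tip.label), x$n_bootstrap))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Bootstrap support for a clade
#'
#' @param snp_tree A [build_tree()] result.
#' @param tips Character vector of accession ids forming the clade.
#' @return Support percentage, or `NA` if the clade is not in the tree.
#' @export
clade_support <- function(snp_tree, tips) {
  tree <- snp_tree$tree
  if (!all(tips %in% tree$tip.label)) return(NA_real_)
  node <- tryCatch(ape::getMRCA(tree, tips), error = function(e) NULL)
  if (is.null(node)) return(NA_real_)
  desc <- ape::extract.clade(tree, node)$tip.label
  if (!setequal(desc, tips)) return(NA_real_)
  as.numeric(tree$node.label[node - length(tree$tip.label)])
}

#' Average retained sites per chromosome
#'
#' The per-chromosome average reported alongside pruned SNP panels, rounded
#' half-up to the nearest integer.
#'
#' @param n_sites Total retained sites.
#' @param n_chromosomes Number of chromosomes (7 for a diploid oat set).
#' @return Integer average.
#' @examples
#' mean_sites_per_chromosome(11530)  # 1647
#' mean_sites_per_chromosome(7221)   # 1032
#' @export
mean_sites_per_chromosome <- function(n_sites, n_chromosomes = 7L) {
  as.integer(round_half_up(n_sites / n_chromosomes))
}
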