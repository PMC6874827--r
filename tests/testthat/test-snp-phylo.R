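gm_from_calls <- function(calls, pos = NULL, chrom = NULL) {
  n_sites <- nrow(calls)
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("s%02d", seq_len(ncol(calls)))
  if (is.null(pos)) pos <- seq_len(n_sites) * 1000L
  if (is.null(chrom)) chrom <- rep("A1", n_sites)
  genotype_matrix(colnames(calls),
                  data.frame(chromosome = chrom, position = pos,
                             ref = "A", alt = "G", stringsAsFactors = FALSE),
                  calls)
}

acc20 <- sprintf("s%02d", 1:20)

test_that("site filters apply the missing/het/MAF rules in order", {
  calls <- rbind(
    c(NA, rep(0L, 19)),                    # 1 missing -> removed_missing
    c(1L, rep(0L, 9), rep(2L, 10)),        # 1 het (5%) -> kept
    c(1L, 1L, rep(0L, 8), rep(2L, 10)),    # 2 het (10%) -> removed_het
    c(2L, rep(0L, 19)),                    # MAF 0.05 -> removed_maf
    c(2L, 2L, rep(0L, 18)),                # MAF 0.10 -> kept
    c(NA, 1L, 1L, rep(0L, 17))             # missing wins over het
  )
  colnames(calls) <- acc20
  res <- filter_sites(gm_from_calls(calls))
  r <- res$report
  expect_equal(r$input_sites, 6)
  expect_equal(r$removed_missing, 2)
  expect_equal(r$removed_het, 1)
  expect_equal(r$removed_maf, 1)
  expect_equal(r$output_sites, 2)
  expect_equal(r$input_sites,
               r$output_sites + r$removed_missing + r$removed_het +
                 r$removed_maf + r$removed_unplaced)
  # retained sites satisfy all thresholds site-wise
  kept <- res$genotypes$calls
  expect_true(all(!is.na(kept)))
  expect_true(all(rowMeans(kept == 1L) <= 0.05))
  f <- rowSums(kept) / (2 * ncol(kept))
  expect_true(all(pmin(f, 1 - f) >= 0.1))
})

test_that("LD pruning drops linked and monomorphic sites but spares distant ones", {
  x <- c(rep(2L, 10), rep(0L, 10))
  y <- c(rep(0L, 10), rep(2L, 10))
  # duplicated signal 1 bp apart: r^2 = 1, second copy dropped
  calls <- rbind(x, x)
  colnames(calls) <- acc20
  res <- ld_prune(gm_from_calls(calls, pos = c(1000L, 1001L)))
  expect_equal(nrow(res$genotypes$sites), 1)
  expect_equal(res$report$reason, "linked")

  # same signal but 600,001 bp apart: outside the window, both kept
  res2 <- ld_prune(gm_from_calls(rbind(x, x), pos = c(1000L, 601001L)))
  expect_equal(nrow(res2$genotypes$sites), 2)

  # r^2 = 0.04 pair within the window: both kept
  a10 <- sprintf("t%02d", 1:10)
  pA <- c(2L, 2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L)
  pB <- c(2L, 2L, 2L, 0L, 0L, 2L, 2L, 0L, 0L, 0L)
  calls3 <- rbind(pA, pB)
  colnames(calls3) <- a10
  expect_equal(cor(pA, pB)^2, 0.04, tolerance = 1e-12)
  res3 <- ld_prune(gm_from_calls(calls3, pos = c(1000L, 2000L)))
  expect_equal(nrow(res3$genotypes$sites), 2)

  # monomorphic sites report their own reason
  calls4 <- rbind(x, rep(0L, 20))
  colnames(calls4) <- acc20
  res4 <- ld_prune(gm_from_calls(calls4, pos = c(1000L, 700000L)))
  expect_true("monomorphic" %in% res4$report$reason)

  expect_error(ld_prune(gm_from_calls(matrix(NA_integer_, 1, 20,
                                             dimnames = list(NULL, acc20)))),
               "missing")
})

test_that("no retained pair within the window exceeds the r2 threshold", {
  g <- simulate_genotypes(small_cfg(seed = 13, chromosome_length = 2e6))
  filt <- filter_sites(g$genotypes)
  pruned <- ld_prune(filt$genotypes)$genotypes
  expect_gt(nrow(pruned$sites), 3)
  dosage <- pruned$calls / 2
  for (ch in unique(pruned$sites$chromosome)) {
    idx <- which(pruned$sites$chromosome == ch)
    for (ii in seq_along(idx)) {
      for (jj in seq_len(ii - 1L)) {
        i <- idx[ii]; j <- idx[jj]
        if (pruned$sites$position[i] - pruned$sites$position[j] <= 500000) {
          r2 <- suppressWarnings(cor(dosage[i, ], dosage[j, ]))^2
          expect_lte(r2, 0.1)
        }
      }
    }
  }
})

test_that("neighbor joining reproduces an additive metric exactly", {
  # tree ((A,B),(C,D)) with tip branches 1,1,2,2 and internal branch 3
  d <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 4,
                6, 6, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- nj_from_distances(d)
  # brute-force oracle: the induced tree metric must match the input
  cd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(cd, d, tolerance = 1e-9)
  expect_true(ape::is.monophyletic(ape::root(tree, "A", resolve.root = TRUE),
                                   c("C", "D")))

  # three taxa: the unique unrooted topology, metric preserved
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_from_distances(d3)
  expect_equal(ape::cophenetic.phylo(t3)[rownames(d3), colnames(d3)], d3,
               tolerance = 1e-9)
})

test_that("bootstrapped trees recover planted clades and root on the outgroup", {
  g <- simulate_genotypes(small_cfg(seed = 17))
  filt <- filter_sites(g$genotypes)$genotypes
  tree <- build_tree(filt, outgroup_id = "OUT1", n_bootstrap = 200, seed = 3)
  cs <- small_cfg()$clade_structure
  expect_gte(clade_support(tree, cs$clades$cladeA), 90)
  expect_gte(clade_support(tree, cs$clades$cladeC), 90)
  # outgroup sits at the root
  expect_true(ape::is.rooted(tree$tree))
  expect_true(ape::is.monophyletic(tree$tree,
                                   setdiff(tree$tree$tip.label, "OUT1")))

  expect_error(build_tree(filt, outgroup_id = "nope"), "outgroup")
  two <- genotype_matrix(c("a", "b"),
                         data.frame(chromosome = "A1", position = 1L,
                                    ref = "A", alt = "G"),
                         matrix(c(0L, 2L), 1, 2))
  expect_error(build_tree(two, "a"), "3 accessions")
})

test_that("bootstrap support is invariant under accession order", {
  g <- simulate_genotypes(small_cfg(seed = 19))
  filt <- filter_sites(g$genotypes)$genotypes
  cs <- small_cfg()$clade_structure
  t1 <- build_tree(filt, "OUT1", n_bootstrap = 100, seed = 5)
  perm <- sample(seq_along(filt$accessions))
  gm2 <- genotype_matrix(filt$accessions[perm], filt$sites,
                         filt$calls[, perm, drop = FALSE])
  t2 <- build_tree(gm2, "OUT1", n_bootstrap = 100, seed = 5)
  expect_equal(clade_support(t1, cs$clades$cladeA),
               clade_support(t2, cs$clades$cladeA))
  expect_equal(clade_support(t1, cs$clades$cladeC),
               clade_support(t2, cs$clades$cladeC))
})

test_that("per-chromosome site averages match the published bookkeeping", {
  expect_equal(mean_sites_per_chromosome(11530), 1647L)
  expect_equal(mean_sites_per_chromosome(7221), 1032L)
})
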