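test_that("truth set generation is deterministic and internally consistent", {
  cfg <- small_cfg(seed = 7)
  b1 <- SMALL_BUNDLE
  b2 <- simulate_truth_set(cfg)
  expect_identical(as.character(b1$genomes$A), as.character(b2$genomes$A))
  expect_identical(as.character(b1$genomes$C), as.character(b2$genomes$C))
  expect_identical(b1$truth_arrays, b2$truth_arrays)

  # every truth array slice tandem-decomposes into its recorded monomer
  for (i in seq_len(nrow(b1$truth_arrays))) {
    rec <- b1$truth_arrays[i, ]
    g <- substr(rec$chromosome, 1, 1)
    slice <- substr(as.character(b1$genomes[[g]][[rec$chromosome]]),
                    rec$start, rec$end)
    len <- nchar(rec$monomer)
    expect_equal(nchar(slice) %% len, 0)
    units <- substring(slice, seq(1, nchar(slice), len),
                       seq(len, nchar(slice), len))
    expect_true(all(units == units[1]))
    expect_identical(canonical_monomer(units[1]),
                     canonical_monomer(rec$monomer))
  }

  # gene intervals are non-overlapping per chromosome
  ann <- b1$annotations$A
  for (ch in unique(ann$chromosome)) {
    a <- ann[ann$chromosome == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1) expect_true(all(a$start[-1] > a$end[-nrow(a)]))
  }
})

test_that("degenerate configurations behave as documented", {
  cfg <- small_cfg(seed = 2, n_genes = 0)
  b <- simulate_truth_set(cfg)
  expect_equal(nrow(b$annotations$A), 0)

  expect_error(simulate_truth_set(small_cfg(chromosome_length = 5e4)),
               "too short")

  pan <- simulate_linkage_panel(SMALL_BUNDLE,
                                small_cfg(n_markers_per_lg = 0))
  expect_equal(nrow(pan$markers), 0)
})

test_that("linkage panel markers sit at their truth coordinates with a monotone map", {
  pan <- simulate_linkage_panel(SMALL_BUNDLE)
  g <- SMALL_BUNDLE$genomes$A
  for (i in seq_len(nrow(pan$truth))) {
    tr <- pan$truth[i, ]
    seq <- substr(as.character(g[[tr$chromosome]]), tr$position + 1,
                  tr$position + nchar(pan$markers$sequence[i]))
    emitted <- pan$markers$sequence[pan$markers$marker_id == tr$marker_id]
    if (tr$strand == "+") expect_identical(emitted, seq)
    else expect_identical(emitted,
                          as.character(Biostrings::reverseComplement(
                            Biostrings::DNAString(seq))))
  }
  # per LG, cM is a strictly monotone transform of physical position
  merged <- merge(pan$markers, pan$truth[, c("marker_id", "position")],
                  by = "marker_id")
  for (lg in unique(merged$lg)) {
    m <- merged[merged$lg == lg, ]
    expect_equal(abs(cor(m$cM, m$position, method = "spearman")), 1)
  }
})

test_that("hexaploid panel encodes subgenome divergence and translocations", {
  cfg <- small_cfg(seed = 9)
  hex <- simulate_hexaploid_panel(cfg, SMALL_BUNDLE)
  expect_equal(nrow(hex$lg_truth), 9)
  # without a translocation every LG is uniform in truth subgenome
  per_lg <- tapply(hex$truth$subgenome, hex$truth$lg,
                   function(x) length(unique(x)))
  expect_true(all(per_lg == 1))

  # D tags match the A reference perfectly more often than C tags do
  ga <- SMALL_BUNDLE$genomes$A
  perfect_vs_A <- function(sub) {
    tr <- hex$truth[hex$truth$subgenome == sub, ]
    tags <- hex$markers$sequence[match(tr$marker_id, hex$markers$marker_id)]
    hits <- vapply(tags, function(tg) {
      sum(Biostrings::vcountPattern(tg, ga)) +
        sum(Biostrings::vcountPattern(as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(tg))), ga))
    }, numeric(1))
    mean(hits > 0)
  }
  expect_gt(perfect_vs_A("D"), perfect_vs_A("C"))

  # planted breakpoint: truth labels switch exactly at the first marker
  # beyond the breakpoint
  cfg_t <- small_cfg(seed = 9, translocation_spec = list(
    lg_subgenome = "A", lg_chromosome = 2, breakpoint_cm = 40,
    donor_subgenome = "C", donor_chromosome = 1))
  hex_t <- simulate_hexaploid_panel(cfg_t, SMALL_BUNDLE)
  lg <- hex_t$lg_truth$lg[hex_t$lg_truth$translocated]
  expect_length(lg, 1)
  tr <- hex_t$truth[hex_t$truth$lg == lg, ]
  tr <- tr[order(tr$cM), ]
  expect_true(all(tr$subgenome[tr$cM <= 40] == "A"))
  expect_true(all(tr$subgenome[tr$cM > 40] == "C"))
  expect_error(simulate_hexaploid_panel(
    small_cfg(translocation_spec = list(lg_subgenome = "A",
                                        lg_chromosome = 1,
                                        breakpoint_cm = 500,
                                        donor_subgenome = "C",
                                        donor_chromosome = 1)),
    SMALL_BUNDLE), "breakpoint")
})

test_that("Ks pair truth bookkeeping matches recomputation", {
  cfg <- small_cfg(seed = 4, n_gene_pairs = 40)
  kp <- simulate_ks_pairs(cfg)
  expect_equal(nrow(kp$pairs), 40)
  ks <- vapply(seq_len(40), function(i)
    ks_ng86(kp$pairs$seq1[i], kp$pairs$seq2[i])$ks, numeric(1))
  expect_equal(ks, kp$truth$ks_applied, tolerance = 1e-12)

  kp0 <- simulate_ks_pairs(small_cfg(ks_peak = 0, n_gene_pairs = 5))
  expect_identical(kp0$pairs$seq1, kp0$pairs$seq2)
  expect_true(all(kp0$truth$ks_applied == 0))

  kpe <- simulate_ks_pairs(small_cfg(n_gene_pairs = 0))
  expect_equal(nrow(kpe$pairs), 0)
})

test_that("genotype panel segregates along the truth tree", {
  cfg <- small_cfg(seed = 6)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$genotypes$calls, g2$genotypes$calls)
  expect_equal(sum(is.na(g1$genotypes$calls)), 0)
  expect_equal(sum(g1$genotypes$calls == 1L), 0)

  # same-clade p-distances are smaller than between-clade
  cs <- cfg$clade_structure
  d <- as.matrix(avenacomp:::p_distance(g1$genotypes))
  a <- cs$clades$cladeA
  c_ <- cs$clades$cladeC
  within <- c(d[a, a][upper.tri(diag(length(a)))],
              d[c_, c_][upper.tri(diag(length(c_)))])
  between <- as.vector(d[a, c_])
  expect_lt(max(within), min(between))

  # contamination rates inject het and missing calls for filter testing
  gc <- simulate_genotypes(small_cfg(seed = 6, het_rate = 0.05,
                                     missing_rate = 0.02))
  expect_gt(sum(gc$genotypes$calls == 1L, na.rm = TRUE), 0)
  expect_gt(sum(is.na(gc$genotypes$calls)), 0)

  expect_error(simulate_genotypes(small_cfg(n_sites = 10)), "branches")
})
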