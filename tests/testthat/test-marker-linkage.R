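test_that("placement demands a single perfect hit over both strands", {
  set.seed(21)
  g <- c(chr1 = random_dna(400), chr2 = random_dna(400))
  fwd <- substr(g[["chr1"]], 101, 120)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g[["chr2"]], 51, 70))))
  mut <- fwd
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  dup <- substr(g[["chr1"]], 201, 220)
  g[["chr2"]] <- paste0(g[["chr2"]], dup)  # second copy genome-wide

  mk <- data.frame(marker_id = c("m_fwd", "m_rc", "m_miss", "m_dup"),
                   sequence = c(fwd, rc, mut, dup),
                   stringsAsFactors = FALSE)
  res <- place_markers(mk, g)
  pl <- res$placements
  expect_equal(pl$chromosome[pl$marker_id == "m_fwd"], "chr1")
  expect_equal(pl$position[pl$marker_id == "m_fwd"], 100)  # 0-based
  expect_equal(pl$strand[pl$marker_id == "m_fwd"], "+")
  expect_equal(pl$chromosome[pl$marker_id == "m_rc"], "chr2")
  expect_equal(pl$position[pl$marker_id == "m_rc"], 50)
  expect_equal(pl$strand[pl$marker_id == "m_rc"], "-")
  rj <- res$rejects
  expect_equal(rj$reason[rj$marker_id == "m_miss"], "no_hit")
  expect_equal(rj$reason[rj$marker_id == "m_dup"], "multi_hit")

  empty <- place_markers(mk[0, ], g)
  expect_equal(nrow(empty$placements), 0)
  expect_equal(nrow(empty$rejects), 0)
})

test_that("plurality assignment reproduces printed-table arithmetic", {
  # a scaffold with 846 placements, 838 from the plurality LG
  mk <- data.frame(marker_id = sprintf("m%04d", 1:846),
                   lg = c(rep("LG7", 838), rep("LG3", 8)),
                   stringsAsFactors = FALSE)
  pl <- data.frame(marker_id = mk$marker_id, chromosome = "scf1",
                   position = seq_len(846), strand = "+",
                   stringsAsFactors = FALSE)
  tab <- assign_linkage_groups(pl, mk)
  expect_equal(tab$plurality_lg, "LG7")
  expect_equal(tab$mismatch_count, 8)
  expect_equal(tab$match_pct, 99.1)
  expect_equal(tab$mismatch_pct, 0.9)

  # single-LG scaffold and order invariance
  one <- assign_linkage_groups(pl[1:838, ], mk)
  expect_equal(one$match_pct, 100.0)
  shuf <- assign_linkage_groups(pl[sample(846), ], mk)
  expect_equal(shuf$match_pct, tab$match_pct)

  # exact tie breaks toward the lexicographically smallest LG id
  mk2 <- data.frame(marker_id = c("a", "b"), lg = c("LGB", "LGA"),
                    stringsAsFactors = FALSE)
  pl2 <- data.frame(marker_id = c("a", "b"), chromosome = "s",
                    position = 1:2, strand = "+", stringsAsFactors = FALSE)
  t2 <- assign_linkage_groups(pl2, mk2)
  expect_equal(t2$plurality_lg, "LGA")
  expect_true(t2$tie)
})

test_that("merge plans order scaffolds by cM span and orient by rank correlation", {
  # two scaffolds covering 0-48 and 49-116 cM on one LG
  mk <- data.frame(marker_id = sprintf("m%02d", 1:12),
                   lg = "LG2",
                   cM = c(0, 10, 20, 30, 40, 48, 49, 60, 80, 95, 110, 116),
                   stringsAsFactors = FALSE)
  pl <- data.frame(marker_id = mk$marker_id,
                   chromosome = rep(c("scfA", "scfB"), each = 6),
                   position = c(1:6 * 100, 6:1 * 100),  # scfB anticorrelated
                   strand = "+", stringsAsFactors = FALSE)
  tab <- assign_linkage_groups(pl, mk)
  plan <- infer_merge_plan(tab, pl, mk)
  p <- plan$plans[["LG2"]]
  expect_equal(p$scaffold, c("scfA", "scfB"))
  expect_equal(p$orientation, c("+", "-"))
  expect_equal(p$cm_min, c(0, 49))
  expect_false(any(p$low_evidence))

  # a single scaffold on an LG yields no plan entry
  tab1 <- assign_linkage_groups(pl[1:6, ], mk)
  expect_length(infer_merge_plan(tab1, pl[1:6, ], mk)$plans, 0)

  # overlapping spans conflict
  mk_bad <- mk
  mk_bad$cM[7] <- 20
  expect_error(infer_merge_plan(assign_linkage_groups(pl, mk_bad), pl, mk_bad),
               "conflict")
})

test_that("merging joins arms with a 1000-N spacer and honours orientation", {
  set.seed(31)
  a <- random_dna(100)
  b <- random_dna(200)
  plan <- structure(list(gap_n = 1000L, plans = list(
    LG1 = data.frame(scaffold = c("s1", "s2"), orientation = c("+", "-"),
                     cm_min = c(0, 50), cm_max = c(49, 100), rho = c(1, -1),
                     low_evidence = FALSE, stringsAsFactors = FALSE))),
    class = "merge_plan")
  merged <- apply_merge(c(s1 = a, s2 = b), plan)
  out <- as.character(merged[["LG1"]])
  expect_equal(nchar(out), 1300)
  expect_equal(substr(out, 1, 100), a)
  expect_equal(substr(out, 101, 1100), strrep("N", 1000))
  expect_equal(substr(out, 1101, 1300),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(b))))

  empty_plan <- structure(list(gap_n = 1000L, plans = list()),
                          class = "merge_plan")
  same <- apply_merge(c(s1 = a, s2 = b), empty_plan)
  expect_equal(as.character(same), c(s1 = a, s2 = b))

  bad <- plan
  bad$plans$LG1$scaffold[2] <- "nope"
  expect_error(apply_merge(c(s1 = a, s2 = b), bad), "unknown scaffold")
})

test_that("interval queries use >= 1 bp overlap on closed coordinates", {
  ann <- data.frame(chromosome = "A1",
                    start = c(100, 500, 900), end = c(199, 599, 999),
                    strand = "+", gene_id = c("g1", "g2", "g3"),
                    stringsAsFactors = FALSE)
  hit <- genes_in_interval(ann, "A1", 150, 550)
  expect_equal(hit$gene_id, c("g1", "g2"))  # g1 straddles the query start
  expect_equal(nrow(genes_in_interval(ann, "A1", 200, 499)), 0)
  expect_equal(genes_in_interval(ann, "A1", 199, 199)$gene_id, "g1")
  expect_error(genes_in_interval(ann, "A9", 1, 10), "unknown chromosome")
})

test_that("the anchoring chain recovers a split chromosome from a clean panel", {
  b <- SMALL_BUNDLE
  sc <- split_chromosome_for_anchoring(b)
  pan <- simulate_linkage_panel(b)
  pl <- place_markers(pan$markers, sc$sequences)
  expect_equal(nrow(pl$rejects), 0)

  tab <- assign_linkage_groups(pl, pan$markers)
  # every scaffold is assigned to the LG of its source chromosome
  truth_lg <- c(scaffold_A1_arm1 = "LG1", scaffold_A1_arm2 = "LG1",
                scaffold_A2 = "LG2", scaffold_A3 = "LG3")
  expect_equal(unname(truth_lg[tab$scaffold]), tab$plurality_lg)
  expect_true(all(tab$match_pct == 100))

  plan <- infer_merge_plan(tab, pl, pan$markers)
  merged <- apply_merge(sc$sequences, plan)
  truth <- as.character(b$genomes$A[["A1"]])
  cut <- as.integer(b$centromere_bp[["A1"]])
  expected <- paste0(substr(truth, 1, cut), strrep("N", 1000),
                     substr(truth, cut + 1, nchar(truth)))
  expect_identical(as.character(merged[["LG1"]]), expected)
})
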