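test_that("monomer canonicalization is idempotent and strand-symmetric", {
  set.seed(41)
  for (i in 1:25) {
    m <- random_dna(sample(2:40, 1))
    can <- canonical_monomer(m)
    expect_identical(canonical_monomer(can), can)
    expect_identical(canonical_monomer(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))),
      can)
    # any rotation maps to the same canonical form
    k <- sample(nchar(m), 1)
    rot <- paste0(substr(m, k, nchar(m)), substr(m, 1, k - 1))
    expect_identical(canonical_monomer(rot), can)
  }
})

test_that("planted arrays are discovered, ranked by array mass, and bounded", {
  set.seed(43)
  mono <- random_dna(159)
  g <- c(chr1 = paste0(random_dna(20000), strrep(mono, 50), random_dna(5000)))
  found <- find_tandem_monomers(g)
  expect_gte(nrow(found), 1)
  expect_identical(found$monomer[1], canonical_monomer(mono))
  expect_equal(found$total_copies[1], 50)
  sp <- attr(found, "spans")
  # boundaries may extend a few bp where background coincidentally matches
  # one period downstream
  expect_lte(abs(sp$start[1] - 20001), 8)
  expect_lte(abs(sp$end[1] - (20000 + 50 * 159)), 8)

  # array-free random sequence yields nothing
  empty <- find_tandem_monomers(c(chr1 = random_dna(30000)))
  expect_equal(nrow(empty), 0)

  # two arrays of the same monomer rank by combined copies; a bigger array
  # of another monomer outranks a smaller one
  m2 <- random_dna(100)
  g2 <- c(chr1 = paste0(random_dna(5000), strrep(mono, 100), random_dna(3000),
                        strrep(m2, 10), random_dna(3000)))
  f2 <- find_tandem_monomers(g2)
  expect_identical(f2$monomer[1], canonical_monomer(mono))
  expect_gt(f2$total_bp[1], f2$total_bp[nrow(f2)])

  expect_error(find_tandem_monomers(g, min_len = 100, max_len = 50),
               "min_len")
})

test_that("density tracks count non-overlapping hits in start windows", {
  set.seed(47)
  mono <- random_dna(60)
  none <- density_track(c(c1 = random_dna(5000)), mono, window_bp = 1000)
  expect_true(all(none$count == 0))
  expect_equal(nrow(none), 5)

  # ten copies planted inside the fourth window (0-based index 3)
  g <- paste0(random_dna(3100), strrep(mono, 10), random_dna(1300))
  tr <- density_track(c(c1 = g), mono, window_bp = 1000)
  expect_equal(tr$count[tr$window == 3], 10)
  expect_equal(sum(tr$count), 10)

  # a copy starting on a window's last base belongs to that window
  g2 <- paste0(random_dna(999), mono, random_dna(500))
  tr2 <- density_track(c(c1 = g2), mono, window_bp = 1000)
  expect_equal(tr2$count[tr2$window == 0], 1)

  # reverse-complement occurrences count too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mono)))
  tr3 <- density_track(c(c1 = paste0(random_dna(100), rc, random_dna(100))),
                       mono, window_bp = 1000)
  expect_equal(sum(tr3$count), 1)

  expect_error(density_track(c(c1 = g), mono, window_bp = 10), "window_bp")
})

test_that("centromere centroids, morphology classes and telomere status follow the rules", {
  mk_track <- function(counts, window = 1000) {
    n <- length(counts)
    data.frame(chromosome = "c1", window = seq_len(n) - 1L,
               start = (seq_len(n) - 1L) * window,
               end = seq_len(n) * window, count = counts,
               stringsAsFactors = FALSE)
  }
  lens <- c(c1 = 12000)
  # centromere mass centred in the middle -> metacentric, ratio 1
  cen_mid <- mk_track(c(0, 0, 0, 0, 0, 10, 10, 0, 0, 0, 0, 0))
  empty_tel <- mk_track(rep(0, 12))
  call <- call_centromeres_telomeres(cen_mid, empty_tel, lens)
  expect_equal(call$centromeres$midpoint, 6000)
  expect_equal(call$centromeres$arm_ratio, 1.0)
  expect_equal(call$centromeres$morphology, "metacentric")

  # centromere at 1/6 of the length -> arm ratio 5, sub-telocentric
  cen_sixth <- mk_track(c(0, 10, 10, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  call2 <- call_centromeres_telomeres(cen_sixth, empty_tel, lens)
  expect_equal(call2$centromeres$arm_ratio, 5.0)
  expect_equal(call2$centromeres$morphology, "sub-telocentric")

  # morphology is monotone in arm ratio
  ratios <- c(1, 1.69, 1.7, 3, 3.01, 7, 7.01, 20)
  morphs <- vapply(ratios, function(r) {
    cen <- mk_track(c(10, rep(0, 11)))
    L <- c(c1 = 500 * (1 + r))
    call_centromeres_telomeres(cen, mk_track(rep(0, 12)), L)$centromeres$morphology
  }, character(1))
  lvl <- c(metacentric = 1, submetacentric = 2, "sub-telocentric" = 3,
           telocentric = 4)
  expect_true(all(diff(lvl[morphs]) >= 0))

  # telomere cluster at mid-chromosome is interstitial; at the end, terminal
  tel <- mk_track(c(1, 0, 0, 0, 0, 5, 5, 0, 0, 0, 0, 1))
  call3 <- call_centromeres_telomeres(cen_mid, tel, lens)
  expect_equal(call3$telomeres$status, c("terminal", "interstitial", "terminal"))

  # an all-zero centromeric track yields a flagged no-call
  call4 <- call_centromeres_telomeres(empty_tel, empty_tel, lens)
  expect_equal(call4$centromeres$morphology, "no_call")
  expect_true(is.na(call4$centromeres$midpoint))
})

test_that("SSR scanning reports canonical primitive motifs above copy minima", {
  s <- scan_ssrs(c(c1 = "ATATATATATAT"))
  expect_equal(nrow(s), 1)
  expect_equal(s$motif, "AT")
  expect_equal(s$copies, 6)

  expect_equal(nrow(scan_ssrs(c(c1 = "GGATATATATGG"))), 0)  # (AT)5 < 6 copies

  s2 <- scan_ssrs(c(c1 = paste0("GGG", strrep("TA", 7), "GGG",
                                strrep("AT", 7), "CCC")))
  expect_equal(nrow(s2), 2)
  expect_equal(unique(s2$motif), "AT")

  # trinucleotide and non-primitive guard: (ACG)5 found, (ATAT) never
  # reported as a tetramer
  s3 <- scan_ssrs(c(c1 = paste0("TT", strrep("ACG", 5), "TT")))
  expect_equal(s3$unit_length, 3)
  expect_equal(s3$copies, 5)
  s4 <- scan_ssrs(c(c1 = strrep("AT", 8)), unit_lengths = 4L,
                  min_copies = c("4" = 2L))
  expect_equal(nrow(s4), 0)
})

test_that("bundle-wide discovery pins the planted centromeric satellite", {
  b <- SMALL_BUNDLE
  found <- find_tandem_monomers(b$genomes$A)
  expect_identical(found$monomer[1],
                   canonical_monomer(b$monomers$A[["centromere"]]))
  tr <- density_track(b$genomes$A, b$monomers$A[["centromere"]],
                      window_bp = 25000, max_mismatch_fraction = 0)
  tel <- density_track(b$genomes$A, b$monomers$A[["telomere"]],
                       window_bp = 25000, max_mismatch_fraction = 0)
  lens <- setNames(Biostrings::width(b$genomes$A), names(b$genomes$A))
  calls <- call_centromeres_telomeres(tr, tel, lens)
  truth <- b$truth_arrays[b$truth_arrays$genome == "A" &
                            b$truth_arrays$role == "centromere", ]
  for (i in seq_len(nrow(truth))) {
    got <- calls$centromeres$midpoint[
      calls$centromeres$chromosome == truth$chromosome[i]]
    expect_lt(abs(got - (truth$start[i] + truth$end[i]) / 2), 25000)
  }
  expect_true(all(calls$telomeres$status == "terminal"))
})
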