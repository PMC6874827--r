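make_hex_fixture <- function(seed = 9, ...) {
  cfg <- small_cfg(seed = seed, ...)
  hex <- simulate_hexaploid_panel(cfg, SMALL_BUNDLE)
  pl_A <- place_markers(hex$markers, SMALL_BUNDLE$genomes$A)
  pl_C <- place_markers(hex$markers, SMALL_BUNDLE$genomes$C)
  list(cfg = cfg, hex = hex, pl_A = pl_A, pl_C = pl_C)
}

FIX_CLEAN <- make_hex_fixture(seed = 9)
FIX_TRANS <- make_hex_fixture(seed = 9, translocation_spec = list(
  lg_subgenome = "A", lg_chromosome = 2, breakpoint_cm = 60,
  donor_subgenome = "C", donor_chromosome = 3))

test_that("contingency tallies equal the generator truth and printed-table fractions", {
  f <- FIX_CLEAN
  m <- build_contingency(f$pl_A, f$hex$markers, "A")
  truth <- merge(f$pl_A$placements, f$hex$truth, by = "marker_id")
  truth_tab <- table(truth$lg, truth$chromosome.x)
  for (lg in rownames(truth_tab)) {
    for (ch in colnames(truth_tab)) {
      got <- if (lg %in% rownames(m$counts) && ch %in% colnames(m$counts))
        m$counts[lg, ch] else 0L
      expect_equal(got, unname(truth_tab[lg, ch]))
    }
  }
  # fraction arithmetic at printed precision: 153 of 322 is 48%
  expect_equal(round_half_up(100 * 153 / 322), 48)

  empty <- build_contingency(f$pl_A$placements[0, ], f$hex$markers, "A")
  expect_equal(length(empty$counts), 0)

  # markers absent from the map are rejected with a report
  pl2 <- f$pl_A$placements
  pl2$marker_id[1] <- "unmapped_tag"
  m2 <- build_contingency(pl2, f$hex$markers, "A")
  expect_equal(m2$rejects, "unmapped_tag")
})

test_that("subgenome labels are recovered on a clean panel", {
  f <- FIX_CLEAN
  asn <- call_subgenomes(build_contingency(f$pl_A, f$hex$markers, "A"),
                         build_contingency(f$pl_C, f$hex$markers, "C"))
  truth <- f$hex$lg_truth
  got <- asn$label[match(truth$lg, asn$lg)]
  expect_equal(got, truth$subgenome)
  # homoeolog pairing is symmetric and shares the primary A chromosome
  for (i in seq_len(nrow(asn))) {
    p <- asn$homoeolog_partner[i]
    if (!is.na(p)) {
      j <- match(p, asn$lg)
      expect_equal(asn$homoeolog_partner[j], asn$lg[i])
      expect_equal(asn$primary_chr_A[i], asn$primary_chr_A[j])
    }
  }
  # row fractions over chromosomes sum to one for placed markers
  m <- build_contingency(f$pl_A, f$hex$markers, "A")
  fr <- m$counts / m$row_totals
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)))
})

test_that("a planted A/C translocation earns a slash label and a breakpoint call", {
  f <- FIX_TRANS
  mat_A <- build_contingency(f$pl_A, f$hex$markers, "A")
  mat_C <- build_contingency(f$pl_C, f$hex$markers, "C")
  asn <- call_subgenomes(mat_A, mat_C)
  lg <- f$hex$lg_truth$lg[f$hex$lg_truth$translocated]
  lab <- asn$label[asn$lg == lg]
  expect_match(lab, "/")
  expect_setequal(strsplit(lab, "/")[[1]], c("A", "C"))
  # the untranslocated LGs keep clean labels
  clean <- f$hex$lg_truth[!f$hex$lg_truth$translocated, ]
  expect_equal(asn$label[match(clean$lg, asn$lg)], clean$subgenome)

  calls <- detect_translocations(f$pl_A, f$pl_C, f$hex$markers)
  calls <- calls[calls$lg == lg, ]
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "intergenomic")
  expect_lte(calls$breakpoint_lo, 60)
  expect_gte(calls$breakpoint_hi, 60)
  expect_equal(calls$chrom_2, "C3")
})

test_that("empty and degenerate inputs stay unassigned or silent", {
  f <- FIX_CLEAN
  e <- build_contingency(f$pl_A$placements[0, ], f$hex$markers, "A")
  asn <- call_subgenomes(e, e)
  expect_equal(nrow(asn), 0)
  expect_equal(nrow(detect_translocations(f$pl_A$placements[0, ],
                                          f$pl_C$placements[0, ],
                                          f$hex$markers)), 0)
  # uniform LGs yield no translocation calls on the clean panel
  calls <- detect_translocations(f$pl_A, f$pl_C, f$hex$markers)
  expect_equal(nrow(calls), 0)
})

test_that("stray markers below the segment minimum never trigger a call", {
  mk <- data.frame(marker_id = sprintf("m%02d", 1:20), lg = "MrgX",
                   cM = seq(1, 20), stringsAsFactors = FALSE)
  plA <- data.frame(marker_id = mk$marker_id[c(1:8, 11:20)],
                    chromosome = "A2", position = 1:18, strand = "+",
                    stringsAsFactors = FALSE)
  # two isolated strays on another chromosome
  plC <- data.frame(marker_id = mk$marker_id[9:10], chromosome = "C7",
                    position = 1:2, strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_translocations(plA, plC, mk)), 0)

  # a run of >= 5 on the other reference is a call with a tight breakpoint
  plA2 <- data.frame(marker_id = mk$marker_id[1:12], chromosome = "A2",
                     position = 1:12, strand = "+", stringsAsFactors = FALSE)
  plC2 <- data.frame(marker_id = mk$marker_id[13:20], chromosome = "C7",
                     position = 1:8, strand = "+", stringsAsFactors = FALSE)
  calls <- detect_translocations(plA2, plC2, mk)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$breakpoint_lo, 12)
  expect_equal(calls$breakpoint_hi, 13)
  expect_equal(calls$kind, "intergenomic")
})
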