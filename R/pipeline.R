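# End-to-end orchestration: simulate -> stats -> anchoring -> subgenome ->
# synteny -> Ks clock -> SNP tree -> repeat landscape, with a file manifest
# and deterministic outputs under a single seed.

pipeline_defaults <- function() {
  list(
    clock = list(calibration_ks = 0.3, calibration_age = 44.3e6,
                 generic_rate = EUKARYOTIC_SYNONYMOUS_RATE),
    snp = list(max_het_fraction = 0.05, min_maf = 0.1,
               window_bp = 500000, r2_threshold = 0.1,
               n_bootstrap = 200),
    repeats = list(window_bp = 100000, max_mismatch_fraction = 0,
                   min_len = 50, max_len = 2000, min_copies = 5),
    subgenome = list(c_ratio = 2, slash_ratio = 0.5, min_segment_markers = 5),
    synteny = list(genes_per_block = 5),
    merge = list(gap_n = 1000, min_markers = 3)
  )
}

#' Pipeline configuration
#'
#' Builds the configuration for [run_pipeline()]. Per-stage parameter blocks
#' default to each module's own defaults; unknown stage or parameter names
#' are rejected.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; per-stage seeds are derived by stable hashing of
#'   stage names, so adding a stage never perturbs another stage's stream.
#' @param sim A [sim_config()] describing the simulated inputs (its seed is
#'   overridden by `seed`).
#' @param params Named list of per-stage overrides, e.g.
#'   `list(snp = list(n_bootstrap = 500))`.
#' @param verbose Emit progress messages to standard error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("avenacomp_run_"),
                            seed = 1L,
                            sim = NULL,
                            params = list(),
                            verbose = TRUE) {
  if (is.null(sim)) sim <- sim_config(
    seed = seed,
    translocation_spec = list(lg_subgenome = "A", lg_chromosome = 1L,
                              breakpoint_cm = 60, donor_subgenome = "C",
                              donor_chromosome = 1L))
  else { sim$seed <- as.integer(seed); validate_sim_config(sim) }
  defaults <- pipeline_defaults()
  bad <- setdiff(names(params), names(defaults))
  if (length(bad))
    stop("unknown pipeline stage(s) in params: ", paste(bad, collapse = ", "))
  for (stage in names(params)) {
    bad <- setdiff(names(params[[stage]]), names(defaults[[stage]]))
    if (length(bad))
      stop(sprintf("unknown parameter(s) for stage '%s': %s", stage,
                   paste(bad, collapse = ", ")))
    defaults[[stage]] <- modifyList(defaults[[stage]], params[[stage]])
  }
  out <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              params = defaults, verbose = isTRUE(verbose))
  class(out) <- "pipeline_config"
  out
}

#' Run the full comparative-genomics pipeline on simulated inputs
#'
#' Executes the stages in dependency order: simulate the truth set and all
#' derived panels; compute assembly statistics; anchor a deliberately split
#' chromosome back together through marker placement, linkage-group
#' assignment and collinearity-based arm merging; deconvolve hexaploid
#' linkage groups into subgenomes and detect the planted translocation; call
#' majority-rule synteny orthologs; estimate the Ks distribution and date
#' the A/C split under a calibrated clock; filter, LD-prune and tree the
#' genotype panel; and profile the repeat landscape. All outputs are written
#' under `config$out_dir` and listed in a checksummed manifest.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `manifest` (file,
#'   md5), `results` (per-stage in-memory results) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  files <- character(0)
  results <- list()
  out <- function(...) file.path(config$out_dir, sprintf(...))
  p <- config$params

  say("[simulate] seed %d", config$seed)
  bundle <- simulate_truth_set(config$sim)
  files <- c(files, write_bundle(bundle, config$out_dir))
  panel <- simulate_linkage_panel(bundle)
  write_marker_tsv(panel$markers, out("linkage_markers.tsv"))
  hex <- simulate_hexaploid_panel(config$sim, bundle)
  write_marker_tsv(hex$markers, out("hexaploid_markers.tsv"))
  pairs <- simulate_ks_pairs(config$sim)
  geno <- simulate_genotypes(config$sim)
  write_genotype_tsv(geno$genotypes, out("genotypes.tsv"))
  write_vcf(geno$genotypes, out("genotypes.vcf"))
  files <- c(files, out("linkage_markers.tsv"), out("hexaploid_markers.tsv"),
             out("genotypes.tsv"), out("genotypes.vcf"))
  results$bundle <- bundle

  say("[stats] assembly statistics")
  stats_tab <- do.call(rbind, lapply(names(bundle$genomes), function(g) {
    df <- as.data.frame(compute_assembly_stats(bundle$genomes[[g]]))
    df$genome <- g
    df
  }))
  write.table(stats_tab, out("assembly_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, out("assembly_stats.tsv"))
  results$assembly_stats <- stats_tab

  say("[anchoring] split, place, assign, merge")
  scaffolds <- split_chromosome_for_anchoring(bundle)
  pl <- place_markers(panel$markers, scaffolds$sequences)
  lg_tab <- assign_linkage_groups(pl, panel$markers)
  plan <- infer_merge_plan(lg_tab, pl, panel$markers,
                           gap_n = p$merge$gap_n,
                           min_markers = p$merge$min_markers)
  merged <- apply_merge(scaffolds$sequences, plan)
  write.table(as.data.frame(lg_tab), out("lg_assignment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(merged, out("merged_assembly.fasta"))
  files <- c(files, out("lg_assignment.tsv"), out("merged_assembly.fasta"))
  results$anchoring <- list(scaffolds = scaffolds, placements = pl,
                            lg_table = lg_tab, plan = plan, merged = merged)

  say("[subgenome] dual-reference placement and deconvolution")
  pl_A <- place_markers(hex$markers, bundle$genomes$A)
  pl_C <- place_markers(hex$markers, bundle$genomes$C)
  mat_A <- build_contingency(pl_A, hex$markers, "A")
  mat_C <- build_contingency(pl_C, hex$markers, "C")
  assign <- call_subgenomes(mat_A, mat_C, c_ratio = p$subgenome$c_ratio,
                            slash_ratio = p$subgenome$slash_ratio)
  trans <- detect_translocations(pl_A, pl_C, hex$markers,
                                 min_segment_markers =
                                   p$subgenome$min_segment_markers)
  write.table(as.data.frame(assign), out("subgenome_assignment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(trans), out("translocations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, out("subgenome_assignment.tsv"), out("translocations.tsv"))
  results$subgenome <- list(panel = hex, matrix_A = mat_A, matrix_C = mat_C,
                            assignment = assign, translocations = trans)

  say("[synteny] majority-rule orthologs")
  blocks <- bundle_synteny_blocks(bundle, "A", "C",
                                  genes_per_block = p$synteny$genes_per_block)
  write_synteny_blocks(blocks, out("synteny_blocks.tsv"))
  orth <- call_orthologs(blocks)
  r2 <- block_size_correlation(blocks)
  write.table(as.data.frame(orth), out("orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, out("synteny_blocks.tsv"), out("orthologs.tsv"))
  results$synteny <- list(blocks = blocks, orthologs = orth,
                          block_size_r2 = as.numeric(r2))

  say("[ks] NG86 over %d pairs", nrow(pairs$pairs))
  ks_values <- vapply(seq_len(nrow(pairs$pairs)), function(i)
    ks_ng86(pairs$pairs$seq1[i], pairs$pairs$seq2[i])$ks, numeric(1))
  peak <- ks_peak(ks_values)
  rate <- calibrate_rate(p$clock$calibration_ks, p$clock$calibration_age)
  clock <- list(ks_peak = peak,
                lineage_rate = rate,
                time_lineage = divergence_time(peak, rate),
                time_generic = divergence_time(peak, p$clock$generic_rate))
  write.table(data.frame(pair_id = pairs$pairs$pair_id, ks = ks_values),
              out("ks_values.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, out("ks_values.tsv"))
  results$ks <- list(values = ks_values, truth = pairs$truth, clock = clock)

  say("[snp] filter, prune, tree")
  filt <- filter_sites(geno$genotypes,
                       max_het_fraction = p$snp$max_het_fraction,
                       min_maf = p$snp$min_maf)
  pruned <- ld_prune(filt$genotypes, window_bp = p$snp$window_bp,
                     r2_threshold = p$snp$r2_threshold)
  # the simulated panel carries no recombination, so windowed LD pruning is
  # far more aggressive than on real data; the tree uses the filtered matrix
  # and the pruned matrix is reported as its own artifact
  tree <- build_tree(filt$genotypes,
                     outgroup_id = config$sim$clade_structure$outgroup,
                     n_bootstrap = p$snp$n_bootstrap, seed = config$seed)
  writeLines(tree$newick, out("tree.nwk"))
  rep_df <- as.data.frame(unclass(filt$report))
  write.table(rep_df, out("filter_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, out("tree.nwk"), out("filter_report.tsv"))
  results$snp <- list(filter = filt, pruned = pruned, tree = tree,
                      truth_tree = geno$truth_tree)

  say("[repeats] tandem monomers and landscape")
  monomers <- find_tandem_monomers(bundle$genomes$A,
                                   min_len = p$repeats$min_len,
                                   max_len = p$repeats$max_len,
                                   min_copies = p$repeats$min_copies)
  if (nrow(monomers) < 1L) stop("no tandem monomer found")
  cen_monomer <- monomers$monomer[1L]
  tel_monomer <- if (nrow(monomers) >= 2L) monomers$monomer[2L] else NULL
  cen_track <- density_track(bundle$genomes$A, cen_monomer,
                             window_bp = p$repeats$window_bp,
                             max_mismatch_fraction =
                               p$repeats$max_mismatch_fraction)
  tel_track <- if (!is.null(tel_monomer))
    density_track(bundle$genomes$A, tel_monomer,
                  window_bp = p$repeats$window_bp,
                  max_mismatch_fraction = p$repeats$max_mismatch_fraction)
  else cen_track[0, ]
  lens <- setNames(Biostrings::width(bundle$genomes$A),
                   names(bundle$genomes$A))
  calls <- call_centromeres_telomeres(cen_track, tel_track, lens)
  ssrs <- scan_ssrs(bundle$genomes$A)
  write_bedgraph(cen_track, out("centromere_density.bedgraph"),
                 "centromeric_repeat")
  write_bedgraph(tel_track, out("telomere_density.bedgraph"),
                 "telomeric_repeat")
  write.table(calls$centromeres, out("centromere_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(ssrs), out("ssrs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, out("centromere_density.bedgraph"),
             out("telomere_density.bedgraph"), out("centromere_calls.tsv"),
             out("ssrs.tsv"))
  results$repeats <- list(monomers = monomers, cen_track = cen_track,
                          tel_track = tel_track, calls = calls, ssrs = ssrs)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, out("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out <- list(manifest = manifest, results = results,
              out_dir = config$out_dir)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d output files under %s\n",
              nrow(x$manifest), x$out_dir))
  invisible(x)
}

#' Split one chromosome of a bundle into two scaffolds
#'
#' Produces the anchoring test case: chromosome A1 is cut at its centromere
#' midpoint into two arm scaffolds, the second of which is
#' reverse-complemented (so the merge plan must re-orient it), and the
#' remaining chromosomes are passed through under scaffold aliases.
#'
#' @param bundle A [simulate_truth_set()] bundle.
#' @return List with `sequences` (the scaffold `DNAStringSet`), `split_chrom`
#'   (the chromosome that was split) and `parts` (its scaffold names).
#' @export
split_chromosome_for_anchoring <- function(bundle) {
  chars <- as.character(bundle$genomes$A)
  target <- names(chars)[1L]
  cut <- as.integer(bundle$centromere_bp[[target]])
  s <- chars[[target]]
  left <- substr(s, 1L, cut)
  right <- revcomp(substr(s, cut + 1L, nchar(s)))
  scafs <- c(setNames(list(left, right),
                      paste0("scaffold_", target, c("_arm1", "_arm2"))),
             as.list(chars[-1L]))
  names(scafs)[-(1:2)] <- paste0("scaffold_", names(chars)[-1L])
  list(sequences = Biostrings::DNAStringSet(unlist(scafs)),
       split_chrom = target,
       parts = paste0("scaffold_", target, c("_arm1", "_arm2")))
}
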