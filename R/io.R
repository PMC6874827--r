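# Readers and writers for the standard interchange formats. All text output
# is UTF-8 with LF line endings.

#' Read and write FASTA
#'
#' Thin wrappers over the Biostrings FASTA I/O, writing 60-column wrapped
#' sequence.
#'
#' @param path File path.
#' @param sequences Named character vector or `DNAStringSet`.
#' @return `read_fasta` returns a `DNAStringSet`; `write_fasta` returns the
#'   path invisibly.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(as_dss(sequences), path, width = 60L)
  invisible(path)
}

#' Read and write gene annotations as GFF3
#'
#' Annotations travel internally as a data frame of 1-based closed intervals
#' (`chromosome`, `start`, `end`, `strand`, `gene_id`); on disk they are
#' standard GFF3 `gene` features.
#'
#' @param annotations Annotation data frame.
#' @param path File path.
#' @return `read_gff3` returns an annotation data frame.
#' @export
write_gff3 <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    annotations$chromosome,
    IRanges::IRanges(annotations$start, annotations$end),
    strand = annotations$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "avenacomp"
  S4Vectors::mcols(gr)$ID <- annotations$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = S4Vectors::mcols(gr)$ID,
             stringsAsFactors = FALSE)
}

#' Read and write marker tables
#'
#' Marker TSVs carry `marker_id`, `sequence`, `lg`, `cM`.
#'
#' @param markers Marker data frame.
#' @param path File path.
#' @return `read_marker_tsv` returns a marker data frame.
#' @export
write_marker_tsv <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @export
read_marker_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(marker_id = "character", sequence = "character",
                            lg = "character", cM = "numeric"))
}

#' Read and write genotype matrices
#'
#' The TSV layout has the site columns `chromosome`, `position`, `ref`,
#' `alt` followed by one column per accession with calls coded 0/1/2
#' (alternate-allele dosage) or `NA`. `write_vcf` emits a minimal VCFv4.2
#' with `GT` genotypes; `read_vcf` parses it back (diploid biallelic GT
#' only).
#'
#' @param gm A [genotype_matrix()].
#' @param path File path.
#' @return Readers return a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- cbind(gm$sites, as.data.frame(gm$calls))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  sites <- df[, c("chromosome", "position", "ref", "alt")]
  calls <- as.matrix(df[, setdiff(names(df), names(sites)), drop = FALSE])
  storage.mode(calls) <- "integer"
  genotype_matrix(colnames(calls), sites, calls)
}

#' @rdname write_genotype_tsv
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=avenacomp",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$accessions), collapse = "\t")),
             con)
  gt <- matrix("./.", nrow = nrow(gm$sites), ncol = length(gm$accessions))
  gt[gm$calls == 0L] <- "0/0"
  gt[gm$calls == 1L] <- "0/1"
  gt[gm$calls == 2L] <- "1/1"
  body <- paste(gm$sites$chromosome, gm$sites$position, ".",
                gm$sites$ref, gm$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", body[1L]), "\t")[[1L]]
  accs <- header[-(1:9)]
  rows <- strsplit(body[-1L], "\t")
  m <- do.call(rbind, rows)
  sites <- data.frame(chromosome = m[, 1L],
                      position = as.integer(m[, 2L]),
                      ref = m[, 4L], alt = m[, 5L],
                      stringsAsFactors = FALSE)
  gt <- m[, -(1:9), drop = FALSE]
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt))
  calls[gt %in% c("0/0", "0|0")] <- 0L
  calls[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  calls[gt %in% c("1/1", "1|1")] <- 2L
  genotype_matrix(accs, sites, calls)
}

#' Write a synthetic bundle to disk
#'
#' Emits the bundle's genomes (FASTA), annotations (GFF3) and truth tables
#' (TSV) under a directory.
#'
#' @param bundle A [simulate_truth_set()] bundle.
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (g in names(bundle$genomes)) {
    p <- file.path(dir, sprintf("genome_%s.fasta", g))
    write_fasta(bundle$genomes[[g]], p)
    paths <- c(paths, p)
    p <- file.path(dir, sprintf("genes_%s.gff3", g))
    write_gff3(bundle$annotations[[g]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth_arrays.tsv")
  write.table(bundle$truth_arrays, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
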