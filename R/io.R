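# File-format helpers: FASTA, BED, window/count TSV, minimal VCF.

#' Write simulated genomes to FASTA
#'
#' @param genome named list of integer-coded chromosomes (or a named
#'   character vector of sequences).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (is.list(genome)) seq_as_character(genome) else genome
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as an integer-coded genome
#'
#' @param path FASTA file.
#' @return Named list of integer-coded chromosomes (1..4 = A,C,G,T).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(x), function(i) {
    match(strsplit(as.character(x[[i]]), "")[[1]], BASES)
  })
  names(out) <- names(x)
  out
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data frame with chrom, start, end and optionally a name
#'   column (e.g. tract `origin`).
#' @param path output file.
#' @param name_col column to place in the BED name field.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  df <- intervals[, c("chrom", "start", "end")]
  if (!is.null(name_col)) df$name <- intervals[[name_col]]
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write or read a window/count table as TSV
#'
#' @param x data frame.
#' @param path file path.
#' @return `write_tsv`: invisibly `path`; `read_tsv`: data frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a genotype matrix from a minimal VCF
#'
#' Parses GT fields of a VCF v4.2 file (requires the `vcfR` package) into a
#' [genotype_matrix()]. Site INFO annotations used by
#' [hard_filter_variant()] (QD, SOR, FS, MQ, MQRankSum, ReadPosRankSum) are
#' attached as attribute `"annotations"` together with QUAL.
#'
#' @param path VCF file.
#' @param populations population label per sample (defaults to
#'   `"unknown"`).
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, populations = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("reading VCF requires the `vcfR` package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    ifelse(x %in% c("0/0"), 0,
           ifelse(x %in% c("0/1", "1/0"), 1,
                  ifelse(x == "1/1", 2, NA)))
  }
  g <- apply(gt, 2, code)
  g <- matrix(g, nrow = nrow(gt), dimnames = dimnames(gt))
  if (is.null(populations)) populations <- rep("unknown", ncol(g))
  qual <- suppressWarnings(as.numeric(v@fix[, "QUAL"]))
  gm <- genotype_matrix(g, populations,
                        positions = as.numeric(v@fix[, "POS"]),
                        chrom = v@fix[, "CHROM"], qual = qual)
  ann <- lapply(c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum"),
                function(k) {
                  suppressWarnings(as.numeric(
                    vcfR::extract.info(v, element = k)))
                })
  names(ann) <- c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  attr(gm, "annotations") <- cbind(data.frame(QUAL = qual),
                                   as.data.frame(ann))
  gm
}

#' Write a genotype matrix as a minimal VCF v4.2
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param sample_names optional sample names (default `s1..sN`).
#' @return Invisibly, `path`.
#' @export
write_genotype_vcf <- function(gm, path, sample_names = NULL) {
  stopifnot(inherits(gm, "malus_genotypes"))
  g <- gm$genotypes
  if (is.null(sample_names)) sample_names <- paste0("s", seq_len(ncol(g)))
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1], nrow = nrow(g))
  gt[is.na(g)] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  qual <- if (is.null(gm$qual)) rep(".", nrow(g)) else gm$qual
  body <- vapply(seq_len(nrow(g)), function(i) {
    paste(c(gm$chrom[i], format(gm$positions[i], scientific = FALSE),
            ".", "G", "A", qual[i], "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}
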