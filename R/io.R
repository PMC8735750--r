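#' Write a simulated locus set to disk
#'
#' Writes loci as a concatenated multi-FASTA (sequence names
#' \code{locus|sample}), genotypes as a TSV (columns \code{locus}, \code{pos},
#' then one 0/1 column per sample) and the generating-parameter record as
#' JSON.  Sequences are materialised from the infinite-sites genotypes: each
#' segregating site gets an ancestral and a derived nucleotide (drawn at
#' simulation time), all other positions carry the ancestral background.
#'
#' @param loci a \code{\link{locus_set}} with the genotype representation.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_locus_set <- function(loci, dir, prefix = "sim") {
  stopifnot(inherits(loci, "locus_set"))
  if (is.null(loci$genotypes))
    stopf("locus set carries no genotypes (distance representation)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  tsv <- file.path(dir, paste0(prefix, "_genotypes.tsv"))
  js <- file.path(dir, paste0(prefix, "_truth.json"))

  con <- file(fa, "w")
  on.exit(close(con), add = TRUE)
  samples <- names(loci$sample_labels)
  for (l in seq_len(loci$n_loci)) {
    seqs <- locus_sequences(loci, l)
    writeLines(paste0(">L", sprintf("%05d", l), "|", samples, "\n", seqs), con)
  }
  utils::write.table(locus_genotypes(loci), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- loci$truth %||% list()
  truth$sample_labels <- as.list(loci$sample_labels)
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(fasta = fa, genotypes = tsv, truth = js))
}

# character vector of full-length sequences for locus l
locus_sequences <- function(loci, l) {
  g <- loci$genotypes[[l]]
  pos <- loci$positions[[l]] + 1L          # stored 0-based
  bases <- loci$site_bases[[l]]
  n <- length(loci$sample_labels)
  background <- rep("A", loci$locus_len)
  if (length(pos)) background[pos] <- bases$anc
  vapply(seq_len(n), function(s) {
    x <- background
    if (length(pos)) {
      der <- g[, s] == 1L
      x[pos[der]] <- bases$der[der]
    }
    paste(x, collapse = "")
  }, "")
}

#' Read a genotype TSV
#'
#' Reads the tab-separated genotype dialect written by
#' \code{\link{write_locus_set}}: columns \code{locus}, \code{pos}, then one
#' dosage column per individual (\code{.} = missing).
#'
#' @param path file path.
#' @return a genotype table suitable for \code{\link{build_jsfs}}.
#' @export
read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           na.strings = c(".", "NA"), stringsAsFactors = FALSE)
  if (!all(c("locus", "pos") %in% colnames(tab)))
    stopf("genotype TSV must have 'locus' and 'pos' columns")
  tab
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Extracts biallelic SNPs from a VCF (via the \pkg{vcfR} package), using
#' CHROM as the locus identifier and the REF allele as ancestral; genotypes
#' become ALT-dosage columns (0/1 haploid, 0/1/2 diploid).  Non-biallelic
#' sites are skipped with a warning.  Positions are converted to the package's
#' 0-based convention.
#'
#' @param path VCF file path.
#' @return a list with \code{genotypes} (table for \code{\link{build_jsfs}})
#'   and \code{ploidy}.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("the vcfR package is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) & nzchar(fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  if (any(!biallelic))
    warning(sum(!biallelic), " non-biallelic site(s) skipped")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  dose <- function(x) {
    x <- sub(":.*", "", x)
    ifelse(x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(as.numeric(a)), 0))
  }
  D <- apply(gt, 2, dose)
  if (is.null(dim(D))) D <- matrix(D, nrow = nrow(gt), dimnames = dimnames(gt))
  ploidy <- max(1, nchar(gsub("[^01.]", "", sub(":.*", "", gt[1, 1]))) %/% 1)
  ploidy <- if (grepl("[/|]", gt[1, 1])) 2L else 1L
  tab <- data.frame(locus = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]) - 1L,
                    D, check.names = FALSE)
  rownames(tab) <- NULL
  list(genotypes = tab, ploidy = ploidy)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file path.
#' @return a character matrix (rows = sequences) for
#'   \code{\link{classify_sites}}.
#' @export
read_alignment <- function(path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stopf("the ape package is required to read FASTA alignments")
  x <- ape::read.FASTA(path)
  m <- as.character(as.matrix(x))
  toupper(m)
}
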