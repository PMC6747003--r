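# Readers and writers for the plain-text formats the pipeline touches:
# dosage TSV, VCF 4.2 (GT only), expression TSV, BED6 gene intervals, and
# BED segmentations. All tabular outputs carry a header comment declaring
# their coordinate convention.

#' Read an expression matrix from TSV
#'
#' First column = gene id, remaining columns = samples. Cells equal to
#' `""`, `"NA"` or `"."` are treated as missing. Duplicate gene or sample
#' labels are an error.
#'
#' @param path File path.
#' @return Numeric gene x sample matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          na.strings = c("", "NA", "."),
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  if (anyDuplicated(names(df)[-1L])) stop("duplicate sample ids in ", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

#' Write an expression matrix to TSV
#' @param mat Gene x sample matrix.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a genotype matrix (dosage TSV or VCF)
#'
#' The TSV dialect has columns `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#' then one 0/1/2 dosage column per sample (`"."` = missing). VCF 4.2 input
#' is parsed via the GT field (`0/0`, `0/1`, `1/1`, `./.`, phased
#' equivalents); multi-allelic records are skipped with a warning.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return List with `variants` (data frame: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`) and `dosages` (variants x samples integer matrix).
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") return(.read_genotypes_vcf(path))
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          na.strings = c("", "NA", "."),
                          stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("malformed genotype TSV header in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  variants <- df[, need]
  dosages <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  mode(dosages) <- "integer"
  rownames(dosages) <- variants$variant_id
  list(variants = variants, dosages = dosages)
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) skipped in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dos[] <- map[gt]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  rownames(dos) <- ids
  list(variants = data.frame(variant_id = ids, chrom = fix$CHROM,
                             pos = as.integer(fix$POS), ref = fix$REF,
                             alt = fix$ALT, stringsAsFactors = FALSE),
       dosages = dos)
}

#' Write a genotype matrix as dosage TSV
#' @param genotypes List with `variants` and `dosages` (see
#'   [read_genotypes()]).
#' @param path Output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  dos <- genotypes$dosages
  dos[is.na(dos)] <- "."
  df <- cbind(genotypes$variants, as.data.frame(dos, stringsAsFactors = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: pos is 1-based; dosages are alt-allele counts (. = missing)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a genotype matrix as minimal VCF 4.2 (GT field only)
#' @inheritParams write_genotypes_tsv
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(genotypes$dosages), ncol(genotypes$dosages))
  ok <- !is.na(genotypes$dosages)
  gt[ok] <- gt_code[genotypes$dosages[ok] + 1L]
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(genotypes$dosages)),
                   collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i],
                       v$alt[i], ".", "PASS", ".", "GT", gt[i, ]),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
}

#' Read gene intervals from BED6
#'
#' BED is 0-based half-open; returned intervals are converted to 1-based
#' inclusive (`start = bed_start + 1`, `end = bed_end`).
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return Data frame: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED file needs at least 4 columns: ", path)
  data.frame(gene_id = as.character(df[[4L]]), chrom = as.character(df[[1L]]),
             start = as.integer(df[[2L]]) + 1L, end = as.integer(df[[3L]]),
             strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else "+",
             stringsAsFactors = FALSE)
}

#' Write gene intervals as BED6 (converting back to 0-based half-open)
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive).
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                    0L, if (is.null(genes$strand)) "+" else genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a labeled BED segmentation (chromatin states or region classes)
#'
#' Accepts BroadHMM-style BED where the 4th column carries the label.
#' Coordinates stay in the 0-based half-open BED convention.
#'
#' @param path BED file path.
#' @param label_name Name for the label column (`"state"` or `"region"`).
#' @return Data frame: `chrom`, `start`, `end`, and the label column.
#' @export
read_bed_intervals <- function(path, label_name = "state") {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("labeled BED needs at least 4 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                    label = as.character(df[[4L]]), stringsAsFactors = FALSE)
  names(out)[4L] <- label_name
  out
}

#' Write a synthetic cohort to a directory of standard files
#'
#' Emits `genotypes.tsv` (dosage dialect), `mrna.tsv`, `protein.tsv`,
#' `genes.bed` (BED6), `truth.tsv`, and optionally `genotypes.vcf`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param vcf Also write a VCF 4.2 copy of the genotypes.
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genotypes.tsv", "mrna.tsv", "protein.tsv",
                            "genes.bed", "truth.tsv"))
  write_genotypes_tsv(cohort$genotypes, paths[1L])
  write_expression(cohort$mrna, paths[2L])
  write_expression(cohort$protein, paths[3L])
  write_gene_bed(cohort$genes, paths[4L])
  utils::write.table(cohort$truth, paths[5L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (vcf) {
    p <- file.path(dir, "genotypes.vcf")
    write_vcf(cohort$genotypes, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
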