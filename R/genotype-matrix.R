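#' Construct a homozygous inbred-line genotype matrix
#'
#' Container for biallelic variant calls on fully inbred lines. Because the
#' lines are homozygous there are no heterozygotes; each call is coded
#' `0` (major allele class), `1` (minor allele class) or `NA` (missing).
#'
#' @param calls Integer matrix, lines in rows and variants in columns, values
#'   in `{0, 1, NA}`. Row names are line identifiers.
#' @param variants `data.frame` with one row per variant: columns `id`,
#'   `chrom`, `pos` (1-based) and `type` (one of `"SNP"`, `"INS"`, `"DEL"`).
#' @param lines Optional character vector of line identifiers (overrides
#'   `rownames(calls)`).
#' @return An object of class `genotype_matrix` with elements `calls`,
#'   `variants` and `lines`.
#' @export
genotype_matrix <- function(calls, variants, lines = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  ok <- calls %in% c(0L, 1L) | is.na(calls)
  if (!all(ok)) stop("calls must be 0, 1 or NA (homozygous inbred coding)", call. = FALSE)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "type") %in% names(variants)),
            nrow(variants) == ncol(calls),
            all(variants$type %in% c("SNP", "INS", "DEL")))
  if (is.null(lines)) lines <- rownames(calls)
  if (is.null(lines)) lines <- sprintf("line_%03d", seq_len(nrow(calls)))
  stopifnot(length(lines) == nrow(calls), !anyDuplicated(lines))
  rownames(calls) <- lines
  colnames(calls) <- variants$id
  structure(list(calls = calls, variants = variants, lines = lines),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d variants (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-variant minor-allele frequency
#'
#' MAF is computed over non-missing calls only and folded to `[0, 0.5]`.
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector, one value per variant (NaN where all calls
#'   are missing).
#' @export
variant_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g$calls, na.rm = TRUE)
  stats::setNames(pmin(p, 1 - p), g$variants$id)
}

#' Per-variant missing-call fraction
#' @param g A [genotype_matrix()].
#' @return Named numeric vector in `[0, 1]`.
#' @export
variant_missing_rate <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  stats::setNames(colMeans(is.na(g$calls)), g$variants$id)
}

subset_variants <- function(g, keep) {
  genotype_matrix(g$calls[, keep, drop = FALSE],
                  g$variants[keep, , drop = FALSE], g$lines)
}

#' Write / read a genotype matrix as TSV
#'
#' Variant-major TSV: columns `chrom`, `pos`, `id`, `type`, then one column
#' per line with calls `0`, `1` or `.` for missing.
#'
#' @param g A [genotype_matrix()].
#' @param path File path.
#' @return `write_genotype_tsv`: `path` invisibly; `read_genotype_tsv`: a
#'   [genotype_matrix()].
#' @export
write_genotype_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- t(g$calls)
  calls[is.na(calls)] <- "."
  out <- cbind(g$variants[, c("chrom", "pos", "id", "type")], calls)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         colClasses = "character")
  meta <- c("chrom", "pos", "id", "type")
  stopifnot(all(meta %in% names(d)))
  line_cols <- setdiff(names(d), meta)
  # vapply over variants returns a lines x variants matrix directly
  calls <- vapply(seq_len(nrow(d)), function(i) {
    v <- unlist(d[i, line_cols], use.names = FALSE)
    as.integer(ifelse(v == ".", NA, v))
  }, integer(length(line_cols)))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(line_cols))
  variants <- data.frame(id = d$id, chrom = d$chrom, pos = as.integer(d$pos),
                         type = d$type, stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, lines = line_cols)
}

#' Read homozygous genotypes from a VCF file
#'
#' Minimal VCF support for inbred panels: the GT field is parsed with the
#' vcfR package; haploid calls (`0` / `1`) and homozygous diploid calls
#' (`0/0`, `1|1`, ...) map to the 0/1 line coding, heterozygous or multiallelic
#' calls are set to missing with a warning.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0", "0/0")] <- 0L
    out[x %in% c("1", "1/1")] <- 1L
    out
  }
  calls <- apply(gt, 2, code)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt))
  n_bad <- sum(!is.na(gt) & is.na(calls))
  if (n_bad > 0) {
    warning(sprintf("%d heterozygous or multiallelic calls set to missing", n_bad))
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  type <- ifelse(nchar(ref) == nchar(alt), "SNP",
                 ifelse(nchar(ref) < nchar(alt), "INS", "DEL"))
  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"], "_", type[no_id])
  variants <- data.frame(id = id, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]), type = type,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(calls), variants, lines = colnames(gt))
}
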