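#' Construct and validate a genotype table
#'
#' Biallelic variants with per-sample allele dosages in \{0, 1, 2\} and -1
#' for missing. Coordinates are stored 0-based half-open (VCF positions are
#' converted on read).
#'
#' @param variants Data frame with columns `variant_id`, `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `ref`, `alt`.
#' @param dosages Integer matrix, variants x samples, values in
#'   \{-1, 0, 1, 2\}.
#' @return An object of class `"genotype_table"`.
#' @export
genotype_table <- function(variants, dosages) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (anyDuplicated(variants$variant_id)) stop_format("duplicate variant ids")
  if (nrow(variants) != nrow(dosages)) {
    stop_format("variants (%d) and dosage rows (%d) differ",
                nrow(variants), nrow(dosages))
  }
  if (is.null(colnames(dosages))) stop_format("dosages need sample column names")
  bad <- !(dosages %in% c(-1L, 0L, 1L, 2L))
  if (any(bad)) stop_format("dosages outside {-1,0,1,2}")
  rownames(dosages) <- variants$variant_id
  structure(list(variants = as.data.frame(variants),
                 dosages = dosages,
                 samples = colnames(dosages)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d variants, %d samples\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

.parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop_format("malformed region '%s' (chrom:start-end)", region)
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

## keep variants whose (1-based) position lies in [start, end]
.filter_region <- function(gt, region) {
  r <- .parse_region(region)
  keep <- gt$variants$chrom == r$chrom &
    gt$variants$start >= r$start - 1 & gt$variants$start < r$end
  genotype_table(gt$variants[keep, , drop = FALSE],
                 gt$dosages[keep, , drop = FALSE])
}

#' Read genotypes from VCF or tab-delimited dosage files
#'
#' Two dialects are supported. VCF (plain or gzip, via the vcfR parser):
#' only biallelic records are returned and dosages are computed from the GT
#' field (count of alternate alleles; missing genotypes become -1).
#' TSV: header `chrom start end variant_id` followed by one dosage column
#' per sample, coordinates 0-based half-open; records with dosage values
#' outside \{-1, 0, 1, 2\} (e.g. collapsed multi-allelic codes) are skipped
#' with a warning. A `region` (`"chrom:start-end"`, 1-based inclusive)
#' restricts the result; the same records are returned as a full scan
#' followed by filtering.
#'
#' @param path Path to the VCF/TSV file.
#' @param region Optional region string `"chrom:start-end"`.
#' @param samples Optional character vector restricting (and ordering) the
#'   sample columns; unknown samples raise an error.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, region = NULL, samples = NULL) {
  is_vcf <- grepl("\\.vcf(\\.gz|\\.bgz)?$", path)
  gt <- if (is_vcf) .read_genotypes_vcf(path) else .read_genotypes_tsv(path)
  if (!is.null(samples)) {
    unknown <- setdiff(samples, gt$samples)
    if (length(unknown)) {
      stop_format("unknown sample(s): %s", paste(head(unknown, 3), collapse = ", "))
    }
    gt <- genotype_table(gt$variants, gt$dosages[, samples, drop = FALSE])
  }
  if (!is.null(region)) gt <- .filter_region(gt, region)
  gt
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  fix <- v@fix[bi, , drop = FALSE]
  gtmat <- vcfR::extract.gt(v, element = "GT")[bi, , drop = FALSE]
  if (is.null(dim(gtmat))) gtmat <- matrix(gtmat, nrow = sum(bi),
                                           dimnames = list(NULL, colnames(v@gt)[-1]))
  dos <- apply(gtmat, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(-1L)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(-1L)
    sum(alleles == "1")
  })
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", pos[no_id])
  variants <- data.frame(variant_id = ids,
                         chrom = fix[, "CHROM"],
                         start = pos - 1L,
                         end = pos - 1L + nchar(ref),
                         ref = ref,
                         alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_table(variants, dos)
}

.read_genotypes_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "variant_id")
  if (!all(need %in% names(df))) {
    stop_format("genotype TSV needs columns: %s", paste(need, collapse = ", "))
  }
  dos <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  if (ncol(dos) == 0) stop_format("genotype TSV has no sample columns")
  ok <- apply(dos, 1L, function(d) all(d %in% c(-1, 0, 1, 2)))
  if (any(!ok)) {
    warning(sprintf("skipping %d non-biallelic record(s)", sum(!ok)))
  }
  genotype_table(df[ok, need, drop = FALSE], dos[ok, , drop = FALSE])
}

#' Write a genotype table in the TSV dosage dialect
#'
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  df <- data.frame(gt$variants[, c("chrom", "start", "end", "variant_id")],
                   gt$dosages, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
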