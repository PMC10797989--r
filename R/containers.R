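#' OTU count table with sample metadata
#'
#' Thin container pairing a samples x OTUs integer count matrix with
#' per-sample metadata (at least diet and batch).
#'
#' @param counts samples x OTUs matrix of non-negative counts with
#'   sample ids as rownames and OTU ids as colnames.
#' @param metadata data.frame with one row per sample, rownames (or an
#'   `animal_id` column) matching the count matrix rows; must contain
#'   `diet` and `batch` columns.
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts in OTU table")
  if (is.null(rownames(counts))) stop("count matrix must have sample ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids")
  if (!is.null(metadata$animal_id)) rownames(metadata) <- metadata$animal_id
  if (!all(rownames(counts) %in% rownames(metadata))) {
    stop("metadata does not cover all samples")
  }
  metadata <- metadata[rownames(counts), , drop = FALSE]
  structure(list(counts = counts, metadata = metadata), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs; row sums %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(range(rowSums(x$counts)), collapse = "-")))
  invisible(x)
}

#' SNP dosage matrix with per-SNP metadata
#'
#' @param dosages animals x SNPs matrix with values in {0, 1, 2, NA} and
#'   animal ids as rownames.
#' @param snp_meta data.frame with one row per SNP: `snp_id`, `chrom`
#'   (NA or "0" means unmapped; "X"/"Y" are sex chromosomes).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, snp_meta = NULL) {
  dosages <- as.matrix(dosages)
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  if (is.null(rownames(dosages))) stop("dosage matrix must have animal ids as rownames")
  if (anyDuplicated(rownames(dosages))) stop("duplicate animal ids")
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(
      snp_id = colnames(dosages) %||% paste0("snp", seq_len(ncol(dosages))),
      chrom = "1", stringsAsFactors = FALSE
    )
  }
  if (nrow(snp_meta) != ncol(dosages)) stop("snp_meta rows must match SNP columns")
  if (is.null(colnames(dosages))) colnames(dosages) <- snp_meta$snp_id
  structure(list(dosages = dosages, snp_meta = snp_meta), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d animals x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
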