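#' Read an OTU count table from TSV
#'
#' Expects a header row of OTU ids and a first column of sample ids
#' (samples x OTUs); `transposed = TRUE` reads the OTUs-as-rows layout.
#' Counts must be non-negative integers. Sample metadata (diet, batch)
#' is joined from a separate CSV when given.
#'
#' @param path TSV path.
#' @param metadata_path optional CSV with animal_id, diet, batch.
#' @param transposed whether rows are OTUs rather than samples.
#' @return an `otu_table`.
#' @export
read_otu_table <- function(path, metadata_path = NULL, transposed = FALSE) {
  raw <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  if (transposed) m <- t(m)
  bad <- which(!is.finite(m) | m != round(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  storage.mode(m) <- "integer"
  meta <- if (!is.null(metadata_path)) {
    utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  } else {
    data.frame(animal_id = rownames(m), diet = NA_character_, batch = NA_integer_,
               stringsAsFactors = FALSE)
  }
  otu_table(m, meta)
}

#' Write an OTU table as TSV (samples x OTUs)
#'
#' @param table an `otu_table`.
#' @param path output TSV path.
#' @param metadata_path optional path for the sample-metadata CSV.
#' @export
write_otu_table <- function(table, path, metadata_path = NULL) {
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.csv(table$metadata, metadata_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read genotypes (PLINK-RAW or VCF dialect)
#'
#' PLINK-RAW: whitespace-separated with header FID IID PAT MAT SEX
#' PHENOTYPE then one 0/1/2/NA column per SNP. VCF: GT fields are
#' summed allele-count-wise ("0/1" -> 1, "./." -> missing); the CHROM
#' column is carried as per-SNP metadata for the sex-chromosome /
#' unmapped QC rules.
#'
#' @param path input path.
#' @param dialect "plink-raw" or "vcf" (default guessed from the
#'   extension).
#' @return a `geno_matrix`.
#' @export
read_genotypes <- function(path, dialect = c("auto", "plink-raw", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink-raw"
  }
  if (dialect == "plink-raw") {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            na.strings = c("NA", "-9"))
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(lead[1:2] %in% names(df))) {
      stop("malformed PLINK-RAW header at line 1: need FID and IID columns")
    }
    snp_cols <- setdiff(names(df), lead)
    m <- as.matrix(df[, snp_cols, drop = FALSE])
    rownames(m) <- df$IID
    geno_matrix(m, data.frame(snp_id = snp_cols,
                              chrom = "1", stringsAsFactors = FALSE))
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("vcfR is required to read VCF genotypes")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", ".|.", "."), NA_integer_,
             vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), integer(1)))
    }
    dos <- matrix(count_alt(as.vector(gt)), nrow = nrow(gt))  # SNPs x samples
    dos <- t(dos)
    rownames(dos) <- colnames(gt)
    colnames(dos) <- rownames(gt)
    geno_matrix(dos, data.frame(snp_id = rownames(gt),
                                chrom = as.character(v@fix[, "CHROM"]),
                                stringsAsFactors = FALSE))
  }
}

#' Write genotypes in the PLINK-RAW dialect
#'
#' @param geno a `geno_matrix`.
#' @param path output path.
#' @export
write_genotypes_raw <- function(geno, path) {
  df <- data.frame(FID = rownames(geno$dosages), IID = rownames(geno$dosages),
                   PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9,
                   geno$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a relationship matrix as TSV with an id header
#'
#' @param k relationship matrix with animal-id dimnames.
#' @param path TSV path.
#' @param kind "G" or "M" (restored as an attribute on read).
#' @export
write_kernel <- function(k, path, kind = attr(k, "kind")) {
  df <- data.frame(animal_id = rownames(k), k, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path, kind = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  attr(m, "kind") <- kind
  m
}

#' Write a JSON sidecar recording the seed and configuration of a run
#'
#' @param path sidecar path (conventionally `<output>.json`).
#' @param seed the seed that produced the artifact.
#' @param config any list of settings (serialized as JSON).
#' @export
write_sidecar <- function(path, seed, config = list()) {
  jsonlite::write_json(
    list(seed = seed, config = config,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("holopred"))),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  invisible(path)
}
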