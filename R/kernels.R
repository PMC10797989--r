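#' Filter an OTU table by prevalence and mean relative abundance
#'
#' Retains OTUs that are present (count > 0) in strictly more than
#' `min_samples` samples and whose mean relative abundance across samples
#' (count / sample total) is strictly greater than `min_mean_abundance`.
#' Both thresholds are applied to the table as given (here, rarefied
#' counts), and the order of retained OTUs is preserved.
#'
#' @param table an `otu_table` object (see [otu_table()]).
#' @param min_samples prevalence threshold; an OTU must occur in more than
#'   this many samples. Default 5.
#' @param min_mean_abundance mean relative-abundance threshold, as a
#'   fraction. Default `1e-5` (i.e. 0.001%).
#' @return an `otu_table` with the same samples and the retained OTUs.
#' @export
filter_otus <- function(table, min_samples = 5, min_mean_abundance = 1e-5) {
  stopifnot(inherits(table, "otu_table"))
  counts <- table$counts
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty OTU table")
  prevalence <- colSums(counts > 0)
  rel <- counts / rowSums(counts)
  mean_abund <- colMeans(rel)
  keep <- prevalence > min_samples & mean_abund > min_mean_abundance
  if (!any(keep)) {
    stop(sprintf(
      "no OTU passes the filters (prevalence > %d samples, mean abundance > %g)",
      min_samples, min_mean_abundance
    ))
  }
  table$counts <- counts[, keep, drop = FALSE]
  table
}

#' Microbiota covariance matrix M = S S^T / n
#'
#' Each count is transformed as log(count + 1); ones are added so that
#' zero counts stay defined under the log. Every OTU column is then
#' centered to mean zero and scaled to unit sample standard deviation
#' (n - 1 denominator), giving the p x n matrix S (p animals, n OTUs),
#' and M = S S^T / n. Zero-variance columns after the log transform
#' carry no information and are dropped with a warning; n is the number
#' of OTUs actually used.
#'
#' @param table an `otu_table`.
#' @return a symmetric positive semi-definite matrix with animal ids as
#'   dimnames and attributes `kind = "M"` and `n_otus_used`.
#' @export
build_m_matrix <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  counts <- table$counts
  if (nrow(counts) < 2L) stop("need at least 2 samples to build M")
  s <- log(counts + 1)
  sds <- apply(s, 2, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (all(zero_var)) stop("all OTU columns have zero variance after log transform")
  if (any(zero_var)) {
    warning(sprintf("dropping %d zero-variance OTU column(s)", sum(zero_var)))
    s <- s[, !zero_var, drop = FALSE]
    sds <- sds[!zero_var]
  }
  s <- scale(s, center = TRUE, scale = sds)
  n <- ncol(s)
  m <- tcrossprod(s) / n
  m <- (m + t(m)) / 2
  dimnames(m) <- list(rownames(counts), rownames(counts))
  attr(m, "kind") <- "M"
  attr(m, "n_otus_used") <- n
  m
}

#' Hardy-Weinberg goodness-of-fit test for one SNP
#'
#' One-degree-of-freedom chi-square test comparing observed genotype
#' counts (AA, Aa, aa) with Hardy-Weinberg expectations at the observed
#' allele frequency.
#'
#' @param n_aa,n_ab,n_bb observed genotype counts.
#' @return list with `chisq` and `p`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(list(chisq = NA_real_, p = NA_real_))
  p <- (2 * n_aa + n_ab) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  observed <- c(n_aa, n_ab, n_bb)
  nz <- expected > 0
  chisq <- sum((observed[nz] - expected[nz])^2 / expected[nz])
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Genotype quality control
#'
#' Retains individuals with call rate > `ind_call_rate` and SNPs with
#' call rate > `snp_call_rate`; removes SNPs with minor allele frequency
#' below `maf_min` (strict `<`, so the boundary is retained), SNPs whose
#' Hardy-Weinberg test p-value falls below `hwe_alpha`, and SNPs on sex
#' chromosomes or without a map position. Remaining missing dosages are
#' imputed to twice the post-QC allele frequency, the mean dosage
#' compatible with the VanRaden method 1 centering.
#'
#' @param geno a `geno_matrix` object (see [geno_matrix()]).
#' @param ind_call_rate,snp_call_rate call-rate thresholds (default 0.95).
#' @param maf_min minor-allele-frequency removal threshold (default 0.05).
#' @param hwe_alpha Hardy-Weinberg p-value threshold (default 1e-6).
#' @return list with the filtered, imputed `geno` and a `report`
#'   data.frame tallying removals per rule.
#' @export
qc_genotypes <- function(geno, ind_call_rate = 0.95, snp_call_rate = 0.95,
                         maf_min = 0.05, hwe_alpha = 1e-6) {
  stopifnot(inherits(geno, "geno_matrix"))
  x <- geno$dosages
  chrom <- geno$snp_meta$chrom

  ind_cr <- rowMeans(!is.na(x))
  keep_ind <- ind_cr > ind_call_rate
  n_ind_removed <- sum(!keep_ind)
  x <- x[keep_ind, , drop = FALSE]
  if (nrow(x) == 0L) stop("no individuals left after call-rate QC")

  snp_cr <- colMeans(!is.na(x))
  fail_cr <- snp_cr <= snp_call_rate

  af <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- maf < maf_min

  hwe_p <- vapply(seq_len(ncol(x)), function(k) {
    g <- x[, k]
    g <- g[!is.na(g)]
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))$p
  }, numeric(1))
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha

  sex_or_unmapped <- is.na(chrom) | chrom %in% c("X", "Y", "0", "")
  # rules applied jointly; the report attributes each SNP to the first
  # failing rule in the order call rate, MAF, HWE, map position
  fail_any <- fail_cr | fail_maf | fail_hwe | sex_or_unmapped
  first_rule <- rep(NA_character_, ncol(x))
  first_rule[sex_or_unmapped] <- "sex_or_unmapped"
  first_rule[fail_hwe] <- "hwe"
  first_rule[fail_maf] <- "maf"
  first_rule[fail_cr] <- "snp_call_rate"

  keep_snp <- !fail_any
  if (!any(keep_snp)) stop("no SNPs left after QC")

  x <- x[, keep_snp, drop = FALSE]
  # impute residual missing dosages to 2 * allele frequency
  af_kept <- colMeans(x, na.rm = TRUE) / 2
  for (k in which(colSums(is.na(x)) > 0)) {
    x[is.na(x[, k]), k] <- 2 * af_kept[k]
  }

  out <- geno
  out$dosages <- x
  out$snp_meta <- geno$snp_meta[keep_ind_snp_index(keep_snp), , drop = FALSE]

  report <- data.frame(
    rule = c("individual_call_rate", "snp_call_rate", "maf", "hwe", "sex_or_unmapped"),
    removed = c(
      n_ind_removed,
      sum(first_rule == "snp_call_rate", na.rm = TRUE),
      sum(first_rule == "maf", na.rm = TRUE),
      sum(first_rule == "hwe", na.rm = TRUE),
      sum(first_rule == "sex_or_unmapped", na.rm = TRUE)
    ),
    stringsAsFactors = FALSE
  )
  attr(report, "n_individuals_retained") <- nrow(x)
  attr(report, "n_snps_retained") <- ncol(x)
  list(geno = out, report = report)
}

keep_ind_snp_index <- function(keep_snp) which(keep_snp)

#' Genomic relationship matrix (VanRaden method 1)
#'
#' With observed allele frequencies p_k, columns are centered as
#' Z = dosages - 2 p_k and G = Z Z^T / (2 sum_k p_k (1 - p_k)).
#' Monomorphic SNPs must have been removed by QC.
#'
#' @param geno a `geno_matrix` with complete dosages.
#' @return a symmetric PSD matrix with animal ids as dimnames and
#'   attribute `kind = "G"`.
#' @export
build_g_matrix <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  x <- geno$dosages
  if (anyNA(x)) stop("missing dosages present; run qc_genotypes() first")
  p <- colMeans(x) / 2
  if (any(p <= 0 | p >= 1)) {
    stop(sprintf("%d monomorphic SNP(s) present; exclude them before building G",
                 sum(p <= 0 | p >= 1)))
  }
  z <- sweep(x, 2, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  g <- tcrossprod(z) / denom
  g <- (g + t(g)) / 2
  dimnames(g) <- list(rownames(x), rownames(x))
  attr(g, "kind") <- "G"
  g
}

#' Check a relationship matrix is symmetric and positive semi-definite
#'
#' @param k square numeric matrix.
#' @param tol relative eigenvalue tolerance; the minimum eigenvalue must
#'   be at least `-tol * max(eigenvalue)`.
#' @return TRUE invisibly, or an error.
#' @export
check_psd <- function(k, tol = 1e-8) {
  if (max(abs(k - t(k))) > 1e-10) stop("matrix is not symmetric")
  ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop(sprintf("matrix is not PSD (min eigenvalue %.3g)", min(ev)))
  }
  invisible(TRUE)
}
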