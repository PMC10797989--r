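#' Configuration for the synthetic pig population
#'
#' Defaults reproduce the study-scale design: 171 sires with full-sib
#' pairs split across a conventional (CO) and a high-fiber (HF) diet,
#' ~32 contiguous batches, OTU tables rarefied to 10,000 counts per
#' sample, and a trait model y = X beta + u + m + e with additive
#' genetic variance `var_u`, microbiota variance `var_m` and residual
#' variance `var_e`.
#'
#' @param n_sires number of sires (default 171).
#' @param sib_pairs_per_sire full-sib pairs per sire, each from its own
#'   dam (default 3, giving 1026 animals).
#' @param n_snps number of unlinked SNPs (default 5000).
#' @param maf_low,maf_high founder allele-frequency bounds in (0, 0.5].
#' @param n_otus number of OTUs (default 1000).
#' @param rarefaction_depth reads per sample (default 10000).
#' @param n_batches number of chronological batches (default 32).
#' @param var_u,var_m,var_e simulation-truth variance components.
#' @param diet_effect_sd per-OTU log-abundance shift scale between diets.
#' @param batch_effect_sd per-OTU per-batch log-abundance shift scale.
#' @param otu_base_sd spread of base OTU log-means.
#' @param otu_animal_sd animal-level log-abundance noise.
#' @param diet_affected_frac fraction of OTUs whose abundance responds
#'   to diet.
#' @param fixed_effect_values list of fixed-effect coefficients applied
#'   when generating phenotypes: `diet` (HF minus CO), `batch_sd`
#'   (spread of batch effects) and `covariate` (effect per SD of the
#'   trait's adjustment covariate).
#' @param geno_on_otu_frac optional host-genetic effect on the
#'   microbiota: fraction of OTUs regressed on a few SNPs (default 0,
#'   i.e. off).
#' @param seed RNG seed; every stage derives its own stream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sires = 171, sib_pairs_per_sire = 3,
                       n_snps = 5000, maf_low = 0.05, maf_high = 0.5,
                       n_otus = 1000, rarefaction_depth = 10000,
                       n_batches = 32,
                       var_u = 0.3, var_m = 0.4, var_e = 0.3,
                       diet_effect_sd = 1, batch_effect_sd = 0.5,
                       otu_base_sd = 1.5, otu_animal_sd = 0.6,
                       diet_affected_frac = 0.2,
                       fixed_effect_values = list(diet = 0.5, batch_sd = 0.3,
                                                  covariate = 0.3),
                       geno_on_otu_frac = 0,
                       seed = 1) {
  cfg <- list(
    n_sires = n_sires, sib_pairs_per_sire = sib_pairs_per_sire,
    n_snps = n_snps, maf_low = maf_low, maf_high = maf_high,
    n_otus = n_otus, rarefaction_depth = rarefaction_depth,
    n_batches = n_batches,
    var_u = var_u, var_m = var_m, var_e = var_e,
    diet_effect_sd = diet_effect_sd, batch_effect_sd = batch_effect_sd,
    otu_base_sd = otu_base_sd, otu_animal_sd = otu_animal_sd,
    diet_affected_frac = diet_affected_frac,
    fixed_effect_values = fixed_effect_values,
    geno_on_otu_frac = geno_on_otu_frac,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_sires < 1 || sib_pairs_per_sire < 1 || n_snps < 1 || n_otus < 1 ||
        n_batches < 1) stop("counts in sim_config must be positive")
    if (rarefaction_depth < 1) stop("rarefaction_depth must be >= 1")
    if (maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high) {
      stop("need 0 < maf_low <= maf_high <= 0.5")
    }
    if (var_u < 0 || var_m < 0 || var_e < 0) stop("variances must be >= 0")
  })
  structure(cfg, class = "sim_config")
}

# deterministic per-stage RNG streams derived from one run seed
stage_seed <- function(config, stage) {
  offs <- c(pedigree = 11L, genotypes = 23L, otu = 37L, phenotypes = 53L)
  (config$seed * 1009L + offs[[stage]]) %% 2147483647L
}

#' Simulate the full-sib-pair pedigree and batch structure
#'
#' Each sire contributes `sib_pairs_per_sire` full-sib pairs, each pair
#' from its own dam; within every pair one animal is fed the CO diet
#' and the other the HF diet. Pairs are assigned to batches contiguously
#' in sire order, so paternal families occupy adjacent (chronological)
#' batches — the structure that makes batch-connected validation sets
#' also sire-connected. Body-weight covariates (end of post-weaning,
#' end of test) are drawn per animal.
#'
#' @param config a `sim_config`.
#' @return a data.frame (class `population`) with one row per animal:
#'   animal_id, sire_id, dam_id, pair_id, diet, batch, weight_pw,
#'   weight_end.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "pedigree"))
  n_pairs <- config$n_sires * config$sib_pairs_per_sire
  pair_id <- seq_len(n_pairs)
  sire_of_pair <- rep(seq_len(config$n_sires), each = config$sib_pairs_per_sire)
  batch_of_pair <- ceiling(pair_id / (n_pairs / config$n_batches))
  # pair weights are homogeneous within a pair: shared pair-level mean
  # plus small individual deviation
  pw_pair <- stats::rnorm(n_pairs, 31, 3)
  end_pair <- stats::rnorm(n_pairs, 115, 3)

  pop <- data.frame(
    animal_id = sprintf("a%04d", seq_len(2 * n_pairs)),
    sire_id = sprintf("s%03d", rep(sire_of_pair, each = 2)),
    dam_id = sprintf("d%04d", rep(pair_id, each = 2)),
    pair_id = rep(pair_id, each = 2),
    diet = rep(c("CO", "HF"), n_pairs),
    batch = rep(batch_of_pair, each = 2),
    weight_pw = rep(pw_pair, each = 2) + stats::rnorm(2 * n_pairs, 0, 1),
    weight_end = rep(end_pair, each = 2) + stats::rnorm(2 * n_pairs, 0, 2),
    stringsAsFactors = FALSE
  )
  class(pop) <- c("population", "data.frame")
  pop
}

#' Simulate unlinked SNP genotypes by Mendelian gamete sampling
#'
#' Founder allele frequencies are uniform on `[maf_low, maf_high]`;
#' each sire and each dam receives two independent founder gametes, and
#' every offspring draws one allele from each parent per SNP. Full sibs
#' therefore share on average half their alleles identical-by-descent.
#'
#' @param pop a `population`.
#' @param config a `sim_config`.
#' @return a `geno_matrix` of 0/1/2 dosages (no missing values), all
#'   SNPs autosomal and mapped.
#' @export
simulate_genotypes <- function(pop, config) {
  stopifnot(inherits(pop, "population"), inherits(config, "sim_config"))
  if (nrow(pop) == 0L) stop("empty population")
  set.seed(stage_seed(config, "genotypes"))
  m <- config$n_snps
  p <- stats::runif(m, config$maf_low, config$maf_high)

  sires <- unique(pop$sire_id)
  dams <- unique(pop$dam_id)
  draw_hap <- function(n) {
    matrix(stats::rbinom(n * m, 1, rep(p, each = n)), nrow = n)
  }
  sA1 <- draw_hap(length(sires)); sA2 <- draw_hap(length(sires))
  dA1 <- draw_hap(length(dams));  dA2 <- draw_hap(length(dams))

  si <- match(pop$sire_id, sires)
  di <- match(pop$dam_id, dams)
  n <- nrow(pop)
  pick_s <- matrix(stats::rbinom(n * m, 1, 0.5), nrow = n)
  pick_d <- matrix(stats::rbinom(n * m, 1, 0.5), nrow = n)
  allele_s <- pick_s * sA1[si, , drop = FALSE] + (1 - pick_s) * sA2[si, , drop = FALSE]
  allele_d <- pick_d * dA1[di, , drop = FALSE] + (1 - pick_d) * dA2[di, , drop = FALSE]
  dos <- allele_s + allele_d
  rownames(dos) <- pop$animal_id
  colnames(dos) <- sprintf("snp%05d", seq_len(m))
  geno_matrix(dos, data.frame(snp_id = colnames(dos), chrom = "1",
                              stringsAsFactors = FALSE))
}

#' Simulate a rarefied OTU table with diet and batch structure
#'
#' Per-animal OTU log-abundances are a base OTU log-mean plus a diet
#' shift (for a configured fraction of OTUs), a batch shift, and
#' animal-level noise; counts are drawn by multinomial sampling of
#' `rarefaction_depth` reads from the softmax-normalised abundances, so
#' every row sums exactly to the depth. Optionally a fraction of OTUs
#' receives a small additive effect of a few SNP dosages, emulating
#' partial host-genetic control of the microbiota.
#'
#' @param pop a `population`.
#' @param config a `sim_config`.
#' @param geno optional `geno_matrix`, used only when
#'   `config$geno_on_otu_frac > 0`.
#' @return an `otu_table`; every row sums to `rarefaction_depth`.
#' @export
simulate_otu_table <- function(pop, config, geno = NULL) {
  stopifnot(inherits(pop, "population"), inherits(config, "sim_config"))
  if (config$n_otus < 2) stop("need at least 2 OTUs")
  set.seed(stage_seed(config, "otu"))
  n <- nrow(pop); k <- config$n_otus
  base <- stats::rnorm(k, 0, config$otu_base_sd)
  n_aff <- floor(config$diet_affected_frac * k)
  diet_shift <- numeric(k)
  affected <- integer(0)
  if (n_aff > 0) {
    affected <- sample.int(k, n_aff)
    diet_shift[affected] <- stats::rnorm(n_aff, 0, config$diet_effect_sd)
  }
  batch_shift <- matrix(stats::rnorm(config$n_batches * k, 0, config$batch_effect_sd),
                        nrow = config$n_batches)
  logab <- matrix(base, n, k, byrow = TRUE) +
    outer(as.numeric(pop$diet == "HF"), diet_shift) +
    batch_shift[pop$batch, , drop = FALSE] +
    matrix(stats::rnorm(n * k, 0, config$otu_animal_sd), n, k)

  if (config$geno_on_otu_frac > 0) {
    if (is.null(geno)) stop("geno required when geno_on_otu_frac > 0")
    n_g <- max(1L, floor(config$geno_on_otu_frac * k))
    g_otus <- sample.int(k, n_g)
    for (j in g_otus) {
      snps <- sample.int(ncol(geno$dosages), 3)
      b <- stats::rnorm(3, 0, 0.3)
      logab[, j] <- logab[, j] + geno$dosages[, snps, drop = FALSE] %*% b
    }
  }

  counts <- t(vapply(seq_len(n), function(i) {
    pr <- exp(logab[i, ] - max(logab[i, ]))
    as.integer(stats::rmultinom(1, config$rarefaction_depth, pr))
  }, integer(k)))
  rownames(counts) <- pop$animal_id
  colnames(counts) <- sprintf("otu%05d", seq_len(k))
  meta <- data.frame(animal_id = pop$animal_id, diet = pop$diet,
                     batch = pop$batch, stringsAsFactors = FALSE)
  tab <- otu_table(counts, meta)
  attr(tab, "diet_affected") <- sort(affected)
  tab
}

# draw from MVN(0, K * s2) through the eigendecomposition of K,
# zeroing numerically negative eigenvalues
rmvn_kernel <- function(k_mat, s2) {
  if (s2 == 0) return(numeric(nrow(k_mat)))
  ed <- eigen(k_mat, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  drop(ed$vectors %*% (sqrt(lam * s2) * stats::rnorm(length(lam))))
}

#' Names and adjustment covariates of the analysis traits
#'
#' Digestibility coefficients (DCE, DCOM, DCN) are adjusted for daily
#' feed intake; ADG and FCR for weight at the end of post-weaning; DFI
#' and RFI for weight at the end of test.
#' @return character vector of the seven trait names.
#' @export
trait_names <- function() c("DCE", "DCOM", "DCN", "ADG", "FCR", "RFI", "DFI")

#' Per-trait simulation-truth variance fractions
#'
#' Default pattern mirrors the trait families: digestive-efficiency
#' traits are microbiota-driven (m2 ~ 0.45, h2 ~ 0.15), growth and
#' feed-efficiency traits more genetics-driven (h2 ~ 0.3, m2 ~ 0.15).
#'
#' @return data.frame with columns trait, var_u, var_m, var_e.
#' @export
default_trait_params <- function() {
  data.frame(
    trait = trait_names(),
    var_u = c(0.15, 0.15, 0.15, 0.30, 0.30, 0.30, 0.30),
    var_m = c(0.45, 0.45, 0.45, 0.15, 0.15, 0.15, 0.15),
    var_e = c(0.40, 0.40, 0.40, 0.55, 0.55, 0.55, 0.55),
    stringsAsFactors = FALSE
  )
}

#' Simulate phenotypes under the hologenomic mixed model
#'
#' For each trait, draws u ~ MVN(0, G var_u), m ~ MVN(0, M var_m) and
#' e ~ MVN(0, I var_e) and sets y = X beta + u + m + e, where X holds
#' an intercept, the diet contrast, batch effects and the trait's
#' standardized adjustment covariate. The simulation truth (u, m,
#' variance components, fixed effects) is stored per trait.
#'
#' @param pop a `population`.
#' @param G,M relationship matrices indexed by `pop$animal_id`.
#' @param config a `sim_config`; `config$var_u/var_m/var_e` are used
#'   when `trait_params` is NULL (all traits alike).
#' @param trait_params optional data.frame as from
#'   [default_trait_params()].
#' @return list with `phenotypes` (data.frame: animal_id, diet, batch,
#'   sire_id, covariates, one column per trait) and `truth` (per-trait
#'   list of u, m, beta, variances).
#' @export
simulate_phenotypes <- function(pop, G, M, config, trait_params = NULL) {
  stopifnot(inherits(pop, "population"), inherits(config, "sim_config"))
  for (nm in c("G", "M")) {
    k_mat <- get(nm)
    if (!identical(rownames(k_mat), pop$animal_id)) {
      stop(sprintf("%s is not indexed by the population's animals", nm))
    }
    tryCatch(check_psd(k_mat, tol = 1e-6),
             error = function(e) stop(sprintf("kernel %s: %s", nm, conditionMessage(e))))
  }
  set.seed(stage_seed(config, "phenotypes"))
  if (is.null(trait_params)) {
    trait_params <- data.frame(trait = trait_names(),
                               var_u = config$var_u, var_m = config$var_m,
                               var_e = config$var_e, stringsAsFactors = FALSE)
  }
  n <- nrow(pop)
  fe <- config$fixed_effect_values
  batch_eff <- stats::rnorm(config$n_batches, 0, fe$batch_sd)
  pheno <- data.frame(
    animal_id = pop$animal_id, diet = pop$diet, batch = pop$batch,
    sire_id = pop$sire_id, weight_pw = pop$weight_pw,
    weight_end = pop$weight_end, stringsAsFactors = FALSE
  )
  truth <- list()
  for (i in seq_len(nrow(trait_params))) {
    tr <- trait_params$trait[i]
    u <- rmvn_kernel(G, trait_params$var_u[i])
    m <- rmvn_kernel(M, trait_params$var_m[i])
    e <- stats::rnorm(n, 0, sqrt(trait_params$var_e[i]))
    cov_name <- fem_covariate(tr)
    cov_val <- if (cov_name %in% names(pheno)) {
      as.numeric(scale(pheno[[cov_name]]))
    } else numeric(n)  # DFI not yet generated when DC traits need it; see below
    xb <- fe$diet * (pop$diet == "HF") + batch_eff[pop$batch] +
      fe$covariate * cov_val
    pheno[[tr]] <- xb + u + m + e
    truth[[tr]] <- list(u = u, m = m, e = e,
                        beta = c(diet = fe$diet, covariate = fe$covariate),
                        batch_eff = batch_eff,
                        var_u = trait_params$var_u[i],
                        var_m = trait_params$var_m[i],
                        var_e = trait_params$var_e[i])
  }
  # DC traits are adjusted for DFI in the analysis; regenerate their
  # fixed parts now that DFI exists so the covariate effect is real
  if ("DFI" %in% names(pheno)) {
    dfi_std <- as.numeric(scale(pheno$DFI))
    for (tr in intersect(c("DCE", "DCOM", "DCN"), names(truth))) {
      t0 <- truth[[tr]]
      pheno[[tr]] <- fe$diet * (pop$diet == "HF") + batch_eff[pop$batch] +
        fe$covariate * dfi_std + t0$u + t0$m + t0$e
    }
  }
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a complete dataset: pedigree, genotypes, kernels, OTU
#' table and phenotypes
#'
#' Convenience wrapper running every stage with streams derived from
#' one seed, building G (VanRaden) from the simulated genotypes and M
#' from the filtered OTU table.
#'
#' @param config a `sim_config`.
#' @param trait_params optional per-trait variance fractions.
#' @param filter whether to apply the default OTU filters before
#'   building M (default TRUE).
#' @return a `sim_dataset` list: population, genotypes, otu_table, G,
#'   M, phenotypes, truth.
#' @export
simulate_dataset <- function(config = sim_config(), trait_params = default_trait_params(),
                             filter = TRUE) {
  pop <- simulate_pedigree(config)
  geno <- simulate_genotypes(pop, config)
  # drop SNPs that drifted to fixation so G is well-defined
  p_hat <- colMeans(geno$dosages) / 2
  poly <- p_hat > 0 & p_hat < 1
  geno$dosages <- geno$dosages[, poly, drop = FALSE]
  geno$snp_meta <- geno$snp_meta[poly, , drop = FALSE]
  G <- build_g_matrix(geno)
  otu <- simulate_otu_table(pop, config, geno)
  otu_f <- if (filter) filter_otus(otu) else otu
  M <- build_m_matrix(otu_f)
  ph <- simulate_phenotypes(pop, G, M, config, trait_params)
  structure(list(population = pop, genotypes = geno, otu_table = otu,
                 G = G, M = M, phenotypes = ph$phenotypes, truth = ph$truth,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d animals, %d batches, %d SNPs, %d OTUs (%d in M)\n",
              nrow(x$population), length(unique(x$population$batch)),
              ncol(x$genotypes$dosages), ncol(x$otu_table$counts),
              attr(x$M, "n_otus_used")))
  invisible(x)
}
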