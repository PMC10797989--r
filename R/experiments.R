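#' Synthetic full factorial grid of per-fold accuracy records
#'
#' One record per scenario x SBE x FEM x model x trait x fold cell
#' (5 x 2 x 2 x 3 x 7 x 4 = 1680 rows) with optional injected effects,
#' used to exercise the post-hoc analysis at the design's true size.
#'
#' @param seed RNG seed.
#' @param sbe_shift accuracy increase for SBE-connected records.
#' @param trait_shift accuracy increase for digestive-efficiency traits.
#' @param noise_sd residual spread of the synthetic r values.
#' @return data.frame of accuracy records.
#' @export
synthetic_accuracy_grid <- function(seed = 1, sbe_shift = 0, trait_shift = 0,
                                    noise_sd = 0.1) {
  set.seed(seed)
  grid <- expand.grid(
    scenario = scenarios()$scenario,
    sbe_connected = c(TRUE, FALSE),
    fem_variant = c("base", "full"),
    model = c("Gen", "Micro", "Micro+Gen"),
    trait = trait_names(),
    fold = 1:4,
    stringsAsFactors = FALSE
  )
  grid$r <- stats::rnorm(nrow(grid), 0.3, noise_sd) +
    sbe_shift * grid$sbe_connected +
    trait_shift * (trait_type(grid$trait) == "digestive")
  grid
}

#' Fixed-variance Gibbs versus the closed-form mixed-model solution
#'
#' Simulates one trait with known variances on a sib-structured G,
#' runs the sampler with variance sampling disabled, and compares the
#' posterior mean of u with the closed-form mixed-model-equation
#' solution u_hat = (I + G^-1 sigma2_e / sigma2_u)^-1 (y - X b_hat).
#'
#' @param seed RNG seed.
#' @param n animals (default 100).
#' @param n_iter chain length (default 20000).
#' @return list: correlation, rmse_over_sd, n.
#' @export
experiment_mme_oracle <- function(seed = 1, n = 100, n_iter = 20000) {
  cfg <- sim_config(n_sires = n / 4, sib_pairs_per_sire = 2, n_snps = 1500,
                    n_otus = 10, rarefaction_depth = 100, n_batches = 4,
                    seed = seed)
  pop <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(pop, cfg)
  p_hat <- colMeans(geno$dosages) / 2
  keep <- p_hat > 0 & p_hat < 1
  geno$dosages <- geno$dosages[, keep, drop = FALSE]
  geno$snp_meta <- geno$snp_meta[keep, , drop = FALSE]
  G <- unclass(build_g_matrix(geno))[seq_len(n), seq_len(n)]

  set.seed(seed + 1)
  su <- 0.5; se <- 0.5
  u_true <- drop(chol(G + diag(1e-8, n)) %*% stats::rnorm(n)) * sqrt(su)
  y <- 1 + u_true + stats::rnorm(n, 0, sqrt(se))
  X <- matrix(1, n, 1)
  fit <- fit_gibbs(y, X, list(G = G),
                   mcmc = mcmc_config(n_iter, min(2000, n_iter %/% 5), 2,
                                      seed = seed),
                   fixed_variances = list(G = su, e = se))
  ed <- eigen(G, symmetric = TRUE)
  lam <- pmax(ed$values, 1e-8 * max(ed$values))
  g_inv <- ed$vectors %*% (t(ed$vectors) / lam)
  V <- G * su + diag(se, n)
  bhat <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  uhat <- solve(diag(n) + g_inv * se / su, y - drop(X %*% bhat))
  list(correlation = stats::cor(fit$effects$G, uhat),
       rmse_over_sd = sqrt(mean((fit$effects$G - uhat)^2)) / stats::sd(uhat),
       n = n)
}

#' Variance-component recovery over replicate simulations
#'
#' Each replicate simulates a ~500-animal sib-structured population
#' (83 sires x 3 pairs), builds G and M, generates one trait at the
#' given truth, and fits the Micro+Gen model with the full fixed-effect
#' design. Returns the per-replicate posterior means of the three
#' variances.
#'
#' @param seed base RNG seed.
#' @param n_reps replicates (default 10).
#' @param truth named variances (default u 0.3, m 0.4, e 0.3).
#' @param mcmc chain settings for each fit.
#' @return data.frame: rep, var_u_hat, var_m_hat, var_e_hat.
#' @export
experiment_variance_recovery <- function(seed = 1, n_reps = 10,
                                         truth = c(u = 0.3, m = 0.4, e = 0.3),
                                         mcmc = mcmc_config(6000, 2000, 4)) {
  out <- lapply(seq_len(n_reps), function(rep) {
    cfg <- sim_config(n_sires = 83, sib_pairs_per_sire = 3, n_snps = 2000,
                      n_otus = 300, rarefaction_depth = 5000, n_batches = 8,
                      var_u = truth[["u"]], var_m = truth[["m"]],
                      var_e = truth[["e"]],
                      seed = seed * 1000L + rep)
    tp <- data.frame(trait = c("ADG", "DFI"), var_u = truth[["u"]],
                     var_m = truth[["m"]], var_e = truth[["e"]])
    ds <- simulate_dataset(cfg, trait_params = tp)
    X <- fem_design(ds$phenotypes, "ADG", "full")
    fit <- fit_gibbs(ds$phenotypes$ADG, X, list(G = ds$G, M = ds$M),
                     mcmc = mcmc_config(mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                                        seed = seed * 1000L + rep))
    vm <- colMeans(fit$var_draws)
    data.frame(rep = rep, var_u_hat = vm[["G"]], var_m_hat = vm[["M"]],
               var_e_hat = vm[["e"]])
  })
  do.call(rbind, out)
}

#' Micro-versus-Gen accuracy contrast on paired synthetic traits
#'
#' Simulates one population carrying a microbiota-driven trait
#' (m2 = 0.5, h2 = 0.05, labelled DCN) and a genetics-driven trait
#' (h2 = 0.35, m2 = 0.05, labelled ADG), then cross-validates models
#' Micro and Gen in the combined-diet scenario and returns the
#' fold-averaged accuracies.
#'
#' @param seed RNG seed.
#' @param cv_mcmc chain settings for the CV fits.
#' @param n_ref,n_val reference/validation sizes (defaults 310/45).
#' @return data.frame: trait, model, r_mean.
#' @export
experiment_model_contrast <- function(seed = 1,
                                      cv_mcmc = mcmc_config(2500, 500, 2),
                                      n_ref = 310, n_val = 45) {
  cfg <- sim_config(n_sires = 83, sib_pairs_per_sire = 3, n_snps = 2000,
                    n_otus = 300, rarefaction_depth = 5000, n_batches = 16,
                    seed = seed)
  tp <- data.frame(
    trait = c("DCN", "ADG", "DFI"),
    var_u = c(0.05, 0.35, 0.30),
    var_m = c(0.50, 0.05, 0.15),
    var_e = c(0.45, 0.60, 0.55)
  )
  ds <- simulate_dataset(cfg, trait_params = tp)
  rows <- list()
  for (trait in c("DCN", "ADG")) {
    for (model in c("Micro", "Gen")) {
      cc <- cv_config(n_folds = 4, n_ref = n_ref, n_val = n_val,
                      model = model, fem_variant = "full", seed = seed)
      rec <- run_cv(ds, trait, "COHFref/COHFval", cc, mcmc = cv_mcmc)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, model = model, r_mean = mean(rec$r, na.rm = TRUE)
      )
    }
  }
  do.call(rbind, rows)
}

#' SBE-connected versus unconnected accuracy for model Micro
#'
#' Replicated simulations under a strong shared-breeding-environment
#' world: batch-structured OTU effects (per-OTU batch shifts on the
#' scale of the base abundance spread) together with batch effects on
#' the phenotype, evaluated on phenotypes not corrected for batch
#' (base adjustment). In this configuration the microbiota kernel can
#' transfer batch-level signal only to validation animals whose
#' batches overlap the reference — the mechanism the SBE contrast
#' probes. Each replicate cross-validates the microbiota-driven trait
#' with model Micro under connected and unconnected fold designs.
#'
#' @param seed base RNG seed.
#' @param n_reps replicates (default 10).
#' @param cv_mcmc chain settings for the CV fits.
#' @return data.frame: rep, r_connected, r_unconnected.
#' @export
experiment_sbe_contrast <- function(seed = 1, n_reps = 10,
                                    cv_mcmc = mcmc_config(1500, 500, 2)) {
  tp <- data.frame(
    trait = c("DCN", "DFI"),
    var_u = c(0.05, 0.30),
    var_m = c(0.50, 0.15),
    var_e = c(0.45, 0.55)
  )
  out <- lapply(seq_len(n_reps), function(rep) {
    cfg <- sim_config(n_sires = 83, sib_pairs_per_sire = 3, n_snps = 1500,
                      n_otus = 300, rarefaction_depth = 5000, n_batches = 16,
                      batch_effect_sd = 1.5,
                      fixed_effect_values = list(diet = 0.5, batch_sd = 0.7,
                                                 covariate = 0.3),
                      seed = seed * 1000L + rep)
    ds <- simulate_dataset(cfg, trait_params = tp)
    r <- vapply(c(TRUE, FALSE), function(conn) {
      cc <- cv_config(n_folds = 4, n_ref = 310, n_val = 45, model = "Micro",
                      sbe_connected = conn, fem_variant = "base",
                      seed = seed * 1000L + rep)
      rec <- run_cv(ds, "DCN", "COHFref/COHFval", cc, mcmc = cv_mcmc)
      mean(rec$r, na.rm = TRUE)
    }, numeric(1))
    data.frame(rep = rep, r_connected = r[1], r_unconnected = r[2])
  })
  do.call(rbind, out)
}

#' Hand-arithmetic kernel checks
#'
#' The 3-animal single-OTU M matrix, the 2-animal 2-SNP VanRaden G,
#' and the Hardy-Weinberg chi-square for genotype counts (50, 0, 50).
#'
#' @return list: m_toy_max_abs_error, g_toy_max_abs_error, hwe_chisq.
#' @export
experiment_kernel_checks <- function() {
  counts <- matrix(c(0, 9, 99), 3, 1,
                   dimnames = list(c("a1", "a2", "a3"), "otu1"))
  tab <- otu_table(counts, data.frame(animal_id = rownames(counts),
                                      diet = "CO", batch = 1L))
  m <- build_m_matrix(tab)
  m_expected <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3)
  g <- geno_matrix(matrix(c(0, 2, 2, 0), 2, 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))))
  g_mat <- build_g_matrix(g)
  g_expected <- matrix(c(2, -2, -2, 2), 2, 2)
  list(
    m_toy_max_abs_error = max(abs(unclass(m)[1:3, 1:3] - m_expected)),
    g_toy_max_abs_error = max(abs(unclass(g_mat)[1:2, 1:2] - g_expected)),
    hwe_chisq = hwe_test(50, 0, 50)$chisq
  )
}
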