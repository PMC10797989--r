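test_that("pedigree arithmetic follows the paired-sib design", {
  cfg <- sim_config(n_sires = 2, sib_pairs_per_sire = 1, n_snps = 10,
                    n_otus = 5, rarefaction_depth = 100, n_batches = 1, seed = 1)
  pop <- simulate_pedigree(cfg)
  expect_equal(nrow(pop), 4)
  expect_equal(sum(pop$diet == "CO"), 2)
  expect_equal(sum(pop$diet == "HF"), 2)
  expect_equal(length(unique(pop$dam_id)), 2)

  cfg2 <- sim_config(n_sires = 171, sib_pairs_per_sire = 3, n_batches = 32,
                     n_snps = 10, n_otus = 5, rarefaction_depth = 100, seed = 1)
  pop2 <- simulate_pedigree(cfg2)
  expect_equal(nrow(pop2), 1026)
  expect_equal(length(unique(pop2$batch)), 32)
  expect_equal(sum(pop2$diet == "CO"), sum(pop2$diet == "HF"))
  # each dam appears in exactly one pair, each pair split across diets
  split_ok <- tapply(pop2$diet, pop2$pair_id, function(d) setequal(d, c("CO", "HF")))
  expect_true(all(split_ok))
  expect_true(all(table(pop2$dam_id) == 2))
  # sib pairs are co-batched and batch labels are contiguous in pair order
  expect_true(all(tapply(pop2$batch, pop2$pair_id, function(b) length(unique(b))) == 1))
  expect_true(all(diff(pop2$batch[!duplicated(pop2$pair_id)]) >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_sires = 0), "positive")
  expect_error(sim_config(rarefaction_depth = 0), "rarefaction_depth")
  expect_error(sim_config(maf_low = 0), "maf_low")
  expect_error(sim_config(var_u = -1), "variances")
})

test_that("identical config and seed give identical outputs", {
  cfg <- sim_config(n_sires = 5, sib_pairs_per_sire = 2, n_snps = 50,
                    n_otus = 30, rarefaction_depth = 500, n_batches = 2, seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$population, d2$population)
  expect_identical(d1$genotypes$dosages, d2$genotypes$dosages)
  expect_identical(d1$otu_table$counts, d2$otu_table$counts)
  expect_identical(d1$phenotypes, d2$phenotypes)
})

test_that("OTU rows sum exactly to the rarefaction depth, no negatives", {
  ds <- small_dataset()
  expect_true(all(rowSums(ds$otu_table$counts) == 2000))
  expect_true(all(ds$otu_table$counts >= 0))
})

test_that("diet signal in the OTU table reflects the injected effects", {
  base_cfg <- list(n_sires = 25, sib_pairs_per_sire = 2, n_snps = 20,
                   n_otus = 100, rarefaction_depth = 5000, n_batches = 2,
                   seed = 21)
  # no injected signal -> no systematic diet difference
  cfg0 <- do.call(sim_config, c(base_cfg, list(diet_effect_sd = 0, batch_effect_sd = 0)))
  pop <- simulate_pedigree(cfg0)
  tab0 <- simulate_otu_table(pop, cfg0)
  la <- log1p(tab0$counts)
  diff0 <- colMeans(la[pop$diet == "HF", ]) - colMeans(la[pop$diet == "CO", ])
  expect_lt(abs(mean(diff0)), 0.05)

  # strong injected diet effects separate the diets on affected OTUs
  cfg1 <- do.call(sim_config, c(base_cfg, list(diet_effect_sd = 2,
                                               diet_affected_frac = 0.3)))
  tab1 <- simulate_otu_table(pop, cfg1)
  aff <- attr(tab1, "diet_affected")
  la1 <- log1p(tab1$counts)
  pvals <- vapply(aff, function(j) {
    stats::t.test(la1[pop$diet == "HF", j], la1[pop$diet == "CO", j])$p.value
  }, numeric(1))
  expect_gt(mean(pvals < 0.01), 0.5)
})

test_that("phenotype variance decomposes as configured", {
  ds <- small_dataset()
  cfg <- ds$config
  # var_u = var_m = 0 leaves only the residual
  tp0 <- data.frame(trait = "ADG", var_u = 0, var_m = 0, var_e = 0.7)
  ph0 <- simulate_phenotypes(ds$population, ds$G, ds$M, cfg, tp0)
  n <- nrow(ds$population)
  # 3-sigma sampling band for a chi-square variance estimate
  expect_lt(abs(stats::var(ph0$truth$ADG$e) - 0.7), 3 * 0.7 * sqrt(2 / (n - 1)))
  expect_equal(ph0$truth$ADG$u, rep(0, nrow(ds$population)))

  # law of total variance over repeated draws: realized variance
  # fractions track the configured ones
  fracs <- sapply(1:50, function(rep) {
    cfg_r <- ds$config
    cfg_r$seed <- 1000L + rep
    tp <- data.frame(trait = "ADG", var_u = 0.3, var_m = 0.4, var_e = 0.3)
    ph <- simulate_phenotypes(ds$population, ds$G, ds$M, cfg_r, tp)
    tr <- ph$truth$ADG
    tot <- stats::var(tr$u + tr$m + tr$e)
    c(h2 = stats::var(tr$u) / tot, m2 = stats::var(tr$m) / tot)
  })
  expect_lt(abs(mean(fracs["h2", ]) - 0.3), 0.05)
  expect_lt(abs(mean(fracs["m2", ]) - 0.4), 0.05)
})

test_that("non-PSD kernels are rejected with the kernel name", {
  ds <- small_dataset()
  bad <- ds$G
  bad[1, 2] <- bad[1, 2] + 5  # break symmetry
  expect_error(simulate_phenotypes(ds$population, bad, ds$M, ds$config),
               "G")
})
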