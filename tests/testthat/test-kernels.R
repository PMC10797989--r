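test_that("filter_otus applies both thresholds with strict inequalities", {
  tab <- toy_filter_table()
  out <- filter_otus(tab)
  expect_setequal(colnames(out$counts), c("otu_a", "otu_fill"))
  # idempotence on a table that already satisfies both rules
  out2 <- filter_otus(out)
  expect_identical(out2$counts, out$counts)
  # everything removed -> error naming both thresholds
  expect_error(filter_otus(tab, min_samples = 10, min_mean_abundance = 0.9),
               "prevalence > 10")
})

test_that("build_m_matrix reproduces the hand-computed toy and its invariants", {
  m <- build_m_matrix(toy_m_table())
  expected <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3)
  expect_equal(unname(unclass(m))[1:3, 1:3], expected, tolerance = 1e-12)
  expect_equal(attr(m, "n_otus_used"), 1L)
  # mean diagonal is (p-1)/p for centered, scaled columns
  expect_equal(mean(diag(m)), 2 / 3, tolerance = 1e-12)
  expect_silent(check_psd(m))
})

test_that("zero-variance OTU columns are dropped, making constant columns a no-op", {
  tab <- toy_m_table()
  tab2 <- tab
  tab2$counts <- cbind(tab$counts, otu_const = c(5L, 5L, 5L))
  m1 <- build_m_matrix(tab)
  expect_warning(m2 <- build_m_matrix(tab2), "zero-variance")
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
  # all columns constant -> error
  tab3 <- tab
  tab3$counts <- matrix(7L, 3, 2, dimnames = list(rownames(tab$counts), c("x", "y")))
  expect_error(build_m_matrix(tab3), "zero variance")
})

test_that("build_g_matrix reproduces the 2-animal toy and rejects bad input", {
  g <- geno_matrix(matrix(c(0, 2, 2, 0), 2, 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))))
  G <- build_g_matrix(g)
  expect_equal(unname(unclass(G))[1:2, 1:2],
               matrix(c(2, -2, -2, 2), 2, 2), tolerance = 1e-12)
  # monomorphic SNP -> error
  g_mono <- geno_matrix(matrix(c(0, 0, 1, 2), 2, 2,
                               dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(build_g_matrix(g_mono), "monomorphic")
  # duplicated animal gives identical rows and equal diagonal entries
  dos <- small_dataset()$genotypes$dosages[1:10, 1:200]
  p10 <- colMeans(dos) / 2
  dos <- dos[, p10 > 0 & p10 < 1]
  dos <- rbind(dos, dup = dos[1, ])
  rownames(dos)[11] <- "dup"
  Gd <- build_g_matrix(geno_matrix(dos))
  expect_equal(unname(Gd[11, ]), unname(Gd[1, ]), tolerance = 1e-12)
  expect_equal(Gd[11, 11], Gd[1, 1], tolerance = 1e-12)
})

test_that("both kernels are equivariant to animal permutation", {
  ds <- small_dataset()
  idx <- sample(nrow(ds$population))
  tab <- ds$otu_table
  tab$counts <- tab$counts[idx, ]
  tab$metadata <- tab$metadata[idx, ]
  m_perm <- suppressWarnings(build_m_matrix(tab))
  m_orig <- suppressWarnings(build_m_matrix(ds$otu_table))
  expect_equal(unclass(m_perm), unclass(m_orig)[idx, idx], ignore_attr = TRUE,
               tolerance = 1e-10)
  g <- ds$genotypes
  g$dosages <- g$dosages[idx, ]
  expect_equal(unclass(build_g_matrix(g)), unclass(ds$G)[idx, idx],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("Hardy-Weinberg chi-square matches hand arithmetic", {
  expect_equal(hwe_test(25, 50, 25)$chisq, 0)
  expect_equal(hwe_test(25, 50, 25)$p, 1)
  h <- hwe_test(50, 0, 50)
  expect_equal(h$chisq, 100)
  expect_lt(h$p, 1e-6)
  expect_equal(h$p, pchisq(100, 1, lower.tail = FALSE))
})

test_that("qc_genotypes applies call-rate, MAF and HWE rules", {
  set.seed(1)
  n <- 100
  # snp1: equilibrium, MAF 0.5 -> kept; snp2: (50,0,50) -> HWE fail
  # snp3: MAF 0.04 -> removed;   snp4: MAF exactly 0.05 -> kept (strict <)
  # snp5: 10% missing -> call-rate fail; snp6: on X -> removed
  s1 <- sample(rep(c(0, 1, 2), c(25, 50, 25)))
  s2 <- sample(rep(c(0, 2), c(50, 50)))
  s3 <- sample(rep(c(0, 1), c(92, 8)))
  s4 <- sample(rep(c(0, 1), c(90, 10)))
  s5 <- s1; s5[1:10] <- NA
  s6 <- s1
  # pad with equilibrium SNPs so individuals missing one of s5 still
  # clear the 95% individual call rate
  pad <- replicate(24, sample(rep(c(0, 1, 2), c(25, 50, 25))))
  colnames(pad) <- sprintf("pad%02d", 1:24)
  dos <- cbind(s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5, s6 = s6, pad)
  rownames(dos) <- sprintf("i%03d", 1:n)
  meta <- data.frame(snp_id = colnames(dos),
                     chrom = c("1", "1", "1", "1", "1", "X", rep("1", 24)))
  out <- qc_genotypes(geno_matrix(dos, meta))
  expect_setequal(colnames(out$geno$dosages),
                  c("s1", "s4", sprintf("pad%02d", 1:24)))
  rep_tab <- out$report
  expect_equal(rep_tab$removed[rep_tab$rule == "hwe"], 1)
  expect_equal(rep_tab$removed[rep_tab$rule == "maf"], 1)
  expect_equal(rep_tab$removed[rep_tab$rule == "snp_call_rate"], 1)
  expect_equal(rep_tab$removed[rep_tab$rule == "sex_or_unmapped"], 1)
  expect_false(anyNA(out$geno$dosages))
  # removed + retained add back up to the input SNP count
  expect_equal(sum(rep_tab$removed[-1]) + attr(rep_tab, "n_snps_retained"),
               ncol(dos))
})

test_that("full sibs and unrelated pairs show the expected G off-diagonals", {
  # Monte-Carlo oracle: mean realized relationship over replicate
  # simulations of sib-structured genotypes
  sib_vals <- c(); unrel_vals <- c()
  for (rep in 1:3) {
    cfg <- sim_config(n_sires = 20, sib_pairs_per_sire = 1, n_snps = 4000,
                      n_otus = 10, rarefaction_depth = 100, n_batches = 2,
                      seed = 500 + rep)
    pop <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(pop, cfg)
    p_hat <- colMeans(geno$dosages) / 2
    poly <- p_hat > 0 & p_hat < 1
    geno$dosages <- geno$dosages[, poly]
    geno$snp_meta <- geno$snp_meta[poly, ]
    G <- build_g_matrix(geno)
    pair_of <- pop$pair_id
    for (p in unique(pair_of)) {
      ij <- which(pair_of == p)
      sib_vals <- c(sib_vals, G[ij[1], ij[2]])
    }
    off <- G[pop$pair_id[row(G)] != pop$pair_id[col(G)] & row(G) < col(G)]
    unrel_vals <- c(unrel_vals, mean(off))
  }
  expect_lt(abs(mean(sib_vals) - 0.5), 0.05)
  expect_lt(abs(mean(unrel_vals)), 0.05)
})

test_that("simulated unrelated-population G has mean diagonal near 1", {
  cfg <- sim_config(n_sires = 100, sib_pairs_per_sire = 1, n_snps = 5000,
                    n_otus = 10, rarefaction_depth = 100, n_batches = 2,
                    seed = 77)
  pop <- simulate_pedigree(cfg)
  G <- build_g_matrix(simulate_genotypes(pop, cfg))
  expect_gt(mean(diag(G)), 0.9)
  expect_lt(mean(diag(G)), 1.1)
})
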