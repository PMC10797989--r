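# Shared fixtures, all built in code.

# 3-animal, 1-OTU table whose M matrix is known by hand arithmetic
toy_m_table <- function() {
  counts <- matrix(c(0, 9, 99), 3, 1,
                   dimnames = list(c("a1", "a2", "a3"), "otu1"))
  otu_table(counts, data.frame(animal_id = c("a1", "a2", "a3"),
                               diet = "CO", batch = 1L))
}

# 7 samples x 3 OTUs exercising both filter rules: otu_a passes both,
# otu_b fails the prevalence rule (present in exactly 5 samples),
# otu_c fails the abundance rule
toy_filter_table <- function() {
  total <- 100000L
  a <- rep(1000L, 7)                      # 1% everywhere
  b <- c(rep(500L, 5), 0L, 0L)            # present in exactly 5 samples
  cc <- rep(1L, 7)                        # mean abundance 1e-5, not above it
  counts <- cbind(otu_a = a, otu_b = b, otu_c = cc)
  filler <- total - rowSums(counts)
  counts <- cbind(counts, otu_fill = filler)
  rownames(counts) <- paste0("s", 1:7)
  otu_table(counts, data.frame(animal_id = rownames(counts),
                               diet = rep(c("CO", "HF"), length.out = 7),
                               batch = 1L))
}

# small but structured simulated dataset, cached per session
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_sires = 30, sib_pairs_per_sire = 3, n_snps = 600,
                        n_otus = 150, rarefaction_depth = 2000, n_batches = 8,
                        seed = 11)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

# a full factorial grid of per-fold accuracy records with noise r values
synthetic_record_grid <- function(seed = 1) {
  synthetic_accuracy_grid(seed)
}
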