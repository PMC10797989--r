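#' The five diet scenarios
#'
#' Reference/validation diet rules: within-diet (COref/COval,
#' HFref/HFval), across-diet (COref/HFval, HFref/COval), and the
#' combined scenario COHFref/COHFval, where both populations mix the
#' two diets in equal proportions.
#'
#' @return data.frame with columns scenario, ref_diet, val_diet (values
#'   "CO", "HF" or "BOTH").
#' @export
scenarios <- function() {
  data.frame(
    scenario = c("COref/COval", "HFref/HFval", "COref/HFval",
                 "HFref/COval", "COHFref/COHFval"),
    ref_diet = c("CO", "HF", "CO", "HF", "BOTH"),
    val_diet = c("CO", "HF", "HF", "CO", "BOTH"),
    stringsAsFactors = FALSE
  )
}

#' Cross-validation settings
#'
#' @param n_folds number of reference/validation samplings (default 4).
#' @param n_ref reference-population size (default 310).
#' @param n_val validation-population size (default 45).
#' @param sbe_connected whether validation animals come from batches
#'   overlapping the reference batches (TRUE) or strictly later,
#'   disjoint batches (FALSE).
#' @param fem_variant "base" (trait-specific covariate only) or "full"
#'   (adds diet and batch fixed effects).
#' @param model one of "Gen", "Micro", "Micro+Gen".
#' @param seed RNG seed for fold sampling.
#' @return a `cv_config` list.
#' @export
cv_config <- function(n_folds = 4, n_ref = 310, n_val = 45,
                      sbe_connected = TRUE, fem_variant = c("base", "full"),
                      model = c("Micro", "Gen", "Micro+Gen"), seed = 1) {
  fem_variant <- match.arg(fem_variant)
  model <- match.arg(model)
  structure(list(n_folds = n_folds, n_ref = n_ref, n_val = n_val,
                 sbe_connected = sbe_connected, fem_variant = fem_variant,
                 model = model, seed = as.integer(seed)),
            class = "cv_config")
}

# the adjustment covariate each trait is corrected for
fem_covariate <- function(trait) {
  switch(trait,
    DCE = , DCOM = , DCN = "DFI",
    ADG = , FCR = "weight_pw",
    DFI = , RFI = "weight_end",
    stop(sprintf("unknown trait '%s'", trait))
  )
}

#' Fixed-effect adjustment set for a trait
#'
#' Base variant: intercept plus the trait's covariate — daily feed
#' intake for the digestibility coefficients, weight at the end of
#' post-weaning for ADG and FCR, weight at the end of test for DFI and
#' RFI. Full variant adds the diet and batch fixed effects.
#'
#' @param trait trait name (see [trait_names()]).
#' @param variant "base" or "full".
#' @return character vector of design columns.
#' @export
fem_adjustment_sets <- function(trait, variant = c("base", "full")) {
  variant <- match.arg(variant)
  base <- c("(Intercept)", fem_covariate(trait))
  if (variant == "base") base else c(base, "diet", "batch")
}

# build the fixed-effect design matrix for a trait/variant on a
# phenotype table slice
fem_design <- function(pheno, trait, variant, batch_levels = NULL) {
  cols <- fem_adjustment_sets(trait, variant)
  x <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  cov_name <- fem_covariate(trait)
  if (is.null(pheno[[cov_name]])) {
    stop(sprintf("adjustment covariate '%s' for trait %s is missing", cov_name, trait))
  }
  x <- cbind(x, pheno[[cov_name]])
  colnames(x) <- c("(Intercept)", cov_name)
  if ("diet" %in% cols && length(unique(pheno$diet)) > 1) {
    x <- cbind(x, dietHF = as.numeric(pheno$diet == "HF"))
  }
  if ("batch" %in% cols) {
    if (is.null(batch_levels)) batch_levels <- sort(unique(pheno$batch))
    bf <- factor(pheno$batch, levels = batch_levels)
    present <- levels(droplevels(bf))
    if (length(present) > 1) {
      bm <- stats::model.matrix(~ bf)[, -1, drop = FALSE]
      # drop contrasts for absent levels to keep X full rank
      keep <- colSums(abs(bm)) > 0
      x <- cbind(x, bm[, keep, drop = FALSE])
    }
  }
  x
}

#' Construct reference/validation folds for a scenario
#'
#' Each fold samples `n_ref` reference and `n_val` validation animals
#' obeying the scenario's diet rules (equal CO/HF proportions in the
#' combined scenario). The design is forward in batch time: reference
#' animals come from the first three quarters of the batches. When
#' `sbe_connected`, validation animals are drawn from batches no
#' earlier than the midpoint of the reference window (so batches — and
#' hence sires — overlap); when not connected, validation animals come
#' only from batches strictly after the reference window. Folds differ
#' by random sampling within these pools and may overlap across
#' samplings; reference and validation are disjoint within a fold.
#'
#' @param dataset a `sim_dataset` (or any list with a `population`).
#' @param scenario one scenario name from [scenarios()].
#' @param config a [cv_config()].
#' @return list of folds, each a list(reference, validation) of animal
#'   ids, with attribute `scenario`.
#' @export
make_folds <- function(dataset, scenario, config) {
  sc <- scenarios()
  row <- sc[sc$scenario == scenario, ]
  if (nrow(row) != 1) stop(sprintf("unknown scenario '%s'", scenario))
  pop <- dataset$population
  batches <- sort(unique(pop$batch))
  b_ref_max <- batches[ceiling(0.75 * length(batches))]
  ref_batches <- batches[batches <= b_ref_max]
  mid <- ref_batches[ceiling(length(ref_batches) / 2)]
  val_batches <- if (config$sbe_connected) {
    batches[batches >= mid]
  } else {
    batches[batches > b_ref_max]
  }

  set.seed(config$seed)
  draw_set <- function(pool_ids, diets, n_total, excluded = character(0)) {
    pool <- setdiff(pool_ids, excluded)
    if (length(diets) == 1L && diets == "BOTH") {
      n_half <- c(floor(n_total / 2), ceiling(n_total / 2))
      ids <- character(0)
      for (j in 1:2) {
        d <- c("CO", "HF")[j]
        cand <- pool[pop$diet[match(pool, pop$animal_id)] == d]
        if (length(cand) < n_half[j]) {
          stop(sprintf("infeasible pool: need %d %s animals, have %d",
                       n_half[j], d, length(cand)))
        }
        ids <- c(ids, sample(cand, n_half[j]))
      }
      ids
    } else {
      cand <- pool[pop$diet[match(pool, pop$animal_id)] == diets]
      if (length(cand) < n_total) {
        stop(sprintf("infeasible pool: need %d %s animals, have %d",
                     n_total, diets, length(cand)))
      }
      sample(cand, n_total)
    }
  }

  ref_pool <- pop$animal_id[pop$batch %in% ref_batches]
  val_pool <- pop$animal_id[pop$batch %in% val_batches]
  folds <- lapply(seq_len(config$n_folds), function(f) {
    ref <- draw_set(ref_pool, row$ref_diet, config$n_ref)
    val <- draw_set(val_pool, row$val_diet, config$n_val, excluded = ref)
    list(reference = ref, validation = val)
  })
  attr(folds, "scenario") <- scenario
  attr(folds, "sbe_connected") <- config$sbe_connected
  folds
}

#' Audit folds against their scenario's rules
#'
#' Checks within-fold disjointness, diet composition, and (for
#' unconnected folds) batch disjointness.
#'
#' @param folds output of [make_folds()].
#' @param dataset the dataset the folds were drawn from.
#' @return TRUE invisibly, or an error describing the violation.
#' @export
validate_folds <- function(folds, dataset) {
  pop <- dataset$population
  sc <- scenarios()
  row <- sc[sc$scenario == attr(folds, "scenario"), ]
  chk_diet <- function(ids, rule, what, f) {
    d <- pop$diet[match(ids, pop$animal_id)]
    if (rule == "BOTH") {
      if (abs(sum(d == "CO") - sum(d == "HF")) > 1) {
        stop(sprintf("fold %d %s: diets not in equal proportions", f, what))
      }
    } else if (!all(d == rule)) {
      stop(sprintf("fold %d %s: diet rule %s violated", f, what, rule))
    }
  }
  for (f in seq_along(folds)) {
    fd <- folds[[f]]
    if (length(intersect(fd$reference, fd$validation)) > 0) {
      stop(sprintf("fold %d: reference and validation overlap", f))
    }
    chk_diet(fd$reference, row$ref_diet, "reference", f)
    chk_diet(fd$validation, row$val_diet, "validation", f)
    if (!isTRUE(attr(folds, "sbe_connected"))) {
      rb <- pop$batch[match(fd$reference, pop$animal_id)]
      vb <- pop$batch[match(fd$validation, pop$animal_id)]
      if (length(intersect(rb, vb)) > 0) {
        stop(sprintf("fold %d: unconnected design but batches overlap", f))
      }
    }
  }
  invisible(TRUE)
}

#' Pairwise shared-animal percentages across fold samplings
#'
#' For every ordered pair of samplings, |A intersect B| / |A| * 100,
#' reported separately for the reference and validation sets.
#'
#' @param folds output of [make_folds()].
#' @return data.frame: set, fold_a, fold_b, overlap_pct.
#' @export
fold_overlap <- function(folds) {
  if (length(folds) < 2) stop("need at least 2 samplings")
  rows <- list()
  for (set in c("reference", "validation")) {
    for (a in seq_along(folds)) {
      for (b in seq_along(folds)) {
        if (a == b) next
        ia <- folds[[a]][[set]]
        ib <- folds[[b]][[set]]
        rows[[length(rows) + 1L]] <- data.frame(
          set = set, fold_a = a, fold_b = b,
          overlap_pct = 100 * length(intersect(ia, ib)) / length(ia)
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the cross-validation for one trait/scenario/model cell
#'
#' For each fold, the model is fitted on the reference animals only and
#' validation animals are predicted by kernel projection (or by a joint
#' fit with masked validation phenotypes). Phenotypes adjusted for
#' fixed effects (y*) come from one full-dataset fit per (trait, model,
#' FEM variant); accuracy is the Pearson correlation between y* and
#' the prediction over the validation animals, per component (EBV, EMV,
#' EBV+EMV as available).
#'
#' @param dataset a `sim_dataset`.
#' @param trait trait name.
#' @param scenario scenario name.
#' @param config a [cv_config()].
#' @param mcmc an [mcmc_config()] for the per-fold fits.
#' @param predict_method "projection" (default) or "joint".
#' @return data.frame of accuracy records: trait, scenario, model,
#'   sbe_connected, fem_variant, fold, component, r.
#' @export
run_cv <- function(dataset, trait, scenario, config,
                   mcmc = mcmc_config(n_iter = 3000, burn_in = 1000, thin = 2),
                   predict_method = c("projection", "joint")) {
  predict_method <- match.arg(predict_method)
  pheno <- dataset$phenotypes
  model_kernels <- switch(config$model,
    "Gen" = list(G = dataset$G),
    "Micro" = list(M = dataset$M),
    "Micro+Gen" = list(G = dataset$G, M = dataset$M))
  components <- switch(config$model,
    "Gen" = "EBV", "Micro" = "EMV", "Micro+Gen" = c("EBV", "EMV", "EBV+EMV"))

  batch_levels <- sort(unique(pheno$batch))
  x_full <- fem_design(pheno, trait, config$fem_variant, batch_levels)
  y_full <- pheno[[trait]]

  # y*: fixed effects estimated once on the whole dataset
  full_fit <- fit_gibbs(y_full, x_full, model_kernels,
                        mcmc = mcmc_config(mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                                           seed = config$seed))
  y_star <- adjust_phenotypes(full_fit, y_full, x_full)
  names(y_star) <- pheno$animal_id

  folds <- make_folds(dataset, scenario, config)
  records <- list()
  for (f in seq_along(folds)) {
    fd <- folds[[f]]
    idx_ref <- match(fd$reference, pheno$animal_id)
    sub_kernels <- lapply(model_kernels, function(k) k[idx_ref, idx_ref])
    x_ref <- fem_design(pheno[idx_ref, ], trait, config$fem_variant, batch_levels)
    # guard rank after subsetting (a batch level can vanish)
    qr_x <- qr(x_ref)
    if (qr_x$rank < ncol(x_ref)) x_ref <- x_ref[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]

    if (predict_method == "projection") {
      fit <- fit_gibbs(y_full[idx_ref], x_ref, sub_kernels, mcmc = mcmc)
      preds <- lapply(components, function(cp) {
        predict(fit, cp, animals = fd$validation, kernels = model_kernels)
      })
    } else {
      idx_all <- match(c(fd$reference, fd$validation), pheno$animal_id)
      sub_all <- lapply(model_kernels, function(k) k[idx_all, idx_all])
      x_all <- fem_design(pheno[idx_all, ], trait, config$fem_variant, batch_levels)
      qr_x <- qr(x_all)
      if (qr_x$rank < ncol(x_all)) x_all <- x_all[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
      mask <- c(rep(FALSE, length(fd$reference)), rep(TRUE, length(fd$validation)))
      fit <- fit_gibbs(y_full[idx_all], x_all, sub_all, mcmc = mcmc, mask = mask)
      preds <- lapply(components, function(cp) {
        predict(fit, cp, animals = fd$validation)
      })
    }
    ys_val <- y_star[fd$validation]
    for (ci in seq_along(components)) {
      pv <- preds[[ci]]
      r <- if (stats::sd(pv) == 0 || stats::sd(ys_val) == 0) {
        warning(sprintf("fold %d component %s: degenerate prediction, r undefined",
                        f, components[ci]))
        NA_real_
      } else {
        stats::cor(ys_val, pv)
      }
      records[[length(records) + 1L]] <- data.frame(
        trait = trait, scenario = scenario, model = config$model,
        sbe_connected = config$sbe_connected, fem_variant = config$fem_variant,
        fold = f, component = components[ci], r = r,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, records)
}

#' Fold-averaged accuracies
#'
#' Mean, min and max of r over folds per trait x scenario x model x
#' SBE x FEM x component cell; undefined correlations are excluded
#' from the averages.
#'
#' @param records accuracy records from [run_cv()].
#' @return aggregated data.frame.
#' @export
summarize_accuracy <- function(records) {
  key <- c("trait", "scenario", "model", "sbe_connected", "fem_variant", "component")
  agg <- stats::aggregate(records$r, records[key], function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), min = min(v), max = max(v), n = length(v))
  })
  out <- cbind(agg[key], as.data.frame(agg$x))
  names(out)[names(out) == "mean"] <- "r_mean"
  out
}
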