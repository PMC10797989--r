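#' Trait family: growth/feed versus digestive efficiency
#'
#' @param trait trait name.
#' @return "digestive" for the digestibility coefficients, otherwise
#'   "growth_feed".
#' @export
trait_type <- function(trait) {
  ifelse(trait %in% c("DCE", "DCOM", "DCN"), "digestive", "growth_feed")
}

#' Five-effect analysis of variance on prediction accuracies
#'
#' Linear model of per-fold accuracy r on the five main design effects
#' — scenario (5 levels), SBE connection (2), trait type coded
#' growth/feed vs digestive (2), model (3) and FEM variant (2) — with
#' no interactions, tested with Type-II sums of squares.
#'
#' @param records accuracy records (one row per fold) with columns
#'   r, scenario, sbe_connected, trait, model, fem_variant.
#' @param type sum-of-squares type for [car::Anova()] (default "II").
#' @return data.frame: effect, df, sum_sq, f_value, p_value, with the
#'   residual row last.
#' @export
anova_accuracy <- function(records, type = "II") {
  records$trait_type <- trait_type(records$trait)
  effects <- c("scenario", "sbe_connected", "trait_type", "model", "fem_variant")
  for (e in effects) {
    records[[e]] <- factor(records[[e]])
    if (nlevels(records[[e]]) < 2) {
      stop(sprintf("effect '%s' has a single level", e))
    }
  }
  fit <- stats::lm(r ~ scenario + sbe_connected + trait_type + model + fem_variant,
                   data = records)
  if (stats::sd(records$r) == 0) {
    # a constant response carries no evidence for any effect
    df <- vapply(records[effects], function(f) nlevels(f) - 1L, integer(1))
    return(data.frame(
      effect = c(names(df), "Residuals"),
      df = c(unname(df), nrow(records) - sum(df) - 1L),
      sum_sq = 0, f_value = c(rep(0, length(df)), NA),
      p_value = c(rep(1, length(df)), NA), stringsAsFactors = FALSE
    ))
  }
  tab <- car::Anova(fit, type = type)
  out <- data.frame(
    effect = rownames(tab),
    df = tab$Df,
    sum_sq = tab$`Sum Sq`,
    f_value = tab$`F value`,
    p_value = tab$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Pairwise Welch comparisons with Bonferroni correction
#'
#' For every pair of groups, the unequal-variance (Welch) t statistic
#' with Satterthwaite degrees of freedom and a two-sided p-value;
#' adjusted p-values are the raw p multiplied by the number of pairs,
#' capped at 1. Pairs where either group has fewer than two
#' observations (or zero variance in both) are left undefined.
#'
#' @param values numeric vector of observations (e.g. accuracies).
#' @param groups grouping factor of the same length.
#' @return list with matrices `t`, `df`, `p` (raw) and `p_adj`
#'   (Bonferroni), group labels as dimnames, and `method = "bonferroni"`.
#' @export
welch_pairwise <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  labs <- levels(groups)
  k <- length(labs)
  tmat <- dfmat <- pmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  n_pairs <- k * (k - 1) / 2
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      xa <- values[groups == labs[a]]
      xb <- values[groups == labs[b]]
      if (length(xa) < 2 || length(xb) < 2) next
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        if (mean(xa) == mean(xb)) { pmat[a, b] <- pmat[b, a] <- 1 }
        next
      }
      tt <- stats::t.test(xa, xb, var.equal = FALSE)
      tmat[a, b] <- tmat[b, a] <- unname(tt$statistic)
      dfmat[a, b] <- dfmat[b, a] <- unname(tt$parameter)
      pmat[a, b] <- pmat[b, a] <- tt$p.value
    }
  }
  list(t = tmat, df = dfmat, p = pmat,
       p_adj = pmin(pmat * n_pairs, 1),
       method = "bonferroni")
}

#' Classify a prediction accuracy into the low/moderate/high bands
#'
#' Accuracies below 0.40 are low, between 0.40 and 0.60 (inclusive)
#' moderate, and above 0.60 high.
#'
#' @param r correlation value(s).
#' @return character vector of bands.
#' @export
classify_accuracy <- function(r) {
  if (any(!is.finite(r))) stop("r must be finite")
  ifelse(r < 0.40, "low", ifelse(r <= 0.60, "moderate", "high"))
}
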