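#' Prior specification for the Bayesian mixed models
#'
#' Variance components get scaled-inverse chi-square priors with `df0`
#' degrees of freedom and scale derived from the sample phenotype
#' variance: each random term k receives S0_k = var(y) * R2_k *
#' (df0 + 2) / df0 with R2 = `r2` split equally across the random
#' terms, and the residual receives the (1 - R2) share. Fixed effects
#' get a zero-mean Gaussian prior with variance `fixed_var`.
#'
#' @param df0 prior degrees of freedom (default 5).
#' @param fixed_var fixed-effect prior variance (default 1e10, i.e.
#'   effectively flat).
#' @param r2 total prior variance share assigned to the random terms
#'   (default 0.5).
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(df0 = 5, fixed_var = 1e10, r2 = 0.5) {
  stopifnot(df0 > 0, fixed_var > 0, r2 > 0, r2 < 1)
  structure(list(df0 = df0, fixed_var = fixed_var, r2 = r2),
            class = "prior_spec")
}

#' MCMC chain settings
#'
#' @param n_iter total Gibbs iterations (default 60000).
#' @param burn_in discarded initial iterations (default 10000).
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param seed RNG seed for the chain, or NULL to use the current RNG
#'   state.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 60000, burn_in = 10000, thin = 10, seed = NULL) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_config")
}

# eigendecomposition of a kernel with near-null eigenvalues floored,
# reused for full conditionals, quadratic forms and projections
kernel_eigen <- function(k_mat, name, floor_tol = 1e-8) {
  tryCatch(check_psd(k_mat), error = function(e) {
    stop(sprintf("kernel %s: %s", name, conditionMessage(e)))
  })
  ed <- eigen(k_mat, symmetric = TRUE)
  lam_max <- max(ed$values)
  floor_val <- floor_tol * lam_max
  list(vectors = ed$vectors, values = pmax(ed$values, floor_val))
}

#' Gibbs sampler for mixed models with relationship-matrix kernels
#'
#' Fits y = X beta + sum_k u_k + e, with u_k ~ N(0, K_k sigma2_k) for
#' each supplied kernel (all animals have records, so the random-effect
#' incidence matrices are identities), e ~ N(0, I sigma2_e), a Gaussian
#' prior on beta and scaled-inverse chi-square priors on all variances.
#' Each Gibbs cycle samples beta from its joint multivariate-normal
#' full conditional, each u_k in the eigenbasis of its kernel (where
#' the full-conditional precision I/sigma2_e + K^-1/sigma2_k is
#' diagonal), and each variance from its scaled-inverse chi-square full
#' conditional. Kernel eigenvalues below 1e-8 of the largest are
#' floored before inversion.
#'
#' @param y numeric response; entries may be NA only where `mask` is
#'   TRUE.
#' @param X fixed-effect design matrix (full column rank), or NULL for
#'   intercept only.
#' @param kernels named list of relationship matrices (e.g.
#'   `list(G = ..., M = ...)`), all indexed like `y`.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param fixed_variances optional named list (one entry per kernel
#'   plus `e`) fixing all variances and disabling their sampling.
#' @param mask optional logical vector; TRUE entries are treated as
#'   unobserved and their phenotypes imputed from the current model
#'   draw each iteration (joint fit with masked validation records).
#' @return a `holopred_fit`: posterior means of beta and each effect
#'   vector, retained draws of beta and the variances, per-draw
#'   variance ratios, effective sample sizes, and the kernel
#'   eigendecompositions used.
#' @export
fit_gibbs <- function(y, X = NULL, kernels, priors = prior_spec(),
                      mcmc = mcmc_config(), fixed_variances = NULL,
                      mask = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, length(kernels) >= 1)
  if (is.null(names(kernels)) || any(names(kernels) == "")) {
    stop("kernels must be a named list")
  }
  if (qr(X)$rank < ncol(X)) stop("X is not full column rank")
  if (is.null(mask)) mask <- rep(FALSE, n)
  obs <- !mask
  if (anyNA(y[obs])) stop("y has NA outside the mask")
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)

  eig <- lapply(names(kernels), function(nm) kernel_eigen(kernels[[nm]], nm))
  names(eig) <- names(kernels)
  nk <- length(kernels)
  p <- ncol(X)
  df0 <- priors$df0

  vy <- stats::var(y[obs])
  s0 <- c(vapply(seq_len(nk), function(k) vy * (priors$r2 / nk) * (df0 + 2) / df0,
                 numeric(1)),
          vy * (1 - priors$r2) * (df0 + 2) / df0)
  names(s0) <- c(names(kernels), "e")

  sample_var <- is.null(fixed_variances)
  if (sample_var) {
    sig2 <- stats::setNames(c(rep(vy * priors$r2 / nk, nk), vy * (1 - priors$r2)),
                            c(names(kernels), "e"))
  } else {
    miss <- setdiff(c(names(kernels), "e"), names(fixed_variances))
    if (length(miss)) stop("fixed_variances missing: ", paste(miss, collapse = ", "))
    sig2 <- unlist(fixed_variances)[c(names(kernels), "e")]
  }

  y_work <- y
  y_work[mask] <- mean(y[obs])
  xtx <- crossprod(X)
  beta <- drop(qr.solve(xtx + diag(1e-8, p), crossprod(X, y_work)))
  u <- lapply(kernels, function(k) numeric(n))

  keep <- seq(mcmc$burn_in + mcmc$thin, mcmc$n_iter, by = mcmc$thin)
  n_keep <- length(keep)
  beta_draws <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  var_draws <- matrix(NA_real_, n_keep, nk + 1,
                      dimnames = list(NULL, c(names(kernels), "e")))
  u_sum <- lapply(u, function(v) numeric(n))
  s <- 0L

  for (it in seq_len(mcmc$n_iter)) {
    total_u <- Reduce(`+`, u)
    # impute masked records from the current draw
    if (any(mask)) {
      mu_mask <- drop(X[mask, , drop = FALSE] %*% beta) + total_u[mask]
      y_work[mask] <- mu_mask + stats::rnorm(sum(mask), 0, sqrt(sig2[["e"]]))
    }
    # beta | rest
    r_beta <- y_work - total_u
    prec_b <- xtx / sig2[["e"]] + diag(1 / priors$fixed_var, p)
    ch <- chol(prec_b)
    mean_b <- backsolve(ch, forwardsolve(t(ch), crossprod(X, r_beta) / sig2[["e"]]))
    beta <- drop(mean_b + backsolve(ch, stats::rnorm(p)))
    xb <- drop(X %*% beta)

    # each random vector in its kernel eigenbasis
    for (k in seq_len(nk)) {
      nm <- names(kernels)[k]
      r <- y_work - xb - (total_u - u[[nm]])
      v <- eig[[nm]]$vectors
      lam <- eig[[nm]]$values
      rt <- crossprod(v, r)
      prec <- 1 / sig2[["e"]] + 1 / (lam * sig2[[nm]])
      alpha <- drop(rt) / sig2[["e"]] / prec + stats::rnorm(n) / sqrt(prec)
      u_new <- drop(v %*% alpha)
      total_u <- total_u - u[[nm]] + u_new
      u[[nm]] <- u_new
      if (sample_var) {
        quad <- sum(alpha^2 / lam)
        sig2[[nm]] <- (quad + df0 * s0[[nm]]) / stats::rchisq(1, df0 + n)
      }
    }

    e <- y_work - xb - total_u
    if (sample_var) {
      sig2[["e"]] <- (sum(e^2) + df0 * s0[["e"]]) / stats::rchisq(1, df0 + n)
    }
    if (!all(is.finite(sig2))) {
      stop(sprintf("divergent variance draw at iteration %d", it))
    }

    if (it %in% keep) {
      s <- s + 1L
      beta_draws[s, ] <- beta
      var_draws[s, ] <- sig2
      for (k in names(u)) u_sum[[k]] <- u_sum[[k]] + u[[k]]
    }
  }

  effects <- lapply(u_sum, function(v) v / n_keep)
  structure(list(
    beta_mean = colMeans(beta_draws),
    effects = effects,
    beta_draws = beta_draws,
    var_draws = var_draws,
    ess = apply(var_draws, 2, ess_acf),
    kernel_names = names(kernels),
    eigen = eig,
    animal_ids = rownames(kernels[[1]]),
    mask = mask,
    priors = priors, mcmc = mcmc,
    fixed_variances = fixed_variances
  ), class = "holopred_fit")
}

# effective sample size from the autocorrelation function, truncated at
# the first negative estimate
ess_acf <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(ac))
}

#' @export
print.holopred_fit <- function(x, ...) {
  vm <- colMeans(x$var_draws)
  cat(sprintf("<holopred_fit> kernels: %s; posterior mean variances: %s\n",
              paste(x$kernel_names, collapse = ", "),
              paste(sprintf("%s=%.3f", names(vm), vm), collapse = ", ")))
  invisible(x)
}

#' Predict breeding and microbiota values
#'
#' For training animals, returns the posterior mean effects. For
#' animals outside the training set, uses the kernel projection
#' K[val, train] K[train, train]^-1 u_train (with the training-kernel
#' inverse taken through the floored eigendecomposition stored in the
#' fit). `component` selects the genomic effect (EBV), the microbiota
#' effect (EMV), or their sum.
#'
#' @param object a `holopred_fit`.
#' @param component one of "EBV", "EMV", "EBV+EMV".
#' @param animals ids of the animals to predict (default: training
#'   animals).
#' @param kernels named list of full relationship matrices covering
#'   training and requested animals; required for out-of-sample
#'   prediction.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.holopred_fit <- function(object, component = c("EBV", "EMV", "EBV+EMV"),
                                 animals = NULL, kernels = NULL, ...) {
  component <- match.arg(component)
  comp_kernels <- switch(component,
    "EBV" = "G", "EMV" = "M", "EBV+EMV" = c("G", "M"))
  missing_k <- setdiff(comp_kernels, object$kernel_names)
  if (length(missing_k)) {
    stop(sprintf("component %s needs kernel(s) %s, absent from this fit",
                 component, paste(missing_k, collapse = ", ")))
  }
  train <- object$animal_ids
  if (is.null(animals)) animals <- train
  in_train <- animals %in% train
  out <- stats::setNames(numeric(length(animals)), animals)
  for (nm in comp_kernels) {
    eff <- object$effects[[nm]]
    if (any(in_train)) {
      out[in_train] <- out[in_train] + eff[match(animals[in_train], train)]
    }
    if (any(!in_train)) {
      if (is.null(kernels) || is.null(kernels[[nm]])) {
        stop(sprintf("full kernel %s required to predict new animals", nm))
      }
      k_full <- kernels[[nm]]
      k_vt <- k_full[animals[!in_train], train, drop = FALSE]
      ed <- object$eigen[[nm]]
      # K_tt^-1 u through the floored spectral inverse
      kinv_u <- drop(ed$vectors %*% (crossprod(ed$vectors, eff) / ed$values))
      out[!in_train] <- out[!in_train] + drop(k_vt %*% kinv_u)
    }
  }
  out
}

#' Adjust phenotypes for fixed effects
#'
#' y* = y - X beta_hat, with beta_hat the posterior mean fixed effects
#' of a fit on the whole dataset.
#'
#' @param fit a `holopred_fit` on the full dataset with the same X.
#' @param y phenotype vector.
#' @param X the fixed-effect design used in the fit.
#' @return numeric vector y*.
#' @export
adjust_phenotypes <- function(fit, y, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(fit$beta_mean) || nrow(X) != length(y)) {
    stop("dimension mismatch between y, X and the fitted coefficients")
  }
  y - drop(X %*% fit$beta_mean)
}

#' Per-draw heritability and microbiability
#'
#' h2 = sigma2_u / (sigma2_u + sigma2_m + sigma2_e) and m2 =
#' sigma2_m / total per retained draw; components absent from the
#' model contribute zero.
#'
#' @param fit a `holopred_fit`.
#' @return list with per-draw vectors `h2`, `m2` and a `summary`
#'   data.frame (posterior mean and central 95% interval).
#' @export
variance_ratios <- function(fit) {
  vd <- fit$var_draws
  get0 <- function(nm) if (nm %in% colnames(vd)) vd[, nm] else 0
  total <- get0("G") + get0("M") + vd[, "e"]
  h2 <- get0("G") / total
  m2 <- get0("M") / total
  if (length(h2) == 1L) h2 <- rep(h2, nrow(vd))
  if (length(m2) == 1L) m2 <- rep(m2, nrow(vd))
  summ <- data.frame(
    ratio = c("h2", "m2"),
    mean = c(mean(h2), mean(m2)),
    lower = c(stats::quantile(h2, 0.025), stats::quantile(m2, 0.025)),
    upper = c(stats::quantile(h2, 0.975), stats::quantile(m2, 0.975))
  )
  list(h2 = h2, m2 = m2, summary = summ)
}
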