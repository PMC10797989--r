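#' Average daily gain
#'
#' Body-weight gain over the test period divided by days on test.
#'
#' @param gain body-weight gain, kg.
#' @param days days on test; must be > 0.
#' @return ADG in kg/day.
#' @export
compute_adg <- function(gain, days) {
  if (any(days <= 0)) stop("days on test must be > 0")
  gain / days
}

#' Feed conversion ratio
#'
#' Daily feed intake divided by average daily gain (kg feed per kg
#' gain).
#'
#' @param dfi daily feed intake, kg/day.
#' @param adg average daily gain, kg/day; must be > 0.
#' @return FCR in kg/kg.
#' @export
compute_fcr <- function(dfi, adg) {
  if (any(adg <= 0)) stop("ADG must be > 0")
  dfi / adg
}

#' Residual feed intake
#'
#' RFI is the residual of one ordinary-least-squares regression of DFI
#' on ADG, lean meat percentage, carcass yield and average metabolic
#' body weight, fitted jointly across both diets. The average metabolic
#' body weight is the mean of start and end test weights raised to
#' `mbw_exponent`. Animals with any missing covariate get NA.
#'
#' @param table data.frame with columns dfi, adg, lean_pct,
#'   carcass_yield, and either ambw or (weight_start, weight_end).
#' @param mbw_exponent metabolic body-weight exponent (default 0.60).
#' @return numeric vector of residuals (kg/day), one per row.
#' @export
compute_rfi <- function(table, mbw_exponent = 0.60) {
  need <- c("dfi", "adg", "lean_pct", "carcass_yield")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(table$ambw)) {
    if (is.null(table$weight_start) || is.null(table$weight_end)) {
      stop("need ambw or weight_start + weight_end")
    }
    table$ambw <- ((table$weight_start + table$weight_end) / 2)^mbw_exponent
  }
  complete <- stats::complete.cases(table[, c(need, "ambw")])
  if (sum(complete) < 6) stop("need at least 6 animals with complete covariates")
  fit <- stats::lm(dfi ~ adg + lean_pct + carcass_yield + ambw,
                   data = table[complete, ])
  if (fit$rank < 5L) {
    ali <- stats::alias(fit)$Complete
    stop("rank-deficient RFI design; collinear columns: ",
         paste(rownames(ali), collapse = ", "))
  }
  out <- rep(NA_real_, nrow(table))
  out[complete] <- stats::residuals(fit)
  out
}
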