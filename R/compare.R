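## Model comparison: likelihood-ratio tests for nested fits, AIC for any
## pair of fits on the same data.

.same_data <- function(a, b) {
  fa <- a$fingerprint; fb <- b$fingerprint
  identical(fa$pair_ids, fb$pair_ids) &&
    fa$n_events == fb$n_events &&
    isTRUE(all.equal(fa$exposure_min, fb$exposure_min, tolerance = 1e-6))
}

## does scheme `fine` refine scheme `coarse`? (every fine class maps into
## exactly one coarse class, edge-wise, on the same space)
.refines <- function(fine, coarse) {
  if (fine$space_name != coarse$space_name) return(FALSE)
  if (!identical(names(fine$class), names(coarse$class))) return(FALSE)
  map <- tapply(unname(coarse$class[names(fine$class)]),
                factor(fine$class, levels = fine$classes),
                function(x) length(unique(x)))
  all(map == 1L)
}

.coef_set <- function(fit) {
  aff <- fit$flags$affected
  if (is.null(aff)) return(character(0))
  unlist(lapply(names(aff), function(v) paste(v, aff[[v]], sep = "@")))
}

#' Likelihood-ratio test between nested CTMC fits
#'
#' Tests the restriction taking the full model down to the nested one:
#' `stat = 2 * (loglik_full - loglik_nested)`, referred to a chi-squared
#' distribution with `df = k_full - k_nested` degrees of freedom.  Nesting
#' is verified structurally: either the nested fit's tying scheme is a
#' coarsening of the full fit's scheme (edge-wise, e.g. memory-free or
#' initiator-only under the full 24-class scheme), or the schemes are
#' identical and the nested fit's covariate-coefficient set is a subset of
#' the full fit's.  Non-nested fits (e.g. the 12-state full model against
#' the 8-state one-step-memory model) signal an error of class
#' `pairlead_not_nested`; compare those with [aic_compare()].
#'
#' @param fit_full,fit_nested `ctmc_fit` objects on the same data.
#' @return an object of class `ctmc_lrt`: list with `stat`, `df`, `p`.
#' @export
lrt <- function(fit_full, fit_nested) {
  stopifnot(inherits(fit_full, "ctmc_fit"), inherits(fit_nested, "ctmc_fit"))
  if (!.same_data(fit_full, fit_nested))
    stop("fits are not on the same data (fingerprint mismatch)")
  not_nested <- function(why)
    stop(errorCondition(paste0("models are not nested: ", why,
                               " — use aic_compare()"),
                        class = c("pairlead_not_nested", "error")))
  if (fit_full$space_name != fit_nested$space_name)
    not_nested(sprintf("different state spaces ('%s' vs '%s')",
                       fit_full$space_name, fit_nested$space_name))
  same_scheme <- identical(fit_full$scheme$class, fit_nested$scheme$class)
  if (!same_scheme && !.refines(fit_full$scheme, fit_nested$scheme))
    not_nested(sprintf("scheme '%s' does not coarsen '%s'",
                       fit_nested$scheme$name, fit_full$scheme$name))
  cf <- .coef_set(fit_full); cn <- .coef_set(fit_nested)
  if (!all(cn %in% cf))
    not_nested("nested fit has coefficients absent from the full fit")
  if (!same_scheme && length(cn))
    not_nested("covariates combined with a scheme change")
  df <- fit_full$k - fit_nested$k
  if (df <= 0) not_nested("no free-parameter difference")
  stat <- 2 * (fit_full$loglik - fit_nested$loglik)
  if (stat < -1e-6)
    warning("negative LRT statistic (", format(stat),
            "): check convergence of the full fit")
  stat <- max(stat, 0)
  structure(list(stat = stat, df = df,
                 p = pchisq(stat, df, lower.tail = FALSE)),
            class = "ctmc_lrt")
}

#' @export
print.ctmc_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi-squared = %.3f, df = %d, p = %.4g\n",
              x$stat, x$df, x$p))
  invisible(x)
}

#' AIC difference between two fits on the same data
#'
#' Returns `AIC(b) - AIC(a)`: positive values favour model `a`.  For
#' nested fits this equals the LRT statistic minus twice the
#' degree-of-freedom difference.  Fits on different data are refused.
#'
#' @param fit_a,fit_b `ctmc_fit` objects.
#' @return the signed AIC difference.
#' @export
aic_compare <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "ctmc_fit"), inherits(fit_b, "ctmc_fit"))
  if (!.same_data(fit_a, fit_b))
    stop("fits are not on the same data (fingerprint mismatch)")
  fit_b$aic - fit_a$aic
}

#' AIC difference implied by a likelihood-ratio statistic
#'
#' For nested models, `delta AIC = stat - 2 * df`: the improvement in
#' twice-log-likelihood minus the parameter penalty.  Useful to check the
#' internal consistency of (statistic, df, delta-AIC) triples.
#'
#' @param stat likelihood-ratio statistic.
#' @param df extra free parameters of the larger model.
#' @return numeric delta AIC (positive favours the larger model).
#' @export
delta_aic_from_lrt <- function(stat, df) stat - 2 * df
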