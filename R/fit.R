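#' Covariate specification for log-linear intensity effects
#'
#' Describes how pair-level temperament scores enter the transition
#' intensities.  Each covariate acts multiplicatively on a set of
#' transition classes: pair p's intensity on class c is
#' `q_c * exp(beta_{c,k} * (x_{p,k} - center_k))`.  By default both
#' covariates (the bold and the shy fish's temperament scores) affect every
#' class; the `"own"` restriction lets a fish's score affect only its own
#' moves (the classes whose mover matches it), fixing the partner effects
#' at zero.
#'
#' @param affected `"all"`, `"own"`, or a named list mapping covariate name
#'   to a character vector of class labels.
#' @param transform `"identity"` (default) or `"log"`: applied to the raw
#'   scores before centering (scores are rate ratios and right-skewed, so a
#'   log transform is sometimes preferred).
#' @param centering optional named numeric offsets; default: across-pair
#'   means of the (transformed) covariates.
#' @return an object of class `covariate_spec`.
#' @export
covariate_spec <- function(affected = "all",
                           transform = c("identity", "log"),
                           centering = NULL) {
  transform <- match.arg(transform)
  if (is.character(affected)) affected <- match.arg(affected, c("all", "own"))
  structure(list(affected = affected, transform = transform,
                 centering = centering),
            class = "covariate_spec")
}

## expand a covariate_spec to the classes each covariate touches
.affected_classes <- function(spec, scheme, space, vars) {
  if (is.list(spec$affected)) {
    stopifnot(all(names(spec$affected) %in% vars))
    out <- lapply(vars, function(v) {
      cl <- spec$affected[[v]]
      if (is.null(cl)) character(0) else {
        stopifnot(all(cl %in% scheme$classes))
        cl
      }
    })
    return(setNames(out, vars))
  }
  if (spec$affected == "all")
    return(setNames(rep(list(scheme$classes), length(vars)), vars))
  ## "own": x_bold -> classes moved by the bold fish, x_shy -> shy classes
  mover_of_class <- tapply(space$edges$mover, factor(scheme$class,
                                                     levels = scheme$classes),
                           function(m) unique(m))
  stopifnot(all(lengths(mover_of_class) == 1L))
  mover_of_class <- unlist(mover_of_class)
  out <- lapply(vars, function(v) {
    f <- switch(v, x_bold = "bold", x_shy = "shy",
                stop("'own' restriction needs covariates named x_bold/x_shy, got ", v))
    scheme$classes[mover_of_class == f]
  })
  setNames(out, vars)
}

.fingerprint <- function(ps) {
  list(n_pairs = length(ps$pair_ids),
       pair_ids = sort(ps$pair_ids),
       n_events = sum(ps$N),
       exposure_min = round(sum(ps$E), 6))
}

.new_fit <- function(scheme, space_name, rates, coefficients, centering,
                     loglik, k, converged, grad_norm, n_events, exposure,
                     fingerprint, flags = list()) {
  structure(list(scheme = scheme, space_name = space_name,
                 rates = rates, log_rates = log(rates),
                 coefficients = coefficients, centering = centering,
                 loglik = loglik, k = k, aic = 2 * k - 2 * loglik,
                 converged = converged, grad_norm = grad_norm,
                 n_events = n_events, exposure_min = exposure,
                 fingerprint = fingerprint, flags = flags),
            class = "ctmc_fit")
}

#' @export
print.ctmc_fit <- function(x, ...) {
  cat(sprintf("<ctmc_fit: scheme '%s' on %s, k = %d>\n",
              x$scheme$name, x$space_name, x$k))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, converged: %s\n",
              x$loglik, x$aic, x$converged))
  tab <- data.frame(rate_per_min = round(x$rates, 4),
                    n_events = x$n_events,
                    exposure_min = round(x$exposure_min, 2))
  print(utils::head(tab, 12))
  if (nrow(tab) > 12) cat("  ...", nrow(tab) - 12, "more classes\n")
  if (!is.null(x$coefficients)) {
    nz <- x$coefficients[rowSums(x$coefficients != 0, na.rm = TRUE) > 0, ,
                         drop = FALSE]
    cat("  coefficients on", nrow(nz), "classes\n")
  }
  invisible(x)
}

#' @export
logLik.ctmc_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Closed-form maximum-likelihood intensities
#'
#' With exactly observed transition times and no covariates, the MLE of a
#' class intensity is events/exposure: the number of observed transitions
#' of the class divided by the total time spent in the class's source
#' states.  Classes with zero exposure are non-estimable and reported as
#' `NA`; classes with exposure but no events estimate to 0.
#'
#' @param trajs list of `ctmc_trajectory` (or one).
#' @param scheme a `tying_scheme` on the trajectories' space.
#' @param pair_ids optional pair ids parallel to `trajs`.
#' @return a `ctmc_fit` with per-class intensities (per minute), the
#'   log-likelihood at the estimate, `k` = number of classes, and AIC.
#' @export
mle_closed_form <- function(trajs, scheme, pair_ids = NULL) {
  ps <- pair_stats(trajs, scheme, pair_ids)
  n <- colSums(ps$N)
  E <- colSums(ps$E)
  rates <- ifelse(E > 0, n / E, NA_real_)
  names(rates) <- scheme$classes
  ll <- .loglik_from_stats(ps$N, ps$E, rates)
  .new_fit(scheme, scheme$space_name, rates, NULL, NULL, ll,
           k = scheme$n_classes, converged = TRUE, grad_norm = 0,
           n_events = n, exposure = E, fingerprint = .fingerprint(ps),
           flags = list(non_estimable = scheme$classes[E == 0],
                        zero_events = scheme$classes[E > 0 & n == 0],
                        method = "closed_form"))
}

## Newton-Raphson with step halving for one class's parameters
## theta = (log q, beta...); nll is a Poisson-type convex function
##   f(theta) = sum_p [ q m_p E_p - n_p (log q + x_p' beta) ]
## X: pairs x (1 + n_covariates) design (first column 1), n, E vectors.
.fit_class <- function(n, E, X, start = NULL, tol = 1e-10, maxit = 60L) {
  keep <- E > 0
  n <- n[keep]; E <- E[keep]; X <- X[keep, , drop = FALSE]
  p <- ncol(X)
  theta <- if (is.null(start)) c(log(max(sum(n), 0.5) / sum(E)), rep(0, p - 1L))
           else start
  nll <- function(th) {
    mu <- E * exp(drop(X %*% th))
    sum(mu) - sum(n * drop(X %*% th))
  }
  f <- nll(theta)
  grad <- NULL
  for (it in seq_len(maxit)) {
    mu <- E * exp(drop(X %*% theta))
    grad <- drop(crossprod(X, mu - n))
    H <- crossprod(X * mu, X)
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H), 1e-8))
    ## step halving keeps the iteration inside the convex bowl
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      fc <- nll(cand)
      if (is.finite(fc) && fc <= f + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- theta; fc <- f; break }
    }
    moved <- max(abs(cand - theta))
    theta <- cand; f <- fc
    if (moved < tol && max(abs(grad)) < 1e-8 * max(1, sum(n))) break
  }
  mu <- E * exp(drop(X %*% theta))
  grad <- drop(crossprod(X, mu - n))
  list(theta = theta, grad = grad,
       converged = max(abs(grad)) < 1e-6 * max(1, sum(n)))
}

#' Maximum-likelihood fit by numerical optimization
#'
#' Maximizes the exact-observation log-likelihood over per-class baseline
#' log-intensities and (optionally) log-linear covariate coefficients.
#' Because the likelihood separates by transition class, the fit decomposes
#' into independent small Newton optimizations, one per class — a Poisson
#' regression of the class's event counts on the centered covariates with
#' the log class exposure as offset.  Baselines are parameterized on the
#' log scale, so positivity holds by construction.
#'
#' Classes with no exposure are non-estimable (`NA` rate); classes with
#' exposure but no events get rate 0 and zero coefficients, and are
#' excluded from log-scale optimization (flagged in `$flags$zero_events`).
#'
#' @param trajs list of `ctmc_trajectory` (or one).
#' @param scheme a `tying_scheme`.
#' @param covariates optional data frame: `pair_id` plus one column per
#'   covariate (e.g. `x_bold`, `x_shy`).  Each covariate must vary across
#'   pairs, otherwise an error of class `pairlead_degenerate_design` is
#'   signalled.
#' @param spec a [covariate_spec()].
#' @param pair_ids optional pair ids parallel to `trajs`.
#' @param start optional named list `list(log_rates=, coefficients=)` of
#'   starting values (useful to verify that different starts reach the same
#'   optimum).
#' @return a `ctmc_fit`; `k` counts all baseline classes plus all requested
#'   coefficients.
#' @export
mle_fit <- function(trajs, scheme, covariates = NULL,
                    spec = covariate_spec(), pair_ids = NULL,
                    start = NULL) {
  ps <- pair_stats(trajs, scheme, pair_ids)
  classes <- scheme$classes
  K <- length(classes)

  vars <- character(0)
  xc <- NULL
  affected <- NULL
  if (!is.null(covariates)) {
    vars <- setdiff(names(covariates), "pair_id")
    cov2 <- covariates
    if (spec$transform == "log") cov2[vars] <- lapply(cov2[vars], log)
    xc <- .centered_covariates(cov2, ps$pair_ids, spec$centering)
    sds <- apply(xc$x, 2, stats::sd)
    if (any(!is.finite(sds) | sds == 0))
      stop(errorCondition(paste0(
        "covariate(s) constant across pairs: ",
        paste(vars[!is.finite(sds) | sds == 0], collapse = ", "),
        " — log-linear effects are unidentifiable"),
        class = c("pairlead_degenerate_design", "error")))
    space <- .space_by_name(scheme$space_name)
    affected <- .affected_classes(spec, scheme, space, vars)
  }

  rates <- setNames(rep(NA_real_, K), classes)
  B <- if (length(vars)) matrix(0, K, length(vars),
                                dimnames = list(classes, vars)) else NULL
  grad_norm <- 0
  converged <- TRUE
  n_tot <- colSums(ps$N)
  E_tot <- colSums(ps$E)
  zero_ev <- character(0)

  for (j in seq_len(K)) {
    cl <- classes[j]
    if (E_tot[j] == 0) next           # non-estimable
    if (n_tot[j] == 0) {              # MLE is 0; coefficients unidentified
      rates[j] <- 0
      zero_ev <- c(zero_ev, cl)
      next
    }
    cvars <- if (length(vars)) vars[vapply(vars, function(v)
      cl %in% affected[[v]], logical(1))] else character(0)
    X <- cbind(intercept = rep(1, nrow(ps$N)))
    if (length(cvars)) X <- cbind(X, xc$x[, cvars, drop = FALSE])
    st <- NULL
    if (!is.null(start)) {
      st <- c(start$log_rates[cl],
              if (length(cvars)) start$coefficients[cl, cvars] else NULL)
      if (anyNA(st)) st <- NULL
    }
    res <- .fit_class(ps$N[, j], ps$E[, j], X, start = st)
    rates[j] <- exp(res$theta[1])
    if (length(cvars)) B[cl, cvars] <- res$theta[-1]
    grad_norm <- max(grad_norm, max(abs(res$grad)))
    converged <- converged && res$converged
  }

  M <- if (length(vars)) .multipliers(B, xc$x, classes) else NULL
  ll <- .loglik_from_stats(ps$N, ps$E, rates, M)
  n_coef <- if (length(vars)) sum(lengths(affected)) else 0L
  .new_fit(scheme, scheme$space_name, rates, B,
           if (is.null(xc)) NULL else xc$centering, ll,
           k = K + n_coef, converged = converged, grad_norm = grad_norm,
           n_events = n_tot, exposure = E_tot,
           fingerprint = .fingerprint(ps),
           flags = list(non_estimable = classes[E_tot == 0],
                        zero_events = zero_ev, method = "newton",
                        covariates = vars, affected = affected,
                        transform = if (length(vars)) spec$transform else NULL))
}

.space_by_name <- function(name) {
  switch(name,
         pair12 = pair_state_space(),
         loc4 = location_state_space(),
         onestep8 = one_step_state_space(),
         indiv2 = individual_state_space(),
         stop("unknown space '", name, "'"))
}
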