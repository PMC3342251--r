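## Sufficient statistics of the exact-observation CTMC likelihood.
##
## With transition times observed exactly, the log-likelihood of a set of
## trajectories under per-class intensities q_c (per minute) and per-pair
## multipliers m_{c,p} is
##
##   sum_{c,p} [ n_{c,p} * log(q_c m_{c,p}) - q_c m_{c,p} E_{c,p} ]
##
## where n_{c,p} counts observed transitions of class c for pair p and
## E_{c,p} is the class exposure: the total time pair p spent in the source
## states of class-c edges (counted once per edge).  Censored final
## sojourns contribute exposure only; unknown-prefix visits contribute
## nothing.  Everything downstream (closed-form MLE, numerical fits,
## bootstrap) works off these (n, E) matrices.

.edge_index_matrix <- function(space) {
  ns <- nrow(space$states)
  M <- matrix(NA_integer_, ns, ns)
  M[cbind(space$edges$from, space$edges$to)] <- seq_len(nrow(space$edges))
  M
}

#' Per-class event counts and exposures of one trajectory
#'
#' @param traj a `ctmc_trajectory`.
#' @param scheme a `tying_scheme` on the trajectory's space.
#' @return list with `n` (named integer vector by class) and `E_min`
#'   (named numeric vector: exposure in minutes).
#' @export
sufficient_stats <- function(traj, scheme) {
  stopifnot(inherits(traj, "ctmc_trajectory"),
            inherits(scheme, "tying_scheme"))
  if (scheme$space_name != traj$space$name)
    stop(errorCondition(
      sprintf("scheme is for space '%s' but trajectory is over '%s'",
              scheme$space_name, traj$space$name),
      class = c("pairlead_scheme_mismatch", "error")))
  space <- traj$space
  v <- traj$visits
  s <- v$state
  d <- diff(c(v$time, traj$end_time)) / 60   # sojourns in minutes
  keep <- !is.na(s)
  ns <- nrow(space$states)
  Tstate <- numeric(ns)
  if (any(keep)) {
    agg <- rowsum(d[keep], s[keep])
    Tstate[as.integer(rownames(agg))] <- agg[, 1]
  }
  ## observed transitions: consecutive known states
  M <- .edge_index_matrix(space)
  n_edges <- nrow(space$edges)
  ne <- integer(n_edges)
  if (sum(keep) > 1L) {
    ks <- s[keep]
    idx <- M[cbind(ks[-length(ks)], ks[-1])]
    if (anyNA(idx)) stop("trajectory contains a non-edge transition")
    ne <- tabulate(idx, n_edges)
  }
  cls <- factor(scheme$class, levels = scheme$classes)
  n <- as.integer(rowsum(ne, cls))
  E <- as.numeric(rowsum(Tstate[space$edges$from], cls))
  list(n = setNames(n, scheme$classes), E_min = setNames(E, scheme$classes))
}

#' Per-pair sufficient-statistic matrices for a trajectory set
#'
#' Aggregates [sufficient_stats()] over trajectories grouped by pair:
#' sessions of the same pair pool into one row.
#'
#' @param trajs list of `ctmc_trajectory` (all over the same space).
#' @param scheme a `tying_scheme`.
#' @param pair_ids optional character vector overriding each trajectory's
#'   own `pair_id`.
#' @return list with matrices `N` and `E` (pairs x classes, dimnames set)
#'   and `pair_ids`.
#' @export
pair_stats <- function(trajs, scheme, pair_ids = NULL) {
  if (inherits(trajs, "ctmc_trajectory")) trajs <- list(trajs)
  if (!length(trajs)) stop("empty trajectory set")
  if (is.null(pair_ids))
    pair_ids <- vapply(trajs, function(t)
      if (is.na(t$pair_id)) "pair" else t$pair_id, character(1))
  stopifnot(length(pair_ids) == length(trajs))
  pairs <- unique(pair_ids)
  K <- scheme$n_classes
  N <- matrix(0, length(pairs), K, dimnames = list(pairs, scheme$classes))
  E <- matrix(0, length(pairs), K, dimnames = list(pairs, scheme$classes))
  for (i in seq_along(trajs)) {
    st <- sufficient_stats(trajs[[i]], scheme)
    p <- pair_ids[i]
    N[p, ] <- N[p, ] + st$n
    E[p, ] <- E[p, ] + st$E_min
  }
  list(N = N, E = E, pair_ids = pairs)
}

## per-pair multiplier matrix m_{p,c} = exp(sum_k B[c,k] * xc[p,k]);
## B: classes x covariates, xc: pairs x covariates (already centered)
.multipliers <- function(B, xc, classes) {
  if (is.null(B) || is.null(xc)) {
    return(matrix(1, nrow = if (is.null(xc)) 1L else nrow(xc),
                  ncol = length(classes), dimnames = list(NULL, classes)))
  }
  exp(xc %*% t(B[classes, , drop = FALSE]))
}

.loglik_from_stats <- function(N, E, rates, M = NULL) {
  q <- rates[colnames(N)]
  if (anyNA(q)) {
    ## non-estimable classes (never any exposure) contribute nothing
    bad <- is.na(q) & (colSums(E) > 0 | colSums(N) > 0)
    if (any(bad)) stop("no rate supplied for class with data: ",
                       paste(colnames(N)[bad], collapse = ", "))
    q[is.na(q)] <- 0
  }
  if (is.null(M)) M <- matrix(1, nrow(N), ncol(N))
  R <- sweep(M, 2, q, "*")          # pair x class rate
  ev <- N > 0
  if (any(ev & R <= 0))
    stop(errorCondition("rate <= 0 on a class with observed transitions",
                        class = c("pairlead_invalid_parameter", "error")))
  sum(N[ev] * log(R[ev])) - sum(R * E)
}

#' Exact-observation CTMC log-likelihood
#'
#' Evaluates the exact-transition-time log-likelihood of a trajectory set
#' under a tying scheme: each sojourn contributes minus its length times
#' the total exit rate of the occupied state, each observed transition adds
#' the log of its edge's intensity, and censored final sojourns contribute
#' exposure only.  With covariates, pair p's intensity on class c is
#' `rates[c] * exp(sum_k coefficients[c,k] * (x[p,k] - centering[k]))`.
#'
#' @param trajs list of `ctmc_trajectory` (or one), all on the scheme's
#'   space.
#' @param scheme a `tying_scheme`.
#' @param rates named per-class intensities, per minute.  Classes with
#'   zero exposure may be `NA`.
#' @param coefficients optional matrix (classes x covariates) of log-linear
#'   effects; rows indexed by class label.
#' @param covariates optional data frame with column `pair_id` plus one
#'   column per covariate.
#' @param centering named offsets subtracted from each covariate before it
#'   enters the log-linear term; defaults to the across-pair means.
#' @param pair_ids optional pair ids parallel to `trajs`.
#' @return the log-likelihood (a scalar).
#' @export
exact_loglik <- function(trajs, scheme, rates, coefficients = NULL,
                         covariates = NULL, centering = NULL,
                         pair_ids = NULL) {
  ps <- pair_stats(trajs, scheme, pair_ids)
  M <- NULL
  if (!is.null(coefficients)) {
    xc <- .centered_covariates(covariates, ps$pair_ids, centering)
    B <- .coef_matrix(coefficients, scheme$classes, colnames(xc$x))
    M <- .multipliers(B, xc$x, colnames(ps$N))
  }
  .loglik_from_stats(ps$N, ps$E, rates, M)
}

.centered_covariates <- function(covariates, pair_ids, centering = NULL) {
  if (is.null(covariates)) stop("covariate values are required")
  stopifnot("pair_id" %in% names(covariates))
  idx <- match(pair_ids, covariates$pair_id)
  if (anyNA(idx)) stop("covariate values missing for pair(s): ",
                       paste(pair_ids[is.na(idx)], collapse = ", "))
  vars <- setdiff(names(covariates), "pair_id")
  x <- as.matrix(covariates[idx, vars, drop = FALSE])
  rownames(x) <- pair_ids
  if (is.null(centering)) centering <- colMeans(x)
  stopifnot(all(is.finite(centering)))
  list(x = sweep(x, 2, centering[vars], "-"), centering = centering[vars])
}

.coef_matrix <- function(coefficients, classes, vars) {
  if (is.matrix(coefficients)) {
    B <- matrix(0, length(classes), length(vars),
                dimnames = list(classes, vars))
    B[rownames(coefficients), colnames(coefficients)] <- coefficients
    return(B)
  }
  ## named list covariate -> named vector over classes
  B <- matrix(0, length(classes), length(vars),
              dimnames = list(classes, vars))
  for (v in names(coefficients)) {
    cf <- coefficients[[v]]
    B[names(cf), v] <- cf
  }
  B
}
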