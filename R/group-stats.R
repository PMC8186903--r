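#' Hedges' g with a bootstrap confidence interval
#'
#' Pooled-SD standardized mean difference (Cohen's d) with the
#' small-sample correction `J = 1 - 3 / (4 df - 1)` (df = nA + nB - 2),
#' and a seeded percentile (or BCa) bootstrap confidence interval over
#' `n_boot` resamples (default 10,000).  Hedges' g outperforms Cohen's
#' d at the small group sizes typical of neuroimaging cohorts.
#'
#' @param groupA,groupB Numeric vectors, each of length >= 2.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param type `"percentile"` (default) or `"bca"`.
#' @param seed Integer seed.
#' @return List with `hedges_g`, `cohens_d`, `ci_low`, `ci_high`,
#'   `n_boot`.
#' @export
#' @examples
#' hedges_g_boot(c(0, 1), c(1, 2), n_boot = 200, seed = 1)$hedges_g
hedges_g_boot <- function(groupA, groupB, n_boot = 10000, conf = 0.95,
                          type = c("percentile", "bca"), seed = 1) {
  type <- match.arg(type)
  nA <- length(groupA); nB <- length(groupB)
  stopifnot(nA >= 2, nB >= 2, n_boot >= 1)
  g_of <- function(a, b) {
    sp2 <- ((length(a) - 1) * stats::var(a) +
              (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 == 0) return(NA_real_)
    d <- (mean(a) - mean(b)) / sqrt(sp2)
    J <- 1 - 3 / (4 * (length(a) + length(b) - 2) - 1)
    d * J
  }
  g <- g_of(groupA, groupB)
  if (is.na(g)) stop("zero pooled variance: effect size undefined")
  J <- 1 - 3 / (4 * (nA + nB - 2) - 1)
  local_rng(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    g_of(groupA[sample.int(nA, replace = TRUE)],
         groupB[sample.int(nB, replace = TRUE)]),
    numeric(1))
  boots <- boots[!is.na(boots)]
  alpha <- 1 - conf
  if (type == "percentile") {
    ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2)))
  } else {
    ## BCa: bias correction from the bootstrap distribution, acceleration
    ## from a jackknife over both groups
    z0 <- stats::qnorm(mean(boots < g))
    jack <- c(
      vapply(seq_len(nA), function(i) g_of(groupA[-i], groupB), numeric(1)),
      vapply(seq_len(nB), function(i) g_of(groupA, groupB[-i]), numeric(1)))
    jm <- mean(jack)
    acc <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
    zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
    ci <- unname(stats::quantile(boots, adj))
  }
  list(hedges_g = g, cohens_d = g / J, ci_low = ci[1], ci_high = ci[2],
       n_boot = n_boot)
}

#' Two one-sided tests (TOST) for equivalence
#'
#' Tests whether the mean difference A - B lies inside the indifference
#' band (`delta_low`, `delta_high`): one one-sided pooled-variance
#' t-test against each bound, reporting the less significant side (the
#' smaller |t|).  p < alpha rejects the null of a true effect at or
#' beyond a bound, declaring equivalence.
#'
#' @param groupA,groupB Numeric vectors (n >= 2 each).
#' @param delta_low,delta_high Equivalence bounds on the raw mean
#'   difference, `delta_low < delta_high`.
#' @param alpha Significance level (default 0.05).
#' @return List with `t`, `df`, `p_value`, `equivalent`, `mean_diff`,
#'   and the per-bound `t_lower`, `t_upper`, `p_lower`, `p_upper`.
#' @export
tost_equivalence <- function(groupA, groupB, delta_low, delta_high,
                             alpha = 0.05) {
  nA <- length(groupA); nB <- length(groupB)
  stopifnot(nA >= 2, nB >= 2)
  if (!(delta_low < delta_high)) stop("delta_low must be < delta_high")
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * stats::var(groupA) + (nB - 1) * stats::var(groupB)) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  if (se == 0) stop("zero pooled variance")
  diff <- mean(groupA) - mean(groupB)
  t_lower <- (diff - delta_low) / se    # H0: diff <= delta_low
  t_upper <- (diff - delta_high) / se   # H0: diff >= delta_high
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  ## the less significant side carries the decision
  if (p_lower >= p_upper) {
    t <- t_lower; p <- p_lower
  } else {
    t <- t_upper; p <- p_upper
  }
  list(t = t, df = df, p_value = p, equivalent = p < alpha,
       mean_diff = diff, t_lower = t_lower, t_upper = t_upper,
       p_lower = p_lower, p_upper = p_upper)
}

## two-sided two-sample t-test power at effect size d (Cohen's units)
t_test_power <- function(d, nA, nB, alpha) {
  df <- nA + nB - 2
  ncp <- d * sqrt(nA * nB / (nA + nB))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Equivalence bounds at 33% detection power
#'
#' Symmetric bounds (in Cohen's d units) set to the effect size that a
#' two-sided two-sample t-test with the given group sizes would detect
#' with 33% power, solved from the noncentral t distribution.  Used to
#' parameterize [tost_equivalence()]: effects smaller than what the
#' study could plausibly detect are treated as inside the indifference
#' band.
#'
#' @param nA,nB Group sizes (>= 2).
#' @param alpha Test level (default 0.05).
#' @param power Target power (default 0.33).
#' @return List with `delta_low`, `delta_high` (= -/+ the bound in d
#'   units) and `d_bound`.
#' @export
power33_bounds <- function(nA, nB, alpha = 0.05, power = 0.33) {
  stopifnot(nA >= 2, nB >= 2, power > alpha, power < 1)
  f <- function(d) t_test_power(d, nA, nB, alpha) - power
  d <- stats::uniroot(f, c(1e-6, 10), tol = 1e-8)$root
  list(delta_low = -d, delta_high = d, d_bound = d)
}

#' Iterative factor model with loading-based variable exclusion
#'
#' Maximum-likelihood factor analysis with promax (oblique) rotation,
#' wrapped in the iterative exclusion procedure: refit after removing,
#' one at a time, (1) the variable with the lowest maximal absolute
#' loading while that maximum is below the cutoff, then (2)
#' cross-loading variables (at least two loadings at or above the
#' cutoff), until every retained variable loads at least `cutoff` in
#' absolute value on exactly one factor, or too few variables remain.
#' Specific variances (psi) near 1 mean no common-factor component;
#' psi near 0 flags a Heywood case.
#'
#' @param X Observations x variables numeric matrix or data frame with
#'   column names; more observations than variables required.
#' @param n_factors Number of factors (< number of variables).
#' @param loading_cutoff Minimum meaningful absolute loading
#'   (default 0.4, ~16% shared variance).
#' @param heywood_tol psi below this is reported as a Heywood case.
#' @return A `factor_model_result`: `loadings` (retained variables x
#'   factors), `psi`, `retained`, `excluded` (in order),
#'   `trace` (data frame of steps), `heywood` (variable names),
#'   `converged`.
#' @export
iterative_factor_model <- function(X, n_factors, loading_cutoff = 0.4,
                                   heywood_tol = 0.005) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(nrow(X) > ncol(X), n_factors >= 1, n_factors < ncol(X))
  vars <- colnames(X)
  trace <- data.frame(step = integer(), action = character(),
                      variable = character(), max_loading = numeric(),
                      stringsAsFactors = FALSE)
  excluded <- character(0)
  step <- 0L
  fit <- NULL
  repeat {
    if (length(vars) <= n_factors + 1) {
      warning("too few variables left for ", n_factors, " factors")
      break
    }
    fit <- tryCatch(
      stats::factanal(X[, vars, drop = FALSE], factors = n_factors,
                      rotation = "promax"),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("factor fit failed with variables {",
              paste(vars, collapse = ", "), "}: ",
              conditionMessage(fit))
      fit <- NULL
      break
    }
    L <- unclass(fit$loadings)
    max_abs <- apply(abs(L), 1, max)
    n_loaded <- rowSums(abs(L) >= loading_cutoff)
    step <- step + 1L
    if (any(max_abs < loading_cutoff)) {
      drop_var <- vars[which.min(max_abs)]
      trace <- rbind(trace, data.frame(
        step = step, action = "drop_low_loading", variable = drop_var,
        max_loading = min(max_abs)))
    } else if (any(n_loaded > 1)) {
      cand <- which(n_loaded > 1)
      drop_var <- vars[cand[which.min(max_abs[cand])]]
      trace <- rbind(trace, data.frame(
        step = step, action = "drop_cross_loading", variable = drop_var,
        max_loading = max_abs[vars == drop_var]))
    } else {
      trace <- rbind(trace, data.frame(
        step = step, action = "accept", variable = NA_character_,
        max_loading = min(max_abs)))
      break
    }
    vars <- setdiff(vars, drop_var)
    excluded <- c(excluded, drop_var)
  }
  if (is.null(fit) || inherits(fit, "error")) {
    return(structure(list(loadings = NULL, psi = NULL, retained = vars,
                          excluded = excluded, trace = trace,
                          heywood = character(0), converged = FALSE),
                     class = "factor_model_result"))
  }
  psi <- fit$uniquenesses
  structure(
    list(loadings = unclass(fit$loadings), psi = psi, retained = vars,
         excluded = excluded, trace = trace,
         heywood = names(psi)[psi < heywood_tol], converged = TRUE),
    class = "factor_model_result")
}

#' @export
print.factor_model_result <- function(x, ...) {
  cat("<factor_model_result>",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$excluded))
    cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  if (length(x$heywood))
    cat("Heywood cases:", paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}
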