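#' Odds ratio with Woolf (log-scale Wald) confidence interval
#'
#' Computes the cross-product odds ratio `(a*d)/(b*c)` of a 2x2 case-control
#' table with the exposure in the numerator, a 95% Woolf interval
#' `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`, and a two-sided
#' p-value from the Pearson chi-square test (no continuity correction) on the
#' same table.
#'
#' @param a Exposed cases.
#' @param b Exposed controls.
#' @param c_ Reference cases.
#' @param d Reference controls.
#' @param correction Zero-cell policy: `"haldane"` (default) adds 0.5 to all
#'   four cells when any cell is zero; `"none"` errors on degenerate tables.
#' @return An object of class `or_estimate`: list with `or`, `ci_low`,
#'   `ci_high`, `log_or`, `se_log_or`, `p`, and the input `table`.
#' @examples
#' or_woolf(148, 141, 131, 605)  # OR 4.85 (3.60-6.53)
#' @export
or_woolf <- function(a, b, c_, d, correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(cells < 0) || sum(cells) == 0)
    stop("invalid 2x2 table: counts must be non-negative with positive total",
         call. = FALSE)
  if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
    stop("degenerate 2x2 table: a whole row or column is zero", call. = FALSE)
  adj <- cells
  if (any(cells == 0)) {
    if (correction == "none")
      stop("zero cell in 2x2 table and correction disabled", call. = FALSE)
    adj <- cells + 0.5
  }
  lor <- log(adj[["a"]] * adj[["d"]]) - log(adj[["b"]] * adj[["c"]])
  se <- sqrt(sum(1 / adj))
  tab <- matrix(c(a, c_, b, d), nrow = 2,
                dimnames = list(status = c("case", "control"),
                                exposure = c("exposed", "reference")))
  # p from the uncorrected Pearson chi-square on the original counts
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  structure(list(or = exp(lor),
                 ci_low = exp(lor - 1.959964 * se),
                 ci_high = exp(lor + 1.959964 * se),
                 log_or = unname(lor),
                 se_log_or = unname(se),
                 p = unname(p),
                 table = tab),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Pearson chi-square test on an r x c contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction), as used
#' for allelic and genotypic case-control association tests.
#'
#' @param table Numeric matrix of counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi2_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero marginal", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Maximum-likelihood logistic regression
#'
#' Thin wrapper around [stats::glm()] (binomial family, IRLS) exposing the
#' pieces downstream interaction analyses need: coefficient vector,
#' covariance matrix, maximized log-likelihood. Frequency weights are
#' supported so that fits on aggregated genotype counts are identical to
#' fits on expanded subject-level records.
#'
#' @param design Numeric model matrix. An intercept column is added unless
#'   one is already present (a column of ones).
#' @param response Binary 0/1 vector (1 = case).
#' @param weights Optional non-negative replicate counts (default 1).
#' @return An object of class `logistic_fit`: `coefficients`, `covariance`,
#'   `loglik`, `n_iter`, `converged`, and the underlying `glm` object.
#' @export
logistic_fit <- function(design, response, weights = NULL) {
  design <- as.matrix(design)
  if (nrow(design) != length(response))
    stop("design rows must match response length", call. = FALSE)
  if (!all(response %in% 0:1))
    stop("response must be binary 0/1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(response))
  keep <- weights > 0
  if (length(unique(response[keep])) < 2L)
    stop("degenerate response: all cases or all controls", call. = FALSE)
  has_icpt <- any(apply(design, 2, function(col) all(col == 1)))
  if (!has_icpt) design <- cbind(`(Intercept)` = 1, design)
  if (is.null(colnames(design)))
    colnames(design) <- c("(Intercept)", paste0("x", seq_len(ncol(design) - 1L)))
  qrX <- qr(design * sqrt(weights))
  if (qrX$rank < ncol(design)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(design))]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(design)[drop_idx], collapse = ", "), call. = FALSE)
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(design, response, weights = weights,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  if (sep_warn && any(abs(beta[-1]) > 10)) {
    worst <- names(beta[-1])[which.max(abs(beta[-1]))]
    stop("separation detected (diverging coefficient for ", worst, ")",
         call. = FALSE)
  }
  # covariance from the weighted cross-product of the final IRLS design
  w_work <- fit$weights
  info <- crossprod(design * sqrt(w_work))
  covar <- tryCatch(solve(info), error = function(e)
    stop("singular information matrix", call. = FALSE))
  dimnames(covar) <- list(names(beta), names(beta))
  mu <- fit$fitted.values
  ll <- sum(weights * (response * log(mu) + (1 - response) * log1p(-mu)))
  structure(list(coefficients = beta,
                 covariance = covar,
                 loglik = ll,
                 n_iter = fit$iter,
                 converged = fit$converged,
                 glm = fit),
            class = "logistic_fit")
}

#' Wald test for one coefficient of a logistic fit
#'
#' @param fit A [logistic_fit()].
#' @param index Coefficient index or name.
#' @return List with `z` and two-sided `p`.
#' @export
wald_test <- function(fit, index) {
  stopifnot(inherits(fit, "logistic_fit"))
  beta <- fit$coefficients[index]
  if (length(beta) != 1L || is.na(beta)) stop("invalid coefficient index", call. = FALSE)
  se <- sqrt(diag(fit$covariance))[index]
  z <- unname(beta / se)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Likelihood-ratio test between nested fits
#'
#' @param ll_full Log-likelihood of the larger model.
#' @param ll_reduced Log-likelihood of the nested model.
#' @param df Difference in number of parameters.
#' @return Chi-square p-value.
#' @export
lrt <- function(ll_full, ll_reduced, df) {
  stat <- 2 * (ll_full - ll_reduced)
  if (stat < -1e-6)
    stop("ll_full < ll_reduced: models are not nested or fit failed", call. = FALSE)
  stat <- max(stat, 0)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Breslow-Day test of odds-ratio homogeneity
#'
#' Classic Breslow-Day chi-square against the Mantel-Haenszel common odds
#' ratio, df = K - 1 over K strata, with optional Tarone correction. Each
#' stratum's expected exposed-case count solves the quadratic implied by
#' fixed margins and the common OR.
#'
#' @param strata List of 2x2 strata; each element a numeric vector
#'   `c(a, b, c, d)` = (exposed cases, exposed controls, reference cases,
#'   reference controls) or an `or_estimate`.
#' @param tarone Apply Tarone's correction (default `FALSE`).
#' @return List with `statistic`, `df`, `p`, `or_mh` (the Mantel-Haenszel
#'   common OR).
#' @export
breslow_day <- function(strata, tarone = FALSE) {
  strata <- lapply(strata, function(s) {
    if (inherits(s, "or_estimate")) s <- c(s$table[1, 1], s$table[2, 1],
                                           s$table[1, 2], s$table[2, 2])
    as.numeric(s)
  })
  if (length(strata) < 2L) stop("need at least two strata", call. = FALSE)
  for (s in strata) {
    if (length(s) != 4L || any(s < 0)) stop("each stratum must be 4 non-negative counts", call. = FALSE)
    if ((s[1] + s[2]) == 0 || (s[3] + s[4]) == 0 || (s[1] + s[3]) == 0 || (s[2] + s[4]) == 0)
      stop("degenerate stratum: zero marginal", call. = FALSE)
  }
  psi <- sum(vapply(strata, function(s) s[1] * s[4] / sum(s), 0)) /
         sum(vapply(strata, function(s) s[2] * s[3] / sum(s), 0))
  stat <- 0
  resid <- 0
  vsum <- 0
  for (s in strata) {
    a <- s[1]; n1 <- s[1] + s[2]; m1 <- s[1] + s[3]; N <- sum(s)
    # E[a] under common OR psi: psi (n1-A)(m1-A) = A (N - n1 - m1 + A)
    qa <- psi - 1
    qb <- -((n1 + m1) * psi + (N - n1 - m1))
    qc <- psi * n1 * m1
    A <- if (abs(qa) < 1e-12) -qc / qb else (-qb - sqrt(qb^2 - 4 * qa * qc)) / (2 * qa)
    V <- 1 / (1 / A + 1 / (n1 - A) + 1 / (m1 - A) + 1 / (N - n1 - m1 + A))
    stat <- stat + (a - A)^2 / V
    resid <- resid + (a - A)
    vsum <- vsum + V
  }
  if (tarone) stat <- stat - resid^2 / vsum
  df <- length(strata) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       or_mh = psi)
}

#' Exact and chi-square tests of Hardy-Weinberg equilibrium
#'
#' `hwe_exact` computes the exact HWE p-value for one biallelic SNP: with the
#' allele counts fixed, it sums the conditional probabilities of all
#' heterozygote counts (same parity as the observed one) that are no more
#' probable than the observed configuration. `hwe_chi2` is the 1-df Pearson
#' chi-square against the HWE-expected genotype counts.
#'
#' @param n_hom_ref Count of reference-homozygotes.
#' @param n_het Count of heterozygotes.
#' @param n_hom_alt Count of alternate-homozygotes.
#' @return p-value in `[0, 1]`.
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("empty genotype table", call. = FALSE)
  n_rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)  # rarer allele
  hets <- seq(n_rare %% 2, n_rare, by = 2)  # feasible het counts, same parity
  # log conditional probability of n_het heterozygotes given allele counts
  logp <- function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) + lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) -
      lgamma(hom_c + 1) -
      (lgamma(2 * n + 1) - lgamma(n_rare + 1) - lgamma(2 * n - n_rare + 1))
  }
  lp <- vapply(hets, logp, 0)
  p_obs <- lp[match(n_het, hets)]
  min(1, sum(exp(lp[lp <= p_obs + 1e-12])))
}

#' @rdname hwe_exact
#' @export
hwe_chi2 <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("empty genotype table", call. = FALSE)
  p <- (2 * n_hom_ref + n_het) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(expected == 0)) return(1)
  stat <- sum((counts - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
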