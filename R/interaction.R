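#' Additive/dominance coding scheme for genotypic interaction
#'
#' Each SNP contributes an additive term (allele dosage in 0/1/2) and a
#' dominance term (heterozygote indicator). `orientation` fixes which allele
#' the additive dosage counts:
#' * `"minor"` (default) — the minor allele, estimated from the pooled
#'   case+control allele frequency of the data being fitted. This is the
#'   convention of the interaction software the published tables come from;
#'   flipping one SNP's axis inverts the additive-by-additive odds ratio.
#' * `"risk"` — the designated risk allele of each [snp_spec()].
#'
#' The dominance term is orientation-invariant.
#'
#' @param orientation `"minor"` or `"risk"`.
#' @return List of class `coding_scheme`.
#' @export
coding_scheme <- function(orientation = c("minor", "risk")) {
  structure(list(orientation = match.arg(orientation)),
            class = "coding_scheme")
}

# Build the weighted 18-row design data for a two_locus_table, or
# subject-level data for a cohort. Returns list(xa, za, xb, zb, y, w, covs,
# flipped_a, flipped_b).
.interaction_data <- function(data, coding, snp_a = NULL, snp_b = NULL,
                              covariates = NULL) {
  if (inherits(data, "two_locus_table")) {
    if (!is.null(covariates))
      stop("covariate adjustment requires subject-level data, not counts",
           call. = FALSE)
    arr <- unclass(data)
    grid <- expand.grid(a = 0:2, b = 0:2)
    da <- c(grid$a, grid$a); db <- c(grid$b, grid$b)
    y <- rep(c(1L, 0L), each = 9)
    w <- c(as.numeric(arr[cbind(grid$a + 1, grid$b + 1, 1)]),
           as.numeric(arr[cbind(grid$a + 1, grid$b + 1, 2)]))
    covs <- NULL
  } else {
    stopifnot(inherits(data, "cohort"))
    specs <- attr(data, "specs")
    da <- dosage(data[[snp_a]], specs[[snp_a]])
    db <- dosage(data[[snp_b]], specs[[snp_b]])
    keep <- !is.na(da) & !is.na(db)
    covs <- NULL
    if (!is.null(covariates) && length(covariates)) {
      covs <- as.matrix(as.data.frame(data)[, covariates, drop = FALSE])
      if ("age" %in% covariates && all(is.na(covs[, "age"]))) {
        warning("age entirely missing; dropping age covariate")
        covariates <- setdiff(covariates, "age")
        covs <- covs[, covariates, drop = FALSE]
      }
      keep <- keep & stats::complete.cases(covs)
      covs <- covs[keep, , drop = FALSE]
      if (ncol(covs) == 0) covs <- NULL
    }
    da <- da[keep]; db <- db[keep]
    y <- as.integer(data$status[keep] == 2)
    w <- rep(1, length(y))
  }
  flip_a <- flip_b <- FALSE
  if (coding$orientation == "minor") {
    # risk-allele frequency in the pooled sample; flip when it is the major allele
    flip_a <- sum(w * da) / (2 * sum(w)) > 0.5
    flip_b <- sum(w * db) / (2 * sum(w)) > 0.5
  }
  list(xa = if (flip_a) 2 - da else da,
       za = as.numeric(da == 1),
       xb = if (flip_b) 2 - db else db,
       zb = as.numeric(db == 1),
       y = y, w = w, covs = covs,
       flipped_a = flip_a, flipped_b = flip_b)
}

# OR/CI/p rows for a set of fit terms.
.term_table <- function(fit, terms) {
  do.call(rbind, lapply(terms, function(t) {
    est <- .or_from_fit(fit, t)
    data.frame(term = t, or = est$or, ci_low = est$ci_low,
               ci_high = est$ci_high, p = est$p)
  }))
}

#' Four-degree-of-freedom genotypic interaction test
#'
#' Fits the full Cordell-Clayton genotypic interaction logistic model:
#' case status on both SNPs' additive dosages and heterozygote indicators
#' plus the four pairwise products (additive-by-additive,
#' additive-by-dominance, dominance-by-additive, dominance-by-dominance),
#' with optional covariates. Per-term odds ratios and p-values are Wald;
#' the global 4-df p-value is a likelihood-ratio test of the full model
#' against the main-effects model.
#'
#' @param data A [two_locus_table()] (counts, fitted with frequency weights)
#'   or a [cohort()].
#' @param coding A [coding_scheme()].
#' @param snp_a,snp_b SNP names (cohort input).
#' @param covariates Optional covariate columns (cohort input).
#' @return Object of class `interaction_fit`: `terms` (data frame for
#'   `axa`, `axd`, `dxa`, `dxd`), `main_terms`, `global_p`, `loglik_full`,
#'   `loglik_main`, `fit_full`, `fit_main`, `coding`, `adjusted`.
#' @export
interaction_test6 <- function(data, coding = coding_scheme(),
                              snp_a = NULL, snp_b = NULL, covariates = NULL) {
  d <- .interaction_data(data, coding, snp_a, snp_b, covariates)
  X_main <- cbind(xa = d$xa, za = d$za, xb = d$xb, zb = d$zb)
  X_int <- cbind(axa = d$xa * d$xb, axd = d$xa * d$zb,
                 dxa = d$za * d$xb, dxd = d$za * d$zb)
  full <- logistic_fit(cbind(X_main, X_int, d$covs), d$y, weights = d$w)
  main <- logistic_fit(cbind(X_main, d$covs), d$y, weights = d$w)
  global_p <- lrt(full$loglik, main$loglik, df = 4)
  structure(list(terms = .term_table(full, c("axa", "axd", "dxa", "dxd")),
                 main_terms = .term_table(full, c("xa", "za", "xb", "zb")),
                 global_p = global_p,
                 loglik_full = full$loglik, loglik_main = main$loglik,
                 fit_full = full, fit_main = main,
                 coding = coding,
                 flipped = c(a = d$flipped_a, b = d$flipped_b),
                 adjusted = !is.null(covariates) && length(covariates) > 0,
                 test = "genotypic interaction (4 df)"),
            class = "interaction_fit")
}

#' Single-term additive-by-additive interaction test
#'
#' The reduced multiplicative-scale model: case status on the two additive
#' dosages and their product (no dominance terms), reporting the
#' additive-by-additive odds ratio with Wald CI and p.
#'
#' @inheritParams interaction_test6
#' @return An `interaction_fit` whose `terms` holds the single `axa` row;
#'   `global_p` is the 1-df LRT against the main-effects-only model.
#' @export
interaction_test5 <- function(data, coding = coding_scheme(),
                              snp_a = NULL, snp_b = NULL, covariates = NULL) {
  d <- .interaction_data(data, coding, snp_a, snp_b, covariates)
  X_main <- cbind(xa = d$xa, xb = d$xb)
  full <- logistic_fit(cbind(X_main, axa = d$xa * d$xb, d$covs), d$y,
                       weights = d$w)
  main <- logistic_fit(cbind(X_main, d$covs), d$y, weights = d$w)
  structure(list(terms = .term_table(full, "axa"),
                 main_terms = .term_table(full, c("xa", "xb")),
                 global_p = lrt(full$loglik, main$loglik, df = 1),
                 loglik_full = full$loglik, loglik_main = main$loglik,
                 fit_full = full, fit_main = main,
                 coding = coding,
                 flipped = c(a = d$flipped_a, b = d$flipped_b),
                 adjusted = !is.null(covariates) && length(covariates) > 0,
                 test = "additive interaction (1 df)"),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("%s%s, coding orientation: %s\n", x$test,
              if (isTRUE(x$adjusted)) " (adjusted)" else "",
              x$coding$orientation))
  tt <- x$terms
  lab <- c(axa = "A x A", axd = "A x D", dxa = "D x A", dxd = "D x D")
  for (i in seq_len(nrow(tt)))
    cat(sprintf("  %s: OR %.2f (%.2f-%.2f), p = %.3g\n",
                lab[[tt$term[i]]], tt$or[i], tt$ci_low[i], tt$ci_high[i],
                tt$p[i]))
  cat(sprintf("  global p = %.3g\n", x$global_p))
  invisible(x)
}

#' Likelihood-ratio comparison of nested interaction models
#'
#' Goodness-of-fit test for a model reduction (e.g. dropping all dominance
#' terms from the 4-df genotypic model down to the additive-only model).
#' Both fits must be on identical data; the df is the difference in
#' parameter counts and is reported explicitly.
#'
#' @param fit_full,fit_reduced Two `interaction_fit`s on the same data,
#'   `fit_reduced` nested in `fit_full`.
#' @return List with `p`, `df`, `statistic`.
#' @export
dominance_reduction_lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "interaction_fit"),
            inherits(fit_reduced, "interaction_fit"))
  k_full <- length(fit_full$fit_full$coefficients)
  k_red <- length(fit_reduced$fit_full$coefficients)
  df <- k_full - k_red
  if (df <= 0) stop("fit_reduced must have fewer parameters", call. = FALSE)
  stat <- 2 * (fit_full$loglik_full - fit_reduced$loglik_full)
  list(p = lrt(fit_full$loglik_full, fit_reduced$loglik_full, df = df),
       df = df, statistic = max(stat, 0))
}
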