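#' Allelic case-control association for one SNP
#'
#' Collapses genotype counts to allele counts (2 x homozygote + heterozygote
#' per status), forms the allele 2x2 table with the risk allele as exposure,
#' and reports the Woolf odds ratio with the uncorrected Pearson chi-square
#' p-value.
#'
#' @param counts A `genotype_counts` matrix from [crosstab_single()] or
#'   [margin_counts()].
#' @return List of class `association_result`: `snp`, `test`, `estimate`
#'   (an `or_estimate`), `p`.
#' @export
allelic_association <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  spec <- attr(counts, "spec")
  risk <- 2 * counts[, "2"] + counts[, "1"]
  nonrisk <- 2 * counts[, "0"] + counts[, "1"]
  est <- or_woolf(risk[["case"]], risk[["control"]],
                  nonrisk[["case"]], nonrisk[["control"]])
  structure(list(snp = spec$name, test = "allelic", adjusted = FALSE,
                 estimate = est, p = est$p),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s association for %s%s: ", x$test, x$snp,
              if (isTRUE(x$adjusted)) " (adjusted)" else ""))
  if (!is.null(x$estimate)) print(x$estimate) else cat(sprintf("p = %.3g\n", x$p))
  invisible(x)
}

#' Genetic-model association for one SNP
#'
#' Dominant model compares carriers (dosage >= 1) against non-carriers as a
#' 2x2; recessive compares risk homozygotes (dosage 2) against the rest;
#' additive fits a logistic regression of status on dosage and reports the
#' per-allele odds ratio. Covariate adjustment (columns of the cohort, e.g.
#' `age`, `sex`) requires subject-level data and uses the additive-style
#' logistic fit for every model, with the genotype term coded per model.
#'
#' @param x A `genotype_counts` matrix or a [cohort()].
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @param snp SNP name, required when `x` is a cohort.
#' @param covariates Character vector of cohort column names (subject-level
#'   input only).
#' @return An `association_result` with an `or_estimate`.
#' @export
model_association <- function(x, model = c("additive", "dominant", "recessive"),
                              snp = NULL, covariates = NULL) {
  model <- match.arg(model)
  if (inherits(x, "cohort")) {
    if (is.null(snp)) stop("snp name required for cohort input", call. = FALSE)
    spec <- attr(x, "specs")[[snp]]
    d <- dosage(x[[snp]], spec)
    keep <- !is.na(d)
    covs <- NULL
    if (!is.null(covariates)) {
      covs <- as.matrix(as.data.frame(x)[, covariates, drop = FALSE])
      if ("age" %in% covariates && all(is.na(covs[, "age"]))) {
        warning("age entirely missing; dropping age covariate")
        covariates <- setdiff(covariates, "age")
        covs <- covs[, covariates, drop = FALSE]
      }
      keep <- keep & stats::complete.cases(covs)
      covs <- covs[keep, , drop = FALSE]
      if (ncol(covs) == 0) covs <- NULL
    }
    d <- d[keep]
    y <- as.integer(x$status[keep] == 2)
    g <- switch(model, additive = d, dominant = as.numeric(d >= 1),
                recessive = as.numeric(d == 2))
    design <- cbind(genotype = g, covs)
    fit <- logistic_fit(design, y)
    est <- .or_from_fit(fit, "genotype")
    return(structure(list(snp = spec$name, test = model,
                          adjusted = !is.null(covariates) && length(covariates) > 0,
                          covariates = covariates, estimate = est, p = est$p),
                     class = "association_result"))
  }
  stopifnot(inherits(x, "genotype_counts"))
  if (!is.null(covariates))
    stop("covariate adjustment requires subject-level data, not counts",
         call. = FALSE)
  spec <- attr(x, "spec")
  if (model == "additive") {
    g <- rep(0:2, times = 2)
    y <- rep(c(1, 0), each = 3)
    w <- c(x["case", ], x["control", ])
    fit <- logistic_fit(cbind(genotype = g), y, weights = w)
    est <- .or_from_fit(fit, "genotype")
  } else {
    exposed <- if (model == "dominant") c("1", "2") else "2"
    ref <- setdiff(c("0", "1", "2"), exposed)
    est <- or_woolf(sum(x["case", exposed]), sum(x["control", exposed]),
                    sum(x["case", ref]), sum(x["control", ref]))
  }
  structure(list(snp = spec$name, test = model, adjusted = FALSE,
                 estimate = est, p = est$p),
            class = "association_result")
}

# Wald OR/CI/p for one coefficient of a logistic_fit, as an or_estimate.
.or_from_fit <- function(fit, term) {
  beta <- fit$coefficients[[term]]
  se <- sqrt(fit$covariance[term, term])
  w <- wald_test(fit, term)
  structure(list(or = exp(beta),
                 ci_low = exp(beta - 1.959964 * se),
                 ci_high = exp(beta + 1.959964 * se),
                 log_or = beta, se_log_or = se, p = w$p, table = NULL),
            class = "or_estimate")
}

#' Hardy-Weinberg equilibrium gate on control genotypes
#'
#' Exact HWE test on the control-group genotype counts; the gate fails when
#' p <= 0.01. Failure is reported, never fatal: downstream analyses proceed
#' but should flag the SNP.
#'
#' @param counts A `genotype_counts` matrix (the control row is used) or a
#'   numeric vector `c(n_hom_nonrisk, n_het, n_hom_risk)` of control counts.
#' @param threshold Gate threshold on the exact p-value (default 0.01).
#' @param method `"exact"` (default) or `"chi2"`.
#' @return List with `pass` (logical) and `p`.
#' @export
hwe_gate <- function(counts, threshold = 0.01, method = c("exact", "chi2")) {
  method <- match.arg(method)
  v <- if (inherits(counts, "genotype_counts")) counts["control", ] else as.numeric(counts)
  if (length(v) != 3) stop("need three genotype counts", call. = FALSE)
  p <- if (method == "exact") hwe_exact(v[[1]], v[[2]], v[[3]])
       else hwe_chi2(v[[1]], v[[2]], v[[3]])
  list(pass = p > threshold, p = p)
}
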