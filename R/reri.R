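#' Relative excess risk due to interaction from component odds ratios
#'
#' `RERI = OR11 - OR10 - OR01 + 1`, where OR11 is the doubly-exposed odds
#' ratio and OR10/OR01 the singly-exposed ones, all against the same
#' doubly-unexposed reference. RERI is 0 under perfect additivity of excess
#' risks; positive values indicate synergy, negative antagonism.
#'
#' @param or11,or10,or01 Positive odds ratios.
#' @return The RERI point estimate.
#' @examples
#' reri_point(4.8476, 2.2175, 1.3711)  # 2.26
#' @export
reri_point <- function(or11, or10, or01) {
  if (any(c(or11, or10, or01) <= 0)) stop("odds ratios must be positive", call. = FALSE)
  or11 - or10 - or01 + 1
}

#' Standard two-locus exposure contrasts for RERI
#'
#' The three dosage-cell quadruples used for biallelic SNP pairs, in
#' `(dosage_A, dosage_B)` notation:
#' * `H1` — exposed to one copy of each risk allele:
#'   reference (0,0), A-only (1,0), B-only (0,1), both (1,1);
#' * `H2` — exposed to two copies:
#'   reference (0,0), A-only (2,0), B-only (0,2), both (2,2);
#' * `H3` — one additional copy given one copy (doubly heterozygous
#'   reference): reference (1,1), A-only (2,1), B-only (1,2), both (2,2).
#'
#' @param label `"H1"`, `"H2"` or `"H3"`, or a custom list with elements
#'   `ref`, `a_only`, `b_only`, `both` (dosage pairs).
#' @return List of class `exposure_contrast`.
#' @export
reri_contrast <- function(label) {
  if (is.list(label)) {
    stopifnot(all(c("ref", "a_only", "b_only", "both") %in% names(label)))
    cells <- label[c("ref", "a_only", "b_only", "both")]
    key <- vapply(cells, paste, "", collapse = ",")
    if (anyDuplicated(key)) stop("contrast cells must be distinct", call. = FALSE)
    return(structure(c(cells, list(label = "custom")),
                     class = "exposure_contrast"))
  }
  cells <- switch(label,
    H1 = list(ref = c(0, 0), a_only = c(1, 0), b_only = c(0, 1), both = c(1, 1)),
    H2 = list(ref = c(0, 0), a_only = c(2, 0), b_only = c(0, 2), both = c(2, 2)),
    H3 = list(ref = c(1, 1), a_only = c(2, 1), b_only = c(1, 2), both = c(2, 2)),
    stop("unknown contrast label: ", label, call. = FALSE))
  structure(c(cells, list(label = label)), class = "exposure_contrast")
}

#' MOVER confidence interval for RERI
#'
#' Method-of-variance-estimates-recovery interval for
#' `theta1 - theta2 - theta3 + 1`, combining the asymmetric Woolf limits of
#' the three component odds ratios, with optional correlations between the
#' log-OR estimates (non-zero when the three 2x2 tables share reference
#' cells).
#'
#' @param estimates List of three `or_estimate`s: OR11, OR10, OR01.
#' @param correlations Numeric vector `c(r12, r13, r23)` of correlations
#'   between the log-OR estimates (default all zero).
#' @return `c(low, high)`.
#' @export
mover_ci <- function(estimates, correlations = c(0, 0, 0)) {
  stopifnot(length(estimates) == 3, length(correlations) == 3)
  if (any(abs(correlations) > 1)) stop("correlations must be in [-1, 1]", call. = FALSE)
  th <- vapply(estimates, `[[`, 0, "or")
  l <- vapply(estimates, `[[`, 0, "ci_low")
  u <- vapply(estimates, `[[`, 0, "ci_high")
  r12 <- correlations[1]; r13 <- correlations[2]; r23 <- correlations[3]
  point <- th[1] - th[2] - th[3] + 1
  low <- point - sqrt((th[1] - l[1])^2 + (u[2] - th[2])^2 + (u[3] - th[3])^2 -
                      2 * r12 * (th[1] - l[1]) * (u[2] - th[2]) -
                      2 * r13 * (th[1] - l[1]) * (u[3] - th[3]) +
                      2 * r23 * (u[2] - th[2]) * (u[3] - th[3]))
  high <- point + sqrt((u[1] - th[1])^2 + (th[2] - l[2])^2 + (th[3] - l[3])^2 -
                       2 * r12 * (u[1] - th[1]) * (th[2] - l[2]) -
                       2 * r13 * (u[1] - th[1]) * (th[3] - l[3]) +
                       2 * r23 * (th[2] - l[2]) * (th[3] - l[3]))
  c(low = low, high = high)
}

# Extract the four contrast cells' (case, control) counts from a table.
.contrast_cells <- function(table, contrast) {
  arr <- unclass(table)
  get <- function(g) c(case = arr[g[1] + 1, g[2] + 1, "case"],
                       control = arr[g[1] + 1, g[2] + 1, "control"])
  list(ref = get(contrast$ref), a_only = get(contrast$a_only),
       b_only = get(contrast$b_only), both = get(contrast$both))
}

#' RERI from a two-locus count table
#'
#' Computes the three component odds ratios of an exposure contrast as
#' closed-form cross-products against the contrast's reference cell, the
#' RERI point estimate, and a MOVER 95% CI whose log-OR correlations follow
#' from the shared reference cell (`cov = 1/ref_case + 1/ref_control` under
#' the multinomial sampling model).
#'
#' @param table A [two_locus_table()].
#' @param contrast An [reri_contrast()] or its label (`"H1"`, `"H2"`, `"H3"`).
#' @param correlated Use the shared-reference correlations in the MOVER CI
#'   (default `TRUE`); `FALSE` combines the limbs as if independent.
#' @return Object of class `reri_result`: `reri`, `ci_low`, `ci_high`,
#'   `or11`, `or10`, `or01` (each an `or_estimate`), `contrast`, `adjusted`.
#' @export
reri_from_counts <- function(table, contrast, correlated = TRUE) {
  stopifnot(inherits(table, "two_locus_table"))
  if (is.character(contrast)) contrast <- reri_contrast(contrast)
  cells <- .contrast_cells(table, contrast)
  for (nm in names(cells))
    if (any(cells[[nm]] == 0))
      stop("degenerate contrast cell (zero count): ", nm, call. = FALSE)
  ref <- cells$ref
  est <- function(cell) or_woolf(cell[["case"]], cell[["control"]],
                                 ref[["case"]], ref[["control"]])
  or11 <- est(cells$both); or10 <- est(cells$a_only); or01 <- est(cells$b_only)
  corr <- c(0, 0, 0)
  if (correlated) {
    cov_shared <- 1 / ref[["case"]] + 1 / ref[["control"]]
    v <- c(or11$se_log_or, or10$se_log_or, or01$se_log_or)^2
    corr <- c(cov_shared / sqrt(v[1] * v[2]),
              cov_shared / sqrt(v[1] * v[3]),
              cov_shared / sqrt(v[2] * v[3]))
  }
  ci <- mover_ci(list(or11, or10, or01), corr)
  structure(list(reri = reri_point(or11$or, or10$or, or01$or),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 or11 = or11, or10 = or10, or01 = or01,
                 contrast = contrast, correlations = corr,
                 adjusted = FALSE, covariates = NULL,
                 cells = cells),
            class = "reri_result")
}

#' @export
print.reri_result <- function(x, ...) {
  cat(sprintf("RERI (%s%s) = %.2f (95%% CI %.2f to %.2f)\n",
              x$contrast$label, if (isTRUE(x$adjusted)) ", adjusted" else "",
              x$reri, x$ci_low, x$ci_high))
  cat(sprintf("  OR11 %.2f, OR10 %.2f, OR01 %.2f\n",
              x$or11$or, x$or10$or, x$or01$or))
  if (!is.null(x$boot_p))
    cat(sprintf("  bootstrap p %s (reps %d, seed %s)\n",
                format.pval(x$boot_p), x$boot_reps, x$boot_seed))
  invisible(x)
}

#' Model-based (optionally covariate-adjusted) RERI
#'
#' Restricts the cohort to subjects in the contrast's four genotype cells,
#' fits a logistic regression of case status on three exposure-cell
#' indicators (reference omitted) plus any covariates, takes the component
#' odds ratios as `exp(beta)` with Wald CIs, and builds the MOVER CI with
#' the correlations of the coefficient estimates from the fit's covariance
#' matrix.
#'
#' @param cohort A [cohort()].
#' @param snp_a,snp_b SNP names in the cohort.
#' @param contrast An [reri_contrast()] or label.
#' @param covariates Character vector of cohort column names (e.g.
#'   `c("age", "sex")`), or `NULL` for an unadjusted model fit.
#' @return A `reri_result` with `adjusted = TRUE` when covariates are used.
#' @export
reri_model <- function(cohort, snp_a, snp_b, contrast, covariates = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.character(contrast)) contrast <- reri_contrast(contrast)
  specs <- attr(cohort, "specs")
  da <- dosage(cohort[[snp_a]], specs[[snp_a]])
  db <- dosage(cohort[[snp_b]], specs[[snp_b]])
  cellkey <- function(g) g[1] * 3 + g[2]
  key <- da * 3 + db
  wanted <- vapply(contrast[c("ref", "a_only", "b_only", "both")], cellkey, 0)
  keep <- !is.na(key) & key %in% wanted
  covs <- NULL
  if (!is.null(covariates) && length(covariates)) {
    covs <- as.matrix(as.data.frame(cohort)[, covariates, drop = FALSE])
    if ("age" %in% covariates && all(is.na(covs[, "age"]))) {
      warning("age entirely missing; dropping age covariate")
      covariates <- setdiff(covariates, "age")
      covs <- covs[, covariates, drop = FALSE]
    }
    keep <- keep & stats::complete.cases(covs)
    covs <- covs[keep, , drop = FALSE]
    if (ncol(covs) == 0) covs <- NULL
  }
  key <- key[keep]
  y <- as.integer(cohort$status[keep] == 2)
  design <- cbind(both = as.numeric(key == wanted[["both"]]),
                  a_only = as.numeric(key == wanted[["a_only"]]),
                  b_only = as.numeric(key == wanted[["b_only"]]))
  fit <- logistic_fit(cbind(design, covs), y)
  ors <- lapply(c("both", "a_only", "b_only"), function(t) .or_from_fit(fit, t))
  v <- fit$covariance[c("both", "a_only", "b_only"), c("both", "a_only", "b_only")]
  corr <- stats::cov2cor(v)
  ci <- mover_ci(ors, c(corr[1, 2], corr[1, 3], corr[2, 3]))
  structure(list(reri = reri_point(ors[[1]]$or, ors[[2]]$or, ors[[3]]$or),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 or11 = ors[[1]], or10 = ors[[2]], or01 = ors[[3]],
                 contrast = contrast,
                 correlations = c(corr[1, 2], corr[1, 3], corr[2, 3]),
                 adjusted = !is.null(covariates) && length(covariates) > 0,
                 covariates = covariates, fit = fit),
            class = "reri_result")
}

#' Stratified-bootstrap p-value for RERI
#'
#' Resamples subjects with replacement within the case and control strata
#' (preserving both sample sizes), recomputes the unadjusted closed-form
#' RERI for each replicate, and reports the two-sided percentile p-value
#' `2 * min(frac <= 0, frac >= 0)`, floored at `1/reps` and capped at 1.
#' Replicates with an empty contrast cell are skipped and counted; more
#' than 10% of them triggers an instability warning.
#'
#' For count-table input the stratified resample is drawn directly as a
#' multinomial over the nine genotype cells, which is exactly equivalent to
#' resampling expanded subjects and far faster.
#'
#' @param x A [two_locus_table()] or a [cohort()].
#' @param contrast An [reri_contrast()] or label.
#' @param reps Bootstrap replicates (default 10000).
#' @param seed Integer seed (required, for reproducibility).
#' @param snp_a,snp_b SNP names (cohort input).
#' @param covariates Optional covariates (cohort input): each replicate then
#'   refits the adjusted model, which is markedly slower.
#' @return List of class `reri_boot`: `p`, `reps`, `n_degenerate`, `seed`,
#'   and the replicate RERI vector `replicates` (NA where degenerate).
#' @export
bootstrap_reri_p <- function(x, contrast, reps = 10000, seed,
                             snp_a = NULL, snp_b = NULL, covariates = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (is.character(contrast)) contrast <- reri_contrast(contrast)
  set.seed(as.integer(seed))
  if (inherits(x, "cohort") && is.null(covariates)) {
    x <- crosstab_pair(x, snp_a, snp_b)
  }
  if (inherits(x, "two_locus_table")) {
    arr <- unclass(x)
    p_case <- as.numeric(arr[, , "case"]); n_case <- sum(p_case)
    p_ctrl <- as.numeric(arr[, , "control"]); n_ctrl <- sum(p_ctrl)
    idx <- function(g) g[1] + 1 + 3 * g[2]  # column-major cell index
    cells <- lapply(contrast[c("ref", "a_only", "b_only", "both")], idx)
    case_rep <- stats::rmultinom(reps, n_case, p_case / n_case)
    ctrl_rep <- stats::rmultinom(reps, n_ctrl, p_ctrl / n_ctrl)
    a1 <- case_rep[cells$both, ];   b1 <- ctrl_rep[cells$both, ]
    a2 <- case_rep[cells$a_only, ]; b2 <- ctrl_rep[cells$a_only, ]
    a3 <- case_rep[cells$b_only, ]; b3 <- ctrl_rep[cells$b_only, ]
    cr <- case_rep[cells$ref, ];    dr <- ctrl_rep[cells$ref, ]
    bad <- a1 == 0 | b1 == 0 | a2 == 0 | b2 == 0 | a3 == 0 | b3 == 0 |
           cr == 0 | dr == 0
    rr <- (a1 * dr) / (b1 * cr) - (a2 * dr) / (b2 * cr) -
          (a3 * dr) / (b3 * cr) + 1
    rr[bad] <- NA_real_
  } else {
    stopifnot(inherits(x, "cohort"))
    case_idx <- which(x$status == 2); ctrl_idx <- which(x$status == 1)
    rr <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      take <- c(sample(case_idx, replace = TRUE),
                sample(ctrl_idx, replace = TRUE))
      boot <- x[take, ]
      boot$id <- sprintf("b%07d", seq_len(nrow(boot)))
      boot <- cohort(as.data.frame(boot), attr(x, "specs"), attr(x, "label"))
      rr[r] <- tryCatch(
        reri_model(boot, snp_a, snp_b, contrast, covariates)$reri,
        error = function(e) NA_real_)
    }
  }
  ok <- !is.na(rr)
  n_deg <- sum(!ok)
  if (n_deg > 0.1 * reps)
    warning(sprintf("unstable bootstrap: %d/%d degenerate replicates",
                    n_deg, reps))
  if (!any(ok)) stop("all bootstrap replicates degenerate", call. = FALSE)
  p <- 2 * min(mean(rr[ok] <= 0), mean(rr[ok] >= 0))
  p <- min(1, max(p, 1 / reps))
  structure(list(p = p, reps = reps, n_degenerate = n_deg,
                 seed = as.integer(seed), replicates = rr),
            class = "reri_boot")
}

#' @export
print.reri_boot <- function(x, ...) {
  cat(sprintf("bootstrap RERI p = %s (%d reps, %d degenerate, seed %d)\n",
              format.pval(x$p), x$reps, x$n_degenerate, x$seed))
  invisible(x)
}
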