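#' Parameters for the case-control cohort simulator
#'
#' Defines the generative model: two biallelic SNPs in linkage equilibrium
#' with Hardy-Weinberg population genotype frequencies, a 3x3 penetrance
#' matrix over joint risk-allele dosages, and covariates (sex, age) drawn
#' independently of genotype whose optional disease effects enter on the
#' log-odds scale. Defaults emulate the combined Chinese Han atrial
#' fibrillation study population: risk-allele frequencies from its control
#' group (0.32 and 0.50), per-allele odds ratios 1.30 and 1.57, disease
#' prevalence 0.6%, 2020 cases and 5315 controls.
#'
#' @param freq_a,freq_b Population risk-allele frequencies, in (0, 1).
#' @param mode Penetrance model: `"odds_multiplicative"` (logit-linear in
#'   dosages: `logit P = mu + gA*bA + gB*bB + gA*gB*gamma`),
#'   `"risk_additive"` (`P = b + gA*eA + gB*eB + gA*gB*eAB` on the risk
#'   scale), or `"custom"` (explicit `penetrance` matrix).
#' @param baseline_risk Disease risk of the doubly non-risk homozygote, in
#'   (0, 1).
#' @param effect_a,effect_b Per-locus effects: log-odds per risk allele in
#'   `odds_multiplicative` mode (defaults `log(1.30)`, `log(1.57)`), excess
#'   risks per risk allele in `risk_additive` mode (defaults 0.004, 0.006).
#' @param interaction Interaction magnitude: log-odds product term
#'   (`odds_multiplicative`) or excess-risk product term (`risk_additive`).
#'   Default 0.
#' @param penetrance Optional 3x3 matrix (rows: dosage of SNP A 0/1/2,
#'   columns: dosage of SNP B), entries in (0, 1); overrides `mode`.
#' @param sex_prop_male Proportion of males in the population (default 0.6,
#'   the usual male excess of AF cohorts).
#' @param age_mean,age_sd Age distribution in years (default 60, sd 10).
#' @param sex_effect Log-odds effect of female sex on disease (default 0).
#' @param age_effect Log-odds effect per year of age, centered at
#'   `age_mean` (default 0).
#' @param n_cases,n_controls Target sample sizes.
#' @param snp_a,snp_b [snp_spec()]s naming the simulated SNPs.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(freq_a = 0.32, freq_b = 0.50,
                       mode = c("odds_multiplicative", "risk_additive", "custom"),
                       baseline_risk = 0.006,
                       effect_a = NULL, effect_b = NULL,
                       interaction = 0,
                       penetrance = NULL,
                       sex_prop_male = 0.6,
                       age_mean = 60, age_sd = 10,
                       sex_effect = 0, age_effect = 0,
                       n_cases = 2020, n_controls = 5315,
                       snp_a = snp_spec("snpA", "G", "A"),
                       snp_b = snp_spec("snpB", "C", "T")) {
  mode <- match.arg(mode)
  if (!is.null(penetrance)) mode <- "custom"
  if (mode == "custom" && is.null(penetrance))
    stop("custom mode requires a penetrance matrix", call. = FALSE)
  if (is.null(effect_a))
    effect_a <- if (mode == "odds_multiplicative") log(1.30) else 0.004
  if (is.null(effect_b))
    effect_b <- if (mode == "odds_multiplicative") log(1.57) else 0.006
  stopifnot(freq_a > 0, freq_a < 1, freq_b > 0, freq_b < 1,
            baseline_risk > 0, baseline_risk < 1,
            sex_prop_male >= 0, sex_prop_male <= 1, age_sd >= 0,
            n_cases >= 1, n_controls >= 1)
  structure(list(freq_a = freq_a, freq_b = freq_b, mode = mode,
                 baseline_risk = baseline_risk,
                 effect_a = effect_a, effect_b = effect_b,
                 interaction = interaction, penetrance = penetrance,
                 sex_prop_male = sex_prop_male,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_effect = sex_effect, age_effect = age_effect,
                 n_cases = n_cases, n_controls = n_controls,
                 snp_a = snp_a, snp_b = snp_b),
            class = "sim_params")
}

#' Build the penetrance matrix and the generating model's true values
#'
#' Evaluates the 3x3 penetrance matrix implied by the parameters (erroring,
#' never clipping, if any entry falls outside (0, 1)) and derives the exact
#' population quantities the estimators target: HWE x linkage-equilibrium
#' joint genotype frequencies, covariate-marginalized penetrance, true odds
#' ratios of every genotype versus the doubly non-risk reference, true RERI
#' for the H1/H2/H3 contrasts, and the true additive-by-additive
#' interaction odds ratio (the infinite-sample logistic projection; equal
#' to `exp(interaction)` in `odds_multiplicative` mode without covariates).
#'
#' @param params A [sim_params()].
#' @return List of class `true_values`: `penetrance`,
#'   `penetrance_marginal`, `geno_freq`, `or_profile` (3x3), `reri`
#'   (named H1/H2/H3), `axa_or`, `prevalence`.
#' @export
build_penetrance <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  g <- 0:2
  pen <- switch(params$mode,
    odds_multiplicative = {
      mu <- stats::qlogis(params$baseline_risk)
      outer(g, g, function(ga, gb)
        stats::plogis(mu + ga * params$effect_a + gb * params$effect_b +
                      ga * gb * params$interaction))
    },
    risk_additive = outer(g, g, function(ga, gb)
      params$baseline_risk + ga * params$effect_a + gb * params$effect_b +
        ga * gb * params$interaction),
    custom = {
      m <- as.matrix(params$penetrance)
      if (!all(dim(m) == c(3, 3))) stop("penetrance must be 3x3", call. = FALSE)
      m
    })
  if (any(pen <= 0) || any(pen >= 1))
    stop("penetrance outside (0, 1); adjust baseline/effects rather than clip",
         call. = FALSE)
  dimnames(pen) <- list(a = 0:2, b = 0:2)
  hwe <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)
  geno_freq <- outer(hwe(params$freq_a), hwe(params$freq_b))
  dimnames(geno_freq) <- dimnames(pen)
  pen_marg <- .marginal_penetrance(pen, params)
  odds <- pen_marg / (1 - pen_marg)
  or_profile <- odds / odds[1, 1]
  true_or <- function(cell, ref) odds[cell[1] + 1, cell[2] + 1] /
                                 odds[ref[1] + 1, ref[2] + 1]
  reri <- vapply(c("H1", "H2", "H3"), function(h) {
    ct <- reri_contrast(h)
    reri_point(true_or(ct$both, ct$ref), true_or(ct$a_only, ct$ref),
               true_or(ct$b_only, ct$ref))
  }, 0)
  # infinite-sample logistic projection for the multiplicative interaction
  grid <- expand.grid(a = 0:2, b = 0:2)
  pm <- pen_marg[cbind(grid$a + 1, grid$b + 1)]
  wt <- geno_freq[cbind(grid$a + 1, grid$b + 1)]
  proj <- suppressWarnings(stats::glm(pm ~ a + b + a:b, data = grid,
                                      family = stats::binomial(),
                                      weights = wt * 1e6))
  structure(list(penetrance = pen, penetrance_marginal = pen_marg,
                 geno_freq = geno_freq, or_profile = or_profile,
                 reri = reri,
                 axa_or = unname(exp(stats::coef(proj)[["a:b"]])),
                 prevalence = sum(geno_freq * pen_marg)),
            class = "true_values")
}

# Covariate-marginalized penetrance: E_{sex,age}[ expit(logit pen + shifts) ].
.marginal_penetrance <- function(pen, params) {
  if (params$sex_effect == 0 && params$age_effect == 0) return(pen)
  shift_sex <- c(male = 0, female = params$sex_effect)
  w_sex <- c(male = params$sex_prop_male, female = 1 - params$sex_prop_male)
  out <- pen
  for (i in 1:3) for (j in 1:3) {
    lp <- stats::qlogis(pen[i, j])
    val <- 0
    for (s in 1:2) {
      if (params$age_effect == 0 || params$age_sd == 0) {
        v <- stats::plogis(lp + shift_sex[s])
      } else {
        v <- stats::integrate(function(z)
          stats::plogis(lp + shift_sex[s] + params$age_effect * params$age_sd * z) *
            stats::dnorm(z), -8, 8)$value
      }
      val <- val + w_sex[s] * v
    }
    out[i, j] <- val
  }
  out
}

#' Simulate a case-control cohort with known penetrance
#'
#' Retrospective (status-conditional) sampling: subjects are drawn from the
#' population model — joint genotype from HWE x linkage equilibrium,
#' covariates independent of genotype — assigned disease status from their
#' penetrance, and accumulated until exactly `n_cases` cases and
#' `n_controls` controls are collected. Deterministic for a fixed seed.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed (required).
#' @return A [cohort()] with columns `id`, `sex`, `age`, `status` and one
#'   genotype column per simulated SNP.
#' @export
simulate_cohort <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  tv <- build_penetrance(params)
  pen <- tv$penetrance
  joint <- as.numeric(tv$geno_freq)  # column-major: a + 1 + 3*b
  need_case <- params$n_cases; need_ctrl <- params$n_controls
  acc <- vector("list", 0)
  total_drawn <- 0
  prev <- tv$prevalence
  while (need_case > 0 || need_ctrl > 0) {
    m <- max(2e4, ceiling(1.5 * (need_case / max(prev, 1e-6) +
                                 need_ctrl / max(1 - prev, 1e-6))))
    m <- min(m, 2e6)
    total_drawn <- total_drawn + m
    if (total_drawn > 5e7)
      stop("simulation quota unreachable: prevalence too extreme for the ",
           "requested sample sizes", call. = FALSE)
    cell <- sample.int(9, m, replace = TRUE, prob = joint)
    da <- (cell - 1) %% 3
    db <- (cell - 1) %/% 3
    sex <- ifelse(stats::runif(m) < params$sex_prop_male, 1L, 2L)
    age <- stats::rnorm(m, params$age_mean, params$age_sd)
    lp <- stats::qlogis(pen[cbind(da + 1, db + 1)]) +
      params$sex_effect * (sex == 2L) +
      params$age_effect * (age - params$age_mean)
    p <- stats::plogis(lp)
    is_case <- stats::runif(m) < p
    take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
    take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
    take <- c(take_case, take_ctrl)
    acc[[length(acc) + 1]] <- data.frame(
      sex = sex[take], age = age[take],
      status = ifelse(is_case[take], 2L, 1L),
      da = da[take], db = db[take])
    need_case <- need_case - length(take_case)
    need_ctrl <- need_ctrl - length(take_ctrl)
  }
  df <- do.call(rbind, acc)
  df <- df[sample.int(nrow(df)), ]  # exchangeable subject order
  out <- data.frame(id = sprintf("sim%06d", seq_len(nrow(df))),
                    sex = df$sex, age = round(df$age, 1), status = df$status)
  out[[params$snp_a$name]] <- genotype_label(df$da, params$snp_a)
  out[[params$snp_b$name]] <- genotype_label(df$db, params$snp_b)
  cohort(out, list(params$snp_a, params$snp_b), label = "simulated")
}

#' Simulate a two-locus count table directly
#'
#' Draws the 3x3x2 genotype counts from the exact status-conditional
#' genotype distributions implied by the penetrance model (covariates
#' marginalized out), i.e. the count-level equivalent of
#' [simulate_cohort()] when only genotype-based analyses are needed. Much
#' faster for replicate studies.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed (required).
#' @return A [two_locus_table()].
#' @export
simulate_table <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  tv <- build_penetrance(params)
  w <- as.numeric(tv$geno_freq)
  pm <- as.numeric(tv$penetrance_marginal)
  p_case <- w * pm / sum(w * pm)
  p_ctrl <- w * (1 - pm) / sum(w * (1 - pm))
  arr <- array(0, dim = c(3, 3, 2))
  arr[, , 1] <- stats::rmultinom(1, params$n_cases, p_case)
  arr[, , 2] <- stats::rmultinom(1, params$n_controls, p_ctrl)
  two_locus_table(arr, params$snp_a, params$snp_b, label = "simulated")
}

#' Replicate study of estimator bias, coverage and rejection rates
#'
#' Simulates `n_reps` case-control samples from a [sim_params()] model and,
#' for each, re-estimates the doubly-exposed genotype odds ratio, the RERI
#' of a chosen contrast with its MOVER CI, and the additive-by-additive
#' interaction odds ratio (risk-allele orientation), comparing each with
#' the generating model's true value.
#'
#' @param params A [sim_params()].
#' @param n_reps Number of replicates (>= 50 for stable rates).
#' @param seed Integer seed.
#' @param contrast RERI contrast label (default `"H2"`).
#' @return List of class `recovery_summary`: per-replicate data frame
#'   `replicates`, plus `true`, `bias` (means), `coverage` (MOVER CI for
#'   RERI, Wald CI for the interaction OR), `rejection` (CI-excludes-null
#'   rates).
#' @export
recovery_suite <- function(params, n_reps, seed, contrast = "H2") {
  stopifnot(inherits(params, "sim_params"))
  if (n_reps < 50) stop("n_reps must be >= 50", call. = FALSE)
  tv <- build_penetrance(params)
  ct <- reri_contrast(contrast)
  true_reri <- tv$reri[[contrast]]
  true_or_both <- tv$or_profile[ct$both[1] + 1, ct$both[2] + 1] /
                  tv$or_profile[ct$ref[1] + 1, ct$ref[2] + 1]
  set.seed(as.integer(seed))
  seeds <- sample.int(2^30, n_reps)  # per-replicate sub-seeds from the master stream
  rows <- lapply(seq_len(n_reps), function(r) {
    tab <- simulate_table(params, seeds[r])
    res <- tryCatch(reri_from_counts(tab, ct), error = function(e) NULL)
    t5 <- tryCatch(interaction_test5(tab, coding_scheme("risk")),
                   error = function(e) NULL)
    data.frame(
      rep = r,
      reri = if (is.null(res)) NA_real_ else res$reri,
      reri_ci_low = if (is.null(res)) NA_real_ else res$ci_low,
      reri_ci_high = if (is.null(res)) NA_real_ else res$ci_high,
      or_both = if (is.null(res)) NA_real_ else res$or11$or,
      axa_or = if (is.null(t5)) NA_real_ else t5$terms$or[1],
      axa_p = if (is.null(t5)) NA_real_ else t5$terms$p[1])
  })
  reps <- do.call(rbind, rows)
  ok <- stats::complete.cases(reps)
  r <- reps[ok, ]
  structure(list(
    replicates = reps,
    n_degenerate = sum(!ok),
    true = list(reri = true_reri, or_both = true_or_both, axa_or = tv$axa_or),
    bias = list(reri = mean(r$reri) - true_reri,
                or_both = mean(r$or_both) - true_or_both,
                axa_or = mean(r$axa_or) - tv$axa_or),
    coverage = list(
      reri = mean(r$reri_ci_low <= true_reri & true_reri <= r$reri_ci_high)),
    rejection = list(
      reri = mean(r$reri_ci_low > 0 | r$reri_ci_high < 0),
      axa = mean(r$axa_p < 0.05))),
    class = "recovery_summary")
}
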