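main_tab <- af_example_counts("rs2106261-rs2200733")

test_that("the 4-df genotypic interaction fit reproduces the published unadjusted terms", {
  fit <- interaction_test6(main_tab)  # minor-allele orientation default
  tt <- fit$terms
  rownames(tt) <- tt$term
  expect_equal(round(tt["axa", "or"], 2), 0.89)
  expect_equal(round(tt["axa", "ci_low"], 2), 0.79)
  expect_equal(round(tt["axa", "ci_high"], 2), 1.01)
  expect_equal(round(tt["axd", "or"], 2), 0.95)
  expect_equal(round(tt["dxa", "or"], 2), 1.06)
  expect_equal(round(tt["dxd", "or"], 2), 1.12)
  expect_equal(round(fit$global_p, 2), 0.23)
  expect_gte(fit$loglik_full, fit$loglik_main)
})

test_that("the 1-df additive interaction fit reproduces the published reduced-model estimate", {
  fit <- interaction_test5(main_tab)
  expect_equal(round(fit$terms$or[1], 2), 0.89)
  expect_equal(round(fit$terms$ci_low[1], 2), 0.80)
  expect_equal(round(fit$terms$ci_high[1], 2), 1.00)
  expect_equal(round(fit$terms$p[1], 2), 0.04)
})

test_that("risk orientation inverts the additive-by-additive OR when one risk allele is major", {
  minor <- interaction_test5(main_tab)
  risk <- interaction_test5(main_tab, coding_scheme("risk"))
  # rs2200733's risk allele T is the major allele, so exactly one axis flips
  expect_true(xor(minor$flipped[["a"]], risk$flipped[["a"]]) ||
                minor$flipped[["b"]] != risk$flipped[["b"]])
  expect_equal(risk$terms$or[1], 1 / minor$terms$or[1], tolerance = 1e-10)
})

test_that("relabelling which SNP is A transposes the mixed terms and keeps the global test", {
  swapped <- two_locus_table(aperm(unclass(main_tab), c(2, 1, 3)),
                             attr(main_tab, "spec_b"), attr(main_tab, "spec_a"))
  f1 <- interaction_test6(main_tab)
  f2 <- interaction_test6(swapped)
  t1 <- f1$terms; rownames(t1) <- t1$term
  t2 <- f2$terms; rownames(t2) <- t2$term
  expect_equal(t1["axa", "or"], t2["axa", "or"], tolerance = 1e-10)
  expect_equal(t1["dxd", "or"], t2["dxd", "or"], tolerance = 1e-10)
  expect_equal(t1["axd", "or"], t2["dxa", "or"], tolerance = 1e-10)
  expect_equal(t1["dxa", "or"], t2["axd", "or"], tolerance = 1e-10)
  expect_equal(f1$global_p, f2$global_p, tolerance = 1e-10)
})

test_that("count-table fits equal subject-level fits on the expanded records", {
  small <- two_locus_table(
    array(c(20, 15, 9, 14, 30, 11, 8, 12, 16,
            60, 40, 20, 35, 70, 25, 18, 22, 10), c(3, 3, 2)),
    spec_zfhx3, spec_pitx2)
  ch <- expand_table(small)
  f_tab <- interaction_test6(small)
  f_coh <- interaction_test6(ch, snp_a = "rs2106261", snp_b = "rs2200733")
  expect_equal(f_tab$fit_full$coefficients, f_coh$fit_full$coefficients,
               tolerance = 1e-8)
  expect_equal(f_tab$global_p, f_coh$global_p, tolerance = 1e-8)
})

test_that("a multiplicative interaction effect is recovered at large n", {
  gamma <- log(1.5)
  params <- sim_params(interaction = gamma, n_cases = 25000,
                       n_controls = 25000)
  tab <- simulate_table(params, seed = 404)
  fit <- interaction_test5(tab, coding_scheme("risk"))
  expect_equal(fit$terms$or[1], exp(gamma), tolerance = 0.05)
  # and the 4-df model's A x A term agrees
  fit6 <- interaction_test6(tab, coding_scheme("risk"))
  tt <- fit6$terms; rownames(tt) <- tt$term
  expect_equal(tt["axa", "or"], exp(gamma), tolerance = 0.1)
})

test_that("null simulations give interaction ORs near one", {
  params <- sim_params(interaction = 0, n_cases = 25000, n_controls = 25000)
  tab <- simulate_table(params, seed = 505)
  fit <- interaction_test6(tab, coding_scheme("risk"))
  expect_true(all(fit$terms$or > 0.95 & fit$terms$or < 1.05))
})

test_that("test #5 is calibrated under a multiplicative null", {
  params <- sim_params(interaction = 0, n_cases = 1500, n_controls = 1500)
  set.seed(66)
  seeds <- sample.int(2^30, 300)
  pvals <- vapply(seeds, function(s) {
    interaction_test5(simulate_table(params, s),
                      coding_scheme("risk"))$terms$p[1]
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("dominance reduction LRT reports the parameter-count df and detects dominance", {
  f6 <- interaction_test6(main_tab)
  f5 <- interaction_test5(main_tab)
  red <- dominance_reduction_lrt(f6, f5)
  expect_equal(red$df, length(f6$fit_full$coefficients) -
                 length(f5$fit_full$coefficients))
  expect_gte(red$statistic, 0)
  expect_error(dominance_reduction_lrt(f5, f6), "fewer parameters")
  # identical models: p = 1
  same <- dominance_reduction_lrt(
    f6, structure(list(loglik_full = f6$loglik_full,
                       fit_full = list(coefficients = f6$fit_full$coefficients[1:5])),
                  class = "interaction_fit"))
  expect_equal(same$p, 1)
  # strong simulated dominance is detected
  pen <- matrix(0.01, 3, 3)
  pen[2, ] <- 0.03  # heterozygote-specific risk at SNP A
  params <- sim_params(penetrance = pen, n_cases = 10000, n_controls = 10000)
  tab <- simulate_table(params, seed = 808)
  p <- dominance_reduction_lrt(interaction_test6(tab, coding_scheme("risk")),
                               interaction_test5(tab, coding_scheme("risk")))$p
  expect_lt(p, 0.01)
})
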