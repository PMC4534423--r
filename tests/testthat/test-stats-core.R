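test_that("Woolf odds ratio and CI reproduce the published double-risk genotype estimate", {
  est <- or_woolf(148, 141, 131, 605)
  expect_equal(round(est$or, 2), 4.85)
  expect_equal(round(est$ci_low, 2), 3.60)
  expect_equal(round(est$ci_high, 2), 6.53)
  expect_lt(est$p, 1e-20)
  # symmetric table
  expect_equal(or_woolf(10, 10, 10, 10)$or, 1)
  # Haldane-Anscombe zero-cell handling: (5.5*10.5)/(0.5*10.5) = 11
  expect_equal(or_woolf(5, 0, 10, 10)$or, 11)
  expect_error(or_woolf(5, 0, 10, 10, correction = "none"), "zero cell")
  expect_error(or_woolf(0, 0, 10, 10), "degenerate")
})

test_that("odds ratio is antisymmetric under exposure swap", {
  set.seed(11)
  for (i in 1:25) {
    t4 <- rpois(4, 40) + 1
    a <- or_woolf(t4[1], t4[2], t4[3], t4[4])
    b <- or_woolf(t4[3], t4[4], t4[1], t4[2])
    expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
    expect_equal(log(a$ci_low), -log(b$ci_high), tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("Pearson chi-square matches the brute-force (O-E)^2/E summation", {
  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 30) + 1, nrow = 2)
    got <- chi2_contingency(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(got$df, 2)
  }
  # proportional rows carry no association
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi2_contingency(prop)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi2_contingency(prop)$p, 1)
  expect_error(chi2_contingency(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("allelic 2x2 from the discovery margins reproduces the published p-value", {
  res <- chi2_contingency(rbind(c(719, 419), c(2008, 1984)))
  expect_equal(res$p, 1.58e-14, tolerance = 0.05)
})

test_that("logistic fit on a single binary predictor matches the closed-form odds ratio", {
  a <- 30; b <- 50; c_ <- 20; d <- 80
  x <- c(rep(1, a + b), rep(0, c_ + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
  fit <- logistic_fit(cbind(exposed = x), y)
  expect_equal(exp(fit$coefficients[["exposed"]]),
               or_woolf(a, b, c_, d)$or, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("frequency-weighted fits equal fits on expanded records", {
  cells <- expand.grid(x = 0:2, z = 0:1)
  cells$w_case <- c(10, 20, 15, 5, 12, 9)
  cells$w_ctrl <- c(40, 35, 10, 22, 18, 4)
  Xw <- as.matrix(rbind(cells[, c("x", "z")], cells[, c("x", "z")]))
  yw <- rep(1:0, each = nrow(cells))
  ww <- c(cells$w_case, cells$w_ctrl)
  wfit <- logistic_fit(Xw, yw, weights = ww)
  Xe <- Xw[rep(seq_len(nrow(Xw)), ww), ]
  ye <- rep(yw, ww)
  efit <- logistic_fit(Xe, ye)
  expect_equal(wfit$coefficients, efit$coefficients, tolerance = 1e-8)
  # covariances agree up to the IRLS stopping tolerance
  expect_equal(wfit$covariance, efit$covariance, tolerance = 1e-6)
  expect_equal(wfit$loglik, efit$loglik, tolerance = 1e-8)
})

test_that("degenerate and separated responses are refused", {
  expect_error(logistic_fit(cbind(x = c(1, 0, 1)), c(0, 0, 0)), "degenerate")
  x <- c(rep(0, 20), rep(1, 20))
  expect_error(logistic_fit(cbind(x = x), x), "separation")
  expect_error(logistic_fit(cbind(x = c(1, 2, 3, 4), x2 = c(2, 4, 6, 8)),
                            c(0, 1, 0, 1)), "collinear")
})

test_that("Wald and LRT behave at the null and agree asymptotically", {
  # beta = 0 exactly: p = 1
  fit <- list(coefficients = c(x = 0), covariance = matrix(1, 1, 1,
              dimnames = list("x", "x")))
  class(fit) <- "logistic_fit"
  expect_equal(wald_test(fit, "x")$p, 1)
  expect_equal(lrt(-100, -100, df = 4), 1)
  # simulated moderate effect: Wald and LRT p agree within 20% relative
  set.seed(42)
  n <- 10000
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.25 * x))
  full <- logistic_fit(cbind(x = x), y)
  null <- logistic_fit(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), y)
  p_wald <- wald_test(full, "x")$p
  p_lrt <- lrt(full$loglik, null$loglik, df = 1)
  expect_equal(p_wald, p_lrt, tolerance = 0.2)
})

test_that("Breslow-Day matches the independent uniroot oracle and is order-invariant", {
  set.seed(3)
  for (i in 1:15) {
    k <- sample(2:4, 1)
    strata <- replicate(k, rpois(4, 50) + 5, simplify = FALSE)
    got <- breslow_day(strata)
    want <- bd_oracle(strata)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
    perm <- breslow_day(rev(strata))
    expect_equal(got$statistic, perm$statistic, tolerance = 1e-10)
  }
  # two identical strata are perfectly homogeneous
  s <- c(12, 18, 30, 40)
  hom <- breslow_day(list(s, s))
  expect_equal(hom$statistic, 0, tolerance = 1e-10)
  expect_equal(hom$p, 1)
  expect_error(breslow_day(list(c(0, 0, 5, 5), s)), "degenerate")
  expect_error(breslow_day(list(s)), "two strata")
})

test_that("Tarone correction shrinks the Breslow-Day statistic", {
  strata <- list(c(30, 20, 15, 35), c(10, 25, 30, 12))
  plain <- breslow_day(strata)
  tar <- breslow_day(strata, tarone = TRUE)
  expect_lte(tar$statistic, plain$statistic + 1e-12)
})

test_that("exact HWE test equals the enumeration oracle for small samples", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(0, 2, 0), c(10, 5, 1),
                c(3, 14, 30), c(20, 20, 2), c(1, 1, 1))
  for (cc in cases) {
    expect_equal(hwe_exact(cc[1], cc[2], cc[3]),
                 hwe_enum_oracle(cc[1], cc[2], cc[3]), tolerance = 1e-10)
  }
  # sweep all configurations with 2n <= 100
  set.seed(9)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    het <- sample(0:n, 1)
    rest <- n - het
    hom1 <- sample(0:rest, 1)
    p <- hwe_exact(hom1, het, rest - hom1)
    expect_gte(p, 0)
    expect_lte(p, 1)
    expect_equal(p, hwe_enum_oracle(hom1, het, rest - hom1), tolerance = 1e-10)
  }
})

test_that("chi-square HWE test is exact at perfect proportions", {
  expect_equal(hwe_chi2(25, 50, 25), 1)
  expect_lt(hwe_chi2(50, 0, 50), 1e-10)
})
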