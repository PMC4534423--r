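# Shared fixtures and independent oracles for the suite.

spec_zfhx3 <- snp_spec("rs2106261", "G", "A")
spec_pitx2 <- snp_spec("rs2200733", "C", "T")
spec_cav1 <- snp_spec("rs3807989", "A", "G")

# Small hand-written cohort: 6 subjects, one missing call, one het each way.
tiny_cohort <- function() {
  df <- data.frame(
    id = paste0("S", 1:6),
    sex = c(2L, 1L, 1L, 2L, 1L, 2L),
    age = c(63, 58, NA, 71, 45, 66),
    status = c(2L, 1L, 2L, 1L, 2L, 1L),
    rs2106261 = c("AA", "GA", "AG", "GG", NA, "GG"),
    rs2200733 = c("TT", "CT", "CC", "TC", "CT", NA))
  cohort(df, list(spec_zfhx3, spec_pitx2), label = "tiny")
}

# Independent Breslow-Day oracle: Mantel-Haenszel OR and per-stratum expected
# counts found numerically (uniroot on the OR condition), never via the
# implementation's closed-form quadratic.
bd_oracle <- function(strata) {
  psi <- sum(sapply(strata, function(s) s[1] * s[4] / sum(s))) /
         sum(sapply(strata, function(s) s[2] * s[3] / sum(s)))
  stat <- 0
  for (s in strata) {
    n1 <- s[1] + s[2]; m1 <- s[1] + s[3]; N <- sum(s)
    lo <- max(0, n1 + m1 - N) + 1e-9
    hi <- min(n1, m1) - 1e-9
    f <- function(A) A * (N - n1 - m1 + A) / ((n1 - A) * (m1 - A)) - psi
    A <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    V <- 1 / (1 / A + 1 / (n1 - A) + 1 / (m1 - A) + 1 / (N - n1 - m1 + A))
    stat <- stat + (s[1] - A)^2 / V
  }
  list(statistic = stat, p = stats::pchisq(stat, length(strata) - 1, lower.tail = FALSE))
}

# Enumeration oracle for the exact HWE test: full probability table over all
# feasible heterozygote counts via exact rational-ish arithmetic in logs.
hwe_enum_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nr <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  hets <- seq(nr %% 2, nr, by = 2)
  probs <- sapply(hets, function(h) {
    hom_r <- (nr - h) / 2
    hom_c <- n - h - hom_r
    exp(h * log(2) + lfactorial(n) - lfactorial(h) - lfactorial(hom_r) -
          lfactorial(hom_c) - (lfactorial(2 * n) - lfactorial(nr) -
                               lfactorial(2 * n - nr)))
  })
  probs <- probs / sum(probs)  # exact normalization of the conditional law
  p_obs <- probs[match(n_het, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}
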