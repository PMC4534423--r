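test_that("genotype parsing is order- and case-insensitive with tolerant missing markers", {
  s <- spec_zfhx3
  expect_equal(parse_genotype(c("AG", "GA", "g/a", "a|g"), s),
               rep("GA", 4))
  expect_equal(parse_genotype(c("", "00", "--", "NN", NA), s),
               rep(NA_character_, 5))
  expect_error(parse_genotype("AT", s), "outside")
  expect_error(parse_genotype("A", s), "two alleles")
})

test_that("dosage counts risk alleles and propagates missingness", {
  expect_equal(dosage(c("AA", "GA", "AG", "GG", NA), spec_zfhx3),
               c(2L, 1L, 1L, 0L, NA))
  expect_equal(dosage(c("TT", "CT", "CC"), spec_pitx2), c(2L, 1L, 0L))
  expect_equal(genotype_label(0:2, spec_zfhx3), c("GG", "AG", "AA"))
  expect_equal(dosage(genotype_label(0:2, spec_pitx2), spec_pitx2), 0:2)
})

test_that("subject rows decode the sex/status coding", {
  ch <- tiny_cohort()
  expect_s3_class(ch, "cohort")
  # row S1: female case, age 63, homozygous risk at both SNPs
  expect_equal(ch$sex[1], 2L)
  expect_equal(ch$status[1], 2L)
  expect_equal(dosage(ch$rs2106261[1], spec_zfhx3), 2L)
  expect_equal(dosage(ch$rs2200733[1], spec_pitx2), 2L)
})

test_that("cohort construction rejects invalid codings and duplicate ids", {
  df <- data.frame(id = c("a", "b"), sex = c(1L, 3L), age = c(50, 60),
                   status = c(1L, 2L), rs2106261 = c("GG", "AA"))
  expect_error(cohort(df, list(spec_zfhx3)), "sex")
  df$sex <- c(1L, 2L); df$status <- c(0L, 2L)
  expect_error(cohort(df, list(spec_zfhx3)), "status")
  df$status <- c(1L, 2L); df$id <- c("a", "a")
  expect_error(cohort(df, list(spec_zfhx3)), "duplicate")
})

test_that("write/read round-trips a cohort field by field", {
  ch <- tiny_cohort()
  path <- tempfile(fileext = ".tsv")
  write_cohort(ch, path)
  back <- read_cohort(path, attr(ch, "specs"), label = "tiny")
  expect_equal(as.data.frame(back), as.data.frame(ch))
})

test_that("empty and header-only inputs yield empty cohorts", {
  path <- tempfile(fileext = ".tsv")
  writeLines("id\tsex\tage\tstatus\trs2106261\trs2200733", path)
  ch <- read_cohort(path, list(spec_zfhx3, spec_pitx2))
  expect_equal(nrow(ch), 0L)
})

test_that("PED dialect reads the six leading columns plus allele pairs", {
  path <- tempfile(fileext = ".ped")
  writeLines(c("F1 I1 0 0 1 2 A A T T",
               "F2 I2 0 0 2 1 G A C T",
               "F3 I3 0 0 1 1 0 0 C C"), path)
  ch <- read_cohort(path, list(spec_zfhx3, spec_pitx2), dialect = "ped")
  expect_equal(ch$status, c(2L, 1L, 1L))
  expect_equal(dosage(ch$rs2106261, spec_zfhx3), c(2L, 1L, NA))
  expect_equal(dosage(ch$rs2200733, spec_pitx2), c(2L, 1L, 0L))
})

test_that("single-SNP crosstab uses per-SNP complete cases", {
  ch <- tiny_cohort()
  ct <- crosstab_single(ch, "rs2106261")
  expect_equal(sum(ct), 5)  # one missing call dropped
  expect_equal(unname(ct["case", ]), c(0, 1, 1))
  expect_equal(unname(ct["control", ]), c(2, 1, 0))
  # crosstab on an empty cohort is all zeros
  empty <- ch[0, ]
  empty <- cohort(as.data.frame(empty), attr(ch, "specs"))
  expect_equal(sum(crosstab_single(empty, "rs2106261")), 0)
})

test_that("pairwise crosstab marginalizes consistently with the single-SNP table", {
  ch <- tiny_cohort()
  tab <- crosstab_pair(ch, "rs2106261", "rs2200733")
  expect_equal(sum(tab), 4)  # pairwise complete cases only
  # marginal of the pair table equals the single-SNP crosstab restricted to
  # the pairwise-complete subset
  both <- !is.na(dosage(ch$rs2106261, spec_zfhx3)) &
          !is.na(dosage(ch$rs2200733, spec_pitx2))
  sub <- cohort(as.data.frame(ch[both, ]), attr(ch, "specs"))
  expect_equal(unclass(margin_counts(tab, "a")),
               unclass(crosstab_single(sub, "rs2106261")),
               ignore_attr = TRUE)
})

test_that("a constructed uniform cohort fills every cell once per status", {
  grid <- expand.grid(a = 0:2, b = 0:2, status = 1:2)
  df <- data.frame(id = paste0("u", seq_len(nrow(grid))), sex = 1L,
                   age = 50, status = grid$status,
                   rs2106261 = genotype_label(grid$a, spec_zfhx3),
                   rs2200733 = genotype_label(grid$b, spec_pitx2))
  tab <- crosstab_pair(cohort(df, list(spec_zfhx3, spec_pitx2)),
                       "rs2106261", "rs2200733")
  expect_true(all(unclass(tab) == 1))
})

test_that("shipped count fixtures reproduce the published marginals", {
  tab <- af_example_counts("rs2106261-rs2200733", "combined")
  expect_equal(sum(unclass(tab)[, , "case"]), 2020)
  expect_equal(sum(unclass(tab)[, , "control"]), 5315)
  mb <- margin_counts(tab, "b")
  expect_equal(unname(mb["case", ]), c(290, 985, 745))
  expect_equal(unname(mb["control", ]), c(1267, 2762, 1286))
  # combined equals the cell-wise sum of the three sub-populations
  pops <- c("discovery", "replication1", "replication2")
  parts <- lapply(pops, function(p) unclass(af_example_counts("rs2106261-rs2200733", p)))
  expect_equal(unclass(tab), Reduce(`+`, parts), ignore_attr = TRUE)
})

test_that("count-table expansion inverts aggregation", {
  tab <- af_example_counts("rs2200733-rs3807989")
  ch <- expand_table(tab)
  back <- crosstab_pair(ch, "rs2200733", "rs3807989")
  expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
})
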