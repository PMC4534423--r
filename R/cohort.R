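#' Construct a case-control cohort
#'
#' A `cohort` is a data frame with one row per subject — columns `id`,
#' `sex` (1 = male, 2 = female), `age` (years, may be `NA`), `status`
#' (1 = control, 2 = case) — plus one normalized genotype column per SNP,
#' carrying its [snp_spec()] list as an attribute.
#'
#' @param subjects Data frame with columns `id`, `sex`, `age`, `status` and
#'   one genotype column named after each SNP in `specs`.
#' @param specs List of [snp_spec()] objects.
#' @param label Free-text population label.
#' @return An object of class `cohort` (a data frame).
#' @export
cohort <- function(subjects, specs, label = "") {
  stopifnot(is.data.frame(subjects))
  if (inherits(specs, "snp_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, `[[`, "", "name")
  need <- c("id", "sex", "age", "status")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  subjects$id <- as.character(subjects$id)
  dup <- duplicated(subjects$id)
  if (any(dup))
    stop("duplicate subject id(s): ",
         paste(utils::head(unique(subjects$id[dup]), 5), collapse = ", "), call. = FALSE)
  for (col in c("sex", "status")) {
    v <- subjects[[col]]
    bad <- !is.na(v) & !(v %in% 1:2)
    if (col == "status") bad <- bad | is.na(v)
    if (any(bad))
      stop("invalid ", col, " coding (must be 1 or 2) in row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(subjects$age) & subjects$age < 0))
    stop("negative age", call. = FALSE)
  for (sn in names(specs)) {
    if (!sn %in% names(subjects))
      stop("missing genotype column for SNP ", sn, call. = FALSE)
    subjects[[sn]] <- parse_genotype(subjects[[sn]], specs[[sn]])
  }
  structure(subjects, specs = specs, label = label,
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  sp <- attr(x, "specs")
  cat(sprintf("<cohort> %s: %d subjects (%d cases / %d controls), SNPs: %s\n",
              if (nzchar(attr(x, "label"))) attr(x, "label") else "(unlabelled)",
              nrow(x), sum(x$status == 2), sum(x$status == 1),
              paste(names(sp), collapse = ", ")))
  invisible(x)
}

#' Read a subject-level genotype table
#'
#' Reads a delimited subject table (columns: id, sex 1=male/2=female, age,
#' status 1=control/2=case, one genotype column per SNP) or a PLINK text
#' PED file. Columns are bound by header name when a header is present and
#' positionally otherwise. Unparseable genotype cells become missing, with
#' a message reporting how many.
#'
#' @param path File path.
#' @param specs List of [snp_spec()] objects, in file order for positional
#'   binding.
#' @param dialect `"table"` (TSV/CSV, default) or `"ped"` (PLINK text PED:
#'   FID IID PAT MAT SEX PHENO then two allele columns per SNP; PHENO
#'   1 = control, 2 = case).
#' @param label Population label for the resulting cohort.
#' @param columns Optional named character vector remapping header names,
#'   e.g. `c(id = "IID", sex = "Gender", status = "AF")`.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, specs, dialect = c("table", "ped"),
                        label = "", columns = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (inherits(specs, "snp_spec")) specs <- list(specs)
  snp_names <- vapply(specs, `[[`, "", "name")
  if (dialect == "ped") {
    raw <- utils::read.table(path, header = FALSE, colClasses = "character")
    if (nrow(raw) && ncol(raw) != 6 + 2 * length(specs))
      stop("PED file must have 6 + 2 columns per SNP", call. = FALSE)
    if (nrow(raw) == 0) {
      df <- data.frame(id = character(), sex = integer(), age = numeric(),
                       status = integer())
      for (sn in snp_names) df[[sn]] <- character()
      return(cohort(df, specs, label))
    }
    df <- data.frame(id = raw[[2]], sex = as.integer(raw[[5]]),
                     age = NA_real_, status = as.integer(raw[[6]]))
    for (i in seq_along(specs)) {
      a1 <- raw[[6 + 2 * i - 1]]
      a2 <- raw[[6 + 2 * i]]
      g <- paste0(a1, a2)
      g[a1 %in% c("0", "-", "N") | a2 %in% c("0", "-", "N")] <- NA_character_
      df[[snp_names[i]]] <- g
    }
    return(cohort(df, specs, label))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  header <- length(first) > 0 && grepl("id", strsplit(first, sep)[[1]][1],
                                       ignore.case = TRUE)
  raw <- utils::read.table(path, header = header, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           check.names = FALSE)
  if (!header && nrow(raw)) {
    if (ncol(raw) != 4 + length(specs))
      stop("positional table must have 4 + one genotype column per SNP",
           call. = FALSE)
    names(raw) <- c("id", "sex", "age", "status", snp_names)
  }
  if (!is.null(columns))
    for (std in names(columns)) names(raw)[names(raw) == columns[[std]]] <- std
  names(raw)[tolower(names(raw)) %in% c("gender", "sex")] <- "sex"
  names(raw)[tolower(names(raw)) %in% c("af", "status", "affection")] <- "status"
  names(raw)[tolower(names(raw)) %in% c("id", "iid", "subject")] <- "id"
  names(raw)[tolower(names(raw)) == "age"] <- "age"
  if (nrow(raw) == 0) {
    df <- data.frame(id = character(), sex = integer(), age = numeric(),
                     status = integer())
    for (sn in snp_names) df[[sn]] <- character()
    return(cohort(df, specs, label))
  }
  df <- data.frame(id = raw$id,
                   sex = suppressWarnings(as.integer(raw$sex)),
                   age = suppressWarnings(as.numeric(raw$age)),
                   status = suppressWarnings(as.integer(raw$status)))
  n_bad <- 0L
  for (i in seq_along(specs)) {
    g <- raw[[snp_names[i]]]
    parsed <- parse_genotype(g, specs[[i]], strict = FALSE)
    newly_missing <- is.na(parsed) &
      !(is.na(g) | toupper(trimws(g)) %in% .missing_tokens)
    n_bad <- n_bad + sum(newly_missing)
    # out-of-spec alleles are a coding error, not silent missingness
    if (any(newly_missing)) {
      chars_ok <- grepl("^[ACGTacgt/| ]+$", trimws(g[newly_missing]))
      if (any(chars_ok))
        stop("genotype with allele outside spec for SNP ", snp_names[i],
             " in row(s): ",
             paste(utils::head(which(newly_missing)[chars_ok], 5), collapse = ", "),
             call. = FALSE)
    }
    df[[snp_names[i]]] <- parsed
  }
  if (n_bad > 0)
    message(n_bad, " unparseable genotype cell(s) set to missing")
  cohort(df, specs, label)
}

#' Write a cohort back to a subject table
#'
#' @param x A [cohort()].
#' @param path Output path; tab-separated with a header.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- as.data.frame(x)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Single-SNP genotype counts by case status
#'
#' Complete-case (for this SNP) counts of subjects by risk-allele dosage and
#' status.
#'
#' @param x A [cohort()].
#' @param snp SNP name (must have a spec in the cohort).
#' @return A 2x3 matrix of class `genotype_counts` (rows case/control,
#'   columns dosage 0/1/2) with the `snp_spec` attached.
#' @export
crosstab_single <- function(x, snp) {
  stopifnot(inherits(x, "cohort"))
  spec <- attr(x, "specs")[[snp]]
  if (is.null(spec)) stop("no spec for SNP ", snp, call. = FALSE)
  d <- dosage(x[[snp]], spec)
  keep <- !is.na(d)
  m <- matrix(0L, 2, 3, dimnames = list(status = c("case", "control"),
                                        dosage = 0:2))
  if (any(keep)) {
    tt <- table(factor(ifelse(x$status[keep] == 2, "case", "control"),
                       levels = c("case", "control")),
                factor(d[keep], levels = 0:2))
    m[] <- as.integer(tt)
    m[, ] <- tt
  }
  structure(m, spec = spec, class = c("genotype_counts", "matrix", "array"))
}

#' Construct a two-locus genotype count table
#'
#' @param counts 3x3x2 array of non-negative counts indexed by
#'   (dosage of SNP A, dosage of SNP B, status), with status slices ordered
#'   case then control.
#' @param spec_a,spec_b [snp_spec()]s for the two SNPs.
#' @param label Population label.
#' @return An object of class `two_locus_table`.
#' @export
two_locus_table <- function(counts, spec_a, spec_b, label = "") {
  counts <- array(as.numeric(counts), dim = c(3, 3, 2),
                  dimnames = list(a = 0:2, b = 0:2,
                                  status = c("case", "control")))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(counts, spec_a = spec_a, spec_b = spec_b, label = label,
            class = c("two_locus_table", "array"))
}

#' @export
print.two_locus_table <- function(x, ...) {
  sa <- attr(x, "spec_a"); sb <- attr(x, "spec_b")
  cat(sprintf("<two_locus_table> %s x %s (%s): %d cases / %d controls\n",
              sa$name, sb$name,
              if (nzchar(attr(x, "label"))) attr(x, "label") else "unlabelled",
              sum(x[, , "case"]), sum(x[, , "control"])))
  for (st in c("case", "control")) {
    cat(st, "counts (rows:", sa$name, "dosage; cols:", sb$name, "dosage)\n")
    print(unclass(x)[, , st])
  }
  invisible(x)
}

#' Two-locus genotype counts by case status
#'
#' Pairwise complete-case 3x3x2 crosstab of joint risk-allele dosages.
#'
#' @param x A [cohort()].
#' @param snp_a,snp_b SNP names.
#' @return A [two_locus_table()].
#' @export
crosstab_pair <- function(x, snp_a, snp_b) {
  stopifnot(inherits(x, "cohort"))
  specs <- attr(x, "specs")
  sa <- specs[[snp_a]]; sb <- specs[[snp_b]]
  if (is.null(sa) || is.null(sb))
    stop("both SNPs need specs in the cohort", call. = FALSE)
  da <- dosage(x[[snp_a]], sa)
  db <- dosage(x[[snp_b]], sb)
  keep <- !is.na(da) & !is.na(db)
  arr <- array(0, dim = c(3, 3, 2))
  if (any(keep)) {
    tt <- table(factor(da[keep], levels = 0:2),
                factor(db[keep], levels = 0:2),
                factor(ifelse(x$status[keep] == 2, "case", "control"),
                       levels = c("case", "control")))
    arr[] <- as.numeric(tt)
  }
  two_locus_table(arr, sa, sb, label = attr(x, "label"))
}

#' Read pre-aggregated two-locus genotype counts
#'
#' Reads a 9-row tab-separated table with columns
#' `genotype_a`, `genotype_b`, `n_case`, `n_control` (header required).
#' A `population` column may be present; then `population` selects one
#' stratum, or `"combined"` (the default when present) sums all strata.
#'
#' @param path TSV path.
#' @param spec_a,spec_b [snp_spec()]s matching the genotype string columns.
#' @param population Optional population label to select.
#' @return A [two_locus_table()].
#' @export
read_counts_table <- function(path, spec_a, spec_b, population = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", strip.white = TRUE)
  label <- if (is.null(population)) "combined" else population
  if ("population" %in% names(df)) {
    if (!is.null(population) && population != "combined") {
      df <- df[df$population == population, , drop = FALSE]
      if (nrow(df) == 0) stop("population not found: ", population, call. = FALSE)
    }
  } else if (!is.null(population) && population != "combined") {
    stop("no population column in ", path, call. = FALSE)
  }
  da <- dosage(df$genotype_a, spec_a)
  db <- dosage(df$genotype_b, spec_b)
  arr <- array(0, dim = c(3, 3, 2))
  for (i in seq_len(nrow(df))) {
    arr[da[i] + 1, db[i] + 1, 1] <- arr[da[i] + 1, db[i] + 1, 1] + as.numeric(df$n_case[i])
    arr[da[i] + 1, db[i] + 1, 2] <- arr[da[i] + 1, db[i] + 1, 2] + as.numeric(df$n_control[i])
  }
  two_locus_table(arr, spec_a, spec_b, label = label)
}

#' Marginal single-SNP counts of a two-locus table
#'
#' @param x A [two_locus_table()].
#' @param which `"a"` or `"b"`.
#' @return A `genotype_counts` 2x3 matrix on the pairwise-complete subset.
#' @export
margin_counts <- function(x, which = c("a", "b")) {
  stopifnot(inherits(x, "two_locus_table"))
  which <- match.arg(which)
  m <- if (which == "a") apply(unclass(x), c(1, 3), sum) else apply(unclass(x), c(2, 3), sum)
  out <- t(m)[c("case", "control"), , drop = FALSE]
  dimnames(out) <- list(status = c("case", "control"), dosage = 0:2)
  structure(out, spec = attr(x, if (which == "a") "spec_a" else "spec_b"),
            class = c("genotype_counts", "matrix", "array"))
}

#' Expand a two-locus count table into subject-level records
#'
#' Produces a minimal [cohort()] (no covariates) with one row per counted
#' subject, so that subject-level model code can be cross-checked against
#' count-based closed forms.
#'
#' @param x A [two_locus_table()].
#' @return A [cohort()].
#' @export
expand_table <- function(x) {
  stopifnot(inherits(x, "two_locus_table"))
  sa <- attr(x, "spec_a"); sb <- attr(x, "spec_b")
  rows <- expand.grid(a = 0:2, b = 0:2, status = c(2L, 1L))
  rows$n <- c(as.numeric(unclass(x)[, , "case"]), as.numeric(unclass(x)[, , "control"]))
  rows <- rows[rep(seq_len(nrow(rows)), rows$n), ]
  df <- data.frame(id = sprintf("s%06d", seq_len(nrow(rows))),
                   sex = NA_integer_, age = NA_real_, status = rows$status)
  df[[sa$name]] <- genotype_label(rows$a, sa)
  df[[sb$name]] <- genotype_label(rows$b, sb)
  cohort(df, list(sa, sb), label = attr(x, "label"))
}

#' Published atrial-fibrillation two-locus genotype counts
#'
#' Genotype counts for the GWAS-replicated AF SNP pairs in Chinese Han
#' case-control populations (rs2106261 in ZFHX3, risk allele A; rs2200733
#' near PITX2c, risk allele T; rs3807989 in CAV1, risk allele G), shipped
#' as plain TSV fixtures with the package.
#'
#' @param pair One of `"rs2106261-rs2200733"`, `"rs2106261-rs3807989"`,
#'   `"rs2200733-rs3807989"`.
#' @param population For the rs2106261-rs2200733 pair: `"discovery"`,
#'   `"replication1"`, `"replication2"` or `"combined"` (default). The CAV1
#'   pairs have a single combined stratum.
#' @return A [two_locus_table()].
#' @export
af_example_counts <- function(pair = c("rs2106261-rs2200733",
                                       "rs2106261-rs3807989",
                                       "rs2200733-rs3807989"),
                              population = "combined") {
  pair <- match.arg(pair)
  specs <- list(rs2106261 = snp_spec("rs2106261", "G", "A"),
                rs2200733 = snp_spec("rs2200733", "C", "T"),
                rs3807989 = snp_spec("rs3807989", "A", "G"))
  parts <- strsplit(pair, "-")[[1]]
  path <- system.file("extdata", paste0("counts_", parts[1], "_", parts[2], ".tsv"),
                      package = "episnp", mustWork = TRUE)
  read_counts_table(path, specs[[parts[1]]], specs[[parts[2]]],
                    population = population)
}
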