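#' Run the full two-locus interaction analysis pipeline
#'
#' Orchestrates, for each configured SNP pair: Hardy-Weinberg gates on the
#' control genotypes, single-locus allelic and genetic-model association,
#' the nine-genotype odds-ratio profile with its additive-scale synergy
#' summary and Breslow-Day comparisons, RERI for the H1/H2/H3 contrasts
#' (with stratified-bootstrap p-values when `reps > 0`), and the genotypic
#' interaction models. Stage errors are caught and reported per analysis
#' without aborting the remaining analyses. Count-only inputs skip the
#' covariate-adjusted analyses with a logged reason.
#'
#' @param config A named list or a YAML file path with fields:
#'   `specs` (list of `name`/`allele_nonrisk`/`allele_risk` entries),
#'   `pairs` (list of two-SNP name vectors), and either `genotypes` (a
#'   subject-table path read via [read_cohort()]) or `counts` (a named list
#'   mapping `"snpA-snpB"` to aggregated-count TSV paths); optional
#'   `dialect`, `covariates`, `reference` (dosage pair), `reps` (bootstrap
#'   replicates, default 10000; 0 disables), `seed` (required when
#'   bootstrapping), `label`, `out_dir` (write TSV/JSON outputs when set).
#' @return List of class `pipeline_bundle`: `results` (nested per pair),
#'   `values` (flat named numeric vector of every headline statistic),
#'   `errors` (named character vector of per-stage failures), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  specs <- lapply(config$specs, function(s) {
    if (inherits(s, "snp_spec")) s
    else snp_spec(s$name, s$allele_nonrisk, s$allele_risk)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  reps <- if (is.null(config$reps)) 10000 else config$reps
  if (reps > 0 && is.null(config$seed))
    stop("seed is required whenever the bootstrap is enabled", call. = FALSE)
  reference <- if (is.null(config$reference)) c(0, 0) else config$reference
  covariates <- config$covariates
  label <- if (is.null(config$label)) "" else config$label

  coh <- NULL
  input_paths <- character(0)
  if (!is.null(config$genotypes)) {
    dialect <- if (is.null(config$dialect)) "table" else config$dialect
    coh <- read_cohort(config$genotypes, specs, dialect = dialect, label = label)
    input_paths <- config$genotypes
  } else if (is.null(config$counts)) {
    stop("config needs either 'genotypes' or 'counts'", call. = FALSE)
  }
  if (is.null(coh) && !is.null(covariates)) {
    message("counts-only input: covariate-adjusted analyses skipped")
    covariates <- NULL
  }

  values <- c()
  errors <- c()
  results <- list()
  put <- function(key, v) values[key] <<- unname(v)
  stage <- function(key, expr) {
    tryCatch(expr, error = function(e) {
      errors[key] <<- conditionMessage(e)
      NULL
    })
  }

  for (pair in config$pairs) {
    pa <- pair[1]; pb <- pair[2]
    pk <- paste(pa, pb, sep = "-")
    if (!all(c(pa, pb) %in% names(specs)))
      stop("pair ", pk, " has SNPs without specs", call. = FALSE)
    tab <- stage(paste0(pk, ".input"), {
      if (!is.null(coh)) crosstab_pair(coh, pa, pb)
      else {
        path <- config$counts[[pk]]
        if (is.null(path)) stop("no counts path for pair ", pk)
        input_paths <- c(input_paths, path)
        read_counts_table(path, specs[[pa]], specs[[pb]])
      }
    })
    if (is.null(tab)) next
    res <- list(table = tab)

    res$hwe <- stage(paste0(pk, ".hwe"), {
      out <- list()
      for (side in c("a", "b")) {
        mc <- margin_counts(tab, side)
        g <- hwe_gate(mc)
        snp <- attr(mc, "spec")$name
        put(paste0(pk, ".hwe.", snp, ".p"), g$p)
        out[[snp]] <- g
      }
      out
    })

    res$single_locus <- stage(paste0(pk, ".single_locus"), {
      out <- list()
      for (side in c("a", "b")) {
        mc <- margin_counts(tab, side)
        snp <- attr(mc, "spec")$name
        al <- allelic_association(mc)
        put(paste0(pk, ".allelic.", snp, ".or"), al$estimate$or)
        put(paste0(pk, ".allelic.", snp, ".p"), al$p)
        models <- lapply(c("additive", "dominant", "recessive"),
                         function(m) model_association(mc, m))
        names(models) <- c("additive", "dominant", "recessive")
        for (m in names(models))
          put(paste0(pk, ".", m, ".", snp, ".or"), models[[m]]$estimate$or)
        out[[snp]] <- c(list(allelic = al), models)
      }
      out
    })

    res$profile <- stage(paste0(pk, ".profile"), {
      prof <- genotype_or_profile(tab, reference = reference, cohort = coh,
                                  covariates = covariates)
      for (i in seq_len(nrow(prof))) {
        gk <- paste0(prof$genotype_a[i], prof$genotype_b[i])
        put(paste0(pk, ".profile.", gk, ".or"), prof$or[i])
      }
      prof
    })

    if (!is.null(res$profile)) {
      res$synergy <- stage(paste0(pk, ".synergy"), {
        syn <- synergy_summary(res$profile)
        put(paste0(pk, ".synergy.or_both"), syn$or_both)
        put(paste0(pk, ".synergy.sum_single"), syn$sum_single)
        put(paste0(pk, ".synergy.bd_p_vs_a"), syn$bd_p_vs_a)
        put(paste0(pk, ".synergy.bd_p_vs_b"), syn$bd_p_vs_b)
        syn
      })
    }

    res$reri <- stage(paste0(pk, ".reri"), {
      out <- list()
      for (h in c("H1", "H2", "H3")) {
        rr <- reri_from_counts(tab, h)
        if (reps > 0) {
          bp <- bootstrap_reri_p(tab, h, reps = reps, seed = config$seed)
          rr$boot_p <- bp$p; rr$boot_reps <- bp$reps; rr$boot_seed <- bp$seed
          put(paste0(pk, ".reri.", h, ".boot_p"), bp$p)
        }
        put(paste0(pk, ".reri.", h, ".reri"), rr$reri)
        out[[h]] <- rr
        if (!is.null(coh)) {
          adj <- reri_model(coh, pa, pb, h, covariates = covariates)
          put(paste0(pk, ".reri.", h, ".reri_adj"), adj$reri)
          out[[paste0(h, "_adj")]] <- adj
        }
      }
      out
    })

    res$interaction <- stage(paste0(pk, ".interaction"), {
      data_in <- if (!is.null(coh)) coh else tab
      t6 <- interaction_test6(data_in, snp_a = pa, snp_b = pb,
                              covariates = covariates)
      t5 <- interaction_test5(data_in, snp_a = pa, snp_b = pb,
                              covariates = covariates)
      for (i in seq_len(nrow(t6$terms)))
        put(paste0(pk, ".test6.", t6$terms$term[i], ".or"), t6$terms$or[i])
      put(paste0(pk, ".test6.global_p"), t6$global_p)
      put(paste0(pk, ".test5.axa.or"), t5$terms$or[1])
      list(test6 = t6, test5 = t5,
           dominance_reduction = dominance_reduction_lrt(t6, t5))
    })

    results[[pk]] <- res
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("episnp")),
    r_version = R.version.string,
    seed = config$seed,
    reps = reps,
    covariates = covariates,
    inputs = if (length(input_paths))
      as.list(tools::md5sum(input_paths)) else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  bundle <- structure(list(results = results, values = values,
                           errors = errors, manifest = manifest),
                      class = "pipeline_bundle")
  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf("<pipeline_bundle> %d pair(s), %d statistic(s), %d error(s)\n",
              length(x$results), length(x$values), length(x$errors)))
  if (length(x$errors))
    for (k in names(x$errors)) cat("  ERROR", k, ":", x$errors[[k]], "\n")
  invisible(x)
}

#' Write a pipeline bundle's result tables to disk
#'
#' Emits one tab-separated table per analysis (odds ratios and RERIs
#' formatted to 2 decimals, percentages to 1) plus a machine-readable JSON
#' summary of every headline statistic and the run manifest.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()], or a named list
#'   of data frames.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_results <- function(bundle, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory ", path, call. = FALSE)
  emit <- function(df, file) {
    utils::write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!inherits(bundle, "pipeline_bundle")) {
    stopifnot(is.list(bundle))
    for (nm in names(bundle)) emit(bundle[[nm]], paste0(nm, ".tsv"))
    return(invisible(path))
  }
  fmt2 <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  for (pk in names(bundle$results)) {
    res <- bundle$results[[pk]]
    if (!is.null(res$profile)) {
      pr <- res$profile
      df <- data.frame(
        genotype_a = pr$genotype_a, genotype_b = pr$genotype_b,
        n_case = sprintf("%d (%.1f%%)", pr$n_case, pr$pct_case),
        n_control = sprintf("%d (%.1f%%)", pr$n_control, pr$pct_control),
        p = signif(pr$p, 3),
        or_ci = ifelse(is.na(pr$ci_low), fmt2(pr$or),
                       sprintf("%s (%s-%s)", fmt2(pr$or), fmt2(pr$ci_low),
                               fmt2(pr$ci_high))))
      if ("or_adj" %in% names(pr)) {
        df$p_adj <- signif(pr$p_adj, 3)
        df$or_adj_ci <- ifelse(is.na(pr$ci_low_adj), fmt2(pr$or_adj),
                               sprintf("%s (%s-%s)", fmt2(pr$or_adj),
                                       fmt2(pr$ci_low_adj), fmt2(pr$ci_high_adj)))
      }
      emit(df, paste0(pk, "_profile.tsv"))
    }
    if (!is.null(res$reri)) {
      hs <- intersect(c("H1", "H2", "H3"), names(res$reri))
      df <- do.call(rbind, lapply(hs, function(h) {
        rr <- res$reri[[h]]
        data.frame(contrast = h,
                   reri_ci = sprintf("%s (%s-%s)", fmt2(rr$reri),
                                     fmt2(rr$ci_low), fmt2(rr$ci_high)),
                   boot_p = if (is.null(rr$boot_p)) NA else
                     format.pval(rr$boot_p, digits = 3))
      }))
      emit(df, paste0(pk, "_reri.tsv"))
    }
    if (!is.null(res$interaction)) {
      t6 <- res$interaction$test6; t5 <- res$interaction$test5
      df <- rbind(
        data.frame(model = "genotypic (4 df)", term = t6$terms$term,
                   or_ci = sprintf("%s (%s-%s)", fmt2(t6$terms$or),
                                   fmt2(t6$terms$ci_low), fmt2(t6$terms$ci_high)),
                   p = signif(t6$terms$p, 3)),
        data.frame(model = "genotypic (4 df)", term = "global",
                   or_ci = "", p = signif(t6$global_p, 3)),
        data.frame(model = "additive (1 df)", term = t5$terms$term,
                   or_ci = sprintf("%s (%s-%s)", fmt2(t5$terms$or),
                                   fmt2(t5$terms$ci_low), fmt2(t5$terms$ci_high)),
                   p = signif(t5$terms$p, 3)))
      emit(df, paste0(pk, "_interaction.tsv"))
    }
  }
  jsonlite::write_json(
    list(values = as.list(bundle$values),
         errors = as.list(bundle$errors),
         manifest = bundle$manifest),
    file.path(path, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' Check a pipeline bundle against reference expectations
#'
#' @param bundle A `pipeline_bundle`.
#' @param expectations Data frame (or TSV path) with columns `key` (a name
#'   in `bundle$values`), `expected`, `tolerance` (absolute).
#' @return Data frame with per-expectation `actual` and `pass`; attribute
#'   `all_pass`.
#' @export
verify_against_reference <- function(bundle, expectations) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  if (is.character(expectations))
    expectations <- utils::read.table(expectations, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
  if (nrow(expectations) == 0) {
    out <- cbind(expectations, actual = numeric(0), pass = logical(0))
    attr(out, "all_pass") <- TRUE
    return(out)
  }
  stopifnot(all(c("key", "expected", "tolerance") %in% names(expectations)))
  actual <- unname(bundle$values[expectations$key])
  pass <- !is.na(actual) &
    abs(actual - as.numeric(expectations$expected)) <=
      as.numeric(expectations$tolerance)
  out <- cbind(expectations, actual = actual, pass = pass)
  attr(out, "all_pass") <- all(pass)
  out
}
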