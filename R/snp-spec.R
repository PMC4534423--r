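#' Define a biallelic SNP with a designated risk allele
#'
#' A `snp_spec` records a SNP's identifier and which of its two alleles is
#' treated as the risk allele. All downstream dosage coding (0/1/2 copies of
#' the risk allele) is oriented by this choice.
#'
#' @param name SNP identifier, e.g. `"rs2106261"`.
#' @param allele_nonrisk Single nucleotide character, the non-risk allele.
#' @param allele_risk Single nucleotide character, the risk allele.
#' @return An object of class `snp_spec`.
#' @examples
#' snp_spec("rs2106261", "G", "A")  # G>A substitution, risk allele A
#' snp_spec("rs2200733", "C", "T")  # C>T substitution, risk allele T
#' @export
snp_spec <- function(name, allele_nonrisk, allele_risk) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  allele_nonrisk <- toupper(allele_nonrisk)
  allele_risk <- toupper(allele_risk)
  ok <- function(a) is.character(a) && length(a) == 1L && a %in% c("A", "C", "G", "T")
  if (!ok(allele_nonrisk) || !ok(allele_risk))
    stop("alleles must be single characters in {A, C, G, T}", call. = FALSE)
  if (allele_nonrisk == allele_risk)
    stop("risk and non-risk alleles must differ for SNP ", name, call. = FALSE)
  structure(list(name = name,
                 allele_nonrisk = allele_nonrisk,
                 allele_risk = allele_risk),
            class = "snp_spec")
}

#' @export
print.snp_spec <- function(x, ...) {
  cat(sprintf("<snp_spec> %s: %s>%s (risk allele %s)\n",
              x$name, x$allele_nonrisk, x$allele_risk, x$allele_risk))
  invisible(x)
}

# Strings treated as missing genotype calls in spreadsheet exports.
.missing_tokens <- c("", "00", "--", "NN", "0", "-", "NA", "N/A", "..", ".")

#' Parse a genotype string into an unordered allele pair
#'
#' Accepts two adjacent characters optionally separated by `/` or `|`
#' (`"AG"`, `"G/A"`, `"a|g"` all parse to the same call). Order- and
#' case-insensitive. Missing markers (`""`, `"00"`, `"--"`, `"NN"`, ...)
#' yield `NA`.
#'
#' @param x Character vector of genotype strings.
#' @param spec A [snp_spec()]; alleles outside its two alleles are an error
#'   unless `strict = FALSE`, in which case they become `NA`.
#' @param strict Error on out-of-spec alleles (default `TRUE`).
#' @return Character vector of normalized two-character genotypes (alleles
#'   sorted so that non-risk precedes risk), `NA` for missing.
#' @export
parse_genotype <- function(x, spec, strict = TRUE) {
  stopifnot(inherits(spec, "snp_spec"))
  x0 <- toupper(gsub("[/| ]", "", trimws(as.character(x))))
  out <- rep(NA_character_, length(x0))
  miss <- is.na(x0) | x0 %in% .missing_tokens
  body <- !miss
  if (any(nchar(x0[body]) != 2L))
    stop("genotype strings must contain exactly two alleles: ",
         paste(unique(x0[body][nchar(x0[body]) != 2L]), collapse = ", "),
         call. = FALSE)
  a1 <- substr(x0, 1L, 1L)
  a2 <- substr(x0, 2L, 2L)
  valid <- c(spec$allele_nonrisk, spec$allele_risk)
  bad <- body & (!(a1 %in% valid) | !(a2 %in% valid))
  if (any(bad)) {
    if (strict)
      stop("genotype allele outside {", paste(valid, collapse = ","),
           "} for SNP ", spec$name, ": ",
           paste(unique(x0[bad]), collapse = ", "), call. = FALSE)
    body <- body & !bad
  }
  # normalize order: non-risk allele first
  first <- ifelse(a1 == spec$allele_nonrisk | a2 == spec$allele_risk, a1, a2)
  second <- ifelse(first == a1, a2, a1)
  swap <- body & (first == spec$allele_risk & second == spec$allele_nonrisk)
  g <- paste0(ifelse(swap, second, first), ifelse(swap, first, second))
  out[body] <- g[body]
  out
}

#' Risk-allele dosage of a genotype call
#'
#' @param call Character vector of genotype strings (or `NA`).
#' @param spec A [snp_spec()].
#' @return Integer vector in `0:2` (copies of the risk allele), `NA` for
#'   missing calls.
#' @examples
#' s <- snp_spec("rs2106261", "G", "A")
#' dosage(c("AA", "GA", "GG", NA), s)  # 2 1 0 NA
#' @export
dosage <- function(call, spec) {
  g <- parse_genotype(call, spec)
  n <- nchar(gsub(sprintf("[^%s]", spec$allele_risk), "", g))
  as.integer(ifelse(is.na(g), NA_integer_, n))
}

#' Genotype label for a risk-allele dosage
#'
#' Inverse of [dosage()]: maps 0/1/2 back to the conventional two-character
#' genotype string (heterozygote alleles in alphabetical order).
#'
#' @param d Integer vector in `0:2`.
#' @param spec A [snp_spec()].
#' @return Character vector of genotype strings.
#' @export
genotype_label <- function(d, spec) {
  stopifnot(all(d %in% 0:2 | is.na(d)))
  het <- paste(sort(c(spec$allele_nonrisk, spec$allele_risk)), collapse = "")
  lab <- c(paste0(spec$allele_nonrisk, spec$allele_nonrisk), het,
           paste0(spec$allele_risk, spec$allele_risk))
  lab[d + 1L]
}
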