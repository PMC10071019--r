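#' Variant allele frequency from genotype counts
#'
#' @param counts A [genotype_counts()] list (or any list with `n_ref_hom`,
#'   `n_het`, `n_alt_hom`).
#' @return `(n_het + 2 * n_alt_hom) / (2 * total)`.
#' @export
allele_frequency <- function(counts) {
  total <- counts$n_ref_hom + counts$n_het + counts$n_alt_hom
  if (total <= 0) stop("zero genotype total")
  (counts$n_het + 2 * counts$n_alt_hom) / (2 * total)
}

test_result <- function(statistic, df, p_value, alpha, note = NA_character_) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 significant = is.finite(p_value) && p_value < alpha,
                 alpha = alpha, note = note),
            class = "pg_test_result")
}

#' @export
print.pg_test_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g%s\n", x$statistic, x$df,
              x$p_value, if (x$significant) " *" else ""))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Hardy-Weinberg goodness-of-fit chi-square test
#'
#' Expected genotype counts p^2 n, 2pq n, q^2 n are computed from the counted
#' allele frequency; the statistic is the usual sum of (obs - exp)^2 / exp
#' with 1 degree of freedom (3 genotype classes, 1 estimated allele
#' frequency). A monomorphic locus returns statistic 0 and p = 1. No
#' continuity correction.
#'
#' @param counts A [genotype_counts()] list.
#' @param alpha Significance level.
#' @return A `pg_test_result`.
#' @export
hwe_test <- function(counts, alpha = 0.05) {
  n <- counts$n_ref_hom + counts$n_het + counts$n_alt_hom
  if (n <= 0) stop("zero genotype total")
  q <- allele_frequency(counts)  # variant allele
  p <- 1 - q
  if (q == 0 || q == 1) return(test_result(0, 1L, 1, alpha, "monomorphic locus"))
  expected <- n * c(p^2, 2 * p * q, q^2)
  observed <- c(counts$n_ref_hom, counts$n_het, counts$n_alt_hom)
  stat <- sum((observed - expected)^2 / expected)
  test_result(stat, 1L, stats::pchisq(stat, df = 1, lower.tail = FALSE), alpha)
}

#' Compare one haplotype's frequency between two cohorts (2x2 chi-square)
#'
#' Units are chromosomes (2n). The table is focal haplotype vs all others,
#' cohort A vs cohort B; plain Pearson chi-square, df = 1, no continuity
#' correction.
#'
#' @param count_a,count_b Length-2 vectors `c(k, chrom_total)`: copies of the
#'   focal haplotype and total chromosomes in each cohort.
#' @param alpha Significance level.
#' @return A `pg_test_result`; a zero margin (haplotype absent on both sides)
#'   yields an undefined-test result flagged in `note`.
#' @export
compare_haplotype_freq <- function(count_a, count_b, alpha = 0.05) {
  if (count_a[1] > count_a[2] || count_b[1] > count_b[2]) {
    stop("haplotype count exceeds chromosome total")
  }
  tab <- rbind(a = c(count_a[1], count_a[2] - count_a[1]),
               b = c(count_b[1], count_b[2] - count_b[1]))
  if (any(colSums(tab) == 0)) {
    return(test_result(NA_real_, 1L, NA_real_, alpha,
                       "undefined: zero margin (haplotype absent in both cohorts)"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(unname(ct$statistic), 1L, unname(ct$p.value), alpha)
}

#' Compare two phenotype count distributions (r x 2 chi-square)
#'
#' Units are individuals. Phenotype categories that are zero in both cohorts
#' are dropped; the remaining r categories give df = r - 1. No continuity
#' correction.
#'
#' @param dist_a,dist_b Named integer vectors of phenotype counts (names
#'   matched by union).
#' @param alpha Significance level.
#' @return A `pg_test_result`.
#' @export
compare_phenotype_distributions <- function(dist_a, dist_b, alpha = 0.05) {
  levels <- union(names(dist_a), names(dist_b))
  a <- stats::setNames(numeric(length(levels)), levels)
  b <- a
  a[names(dist_a)] <- dist_a
  b[names(dist_b)] <- dist_b
  keep <- (a + b) > 0
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("fewer than 2 usable phenotype categories")
  ct <- suppressWarnings(stats::chisq.test(cbind(a, b), correct = FALSE))
  test_result(unname(ct$statistic), length(a) - 1L, unname(ct$p.value), alpha)
}
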