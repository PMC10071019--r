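#' Configuration of a synthetic diploid cohort
#'
#' Describes a cohort to be simulated under random mating: `n` diploid
#' individuals, each formed by two independent haplotype draws from
#' `hap_freqs` (Hardy-Weinberg equilibrium at the haplotype level).
#' Frequencies must sum to 1 within 1e-6; renormalization of an off-sum
#' table happens only with an explicit flag and a warning, so published
#' columns are never silently altered.
#'
#' @param name Cohort name.
#' @param n Number of individuals (> 0).
#' @param hap_freqs Named numeric vector: CYP2C 2-letter labels (`"TG"`) or
#'   combined labels (`"*2CG"`) mapped to frequencies.
#' @param seed Integer seed; a fixed config is reproducible byte-for-byte.
#' @param missing_rate Per-call missingness probability (default 0).
#' @param renormalize Rescale frequencies to sum to 1 (with a warning).
#' @param validate_sum Set `FALSE` to store an off-sum table verbatim
#'   (the config is then flagged `normalized = FALSE` and refuses to
#'   simulate).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(name, n, hap_freqs, seed = 1L, missing_rate = 0,
                          renormalize = FALSE, validate_sum = TRUE) {
  if (n <= 0) stop("n must be positive")
  if (is.null(names(hap_freqs)) || any(names(hap_freqs) == "")) {
    stop("hap_freqs must be a named vector of haplotype labels")
  }
  if (any(hap_freqs < 0)) stop("negative haplotype frequency")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  s <- sum(hap_freqs)
  normalized <- abs(s - 1) <= 1e-6
  if (!normalized && renormalize) {
    warning("renormalizing haplotype frequencies of '", name, "' (sum = ",
            format(s), ")")
    hap_freqs <- hap_freqs / s
    normalized <- TRUE
  }
  if (!normalized && validate_sum) {
    stop("haplotype frequencies of '", name, "' sum to ", format(s),
         ", not 1; pass renormalize = TRUE to rescale explicitly")
  }
  structure(list(name = name, n = as.integer(n), hap_freqs = hap_freqs,
                 seed = as.integer(seed), missing_rate = missing_rate,
                 normalized = normalized),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config '", x$name, "': n = ", x$n, ", seed = ", x$seed,
      if (!x$normalized) " [non-normalized, verbatim]" else "", "\n", sep = "")
  print(round(x$hap_freqs, 4))
  invisible(x)
}

#' Simulate a diploid cohort under random mating, with truth tracking
#'
#' Each individual receives two haplotypes drawn independently from the
#' config's frequency table (random mating, so genotypes are in
#' Hardy-Weinberg proportions in expectation). Labels are expanded to full
#' allele strings over the panel via [expand_label()], so star-site /
#' CYP2C-site linkage holds by construction for label sets drawn from the
#' observed haplotypes; deliberately linkage-violating labels (e.g. `"*2TG"`)
#' are accepted, which exercises the warning path downstream. Haplotype pairs
#' are then collapsed to unphased genotypes, and per-call missingness is
#' injected at `missing_rate`. Output is deterministic for a fixed config.
#'
#' @param config A [cohort_config()] (must be normalized).
#' @param panel A [variant_panel]; defaults to the 2-SNP CYP2C panel for
#'   2-letter labels and the full built-in panel for combined labels.
#' @param star_defs Star definition table.
#' @return A `truth_cohort` list: `matrix` (a [genotype_matrix]) and `truth`
#'   (data.frame `sample_id`, `hap_a`, `hap_b`, `label_a`, `label_b`; pairs
#'   sorted so the truth diplotype is canonical).
#' @export
generate_cohort <- function(config, panel = NULL,
                            star_defs = default_star_defs()) {
  if (!config$normalized) {
    stop("config '", config$name, "' is non-normalized (verbatim); use the _norm variant or renormalize")
  }
  labels <- names(config$hap_freqs)
  two_snp <- all(grepl("^[TC][GA]$", labels))
  if (is.null(panel)) {
    panel <- if (two_snp) default_panel(loci = c("rs2860840", "rs11188059"))
             else default_panel()
  }
  haps <- vapply(labels, expand_label, character(1), panel = panel,
                 star_defs = star_defs)
  withr::with_seed(config$seed, {
    draw <- sample(labels, 2 * config$n, replace = TRUE,
                   prob = config$hap_freqs)
    la <- draw[seq_len(config$n)]
    lb <- draw[config$n + seq_len(config$n)]
    ha <- haps[la]
    hb <- haps[lb]
    # canonical unordered pair
    swap <- ha > hb
    tmp <- ha[swap]; ha[swap] <- hb[swap]; hb[swap] <- tmp
    tmp <- la[swap]; la[swap] <- lb[swap]; lb[swap] <- tmp
    ids <- sprintf("S%03d", seq_len(config$n))
    calls <- matrix(NA_character_, nrow = config$n, ncol = nrow(panel),
                    dimnames = list(ids, panel$rsid))
    for (j in seq_len(nrow(panel))) {
      a1 <- substr(ha, j, j)
      a2 <- substr(hb, j, j)
      calls[, j] <- ifelse(a1 <= a2, paste0(a1, "/", a2), paste0(a2, "/", a1))
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(calls)) < config$missing_rate,
                     nrow = nrow(calls))
      calls[miss] <- NA_character_
    }
    truth <- data.frame(sample_id = ids, hap_a = unname(ha), hap_b = unname(hb),
                        label_a = unname(la), label_b = unname(lb),
                        stringsAsFactors = FALSE)
    structure(list(matrix = genotype_matrix(calls, panel), truth = truth,
                   config = config),
              class = "truth_cohort")
  })
}

#' @export
print.truth_cohort <- function(x, ...) {
  cat("truth_cohort '", x$config$name, "': ", x$config$n, " individuals over ",
      nrow(x$matrix$panel), " SNPs\n", sep = "")
  print(utils::head(x$truth, 3))
  invisible(x)
}
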