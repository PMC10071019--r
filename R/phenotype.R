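#' Phenotype schemes: activity classes plus a decision ladder
#'
#' Both translation schemes are encoded the same way: each allele label maps
#' to an activity class (`no_function`, `decreased`, `normal`, `increased`)
#' and an unordered pair of classes maps to a metabolizer phenotype through a
#' fixed ladder:
#'
#' * two no-function alleles -> PM
#' * one no-function allele with anything else -> IM
#' * decreased with decreased or normal -> IM
#' * decreased with increased -> NM (extrapolated; flagged, see Details)
#' * normal + normal -> NM
#' * normal + increased -> RM
#' * increased + increased -> UM
#'
#' The `cpic` scheme works on star alleles (*1 normal, *2/*3 no function,
#' *9 decreased, *17 increased). The `combined` scheme works on merged
#' CYP2C19-CYP2C labels and credits the TG haplotype with increased activity:
#' *1TG and *17CG increased, *1CG-or-TA (and its unmerged forms) normal,
#' *2CG no function.
#'
#' @details Diplotypes involving the decreased class paired with the
#' increased class have no published assignment in this allele set; the
#' ladder's NM result for them is an extrapolation and such calls carry
#' `extrapolated = TRUE`.
#'
#' @param name `"cpic"` or `"combined"`.
#' @return A `phenotype_scheme` list: `name`, `allele_classes`.
#' @export
phenotype_scheme <- function(name = c("cpic", "combined")) {
  name <- match.arg(name)
  classes <- if (name == "cpic") {
    c("*1" = "normal", "*2" = "no_function", "*3" = "no_function",
      "*9" = "decreased", "*17" = "increased")
  } else {
    c("*1TG" = "increased", "*17CG" = "increased",
      "*1CG" = "normal", "*1TA" = "normal", "*1CG-or-TA" = "normal",
      "*2CG" = "no_function", "*3CG" = "no_function")
  }
  structure(list(name = name, allele_classes = classes),
            class = "phenotype_scheme")
}

#' Metabolizer phenotype of one unordered allele pair
#'
#' @param a,b Allele labels in the scheme's label space (star alleles for
#'   `cpic`, combined/merged labels for `combined`). The result is symmetric
#'   in `a` and `b`.
#' @param scheme A [phenotype_scheme()] or its name.
#' @return Character phenotype (`"PM"`, `"IM"`, `"NM"`, `"RM"`, `"UM"`),
#'   with attribute `extrapolated` on ladder cases not covered by the
#'   published tables.
#' @export
assign_phenotype <- function(a, b, scheme) {
  if (is.character(scheme)) scheme <- phenotype_scheme(scheme)
  cls <- scheme$allele_classes[c(a, b)]
  if (anyNA(cls)) {
    stop("unknown allele label for scheme '", scheme$name, "': ",
         paste(c(a, b)[is.na(cls)], collapse = ", "))
  }
  cls <- sort(unname(cls))
  key <- paste(cls, collapse = "+")
  extrapolated <- FALSE
  pheno <- switch(
    key,
    "no_function+no_function" = "PM",
    "decreased+no_function" = "IM",
    "no_function+normal" = "IM",
    "increased+no_function" = "IM",
    "decreased+decreased" = "IM",
    "decreased+normal" = "IM",
    "decreased+increased" = { extrapolated <- TRUE; "NM" },
    "normal+normal" = "NM",
    "increased+normal" = "RM",
    "increased+increased" = "UM",
    stop("no ladder rule for class pair ", key)
  )
  structure(pheno, extrapolated = extrapolated)
}

#' @rdname assign_phenotype
#' @export
assign_cpic <- function(a, b) assign_phenotype(a, b, "cpic")

#' @rdname assign_phenotype
#' @export
assign_combined <- function(a, b) assign_phenotype(a, b, "combined")

phenotype_levels <- c("PM", "IM", "NM", "RM", "UM")

#' Phenotype distribution of a set of diplotype calls
#'
#' Assigns a phenotype to every included call and tabulates counts and
#' frequencies over the five-level metabolizer scale. Haplotypes are named
#' through the scheme's labeling (star alleles for `cpic`, merged combined
#' labels for `combined`); conflict-flagged haplotypes are dropped and
#' counted.
#'
#' @param calls data.frame from [call_diplotypes()] (only rows with
#'   `included = TRUE` are used).
#' @param panel The [variant_panel].
#' @param scheme `"cpic"` or `"combined"` (or a [phenotype_scheme()]).
#' @param star_defs Star definition table.
#' @return list: `counts` and `freq` (named over PM/IM/NM/RM/UM), `n`,
#'   `per_sample` data.frame, `n_conflict`.
#' @export
phenotype_distribution <- function(calls, panel, scheme = "cpic",
                                   star_defs = default_star_defs()) {
  if (is.character(scheme)) scheme <- phenotype_scheme(scheme)
  use <- calls[calls$included & !calls$unresolvable, , drop = FALSE]
  if (nrow(use) == 0) stop("no included individuals to tabulate")
  lab <- function(h) {
    cl <- combined_label(h, panel, star_defs)
    if (cl$conflict) return(NA_character_)
    if (scheme$name == "cpic") cl$star else merge_class(cl$label)
  }
  la <- vapply(use$hap_a, lab, character(1))
  lb <- vapply(use$hap_b, lab, character(1))
  conflict <- is.na(la) | is.na(lb)
  n_conflict <- sum(conflict)
  use <- use[!conflict, , drop = FALSE]
  la <- la[!conflict]; lb <- lb[!conflict]
  pheno <- mapply(function(a, b) as.character(assign_phenotype(a, b, scheme)), la, lb)
  counts <- stats::setNames(integer(5), phenotype_levels)
  tab <- table(factor(pheno, levels = phenotype_levels))
  counts[names(tab)] <- as.integer(tab)
  per_sample <- data.frame(sample_id = use$sample_id, allele_a = la,
                           allele_b = lb, phenotype = pheno,
                           stringsAsFactors = FALSE, row.names = NULL)
  list(counts = counts, freq = counts / sum(counts), n = sum(counts),
       per_sample = per_sample, n_conflict = n_conflict)
}

#' Phenotype totals from a printed diplotype frequency table
#'
#' Applies a scheme's decision ladder to a diplotype frequency table (rows of
#' allele-label pairs with their cohort frequency) and sums frequency by
#' phenotype — the desk computation that turns a published diplotype table
#' into the phenotype distribution shown alongside it.
#'
#' @param diplotypes data.frame with columns `allele_a`, `allele_b`, `freq`.
#' @param scheme `"cpic"` or `"combined"` (or a [phenotype_scheme()]).
#' @return Named numeric vector of summed frequencies over PM/IM/NM/RM/UM.
#' @export
phenotype_totals_from_freqs <- function(diplotypes, scheme) {
  if (is.character(scheme)) scheme <- phenotype_scheme(scheme)
  pheno <- mapply(function(a, b) as.character(assign_phenotype(a, b, scheme)),
                  diplotypes$allele_a, diplotypes$allele_b)
  out <- stats::setNames(numeric(5), phenotype_levels)
  agg <- tapply(diplotypes$freq, factor(pheno, levels = phenotype_levels), sum)
  out[!is.na(agg)] <- agg[!is.na(agg)]
  out
}

#' Round half away from zero
#'
#' Percentage reporting uses round-half-away-from-zero (0.556 -> 56%,
#' 0.204 -> 20%, 0.241 -> 24%), not base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Whole-percent rendering of a frequency vector
#' @param freq Numeric frequencies in `[0, 1]`.
#' @return Integer percents (half away from zero).
#' @export
as_percent <- function(freq) as.integer(round_half_up(100 * freq))
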