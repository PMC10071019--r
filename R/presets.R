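#' Reference cohort sizes
#'
#' The four Native American study cohorts and their sample sizes: a
#' Native-ancestry subset of the 1000 Genomes admixed-American superpopulation
#' (1KG_NAT, n = 68), the Human Genome Diversity Project Native Americans
#' (HGDP, n = 61), and the Kaingang (n = 54) and Guarani (n = 33) from
#' southern Brazil.
#'
#' @return Named integer vector of cohort sizes.
#' @export
reference_cohorts <- function() {
  c("1KG_NAT" = 68L, "HGDP" = 61L, "Kaingang" = 54L, "Guarani" = 33L)
}

#' Reported CYP2C (2-SNP) haplotype frequencies per cohort
#'
#' The published TG/TA/CG/CA haplotype frequencies over rs2860840 and
#' rs11188059, transcribed verbatim (some columns do not sum exactly to 1
#' because of rounding in the source).
#'
#' @return data.frame: `cohort`, `label`, `freq`.
#' @export
reference_cyp2c_hap_freqs <- function() {
  labels <- c("TG", "TA", "CG", "CA")
  data.frame(
    cohort = rep(names(reference_cohorts()), each = 4),
    label = rep(labels, 4),
    freq = c(0.493, 0.265, 0.243, 0,    # 1KG_NAT
             0.598, 0.107, 0.295, 0,    # HGDP
             0.490, 0.471, 0.038, 0,    # Kaingang
             0.469, 0.250, 0.281, 0),   # Guarani
    stringsAsFactors = FALSE
  )
}

#' Reported SNP variant allele frequencies per cohort
#'
#' Variant allele frequencies at the two CYP2C18 sites and the four CYP2C19
#' star sites. `NA` marks loci not genotyped in a cohort (the Kaingang and
#' Guarani samples were typed at 4 of the 6 loci).
#'
#' @return data.frame: `cohort`, `rsid`, `freq`.
#' @export
reference_allele_freqs <- function() {
  rsids <- c("rs2860840", "rs11188059", "rs4244285", "rs4986893",
             "rs17884712", "rs12248560")
  data.frame(
    cohort = rep(names(reference_cohorts()), each = 6),
    rsid = rep(rsids, 4),
    freq = c(0.757, 0.265, 0.066, 0, 0, 0.022,   # 1KG_NAT
             0.705, 0.107, 0.057, 0, 0, 0,       # HGDP
             0.963, 0.481, 0,     NA, NA, 0,     # Kaingang
             0.727, 0.242, 0.109, NA, NA, 0.018),# Guarani
    stringsAsFactors = FALSE
  )
}

#' Reported star-allele diplotype frequencies per cohort
#'
#' The published CYP2C19 star-allele diplotype table (the CPIC-scheme input):
#' four observed diplotypes per cohort.
#'
#' @return data.frame: `cohort`, `allele_a`, `allele_b`, `freq`.
#' @export
reference_star_diplotype_freqs <- function() {
  pairs <- rbind(c("*1", "*1"), c("*1", "*2"), c("*2", "*17"), c("*1", "*17"))
  data.frame(
    cohort = rep(names(reference_cohorts()), each = 4),
    allele_a = rep(pairs[, 1], 4),
    allele_b = rep(pairs[, 2], 4),
    freq = c(0.838, 0.118, 0.015, 0.029,  # 1KG_NAT
             0.885, 0.115, 0,     0,      # HGDP
             1.0,   0,     0,     0,      # Kaingang
             0.758, 0.212, 0,     0.030), # Guarani
    stringsAsFactors = FALSE
  )
}

#' Reported combined CYP2C19-CYP2C haplotype frequencies per cohort
#'
#' Five haplotypes were observed: *1CG, *1TA, *1TG, *2CG and *17CG. Some
#' columns do not sum to 1 as printed (the Guarani column sums to 0.839).
#'
#' @return data.frame: `cohort`, `label`, `freq`.
#' @export
reference_combined_hap_freqs <- function() {
  labels <- c("*1CG", "*1TA", "*1TG", "*2CG", "*17CG")
  data.frame(
    cohort = rep(names(reference_cohorts()), each = 5),
    label = rep(labels, 4),
    freq = c(0.154, 0.265, 0.493, 0.066, 0.022,  # 1KG_NAT
             0.238, 0.107, 0.598, 0.057, 0,      # HGDP
             0.037, 0.481, 0.481, 0,     0,      # Kaingang
             0.081, 0.167, 0.470, 0.106, 0.015), # Guarani
    stringsAsFactors = FALSE
  )
}

#' Reported combined-scheme diplotype frequencies per cohort
#'
#' The eight observed CYP2C19-CYP2C diplotypes over merged labels (*1CG and
#' *1TA merged into one class), with their published per-cohort frequencies —
#' the input for the combined-scheme phenotype translation.
#'
#' @return data.frame: `cohort`, `allele_a`, `allele_b`, `freq`.
#' @export
reference_combined_diplotype_freqs <- function() {
  m <- "*1CG-or-TA"
  pairs <- rbind(c(m, m), c(m, "*1TG"), c("*1TG", "*1TG"), c(m, "*2CG"),
                 c("*1TG", "*2CG"), c(m, "*17CG"), c("*1TG", "*17CG"),
                 c("*2CG", "*17CG"))
  data.frame(
    cohort = rep(names(reference_cohorts()), each = 8),
    allele_a = rep(pairs[, 1], 4),
    allele_b = rep(pairs[, 2], 4),
    freq = c(0.162, 0.426, 0.250, 0.088, 0.029, 0,     0.029, 0.015,  # 1KG_NAT
             0.180, 0.279, 0.426, 0.049, 0.066, 0,     0,     0,      # HGDP
             0.241, 0.556, 0.204, 0,     0,     0,     0,     0,      # Kaingang
             0.182, 0.394, 0.182, 0.030, 0.182, 0.030, 0,     0),     # Guarani
    stringsAsFactors = FALSE
  )
}

#' Simulation presets for the four reference cohorts
#'
#' One [cohort_config()] per cohort and labeling mode: `<cohort>_cyp2c` uses
#' the 2-SNP TG/TA/CG haplotype frequencies, `<cohort>_combined` the
#' CYP2C19-CYP2C haplotype frequencies. A preset whose published column does
#' not sum to 1 within 1e-6 is shipped verbatim under a `_verbatim` suffix
#' (flagged non-normalized, unusable for simulation as-is) together with a
#' renormalized `_norm` variant; columns that already sum to 1 get a single
#' unsuffixed preset. Zero-frequency labels are dropped.
#'
#' @param seed Seed stored in every preset (resettable per run).
#' @return Named list of [cohort_config()] objects.
#' @export
cohort_presets <- function(seed = 1L) {
  sizes <- reference_cohorts()
  out <- list()
  add <- function(tbl, mode) {
    for (co in names(sizes)) {
      f <- tbl[tbl$cohort == co & tbl$freq > 0, ]
      freqs <- stats::setNames(f$freq, f$label)
      base <- paste0(tolower(sub("1KG_NAT", "kg_nat", co)), "_", mode)
      if (abs(sum(freqs) - 1) <= 1e-6) {
        out[[base]] <<- cohort_config(base, n = sizes[[co]], hap_freqs = freqs,
                                      seed = seed)
      } else {
        out[[paste0(base, "_verbatim")]] <<- cohort_config(
          paste0(base, "_verbatim"), n = sizes[[co]], hap_freqs = freqs,
          seed = seed, validate_sum = FALSE)
        out[[paste0(base, "_norm")]] <<- suppressWarnings(cohort_config(
          paste0(base, "_norm"), n = sizes[[co]], hap_freqs = freqs,
          seed = seed, renormalize = TRUE))
      }
    }
  }
  tbl1 <- reference_cyp2c_hap_freqs()
  tbl1$label <- as.character(tbl1$label)
  add(tbl1, "cyp2c")
  add(reference_combined_hap_freqs(), "combined")
  out
}
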