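#' Pipeline configuration
#'
#' Binds an input source (exactly one of a genotype file or a simulation
#' config) to a panel, EM settings and phenotype schemes.
#'
#' @param panel A [variant_panel], or a path accepted by [load_panel()];
#'   `NULL` lets a simulation preset pick its own default panel.
#' @param genotypes Optional list `list(path =, format =)` for file input.
#' @param preset Optional [cohort_config()] (or the name of one of
#'   [cohort_presets()]) for simulated input.
#' @param em List of EM settings: `tol`, `max_iter`, `threshold`,
#'   `n_restarts`, `seed`.
#' @param schemes Phenotype schemes to apply (`"cpic"`, `"combined"`).
#' @param star_defs Star definition table.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(panel = NULL, genotypes = NULL, preset = NULL,
                            em = list(), schemes = c("cpic", "combined"),
                            star_defs = default_star_defs()) {
  if (is.null(genotypes) == is.null(preset)) {
    stop("exactly one of 'genotypes' or 'preset' must be given")
  }
  if (is.character(preset)) {
    presets <- cohort_presets()
    if (!preset %in% names(presets)) stop("unknown preset: ", preset)
    preset <- presets[[preset]]
  }
  if (is.character(panel)) panel <- load_panel(panel)
  em_defaults <- list(tol = 1e-10, max_iter = 500L, threshold = 0.95,
                      n_restarts = 0L, seed = 1L)
  em <- utils::modifyList(em_defaults, em)
  structure(list(panel = panel, genotypes = genotypes, preset = preset,
                 em = em, schemes = schemes, star_defs = star_defs),
            class = "pipeline_config")
}

#' Run the full inference pipeline on one cohort
#'
#' read/simulate genotypes -> EM haplotype frequencies -> diplotype calls at
#' the posterior inclusion threshold -> haplotype naming -> phenotype
#' assignment under the requested schemes -> per-SNP allele frequencies and
#' Hardy-Weinberg tests. Exclusion accounting (missingness, posterior below
#' threshold) is part of the report.
#'
#' @param config A [pipeline_config()].
#' @return A `cohort_report` list: `alleles` (per-SNP counts, frequency, HWE),
#'   `fit` (the EM `hap_freq_fit`), `haplotypes` (identified haplotypes with
#'   labels), `calls` (diplotype calls with combined labels), `phenotypes`
#'   (per scheme: counts/freq/per-sample), `excluded`, `log`, and `truth`
#'   when the input was simulated.
#' @export
run_pipeline <- function(config) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  if (!is.null(config$preset)) {
    cohort <- generate_cohort(config$preset, panel = config$panel,
                              star_defs = config$star_defs)
    gm <- cohort$matrix
    truth <- cohort$truth
    note("stage simulate: cohort '", config$preset$name, "', n = ",
         config$preset$n, ", seed = ", config$preset$seed)
  } else {
    if (is.null(config$panel)) stop("stage input: file input requires a panel")
    gm <- tryCatch(
      read_genotypes(config$genotypes$path, config$genotypes$format, config$panel),
      error = function(e) stop("stage input: ", conditionMessage(e), call. = FALSE))
    truth <- NULL
    note("stage input: read ", n_samples(gm), " samples from ",
         config$genotypes$path)
  }
  panel <- gm$panel

  alleles <- do.call(rbind, lapply(panel$rsid, function(rs) {
    cnt <- genotype_counts(gm, rs)
    total <- cnt$n_ref_hom + cnt$n_het + cnt$n_alt_hom
    if (total == 0) {
      return(data.frame(rsid = rs, n = 0L, variant_freq = NA_real_,
                        hwe_chisq = NA_real_, hwe_p = NA_real_))
    }
    hw <- hwe_test(cnt)
    data.frame(rsid = rs, n = total, variant_freq = allele_frequency(cnt),
               hwe_chisq = hw$statistic, hwe_p = hw$p_value)
  }))

  fit <- em_haplotype_frequencies(gm, tol = config$em$tol,
                                  max_iter = config$em$max_iter,
                                  n_restarts = config$em$n_restarts,
                                  seed = config$em$seed)
  note("stage em: ", fit$n_samples_used, " samples used, ",
       fit$n_excluded_missing, " excluded for missingness, ",
       fit$n_iter, " iterations")

  idf <- identified_haplotypes(fit)
  haplotypes <- cbind(label_haplotypes(names(idf), panel, config$star_defs),
                      frequency = unname(idf))
  if (any(haplotypes$linkage_violation)) {
    note("stage naming: WARNING ", sum(haplotypes$linkage_violation),
         " identified haplotype(s) violate the expected TG linkage pattern")
  }

  calls <- call_diplotypes(gm, fit, threshold = config$em$threshold)
  n_below <- sum(!calls$included)
  note("stage call: ", sum(calls$included), " individuals included at posterior >= ",
       config$em$threshold, "; ", n_below, " excluded below threshold")

  lab <- function(h) {
    cl <- combined_label(h, panel, config$star_defs)
    if (cl$conflict) NA_character_ else cl$label
  }
  calls$label_a <- vapply(calls$hap_a, lab, character(1))
  calls$label_b <- vapply(calls$hap_b, lab, character(1))

  phenotypes <- lapply(stats::setNames(config$schemes, config$schemes),
                       function(s) {
                         phenotype_distribution(calls, panel, scheme = s,
                                                star_defs = config$star_defs)
                       })
  for (s in names(phenotypes)) {
    note("stage phenotype[", s, "]: n = ", phenotypes[[s]]$n, "; ",
         paste(names(phenotypes[[s]]$counts), phenotypes[[s]]$counts,
               sep = "=", collapse = " "))
  }

  structure(list(alleles = alleles, fit = fit, haplotypes = haplotypes,
                 calls = calls, phenotypes = phenotypes,
                 excluded = list(missing = attr(calls, "excluded_missing"),
                                 below_threshold = calls$sample_id[!calls$included]),
                 truth = truth, log = log),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

fmt3 <- function(x) formatC(round_half_up(x, 3), format = "f", digits = 3)

#' Write a cohort report to disk
#'
#' Deterministic layout and rounding so reruns diff cleanly: frequencies to 3
#' decimals, percentages to whole numbers (half away from zero). TSV output
#' writes `alleles.tsv`, `haplotypes.tsv`, `diplotypes.tsv` and
#' `phenotypes_<scheme>.tsv`; JSON output writes a single `report.json`.
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"json"`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  if (format == "tsv") {
    al <- report$alleles
    al$variant_freq <- fmt3(al$variant_freq)
    al$hwe_chisq <- fmt3(al$hwe_chisq)
    al$hwe_p <- fmt3(al$hwe_p)
    wr(al, "alleles.tsv")
    hp <- report$haplotypes[order(-report$haplotypes$frequency,
                                  report$haplotypes$haplotype), ]
    hp$frequency <- fmt3(hp$frequency)
    wr(hp, "haplotypes.tsv")
    dp <- report$calls[order(report$calls$sample_id), ]
    dp$posterior <- fmt3(dp$posterior)
    wr(dp, "diplotypes.tsv")
    for (s in names(report$phenotypes)) {
      ph <- report$phenotypes[[s]]
      df <- data.frame(phenotype = names(ph$counts), count = ph$counts,
                       frequency = fmt3(ph$freq),
                       percent = as_percent(ph$freq))
      wr(df, paste0("phenotypes_", s, ".tsv"))
    }
  } else {
    path <- file.path(dir, "report.json")
    obj <- list(
      alleles = report$alleles,
      haplotypes = report$haplotypes,
      phenotypes = lapply(report$phenotypes, function(ph) {
        list(counts = as.list(ph$counts),
             frequency = as.list(round_half_up(ph$freq, 3)),
             percent = as.list(as_percent(ph$freq)), n = ph$n)
      }),
      excluded = report$excluded,
      log = report$log
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    written <- c(written, path)
  }
  invisible(written)
}

#' Paired-column phenotype comparison plot
#'
#' A simple paired bar chart: for each cohort, the phenotype distribution
#' under the star-allele (CPIC) scheme next to the combined-scheme one.
#'
#' @param dists Named list (cohorts) of lists with elements `cpic` and
#'   `combined`, each a named frequency vector over PM/IM/NM/RM/UM.
#' @param main Plot title.
#' @return Invisibly, the matrix passed to [graphics::barplot()].
#' @export
plot_phenotype_comparison <- function(dists, main = "CYP2C19 phenotype assignment") {
  levels <- c("PM", "IM", "NM", "RM", "UM")
  cols <- c(PM = "#d73027", IM = "#fc8d59", NM = "#cccccc",
            RM = "#91bfdb", UM = "#4575b4")
  m <- do.call(cbind, lapply(names(dists), function(co) {
    cbind(dists[[co]]$cpic[levels], dists[[co]]$combined[levels])
  }))
  m[is.na(m)] <- 0
  rownames(m) <- levels
  colnames(m) <- as.vector(rbind(paste0(names(dists), "\nstar"),
                                 paste0(names(dists), "\ncombined")))
  graphics::barplot(m, col = cols[levels], las = 2, main = main,
                    ylab = "frequency", cex.names = 0.7)
  invisible(m)
}
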