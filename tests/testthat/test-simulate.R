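test_that("a degenerate single-haplotype config yields a uniform cohort", {
  cfg <- cohort_config("tg", n = 20, hap_freqs = c(TG = 1.0), seed = 1)
  co <- generate_cohort(cfg)
  expect_true(all(co$matrix$calls[, "rs2860840"] == "T/T"))
  expect_true(all(co$matrix$calls[, "rs11188059"] == "G/G"))
  expect_true(all(co$truth$hap_a == "TG" & co$truth$hap_b == "TG"))
})

test_that("empirical haplotype frequencies sit within the binomial envelope", {
  f <- c(TG = 0.5, TA = 0.3, CG = 0.2)
  cfg <- cohort_config("big", n = 1000, hap_freqs = f, seed = 202)
  co <- generate_cohort(cfg)
  draws <- c(co$truth$label_a, co$truth$label_b)
  for (l in names(f)) {
    emp <- mean(draws == l)
    bound <- 3 * sqrt(f[[l]] * (1 - f[[l]]) / 2000)
    expect_lt(abs(emp - f[[l]]), bound)
  }
})

test_that("unphasing the truth diplotypes reproduces the genotype matrix", {
  cfg <- cohort_config("rt", n = 50,
                       hap_freqs = c("*1TG" = 0.5, "*1TA" = 0.3, "*2CG" = 0.2),
                       seed = 31)
  co <- generate_cohort(cfg)
  panel <- co$matrix$panel
  for (i in seq_len(nrow(co$truth))) {
    rebuilt <- vapply(seq_len(nrow(panel)), function(j) {
      a <- sort(c(substr(co$truth$hap_a[i], j, j), substr(co$truth$hap_b[i], j, j)))
      paste(a, collapse = "/")
    }, character(1))
    expect_equal(unname(co$matrix$calls[co$truth$sample_id[i], ]), rebuilt)
  }
})

test_that("generation is reproducible byte-for-byte under a fixed config", {
  cfg <- cohort_config("det", n = 40,
                       hap_freqs = c(TG = 0.6, TA = 0.4), seed = 77,
                       missing_rate = 0.1)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(generate_cohort(cfg)$matrix, f1, "tsv")
  write_genotypes(generate_cohort(cfg)$matrix, f2, "tsv")
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the draw
  cfg2 <- cohort_config("det", n = 40, hap_freqs = c(TG = 0.6, TA = 0.4),
                        seed = 78, missing_rate = 0.1)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(generate_cohort(cfg2)$matrix, f3, "tsv")
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("missingness is injected at the configured per-call rate", {
  cfg <- cohort_config("miss", n = 500, hap_freqs = c(TG = 0.7, CG = 0.3),
                       seed = 5, missing_rate = 0.2)
  co <- generate_cohort(cfg)
  rate <- mean(is.na(co$matrix$calls))
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / length(co$matrix$calls)))
})

test_that("off-sum frequency tables are never silently renormalized", {
  f <- c(TG = 0.5, TA = 0.3)  # sums to 0.8
  expect_error(cohort_config("bad", n = 10, hap_freqs = f), "sum to 0.8")
  expect_warning(ok <- cohort_config("fixed", n = 10, hap_freqs = f,
                                     renormalize = TRUE), "renormalizing")
  expect_equal(sum(ok$hap_freqs), 1)
  verb <- cohort_config("verb", n = 10, hap_freqs = f, validate_sum = FALSE)
  expect_false(verb$normalized)
  expect_error(generate_cohort(verb), "non-normalized")
})

test_that("presets transcribe the published frequency columns", {
  pr <- cohort_presets()
  expect_equal(pr[["hgdp_combined"]]$hap_freqs,
               c("*1CG" = 0.238, "*1TA" = 0.107, "*1TG" = 0.598, "*2CG" = 0.057))
  expect_equal(pr[["hgdp_combined"]]$n, 61L)
  expect_equal(pr[["kaingang_cyp2c_verbatim"]]$hap_freqs,
               c(TG = 0.490, TA = 0.471, CG = 0.038))
  expect_equal(pr[["kaingang_cyp2c_verbatim"]]$n, 54L)
  expect_false(pr[["kaingang_cyp2c_verbatim"]]$normalized)
  expect_true(pr[["kaingang_cyp2c_norm"]]$normalized)
  # the Guarani combined column sums to 0.839 as printed
  expect_equal(sum(pr[["guarani_combined_verbatim"]]$hap_freqs), 0.839)
  expect_false(pr[["guarani_combined_verbatim"]]$normalized)
  # columns that sum to 1 ship as a single normalized preset
  expect_true(pr[["hgdp_cyp2c"]]$normalized)
  expect_equal(pr[["guarani_cyp2c"]]$n, 33L)
  expect_equal(pr[["kg_nat_combined"]]$n, 68L)
})

test_that("a linkage-violating label set is generable and triggers the flag", {
  cfg <- cohort_config("viol", n = 10,
                       hap_freqs = c("*2TG" = 0.5, "*1CG" = 0.5), seed = 2)
  co <- generate_cohort(cfg)
  labs <- label_haplotypes(unique(c(co$truth$hap_a, co$truth$hap_b)),
                           co$matrix$panel)
  expect_true(any(labs$linkage_violation))
})
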