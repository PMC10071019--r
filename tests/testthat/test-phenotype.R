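test_that("the CPIC-style ladder reproduces the published star diplotype rows", {
  expect_equal(as.character(assign_cpic("*1", "*1")), "NM")
  expect_equal(as.character(assign_cpic("*1", "*2")), "IM")
  expect_equal(as.character(assign_cpic("*2", "*17")), "IM")
  expect_equal(as.character(assign_cpic("*1", "*17")), "RM")
  expect_equal(as.character(assign_cpic("*2", "*2")), "PM")
  expect_equal(as.character(assign_cpic("*17", "*17")), "UM")
  expect_equal(as.character(assign_cpic("*2", "*3")), "PM")
  expect_equal(as.character(assign_cpic("*1", "*9")), "IM")
  expect_equal(as.character(assign_cpic("*9", "*9")), "IM")
})

test_that("decreased-with-increased pairs are flagged as extrapolated", {
  ph <- assign_cpic("*9", "*17")
  expect_equal(as.character(ph), "NM")
  expect_true(attr(ph, "extrapolated"))
  expect_false(attr(assign_cpic("*1", "*9"), "extrapolated"))
})

test_that("the combined-scheme ladder reproduces all eight published rows", {
  rows <- reference_combined_diplotype_freqs()
  rows <- unique(rows[, c("allele_a", "allele_b")])
  want <- c("NM", "RM", "UM", "IM", "IM", "RM", "UM", "IM")
  got <- mapply(function(a, b) as.character(assign_combined(a, b)),
                rows$allele_a, rows$allele_b)
  expect_equal(unname(got), want)
  # unobserved pairs get principled ladder assignments
  expect_equal(as.character(assign_combined("*2CG", "*2CG")), "PM")
  expect_equal(as.character(assign_combined("*17CG", "*17CG")), "UM")
  # unmerged *1 labels behave like the merged class
  expect_equal(as.character(assign_combined("*1TA", "*1TG")), "RM")
  expect_equal(as.character(assign_combined("*1CG", "*1TG")), "RM")
})

test_that("phenotype assignment is symmetric and rejects unknown labels", {
  pairs <- list(c("*1", "*2"), c("*2", "*17"), c("*1", "*17"), c("*9", "*17"))
  for (p in pairs) {
    expect_equal(as.character(assign_cpic(p[1], p[2])),
                 as.character(assign_cpic(p[2], p[1])))
  }
  expect_equal(as.character(assign_combined("*1TG", "*2CG")),
               as.character(assign_combined("*2CG", "*1TG")))
  expect_error(assign_cpic("*1", "*42"), "unknown allele label")
  expect_error(assign_combined("*1TG", "*1"), "unknown allele label")
})

test_that("combined and CPIC schemes agree on whether a diplotype is IM or PM", {
  # every unordered pair over the observed combined labels vs its star image
  combined_labels <- c("*1TG", "*1CG", "*1TA", "*2CG", "*17CG")
  star_of <- c("*1TG" = "*1", "*1CG" = "*1", "*1TA" = "*1",
               "*2CG" = "*2", "*17CG" = "*17")
  for (i in seq_along(combined_labels)) {
    for (j in i:length(combined_labels)) {
      a <- combined_labels[i]; b <- combined_labels[j]
      ph_c <- as.character(assign_combined(a, b))
      ph_s <- as.character(assign_cpic(star_of[a], star_of[b]))
      expect_equal(ph_c %in% c("IM", "PM"), ph_s %in% c("IM", "PM"),
                   label = paste(a, b))
      expect_equal(ph_c == "PM", ph_s == "PM", label = paste(a, b))
    }
  }
})

test_that("phenotype totals from a printed diplotype table sum per phenotype", {
  tab <- reference_combined_diplotype_freqs()
  kng <- tab[tab$cohort == "Kaingang", ]
  tot <- phenotype_totals_from_freqs(kng, "combined")
  expect_equal(unname(tot["NM"]), 0.241)
  expect_equal(unname(tot["RM"]), 0.556)
  expect_equal(unname(tot["UM"]), 0.204)
  expect_equal(unname(tot["PM"]), 0)
})

test_that("phenotype distributions tabulate included individuals only", {
  cfg <- cohort_config("mix", n = 30,
                       hap_freqs = c("*1TG" = 0.6, "*2CG" = 0.4), seed = 3)
  co <- generate_cohort(cfg)
  fit <- em_haplotype_frequencies(co$matrix)
  calls <- call_diplotypes(co$matrix, fit)
  dist <- phenotype_distribution(calls, co$matrix$panel, "combined")
  expect_equal(dist$n, sum(calls$included))
  expect_equal(sum(dist$freq), 1, tolerance = 1e-12)
  expect_equal(sum(dist$counts), dist$n)
  # single individual -> a single phenotype at frequency 1
  one <- calls[1, , drop = FALSE]
  d1 <- phenotype_distribution(one, co$matrix$panel, "cpic")
  expect_equal(max(d1$freq), 1)
  # all-excluded input errors
  none <- calls; none$included <- FALSE
  expect_error(phenotype_distribution(none, co$matrix$panel), "no included")
})

test_that("percent rendering rounds half away from zero", {
  expect_equal(as_percent(c(0.556, 0.241, 0.204)), c(56L, 24L, 20L))
  expect_equal(as_percent(0.205), 21L)   # 20.5 rounds up, not to even
  expect_equal(round_half_up(0.2037, 3), 0.204)
  expect_equal(round_half_up(-0.5), -1)
})
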