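p2 <- two_snp_panel()

test_that("diplotype enumeration returns 2^(h-1) configurations", {
  hom <- enumerate_diplotypes(c("T/T", "G/G"), p2)
  expect_equal(nrow(hom), 1)
  expect_equal(unname(hom[1, ]), c("TG", "TG"))

  dh <- enumerate_diplotypes(c("C/T", "A/G"), p2)
  expect_equal(nrow(dh), 2)
  expect_equal(unname(dh[, 1]), c("CA", "CG"))
  expect_equal(unname(dh[, 2]), c("TG", "TA"))

  expect_error(enumerate_diplotypes(c("C/T", NA), p2), "missing")
})

test_that("enumeration agrees with brute force over all phase assignments", {
  p4 <- default_panel(loci = c("rs2860840", "rs11188059", "rs4244285",
                               "rs12248560"))
  genos <- list(
    c("C/T", "A/G", "A/G", "C/C"),          # 3 het loci -> 4 configs
    c("C/T", "A/G", "A/G", "C/T"),          # 4 het loci -> 8 configs
    c("C/C", "A/G", "G/G", "C/C"),          # 1 het locus -> 1 config
    c("T/T", "G/G", "A/A", "T/T")           # 0 het loci  -> 1 config
  )
  for (g in genos) {
    got <- enumerate_diplotypes(g, p4)
    want <- brute_force_diplotypes(g)
    h <- sum(vapply(strsplit(g, "/"), function(a) a[1] != a[2], logical(1)))
    expect_equal(nrow(got), max(1, 2^(max(h, 1) - 1)))
    expect_equal(unname(got), unname(want))
  }
})

test_that("a single-haplotype cohort is an EM fixed point with a flat trace", {
  gm <- gm_from_calls(rep(list(c("T/T", "G/G")), 10), p2)
  fit <- em_haplotype_frequencies(gm)
  expect_equal(unname(fit$freqs["TG"]), 1.0)
  expect_true(fit$converged)
  expect_lt(diff(range(fit$loglik_trace)), 1e-12)
})

test_that("EM reaches the likelihood maximum found by simplex search", {
  gm <- gm_from_calls(list(c("T/T", "G/G"), c("C/T", "G/G"), c("C/T", "A/G")),
                      p2)
  fit <- em_haplotype_frequencies(gm)
  configs <- lapply(seq_len(3), function(i) enumerate_diplotypes(gm$calls[i, ], p2))
  haps <- sort(unique(unlist(configs)))
  oracle_ll <- grid_search_max_loglik(configs, haps, step = 0.05)
  expect_gte(fit$loglik, oracle_ll - 1e-6)
  # and the EM frequencies evaluate to the same likelihood under the oracle
  expect_equal(oracle_loglik(fit$freqs, configs), fit$loglik, tolerance = 1e-9)
})

test_that("EM log-likelihood is non-decreasing on random cohorts", {
  presets <- list(c(TG = 0.5, TA = 0.3, CG = 0.15, CA = 0.05),
                  c(TG = 0.7, TA = 0.2, CG = 0.1),
                  c(TG = 0.4, TA = 0.4, CG = 0.2))
  for (k in seq_along(presets)) {
    cfg <- cohort_config(paste0("mono", k), n = 30, hap_freqs = presets[[k]],
                         seed = 100 + k)
    gm <- generate_cohort(cfg)$matrix
    fit <- em_haplotype_frequencies(gm)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
    expect_equal(sum(fit$freqs), 1, tolerance = 1e-9)
    expect_true(all(fit$freqs >= 0))
  }
})

test_that("diplotype posteriors follow the frequency model and normalize", {
  # unique configuration -> posterior 1
  post <- diplotype_posteriors(c("T/T", "G/G"), c(TG = 0.6, TA = 0.4), p2)
  expect_equal(post$posterior, 1)

  # symmetric frequencies -> both configurations at 0.5
  post <- diplotype_posteriors(c("C/T", "A/G"),
                               c(TG = 0.25, TA = 0.25, CG = 0.25, CA = 0.25), p2)
  expect_equal(post$posterior, c(0.5, 0.5))

  # hand-computed: P({TA,CG}) = 2*.3*.15 / (2*.5*.05 + 2*.3*.15)
  freqs <- c(TG = 0.5, TA = 0.3, CG = 0.15, CA = 0.05)
  post <- diplotype_posteriors(c("C/T", "A/G"), freqs, p2)
  i <- which(post$hap_a == "CG" & post$hap_b == "TA")
  expect_equal(post$posterior[i], (2 * 0.3 * 0.15) / (2 * 0.5 * 0.05 + 2 * 0.3 * 0.15))
  expect_equal(sum(post$posterior), 1, tolerance = 1e-9)

  # incompatible with every positive-frequency haplotype -> unresolvable
  post <- diplotype_posteriors(c("C/C", "G/G"), c(TG = 1), p2)
  expect_true(attr(post, "unresolvable"))
  expect_equal(post$posterior, 0)
})

test_that("samples with at most one heterozygous locus have posterior 1", {
  cfg <- cohort_config("ph", n = 40,
                       hap_freqs = c(TG = 0.5, TA = 0.3, CG = 0.2), seed = 11)
  co <- generate_cohort(cfg)
  fit <- em_haplotype_frequencies(co$matrix)
  calls <- call_diplotypes(co$matrix, fit)
  het <- apply(co$matrix$calls, 1, function(g) {
    sum(vapply(strsplit(g, "/"), function(a) a[1] != a[2], logical(1)))
  })
  expect_true(all(calls$posterior[het <= 1] == 1))
})

test_that("the posterior inclusion boundary is inclusive and ties are flagged", {
  gm <- gm_from_calls(list(c("C/T", "A/G")), p2)
  freqs <- c(TG = 0.5, TA = 0.3, CG = 0.15, CA = 0.05)
  post <- diplotype_posteriors(c("C/T", "A/G"), freqs, p2)
  best <- max(post$posterior)
  calls <- call_diplotypes(gm, freqs, threshold = best)
  expect_true(calls$included)          # posterior == threshold counts as in
  calls <- call_diplotypes(gm, freqs, threshold = best + 1e-9)
  expect_false(calls$included)

  # exact tie under uniform frequencies: deterministic lexicographic winner
  calls <- call_diplotypes(gm, c(TG = 0.25, TA = 0.25, CG = 0.25, CA = 0.25),
                           threshold = 0.95)
  expect_true(calls$ambiguous)
  expect_false(calls$included)         # posterior 0.5 < 0.95
  expect_equal(c(calls$hap_a, calls$hap_b), c("CA", "TG"))
})

test_that("samples with missing calls are excluded from EM but counted", {
  rows <- c(rep(list(c("T/T", "G/G")), 5), list(c(NA, "G/G")))
  gm <- gm_from_calls(rows, p2)
  fit <- em_haplotype_frequencies(gm)
  expect_equal(fit$n_samples_used, 5)
  expect_equal(fit$n_excluded_missing, 1)
  calls <- call_diplotypes(gm, fit)
  expect_equal(nrow(calls), 5)
  expect_equal(attr(calls, "excluded_missing"), "S6")

  gm_all_missing <- gm_from_calls(list(c(NA, "G/G")), p2)
  expect_error(em_haplotype_frequencies(gm_all_missing), "no samples")
})

test_that("EM estimates tighten toward truth as the cohort grows", {
  truth <- c(TG = 0.5, TA = 0.3, CG = 0.2)
  rmse_at <- function(n, n_rep = 100) {
    errs <- vapply(seq_len(n_rep), function(r) {
      cfg <- cohort_config("c", n = n, hap_freqs = truth, seed = 5000 + r)
      fit <- em_haplotype_frequencies(generate_cohort(cfg)$matrix)
      est <- fit$freqs[names(truth)]
      est[is.na(est)] <- 0
      sqrt(mean((est - truth)^2))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(rmse_at(500), rmse_at(50))
})
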