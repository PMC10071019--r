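# Independent oracles used to pin down expected values. These deliberately
# avoid the package's own code paths: brute-force enumeration, direct
# likelihood evaluation and grid/simplex search.

# all unordered haplotype pairs compatible with an unphased genotype, by
# brute force over every allele assignment at every locus
brute_force_diplotypes <- function(geno) {
  alleles <- strsplit(geno, "/")
  L <- length(alleles)
  grids <- lapply(alleles, function(a) 1:2)
  assign <- expand.grid(grids)
  pairs <- unique(t(apply(assign, 1, function(row) {
    ha <- vapply(seq_len(L), function(j) alleles[[j]][row[j]], character(1))
    hb <- vapply(seq_len(L), function(j) alleles[[j]][3 - row[j]], character(1))
    sort(c(paste(ha, collapse = ""), paste(hb, collapse = "")))
  })))
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# log-likelihood of a haplotype frequency vector for a list of per-sample
# compatible-configuration matrices, computed directly from the model
oracle_loglik <- function(freqs, config_list) {
  sum(vapply(config_list, function(cfg) {
    fa <- freqs[cfg[, 1]]; fb <- freqs[cfg[, 2]]
    fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
    log(sum(fa * fb * ifelse(cfg[, 1] == cfg[, 2], 1, 2)))
  }, numeric(1)))
}

# maximum of the haplotype-frequency likelihood over the simplex, found by a
# coarse grid scan polished with Nelder-Mead on softmax coordinates --
# independent of the EM iteration it is used to check
grid_search_max_loglik <- function(config_list, haps, step = 0.05) {
  k <- length(haps)
  grid_pts <- seq(0, 1, by = step)
  combos <- expand.grid(rep(list(grid_pts), k - 1))
  best_f <- rep(1 / k, k)
  best_ll <- -Inf
  for (i in seq_len(nrow(combos))) {
    f <- as.numeric(combos[i, ])
    if (sum(f) > 1 + 1e-12) next
    ff <- c(f, max(0, 1 - sum(f)))
    names(ff) <- haps
    ll <- oracle_loglik(ff, config_list)
    if (is.finite(ll) && ll > best_ll) { best_ll <- ll; best_f <- ff }
  }
  obj <- function(z) {
    f <- exp(z - max(z)); f <- f / sum(f); names(f) <- haps
    -oracle_loglik(f, config_list)
  }
  z0 <- log(pmax(best_f, 1e-6))
  opt <- stats::optim(z0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  max(best_ll, -opt$value)
}

# Pearson chi-square of an r x 2 table by the textbook formula
hand_chisq <- function(tab) {
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp_tab)^2 / exp_tab)
}

# genotype matrix built directly from per-sample call vectors
gm_from_calls <- function(call_rows, panel, ids = NULL) {
  m <- do.call(rbind, call_rows)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(m)))
  rownames(m) <- ids
  genotype_matrix(m, panel)
}

two_snp_panel <- function() default_panel(loci = c("rs2860840", "rs11188059"))
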