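#' Enumerate the diplotype configurations compatible with an unphased genotype
#'
#' A sample heterozygous at `h` panel loci admits `2^(h-1)` unordered
#' haplotype pairs (one pair when `h = 0`). Haplotypes are returned as allele
#' strings in panel order, each pair sorted lexicographically so the pair is
#' canonical.
#'
#' @param geno Character vector of unordered `"X/Y"` calls, one per panel SNP,
#'   with no missing values.
#' @param panel The [variant_panel].
#' @return A two-column character matrix (`hap_a`, `hap_b`), one row per
#'   compatible configuration.
#' @export
enumerate_diplotypes <- function(geno, panel) {
  if (length(geno) != nrow(panel)) stop("genotype length does not match panel")
  if (any(is.na(geno))) stop("missing call present; cannot enumerate diplotypes")
  alleles <- strsplit(geno, "/")
  het <- vapply(alleles, function(a) a[1] != a[2], logical(1))
  h <- sum(het)
  a1 <- vapply(alleles, `[`, character(1), 1)
  a2 <- vapply(alleles, `[`, character(1), 2)
  if (h == 0) {
    hap <- paste(a1, collapse = "")
    return(matrix(c(hap, hap), nrow = 1, dimnames = list(NULL, c("hap_a", "hap_b"))))
  }
  het_idx <- which(het)
  # fix the phase at the first het locus to collapse the orientation symmetry
  free <- het_idx[-1]
  n_cfg <- 2^(h - 1)
  out <- matrix(NA_character_, nrow = n_cfg, ncol = 2,
                dimnames = list(NULL, c("hap_a", "hap_b")))
  for (k in seq_len(n_cfg)) {
    bits <- as.integer(intToBits(k - 1))[seq_along(free)]
    ha <- a1
    hb <- a2
    hb[!het] <- a1[!het]
    flip <- free[bits == 1L]
    tmp <- ha[flip]; ha[flip] <- hb[flip]; hb[flip] <- tmp
    pair <- sort(c(paste(ha, collapse = ""), paste(hb, collapse = "")))
    out[k, ] <- pair
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# per-sample list of compatible configurations for all complete samples
compatible_configs <- function(gm) {
  complete <- !apply(is.na(gm$calls), 1, any)
  lapply(which(complete), function(i) enumerate_diplotypes(gm$calls[i, ], gm$panel))
}

#' Estimate haplotype frequencies from unphased genotypes by EM
#'
#' The standard multilocus haplotype-frequency EM (as in haplo.stats or the
#' Excoffier-Slatkin algorithm): the E-step weights each configuration
#' `{a, b}` of sample `i` by `f_a * f_b * (2 if a != b)`, normalized within
#' the sample; the M-step sets each haplotype frequency to its expected share
#' of the `2n` chromosomes. Iteration stops when the log-likelihood gain falls
#' below `tol` or after `max_iter` iterations. Samples with a missing call at
#' any panel locus are excluded (and counted).
#'
#' @param gm A [genotype_matrix].
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations.
#' @param n_restarts Additional random-frequency restarts (0 = single run from
#'   the uniform start over observed-compatible haplotypes); the best
#'   log-likelihood wins. Guards against rare local optima.
#' @param seed Seed for the random restarts (ignored when `n_restarts = 0`).
#' @return A `hap_freq_fit` list: `freqs` (named, sums to 1), `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `n_samples_used`,
#'   `n_excluded_missing`.
#' @export
em_haplotype_frequencies <- function(gm, tol = 1e-10, max_iter = 500L,
                                     n_restarts = 0L, seed = 1L) {
  complete <- !apply(is.na(gm$calls), 1, any)
  n_used <- sum(complete)
  if (n_used == 0) stop("no samples with complete calls at the panel loci")
  configs <- compatible_configs(gm)
  haps <- sort(unique(unlist(lapply(configs, as.vector))))
  starts <- list(stats::setNames(rep(1 / length(haps), length(haps)), haps))
  if (n_restarts > 0) {
    starts <- c(starts, withr::with_seed(seed, {
      lapply(seq_len(n_restarts), function(i) {
        f <- stats::runif(length(haps))
        stats::setNames(f / sum(f), haps)
      })
    }))
  }
  best <- NULL
  for (f0 in starts) {
    fit <- em_run(configs, f0, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$n_samples_used <- n_used
  best$n_excluded_missing <- sum(!complete)
  class(best) <- "hap_freq_fit"
  best
}

em_run <- function(configs, freqs, tol, max_iter) {
  haps <- names(freqs)
  # index configs once
  idx <- lapply(configs, function(m) {
    cbind(match(m[, 1], haps), match(m[, 2], haps))
  })
  mult <- lapply(configs, function(m) ifelse(m[, 1] == m[, 2], 1, 2))
  n <- length(configs)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- stats::setNames(numeric(length(haps)), haps)
    ll <- 0
    for (i in seq_len(n)) {
      w <- freqs[idx[[i]][, 1]] * freqs[idx[[i]][, 2]] * mult[[i]]
      s <- sum(w)
      if (!is.finite(s) || s <= 0) stop("sample ", i, " incompatible with current frequencies (non-finite likelihood)")
      ll <- ll + log(s)
      w <- w / s
      for (k in seq_along(w)) {
        counts[idx[[i]][k, 1]] <- counts[idx[[i]][k, 1]] + w[k]
        counts[idx[[i]][k, 2]] <- counts[idx[[i]][k, 2]] + w[k]
      }
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    freqs <- counts / (2 * n)
  }
  list(freqs = freqs / sum(freqs), loglik = trace[length(trace)],
       loglik_trace = trace, n_iter = iter, converged = converged)
}

#' @export
print.hap_freq_fit <- function(x, ...) {
  cat("EM haplotype frequencies (", x$n_samples_used, "samples,",
      x$n_iter, "iterations,", if (x$converged) "converged" else "NOT converged", ")\n")
  f <- sort(x$freqs[x$freqs >= 1e-6], decreasing = TRUE)
  print(round(f, 4))
  invisible(x)
}

#' Haplotypes retained for reporting
#'
#' Frequencies below `drop` are treated as numerical zeros of the EM;
#' `identified` is the discreteness threshold that turns the continuous
#' estimate into the reported "identified haplotypes" list.
#'
#' @param fit A `hap_freq_fit`.
#' @param identified Report threshold (default 0.01).
#' @param drop Numerical-zero threshold (default 1e-6).
#' @return Named frequency vector of identified haplotypes, decreasing.
#' @export
identified_haplotypes <- function(fit, identified = 0.01, drop = 1e-6) {
  f <- fit$freqs[fit$freqs >= drop]
  sort(f[f > identified], decreasing = TRUE)
}

#' Posterior probabilities of the diplotype configurations of one sample
#'
#' `posterior({a, b}) proportional to f_a * f_b * (2 if a != b)`, normalized
#' over the sample's compatible configurations.
#'
#' @param geno Character vector of unordered calls (no missing).
#' @param freqs Named haplotype frequency vector (normalized).
#' @param panel The [variant_panel].
#' @return A data.frame `hap_a`, `hap_b`, `posterior` (sums to 1), with
#'   attribute `unresolvable = TRUE` when every configuration has zero
#'   probability under `freqs`.
#' @export
diplotype_posteriors <- function(geno, freqs, panel) {
  cfg <- enumerate_diplotypes(geno, panel)
  fa <- freqs[cfg[, 1]]
  fb <- freqs[cfg[, 2]]
  fa[is.na(fa)] <- 0
  fb[is.na(fb)] <- 0
  w <- unname(fa * fb * ifelse(cfg[, 1] == cfg[, 2], 1, 2))
  out <- data.frame(hap_a = cfg[, 1], hap_b = cfg[, 2], posterior = NA_real_,
                    stringsAsFactors = FALSE)
  if (sum(w) <= 0) {
    out$posterior <- 0
    attr(out, "unresolvable") <- TRUE
  } else {
    out$posterior <- w / sum(w)
    attr(out, "unresolvable") <- FALSE
  }
  out
}

#' Call the best diplotype per sample with a posterior inclusion threshold
#'
#' The best configuration is the posterior argmax (ties broken by
#' lexicographic order on the haplotype strings and flagged `ambiguous`).
#' An individual is `included` when its posterior is at or above `threshold`
#' (inclusive boundary); 0.95 is the default inclusion cutoff. Samples with
#' missing calls are excluded up front and reported in the
#' `excluded_missing` attribute.
#'
#' @param gm A [genotype_matrix].
#' @param fit A `hap_freq_fit` from [em_haplotype_frequencies()] on the same
#'   matrix (or any normalized frequency vector via `fit$freqs`).
#' @param threshold Posterior inclusion threshold.
#' @return A data.frame with one row per complete sample: `sample_id`,
#'   `hap_a`, `hap_b`, `posterior`, `included`, `ambiguous`, `unresolvable`.
#' @export
call_diplotypes <- function(gm, fit, threshold = 0.95) {
  freqs <- if (inherits(fit, "hap_freq_fit")) fit$freqs else fit
  complete <- !apply(is.na(gm$calls), 1, any)
  ids <- sample_ids(gm)[complete]
  rows <- lapply(which(complete), function(i) {
    post <- diplotype_posteriors(gm$calls[i, ], freqs, gm$panel)
    best <- which(post$posterior == max(post$posterior))
    tie <- length(best) > 1
    best <- best[1]  # rows are already in lexicographic order
    data.frame(sample_id = sample_ids(gm)[i],
               hap_a = post$hap_a[best], hap_b = post$hap_b[best],
               posterior = post$posterior[best],
               included = post$posterior[best] >= threshold,
               ambiguous = tie,
               unresolvable = isTRUE(attr(post, "unresolvable")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded_missing") <- sample_ids(gm)[!complete]
  out
}
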