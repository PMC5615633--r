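# Brute-force oracle for the modified cosine: enumerates every one-to-one
# assignment of candidate peak pairs (a peak of A to at most one peak of B)
# and returns the maximum summed intensity product. Independent of the
# package's matching path; exponential, so only for small spectra.
bf_modified_cosine <- function(spec_a, spec_b, fragment_tol = 0.5) {
  norm_w <- function(p) {
    w <- sqrt(p$intensity)
    w / sqrt(sum(w^2))
  }
  pa <- spec_a$peaks
  pb <- spec_b$peaks
  if (is.list(pa) && !is.data.frame(pa)) pa <- pa[[1]]
  if (is.list(pb) && !is.data.frame(pb)) pb <- pb[[1]]
  wa <- norm_w(pa)
  wb <- norm_w(pb)
  delta <- spec_a$precursor_mz - spec_b$precursor_mz
  d <- outer(pa$mz, pb$mz, "-")
  cand <- (abs(d) <= fragment_tol | abs(d - delta) <= fragment_tol) &
    outer(wa, wb) > 0
  w <- outer(wa, wb)
  best <- list(score = 0, n = 0L)
  nb <- nrow(pb)
  rec <- function(i, used_b, s, n) {
    if (i > nrow(pa)) {
      if (s > best$score + 1e-15) best <<- list(score = s, n = n)
      return(invisible())
    }
    rec(i + 1, used_b, s, n) # leave peak i unmatched
    for (j in seq_len(nb)) {
      if (cand[i, j] && !used_b[j]) {
        used_b[j] <- TRUE
        rec(i + 1, used_b, s + w[i, j], n + 1L)
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), 0, 0L)
  best
}

# random small spectrum; optionally reuses mz positions from another peak
# table (directly or shifted) so candidate structures are non-trivial
random_spectrum <- function(n_peaks, precursor = runif(1, 150, 500),
                            base_mz = NULL, shift = 0) {
  mz <- runif(n_peaks, 50, precursor - 10)
  if (!is.null(base_mz)) {
    k <- min(length(base_mz), max(1, n_peaks %/% 2))
    reuse <- sample(base_mz, k)
    mz[seq_len(k)] <- reuse + shift + runif(k, -0.3, 0.3)
  }
  list(precursor_mz = precursor,
       peaks = tibble::tibble(mz = sort(mz),
                              intensity = runif(n_peaks, 0.05, 1)))
}

# ordinary least squares through explicit normal equations (on rescaled
# abscissae for conditioning), as an independent check on the regression fit
normal_equation_fit <- function(x, y) {
  sx <- max(abs(x))
  X <- cbind(1, x / sx)
  beta <- solve(t(X) %*% X, t(X) %*% y)[, 1]
  c(beta[1], beta[2] / sx)
}

# noise-free scenario used by several recovery tests
noise_free_scenario <- function(seed = 11) {
  synthetic_scenario(seed = seed, noise_sd_fraction = 0, blank_offset_ppb = 0)
}
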