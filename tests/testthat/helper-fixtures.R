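# Shared fixture builders: everything is generated in code at test time.

# minimal DEMO-style frame for deduplication tests
make_demo <- function(primaryid, caseid, fda_dt) {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             fda_dt = as.character(fda_dt),
             stringsAsFactors = FALSE)
}

# brute-force deduplication oracle: group by caseid, keep the row maximizing
# (fda_dt, then numeric primaryid) -- independent of the implementation
dedup_oracle <- function(demo) {
  picked <- lapply(split(seq_len(nrow(demo)), demo$caseid), function(i) {
    sub <- demo[i, , drop = FALSE]
    best <- sub[sub$fda_dt == max(sub$fda_dt), , drop = FALSE]
    best[which.max(as.numeric(best$primaryid)), , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  out <- out[order(out$caseid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random DEMO frame with controlled duplication, for property tests
random_demo <- function(n_cases, max_versions = 3) {
  rows <- lapply(seq_len(n_cases), function(i) {
    k <- sample.int(max_versions, 1)
    make_demo(primaryid = i * 100 + seq_len(k),
              caseid = i,
              fda_dt = format(as.Date("2023-01-01") +
                                sort(sample.int(400, k)), "%Y%m%d"))
  })
  demo <- do.call(rbind, rows)
  demo[sample.int(nrow(demo)), , drop = FALSE]
}

# random strictly-positive 2x2 tables as a data.frame of cells (numeric to
# keep marginal products overflow-free)
random_tables <- function(n, max_cell = 5000) {
  data.frame(a = as.numeric(sample.int(max_cell, n, replace = TRUE)),
             b = as.numeric(sample.int(max_cell, n, replace = TRUE)),
             c = as.numeric(sample.int(max_cell, n, replace = TRUE)),
             d = as.numeric(sample.int(max_cell, n, replace = TRUE)))
}

# all 2x2 tables with nonnegative cells and 1 <= N <= nmax, enumerated as
# compositions (three free cells plus a run over the remainder)
enumerate_tables <- function(nmax) {
  g3 <- expand.grid(a = 0:nmax, b = 0:nmax, c = 0:nmax)
  g3 <- g3[g3$a + g3$b + g3$c <= nmax, , drop = FALSE]
  rem <- nmax - (g3$a + g3$b + g3$c)
  idx <- rep(seq_len(nrow(g3)), rem + 1)
  g <- data.frame(a = g3$a[idx], b = g3$b[idx], c = g3$c[idx],
                  d = sequence(rem + 1) - 1L)
  g[g$a + g$b + g$c + g$d >= 1, , drop = FALSE]
}

# direct quadrature of the EBGM posterior: integrate lambda over the
# (non-conjugate form of the) posterior density w g1 + (1-w) g2 times the
# Poisson likelihood, normalized numerically. Independent of the conjugate
# closed form used by the implementation.
ebgm_quadrature <- function(a, e, prior) {
  post_kernel <- function(l) {
    pri <- prior$w * dgamma(l, prior$alpha1, rate = prior$beta1) +
      (1 - prior$w) * dgamma(l, prior$alpha2, rate = prior$beta2)
    pri * dpois(a, l * e)
  }
  z <- integrate(post_kernel, 0, Inf, rel.tol = 1e-11)$value
  elog <- integrate(function(l) log(l) * post_kernel(l), 0, Inf,
                    rel.tol = 1e-11)$value / z
  exp(elog)
}

# posterior CDF at x by quadrature, for checking the EBGM05 percentile
ebgm_cdf_quadrature <- function(x, a, e, prior) {
  post_kernel <- function(l) {
    pri <- prior$w * dgamma(l, prior$alpha1, rate = prior$beta1) +
      (1 - prior$w) * dgamma(l, prior$alpha2, rate = prior$beta2)
    pri * dpois(a, l * e)
  }
  z <- integrate(post_kernel, 0, Inf, rel.tol = 1e-11)$value
  integrate(post_kernel, 0, x, rel.tol = 1e-11)$value / z
}
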