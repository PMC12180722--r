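# The frequentist disproportionality statistics: reporting odds ratio (ROR),
# proportional reporting ratio (PRR) with the Yates-corrected chi-square, and
# the BCPNN information component. All are vectorized over table cells so that
# whole-database screens and exhaustive property sweeps evaluate in one call.

# Haldane-Anscombe correction: if any cell of a table is zero, add 0.5 to all
# four cells of that table. Returns corrected cells plus the flag.
haldane <- function(cells) {
  zero <- cells$a == 0 | cells$b == 0 | cells$c == 0 | cells$d == 0
  add <- ifelse(zero, 0.5, 0)
  list(a = cells$a + add, b = cells$b + add,
       c = cells$c + add, d = cells$d + add, corrected = zero)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a*d)/(b*c)` with the log-scale Wald interval
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. Tables with any zero
#' cell receive the Haldane +0.5 correction to all cells and are flagged
#' `corrected`.
#'
#' @param t a [contingency_table()], or a list/data.frame with numeric fields
#'   `a`, `b`, `c`, `d` (vectorized).
#' @return data.frame with columns `ror`, `ror_lo`, `ror_hi`, `corrected`.
#' @export
#' @examples
#' ror_estimate(contingency_table(10, 90, 100, 9900))
ror_estimate <- function(t) {
  k <- haldane(as_cells(t))
  est <- (k$a * k$d) / (k$b * k$c)
  se <- sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)
  data.frame(ror = est,
             ror_lo = exp(log(est) - 1.96 * se),
             ror_hi = exp(log(est) + 1.96 * se),
             corrected = k$corrected)
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with interval
#' `exp(ln PRR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`; zero cells
#' are Haldane-corrected and flagged as for [ror_estimate()].
#'
#' @inheritParams ror_estimate
#' @return data.frame with columns `prr`, `prr_lo`, `prr_hi`, `corrected`.
#' @export
prr_estimate <- function(t) {
  k <- haldane(as_cells(t))
  est <- (k$a / (k$a + k$b)) / (k$c / (k$c + k$d))
  se <- sqrt(1 / k$a - 1 / (k$a + k$b) + 1 / k$c - 1 / (k$c + k$d))
  data.frame(prr = est,
             prr_lo = exp(log(est) - 1.96 * se),
             prr_hi = exp(log(est) + 1.96 * se),
             corrected = k$corrected)
}

#' Yates-corrected chi-square statistic for a 2x2 table
#'
#' `chi2 = N * (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`, floored at 0
#' when `|ad - bc| < N/2` (the continuity correction would otherwise
#' overshoot). Used with the MHRA joint criterion `PRR >= 2 and chi2 >= 4`.
#'
#' @inheritParams ror_estimate
#' @return numeric vector of chi-square values.
#' @export
chi_square_yates <- function(t) {
  k <- as_cells(t)
  n <- k$a + k$b + k$c + k$d
  m <- list(k$a + k$b, k$c + k$d, k$a + k$c, k$b + k$d)
  if (any(vapply(m, function(x) any(x <= 0), logical(1)))) {
    stop("chi-square undefined: a zero marginal")
  }
  dev <- abs(k$a * k$d - k$b * k$c)
  dev_c <- pmax(dev - n / 2, 0)
  n * dev_c^2 / (m[[1]] * m[[2]] * m[[3]] * m[[4]])
}

#' BCPNN information component
#'
#' The information component is a shrunk log2 observed-to-expected ratio with
#' expected count `E = (a+b)(a+c)/N`. The default (`variant = "noren"`) uses
#' `IC = log2((a + 0.5)/(E + 0.5))` with the closed-form lower credibility
#' bound `IC025 = IC - 3.3*a^(-1/2) - 2*a^(-3/2)` (valid for `a >= 1`; for
#' `a = 0` the shrunk IC is returned and IC025 is `-Inf`). The original
#' variance-based formulation (`variant = "bate"`) computes E(IC) and V(IC)
#' under the default Dirichlet-style priors and `IC025 = E(IC) -
#' 1.96*sqrt(V(IC))`.
#'
#' @inheritParams ror_estimate
#' @param variant `"noren"` (default) or `"bate"`.
#' @return data.frame with columns `ic`, `ic025`.
#' @export
information_component <- function(t, variant = c("noren", "bate")) {
  variant <- match.arg(variant)
  k <- as_cells(t)
  n <- k$a + k$b + k$c + k$d
  if (any(n <= 0)) stop("empty table")
  e <- (k$a + k$b) * (k$a + k$c) / n
  if (variant == "noren") {
    ic <- log2((k$a + 0.5) / (e + 0.5))
    ic025 <- ifelse(k$a >= 1,
                    ic - 3.3 * k$a^(-0.5) - 2 * k$a^(-1.5),
                    -Inf)
    return(data.frame(ic = ic, ic025 = ic025))
  }
  # Bate et al. closed-form posterior moments with gamma11 = 1, alpha = beta = 2,
  # alpha1 = beta1 = 1 and gamma chosen so the prior IC expectation is 0.
  a <- k$a; r1 <- k$a + k$b; c1 <- k$a + k$c
  gamma11 <- 1
  alpha1 <- 1; beta1 <- 1; alpha <- 2; beta <- 2
  gamma <- gamma11 * (n + alpha) * (n + beta) / ((r1 + alpha1) * (c1 + beta1))
  eic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
                ((n + gamma) * (r1 + alpha1) * (c1 + beta1)))
  vic <- ((n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
            (n - r1 + alpha - alpha1) / ((r1 + alpha1) * (1 + n + alpha)) +
            (n - c1 + beta - beta1) / ((c1 + beta1) * (1 + n + beta))) /
    log(2)^2
  data.frame(ic = eic, ic025 = eic - 1.96 * sqrt(vic))
}

#' All four disproportionality statistics for one table
#'
#' Convenience wrapper computing ROR, PRR, Yates chi-square, the information
#' component and EBGM for a single 2x2 table, the per-method criterion flags,
#' and the joint signal decision.
#'
#' @param t a [contingency_table()].
#' @param prior an [mgps_prior()] for the EBGM stage.
#' @param ic_variant passed to [information_component()].
#' @return object of class `signal_metrics`: a one-row data.frame with columns
#'   `n_cases`, `ror`, `ror_lo`, `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `chi2`,
#'   `ic`, `ic025`, `ebgm`, `ebgm05`, `corrected`.
#' @export
#' @examples
#' m <- signal_metrics(contingency_table(10, 90, 100, 9900))
#' evaluate_signal(m)
signal_metrics <- function(t, prior = mgps_prior(),
                           ic_variant = c("noren", "bate")) {
  stopifnot(inherits(t, "contingency_table"))
  ror <- ror_estimate(t)
  prr <- prr_estimate(t)
  chi2 <- tryCatch(chi_square_yates(t), error = function(e) NA_real_)
  ic <- information_component(t, match.arg(ic_variant))
  eb <- ebgm_estimate(t, prior)
  out <- data.frame(n_cases = t$a, ror[c("ror", "ror_lo", "ror_hi")],
                    prr[c("prr", "prr_lo", "prr_hi")], chi2 = chi2,
                    ic, ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
                    corrected = ror$corrected)
  class(out) <- c("signal_metrics", "data.frame")
  out
}

#' @export
print.signal_metrics <- function(x, digits = 3, ...) {
  cat("Disproportionality metrics (a =", x$n_cases, "cases)\n")
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  cat(sprintf("  ROR  %s (%s, %s)%s\n", fmt(x$ror), fmt(x$ror_lo),
              fmt(x$ror_hi), if (x$corrected) "  [Haldane-corrected]" else ""))
  cat(sprintf("  PRR  %s (%s, %s)   chi2 = %s\n", fmt(x$prr), fmt(x$prr_lo),
              fmt(x$prr_hi), fmt(x$chi2)))
  cat(sprintf("  IC   %s (IC025 %s)\n", fmt(x$ic), fmt(x$ic025)))
  cat(sprintf("  EBGM %s (EBGM05 %s)\n", fmt(x$ebgm), fmt(x$ebgm05)))
  invisible(x)
}

#' Apply the joint signal-detection criteria
#'
#' Per-method positivity thresholds, with the case-count gate `a >= a_min`
#' applied globally:
#' * ROR: lower 95% bound > 1;
#' * PRR: `PRR >= 2` and `chi2 >= 4`;
#' * BCPNN: `IC025 > 0`;
#' * MGPS: `EBGM05 > 2`.
#'
#' `mode = "all"` requires every method to be positive (the conservative
#' joint rule); `mode = "any"` requires at least one.
#'
#' @param m a [signal_metrics()] object (or any list with the needed fields).
#' @param mode `"all"` or `"any"`.
#' @param a_min minimum case count, default 3.
#' @return list with `is_signal` (logical) and `flags`, a named logical vector
#'   per method.
#' @export
evaluate_signal <- function(m, mode = c("all", "any"), a_min = 3) {
  mode <- match.arg(mode)
  gate <- m$n_cases >= a_min
  flags <- c(
    ror = isTRUE(gate && is.finite(m$ror_lo) && m$ror_lo > 1),
    prr = isTRUE(gate && is.finite(m$prr) && m$prr >= 2 &&
                   is.finite(m$chi2) && m$chi2 >= 4),
    bcpnn = isTRUE(gate && m$ic025 > 0),
    mgps = isTRUE(gate && is.finite(m$ebgm05) && m$ebgm05 > 2)
  )
  list(is_signal = if (mode == "all") all(flags) else any(flags),
       flags = flags)
}

#' Rank a table of signal results
#'
#' Stable descending sort by the chosen key; ties are broken by the other key
#' (descending), then alphabetically by term.
#'
#' @param results data.frame with at least columns `term`, `ror`, `n_cases`.
#' @param key `"ror"` or `"n_cases"`.
#' @return the reordered data.frame.
#' @export
rank_signals <- function(results, key = c("ror", "n_cases")) {
  key <- match.arg(key)
  if (nrow(results) == 0L) return(results)
  other <- setdiff(c("ror", "n_cases"), key)
  o <- order(-results[[key]], -results[[other]], results$term)
  out <- results[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen every event reported with a target drug
#'
#' Builds the 2x2 table of each event term (PT, or SOC after mapping) observed
#' with the target drug against the full background and computes all four
#' disproportionality statistics plus the joint criteria in both modes.
#'
#' @inheritParams build_contingency
#' @param prior an [mgps_prior()], or `"fit"` to estimate the gamma-mixture
#'   hyperparameters from all screened tables via [fit_mgps_prior()] first.
#' @param a_min minimum case count for the criteria gate.
#' @param ic_variant passed to [information_component()].
#' @return data.frame of class `disprop_screen`, one row per term, with the
#'   metric columns of [signal_metrics()] plus `term`, `soc_name`, per-method
#'   flags, and `signal_all` / `signal_any`.
#' @export
disproportionality <- function(event_pairs, target_drug,
                               level = c("PT", "SOC"), soc_map = NULL,
                               prior = mgps_prior(), a_min = 3,
                               counting = c("case", "event"),
                               ic_variant = c("noren", "bate")) {
  level <- match.arg(level)
  counting <- match.arg(counting)
  ic_variant <- match.arg(ic_variant)
  is_tgt <- toupper(trimws(event_pairs$drug)) == toupper(trimws(target_drug))
  if (!any(is_tgt)) stop("no exposure rows for target drug '", target_drug, "'")
  terms <- if (level == "SOC") {
    if (is.null(soc_map)) stop("soc_map is required at level = 'SOC'")
    unique(map_pt_to_soc(event_pairs$pt[is_tgt], soc_map)$soc_name)
  } else {
    unique(event_pairs$pt[is_tgt])
  }
  terms <- sort(terms)
  tabs <- lapply(terms, function(term) {
    build_contingency(event_pairs, target_drug, term, level = level,
                      soc_map = soc_map, counting = counting)
  })
  if (identical(prior, "fit")) prior <- fit_mgps_prior(tabs)
  rows <- lapply(seq_along(terms), function(i) {
    m <- signal_metrics(tabs[[i]], prior = prior, ic_variant = ic_variant)
    sa <- evaluate_signal(m, "all", a_min = a_min)
    sy <- evaluate_signal(m, "any", a_min = a_min)
    cbind(data.frame(term = terms[i], stringsAsFactors = FALSE),
          as.data.frame(unclass(m)),
          data.frame(flag_ror = sa$flags[["ror"]], flag_prr = sa$flags[["prr"]],
                     flag_bcpnn = sa$flags[["bcpnn"]],
                     flag_mgps = sa$flags[["mgps"]],
                     signal_all = sa$is_signal, signal_any = sy$is_signal))
  })
  out <- do.call(rbind, rows)
  if (level == "PT" && !is.null(soc_map)) {
    out <- cbind(soc_name = map_pt_to_soc(out$term, soc_map)$soc_name, out)
  } else if (level == "SOC") {
    out <- cbind(soc_name = out$term, out)
  }
  attr(out, "prior") <- prior
  attr(out, "level") <- level
  class(out) <- c("disprop_screen", "data.frame")
  out
}

#' @export
print.disprop_screen <- function(x, n = 10, ...) {
  cat(sprintf("Disproportionality screen: %d %s term(s), %d joint signal(s)\n",
              nrow(x), attr(x, "level") %||% "event",
              sum(x$signal_all)))
  cols <- intersect(c("term", "n_cases", "ror", "ror_lo", "prr", "chi2",
                      "ic025", "ebgm05", "signal_all"), names(x))
  print(head(as.data.frame(x)[order(-x$ror), cols], n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more row(s)\n")
  invisible(x)
}
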