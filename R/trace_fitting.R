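# Exponential analysis of individual stopped-flow transients.
#
# Fits use variable projection: for fixed rates the baseline and amplitudes
# are linear and solved by least squares, so the nonlinear search runs only
# over the (log) rates.  All fits are deterministic given the data.

# Linear solve for baseline + amplitudes given rates; returns RSS and
# coefficients.  rates may be length 1 or 2.
.exp_linear_fit <- function(time, signal, rates) {
  X <- cbind(1, vapply(rates, function(a) exp(-a * time), numeric(length(time))))
  fit <- stats::lm.fit(X, signal)
  rss <- sum(fit$residuals^2)
  list(baseline = fit$coefficients[1],
       amplitudes = fit$coefficients[-1],
       rss = rss, fitted = fit$fitted.values)
}

# Jacobian of the full nonlinear model (baseline, A_i, alpha_i) at the
# optimum; used for standard errors.
.exp_jacobian <- function(time, amplitudes, rates) {
  J <- cbind(rep(1, length(time)))
  for (a in rates) J <- cbind(J, exp(-a * time))
  for (i in seq_along(rates))
    J <- cbind(J, -amplitudes[i] * time * exp(-rates[i] * time))
  J
}

.initial_rates <- function(time, signal, n) {
  tail_n <- max(3L, ceiling(0.05 * length(signal)))
  base <- mean(utils::tail(signal, tail_n))
  delta <- signal[1] - base
  if (abs(delta) < .Machine$double.eps) return(NULL)
  # time at which 1 - 1/e of the signal change is complete
  idx <- which(abs(signal - base) <= abs(delta) / exp(1))
  t63 <- if (length(idx)) time[idx[1]] else time[length(time)]
  r1 <- 1 / max(t63, time[1])
  if (n == 1) r1 else c(5 * r1, r1)
}

#' Fit a sum of exponentials to a stopped-flow trace
#'
#' Least-squares fit of `signal(t) = baseline + sum_i A_i exp(-alpha_i t)`
#' with `n` = 1 or 2 exponential phases.  Rates are returned positive and
#' sorted descending.  Non-convergence (flat trace, unidentifiable rate) is
#' flagged, not raised.
#'
#' @param trace an [sf_trace()].
#' @param n number of exponentials, 1 or 2.
#' @return an object of class `exp_fit`: list with `rates`, `amplitudes`,
#'   `baseline`, `rss`, `dof`, `se` (named standard errors), `converged`,
#'   `degenerate`, and the trace metadata.
#' @export
fit_exponentials <- function(trace, n) {
  stopifnot(inherits(trace, "sf_trace"), n %in% c(1L, 2L))
  time <- trace$time - trace$time[1]   # shift so amplitudes refer to t0
  signal <- trace$signal
  npar <- 1L + 2L * n
  if (length(time) <= npar + 1L)
    stop("fewer points than parameters", call. = FALSE)
  dof <- length(time) - npar

  fail <- function() {
    structure(list(rates = rep(NA_real_, n), amplitudes = rep(0, n),
                   baseline = mean(signal), rss = sum((signal - mean(signal))^2),
                   dof = dof, se = rep(NA_real_, npar), converged = FALSE,
                   degenerate = TRUE, ligand_uM = trace$ligand_uM,
                   temp_K = trace$temp_K, t_offset = trace$time[1]),
              class = "exp_fit")
  }

  r0 <- .initial_rates(time, signal, n)
  if (is.null(r0) || diff(range(signal)) < 1e-12 * max(1, abs(mean(signal))))
    return(fail())

  obj <- function(lr) .exp_linear_fit(time, signal, exp(lr))$rss
  opt <- stats::optim(log(r0), obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  # polish: golden-section for one rate, Nelder-Mead for two
  if (n == 1L) {
    o2 <- stats::optimize(obj, opt$par + c(-0.5, 0.5), tol = 1e-12)
    if (o2$objective < opt$value)
      opt <- list(par = o2$minimum, value = o2$objective, convergence = 0L)
  } else {
    o2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-15, maxit = 2000))
    if (o2$value < opt$value) opt <- o2
  }
  rates <- exp(opt$par)
  ord <- order(rates, decreasing = TRUE)
  rates <- rates[ord]
  lin <- .exp_linear_fit(time, signal, rates)

  J <- .exp_jacobian(time, lin$amplitudes, rates)
  sigma2 <- lin$rss / dof
  cov <- tryCatch(chol2inv(chol(crossprod(J))) * sigma2,
                  error = function(e) matrix(NA_real_, npar, npar))
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- c("baseline", paste0("a", seq_len(n)), paste0("alpha", seq_len(n)))

  converged <- opt$convergence == 0 && all(is.finite(rates)) &&
    all(rates > 0) && any(abs(lin$amplitudes) >
                            1e-8 * max(abs(signal - lin$baseline), 1e-300))
  structure(list(rates = unname(rates), amplitudes = unname(lin$amplitudes),
                 baseline = unname(lin$baseline), rss = lin$rss, dof = dof,
                 se = se, converged = converged,
                 degenerate = n == 2 && rates[1] / rates[2] < 1 + 1e-9,
                 ligand_uM = trace$ligand_uM, temp_K = trace$temp_K,
                 t_offset = trace$time[1]),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit: %d phase(s), converged = %s>\n",
              length(x$rates), x$converged))
  cat("  rates (1/s):", paste(signif(x$rates, 4), collapse = ", "), "\n")
  cat("  amplitudes :", paste(signif(x$amplitudes, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Choose between one and two exponentials by residual analysis
#'
#' Nested F-test on the residual sum of squares, accepting the
#' two-exponential model only when the improvement is significant at
#' `alpha_level` and the second phase is identifiable: both rates positive,
#' separated by more than a 1.5-fold ratio, with finite standard errors.
#' Degenerate traces fall back to one exponential with a warning.
#'
#' @param trace an [sf_trace()].
#' @param alpha_level significance level of the nested F-test.
#' @return list with `n` (1 or 2), `fit1`, `fit2`, `f_statistic`, `p_value`.
#' @export
choose_exponential_count <- function(trace, alpha_level = 0.01) {
  fit1 <- fit_exponentials(trace, 1L)
  fit2 <- tryCatch(fit_exponentials(trace, 2L), error = function(e) NULL)
  if (!fit1$converged) {
    warning("trace is degenerate (no resolvable signal change); using n = 1")
    return(list(n = 1L, fit1 = fit1, fit2 = fit2,
                f_statistic = NA_real_, p_value = NA_real_))
  }
  reject <- FALSE; Fstat <- NA_real_; pval <- NA_real_
  ss <- sum((trace$signal - mean(trace$signal))^2)
  if (fit1$rss <= 1e-14 * ss) {
    # the single exponential already fits to machine precision
    pval <- 1
  } else if (!is.null(fit2) && fit2$converged) {
    df_extra <- 2
    num <- (fit1$rss - fit2$rss) / df_extra
    den <- fit2$rss / fit2$dof
    if (den <= 1e-18 * ss / fit2$dof) {
      # the two-exponential fit is exact while the single is not
      reject <- TRUE
      pval <- 0
    } else {
      Fstat <- num / den
      pval <- stats::pf(Fstat, df_extra, fit2$dof, lower.tail = FALSE)
      reject <- is.finite(Fstat) && pval < alpha_level
    }
    identifiable <- all(fit2$rates > 0) &&
      fit2$rates[1] / fit2$rates[2] > 1.5 &&
      all(is.finite(fit2$se)) &&
      # a phase carrying a negligible share of the signal change is not a
      # resolvable relaxation
      all(abs(fit2$amplitudes) > 5e-3 * diff(range(trace$signal)))
    reject <- reject && identifiable
  }
  list(n = if (reject) 2L else 1L, fit1 = fit1, fit2 = fit2,
       f_statistic = Fstat, p_value = pval)
}

#' Extract a relaxation profile from a set of traces
#'
#' Fits every trace, selects the exponential count by
#' [choose_exponential_count()], and tabulates rates and amplitudes by
#' condition.  Replicate (L, T) rows are retained.
#'
#' @param traces list of [sf_trace()] objects.
#' @param alpha_level forwarded to [choose_exponential_count()].
#' @return data.frame with columns `ligand_uM`, `temp_K`, `alpha1_s`,
#'   `alpha2_s`, `a1`, `a2`, `n_exp`, sorted by temperature then ligand.
#' @export
extract_relaxation_profile <- function(traces, alpha_level = 0.01) {
  cols <- c("ligand_uM", "temp_K", "alpha1_s", "alpha2_s", "a1", "a2", "n_exp")
  if (length(traces) == 0) {
    out <- as.data.frame(matrix(numeric(0), ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  rows <- lapply(traces, function(tr) {
    sel <- suppressWarnings(choose_exponential_count(tr, alpha_level))
    fit <- if (sel$n == 2L) sel$fit2 else sel$fit1
    data.frame(ligand_uM = tr$ligand_uM, temp_K = tr$temp_K,
               alpha1_s = fit$rates[1],
               alpha2_s = if (sel$n == 2L) fit$rates[2] else NA_real_,
               a1 = fit$amplitudes[1],
               a2 = if (sel$n == 2L) fit$amplitudes[2] else NA_real_,
               n_exp = sel$n)
  })
  out <- do.call(rbind, rows)
  out[order(out$temp_K, out$ligand_uM), , drop = FALSE]
}
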