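# Two-state chemical denaturation (linear extrapolation method) and
# hyperbolic cation-titration fitting.

#' Two-state denaturation parameters
#'
#' Linear-extrapolation-method (LEM) description of a two-state unfolding
#' transition monitored by fluorescence: a midpoint `[GuHCl]50` (M), an
#' m-value (kcal/mol/M) and linear folded/unfolded baselines
#' `intercept + slope * D`.
#'
#' @param midpoint_M denaturant midpoint, M; > 0.
#' @param m_value kcal/mol/M; > 0.
#' @param folded,unfolded numeric length-2 `c(intercept, slope)` baselines
#'   in signal units.
#' @param temp_K temperature, K (default 293.15, i.e. 20 C).
#' @return object of class `denaturation_params`.
#' @export
denaturation_params <- function(midpoint_M, m_value,
                                folded = c(1, 0), unfolded = c(0.4, 0),
                                temp_K = 293.15) {
  if (midpoint_M <= 0) stop("midpoint must be > 0", call. = FALSE)
  if (m_value <= 0) stop("m-value must be > 0", call. = FALSE)
  structure(list(midpoint_M = midpoint_M, m_value = m_value,
                 folded = folded, unfolded = unfolded, temp_K = temp_K),
            class = "denaturation_params")
}

#' Fraction of unfolded molecules at a denaturant concentration
#'
#' Two-state LEM: the folding free energy is linear in denaturant,
#' `dG_fold(D) = m * (midpoint - D)`, and the unfolded fraction is the
#' Boltzmann logistic `1 / (1 + exp(dG_fold / (R T)))`.  Exactly 0.5 at the
#' midpoint and strictly increasing in D.
#'
#' @param params a [denaturation_params()].
#' @param D denaturant concentration, M (vectorized, >= 0).
#' @param temp_K temperature, K.
#' @return fractions in (0, 1).
#' @export
fraction_unfolded <- function(params, D, temp_K = params$temp_K) {
  if (any(D < 0)) stop("denaturant concentration must be >= 0", call. = FALSE)
  dG <- params$m_value * (params$midpoint_M - D)
  1 / (1 + exp(dG / (R_KCAL * temp_K)))
}

.denaturation_signal <- function(params, D, temp_K = params$temp_K) {
  fu <- fraction_unfolded(params, D, temp_K)
  (1 - fu) * (params$folded[1] + params$folded[2] * D) +
    fu * (params$unfolded[1] + params$unfolded[2] * D)
}

# Variable projection: for fixed (midpoint, m) the four baseline
# coefficients are linear.
.den_linear <- function(D, signal, midpoint, m, temp_K) {
  fu <- 1 / (1 + exp(m * (midpoint - D) / (R_KCAL * temp_K)))
  X <- cbind((1 - fu), (1 - fu) * D, fu, fu * D)
  f <- stats::lm.fit(X, signal)
  list(coef = f$coefficients, rss = sum(f$residuals^2),
       fitted = f$fitted.values)
}

#' Fit a two-state denaturation curve
#'
#' Least squares of `signal = (1 - fU) * folded(D) + fU * unfolded(D)` with
#' the LEM unfolded fraction; baselines are solved linearly at each trial
#' (midpoint, m).  A curve with no resolvable transition is returned with
#' `converged = FALSE` rather than raising.
#'
#' @param D denaturant concentrations, M (>= 8 points).
#' @param signal fluorescence, a.u.
#' @param temp_K temperature, K.
#' @return a [denaturation_params()] with extra fields `rss`, `dof`, `se`
#'   (midpoint and m-value standard errors) and `converged`.
#' @export
fit_denaturation <- function(D, signal, temp_K = 293.15) {
  stopifnot(length(D) == length(signal))
  if (length(D) < 8) stop("need at least 8 points", call. = FALSE)
  if (any(D < 0)) stop("denaturant concentration must be >= 0", call. = FALSE)
  ord <- order(D); D <- D[ord]; signal <- signal[ord]

  fail <- function(par = NULL) {
    p <- denaturation_params(max(stats::median(D), 1e-6), 1,
                             temp_K = temp_K)
    p$rss <- NA_real_; p$dof <- length(D) - 6L
    p$se <- c(midpoint = NA_real_, m_value = NA_real_)
    p$converged <- FALSE
    p
  }
  if (diff(range(signal)) < 1e-12 * max(1, abs(mean(signal))))
    return(fail())

  # midpoint guess: where the signal crosses halfway between its ends
  half <- (signal[1] + signal[length(signal)]) / 2
  i <- which.min(abs(signal - half))
  mid0 <- max(D[i], 1e-3)
  obj <- function(p) {
    mid <- exp(p[1]); m <- exp(p[2])
    .den_linear(D, signal, mid, m, temp_K)$rss
  }
  best <- NULL
  for (m0 in c(1, 3, 8)) {
    o <- stats::optim(c(log(mid0), log(m0)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 3000))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  mid <- exp(best$par[1]); m <- exp(best$par[2])
  lin <- .den_linear(D, signal, mid, m, temp_K)
  out <- denaturation_params(mid, m, folded = unname(lin$coef[1:2]),
                             unfolded = unname(lin$coef[3:4]),
                             temp_K = temp_K)
  npar <- 6L
  out$rss <- lin$rss
  out$dof <- length(D) - npar

  # numeric Jacobian over (midpoint, m) with baselines re-projected
  resid_of <- function(mid, m) signal - .den_linear(D, signal, mid, m,
                                                    temp_K)$fitted
  h1 <- 1e-6 * mid; h2 <- 1e-6 * m
  J <- cbind((resid_of(mid + h1, m) - resid_of(mid - h1, m)) / (2 * h1),
             (resid_of(mid, m + h2) - resid_of(mid, m - h2)) / (2 * h2))
  sigma2 <- out$rss / out$dof
  cov <- tryCatch(chol2inv(chol(crossprod(J))) * sigma2,
                  error = function(e) matrix(NA_real_, 2, 2))
  out$se <- c(midpoint = sqrt(max(cov[1, 1], 0)),
              m_value = sqrt(max(cov[2, 2], 0)))
  # sanity: the transition must sit inside the data and the baselines
  # must differ where it happens
  amp <- abs(.denaturation_signal(out, mid) -
               (out$folded[1] + out$folded[2] * mid)) * 2
  out$converged <- best$convergence == 0 && mid > min(D) && mid < max(D) &&
    amp > 1e-6 * diff(range(signal))
  out
}

#' Ligand-linked stabilization shift
#'
#' Difference of denaturation midpoints, bound minus apo (M).  The sign is
#' preserved: active-site ligation usually shifts the midpoint up, but a
#' zymogen can be destabilized.
#'
#' @param apo,bound fitted [denaturation_params()].
#' @return shift in M.
#' @export
stabilization_shift <- function(apo, bound) {
  if (isFALSE(apo$converged) || isFALSE(bound$converged))
    stop("both fits must have converged", call. = FALSE)
  bound$midpoint_M - apo$midpoint_M
}

#' Titration parameters (rectangular hyperbola)
#'
#' `F(x) = F0 + dFmax * x / (Kd + x)` for equilibrium fluorescence
#' titration of a monovalent cation (concentrations in mM).
#'
#' @param Kd_mM dissociation constant, mM; > 0.
#' @param F0 signal at zero cation, a.u.
#' @param dFmax maximal signal change, a.u.
#' @return object of class `titration_params`.
#' @export
titration_params <- function(Kd_mM, F0, dFmax) {
  if (Kd_mM <= 0) stop("Kd must be > 0", call. = FALSE)
  structure(list(Kd_mM = Kd_mM, F0 = F0, dFmax = dFmax),
            class = "titration_params")
}

.titration_signal <- function(params, x)
  params$F0 + params$dFmax * x / (params$Kd_mM + x)

#' Fit an equilibrium titration curve
#'
#' Least-squares fit of the rectangular hyperbola
#' `F = F0 + dFmax * x / (Kd + x)`; `F0` and `dFmax` are solved linearly at
#' each trial Kd.  At `x = Kd` the fractional change is half of `dFmax`.
#' A curve with no curvature is flagged, not raised.
#'
#' @param conc_mM cation concentrations, mM (>= 6 points).
#' @param signal fluorescence, a.u.
#' @return a [titration_params()] with `rss`, `dof`, `se` (Kd standard
#'   error) and `converged`.
#' @export
fit_titration <- function(conc_mM, signal) {
  stopifnot(length(conc_mM) == length(signal))
  if (length(conc_mM) < 6) stop("need at least 6 points", call. = FALSE)
  if (any(conc_mM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  ord <- order(conc_mM); x <- conc_mM[ord]; y <- signal[ord]

  lin_at <- function(Kd) {
    X <- cbind(1, x / (Kd + x))
    f <- stats::lm.fit(X, y)
    list(coef = f$coefficients, rss = sum(f$residuals^2),
         fitted = f$fitted.values)
  }
  if (diff(range(y)) < 1e-12 * max(1, abs(mean(y)))) {
    out <- titration_params(max(stats::median(x[x > 0]), 1e-6), mean(y), 0)
    out$rss <- NA_real_; out$dof <- length(x) - 3L
    out$se <- c(Kd = NA_real_); out$converged <- FALSE
    return(out)
  }
  half <- y[1] + (y[length(y)] - y[1]) / 2
  Kd0 <- max(x[which.min(abs(y - half))], min(x[x > 0]))
  obj <- function(lk) lin_at(exp(lk))$rss
  o <- stats::optim(log(Kd0), obj, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 500))
  o2 <- stats::optimize(obj, o$par + c(-1, 1), tol = 1e-12)
  if (o2$objective < o$value)
    o <- list(par = o2$minimum, value = o2$objective, convergence = 0L)
  Kd <- exp(o$par)
  lin <- lin_at(Kd)
  out <- titration_params(Kd, unname(lin$coef[1]), unname(lin$coef[2]))
  out$rss <- lin$rss
  out$dof <- length(x) - 3L
  resid_of <- function(K) y - lin_at(K)$fitted
  h <- 1e-6 * Kd
  J <- cbind((resid_of(Kd + h) - resid_of(Kd - h)) / (2 * h))
  sigma2 <- out$rss / out$dof
  seK <- tryCatch(sqrt(sigma2 / sum(J^2)), error = function(e) NA_real_)
  out$se <- c(Kd = seK)
  # no-curvature guard: the hyperbola must beat a straight line and the
  # saturation must be partly resolved inside the data range
  rss_line <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  out$converged <- o$convergence == 0 && abs(out$dFmax) >
    1e-6 * diff(range(y)) && Kd < 10 * max(x) &&
    (out$rss < rss_line || rss_line < .Machine$double.eps)
  out
}

#' Fold change in binding affinity
#'
#' Ratio of dissociation constants, variant over reference; > 1 means the
#' variant binds more weakly.
#'
#' @param kd_variant,kd_reference dissociation constants (same units); > 0.
#' @return dimensionless ratio.
#' @export
affinity_fold_change <- function(kd_variant, kd_reference) {
  if (kd_variant <= 0 || kd_reference <= 0)
    stop("dissociation constants must be > 0", call. = FALSE)
  kd_variant / kd_reference
}
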