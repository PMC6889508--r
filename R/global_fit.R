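# Global Arrhenius analysis of relaxation profiles and derived binding
# thermodynamics.

#' Arrhenius temperature law for a rate constant
#'
#' Parameterized by the rate `k0` at a reference temperature `T0` and an
#' activation energy `E` (kcal/mol, any sign):
#' `k(T) = k0 * exp(-(E/R) * (1/T - 1/T0))`.
#'
#' @param k0 rate at `T0` (units of the rate constant it describes); > 0.
#' @param E activation energy, kcal/mol.
#' @param T0 reference temperature, K (default 288.15, i.e. 15 C).
#' @return an object of class `arrhenius_law`.
#' @export
arrhenius_law <- function(k0, E, T0 = 288.15) {
  if (k0 <= 0) stop("k0 must be > 0", call. = FALSE)
  if (T0 <= 0) stop("T0 must be > 0", call. = FALSE)
  structure(list(k0 = k0, E = E, T0 = T0), class = "arrhenius_law")
}

#' Evaluate an Arrhenius law
#'
#' @param law an [arrhenius_law()].
#' @param T temperature, K (vectorized, all > 0).
#' @return rate constant(s) at `T`.
#' @export
arrhenius_eval <- function(law, T) {
  stopifnot(inherits(law, "arrhenius_law"))
  if (any(T <= 0)) stop("temperature must be > 0", call. = FALSE)
  law$k0 * exp(-(law$E / R_KCAL) * (1 / T - 1 / law$T0))
}

#' Construct a global kinetic model
#'
#' Bundle of one Arrhenius law per rate constant of a binding mechanism.
#' For conformational selection (`kind = "cs"`) laws are required for
#' `k12`, `k21`, `kon`, `koff`; for lock and key (`kind = "lk"`), for
#' `kon` and `koff`.  All laws must share the same reference temperature.
#'
#' @param kind `"cs"` or `"lk"`.
#' @param laws named list of [arrhenius_law()] objects.
#' @param diagnostics optional fit diagnostics (attached by [fit_global()]).
#' @return an object of class `global_kinetic_model`.
#' @export
global_kinetic_model <- function(kind = c("cs", "lk"), laws,
                                 diagnostics = NULL) {
  kind <- match.arg(kind)
  need <- if (kind == "cs") c("k12", "k21", "kon", "koff") else c("kon", "koff")
  if (!all(need %in% names(laws)))
    stop("laws must be named ", paste(need, collapse = ", "), call. = FALSE)
  laws <- laws[need]
  T0s <- vapply(laws, `[[`, numeric(1), "T0")
  if (length(unique(T0s)) != 1)
    stop("all laws must share the same reference temperature", call. = FALSE)
  structure(list(kind = kind, laws = laws, T0 = T0s[[1]],
                 diagnostics = diagnostics),
            class = "global_kinetic_model")
}

#' @export
print.global_kinetic_model <- function(x, ...) {
  cat(sprintf("<global_kinetic_model: %s, T0 = %g K>\n",
              toupper(x$kind), x$T0))
  for (nm in names(x$laws))
    cat(sprintf("  %-5s k0 = %-10.4g E = %.4g kcal/mol\n",
                nm, x$laws[[nm]]$k0, x$laws[[nm]]$E))
  if (!is.null(x$diagnostics))
    cat(sprintf("  RSS = %.4g on %d dof, converged = %s\n",
                x$diagnostics$rss, x$diagnostics$dof,
                x$diagnostics$converged))
  invisible(x)
}

#' Instantiate the mechanism of a global model at a temperature
#'
#' @param model a [global_kinetic_model()].
#' @param T temperature, K.
#' @return a [mechanism_cs()] or [mechanism_lk()].
#' @export
mechanism_at <- function(model, T) {
  k <- lapply(model$laws, arrhenius_eval, T = T)
  if (model$kind == "cs")
    mechanism_cs(k$k12, k$k21, k$kon, k$koff)
  else
    mechanism_lk(k$kon, k$koff)
}

# Predicted relaxation rates for one profile row.  Rates are clamped away
# from zero so optimizer excursions cannot underflow the constructors.
.predict_alphas <- function(model, L, T) {
  k <- lapply(model$laws, function(l) {
    max(min(arrhenius_eval(l, T), 1e300), 1e-300)
  })
  if (model$kind == "lk") {
    m <- mechanism_lk(k$kon, k$koff)
    c(lk_relaxation(m, L), NA_real_)
  } else {
    m <- mechanism_cs(k$k12, k$k21, k$kon, k$koff)
    r <- cs_relaxations(m, L)
    c(r$alpha1, r$alpha2)
  }
}

# theta <-> model packing (log-scale for k0, linear for E)
.theta_names <- function(kind) {
  rates <- if (kind == "cs") c("k12", "k21", "kon", "koff") else c("kon", "koff")
  c(paste0("log_", rates), paste0("E_", rates))
}

.theta_to_model <- function(theta, kind, T0) {
  theta <- unname(theta)
  nr <- length(theta) / 2
  # clamp against under/overflow while the optimizer explores
  k0 <- pmin(pmax(exp(theta[seq_len(nr)]), 1e-300), 1e300)
  E <- theta[nr + seq_len(nr)]
  rates <- if (kind == "cs") c("k12", "k21", "kon", "koff") else c("kon", "koff")
  laws <- stats::setNames(
    lapply(seq_len(nr), function(i) arrhenius_law(k0[i], E[i], T0)), rates)
  global_kinetic_model(kind, laws)
}

# Residual vector of a parameter vector against the observed profile.
.global_residuals <- function(theta, profile, kind, T0) {
  model <- .theta_to_model(theta, kind, T0)
  res <- numeric(0)
  for (i in seq_len(nrow(profile))) {
    pred <- .predict_alphas(model, profile$ligand_uM[i], profile$temp_K[i])
    obs1 <- profile$alpha1_s[i]
    obs2 <- profile$alpha2_s[i]
    if (kind == "lk") {
      res <- c(res, obs1 - pred[1])
    } else if (!is.na(obs2)) {
      res <- c(res, obs1 - pred[1], obs2 - pred[2])
    } else {
      # single observed relaxation on a two-relaxation scheme: attribute it
      # to whichever predicted rate it is closest to
      res <- c(res, obs1 - pred[which.min(abs(pred - obs1))])
    }
  }
  res
}

# Arrhenius regression of per-temperature rate estimates -> (log k0, E) init.
.arrhenius_init <- function(temps, k, T0) {
  ok <- is.finite(k) & k > 0
  if (sum(ok) < 2) return(c(log(stats::median(k[ok], na.rm = TRUE)), 0))
  x <- 1 / temps[ok] - 1 / T0
  fit <- stats::lm(log(k[ok]) ~ x)
  c(unname(stats::coef(fit)[1]), -R_KCAL * unname(stats::coef(fit)[2]))
}

# Per-temperature LK estimates: alpha = koff + kon * L.
.lk_temp_estimates <- function(profile) {
  out <- lapply(split(profile, profile$temp_K), function(d) {
    if (length(unique(d$ligand_uM)) < 2) return(NULL)
    co <- stats::coef(stats::lm(alpha1_s ~ ligand_uM, data = d))
    data.frame(temp_K = d$temp_K[1],
               kon = max(co[2], 1e-8), koff = max(co[1], 1e-8))
  })
  do.call(rbind, out)
}

# Per-temperature CS estimates from the sum/product identities
#   alpha1 + alpha2 = (k12 + k21 + koff) + kon * L
#   alpha1 * alpha2 = (k12 + k21) * koff + (k12 * kon) * L
# The intercept pair (c1, c2) determines {koff, k12 + k21} as the roots of
# x^2 - (c1 - kon L term...)  -- two orderings, both returned as candidates.
.cs_temp_estimates <- function(profile) {
  res <- lapply(split(profile, profile$temp_K), function(d) {
    d <- d[d$n_exp == 2 & is.finite(d$alpha2_s), , drop = FALSE]
    if (nrow(d) < 3 || length(unique(d$ligand_uM)) < 3) return(NULL)
    s <- d$alpha1_s + d$alpha2_s
    p <- d$alpha1_s * d$alpha2_s
    cs <- stats::coef(stats::lm(s ~ d$ligand_uM))
    cp <- stats::coef(stats::lm(p ~ d$ligand_uM))
    kon <- max(cs[2], 1e-8)
    k12 <- max(cp[2] / kon, 1e-8)
    c1 <- max(cs[1], 1e-8)   # k12 + k21 + koff
    c2 <- max(cp[1], 1e-8)   # (k12 + k21) * koff
    disc <- c1^2 - 4 * c2
    roots <- if (disc >= 0) sort((c1 + c(-1, 1) * sqrt(disc)) / 2)
             else rep(c1 / 2, 2)
    cand <- lapply(1:2, function(j) {
      koff <- roots[j]; ex <- c1 - koff   # k12 + k21
      k21 <- ex - k12
      if (koff <= 0 || k21 <= 0) return(NULL)
      data.frame(temp_K = d$temp_K[1], k12 = k12, k21 = k21,
                 kon = kon, koff = koff, branch = j)
    })
    do.call(rbind, cand)
  })
  do.call(rbind, res)
}

#' Globally fit a relaxation profile with Arrhenius-parameterized rates
#'
#' Simultaneous unweighted least-squares fit of all observed relaxation
#' rates (all ligand concentrations and temperatures at once), with each
#' rate constant of the chosen mechanism expressed through an
#' [arrhenius_law()] anchored at `T0`.  Initialization is analytic
#' (per-temperature linear regressions followed by Arrhenius regression),
#' then polished numerically.
#'
#' @param profile data.frame as produced by [extract_relaxation_profile()].
#' @param kind `"cs"` or `"lk"`.
#' @param T0 reference temperature, K.
#' @return a [global_kinetic_model()] with `diagnostics` (rss, dof,
#'   standard errors, covariance, convergence flag).
#' @export
fit_global <- function(profile, kind = c("cs", "lk"), T0 = 288.15) {
  kind <- match.arg(kind)
  if (length(unique(profile$temp_K)) < 2)
    stop("profile must span at least 2 temperatures (activation energies ",
         "are unidentifiable at a single temperature)", call. = FALSE)
  if (length(unique(profile$ligand_uM)) < 2)
    stop("profile must span at least 2 ligand concentrations", call. = FALSE)

  starts <- list()
  if (kind == "lk") {
    est <- .lk_temp_estimates(profile)
    th <- c(.arrhenius_init(est$temp_K, est$kon, T0),
            .arrhenius_init(est$temp_K, est$koff, T0))
    starts[[1]] <- c(th[1], th[3], th[2], th[4])  # log kon, log koff, Eon, Eoff
  } else {
    est <- .cs_temp_estimates(profile)
    if (is.null(est) || nrow(est) == 0)
      stop("profile has too few double-exponential rows for a CS fit",
           call. = FALSE)
    for (b in unique(est$branch)) {
      e <- est[est$branch == b, , drop = FALSE]
      th <- c(.arrhenius_init(e$temp_K, e$k12, T0),
              .arrhenius_init(e$temp_K, e$k21, T0),
              .arrhenius_init(e$temp_K, e$kon, T0),
              .arrhenius_init(e$temp_K, e$koff, T0))
      starts[[length(starts) + 1]] <- c(th[c(1, 3, 5, 7)], th[c(2, 4, 6, 8)])
    }
  }

  obj <- function(theta) sum(.global_residuals(theta, profile, kind, T0)^2)
  best <- NULL
  for (th0 in starts) {
    if (any(!is.finite(th0))) next
    o1 <- stats::optim(th0, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-15, maxit = 5000))
    o2 <- stats::optim(o1$par, obj, method = "BFGS",
                       control = list(reltol = 1e-15, maxit = 1000))
    o <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("global fit failed to start", call. = FALSE)

  theta <- best$par
  names(theta) <- .theta_names(kind)
  r <- .global_residuals(theta, profile, kind, T0)
  dof <- length(r) - length(theta)
  # numeric Jacobian for the covariance of the estimates
  J <- vapply(seq_along(theta), function(j) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (.global_residuals(tp, profile, kind, T0) -
       .global_residuals(tm, profile, kind, T0)) / (2 * h)
  }, numeric(length(r)))
  sigma2 <- if (dof > 0) sum(r^2) / dof else NA_real_
  cov <- tryCatch(chol2inv(chol(crossprod(J))) * sigma2,
                  error = function(e) matrix(NA_real_, length(theta),
                                             length(theta)))
  se_theta <- sqrt(pmax(diag(cov), 0))
  nr <- length(theta) / 2
  # delta method: se(k0) = k0 * se(log k0)
  se <- c(exp(theta[seq_len(nr)]) * se_theta[seq_len(nr)],
          se_theta[nr + seq_len(nr)])
  names(se) <- sub("^log_", "k0_", names(theta))

  model <- .theta_to_model(theta, kind, T0)
  model$diagnostics <- list(rss = sum(r^2), dof = dof, se = se,
                            covariance = cov,
                            converged = best$convergence == 0)
  model
}

#' Binding thermodynamics from a global kinetic model
#'
#' Equilibrium dissociation constant and thermodynamic decomposition at a
#' chosen temperature:
#' `Kd = koff/kon` (uM), `dG = R T ln(Kd in M)` (kcal/mol),
#' `dH = Eon - Eoff` (kcal/mol), `dS = (dH - dG)/T * 1000` (cal/mol/K).
#' The identity `dG = dH - T dS` holds by construction.
#'
#' @param model a [global_kinetic_model()] (any kind; uses kon/koff laws).
#' @param T evaluation temperature, K (default: the model's T0).
#' @return object of class `thermo_summary`: list with `Kd_uM`,
#'   `dG_kcal`, `dH_kcal`, `dS_cal`, `T`.
#' @export
derive_thermo <- function(model, T = model$T0) {
  kon <- arrhenius_eval(model$laws$kon, T)
  koff <- arrhenius_eval(model$laws$koff, T)
  Kd_uM <- koff / kon
  dG <- R_KCAL * T * log(Kd_uM * 1e-6)   # standard state 1 M
  dH <- model$laws$kon$E - model$laws$koff$E
  dS <- (dH - dG) / T * 1000
  structure(list(Kd_uM = Kd_uM, dG_kcal = dG, dH_kcal = dH, dS_cal = dS,
                 T = T),
            class = "thermo_summary")
}

#' @export
print.thermo_summary <- function(x, ...) {
  cat(sprintf("<thermo_summary at %g K>\n", x$T))
  cat(sprintf("  Kd = %.3g uM   dG = %.3g kcal/mol\n", x$Kd_uM, x$dG_kcal))
  cat(sprintf("  dH = %.3g kcal/mol   dS = %.3g cal/mol/K\n",
              x$dH_kcal, x$dS_cal))
  invisible(x)
}

# Saturating-vs-linear comparison of alpha2 against L at one temperature:
# variable-projection fit of a + b*exp(-L/tau) over a log grid of tau.
.saturation_test <- function(L, alpha2) {
  lin <- stats::lm(alpha2 ~ L)
  rss_lin <- sum(stats::residuals(lin)^2)
  span <- diff(range(L))
  taus <- exp(seq(log(span / 50), log(span * 5), length.out = 40))
  rss_sat <- Inf
  for (tau in taus) {
    X <- cbind(1, exp(-L / tau))
    f <- stats::lm.fit(X, alpha2)
    rss <- sum(f$residuals^2)
    if (rss < rss_sat) rss_sat <- rss
  }
  dof2 <- length(L) - 3
  if (dof2 <= 0) return(list(F = NA_real_, p = NA_real_,
                             rss_lin = rss_lin, rss_sat = rss_sat))
  den <- rss_sat / dof2
  Fst <- if (den <= .Machine$double.eps * max(rss_lin, 1)) {
    if (rss_lin > rss_sat * (1 + 1e-6) + .Machine$double.eps) Inf else 0
  } else (rss_lin - rss_sat) / den
  list(F = Fst, p = stats::pf(Fst, 1, dof2, lower.tail = FALSE),
       rss_lin = rss_lin, rss_sat = rss_sat)
}

#' Discriminate conformational selection from lock and key
#'
#' Classifies a relaxation profile as conformational selection (`"cs"`)
#' when a second, saturating relaxation is established: a majority of
#' conditions require two exponentials, and the slow rate's dependence on
#' ligand concentration is fit significantly better by a saturating curve
#' than by a straight line.  Otherwise the profile is lock and key
#' (`"lk"`): a single relaxation, linear in ligand.
#'
#' @param profile a relaxation profile data.frame.
#' @param alpha_level significance level for the per-temperature
#'   saturation test.
#' @return list with `kind` ("cs"/"lk"), `confidence` ("high"/"low"),
#'   and `evidence` (fraction of double-exponential rows and the
#'   per-temperature saturation statistics).
#' @export
discriminate_mechanism <- function(profile, alpha_level = 0.01) {
  if (nrow(profile) < 2) {
    return(list(kind = "lk", confidence = "low",
                evidence = list(frac_double = NA_real_,
                                note = "too few conditions to resolve saturation")))
  }
  frac2 <- mean(profile$n_exp == 2)
  if (frac2 <= 0.5) {
    return(list(kind = "lk",
                confidence = if (nrow(profile) >= 6) "high" else "low",
                evidence = list(frac_double = frac2)))
  }
  d2 <- profile[profile$n_exp == 2 & is.finite(profile$alpha2_s), ,
                drop = FALSE]
  tests <- lapply(split(d2, d2$temp_K), function(d) {
    if (nrow(d) < 4 || length(unique(d$ligand_uM)) < 4) return(NULL)
    st <- .saturation_test(d$ligand_uM, d$alpha2_s)
    data.frame(temp_K = d$temp_K[1], F = st$F, p = st$p,
               rss_lin = st$rss_lin, rss_sat = st$rss_sat)
  })
  tab <- do.call(rbind, tests)
  if (is.null(tab) || nrow(tab) == 0) {
    return(list(kind = "cs", confidence = "low",
                evidence = list(frac_double = frac2,
                                note = "saturation untestable per temperature")))
  }
  # pool the per-temperature tests with Fisher's method; a single
  # temperature rarely has the points to reject linearity on its own
  pv <- pmin(pmax(tab$p[is.finite(tab$p)], 1e-300), 1)
  p_comb <- stats::pchisq(-2 * sum(log(pv)), df = 2 * length(pv),
                          lower.tail = FALSE)
  list(kind = if (p_comb < alpha_level) "cs" else "lk",
       confidence = "high",
       evidence = list(frac_double = frac2, saturation = tab,
                       p_combined = p_comb))
}
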