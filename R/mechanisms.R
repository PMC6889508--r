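# Binding mechanisms and closed-form relaxation kinetics.
#
# Units package-wide: concentrations in uM (molar only inside free-energy
# terms), time in s, first-order rates in 1/s, second-order rates in
# 1/(uM s), temperatures in K, energies in kcal/mol.

#' Gas constant in kcal/mol/K
#'
#' Used throughout for Arrhenius laws, binding free energies and two-state
#' unfolding.
#' @export
R_KCAL <- 1.9872e-3

#' Conformational-selection mechanism
#'
#' Two-step linear scheme E* <-> E <-> E:L in which the ligand binds only
#' the open conformation E of a pre-equilibrating E*/E pair.  `k12` is the
#' E* -> E rate, `k21` the E -> E* rate (both 1/s), `kon` the second-order
#' association rate (1/(uM s)) and `koff` the dissociation rate (1/s).
#' The ratio k21/k12 sets the E*:E partition at zero ligand.
#'
#' @param k12,k21 conformational exchange rates, 1/s; must be >= 0.
#' @param kon association rate constant, 1/(uM s); must be > 0.
#' @param koff dissociation rate constant, 1/s; must be > 0.
#' @return an object of class `mechanism_cs`.
#' @examples
#' m <- mechanism_cs(k12 = 2, k21 = 8, kon = 1, koff = 5)
#' cs_relaxations(m, L = 10)
#' @export
mechanism_cs <- function(k12, k21, kon, koff) {
  stopifnot(is.numeric(k12), is.numeric(k21), is.numeric(kon), is.numeric(koff))
  if (any(c(k12, k21, kon, koff) < 0))
    stop("all rate constants must be >= 0", call. = FALSE)
  if (kon <= 0 || koff <= 0)
    stop("kon and koff must be > 0 for a binding-competent scheme",
         call. = FALSE)
  structure(list(k12 = k12, k21 = k21, kon = kon, koff = koff),
            class = c("mechanism_cs", "mechanism"))
}

#' Lock-and-key mechanism
#'
#' One-step rigid-body binding E + L <-> E:L with a single relaxation
#' linear in ligand concentration.
#'
#' @param kon association rate constant, 1/(uM s); must be > 0.
#' @param koff dissociation rate constant, 1/s; must be >= 0.
#' @return an object of class `mechanism_lk`.
#' @export
mechanism_lk <- function(kon, koff) {
  stopifnot(is.numeric(kon), is.numeric(koff))
  if (kon <= 0) stop("kon must be > 0", call. = FALSE)
  if (koff < 0) stop("koff must be >= 0", call. = FALSE)
  structure(list(kon = kon, koff = koff),
            class = c("mechanism_lk", "mechanism"))
}

#' @export
print.mechanism <- function(x, ...) {
  kind <- if (inherits(x, "mechanism_cs")) "conformational selection" else
    "lock and key"
  cat("<mechanism:", kind, ">\n")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}

#' Species labels of a mechanism
#'
#' `c("Estar", "E", "EL")` for conformational selection, `c("E", "EL")`
#' for lock and key.
#' @param m a mechanism object.
#' @return character vector of species names.
#' @export
species <- function(m) {
  if (inherits(m, "mechanism_cs")) c("Estar", "E", "EL") else c("E", "EL")
}

#' Relaxation rates of the conformational-selection scheme
#'
#' Closed-form pair of relaxation rates for the linear three-state scheme
#' under pseudo-first-order conditions (ligand in large excess over the
#' macromolecule):
#'
#'   2 alpha_{1,2} = k12 + k21 + kon L + koff
#'                   +/- sqrt((kon L + koff - k12 - k21)^2 + 4 k21 kon L)
#'
#' The fast relaxation alpha1 (+ root) reflects binding and grows linearly
#' with L at high ligand; the slow relaxation alpha2 (- root) saturates to
#' k12 and reflects the conformational transition.
#'
#' @param m a `mechanism_cs`.
#' @param L ligand concentration, uM; must be >= 0 (vectorized).
#' @return a list with `alpha1`, `alpha2` (same length as `L`) and a
#'   `degenerate` flag set when the discriminant vanishes (alpha1 == alpha2).
#' @export
cs_relaxations <- function(m, L) {
  stopifnot(inherits(m, "mechanism_cs"))
  if (any(L < 0)) stop("ligand concentration must be >= 0", call. = FALSE)
  s <- m$k12 + m$k21 + m$kon * L + m$koff
  disc <- (m$kon * L + m$koff - m$k12 - m$k21)^2 + 4 * m$k21 * m$kon * L
  d <- sqrt(disc)
  a1 <- (s + d) / 2
  # the (s - d)/2 form cancels catastrophically at high L; the product of
  # the roots, alpha1 * alpha2 = (k12 + k21) koff + k12 kon L, is exact
  prod <- (m$k12 + m$k21) * m$koff + m$k12 * m$kon * L
  a2 <- ifelse(a1 > 0, prod / a1, (s - d) / 2)
  list(alpha1 = a1, alpha2 = a2, degenerate = any(d == 0))
}

#' Relaxation rate of the lock-and-key scheme
#'
#' Single relaxation alpha1 = koff + kon * L, the k12 = k21 = 0 limit of
#' the conformational-selection expression.
#'
#' @param m a `mechanism_lk`.
#' @param L ligand concentration, uM; >= 0 (vectorized).
#' @return numeric vector of relaxation rates, 1/s.
#' @export
lk_relaxation <- function(m, L) {
  stopifnot(inherits(m, "mechanism_lk"))
  if (any(L < 0)) stop("ligand concentration must be >= 0", call. = FALSE)
  m$koff + m$kon * L
}

#' First-order generator matrix of a mechanism
#'
#' Linearization of the scheme under pseudo-first-order conditions: a
#' column generator matrix K with K[i, j] the rate from species j to
#' species i, columns summing to zero.  The nonzero eigenvalue magnitudes
#' of K are the closed-form relaxation rates.
#'
#' @param m a mechanism object.
#' @param L ligand concentration, uM (scalar >= 0).
#' @return square numeric matrix with dimnames from [species()].
#' @export
rate_matrix <- function(m, L) {
  stopifnot(length(L) == 1L)
  if (L < 0) stop("ligand concentration must be >= 0", call. = FALSE)
  if (inherits(m, "mechanism_cs")) {
    b <- m$kon * L
    K <- matrix(c(     0,  m$k21,       0,
                  m$k12,       0,  m$koff,
                       0,      b,       0),
                nrow = 3, byrow = TRUE)
  } else {
    b <- m$kon * L
    K <- matrix(c(0, m$koff,
                  b, 0), nrow = 2, byrow = TRUE)
  }
  # diagonal as the exact negation of each column's outflow, so columns
  # sum to zero exactly in floating point
  diag(K) <- -colSums(K)
  dimnames(K) <- list(species(m), species(m))
  K
}

#' Equilibrium species populations
#'
#' Stationary distribution of the scheme at ligand concentration `L`
#' (the normalized null vector of [rate_matrix()]), computed from detailed
#' balance: E*:E = k21:k12 and E:L / E = kon L / koff.
#'
#' @param m a `mechanism_cs` or `mechanism_lk`.
#' @param L ligand concentration, uM (scalar >= 0).
#' @return named numeric vector of fractions summing to 1.
#' @export
equilibrium_populations <- function(m, L) {
  stopifnot(length(L) == 1L)
  if (L < 0) stop("ligand concentration must be >= 0", call. = FALSE)
  if (inherits(m, "mechanism_lk")) {
    w <- c(E = 1, EL = m$kon * L / m$koff)
    return(w / sum(w))
  }
  if (m$k12 == 0 && m$k21 == 0)
    stop("degenerate scheme: k12 = k21 = 0 has no unique E*/E equilibrium",
         call. = FALSE)
  if (m$k12 == 0) {
    # E* is absorbing: everything drains into the closed form
    return(c(Estar = 1, E = 0, EL = 0))
  }
  w <- c(Estar = m$k21 / m$k12, E = 1, EL = m$kon * L / m$koff)
  w / sum(w)
}

#' Fluorescence observable model
#'
#' Per-species fluorescence coefficients and the population distribution at
#' the moment of mixing.  Defaults mimic quenching on binding (bound complex
#' at 0.7 of the free-enzyme yield) and start the system at the zero-ligand
#' conformational equilibrium, which is what a stopped-flow mix against
#' ligand produces.
#'
#' @param coefficients named numeric vector of per-species fluorescence
#'   yields (a.u. per unit population); names must match [species()] of the
#'   mechanism it is used with.  `NULL` picks the quenching default.
#' @param p0 initial population distribution (same names), nonnegative,
#'   summing to 1; `NULL` defers to the zero-ligand equilibrium of the
#'   mechanism at simulation time.
#' @return an object of class `observable_model`.
#' @export
observable_model <- function(coefficients = NULL, p0 = NULL) {
  if (!is.null(p0)) {
    if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
      stop("initial populations must be >= 0 and sum to 1", call. = FALSE)
  }
  if (!is.null(coefficients) && length(unique(coefficients)) < 2)
    stop("at least two species need distinct coefficients (no signal change)",
         call. = FALSE)
  structure(list(coefficients = coefficients, p0 = p0),
            class = "observable_model")
}

default_coefficients <- function(m) {
  if (inherits(m, "mechanism_cs")) c(Estar = 1.0, E = 1.0, EL = 0.7)
  else c(E = 1.0, EL = 0.7)
}

resolve_observable <- function(m, obs) {
  co <- obs$coefficients
  if (is.null(co)) co <- default_coefficients(m)
  co <- co[species(m)]
  if (anyNA(co)) stop("coefficients must cover all species of the mechanism",
                      call. = FALSE)
  p0 <- obs$p0
  if (is.null(p0)) {
    p0 <- if (inherits(m, "mechanism_cs")) equilibrium_populations(m, 0)
          else c(E = 1, EL = 0)
  }
  p0 <- p0[species(m)]
  if (anyNA(p0)) stop("p0 must cover all species of the mechanism",
                      call. = FALSE)
  list(coefficients = co, p0 = p0)
}

#' Stopped-flow trace container
#'
#' @param time seconds, strictly increasing, all >= `dead_time`.
#' @param signal fluorescence, arbitrary units, same length as `time`.
#' @param ligand_uM ligand concentration after mixing, uM.
#' @param temp_K temperature, K.
#' @param dead_time_s instrument dead time, s (points before it are
#'   unobservable).
#' @return an object of class `sf_trace` (a list).
#' @export
sf_trace <- function(time, signal, ligand_uM, temp_K, dead_time_s = 0) {
  if (length(time) != length(signal) || length(time) < 10)
    stop("time and signal must have equal length >= 10", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing",
                                 call. = FALSE)
  if (time[1] < dead_time_s)
    stop("time grid must start at or after the dead time", call. = FALSE)
  if (ligand_uM < 0 || dead_time_s < 0 || temp_K <= 0)
    stop("invalid trace metadata", call. = FALSE)
  structure(list(time = as.numeric(time), signal = as.numeric(signal),
                 ligand_uM = ligand_uM, temp_K = temp_K,
                 dead_time_s = dead_time_s),
            class = "sf_trace")
}

#' @export
print.sf_trace <- function(x, ...) {
  cat(sprintf("<sf_trace: %d pts, [L] = %g uM, T = %g K, dead time %g s>\n",
              length(x$time), x$ligand_uM, x$temp_K, x$dead_time_s))
  invisible(x)
}

# Propagate populations exactly: p(t) = expm(K t) p0, evaluated through the
# eigendecomposition of K when it is well conditioned, otherwise through
# Matrix::expm per time point (degenerate relaxations).
propagate_populations <- function(K, p0, time) {
  eg <- eigen(K)
  V <- eg$vectors
  use_eigen <- !is.complex(eg$values) &&
    abs(det(V)) > 1e-12 && kappa(V) < 1e10
  if (use_eigen) {
    c0 <- solve(V, p0)
    P <- vapply(time,
                function(t) Re(V %*% (exp(eg$values * t) * c0))[, 1],
                numeric(length(p0)))
  } else {
    P <- vapply(time,
                function(t) as.numeric(Matrix::expm(K * t) %*% p0),
                numeric(length(p0)))
  }
  P  # species x time
}

#' Simulate a stopped-flow fluorescence transient
#'
#' Exact propagation of the species populations under the generator matrix
#' of the mechanism (matrix exponential), projected onto the fluorescence
#' coefficients of `obs`.  Time points earlier than the dead time are
#' censored (dropped), not convolved.
#'
#' @param m a mechanism object.
#' @param obs an [observable_model()]; `NULL` for the defaults.
#' @param L ligand concentration after mixing, uM.
#' @param time_grid positive increasing time points, s.
#' @param temp_K temperature annotation for the trace, K.
#' @param dead_time_s instrument dead time, s.
#' @return an [sf_trace()].
#' @export
simulate_trace <- function(m, obs = NULL, L, time_grid, temp_K = 288.15,
                           dead_time_s = 0) {
  if (is.null(obs)) obs <- observable_model()
  ro <- resolve_observable(m, obs)
  if (any(diff(time_grid) <= 0) || any(time_grid < 0))
    stop("time grid must be positive increasing", call. = FALSE)
  keep <- time_grid >= dead_time_s
  if (sum(keep) < 10)
    stop("fewer than 10 points survive dead-time censoring", call. = FALSE)
  tt <- time_grid[keep]
  K <- rate_matrix(m, L)
  P <- propagate_populations(K, ro$p0, tt)
  sig <- as.numeric(crossprod(ro$coefficients, P))
  out <- sf_trace(tt, sig, ligand_uM = L, temp_K = temp_K,
                  dead_time_s = dead_time_s)
  attr(out, "populations") <- t(P)
  out
}
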