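# Seeded synthetic-data generators: the stand-in for the stopped-flow
# instrument and the equilibrium fluorimeter.

#' Additive Gaussian noise model
#'
#' Homoscedastic noise whose standard deviation is a fraction of the total
#' signal change of the curve it is applied to.  Identical seeds give
#' identical output.
#'
#' @param sd_frac standard deviation as a fraction of the signal range
#'   (>= 0; 0 means noiseless).
#' @param seed integer RNG seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sd_frac = 0, seed = 1L) {
  if (sd_frac < 0) stop("sd_frac must be >= 0", call. = FALSE)
  structure(list(sd_frac = sd_frac, seed = as.integer(seed)),
            class = "noise_model")
}

.apply_noise <- function(signal, noise) {
  if (noise$sd_frac == 0) return(signal)
  sd <- noise$sd_frac * diff(range(signal))
  signal + stats::rnorm(length(signal), 0, sd)
}

#' Stopped-flow experiment design
#'
#' The grid of conditions emulated by [gen_stopped_flow_dataset()].
#' Defaults follow the published design: six temperatures from 5 to 30 C
#' in 5 K steps, ligand in the tens of uM (pseudo-first-order excess over
#' a ~0.2 uM macromolecule), a 1 ms dead time, and a logarithmic time grid
#' to resolve fast phases.
#'
#' @param ligand_uM ligand concentrations, uM.
#' @param temp_K temperatures, K.
#' @param points points per trace.
#' @param duration_s trace duration, s; must exceed the dead time.
#' @param dead_time_s instrument dead time, s.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(ligand_uM = c(5, 10, 20, 30, 45, 60),
                              temp_K = seq(278.15, 303.15, by = 5),
                              points = 200,
                              duration_s = 1,
                              dead_time_s = 1e-3) {
  if (length(ligand_uM) == 0 || length(temp_K) == 0)
    stop("condition grids must be nonempty", call. = FALSE)
  if (duration_s <= dead_time_s)
    stop("duration must exceed the dead time", call. = FALSE)
  structure(list(ligand_uM = ligand_uM, temp_K = temp_K, points = points,
                 duration_s = duration_s, dead_time_s = dead_time_s),
            class = "experiment_design")
}

.time_grid <- function(design) {
  t0 <- max(design$dead_time_s, 1e-6)
  exp(seq(log(t0), log(design$duration_s), length.out = design$points))
}

#' Generate a synthetic stopped-flow dataset
#'
#' One trace per (ligand, temperature) cell, simulated exactly under the
#' mechanism of `model` with rate constants evaluated through the Arrhenius
#' laws at each temperature, then corrupted by seeded additive Gaussian
#' noise.  The RNG state is set once from the noise seed, so the full
#' dataset is reproducible bit-for-bit.
#'
#' @param model a [global_kinetic_model()].
#' @param obs an [observable_model()] or `NULL` for the defaults.
#' @param design an [experiment_design()].
#' @param noise a [noise_model()].
#' @return list of [sf_trace()] objects, ordered temperature-major.
#' @export
gen_stopped_flow_dataset <- function(model, obs = NULL,
                                     design = experiment_design(),
                                     noise = noise_model()) {
  stopifnot(inherits(model, "global_kinetic_model"),
            inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  tt <- .time_grid(design)
  set.seed(noise$seed)
  traces <- list()
  for (T in design$temp_K) {
    m <- mechanism_at(model, T)
    for (L in design$ligand_uM) {
      tr <- simulate_trace(m, obs, L, tt, temp_K = T,
                           dead_time_s = design$dead_time_s)
      tr$signal <- .apply_noise(tr$signal, noise)
      attr(tr, "populations") <- NULL
      traces[[length(traces) + 1]] <- tr
    }
  }
  traces
}

#' Generate a synthetic denaturation curve
#'
#' LEM two-state signal plus seeded additive Gaussian noise.
#'
#' @param params a [denaturation_params()].
#' @param grid denaturant concentrations, M; default spans both baselines
#'   around the midpoint.
#' @param noise a [noise_model()].
#' @return data.frame with columns `den_M`, `signal` and attribute
#'   `temp_K`.
#' @export
gen_denaturation_curve <- function(params,
                                   grid = seq(0, params$midpoint_M + 2,
                                              length.out = 30),
                                   noise = noise_model()) {
  if (length(grid) == 0) stop("empty denaturant grid", call. = FALSE)
  set.seed(noise$seed)
  sig <- .apply_noise(.denaturation_signal(params, grid), noise)
  out <- data.frame(den_M = grid, signal = sig)
  attr(out, "temp_K") <- params$temp_K
  out
}

#' Generate a synthetic titration curve
#'
#' Rectangular-hyperbola signal plus seeded additive Gaussian noise.
#'
#' @param params a [titration_params()].
#' @param grid cation concentrations, mM; default spans 0.1x to 16x Kd.
#' @param noise a [noise_model()].
#' @return data.frame with columns `na_mM`, `signal`.
#' @export
gen_titration_curve <- function(params,
                                grid = params$Kd_mM *
                                  c(0, 0.1, 0.2, 0.5, 1, 2, 4, 8, 16),
                                noise = noise_model()) {
  if (length(grid) == 0) stop("empty concentration grid", call. = FALSE)
  set.seed(noise$seed)
  sig <- .apply_noise(.titration_signal(params, grid), noise)
  data.frame(na_mM = grid, signal = sig)
}
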