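# Published reference values for FPR binding to thrombin variants and the
# zymogen prethrombin-2, used as generator inputs and reporting checks.

#' Published FPR-binding kinetic constants for thrombin variants
#'
#' Stopped-flow rate constants (at the reference temperature 288.15 K) and
#' Arrhenius activation energies for binding of the active-site probe FPR
#' (H-D-Phe-Pro-Arg-p-nitroanilide) to the zymogen prethrombin-2 and the
#' thrombin mutants I16T and D194A (all on the S195A background), plus the
#' wild-type rate constants for comparison (no activation energies were
#' reported for wild type).  All three variants bind by a single-relaxation
#' lock-and-key mechanism.
#'
#' @return data.frame with columns `variant`, `koff0_s` (1/s), `kon0_uMs`
#'   (1/(uM s)), `Eoff_kcal`, `Eon_kcal` (kcal/mol), and `T0_K`.
#' @export
fpr_kinetic_constants <- function() {
  data.frame(
    variant = c("prethrombin2", "I16T", "D194A", "wt"),
    koff0_s = c(46, 29, 7.8, 0.6),
    kon0_uMs = c(0.46, 0.73, 1.6, 2.6),
    Eoff_kcal = c(17, 23, 13, NA),
    Eon_kcal = c(8.6, 3.0, 8.9, NA),
    T0_K = 288.15
  )
}

#' Lock-and-key Arrhenius model for a published variant
#'
#' Convenience constructor building a [global_kinetic_model()] from the
#' printed constants of [fpr_kinetic_constants()].
#'
#' @param variant one of `"prethrombin2"`, `"I16T"`, `"D194A"`.
#' @return a [global_kinetic_model()] of kind `"lk"`.
#' @export
variant_lk_model <- function(variant = c("prethrombin2", "I16T", "D194A")) {
  variant <- match.arg(variant)
  tab <- fpr_kinetic_constants()
  row <- tab[tab$variant == variant, ]
  global_kinetic_model("lk", list(
    kon = arrhenius_law(row$kon0_uMs, row$Eon_kcal, row$T0_K),
    koff = arrhenius_law(row$koff0_s, row$Eoff_kcal, row$T0_K)))
}

#' Published GuHCl denaturation midpoints
#'
#' Midpoints of two-state GuHCl-induced unfolding at 20 C for thrombin
#' wild-type, the mutants I16T, D194A, D189A and prethrombin-2, measured
#' free (`apo`) and saturated with the irreversible active-site inhibitor
#' PPACK (`ppack`).
#'
#' @return data.frame with columns `variant`, `condition`, `midpoint_M`.
#' @export
guhcl_midpoints <- function() {
  data.frame(
    variant = rep(c("wt", "I16T", "D194A", "D189A", "prethrombin2"), 2),
    condition = rep(c("apo", "ppack"), each = 5),
    midpoint_M = c(1.32, 1.13, 1.29, 1.50, 0.85,
                   3.75, 1.65, 1.58, 2.10, 0.73)
  )
}

#' Published Na+ dissociation constants
#'
#' Equilibrium Na+ binding affinities (25 C, intrinsic fluorescence
#' titration) for thrombin wild-type and the I16T and D194A mutants.
#'
#' @return data.frame with columns `variant`, `Kd_mM`.
#' @export
na_binding_kd <- function() {
  data.frame(variant = c("wt", "I16T", "D194A"),
             Kd_mM = c(16, 1100, 80))
}
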