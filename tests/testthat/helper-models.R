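# Shared fixtures: canonical kinetic models and an independent
# eigenvalue-based oracle for relaxation rates.

# Lock-and-key Arrhenius laws of the D194A variant (published constants).
lk_d194a <- function() variant_lk_model("D194A")

# A conformational-selection model with the slow relaxation comfortably
# inside a multi-second observation window.
cs_example <- function() {
  global_kinetic_model("cs", list(
    k12 = arrhenius_law(2, 15), k21 = arrhenius_law(8, 15),
    kon = arrhenius_law(1, 8), koff = arrhenius_law(5, 13)))
}

# Independent oracle: relaxation rates as the nonzero eigenvalue
# magnitudes of the generator matrix (no use of the closed forms).
relax_rates_eigen <- function(m, L) {
  K <- rate_matrix(m, L)
  ev <- sort(abs(Re(eigen(K, only.values = TRUE)$values)),
             decreasing = TRUE)
  ev[-length(ev)]   # drop the stationary zero mode
}

# Log time grid helper for direct simulate_trace calls.
log_grid <- function(from = 1e-3, to = 1, n = 200)
  exp(seq(log(from), log(to), length.out = n))

# Random valid CS mechanism, rates log-uniform over ~4 decades.
random_cs <- function() {
  r <- 10^stats::runif(4, -1, 2)
  mechanism_cs(r[1], r[2], r[3], r[4])
}
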