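# Independent oracle implementations used to cross-check the package's
# physics. Deliberately written as direct transcriptions of the closed
# forms, composed differently from the package code paths.

# capture velocity composed in one expression from the raw constants
oracle_capture_velocity <- function(d_p, rho_p,
                                    E_s = 4.1e9, E_p = 1e9,
                                    v_s = 0.35, v_p = 0.40) {
  k1 <- (1 - v_s^2) / (pi * E_s)
  k2 <- (1 - v_p^2) / (pi * E_p)
  E <- 0.51 * ((5 * pi^2 * (k1 + k2)) / (4 * rho_p^(3 / 2)))^(2 / 5)
  ((2 * E) / d_p)^(10 / 7)
}

# grid-search fit of the Rosin-Rammler law minimizing squared log-quantile
# misfit; coarse grid refined once around the optimum
oracle_rr_gridsearch <- function(dv10, dv50, dv90) {
  target <- log(c(dv10, dv50, dv90))
  y <- log(-log(1 - c(0.1, 0.5, 0.9)))
  obj <- function(delta, n) sum((log(delta) + y / n - target)^2)
  best <- c(delta = NA, n = NA, val = Inf)
  search <- function(deltas, ns) {
    for (d in deltas) for (n in ns) {
      v <- obj(d, n)
      if (v < best[["val"]]) best <<- c(delta = d, n = n, val = v)
    }
  }
  search(seq(dv50 * 0.5, dv50 * 2, length.out = 120),
         seq(0.5, 6, length.out = 120))
  d0 <- best[["delta"]]; n0 <- best[["n"]]
  search(seq(d0 * 0.95, d0 * 1.05, length.out = 120),
         seq(n0 * 0.95, n0 * 1.05, length.out = 120))
  d0 <- best[["delta"]]; n0 <- best[["n"]]
  search(seq(d0 * 0.995, d0 * 1.005, length.out = 120),
         seq(n0 * 0.995, n0 * 1.005, length.out = 120))
  best
}

# exact stage table for a lognormal aerosol evaluated at given cut-offs,
# with the above-top-cutoff mass in the induction-port row
lognormal_stage_table <- function(median_um, gsd, cutoffs = ngi_cutoffs_60lpm()) {
  u <- stats::plnorm(cutoffs, meanlog = log(median_um), sdlog = log(gsd))
  stage_table(label = c("IP", names(cutoffs), "MOC"),
              cutoff_um = c(NA, unname(cutoffs), NA),
              mass = c(1 - u[1], 0, -diff(unname(u)), u[length(u)]))
}

# small default-config simulation shared by tracker tests
run_default_sim <- function(seed = 42, n = 100, formulation = "F1", ...) {
  geo <- build_geometry()
  field <- analytic_swirl_field(geo, Q = 1e-3)
  run_simulation(get_formulation(formulation), geo, field,
                 n = n, seed = seed, ...)
}
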