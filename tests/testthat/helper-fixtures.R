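# Noiseless replicate survival points from a known LQ truth.
lq_points <- function(alpha, beta, doses = 0:6, replicates = 3) {
  d <- rep(doses, each = replicates)
  data.frame(dose = d, sf = lq_sf(d, alpha, beta))
}

# Independent root-finder oracle for iso-survival doses (no closed form).
bisect_dose <- function(alpha, beta, target_sf, upper = 50) {
  stats::uniroot(function(d) lq_sf(d, alpha, beta) - target_sf,
                 c(0, upper), tol = 1e-9)$root
}

# Small well-formed colony-record table: triplicates at 0 and 2 Gy.
tiny_records <- function() {
  data.frame(
    modality = "HDR-BT", dose_rate_gy_min = 1.1, arm = "CTRL",
    dose_gy = rep(c(0, 2), each = 3), replicate = rep(1:3, 2),
    n_seeded = rep(c(100, 500), each = 3),
    n_colonies = c(40, 50, 60, 75, 83, 91)
  )
}

# One simulated CTRL/GNP pair at the default assay design, fitted.
fit_pair <- function(truth_ctrl, truth_treat, seed) {
  rc <- simulate_clonogenic(truth_ctrl, seed = seed)
  rt <- simulate_clonogenic(truth_treat, seed = seed + 500000L, arm = "GNP")
  list(ctrl = clonofit(survival_curve(rc)),
       treat = clonofit(survival_curve(rt)))
}
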