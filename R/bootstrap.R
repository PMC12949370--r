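#' Percentile bootstrap confidence interval
#'
#' Empirical quantiles at \code{(1-level)/2} and \code{1-(1-level)/2} with
#' linear interpolation between order statistics.
#'
#' @param samples Numeric vector of bootstrap draws (at least 20).
#' @param level Confidence level, strictly in (0, 1); default 0.95.
#' @return Named vector \code{c(low, high)}.
#' @examples
#' percentile_ci(1:1000)  # c(25.975, 975.025)
#' @export
percentile_ci <- function(samples, level = 0.95) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 20)
    stop("need at least 20 samples for a percentile interval", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("'level' must be strictly between 0 and 1", call. = FALSE)
  q <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Two-sided bootstrap p-value against a reference
#'
#' Twice the smaller of the fractions of draws above and below the
#' reference, capped at 1. Draws exactly at the reference are excluded from
#' both one-sided counts (a symmetric treatment of ties); the denominator is
#' the full number of draws. A returned 0 means no draw fell on the smaller
#' side and should be read as p < 2/n; when every draw sits exactly at the
#' reference there is no evidence of departure and p = 1.
#'
#' @param samples Numeric vector of bootstrap draws (non-empty).
#' @param reference Null reference value (1 for SER, 0 for an SER
#'   difference).
#' @return p-value in [0, 1].
#' @examples
#' two_sided_bootstrap_p(c(rep(2, 975), rep(-1, 25)), 0)  # 0.05
#' @export
two_sided_bootstrap_p <- function(samples, reference) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n == 0) stop("no samples to compute a p-value from", call. = FALSE)
  above <- sum(samples > reference)
  below <- sum(samples < reference)
  if (above == 0 && below == 0) return(1)  # every draw at the reference
  min(1, 2 * min(above, below) / n)
}

# ---------------------------------------------------------------------------
# synthesis core

# Per-iteration, per-arm RNG streams derived from one master seed, so that a
# paired comparison reproduces each arm's standalone bootstrap draws.
derive_seed <- function(master, arm, iter) {
  as.integer((as.double(master) + 999983 * arm + 104729 * iter) %% 2147483647)
}

# The bootstrap design of a fit: per fitted dose, the replicate count and
# the synthesis SD (per-dose replicate SD; pooled residual SD fallback).
boot_design <- function(fit) {
  doses <- sort(unique(fit$data$dose))
  n <- vapply(doses, function(d) sum(fit$data$dose == d), 0L)
  sd <- fit$sigma_by_dose[as.character(doses)]
  sd[is.na(sd)] <- fit$sigma
  sd[is.na(sd)] <- 0
  data.frame(dose = doses, n = n, sd = unname(sd))
}

#' Binomial bootstrap design from colony records
#'
#' Builds the design table needed by the mechanistic (\code{noise =
#' "binomial"}) bootstrap: per dose, the replicate count, the cells seeded
#' per plate and the group's plating efficiency. With this design each
#' bootstrap iteration re-draws colony counts plate by plate (controls
#' included) and re-estimates the plating efficiency, so count noise and
#' the shared normalisation error both propagate.
#'
#' @param records Colony records for one group.
#' @param max_dose Doses above this are excluded (match the fit range);
#'   default 6.
#' @return Data frame with columns \code{dose}, \code{n}, \code{sd}
#'   (\code{NA}; unused by binomial synthesis), \code{n_seeded}, \code{pe}.
#' @export
binomial_design <- function(records, max_dose = 6) {
  check_colony_records(records)
  pe <- plating_efficiency(records)
  recs <- records[records$dose_gy <= max_dose, , drop = FALSE]
  doses <- sort(unique(recs$dose_gy))
  data.frame(
    dose = doses,
    n = vapply(doses, function(d) sum(recs$dose_gy == d), 0L),
    sd = NA_real_,
    n_seeded = vapply(doses, function(d)
      round(mean(recs$n_seeded[recs$dose_gy == d])), 0),
    pe = pe
  )
}

# One synthetic dataset under the fitted model: prediction + Gaussian noise,
# truncated at zero (no negative survival). Uses the current RNG state.
synth_dataset <- function(fit, design, noise = "gaussian") {
  fun <- sf_model_fun(fit$model)
  dose <- rep(design$dose, design$n)
  mu <- fun(dose, fit$coefficients)
  if (noise == "gaussian") {
    sf <- pmax(0, mu + stats::rnorm(length(dose), 0,
                                    rep(design$sd, design$n)))
  } else {  # binomial colony-count synthesis (sensitivity alternative)
    if (is.null(design$n_seeded) || is.null(design$pe))
      stop("binomial synthesis needs 'n_seeded' and 'pe' in the design",
           call. = FALSE)
    seeded <- rep(design$n_seeded, design$n)
    pe <- rep(design$pe, design$n)
    counts <- stats::rbinom(length(dose), seeded, pmin(1, pe * mu))
    # re-estimate the plating efficiency from the synthetic control plates,
    # so its sampling error propagates into the survival fractions exactly
    # as it does in a real assay
    pe_hat <- if (any(dose == 0))
      sum(counts[dose == 0]) / sum(seeded[dose == 0]) else pe
    if (all(pe_hat > 0)) pe <- pe_hat
    sf <- counts / seeded / pe
  }
  data.frame(dose = dose, sf = sf)
}

refit_synth <- function(fit, design, noise) {
  d <- synth_dataset(fit, design, noise)
  fit_ls(d$dose, d$sf, fit$model, fit$coefficients, fit$lower, fit$upper,
         fit$control)
}

# ---------------------------------------------------------------------------
# bootstrap drivers

#' Parametric bootstrap distribution of fitted parameters
#'
#' Repeatedly synthesizes survival data from the fitted model (prediction
#' plus zero-mean Gaussian noise with per-dose replicate SD, pooled residual
#' SD where a dose lacks replication; negatives truncated to 0), refits, and
#' collects the parameter draws. Point estimates are those of the measured
#' dataset, never bootstrap means. Deterministic given \code{seed}.
#'
#' @param fit A converged [clonofit()] object.
#' @param n_boot Number of iterations (default 1000).
#' @param seed Integer master seed.
#' @param noise \code{"gaussian"} (default) or \code{"binomial"} (re-draws
#'   colony counts; requires \code{n_seeded} and \code{pe} columns in
#'   \code{design}).
#' @param design Optional data frame of \code{dose}, \code{n}, \code{sd}
#'   overriding the design derived from the fit.
#' @param arm_id Stream index for the per-arm RNG derivation (used by the
#'   paired comparisons; leave at 1 for standalone use).
#' @return An object of class \code{"clono_boot"}: the draw matrix (one row
#'   per iteration, \code{NA} rows for failed refits), per-parameter 95%
#'   percentile CIs, the measured-point estimates, and failure counts. For
#'   LQ fits an \code{alpha_beta} column is included.
#' @export
boot_params <- function(fit, n_boot = 1000, seed = NULL,
                        noise = c("gaussian", "binomial"), design = NULL,
                        arm_id = 1L) {
  noise <- match.arg(noise)
  if (!fit$converged) stop("fit has not converged", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  if (is.null(design)) design <- boot_design(fit)
  pn <- names(fit$coefficients)
  draws <- matrix(NA_real_, n_boot, length(pn), dimnames = list(NULL, pn))
  failed <- 0L
  for (i in seq_len(n_boot)) {
    set.seed(derive_seed(seed, arm_id, i))
    r <- refit_synth(fit, design, noise)
    if (r$converged) draws[i, ] <- r$par else failed <- failed + 1L
  }
  draws <- as.data.frame(draws)
  if (fit$model == "lq")
    draws$alpha_beta <- alpha_beta_ratio(draws$alpha, draws$beta)
  if (failed > n_boot / 10)
    warning("degraded inference: ", failed, "/", n_boot, " refits failed",
            call. = FALSE)
  if (failed == n_boot) stop("all bootstrap refits failed", call. = FALSE)
  point <- fit$coefficients
  if (fit$model == "lq")
    point <- c(point, alpha_beta = alpha_beta_ratio(point[["alpha"]],
                                                    point[["beta"]]))
  ci <- t(vapply(names(draws), function(v) percentile_ci(draws[[v]]),
                 c(low = 0, high = 0)))
  structure(list(statistic = "params", draws = draws, point = point,
                 ci = ci, n_boot = n_boot, seed = seed,
                 n_failed = failed, noise = noise),
            class = "clono_boot")
}

#' @export
print.clono_boot <- function(x, digits = 4, ...) {
  cat(sprintf("Parametric bootstrap (%d iterations, seed %d, %d failed refits)\n",
              x$n_boot, x$seed, x$n_failed))
  tab <- cbind(estimate = x$point[rownames(x$ci)], x$ci)
  print(round(tab, digits))
  invisible(x)
}

#' Bootstrap inference for the sensitizer enhancement ratio
#'
#' Per iteration both arms are independently re-synthesized from their
#' fitted models and refitted, and the SER recomputed. The reported point
#' estimate is the SER of the measured fits; the CI is the 2.5/97.5
#' percentile of the draws; the p-value tests the reference SER = 1 by the
#' two-sided bootstrap rule. Significance at level 0.05 corresponds to 1
#' lying outside the 95% percentile interval (up to percentile ties).
#'
#' @param fit_ctrl,fit_treat Converged [clonofit()] objects for the control
#'   and sensitizer-treated arms.
#' @param n_boot Iterations (default 1000).
#' @param seed Integer master seed.
#' @param noise Synthesis noise model, see [boot_params()].
#' @param designs Optional list of two design data frames (control,
#'   treated).
#' @param target_sf Iso-survival level, default 0.1.
#' @param arm_ids Length-2 stream indices for the two arms.
#' @return A \code{"boot_summary"} object: point estimate, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, draws, seed and failure count.
#' @export
boot_ser <- function(fit_ctrl, fit_treat, n_boot = 1000, seed = NULL,
                     noise = c("gaussian", "binomial"), designs = NULL,
                     target_sf = 0.1, arm_ids = c(1L, 2L)) {
  noise <- match.arg(noise)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  if (is.null(designs))
    designs <- list(boot_design(fit_ctrl), boot_design(fit_treat))
  draws <- ser_draws(fit_ctrl, fit_treat, designs, n_boot, seed, noise,
                     target_sf, arm_ids)
  failed <- sum(is.na(draws))
  if (failed > n_boot / 10)
    warning("degraded inference: ", failed, "/", n_boot,
            " iterations failed", call. = FALSE)
  if (failed == n_boot) stop("all bootstrap iterations failed", call. = FALSE)
  ci <- percentile_ci(draws)
  structure(list(statistic = "ser",
                 point = ser(fit_ctrl, fit_treat, target_sf),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 p_value = two_sided_bootstrap_p(draws, 1),
                 reference = 1, draws = draws, n_boot = n_boot,
                 seed = seed, n_failed = failed),
            class = "boot_summary")
}

# one SER draw per iteration; NA when either arm's refit fails
ser_draws <- function(fit_ctrl, fit_treat, designs, n_boot, seed, noise,
                      target_sf, arm_ids) {
  vapply(seq_len(n_boot), function(i) {
    set.seed(derive_seed(seed, arm_ids[1], i))
    rc <- refit_synth(fit_ctrl, designs[[1]], noise)
    set.seed(derive_seed(seed, arm_ids[2], i))
    rt <- refit_synth(fit_treat, designs[[2]], noise)
    if (!rc$converged || !rt$converged) return(NA_real_)
    dc <- iso_dose(fit_ctrl$model, rc$par, target_sf)
    dt <- iso_dose(fit_treat$model, rt$par, target_sf)
    if (is.na(dc) || is.na(dt)) return(NA_real_)
    dc / dt
  }, 0)
}

iso_dose <- function(model, par, target_sf) {
  if (model == "lq") {
    if (par[["alpha"]] == 0 && par[["beta"]] == 0) return(NA_real_)
    return(lq_dose(par[["alpha"]], par[["beta"]], target_sf))
  }
  f <- function(d) sf_model_fun(model)(d, par) - target_sf
  if (f(0) <= 0 || f(50) > 0) return(NA_real_)
  stats::uniroot(f, c(0, 50), tol = 1e-6)$root
}

#' Bootstrap comparison of SERs between two group pairs
#'
#' For paired groups (e.g. the same modality at two dose rates), computes
#' the SER difference \eqn{\Delta = SER_A - SER_B} in each bootstrap
#' iteration from four independently re-synthesized arms, with a percentile
#' CI and a two-sided bootstrap p-value against the reference
#' \eqn{\Delta = 0}.
#'
#' @param fits_a,fits_b Lists of two converged fits each,
#'   \code{list(ctrl, treat)}.
#' @param n_boot Iterations.
#' @param seed Integer master seed.
#' @param noise Synthesis noise model.
#' @param target_sf Iso-survival level, default 0.1.
#' @param arm_ids Length-4 stream indices (A-ctrl, A-treat, B-ctrl,
#'   B-treat). Swapping the pairs together with their stream indices negates
#'   the draw distribution exactly.
#' @return A \code{"boot_summary"} object for the statistic
#'   \code{"delta_ser"}.
#' @export
boot_compare_ser <- function(fits_a, fits_b, n_boot = 1000, seed = NULL,
                             noise = c("gaussian", "binomial"),
                             target_sf = 0.1, arm_ids = 1:4) {
  noise <- match.arg(noise)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  da <- list(boot_design(fits_a[[1]]), boot_design(fits_a[[2]]))
  db <- list(boot_design(fits_b[[1]]), boot_design(fits_b[[2]]))
  sa <- ser_draws(fits_a[[1]], fits_a[[2]], da, n_boot, seed, noise,
                  target_sf, arm_ids[1:2])
  sb <- ser_draws(fits_b[[1]], fits_b[[2]], db, n_boot, seed, noise,
                  target_sf, arm_ids[3:4])
  draws <- sa - sb
  failed <- sum(is.na(draws))
  if (failed > n_boot / 10)
    warning("degraded inference: ", failed, "/", n_boot,
            " iterations failed", call. = FALSE)
  if (failed == n_boot) stop("all bootstrap iterations failed", call. = FALSE)
  ci <- percentile_ci(draws)
  structure(list(statistic = "delta_ser",
                 point = ser(fits_a[[1]], fits_a[[2]], target_sf) -
                         ser(fits_b[[1]], fits_b[[2]], target_sf),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 p_value = two_sided_bootstrap_p(draws, 0),
                 reference = 0, draws = draws, n_boot = n_boot,
                 seed = seed, n_failed = failed),
            class = "boot_summary")
}

#' @export
print.boot_summary <- function(x, digits = 3, ...) {
  lab <- switch(x$statistic, ser = "SER", delta_ser = "Delta SER",
                x$statistic)
  p <- if (x$p_value == 0) sprintf("< %.3g", 2 / x$n_boot)
       else format(round(x$p_value, 4))
  cat(sprintf("%s = %.*f [95%% CI %.*f, %.*f], p %s\n", lab,
              digits, x$point, digits, x$ci_low, digits, x$ci_high,
              if (x$p_value == 0) p else paste("=", p)))
  cat(sprintf("(%d bootstrap iterations, seed %d, %d failed)\n",
              x$n_boot, x$seed, x$n_failed))
  invisible(x)
}

#' Write a bootstrap summary to structured text
#'
#' Key-value report with the point estimate, CI bounds, p-value (with a
#' \code{p_floor} note when no draw crossed the reference), seed, iteration
#' and failure counts; the full draw vector is optionally emitted alongside
#' for audit.
#'
#' @param x A \code{"boot_summary"} object.
#' @param file Output path.
#' @param draws_file Optional path for a long-format table of all draws.
#' @export
write_boot_report <- function(x, file, draws_file = NULL) {
  lines <- c(
    paste0("statistic: ", x$statistic),
    paste0("point_estimate: ", format(x$point, digits = 15)),
    paste0("ci_low: ", format(x$ci_low, digits = 15)),
    paste0("ci_high: ", format(x$ci_high, digits = 15)),
    paste0("p_value: ", format(x$p_value, digits = 15)),
    if (x$p_value == 0) paste0("p_floor: < ", format(2 / x$n_boot)),
    paste0("reference: ", x$reference),
    paste0("n_boot: ", x$n_boot),
    paste0("rng_seed: ", x$seed),
    paste0("n_failed_refits: ", x$n_failed)
  )
  writeLines(lines, file)
  if (!is.null(draws_file))
    utils::write.csv(data.frame(iteration = seq_along(x$draws),
                                value = x$draws),
                     draws_file, row.names = FALSE)
  invisible(file)
}
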