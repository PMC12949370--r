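#' Linear-quadratic survival fraction
#'
#' Cell survival under the linear-quadratic (LQ) model,
#' \eqn{SF(D) = \exp(-\alpha D - \beta D^2)}. \code{alpha} (Gy^-1) captures
#' lethal single-track damage, \code{beta} (Gy^-2) sub-lethal two-track
#' damage.
#'
#' @param dose Dose in Gy (vectorised, must be >= 0).
#' @param alpha Linear coefficient, Gy^-1 (>= 0).
#' @param beta Quadratic coefficient, Gy^-2 (>= 0).
#' @return Survival fraction(s) in (0, 1].
#' @examples
#' lq_sf(2, alpha = 0.45, beta = 0.05)  # exp(-1.1)
#' @seealso [mtsh_sf()], [tc_sf()], [lq_dose()]
#' @export
lq_sf <- function(dose, alpha, beta) {
  check_dose(dose)
  if (any(alpha < 0) || any(beta < 0))
    stop("'alpha' and 'beta' must be non-negative", call. = FALSE)
  exp(-(alpha * dose + beta * dose^2))
}

#' Multi-target single-hit survival fraction
#'
#' The cell is modelled as \code{n} sub-targets, each inactivated by
#' single-hit kinetics with mean lethal dose \code{d0}; the cell dies when
#' all targets are hit: \eqn{SF(D) = 1 - (1 - e^{-D/D_0})^n}.
#'
#' @param dose Dose in Gy (>= 0).
#' @param d0 Mean lethal dose per target, Gy (> 0).
#' @param n Number of targets (real-valued, >= 1).
#' @return Survival fraction(s) in [0, 1]; exactly 1 at dose 0.
#' @export
mtsh_sf <- function(dose, d0, n) {
  check_dose(dose)
  if (any(d0 <= 0)) stop("'d0' must be positive", call. = FALSE)
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  1 - (1 - exp(-dose / d0))^n
}

#' Two-component survival fraction
#'
#' Multi-target single-hit survival multiplied by an additional single-hit
#' exponential term, improving low-dose behaviour:
#' \eqn{SF(D) = e^{-D/D_1}\,[1 - (1 - e^{-D/D_n})^n]}.
#'
#' @param dose Dose in Gy (>= 0).
#' @param d1 Single-hit component mean lethal dose, Gy (> 0).
#' @param dn Multi-target component mean lethal dose, Gy (> 0).
#' @param n Number of targets (>= 1).
#' @return Survival fraction(s) in [0, 1]; exactly 1 at dose 0.
#' @export
tc_sf <- function(dose, d1, dn, n) {
  check_dose(dose)
  if (any(d1 <= 0) || any(dn <= 0))
    stop("'d1' and 'dn' must be positive", call. = FALSE)
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  exp(-dose / d1) * (1 - (1 - exp(-dose / dn))^n)
}

#' Iso-survival dose under the LQ model (closed form)
#'
#' Solves \eqn{\exp(-\alpha D - \beta D^2) = s} for the positive dose, i.e.
#' the positive root of \eqn{\beta D^2 + \alpha D + \ln s = 0}. With
#' \code{beta = 0} this reduces to \eqn{\ln(1/s)/\alpha}. The default target
#' of 0.1 gives the D10 used in the sensitizer enhancement ratio.
#'
#' @param alpha,beta LQ coefficients (Gy^-1, Gy^-2).
#' @param target_sf Target survival fraction, strictly in (0, 1).
#' @return Dose in Gy.
#' @examples
#' lq_dose(0.45, 0.05)       # D10 = 3.6426 Gy
#' lq_dose(0.45, 0, 0.1)     # log(10)/0.45
#' @export
lq_dose <- function(alpha, beta, target_sf = 0.1) {
  if (target_sf <= 0 || target_sf >= 1)
    stop("'target_sf' must be strictly between 0 and 1", call. = FALSE)
  if (alpha == 0 && beta == 0)
    stop("survival level is unattainable: alpha = beta = 0", call. = FALSE)
  ls <- log(target_sf)
  if (beta == 0) return(-ls / alpha)
  (-alpha + sqrt(alpha^2 - 4 * beta * ls)) / (2 * beta)
}

#' Iso-survival dose from a fitted model
#'
#' Inverts a fitted dose-response curve at a target survival level. For LQ
#' fits the quadratic closed form is used; for MTSH and TC fits the root is
#' bracketed on [0, 50] Gy and solved to 1e-6 Gy.
#'
#' @param fit A [clonofit()] object.
#' @param target_sf Target survival fraction, strictly in (0, 1); default 0.1
#'   (the D10 entering the SER).
#' @return Dose in Gy.
#' @export
dose_at_sf <- function(fit, target_sf = 0.1) {
  stopifnot(inherits(fit, "clonofit"))
  if (target_sf <= 0 || target_sf >= 1)
    stop("'target_sf' must be strictly between 0 and 1", call. = FALSE)
  p <- fit$coefficients
  if (fit$model == "lq")
    return(lq_dose(p[["alpha"]], p[["beta"]], target_sf))
  f <- function(d) sf_model_fun(fit$model)(d, p) - target_sf
  if (f(0) <= 0 || f(50) > 0)
    stop("target survival not bracketed within [0, 50] Gy", call. = FALSE)
  stats::uniroot(f, c(0, 50), tol = 1e-6)$root
}

#' Alpha/beta ratio
#'
#' The dose (Gy) at which linear and quadratic kill contributions of the LQ
#' model are equal; a conventional radiosensitivity summary.
#'
#' @param alpha,beta LQ coefficients. With \code{beta = 0} the ratio is
#'   undefined and \code{NA} is returned (not an error).
#' @return alpha/beta in Gy, or \code{NA_real_} when \code{beta = 0}.
#' @export
alpha_beta_ratio <- function(alpha, beta) {
  ifelse(beta == 0, NA_real_, alpha / beta)
}

#' Sensitizer enhancement ratio from two fitted curves
#'
#' SER = dose for the target survival level (default 10%) without sensitizer
#' divided by the dose with sensitizer; SER > 1 indicates radiosensitization.
#'
#' @param fit_ctrl Fitted curve for the untreated (control) arm.
#' @param fit_treat Fitted curve for the sensitizer-treated arm.
#' @param target_sf Iso-survival level, default 0.1.
#' @return Dimensionless ratio.
#' @examples
#' d <- data.frame(dose = rep(0:6, 2))
#' d$sf <- lq_sf(d$dose, 0.45, 0.05)
#' fc <- clonofit(sf ~ dose, d)
#' d$sf <- lq_sf(d$dose, 0.5686, 0.06)
#' ft <- clonofit(sf ~ dose, d)
#' ser(fc, ft)  # 1.19
#' @export
ser <- function(fit_ctrl, fit_treat, target_sf = 0.1) {
  if (!fit_ctrl$converged || !fit_treat$converged)
    stop("both fits must have converged to compute an SER", call. = FALSE)
  dose_at_sf(fit_ctrl, target_sf) / dose_at_sf(fit_treat, target_sf)
}

# model registry ------------------------------------------------------------

# Each model function takes (dose, named parameter vector).
sf_model_fun <- function(model) {
  switch(model,
    lq   = function(d, p) exp(-(p[[1]] * d + p[[2]] * d^2)),
    mtsh = function(d, p) 1 - (1 - exp(-d / p[[1]]))^p[[2]],
    tc   = function(d, p) exp(-d / p[[1]]) * (1 - (1 - exp(-d / p[[2]]))^p[[3]]),
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

sf_model_info <- function(model) {
  switch(model,
    lq = list(
      par   = c("alpha", "beta"),
      start = c(alpha = 0.3, beta = 0.03),
      lower = c(alpha = 0, beta = 0),
      upper = c(alpha = 3, beta = 1),
      min_doses = 3L,
      jac = function(d, p) {
        f <- exp(-(p[[1]] * d + p[[2]] * d^2))
        cbind(d * f, d^2 * f)
      }
    ),
    mtsh = list(
      par   = c("d0", "n"),
      start = c(d0 = 1.5, n = 3),
      lower = c(d0 = 1e-3, n = 1),
      upper = c(d0 = 50, n = 100),
      min_doses = 4L,
      jac = NULL
    ),
    tc = list(
      par   = c("d1", "dn", "n"),
      start = c(d1 = 10, dn = 1.5, n = 3),
      lower = c(d1 = 1e-3, dn = 1e-3, n = 1),
      upper = c(d1 = 1e3, dn = 50, n = 100),
      min_doses = 4L,
      jac = NULL
    ),
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

check_dose <- function(dose) {
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("'dose' must be finite and non-negative", call. = FALSE)
  invisible(dose)
}
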