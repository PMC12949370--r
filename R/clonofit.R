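#' Fit a dose-response model to clonogenic survival data
#'
#' Fits the linear-quadratic (LQ), multi-target single-hit (MTSH) or
#' two-component (TC) survival model to clonogenic data by
#' Levenberg-Marquardt nonlinear least squares ([minpack.lm::nls.lm]),
#' minimising \eqn{\sum_i (SF_i^{obs} - SF(D_i))^2} on the linear survival
#' scale. All replicate points are fitted jointly by default; set
#' \code{aggregate = TRUE} to fit the per-dose means instead.
#'
#' Fitting on the linear scale keeps plates with zero colonies (SF = 0)
#' usable, which a log-transform would discard. The LQ fit is restricted to
#' doses at or below \code{max_dose} (default 6 Gy, where the model is most
#' relevant clinically); MTSH and TC default to the full dose range.
#'
#' @param formula A formula \code{sf ~ dose}, or a [survival_curve()] object
#'   (in which case \code{data} is ignored and the curve's per-replicate
#'   points are fitted).
#' @param data A data frame containing the formula variables.
#' @param model One of \code{"lq"}, \code{"mtsh"}, \code{"tc"}.
#' @param max_dose Upper dose limit (Gy) of points entering the fit.
#'   Defaults to 6 for LQ and \code{Inf} for MTSH/TC.
#' @param aggregate Fit per-dose mean survival instead of all replicate
#'   points jointly.
#' @param start,lower,upper Optional named parameter vectors overriding the
#'   defaults (LQ: start \eqn{\alpha = 0.3, \beta = 0.03}, bounds
#'   \eqn{\alpha \in [0,3]}, \eqn{\beta \in [0,1]}).
#' @param control List with elements \code{ftol} (objective tolerance,
#'   default 1e-10) and \code{maxiter} (default 200).
#' @param group Optional label describing the experimental group.
#' @return An object of class \code{"clonofit"}: a list with components
#'   \code{coefficients}, \code{fitted.values}, \code{residuals},
#'   \code{sigma} (pooled residual SD), \code{sigma_by_dose} (replicate SD
#'   per dose, \code{NA} where a dose has one point), \code{r_squared},
#'   \code{converged}, \code{model}, \code{data} and \code{pe} (plating
#'   efficiency when fitted from a survival curve).
#' @examples
#' d <- data.frame(dose = rep(0:6, each = 3))
#' d$sf <- lq_sf(d$dose, 0.45, 0.05)
#' fit <- clonofit(sf ~ dose, d)
#' coef(fit)
#' dose_at_sf(fit)      # D10
#' @seealso [dose_at_sf()], [ser()], [boot_params()], [boot_ser()]
#' @export
clonofit <- function(formula, data = NULL, model = c("lq", "mtsh", "tc"),
                     max_dose = NULL, aggregate = FALSE,
                     start = NULL, lower = NULL, upper = NULL,
                     control = list(), group = NULL) {
  model <- match.arg(model)
  cl <- match.call()
  pe <- NULL
  if (inherits(formula, "survival_curve")) {
    pe <- attr(formula, "pe")
    if (aggregate) {
      pts <- data.frame(dose = formula$dose_gy, sf = formula$sf_mean)
    } else {
      sp <- attr(formula, "sf_points")
      pts <- data.frame(dose = sp$dose_gy, sf = sp$sf)
    }
  } else {
    mf <- stats::model.frame(formula, data)
    pts <- data.frame(dose = mf[[2L]], sf = mf[[1L]])
    if (aggregate)
      pts <- stats::aggregate(sf ~ dose, pts, mean)
  }
  if (is.null(max_dose)) max_dose <- if (model == "lq") 6 else Inf
  pts <- pts[pts$dose <= max_dose, , drop = FALSE]
  pts <- pts[order(pts$dose), , drop = FALSE]
  rownames(pts) <- NULL
  check_dose(pts$dose)
  if (any(pts$sf < 0))
    stop("survival fractions must be non-negative", call. = FALSE)

  info <- sf_model_info(model)
  if (length(unique(pts$dose)) < info$min_doses)
    stop("need at least ", info$min_doses, " distinct doses for a ",
         toupper(model), " fit", call. = FALSE)
  if (nrow(pts) < length(info$par))
    stop("fewer points than parameters: underdetermined fit", call. = FALSE)

  start <- resolve_par(start, info$start)
  lower <- resolve_par(lower, info$lower)
  upper <- resolve_par(upper, info$upper)
  ctrl <- utils::modifyList(list(ftol = 1e-10, maxiter = 200), control)

  ls <- fit_ls(pts$dose, pts$sf, model, start, lower, upper, ctrl)
  if (!ls$converged)
    warning("fit did not converge: ", ls$message, call. = FALSE)

  fun <- sf_model_fun(model)
  fitted <- fun(pts$dose, ls$par)
  resid <- pts$sf - fitted
  n <- nrow(pts); p <- length(ls$par)
  sigma <- if (n > p) sqrt(sum(resid^2) / (n - p)) else NA_real_
  doses <- sort(unique(pts$dose))
  sigma_by_dose <- vapply(doses, function(d) {
    x <- pts$sf[pts$dose == d]
    if (length(x) < 2) NA_real_ else stats::sd(x)
  }, 0)
  names(sigma_by_dose) <- doses
  tss <- sum((pts$sf - mean(pts$sf))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else NA_real_

  structure(list(
    call = cl, model = model, coefficients = ls$par,
    fitted.values = fitted, residuals = resid,
    sigma = sigma, sigma_by_dose = sigma_by_dose, r_squared = r2,
    converged = ls$converged, niter = ls$niter, message = ls$message,
    data = pts, start = start, lower = lower, upper = upper,
    control = ctrl, pe = pe, group = group
  ), class = "clonofit")
}

resolve_par <- function(user, default) {
  if (is.null(user)) return(default)
  out <- default
  out[names(user)] <- user
  out
}

# Fast internal least-squares core shared by clonofit() and the bootstrap.
fit_ls <- function(dose, sf, model, start, lower, upper, ctrl) {
  fun <- sf_model_fun(model)
  jac <- sf_model_info(model)$jac
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = function(p, d, y) y - fun(d, p),
      jac = if (!is.null(jac)) function(p, d, y) jac(d, p),
      d = dose, y = sf,
      control = minpack.lm::nls.lm.control(ftol = ctrl$ftol,
                                           maxiter = ctrl$maxiter)
    ),
    error = function(e) e
  )
  if (inherits(res, "error"))
    return(list(par = start, converged = FALSE, niter = 0L,
                message = conditionMessage(res)))
  par <- res$par
  names(par) <- names(start)
  # info codes 1:4 and 8 indicate a satisfied convergence test
  list(par = par, converged = res$info %in% c(1:4, 8),
       niter = res$niter, message = res$message)
}

# ---------------------------------------------------------------------------
# methods

#' @export
print.clonofit <- function(x, digits = 4, ...) {
  cat("Clonogenic survival fit (", toupper(x$model), " model)\n", sep = "")
  if (!is.null(x$group)) cat("Group:", x$group, "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  if (x$converged && x$model == "lq") {
    ab <- alpha_beta_ratio(x$coefficients[["alpha"]], x$coefficients[["beta"]])
    cat(sprintf("alpha/beta: %s Gy\n",
                if (is.na(ab)) "unavailable (beta = 0)" else round(ab, digits)))
  }
  if (x$converged)
    cat(sprintf("D10: %.4f Gy   R-squared: %.4f\n",
                dose_at_sf(x), x$r_squared))
  else
    cat("Fit did not converge:", x$message, "\n")
  invisible(x)
}

#' @export
summary.clonofit <- function(object, ...) {
  out <- list(
    model = object$model, coefficients = object$coefficients,
    converged = object$converged, r_squared = object$r_squared,
    sigma = object$sigma, n = nrow(object$data),
    d10 = if (object$converged) dose_at_sf(object) else NA_real_,
    alpha_beta = if (object$model == "lq")
      alpha_beta_ratio(object$coefficients[["alpha"]],
                       object$coefficients[["beta"]]) else NA_real_,
    group = object$group
  )
  class(out) <- "summary.clonofit"
  out
}

#' @export
print.summary.clonofit <- function(x, digits = 4, ...) {
  cat("Model:", toupper(x$model), " Points:", x$n, "\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Residual SD: %.4g  R-squared: %.4f\n", x$sigma, x$r_squared))
  if (!is.na(x$d10)) cat(sprintf("D10: %.4f Gy\n", x$d10))
  if (!is.na(x$alpha_beta)) cat(sprintf("alpha/beta: %.3f Gy\n", x$alpha_beta))
  invisible(x)
}

#' @export
coef.clonofit <- function(object, ...) object$coefficients

#' @export
residuals.clonofit <- function(object, ...) object$residuals

#' @export
fitted.clonofit <- function(object, ...) object$fitted.values

#' Predicted survival fractions from a fitted model
#'
#' @param object A [clonofit()] object.
#' @param newdata Optional data frame with a \code{dose} column, or a
#'   numeric dose vector. Defaults to the fitted doses.
#' @param ... Unused.
#' @return Predicted survival fractions.
#' @export
predict.clonofit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose
          else if (is.numeric(newdata)) newdata
          else newdata$dose
  check_dose(dose)
  sf_model_fun(object$model)(dose, object$coefficients)
}

#' Plot a fitted clonogenic survival curve
#'
#' Observed points and the fitted model on a logarithmic survival axis, the
#' conventional display for clonogenic data. Zero survival fractions are
#' shown at the axis floor.
#'
#' @param x A [clonofit()] object.
#' @param floor Lower display limit for the survival axis.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.clonofit <- function(x, floor = 1e-4, ...) {
  d <- x$data
  y <- pmax(d$sf, floor)
  graphics::plot(d$dose, y, log = "y", xlab = "Dose (Gy)",
                 ylab = "Survival fraction",
                 main = paste(toupper(x$model), "fit"), ...)
  dg <- seq(0, max(d$dose), length.out = 200)
  graphics::lines(dg, pmax(predict(x, dg), floor), col = 2)
  invisible(x)
}

#' Simulate survival data from a fitted model
#'
#' Draws synthetic datasets under the parametric-bootstrap noise model: at
#' each fitted design point the model prediction plus zero-mean Gaussian
#' noise with the per-dose replicate SD (pooled residual SD where a dose has
#' a single replicate), truncated at zero.
#'
#' @param object A [clonofit()] object.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of \code{nsim} data frames with columns \code{dose},
#'   \code{sf}.
#' @export
simulate.clonofit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- boot_design(object)
  lapply(seq_len(nsim), function(i) synth_dataset(object, design))
}

#' Write a structured fit report
#'
#' Key-value text with model kind, parameters, alpha/beta, iso-survival
#' dose, goodness of fit, convergence flag and an MD5 digest of the fitted
#' points for reproducibility.
#'
#' @param fit A [clonofit()] object.
#' @param file Output path.
#' @param target_sf Iso-survival level reported, default 0.1.
#' @export
write_fit_report <- function(fit, file, target_sf = 0.1) {
  p <- fit$coefficients
  lines <- c(
    paste0("model: ", fit$model),
    if (!is.null(fit$group)) paste0("group: ", fit$group),
    paste0(names(p), ": ", format(p, digits = 15)),
    if (fit$model == "lq")
      paste0("alpha_beta: ",
             format(alpha_beta_ratio(p[["alpha"]], p[["beta"]]), digits = 15)),
    paste0("d", round(100 * target_sf), ": ",
           if (fit$converged) format(dose_at_sf(fit, target_sf), digits = 15)
           else "NA"),
    paste0("r_squared: ", format(fit$r_squared, digits = 15)),
    paste0("residual_sigma: ", format(fit$sigma, digits = 15)),
    paste0("converged: ", fit$converged),
    paste0("n_points: ", nrow(fit$data)),
    if (!is.null(fit$pe)) paste0("plating_efficiency: ",
                                 format(fit$pe, digits = 15)),
    paste0("input_digest: ", input_digest(fit$data))
  )
  writeLines(lines, file)
  invisible(file)
}

input_digest <- function(df) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(format(unlist(df), digits = 15), collapse = ","), tmp)
  unname(tools::md5sum(tmp))
}
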