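#' Mean DNA damage foci per cell
#'
#' @param x Numeric vector of per-nucleus foci counts, or a foci-record data
#'   frame with an \code{n_foci} column.
#' @return Arithmetic mean foci per cell.
#' @export
mean_foci_per_cell <- function(x) {
  if (is.data.frame(x)) x <- x$n_foci
  if (length(x) == 0) stop("no foci records for this condition", call. = FALSE)
  mean(x)
}

#' Relative increase in mean foci per cell
#'
#' @param mean_treat,mean_ctrl Mean foci/cell in the treated and control
#'   conditions; \code{mean_ctrl} must be positive.
#' @return Percent increase, \code{100 * (mean_treat - mean_ctrl) /
#'   mean_ctrl}.
#' @export
relative_increase <- function(mean_treat, mean_ctrl) {
  if (any(mean_ctrl <= 0))
    stop("control mean must be positive", call. = FALSE)
  100 * (mean_treat - mean_ctrl) / mean_ctrl
}

#' Two-sample equal-variance t-test
#'
#' Classical pooled-variance two-sided Student's t-test with
#' \code{df = n_a + n_b - 2}. When both samples are constant and equal (no
#' variance anywhere) the test degenerates to t = 0, p = 1 rather than an
#' error.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @return List with \code{t}, \code{df}, \code{p_value},
#'   \code{mean_a}, \code{mean_b}.
#' @export
equal_variance_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  res <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                  error = function(e) e)
  if (inherits(res, "error")) {
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop(res)
  }
  list(t = unname(res$statistic), df = as.integer(res$parameter),
       p_value = res$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Compare foci counts between control and treated arms
#'
#' Summarises per-cell 53BP1 (or similar) foci counts for one condition
#' pair: arm means, the relative increase in mean foci/cell, and a
#' two-tailed equal-variance t-test. By default individual cells are the
#' experimental units; \code{unit = "replicate"} first averages within
#' replicates (requires a \code{replicate} column) and tests the replicate
#' means, a stricter reading with far fewer degrees of freedom.
#'
#' @param records Foci-record data frame with columns \code{arm},
#'   \code{n_foci} (and \code{replicate} for the replicate-mean mode).
#' @param ctrl_label,treat_label Arm labels, defaults \code{"CTRL"} and
#'   \code{"GNP"}.
#' @param unit \code{"cell"} (default) or \code{"replicate"}.
#' @return Object of class \code{"foci_comparison"} with \code{mean_ctrl},
#'   \code{mean_treat}, \code{relative_increase} (percent), \code{t},
#'   \code{df}, \code{p_value}, \code{n_ctrl}, \code{n_treat}.
#' @export
compare_foci <- function(records, ctrl_label = "CTRL", treat_label = "GNP",
                         unit = c("cell", "replicate")) {
  unit <- match.arg(unit)
  check_foci_records(records)
  pick <- function(lab) records[records$arm == lab, , drop = FALSE]
  ctrl <- pick(ctrl_label); treat <- pick(treat_label)
  if (nrow(ctrl) == 0 || nrow(treat) == 0)
    stop("arm '", if (nrow(ctrl) == 0) ctrl_label else treat_label,
         "' has no foci records", call. = FALSE)
  vals <- function(df) {
    if (unit == "cell") return(df$n_foci)
    if (is.null(df$replicate))
      stop("replicate-mean mode needs a 'replicate' column", call. = FALSE)
    as.numeric(tapply(df$n_foci, df$replicate, mean))
  }
  a <- vals(treat); b <- vals(ctrl)
  tt <- equal_variance_t_test(a, b)
  structure(list(
    mean_ctrl = mean(b), mean_treat = mean(a),
    relative_increase = relative_increase(mean(a), mean(b)),
    t = tt$t, df = tt$df, p_value = tt$p_value,
    n_ctrl = length(b), n_treat = length(a), unit = unit
  ), class = "foci_comparison")
}

#' @export
print.foci_comparison <- function(x, ...) {
  cat(sprintf("Foci per cell: treated %.1f vs control %.1f (+%.1f%%)\n",
              x$mean_treat, x$mean_ctrl, x$relative_increase))
  cat(sprintf("Equal-variance t-test: t = %.3f, df = %d, p = %.4g (units: %s)\n",
              x$t, x$df, x$p_value, x$unit))
  invisible(x)
}

#' Write a foci comparison table
#'
#' @param x A \code{"foci_comparison"} object or list of them.
#' @param file Output path (comma-delimited).
#' @export
write_foci_comparison <- function(x, file) {
  if (inherits(x, "foci_comparison")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(f)
    data.frame(mean_ctrl = f$mean_ctrl, mean_treat = f$mean_treat,
               relative_increase_pct = f$relative_increase,
               t = f$t, df = f$df, p_value = f$p_value)))
  nm <- names(x)
  if (!is.null(nm)) rows <- cbind(comparison = nm, rows)
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
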