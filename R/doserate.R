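#' Brachytherapy source description
#'
#' Physical constants of a high-dose-rate stepping source (e.g. Ir-192).
#'
#' @param sk Air kerma strength in mGy m^2/h.
#' @param gamma Air kerma rate constant, cGy cm^2/h/mCi (default 4.037).
#' @param lambda Dose-rate constant, cGy/h per unit air kerma strength
#'   (1 uGy m^2/h) at 1 cm (default 1.109).
#' @return Object of class \code{"source_spec"}.
#' @export
source_spec <- function(sk, gamma = 4.037, lambda = 1.109) {
  if (sk <= 0 || gamma <= 0 || lambda <= 0)
    stop("source parameters must be strictly positive", call. = FALSE)
  structure(list(sk = sk, gamma = gamma, lambda = lambda),
            class = "source_spec")
}

as_source_spec <- function(source) {
  if (inherits(source, "source_spec")) return(source)
  if (is.numeric(source) && length(source) == 1) return(source_spec(source))
  stop("'source' must be a source_spec or a single air kerma strength",
       call. = FALSE)
}

#' Particle histories for a dwell
#'
#' Converts air kerma strength to apparent activity via the air kerma rate
#' constant and scales by the dwell time:
#' S_k in mGy m^2/h is converted to cGy cm^2/h (factor 1000: 0.1 cGy/mGy
#' times 1e4 cm^2/m^2), divided by Gamma to give mCi, converted to Ci, and
#' multiplied by 3.7e10 disintegrations/s/Ci and the dwell time.
#'
#' @param source A [source_spec()] or air kerma strength in mGy m^2/h.
#' @param dwell_time Dwell time in seconds (>= 0).
#' @return Number of particle histories (linear in both S_k and time).
#' @examples
#' particle_histories(37.95, 1)  # 3.478e11
#' @export
particle_histories <- function(source, dwell_time) {
  s <- as_source_spec(source)
  if (any(dwell_time < 0)) stop("'dwell_time' must be >= 0", call. = FALSE)
  activity_ci <- (s$sk * 1000) / s$gamma / 1000
  activity_ci * 3.7e10 * dwell_time
}

#' Dwell dose rate
#'
#' Dose delivered to a voxel divided by the dwell time.
#'
#' @param dose_gy Dose in Gy.
#' @param dwell_time_s Dwell time in seconds (> 0).
#' @return Dose rate in Gy/s.
#' @export
dwell_dose_rate <- function(dose_gy, dwell_time_s) {
  if (any(dwell_time_s <= 0)) stop("dwell time must be positive", call. = FALSE)
  dose_gy / dwell_time_s
}

#' Average delivery dose rate
#'
#' Total planned dose divided by the reported treatment delivery time.
#'
#' @param total_dose_gy Delivered dose in Gy.
#' @param delivery_time_s Delivery time in seconds (> 0).
#' @return Average dose rate in Gy/min.
#' @examples
#' average_dose_rate(2, 109.09)  # 1.1 Gy/min
#' @export
average_dose_rate <- function(total_dose_gy, delivery_time_s) {
  if (any(delivery_time_s <= 0))
    stop("delivery time must be positive", call. = FALSE)
  60 * total_dose_gy / delivery_time_s
}

#' Linac pulse description
#'
#' @param pulse_width Pulse width in seconds (default 4e-6).
#' @param mu_per_pulse Monitor units per pulse (default 0.08).
#' @param machine_output Machine output in MU/min (default 100).
#' @param calibration Dose calibration at the sample point, cGy/MU.
#' @return Object of class \code{"pulse_spec"}.
#' @export
pulse_spec <- function(pulse_width = 4e-6, mu_per_pulse = 0.08,
                       machine_output = 100, calibration = NULL) {
  if (pulse_width <= 0 || mu_per_pulse <= 0 || machine_output <= 0)
    stop("pulse parameters must be strictly positive", call. = FALSE)
  if (!is.null(calibration) && calibration <= 0)
    stop("'calibration' must be strictly positive", call. = FALSE)
  structure(list(pulse_width = pulse_width, mu_per_pulse = mu_per_pulse,
                 machine_output = machine_output, calibration = calibration),
            class = "pulse_spec")
}

#' Dose per linac pulse
#'
#' Calibration (cGy/MU at the sample point) times monitor units per pulse.
#'
#' @param pulse A [pulse_spec()] with \code{calibration} set.
#' @return Dose per pulse in cGy.
#' @examples
#' dose_per_pulse(pulse_spec(calibration = 200 / 220))  # ~0.0727 cGy
#' @export
dose_per_pulse <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_spec"))
  if (is.null(pulse$calibration))
    stop("pulse calibration (cGy/MU) is not set", call. = FALSE)
  pulse$calibration * pulse$mu_per_pulse
}

#' Instantaneous intra-pulse dose rate
#'
#' Dose per pulse divided by the pulse width; during the few-microsecond
#' pulse the dose rate far exceeds the average machine output.
#'
#' @param dose_per_pulse_cgy Dose per pulse in cGy.
#' @param pulse_width_s Pulse width in seconds (> 0), default 4e-6.
#' @return Instantaneous dose rate in Gy/s.
#' @examples
#' pulse_instantaneous_dose_rate(0.072, 4e-6)  # 180 Gy/s
#' @export
pulse_instantaneous_dose_rate <- function(dose_per_pulse_cgy,
                                          pulse_width_s = 4e-6) {
  if (any(pulse_width_s <= 0))
    stop("pulse width must be positive", call. = FALSE)
  (dose_per_pulse_cgy / 100) / pulse_width_s
}

#' Source-to-sample distance for a dose-rate scaling factor
#'
#' Inverse-square scaling at fixed depth: to scale the dose rate by
#' \code{factor}, move the sample to \code{reference_distance /
#' sqrt(factor)}. Tissue-maximum-ratio variation with distance is
#' neglected.
#'
#' @param reference_distance Reference distance in cm (> 0).
#' @param factor Desired dose-rate multiple (> 0); 0.5 halves the rate.
#' @return New distance in cm.
#' @examples
#' distance_for_dose_rate_factor(91, 0.5)  # 128.69 -> 129 cm
#' @export
distance_for_dose_rate_factor <- function(reference_distance, factor) {
  if (any(reference_distance <= 0) || any(factor <= 0))
    stop("distance and factor must be strictly positive", call. = FALSE)
  reference_distance / sqrt(factor)
}

#' Point-source dose rate
#'
#' Inverse-square point-source kernel: air kerma strength (converted to the
#' conventional unit U = 1 uGy m^2/h) times the dose-rate constant, scaled
#' by 1/r^2, with anisotropy and radial dose functions set to unity. An
#' approximation for near-source geometry bookkeeping, not a transport
#' calculation.
#'
#' @param source A [source_spec()] or air kerma strength in mGy m^2/h.
#' @param distance_cm Distance from the source in cm (> 0).
#' @return Dose rate in Gy/min.
#' @examples
#' point_source_rate(37.95, 1)  # ~7.0 Gy/min
#' @export
point_source_rate <- function(source, distance_cm) {
  s <- as_source_spec(source)
  if (any(distance_cm <= 0))
    stop("distance must be strictly positive (point-source singularity)",
         call. = FALSE)
  sk_u <- s$sk * 1000                       # mGy m^2/h -> uGy m^2/h
  cgy_per_h <- sk_u * s$lambda / distance_cm^2
  cgy_per_h / 100 / 60
}

# ---------------------------------------------------------------------------
# dwell plans and timeline maps

#' Read a dwell plan from delimited text
#'
#' Expects header columns \code{dwell_index}, \code{x_cm}, \code{y_cm},
#' \code{z_cm}, \code{time_s}.
#'
#' @param file Path to a comma-delimited text file.
#' @return A dwell-plan data frame.
#' @export
read_dwell_plan <- function(file) {
  df <- utils::read.csv(file)
  check_dwell_plan(df)
  df
}

check_dwell_plan <- function(plan) {
  need <- c("x_cm", "y_cm", "z_cm", "time_s")
  miss <- setdiff(need, names(plan))
  if (length(miss))
    stop("dwell plan missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(plan) < 1) stop("dwell plan is empty", call. = FALSE)
  if (any(plan$time_s < 0))
    stop("dwell times must be >= 0", call. = FALSE)
  invisible(plan)
}

#' Planar dose-rate map for a dwell plan
#'
#' Scores a square grid in the z = 0 plane. For each voxel centre the dose
#' rate during each dwell comes from [point_source_rate()] at the
#' dwell-to-voxel distance; the map records the maximum rate over dwells,
#' the time-weighted average rate, and the total dose (sum of rate times
#' dwell time).
#'
#' @param plan Dwell-plan data frame (\code{x_cm}, \code{y_cm}, \code{z_cm},
#'   \code{time_s}); all dwell positions must be off the scoring plane.
#' @param source A [source_spec()] or air kerma strength in mGy m^2/h.
#' @param grid_bins Bins per axis (default 50).
#' @param extent_cm Full grid width in cm (default 3.5, a 35 mm dish).
#' @return Object of class \code{"dose_rate_map"}: grid coordinates
#'   \code{x}, \code{y}; matrices \code{max_rate}, \code{avg_rate} (Gy/min)
#'   and \code{total_dose} (Gy); plus the plan and source.
#' @export
dwell_dose_rate_map <- function(plan, source, grid_bins = 50,
                                extent_cm = 3.5) {
  check_dwell_plan(plan)
  s <- as_source_spec(source)
  half <- extent_cm / 2
  width <- extent_cm / grid_bins
  centres <- seq(-half + width / 2, half - width / 2, length.out = grid_bins)
  nx <- length(centres)
  maxr <- avg_num <- total <- matrix(0, nx, nx)
  ttot <- sum(plan$time_s)
  for (k in seq_len(nrow(plan))) {
    dx <- outer(centres - plan$x_cm[k], centres - plan$y_cm[k],
                function(a, b) sqrt(a^2 + b^2 + plan$z_cm[k]^2))
    if (any(dx == 0))
      stop("dwell position coincides with a voxel centre", call. = FALSE)
    r <- point_source_rate(s, dx)
    maxr <- pmax(maxr, r)
    avg_num <- avg_num + r * plan$time_s[k]
    total <- total + r * plan$time_s[k] / 60
  }
  avg <- if (ttot > 0) avg_num / ttot else maxr * 0
  structure(list(x = centres, y = centres, max_rate = maxr,
                 avg_rate = pmin(avg, maxr),  # guard roundoff at 1 dwell
                 total_dose = total, plan = plan, source = s,
                 grid_bins = grid_bins, extent_cm = extent_cm),
            class = "dose_rate_map")
}

#' Dose-rate timeline at a point during plan delivery
#'
#' Sequential dwell-by-dwell dose rate at a query point as the source steps
#' through the plan.
#'
#' @param plan Dwell-plan data frame.
#' @param source A [source_spec()] or air kerma strength.
#' @param point Query point \code{c(x, y, z)} in cm, default the plane
#'   centre.
#' @return Data frame with \code{t_start}, \code{t_end} (s),
#'   \code{rate_gy_min} and \code{dose_gy} per dwell.
#' @export
dose_rate_timeline <- function(plan, source, point = c(0, 0, 0)) {
  check_dwell_plan(plan)
  s <- as_source_spec(source)
  d <- sqrt((plan$x_cm - point[1])^2 + (plan$y_cm - point[2])^2 +
            (plan$z_cm - point[3])^2)
  if (any(d == 0))
    stop("dwell position coincides with the query point", call. = FALSE)
  rate <- point_source_rate(s, d)
  tend <- cumsum(plan$time_s)
  data.frame(t_start = tend - plan$time_s, t_end = tend,
             rate_gy_min = rate, dose_gy = rate * plan$time_s / 60)
}

#' @export
summary.dose_rate_map <- function(object, ...) {
  m <- object$max_rate
  out <- list(min_max_rate = min(m), max_max_rate = max(m),
              mean_max_rate = mean(m),
              total_dose_range = range(object$total_dose),
              n_dwells = nrow(object$plan), sk = object$source$sk)
  class(out) <- "summary.dose_rate_map"
  out
}

#' @export
print.summary.dose_rate_map <- function(x, ...) {
  cat(sprintf("Maximum dose rates across the plane: %.2f to %.2f (avg. %.2f) Gy/min\n",
              x$min_max_rate, x$max_max_rate, x$mean_max_rate))
  cat(sprintf("Total dose range: %.3f to %.3f Gy over %d dwells (S_k %.2f mGy m2/h)\n",
              x$total_dose_range[1], x$total_dose_range[2], x$n_dwells, x$sk))
  invisible(x)
}

#' @export
print.dose_rate_map <- function(x, ...) {
  cat(sprintf("Dose-rate map: %d x %d voxels over %.1f cm\n",
              x$grid_bins, x$grid_bins, x$extent_cm))
  print(summary(x))
  invisible(x)
}

#' Write a dose-rate map to delimited matrices plus a summary
#'
#' Writes \code{<prefix>_max_rate.csv}, \code{<prefix>_avg_rate.csv},
#' \code{<prefix>_total_dose.csv} and \code{<prefix>_summary.txt}.
#'
#' @param map A \code{"dose_rate_map"}.
#' @param prefix Output path prefix.
#' @export
write_dose_rate_map <- function(map, prefix) {
  for (nm in c("max_rate", "avg_rate", "total_dose"))
    utils::write.table(map[[nm]], paste0(prefix, "_", nm, ".csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  s <- summary(map)
  writeLines(c(
    sprintf("max_rate_min_gy_min: %.6g", s$min_max_rate),
    sprintf("max_rate_max_gy_min: %.6g", s$max_max_rate),
    sprintf("max_rate_mean_gy_min: %.6g", s$mean_max_rate),
    sprintf("total_dose_min_gy: %.6g", s$total_dose_range[1]),
    sprintf("total_dose_max_gy: %.6g", s$total_dose_range[2]),
    sprintf("n_dwells: %d", s$n_dwells),
    sprintf("sk_mgy_m2_h: %.6g", s$sk)
  ), paste0(prefix, "_summary.txt"))
  invisible(prefix)
}
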