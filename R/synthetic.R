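#' Simulate a clonogenic assay for one experimental group
#'
#' Generates plate-level colony counts under a known survival-model truth.
#' Each seeded cell independently forms a colony with probability
#' \code{pe * SF(dose)}, so counts are binomial at the plate level; with
#' \code{overdispersion > 0} the per-plate success probability is drawn
#' from a beta distribution with intra-class correlation
#' \code{overdispersion}, giving beta-binomial plate-to-plate
#' heterogeneity. The default design mirrors a triplicate assay seeded at
#' increasing densities for increasing doses (0-8 Gy, 100 to 10000 cells
#' per plate).
#'
#' @param params Named true parameter vector for \code{model}
#'   (LQ: \code{c(alpha =, beta =)}).
#' @param model Survival model generating the truth, default \code{"lq"}.
#' @param pe True plating efficiency in (0, 1].
#' @param doses Dose levels in Gy.
#' @param n_seeded Cells seeded per plate at each dose (same length as
#'   \code{doses}).
#' @param replicates Plates per dose (default 3).
#' @param overdispersion Beta-binomial intra-class correlation in [0, 1);
#'   0 gives pure binomial noise.
#' @param seed Optional integer seed (deterministic output when set).
#' @param modality,dose_rate_gy_min,arm Group labels stamped on the records.
#' @return A colony-record data frame in the schema read by
#'   [survival_curve()].
#' @examples
#' r <- simulate_clonogenic(c(alpha = 0.45, beta = 0.05), seed = 1)
#' survival_curve(r)
#' @export
simulate_clonogenic <- function(params = c(alpha = 0.45, beta = 0.05),
                                model = c("lq", "mtsh", "tc"),
                                pe = 0.5,
                                doses = c(0, 1, 2, 3, 4, 5, 6, 8),
                                n_seeded = c(100, 300, 500, 1000, 4000,
                                             5000, 8000, 10000),
                                replicates = 3, overdispersion = 0,
                                seed = NULL, modality = "HDR-BT",
                                dose_rate_gy_min = 1.1, arm = "CTRL") {
  model <- match.arg(model)
  if (length(n_seeded) != length(doses))
    stop("'n_seeded' must match 'doses' in length", call. = FALSE)
  if (pe <= 0 || pe > 1) stop("'pe' must be in (0, 1]", call. = FALSE)
  if (overdispersion < 0 || overdispersion >= 1)
    stop("'overdispersion' must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sf_true <- sf_model_fun(model)(doses, params)
  p <- pe * sf_true
  if (any(p > 1))
    stop("pe * SF exceeds 1: impossible colony-formation probability",
         call. = FALSE)
  rows <- lapply(seq_along(doses), function(i) {
    pp <- rep(p[i], replicates)
    if (overdispersion > 0 && p[i] > 0 && p[i] < 1) {
      rho <- overdispersion
      pp <- stats::rbeta(replicates, p[i] * (1 - rho) / rho,
                         (1 - p[i]) * (1 - rho) / rho)
    }
    data.frame(modality = modality, dose_rate_gy_min = dose_rate_gy_min,
               arm = arm, dose_gy = doses[i], replicate = seq_len(replicates),
               n_seeded = n_seeded[i],
               n_colonies = stats::rbinom(replicates, n_seeded[i], pp))
  })
  do.call(rbind, rows)
}

#' Simulate per-cell DNA damage foci counts for one condition
#'
#' @param mean_foci True mean foci per cell (>= 0).
#' @param n_cells Number of cells (>= 1).
#' @param distribution \code{"poisson"} (default) or \code{"nbinom"}
#'   (negative binomial, for overdispersed counts).
#' @param dispersion For \code{"nbinom"}: the negative-binomial dispersion
#'   (variance = mean + dispersion * mean^2); must be > 0.
#' @param seed Optional integer seed.
#' @param modality,dose_rate_gy_min,arm Condition labels.
#' @return A foci-record data frame in the schema read by [compare_foci()].
#' @export
simulate_foci <- function(mean_foci, n_cells,
                          distribution = c("poisson", "nbinom"),
                          dispersion = NULL, seed = NULL,
                          modality = "HDR-BT", dose_rate_gy_min = 1.1,
                          arm = "CTRL") {
  distribution <- match.arg(distribution)
  if (mean_foci < 0) stop("'mean_foci' must be >= 0", call. = FALSE)
  if (n_cells < 1) stop("'n_cells' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  counts <- if (distribution == "poisson") {
    stats::rpois(n_cells, mean_foci)
  } else {
    if (is.null(dispersion) || dispersion <= 0)
      stop("negative-binomial simulation needs 'dispersion' > 0",
           call. = FALSE)
    stats::rnbinom(n_cells, size = 1 / dispersion, mu = mean_foci)
  }
  data.frame(modality = modality, dose_rate_gy_min = dose_rate_gy_min,
             arm = arm, cell_id = seq_len(n_cells), n_foci = counts)
}

#' Generate a simple collinear dwell plan
#'
#' Equally spaced dwell positions along x at a fixed height above the
#' scoring plane, symmetric about the origin, with constant dwell times.
#'
#' @param n_dwells Number of dwell positions (>= 1).
#' @param step_cm Spacing between dwells in cm (must be > 0 when
#'   \code{n_dwells > 1}).
#' @param time_per_dwell_s Dwell time in seconds.
#' @param channel_height_cm Source-channel height above the plane, cm
#'   (default 1.5).
#' @return A dwell-plan data frame (\code{dwell_index}, \code{x_cm},
#'   \code{y_cm}, \code{z_cm}, \code{time_s}).
#' @export
generate_dwell_plan <- function(n_dwells, step_cm = 0.5,
                                time_per_dwell_s = 10,
                                channel_height_cm = 1.5) {
  if (n_dwells < 1) stop("'n_dwells' must be >= 1", call. = FALSE)
  if (n_dwells > 1 && step_cm <= 0)
    stop("'step_cm' must be positive for multiple dwells", call. = FALSE)
  x <- (seq_len(n_dwells) - (n_dwells + 1) / 2) * step_cm
  data.frame(dwell_index = seq_len(n_dwells), x_cm = x, y_cm = 0,
             z_cm = channel_height_cm, time_s = time_per_dwell_s)
}
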