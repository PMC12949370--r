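#' End-to-end radiosensitization analysis
#'
#' Runs the full analysis on a table of colony records (and optionally foci
#' records): per experimental group (modality x dose rate x arm) the
#' plating efficiency, survival curve, dose-response fit and bootstrap
#' parameter CIs; per control/treated pair the SER with CI and p-value; per
#' modality with two dose rates the SER difference between the higher- and
#' lower-rate pairs; and per condition the foci comparison. Every
#' stochastic step is seeded from the single master seed, so reruns with
#' the same inputs and seed are bit-identical.
#'
#' @param records Colony-record data frame (see [read_colony_records()]).
#' @param foci Optional foci-record data frame.
#' @param model Dose-response model, default \code{"lq"}.
#' @param max_dose Fit range upper limit in Gy (default 6 for LQ).
#' @param n_boot Bootstrap iterations per inference (default 1000).
#' @param seed Master integer seed (mandatory: every stochastic step
#'   derives from it).
#' @param ctrl_label,treat_label Arm labels, defaults \code{"CTRL"} /
#'   \code{"GNP"}.
#' @param shared_controls Optional named character vector mapping a group
#'   key \code{"modality|dose_rate|arm"} to the group key donating its
#'   dose-0 plates (for conditions that share one unirradiated control).
#' @param target_sf Iso-survival level for the SER, default 0.1.
#' @param alpha_level Significance threshold echoed in the report, default
#'   0.05.
#' @param out_dir Optional directory; when set, curves, fit reports and
#'   bootstrap summaries are written there as delimited/key-value text.
#' @return Object of class \code{"ser_analysis"}: lists \code{curves},
#'   \code{fits}, \code{param_boots} keyed by group; \code{sers} keyed by
#'   \code{"modality|dose_rate"}; \code{delta_sers} keyed by modality;
#'   \code{foci} keyed by condition; and the \code{config} used.
#' @export
run_full_analysis <- function(records, foci = NULL, model = "lq",
                              max_dose = NULL, n_boot = 1000, seed,
                              ctrl_label = "CTRL", treat_label = "GNP",
                              shared_controls = NULL, target_sf = 0.1,
                              alpha_level = 0.05, out_dir = NULL) {
  if (missing(seed) || is.null(seed))
    stop("a master 'seed' is mandatory for the stochastic steps",
         call. = FALSE)
  findings <- validate_colony_records(records)
  findings <- findings[!grepl("no dose-0", findings$message) |
                       !key_of(records)[findings$row] %in%
                         names(shared_controls), , drop = FALSE]
  if (nrow(findings))
    stop("invalid colony records:\n",
         paste(sprintf("  row %s [%s]: %s", findings$row, findings$field,
                       findings$message), collapse = "\n"), call. = FALSE)

  keys <- key_of(records)
  groups <- unique(keys)
  curves <- fits <- param_boots <- list()
  for (g in groups) {
    recs <- records[keys == g, , drop = FALSE]
    donor <- NULL
    if (!is.null(shared_controls) && g %in% names(shared_controls))
      donor <- records[keys == shared_controls[[g]], , drop = FALSE]
    curves[[g]] <- survival_curve(recs, shared_control = donor)
    fits[[g]] <- clonofit(curves[[g]], model = model, max_dose = max_dose,
                          group = g)
    param_boots[[g]] <- boot_params(fits[[g]], n_boot = n_boot,
                                    seed = derive_seed(seed, 0L,
                                                       match(g, groups)))
  }

  meta <- unique(records[c("modality", "dose_rate_gy_min")])
  sers <- list()
  for (i in seq_len(nrow(meta))) {
    kc <- paste(meta$modality[i], meta$dose_rate_gy_min[i], ctrl_label,
                sep = "|")
    kt <- paste(meta$modality[i], meta$dose_rate_gy_min[i], treat_label,
                sep = "|")
    if (!all(c(kc, kt) %in% groups)) next
    pk <- paste(meta$modality[i], meta$dose_rate_gy_min[i], sep = "|")
    sers[[pk]] <- boot_ser(fits[[kc]], fits[[kt]], n_boot = n_boot,
                           seed = derive_seed(seed, 10L, i),
                           target_sf = target_sf,
                           arm_ids = c(2L * i - 1L, 2L * i))
  }

  delta_sers <- list()
  for (m in unique(meta$modality)) {
    rates <- sort(meta$dose_rate_gy_min[meta$modality == m],
                  decreasing = TRUE)
    if (length(rates) != 2) next
    ka <- paste(m, rates[1], sep = "|"); kb <- paste(m, rates[2], sep = "|")
    if (!all(c(ka, kb) %in% names(sers))) next
    fa <- list(fits[[paste(ka, ctrl_label, sep = "|")]],
               fits[[paste(ka, treat_label, sep = "|")]])
    fb <- list(fits[[paste(kb, ctrl_label, sep = "|")]],
               fits[[paste(kb, treat_label, sep = "|")]])
    delta_sers[[m]] <- boot_compare_ser(
      fa, fb, n_boot = n_boot,
      seed = derive_seed(seed, 20L, match(m, unique(meta$modality))),
      target_sf = target_sf)
  }

  foci_cmp <- list()
  if (!is.null(foci)) {
    fmeta <- unique(foci[c("modality", "dose_rate_gy_min")])
    for (i in seq_len(nrow(fmeta))) {
      sub <- foci[foci$modality == fmeta$modality[i] &
                  foci$dose_rate_gy_min == fmeta$dose_rate_gy_min[i], ,
                  drop = FALSE]
      pk <- paste(fmeta$modality[i], fmeta$dose_rate_gy_min[i], sep = "|")
      foci_cmp[[pk]] <- compare_foci(sub, ctrl_label, treat_label)
    }
  }

  out <- structure(list(
    curves = curves, fits = fits, param_boots = param_boots,
    sers = sers, delta_sers = delta_sers, foci = foci_cmp,
    config = list(model = model, max_dose = max_dose, n_boot = n_boot,
                  seed = seed, ctrl_label = ctrl_label,
                  treat_label = treat_label, target_sf = target_sf,
                  alpha_level = alpha_level,
                  input_digest = input_digest(records))
  ), class = "ser_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

key_of <- function(records) {
  paste(records$modality, records$dose_rate_gy_min, records$arm, sep = "|")
}

#' @export
print.ser_analysis <- function(x, ...) {
  cat("Radiosensitization analysis (seed ", x$config$seed, ", ",
      x$config$n_boot, " bootstrap iterations)\n\n", sep = "")
  for (g in names(x$fits)) {
    f <- x$fits[[g]]
    cat(g, ": ", paste(names(coef(f)), "=", round(coef(f), 3),
                       collapse = ", "), "\n", sep = "")
  }
  cat("\n")
  for (pk in names(x$sers)) {
    cat(pk, ": ", sep = "")
    print(x$sers[[pk]])
  }
  for (m in names(x$delta_sers)) {
    cat(m, " (high vs low dose rate): ", sep = "")
    print(x$delta_sers[[m]])
  }
  for (pk in names(x$foci)) {
    cat("Foci ", pk, ": ", sep = "")
    print(x$foci[[pk]])
  }
  invisible(x)
}

write_analysis <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- function(s) gsub("[^A-Za-z0-9._-]", "_", s)
  for (g in names(x$curves))
    write_survival_curve(x$curves[[g]],
                         file.path(dir, paste0("curve_", safe(g), ".csv")))
  for (g in names(x$fits))
    write_fit_report(x$fits[[g]],
                     file.path(dir, paste0("fit_", safe(g), ".txt")),
                     target_sf = x$config$target_sf)
  for (pk in names(x$sers))
    write_boot_report(x$sers[[pk]],
                      file.path(dir, paste0("ser_", safe(pk), ".txt")))
  for (m in names(x$delta_sers))
    write_boot_report(x$delta_sers[[m]],
                      file.path(dir, paste0("delta_ser_", safe(m), ".txt")))
  if (length(x$foci))
    write_foci_comparison(x$foci, file.path(dir, "foci_comparisons.csv"))
  cfg <- x$config
  writeLines(paste0(names(cfg), ": ",
                    vapply(cfg, function(v) paste(format(v), collapse = " "),
                           "")),
             file.path(dir, "config.txt"))
  invisible(dir)
}
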