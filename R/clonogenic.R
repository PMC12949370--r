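#' Plating efficiency from unirradiated plates
#'
#' Pools all dose-0 plates of a group: total colonies divided by total cells
#' seeded. Pooling (rather than averaging per-plate ratios) weights each
#' plate by its seeding density.
#'
#' @param records Colony records (see [read_colony_records()]): a data frame
#'   with at least \code{dose_gy}, \code{n_seeded}, \code{n_colonies}.
#' @return Plating efficiency, a fraction in (0, 1].
#' @examples
#' r <- data.frame(dose_gy = c(0, 0), n_seeded = c(100, 300),
#'                 n_colonies = c(50, 150))
#' plating_efficiency(r)  # 0.5
#' @export
plating_efficiency <- function(records) {
  check_colony_records(records)
  ctrl <- records[records$dose_gy == 0, , drop = FALSE]
  if (nrow(ctrl) == 0)
    stop("no dose-0 (unirradiated control) records in this group", call. = FALSE)
  pe <- sum(ctrl$n_colonies) / sum(ctrl$n_seeded)
  if (pe == 0)
    stop("degenerate control: zero colonies on all dose-0 plates", call. = FALSE)
  pe
}

#' Survival fraction for a plate
#'
#' Colonies per seeded cell, normalised by the group's plating efficiency:
#' \code{(n_colonies / n_seeded) / pe}.
#'
#' @param n_colonies,n_seeded Plate counts (vectorised).
#' @param pe Plating efficiency, must be > 0.
#' @return Survival fraction(s).
#' @examples
#' survival_fraction(120, 4000, pe = 0.5)  # 0.06
#' @export
survival_fraction <- function(n_colonies, n_seeded, pe) {
  if (any(pe <= 0)) stop("plating efficiency must be positive", call. = FALSE)
  if (any(n_seeded < 1)) stop("'n_seeded' must be >= 1", call. = FALSE)
  (n_colonies / n_seeded) / pe
}

#' Per-dose survival curve for one experimental group
#'
#' Computes the group's plating efficiency from its dose-0 plates (or from a
#' designated shared control), converts each plate to a survival fraction,
#' and summarises replicates per dose. The dose-0 entry is pinned to an SF
#' mean of exactly 1 (self-normalisation). Plates with zero colonies at dose
#' > 0 yield SF = 0 and are retained. A dose with a single replicate has its
#' SD reported as \code{NA} (unavailable), not zero.
#'
#' @param records Colony records for one group (one modality, dose rate and
#'   arm). Each (dose, replicate) pair must be unique.
#' @param shared_control Optional colony records supplying the dose-0 plates
#'   when this group shares an unirradiated control with another (e.g. linac
#'   conditions irradiated on the same day from one passage).
#' @return A data frame of class \code{"survival_curve"} with columns
#'   \code{dose_gy}, \code{sf_mean}, \code{sf_sd}, \code{n_replicates}, and
#'   attributes \code{pe} (plating efficiency) and \code{sf_points} (the
#'   per-replicate dose/SF table used for joint fitting).
#' @export
survival_curve <- function(records, shared_control = NULL) {
  check_colony_records(records)
  dup <- duplicated(records[c("dose_gy", "replicate")])
  if (any(dup))
    stop("duplicate (dose, replicate) pairs: rows ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  ctrl_src <- if (is.null(shared_control)) records else shared_control
  pe <- plating_efficiency(ctrl_src)

  recs <- records
  if (!is.null(shared_control)) {
    sc <- shared_control[shared_control$dose_gy == 0, , drop = FALSE]
    recs <- rbind(recs[recs$dose_gy > 0,
                       c("dose_gy", "replicate", "n_seeded", "n_colonies")],
                  sc[, c("dose_gy", "replicate", "n_seeded", "n_colonies")])
  }
  sf <- survival_fraction(recs$n_colonies, recs$n_seeded, pe)
  pts <- data.frame(dose_gy = recs$dose_gy, replicate = recs$replicate, sf = sf)
  pts <- pts[order(pts$dose_gy, pts$replicate), , drop = FALSE]
  rownames(pts) <- NULL

  doses <- sort(unique(pts$dose_gy))
  curve <- data.frame(
    dose_gy = doses,
    sf_mean = vapply(doses, function(d) mean(pts$sf[pts$dose_gy == d]), 0),
    sf_sd = vapply(doses, function(d) {
      x <- pts$sf[pts$dose_gy == d]
      if (length(x) < 2) NA_real_ else stats::sd(x)
    }, 0),
    n_replicates = vapply(doses, function(d) sum(pts$dose_gy == d), 0L)
  )
  curve$sf_mean[curve$dose_gy == 0] <- 1
  attr(curve, "pe") <- pe
  attr(curve, "sf_points") <- pts
  class(curve) <- c("survival_curve", "data.frame")
  curve
}

#' @export
print.survival_curve <- function(x, digits = 4, ...) {
  cat("Clonogenic survival curve\n")
  cat(sprintf("Plating efficiency: %.4f\n", attr(x, "pe")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# I/O

#' Read colony-count records from delimited text
#'
#' Expects header columns \code{modality}, \code{dose_rate_gy_min},
#' \code{arm}, \code{dose_gy} (or \code{dose_cgy} with
#' \code{dose_unit = "cgy"}), \code{replicate}, \code{n_seeded},
#' \code{n_colonies}. cGy doses are converted to Gy on read.
#'
#' @param file Path to a comma-delimited text file.
#' @param dose_unit Unit of the dose column, \code{"gy"} (default) or
#'   \code{"cgy"}.
#' @return A colony-record data frame with doses in Gy.
#' @export
read_colony_records <- function(file, dose_unit = c("gy", "cgy")) {
  dose_unit <- match.arg(dose_unit)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (dose_unit == "cgy") {
    dcol <- if ("dose_cgy" %in% names(df)) "dose_cgy" else "dose_gy"
    df$dose_gy <- df[[dcol]] / 100
    df[[setdiff(dcol, "dose_gy")]] <- NULL
  }
  check_colony_records(df)
  df
}

#' Write a survival curve to delimited text
#'
#' Columns: \code{dose_gy}, \code{sf_mean}, \code{sf_sd},
#' \code{n_replicates}, \code{pe}.
#'
#' @param curve A [survival_curve()] object.
#' @param file Output path.
#' @export
write_survival_curve <- function(curve, file) {
  out <- as.data.frame(curve)
  out$pe <- attr(curve, "pe")
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Read DNA damage-foci records from delimited text
#'
#' Expects header columns \code{modality}, \code{dose_rate_gy_min},
#' \code{arm}, \code{cell_id}, \code{n_foci}.
#'
#' @param file Path to a comma-delimited text file.
#' @return A foci-record data frame.
#' @export
read_foci_records <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_foci_records(df)
  df
}

# ---------------------------------------------------------------------------
# validation

check_colony_records <- function(records) {
  need <- c("dose_gy", "n_seeded", "n_colonies")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("colony records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"replicate" %in% names(records))
    records$replicate <- seq_len(nrow(records))
  bad <- which(records$n_colonies < 0 | records$n_seeded < 1 |
               records$dose_gy < 0 | records$n_colonies > records$n_seeded)
  if (length(bad))
    stop("invalid colony records at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

check_foci_records <- function(records) {
  need <- c("arm", "n_foci")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("foci records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(records$n_foci < 0) || any(records$n_foci != round(records$n_foci)))
    stop("'n_foci' must be non-negative integers", call. = FALSE)
  invisible(records)
}

#' Validate colony records and report findings
#'
#' Schema and invariant checks with machine-readable findings instead of
#' errors: every violated rule is reported with its row number.
#'
#' @param records A colony-record data frame (or a path to one).
#' @return A data frame with columns \code{row}, \code{field},
#'   \code{message}; zero rows when the input is well-formed.
#' @export
validate_colony_records <- function(records) {
  if (is.character(records)) records <- utils::read.csv(records)
  findings <- data.frame(row = integer(), field = character(),
                         message = character(), stringsAsFactors = FALSE)
  add <- function(row, field, message)
    rbind(findings, data.frame(row = row, field = field, message = message))
  need <- c("modality", "dose_rate_gy_min", "arm", "dose_gy", "replicate",
            "n_seeded", "n_colonies")
  for (col in setdiff(need, names(records)))
    findings <- add(NA_integer_, col, "missing column")
  if (nrow(findings)) return(findings)
  for (i in which(records$n_colonies > records$n_seeded))
    findings <- add(i, "n_colonies", "more colonies than cells seeded")
  for (i in which(records$n_seeded < 1))
    findings <- add(i, "n_seeded", "fewer than one cell seeded")
  for (i in which(records$n_colonies < 0))
    findings <- add(i, "n_colonies", "negative colony count")
  for (i in which(records$dose_gy < 0))
    findings <- add(i, "dose_gy", "negative dose")
  grp <- interaction(records$modality, records$dose_rate_gy_min, records$arm,
                     drop = TRUE)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    if (!any(records$dose_gy[rows] == 0))
      findings <- add(rows[1], "dose_gy",
                      paste0("group ", g, " has no dose-0 control"))
  }
  findings
}
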