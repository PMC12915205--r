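# Report writers.
#
# JSON is the canonical, lossless representation (nested per-object
# records, full parameter echo); CSV is a flat projection with one row per
# spot/cell plus a summary row. Reports are validated against their
# structural invariants before anything touches the disk, so an
# inconsistent report can never be written.

#' Validate a report's structural invariants
#'
#' @param report a \code{SpotReport}, \code{InfiltrationResult} or
#'   \code{PooledSummary}.
#' @return the report, invisibly, if consistent; otherwise an error naming
#'   the violated invariant.
#' @export
validate_report <- function(report) {
  if (inherits(report, "SpotReport")) {
    if (report$n_labeled != report$n_accepted + report$n_rejected_small +
        report$n_rejected_large)
      stop("SpotReport invariant violated: n_labeled (", report$n_labeled,
           ") != accepted + rejected_small + rejected_large (",
           report$n_accepted + report$n_rejected_small +
             report$n_rejected_large, ")")
    if (report$n_accepted != sum(report$spots$accepted))
      stop("SpotReport invariant violated: n_accepted (", report$n_accepted,
           ") != number of accepted spot records (",
           sum(report$spots$accepted), ")")
  } else if (inherits(report, "InfiltrationResult")) {
    n_inf <- sum(report$records$classification == "infiltrated")
    if (report$n_infiltrated != n_inf)
      stop("InfiltrationResult invariant violated: n_infiltrated (",
           report$n_infiltrated, ") != infiltrated records (", n_inf, ")")
    expect_frac <- if (report$n_cells_total > 0)
      report$n_infiltrated / report$n_cells_total else 0
    if (abs(report$infiltrated_fraction - expect_frac) > 1e-12)
      stop("InfiltrationResult invariant violated: infiltrated_fraction")
  } else if (!inherits(report, "PooledSummary")) {
    stop("not a writable report: ", paste(class(report), collapse = "/"))
  }
  invisible(report)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, strip_classes)
  }
  x
}

#' Write a report to JSON or CSV
#'
#' @param report a validated \code{SpotReport}, \code{InfiltrationResult}
#'   or \code{PooledSummary}.
#' @param path output file.
#' @param format \code{"json"} (canonical, lossless) or \code{"csv"}
#'   (one row per record plus a summary row).
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  validate_report(report)
  if (format == "json") {
    payload <- strip_classes(report)
    payload$class <- class(report)[1L]
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", dataframe = "columns")
  } else {
    utils::write.csv(report_as_rows(report), path, row.names = FALSE)
  }
  invisible(path)
}

report_as_rows <- function(report) {
  if (inherits(report, "SpotReport")) {
    sp <- report$spots
    rows <- data.frame(record = rep("spot", nrow(sp)),
                       well_id = rep(report$well_id, nrow(sp)), sp)
    summary_row <- data.frame(record = "summary", well_id = report$well_id,
                              spot_id = NA, centroid_row_px = NA,
                              centroid_col_px = NA, centroid_y_um = NA,
                              centroid_x_um = NA,
                              area_px = report$n_labeled,
                              area_um2 = report$size_stats$mean,
                              equivalent_diameter_um = NA,
                              mean_intensity = NA, eccentricity = NA,
                              accepted = report$n_accepted)
    rbind(rows, summary_row)
  } else if (inherits(report, "InfiltrationResult")) {
    rc <- report$records
    rows <- data.frame(record = rep("cell", nrow(rc)),
                       chamber_id = rep(report$chamber_id, nrow(rc)), rc)
    summary_row <- data.frame(record = "summary",
                              chamber_id = report$chamber_id,
                              cell_id = report$n_cells_total,
                              signed_distance_um = report$organoid_volume_um3,
                              classification = paste0("infiltrated=",
                                                      report$n_infiltrated))
    rbind(rows, summary_row)
  } else {
    ids <- report$chamber_ids
    x <- length(ids)
    data.frame(record = c(rep("chip", x), "summary"),
               chamber_id = c(ids, "pooled"),
               n_infiltrated = c(report$n_infiltrated$values,
                                 report$n_infiltrated$mean),
               n_infiltrated_sem = c(rep(NA, x), report$n_infiltrated$sem),
               infiltrated_fraction = c(report$infiltrated_fraction$values,
                                        report$infiltrated_fraction$mean),
               infiltrated_fraction_sem = c(rep(NA, x),
                                            report$infiltrated_fraction$sem))
  }
}

#' Read a JSON report back into its report object
#'
#' @param path JSON file written by [write_report()].
#' @return the reconstructed report, revalidated.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$class
  x$class <- NULL
  if (identical(cls, "SpotReport")) {
    x$spots <- as.data.frame(x$spots)
    x$size_stats <- lapply(x$size_stats, function(v) if (is.null(v)) NA_real_ else v)
  } else if (identical(cls, "InfiltrationResult")) {
    x$records <- as.data.frame(x$records)
    if (is.null(x$organoid_volume_um3)) x$organoid_volume_um3 <- NA_real_
    if (is.null(x$infiltrated_per_mm3)) x$infiltrated_per_mm3 <- NA_real_
  } else if (!identical(cls, "PooledSummary")) {
    stop("unrecognised report class in ", path, ": ", cls)
  }
  report <- structure(x, class = cls)
  validate_report(report)
  report
}
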