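#' Write a results table to CSV or JSON
#'
#' Serializes per-NMJ records with a deterministic column order. Distance
#' columns (names ending in `_um`) are rounded to 3 decimals (micrometre
#' precision well below a voxel), so re-reading reproduces values exactly at
#' that precision, and CSV and JSON agree record-wise.
#'
#' @param table A data frame of records, or a study result object carrying a
#'   `records` data frame (e.g. from [accumulation_study()] or
#'   [run_proximity_study()]).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.null(table)) nmj_validation_error("table must be non-null")
  if (!is.data.frame(table)) {
    if (is.list(table) && is.data.frame(table$records)) table <- table$records
    else nmj_validation_error("table must be a data frame or carry $records")
  }
  tab <- table
  um <- grepl("_um$", names(tab))
  for (j in which(um)) tab[[j]] <- round(as.numeric(tab[[j]]), 3)
  dir <- dirname(path)
  if (!dir.exists(dir)) nmj_io_error(sprintf("directory does not exist: %s", dir))
  if (format == "csv") {
    tryCatch(utils::write.csv(tab, path, row.names = FALSE),
             error = function(e) nmj_io_error(conditionMessage(e)))
  } else {
    jsonlite::write_json(tab, path, auto_unbox = FALSE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
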