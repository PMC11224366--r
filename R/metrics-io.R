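## Metric table I/O: rectangular per-muscle records, CSV or JSON.

#' Write a per-muscle metrics table
#'
#' Records are written with a stable column order and 6-significant-digit
#' numeric formatting, so save -> load -> save is byte-identical and a
#' round-trip read reproduces the written values.
#'
#' @param rows data.frame of per-muscle metric records.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(rows))
    mq_stop("rows must be a data.frame", "mq_parameter_error")
  if (nrow(rows) == 0L)
    mq_warn("writing empty metrics table (header only)")
  out <- rows
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  for (j in which(num)) out[[j]] <- signif(out[[j]], 6)
  ok <- tryCatch({
    if (format == "csv") {
      write.csv(out, path, row.names = FALSE)
    } else {
      jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    mq_stop(sprintf("cannot write metrics table to %s: %s",
                    path, conditionMessage(ok)), "mq_io_error")
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    mq_stop(sprintf("file not found: %s", path), "mq_io_error")
  if (format == "csv") read.csv(path, stringsAsFactors = FALSE)
  else as.data.frame(jsonlite::fromJSON(path))
}
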