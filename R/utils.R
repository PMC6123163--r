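#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx median qnorm quantile rbinom rnorm runif sd setNames
#' @importFrom utils head tail write.csv
#' @importFrom rlang .data
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed condition helpers: every failure raised by the package carries
# class "pc_error" plus a specific subclass, so batch drivers can catch and
# log per-file problems without aborting a whole ingest.
pc_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "pc_error", "error")))
}

pc_parse_error <- function(path, detail) {
  pc_abort(sprintf("malformed JSON in '%s': %s", path, detail),
           class = "pc_parse_error", path = path)
}

pc_validation_error <- function(field, detail, path = NULL) {
  msg <- sprintf("invalid field '%s': %s", field, detail)
  if (!is.null(path)) msg <- sprintf("%s (file '%s')", msg, path)
  pc_abort(msg, class = "pc_validation_error", field = field, path = path)
}

# ISO-8601 datetimes, one convention package-wide: UTC, second resolution,
# trailing "Z" on output; "Z" or no zone accepted on input.
parse_iso_datetime <- function(x) {
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
  if (anyNA(out)) stop("unparseable ISO-8601 datetime: ", x[is.na(out)][1])
  out
}

format_iso_datetime <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
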