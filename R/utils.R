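#' @importFrom rlang abort %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct count n bind_rows rename
#' @importFrom tibble tibble as_tibble
NULL

abort_format <- function(msg, ...) {
  abort(msg, class = "compmut_format_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "compmut_validation_error", ...)
}

abort_stat <- function(msg, class = "compmut_stat_error", ...) {
  abort(msg, class = class, ...)
}

# shared stopifnot-style check for a data frame having required columns
check_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# case-normalized protein-change key used for hotspot lookups
pchange_key <- function(x) toupper(sub("^p\\.", "", x))
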