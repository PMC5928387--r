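#' Round half away from zero
#'
#' Reported medians use commercial ("half up") rounding rather than the IEC
#' banker's rounding of [base::round()], so that e.g. 5.75 months is reported
#' as 5.8.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half up.
#' @examples
#' round_half_up(5.75, 1) # 5.8
#' round_half_up(1.75, 1) # 1.8
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# path to a packaged extdata file; errors if missing
ncr_extdata <- function(file) {
  p <- system.file("extdata", file, package = "ncrscreen")
  if (!nzchar(p)) abort(paste0("packaged data file not found: ", file))
  p
}

# stop with a schema error naming row and column
schema_abort <- function(row, column, why) {
  abort(sprintf("schema error at row %s, column '%s': %s", row, column, why),
        class = "ncrscreen_schema_error")
}
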