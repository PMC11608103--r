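#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Numeric formatter used by all serializers: full precision, no scientific
# surprises on round-trip.
fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = NA, trim = TRUE),
         character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

warnf <- function(fmt, ...) warn(sprintf(fmt, ...))

# named numeric -> named numeric with given names, filling zeros
expand_named <- function(x, names) {
  out <- stats::setNames(numeric(length(names)), names)
  if (length(x)) out[names(x)[names(x) %in% names]] <- x[names(x) %in% names]
  out
}
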