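#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Fail with a classed condition so callers/tests can target specific errors.
stop_conjscreen <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "conjscreen_error"), ...)
}

# Strict numeric parsing: reject anything that is not a plain decimal number.
# Locale-independent ("." decimal point), no coercion of malformed cells.
parse_strict_numeric <- function(x, context = "value") {
  x <- trimws(x)
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
  if (!all(ok)) {
    stop_conjscreen(
      sprintf("malformed numeric %s: '%s'", context, x[!ok][1]),
      "conjscreen_parse_error"
    )
  }
  as.numeric(x)
}

# Deterministic formatting used by all writers so read/write round trips are
# byte-exact: up to 15 significant digits, "." decimal point, no scientific
# drift between platforms.
format_num <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    # trim trailing zeros after a decimal point, but keep integers intact
    if (grepl("\\.", s)) s <- sub("\\.?0+$", "", s)
    s
  }, character(1))
}

# Derive an independent 32-bit seed for a named pseudo-random substream.
# Adding a new stream name never perturbs draws made under other names.
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  force(code)
}
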