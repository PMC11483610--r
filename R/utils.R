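# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(sprintf("'%s' must be a positive finite number", name))
  }
  invisible(x)
}

assert_fraction <- function(x, name, open_lower = FALSE) {
  lo_ok <- if (open_lower) all(x > 0) else all(x >= 0)
  if (!is.numeric(x) || any(!is.finite(x)) || !lo_ok || any(x > 1)) {
    stop_domain(sprintf("'%s' must be a fraction in %s0, 1]", name,
                        if (open_lower) "(" else "["))
  }
  invisible(x)
}

#' Trapezoid integration over an irregular grid
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

extdata_path <- function(...) {
  p <- system.file("extdata", ..., package = "isopbpk")
  if (!nzchar(p)) stop_domain("packaged data file not found: ", file.path(...))
  p
}

read_ref_csv <- function(...) {
  utils::read.csv(extdata_path(...), comment.char = "#", strip.white = TRUE)
}
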