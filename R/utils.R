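# Internal input checkers. All user-facing errors are classed so callers and
# tests can condition on them.

fd_stop <- function(message, class) {
  rlang::abort(message, class = c(class, "fluordepth_error"))
}

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         finite = TRUE, class = "fluordepth_invalid_input") {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    fd_stop(sprintf("`%s` must be numeric and non-missing.", name), class)
  }
  if (finite && !all(is.finite(x))) {
    fd_stop(sprintf("`%s` must be finite.", name), class)
  }
  if (positive && !all(x > 0)) {
    fd_stop(sprintf("`%s` must be > 0.", name), class)
  }
  if (nonnegative && !all(x >= 0)) {
    fd_stop(sprintf("`%s` must be >= 0.", name), class)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    fd_stop(sprintf("`%s` must be TRUE or FALSE.", name), "fluordepth_invalid_input")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
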