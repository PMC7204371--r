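# Input validation helpers. Validation failures signal a classed condition so
# the CLI can map them to exit status 2.

stop_validation <- function(...) {
  msg <- paste0(...)
  stop(structure(class = c("shearfuse_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_gray_image <- function(x, name = deparse(substitute(x)),
                              require_finite = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_validation(name, " must be a numeric matrix")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop_validation(name, " must be at least 2x2")
  if (require_finite && !all(is.finite(x)))
    stop_validation(name, " contains non-finite pixels")
  invisible(x)
}

assert_same_shape <- function(..., names = NULL) {
  mats <- list(...)
  if (is.null(names)) names <- paste0("argument ", seq_along(mats))
  d <- dim(mats[[1L]])
  for (i in seq_along(mats)[-1L]) {
    if (!identical(dim(mats[[i]]), d))
      stop_validation(names[i], " (", paste(dim(mats[[i]]), collapse = "x"),
                      ") does not match the shape of ", names[1L],
                      " (", paste(d, collapse = "x"), ")")
  }
  invisible(d)
}

assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop_validation(name, " must be a finite numeric scalar")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_validation(name, " must be in ",
                    if (strict_lower) "(" else "[", lower, ", ", upper, "]")
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
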