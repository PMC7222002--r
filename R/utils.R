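# internal numerical helpers

# trapezoidal integral of y over x; x must be sorted increasing
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# R^2 about the mean; can be negative for a through-origin or constrained fit
r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    return(if (ss_res == 0) 1 else NA_real_)
  }
  1 - ss_res / ss_tot
}

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "ointchar_input_error")

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stop_input("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_input("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}
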