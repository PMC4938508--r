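# Small shared helpers.

#' Round half away from zero
#'
#' Commercial rounding (0.005 -> 0.01 at two digits), used for reported
#' percentages so printed tables are reproduced exactly. Base `round()`
#' rounds half to even, which differs on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# rbind a list of data frames, dropping NULLs; `empty` is returned when
# nothing is left (plain do.call(rbind, ...) on an all-NULL list would
# dispatch to the default method and produce garbage).
.rbind_rows <- function(rows, empty) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Windowed running mean with symmetric shrinking at the termini: at
# position i the window is i-r..i+r with r = min((window-1)/2, i-1, n-i),
# so every position gets a value and terminal windows stay centred.
.window_mean <- function(x, window) {
  stopifnot(window >= 3L, window %% 2L == 1L)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  r <- pmin(h, i - 1L, n - i)
  cs <- c(0, cumsum(x))
  (cs[i + r + 1L] - cs[i - r]) / (2L * r + 1L)
}
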