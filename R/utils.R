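# Shared helpers: wall-clock parsing, reflective folding for bounded random
# walks, small validators.

parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x) %% 86400)
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?$", x))[[1]]
  if (length(m) == 0) {
    abort(sprintf("invalid clock time '%s'; expected \"hh:mm\" or \"hh:mm:ss\"", x))
  }
  hh <- as.numeric(m[2]); mm <- as.numeric(m[3])
  ss <- if (m[4] == "") 0 else as.numeric(m[4])
  if (hh > 23 || mm > 59 || ss > 59) {
    abort(sprintf("invalid clock time '%s'", x))
  }
  hh * 3600 + mm * 60 + ss
}

format_clock <- function(sec) {
  sec <- round(sec %% 86400)
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

# Fold an unconstrained coordinate into [lo, hi] by reflection (triangular
# wave), vectorised; used to keep the rendered target inside the frame.
fold_reflect <- function(x, lo, hi) {
  L <- hi - lo
  if (L <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * L)
  lo + pmin(y, 2 * L - y)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE,
                         integerish = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict_min) x > min else x >= min) && x <= max &&
    (!integerish || abs(x - round(x)) < 1e-8)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single %s %s %s%s", name,
      if (integerish) "integer" else "number",
      if (strict_min) ">" else ">=", format(min),
      if (is.finite(max)) paste0(" and <= ", format(max)) else ""
    ))
  }
  invisible(x)
}

is_multiple <- function(x, of, tol = 1e-8) {
  r <- x / of
  abs(r - round(r)) < tol
}

# seconds-per-bin helper shared by the tibble-backed time series classes
bin_s_of <- function(x) {
  b <- attr(x, "bin_s", exact = TRUE)
  if (is.null(b)) abort("object has no `bin_s` attribute; not a sleepcam time series?")
  b
}

start_clock_of <- function(x) attr(x, "start_clock", exact = TRUE) %||% "08:00"

span_s <- function(x) nrow(x) * bin_s_of(x)
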