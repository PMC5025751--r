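# Internal helpers shared across modules.

#' Wrap an angle in degrees to the interval (-180, 180]
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element in (-180, 180].
#' @examples
#' wrap_angle(c(0, 180, -180, 360, 190))
#' @export
wrap_angle <- function(deg) {
  stopifnot(is.numeric(deg))
  out <- deg %% 360
  out[out > 180] <- out[out > 180] - 360
  # -180 maps to 180 under the (-180, 180] convention
  out[out == -180] <- 180
  out
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a root seed. Stays below 2^31.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + h * 7919) %% 2147483629L)
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number", name))
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_domain(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}
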