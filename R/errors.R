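#' @keywords internal
"_PACKAGE"

# Classed conditions. Every error raised by the package carries a specific
# class ("heartkit_<kind>") plus the umbrella class "heartkit_error", so
# callers can catch either the precise failure or anything from the package.
hk_stop <- function(class, msg, ...) {
  message <- if (length(list(...))) sprintf(msg, ...) else msg
  cond <- structure(
    class = c(paste0("heartkit_", class), "heartkit_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

hk_warn <- function(class, msg, ...) {
  message <- if (length(list(...))) sprintf(msg, ...) else msg
  cond <- structure(
    class = c(paste0("heartkit_", class), "heartkit_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  )
  warning(cond)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# random stream.
hk_with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Population standard deviation (divisor n, not n-1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
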