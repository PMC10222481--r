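# internal helpers shared across modules

# canonical sensor order: top-left, bottom-left, top-right, bottom-right
SEAT_SENSORS <- c("Lt", "Lb", "Rt", "Rb")

seat_abort <- function(message, class, call = NULL) {
  stop(structure(
    class = c(class, "seatsense_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream; a NULL seed leaves the stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    seat_abort(sprintf("`%s` must be a single finite number", name),
               "seatsense_value_error")
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    seat_abort(sprintf("`%s` must be %s %s", name,
                       if (strict) ">" else ">=", format(lower)),
               "seatsense_value_error")
  }
  invisible(x)
}
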