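# Independent batch oracle: recomputes the full decode -> filter -> normalize
# -> flag chain on a whole recorded trace at once, using vectorized matrix
# algebra and stats::filter instead of the package's streaming queues.

oracle_decode_counts <- function(counts, cfg) {
  v <- counts * cfg$supply_voltage / (2^cfg$adc_bits - 1)
  g <- cfg$ref_conductance * v / (cfg$supply_voltage - v)
  pmax((g - cfg$cal_intercept) / cfg$cal_slope, 0)
}

# trace: data.frame with columns tick, Lt, Lb, Rt, Rb (ADC counts)
oracle_session <- function(trace, cfg) {
  sensors <- c("Lt", "Lb", "Rt", "Rb")
  cm <- as.matrix(trace[, sensors])
  f <- apply(cm, 2, oracle_decode_counts, cfg = cfg)
  u <- cfg$accuracy_fraction * f / sqrt(3)
  L <- cfg$queue_length
  ma <- apply(f, 2, function(x) as.numeric(stats::filter(x, rep(1 / L, L), sides = 1)))
  rss <- apply(u^2, 2, function(x) sqrt(as.numeric(stats::filter(x, rep(1, L), sides = 1))))
  uk <- if (cfg$uncertainty_propagation == "mean") rss / L else rss
  ref <- ma[L, ]
  rows <- seq.int(L + 1L, nrow(f))
  nl <- sweep(ma - uk, 2, ref, "/")
  nu <- sweep(ma + uk, 2, ref, "/")
  asym <- (nu[rows, "Rt"] < nl[rows, "Lt"]) | (nu[rows, "Rb"] < nl[rows, "Lb"]) |
          (nu[rows, "Lt"] < nl[rows, "Rt"]) | (nu[rows, "Lb"] < nl[rows, "Rb"])
  flags <- data.frame(tick = trace$tick[rows], asymmetric = unname(asym))
  prev <- c(FALSE, asym[-length(asym)])
  edge <- which(asym != prev)
  events <- data.frame(
    tick_index = flags$tick[edge],
    direction = ifelse(asym[edge], "ToAsymmetric", "ToSymmetric"),
    stringsAsFactors = FALSE
  )
  list(reference = ref, flags = flags, events = events)
}
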