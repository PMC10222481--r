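# Serial frame dialect: one ASCII line per tick,
#   <tick>,<Lt>,<Lb>,<Rt>,<Rb>
# counts as base-10 integers, trailing whitespace tolerated. Malformed lines
# are skipped by readers and counted, never fatal mid-stream.

#' Format a raw sample as a serial frame line
#'
#' @param sample A [raw_sample()].
#' @return A single string `"<tick>,<Lt>,<Lb>,<Rt>,<Rb>"`.
#' @export
format_frame <- function(sample) {
  stopifnot(inherits(sample, "raw_sample"))
  paste(c(sample$tick_index, as.integer(round(sample$counts[SEAT_SENSORS]))),
        collapse = ",")
}

#' Parse one serial frame line
#'
#' @param line A single text line.
#' @param cfg A [readout_config()] used to range-check the counts.
#' @return A [raw_sample()], or `NULL` if the line is malformed (wrong field
#'   count, non-integer fields, or counts out of ADC range).
#' @export
parse_frame <- function(line, cfg) {
  stopifnot(inherits(cfg, "readout_config"))
  if (!is.character(line) || length(line) != 1L) return(NULL)
  line <- trimws(line)
  if (!nzchar(line)) return(NULL)
  fields <- strsplit(line, ",", fixed = TRUE)[[1]]
  if (length(fields) != 5L) return(NULL)
  fields <- trimws(fields)
  if (!all(grepl("^[0-9]+$", fields))) return(NULL)
  vals <- suppressWarnings(as.numeric(fields))
  if (any(is.na(vals))) return(NULL)
  counts <- vals[-1]
  if (any(counts > 2^cfg$adc_bits - 1)) return(NULL)
  names(counts) <- SEAT_SENSORS
  raw_sample(vals[1], counts, cfg)
}

#' Read a serial frame stream
#'
#' Reads frames from a file or a character vector of lines. Malformed lines
#' are skipped and counted; blank lines are ignored.
#'
#' @param x Path to a frame file, or a character vector of lines.
#' @param cfg A [readout_config()].
#' @return A list with `samples` (list of [raw_sample()]) and `frame_errors`
#'   (count of malformed lines).
#' @export
read_frames <- function(x, cfg) {
  lines <- if (length(x) == 1L && !grepl("[,\n]", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    as.character(x)
  }
  lines <- lines[nzchar(trimws(lines))]
  samples <- vector("list", length(lines))
  errors <- 0L
  k <- 0L
  for (ln in lines) {
    s <- parse_frame(ln, cfg)
    if (is.null(s)) {
      errors <- errors + 1L
    } else {
      k <- k + 1L
      samples[[k]] <- s
    }
  }
  list(samples = samples[seq_len(k)], frame_errors = errors)
}

#' Write frames to a file in the serial dialect
#'
#' @param x A simulated trace (see [generate_trace()]), a data frame with
#'   columns `tick, Lt, Lb, Rt, Rb`, or a list of [raw_sample()]s.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path) {
  lines <- frame_lines(x)
  writeLines(lines, path)
  invisible(path)
}

# turn any accepted frame container into dialect lines
frame_lines <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("tick", SEAT_SENSORS) %in% names(x)))
    apply(x[, c("tick", SEAT_SENSORS)], 1L, function(r) {
      paste(as.integer(round(r)), collapse = ",")
    })
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "raw_sample"))) {
    vapply(x, format_frame, character(1))
  } else {
    seat_abort("cannot format frames from this object", "seatsense_value_error")
  }
}

# normalize any supported input into an ordered list of entries, keeping
# malformed lines in place as NULL so sessions can count them as they stream
as_frame_stream <- function(x, cfg) {
  if (is.null(x)) return(list())
  if (inherits(x, "raw_sample")) return(list(x))
  if (is.data.frame(x)) {
    stopifnot(all(c("tick", SEAT_SENSORS) %in% names(x)))
    return(lapply(seq_len(nrow(x)), function(i) {
      raw_sample(x$tick[i],
                 c(Lt = x$Lt[i], Lb = x$Lb[i], Rt = x$Rt[i], Rb = x$Rb[i]),
                 cfg)
    }))
  }
  if (is.character(x)) {
    lines <- if (length(x) == 1L && !grepl("[,\n]", x) && file.exists(x)) {
      readLines(x, warn = FALSE)
    } else {
      x
    }
    lines <- lines[nzchar(trimws(lines))]
    return(lapply(lines, parse_frame, cfg = cfg))
  }
  if (is.list(x)) {
    ok <- vapply(x, function(e) is.null(e) || inherits(e, "raw_sample"), logical(1))
    if (all(ok)) return(x)
  }
  seat_abort("unsupported frame source", "seatsense_value_error")
}
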