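# Thermal-cycle segmentation from the meander synchronization channels.
#
# Indexing convention: 0-based sample indices and half-open [start, end)
# intervals everywhere in this module (slicing converts to R's 1-based
# subscripts internally).

#' Signal a synchronization error
#' @noRd
abort_sync <- function(message, ...) {
  abort_enose(message, "enose_sync_error", ...)
}

# Run-length encode a binarized sync channel with debouncing: maximal runs
# shorter than `min_run` samples are treated as glitches and absorbed into
# the preceding run (a leading short run is absorbed into the following
# one). Returns data.frame(value, start, end) with 0-based half-open runs.
sync_runs <- function(x, min_run = 5L) {
  r <- rle(as.integer(x > 0))
  val <- r$values; len <- r$lengths
  repeat {
    short <- which(len < min_run)
    if (!length(short)) break
    k <- short[1]
    if (k == 1L) {
      # absorb into the following run
      val[1] <- val[2]
    }
    # merge any adjacent equal-valued runs (absorbing k into its neighbour)
    if (k > 1L) val[k] <- val[k - 1L]
    keep <- c(TRUE, val[-1] != val[-length(val)])
    len <- as.vector(tapply(len, cumsum(keep), sum))
    val <- val[keep]
  }
  ends <- cumsum(len)
  data.frame(value = val, start = c(0L, head(ends, -1L)), end = ends)
}

# 0-based indices of high->low and low->high transitions after debouncing.
sync_transitions <- function(x, min_run = 5L) {
  runs <- sync_runs(x, min_run)
  n <- nrow(runs)
  if (n < 2L) return(list(high_to_low = integer(), low_to_high = integer()))
  starts <- runs$start[-1L]
  to <- runs$value[-1L]
  list(high_to_low = starts[to == 0L], low_to_high = starts[to == 1L])
}

#' Detect thermal cycles from the synchronization channels
#'
#' Locates heating/cooling periods from the two meander channels (high
#' during heating, zero during cooling). The two channels must agree on
#' every transition index after debouncing (runs shorter than `min_run`
#' samples are ignored as glitches); disagreement is a hard
#' synchronization error, because acquisition integrity is these channels'
#' only purpose. Only cycles whose full 165-sample cooling phase fits in
#' the record are returned; a partial first heating phase is tolerated
#' (the recording may open mid-phase).
#'
#' @param rec a `sensor_record`.
#' @param min_run debounce length in samples (default 5).
#' @return data.frame with columns `cycle_index` (1-based count of complete
#'   cycles), `heat_start`, `cool_start`, `cool_end` (0-based sample
#'   indices, half-open).
#' @export
detect_cycles <- function(rec, min_run = 5L) {
  a <- rec$channels[15, ]
  b <- rec$channels[16, ]
  ta <- sync_transitions(a, min_run)
  tb <- sync_transitions(b, min_run)
  if (!identical(ta, tb)) {
    all_a <- sort(c(ta$high_to_low, ta$low_to_high))
    all_b <- sort(c(tb$high_to_low, tb$low_to_high))
    m <- min(length(all_a), length(all_b))
    diff_at <- c(all_a[seq_len(m)][all_a[seq_len(m)] != all_b[seq_len(m)]],
                 all_a[-seq_len(m)], all_b[-seq_len(m)])[1]
    abort_sync(sprintf(
      "sync channels 15 and 16 disagree on a phase transition near sample %d",
      diff_at))
  }

  cool_len <- 165L
  n_samples <- length(a)
  hl <- ta$high_to_low
  lh <- ta$low_to_high
  cycles <- data.frame(cycle_index = integer(), heat_start = integer(),
                       cool_start = integer(), cool_end = integer())
  idx <- 0L
  for (t in hl) {
    if (t + cool_len > n_samples) next # cooling phase truncated
    nxt <- lh[lh > t]
    if (length(nxt) && nxt[1] < t + cool_len) {
      abort_sync(sprintf(
        "cooling phase starting at sample %d ends after only %d samples (expected %d)",
        t, nxt[1] - t, cool_len))
    }
    prev_lh <- lh[lh < t]
    heat_start <- if (length(prev_lh)) max(prev_lh) else {
      if (length(a) && a[1] > 0) 0L else next # record opens mid-cooling: no heat observed
    }
    idx <- idx + 1L
    cycles[idx, ] <- list(idx, as.integer(heat_start), as.integer(t),
                          as.integer(t + cool_len))
  }
  if (nrow(cycles) < 4L) {
    abort_enose(sprintf(
      "only %d complete thermal cycle(s) detected; at least 4 are required",
      nrow(cycles)), "enose_insufficient_cycles_error")
  }
  cycles
}

#' Extract per-sensor cooling segments
#'
#' Slices, for each of the 14 gas-sensor channels and each complete cycle,
#' the 165-sample cooling block `[cool_start, cool_end)`.
#'
#' @param rec a `sensor_record`.
#' @param cycles cycle table from [detect_cycles()].
#' @return an object of class `segmented_record`: record id, cycle table, a
#'   `14 x n_cycles x 165` array `cooling_segments`, and the subject
#'   metadata passed through.
#' @export
extract_cooling_segments <- function(rec, cycles) {
  n_cyc <- nrow(cycles)
  seg <- array(NA_real_, dim = c(ENOSE_N_SENSORS, n_cyc, 165L),
               dimnames = list(sensor = rec$channel_names[1:14],
                               cycle = NULL, sample = NULL))
  for (c_i in seq_len(n_cyc)) {
    cols <- (cycles$cool_start[c_i] + 1L):cycles$cool_end[c_i]
    seg[, c_i, ] <- rec$channels[1:14, cols]
  }
  structure(
    list(record_id = rec$record_id, cycles = cycles, cooling_segments = seg,
         age = rec$age, sex = rec$sex, smoking = rec$smoking,
         label = rec$label),
    class = "segmented_record"
  )
}

#' Segment a record end to end
#'
#' @param rec a `sensor_record`.
#' @param min_run debounce length, see [detect_cycles()].
#' @return a `segmented_record`.
#' @export
segment_record <- function(rec, min_run = 5L) {
  extract_cooling_segments(rec, detect_cycles(rec, min_run))
}

#' @export
print.segmented_record <- function(x, ...) {
  cat(sprintf("<segmented_record '%s'> %d complete cycles, 14 x %d x 165 cooling array\n",
              x$record_id, nrow(x$cycles), nrow(x$cycles)))
  invisible(x)
}

#' Dump detected cooling boundaries as a BED-like table
#'
#' Three columns: record_id, cool_start, cool_end (0-based, half-open),
#' tab-separated, no header.
#'
#' @param rec a `sensor_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cycle_bounds <- function(rec, path) {
  cyc <- detect_cycles(rec)
  data.table::fwrite(
    data.frame(rec$record_id, cyc$cool_start, cyc$cool_end),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}
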