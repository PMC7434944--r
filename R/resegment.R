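#' Mean and population standard deviation of a signal interval
#'
#' @param signal an `nr_raw_signal` or numeric vector.
#' @param start 0-based first sample of the interval.
#' @param length number of samples; must be positive.
#' @return numeric vector `c(mean, stdv)`; `stdv` is the population (divide
#'   by n) standard deviation, matching basecaller event statistics.
#' @export
interval_stats <- function(signal, start, length) {
  x <- if (inherits(signal, "nr_raw_signal")) signal$samples else signal
  if (length <= 0) stop("interval length must be positive", call. = FALSE)
  if (start < 0 || start + length > base::length(x)) {
    stop("interval [", start, ", ", start + length,
         ") outside signal of ", base::length(x), " samples", call. = FALSE)
  }
  v <- x[(start + 1):(start + length)]
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  c(mean = m, stdv = s)
}

#' Re-segment basecaller events to one event per called base
#'
#' Converts the basecaller's event stream into exactly `sum(move)` events,
#' one per called base in read order, using the `move` field:
#' \itemize{
#'   \item `move == 1` starts a new base-level event;
#'   \item `move == 0` (pore state did not advance) merges the event's
#'     samples into the preceding base-level event; a leading run of
#'     `move == 0` events merges forward into the first advancing event;
#'   \item `move == 2` (two bases advanced in one event) splits the sample
#'     interval at its midpoint, `ceiling(length / 2)` samples to the first
#'     base.
#' }
#' `mean` and `stdv` are recomputed from the raw samples of each merged or
#' split interval; `weight` and `p_model_state` carry the values of the
#' longest constituent input event. The union of output sample intervals
#' equals the union of input intervals.
#'
#' @param events an `nr_events` table (basecaller events).
#' @param signal the matching `nr_raw_signal`.
#' @return an `nr_events` table with one event per called base (all moves 1).
#' @export
resegment_events <- function(events, signal) {
  stopifnot(inherits(events, "nr_events"), inherits(signal, "nr_raw_signal"))
  ev <- events$events
  validate_events(ev, events$sequence, signal$sample_count)
  n_out <- sum(ev$move)
  if (n_out == 0L) {
    stop("unalignable read '", events$read_id, "': sum of moves is zero",
         call. = FALSE)
  }
  bases <- strsplit(events$sequence, "", fixed = TRUE)[[1L]]
  stopifnot(length(bases) == n_out)

  out_start <- numeric(n_out)
  out_end <- numeric(n_out)
  src <- integer(n_out)       # representative input event (longest constituent)
  src_len <- numeric(n_out)
  j <- 0L                     # current output event
  pending <- 0                # samples from leading move-0 events
  pending_src <- 0L
  pending_len <- -1
  for (i in seq_len(nrow(ev))) {
    s <- ev$start[i]; L <- ev$length[i]; mv <- ev$move[i]
    if (mv == 0L) {
      if (j == 0L) {
        pending <- pending + L
        if (L > pending_len) { pending_len <- L; pending_src <- i }
      } else {
        out_end[j] <- out_end[j] + L
        if (L > src_len[j]) { src_len[j] <- L; src[j] <- i }
      }
    } else if (mv == 1L) {
      j <- j + 1L
      out_start[j] <- s - pending
      out_end[j] <- s + L
      src[j] <- if (pending_len > L) pending_src else i
      src_len[j] <- max(pending_len, L)
      pending <- 0; pending_len <- -1
    } else { # mv == 2: midpoint split, first base gets ceiling(L / 2)
      first_len <- ceiling(L / 2)
      j <- j + 1L
      out_start[j] <- s - pending
      out_end[j] <- s + first_len
      src[j] <- if (pending_len > first_len) pending_src else i
      src_len[j] <- max(pending_len, first_len)
      j <- j + 1L
      out_start[j] <- s + first_len
      out_end[j] <- s + L
      src[j] <- i
      src_len[j] <- L - first_len
      pending <- 0; pending_len <- -1
    }
  }
  stopifnot(j == n_out)

  stats <- vapply(seq_len(n_out), function(i) {
    interval_stats(signal, out_start[i], out_end[i] - out_start[i])
  }, numeric(2))
  out <- data.frame(
    start = out_start,
    length = out_end - out_start,
    mean = stats[1L, ],
    stdv = stats[2L, ],
    model_state = ev$model_state[src],
    move = rep(1L, n_out),
    weight = ev$weight[src],
    p_model_state = ev$p_model_state[src],
    base = bases,
    stringsAsFactors = FALSE)
  event_table(events$read_id, out, events$sequence,
              sample_count = signal$sample_count)
}
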