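#' @useDynLib nanorevise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rgeom setNames
#' @importFrom utils head tail
NULL

EVENT_COLUMNS <- c("start", "length", "mean", "stdv", "model_state", "move",
                   "weight", "p_model_state", "base")

#' Construct a raw-signal record
#'
#' A raw-signal record holds the ordered current samples of one read (raw DAC
#' counts or picoamperes) together with the read identifier.
#'
#' @param read_id character scalar.
#' @param samples numeric vector of current samples; must be non-empty.
#' @return An object of class `nr_raw_signal` with elements `read_id`,
#'   `samples` and `sample_count`.
#' @export
raw_signal <- function(read_id, samples) {
  stopifnot(is.character(read_id), length(read_id) == 1L)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("raw signal for read '", read_id, "' is empty", call. = FALSE)
  }
  structure(list(read_id = read_id, samples = samples,
                 sample_count = length(samples)),
            class = "nr_raw_signal")
}

#' Construct a basecaller event table
#'
#' Events are ordered, non-overlapping intervals of the raw signal, each with
#' the basecaller's summary statistics and the `move` value (0 = pore state
#' stayed, 1/2 = DNA advanced one/two bases). The invariant
#' `sum(move) == nchar(sequence)` ties the event stream to the basecalled
#' read.
#'
#' @param read_id character scalar.
#' @param events data.frame with columns `start`, `length`, `mean`, `stdv`,
#'   `model_state`, `move`, `weight`, `p_model_state`, `base`. `start` is a
#'   0-based sample index; intervals are half-open `[start, start + length)`.
#' @param sequence the basecalled read (character scalar).
#' @param sample_count total samples of the parent signal, used for bounds
#'   checking (optional).
#' @return An object of class `nr_events`.
#' @export
event_table <- function(read_id, events, sequence, sample_count = NULL) {
  stopifnot(is.character(read_id), length(read_id) == 1L, is.data.frame(events))
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols) > 0L) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events <- events[, EVENT_COLUMNS]
  events$start <- as.numeric(events$start)
  events$length <- as.numeric(events$length)
  events$move <- as.integer(events$move)
  validate_events(events, sequence, sample_count)
  structure(list(read_id = read_id, events = events, sequence = sequence),
            class = "nr_events")
}

validate_events <- function(events, sequence = NULL, sample_count = NULL) {
  if (nrow(events) == 0L) return(invisible(TRUE))
  if (any(!events$move %in% 0:2)) {
    bad <- which(!events$move %in% 0:2)[1L]
    stop("invalid move value ", events$move[bad], " at event ", bad,
         " (move must be 0, 1 or 2)", call. = FALSE)
  }
  if (any(events$length <= 0)) {
    stop("event lengths must be positive", call. = FALSE)
  }
  if (is.unsorted(events$start)) {
    stop("events must be sorted by start", call. = FALSE)
  }
  if (!is.null(sample_count) &&
      any(events$start + events$length > sample_count)) {
    stop("event interval exceeds signal bounds (sample_count = ",
         sample_count, ")", call. = FALSE)
  }
  if (!is.null(sequence) && sum(events$move) != nchar(sequence)) {
    stop("sum of event moves (", sum(events$move),
         ") does not equal sequence length (", nchar(sequence), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.nr_events <- function(x, ...) {
  cat(sprintf("<nr_events> read '%s': %d events, %d called bases\n",
              x$read_id, nrow(x$events), nchar(x$sequence)))
  invisible(x)
}

#' @export
print.nr_raw_signal <- function(x, ...) {
  cat(sprintf("<nr_raw_signal> read '%s': %d samples\n",
              x$read_id, x$sample_count))
  invisible(x)
}

# ---------------------------------------------------------------------------
# TSV dialect: '##key=value' metadata lines, a '#'-prefixed column header,
# then one tab-separated row per event. The raw signal travels in the
# '##signal=' metadata line (comma-separated), the basecalled read in
# '##sequence='. This keeps per-read fixtures plain-text and lossless.

#' Write a read's signal and event table as TSV
#'
#' @param signal an `nr_raw_signal`.
#' @param events an `nr_events` for the same read.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_tsv <- function(signal, events, path) {
  stopifnot(inherits(signal, "nr_raw_signal"), inherits(events, "nr_events"))
  ev <- events$events
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("##read_id=", events$read_id),
    paste0("##sequence=", events$sequence),
    paste0("##signal=", paste(format_signal(signal$samples), collapse = ",")),
    paste0("#", paste(EVENT_COLUMNS, collapse = "\t"))
  ), con)
  if (nrow(ev) > 0L) {
    lines <- sprintf("%d\t%d\t%s\t%s\t%s\t%d\t%s\t%s\t%s",
                     as.integer(ev$start), as.integer(ev$length),
                     format_signal(ev$mean), format_signal(ev$stdv),
                     ev$model_state, ev$move,
                     format_signal(ev$weight), format_signal(ev$p_model_state),
                     ev$base)
    writeLines(lines, con)
  }
  invisible(path)
}

format_signal <- function(x) formatC(x, format = "g", digits = 17)

#' Read a read's signal and event table from TSV
#'
#' @param path file written by [write_event_tsv()].
#' @return list with elements `signal` (`nr_raw_signal`) and `events`
#'   (`nr_events`).
#' @export
read_event_tsv <- function(path) {
  lines <- readLines(path)
  meta_idx <- grepl("^##", lines)
  meta <- lines[meta_idx]
  get_meta <- function(key) {
    hit <- grep(paste0("^##", key, "="), meta, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^##", key, "="), "", hit[1L])
  }
  read_id <- get_meta("read_id")
  if (is.null(read_id)) stop("TSV lacks '##read_id=' metadata", call. = FALSE)
  sequence <- get_meta("sequence")
  sig_txt <- get_meta("signal")
  if (is.null(sig_txt) || !nzchar(sig_txt)) {
    stop("TSV lacks '##signal=' metadata for read '", read_id, "'",
         call. = FALSE)
  }
  samples <- as.numeric(strsplit(sig_txt, ",", fixed = TRUE)[[1L]])

  body <- lines[!meta_idx]
  header_i <- grep("^#", body)
  if (length(header_i) == 0L) stop("TSV lacks a '#' column header", call. = FALSE)
  rows <- body[-seq_len(header_i[1L])]
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0L) {
    warning("event TSV '", path, "' contains no event rows", call. = FALSE)
    ev <- empty_events()
  } else {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield != length(EVENT_COLUMNS))) {
      bad <- which(nfield != length(EVENT_COLUMNS))[1L]
      # +1 for the header line offset inside the body block
      line_no <- which(!meta_idx)[header_i[1L]] + bad
      stop("TSV parse error at line ", line_no, ": expected ",
           length(EVENT_COLUMNS), " fields, found ", nfield[bad],
           call. = FALSE)
    }
    m <- do.call(rbind, parts)
    ev <- data.frame(
      start = as.numeric(m[, 1L]), length = as.numeric(m[, 2L]),
      mean = as.numeric(m[, 3L]), stdv = as.numeric(m[, 4L]),
      model_state = m[, 5L], move = as.integer(m[, 6L]),
      weight = as.numeric(m[, 7L]), p_model_state = as.numeric(m[, 8L]),
      base = m[, 9L], stringsAsFactors = FALSE)
  }
  if (is.null(sequence)) sequence <- reconstruct_sequence(ev)
  sig <- raw_signal(read_id, samples)
  evt <- event_table(read_id, ev, sequence, sample_count = sig$sample_count)
  list(signal = sig, events = evt)
}

empty_events <- function() {
  data.frame(start = numeric(), length = numeric(), mean = numeric(),
             stdv = numeric(), model_state = character(), move = integer(),
             weight = numeric(), p_model_state = numeric(), base = character(),
             stringsAsFactors = FALSE)
}

# Reconstruct the called sequence from model_state/move, using the
# convention that each move contributes that many bases from the 3' end of
# the event's model_state.
reconstruct_sequence <- function(ev) {
  if (nrow(ev) == 0L) return("")
  pieces <- character(nrow(ev))
  k <- nchar(ev$model_state[1L])
  for (i in seq_len(nrow(ev))) {
    mv <- ev$move[i]
    if (mv > 0L) {
      pieces[i] <- substr(ev$model_state[i], k - mv + 1L, k)
    }
  }
  paste(pieces, collapse = "")
}

# ---------------------------------------------------------------------------
# fast5-style HDF5 container

#' Default dataset paths of the fast5-style container
#'
#' A `*` component matches the first child group, mirroring the usual
#' `Raw/Reads/<read>/Signal` layout.
#' @return named list of the three dataset paths.
#' @export
fast5_paths <- function() {
  list(signal = "Raw/Reads/*/Signal",
       events = "Analyses/Basecall_1D_000/BaseCalled_template/Events",
       fastq = "Analyses/Basecall_1D_000/BaseCalled_template/Fastq")
}

#' Write a read to a fast5-style HDF5 container
#'
#' @inheritParams write_event_tsv
#' @param path output `.fast5` path.
#' @param paths dataset paths, see [fast5_paths()]. A literal group name is
#'   substituted for the `*` component on write (the read id).
#' @return `path`, invisibly.
#' @export
write_fast5 <- function(signal, events, path, paths = fast5_paths()) {
  stopifnot(inherits(signal, "nr_raw_signal"), inherits(events, "nr_events"))
  sig_path <- sub("*", paste0("Read_", events$read_id), paths$signal, fixed = TRUE)
  fastq <- paste0("@", events$read_id, "\n", events$sequence, "\n+\n",
                  strrep("!", nchar(events$sequence)))
  cpp_h5_write(path, signal$samples, as.list(events$events), fastq,
               sig_path, paths$events, paths$fastq)
  invisible(path)
}

#' Read a read from a fast5-style HDF5 container
#'
#' @param path `.fast5` path.
#' @param read_id read identifier to assign; defaults to the container
#'   basename.
#' @param paths dataset paths, see [fast5_paths()].
#' @return list with elements `signal` and `events`, as [read_event_tsv()].
#' @export
read_fast5 <- function(path, read_id = NULL, paths = fast5_paths()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- cpp_h5_read(path, paths$signal, paths$events, paths$fastq)
  if (length(raw$signal) == 0L) {
    stop("malformed container: raw signal dataset is empty in '", path, "'",
         call. = FALSE)
  }
  if (is.null(read_id)) {
    read_id <- sub("\\.fast5$", "", basename(path))
  }
  ev <- as.data.frame(raw$events, stringsAsFactors = FALSE)
  sequence <- NULL
  if (!is.null(raw$fastq)) {
    fq <- strsplit(raw$fastq, "\n", fixed = TRUE)[[1L]]
    if (length(fq) >= 2L) {
      sequence <- fq[2L]
      id <- sub("^@", "", fq[1L])
      if (nzchar(id)) read_id <- id
    }
  }
  if (!is.null(raw$base)) {
    ev$base <- raw$base
  } else {
    # compatibility heuristic for tables without an explicit base field
    k <- nchar(ev$model_state[1L])
    ev$base <- substr(ev$model_state, k, k)
  }
  if (is.null(sequence)) sequence <- reconstruct_sequence(ev)
  sig <- raw_signal(read_id, raw$signal)
  evt <- event_table(read_id, ev, sequence, sample_count = sig$sample_count)
  list(signal = sig, events = evt)
}

# ---------------------------------------------------------------------------

#' Normalize a raw signal by median/MAD scaling
#'
#' Robust per-read normalization: `(x - median(x)) / (1.4826 * MAD)` where
#' MAD is the raw median absolute deviation. If the MAD is zero the standard
#' deviation is used as the scale; if that is also zero the output is all
#' zeros. The chosen center and scale are attached as attributes so event
#' summary statistics can be placed on the same scale.
#'
#' @param signal an `nr_raw_signal` (or bare numeric vector).
#' @return the normalized signal of the same class, with attributes `center`
#'   and `scale`.
#' @export
normalize_signal <- function(signal) {
  x <- if (inherits(signal, "nr_raw_signal")) signal$samples else as.numeric(signal)
  ctr <- median(x)
  scl <- 1.4826 * median(abs(x - ctr))
  if (scl == 0) scl <- stats::sd(x)
  if (is.na(scl) || scl == 0) {
    y <- rep(0, length(x))
    scl <- 1
  } else {
    y <- (x - ctr) / scl
  }
  if (inherits(signal, "nr_raw_signal")) {
    out <- raw_signal(signal$read_id, y)
  } else {
    out <- y
  }
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}
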