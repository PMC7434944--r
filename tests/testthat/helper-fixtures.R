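# shared helpers: tiny fixtures and independent (naive) oracles

# random basecaller-style event table with a contiguous signal; moves drawn
# from {0,1,2}, first event forced to advance
random_event_table <- function(n_events = 30, seed = NULL, read_id = "rnd") {
  if (!is.null(seed)) set.seed(seed)
  moves <- sample(0:2, n_events, replace = TRUE, prob = c(0.25, 0.6, 0.15))
  moves[1] <- sample(1:2, 1)
  lens <- sample(3:12, n_events, replace = TRUE)
  starts <- cumsum(c(0, lens[-n_events]))
  total <- sum(lens)
  sig <- raw_signal(read_id, rnorm(total, 90, 8))
  seq_len_bases <- sum(moves)
  bases <- sample(c("A", "C", "G", "T"), seq_len_bases, replace = TRUE)
  ev <- data.frame(start = starts, length = lens, mean = 0, stdv = 0,
                   model_state = strrep("A", 5), move = moves, weight = 1,
                   p_model_state = 0.9,
                   base = substr(strrep("A", 1), 1, 1),
                   stringsAsFactors = FALSE)
  st <- vapply(seq_len(n_events), function(i) {
    interval_stats(sig, ev$start[i], ev$length[i])
  }, numeric(2))
  ev$mean <- st[1, ]; ev$stdv <- st[2, ]
  list(signal = sig,
       events = event_table(read_id, ev, paste(bases, collapse = "")))
}

# naive median/MAD normalization (independent of the package code path)
naive_normalize <- function(x) {
  ctr <- median(x)
  scl <- 1.4826 * median(abs(x - ctr))
  if (scl == 0) scl <- sd(x)
  if (is.na(scl) || scl == 0) return(rep(0, length(x)))
  (x - ctr) / scl
}

# naive CIGAR recount: regex-split the string, sum lengths per op
naive_cigar_counts <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(read_length = sum(lens[ops %in% c("M", "=", "X", "I", "S")]),
       deletion = sum(lens[ops == "D"]),
       insertion = sum(lens[ops == "I"]),
       mismatch = sum(lens[ops == "X"]))
}

# naive per-character interpreter for revision actions
naive_revise <- function(sequence, actions) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(bases)) {
    a <- actions[i]
    if (a == "KEEP") {
      out <- c(out, bases[i])
    } else if (startsWith(a, "SUBSTITUTE:")) {
      out <- c(out, sub("SUBSTITUTE:", "", a))
    } else if (a == "DELETE") {
      # nothing
    } else {
      out <- c(out, bases[i], sub("KEEP_THEN_INSERT:", "", a))
    }
  }
  paste(out, collapse = "")
}

# build an nr_windows object directly from matrices (for model unit tests)
tiny_windows <- function(n, window = 5L, cap = 3L, feat_dim = 7L, K = 4L,
                         seed = 1L) {
  set.seed(seed)
  structure(list(
    signal = matrix(rnorm(n * window * cap), n),
    features = matrix(rnorm(n * window * feat_dim), n),
    label1 = sample.int(6L, n, replace = TRUE),
    label2 = sample.int(4L, n, replace = TRUE),
    clipped = rep(FALSE, n),
    window = as.integer(window), signal_cap = as.integer(cap),
    feat_dim = as.integer(feat_dim), with_methyl = FALSE),
    class = "nr_windows")
}

# tiny model configuration for fast exact checks (double precision)
tiny_config <- function(num_classes = 4L, ...) {
  args <- list(num_classes = num_classes, window = 5L, feat_dim = 7L,
               signal_cap = 3L, conv_filters = 2L, n_res_blocks = 1L,
               feat_lstm_state = 2L, n_feat_lstm = 1L,
               trunk_lstm_state = 3L, n_trunk_lstm = 1L, dense_units = 4L,
               dropout = 0, batch_size = 8L, epochs = 2L, seed = 7L)
  upd <- list(...)
  args[names(upd)] <- upd
  do.call(nr_model_config, args)
}

# reconstruct the true sequence from labels: the labeling round-trip edit
apply_labels <- function(labeled) {
  out <- character(0)
  for (i in seq_len(nrow(labeled))) {
    if (isTRUE(labeled$clipped[i])) next
    l1 <- labeled$label1[i]
    if (is.na(l1) || l1 == "I") next
    if (l1 == "D") {
      out <- c(out, labeled$base[i], labeled$label2[i])
    } else {
      out <- c(out, labeled$label2[i])
    }
  }
  paste(out, collapse = "")
}
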