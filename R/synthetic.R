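#' Synthetic pore model
#'
#' Minimal generative model of the event signal: each k-mer occupying the
#' pore draws Gaussian current samples around a k-mer-dependent level, dwell
#' times are (shifted) geometric, and annotated methylated positions shift
#' the current level additively. The level is a weighted sum of per-base
#' codes with the central base dominant, so the true central base is
#' recoverable from the signal while neighbors modulate it — the minimal
#' structure consistent with event mean/stdv/length semantics, with no
#' attempt to mimic real pore chemistry.
#'
#' @param k k-mer length (odd).
#' @param level pA baseline of the current.
#' @param weights per-offset contribution of the base code, centered on the
#'   middle position; length `k`.
#' @param sd Gaussian noise of the samples (pA).
#' @param dwell_mean,dwell_min mean and minimum samples per base; dwell is
#'   `dwell_min + geometric`.
#' @param methyl_shift additive current offset (pA) at annotated methylated
#'   positions.
#' @return list of class `nr_pore_model`.
#' @export
pore_model <- function(k = 5L, level = 90, weights = c(1, 2.5, 12, 2.5, 1),
                       sd = 1.5, dwell_mean = 8, dwell_min = 2L,
                       methyl_shift = 6) {
  stopifnot(k %% 2L == 1L, length(weights) == k, sd > 0, dwell_mean >= 1,
            dwell_min >= 1, dwell_mean > dwell_min)
  structure(list(k = as.integer(k), level = level, weights = weights,
                 sd = sd, dwell_mean = dwell_mean,
                 dwell_min = as.integer(dwell_min),
                 methyl_shift = methyl_shift),
            class = "nr_pore_model")
}

BASE_CODE <- c(A = -1.5, C = -0.5, G = 0.5, T = 1.5)

#' Current level of k-mer contexts
#'
#' @param pore an `nr_pore_model`.
#' @param kmers character vector of k-mers over A/C/G/T.
#' @return numeric vector of mean current levels (pA).
#' @export
pore_current <- function(pore, kmers) {
  m <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  stopifnot(ncol(m) == pore$k)
  codes <- matrix(BASE_CODE[m], nrow(m), ncol(m))
  pore$level + as.numeric(codes %*% pore$weights)
}

#' Synthetic error profile
#'
#' Single-base mismatch/insertion/deletion events injected along the
#' reference with a minimum spacing between consecutive error events (so
#' every injected error is independently recoverable from a single-pass
#' per-event labeling). Rates are targets on the alignment-length scale
#' (read length + deletions); the generator calibrates its per-position
#' draw probabilities so the realized rates match them in expectation.
#' `stay_prob` and `fuse_prob` emulate basecaller event streams: the
#' probability that a base's event is split by a stay (`move = 0`) and that
#' two neighboring bases fuse into one `move = 2` event.
#'
#' @param mismatch,insertion,deletion target rates (fractions of the
#'   alignment length); their sum must be < 1.
#' @param min_spacing minimum reference distance between error events.
#' @param stay_prob,fuse_prob event-stream perturbation probabilities.
#' @return list of class `nr_error_profile`.
#' @export
error_profile <- function(mismatch = 0.15 * 8 / 19, insertion = 0.15 * 5 / 19,
                          deletion = 0.15 * 6 / 19, min_spacing = 2L,
                          stay_prob = 0.15, fuse_prob = 0.05) {
  stopifnot(mismatch >= 0, insertion >= 0, deletion >= 0,
            mismatch + insertion + deletion < 1, min_spacing >= 1)
  structure(list(mismatch = mismatch, insertion = insertion,
                 deletion = deletion, min_spacing = as.integer(min_spacing),
                 stay_prob = stay_prob, fuse_prob = fuse_prob),
            class = "nr_error_profile")
}

# per-eligible-position draw probabilities implied by the target rates
error_draw_probs <- function(errors) {
  r <- c(errors$mismatch, errors$insertion, errors$deletion)
  if (sum(r) == 0) return(c(mismatch = 0, insertion = 0, deletion = 0))
  # rates are per alignment length G + I; per-reference-position frequencies
  # are inflated by 1/(1 - insertion rate), and spacing suppression is
  # undone by the renewal relation q = t / (1 - t * (s - 1))
  t <- r / (1 - r[2L])
  tt <- sum(t)
  q <- tt / (1 - tt * (errors$min_spacing - 1))
  stats::setNames(q * t / tt, c("mismatch", "insertion", "deletion"))
}

#' Simulate a random reference with optional methylation annotation
#'
#' @param length reference length (>= the pore model k-mer size).
#' @param seed integer seed.
#' @param methyl_density per-base probability of an annotated methylation
#'   site. Site type follows the underlying base: A sites become m6A, C
#'   sites m4C, anything else "modified".
#' @param gc GC content of the uniform random sequence.
#' @param k minimum admissible length (the pore k-mer size).
#' @param ref_name sequence name.
#' @return list with `sequence` (character), `ref_name` and `methyl`
#'   (BED-like data.frame: chrom, 0-based half-open start/end, type).
#' @export
simulate_reference <- function(length, seed = 1L, methyl_density = 0,
                               gc = 0.5, k = 5L, ref_name = "synthetic_ref") {
  if (length < k) {
    stop("reference length (", length, ") must be >= k (", k, ")",
         call. = FALSE)
  }
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  methyl <- data.frame(chrom = character(), start = integer(),
                       end = integer(), type = character(),
                       stringsAsFactors = FALSE)
  if (methyl_density > 0) {
    site <- which(runif(length) < methyl_density)
    if (length(site) > 0L) {
      type <- ifelse(bases[site] == "A", "m6A",
                     ifelse(bases[site] == "C", "m4C", "modified"))
      methyl <- data.frame(chrom = ref_name, start = site - 1L, end = site,
                           type = type, stringsAsFactors = FALSE)
    }
  }
  list(sequence = paste(bases, collapse = ""), ref_name = ref_name,
       methyl = methyl)
}

# k-mer context around position j of a padded sequence (edges repeat)
context_kmers <- function(bases, pore) {
  n <- length(bases)
  half <- (pore$k - 1L) %/% 2L
  idx <- outer(seq_len(n), (-half):half, "+")
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  m <- matrix(bases[idx], n, pore$k)
  apply(m, 1L, paste, collapse = "")
}

#' Simulate one read: signal, basecaller events and ground truth
#'
#' Applies the error profile to the reference window to obtain the "called"
#' sequence, then emits raw current per called base from the pore model
#' (geometric dwell, Gaussian k-mer currents, methylation shift at annotated
#' positions) and perturbs the event stream with stays (`move = 0`) and
#' fusions (`move = 2`). A deleted base's dwell samples are folded into the
#' preceding called base's event — the pore traversed the base, the
#' basecaller missed it — which is what makes deletions learnable. Inserted
#' bases reuse the previous position's k-mer context (a stay miscalled as a
#' move). The truth record logs every injected error, the alignment, the
#' expected training labels and the canonical base-level sample intervals.
#'
#' @param ref a reference from [simulate_reference()] (or a bare character
#'   string).
#' @param start 0-based window start on the reference.
#' @param length window length (bases).
#' @param pore an `nr_pore_model`.
#' @param errors an `nr_error_profile`.
#' @param strand "+" or "-"; minus-strand reads are basecalled as the
#'   reverse complement of the window.
#' @param read_id read identifier.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return list with `signal` (`nr_raw_signal`), `events` (`nr_events`,
#'   basecaller-style with move 0/1/2) and `truth`.
#' @export
simulate_read <- function(ref, start = 0L, length = NULL, pore = pore_model(),
                          errors = error_profile(), strand = "+",
                          read_id = "read_1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  refseq <- if (is.list(ref)) ref$sequence else ref
  ref_name <- if (is.list(ref)) ref$ref_name else "ref"
  methyl <- if (is.list(ref)) ref$methyl else NULL
  if (is.null(length)) length <- nchar(refseq) - start
  stopifnot(start >= 0, start + length <= nchar(refseq), length >= pore$k)

  W <- substr(refseq, start + 1L, start + length)
  true_read <- if (strand == "-") revcomp_chr(W) else W
  tb <- strsplit(true_read, "", fixed = TRUE)[[1L]]
  # genomic 0-based position of each true base, in read orientation
  gpos <- if (strand == "-") (start + length - 1L):start else start:(start + length - 1L)
  methylated <- rep(FALSE, length)
  if (!is.null(methyl) && nrow(methyl) > 0L) {
    site <- methyl$start[methyl$chrom == ref_name]
    methylated <- gpos %in% site
  }

  # --- error injection walk (read orientation) -----------------------------
  q <- error_draw_probs(errors)
  etype <- rep("match", length)   # match / mismatch / deletion / ins_after
  cooldown <- 0L
  for (j in seq_len(length)) {
    if (cooldown > 0L) { cooldown <- cooldown - 1L; next }
    if (j == 1L || j == length) next   # anchor the read ends
    u <- runif(1)
    if (u < q["mismatch"]) {
      etype[j] <- "mismatch"
    } else if (u < q["mismatch"] + q["insertion"]) {
      etype[j] <- "ins_after"
    } else if (u < q["mismatch"] + q["insertion"] + q["deletion"]) {
      etype[j] <- "deletion"
    } else next
    cooldown <- errors$min_spacing - 1L
  }

  # --- called sequence, per-called-base generation contexts ----------------
  kmers <- context_kmers(tb, pore)
  levels0 <- pore_current(pore, kmers) + ifelse(methylated, pore$methyl_shift, 0)

  called <- character(0)
  src_level <- numeric(0)     # current level for the called base's own dwell
  op <- character(0)          # per called base: "=", "X", "I"
  lab1 <- character(0); lab2 <- character(0)
  extra_level <- numeric(0)   # deleted-base level appended to this event (NA if none)
  ref_of_called <- integer(0) # genomic position (0-based) or NA for insertions
  cigar_ops <- character(0)   # unit ops in read orientation, incl. "D"

  other <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  for (j in seq_len(length)) {
    t <- etype[j]
    if (t == "deletion") {
      # dwell folds into the previous called base's event
      ne <- base::length(called)
      stopifnot(ne > 0L)
      extra_level[ne] <- levels0[j]
      lab1[ne] <- "D"; lab2[ne] <- tb[j]
      cigar_ops <- c(cigar_ops, "D")
      next
    }
    if (t == "mismatch") {
      cb <- other(tb[j])
      called <- c(called, cb); src_level <- c(src_level, levels0[j])
      op <- c(op, "X"); lab1 <- c(lab1, tb[j]); lab2 <- c(lab2, tb[j])
      extra_level <- c(extra_level, NA_real_)
      ref_of_called <- c(ref_of_called, gpos[j])
      cigar_ops <- c(cigar_ops, "X")
    } else { # match (possibly with a following insertion)
      called <- c(called, tb[j]); src_level <- c(src_level, levels0[j])
      op <- c(op, "="); lab1 <- c(lab1, tb[j]); lab2 <- c(lab2, tb[j])
      extra_level <- c(extra_level, NA_real_)
      ref_of_called <- c(ref_of_called, gpos[j])
      cigar_ops <- c(cigar_ops, "=")
      if (t == "ins_after") {
        ib <- sample(c("A", "C", "G", "T"), 1L)
        called <- c(called, ib)
        src_level <- c(src_level, levels0[j])  # stay miscalled as a move
        op <- c(op, "I"); lab1 <- c(lab1, "I"); lab2 <- c(lab2, ib)
        extra_level <- c(extra_level, NA_real_)
        ref_of_called <- c(ref_of_called, NA_integer_)
        cigar_ops <- c(cigar_ops, "I")
      }
    }
  }
  n_called <- base::length(called)

  # --- dwells and raw samples ----------------------------------------------
  draw_dwell <- function(n) {
    pore$dwell_min +
      stats::rgeom(n, prob = 1 / (pore$dwell_mean - pore$dwell_min + 1))
  }
  dwell <- draw_dwell(n_called)
  extra_dwell <- ifelse(is.na(extra_level), 0L, draw_dwell(n_called))
  samples <- vector("list", n_called)
  for (i in seq_len(n_called)) {
    s <- rnorm(dwell[i], src_level[i], pore$sd)
    if (extra_dwell[i] > 0L) {
      s <- c(s, rnorm(extra_dwell[i], extra_level[i], pore$sd))
    }
    samples[[i]] <- s
  }
  ev_len <- dwell + extra_dwell
  ev_end <- cumsum(ev_len)
  ev_start <- ev_end - ev_len
  raw <- unlist(samples)

  # --- basecaller-style event stream (stays and fusions) -------------------
  k <- pore$k
  padded <- paste0(strrep("A", k), paste(called, collapse = ""))
  state_for <- function(e) substr(padded, e + 1L, e + k)  # ends at base e
  rows <- list()
  canon_start <- ev_start; canon_end <- ev_end  # canonical base-level intervals
  i <- 1L
  while (i <= n_called) {
    fuse <- i < n_called && runif(1) < errors$fuse_prob
    if (fuse) {
      a <- ev_start[i]; b <- ev_end[i + 1L]
      rows[[base::length(rows) + 1L]] <-
        list(start = a, length = b - a, move = 2L, state = state_for(i + 1L),
             base = called[i + 1L])
      first_len <- ceiling((b - a) / 2)
      canon_start[i] <- a; canon_end[i] <- a + first_len
      canon_start[i + 1L] <- a + first_len; canon_end[i + 1L] <- b
      i <- i + 2L
    } else {
      L <- ev_len[i]
      if (runif(1) < errors$stay_prob && L >= 2L) {
        cut <- sample.int(L - 1L, 1L)
        rows[[base::length(rows) + 1L]] <-
          list(start = ev_start[i], length = cut, move = 1L,
               state = state_for(i), base = called[i])
        rows[[base::length(rows) + 1L]] <-
          list(start = ev_start[i] + cut, length = L - cut, move = 0L,
               state = state_for(i), base = called[i])
      } else {
        rows[[base::length(rows) + 1L]] <-
          list(start = ev_start[i], length = L, move = 1L,
               state = state_for(i), base = called[i])
      }
      i <- i + 1L
    }
  }
  ev <- data.frame(
    start = vapply(rows, `[[`, numeric(1), "start"),
    length = vapply(rows, `[[`, numeric(1), "length"),
    mean = 0, stdv = 0,
    model_state = vapply(rows, `[[`, character(1), "state"),
    move = vapply(rows, `[[`, integer(1), "move"),
    weight = vapply(rows, `[[`, numeric(1), "length"),
    p_model_state = 0.9,
    base = vapply(rows, `[[`, character(1), "base"),
    stringsAsFactors = FALSE)
  st <- vapply(seq_len(nrow(ev)), function(r) {
    interval_stats(raw, ev$start[r], ev$length[r])
  }, numeric(2))
  ev$mean <- st[1L, ]; ev$stdv <- st[2L, ]

  called_seq <- paste(called, collapse = "")
  sig <- raw_signal(read_id, raw)
  evt <- event_table(read_id, ev, called_seq, sample_count = sig$sample_count)

  # --- SAM-style truth alignment -------------------------------------------
  sam_ops <- if (strand == "-") rev(cigar_ops) else cigar_ops
  r <- rle(sam_ops)
  cigar <- paste0(r$lengths, r$values, collapse = "")
  truth <- list(
    read_id = read_id, ref_name = ref_name, strand = strand,
    ref_start = start, ref_span = length,
    called = called_seq, true_read = true_read,
    cigar = cigar,
    sam_seq = if (strand == "-") revcomp_chr(called_seq) else called_seq,
    label1 = lab1, label2 = lab2, ref_of_called = ref_of_called,
    n_mismatch = sum(etype == "mismatch"),
    n_insertion = sum(etype == "ins_after"),
    n_deletion = sum(etype == "deletion"),
    canonical_start = canon_start, canonical_end = canon_end,
    methylated_called = ref_of_called %in% gpos[methylated] &
      !is.na(ref_of_called))
  list(signal = sig, events = evt, truth = truth)
}

#' Generate a self-consistent synthetic dataset
#'
#' Simulates a reference, reads with known injected errors, and (optionally)
#' writes the fixture set to disk: per-read event TSVs, the reference FASTA,
#' a truth SAM (written directly from the injection log, never re-aligned)
#' and the methylation BED.
#'
#' @param n_reads number of reads (>= 1).
#' @param read_length bases per read.
#' @param pore,errors generator models.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param methyl_density per-base methylation site probability of the
#'   reference.
#' @param reference_length reference size.
#' @param minus_prob probability a read is minus-strand.
#' @param dir if non-NULL, write the fixture files under this directory.
#' @return list with `reference`, `reads` (each with `signal`, `events`,
#'   `truth`) and, when written, the file paths.
#' @export
generate_dataset <- function(n_reads, read_length = 500L, pore = pore_model(),
                             errors = error_profile(), seed = 1L,
                             methyl_density = 0,
                             reference_length = max(4L * read_length, 4000L),
                             minus_prob = 0.3, dir = NULL) {
  stopifnot(n_reads >= 1L)
  ref <- simulate_reference(reference_length, seed = seed,
                            methyl_density = methyl_density, k = pore$k)
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    start <- sample.int(reference_length - read_length + 1L, 1L) - 1L
    strand <- if (runif(1) < minus_prob) "-" else "+"
    reads[[i]] <- simulate_read(ref, start = start, length = read_length,
                                pore = pore, errors = errors, strand = strand,
                                read_id = sprintf("synth_%04d", i))
  }
  out <- list(reference = ref, reads = reads, pore = pore, errors = errors)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "reference.fa")
    seqs <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$ref_name))
    Biostrings::writeXStringSet(seqs, fa)
    tsvs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      tsvs[i] <- file.path(dir, "reads", paste0(reads[[i]]$truth$read_id, ".tsv"))
      write_event_tsv(reads[[i]]$signal, reads[[i]]$events, tsvs[i])
    }
    sam <- file.path(dir, "truth.sam")
    write_truth_sam(reads, ref, sam)
    bed <- NULL
    if (nrow(ref$methyl) > 0L) {
      bed <- file.path(dir, "methylation.bed")
      utils::write.table(ref$methyl, bed, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    out$paths <- list(reference = fa, reads = tsvs, sam = sam, bed = bed)
  }
  out
}

#' Write the ground-truth alignments of simulated reads as SAM
#'
#' Records come straight from the injection log (position, strand, CIGAR
#' with explicit =/X ops), so labeling and metric tests are independent of
#' any aligner.
#'
#' @param reads list of simulated reads (from [generate_dataset()] or
#'   [simulate_read()]).
#' @param ref the reference they were simulated from.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(reads, ref, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$ref_name, nchar(ref$sequence)))
  recs <- vapply(reads, function(r) {
    t <- r$truth
    flag <- if (t$strand == "-") 16L else 0L
    paste(t$read_id, flag, t$ref_name, t$ref_start + 1L, 60L, t$cigar,
          "*", 0L, 0L, t$sam_seq, "*", sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
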