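LABEL1_CLASSES <- c("A", "C", "G", "T", "I", "D")
LABEL2_CLASSES <- c("A", "C", "G", "T")
METHYL_TYPES <- c("m6A", "m4C", "modified")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Parse primary alignments from a SAM/BAM file
#'
#' Keeps primary alignments only; unmapped, secondary and supplementary
#' records are skipped and counted. SAM input is converted through
#' [Rsamtools::asBam()].
#'
#' @param path SAM or BAM file.
#' @param read_ids optional character vector; if given, only these reads are
#'   returned and absent reads are reported in the `missing` attribute.
#' @return named list of alignment records (one per read), each a list with
#'   `read_id`, `ref_name`, `ref_start` (0-based), `strand`, `cigar`, `seq`.
#'   Attributes `n_excluded` and `missing` report filtering.
#' @export
parse_alignment <- function(path, read_ids = NULL) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  flag <- res$flag
  keep <- !bitwAnd(flag, 0x4) & !bitwAnd(flag, 0x100) & !bitwAnd(flag, 0x800)
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message(n_excluded,
            " unmapped/secondary/supplementary record(s) skipped")
  }
  idx <- which(keep)
  records <- lapply(idx, function(i) {
    list(read_id = res$qname[i],
         ref_name = as.character(res$rname[i]),
         ref_start = res$pos[i] - 1L,
         strand = if (bitwAnd(flag[i], 0x10)) "-" else "+",
         cigar = res$cigar[i],
         seq = as.character(res$seq[i]))
  })
  names(records) <- vapply(records, `[[`, character(1), "read_id")
  missing <- character()
  if (!is.null(read_ids)) {
    missing <- setdiff(read_ids, names(records))
    if (length(missing) > 0L) {
      message(length(missing), " read(s) absent from the alignment file")
    }
    records <- records[intersect(read_ids, names(records))]
  }
  attr(records, "n_excluded") <- n_excluded
  attr(records, "missing") <- missing
  records
}

#' Label base-level events from a reference alignment
#'
#' Produces the two training labels per event: the error-type label
#' (`label1` in A/C/G/T/I/D) and the true-base label (`label2` in A/C/G/T).
#' Matches and mismatches carry the reference base in both labels; an
#' inserted read base is labeled `I` with `label2` equal to its called base;
#' a reference deletion attaches `D` to the event immediately preceding the
#' deleted bases (in read orientation), with `label2` the first deleted
#' reference base. Events on minus-strand alignments stay in read (basecall)
#' orientation: reference bases are reverse-complemented into read
#' orientation before labeling. Soft-clipped events are flagged and excluded
#' from training.
#'
#' @param events a base-level `nr_events` (from [resegment_events()]).
#' @param aln one alignment record from [parse_alignment()].
#' @param reference named character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @return the event data.frame extended with columns `label1`, `label2`,
#'   `refpos` (0-based reference coordinate, NA for insertions/clips),
#'   `methyl` (initialized to "none") and `clipped`.
#' @export
label_events <- function(events, aln, reference) {
  stopifnot(inherits(events, "nr_events"))
  ev <- events$events
  n <- nrow(ev)
  if (inherits(reference, "DNAStringSet")) {
    refchr <- as.character(reference[[aln$ref_name]])
  } else {
    refchr <- reference[[aln$ref_name]]
  }
  ops <- GenomicAlignments::explodeCigarOps(aln$cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)[[1L]]
  if (any(!ops %in% c("M", "=", "X", "I", "D", "S", "H"))) {
    stop("unsupported CIGAR op in '", aln$cigar, "'", call. = FALSE)
  }
  nquery <- sum(lens[ops %in% c("M", "=", "X", "I", "S")])
  if (nquery != n) {
    stop("CIGAR consumes ", nquery, " query bases but the read has ", n,
         " events", call. = FALSE)
  }
  refspan <- sum(lens[ops %in% c("M", "=", "X", "D")])
  refseg <- substr(refchr, aln$ref_start + 1L, aln$ref_start + refspan)

  if (identical(aln$strand, "-")) {
    ops <- rev(ops); lens <- rev(lens)
    oriented_ref <- strsplit(revcomp_chr(refseg), "", fixed = TRUE)[[1L]]
    g <- aln$ref_start + refspan - 1L   # genomic coordinate, descending
    gstep <- -1L
  } else {
    oriented_ref <- strsplit(refseg, "", fixed = TRUE)[[1L]]
    g <- aln$ref_start
    gstep <- 1L
  }

  label1 <- rep(NA_character_, n)
  label2 <- rep(NA_character_, n)
  refpos <- rep(NA_real_, n)
  clipped <- rep(FALSE, n)
  called <- ev$base
  qi <- 1L; ri <- 1L
  n_unattached_del <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]; L <- lens[k]
    if (op == "H") next
    if (op == "S") {
      clipped[qi:(qi + L - 1L)] <- TRUE
      qi <- qi + L
    } else if (op %in% c("M", "=", "X")) {
      q <- qi:(qi + L - 1L)
      rb <- oriented_ref[ri:(ri + L - 1L)]
      if (op == "=" && any(rb != called[q])) {
        stop("CIGAR '=' op disagrees with the reference for read '",
             events$read_id, "'", call. = FALSE)
      }
      label1[q] <- rb
      label2[q] <- rb
      refpos[q] <- g + gstep * (seq_len(L) - 1L)
      qi <- qi + L; ri <- ri + L; g <- g + gstep * L
    } else if (op == "I") {
      q <- qi:(qi + L - 1L)
      label1[q] <- "I"
      label2[q] <- called[q]
      qi <- qi + L
    } else { # D
      if (qi > 1L && !clipped[qi - 1L]) {
        label1[qi - 1L] <- "D"
        label2[qi - 1L] <- oriented_ref[ri]
      } else {
        n_unattached_del <- n_unattached_del + 1L
      }
      ri <- ri + L; g <- g + gstep * L
    }
  }
  out <- ev
  out$label1 <- label1
  out$label2 <- label2
  out$refpos <- refpos
  out$methyl <- rep("none", n)
  out$clipped <- clipped
  attr(out, "read_id") <- events$read_id
  attr(out, "ref_name") <- aln$ref_name
  attr(out, "n_unattached_deletions") <- n_unattached_del
  out
}

#' Read a methylation annotation from a BED3+1 file
#'
#' The fourth BED column carries the methylation type, one of `m6A`, `m4C`
#' or `modified`.
#'
#' @param path BED file.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `type`.
#' @export
read_methyl_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  type <- gr$name
  bad <- setdiff(unique(type), METHYL_TYPES)
  if (length(bad) > 0L) {
    stop("unknown methylation type(s) in '", path, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             type = type, stringsAsFactors = FALSE)
}

#' Attach methylation flags to labeled events
#'
#' Events whose reference position falls inside an annotated interval get
#' that interval's type; overlaps resolve by the priority
#' `m6A > m4C > modified`.
#'
#' @param labeled labeled events from [label_events()].
#' @param aln the alignment record the labels came from.
#' @param annotation data.frame from [read_methyl_bed()] (or equivalent).
#' @return `labeled` with its `methyl` column filled.
#' @export
annotate_methylation <- function(labeled, aln, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L) return(labeled)
  ann <- annotation[annotation$chrom == aln$ref_name, , drop = FALSE]
  if (nrow(ann) == 0L) {
    warning("annotation has no intervals on reference '", aln$ref_name,
            "'; all methylation flags set to 'none'", call. = FALSE)
    return(labeled)
  }
  idx <- which(!is.na(labeled$refpos))
  if (length(idx) == 0L) return(labeled)
  gr_ev <- GenomicRanges::GRanges(aln$ref_name,
                                  IRanges::IRanges(labeled$refpos[idx] + 1L,
                                                   width = 1L))
  gr_ann <- GenomicRanges::GRanges(ann$chrom,
                                   IRanges::IRanges(ann$start + 1L, ann$end))
  fo <- GenomicRanges::findOverlaps(gr_ev, gr_ann)
  if (length(fo) > 0L) {
    pri <- match(ann$type, METHYL_TYPES)[S4Vectors::subjectHits(fo)]
    qh <- S4Vectors::queryHits(fo)
    best <- tapply(pri, qh, min)
    labeled$methyl[idx[as.integer(names(best))]] <- METHYL_TYPES[best]
  }
  labeled
}

#' Cut a read into fixed-size training/inference windows
#'
#' One window per base-level event (stride 1, centered). The per-position
#' feature vector is the one-hot called base (4), the event mean and stdv on
#' the normalized-signal scale, and the event length relative to the read's
#' median event length (3) — plus a one-hot methylation type (3) when
#' `with_methyl`. Positions beyond the read ends are all-zero padding. The
#' window's signal input concatenates the member events' normalized samples,
#' each truncated (from the event tail) or zero-padded to `signal_cap`
#' samples. Window labels are the center event's.
#'
#' @param labeled labeled events (from [label_events()]) or a bare base-level
#'   event data.frame for inference.
#' @param signal the read's `nr_raw_signal`; normalized internally if it does
#'   not carry normalization attributes.
#' @param window odd window size >= 3 (number of events).
#' @param signal_cap samples kept per event.
#' @param with_methyl include the methylation feature channel.
#' @return list of class `nr_windows` with matrices `signal`
#'   (n x window*signal_cap) and `features` (n x window*feat_dim), integer
#'   label vectors `label1`/`label2` (NA where unlabeled), and bookkeeping
#'   fields.
#' @export
make_windows <- function(labeled, signal, window = 13L, signal_cap = 40L,
                         with_methyl = FALSE) {
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  ev <- labeled
  n <- nrow(ev)
  if (window > 2L * n + 1L) {
    stop("window (", window, ") larger than 2 * read length + 1 (",
         2L * n + 1L, ")", call. = FALSE)
  }
  if (is.null(attr(signal, "scale"))) signal <- normalize_signal(signal)
  samples <- if (inherits(signal, "nr_raw_signal")) signal$samples else signal
  ctr <- attr(signal, "center"); scl <- attr(signal, "scale")

  F <- if (with_methyl) 10L else 7L
  featm <- matrix(0, n, F)
  base_idx <- match(ev$base, LABEL2_CLASSES)
  featm[cbind(seq_len(n), base_idx)] <- 1
  featm[, 5L] <- (ev$mean - ctr) / scl
  featm[, 6L] <- ev$stdv / scl
  featm[, 7L] <- ev$length / stats::median(ev$length)
  if (with_methyl && !is.null(ev$methyl)) {
    m_idx <- match(ev$methyl, METHYL_TYPES)
    has <- !is.na(m_idx)
    featm[cbind(which(has), 7L + m_idx[has])] <- 1
  }

  sigm <- matrix(0, n, signal_cap)
  for (i in seq_len(n)) {
    L <- min(ev$length[i], signal_cap)
    sigm[i, seq_len(L)] <- samples[(ev$start[i] + 1L):(ev$start[i] + L)]
  }

  half <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), (-half):half, "+")
  idx[idx < 1L | idx > n] <- n + 1L  # padding row
  featm <- rbind(featm, 0)
  sigm <- rbind(sigm, 0)
  feats <- do.call(cbind, lapply(seq_len(window), function(t) {
    featm[idx[, t], , drop = FALSE]
  }))
  sig <- do.call(cbind, lapply(seq_len(window), function(t) {
    sigm[idx[, t], , drop = FALSE]
  }))

  label1 <- if (!is.null(ev$label1)) match(ev$label1, LABEL1_CLASSES) else rep(NA_integer_, n)
  label2 <- if (!is.null(ev$label2)) match(ev$label2, LABEL2_CLASSES) else rep(NA_integer_, n)
  clipped <- if (!is.null(ev$clipped)) ev$clipped else rep(FALSE, n)
  structure(list(signal = sig, features = feats,
                 label1 = label1, label2 = label2,
                 clipped = clipped, base = ev$base,
                 window = as.integer(window), signal_cap = as.integer(signal_cap),
                 feat_dim = F, with_methyl = with_methyl,
                 read_id = attr(ev, "read_id")),
            class = "nr_windows")
}

#' Concatenate window sets from several reads
#'
#' @param window_list list of `nr_windows`.
#' @return one `nr_windows` with a `read` index column mapping rows to input
#'   elements.
#' @export
bind_windows <- function(window_list) {
  stopifnot(length(window_list) > 0L)
  w1 <- window_list[[1L]]
  structure(list(
    signal = do.call(rbind, lapply(window_list, `[[`, "signal")),
    features = do.call(rbind, lapply(window_list, `[[`, "features")),
    label1 = unlist(lapply(window_list, `[[`, "label1")),
    label2 = unlist(lapply(window_list, `[[`, "label2")),
    clipped = unlist(lapply(window_list, `[[`, "clipped")),
    base = unlist(lapply(window_list, `[[`, "base")),
    read = rep(seq_along(window_list),
               vapply(window_list, function(w) nrow(w$signal), integer(1))),
    window = w1$window, signal_cap = w1$signal_cap,
    feat_dim = w1$feat_dim, with_methyl = w1$with_methyl),
    class = "nr_windows")
}
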