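#' Alignment error statistics for one read
#'
#' Counts deletion/insertion/mismatch lengths over the CIGAR (the operands
#' of the rate formulas), optionally restricted to annotated methylated
#' reference positions per type. `read_length` is the full query length
#' including soft clips. CIGAR `M` ops are resolved against the reference;
#' `=`/`X` are used directly.
#'
#' @param aln alignment record from [parse_alignment()].
#' @param reference named character vector or `DNAStringSet`; required when
#'   the CIGAR contains `M` ops or an annotation is given.
#' @param annotation optional methylation annotation data.frame
#'   (see [read_methyl_bed()]).
#' @return list of class `nr_alignment_stats` with `read_length`,
#'   `deletion_length`, `insertion_length`, `mismatch_length` and a `methyl`
#'   data.frame (`type`, `bases`, `deletion`, `insertion`, `mismatch`).
#' @export
stats_from_alignment <- function(aln, reference = NULL, annotation = NULL) {
  ops <- GenomicAlignments::explodeCigarOps(aln$cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)[[1L]]
  read_length <- sum(lens[ops %in% c("M", "=", "X", "I", "S")])
  del <- sum(lens[ops == "D"])
  ins <- sum(lens[ops == "I"])
  need_walk <- any(ops == "M") || !is.null(annotation)
  refchr <- NULL
  if (need_walk) {
    if (is.null(reference)) {
      stop("CIGAR contains 'M' (or methylation stratification was requested); ",
           "a reference is required", call. = FALSE)
    }
    refchr <- if (inherits(reference, "DNAStringSet")) {
      as.character(reference[[aln$ref_name]])
    } else reference[[aln$ref_name]]
  }

  mm <- 0L
  refspan <- sum(lens[ops %in% c("M", "=", "X", "D")])
  # per consumed reference base: 0 = match, 1 = mismatch, 2 = deleted
  status <- integer(0)
  ins_after <- integer(0)  # 0-based ref position preceding each insertion
  if (need_walk) {
    qseq <- strsplit(aln$seq, "", fixed = TRUE)[[1L]]
    rseq <- strsplit(substr(refchr, aln$ref_start + 1L,
                            aln$ref_start + refspan), "", fixed = TRUE)[[1L]]
    status <- integer(refspan)
    qi <- 1L; ri <- 1L
    for (k in seq_along(ops)) {
      op <- ops[k]; L <- lens[k]
      if (op == "H") next
      if (op == "S") { qi <- qi + L }
      else if (op %in% c("M", "=", "X")) {
        if (op == "X") {
          status[ri:(ri + L - 1L)] <- 1L
        } else if (op == "M") {
          neq <- qseq[qi:(qi + L - 1L)] != rseq[ri:(ri + L - 1L)]
          status[ri:(ri + L - 1L)] <- as.integer(neq)
        }
        qi <- qi + L; ri <- ri + L
      } else if (op == "I") {
        if (ri > 1L) ins_after <- c(ins_after, rep(aln$ref_start + ri - 2L, L))
        qi <- qi + L
      } else { # D
        status[ri:(ri + L - 1L)] <- 2L
        ri <- ri + L
      }
    }
    mm <- sum(status == 1L)
  } else {
    mm <- sum(lens[ops == "X"])
  }

  methyl <- data.frame(type = METHYL_TYPES, bases = 0L, deletion = 0L,
                       insertion = 0L, mismatch = 0L, stringsAsFactors = FALSE)
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    ann <- annotation[annotation$chrom == aln$ref_name, , drop = FALSE]
    if (nrow(ann) > 0L && refspan > 0L) {
      pos <- aln$ref_start + seq_len(refspan) - 1L  # 0-based covered positions
      gr_pos <- GenomicRanges::GRanges(aln$ref_name,
                                       IRanges::IRanges(pos + 1L, width = 1L))
      gr_ann <- GenomicRanges::GRanges(ann$chrom,
                                       IRanges::IRanges(ann$start + 1L, ann$end))
      fo <- GenomicRanges::findOverlaps(gr_pos, gr_ann)
      ptype <- rep(NA_integer_, refspan)
      if (length(fo) > 0L) {
        pri <- match(ann$type, METHYL_TYPES)[S4Vectors::subjectHits(fo)]
        best <- tapply(pri, S4Vectors::queryHits(fo), min)
        ptype[as.integer(names(best))] <- best
      }
      ins_counts <- tabulate(match(ins_after, pos), nbins = refspan)
      for (t in seq_along(METHYL_TYPES)) {
        sel <- which(ptype == t)
        methyl$bases[t] <- length(sel)
        methyl$deletion[t] <- sum(status[sel] == 2L)
        methyl$mismatch[t] <- sum(status[sel] == 1L)
        methyl$insertion[t] <- sum(ins_counts[sel])
      }
    }
  }
  structure(list(read_length = read_length, deletion_length = del,
                 insertion_length = ins, mismatch_length = mm,
                 methyl = methyl),
            class = "nr_alignment_stats")
}

#' Pool alignment statistics across reads
#'
#' Micro-averaging: lengths are summed and rates computed on the pooled
#' totals, which keeps the shared alignment-length denominator consistent.
#'
#' @param stats_list list of `nr_alignment_stats`.
#' @return one pooled `nr_alignment_stats`.
#' @export
aggregate_stats <- function(stats_list) {
  stopifnot(length(stats_list) > 0L)
  out <- stats_list[[1L]]
  for (s in stats_list[-1L]) {
    out$read_length <- out$read_length + s$read_length
    out$deletion_length <- out$deletion_length + s$deletion_length
    out$insertion_length <- out$insertion_length + s$insertion_length
    out$mismatch_length <- out$mismatch_length + s$mismatch_length
    for (col in c("bases", "deletion", "insertion", "mismatch")) {
      out$methyl[[col]] <- out$methyl[[col]] + s$methyl[[col]]
    }
  }
  out
}

#' Error rates from alignment statistics
#'
#' `XRate = Xlength / Alignlength` for X in deletion/insertion/mismatch and
#' `ErrorRate` their sum, with the shared denominator
#' `Alignlength = readlength + deletionlength`. Rates are percentages.
#'
#' @param stats an `nr_alignment_stats` (single read or pooled).
#' @return list of class `nr_rate_report` with `deletion_rate`,
#'   `insertion_rate`, `mismatch_rate`, `error_rate`, `align_length` and the
#'   input lengths.
#' @export
compute_rates <- function(stats) {
  if (stats$read_length <= 0) {
    stop("read length must be positive", call. = FALSE)
  }
  align_length <- stats$read_length + stats$deletion_length
  if (align_length == 0) stop("zero alignment length", call. = FALSE)
  drate <- 100 * stats$deletion_length / align_length
  irate <- 100 * stats$insertion_length / align_length
  mrate <- 100 * stats$mismatch_length / align_length
  structure(list(deletion_rate = drate, insertion_rate = irate,
                 mismatch_rate = mrate, error_rate = drate + irate + mrate,
                 align_length = align_length,
                 read_length = stats$read_length,
                 deletion_length = stats$deletion_length,
                 insertion_length = stats$insertion_length,
                 mismatch_length = stats$mismatch_length),
            class = "nr_rate_report")
}

#' @export
print.nr_rate_report <- function(x, ...) {
  cat(sprintf(
    "deletion %.2f%%  insertion %.2f%%  mismatch %.2f%%  error %.2f%%  (align length %d)\n",
    x$deletion_rate, x$insertion_rate, x$mismatch_rate, x$error_rate,
    as.integer(x$align_length)))
  invisible(x)
}

#' Error rates on methylated areas
#'
#' Per methylation type k: `XRate_k = Xbases_k / methylated_bases_k` and
#' `ErrorRate_k` their sum. The pooled rates reproduce the published pooled
#' definition literally: a plain sum of the per-type rates
#' (`XRate = sum_k XRate_k`); set `weighted = TRUE` for the base-weighted
#' alternative (`sum_k Xbases_k / sum_k methylated_bases_k`). Types without
#' covered methylated bases are omitted and listed in the `omitted` field.
#'
#' @param stats an `nr_alignment_stats` (usually pooled).
#' @param weighted use base-weighted pooling instead of the literal
#'   rate sum.
#' @return list of class `nr_methyl_rates` with a `per_type` data.frame
#'   (percent rates), `pooled` (named numeric), and `omitted`.
#' @export
methylated_rates <- function(stats, weighted = FALSE) {
  m <- stats$methyl
  has <- m$bases > 0L
  omitted <- m$type[!has]
  per <- m[has, , drop = FALSE]
  if (nrow(per) > 0L) {
    per$deletion_rate <- 100 * per$deletion / per$bases
    per$insertion_rate <- 100 * per$insertion / per$bases
    per$mismatch_rate <- 100 * per$mismatch / per$bases
    per$error_rate <- per$deletion_rate + per$insertion_rate + per$mismatch_rate
    if (weighted) {
      pooled <- c(deletion_rate = 100 * sum(per$deletion) / sum(per$bases),
                  insertion_rate = 100 * sum(per$insertion) / sum(per$bases),
                  mismatch_rate = 100 * sum(per$mismatch) / sum(per$bases))
    } else {
      pooled <- c(deletion_rate = sum(per$deletion_rate),
                  insertion_rate = sum(per$insertion_rate),
                  mismatch_rate = sum(per$mismatch_rate))
    }
    pooled["error_rate"] <- sum(pooled)
  } else {
    pooled <- c(deletion_rate = NA_real_, insertion_rate = NA_real_,
                mismatch_rate = NA_real_, error_rate = NA_real_)
  }
  structure(list(per_type = per, pooled = pooled, omitted = omitted,
                 weighted = weighted),
            class = "nr_methyl_rates")
}

#' Alignment statistics from a global pairwise alignment
#'
#' Aligner-independent evaluation route: the read is globally aligned to its
#' known reference window (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment()], ONT-style scoring) and
#' deletion/insertion/mismatch lengths are counted from the alignment
#' columns. Useful when reads are short or error-dense enough that seed-based
#' mappers drop them, and for simulated reads whose true window is known.
#'
#' @param query read sequence (character scalar).
#' @param ref reference window the read derives from (character scalar).
#' @param ref_offset 0-based genomic position of `ref`'s first base (for
#'   annotation lookup).
#' @param ref_name reference name (for annotation lookup).
#' @param annotation optional methylation annotation data.frame.
#' @return an `nr_alignment_stats`.
#' @export
stats_vs_reference <- function(query, ref, ref_offset = 0L, ref_name = "ref",
                               annotation = NULL) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4)
  aln <- Biostrings::pairwiseAlignment(query, ref, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  is_del <- p == "-"
  is_ins <- s == "-"
  is_mm <- !is_del & !is_ins & p != s
  read_length <- sum(!is_del)

  methyl <- data.frame(type = METHYL_TYPES, bases = 0L, deletion = 0L,
                       insertion = 0L, mismatch = 0L, stringsAsFactors = FALSE)
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    ann <- annotation[annotation$chrom == ref_name, , drop = FALSE]
    if (nrow(ann) > 0L) {
      refcol <- !is_ins
      # genomic 0-based position of each reference-consuming column
      gpos <- rep(NA_integer_, length(p))
      gpos[refcol] <- ref_offset + seq_len(sum(refcol)) - 1L
      site_type <- rep(NA_integer_, nchar(ref))
      for (t in rev(seq_along(METHYL_TYPES))) {
        rows <- ann[ann$type == METHYL_TYPES[t], , drop = FALSE]
        for (r in seq_len(nrow(rows))) {
          lo <- max(rows$start[r], ref_offset)
          hi <- min(rows$end[r], ref_offset + nchar(ref))
          if (hi > lo) site_type[(lo - ref_offset + 1L):(hi - ref_offset)] <- t
        }
      }
      col_type <- rep(NA_integer_, length(p))
      col_type[refcol] <- site_type[gpos[refcol] - ref_offset + 1L]
      # insertions attach to the preceding reference position
      last_ref_type <- NA_integer_
      ins_type <- rep(NA_integer_, length(p))
      for (i in seq_along(p)) {
        if (refcol[i]) last_ref_type <- col_type[i] else ins_type[i] <- last_ref_type
      }
      for (t in seq_along(METHYL_TYPES)) {
        sel <- which(col_type == t)
        methyl$bases[t] <- length(sel)
        methyl$deletion[t] <- sum(is_del[sel])
        methyl$mismatch[t] <- sum(is_mm[sel])
        methyl$insertion[t] <- sum(ins_type == t & is_ins, na.rm = TRUE)
      }
    }
  }
  structure(list(read_length = read_length,
                 deletion_length = sum(is_del),
                 insertion_length = sum(is_ins),
                 mismatch_length = sum(is_mm),
                 methyl = methyl),
            class = "nr_alignment_stats")
}
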