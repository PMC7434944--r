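#' Merge the two model predictions for one event into a revision action
#'
#' The fixed merging rules, in order:
#' \enumerate{
#'   \item if the error-type prediction is a base (not I/D) and either
#'     prediction equals the original base, keep the original base;
#'   \item if both models predict the same base, different from the
#'     original, substitute it;
#'   \item if the error-type model calls an insertion and the true-base
#'     model agrees with the original base, delete the base;
#'   \item if the error-type model calls a deletion, keep the original base
#'     and insert the true-base model's base after it (a deletion prediction
#'     concerns a missing neighbor, so it takes precedence over
#'     preservation);
#'   \item otherwise keep the original base (the conservative default that
#'     avoids introducing new errors).
#' }
#'
#' @param original called base(s), in A/C/G/T.
#' @param pred1 error-type model argmax class(es), in A/C/G/T/I/D.
#' @param pred2 true-base model argmax class(es), in A/C/G/T.
#' @return character vector of actions: `"KEEP"`, `"SUBSTITUTE:<b>"`,
#'   `"DELETE"` or `"KEEP_THEN_INSERT:<b>"`.
#' @export
decide <- function(original, pred1, pred2) {
  n <- length(original)
  stopifnot(length(pred1) == n, length(pred2) == n)
  if (any(!original %in% LABEL2_CLASSES)) {
    stop("invalid original base(s)", call. = FALSE)
  }
  if (any(!pred1 %in% LABEL1_CLASSES)) {
    stop("invalid error-type prediction(s)", call. = FALSE)
  }
  if (any(!pred2 %in% LABEL2_CLASSES)) {
    stop("invalid true-base prediction(s)", call. = FALSE)
  }
  out <- rep("KEEP", n)
  is_base1 <- !pred1 %in% c("I", "D")
  rule1 <- is_base1 & (pred1 == original | pred2 == original)
  rule2 <- !rule1 & is_base1 & pred1 == pred2 & pred1 != original
  rule3 <- !rule1 & !rule2 & pred1 == "I" & pred2 == original
  rule4 <- !rule1 & !rule2 & !rule3 & pred1 == "D"
  out[rule2] <- paste0("SUBSTITUTE:", pred1[rule2])
  out[rule3] <- "DELETE"
  out[rule4] <- paste0("KEEP_THEN_INSERT:", pred2[rule4])
  out
}

#' Apply per-event revision actions to a read
#'
#' Actions are applied left to right; `KEEP_THEN_INSERT` emits the original
#' base followed by the inserted base, so the read length changes by the
#' number of insertions minus deletions.
#'
#' @param sequence the read (character scalar).
#' @param actions one action per base, from [decide()].
#' @return the revised sequence.
#' @export
revise_read <- function(sequence, actions) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (length(actions) != length(bases)) {
    stop("got ", length(actions), " decisions for ", length(bases),
         " bases", call. = FALSE)
  }
  op <- sub(":.*$", "", actions)
  arg <- ifelse(grepl(":", actions, fixed = TRUE),
                sub("^.*:", "", actions), "")
  out <- character(length(bases))
  out[op == "KEEP"] <- bases[op == "KEEP"]
  out[op == "SUBSTITUTE"] <- arg[op == "SUBSTITUTE"]
  out[op == "DELETE"] <- ""
  ins <- op == "KEEP_THEN_INSERT"
  out[ins] <- paste0(bases[ins], arg[ins])
  paste(out, collapse = "")
}

#' Revise one read from model probability outputs
#'
#' @param sequence the called read.
#' @param probs1 matrix of error-type class probabilities (events x 6).
#' @param probs2 matrix of true-base class probabilities (events x 4).
#' @return the revised sequence (argmax decoding, then [decide()] and
#'   [revise_read()]).
#' @export
revise_from_probs <- function(sequence, probs1, probs2) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  stopifnot(nrow(probs1) == length(bases), nrow(probs2) == length(bases))
  pred1 <- LABEL1_CLASSES[max.col(probs1, ties.method = "first")]
  pred2 <- LABEL2_CLASSES[max.col(probs2, ties.method = "first")]
  revise_read(sequence, decide(bases, pred1, pred2))
}

#' Revise a set of reads and write FASTA/FASTQ
#'
#' Reads without predictions pass through unchanged (and are counted).
#' Inserted bases get a fixed quality in FASTQ output.
#'
#' @param reads named character vector of read sequences (names = ids), or a
#'   named list with `seq` and optional `qual` per read.
#' @param predictions named list: per read id, a list with `probs1` and
#'   `probs2` matrices (may omit reads).
#' @param path output file; format chosen by extension (`.fastq`/`.fq` =>
#'   FASTQ, else FASTA).
#' @param insert_qual quality character assigned to inserted bases (and to
#'   all bases when no input qualities exist).
#' @return invisibly, a list with `n_written` and `n_passthrough`.
#' @export
revise_file <- function(reads, predictions, path, insert_qual = "!") {
  if (is.list(reads) && !is.null(reads$seq)) reads <- stats::setNames(reads$seq, names(reads$seq))
  ids <- names(reads)
  stopifnot(!is.null(ids), all(nzchar(ids)))
  fastq <- grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)
  out <- character(0)
  n_pass <- 0L
  for (id in ids) {
    seq_in <- reads[[id]]
    pr <- predictions[[id]]
    if (is.null(pr)) {
      seq_out <- seq_in
      n_pass <- n_pass + 1L
    } else {
      seq_out <- revise_from_probs(seq_in, pr$probs1, pr$probs2)
    }
    if (fastq) {
      out <- c(out, paste0("@", id), seq_out, "+",
               strrep(insert_qual, nchar(seq_out)))
    } else {
      out <- c(out, paste0(">", id), seq_out)
    }
  }
  writeLines(out, path)
  invisible(list(n_written = length(ids), n_passthrough = n_pass))
}
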