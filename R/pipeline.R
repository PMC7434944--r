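#' Prepare labeled windows from reads and alignments
#'
#' Runs the preprocessing chain per read: re-segmentation to base-level
#' events, per-read signal normalization, label generation from the primary
#' alignment, optional methylation annotation, and windowing.
#'
#' @param reads list of per-read lists with `signal` (`nr_raw_signal`) and
#'   `events` (`nr_events`), or a character vector of event-TSV paths.
#' @param alignments result of [parse_alignment()] (named by read id).
#' @param reference named character vector or `DNAStringSet`.
#' @param window,signal_cap window geometry (see [make_windows()]).
#' @param with_methyl build the methylation feature channel.
#' @param annotation methylation annotation data.frame (required when
#'   `with_methyl`).
#' @return list with `windows` (bound `nr_windows`), `events` (per-read
#'   base-level labeled event tables), `sequences` (called reads) and
#'   `read_ids`; reads without a primary alignment are dropped and counted
#'   in `n_unaligned`.
#' @export
nr_prepare_windows <- function(reads, alignments, reference, window = 13L,
                               signal_cap = 40L, with_methyl = FALSE,
                               annotation = NULL) {
  if (is.character(reads)) {
    reads <- lapply(reads, read_event_tsv)
  }
  if (with_methyl && is.null(annotation)) {
    stop("with_methyl = TRUE requires a methylation annotation", call. = FALSE)
  }
  win_list <- list()
  ev_list <- list()
  seqs <- character(0)
  ids <- character(0)
  n_unaligned <- 0L
  for (rd in reads) {
    id <- rd$events$read_id
    aln <- alignments[[id]]
    if (is.null(aln)) { n_unaligned <- n_unaligned + 1L; next }
    base_ev <- resegment_events(rd$events, rd$signal)
    nsig <- normalize_signal(rd$signal)
    lab <- label_events(base_ev, aln, reference)
    if (!is.null(annotation)) {
      lab <- annotate_methylation(lab, aln, annotation)
    }
    win_list[[base::length(win_list) + 1L]] <-
      make_windows(lab, nsig, window = window, signal_cap = signal_cap,
                   with_methyl = with_methyl)
    ev_list[[base::length(ev_list) + 1L]] <- lab
    seqs <- c(seqs, rd$events$sequence)
    ids <- c(ids, id)
  }
  if (base::length(win_list) == 0L) {
    stop("no mappable reads: every read lacked a primary alignment",
         call. = FALSE)
  }
  list(windows = bind_windows(win_list), events = ev_list, sequences = seqs,
       read_ids = ids, n_unaligned = n_unaligned)
}

#' Train the two revision models
#'
#' Builds labeled windows from the inputs and trains the error-type model
#' (6 classes) and the true-base model (4 classes) independently with the
#' same hyper-parameters. Checkpoints and a per-epoch loss log (columns
#' epoch, total, ls, lc per model) are written when `out_dir` is given.
#'
#' @inheritParams nr_prepare_windows
#' @param sam SAM/BAM path with the training alignments (or a parsed
#'   alignment list).
#' @param config base `nr_model_config`; `num_classes` and `feat_dim` are
#'   set per model automatically.
#' @param out_dir optional output directory for `model1.rds`, `model2.rds`
#'   and `loss_log.tsv`.
#' @param seed seed for both trainings (offset by model index).
#' @return list with `model1`, `model2`, `log` and `prep` bookkeeping.
#' @export
nr_train_pipeline <- function(reads, sam, reference, config = nr_model_config(),
                              with_methyl = FALSE, annotation = NULL,
                              out_dir = NULL, seed = config$seed) {
  alignments <- if (is.character(sam)) parse_alignment(sam) else sam
  if (inherits(reference, "character") && base::length(reference) == 1L &&
      file.exists(reference)) {
    reference <- read_reference(reference)
  }
  feat_dim <- if (with_methyl) 10L else 7L
  prep <- nr_prepare_windows(reads, alignments, reference,
                             window = config$window,
                             signal_cap = config$signal_cap,
                             with_methyl = with_methyl,
                             annotation = annotation)
  cfg1 <- modify_config(config, num_classes = 6L, feat_dim = feat_dim,
                        seed = seed)
  cfg2 <- modify_config(config, num_classes = 4L, feat_dim = feat_dim,
                        seed = seed + 1L)
  m1 <- nr_train(nr_init_model(cfg1), prep$windows, which_label = 1L)
  m2 <- nr_train(nr_init_model(cfg2), prep$windows, which_label = 2L)
  log <- rbind(cbind(model = 1L, m1$history), cbind(model = 2L, m2$history))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    nr_save_model(m1, file.path(out_dir, "model1.rds"))
    nr_save_model(m2, file.path(out_dir, "model2.rds"))
    utils::write.table(log, file.path(out_dir, "loss_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(model1 = m1, model2 = m2, log = log, prep = prep)
}

modify_config <- function(config, ...) {
  upd <- list(...)
  cfg <- unclass(config)
  cfg[names(upd)] <- upd
  do.call(nr_model_config, cfg)
}

#' Read a reference FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Revise reads with a trained model pair
#'
#' Every input read yields exactly one output record (ids preserved). The
#' model pair must share the window geometry and feature dimension;
#' mismatches abort before any inference.
#'
#' @param reads as in [nr_prepare_windows()].
#' @param model1,model2 trained `nr_model`s or checkpoint paths.
#' @param output optional FASTA/FASTQ output path.
#' @param alignments,annotation required only for methylation-aware models
#'   (feature dimension 10): per-read reference positions come from the
#'   alignments.
#' @return named character vector of revised sequences (invisibly when
#'   `output` is written).
#' @export
nr_revise_pipeline <- function(reads, model1, model2, output = NULL,
                               alignments = NULL, annotation = NULL) {
  if (is.character(model1)) model1 <- nr_load_model(model1)
  if (is.character(model2)) model2 <- nr_load_model(model2)
  if (model1$config$num_classes != 6L || model2$config$num_classes != 4L) {
    stop("model1 must have 6 classes and model2 4 classes", call. = FALSE)
  }
  for (fld in c("window", "signal_cap", "feat_dim")) {
    if (!identical(model1$config[[fld]], model2$config[[fld]])) {
      stop("model checkpoints disagree on '", fld, "'", call. = FALSE)
    }
  }
  cfg <- model1$config
  with_methyl <- cfg$feat_dim == 10L
  if (with_methyl && (is.null(alignments) || is.null(annotation))) {
    stop("methylation-aware models need alignments and an annotation at ",
         "inference time", call. = FALSE)
  }
  if (is.character(reads)) reads <- lapply(reads, read_event_tsv)
  out <- character(0)
  for (rd in reads) {
    id <- rd$events$read_id
    base_ev <- resegment_events(rd$events, rd$signal)
    nsig <- normalize_signal(rd$signal)
    lab <- base_ev$events
    attr(lab, "read_id") <- id
    if (with_methyl) {
      aln <- alignments[[id]]
      if (!is.null(aln)) {
        lab <- label_events(base_ev, aln, attr(alignments, "reference"))
        lab <- annotate_methylation(lab, aln, annotation)
      }
    }
    win <- make_windows(lab, nsig, window = cfg$window,
                        signal_cap = cfg$signal_cap,
                        with_methyl = with_methyl)
    p1 <- nr_predict(model1, win)
    p2 <- nr_predict(model2, win)
    out[id] <- revise_from_probs(base_ev$sequence, p1, p2)
  }
  if (!is.null(output)) {
    fastq <- grepl("\\.(fastq|fq)$", output, ignore.case = TRUE)
    lines <- character(0)
    for (id in names(out)) {
      if (fastq) {
        lines <- c(lines, paste0("@", id), out[[id]], "+",
                   strrep("!", nchar(out[[id]])))
      } else {
        lines <- c(lines, paste0(">", id), out[[id]])
      }
    }
    writeLines(lines, output)
    return(invisible(out))
  }
  out
}

#' Evaluate alignments with the error-rate metrics
#'
#' @param sam SAM/BAM path (or parsed alignments).
#' @param reference FASTA path or named character vector.
#' @param bed optional methylation BED path (or annotation data.frame).
#' @param out_prefix optional path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return list with `n_reads`, `rates` (`nr_rate_report`), `methyl`
#'   (`nr_methyl_rates` or NULL) and `stats` (pooled).
#' @export
nr_eval_pipeline <- function(sam, reference, bed = NULL, out_prefix = NULL) {
  alignments <- if (is.character(sam)) parse_alignment(sam) else sam
  if (is.character(reference) && base::length(reference) == 1L &&
      file.exists(reference)) {
    reference <- read_reference(reference)
  }
  annotation <- NULL
  if (!is.null(bed)) {
    annotation <- if (is.character(bed)) read_methyl_bed(bed) else bed
  }
  n_reads <- base::length(alignments)
  if (n_reads == 0L) {
    return(list(n_reads = 0L, rates = NULL, methyl = NULL, stats = NULL))
  }
  stats_list <- lapply(alignments, stats_from_alignment,
                       reference = reference, annotation = annotation)
  pooled <- aggregate_stats(stats_list)
  rates <- compute_rates(pooled)
  methyl <- if (!is.null(annotation)) methylated_rates(pooled) else NULL
  if (!is.null(out_prefix)) {
    tab <- data.frame(metric = c("deletion_rate", "insertion_rate",
                                 "mismatch_rate", "error_rate"),
                      percent = c(rates$deletion_rate, rates$insertion_rate,
                                  rates$mismatch_rate, rates$error_rate))
    utils::write.table(tab, paste0(out_prefix, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    json <- list(n_reads = n_reads,
                 rates = rates[c("deletion_rate", "insertion_rate",
                                 "mismatch_rate", "error_rate")])
    if (!is.null(methyl)) {
      json$methylated_areas <- list(per_type = methyl$per_type,
                                    pooled = as.list(methyl$pooled))
    }
    jsonlite::write_json(json, paste0(out_prefix, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(n_reads = n_reads, rates = rates, methyl = methyl, stats = pooled)
}

#' Load a YAML run configuration
#'
#' Keys mirror [nr_model_config()] plus path entries (`reads`, `sam`,
#' `reference`, `bed`, `out`). Unknown keys are ignored by the model
#' configuration.
#'
#' @param path YAML file.
#' @return list with `paths` and `config` (`nr_model_config`).
#' @export
nr_read_config <- function(path) {
  y <- yaml::read_yaml(path)
  path_keys <- intersect(names(y), c("reads", "sam", "reference", "bed",
                                     "out", "with_methyl"))
  cfg_keys <- intersect(names(y), names(formals(nr_model_config)))
  list(paths = y[path_keys], config = do.call(nr_model_config, y[cfg_keys]))
}
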