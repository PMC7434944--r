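# signal/event container I/O and normalization

test_that("event TSV round-trips losslessly and validates its input", {
  rd <- random_event_table(25, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_tsv(rd$signal, rd$events, path)
  back <- read_event_tsv(path)
  expect_equal(back$signal$samples, rd$signal$samples, tolerance = 1e-12)
  expect_equal(back$events$events, rd$events$events, tolerance = 1e-12)
  expect_identical(back$events$sequence, rd$events$sequence)
  expect_identical(back$events$read_id, rd$events$read_id)

  # header-only file: empty table with a warning
  writeLines(c("##read_id=x", "##sequence=", "##signal=1,2,3",
               paste0("#", paste(c("start", "length", "mean", "stdv",
                                   "model_state", "move", "weight",
                                   "p_model_state", "base"), collapse = "\t"))),
             path)
  expect_warning(empty <- read_event_tsv(path), "no event rows")
  expect_equal(nrow(empty$events$events), 0L)

  # an out-of-domain move value is rejected
  bad <- rd$events$events
  bad$move[3] <- 3L
  expect_error(event_table("x", bad, rd$events$sequence), "move")

  # a short row reports its line number
  lines <- readLines({write_event_tsv(rd$signal, rd$events, path); path})
  lines[6] <- "1\t2\t3"
  writeLines(lines, path)
  expect_error(read_event_tsv(path), "line 6")
})

test_that("fast5-style container round-trips and rejects malformed files", {
  rd <- random_event_table(20, seed = 3, read_id = "f5test")
  path <- withr::local_tempfile(fileext = ".fast5")
  write_fast5(rd$signal, rd$events, path)
  back <- read_fast5(path)
  expect_identical(back$events$read_id, "f5test")
  expect_equal(back$signal$samples, rd$signal$samples, tolerance = 1e-12)
  expect_equal(back$events$events$start, rd$events$events$start)
  expect_equal(back$events$events$mean, rd$events$events$mean, tolerance = 1e-12)
  expect_identical(back$events$events$model_state, rd$events$events$model_state)
  expect_identical(back$events$events$move, rd$events$events$move)
  expect_identical(back$events$sequence, rd$events$sequence)
  # signal length covers the events
  expect_gte(back$signal$sample_count,
             max(back$events$events$start + back$events$events$length))

  # a container missing the event group names the absent path
  expect_error(
    read_fast5(path, paths = list(signal = "Raw/Reads/*/Signal",
                                  events = "Analyses/Nope/Events",
                                  fastq = "none")),
    "malformed container")
})

test_that("median/MAD normalization matches a naive oracle and its contract", {
  # zero-spread fallback
  expect_equal(normalize_signal(c(5, 5, 5)), c(0, 0, 0),
               ignore_attr = TRUE)
  # affine invariance
  set.seed(9)
  x <- rnorm(101, 80, 10)
  expect_equal(as.numeric(normalize_signal(x)),
               as.numeric(normalize_signal(3.2 * x + 17)), tolerance = 1e-9)
  # agreement with an independent implementation
  v <- c(1, 2, 3, 4, 100)
  expect_equal(as.numeric(normalize_signal(v)), naive_normalize(v),
               tolerance = 1e-12)
  expect_equal(naive_normalize(v), (v - 3) / 1.4826, tolerance = 1e-12)
  # idempotence when MAD > 0
  y <- as.numeric(normalize_signal(x))
  expect_equal(as.numeric(normalize_signal(y)), y, tolerance = 1e-6)
})

test_that("raw signal and event table constructors enforce invariants", {
  expect_error(raw_signal("r", numeric(0)), "empty")
  rd <- random_event_table(10, seed = 5)
  expect_error(event_table("r", rd$events$events, "ACGT"),
               "does not equal sequence length")
  expect_error(event_table("r", rd$events$events, rd$events$sequence,
                           sample_count = 5), "exceeds signal bounds")
})
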