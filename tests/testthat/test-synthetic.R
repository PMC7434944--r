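# synthetic signal/event/alignment generator

test_that("reference simulation is seeded and validates its inputs", {
  a <- simulate_reference(1000, seed = 7)
  b <- simulate_reference(1000, seed = 7)
  expect_identical(a$sequence, b$sequence)
  expect_equal(nchar(a$sequence), 1000L)
  expect_error(simulate_reference(4, k = 5), "must be >=")
  # methylation site count stays within binomial 99% bounds of n * density
  m <- simulate_reference(1000, seed = 3, methyl_density = 0.02)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.02)
  expect_gte(nrow(m$methyl), bounds[1])
  expect_lte(nrow(m$methyl), bounds[2])
  expect_true(all(m$methyl$end - m$methyl$start == 1L))
  expect_true(all(m$methyl$type %in% c("m6A", "m4C", "modified")))
})

test_that("a zero error profile reproduces the reference window", {
  ref <- simulate_reference(400, seed = 5)
  rd <- simulate_read(ref, start = 50, length = 200, seed = 9,
                      errors = error_profile(0, 0, 0))
  expect_identical(rd$truth$called,
                   substr(ref$sequence, 51, 250))
  expect_identical(rd$truth$cigar, "200=")
  # sample count equals the sum of event lengths
  expect_equal(rd$signal$sample_count, sum(rd$events$events$length))
})

test_that("re-segmentation recovers the generator's canonical intervals", {
  ref <- simulate_reference(3000, seed = 11)
  for (s in 1:10) {
    strand <- if (s %% 2 == 0) "-" else "+"
    rd <- simulate_read(ref, start = 100 * s, length = 300, seed = 100 + s,
                        strand = strand)
    base <- resegment_events(rd$events, rd$signal)
    expect_equal(nrow(base$events), nchar(rd$truth$called))
    expect_equal(base$events$start, rd$truth$canonical_start)
    expect_equal(base$events$start + base$events$length,
                 rd$truth$canonical_end)
  }
})

test_that("labeling recovers every injected error from the truth alignment", {
  ref <- simulate_reference(5000, seed = 17, methyl_density = 0.02)
  refv <- setNames(ref$sequence, ref$ref_name)
  set.seed(17)
  reads <- lapply(1:25, function(i) {
    simulate_read(ref, start = sample(0:4500, 1), length = 400,
                  strand = sample(c("+", "-"), 1),
                  read_id = sprintf("lab_%02d", i))
  })
  sam <- withr::local_tempfile(fileext = ".sam")
  write_truth_sam(reads, ref, sam)
  alns <- parse_alignment(sam)
  for (rd in reads) {
    base <- resegment_events(rd$events, rd$signal)
    lab <- label_events(base, alns[[rd$truth$read_id]], refv)
    expect_identical(lab$label1, rd$truth$label1)
    expect_identical(lab$label2, rd$truth$label2)
    expect_equal(lab$refpos, as.numeric(rd$truth$ref_of_called))
    # the round-trip edit reconstructs the true (oriented) read exactly
    expect_identical(apply_labels(lab), rd$truth$true_read)
    # methylation flags match the generator's bookkeeping
    lab <- annotate_methylation(lab, alns[[rd$truth$read_id]], ref$methyl)
    expect_identical(lab$methyl != "none", rd$truth$methylated_called)
  }
})

test_that("realized error rates match the configured targets within 3 sigma", {
  errors <- error_profile()  # 15% split 6:5:8 deletion:insertion:mismatch
  ds <- generate_dataset(60, read_length = 500, errors = errors, seed = 23,
                         reference_length = 20000)
  stats <- aggregate_stats(lapply(ds$reads, function(r) {
    t <- r$truth
    stats_from_alignment(list(read_id = t$read_id, ref_name = t$ref_name,
                              ref_start = t$ref_start, strand = t$strand,
                              cigar = t$cigar, seq = t$sam_seq))
  }))
  rates <- compute_rates(stats)
  n <- rates$align_length
  for (pair in list(c(rates$deletion_rate / 100, errors$deletion),
                    c(rates$insertion_rate / 100, errors$insertion),
                    c(rates$mismatch_rate / 100, errors$mismatch))) {
    sigma <- sqrt(pair[2] * (1 - pair[2]) / n)
    expect_lt(abs(pair[1] - pair[2]), 3 * sigma)
  }
  # and the generator's own error log agrees with the CIGAR recount
  expect_equal(stats$deletion_length,
               sum(vapply(ds$reads, function(r) r$truth$n_deletion, numeric(1))))
  expect_equal(stats$insertion_length,
               sum(vapply(ds$reads, function(r) r$truth$n_insertion, numeric(1))))
  expect_equal(stats$mismatch_length,
               sum(vapply(ds$reads, function(r) r$truth$n_mismatch, numeric(1))))
})

test_that("dataset generation is reproducible and writes coherent fixtures", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  d1 <- generate_dataset(4, read_length = 150, seed = 8, methyl_density = 0.02,
                         reference_length = 2000, dir = dir1)
  d2 <- generate_dataset(4, read_length = 150, seed = 8, methyl_density = 0.02,
                         reference_length = 2000, dir = dir2)
  # identical seed, identical fixtures
  expect_identical(readLines(d1$paths$sam), readLines(d2$paths$sam))
  expect_identical(readLines(d1$paths$reads[1]), readLines(d2$paths$reads[1]))
  # one event TSV per read, all reads present in the SAM
  expect_equal(length(d1$paths$reads), 4L)
  sam_ids <- vapply(strsplit(grep("^[^@]", readLines(d1$paths$sam),
                                  value = TRUE), "\t"), `[[`, "", 1L)
  expect_setequal(sam_ids, vapply(d1$reads, function(r) r$truth$read_id, ""))
  # the TSV round-trips to the in-memory read
  back <- read_event_tsv(d1$paths$reads[2])
  expect_equal(back$events$events, d1$reads[[2]]$events$events,
               tolerance = 1e-12)
  # the written reference parses and matches
  refv <- read_reference(d1$paths$reference)
  expect_identical(unname(refv), d1$reference$sequence)
})
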