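# alignment parsing, label generation, methylation flags, windowing

ref1 <- c(chr = "ACGTACGTACGTACGTACGT")

# build a base-level event table for an arbitrary called read
base_events <- function(read, read_id = "r") {
  n <- nchar(read)
  ev <- data.frame(start = seq(0, by = 4, length.out = n), length = 4,
                   mean = 90, stdv = 1, model_state = strrep("A", 5),
                   move = 1L, weight = 1, p_model_state = 0.9,
                   base = strsplit(read, "", fixed = TRUE)[[1]],
                   stringsAsFactors = FALSE)
  event_table(read_id, ev, read, sample_count = 4 * n)
}

aln_rec <- function(read, cigar, pos = 0L, strand = "+", rname = "chr") {
  list(read_id = "r", ref_name = rname, ref_start = pos, strand = strand,
       cigar = cigar, seq = read)
}

test_that("SAM parsing keeps primaries and reports exclusions", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr\tLN:20",
               "r1\t0\tchr\t1\t60\t4=\t*\t0\t0\tACGT\t*",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*",
               "r3\t16\tchr\t3\t60\t2=1X1=\t*\t0\t0\tTACG\t*"), sam)
  suppressMessages(recs <- parse_alignment(sam))
  expect_setequal(names(recs), c("r1", "r3"))
  expect_identical(attr(recs, "n_excluded"), 1L)
  expect_identical(recs$r1$cigar, "4=")
  expect_identical(recs$r3$strand, "-")
  expect_identical(recs$r1$ref_start, 0L)
  suppressMessages(sub <- parse_alignment(sam, read_ids = c("r1", "zz")))
  expect_identical(attr(sub, "missing"), "zz")
})

test_that("insertions label I with the called base, matches carry the reference", {
  # read ACGT vs ref ACT...: the G is inserted
  refi <- c(chr = "ACTACTACT")
  lab <- label_events(base_events("ACGT"), aln_rec("ACGT", "2=1I1="), refi)
  expect_identical(lab$label1, c("A", "C", "I", "T"))
  expect_identical(lab$label2, c("A", "C", "G", "T"))
  expect_true(is.na(lab$refpos[3]))
  expect_equal(lab$refpos[-3], c(0, 1, 2))
})

test_that("deletions attach to the preceding event with the lost base", {
  # read ACT vs ref ACGT: G deleted after the C
  lab <- label_events(base_events("ACT"), aln_rec("ACT", "2=1D1="), ref1)
  expect_identical(lab$label1, c("A", "D", "T"))
  expect_identical(lab$label2, c("A", "G", "T"))
})

test_that("a perfect alignment labels every event with its own base", {
  lab <- label_events(base_events("ACGT"), aln_rec("ACGT", "4="), ref1)
  expect_identical(lab$label1, lab$label2)
  expect_identical(lab$label1, c("A", "C", "G", "T"))
})

test_that("minus-strand reference bases are complemented into read orientation", {
  # reference window [0,4) of AACCGGTT is AACC; a minus-strand read covering
  # it is basecalled as GGTT and must label as a perfect match with
  # descending reference coordinates
  ref2 <- c(chr = "AACCGGTT")
  lab <- label_events(base_events("GGTT"),
                      aln_rec("AACC", "4=", pos = 0L, strand = "-"), ref2)
  expect_identical(lab$label1, c("G", "G", "T", "T"))
  expect_equal(lab$refpos, c(3, 2, 1, 0))
})

test_that("soft clips are excluded and CIGAR/event mismatches are caught", {
  lab <- label_events(base_events("AACGT"), aln_rec("AACGT", "1S4="), ref1)
  expect_true(lab$clipped[1])
  expect_true(is.na(lab$label1[1]))
  expect_identical(lab$label1[-1], c("A", "C", "G", "T"))
  expect_error(label_events(base_events("ACGT"), aln_rec("ACGT", "3="), ref1),
               "3 query bases")
})

test_that("methylation flags respect containment and the type priority", {
  lab <- label_events(base_events("ACGT"), aln_rec("ACGT", "4=", pos = 8L), ref1)
  ann <- data.frame(chrom = "chr", start = c(5L, 9L), end = c(15L, 10L),
                    type = c("modified", "m6A"), stringsAsFactors = FALSE)
  out <- annotate_methylation(lab, aln_rec("ACGT", "4=", pos = 8L), ann)
  # position 9 overlaps both intervals: m6A wins by priority
  expect_identical(out$methyl, c("modified", "m6A", "modified", "modified"))
  # empty annotation leaves everything unflagged
  out2 <- annotate_methylation(lab, aln_rec("ACGT", "4="),
                               ann[integer(0), , drop = FALSE])
  expect_true(all(out2$methyl == "none"))
  # unknown chromosome: warning, all none
  expect_warning(
    out3 <- annotate_methylation(lab, aln_rec("ACGT", "4=", rname = "chr2"),
                                 within(ann, chrom <- "chr")),
    "no intervals")
})

test_that("priority is resolved correctly for every 3-interval arrangement", {
  lab <- label_events(base_events("ACGT"), aln_rec("ACGT", "4="), ref1)
  types <- c("m6A", "m4C", "modified")
  for (perm in list(1:3, c(2, 1, 3), c(3, 2, 1), c(1, 3, 2), c(2, 3, 1), c(3, 1, 2))) {
    ann <- data.frame(chrom = "chr", start = 0L, end = 4L,
                      type = types[perm], stringsAsFactors = FALSE)
    out <- annotate_methylation(lab, aln_rec("ACGT", "4="), ann)
    expect_true(all(out$methyl == "m6A"), info = paste(perm, collapse = ","))
  }
})

test_that("windows are centered, padded and sized per the feature layout", {
  set.seed(6)
  read <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  base <- base_events(read)
  sig <- raw_signal("r", rnorm(80, 90, 4))
  lab <- base$events
  attr(lab, "read_id") <- "r"
  win <- make_windows(lab, sig, window = 13, signal_cap = 6)
  expect_equal(nrow(win$signal), 20)      # one window per center
  expect_equal(ncol(win$features), 13 * 7)
  expect_equal(ncol(win$signal), 13 * 6)
  # first window: 6 left positions are padding
  expect_true(all(win$features[1, 1:(6 * 7)] == 0))
  expect_true(any(win$features[1, (6 * 7 + 1):(7 * 7)] != 0))
  # methylation channel widens the per-position vector to 10
  lab$methyl <- rep("m6A", nrow(lab))
  win10 <- make_windows(lab, sig, window = 13, signal_cap = 6,
                        with_methyl = TRUE)
  expect_equal(ncol(win10$features), 13 * 10)
  # geometry errors
  expect_error(make_windows(lab, sig, window = 12), "odd")
  expect_error(make_windows(lab[1:3, ], sig, window = 13),
               "larger than")
})
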