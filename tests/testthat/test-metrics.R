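# alignment-based error rates

ref <- c(chr = paste(rep("ACGT", 10), collapse = ""))

rec <- function(cigar, seq, pos = 0L) {
  list(read_id = "r", ref_name = "chr", ref_start = pos, strand = "+",
       cigar = cigar, seq = seq)
}

test_that("CIGAR walks count deletion/insertion/mismatch lengths", {
  s <- stats_from_alignment(rec("5=", "ACGTA"))
  expect_equal(unlist(s[c("read_length", "deletion_length",
                          "insertion_length", "mismatch_length")]),
               c(read_length = 5, deletion_length = 0,
                 insertion_length = 0, mismatch_length = 0))
  # 3=1X1=2D2=1I consumes 8 query bases and 7+2 reference bases
  s2 <- stats_from_alignment(rec("3=1X1=2D2=1I", "ACGAATCG"))
  expect_equal(s2$read_length, 8)
  expect_equal(s2$deletion_length, 2)
  expect_equal(s2$insertion_length, 1)
  expect_equal(s2$mismatch_length, 1)
  # 'M' ops are resolved against the reference
  s3 <- stats_from_alignment(rec("8M", "ACGTAAAT"), reference = ref)
  expect_equal(s3$mismatch_length, 2)
  expect_error(stats_from_alignment(rec("4M", "ACGT")), "reference")
})

test_that("rates follow the shared alignment-length denominator", {
  st <- structure(list(read_length = 8, deletion_length = 2,
                       insertion_length = 1, mismatch_length = 1,
                       methyl = data.frame(type = c("m6A", "m4C", "modified"),
                                           bases = 0L, deletion = 0L,
                                           insertion = 0L, mismatch = 0L)),
                  class = "nr_alignment_stats")
  r <- compute_rates(st)
  expect_equal(r$align_length, 10)
  expect_equal(r$deletion_rate, 20)
  expect_equal(r$insertion_rate, 10)
  expect_equal(r$mismatch_rate, 10)
  expect_equal(r$error_rate, 40)
  # error-free input
  st0 <- st; st0$deletion_length <- st0$insertion_length <- st0$mismatch_length <- 0
  r0 <- compute_rates(st0)
  expect_equal(r0$error_rate, 0)
  # error rate decomposes exactly, and random cases match a direct recompute
  set.seed(13)
  for (i in 1:50) {
    sti <- st
    sti$read_length <- sample(50:500, 1)
    sti$deletion_length <- sample(0:40, 1)
    sti$insertion_length <- sample(0:40, 1)
    sti$mismatch_length <- sample(0:40, 1)
    ri <- compute_rates(sti)
    al <- sti$read_length + sti$deletion_length
    expect_equal(ri$deletion_rate, 100 * sti$deletion_length / al)
    expect_equal(ri$error_rate,
                 ri$deletion_rate + ri$insertion_rate + ri$mismatch_rate)
    expect_equal(ri$error_rate, 100 * (sti$deletion_length +
                 sti$insertion_length + sti$mismatch_length) / al)
  }
})

test_that("rates are invariant under read duplication", {
  s <- stats_from_alignment(rec("3=1X1=2D2=1I", "ACGAATCG"))
  one <- compute_rates(s)
  two <- compute_rates(aggregate_stats(list(s, s)))
  expect_equal(two$deletion_rate, one$deletion_rate)
  expect_equal(two$error_rate, one$error_rate)
  expect_equal(two$align_length, 2 * one$align_length)
})

test_that("methylated-area rates follow the per-type and pooled formulas", {
  st <- structure(list(read_length = 500, deletion_length = 10,
                       insertion_length = 5, mismatch_length = 30,
                       methyl = data.frame(
                         type = c("m6A", "m4C", "modified"),
                         bases = c(100L, 40L, 0L),
                         deletion = c(5L, 2L, 0L),
                         insertion = c(0L, 0L, 0L),
                         mismatch = c(25L, 10L, 0L))),
                  class = "nr_alignment_stats")
  m <- methylated_rates(st)
  m6 <- m$per_type[m$per_type$type == "m6A", ]
  expect_equal(m6$mismatch_rate, 25)
  expect_equal(m6$deletion_rate, 5)
  expect_equal(m6$error_rate, 30)
  # the pooled definition is the literal sum of the per-type rates
  expect_equal(unname(m$pooled["mismatch_rate"]), 25 + 25)
  expect_equal(unname(m$pooled["error_rate"]),
               unname(sum(m$pooled[c("deletion_rate", "insertion_rate",
                                     "mismatch_rate")])))
  expect_identical(m$omitted, "modified")
  # with no insertions on methylated bases, error = deletion + mismatch
  expect_equal(unname(m$pooled["error_rate"]),
               unname(m$pooled["deletion_rate"] + m$pooled["mismatch_rate"]))
  # weighted alternative pools by bases
  mw <- methylated_rates(st, weighted = TRUE)
  expect_equal(unname(mw$pooled["mismatch_rate"]), 100 * 35 / 140)
  # no methylated bases anywhere: empty section
  st$methyl$bases <- 0L
  st$methyl$deletion <- st$methyl$mismatch <- 0L
  m0 <- methylated_rates(st)
  expect_equal(nrow(m0$per_type), 0L)
})

test_that("methylation counters restrict to annotated covered positions", {
  ann <- data.frame(chrom = "chr", start = c(1L, 3L), end = c(2L, 4L),
                    type = c("m6A", "m4C"), stringsAsFactors = FALSE)
  # read AGGT vs ref ACGT: mismatch at ref pos 1 (m6A); deletion of pos 3 (m4C)
  s <- stats_from_alignment(rec("2=1X1D", "ACT"), reference = ref,
                            annotation = ann)
  expect_equal(s$methyl$bases, c(1L, 1L, 0L))
  expect_equal(s$methyl$mismatch, c(0L, 0L, 0L))
  expect_equal(s$methyl$deletion, c(0L, 1L, 0L))
})

test_that("pairwise-alignment statistics agree with the CIGAR route", {
  set.seed(77)
  ds <- generate_dataset(5, read_length = 200, seed = 99,
                         reference_length = 1000)
  for (rd in ds$reads) {
    t <- rd$truth
    cig <- stats_from_alignment(
      list(read_id = t$read_id, ref_name = t$ref_name, ref_start = t$ref_start,
           strand = t$strand, cigar = t$cigar, seq = t$sam_seq))
    w <- substr(ds$reference$sequence, t$ref_start + 1,
                t$ref_start + t$ref_span)
    if (t$strand == "-") w <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(w)))
    pw <- stats_vs_reference(t$called, w)
    expect_equal(pw$read_length, cig$read_length)
    # alignment-score optima may trade a mismatch against an indel pair, so
    # totals agree while the split can differ by a base or two
    tot_cig <- cig$deletion_length + cig$insertion_length + cig$mismatch_length
    tot_pw <- pw$deletion_length + pw$insertion_length + pw$mismatch_length
    expect_lte(abs(tot_pw - tot_cig), 0.1 * tot_cig + 2)
  }
})
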