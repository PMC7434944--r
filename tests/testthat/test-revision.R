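# merging model predictions into revision actions

test_that("the five merging rules fire in their documented order", {
  expect_identical(decide("A", "A", "G"), "KEEP")
  expect_identical(decide("A", "C", "C"), "SUBSTITUTE:C")
  expect_identical(decide("A", "I", "A"), "DELETE")
  expect_identical(decide("C", "D", "G"), "KEEP_THEN_INSERT:G")
  expect_identical(decide("A", "C", "G"), "KEEP")
  # the conservative defaults: I without agreement, D regardless of agreement
  expect_identical(decide("A", "I", "C"), "KEEP")
  expect_identical(decide("C", "D", "C"), "KEEP_THEN_INSERT:C")
  expect_error(decide("N", "A", "A"), "invalid")
  expect_error(decide("A", "Z", "A"), "invalid")
})

test_that("revision actions splice the read as a character-level edit", {
  expect_identical(revise_read("ACGT", rep("KEEP", 4)), "ACGT")
  expect_identical(revise_read("ACGT", c("KEEP", "KEEP", "DELETE", "KEEP")),
                   "ACT")
  expect_identical(
    revise_read("AC", c("KEEP_THEN_INSERT:T", "SUBSTITUTE:G")), "ATG")
  expect_error(revise_read("ACGT", rep("KEEP", 3)), "3 decisions")
})

test_that("revise_read equals a naive interpreter on random action vectors", {
  set.seed(31)
  acts <- c("KEEP", "DELETE", paste0("SUBSTITUTE:", c("A", "C", "G", "T")),
            paste0("KEEP_THEN_INSERT:", c("A", "C", "G", "T")))
  for (i in 1:200) {
    n <- sample(1:40, 1)
    read <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
    a <- sample(acts, n, replace = TRUE)
    expect_identical(revise_read(read, a), naive_revise(read, a))
  }
})

test_that("perfect three-way agreement leaves any read unchanged", {
  set.seed(5)
  for (i in 1:10) {
    read <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                  collapse = "")
    b <- strsplit(read, "", fixed = TRUE)[[1]]
    expect_identical(revise_read(read, decide(b, b, b)), read)
  }
})

test_that("revise_file passes reads through when predictions are missing", {
  reads <- c(r1 = "ACGTACGT", r2 = "GGGTTT")
  fa <- withr::local_tempfile(fileext = ".fasta")
  res <- revise_file(reads, predictions = list(), path = fa)
  expect_equal(res$n_written, 2L)
  expect_equal(res$n_passthrough, 2L)
  lines <- readLines(fa)
  expect_identical(lines, c(">r1", "ACGTACGT", ">r2", "GGGTTT"))

  # FASTQ output keeps quality length equal to sequence length
  fq <- withr::local_tempfile(fileext = ".fastq")
  p1 <- matrix(0, 8, 6); p1[, 5] <- 1            # model 1 says insertion
  p2 <- matrix(0.25, 8, 4)
  p2[cbind(1:8, match(strsplit(reads[["r1"]], "")[[1]],
                      c("A", "C", "G", "T")))] <- 1  # model 2 echoes the read
  revise_file(reads, predictions = list(r1 = list(probs1 = p1, probs2 = p2)),
              path = fq)
  fql <- readLines(fq)
  expect_equal(length(fql), 8L)
  expect_identical(fql[2], "")                    # every base deleted
  expect_equal(nchar(fql[4]), nchar(fql[2]))
  expect_equal(nchar(fql[8]), nchar(fql[6]))
})
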