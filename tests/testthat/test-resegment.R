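# event re-segmentation: one event per called base

test_that("interval statistics match hand arithmetic and a naive two-pass", {
  expect_equal(interval_stats(c(2, 2, 2), 0, 3), c(mean = 2, stdv = 0))
  expect_equal(interval_stats(c(1, 3), 0, 2), c(mean = 2, stdv = 1))
  set.seed(21)
  x <- rnorm(200, 90, 9)
  st <- interval_stats(x, 40, 50)
  v <- x[41:90]
  expect_equal(unname(st[1]), sum(v) / 50, tolerance = 1e-9)
  expect_equal(unname(st[2]), sqrt(sum((v - mean(v))^2) / 50), tolerance = 1e-9)
  expect_error(interval_stats(x, 0, 0), "positive")
  expect_error(interval_stats(x, 190, 20), "outside")
})

test_that("moves are resolved by merge (0), keep (1) and midpoint split (2)", {
  # enumeration oracle: moves 1,0,2,1 with lengths 5,3,4,2 give intervals
  # [0,8) [8,10) [10,12) [12,14): the stay merges into its predecessor and
  # the double-move interval splits at its midpoint
  sig <- raw_signal("e", rnorm(14, 90, 2))
  ev <- data.frame(start = c(0, 5, 8, 12), length = c(5, 3, 4, 2),
                   mean = 0, stdv = 0, model_state = "AAAAA",
                   move = c(1L, 0L, 2L, 1L), weight = 1, p_model_state = 0.9,
                   base = "A", stringsAsFactors = FALSE)
  tab <- event_table("e", ev, "ACGT")
  out <- resegment_events(tab, sig)
  expect_equal(out$events$start, c(0, 8, 10, 12))
  expect_equal(out$events$length, c(8, 2, 2, 2))
  expect_equal(out$events$base, c("A", "C", "G", "T"))
  expect_true(all(out$events$move == 1L))

  # all moves already 1: identity with recomputed statistics
  rd <- random_event_table(15, seed = 2)
  rd$events$events$move <- 1L
  rd$events$sequence <- strrep("A", 15)
  rd$events$events$base <- "A"
  out2 <- resegment_events(rd$events, rd$signal)
  expect_equal(out2$events$start, rd$events$events$start)
  expect_equal(out2$events$length, rd$events$events$length)

  # a read that never advances is unalignable
  rd0 <- random_event_table(5, seed = 4)
  rd0$events$events$move <- 0L
  rd0$events$sequence <- ""
  expect_error(resegment_events(rd0$events, rd0$signal), "unalignable")
})

test_that("re-segmentation conserves samples, preserves order and is idempotent", {
  for (seed in 1:30) {
    rd <- random_event_table(40, seed = seed)
    out <- resegment_events(rd$events, rd$signal)
    ev_in <- rd$events$events
    ev_out <- out$events
    # exactly one event per called base, in order
    expect_equal(nrow(ev_out), sum(ev_in$move))
    expect_identical(paste(ev_out$base, collapse = ""), rd$events$sequence)
    # sample conservation: same span, contiguous, no overlap
    expect_equal(min(ev_out$start), min(ev_in$start))
    expect_equal(max(ev_out$start + ev_out$length),
                 max(ev_in$start + ev_in$length))
    expect_true(all(utils::head(ev_out$start + ev_out$length, -1) ==
                    utils::tail(ev_out$start, -1)))
    # statistics recomputed from the raw samples
    i <- which.max(ev_out$length)
    expect_equal(unname(interval_stats(rd$signal, ev_out$start[i],
                                       ev_out$length[i])[1]),
                 ev_out$mean[i], tolerance = 1e-9)
    # idempotence
    again <- resegment_events(out, rd$signal)
    expect_equal(again$events, out$events, tolerance = 1e-12)
  }
})
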