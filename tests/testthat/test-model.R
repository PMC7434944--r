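# network construction, losses, training and prediction

test_that("topology follows the configuration and is seed-deterministic", {
  win <- tiny_windows(6, seed = 2)
  m6 <- nr_init_model(tiny_config(num_classes = 6L))
  p6 <- nr_predict(m6, win)
  expect_equal(dim(p6), c(6L, 6L))
  m4 <- nr_init_model(tiny_config(num_classes = 4L))
  expect_equal(ncol(nr_predict(m4, win)), 4L)
  # identical seed and config reproduce the initial forward pass exactly
  again <- nr_predict(nr_init_model(tiny_config(num_classes = 6L)), win)
  expect_identical(p6, again)
  # invalid class counts are rejected at configuration time
  expect_error(nr_model_config(num_classes = 5L), "4 or 6")
})

test_that("the residual shortcut is live: removing it changes outputs", {
  win <- tiny_windows(4, seed = 8)
  cfg <- tiny_config(num_classes = 4L)
  m <- nr_init_model(cfg)
  m_cut <- m
  m_cut$config$use_shortcut <- FALSE
  p <- nr_predict(m, win)
  p_cut <- nr_predict(m_cut, win)
  expect_gt(max(abs(p - p_cut)), 1e-8)
})

test_that("center loss matches its closed form and a naive loop", {
  centers <- matrix(0, 4, 2)
  expect_equal(nr_center_loss(matrix(c(3, 4), 1), 1L, centers, "sum"), 12.5)
  # features equal to their centers give zero
  cent <- matrix(rnorm(8), 4, 2)
  y <- c(1L, 3L, 2L)
  expect_equal(nr_center_loss(cent[y, ], y, cent, "sum"), 0)
  # random batch vs an explicit per-sample loop
  set.seed(41)
  f <- matrix(rnorm(8 * 5), 8)
  cen <- matrix(rnorm(4 * 5), 4)
  yy <- sample.int(4L, 8, replace = TRUE)
  naive <- sum(vapply(1:8, function(i) 0.5 * sum((f[i, ] - cen[yy[i], ])^2),
                      numeric(1)))
  expect_equal(nr_center_loss(f, yy, cen, "sum"), naive, tolerance = 1e-9)
  expect_equal(nr_center_loss(f, yy, cen, "mean"), naive / 8, tolerance = 1e-9)
  expect_error(nr_center_loss(f, rep(9L, 8), cen), "center set")
})

test_that("total loss is cross-entropy plus the weighted center term", {
  set.seed(42)
  logits <- matrix(rnorm(6 * 6), 6)
  f <- matrix(rnorm(6 * 3), 6)
  cen <- matrix(rnorm(6 * 3), 6)
  y <- sample.int(6L, 6, replace = TRUE)
  # lambda = 0 reduces to the cross-entropy alone
  expect_equal(nr_total_loss(logits, f, y, cen, lambda = 0),
               nr_softmax_ce(logits, y), tolerance = 1e-12)
  # uniform logits give ln(K) per sample
  expect_equal(nr_softmax_ce(matrix(0, 5, 6), rep(2L, 5), "mean"), log(6),
               tolerance = 1e-12)
  # naive independent computation at lambda = 0.2
  naive_ce <- -mean(vapply(seq_along(y), function(i) {
    z <- logits[i, ] - max(logits[i, ])
    z[y[i]] - log(sum(exp(z)))
  }, numeric(1)))
  naive_lc <- mean(vapply(seq_along(y), function(i) {
    0.5 * sum((f[i, ] - cen[y[i], ])^2)
  }, numeric(1)))
  expect_equal(nr_total_loss(logits, f, y, cen, lambda = 0.2),
               naive_ce + 0.2 * naive_lc, tolerance = 1e-9)
  expect_error(nr_total_loss(logits, f, y, cen, lambda = -1), ">= 0")
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_config(num_classes = 4L, dropout = 0)
  m <- nr_init_model(cfg)
  set.seed(3)
  m$centers <- matrix(rnorm(16) * 0.1, 4, 4)
  win <- tiny_windows(3, seed = 12)
  y <- c(1L, 3L, 2L)
  res <- nr_loss_grads(m, win, y)
  # loss decomposition holds exactly
  expect_equal(res$total, res$ls + cfg$lambda_center * res$lc,
               tolerance = 1e-9)
  h <- 1e-5
  worst <- 0
  for (pn in names(m$params)) {
    idx <- seq_along(m$params[[pn]])
    if (length(idx) > 40) idx <- sort(sample(idx, 40))
    for (j in idx) {
      up <- m; up$params[[pn]][j] <- up$params[[pn]][j] + h
      dn <- m; dn$params[[pn]][j] <- dn$params[[pn]][j] - h
      fd <- (nr_loss_grads(up, win, y, gradients = FALSE)$total -
             nr_loss_grads(dn, win, y, gradients = FALSE)$total) / (2 * h)
      rel <- abs(fd - res$grads[[pn]][j]) /
        max(1e-4, abs(fd), abs(res$grads[[pn]][j]))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("training reduces the loss and can overfit a tiny set", {
  set.seed(10)
  # separable toy task: the center feature column encodes the class
  n <- 200
  win <- tiny_windows(n, seed = 10)
  y <- sample.int(4L, n, replace = TRUE)
  win$features[, 2 * 7 + 1:4] <- 0
  win$features[cbind(seq_len(n), 2 * 7 + y)] <- 3
  win$label2 <- y
  cfg <- tiny_config(num_classes = 4L, epochs = 5L, batch_size = 32L)
  m <- nr_train(nr_init_model(cfg), win, which_label = 2L)
  expect_lt(tail(m$history$total, 1), m$history$total[1])
  # loss decomposition holds at every logged epoch
  expect_equal(m$history$total, m$history$ls + cfg$lambda_center * m$history$lc,
               tolerance = 1e-6)

  # overfit probe: 32 windows, 200 epochs, > 90% training accuracy
  win32 <- tiny_windows(32, seed = 22)
  y32 <- sample.int(4L, 32, replace = TRUE)
  win32$features[, 2 * 7 + 1:4] <- 0
  win32$features[cbind(1:32, 2 * 7 + y32)] <- 3
  win32$label2 <- y32
  cfg2 <- tiny_config(num_classes = 4L, epochs = 200L, batch_size = 16L,
                      dense_units = 8L, trunk_lstm_state = 6L)
  m2 <- nr_train(nr_init_model(cfg2), win32, which_label = 2L)
  acc <- mean(max.col(nr_predict(m2, win32)) == y32)
  expect_gt(acc, 0.9)
})

test_that("the first logged cross-entropy is unaffected by the center term", {
  # the center-loss gradient only acts through parameter updates, so the
  # first epoch's first-step Ls is common to lambda = 0 and lambda = 0.2;
  # with a single batch per epoch the logged epoch-1 Ls must coincide
  win <- tiny_windows(16, seed = 33)
  cfg_a <- tiny_config(num_classes = 4L, epochs = 1L, batch_size = 16L,
                       lambda_center = 0)
  cfg_b <- tiny_config(num_classes = 4L, epochs = 1L, batch_size = 16L,
                       lambda_center = 0.2)
  ha <- nr_train(nr_init_model(cfg_a), win, which_label = 2L)$history
  hb <- nr_train(nr_init_model(cfg_b), win, which_label = 2L)$history
  expect_equal(ha$ls[1], hb$ls[1], tolerance = 1e-9)
  expect_equal(ha$total[1], ha$ls[1], tolerance = 1e-12)
})

test_that("prediction is a per-window distribution, independent of batch order", {
  win <- tiny_windows(9, seed = 14)
  m <- nr_init_model(tiny_config(num_classes = 6L, batch_size = 4L))
  p <- nr_predict(m, win)
  expect_equal(nrow(p), 9L)
  expect_equal(rowSums(p), rep(1, 9), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # permuting the windows permutes the rows and nothing else
  perm <- c(5, 1, 9, 2, 7, 3, 8, 4, 6)
  win_p <- win
  win_p$signal <- win$signal[perm, ]
  win_p$features <- win$features[perm, ]
  expect_equal(nr_predict(m, win_p), p[perm, ], tolerance = 1e-12)
  # feature-dimension mismatches abort
  win_bad <- win
  win_bad$feat_dim <- 10L
  expect_error(nr_predict(m, win_bad), "feature dimension")
})

test_that("checkpoints save and restore the full model", {
  m <- nr_init_model(tiny_config(num_classes = 6L))
  path <- withr::local_tempfile(fileext = ".rds")
  nr_save_model(m, path)
  back <- nr_load_model(path)
  expect_identical(back$params, m$params)
  expect_identical(back$config, m$config)
  saveRDS(list(1), path)
  expect_error(nr_load_model(path), "not a model checkpoint")
})
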