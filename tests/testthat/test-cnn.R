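# Tiny synthetic records for training smoke tests: 8^3 boxes, 5 channels,
# with a label that is a simple function of the channel contents.
syntheticRecords <- function(n, seed, inputN = 8L) {
  BoxCC:::withSeed(seed, lapply(seq_len(n), function(i) {
    lab <- runif(1)
    ch <- array(rnorm(inputN^3 * 5, sd = 0.1), c(inputN, inputN, inputN, 5))
    # plant the label as a strong mean shift of channel 1
    ch[, , , 1] <- ch[, , , 1] + lab
    DescriptorRecord(ch, lab, meta = list(aa = "ALA", chain = "A",
                                          resno = i, structureId = "syn",
                                          resolutionTag = "",
                                          center = c(0, 0, 0),
                                          edge = inputN * 0.5, spacing = 0.5))
  }))
}

tinyConfig <- function(epochs = 4L, seed = 2L, lr = 2e-4) {
  cnnConfig(inputN = 8L, squeeze = c(2L, 2L, 2L, 2L),
            expand = c(4L, 4L, 4L, 4L), pool = c(1L, 1L, 0L, 0L),
            dropout = 0, lr = lr, epochs = epochs, batchSize = 8L,
            seed = seed, augment = 1L)
}

test_that("training converges toward a constant label", {
  recs <- syntheticRecords(24, seed = 5)
  for (i in seq_along(recs)) recs[[i]]@label <- 0.62
  m <- trainModel(recs, "ALA", tinyConfig(epochs = 3L))
  pred <- predictBcc(m, recs[1:8])
  expect_lt(max(abs(pred$bccPred - 0.62)), 0.1)
  expect_lt(abs(mean(pred$bccPred) - 0.62), 0.05)
  expect_length(m@history, 3)
  expect_true(all(is.finite(m@history)))
})

test_that("training is deterministic under the config seed", {
  recs <- syntheticRecords(24, seed = 6)
  m1 <- trainModel(recs, "ALA", tinyConfig(epochs = 2L, seed = 9L))
  m2 <- trainModel(recs, "ALA", tinyConfig(epochs = 2L, seed = 9L))
  expect_identical(m1@history, m2@history)
  expect_identical(predictBcc(m1, recs[1:4])$bccPred,
                   predictBcc(m2, recs[1:4])$bccPred)
  m3 <- trainModel(recs, "ALA", tinyConfig(epochs = 2L, seed = 10L))
  expect_false(identical(m1@history, m3@history))
})

test_that("more epochs reduce the training loss", {
  recs <- syntheticRecords(32, seed = 7)
  m <- trainModel(recs, "ALA", tinyConfig(epochs = 6L))
  expect_lt(m@history[6], m@history[1])
})

test_that("prediction validates record type and clamps to [0, 1]", {
  recs <- syntheticRecords(24, seed = 8)
  m <- trainModel(recs, "ALA", tinyConfig(epochs = 2L))
  bad <- recs[[1]]
  bad@meta$aa <- "GLY"
  expect_error(predictBcc(m, list(bad)), "do not match")
  p <- predictBcc(m, recs)
  expect_true(all(p$bccPred >= 0 & p$bccPred <= 1))
  expect_named(p, c("structureId", "resolutionTag", "chain", "resno", "aa",
                    "bccPred"))
  # single record accepted without wrapping
  p1 <- predictBcc(m, recs[[1]])
  expect_equal(nrow(p1), 1)
})

test_that("training validates input sizes", {
  recs <- syntheticRecords(4, seed = 9)
  expect_error(trainModel(recs, "ALA", tinyConfig()), "batchSize")
  recs <- syntheticRecords(24, seed = 9)
  cfgWrong <- tinyConfig()
  cfgWrong@inputN <- 12L
  expect_error(trainModel(recs, "ALA", cfgWrong), "inputN")
})

test_that("forward pass matches a hand-computed degenerate network", {
  # one squeeze filter copying channel 1, expand filters as pure center
  # taps: the network output reduces to head_b + head_w * GAP(relu(x1))
  cfg <- cnnConfig(inputN = 4L, channels = 2L, squeeze = rep(1L, 4),
                   expand = rep(1L, 4), pool = rep(0L, 4), dropout = 0,
                   epochs = 1L, batchSize = 1L, augment = 1L)
  w <- list(stages = lapply(1:4, function(s) {
    cen <- numeric(27); cen[14] <- 1      # center of the 3^3 stencil
    list(Wsq = matrix(c(1, 0), 1, 2)[, seq_len(if (s == 1) 2 else 1),
                                     drop = FALSE],
         bsq = 0, Wex = matrix(cen, 1, 27), bex = 0)
  }), head_w = 2, head_b = 0.1)
  x <- abs(rnorm(4^3 * 2))
  X <- matrix(0, 2 * 4^3, 1)
  X[seq(1, by = 2, length.out = 4^3), 1] <- x[1:64]   # channel 1
  X[seq(2, by = 2, length.out = 4^3), 1] <- x[65:128] # channel 2
  out <- BoxCC:::cpp_cnn_forward(w, X, 4L, 2L, rep(0L, 4))
  expect_equal(out, 0.1 + 2 * mean(x[1:64]), tolerance = 1e-10)
})
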