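#' Configuration for the 3D CNN bCC regressor
#'
#' The architecture is four fire stages (1^3 squeeze + 3^3 expand
#' convolutions, ReLU), max pooling after stages 1 and 2, dropout before
#' the last stage, global average pooling after stage 4 and a linear scalar
#' head. The loss is mean squared error and the optimizer Adam. Defaults
#' mirror the reference training protocol (learning rate 1e-5, 40 epochs,
#' all 24 rotations); tests and desk-scale runs pass reduced
#' configurations.
#'
#' @param inputN samples per box axis (24 for 12 A boxes at 0.5 A spacing)
#' @param channels input channels (5)
#' @param squeeze,expand filter counts for the four stages
#' @param pool per-stage pooling: 0 none, 1 max 2^3, 2 average 2^3
#' @param dropout dropout rate applied to the input of stage 4
#' @param lr Adam learning rate
#' @param epochs training epochs
#' @param batchSize mini-batch size
#' @param seed RNG seed (weight init, shuffling, dropout)
#' @param normalize per-channel z-scoring with training-set statistics
#' @param augment rotations presented per record per epoch (1..24)
#' @return a [CNNConfig-class]
#' @export
cnnConfig <- function(inputN = 24L, channels = 5L,
                      squeeze = c(8L, 8L, 12L, 12L),
                      expand = c(16L, 16L, 24L, 24L),
                      pool = c(1L, 1L, 0L, 0L),
                      dropout = 0.5, lr = 1e-5, epochs = 40L,
                      batchSize = 16L, seed = 1L, normalize = TRUE,
                      augment = 24L) {
  new("CNNConfig", inputN = as.integer(inputN),
      channels = as.integer(channels), squeeze = as.integer(squeeze),
      expand = as.integer(expand), pool = as.integer(pool),
      dropout = as.numeric(dropout), lr = as.numeric(lr),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      seed = as.integer(seed), normalize = normalize,
      augment = as.integer(augment))
}

initWeights <- function(config) {
  withSeed(config@seed, {
    cin <- config@channels
    stages <- vector("list", 4)
    for (s in 1:4) {
      sq <- config@squeeze[s]; ex <- config@expand[s]
      stages[[s]] <- list(
        Wsq = matrix(rnorm(sq * cin, sd = sqrt(2 / cin)), sq, cin),
        bsq = numeric(sq),
        Wex = matrix(rnorm(ex * sq * 27, sd = sqrt(2 / (sq * 27))),
                     ex, sq * 27),
        bex = numeric(ex))
      cin <- ex
    }
    list(stages = stages,
         head_w = rnorm(cin, sd = 1 / sqrt(cin)), head_b = 0)
  })
}

mapTree <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) mapTree(f, x, y), a, b)
    out
  } else f(a, b)
}

zeroLike <- function(w) mapTree(function(a, b) a * 0, w, w)

# pack records into a (channels * N^3) x n matrix, channel index fastest
recordsToMatrix <- function(records) {
  d <- dim(records[[1]]@channels)
  V <- prod(d[1:3]); C <- d[4]
  X <- matrix(0, C * V, length(records))
  for (i in seq_along(records)) {
    m <- matrix(as.numeric(records[[i]]@channels), V, C)
    X[, i] <- as.numeric(t(m))
  }
  X
}

channelStats <- function(X, C) {
  V <- nrow(X) / C
  mu <- numeric(C); sdv <- numeric(C)
  for (c in 1:C) {
    rows <- seq(c, by = C, length.out = V)
    v <- X[rows, ]
    mu[c] <- mean(v)
    sdv[c] <- sd(as.numeric(v))
    if (!is.finite(sdv[c]) || sdv[c] == 0) sdv[c] <- 1
  }
  list(mu = mu, sd = sdv)
}

applyStats <- function(X, stats) {
  C <- length(stats$mu)
  V <- nrow(X) / C
  for (c in 1:C) {
    rows <- seq(c, by = C, length.out = V)
    X[rows, ] <- (X[rows, ] - stats$mu[c]) / stats$sd[c]
  }
  X
}

# voxel-rotation permutation of the packed (channel-fastest) layout
packedRotationIndex <- function(n, C, k) {
  rotv <- rotationIndex(n, k)
  rep((rotv - 1L) * C, each = C) + rep(seq_len(C), times = length(rotv))
}

#' Train a per-amino-acid bCC regressor
#'
#' Trains the 3D CNN on the labeled records of one amino-acid type with
#' squared-error loss and Adam. Fully deterministic under the config seed.
#' Aborts with diagnostics when the loss turns non-finite.
#'
#' @param archive a [DescriptorArchive-class] or a plain list of labeled
#'   [DescriptorRecord-class]
#' @param aminoAcid three-letter type to train on
#' @param config a [CNNConfig-class]
#' @return a [TrainedModel-class] with per-epoch loss history
#' @export
trainModel <- function(archive, aminoAcid, config = cnnConfig()) {
  records <- if (is(archive, "DescriptorArchive"))
    readRecords(archive, aminoAcid)
  else
    Filter(function(r) identical(r@meta$aa, aminoAcid), archive)
  records <- Filter(function(r) !is.na(r@label), records)
  if (length(records) < config@batchSize)
    stop("need at least batchSize (", config@batchSize,
         ") labeled ", aminoAcid, " records, have ", length(records))
  d <- dim(records[[1]]@channels)
  if (d[1] != config@inputN)
    stop("record grid ", d[1], " does not match config inputN ",
         config@inputN)
  y <- vapply(records, function(r) r@label, numeric(1))
  X <- recordsToMatrix(records)
  stats <- if (config@normalize) channelStats(X, config@channels)
           else list(mu = rep(0, config@channels),
                     sd = rep(1, config@channels))
  X <- applyStats(X, stats)
  w <- initWeights(config)
  w$head_b <- mean(y)
  mAdam <- zeroLike(w); vAdam <- zeroLike(w); tAdam <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  rots <- unique(as.integer(floor(seq(0, 23.999,
                                      length.out = config@augment))))
  perms <- lapply(rots, function(k)
    if (k == 0) NULL else packedRotationIndex(config@inputN,
                                              config@channels, k))
  n <- length(records)
  history <- numeric(config@epochs)
  pool <- config@pool
  for (epoch in seq_len(config@epochs)) {
    sched <- expand.grid(samp = seq_len(n), rot = seq_along(rots))
    ord <- withSeed(config@seed + 7919L * epoch, sample(nrow(sched)))
    sched <- sched[ord, , drop = FALSE]
    nb <- ceiling(nrow(sched) / config@batchSize)
    eloss <- 0
    for (bi in seq_len(nb)) {
      rows <- sched[((bi - 1) * config@batchSize + 1):
                      min(bi * config@batchSize, nrow(sched)), , drop = FALSE]
      Xb <- X[, rows$samp, drop = FALSE]
      for (j in seq_len(nrow(rows))) {
        p <- perms[[rows$rot[j]]]
        if (!is.null(p)) Xb[, j] <- Xb[p, j]
      }
      g <- cpp_cnn_grad(w, Xb, y[rows$samp], config@inputN,
                        config@channels, pool, config@dropout,
                        (config@seed %% 1000L) * 1000000L +
                          epoch * 10000L + bi)
      if (!is.finite(g$loss))
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi,
             " (lr = ", config@lr, "); reduce the learning rate")
      eloss <- eloss + g$loss * nrow(rows)
      tAdam <- tAdam + 1
      grad <- g[c("stages", "head_w", "head_b")]
      mAdam <- mapTree(function(m, gg) b1 * m + (1 - b1) * gg, mAdam, grad)
      vAdam <- mapTree(function(v, gg) b2 * v + (1 - b2) * gg^2, vAdam, grad)
      corr <- config@lr * sqrt(1 - b2^tAdam) / (1 - b1^tAdam)
      upd <- mapTree(function(m, v) corr * m / (sqrt(v) + eps), mAdam, vAdam)
      w <- mapTree(function(wi, u) wi - u, w, upd)
    }
    history[epoch] <- eloss / nrow(sched)
  }
  new("TrainedModel", aminoAcid = aminoAcid, weights = w, config = config,
      history = history, normStats = stats,
      manifestHash = if (is(archive, "DescriptorArchive"))
        (archive@manifest$hash %||% "") else "")
}

#' Predict bCC for descriptor records
#'
#' Deterministic given the weights; predictions are clamped to \[0, 1\].
#'
#' @param model a [TrainedModel-class]
#' @param records list of [DescriptorRecord-class] of the model's
#'   amino-acid type
#' @return data.frame (structureId, resolutionTag, chain, resno, aa,
#'   bccPred)
#' @export
predictBcc <- function(model, records) {
  if (is(records, "DescriptorRecord")) records <- list(records)
  aa <- vapply(records, function(r) r@meta$aa %||% "UNK", character(1))
  bad <- aa != model@aminoAcid
  if (any(bad))
    stop("record type(s) ", paste(unique(aa[bad]), collapse = ", "),
         " do not match model type ", model@aminoAcid)
  cfg <- model@config
  X <- applyStats(recordsToMatrix(records), model@normStats)
  p <- cpp_cnn_forward(model@weights, X, cfg@inputN, cfg@channels, cfg@pool)
  meta <- function(f, default) vapply(records, function(r)
    r@meta[[f]] %||% default, default)
  data.frame(structureId = meta("structureId", ""),
             resolutionTag = meta("resolutionTag", ""),
             chain = meta("chain", ""),
             resno = as.integer(meta("resno", NA_integer_)),
             aa = aa,
             bccPred = pmin(pmax(p, 0), 1),
             stringsAsFactors = FALSE)
}
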