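# Shared small descriptor set, cached per session.
descEnv <- new.env(parent = emptyenv())
descSet <- function() {
  if (is.null(descEnv$recs)) {
    fx <- helixFixture()
    descEnv$recs <- buildDescriptorSet(fx$structure, fx$map, edge = 6,
                                       spacing = 0.5,
                                       structureId = "helix8",
                                       resolutionTag = "1.5")
  }
  descEnv$recs
}

test_that("descriptor channels are element-linear in the calculated density", {
  fx <- helixFixture()
  recs <- descSet()
  expect_gt(length(recs), 3)
  r <- recs[[2]]
  expect_equal(dim(r@channels), c(12L, 12L, 12L, 5L))
  # channel 1 is exactly the observed box
  obox <- extractBox(fx$map, r@meta$center, r@meta$edge, r@meta$spacing)
  expect_equal(r@channels[, , , 1], boxValues(obox), tolerance = 1e-12)
  # the sum of the element channels equals the full-model calculated box
  model <- setUniformBfactor(stripStructure(fx$structure), 2)
  cmap <- synthesizeMap(model, gridDimsForSpacing(unitCell(model), 0.5))
  cbox <- boxValues(extractBox(cmap, r@meta$center, r@meta$edge,
                               r@meta$spacing))
  s4 <- r@channels[, , , 2] + r@channels[, , , 3] + r@channels[, , , 4] +
    r@channels[, , , 5]
  # the model carries no atoms outside C/N/O/S, so the decomposition is exact
  expect_equal(s4, cbox, tolerance = 1e-6)
  # metadata
  expect_equal(r@meta$structureId, "helix8")
  expect_true(r@meta$aa %in% STANDARD_AA)
})

test_that("labelRecord scores the box against the correct map", {
  fx <- helixFixture()
  recs <- descSet()
  lab <- labelRecord(recs[[1]], fx$map)
  expect_false(is.na(lab@label))
  expect_true(lab@label >= -1 && lab@label <= 1)
  # oracle: bcc of observed box vs summed element channels
  r <- recs[[1]]
  obox <- extractBox(fx$map, r@meta$center, r@meta$edge, r@meta$spacing)
  calc <- r@channels[, , , 2] + r@channels[, , , 3] + r@channels[, , , 4] +
    r@channels[, , , 5]
  expect_equal(lab@label, bcc(boxValues(obox), calc), tolerance = 1e-12)
  # degenerate correct map leaves the record unlabeled and flagged
  flat <- fx$map
  flat@values[] <- 0
  lab0 <- labelRecord(r, flat)
  expect_true(is.na(lab0@label))
  expect_equal(lab0@meta$flag, "degenerate")
})

test_that("balanceDataset caps bins, shuffles deterministically", {
  mk <- function(lab) {
    r <- descSet()[[1]]
    r@label <- lab
    r
  }
  labs <- c(rep(0.05, 20), rep(0.55, 4), rep(0.95, 10), NA)
  recs <- lapply(labs, mk)
  out <- balanceDataset(recs, nBins = 10, perBinCap = 5, seed = 3)
  got <- vapply(out, function(r) r@label, numeric(1))
  expect_equal(sum(got == 0.05), 5)
  expect_equal(sum(got == 0.55), 4)
  expect_equal(sum(got == 0.95), 5)
  expect_false(anyNA(got))
  out2 <- balanceDataset(recs, nBins = 10, perBinCap = 5, seed = 3)
  expect_identical(vapply(out2, function(r) r@label, numeric(1)), got)
  out3 <- balanceDataset(recs, nBins = 10, perBinCap = 5, seed = 4)
  expect_false(identical(vapply(out3, function(r) r@label, numeric(1)), got))
  expect_error(balanceDataset(recs, nBins = 1), ">= 2")
})

test_that("rotation augmentation preserves labels and voxel multisets", {
  fx <- helixFixture()
  r <- labelRecord(descSet()[[1]], fx$map)
  aug <- augmentRotations(r)
  expect_length(aug, 24)
  expect_identical(aug[[1]]@channels, r@channels)
  for (k in c(5, 13, 24)) {
    a <- aug[[k]]
    for (c in 1:5)
      expect_identical(sort(as.numeric(a@channels[, , , c])),
                       sort(as.numeric(r@channels[, , , c])))
    # label invariance under a joint rotation
    calc <- a@channels[, , , 2] + a@channels[, , , 3] +
      a@channels[, , , 4] + a@channels[, , , 5]
    expect_equal(bcc(a@channels[, , , 1], calc), r@label, tolerance = 1e-12)
  }
})

test_that("archives round-trip bit-identically with a checked manifest", {
  fx <- helixFixture()
  recs <- lapply(descSet(), labelRecord, correctObsMap = fx$map)
  p <- file.path(tempdir(), "arch-test")
  arch <- writeArchive(recs, p, provenance = list(generator = "test",
                                                  seed = 3),
                       overwrite = TRUE)
  expect_error(writeArchive(recs, p), "already exists")
  back <- readArchive(p)
  expect_setequal(archiveTypes(back), unique(vapply(recs, function(r)
    r@meta$aa, "")))
  all2 <- readRecords(back)
  expect_equal(length(all2), length(recs))
  # bit-identical channels and labels for a matched record
  key <- function(r) paste(r@meta$chain, r@meta$resno)
  m <- match(key(recs[[1]]), vapply(all2, key, ""))
  expect_identical(all2[[m]]@channels, recs[[1]]@channels)
  expect_identical(all2[[m]]@label, recs[[1]]@label)
  expect_equal(back@manifest$provenance$seed, 3)
  expect_equal(back@manifest$nRecords, length(recs))
  # corrupting a chunk breaks the count check
  f <- file.path(p, paste0("records-", archiveTypes(back)[1], ".rds"))
  saveRDS(list(), f, version = 2)
  expect_error(readArchive(p), "mismatch")
  unlink(p, recursive = TRUE)
  expect_error(readArchive(p), "manifest")
})

test_that("evaluatePredictions joins on keys and reports correlation", {
  pred <- data.frame(chain = "A", resno = 1:6, aa = "ALA",
                     bccPred = c(0.2, 0.4, 0.5, 0.6, 0.8, 0.9))
  act <- data.frame(chain = "A", resno = c(1:5, 99),
                    bcc = c(0.25, 0.35, 0.55, 0.6, 0.75, 0.5))
  ev <- evaluatePredictions(pred, act)
  expect_equal(ev$n, 5)
  expect_equal(ev$r, cor(pred$bccPred[1:5], act$bcc[1:5]), tolerance = 1e-12)
  expect_equal(ev$meanDelta, mean(pred$bccPred[1:5] - act$bcc[1:5]),
               tolerance = 1e-12)
  expect_equal(ev$unmatched, 2)   # resno 6 on one side, 99 on the other
  expect_false(is.null(ev$perAA))
  expect_error(evaluatePredictions(data.frame(bccPred = 1),
                                   data.frame(bcc = 1)), "key")
})
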