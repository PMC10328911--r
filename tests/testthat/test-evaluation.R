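test_that("confusion matrix orientation is rows = truth, columns =
           prediction", {
  cm <- confusionCounts(c("maize", "maize"), c("maize", "nonmaize"),
                        classes = c("maize", "nonmaize"))
  expect_identical(cm, matrix(c(1L, 0L, 1L, 0L), 2,
                              dimnames = list(truth = c("maize", "nonmaize"),
                                              predicted = c("maize",
                                                            "nonmaize"))))
  # perfect predictions give a diagonal matrix
  y <- sample(phenoClasses(), 50, TRUE)
  cmd <- confusionCounts(y, y, classes = phenoClasses())
  expect_equal(cmd, diag(as.vector(table(factor(y, phenoClasses())))),
               ignore_attr = TRUE)
  # permutation invariance
  set.seed(3)
  truth <- sample(phenoClasses(), 80, TRUE)
  pred <- sample(phenoClasses(), 80, TRUE)
  ord <- sample(80)
  expect_identical(confusionCounts(truth, pred, phenoClasses()),
                   confusionCounts(truth[ord], pred[ord], phenoClasses()))
  expect_equal(sum(confusionCounts(truth, pred, phenoClasses())), 80)
  expect_error(confusionCounts("wheat", "maize", classes = phenoClasses()),
               "unknown label")
})

test_that("binarization collapses negatives and conserves counts", {
  m <- matrix(c(10L, 1L, 2L, 0L,
                0L, 20L, 3L, 1L,
                1L, 4L, 30L, 2L,
                0L, 5L, 6L, 40L), 4, byrow = TRUE,
              dimnames = list(truth = phenoClasses(),
                              predicted = phenoClasses()))
  b <- binarizeMatrix(m, positive = "maize")
  expect_equal(sum(b), sum(m))
  expect_equal(b["maize", "maize"], 10L)
  expect_equal(b["maize", "nonmaize"], 3L)
  expect_equal(b["nonmaize", "maize"], 1L)
  expect_equal(b["nonmaize", "nonmaize"], sum(m) - 14L)
  # diagonal 4-class matrix -> diagonal 2-class matrix
  d <- diag(c(5L, 6L, 7L, 8L))
  dimnames(d) <- dimnames(m)
  bd <- binarizeMatrix(d)
  expect_equal(bd, matrix(c(5L, 0L, 0L, 21L), 2), ignore_attr = TRUE)
  # off-diagonal counts among the three negative classes land on the
  # negative diagonal
  neg <- matrix(0L, 4, 4, dimnames = dimnames(m))
  neg["soybean", "rice"] <- 9L
  expect_equal(binarizeMatrix(neg)["nonmaize", "nonmaize"], 9L)
})

test_that("accuracy metrics match hand arithmetic and a per-sample recount
           oracle", {
  m <- matrix(c(8L, 2L, 1L, 9L), 2, byrow = TRUE,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  a <- accuracyMetrics(m)
  expect_equal(a$perClass$ua[1], 8 / 9, tolerance = 1e-12)
  expect_equal(a$perClass$pa[1], 0.8, tolerance = 1e-12)
  expect_equal(a$oa, 0.85, tolerance = 1e-12)
  # min(UA, PA) <= F1 <= max(UA, PA)
  expect_gte(a$perClass$f1[1], min(a$perClass$ua[1], a$perClass$pa[1]))
  expect_lte(a$perClass$f1[1], max(a$perClass$ua[1], a$perClass$pa[1]))

  # recount oracle on random label lists
  set.seed(4)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    truth <- sample(phenoClasses(), n, TRUE)
    pred <- sample(phenoClasses(), n, TRUE)
    cm <- confusionCounts(truth, pred, phenoClasses())
    a <- accuracyMetrics(cm)
    expect_equal(a$oa, mean(truth == pred), tolerance = 1e-12)
    for (k in seq_along(phenoClasses())) {
      cl <- phenoClasses()[k]
      uaOracle <- sum(truth == cl & pred == cl) / sum(pred == cl)
      paOracle <- sum(truth == cl & pred == cl) / sum(truth == cl)
      expect_equal(a$perClass$ua[k], uaOracle, tolerance = 1e-12)
      expect_equal(a$perClass$pa[k], paOracle, tolerance = 1e-12)
    }
    # OA equals the prevalence-weighted mean of per-class PA
    w <- as.vector(table(factor(truth, phenoClasses()))) / n
    expect_equal(a$oa, sum(w * a$perClass$pa), tolerance = 1e-12)
  }
  # empty column -> undefined UA, not an error
  e <- matrix(c(0L, 0L, 5L, 5L), 2,
              dimnames = list(truth = c("a", "b"), predicted = c("a", "b")))
  expect_true(is.na(accuracyMetrics(e)$perClass$ua[1]))
})

test_that("rounding for printed tables is half-up at the requested digits", {
  expect_equal(phenoMaize:::roundHalfUp(0.865, 2), 0.87)
  expect_equal(phenoMaize:::roundHalfUp(0.9073, 3), 0.907)
  expect_equal(phenoMaize:::roundHalfUp(0.825, 2), 0.83)
  expect_equal(phenoMaize:::roundHalfUp(-0.825, 2), -0.83)
})

test_that("mapped area honors units, nodata and region splits", {
  map <- matrix(0L, 20, 20)
  map[1:10, 1:10] <- 1L
  a <- areaByRegion(map, NULL)
  expect_equal(a$area_ha, 100 * 900 / 1e4)     # 9 ha
  expect_equal(areaByRegion(matrix(0L, 5, 5), NULL)$area_ha, 0)
  # nodata pixels are excluded
  mapNA <- map; mapNA[1, 1] <- NA
  expect_equal(areaByRegion(mapNA, NULL)$area_ha, 99 * 0.09)
  # splitting a region conserves total area
  regions <- matrix(1L, 20, 20); regions[, 11:20] <- 2L
  split <- areaByRegion(map, regions)
  expect_equal(sum(split$area_ha), sum(a$area_ha))
})

test_that("area R^2 is squared Pearson with its degenerate cases", {
  expect_equal(rSquared(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # affine maps leave Pearson correlation untouched
  expect_equal(rSquared(2 * c(1, 2, 3, 4) + 5, c(1, 2, 3, 4)), 1)
  # hand-oracle Pearson on a non-trivial quadruple
  mapped <- c(1, 2, 3, 4); ref <- c(1, 2, 3, 0)
  num <- sum((mapped - mean(mapped)) * (ref - mean(ref)))
  den <- sqrt(sum((mapped - mean(mapped))^2) * sum((ref - mean(ref))^2))
  expect_equal(rSquared(mapped, ref), (num / den)^2, tolerance = 1e-12)
  expect_true(is.na(rSquared(c(1, 1, 1), c(1, 2, 3))))
  expect_error(rSquared(c(1, 2), c(1, 2)), "3 paired")
  # identity-line variant penalizes bias
  expect_equal(agreementR2(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_lt(agreementR2(2 * c(1, 2, 3, 4) + 5, c(1, 2, 3, 4)), 1)
})
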