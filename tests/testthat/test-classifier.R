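test_that("model construction is deterministic and input-checked", {
  cfg <- classifierConfig(seed = 1)
  m1 <- buildClassifier(cfg)
  m2 <- buildClassifier(cfg)
  expect_identical(m1@params, m2@params)
  m3 <- buildClassifier(classifierConfig(seed = 2))
  expect_false(identical(m1@params, m3@params))
  # wrong timestep / band counts are rejected
  expect_error(predictProbabilities(m1, array(0, c(3, 5, 6))), "timesteps")
  expect_error(predictProbabilities(m1, array(0, c(3, 4, 7))), "bands")
})

test_that("forward pass yields normalized probabilities and the closed-form
           parameter count", {
  m <- buildClassifier(classifierConfig(seed = 3))
  set.seed(3)
  X <- array(runif(10 * 4 * 6), c(10, 4, 6))
  P <- predictProbabilities(m, X)
  expect_equal(dim(P), c(10L, 4L))
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-6)
  expect_true(all(P > 0))
  # LSTM: 4H(D + H + 1) per layer; head: dense layers + softmax output
  H <- 128
  expected <- 4 * H * (6 + H + 1) + 2 * (4 * H * (H + H + 1)) +
    (H * 128 + 128) + (128 * 128 + 128) + (128 * 64 + 64) + (64 * 4 + 4)
  expect_identical(nParameters(m), as.integer(expected))
  # features are sigmoid-bounded
  f <- extractFeatures(m, X)
  expect_equal(dim(f), c(10L, 64L))
  expect_true(all(f > 0 & f < 1))
})

test_that("cross-entropy matches closed forms and a brute-force oracle", {
  # certainty on the true class -> zero loss
  q <- diag(4)[c(1, 3), ]
  expect_equal(crossEntropy(q, q), 0, tolerance = 1e-9)
  # uniform prediction over 4 classes -> log 4
  expect_equal(crossEntropy(matrix(0.25, 1, 4), diag(4)[2, , drop = FALSE]),
               log(4), tolerance = 1e-12)
  expect_equal(log(4), 1.386294, tolerance = 1e-6)
  # mean over a batch mixing the two cases above
  p <- rbind(diag(4)[1, ], rep(0.25, 4))
  expect_equal(crossEntropy(p, diag(4)[c(1, 1), ]), log(4) / 2,
               tolerance = 1e-9)
  expect_equal(log(4) / 2, 0.693147, tolerance = 1e-6)
  # brute-force double loop on random batches
  set.seed(11)
  for (i in 1:10) {
    N <- sample(2:10, 1)
    praw <- matrix(runif(N * 4), N)
    p <- praw / rowSums(praw)
    y <- sample(4, N, replace = TRUE)
    q <- diag(4)[y, , drop = FALSE]
    acc <- 0
    for (r in seq_len(N)) for (j in 1:4) acc <- acc - q[r, j] * log(p[r, j])
    expect_equal(crossEntropy(p, q), acc / N, tolerance = 1e-10)
  }
})

test_that("center loss matches closed forms, an oracle, and is
           translation-invariant", {
  centers <- matrix(0, 4, 64)
  f <- matrix(0, 3, 64)
  expect_equal(centerLoss(f, c(1, 2, 3), centers), 0)
  # unit offset in one coordinate -> 1/2
  f1 <- matrix(0, 1, 64); f1[1, 1] <- 1
  expect_equal(centerLoss(f1, 2L, centers), 0.5)
  set.seed(12)
  for (i in 1:10) {
    N <- sample(2:10, 1)
    f <- matrix(rnorm(N * 8), N)
    y <- sample(4, N, replace = TRUE)
    cs <- matrix(rnorm(4 * 8), 4)
    acc <- 0
    for (r in seq_len(N)) acc <- acc + sum((f[r, ] - cs[y[r], ])^2)
    expect_equal(centerLoss(f, y, cs), acc / 2, tolerance = 1e-10)
    shift <- matrix(rnorm(8), N, 8, byrow = TRUE)
    expect_equal(centerLoss(f + shift, y, cs + shift[rep(1, 4), ]),
                 centerLoss(f, y, cs), tolerance = 1e-9)
  }
})

test_that("total loss composes linearly with the center weight", {
  expect_equal(totalLoss(1.0, 2.0, 0), 1.0)
  expect_equal(totalLoss(1.0, 2.0, -0.001), 0.998)
  expect_equal(totalLoss(1.0, 2.0, +0.001), 1.002)
})

test_that("center updates follow the mini-batch rule", {
  cs <- matrix(0, 4, 2)
  f <- matrix(c(1, 0), 1, 2)
  # alpha = 1 with one sample moves the center onto the feature
  expect_equal(updateCenters(cs, f, 2L, alpha = 1)[2, ], c(1, 0))
  # alpha = 0.5 moves halfway
  expect_equal(updateCenters(cs, f, 2L, alpha = 0.5)[2, ], c(0.5, 0))
  # classes absent from the batch stay put
  upd <- updateCenters(cs, f, 2L, alpha = 0.5)
  expect_equal(upd[c(1, 3, 4), ], cs[c(1, 3, 4), ])
  # mean rule over several samples of one class
  f2 <- rbind(c(2, 0), c(0, 2))
  expect_equal(updateCenters(cs, f2, c(1L, 1L), alpha = 0.5)[1, ], c(0.5, 0.5))
  expect_error(updateCenters(cs, f, 2L, alpha = 0), "alpha")
})

test_that("analytic gradients match finite differences on a small model", {
  cfg <- classifierConfig(recurrentLayers = 2, hiddenDim = 5,
                          headDims = c(6, 5, 4), nClasses = 3, seed = 7,
                          centerLossWeight = -0.01)
  m <- buildClassifier(cfg)
  set.seed(42)
  N <- 4
  X <- array(rnorm(N * 4 * 6, 0.3, 0.2), c(N, 4, 6))
  y <- c(1, 2, 3, 1)
  Q <- diag(3)[y, ]
  centers <- matrix(rnorm(3 * 4), 3, 4)
  lossAt <- function(params) {
    fwd <- phenoMaize:::.nnForward(params, cfg, X)
    crossEntropy(fwd$P, Q) +
      cfg$centerLossWeight * centerLoss(fwd$feat, y, centers)
  }
  fwd <- phenoMaize:::.nnForward(m@params, cfg, X, keepCache = TRUE)
  g <- phenoMaize:::.nnBackward(m@params, cfg, fwd, Q,
                                centers[y, , drop = FALSE],
                                cfg$centerLossWeight)
  eps <- 1e-6
  for (nm in names(m@params)) {
    idx <- sample(length(m@params[[nm]]), min(5, length(m@params[[nm]])))
    for (j in idx) {
      pp <- m@params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- m@params; pm[[nm]][j] <- pm[[nm]][j] - eps
      expect_equal(g[[nm]][j], (lossAt(pp) - lossAt(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic, records history, learns separable
           data, and aborts on non-finite loss", {
  toy <- makeSeparableSequences(120, seed = 21)
  cfg <- classifierConfig(recurrentLayers = 1, hiddenDim = 32,
                          headDims = c(32, 32, 16), epochs = 30, seed = 21,
                          centerLossWeight = 0)
  m1 <- trainClassifier(buildClassifier(cfg), toy$X, toy$y)
  h <- trainingHistory(m1)
  expect_equal(nrow(h), 30)
  expect_equal(h$epoch, 1:30)
  expect_true(all(is.finite(h$total)))
  expect_gte(h$trainAcc[30], 0.99)
  expect_lt(h$ce[30], h$ce[1])
  m2 <- trainClassifier(buildClassifier(cfg), toy$X, toy$y)
  expect_identical(trainingHistory(m1)$total, trainingHistory(m2)$total)
  expect_identical(m1@params, m2@params)
  # labels can be class names
  m3 <- trainClassifier(buildClassifier(cfg), toy$X, phenoClasses()[toy$y])
  expect_identical(m3@params, m1@params)
  badX <- toy$X; badX[1, 1, 1] <- NA
  expect_error(trainClassifier(buildClassifier(cfg), badX, toy$y))
})

test_that("binary prediction takes the maize argmax and is invariant to
           monotone score transforms", {
  toy <- makeSeparableSequences(80, seed = 31)
  cfg <- classifierConfig(recurrentLayers = 1, hiddenDim = 12,
                          headDims = c(12, 12, 6), epochs = 12, seed = 31,
                          centerLossWeight = 0)
  m <- trainClassifier(buildClassifier(cfg), toy$X, toy$y)
  # build a composite whose pixels are the toy sequences
  n <- dim(toy$X)[1]
  vals <- array(NA_real_, c(n, 1, 6, 4))
  for (p in 1:4) vals[, 1, , p] <- toy$X[, p, ]
  comp <- new("CompositeFeatures", values = vals,
              valid = array(TRUE, c(n, 1, 4)), periods = defaultPeriods())
  map <- predictBinary(m, comp)
  P <- predictProbabilities(m, toy$X)
  expect_identical(as.vector(map), as.integer(max.col(P) == 1L))
  # argmax equivalence under strictly increasing transforms of the scores
  expect_identical(max.col(P), max.col(log(P)))
  expect_identical(max.col(P), max.col(P^3))
  # invalid pixels propagate as NA
  comp@valid[5, 1, 2] <- FALSE
  expect_true(is.na(predictBinary(m, comp)[5, 1]))
  expect_true(all(predictBinary(m, comp) %in% c(0L, 1L, NA)))
})

test_that("checkpoints round-trip the full classifier state", {
  toy <- makeSeparableSequences(40, seed = 41)
  cfg <- classifierConfig(recurrentLayers = 1, hiddenDim = 8,
                          headDims = c(8, 8, 4), epochs = 3, seed = 41)
  m <- trainClassifier(buildClassifier(cfg), toy$X, toy$y)
  f <- tempfile(fileext = ".rds")
  saveClassifier(m, f)
  m2 <- loadClassifier(f)
  expect_identical(m2@params, m@params)
  expect_identical(m2@centers, m@centers)
  expect_identical(trainingHistory(m2), trainingHistory(m))
  expect_equal(predictProbabilities(m2, toy$X), predictProbabilities(m, toy$X))
  saveRDS(list(format = "something-else"), f)
  expect_error(loadClassifier(f), "checkpoint")
})

test_that("an attractive center loss with appreciable weight compacts
           held-out class features at convergence", {
  # the mechanism check runs at w = 0.01, where the compaction force is
  # well above run-to-run trajectory noise; the package-default magnitude
  # 0.001 perturbs training by less than that noise (see the methods
  # vignette)
  runC <- function(seed, w) {
    sc <- simScenario(gridShape = c(48L, 48L), cloudProb = 0.05, seed = seed)
    sim <- simulateSceneStack(sc, defaultProfiles(seed))
    st <- replaceCloudyBands(dropCloudyScenes(sim$stack))
    comp <- maxValueComposite(st)
    samples <- simulateSamples(sim, sc, nPerClass = 60)
    fl <- flattenFeatures(comp)
    idx <- (samples$col - 1L) * 48L + samples$row
    X <- unflattenFeatures(fl[idx, , drop = FALSE])
    y <- samples$class
    tr <- samples$split == "train"
    cfg <- classifierConfig(recurrentLayers = 3, hiddenDim = 32,
                            headDims = c(32, 32, 16), epochs = 200,
                            seed = seed, centerLossWeight = w,
                            swaFrom = 1, lrDecay = 1)
    m <- trainClassifier(buildClassifier(cfg), X[tr, , , drop = FALSE],
                         y[tr])
    f <- extractFeatures(m, X[!tr, , , drop = FALSE])
    meanIntraclassDistance(f, y[!tr])
  }
  reduced <- 0
  for (s in 1:3)
    if (runC(s, 0.01) <= runC(s, 0)) reduced <- reduced + 1
  expect_gte(reduced, 2)
})
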