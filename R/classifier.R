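#' Classifier hyperparameter configuration
#'
#' Collects the hyperparameters of the recurrent maize classifier. Defaults
#' follow the published configuration: a 3-layer LSTM with 128-dimensional
#' hidden states, a three-layer fully connected head (128, 128, 64 nodes;
#' tanh on the first two layers, linear features into a softmax output),
#' Adam at learning rate 0.001, batch size 20, 250 training epochs
#' (convergence is typically reached around 200), and a center-loss weight
#' of -0.001.
#'
#' @param recurrentLayers number of stacked LSTM layers.
#' @param hiddenDim LSTM hidden state size.
#' @param headDims output sizes of the three fully connected layers; the
#'   last is the feature dimension used by the center loss.
#' @param nClasses number of training classes.
#' @param learningRate initial Adam step size.
#' @param lrDecay per-epoch multiplicative decay of the learning rate
#'   (1 = constant). The published value is an *initial* rate; the default
#'   0.98 applies a mild exponential schedule, which improves held-out
#'   accuracy at small training-set sizes.
#' @param batchSize mini-batch size.
#' @param epochs number of passes over the training set.
#' @param centerLossWeight weight `w` of the center loss in
#'   `L = Lce + w * Lc`. The published value is -0.001; note that a negative
#'   weight rewards (rather than penalizes) intraclass spread, so `+0.001`
#'   is the recommended setting when compact class clusters are the goal.
#'   Both signs are supported.
#' @param centerUpdateRate step size `alpha` in (0, 1] of the per-batch
#'   class-center update.
#' @param outputActivation `"softmax"` (default; proper multiclass
#'   probabilities, required by the cross-entropy loss) or `"sigmoid"`
#'   (independent per-class scores).
#' @param whiten input normalization mode: `"feature"` (default)
#'   standardizes each of the 24 features independently; `"period"`
#'   additionally decorrelates the six bands within each period with a
#'   train-set inverse-square-root covariance transform; `"none"` feeds
#'   raw reflectance.
#' @param swaFrom fraction of training after which parameters are averaged
#'   into a tail (Polyak) average used as the final model (default 0.5:
#'   average the second half); 1 disables averaging. Averaging the
#'   low-learning-rate tail is a standard generalization aid that leaves
#'   loss and architecture untouched.
#' @param initScale multiplier on the LSTM weight initialization scale
#'   (`initScale / sqrt(hiddenDim)` uniform bounds). The default 3 keeps
#'   the top-layer state responsive through three stacked layers over a
#'   short 4-step sequence; 1 reproduces the common framework default.
#' @param standardize if `TRUE` (default), training estimates a per-
#'   (period, band) mean and standard deviation on the training set, stores
#'   them in the model and applies them to every input; reflectance
#'   contrasts between crop classes are small fractions of the [0, 1]
#'   range, and whitening them is what makes the printed learning rate and
#'   batch size converge at small sample sizes.
#' @param inputDim number of spectral bands per timestep.
#' @param nTimesteps number of periods in the input sequence.
#' @param seed integer seed for parameter initialization and batch order.
#' @return Named list of validated hyperparameters.
#' @export
#' @examples
#' cfg <- classifierConfig(epochs = 50, seed = 1)
classifierConfig <- function(recurrentLayers = 3L, hiddenDim = 128L,
                             headDims = c(128L, 128L, 64L), nClasses = 4L,
                             learningRate = 0.001, lrDecay = 0.98,
                             batchSize = 20L,
                             epochs = 250L, centerLossWeight = -0.001,
                             centerUpdateRate = 0.5,
                             outputActivation = c("softmax", "sigmoid"),
                             initScale = 3, standardize = TRUE,
                             whiten = c("feature", "period", "none"),
                             swaFrom = 0.5,
                             inputDim = 6L, nTimesteps = 4L, seed = 0L) {
  whiten <- match.arg(whiten)
  outputActivation <- match.arg(outputActivation)
  cfg <- list(recurrentLayers = as.integer(recurrentLayers),
              hiddenDim = as.integer(hiddenDim),
              headDims = as.integer(headDims), nClasses = as.integer(nClasses),
              learningRate = learningRate, lrDecay = lrDecay,
              batchSize = as.integer(batchSize),
              epochs = as.integer(epochs),
              centerLossWeight = centerLossWeight,
              centerUpdateRate = centerUpdateRate,
              outputActivation = outputActivation,
              initScale = initScale, standardize = isTRUE(standardize),
              whiten = whiten, swaFrom = swaFrom,
              inputDim = as.integer(inputDim),
              nTimesteps = as.integer(nTimesteps), seed = as.integer(seed))
  stopifnot(cfg$recurrentLayers >= 1, cfg$hiddenDim >= 1,
            length(cfg$headDims) == 3, all(cfg$headDims >= 1),
            cfg$nClasses >= 2, cfg$learningRate > 0, cfg$lrDecay > 0,
            cfg$lrDecay <= 1, cfg$batchSize >= 1,
            cfg$epochs >= 1, abs(cfg$centerLossWeight) <= 1,
            cfg$centerUpdateRate > 0, cfg$centerUpdateRate <= 1,
            cfg$initScale > 0, cfg$swaFrom > 0, cfg$swaFrom <= 1)
  cfg
}

#' Build an untrained classifier
#'
#' Initializes all LSTM and head parameters deterministically from the
#' config seed and zero-initializes the class centers.
#'
#' @param config output of [classifierConfig()].
#' @return An untrained [MaizeClassifier-class].
#' @export
#' @examples
#' m <- buildClassifier(classifierConfig(seed = 1))
#' nParameters(m)
buildClassifier <- function(config = classifierConfig()) {
  params <- withSeed(childSeed(config$seed, 404L), .initParams(config))
  new("MaizeClassifier", config = config, params = params,
      centers = matrix(0, config$nClasses, config$headDims[3]),
      optState = .adamInit(params), norm = list(),
      history = data.frame(epoch = integer(), ce = numeric(),
                           center = numeric(), total = numeric(),
                           trainAcc = numeric()),
      trained = FALSE)
}

# Apply the model's stored input normalization, if any: per-feature
# z-scoring, optionally followed by a per-period decorrelating transform.
.applyNorm <- function(model, X) {
  nrm <- model@norm
  if (!length(nrm)) return(X)
  for (p in seq_len(dim(X)[2])) {
    for (b in seq_len(dim(X)[3]))
      X[, p, b] <- (X[, p, b] - nrm$mean[p, b]) / nrm$sd[p, b]
    if (!is.null(nrm$trans))
      X[, p, ] <- X[, p, , drop = FALSE][, 1, ] %*% nrm$trans[[p]]
  }
  X
}

# Symmetric inverse square root of a covariance matrix (ridge-stabilized).
.invSqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 1e-8)
  e$vectors %*% diag(1 / sqrt(v)) %*% t(e$vectors)
}

.checkInput <- function(model, X) {
  cfg <- model@config
  if (length(dim(X)) != 3 || dim(X)[2] != cfg$nTimesteps ||
      dim(X)[3] != cfg$inputDim)
    stop(sprintf("input must be [n, %d, %d] (timesteps x bands), got [%s]",
                 cfg$nTimesteps, cfg$inputDim,
                 paste(dim(X), collapse = ", ")))
}

#' Class probabilities for a batch of feature sequences
#'
#' @param model a [MaizeClassifier-class].
#' @param X numeric array `[n, nTimesteps, inputDim]` of composite feature
#'   sequences (see [unflattenFeatures()]).
#' @return Matrix `[n, nClasses]` of class probabilities (softmax rows sum
#'   to 1).
#' @export
predictProbabilities <- function(model, X) {
  .checkInput(model, X)
  .nnForward(model@params, model@config, .applyNorm(model, X))$P
}

#' Deep features (head output) for a batch of sequences
#'
#' Returns the feature vectors entering the classification layer, the `f`
#' vectors referenced by the center loss; useful for inspecting class
#' compactness.
#'
#' @inheritParams predictProbabilities
#' @return Matrix `[n, featureDim]`.
#' @export
extractFeatures <- function(model, X) {
  .checkInput(model, X)
  .nnForward(model@params, model@config, .applyNorm(model, X))$feat
}

#' Cross-entropy loss
#'
#' Mean over samples of the negative log-probability assigned to the true
#' class: `Lce = -(1/N) sum_i sum_j q_ij log p_ij` with `q` one-hot.
#' Probabilities are clipped to `[1e-12, 1 - 1e-12]` before the logarithm.
#'
#' @param p numeric matrix `[N, C]` of predicted class probabilities.
#' @param q numeric matrix `[N, C]` of one-hot labels.
#' @return Scalar loss.
#' @export
#' @examples
#' crossEntropy(matrix(0.25, 1, 4), matrix(c(1, 0, 0, 0), 1))  # log(4)
crossEntropy <- function(p, q) {
  stopifnot(identical(dim(p), dim(q)))
  eps <- 1e-12
  pc <- pmin(pmax(p, eps), 1 - eps)
  -sum(q * log(pc)) / nrow(p)
}

#' Center loss
#'
#' Half the summed squared Euclidean distance between each sample's feature
#' vector and its own class center:
#' `Lc = 0.5 * sum_i || f_i - c_{y_i} ||^2`.
#'
#' @param features numeric matrix `[N, featureDim]`.
#' @param labels integer class indices (1-based) of length N.
#' @param centers numeric matrix `[nClasses, featureDim]`.
#' @return Scalar loss.
#' @export
centerLoss <- function(features, labels, centers) {
  stopifnot(nrow(features) == length(labels),
            ncol(features) == ncol(centers))
  0.5 * sum((features - centers[labels, , drop = FALSE])^2)
}

#' Total training loss
#'
#' `L = Lce + w * Lc`.
#'
#' @param lce cross-entropy loss.
#' @param lc center loss.
#' @param w center-loss weight.
#' @return Scalar.
#' @export
totalLoss <- function(lce, lc, w) lce + w * lc

#' Update class centers from a batch
#'
#' Standard mini-batch center update: for every class `j` present in the
#' batch, `c_j <- c_j - alpha * mean_i (c_j - f_i)` over that class's batch
#' samples; classes absent from the batch are unchanged.
#'
#' @param centers numeric matrix `[nClasses, featureDim]`.
#' @param features numeric matrix `[N, featureDim]`.
#' @param labels integer class indices (1-based) of length N.
#' @param alpha update rate in (0, 1].
#' @return Updated centers matrix.
#' @export
updateCenters <- function(centers, features, labels, alpha = 0.5) {
  stopifnot(nrow(features) == length(labels), alpha > 0, alpha <= 1)
  for (j in unique(labels)) {
    idx <- which(labels == j)
    delta <- centers[j, ] - colMeans(features[idx, , drop = FALSE])
    centers[j, ] <- centers[j, ] - alpha * delta
  }
  centers
}

#' Train the classifier
#'
#' Mini-batch training with Adam on `L = Lce + w * Lc`. The center-loss
#' gradient with respect to the features flows through the network; the
#' centers themselves are moved by the explicit [updateCenters()] rule after
#' every gradient step, not by the optimizer. Batch order is reshuffled
#' every epoch from the config seed, so training is deterministic
#' (single-threaded) given the configuration.
#'
#' @param model an untrained (or partially trained) [MaizeClassifier-class].
#' @param X numeric array `[n, nTimesteps, inputDim]` of training sequences.
#' @param labels class labels: either integer indices 1..nClasses or a
#'   character vector of [phenoClasses()] names.
#' @return The trained [MaizeClassifier-class] with its per-epoch history
#'   (columns epoch, ce, center, total, trainAcc).
#' @export
trainClassifier <- function(model, X, labels) {
  .checkInput(model, X)
  cfg <- model@config
  if (is.character(labels) || is.factor(labels))
    labels <- match(as.character(labels), phenoClasses())
  labels <- as.integer(labels)
  stopifnot(all(labels >= 1), all(labels <= cfg$nClasses),
            length(labels) == dim(X)[1], !anyNA(X))
  n <- dim(X)[1]
  norm <- model@norm
  if (cfg$standardize && cfg$whiten != "none" && !length(norm)) {
    sdArr <- apply(X, c(2, 3), stats::sd)
    sdArr[!is.finite(sdArr) | sdArr == 0] <- 1
    norm <- list(mean = apply(X, c(2, 3), mean), sd = sdArr)
    if (cfg$whiten == "period") {
      Z <- X
      for (p in seq_len(dim(X)[2]))
        for (b in seq_len(dim(X)[3]))
          Z[, p, b] <- (X[, p, b] - norm$mean[p, b]) / norm$sd[p, b]
      norm$trans <- lapply(seq_len(dim(X)[2]), function(p)
        .invSqrt(stats::cov(Z[, p, , drop = FALSE][, 1, ])))
    }
  }
  if (length(norm)) {
    fake <- new("MaizeClassifier", config = cfg, params = model@params,
                centers = model@centers, optState = model@optState,
                norm = norm, history = model@history,
                trained = model@trained)
    X <- .applyNorm(fake, X)
  }
  params <- model@params
  centers <- model@centers
  state <- model@optState
  w <- cfg$centerLossWeight
  Qall <- diag(cfg$nClasses)[labels, , drop = FALSE]
  hist <- vector("list", cfg$epochs)
  swaStart <- if (cfg$swaFrom >= 1) Inf else
    max(1L, ceiling(cfg$swaFrom * cfg$epochs) + 1L)
  swaSum <- NULL; swaN <- 0L
  withSeed(childSeed(cfg$seed, 505L), {
    for (ep in seq_len(cfg$epochs)) {
      lrEp <- cfg$learningRate * cfg$lrDecay^(ep - 1)
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batchSize)
      ceSum <- 0; lcSum <- 0; correct <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batchSize - 1, n)]
        Xb <- X[idx, , , drop = FALSE]
        yb <- labels[idx]
        Qb <- Qall[idx, , drop = FALSE]
        fwd <- .nnForward(params, cfg, Xb, keepCache = TRUE)
        lce <- crossEntropy(fwd$P, Qb)
        lc <- centerLoss(fwd$feat, yb, centers)
        if (!is.finite(lce) || !is.finite(lc))
          stop(sprintf("non-finite loss at epoch %d (ce=%g, center=%g)",
                       ep, lce, lc))
        grads <- .nnBackward(params, cfg, fwd, Qb,
                             centers[yb, , drop = FALSE], w)
        upd <- .adamStep(params, grads, state, lrEp)
        params <- upd$params
        state <- upd$state
        centers <- updateCenters(centers, fwd$feat, yb,
                                 cfg$centerUpdateRate)
        ceSum <- ceSum + lce * length(idx)
        lcSum <- lcSum + lc
        correct <- correct + sum(max.col(fwd$P) == yb)
      }
      hist[[ep]] <- data.frame(epoch = ep, ce = ceSum / n, center = lcSum,
                               total = ceSum / n + w * lcSum,
                               trainAcc = correct / n)
      if (ep >= swaStart) {
        if (is.null(swaSum)) swaSum <- lapply(params, function(p) p * 0)
        for (nm in names(params))
          swaSum[[nm]] <- swaSum[[nm]] + params[[nm]]
        swaN <- swaN + 1L
      }
    }
    if (swaN > 0L)
      params <- lapply(swaSum, function(p) p / swaN)
  })
  new("MaizeClassifier", config = cfg, params = params, centers = centers,
      optState = state, norm = norm, history = do.call(rbind, hist),
      trained = TRUE)
}

#' Predict a binary maize map from composite features
#'
#' Runs the 4-class model over every pixel with four valid composite periods
#' and binarizes the argmax: maize becomes 1, the other three classes 0.
#' Pixels with an invalid period become `NA` (nodata).
#'
#' @param model a trained [MaizeClassifier-class].
#' @param composite a [CompositeFeatures-class].
#' @param chunkSize pixels per forward-pass chunk (memory control).
#' @return Integer matrix of the grid shape with values 1, 0 or `NA`.
#' @export
predictBinary <- function(model, composite, chunkSize = 2048L) {
  flat <- flattenFeatures(composite)
  d <- gridDim(composite)
  out <- rep(NA_integer_, nrow(flat))
  okIdx <- which(!is.na(flat[, 1]))
  maize <- match("maize", phenoClasses())
  for (s in seq(1, length(okIdx), by = chunkSize)) {
    idx <- okIdx[s:min(s + chunkSize - 1, length(okIdx))]
    Xc <- unflattenFeatures(flat[idx, , drop = FALSE])
    P <- predictProbabilities(model, Xc)
    out[idx] <- as.integer(max.col(P) == maize)
  }
  matrix(out, d[1], d[2])
}

#' Save / load a classifier checkpoint
#'
#' Serializes the full classifier state (config header, parameters, centers,
#' optimizer state, history) to a single file.
#'
#' @param model a [MaizeClassifier-class].
#' @param path checkpoint file path.
#' @return `saveClassifier` returns `path` invisibly; `loadClassifier`
#'   returns the restored [MaizeClassifier-class].
#' @export
saveClassifier <- function(model, path) {
  saveRDS(list(format = "phenoMaize-checkpoint-v1", config = model@config,
               params = model@params, centers = model@centers,
               optState = model@optState, norm = model@norm,
               history = model@history, trained = model@trained), path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "phenoMaize-checkpoint-v1"))
    stop("not a phenoMaize checkpoint: ", path)
  new("MaizeClassifier", config = x$config, params = x$params,
      centers = x$centers, optState = x$optState,
      norm = if (is.null(x$norm)) list() else x$norm,
      history = x$history, trained = x$trained)
}
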