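# Native implementation of the recurrent classifier: a stacked LSTM over the
# 4-period x 6-band sequence, a fully connected head (tanh, tanh, sigmoid)
# producing a bounded feature vector, and a linear classification layer.
# Bounded (sigmoid) features keep the center-loss term well behaved for
# either sign of its weight. Forward, full
# backpropagation through time, and Adam are written against base matrix
# ops; batches are rows. Gate order inside the packed weight matrices is
# i (input), f (forget), g (cell candidate), o (output).

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Slice a [N, T, K] array at time t as an [N, K] matrix (safe for N = 1).
.sl <- function(a, t) {
  m <- a[, t, , drop = FALSE]
  dim(m) <- dim(a)[c(1, 3)]
  m
}

.uniformMat <- function(nr, nc, k) matrix(runif(nr * nc, -k, k), nr, nc)

# Parameter initialization: uniform(-1/sqrt(fanIn), 1/sqrt(fanIn)) for the
# dense head (the convention most frameworks default to); see below for the
# LSTM scale.
.initParams <- function(cfg) {
  H <- cfg$hiddenDim
  k <- 1 / sqrt(H)
  # LSTM weight matrices get an enlarged scale (initScale/sqrt(H)): with
  # only four timesteps the risk is signal attenuation through the stacked
  # layers, not exploding recurrence, and the default uniform scale leaves
  # the top-layer state nearly constant across inputs.
  kw <- cfg$initScale / sqrt(H)
  p <- list()
  dIn <- cfg$inputDim
  for (l in seq_len(cfg$recurrentLayers)) {
    p[[paste0("Wx", l)]] <- .uniformMat(dIn, 4 * H, kw)
    p[[paste0("Wh", l)]] <- .uniformMat(H, 4 * H, kw)
    p[[paste0("b", l)]] <- runif(4 * H, -k, k)
    dIn <- H
  }
  dims <- c(H, cfg$headDims)
  for (j in 1:3) {
    kj <- 1 / sqrt(dims[j])
    p[[paste0("Wf", j)]] <- .uniformMat(dims[j], dims[j + 1], kj)
    p[[paste0("bf", j)]] <- runif(dims[j + 1], -kj, kj)
  }
  ko <- 1 / sqrt(dims[4])
  p$Wo <- .uniformMat(dims[4], cfg$nClasses, ko)
  p$bo <- runif(cfg$nClasses, -ko, ko)
  p
}

# Forward pass. X: [N, T, inputDim]. Returns class probabilities P
# [N, C], features F [N, featureDim] and (optionally) the caches needed for
# backpropagation.
.nnForward <- function(params, cfg, X, keepCache = FALSE) {
  N <- dim(X)[1]; T <- dim(X)[2]; H <- cfg$hiddenDim
  L <- cfg$recurrentLayers
  caches <- if (keepCache) vector("list", L) else NULL
  inp <- X
  for (l in seq_len(L)) {
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    b <- params[[paste0("b", l)]]
    h <- matrix(0, N, H); c <- matrix(0, N, H)
    Hs <- array(0, c(N, T, H))
    if (keepCache) {
      gi <- array(0, c(N, T, H)); gf <- gi; gg <- gi; go <- gi
      cs <- gi; tc <- gi
    }
    for (t in seq_len(T)) {
      G <- .sl(inp, t) %*% Wx + h %*% Wh + matrix(b, N, 4 * H, byrow = TRUE)
      i <- .sigmoid(G[, 1:H, drop = FALSE])
      f <- .sigmoid(G[, H + 1:H, drop = FALSE])
      g <- tanh(G[, 2 * H + 1:H, drop = FALSE])
      o <- .sigmoid(G[, 3 * H + 1:H, drop = FALSE])
      c <- f * c + i * g
      tct <- tanh(c)
      h <- o * tct
      Hs[, t, ] <- h
      if (keepCache) {
        gi[, t, ] <- i; gf[, t, ] <- f; gg[, t, ] <- g; go[, t, ] <- o
        cs[, t, ] <- c; tc[, t, ] <- tct
      }
    }
    if (keepCache)
      caches[[l]] <- list(inp = inp, i = gi, f = gf, g = gg, o = go,
                          c = cs, tanhc = tc, h = Hs)
    inp <- Hs
  }
  hTop <- .sl(inp, T)
  a1 <- tanh(hTop %*% params$Wf1 +
               matrix(params$bf1, N, length(params$bf1), byrow = TRUE))
  a2 <- tanh(a1 %*% params$Wf2 +
               matrix(params$bf2, N, length(params$bf2), byrow = TRUE))
  feat <- .sigmoid(a2 %*% params$Wf3 +
                     matrix(params$bf3, N, length(params$bf3), byrow = TRUE))
  z <- feat %*% params$Wo +
    matrix(params$bo, N, cfg$nClasses, byrow = TRUE)
  if (cfg$outputActivation == "softmax") {
    zs <- z - apply(z, 1, max)
    ez <- exp(zs)
    P <- ez / rowSums(ez)
  } else {                              # independent per-class sigmoid
    P <- .sigmoid(z)
  }
  out <- list(P = P, feat = feat)
  if (keepCache)
    out$cache <- list(caches = caches, hTop = hTop, a1 = a1, a2 = a2,
                      z = z, X = X)
  out
}

# Backward pass for loss L = Lce + wCenter * Lc, where Lce is the mean
# negative log-probability of the true class and Lc = 0.5 * sum_i
# ||f_i - c_{y_i}||^2. Q: one-hot [N, C]; centersY: [N, featureDim] rows of
# the true-class centers. Returns gradients named like the parameters.
.nnBackward <- function(params, cfg, fwd, Q, centersY, wCenter) {
  cache <- fwd$cache
  N <- nrow(Q); H <- cfg$hiddenDim; L <- cfg$recurrentLayers
  T <- dim(cache$X)[2]
  g <- list()
  if (cfg$outputActivation == "softmax") {
    dz <- (fwd$P - Q) / N
  } else {
    # d/dz of -(1/N) sum q log sigmoid(z): only true-class entries
    dz <- -(Q * (1 - fwd$P)) / N
  }
  g$Wo <- crossprod(fwd$feat, dz)
  g$bo <- colSums(dz)
  dfeat <- dz %*% t(params$Wo)
  if (wCenter != 0) dfeat <- dfeat + wCenter * (fwd$feat - centersY)
  dz3 <- dfeat * fwd$feat * (1 - fwd$feat)
  g$Wf3 <- crossprod(cache$a2, dz3)
  g$bf3 <- colSums(dz3)
  da2 <- dz3 %*% t(params$Wf3)
  dz2 <- da2 * (1 - cache$a2^2)
  g$Wf2 <- crossprod(cache$a1, dz2)
  g$bf2 <- colSums(dz2)
  da1 <- dz2 %*% t(params$Wf2)
  dz1 <- da1 * (1 - cache$a1^2)
  g$Wf1 <- crossprod(cache$hTop, dz1)
  g$bf1 <- colSums(dz1)
  dhTop <- dz1 %*% t(params$Wf1)

  # gradient flowing into each LSTM layer's output sequence
  dOut <- array(0, c(N, T, H))
  dOut[, T, ] <- dhTop
  for (l in rev(seq_len(L))) {
    ch <- cache$caches[[l]]
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    dWx <- matrix(0, nrow(Wx), ncol(Wx))
    dWh <- matrix(0, H, 4 * H)
    db <- numeric(4 * H)
    dInp <- array(0, dim(ch$inp))
    dhNext <- matrix(0, N, H)
    dcNext <- matrix(0, N, H)
    for (t in rev(seq_len(T))) {
      dh <- .sl(dOut, t) + dhNext
      i <- .sl(ch$i, t); f <- .sl(ch$f, t); gg <- .sl(ch$g, t)
      o <- .sl(ch$o, t); tct <- .sl(ch$tanhc, t)
      dc <- dcNext + dh * o * (1 - tct^2)
      cPrev <- if (t > 1) .sl(ch$c, t - 1) else matrix(0, N, H)
      hPrev <- if (t > 1) .sl(ch$h, t - 1) else matrix(0, N, H)
      di <- dc * gg; df <- dc * cPrev; dg <- dc * i; do_ <- dh * tct
      dG <- cbind(di * i * (1 - i), df * f * (1 - f),
                  dg * (1 - gg^2), do_ * o * (1 - o))
      dWx <- dWx + crossprod(.sl(ch$inp, t), dG)
      dWh <- dWh + crossprod(hPrev, dG)
      db <- db + colSums(dG)
      dInp[, t, ] <- dG %*% t(Wx)
      dhNext <- dG %*% t(Wh)
      dcNext <- dc * f
    }
    g[[paste0("Wx", l)]] <- dWx
    g[[paste0("Wh", l)]] <- dWh
    g[[paste0("b", l)]] <- db
    dOut <- dInp
  }
  g
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
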