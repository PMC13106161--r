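## Hybrid Transformer-GCN action classifier.
##
## Architecture: each 2-s window (T x D) is cut into `subFrames`
## sub-frames; per sub-frame and placement node, fixed summary statistics
## (mean, sd, RMS of the first difference per channel) form the node
## features. Node features are embedded (per-node linear map), mixed by
## graph-convolution layers over the normalised self-looped placement
## adjacency, concatenated into one token per sub-frame, projected to the
## model width and tagged with sinusoidal positional encoding. A
## post-norm Transformer encoder (multi-head self-attention + two-layer
## feed-forward, residual connections, layer normalisation) processes the
## token sequence; mean pooling and a linear softmax head give class
## probabilities. Forward and backward passes are written out explicitly
## (no autodiff framework is available in R here) and the backward pass
## is verified against numerical gradients in the test suite.

#' Default Transformer-GCN configuration
#'
#' The test-scale default uses model width 64 with 4 attention heads; the
#' full-scale configuration (width 512, 8 heads) is available by
#' argument.
#'
#' @param dModel token width (must be divisible by \code{nHeads})
#' @param nHeads attention heads
#' @param nLayers encoder layers
#' @param dff feed-forward inner width
#' @param dGcn per-node embedding width for the graph block
#' @param nGcnLayers graph-convolution layers
#' @param subFrames tokens per window
#' @param seed weight-initialisation seed
#' @return a named list
#' @export
harConfig <- function(dModel = 64, nHeads = 4, nLayers = 1, dff = 128,
                      dGcn = 16, nGcnLayers = 1, subFrames = 8,
                      seed = 1) {
  .stopIfNot(dModel %% nHeads == 0, "dModel must be divisible by nHeads")
  list(dModel = dModel, nHeads = nHeads, nLayers = nLayers, dff = dff,
       dGcn = dGcn, nGcnLayers = nGcnLayers, subFrames = subFrames,
       seed = seed)
}

## ---- fixed feature extraction: window -> per-node sub-frame stats ----

.nodeChannelMap <- function(channels, nodes) {
  map <- lapply(nodes, function(nd)
    grep(paste0("^", nd, "_"), channels))
  names(map) <- nodes
  rest <- setdiff(seq_along(channels), unlist(map))
  home <- if ("chest" %in% nodes) "chest" else nodes[1]
  map[[home]] <- sort(c(map[[home]], rest))
  map
}

## returns list per node: (B*subFrames) x (3*#chan) feature matrix;
## token row order groups by window: ((b-1)*S + s)
.windowNodeFeatures <- function(fw, nodes, subFrames) {
  arr <- windowArray(fw)
  Tn <- dim(arr)[1]; B <- dim(arr)[3]
  S <- subFrames
  cuts <- floor(seq(0, Tn, length.out = S + 1))
  map <- .nodeChannelMap(channelNames(fw), nodes)
  out <- vector("list", length(nodes)); names(out) <- nodes
  for (nd in nodes) {
    ch <- map[[nd]]
    F <- matrix(0, B * S, 3 * length(ch))
    for (s in seq_len(S)) {
      seg <- arr[(cuts[s] + 1):cuts[s + 1], ch, , drop = FALSE]
      mu <- apply(seg, c(2, 3), mean)                 # ch x B
      sg <- apply(seg, c(2, 3), sd)
      dr <- apply(seg, c(2, 3), function(v) .rms(diff(v)))
      rows <- (seq_len(B) - 1) * S + s
      F[rows, ] <- t(rbind(mu, sg, dr))
    }
    out[[nd]] <- F
  }
  out
}

.posEncoding <- function(S, d) {
  pe <- matrix(0, S, d)
  pos <- seq_len(S) - 1
  for (i in seq_len(d)) {
    k <- (i - 1) %/% 2
    w <- 1 / 10000^(2 * k / d)
    pe[, i] <- if (i %% 2 == 1) sin(pos * w) else cos(pos * w)
  }
  pe
}

## ---- parameter initialisation / flattening --------------------------

.initHarParams <- function(config, nodeDims, nClasses) {
  .withSeed(config$seed, {
    gl <- function(nin, nout)
      matrix(rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
    d <- config$dModel
    p <- list()
    p$emb <- lapply(nodeDims, function(nd)
      list(W = gl(nd, config$dGcn), b = rep(0, config$dGcn)))
    p$gcn <- lapply(seq_len(config$nGcnLayers), function(i)
      gl(config$dGcn, config$dGcn))
    p$tok <- list(W = gl(length(nodeDims) * config$dGcn, d),
                  b = rep(0, d))
    p$layers <- lapply(seq_len(config$nLayers), function(l) list(
      Wq = gl(d, d), Wk = gl(d, d), Wv = gl(d, d), Wo = gl(d, d),
      g1 = rep(1, d), be1 = rep(0, d),
      W1 = gl(d, config$dff), b1 = rep(0, config$dff),
      W2 = gl(config$dff, d), b2 = rep(0, d),
      g2 = rep(1, d), be2 = rep(0, d)))
    p$head <- list(W = gl(d, nClasses), b = rep(0, nClasses))
    p
  })
}

## flatten a nested list of numerics into one vector (stable order)
.flattenParams <- function(p) {
  unlist(p, use.names = FALSE)
}

.unflattenParams <- function(template, v) {
  rel <- utils::relist(v, template)
  rel
}

## ---- layer normalisation --------------------------------------------

.lnForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

.lnBackward <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

## ---- multi-head self-attention --------------------------------------

.mhaForward <- function(X, lp, B, S, nHeads) {
  d <- ncol(X); dk <- d %/% nHeads
  Q <- X %*% lp$Wq; K <- X %*% lp$Wk; V <- X %*% lp$Wv
  O <- matrix(0, nrow(X), d)
  Acache <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * S + 1):(b * S)
    Ab <- vector("list", nHeads)
    for (h in seq_len(nHeads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      sc <- (Q[rows, cols, drop = FALSE] %*%
               t(K[rows, cols, drop = FALSE])) / sqrt(dk)
      sc <- sc - apply(sc, 1, max)
      A <- exp(sc); A <- A / rowSums(A)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      Ab[[h]] <- A
    }
    Acache[[b]] <- Ab
  }
  list(out = O %*% lp$Wo, Q = Q, K = K, V = V, O = O, A = Acache)
}

.mhaBackward <- function(dOut, cache, X, lp, B, S, nHeads) {
  d <- ncol(X); dk <- d %/% nHeads
  dWo <- t(cache$O) %*% dOut
  dO <- dOut %*% t(lp$Wo)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1) * S + 1):(b * S)
    for (h in seq_len(nHeads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      A <- cache$A[[b]][[h]]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dV[rows, cols] <- dV[rows, cols] + t(A) %*% dOb
      dA <- dOb %*% t(Vb)
      dS <- A * (dA - rowSums(dA * A))       # row-softmax jacobian
      dS <- dS / sqrt(dk)
      dQ[rows, cols] <- dQ[rows, cols] +
        dS %*% cache$K[rows, cols, drop = FALSE]
      dK[rows, cols] <- dK[rows, cols] +
        t(dS) %*% cache$Q[rows, cols, drop = FALSE]
    }
  }
  list(dX = dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv),
       dWq = t(X) %*% dQ, dWk = t(X) %*% dK, dWv = t(X) %*% dV,
       dWo = dWo)
}

## ---- full forward pass ----------------------------------------------

.harForward <- function(p, feats, Ahat, config, B) {
  S <- config$subFrames
  nodes <- names(feats)
  cache <- list()
  ## per-node embedding
  E <- lapply(nodes, function(nd)
    feats[[nd]] %*% p$emb[[nd]]$W +
      rep(p$emb[[nd]]$b, each = nrow(feats[[nd]])))
  names(E) <- nodes
  cache$E <- E
  ## GCN layers with shared W: G_i = relu(sum_j Ahat[i,j] (H_j W))
  H <- E
  cache$gcn <- vector("list", length(p$gcn))
  for (l in seq_along(p$gcn)) {
    P <- lapply(H, function(h) h %*% p$gcn[[l]])
    Z <- lapply(seq_along(nodes), function(i) {
      z <- 0
      for (j in seq_along(nodes)) z <- z + Ahat[i, j] * P[[j]]
      z
    })
    names(Z) <- nodes
    G <- lapply(Z, function(z) pmax(z, 0))
    cache$gcn[[l]] <- list(Hin = H, Z = Z)
    H <- G
  }
  cache$Hout <- H
  ## tokens
  Xc <- do.call(cbind, H)
  cache$Xc <- Xc
  X <- Xc %*% p$tok$W + rep(p$tok$b, each = nrow(Xc))
  pe <- .posEncoding(S, config$dModel)
  X <- X + pe[rep(seq_len(S), B), ]
  ## encoder layers
  cache$layers <- vector("list", length(p$layers))
  for (l in seq_along(p$layers)) {
    lp <- p$layers[[l]]
    mha <- .mhaForward(X, lp, B, S, config$nHeads)
    ln1 <- .lnForward(X + mha$out, lp$g1, lp$be1)
    X1 <- ln1$out
    Fpre <- X1 %*% lp$W1 + rep(lp$b1, each = nrow(X1))
    Fact <- pmax(Fpre, 0)
    Fout <- Fact %*% lp$W2 + rep(lp$b2, each = nrow(X1))
    ln2 <- .lnForward(X1 + Fout, lp$g2, lp$be2)
    cache$layers[[l]] <- list(Xin = X, mha = mha, ln1 = ln1, X1 = X1,
                              Fpre = Fpre, Fact = Fact, ln2 = ln2)
    X <- ln2$out
  }
  ## mean pool over sub-frames
  grp <- rep(seq_len(B), each = S)
  pool <- rowsum(X, grp) / S
  logits <- pool %*% p$head$W + rep(p$head$b, each = B)
  cache$Xfinal <- X; cache$pool <- pool
  list(logits = logits, cache = cache)
}

.softmaxRows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

## full backward pass; y: integer class index per window
.harBackward <- function(p, feats, Ahat, config, B, fw, y) {
  S <- config$subFrames
  nodes <- names(feats)
  cache <- fw$cache
  probs <- .softmaxRows(fw$logits)
  dLogits <- probs
  dLogits[cbind(seq_len(B), y)] <- dLogits[cbind(seq_len(B), y)] - 1
  dLogits <- dLogits / B
  g <- list()
  g$head <- list(W = t(cache$pool) %*% dLogits, b = colSums(dLogits))
  dPool <- dLogits %*% t(p$head$W)
  dX <- dPool[rep(seq_len(B), each = S), ] / S
  g$layers <- vector("list", length(p$layers))
  for (l in rev(seq_along(p$layers))) {
    lp <- p$layers[[l]]; lc <- cache$layers[[l]]
    bn2 <- .lnBackward(dX, lc$ln2, lp$g2)
    dX1pF <- bn2$dX
    dW2 <- t(lc$Fact) %*% dX1pF
    db2 <- colSums(dX1pF)
    dFact <- dX1pF %*% t(lp$W2)
    dFpre <- dFact * (lc$Fpre > 0)
    dW1 <- t(lc$X1) %*% dFpre
    db1 <- colSums(dFpre)
    dX1 <- dX1pF + dFpre %*% t(lp$W1)
    bn1 <- .lnBackward(dX1, lc$ln1, lp$g1)
    dXpA <- bn1$dX
    mb <- .mhaBackward(dXpA, lc$mha, lc$Xin, lp, B, S, config$nHeads)
    dX <- dXpA + mb$dX
    g$layers[[l]] <- list(Wq = mb$dWq, Wk = mb$dWk, Wv = mb$dWv,
                          Wo = mb$dWo, g1 = bn1$dg, be1 = bn1$db,
                          W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                          g2 = bn2$dg, be2 = bn2$db)
  }
  g$tok <- list(W = t(cache$Xc) %*% dX, b = colSums(dX))
  dXc <- dX %*% t(p$tok$W)
  dG <- dGcn <- config$dGcn
  dH <- lapply(seq_along(nodes), function(i)
    dXc[, ((i - 1) * dGcn + 1):(i * dGcn), drop = FALSE])
  names(dH) <- nodes
  g$gcn <- vector("list", length(p$gcn))
  for (l in rev(seq_along(p$gcn))) {
    lc <- cache$gcn[[l]]
    dZ <- lapply(seq_along(nodes), function(i)
      dH[[i]] * (lc$Z[[i]] > 0))
    dP <- lapply(seq_along(nodes), function(j) {
      z <- 0
      for (i in seq_along(nodes)) z <- z + Ahat[i, j] * dZ[[i]]
      z
    })
    gW <- 0
    for (j in seq_along(nodes))
      gW <- gW + t(lc$Hin[[j]]) %*% dP[[j]]
    g$gcn[[l]] <- gW
    dH <- lapply(seq_along(nodes), function(j)
      dP[[j]] %*% t(p$gcn[[l]]))
    names(dH) <- nodes
  }
  g$emb <- lapply(nodes, function(nd) {
    i <- match(nd, nodes)
    list(W = t(feats[[nd]]) %*% dH[[i]], b = colSums(dH[[i]]))
  })
  names(g$emb) <- nodes
  ## reorder to match the parameter template (emb, gcn, tok, layers, head)
  list(grad = g[names(p)],
       loss = -mean(log(pmax(probs[cbind(seq_len(B), y)], 1e-12))))
}

## ---- public API ------------------------------------------------------

#' Train the Transformer-GCN classifier
#'
#' Full-batch Adam on the cross-entropy; fixed-seed initialisation makes
#' training deterministic. The per-epoch log (loss, training accuracy
#' and, if given, validation accuracy) is stored in the returned model;
#' when a validation set is supplied the parameters with the best
#' validation accuracy are kept (early stopping).
#'
#' @param fw training \linkS4class{FeatureWindows} (Z-scored)
#' @param config a \code{\link{harConfig}} list
#' @param graph the placement \linkS4class{SkeletonGraph}
#' @param epochs Adam steps
#' @param lr learning rate
#' @param validation optional \linkS4class{FeatureWindows} monitored for
#'   early stopping
#' @param verbose print per-epoch progress
#' @return a trained \linkS4class{HarModel}
#' @export
trainHarModel <- function(fw, config = harConfig(),
                          graph = skeletonGraph(), epochs = 40,
                          lr = 0.01, validation = NULL,
                          verbose = FALSE) {
  stopifnot(is(fw, "FeatureWindows"))
  nodes <- graphNodes(graph)
  feats <- .windowNodeFeatures(fw, nodes, config$subFrames)
  Ahat <- buildNormalizedAdjacency(graph)
  classes <- levels(windowLabels(fw))
  y <- as.integer(windowLabels(fw))
  B <- nWindows(fw)
  nodeDims <- lapply(feats, ncol)
  p <- .initHarParams(config, nodeDims, length(classes))
  m <- v <- lapply(.flattenParams(p), function(x) 0)
  mv <- 0 * .flattenParams(p); vv <- mv
  b1 <- 0.9; b2 <- 0.999
  valFeats <- NULL
  if (!is.null(validation))
    valFeats <- .windowNodeFeatures(validation, nodes, config$subFrames)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    train_acc = numeric(0), val_acc = numeric(0))
  bestAcc <- -Inf; bestP <- p
  for (it in seq_len(epochs)) {
    fwp <- .harForward(p, feats, Ahat, config, B)
    bk <- .harBackward(p, feats, Ahat, config, B, fwp, y)
    gv <- .flattenParams(bk$grad)
    pv <- .flattenParams(p)
    mv <- b1 * mv + (1 - b1) * gv
    vv <- b2 * vv + (1 - b2) * gv^2
    pv <- pv - lr * (mv / (1 - b1^it)) / (sqrt(vv / (1 - b2^it)) + 1e-8)
    p <- .unflattenParams(p, pv)
    trAcc <- 100 * mean(max.col(fwp$logits) == y)
    vAcc <- NA_real_
    if (!is.null(validation)) {
      vl <- .harForward(p, valFeats, Ahat, config,
                        nWindows(validation))$logits
      vAcc <- 100 * mean(max.col(vl) ==
                           as.integer(factor(
                             as.character(windowLabels(validation)),
                             levels = classes)))
      if (vAcc >= bestAcc) { bestAcc <- vAcc; bestP <- p }
    }
    log <- rbind(log, data.frame(epoch = it, loss = bk$loss,
                                 train_acc = trAcc, val_acc = vAcc))
    if (verbose)
      message(sprintf("epoch %3d loss %.4f acc %.1f%% val %.1f%%",
                      it, bk$loss, trAcc, vAcc))
  }
  if (!is.null(validation)) p <- bestP
  new("HarModel", config = config, params = p, graph = graph,
      classes = classes, trained = TRUE, log = log)
}

#' Build an untrained model (seeded initialisation)
#'
#' @param fw \linkS4class{FeatureWindows} defining input shape/classes
#' @param config a \code{\link{harConfig}}
#' @param graph placement graph
#' @param zeroHead zero the output layer (gives exactly uniform class
#'   probabilities)
#' @return an untrained \linkS4class{HarModel}
#' @export
initHarModel <- function(fw, config = harConfig(),
                         graph = skeletonGraph(), zeroHead = FALSE) {
  nodes <- graphNodes(graph)
  feats <- .windowNodeFeatures(fw, nodes, config$subFrames)
  classes <- levels(windowLabels(fw))
  p <- .initHarParams(config, lapply(feats, ncol), length(classes))
  if (zeroHead) {
    p$head$W[] <- 0; p$head$b[] <- 0
  }
  new("HarModel", config = config, params = p, graph = graph,
      classes = classes, trained = FALSE,
      log = data.frame())
}

#' Classify windows
#'
#' Deterministic forward pass in evaluation mode: per-window class
#' probabilities (rows sum to 1) and hard predictions.
#'
#' @param model a \linkS4class{HarModel}
#' @param fw \linkS4class{FeatureWindows} with the same channel layout
#'   the model was built on
#' @return list(probabilities = N x classes matrix, predictions = factor)
#' @export
classifyWindows <- function(model, fw) {
  stopifnot(is(model, "HarModel"), is(fw, "FeatureWindows"))
  nodes <- graphNodes(model@graph)
  feats <- .windowNodeFeatures(fw, nodes, model@config$subFrames)
  expDim <- vapply(model@params$emb, function(e) nrow(e$W), 0)
  gotDim <- vapply(feats, ncol, 0)
  .stopIfNot(all(expDim == gotDim),
             "feature dimensions (", paste(gotDim, collapse = ","),
             ") do not match the trained model (",
             paste(expDim, collapse = ","), ")")
  Ahat <- buildNormalizedAdjacency(model@graph)
  logits <- .harForward(model@params, feats, Ahat, model@config,
                        nWindows(fw))$logits
  probs <- .softmaxRows(logits)
  colnames(probs) <- model@classes
  list(probabilities = probs,
       predictions = factor(model@classes[max.col(probs)],
                            levels = model@classes))
}
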