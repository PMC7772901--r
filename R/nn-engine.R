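## Forward/backward engine for the branch-and-head networks.
##
## Convolutional branches carry activations as (outLen * batch) x channels
## matrices: rows are sample-major time positions, columns are feature maps.
## In this layout a valid 1D convolution is a strided-row gather (im2col)
## followed by one BLAS matrix product, and its output is already the next
## layer's input -- no transposes. Max pooling is a running pmax over the
## same strided rows. Dense layers (wrist branches and the fused head) use
## the conventional (features x batch) layout; branch outputs are
## flattened/concatenated between the two. Everything is plain double
## arithmetic, so seeded runs are bit-for-bit reproducible.

planBranch <- function(branch) {
  len <- branch$inputLen
  ch <- 1L
  plan <- list()
  for (ly in branch$layers) {
    if (ly$type == "conv") {
      outLen <- layerOutLen(len, ly$kernel, ly$stride)
      plan[[length(plan) + 1L]] <- list(
        type = "conv", inLen = len, inCh = ch, outLen = outLen,
        kernel = ly$kernel, stride = ly$stride, nFilters = ly$nFilters,
        activation = ly$activation)
      len <- outLen; ch <- ly$nFilters
    } else if (ly$type == "maxpool") {
      outLen <- layerOutLen(len, ly$pool, ly$poolStride)
      plan[[length(plan) + 1L]] <- list(
        type = "maxpool", inLen = len, inCh = ch, outLen = outLen,
        pool = ly$pool, poolStride = ly$poolStride)
      len <- outLen
    } else if (ly$type == "dense") {
      if (ch != 1L)
        stop("dense layers after convolutional stages are not supported ",
             "inside a branch")
      plan[[length(plan) + 1L]] <- list(
        type = "dense", inWidth = len, width = ly$width,
        activation = ly$activation)
      len <- ly$width
    } else stop("unknown layer type ", ly$type)
  }
  list(layers = plan, outLen = len, outCh = ch, outWidth = len * ch,
       hasConv = any(vapply(plan, function(l)
         l$type %in% c("conv", "maxpool"), logical(1))))
}

planGraph <- function(graph) {
  plans <- lapply(graph@branches, planBranch)
  for (nm in names(plans)) {
    if (plans[[nm]]$outWidth != graph@branches[[nm]]$outWidth)
      stop(sprintf("branch %s: planned width %d != declared %d", nm,
                   plans[[nm]]$outWidth, graph@branches[[nm]]$outWidth))
  }
  inW <- sum(vapply(plans, function(p) p$outWidth, numeric(1)))
  head <- list()
  for (l in graph@head) {
    head[[length(head) + 1L]] <- list(type = "dense", inWidth = inW,
                                      width = l$width,
                                      activation = l$activation)
    inW <- l$width
  }
  list(branches = plans, head = head,
       rowsCache = new.env(parent = emptyenv()))
}

## Strided base-row index for a whole batch: entry (p, s) addresses input
## row (s-1)*len + (p-1)*stride + 1, ordered p-fastest -- which is exactly
## output row (s-1)*outLen + p. Cached per layer and batch size.
strideRows <- function(cache, key, outLen, stride, len, B) {
  k <- paste0(key, ":", B)
  rows <- cache[[k]]
  if (is.null(rows)) {
    rows <- as.vector(outer((seq_len(outLen) - 1L) * stride + 1L,
                            (seq_len(B) - 1L) * len, `+`))
    cache[[k]] <- rows
  }
  rows
}

glorotUniform <- function(nr, nc, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

## Weight containers mirror the plan: branches -> layers -> (W, b).
## Conv filter matrices are (kernel * inCh) x nFilters with rows ordered
## kernel-offset-fastest within input channel.
initWeights <- function(plan) {
  initLayer <- function(ly) {
    switch(ly$type,
      conv = list(W = glorotUniform(ly$kernel * ly$inCh, ly$nFilters,
                                    ly$kernel * ly$inCh,
                                    ly$kernel * ly$nFilters),
                  b = numeric(ly$nFilters)),
      dense = list(W = glorotUniform(ly$inWidth, ly$width, ly$inWidth,
                                     ly$width),
                   b = numeric(ly$width)),
      maxpool = list())
  }
  list(branches = lapply(plan$branches, function(p)
         lapply(p$layers, initLayer)),
       head = lapply(plan$head, initLayer))
}

flattenParams <- function(w) unlist(w, use.names = FALSE)

unflattenParams <- function(skel, vec) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(x)
    out
  }
  out <- fill(skel)
  stopifnot(pos == length(vec))
  out
}

## (len*ch) x B feature layout  <->  (len*B) x ch batch-rows layout
toBatchRows <- function(X, len, ch, B) {
  if (ch == 1L) { dim(X) <- c(len * B, 1L); return(X) }
  dim(X) <- c(len, ch, B)
  X <- aperm(X, c(1L, 3L, 2L))
  dim(X) <- c(len * B, ch)
  X
}

toFeatureCols <- function(A, len, ch, B) {
  if (ch == 1L) { dim(A) <- c(len, B); return(A) }
  dim(A) <- c(len, B, ch)
  A <- aperm(A, c(1L, 3L, 2L))
  dim(A) <- c(len * ch, B)
  A
}

denseForward <- function(w, A, activation, keepCache = FALSE) {
  Z <- crossprod(w$W, A) + w$b
  act <- switch(activation,
    relu = pmax(Z, 0),
    sigmoid = 1 / (1 + exp(-Z)),
    softmax = {
      Zs <- sweep(Z, 2L, apply(Z, 2L, max))
      E <- exp(Zs)
      sweep(E, 2L, colSums(E), "/")
    },
    linear = Z)
  if (keepCache) list(out = act, cache = list(A = A, Z = Z))
  else list(out = act, cache = NULL)
}

## Forward through one branch. X in feature layout; returns feature layout.
branchForward <- function(plan, weights, X, B, rowsCache, key,
                          keepCache = FALSE) {
  caches <- vector("list", length(plan$layers))
  A <- if (plan$hasConv)
    toBatchRows(X, plan$layers[[1]]$inLen, plan$layers[[1]]$inCh, B)
  else X
  for (i in seq_along(plan$layers)) {
    ly <- plan$layers[[i]]
    if (ly$type == "conv") {
      rows <- strideRows(rowsCache, paste0(key, i), ly$outLen, ly$stride,
                         ly$inLen, B)
      kch <- ly$kernel * ly$inCh
      G <- matrix(0, ly$outLen * B, kch)
      for (c in seq_len(ly$inCh)) {
        Ac <- A[, c]
        for (j in seq_len(ly$kernel))
          G[, (c - 1L) * ly$kernel + j] <- Ac[rows + (j - 1L)]
      }
      Z <- G %*% weights[[i]]$W
      Z <- Z + rep(weights[[i]]$b, each = nrow(Z))
      A <- pmax(Z, 0)
      if (keepCache) caches[[i]] <- list(G = G, mask = Z > 0)
    } else if (ly$type == "maxpool") {
      rows <- strideRows(rowsCache, paste0(key, i), ly$outLen,
                         ly$poolStride, ly$inLen, B)
      M <- A[rows, , drop = FALSE]
      if (ly$pool > 1L)
        for (j in 2:ly$pool)
          M <- pmax(M, A[rows + (j - 1L), , drop = FALSE])
      if (keepCache) caches[[i]] <- list(Ain = A, M = M)
      A <- M
    } else {
      r <- denseForward(weights[[i]], A, ly$activation, keepCache)
      caches[[i]] <- r$cache
      A <- r$out
    }
  }
  if (plan$hasConv) A <- toFeatureCols(A, plan$outLen, plan$outCh, B)
  list(out = A, caches = caches)
}

## Backward through one branch. dOut in feature layout. Gradients w.r.t.
## the branch input are only computed when needInputGrad (the head needs
## them, raw-signal branches do not).
branchBackward <- function(plan, weights, caches, dOut, B, rowsCache, key,
                           needInputGrad = FALSE) {
  grads <- vector("list", length(plan$layers))
  dA <- if (plan$hasConv)
    toBatchRows(dOut, plan$outLen, plan$outCh, B)
  else dOut
  for (i in rev(seq_along(plan$layers))) {
    ly <- plan$layers[[i]]
    cache <- caches[[i]]
    last <- (i == 1L) && !needInputGrad
    if (ly$type == "conv") {
      dZ <- dA * cache$mask
      grads[[i]] <- list(W = crossprod(cache$G, dZ), b = colSums(dZ))
      if (!last) {
        rows <- strideRows(rowsCache, paste0(key, i), ly$outLen, ly$stride,
                           ly$inLen, B)
        dG <- dZ %*% t(weights[[i]]$W)
        dA <- matrix(0, ly$inLen * B, ly$inCh)
        for (c in seq_len(ly$inCh)) {
          acc <- numeric(ly$inLen * B)
          for (j in seq_len(ly$kernel)) {
            idx <- rows + (j - 1L)
            acc[idx] <- acc[idx] + dG[, (c - 1L) * ly$kernel + j]
          }
          dA[, c] <- acc
        }
      }
    } else if (ly$type == "maxpool") {
      grads[[i]] <- list()
      if (!last) {
        rows <- strideRows(rowsCache, paste0(key, i), ly$outLen,
                           ly$poolStride, ly$inLen, B)
        Ain <- cache$Ain; M <- cache$M
        eq <- vector("list", ly$pool)
        cnt <- 0
        for (j in seq_len(ly$pool)) {
          eq[[j]] <- (Ain[rows + (j - 1L), , drop = FALSE] == M)
          cnt <- cnt + eq[[j]]
        }
        dM <- dA
        dA <- matrix(0, nrow(Ain), ncol(Ain))
        for (j in seq_len(ly$pool)) {
          idx <- rows + (j - 1L)
          ## ties split the gradient equally (a valid subgradient)
          dA[idx, ] <- dA[idx, ] + (eq[[j]] / cnt) * dM
        }
      }
    } else {                                   # dense (relu/linear hidden)
      dZ <- switch(ly$activation,
        relu = dA * (cache$Z > 0),
        linear = dA,
        stop("backward through ", ly$activation,
             " is handled at the loss layer"))
      grads[[i]] <- list(W = cache$A %*% t(dZ), b = rowSums(dZ))
      if (!last) dA <- weights[[i]]$W %*% dZ
    }
  }
  list(grads = grads, dIn = if (needInputGrad) dA else NULL)
}

## Full-model forward. X: named list of branch input matrices
## (features x batch).
nnForward <- function(plan, weights, X, keepCache = FALSE) {
  B <- ncol(X[[1]])
  bout <- list(); bcache <- list()
  for (nm in names(plan$branches)) {
    r <- branchForward(plan$branches[[nm]], weights$branches[[nm]], X[[nm]],
                       B, plan$rowsCache, nm, keepCache)
    bout[[nm]] <- r$out
    bcache[[nm]] <- r$caches
  }
  A <- do.call(rbind, bout)
  hc <- vector("list", length(plan$head))
  for (i in seq_along(plan$head)) {
    r <- denseForward(weights$head[[i]], A, plan$head[[i]]$activation,
                      keepCache)
    hc[[i]] <- r$cache
    A <- r$out
  }
  list(out = A, headCaches = hc, branchCaches = bcache,
       splitRows = vapply(bout, nrow, integer(1)), B = B)
}

## Loss and output-layer gradient. The final layer's softmax/sigmoid is
## fused with cross-entropy: dZ = (p - y) / B.
nnLoss <- function(out, y, loss) {
  B <- ncol(out)
  eps <- 1e-12
  if (loss == "categorical_cross_entropy") {
    Y <- matrix(0, nrow(out), B)
    Y[cbind(y + 1L, seq_len(B))] <- 1
    list(loss = -mean(log(pmax(out[cbind(y + 1L, seq_len(B))], eps))),
         dZ = (out - Y) / B)
  } else {
    p <- out[1L, ]
    list(loss = -mean(y * log(pmax(p, eps)) +
                        (1 - y) * log(pmax(1 - p, eps))),
         dZ = matrix((p - y) / B, 1L, B))
  }
}

nnBackward <- function(plan, weights, fwd, dZout) {
  nh <- length(plan$head)
  hc <- fwd$headCaches
  grads <- list(branches = list(), head = vector("list", nh))
  dZ <- dZout
  for (i in rev(seq_len(nh))) {
    if (i < nh) {
      stopifnot(plan$head[[i]]$activation == "relu")
      dZ <- dA * (hc[[i]]$Z > 0)
    }
    grads$head[[i]] <- list(W = hc[[i]]$A %*% t(dZ), b = rowSums(dZ))
    dA <- weights$head[[i]]$W %*% dZ
  }
  offsets <- c(0L, cumsum(fwd$splitRows))
  nms <- names(plan$branches)
  for (k in seq_along(nms)) {
    nm <- nms[k]
    dBr <- dA[(offsets[k] + 1L):offsets[k + 1L], , drop = FALSE]
    r <- branchBackward(plan$branches[[nm]], weights$branches[[nm]],
                        fwd$branchCaches[[nm]], dBr, fwd$B, plan$rowsCache,
                        nm)
    grads$branches[[nm]] <- r$grads
  }
  grads
}

adamInit <- function(nParams) {
  list(m = numeric(nParams), v = numeric(nParams), t = 0L)
}

adamStep <- function(state, w, g, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(w = w - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' @describeIn accessors trainable parameters actually instantiated in a
#'   fitted model (equals the graph's closed-form `parameterCount`).
#' @export
setMethod("parameterCount", "FittedModel", function(object)
  length(flattenParams(object@weights)))
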