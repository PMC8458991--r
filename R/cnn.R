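## ---- index caches ----------------------------------------------------------
## im2col and pooling are pure index gymnastics; the index vectors depend only
## on (H, W, batch) and are cached across calls
.indexCache <- new.env(parent = emptyenv())

## neighbor indices for a 3x3 convolution with zero padding, for a batch:
## FI is an (H*W*B) x 9 integer matrix of flat input indices (0 = out of
## bounds); idx is as.vector(FI) + 1 for gathering from a zero-padded matrix
convIndices <- function(H, W, B) {
  key <- sprintf("c%d.%d.%d", H, W, B)
  if (!is.null(.indexCache[[key]])) return(.indexCache[[key]])
  h <- rep(seq_len(H), W)
  w <- rep(seq_len(W), each = H)
  FI <- matrix(0L, H * W * B, 9L)
  add <- rep.int((0:(B - 1L)) * (H * W), rep.int(H * W, B))
  k <- 0L
  for (dw in -1:1) for (dh in -1:1) {
    k <- k + 1L
    hh <- h + dh; ww <- w + dw
    ok <- hh >= 1L & hh <= H & ww >= 1L & ww <= W
    ni <- ifelse(ok, hh + (ww - 1L) * H, 0L)
    fi <- rep.int(ni, B)
    sel <- fi > 0L
    fi[sel] <- fi[sel] + add[sel]
    FI[, k] <- fi
  }
  out <- list(FI = FI, idx = as.vector(FI) + 1L, HWB = H * W * B)
  .indexCache[[key]] <- out
  out
}

## 2x2 average pooling: four index vectors into the input rows, output rows
## ordered (ho, wo, sample)
poolIndices <- function(H, W, B) {
  key <- sprintf("p%d.%d.%d", H, W, B)
  if (!is.null(.indexCache[[key]])) return(.indexCache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ho <- rep(seq_len(Ho), Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  add <- rep.int((0:(B - 1L)) * (H * W), rep.int(Ho * Wo, B))
  q <- vector("list", 4L)
  k <- 0L
  for (b in 0:1) for (a in 0:1) {
    k <- k + 1L
    base <- (2L * ho - 1L + a) + (2L * wo - 2L + b) * H
    q[[k]] <- rep.int(base, B) + add
  }
  out <- list(q = q, Ho = Ho, Wo = Wo)
  .indexCache[[key]] <- out
  out
}

im2col <- function(A, ci, C) {
  Apad <- matrix(0, ci$HWB + 1L, C)
  Apad[-1L, ] <- A
  G <- Apad[ci$idx, , drop = FALSE]
  dim(G) <- c(ci$HWB, 9L * C)
  G
}

col2im <- function(dG, ci, C) {
  dA <- matrix(0, ci$HWB, C)
  dim(dG) <- c(ci$HWB, 9L, C)
  for (k in 1:9) {
    fi <- ci$FI[, k]
    sel <- fi > 0L
    dA[fi[sel], ] <- dA[fi[sel], ] +
      matrix(dG[sel, k, ], ncol = C)
  }
  dA
}

avgPool <- function(A, pi_) {
  (A[pi_$q[[1]], , drop = FALSE] + A[pi_$q[[2]], , drop = FALSE] +
   A[pi_$q[[3]], , drop = FALSE] + A[pi_$q[[4]], , drop = FALSE]) * 0.25
}

avgUnpool <- function(dP, pi_, HWB) {
  dA <- matrix(0, HWB, ncol(dP))
  g <- dP * 0.25
  for (k in 1:4) dA[pi_$q[[k]], ] <- g
  dA
}

addBias <- function(Z, b) Z + rep(b, each = nrow(Z))

## (P*B) x C per-position layout -> B x (P*C) per-sample feature rows
flattenSamples <- function(A, P, B) {
  C <- ncol(A)
  dim(A) <- c(P, B, C)
  A <- aperm(A, c(1L, 3L, 2L))
  dim(A) <- c(P * C, B)
  t(A)
}

unflattenSamples <- function(X, P, B) {
  C <- ncol(X) / P
  A <- t(X)
  dim(A) <- c(P, C, B)
  A <- aperm(A, c(1L, 3L, 2L))
  dim(A) <- c(P * B, C)
  A
}

heInit <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Construct the small convolutional classifier
#'
#' Three 3x3 convolution (same padding) + ReLU + 2x2 average-pooling blocks
#' followed by one hidden fully connected ReLU layer and a softmax output.
#' Weights use He-normal initialization from the given seed; biases start at
#' zero.
#'
#' @param input_size square input side in pixels; must be divisible by 8.
#' @param n_classes number of output classes.
#' @param conv_widths integer(3), channels of the three convolution blocks.
#' @param hidden units in the hidden fully connected layer.
#' @param seed integer seed for weight initialization.
#' @param clip_norm global gradient-norm ceiling applied at each update
#'   (set \code{Inf} to disable).
#' @return A [SmallCNN-class].
#' @examples
#' m <- smallCNN(32, 4, seed = 1)
#' p <- modelPredict(m, array(runif(32 * 32 * 2), c(32, 32, 2)))
#' rowSums(p)  # softmax rows sum to 1
#' @export
smallCNN <- function(input_size, n_classes, conv_widths = c(8L, 16L, 16L),
                     hidden = 64L, seed = 1L, clip_norm = 5) {
  if (input_size %% 8L != 0L)
    stop("input_size must be divisible by 8 (three 2x2 pooling stages)")
  f <- as.integer(conv_widths)
  P3 <- (input_size %/% 8L)^2
  weights <- withSeed(seed, list(
    W1 = heInit(9L, f[1], 9),
    b1 = numeric(f[1]),
    W2 = heInit(9L * f[1], f[2], 9 * f[1]),
    b2 = numeric(f[2]),
    W3 = heInit(9L * f[2], f[3], 9 * f[2]),
    b3 = numeric(f[3]),
    W4 = heInit(P3 * f[3], hidden, P3 * f[3]),
    b4 = numeric(hidden),
    W5 = heInit(hidden, n_classes, hidden),
    b5 = numeric(n_classes)))
  new("SmallCNN",
      weights = weights,
      velocities = lapply(weights, function(w) w * 0),
      arch = list(input_size = as.integer(input_size),
                  n_classes = as.integer(n_classes),
                  conv_widths = f, hidden = as.integer(hidden),
                  clip_norm = clip_norm))
}

asBatchArray <- function(x, input_size) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 3L || d[1] != input_size || d[2] != input_size)
    stop("expected ", input_size, " x ", input_size,
         " x n image array, got ", paste(d, collapse = " x "))
  x
}

cnnForward <- function(model, x, keep = FALSE) {
  w <- model@weights
  N <- model@arch$input_size
  x <- asBatchArray(x, N)
  B <- dim(x)[3]
  f <- model@arch$conv_widths
  A0 <- matrix(as.vector(x), ncol = 1L)
  sizes <- c(N, N %/% 2L, N %/% 4L)
  cis <- list(convIndices(N, N, B),
              convIndices(sizes[2], sizes[2], B),
              convIndices(sizes[3], sizes[3], B))
  pis <- list(poolIndices(N, N, B),
              poolIndices(sizes[2], sizes[2], B),
              poolIndices(sizes[3], sizes[3], B))
  Wc <- list(w$W1, w$W2, w$W3)
  bc <- list(w$b1, w$b2, w$b3)
  Cin <- c(1L, f[1], f[2])
  A <- A0
  G <- Z <- Ap <- vector("list", 3L)
  for (i in 1:3) {
    G[[i]] <- im2col(A, cis[[i]], Cin[i])
    Z[[i]] <- addBias(G[[i]] %*% Wc[[i]], bc[[i]])
    Arelu <- Z[[i]]
    Arelu[Arelu < 0] <- 0
    Ap[[i]] <- avgPool(Arelu, pis[[i]])
    A <- Ap[[i]]
  }
  P3 <- (N %/% 8L)^2
  X <- flattenSamples(Ap[[3]], P3, B)
  H1z <- addBias(X %*% w$W4, w$b4)
  H1 <- H1z; H1[H1 < 0] <- 0
  logits <- addBias(H1 %*% w$W5, w$b5)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  out <- list(probs = probs, logits = logits, H1 = H1, B = B)
  if (keep)
    out <- c(out, list(G = G, Z = Z, Ap = Ap, X = X, H1z = H1z,
                       cis = cis, pis = pis, sizes = sizes, Cin = Cin))
  out
}

#' @rdname model-contract
#' @export
setMethod("modelPredict", "SmallCNN", function(model, x, ...) {
  cnnForward(model, x)$probs
})

#' @rdname model-contract
#' @export
setMethod("availableLayers", "SmallCNN", function(model) {
  c("conv1", "conv2", "conv3", "hidden", "logits", "probs")
})

#' @rdname model-contract
#' @export
setMethod("modelActivations", "SmallCNN", function(model, x, layer, ...) {
  layer <- as.character(layer)
  if (!layer %in% availableLayers(model))
    stop("unknown layer '", layer, "'; available: ",
         paste(availableLayers(model), collapse = ", "))
  fw <- cnnForward(model, x, keep = TRUE)
  N <- model@arch$input_size
  B <- fw$B
  switch(layer,
    conv1 = flattenSamples(fw$Ap[[1]], (N %/% 2L)^2, B),
    conv2 = flattenSamples(fw$Ap[[2]], (N %/% 4L)^2, B),
    conv3 = flattenSamples(fw$Ap[[3]], (N %/% 8L)^2, B),
    hidden = fw$H1,
    logits = fw$logits,
    probs = fw$probs)
})

cnnGradients <- function(model, fw, y) {
  w <- model@weights
  B <- fw$B
  K <- model@arch$n_classes
  Y <- matrix(0, B, K)
  Y[cbind(seq_len(B), y)] <- 1
  dlogits <- (fw$probs - Y) / B
  g <- list()
  g$W5 <- crossprod(fw$H1, dlogits)
  g$b5 <- colSums(dlogits)
  dH1 <- tcrossprod(dlogits, w$W5)
  dH1[fw$H1z <= 0] <- 0
  g$W4 <- crossprod(fw$X, dH1)
  g$b4 <- colSums(dH1)
  dX <- tcrossprod(dH1, w$W4)
  N <- model@arch$input_size
  dAp <- unflattenSamples(dX, (N %/% 8L)^2, B)
  Wc <- list(w$W1, w$W2, w$W3)
  for (i in 3:1) {
    dZ <- avgUnpool(dAp, fw$pis[[i]], fw$cis[[i]]$HWB)
    dZ[fw$Z[[i]] <= 0] <- 0
    g[[paste0("W", i)]] <- crossprod(fw$G[[i]], dZ)
    g[[paste0("b", i)]] <- colSums(dZ)
    if (i > 1L) {
      dG <- tcrossprod(dZ, Wc[[i]])
      dAp <- col2im(dG, fw$cis[[i]], fw$Cin[i])
    }
  }
  g
}

#' @rdname model-contract
#' @export
setMethod("modelUpdate", "SmallCNN",
          function(model, x, y, lr, momentum = 0.9, ...) {
  fw <- cnnForward(model, x, keep = TRUE)
  B <- fw$B
  if (length(y) != B)
    stop("labels length ", length(y), " does not match batch size ", B)
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(B), y)], 1e-12)))
  acc <- mean(max.col(fw$probs, ties.method = "first") == y)
  g <- cnnGradients(model, fw, y)
  ## clip the global gradient norm; guards against rare blow-ups at the
  ## higher end of usable learning rates
  gnorm <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
  clip <- model@arch$clip_norm
  if (!is.null(clip) && is.finite(gnorm) && gnorm > clip)
    g <- lapply(g, function(x) x * (clip / gnorm))
  w <- model@weights
  v <- model@velocities
  for (nm in names(w)) {
    v[[nm]] <- momentum * v[[nm]] - lr * g[[nm]]
    w[[nm]] <- w[[nm]] + momentum * v[[nm]] - lr * g[[nm]]
  }
  model@weights <- w
  model@velocities <- v
  list(model = model, loss = loss, accuracy = acc)
})
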