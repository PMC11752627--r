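# Small reference convolutional network, written against base R matrix
# algebra: two 3x3 conv blocks (relu + 2x2 max pool) and a fully-connected
# softmax head. Convolution is im2col + matrix multiplication; training is
# minibatch rmsprop on the softmax cross-entropy. This is the bundled
# CPU-scale backbone; a pretrained feature-extractor backbone can be plugged
# in instead, in which case only the replaced head is trained.

KERNEL <- 3L

# 1-based linear indices into an (h, w, c) array for all k x k patches,
# positions ordered column-major (row index fastest): (npos, k*k*c) matrix.
im2col_idx <- function(h, w, c, k = KERNEL) {
  oh <- h - k + 1L
  ow <- w - k + 1L
  pos_i <- rep(seq_len(oh), times = ow)
  pos_j <- rep(seq_len(ow), each = oh)
  offs <- as.vector(outer(
    as.vector(outer(0:(k - 1L), (0:(k - 1L)) * h, "+")),
    (0:(c - 1L)) * h * w, "+"))
  base <- pos_i + (pos_j - 1L) * h
  outer(base, offs, "+")
}

cnn_geometry <- function(input_size, n_channels = 3L,
                         f1 = 16L, f2 = 32L) {
  h <- input_size
  oh1 <- h - KERNEL + 1L; ph1 <- oh1 %/% 2L
  oh2 <- ph1 - KERNEL + 1L; ph2 <- oh2 %/% 2L
  list(h = h, c = n_channels, f1 = f1, f2 = f2,
       oh1 = oh1, ph1 = ph1, oh2 = oh2, ph2 = ph2,
       n_feat = ph2 * ph2 * f2,
       idx1 = im2col_idx(h, h, n_channels),
       idx2 = im2col_idx(ph1, ph1, f1))
}

new_small_cnn <- function(input_size, n_classes, n_channels = 3L,
                          seed = NULL) {
  geo <- cnn_geometry(as.integer(input_size), as.integer(n_channels))
  with_seed(seed, {
    he <- function(fan_in, nr, nc) {
      matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
    }
    kk1 <- KERNEL^2 * geo$c
    kk2 <- KERNEL^2 * geo$f1
    weights <- list(
      W1 = he(kk1, kk1, geo$f1), b1 = numeric(geo$f1),
      W2 = he(kk2, kk2, geo$f2), b2 = numeric(geo$f2),
      Wfc = he(geo$n_feat, geo$n_feat, n_classes), bfc = numeric(n_classes)
    )
    structure(
      list(kind = "small_cnn", input_size = as.integer(input_size),
           n_channels = as.integer(n_channels),
           n_classes = as.integer(n_classes), weights = weights, geo = geo,
           class_names = NULL, backbone = NULL),
      class = "afw_model"
    )
  })
}

maxpool2 <- function(x) {
  # x: (h, w, f); returns list(out, which) with which in 1..4 for backward
  h <- dim(x)[1]; w <- dim(x)[2]
  ph <- h %/% 2L; pw <- w %/% 2L
  i1 <- seq.int(1L, 2L * ph, 2L); j1 <- seq.int(1L, 2L * pw, 2L)
  s <- list(x[i1, j1, , drop = FALSE], x[i1 + 1L, j1, , drop = FALSE],
            x[i1, j1 + 1L, , drop = FALSE], x[i1 + 1L, j1 + 1L, , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  which4 <- 1L * (s[[1]] == out)
  which4[s[[2]] == out & which4 == 0] <- 2L
  which4[s[[3]] == out & which4 == 0] <- 3L
  which4[s[[4]] == out & which4 == 0] <- 4L
  list(out = out, which = which4, ph = ph, pw = pw)
}

maxpool2_backward <- function(dout, pool, h, w, f) {
  dx <- array(0, dim = c(h, w, f))
  i1 <- seq.int(1L, 2L * pool$ph, 2L); j1 <- seq.int(1L, 2L * pool$pw, 2L)
  for (q in 1:4) {
    mask <- pool$which == q
    if (!any(mask)) next
    di <- i1 + (q - 1L) %% 2L
    dj <- j1 + (q - 1L) %/% 2L
    sub <- array(0, dim = dim(dout))
    sub[mask] <- dout[mask]
    dx[di, dj, ] <- dx[di, dj, ] + sub
  }
  dx
}

# Forward pass for one image x (h, w, c) with values in [0, 1]; inputs are
# zero-centred before the first convolution. Returns caches when train = TRUE.
small_cnn_forward <- function(model, x, train = FALSE) {
  geo <- model$geo; wts <- model$weights
  x <- x - 0.5
  P1 <- matrix(x[geo$idx1], nrow = nrow(geo$idx1))
  A1 <- sweep(P1 %*% wts$W1, 2L, wts$b1, "+")
  A1r <- pmax(A1, 0)
  C1 <- array(A1r, dim = c(geo$oh1, geo$oh1, geo$f1))
  pool1 <- maxpool2(C1)
  P2 <- matrix(pool1$out[geo$idx2], nrow = nrow(geo$idx2))
  A2 <- sweep(P2 %*% wts$W2, 2L, wts$b2, "+")
  A2r <- pmax(A2, 0)
  C2 <- array(A2r, dim = c(geo$oh2, geo$oh2, geo$f2))
  pool2 <- maxpool2(C2)
  feat <- as.vector(pool2$out)
  logits <- as.vector(feat %*% wts$Wfc) + wts$bfc
  if (!train) return(list(logits = logits))
  list(logits = logits, P1 = P1, A1 = A1, pool1 = pool1, P2 = P2, A2 = A2,
       pool2 = pool2, feat = feat)
}

softmax_probs <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

# Gradients of softmax cross-entropy for one image; y is the 1-based class.
small_cnn_backward <- function(model, cache, y) {
  geo <- model$geo; wts <- model$weights
  probs <- softmax_probs(cache$logits)
  dlogits <- probs
  dlogits[y] <- dlogits[y] - 1
  dWfc <- outer(cache$feat, dlogits)
  dbfc <- dlogits
  dfeat <- as.vector(wts$Wfc %*% dlogits)
  dpool2 <- array(dfeat, dim = c(geo$ph2, geo$ph2, geo$f2))
  dC2 <- maxpool2_backward(dpool2, cache$pool2, geo$oh2, geo$oh2, geo$f2)
  dA2 <- matrix(dC2, nrow = nrow(geo$idx2) , ncol = geo$f2)
  dA2[cache$A2 <= 0] <- 0
  dW2 <- crossprod(cache$P2, dA2)
  db2 <- colSums(dA2)
  dP2 <- tcrossprod(dA2, wts$W2)
  dpool1_flat <- rowsum(as.vector(dP2), as.vector(geo$idx2))
  dpool1 <- array(0, dim = c(geo$ph1, geo$ph1, geo$f1))
  dpool1[as.integer(rownames(dpool1_flat))] <- dpool1_flat
  dC1 <- maxpool2_backward(dpool1, cache$pool1, geo$oh1, geo$oh1, geo$f1)
  dA1 <- matrix(dC1, nrow = nrow(geo$idx1), ncol = geo$f1)
  dA1[cache$A1 <= 0] <- 0
  dW1 <- crossprod(cache$P1, dA1)
  db1 <- colSums(dA1)
  loss <- -log(max(probs[y], 1e-12))
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    Wfc = dWfc, bfc = dbfc),
       loss = loss)
}

# Minibatch loss and averaged gradients for a small CNN.
small_cnn_batch_grads <- function(model, images, ys) {
  n <- length(ys)
  acc <- NULL
  total_loss <- 0
  for (i in seq_len(n)) {
    cache <- small_cnn_forward(model, images[, , , i], train = TRUE)
    bw <- small_cnn_backward(model, cache, ys[i])
    total_loss <- total_loss + bw$loss
    if (is.null(acc)) {
      acc <- bw$grads
    } else {
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + bw$grads[[nm]]
    }
  }
  list(grads = lapply(acc, function(g) g / n), loss = total_loss / n)
}

rmsprop_init <- function(weights) lapply(weights, function(w) w * 0)

rmsprop_step <- function(weights, grads, cache, lr, rho = 0.9, eps = 1e-8,
                         gradient_threshold = Inf) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.finite(gradient_threshold)) {
      gn <- sqrt(sum(g^2))
      if (gn > gradient_threshold) g <- g * (gradient_threshold / gn)
    }
    cache[[nm]] <- rho * cache[[nm]] + (1 - rho) * g^2
    weights[[nm]] <- weights[[nm]] - lr * g / (sqrt(cache[[nm]]) + eps)
  }
  list(weights = weights, cache = cache)
}

# Scores for a stack of images (h, w, c, n) under either model kind.
model_scores <- function(model, images) {
  n <- dim(images)[4]
  K <- model$n_classes
  scores <- matrix(0, nrow = n, ncol = K)
  if (model$kind == "small_cnn") {
    for (i in seq_len(n)) {
      fwd <- small_cnn_forward(model, images[, , , i])
      scores[i, ] <- softmax_probs(fwd$logits)
    }
  } else {
    feats <- model$backbone$features(images)
    logits <- sweep(feats %*% model$weights$Wfc, 2L, model$weights$bfc, "+")
    for (i in seq_len(n)) scores[i, ] <- softmax_probs(logits[i, ])
  }
  scores
}

# Averaged head gradients for the pretrained-backbone (head-only) model.
head_only_batch_grads <- function(model, images, ys) {
  feats <- model$backbone$features(images)
  logits <- sweep(feats %*% model$weights$Wfc, 2L, model$weights$bfc, "+")
  n <- length(ys)
  dlog <- t(apply(logits, 1L, softmax_probs))
  loss <- mean(-log(pmax(dlog[cbind(seq_len(n), ys)], 1e-12)))
  dlog[cbind(seq_len(n), ys)] <- dlog[cbind(seq_len(n), ys)] - 1
  list(grads = list(Wfc = crossprod(feats, dlog) / n,
                    bfc = colSums(dlog) / n),
       loss = loss)
}
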