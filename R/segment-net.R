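# A compact trainable encoder-decoder segmenter.
#
# Architecture (one pooling level, one skip connection):
#   input s x s x 3 (scaled to [0,1])
#   enc:  conv3x3(3 -> w)  relu, conv3x3(w -> w)   relu      -> A1
#         maxpool 2x2                                        -> s/2
#         conv3x3(w -> 2w) relu, conv3x3(2w -> 2w) relu      -> A2
#   dec:  nearest upsample 2x2, concat with A1 (3w channels)
#         conv3x3(3w -> w) relu, conv3x3(w -> w)   relu
#   head: conv1x1(w -> 2), per-channel sigmoid (wound, splint-inner)
# Two independent sigmoid channels rather than a softmax: the wound lies
# inside the splint-inner disk, so the classes overlap and must not compete.
# All convolutions run as im2col matrix products on BLAS; gradients are
# hand-derived; optimization is Adam on the smoothed dice loss.

# ---- conv primitives --------------------------------------------------------

# im2col for 3x3 same-padding convolution: returns (h*w) x (9*cin)
im2col3 <- function(X) {
  d <- dim(X); h <- d[1L]; w <- d[2L]; cin <- d[3L]
  P <- matrix(0, h * w, 9L * cin)
  pad <- array(0, dim = c(h + 2L, w + 2L, cin))
  pad[2:(h + 1L), 2:(w + 1L), ] <- X
  j <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    blk <- pad[dy + seq_len(h), dx + seq_len(w), , drop = FALSE]
    P[, j + seq_len(cin)] <- matrix(blk, h * w, cin)
    j <- j + cin
  }
  P
}

# scatter-add of dP (h*w x 9cin) back onto an input gradient array
col2im3 <- function(dP, h, w, cin) {
  pad <- array(0, dim = c(h + 2L, w + 2L, cin))
  j <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    pad[dy + seq_len(h), dx + seq_len(w), ] <-
      pad[dy + seq_len(h), dx + seq_len(w), , drop = FALSE] +
      array(dP[, j + seq_len(cin)], dim = c(h, w, cin))
    j <- j + cin
  }
  pad[2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

convForward <- function(X, W, b) {
  d <- dim(X)
  P <- im2col3(X)
  Z <- sweep(P %*% W, 2L, b, "+")
  list(out = array(Z, dim = c(d[1L], d[2L], ncol(W))), P = P)
}

convBackward <- function(dOut, cache_P, W, h, w, cin) {
  dZ <- matrix(dOut, nrow = h * w)
  list(dW = crossprod(cache_P, dZ), db = colSums(dZ),
       dX = col2im3(dZ %*% t(W), h, w, cin))
}

relu <- function(x) pmax(x, 0)

maxpool2 <- function(X) {
  d <- dim(X); h2 <- d[1L] %/% 2L; w2 <- d[2L] %/% 2L
  i1 <- seq(1L, 2L * h2, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * w2, 2L); j2 <- j1 + 1L
  a <- X[i1, j1, , drop = FALSE]; b <- X[i2, j1, , drop = FALSE]
  cc <- X[i1, j2, , drop = FALSE]; dd <- X[i2, j2, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  which4 <- (out == a) * 1
  which4[which4 == 0 & out == b] <- 2
  which4[which4 == 0 & out == cc] <- 3
  which4[which4 == 0 & out == dd] <- 4
  list(out = out, which = which4)
}

maxpool2Backward <- function(dOut, which4, h, w) {
  cout <- dim(dOut)[3L]
  dX <- array(0, dim = c(h, w, cout))
  h2 <- dim(dOut)[1L]; w2 <- dim(dOut)[2L]
  i1 <- seq(1L, 2L * h2, 2L); j1 <- seq(1L, 2L * w2, 2L)
  sel <- function(k) dOut * (which4 == k)
  dX[i1, j1, ] <- dX[i1, j1, , drop = FALSE] + sel(1)
  dX[i1 + 1L, j1, ] <- dX[i1 + 1L, j1, , drop = FALSE] + sel(2)
  dX[i1, j1 + 1L, ] <- dX[i1, j1 + 1L, , drop = FALSE] + sel(3)
  dX[i1 + 1L, j1 + 1L, ] <- dX[i1 + 1L, j1 + 1L, , drop = FALSE] + sel(4)
  dX
}

upsample2 <- function(X) {
  d <- dim(X)
  idr <- rep(seq_len(d[1L]), each = 2L); idc <- rep(seq_len(d[2L]), each = 2L)
  X[idr, idc, , drop = FALSE]
}

upsample2Backward <- function(dOut) {
  d <- dim(dOut); h2 <- d[1L] %/% 2L; w2 <- d[2L] %/% 2L
  i1 <- seq(1L, 2L * h2, 2L); j1 <- seq(1L, 2L * w2, 2L)
  dOut[i1, j1, , drop = FALSE] + dOut[i1 + 1L, j1, , drop = FALSE] +
    dOut[i1, j1 + 1L, , drop = FALSE] + dOut[i1 + 1L, j1 + 1L, , drop = FALSE]
}

# ---- model ------------------------------------------------------------------

initWeights <- function(width) {
  w <- width
  he <- function(k, cin, cout)
    matrix(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))), k * cin, cout)
  list(W1a = he(9, 3, w), b1a = numeric(w),
       W1b = he(9, w, w), b1b = numeric(w),
       W2a = he(9, w, 2 * w), b2a = numeric(2 * w),
       W2b = he(9, 2 * w, 2 * w), b2b = numeric(2 * w),
       W3a = he(9, 3 * w, w), b3a = numeric(w),
       W3b = he(9, w, w), b3b = numeric(w),
       Wh = matrix(stats::rnorm(w * 2, 0, sqrt(1 / w)), w, 2),
       bh = numeric(2))
}

netForward <- function(X, wt, keep_cache = FALSE) {
  d <- dim(X); h <- d[1L]; w2 <- d[2L]
  c1a <- convForward(X, wt$W1a, wt$b1a); A1a <- relu(c1a$out)
  c1b <- convForward(A1a, wt$W1b, wt$b1b); A1b <- relu(c1b$out)
  mp <- maxpool2(A1b)
  c2a <- convForward(mp$out, wt$W2a, wt$b2a); A2a <- relu(c2a$out)
  c2b <- convForward(A2a, wt$W2b, wt$b2b); A2b <- relu(c2b$out)
  up <- upsample2(A2b)
  cat3 <- array(c(up, A1b), dim = c(h, w2, dim(up)[3L] + dim(A1b)[3L]))
  c3a <- convForward(cat3, wt$W3a, wt$b3a); A3a <- relu(c3a$out)
  c3b <- convForward(A3a, wt$W3b, wt$b3b); A3b <- relu(c3b$out)
  Zm <- matrix(A3b, h * w2) %*% wt$Wh
  Zm <- sweep(Zm, 2L, wt$bh, "+")
  Y <- array(1 / (1 + exp(-Zm)), dim = c(h, w2, 2L))
  if (!keep_cache) return(list(Y = Y))
  list(Y = Y, X = X, c1a = c1a, A1a = A1a, c1b = c1b, A1b = A1b, mp = mp,
       c2a = c2a, A2a = A2a, c2b = c2b, A2b = A2b, up = up, cat3 = cat3,
       c3a = c3a, A3a = A3a, c3b = c3b, A3b = A3b)
}

# dice loss + full backward pass; T is h x w x 2 of 0/1 targets
netBackward <- function(cache, Tgt, wt, smooth = 1) {
  Y <- cache$Y
  d <- dim(Y); h <- d[1L]; w2 <- d[2L]
  loss <- 0
  dY <- array(0, dim = d)
  for (k in 1:2) {
    p <- Y[, , k]; t <- Tgt[, , k]
    sp <- sum(p); st <- sum(t); spt <- sum(p * t)
    num <- 2 * spt + smooth; den <- sp + st + smooth
    loss <- loss + (1 - num / den) / 2
    dY[, , k] <- -(2 * t * den - num) / den^2 / 2
  }
  dZ <- dY * Y * (1 - Y)
  dZm <- matrix(dZ, h * w2)
  g <- list()
  g$Wh <- crossprod(matrix(cache$A3b, h * w2), dZm)
  g$bh <- colSums(dZm)
  dA3b <- array(dZm %*% t(wt$Wh), dim = dim(cache$A3b))
  dA3b <- dA3b * (cache$A3b > 0)
  bk <- convBackward(dA3b, cache$c3b$P, wt$W3b, h, w2, dim(cache$A3a)[3L])
  g$W3b <- bk$dW; g$b3b <- bk$db
  dA3a <- bk$dX * (cache$A3a > 0)
  bk <- convBackward(dA3a, cache$c3a$P, wt$W3a, h, w2, dim(cache$cat3)[3L])
  g$W3a <- bk$dW; g$b3a <- bk$db
  cup <- dim(cache$up)[3L]
  dUp <- bk$dX[, , seq_len(cup), drop = FALSE]
  dA1b_skip <- bk$dX[, , cup + seq_len(dim(cache$A1b)[3L]), drop = FALSE]
  dA2b <- upsample2Backward(dUp) * (cache$A2b > 0)
  h2 <- h %/% 2L; w22 <- w2 %/% 2L
  bk <- convBackward(dA2b, cache$c2b$P, wt$W2b, h2, w22, dim(cache$A2a)[3L])
  g$W2b <- bk$dW; g$b2b <- bk$db
  dA2a <- bk$dX * (cache$A2a > 0)
  bk <- convBackward(dA2a, cache$c2a$P, wt$W2a, h2, w22, dim(cache$mp$out)[3L])
  g$W2a <- bk$dW; g$b2a <- bk$db
  dP <- maxpool2Backward(bk$dX, cache$mp$which, h, w2)
  dA1b <- (dP + dA1b_skip) * (cache$A1b > 0)
  bk <- convBackward(dA1b, cache$c1b$P, wt$W1b, h, w2, dim(cache$A1a)[3L])
  g$W1b <- bk$dW; g$b1b <- bk$db
  dA1a <- bk$dX * (cache$A1a > 0)
  bk <- convBackward(dA1a, cache$c1a$P, wt$W1a, h, w2, 3L)
  g$W1a <- bk$dW; g$b1a <- bk$db
  list(loss = loss, grads = g)
}

adamStep <- function(wt, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    wt[[nm]] <- wt[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(wt = wt, state = state)
}

# crop one scene about its wound-of-interest into a training sample
sceneToSample <- function(scene, side) {
  mid <- c(scene@bbox["cx"], scene@bbox["cy"])
  cr <- cropAboutMidpoint(scene@image, mid, side)
  wm <- cropAboutMidpoint(scene@wound_mask * 1, mid, side)$crop > 0.5
  sm <- cropAboutMidpoint(scene@splint_inner_mask * 1, mid, side)$crop > 0.5
  list(image = cr$crop, masks = list(wound = wm, splint = sm))
}

sampleIoU <- function(Y, Tgt, thr = 0.5) {
  mean(vapply(1:2, function(k)
    segmentationScores(Y[, , k] >= thr, Tgt[, , k])["iou"], numeric(1)))
}

#' Train the encoder-decoder segmenter on phantom scenes
#'
#' Scenes are split into training and validation by whole wound series
#' (never by frame): every scene whose `wound_id` is in `val_ids` is held
#' out. Each epoch reshuffles the training set and applies on-the-fly
#' augmentation, so the effective training set grows with the epoch count.
#' Optimization is Adam on the smoothed dice loss over the two sigmoid
#' output channels. Training is deterministic given `config@seed` under
#' single-threaded BLAS.
#'
#' @param scenes list of [PhantomScene-class] with ground-truth masks.
#' @param val_ids character vector of wound_ids held out for validation
#'   (at least one, and at least one training id must remain).
#' @param config a [TrainConfig-class].
#' @param augmentation an [AugmentationConfig-class]; geometric/photometric
#'   settings applied to training samples each epoch.
#' @return A [SegmenterModel-class] with a per-epoch log (train/val loss and
#'   IoU).
#' @export
trainSegmenter <- function(scenes, val_ids, config = trainConfig(),
                           augmentation = augmentationConfig()) {
  stopifnot(is(config, "TrainConfig"), is(augmentation, "AugmentationConfig"))
  ids <- vapply(scenes, function(s) s@wound_id, character(1))
  if (length(intersect(val_ids, ids)) == 0L)
    stop("configuration error: no validation series present")
  is_val <- ids %in% val_ids
  if (!any(is_val)) stop("configuration error: no validation series present")
  if (all(is_val)) stop("configuration error: no training series remain")
  side <- config@input_size
  tr <- lapply(scenes[!is_val], sceneToSample, side = side)
  va <- lapply(scenes[is_val], sceneToSample, side = side)
  toT <- function(masks)
    array(c(masks$wound * 1, masks$splint * 1), dim = c(side, side, 2L))

  withSeed(config@seed, {
    wt <- initWeights(config@width)
    state <- list(m = lapply(wt, function(x) x * 0),
                  v = lapply(wt, function(x) x * 0))
    log <- data.frame()
    step <- 0L
    for (ep in seq_len(config@epochs)) {
      ord <- sample(length(tr))
      ep_loss <- c(); ep_iou <- c()
      i <- 1L
      while (i <= length(ord)) {
        bidx <- ord[i:min(i + config@batch_size - 1L, length(ord))]
        acc <- NULL
        bloss <- 0
        for (j in bidx) {
          s <- tr[[j]]
          aug <- augmentSample(s$image, s$masks, augmentation)
          fw <- netForward(aug$image / 255, wt, keep_cache = TRUE)
          bw <- netBackward(fw, toT(aug$masks), wt)
          bloss <- bloss + bw$loss
          ep_iou <- c(ep_iou, sampleIoU(fw$Y, toT(aug$masks)))
          if (is.null(acc)) acc <- bw$grads
          else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + bw$grads[[nm]]
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(bidx)
        step <- step + 1L
        up <- adamStep(wt, acc, state, config@learning_rate, step)
        wt <- up$wt; state <- up$state
        ep_loss <- c(ep_loss, bloss / length(bidx))
        i <- i + config@batch_size
      }
      vl <- 0; vi <- 0
      for (s in va) {
        fw <- netForward(s$image / 255, wt)
        Tg <- toT(s$masks)
        vl <- vl + diceLoss(fw$Y, Tg)
        vi <- vi + sampleIoU(fw$Y, Tg)
      }
      log <- rbind(log, data.frame(
        epoch = ep, train_loss = mean(ep_loss), val_loss = vl / length(va),
        train_iou = mean(ep_iou), val_iou = vi / length(va)))
    }
    new("SegmenterModel", weights = wt, config = config, log = log)
  })
}

#' Predict per-class score maps for a crop
#'
#' @param model a [SegmenterModel-class].
#' @param crop square RGB array (0-255) with side `config@input_size`.
#' @return A [ProbabilityMaps-class] (scores scaled to 0-255).
#' @export
predictMaps <- function(model, crop) {
  stopifnot(is(model, "SegmenterModel"))
  d <- dim(crop)
  s <- model@config@input_size
  if (length(d) != 3L || d[1L] != s || d[2L] != s || d[3L] != 3L)
    stop(sprintf("crop must be %d x %d x 3", s, s))
  Y <- netForward(crop / 255, model@weights)$Y
  probabilityMaps(Y[, , 1L] * 255, Y[, , 2L] * 255)
}

#' Training log accessor
#' @param model a [SegmenterModel-class].
#' @return data.frame: epoch, train_loss, val_loss, train_iou, val_iou.
#' @export
trainingLog <- function(model) {
  stopifnot(is(model, "SegmenterModel")); model@log
}

#' Write the training log as CSV
#' @param model a [SegmenterModel-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeTrainingLog <- function(model, path) {
  utils::write.csv(trainingLog(model), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained segmenter with its config and seed manifest
#' @param model a [SegmenterModel-class].
#' @param path checkpoint path (RDS).
#' @return `saveSegmenter` invisibly returns `path`; `loadSegmenter` returns
#'   the model.
#' @export
saveSegmenter <- function(model, path) {
  stopifnot(is(model, "SegmenterModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveSegmenter
#' @export
loadSegmenter <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "SegmenterModel"))
  m
}
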