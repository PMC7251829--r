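# Convolutional BrdU-content estimator.
#
# A small 1-D convnet maps a window of 96 (base, normalized shift)
# plateaus to the fraction of substituted T sites in the window: three
# convolutional layers (32 filters, kernel 5, 'same' padding, ReLU) with
# 4x max-pooling after the first two (hence the window must be a multiple
# of 16), then a shared dense+sigmoid head applied at each of the 6
# remaining positions and averaged.  Trained with plain SGD (momentum,
# multiplicative decay) on mean squared error against cohort-level
# content labels.  Everything is implemented with base R matrix algebra.

#' Architecture of the convolutional BrdU-content estimator
#'
#' @param window Input window length in transitions; must be a multiple
#'   of 16 (two 4x poolings).
#' @param channels Input channels: 4 one-hot base channels + 1 shift.
#' @param filters Filters per convolutional layer.
#' @param kernel Convolution kernel size.
#' @param pool Pooling factor after layers 1 and 2.
#' @param stride Window stride used at inference by [call_cnn()].
#' @return List of class `cnn_spec`.
#' @export
cnn_spec <- function(window = 96L, channels = 5L, filters = 32L,
                     kernel = 5L, pool = 4L, stride = 10L) {
  stopifnot(window %% (pool * pool) == 0L, kernel %% 2L == 1L)
  structure(list(window = as.integer(window), channels = as.integer(channels),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), stride = as.integer(stride)),
            class = "cnn_spec")
}

#' Training schedule for the convolutional estimator
#'
#' @param learning_rate,decay,momentum SGD hyperparameters; the effective
#'   rate at update `t` is `learning_rate / (1 + decay * t)`.
#' @param val_fraction Fraction of windows held out for validation.
#' @param patience Epochs without validation-loss improvement before
#'   stopping.
#' @param max_epochs Hard cap on epochs per pass.
#' @param batch_size Minibatch size.
#' @param two_pass If `TRUE`, after a first training pass the BrdU-rich
#'   cohorts are cleaned: the per-read predicted contents of each rich
#'   cohort are split into two groups (2-means), and when the group
#'   centers are more than `relabel_gap` apart the lower mode -
#'   unsubstituted parental strands mixed into a substituted sample - is
#'   dropped and training restarts on the cleaned set.
#' @param relabel_content Cohort label at or above which the cleaning is
#'   applied.
#' @param relabel_gap Minimal separation of the two prediction modes for
#'   a cohort to be considered contaminated.
#' @return List of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 0.1, decay = 1e-6, momentum = 0.9,
                       val_fraction = 0.1, patience = 5L, max_epochs = 60L,
                       batch_size = 32L, two_pass = FALSE,
                       relabel_content = 0.5, relabel_gap = 0.15) {
  stopifnot(patience >= 1L, val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate, decay = decay,
                 momentum = momentum, val_fraction = val_fraction,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 two_pass = isTRUE(two_pass),
                 relabel_content = relabel_content,
                 relabel_gap = relabel_gap),
            class = "train_spec")
}

# ---- low-level layers -----------------------------------------------------

# im2col for 'same' 1-D convolution: A is a (B, L, C) array, returns a
# (B*L, kernel*C) matrix whose rows follow R's column-major (b, l) order.
conv_cols <- function(A, kernel) {
  d <- dim(A); B <- d[1]; L <- d[2]; C <- d[3]
  p <- (kernel - 1L) %/% 2L
  Ap <- array(0, c(B, L + 2L * p, C))
  Ap[, (p + 1L):(p + L), ] <- A
  M <- matrix(0, B * L, kernel * C)
  for (k in seq_len(kernel)) {
    M[, ((k - 1L) * C + 1L):(k * C)] <- matrix(Ap[, k:(k + L - 1L), , drop = FALSE],
                                               B * L, C)
  }
  M
}

# scatter-add of column gradients back onto the (B, L, C) input
conv_cols_backward <- function(gM, kernel, B, L, C) {
  p <- (kernel - 1L) %/% 2L
  gAp <- array(0, c(B, L + 2L * p, C))
  for (k in seq_len(kernel)) {
    gAp[, k:(k + L - 1L), ] <- gAp[, k:(k + L - 1L), , drop = FALSE] +
      array(gM[, ((k - 1L) * C + 1L):(k * C)], c(B, L, C))
  }
  gAp[, (p + 1L):(p + L), , drop = FALSE]
}

# max-pool by factor p along dim 2 of a (B, L, F) array; returns pooled
# array and the argmax masks needed for the backward pass
maxpool_forward <- function(A, p) {
  d <- dim(A); B <- d[1]; L <- d[2]; F <- d[3]
  L2 <- L %/% p
  slices <- lapply(seq_len(p), function(k) A[, seq(k, L, by = p), , drop = FALSE])
  P <- Reduce(pmax, slices)
  masks <- vector("list", p)
  taken <- array(FALSE, dim(P))
  for (k in seq_len(p)) {
    m <- (slices[[k]] == P) & !taken
    taken <- taken | m
    masks[[k]] <- m
  }
  list(out = P, masks = masks, L = L)
}

maxpool_backward <- function(gP, pool_cache, p) {
  d <- dim(gP); B <- d[1]; L2 <- d[2]; F <- d[3]
  gA <- array(0, c(B, pool_cache$L, F))
  for (k in seq_len(p)) {
    gA[, seq(k, pool_cache$L, by = p), ] <- gP * pool_cache$masks[[k]]
  }
  gA
}

cnn_init_weights <- function(spec) {
  k <- spec$kernel; C <- spec$channels; F <- spec$filters
  he <- function(fan_in, nr, nc) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  list(
    W1 = he(k * C, k * C, F), b1 = numeric(F),
    W2 = he(k * F, k * F, F), b2 = numeric(F),
    W3 = he(k * F, k * F, F), b3 = numeric(F),
    W4 = matrix(stats::rnorm(F, 0, sqrt(1 / F)), F, 1L), b4 = 0
  )
}

# Forward pass over a (B, window, channels) array.  With cache = TRUE the
# intermediates needed by the backward pass are returned.
cnn_forward <- function(X, w, spec, cache = FALSE) {
  B <- dim(X)[1]; L <- spec$window; F <- spec$filters; p <- spec$pool
  M1 <- conv_cols(X, spec$kernel)
  Z1 <- sweep(M1 %*% w$W1, 2L, w$b1, "+")
  A1 <- array(pmax(Z1, 0), c(B, L, F))
  P1 <- maxpool_forward(A1, p)
  L1 <- L %/% p

  M2 <- conv_cols(P1$out, spec$kernel)
  Z2 <- sweep(M2 %*% w$W2, 2L, w$b2, "+")
  A2 <- array(pmax(Z2, 0), c(B, L1, F))
  P2 <- maxpool_forward(A2, p)
  L2 <- L1 %/% p

  M3 <- conv_cols(P2$out, spec$kernel)
  Z3 <- sweep(M3 %*% w$W3, 2L, w$b3, "+")
  A3 <- matrix(pmax(Z3, 0), B * L2, F)

  Z4 <- A3 %*% w$W4 + w$b4
  S <- matrix(stats::plogis(Z4), B, L2)
  yhat <- rowMeans(S)
  if (!cache) return(yhat)
  list(yhat = yhat, S = S, A3 = A3, Z3 = Z3, M3 = M3, P2 = P2, Z2 = Z2,
       M2 = M2, P1 = P1, Z1 = Z1, M1 = M1, L1 = L1, L2 = L2, B = B)
}

cnn_backward <- function(fw, y, w, spec) {
  B <- fw$B; F <- spec$filters; p <- spec$pool
  L <- spec$window; L1 <- fw$L1; L2 <- fw$L2
  g_yhat <- 2 * (fw$yhat - y) / B
  gS <- matrix(g_yhat / L2, B, L2)
  gZ4 <- as.numeric(gS) * fw$S * (1 - fw$S)   # same layout B x L2
  gZ4 <- matrix(gZ4, B * L2, 1L)
  gW4 <- crossprod(fw$A3, gZ4)
  gb4 <- sum(gZ4)
  gA3 <- gZ4 %*% t(w$W4)
  gZ3 <- gA3 * (matrix(fw$Z3, B * L2, F) > 0)
  gW3 <- crossprod(fw$M3, gZ3)
  gb3 <- colSums(gZ3)
  gM3 <- gZ3 %*% t(w$W3)
  gP2 <- conv_cols_backward(gM3, spec$kernel, B, L2, F)
  gA2 <- maxpool_backward(gP2, fw$P2, p)
  gZ2 <- matrix(gA2, B * L1, F) * (fw$Z2 > 0)
  gW2 <- crossprod(fw$M2, gZ2)
  gb2 <- colSums(gZ2)
  gM2 <- gZ2 %*% t(w$W2)
  gP1 <- conv_cols_backward(gM2, spec$kernel, B, L1, F)
  gA1 <- maxpool_backward(gP1, fw$P1, p)
  gZ1 <- matrix(gA1, B * L, F) * (fw$Z1 > 0)
  gW1 <- crossprod(fw$M1, gZ1)
  gb1 <- colSums(gZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
       W4 = gW4, b4 = gb4)
}

# ---- window construction --------------------------------------------------

# (n-1) x 5 feature matrix for one read: one-hot base + normalized shift
read_features <- function(bases, shifts) {
  codes <- base_codes(bases)
  nt <- length(shifts)
  ohe <- matrix(0, nt, 4L)
  ohe[cbind(seq_len(nt), codes[seq_len(nt)] + 1L)] <- 1
  cbind(ohe, shifts)
}

# Windows of `window` transitions starting at `starts` (1-based), stacked
# into a (n_windows, window, 5) array.
stack_windows <- function(feats, starts, window) {
  X <- array(0, c(length(starts), window, 5L))
  for (i in seq_along(starts)) {
    X[i, , ] <- feats[starts[i]:(starts[i] + window - 1L), ]
  }
  X
}

# Non-overlapping training windows for a reads tibble; labels from the
# `content` column (per-window copies of the cohort-level content).
build_training_windows <- function(reads, spec) {
  shifts <- read_shifts(reads)
  xs <- list(); ys <- list(); rid <- list()
  for (i in seq_len(nrow(reads))) {
    nt <- length(shifts[[i]])
    if (nt < spec$window) next
    starts <- seq(1L, nt - spec$window + 1L, by = spec$window)
    feats <- read_features(reads$bases[[i]], shifts[[i]])
    xs[[length(xs) + 1L]] <- stack_windows(feats, starts, spec$window)
    ys[[length(ys) + 1L]] <- rep(reads$content[[i]], length(starts))
    rid[[length(rid) + 1L]] <- rep(reads$read_id[[i]], length(starts))
  }
  if (!length(xs)) stop("no read is long enough for a ", spec$window,
                        "-transition window")
  X <- array(0, c(sum(vapply(xs, function(x) dim(x)[1], integer(1))),
                  spec$window, 5L))
  at <- 1L
  for (x in xs) {
    X[at:(at + dim(x)[1] - 1L), , ] <- x
    at <- at + dim(x)[1]
  }
  list(X = X, y = unlist(ys), read_id = unlist(rid))
}

cnn_predict_array <- function(w, spec, X, batch = 512L) {
  n <- dim(X)[1]
  out <- numeric(n)
  at <- 1L
  while (at <= n) {
    hi <- min(at + batch - 1L, n)
    out[at:hi] <- cnn_forward(X[at:hi, , , drop = FALSE], w, spec)
    at <- hi + 1L
  }
  out
}

sgd_pass <- function(X, y, spec, tspec, seed) {
  with_seed(seed, {
    w <- cnn_init_weights(spec)
    v <- lapply(w, function(p) p * 0)
    n <- length(y)
    val <- sample.int(n, max(1L, round(tspec$val_fraction * n)))
    tr <- setdiff(seq_len(n), val)
    Xval <- X[val, , , drop = FALSE]; yval <- y[val]
    best <- Inf; best_w <- w; stall <- 0L; t_upd <- 0
    history <- list()
    for (epoch in seq_len(tspec$max_epochs)) {
      ord <- sample(tr)
      tl <- 0; nb <- 0L
      for (at in seq(1L, length(ord), by = tspec$batch_size)) {
        idx <- ord[at:min(at + tspec$batch_size - 1L, length(ord))]
        fw <- cnn_forward(X[idx, , , drop = FALSE], w, spec, cache = TRUE)
        g <- cnn_backward(fw, y[idx], w, spec)
        t_upd <- t_upd + 1
        lr <- tspec$learning_rate / (1 + tspec$decay * t_upd)
        for (nm in names(w)) {
          v[[nm]] <- tspec$momentum * v[[nm]] - lr * g[[nm]]
          w[[nm]] <- w[[nm]] + v[[nm]]
        }
        tl <- tl + mean((fw$yhat - y[idx])^2); nb <- nb + 1L
      }
      vl <- mean((cnn_predict_array(w, spec, Xval) - yval)^2)
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = tl / nb, val_loss = vl)
      if (vl < best - 1e-9) {
        best <- vl; best_w <- w; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tspec$patience) break
      }
    }
    list(w = best_w, history = dplyr::bind_rows(history), val_loss = best)
  })
}

# ---- user-facing training / inference -------------------------------------

#' Train the convolutional BrdU-content estimator
#'
#' Splits each labeled read into non-overlapping windows carrying the
#' read's cohort-level content as label, holds out a validation fraction,
#' and minimizes mean squared error by seeded stochastic gradient
#' descent with momentum, stopping after `patience` epochs without
#' validation improvement (the best weights are kept).  With
#' `train_spec(two_pass = TRUE)`, reads from BrdU-rich cohorts whose
#' first-pass predicted content falls below half their label are dropped
#' (parental strands contaminating a substituted sample) and training is
#' repeated on the cleaned set.
#'
#' @param labeled_reads Reads tibble with a `content` column (known mean
#'   BrdU content per read).
#' @param spec A [cnn_spec()].
#' @param tspec A [train_spec()].
#' @param seed Integer seed; training is fully reproducible.
#' @return Object of class `brdu_cnn` with elements `spec`, `weights`,
#'   `history` (per-epoch losses, with a `pass` column), `dropped`
#'   (read ids removed by the second pass) and `seed`.
#' @export
train_cnn <- function(labeled_reads, spec = cnn_spec(), tspec = train_spec(),
                      seed = 1L) {
  stopifnot(is.data.frame(labeled_reads), "content" %in% names(labeled_reads))
  if (length(unique(labeled_reads$content)) < 2L) {
    stop("training requires at least 2 distinct content levels")
  }
  tw <- build_training_windows(labeled_reads, spec)
  pass1 <- sgd_pass(tw$X, tw$y, spec, tspec, seed)
  history <- dplyr::mutate(pass1$history, pass = 1L)
  weights <- pass1$w
  dropped <- character(0)
  if (tspec$two_pass) {
    pred <- cnn_predict_array(weights, spec, tw$X)
    read_pred <- tapply(pred, tw$read_id, mean)
    labels <- stats::setNames(labeled_reads$content, labeled_reads$read_id)
    for (lv in unique(labels[labels >= tspec$relabel_content])) {
      rich <- names(labels)[labels == lv]
      rich <- rich[rich %in% names(read_pred)]
      if (length(rich) < 4L) next
      km <- stats::kmeans(as.numeric(read_pred[rich]), centers = 2L,
                          nstart = 5L)
      if (abs(diff(km$centers)) > tspec$relabel_gap) {
        low <- which.min(km$centers)
        dropped <- c(dropped, rich[km$cluster == low])
      }
    }
    if (length(dropped)) {
      keep <- !(tw$read_id %in% dropped)
      pass2 <- sgd_pass(tw$X[keep, , , drop = FALSE], tw$y[keep], spec,
                        tspec, seed + 1L)
      weights <- pass2$w
      history <- dplyr::bind_rows(history,
                                  dplyr::mutate(pass2$history, pass = 2L))
    }
  }
  structure(list(spec = spec, tspec = tspec, weights = weights,
                 history = history, dropped = dropped, seed = seed),
            class = "brdu_cnn")
}

#' @export
print.brdu_cnn <- function(x, ...) {
  cat("<brdu_cnn> window", x$spec$window, "| epochs run:",
      nrow(x$history), "| best val loss:",
      format(min(x$history$val_loss), digits = 4), "\n")
  invisible(x)
}

#' @rdname train_cnn
#' @param x,object A `brdu_cnn`.
#' @param ... Unused.
#' @export
tidy.brdu_cnn <- function(x, ...) x$history

#' @rdname train_cnn
#' @export
glance.brdu_cnn <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 passes = max(x$history$pass),
                 val_loss = min(x$history$val_loss),
                 n_dropped = length(x$dropped))
}

#' Predict window-level BrdU content
#'
#' @param object A trained `brdu_cnn`.
#' @param newdata A `(n, window, 5)` array of window features.
#' @param ... Unused.
#' @return Numeric vector of content fractions in `[0, 1]`.
#' @export
predict.brdu_cnn <- function(object, newdata, ...) {
  cnn_predict_array(object$weights, object$spec, newdata)
}

#' Per-read mean BrdU content from the convolutional estimator
#'
#' @param reads Reads tibble.
#' @param estimator A trained `brdu_cnn`.
#' @return Tibble with `read_id` and `content_hat` (reads shorter than
#'   one window are skipped).
#' @export
predict_read_content <- function(reads, estimator) {
  spec <- estimator$spec
  shifts <- read_shifts(reads)
  out <- purrr::map(seq_len(nrow(reads)), function(i) {
    nt <- length(shifts[[i]])
    if (nt < spec$window) return(NULL)
    starts <- seq(1L, nt - spec$window + 1L, by = spec$window)
    feats <- read_features(reads$bases[[i]], shifts[[i]])
    X <- stack_windows(feats, starts, spec$window)
    tibble::tibble(read_id = reads$read_id[[i]],
                   content_hat = mean(predict(estimator, X)))
  })
  dplyr::bind_rows(out)
}

#' BrdU-content profile of a read from the convolutional estimator
#'
#' Evaluates overlapping windows shifted by the spec's stride (plus a
#' final window flush with the read end) and reports, for every full
#' 10-transition segment, the mean prediction over all windows fully
#' containing it.  Reads shorter than one window yield an empty profile.
#'
#' @param reads Reads tibble.
#' @param estimator A trained `brdu_cnn`.
#' @return Profile tibble with `read_id`, `chrom`, `position` (segment
#'   center, 0-based reference coordinate), `value`.
#' @export
call_cnn <- function(reads, estimator) {
  spec <- estimator$spec
  W <- spec$window; st <- spec$stride
  shifts <- read_shifts(reads)
  out <- purrr::map(seq_len(nrow(reads)), function(i) {
    nt <- length(shifts[[i]])
    if (nt < W) {
      message("read ", reads$read_id[[i]], " shorter than one window; skipped")
      return(NULL)
    }
    starts <- unique(c(seq(1L, nt - W + 1L, by = st), nt - W + 1L))
    feats <- read_features(reads$bases[[i]], shifts[[i]])
    preds <- predict(estimator, stack_windows(feats, starts, W))
    n_seg <- nt %/% st
    seg_lo <- (seq_len(n_seg) - 1L) * st + 1L
    seg_hi <- seg_lo + st - 1L
    value <- vapply(seq_len(n_seg), function(j) {
      covering <- starts <= seg_lo[j] & (starts + W - 1L) >= seg_hi[j]
      if (!any(covering)) return(NA_real_)
      mean(preds[covering])
    }, numeric(1))
    keep <- !is.na(value)
    tibble::tibble(read_id = reads$read_id[[i]], chrom = reads$chrom[[i]],
                   position = reads$ref_start[[i]] + (seg_lo[keep] + seg_hi[keep]) / 2 - 1,
                   value = value[keep])
  })
  dplyr::bind_rows(out)
}
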