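# Four-branch multi-kernel 1-D CNN for OT-action classification of 200 x 3
# sEMG segments. Parallel branches convolve the time axis with kernels of
# different lengths (the multi-kernel "TextCNN" pattern), each with two
# conv/pool stages; flattened branch features feed two fully connected layers
# with dropout. Implemented directly on base matrix algebra (im2col + BLAS),
# so training is deterministic under a fixed seed.
#
# The 3-electrode axis is preserved through convolution and pooling (kernels
# are k x 1 along time, weights shared across electrodes, depth = incoming
# feature maps), which is the only reading that reproduces the published
# per-layer map sizes and the 1,728-feature flatten.

#' Architecture specification for the action classifier
#'
#' Defaults encode the published geometry: 200 x 3 input; four branches with
#' first-stage kernels 20/16/12/8 (32 filters) and a 12-wide non-overlapping
#' first pooling; second-stage kernels and pooling windows paired per branch.
#' The default second-stage pairing — kernels (2,3,4,5), windows (5,4,3,2)
#' with a common stride of 5 — is the unique configuration (see
#' [search_branch_pairing()]) whose arithmetic reproduces every printed map
#' size: conv2 (14,13,12,12), pool2 (2,2,2,3), flatten (384,384,384,576),
#' total 1728.
#'
#' @param input_len Segment length (samples).
#' @param n_electrodes Number of sEMG channels.
#' @param conv1_kernels,conv1_filters First-stage kernel lengths (per branch)
#'   and filter count.
#' @param pool1_window,pool1_stride First pooling geometry.
#' @param conv2_kernels,conv2_filters Second-stage kernel lengths and filters.
#' @param pool2_windows,pool2_strides Second pooling geometry per branch.
#' @param fc_hidden Width of the hidden fully connected layer.
#' @param n_classes Output classes.
#' @param dropout_p Dropout probability on both fully connected layers.
#' @return Object of class `textcnn_spec`.
#' @export
textcnn_spec <- function(input_len = 200, n_electrodes = 3,
                         conv1_kernels = c(20, 16, 12, 8), conv1_filters = 32,
                         pool1_window = 12, pool1_stride = 12,
                         conv2_kernels = c(2, 3, 4, 5), conv2_filters = 64,
                         pool2_windows = c(5, 4, 3, 2),
                         pool2_strides = c(5, 5, 5, 5),
                         fc_hidden = 128, n_classes = 4, dropout_p = 0.5) {
  stop_if(length(conv1_kernels) != length(conv2_kernels) ||
            length(conv1_kernels) != length(pool2_windows) ||
            length(pool2_windows) != length(pool2_strides),
          "per-branch parameter vectors must have equal length")
  stop_if(any(c(conv1_kernels, conv2_kernels, pool1_window, pool2_windows,
                pool2_strides, pool1_stride) < 1),
          "kernel and window lengths must be >= 1")
  structure(list(input_len = input_len, n_electrodes = n_electrodes,
                 conv1_kernels = conv1_kernels, conv1_filters = conv1_filters,
                 pool1_window = pool1_window, pool1_stride = pool1_stride,
                 conv2_kernels = conv2_kernels, conv2_filters = conv2_filters,
                 pool2_windows = pool2_windows, pool2_strides = pool2_strides,
                 fc_hidden = fc_hidden, n_classes = n_classes,
                 dropout_p = dropout_p),
            class = "textcnn_spec")
}

pool_out_len <- function(len, window, stride) {
  if (len < window) 0L else (len - window) %/% stride + 1L
}

#' Per-layer, per-branch feature-shape table
#'
#' Propagates valid-convolution and pooling arithmetic through every branch:
#' conv length = in - kernel + 1; pool length = floor((in - window)/stride)+1
#' (equal to floor(in / window) for non-overlapping pooling); flattened
#' features per branch = filters x length x electrodes. Also reports, for
#' audit, the shapes under the naive reading that pairs the printed
#' second-stage kernels and windows in printed order with non-overlapping
#' pooling — which does not reproduce the printed sizes.
#'
#' @param spec A [textcnn_spec()].
#' @return `list(table, total, naive_inorder)`; `table` has one row per
#'   branch, `total` is the summed flattened feature count.
#' @examples
#' compute_feature_shapes(textcnn_spec())$total  # 1728
#' @export
compute_feature_shapes <- function(spec = textcnn_spec()) {
  stopifnot(inherits(spec, "textcnn_spec"))
  nb <- length(spec$conv1_kernels)
  rows <- lapply(seq_len(nb), function(i) {
    c1 <- spec$input_len - spec$conv1_kernels[i] + 1L
    stop_if(c1 < 1, sprintf("branch %d conv1: kernel %d longer than input %d",
                            i, spec$conv1_kernels[i], spec$input_len))
    p1 <- pool_out_len(c1, spec$pool1_window, spec$pool1_stride)
    stop_if(p1 < 1, sprintf("branch %d pool1: window %d longer than input %d",
                            i, spec$pool1_window, c1))
    c2 <- p1 - spec$conv2_kernels[i] + 1L
    stop_if(c2 < 1, sprintf("branch %d conv2: kernel %d longer than input %d",
                            i, spec$conv2_kernels[i], p1))
    p2 <- pool_out_len(c2, spec$pool2_windows[i], spec$pool2_strides[i])
    stop_if(p2 < 1, sprintf("branch %d pool2: window %d longer than input %d",
                            i, spec$pool2_windows[i], c2))
    data.frame(branch = i, conv1_kernel = spec$conv1_kernels[i],
               conv1_len = c1, pool1_len = p1,
               conv2_kernel = spec$conv2_kernels[i], conv2_len = c2,
               pool2_window = spec$pool2_windows[i],
               pool2_stride = spec$pool2_strides[i], pool2_len = p2,
               flatten = spec$conv2_filters * p2 * spec$n_electrodes)
  })
  tab <- do.call(rbind, rows)
  naive <- data.frame(
    branch = seq_len(nb),
    conv2_kernel = sort(spec$conv2_kernels, decreasing = TRUE),
    conv2_len = tab$pool1_len - sort(spec$conv2_kernels, decreasing = TRUE) + 1L
  )
  naive$pool2_window <- sort(spec$pool2_windows, decreasing = TRUE)
  naive$pool2_len <- mapply(pool_out_len, naive$conv2_len,
                            naive$pool2_window, naive$pool2_window)
  list(table = tab, total = sum(tab$flatten), naive_inorder = naive)
}

#' Exhaustive search for the branch pairing that reproduces printed map sizes
#'
#' Enumerates all assignments of the four second-stage kernels and the four
#' second-stage pooling windows to branches, under non-overlapping pooling
#' (stride = window) and under every common stride 2..12, and returns the
#' configurations whose conv2 and pool2 lengths equal the targets.
#'
#' @param target_conv2,target_pool2 Target per-branch lengths.
#' @param kernels,windows Values to permute.
#' @param pool1_len First-pooling output lengths per branch.
#' @return Data frame of matching configurations (possibly empty), one row
#'   per match, with columns `k1..k4`, `w1..w4`, `stride` (`NA` =
#'   non-overlapping).
#' @export
search_branch_pairing <- function(target_conv2 = c(14, 13, 12, 12),
                                  target_pool2 = c(2, 2, 2, 3),
                                  kernels = c(5, 4, 3, 2),
                                  windows = c(5, 4, 3, 2),
                                  pool1_len = c(15, 15, 15, 16)) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  hits <- list()
  for (kp in perms(kernels)) {
    c2 <- pool1_len - kp + 1L
    if (any(c2 != target_conv2)) next
    for (wp in perms(windows)) {
      strides <- c(list(wp), lapply(2:12, function(s) rep(s, length(wp))))
      for (si in seq_along(strides)) {
        s <- strides[[si]]
        p2 <- mapply(pool_out_len, c2, wp, s)
        if (all(p2 == target_pool2)) {
          hits[[length(hits) + 1L]] <- data.frame(
            t(stats::setNames(kp, paste0("k", seq_along(kp)))),
            t(stats::setNames(wp, paste0("w", seq_along(wp)))),
            stride = if (si == 1L) NA_integer_ else s[1])
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(k1 = integer(0), k2 = integer(0), k3 = integer(0),
                      k4 = integer(0), w1 = integer(0), w2 = integer(0),
                      w3 = integer(0), w4 = integer(0), stride = integer(0)))
  }
  do.call(rbind, hits)
}

# ---- layer primitives (im2col convolution, max pooling, dense) -------------

# X: array (C_in, L, N); W: (C_out, C_in * k). Valid convolution along L.
conv1d_forward <- function(X, W, b, k) {
  d <- dim(X); C_in <- d[1]; L <- d[2]; N <- d[3]
  L_out <- L - k + 1L
  Xc <- matrix(0, C_in * k, L_out * N)
  for (o in seq_len(k)) {
    sl <- X[, o:(o + L_out - 1L), , drop = FALSE]
    dim(sl) <- c(C_in, L_out * N)
    Xc[((o - 1L) * C_in + 1L):(o * C_in), ] <- sl
  }
  Y <- W %*% Xc + b
  dim(Y) <- c(nrow(W), L_out, N)
  list(Y = Y, Xc = Xc, dims = c(C_in, L, N, L_out, k))
}

conv1d_backward <- function(dY, W, cache) {
  C_in <- cache$dims[1]; L <- cache$dims[2]; N <- cache$dims[3]
  L_out <- cache$dims[4]; k <- cache$dims[5]
  dYm <- dY; dim(dYm) <- c(dim(dY)[1], L_out * N)
  dW <- dYm %*% t(cache$Xc)
  db <- rowSums(dYm)
  dXc <- t(W) %*% dYm
  dX <- array(0, c(C_in, L, N))
  for (o in seq_len(k)) {
    sl <- dXc[((o - 1L) * C_in + 1L):(o * C_in), , drop = FALSE]
    dim(sl) <- c(C_in, L_out, N)
    dX[, o:(o + L_out - 1L), ] <- dX[, o:(o + L_out - 1L), , drop = FALSE] + sl
  }
  list(dX = dX, dW = dW, db = db)
}

maxpool_forward <- function(X, window, stride) {
  d <- dim(X); C <- d[1]; L <- d[2]; N <- d[3]
  L_out <- pool_out_len(L, window, stride)
  starts <- seq(1L, by = stride, length.out = L_out)
  Y <- array(-Inf, c(C, L_out, N))
  amax <- array(1L, c(C, L_out, N))
  for (o in seq_len(window)) {
    cand <- X[, starts + o - 1L, , drop = FALSE]
    upd <- cand > Y
    Y[upd] <- cand[upd]
    amax[upd] <- o
  }
  list(Y = Y, amax = amax, starts = starts, in_dim = d,
       window = window)
}

maxpool_backward <- function(dY, cache) {
  dX <- array(0, cache$in_dim)
  for (o in seq_len(cache$window)) {
    mask <- cache$amax == o
    if (!any(mask)) next
    cols <- cache$starts + o - 1L
    sub <- dX[, cols, , drop = FALSE]
    sub[mask] <- sub[mask] + dY[mask]
    dX[, cols, ] <- sub
  }
  dX
}

relu <- function(X) {
  X[X < 0] <- 0
  X
}

# ---- model -----------------------------------------------------------------

init_mat <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build an initialized action-classifier network
#'
#' @param spec A [textcnn_spec()].
#' @param dropout_p Dropout probability override (default from `spec`).
#' @param seed Integer seed; the same seed yields identical initial
#'   parameters.
#' @return Object of class `textcnn_model`.
#' @export
build_model <- function(spec = textcnn_spec(), dropout_p = NULL, seed = 1) {
  stopifnot(inherits(spec, "textcnn_spec"))
  shapes <- compute_feature_shapes(spec)
  if (!is.null(dropout_p)) spec$dropout_p <- dropout_p
  with_seed(seed, {
    branches <- lapply(seq_along(spec$conv1_kernels), function(i) {
      k1 <- spec$conv1_kernels[i]; k2 <- spec$conv2_kernels[i]
      list(
        W1 = init_mat(spec$conv1_filters, k1, k1),
        b1 = numeric(spec$conv1_filters),
        W2 = init_mat(spec$conv2_filters, spec$conv1_filters * k2,
                      spec$conv1_filters * k2),
        b2 = numeric(spec$conv2_filters)
      )
    })
    model <- list(
      spec = spec, shapes = shapes, branches = branches,
      Wf1 = init_mat(spec$fc_hidden, shapes$total, shapes$total),
      bf1 = numeric(spec$fc_hidden),
      Wf2 = init_mat(spec$n_classes, spec$fc_hidden, spec$fc_hidden),
      bf2 = numeric(spec$n_classes)
    )
    structure(model, class = "textcnn_model")
  })
}

# Accepts a list of 200 x 3 matrices or an array (B, 200, 3); returns the
# internal layout: array (1, L, 3 * B) with electrode-major sequence index.
as_input_array <- function(x, spec) {
  if (is.list(x)) {
    B <- length(x)
    arr <- array(0, c(B, spec$input_len, spec$n_electrodes))
    for (i in seq_len(B)) arr[i, , ] <- x[[i]]
    x <- arr
  }
  d <- dim(x)
  stop_if(length(d) != 3 || d[2] != spec$input_len ||
            d[3] != spec$n_electrodes,
          sprintf("input must be B x %d x %d", spec$input_len,
                  spec$n_electrodes))
  B <- d[1]
  S <- array(0, c(1, spec$input_len, spec$n_electrodes * B))
  for (e in seq_len(spec$n_electrodes)) {
    S[1, , (seq_len(B) - 1L) * spec$n_electrodes + e] <- t(x[, , e])
  }
  list(S = S, B = B)
}

model_forward <- function(model, S, B, training = FALSE) {
  spec <- model$spec
  E <- spec$n_electrodes
  caches <- vector("list", length(model$branches))
  feats <- vector("list", length(model$branches))
  for (i in seq_along(model$branches)) {
    br <- model$branches[[i]]
    c1 <- conv1d_forward(S, br$W1, br$b1, spec$conv1_kernels[i])
    r1 <- relu(c1$Y)
    p1 <- maxpool_forward(r1, spec$pool1_window, spec$pool1_stride)
    c2 <- conv1d_forward(p1$Y, br$W2, br$b2, spec$conv2_kernels[i])
    r2 <- relu(c2$Y)
    p2 <- maxpool_forward(r2, spec$pool2_windows[i], spec$pool2_strides[i])
    # flatten per original sample: (C_out, p2_len, E) blocks per sample
    d <- dim(p2$Y)  # (C, L2, E*B); sequence index is electrode-major per sample
    Yb <- p2$Y
    dim(Yb) <- c(d[1] * d[2] * E, B)
    feats[[i]] <- Yb
    caches[[i]] <- list(c1 = c1, r1 = (c1$Y > 0), p1 = p1, c2 = c2,
                        r2 = (c2$Y > 0), p2 = p2, fdim = d)
  }
  F_all <- do.call(rbind, feats)
  drop1 <- NULL; drop2 <- NULL
  Fd <- F_all
  if (training && spec$dropout_p > 0) {
    keep <- 1 - spec$dropout_p
    drop1 <- matrix(stats::runif(length(F_all)) < keep, nrow(F_all)) / keep
    Fd <- F_all * drop1
  }
  H_pre <- model$Wf1 %*% Fd + model$bf1
  H <- relu(H_pre)
  Hd <- H
  if (training && spec$dropout_p > 0) {
    keep <- 1 - spec$dropout_p
    drop2 <- matrix(stats::runif(length(H)) < keep, nrow(H)) / keep
    Hd <- H * drop2
  }
  logits <- model$Wf2 %*% Hd + model$bf2
  list(logits = logits, caches = caches, F_all = F_all, Fd = Fd,
       H_pre = H_pre, H = H, Hd = Hd, drop1 = drop1, drop2 = drop2, B = B)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  sweep(ez, 2, colSums(ez), "/")
}

model_backward <- function(model, fwd, y) {
  spec <- model$spec
  B <- fwd$B
  P <- softmax_cols(fwd$logits)
  Yh <- matrix(0, spec$n_classes, B)
  Yh[cbind(y, seq_len(B))] <- 1
  dLogits <- (P - Yh) / B
  grads <- list()
  grads$Wf2 <- dLogits %*% t(fwd$Hd)
  grads$bf2 <- rowSums(dLogits)
  dHd <- t(model$Wf2) %*% dLogits
  if (!is.null(fwd$drop2)) dHd <- dHd * fwd$drop2
  dH <- dHd * (fwd$H_pre > 0)
  grads$Wf1 <- dH %*% t(fwd$Fd)
  grads$bf1 <- rowSums(dH)
  dFd <- t(model$Wf1) %*% dH
  if (!is.null(fwd$drop1)) dFd <- dFd * fwd$drop1
  # split features back into branches
  offs <- 0L
  grads$branches <- vector("list", length(model$branches))
  for (i in seq_along(model$branches)) {
    cache <- fwd$caches[[i]]
    d <- cache$fdim
    nfeat <- d[1] * d[2] * spec$n_electrodes
    dFb <- dFd[(offs + 1L):(offs + nfeat), , drop = FALSE]
    offs <- offs + nfeat
    dP2 <- dFb
    dim(dP2) <- d
    dR2 <- maxpool_backward(dP2, cache$p2)
    dC2 <- dR2 * cache$r2
    bw2 <- conv1d_backward(dC2, model$branches[[i]]$W2, cache$c2)
    dR1 <- maxpool_backward(bw2$dX, cache$p1)
    dC1 <- dR1 * cache$r1
    bw1 <- conv1d_backward(dC1, model$branches[[i]]$W1, cache$c1)
    grads$branches[[i]] <- list(W1 = bw1$dW, b1 = bw1$db,
                                W2 = bw2$dW, b2 = bw2$db)
  }
  loss <- -mean(log(pmax(colSums(P * Yh), 1e-12)))
  list(grads = grads, loss = loss, probs = P)
}

# ---- training --------------------------------------------------------------

flatten_params <- function(model) {
  out <- list(Wf1 = model$Wf1, bf1 = model$bf1, Wf2 = model$Wf2,
              bf2 = model$bf2)
  for (i in seq_along(model$branches)) {
    for (nm in names(model$branches[[i]])) {
      out[[paste0("br", i, "_", nm)]] <- model$branches[[i]][[nm]]
    }
  }
  out
}

apply_params <- function(model, params) {
  model$Wf1 <- params$Wf1; model$bf1 <- params$bf1
  model$Wf2 <- params$Wf2; model$bf2 <- params$bf2
  for (i in seq_along(model$branches)) {
    for (nm in names(model$branches[[i]])) {
      model$branches[[i]][[nm]] <- params[[paste0("br", i, "_", nm)]]
    }
  }
  model
}

grads_as_params <- function(grads) {
  out <- list(Wf1 = grads$Wf1, bf1 = grads$bf1, Wf2 = grads$Wf2,
              bf2 = grads$bf2)
  for (i in seq_along(grads$branches)) {
    for (nm in names(grads$branches[[i]])) {
      out[[paste0("br", i, "_", nm)]] <- grads$branches[[i]][[nm]]
    }
  }
  out
}

#' Train the action classifier
#'
#' Mini-batch Adam on the softmax cross-entropy objective. Training is
#' deterministic for a fixed seed on a given machine (all randomness — batch
#' shuffling and dropout — flows through R's RNG).
#'
#' @param model A [build_model()] network.
#' @param x Training segments: list of `200 x 3` matrices or array
#'   `(B, 200, 3)`.
#' @param y Integer action labels 1--4 (length B).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss.
#' @return `list(model, history)`; `history` is a data frame with one row per
#'   epoch (`epoch`, `loss`, `accuracy`).
#' @export
train_classifier <- function(model, x, y, epochs = 100, lr = 1e-3,
                             batch_size = 32, seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "textcnn_model"))
  spec <- model$spec
  inp <- as_input_array(x, spec)
  y <- as.integer(y)
  stop_if(length(y) != inp$B, "label count must match segment count")
  stop_if(!all(y %in% seq_len(spec$n_classes)), "labels must be in 1..n_classes")
  stop_if(!all(seq_len(spec$n_classes) %in% y),
          "every class must appear in the training set")
  E <- spec$n_electrodes
  params <- flatten_params(model)
  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(inp$B)
      ep_loss <- 0; ep_correct <- 0L
      nb <- ceiling(inp$B / batch_size)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, inp$B)]
        scol <- as.vector(t(outer(idx - 1L, seq_len(E), function(a, b)
          a * E + b)))
        Sb <- inp$S[, , scol, drop = FALSE]
        model_cur <- apply_params(model, params)
        fwd <- model_forward(model_cur, Sb, length(idx), training = TRUE)
        bwd <- model_backward(model_cur, fwd, y[idx])
        g <- grads_as_params(bwd$grads)
        t_step <- t_step + 1L
        for (nm in names(params)) {
          m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g[[nm]]
          v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g[[nm]]^2
          mhat <- m_state[[nm]] / (1 - beta1^t_step)
          vhat <- v_state[[nm]] / (1 - beta2^t_step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + bwd$loss * length(idx)
        ep_correct <- ep_correct +
          sum(apply(bwd$probs, 2, which.max) == y[idx])
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = ep_loss / inp$B,
                                  accuracy = ep_correct / inp$B))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                        ep_loss / inp$B, ep_correct / inp$B))
      }
    }
  })
  list(model = apply_params(model, params), history = history)
}

#' Predict action labels for segments
#'
#' @param object A trained `textcnn_model`.
#' @param x Segments (list of `200 x 3` matrices or array `(B, 200, 3)`).
#' @param type `"class"` for integer labels 1--4, `"prob"` for a B x 4
#'   probability matrix.
#' @param ... Unused.
#' @export
predict.textcnn_model <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  inp <- as_input_array(x, object$spec)
  fwd <- model_forward(object, inp$S, inp$B, training = FALSE)
  P <- softmax_cols(fwd$logits)
  if (type == "prob") return(t(P))
  apply(P, 2, which.max)
}

#' Stratified train/test split
#'
#' Disjoint, exhaustive, stratified by label and reproducible under the seed.
#' The test set receives `floor((1 - train_frac) * N)` items, apportioned to
#' classes by largest remainder so the overall test size is exact.
#'
#' @param labels Integer class labels.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @param n_classes Number of classes that must all be present.
#' @return `list(train, test)` of index vectors.
#' @examples
#' sp <- split_dataset(rep(1:4, each = 134), seed = 1)
#' length(sp$test)  # 107
#' @export
split_dataset <- function(labels, train_frac = 0.8, seed = 1, n_classes = 4) {
  labels <- as.integer(labels)
  stop_if(length(labels) < n_classes, "need at least one item per class")
  stop_if(!all(seq_len(n_classes) %in% labels),
          paste0("class absent from dataset: ",
                 paste(setdiff(seq_len(n_classes), unique(labels)),
                       collapse = ", ")))
  n <- length(labels)
  # guard against floating-point (1 - 0.8) * 100 = 19.999...
  n_test <- floor((1 - train_frac) * n + 1e-9)
  counts <- tabulate(labels, n_classes)
  quota <- (1 - train_frac) * counts
  base <- floor(quota + 1e-9)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  with_seed(seed, {
    test <- integer(0)
    for (cl in seq_len(n_classes)) {
      members <- which(labels == cl)
      test <- c(test, sample(members, min(base[cl], length(members))))
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Evaluate a classifier on a labeled test set
#'
#' @param model A trained `textcnn_model` (or any function mapping segments
#'   to predicted labels, for oracle tests).
#' @param x Test segments.
#' @param y True labels 1--4.
#' @return Object of class `eval_report`: `list(accuracy, confusion,
#'   per_class_accuracy)`. `confusion` is indexed `[true, predicted]` with
#'   row/col `i` = action `i`.
#' @export
evaluate_classifier <- function(model, x, y) {
  y <- as.integer(y)
  stop_if(length(y) == 0, "test set is empty")
  pred <- if (inherits(model, "textcnn_model")) {
    predict(model, x)
  } else {
    model(x)
  }
  n_classes <- if (inherits(model, "textcnn_model")) {
    model$spec$n_classes
  } else 4L
  confusion <- matrix(0L, n_classes, n_classes,
                      dimnames = list(true = paste0("action", 1:n_classes),
                                      predicted = paste0("action", 1:n_classes)))
  for (i in seq_along(y)) {
    confusion[y[i], pred[i]] <- confusion[y[i], pred[i]] + 1L
  }
  acc <- sum(diag(confusion)) / length(y)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1L)
  structure(list(accuracy = acc, confusion = confusion,
                 per_class_accuracy = per_class),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Save / load a trained model as portable JSON
#'
#' @param model A `textcnn_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "textcnn_model"))
  obj <- list(spec = unclass(model$spec),
              branches = lapply(model$branches, function(b)
                lapply(b, function(p) if (is.matrix(p))
                  list(dim = dim(p), data = as.vector(p))
                  else list(dim = length(p), data = as.vector(p)))),
              Wf1 = list(dim = dim(model$Wf1), data = as.vector(model$Wf1)),
              bf1 = list(dim = length(model$bf1), data = model$bf1),
              Wf2 = list(dim = dim(model$Wf2), data = as.vector(model$Wf2)),
              bf2 = list(dim = length(model$bf2), data = model$bf2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  unpack <- function(p) {
    d <- unlist(p$dim)
    v <- as.numeric(unlist(p$data))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  spec_args <- lapply(obj$spec[names(obj$spec) %in%
                                 names(formals(textcnn_spec))], unlist)
  spec <- do.call(textcnn_spec, spec_args)
  model <- build_model(spec, seed = 0)
  for (i in seq_along(model$branches)) {
    for (nm in names(model$branches[[i]])) {
      model$branches[[i]][[nm]] <- unpack(obj$branches[[i]][[nm]])
    }
  }
  model$Wf1 <- unpack(obj$Wf1); model$bf1 <- unpack(obj$bf1)
  model$Wf2 <- unpack(obj$Wf2); model$bf2 <- unpack(obj$bf2)
  model
}
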