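## The classifier: a small two-convolution-layer network trained on 32x32
## scalogram images.
##
##   input 32x32xC
##   conv 5x5, 16 filters, stride 1, no padding, ReLU  -> 16 @ 28x28
##   max pool 2x2, stride 2                            -> 16 @ 14x14
##   conv 5x5, 64 filters, stride 1, no padding, ReLU  -> 64 @ 10x10
##   max pool 2x2, stride 2                            -> 64 @ 5x5
##   flatten (1600) -> fully connected 1000, ReLU -> softmax over classes
##
## Implemented directly in R: convolutions are im2col gathers followed by
## BLAS matrix products, backpropagation is written out layer by layer, and
## the optimizer is Adadelta. Everything is seeded, so a training run on
## fixed data is exactly reproducible.

#' Architecture specification of the scalogram classifier
#'
#' The layer dimensions are fixed by the 32x32 input contract: valid (unpadded)
#' 5x5 convolutions and 2x2/stride-2 max pooling give the shape trace
#' 32x32 -> 16@28x28 -> 16@14x14 -> 64@10x10 -> 64@5x5 -> 1600 features.
#'
#' @param n_classes number of output classes (>= 2).
#' @param channels input channels, 1 (grayscale) or 3.
#' @param conv1_filters,conv2_filters,kernel,pool,fc_units architecture knobs;
#'   defaults are the reference architecture.
#' @param input_size input image size; must be `c(32, 32)`.
#' @return An object of class `"cnn_spec"` with the layer sizes, the shape
#'   trace and the total parameter count.
#' @examples
#' model_spec(n_classes = 5)$shape_trace
#' @export
model_spec <- function(n_classes, channels = 1, conv1_filters = 16,
                       conv2_filters = 64, kernel = 5, pool = 2,
                       fc_units = 1000, input_size = c(32, 32)) {
  if (n_classes < 2) stop_validation("n_classes must be >= 2")
  if (!channels %in% c(1, 3)) stop_validation("channels must be 1 or 3")
  if (!identical(as.integer(input_size), c(32L, 32L))) {
    stop_validation(
      "input must be 32x32: the architecture contract fixes the shape trace ",
      "32x32 -> 16@28x28 -> 16@14x14 -> 64@10x10 -> 64@5x5")
  }
  c1 <- input_size[1] - kernel + 1L          # 28
  p1 <- c1 %/% pool                          # 14
  c2 <- p1 - kernel + 1L                     # 10
  p2 <- c2 %/% pool                          # 5
  if (c1 %% pool != 0 || c2 %% pool != 0) {
    stop_validation("kernel/pool sizes do not tile the input")
  }
  flat <- as.integer(conv2_filters * p2 * p2)
  n_params <- conv1_filters * kernel^2 * channels + conv1_filters +
    conv2_filters * kernel^2 * conv1_filters + conv2_filters +
    fc_units * flat + fc_units +
    n_classes * fc_units + n_classes
  structure(list(
    n_classes = as.integer(n_classes), channels = as.integer(channels),
    conv1_filters = as.integer(conv1_filters),
    conv2_filters = as.integer(conv2_filters),
    kernel = as.integer(kernel), pool = as.integer(pool),
    fc_units = as.integer(fc_units), input_size = as.integer(input_size),
    conv1_out = as.integer(c1), pool1_out = as.integer(p1),
    conv2_out = as.integer(c2), pool2_out = as.integer(p2),
    flat = as.integer(flat), n_params = n_params,
    shape_trace = list(
      input = c(channels, input_size[1], input_size[2]),
      conv1 = c(conv1_filters, c1, c1), pool1 = c(conv1_filters, p1, p1),
      conv2 = c(conv2_filters, c2, c2), pool2 = c(conv2_filters, p2, p2),
      flatten = flat)
  ), class = "cnn_spec")
}

#' Training configuration
#'
#' Defaults are the reference protocol: Adadelta with learning rate 0.001 and
#' decay coefficient (rho) 0.9, categorical cross-entropy, 50 epochs, batch
#' size 4, with a stratified 20% of the provided training images held out as
#' validation data that is used for monitoring only. Note that classical
#' Adadelta implementations commonly use a learning rate of 1.0; 0.001 trains
#' very slowly and is kept only for protocol fidelity.
#'
#' @param learning_rate Adadelta learning-rate multiplier.
#' @param rho Adadelta decay coefficient (the protocol's "momentum" 0.9).
#' @param epsilon Adadelta conditioning constant.
#' @param epochs number of passes over the training data (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param validation_fraction fraction in `[0, 1)` held out for monitoring.
#' @param seed integer seed controlling initialization, the validation split
#'   and epoch shuffling.
#' @return An object of class `"cnn_train_config"`.
#' @export
train_config <- function(learning_rate = 0.001, rho = 0.9, epsilon = 1e-6,
                         epochs = 50, batch_size = 4,
                         validation_fraction = 0.20, seed = 1) {
  if (epochs < 1) stop_validation("epochs must be >= 1")
  if (batch_size < 1) stop_validation("batch_size must be >= 1")
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop_validation("validation_fraction must be in [0, 1)")
  }
  structure(list(learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "cnn_train_config")
}

## ---- im2col / pooling index tables ---------------------------------------

# Index tables mapping an image vector (column-major h x w x C) to im2col
# patch matrices, and conv-output columns to pooling windows. Computed once
# per spec and cached on the model; batched variants add per-image offsets.
.make_indices <- function(spec) {
  k <- spec$kernel; C <- spec$channels
  h <- spec$input_size[1]
  c1 <- spec$conv1_out; p1 <- spec$pool1_out
  c2 <- spec$conv2_out; p2 <- spec$pool2_out
  f1 <- spec$conv1_filters

  # conv1: patch element (dr, dc, ch) x output position (i, j)
  pos <- expand.grid(i = seq_len(c1), j = seq_len(c1))
  pat <- expand.grid(dr = seq_len(k), dc = seq_len(k), ch = seq_len(C))
  idx1 <- outer(seq_len(nrow(pat)), seq_len(nrow(pos)), function(e, p) {
    (pat$dr[e] + pos$i[p] - 1L) + h * (pat$dc[e] + pos$j[p] - 2L) +
      h * h * (pat$ch[e] - 1L)
  })
  # pool1: window slot a x pooled position (i, j), as columns of the 16 x 784
  # conv1 activation matrix
  ppos <- expand.grid(i = seq_len(p1), j = seq_len(p1))
  slot <- expand.grid(a = 0:1, b = 0:1)
  pidx1 <- outer(1:4, seq_len(nrow(ppos)), function(s, p) {
    (2L * ppos$i[p] - 1L + slot$a[s]) + c1 * (2L * ppos$j[p] - 2L + slot$b[s])
  })
  # conv2: patch element (f, dr, dc) x output position, over the pooled map
  # stored as an f1 x (p1*p1) matrix (channel index fastest)
  pos2 <- expand.grid(i = seq_len(c2), j = seq_len(c2))
  pat2 <- expand.grid(f = seq_len(f1), dr = seq_len(k), dc = seq_len(k))
  idx2 <- outer(seq_len(nrow(pat2)), seq_len(nrow(pos2)), function(e, p) {
    pat2$f[e] + f1 * ((pat2$dr[e] + pos2$i[p] - 2L) +
                        p1 * (pat2$dc[e] + pos2$j[p] - 2L))
  })
  ppos2 <- expand.grid(i = seq_len(p2), j = seq_len(p2))
  pidx2 <- outer(1:4, seq_len(nrow(ppos2)), function(s, p) {
    (2L * ppos2$i[p] - 1L + slot$a[s]) + c2 * (2L * ppos2$j[p] - 2L + slot$b[s])
  })
  list(idx1 = idx1, pidx1 = pidx1, idx2 = idx2, pidx2 = pidx2,
       img_len = h * h * C, c1sq = c1 * c1, p1len = f1 * p1 * p1,
       c2sq = c2 * c2)
}

# batched index tables for a batch of n images
.batch_indices <- function(ix, n) {
  off <- function(m, stride) {
    do.call(cbind, lapply(seq_len(n) - 1L, function(o) m + o * stride))
  }
  list(idx1 = off(ix$idx1, ix$img_len),
       pidx1 = off(ix$pidx1, ix$c1sq),
       idx2 = off(ix$idx2, ix$p1len),
       pidx2 = off(ix$pidx2, ix$c2sq))
}

## ---- parameters -----------------------------------------------------------

# Glorot-uniform initialization, seeded by the caller
.init_params <- function(spec) {
  k <- spec$kernel; C <- spec$channels
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  f1 <- spec$conv1_filters; f2 <- spec$conv2_filters
  list(
    W1 = glorot(f1, k * k * C, k * k * C, k * k * f1), b1 = numeric(f1),
    W2 = glorot(f2, k * k * f1, k * k * f1, k * k * f2), b2 = numeric(f2),
    Wf = glorot(spec$fc_units, spec$flat, spec$flat, spec$fc_units),
    bf = numeric(spec$fc_units),
    Wo = glorot(spec$n_classes, spec$fc_units, spec$fc_units, spec$n_classes),
    bo = numeric(spec$n_classes)
  )
}

## ---- forward / backward ---------------------------------------------------

# forward pass over a batch; xall = concatenated image vectors, bx = batched
# index tables for this batch size. Returns softmax probabilities and (when
# keep = TRUE) the intermediates needed by .backward().
.forward <- function(params, spec, xall, bx, n, keep = FALSE) {
  X1 <- matrix(xall[bx$idx1], nrow = nrow(bx$idx1))
  Z1 <- params$W1 %*% X1 + params$b1
  A1 <- Z1 * (Z1 > 0)
  pool1 <- .maxpool(A1, bx$pidx1, keep)
  X2 <- matrix(as.vector(pool1$P)[bx$idx2], nrow = nrow(bx$idx2))
  Z2 <- params$W2 %*% X2 + params$b2
  A2 <- Z2 * (Z2 > 0)
  pool2 <- .maxpool(A2, bx$pidx2, keep)
  FT <- matrix(as.vector(pool2$P), nrow = spec$flat, ncol = n)
  Zf <- params$Wf %*% FT + params$bf
  Af <- Zf * (Zf > 0)
  Zo <- params$Wo %*% Af + params$bo
  # column-wise softmax, shifted for stability
  Zs <- sweep(Zo, 2, apply(Zo, 2, max), "-")
  E <- exp(Zs)
  probs <- sweep(E, 2, colSums(E), "/")
  out <- list(probs = probs)
  if (keep) {
    out <- c(out, list(X1 = X1, Z1 = Z1, sel1 = pool1$sel, X2 = X2, Z2 = Z2,
                       sel2 = pool2$sel, FT = FT, Zf = Zf, Af = Af))
  }
  out
}

# backward pass; Y = one-hot matrix (n_classes x n). Returns gradients named
# like the parameters.
.backward <- function(params, spec, fwd, bx, Y, n) {
  dZo <- (fwd$probs - Y) / n
  dWo <- tcrossprod(dZo, fwd$Af)
  dbo <- rowSums(dZo)
  dZf <- crossprod(params$Wo, dZo) * (fwd$Zf > 0)
  dWf <- tcrossprod(dZf, fwd$FT)
  dbf <- rowSums(dZf)
  dFT <- crossprod(params$Wf, dZf)
  # unflatten to the pooled conv2 layout and unpool (windows are disjoint)
  dP2 <- matrix(as.vector(dFT), nrow = spec$conv2_filters)
  dA2 <- matrix(0, spec$conv2_filters, ncol(fwd$Z2))
  for (k in 1:4) dA2[, bx$pidx2[k, ]] <- dP2 * fwd$sel2[[k]]
  dZ2 <- dA2 * (fwd$Z2 > 0)
  dW2 <- tcrossprod(dZ2, fwd$X2)
  db2 <- rowSums(dZ2)
  dX2 <- crossprod(params$W2, dZ2)
  # col2im scatter back to the pooled conv1 map; indices are distinct within
  # each patch-element row, so row-wise accumulation is exact
  dP1vec <- numeric(spec$conv1_filters * spec$pool1_out^2 * n)
  for (r in seq_len(nrow(bx$idx2))) {
    ii <- bx$idx2[r, ]
    dP1vec[ii] <- dP1vec[ii] + dX2[r, ]
  }
  dP1 <- matrix(dP1vec, nrow = spec$conv1_filters)
  dA1 <- matrix(0, spec$conv1_filters, ncol(fwd$Z1))
  for (k in 1:4) dA1[, bx$pidx1[k, ]] <- dP1 * fwd$sel1[[k]]
  dZ1 <- dA1 * (fwd$Z1 > 0)
  list(W1 = tcrossprod(dZ1, fwd$X1), b1 = rowSums(dZ1),
       W2 = dW2, b2 = db2, Wf = dWf, bf = dbf, Wo = dWo, bo = dbo)
}

# Adadelta step; state carries the running averages E[g^2] and E[dx^2]
.adadelta_step <- function(params, grads, state, cfg) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$Eg[[nm]] <- cfg$rho * state$Eg[[nm]] + (1 - cfg$rho) * g^2
    dx <- -sqrt(state$Ed[[nm]] + cfg$epsilon) /
      sqrt(state$Eg[[nm]] + cfg$epsilon) * g
    state$Ed[[nm]] <- cfg$rho * state$Ed[[nm]] + (1 - cfg$rho) * dx^2
    params[[nm]] <- params[[nm]] + cfg$learning_rate * dx
  }
  list(params = params, state = state)
}

# max pooling over disjoint 4-column windows; returns pooled matrix and,
# optionally, the per-slot argmax masks (ties broken toward the first slot)
.maxpool <- function(A, pidx, keep) {
  c1 <- A[, pidx[1, ], drop = FALSE]
  c2 <- A[, pidx[2, ], drop = FALSE]
  c3 <- A[, pidx[3, ], drop = FALSE]
  c4 <- A[, pidx[4, ], drop = FALSE]
  P <- pmax(c1, c2, c3, c4)
  if (!keep) return(list(P = P))
  sel <- vector("list", 4L)
  taken <- matrix(FALSE, nrow(P), ncol(P))
  for (k in 1:4) {
    ck <- list(c1, c2, c3, c4)[[k]]
    sk <- (ck == P) & !taken
    taken <- taken | sk
    sel[[k]] <- sk
  }
  list(P = P, sel = sel)
}

## ---- image coercion -------------------------------------------------------

# Coerce a list of scalogram images (or an array) into a flat numeric matrix
# (img_len x n) plus labels. Accepts h x w x n or h x w x C x n arrays.
.coerce_images <- function(images, spec, labels = NULL) {
  if (is.list(images) && length(images) > 0L &&
      inherits(images[[1L]], "scalogram_image")) {
    if (is.null(labels)) {
      labels <- vapply(images, function(im) im$class_label, character(1))
    }
    mats <- lapply(images, function(im) im$pixels)
  } else if (is.array(images)) {
    nd <- length(dim(images))
    n <- dim(images)[nd]
    mats <- lapply(seq_len(n), function(i) {
      if (nd == 3L) images[, , i] else images[, , , i]
    })
  } else {
    stop_validation("images must be a list of scalogram images or an array")
  }
  h <- spec$input_size[1]; w <- spec$input_size[2]; C <- spec$channels
  xmat <- vapply(mats, function(m) {
    d <- dim(m)
    if (!(identical(d[1:2], c(h, w)) &&
          (length(d) == 2L && C == 1L || length(d) == 3L && d[3] == C))) {
      stop_validation("image shape ", paste(d, collapse = "x"),
                      " does not match model input ", h, "x", w, "x", C)
    }
    as.numeric(m)
  }, numeric(h * w * C))
  list(x = xmat, labels = labels)
}

## ---- construction / training ---------------------------------------------

#' Build an untrained scalogram classifier
#'
#' Initializes the network of [model_spec()] with seeded Glorot-uniform
#' weights. The returned object can be used with [predict()] (deterministic
#' given the seed) or trained with [cnn_train()].
#'
#' @param spec a [model_spec()], or `n_classes` to use defaults.
#' @param seed integer seed for the weight initialization.
#' @return An object of class `"scalocnn_cnn"` with `trained = FALSE`.
#' @examples
#' m <- cnn_build(model_spec(n_classes = 2), seed = 1)
#' @export
cnn_build <- function(spec, seed = 1) {
  if (is.numeric(spec)) spec <- model_spec(n_classes = spec)
  stopifnot(inherits(spec, "cnn_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "cnn-init"))
  structure(list(spec = spec, params = .init_params(spec),
                 indices = .make_indices(spec), classes = NULL,
                 trained = FALSE, history = NULL, seed = as.integer(seed)),
            class = "scalocnn_cnn")
}

#' Train a scalogram classifier
#'
#' `cnn_fit()` is the one-call fitting interface: it builds the network for
#' the classes present in `labels` and trains it. `cnn_train()` trains an
#' existing [cnn_build()] model. Training holds out a stratified
#' `validation_fraction` of the provided images for monitoring only --
#' validation items never update weights -- and optimizes categorical
#' cross-entropy with Adadelta. With a fixed seed and fixed data the run is
#' exactly reproducible (single-threaded).
#'
#' @param images list of [segment_to_input()] images, or an array
#'   `h x w x n` / `h x w x channels x n`.
#' @param labels class labels per image; defaults to the images' own labels.
#' @param spec a [model_spec()]; defaults to the reference architecture sized
#'   to the classes present.
#' @param config a [train_config()].
#' @param channels input channel count used when `spec` is `NULL`.
#' @return An object of class `"scalocnn_cnn"`: the spec, trained parameters,
#'   the class levels, the split sizes (`n_train`, `n_val`) and a per-epoch
#'   `history` data frame (epoch, loss, accuracy, val_loss, val_accuracy).
#' @examples
#' \donttest{
#' ds <- generate_dataset(synthesis_config(n_per_class = 6, seed = 1),
#'                        classes = c("A", "E"))
#' imgs <- dataset_to_inputs(ds, scalogram_config(n_scales = 32))
#' fit <- cnn_fit(imgs, config = train_config(epochs = 2, learning_rate = 1))
#' fit$history
#' }
#' @export
cnn_fit <- function(images, labels = NULL, spec = NULL,
                    config = train_config(), channels = 1) {
  probe <- if (is.null(spec)) model_spec(2, channels = channels) else spec
  co <- .coerce_images(images, probe, labels)
  classes <- sort(unique(co$labels))
  if (length(classes) < 2L) stop_validation("need >= 2 classes to train")
  if (is.null(spec)) {
    spec <- model_spec(length(classes), channels = channels)
  } else if (spec$n_classes != length(classes)) {
    stop_validation("spec has ", spec$n_classes, " output classes but data has ",
                    length(classes))
  }
  model <- cnn_build(spec, seed = config$seed)
  cnn_train(model, images, labels = co$labels, config = config)
}

#' @rdname cnn_fit
#' @param model an untrained (or previously trained) `"scalocnn_cnn"`.
#' @export
cnn_train <- function(model, images, labels = NULL, config = train_config()) {
  stopifnot(inherits(model, "scalocnn_cnn"),
            inherits(config, "cnn_train_config"))
  spec <- model$spec
  co <- .coerce_images(images, spec, labels)
  x <- co$x
  labels <- co$labels
  if (is.null(labels) || anyNA(labels)) {
    stop_validation("every training image needs a class label")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_validation("need >= 2 classes to train")
  if (length(classes) != spec$n_classes) {
    stop_validation("data has ", length(classes), " classes but the model has ",
                    spec$n_classes, " outputs")
  }
  y <- match(labels, classes)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "cnn-train"))

  # stratified validation split (monitoring only)
  n <- ncol(x)
  val_idx <- integer(0)
  if (config$validation_fraction > 0) {
    small <- classes[tabulate(y, length(classes)) < 2L]
    if (length(small) > 0L) {
      stop_validation("class(es) with fewer than 2 images cannot be split for ",
                      "validation: ", paste(small, collapse = ", "))
    }
    for (k in seq_along(classes)) {
      members <- which(y == k)
      n_val_k <- round(length(members) * config$validation_fraction)
      if (n_val_k > 0) {
        val_idx <- c(val_idx, sample(members, n_val_k))
      }
    }
    val_idx <- sort(val_idx)
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  log_info(sprintf("stage=train n_train=%d n_val=%d classes=%s",
                   length(train_idx), length(val_idx),
                   paste(classes, collapse = ",")))

  params <- model$params
  state <- list(Eg = lapply(params, function(p) p * 0),
                Ed = lapply(params, function(p) p * 0))
  ix <- model$indices
  bx_cache <- list()
  bx_for <- function(m) {
    key <- as.character(m)
    if (is.null(bx_cache[[key]])) bx_cache[[key]] <<- .batch_indices(ix, m)
    bx_cache[[key]]
  }

  onehot <- function(idx, m) {
    Y <- matrix(0, spec$n_classes, m)
    Y[cbind(idx, seq_len(m))] <- 1
    Y
  }
  eval_set <- function(idx) {
    if (length(idx) == 0L) return(c(NA_real_, NA_real_))
    loss <- 0; correct <- 0
    for (start in seq(1L, length(idx), by = 32L)) {
      chunk <- idx[start:min(start + 31L, length(idx))]
      m <- length(chunk)
      fw <- .forward(params, spec, as.vector(x[, chunk]), bx_for(m), m)
      p_true <- fw$probs[cbind(y[chunk], seq_len(m))]
      loss <- loss + sum(-log(pmax(p_true, 1e-12)))
      correct <- correct + sum(apply(fw$probs, 2, which.max) == y[chunk])
    }
    c(loss / length(idx), correct / length(idx))
  }

  hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                     accuracy = NA_real_, val_loss = NA_real_,
                     val_accuracy = NA_real_)
  for (ep in seq_len(config$epochs)) {
    order_ep <- sample(train_idx)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, length(order_ep), by = config$batch_size)) {
      batch <- order_ep[start:min(start + config$batch_size - 1L,
                                  length(order_ep))]
      m <- length(batch)
      bx <- bx_for(m)
      fw <- .forward(params, spec, as.vector(x[, batch]), bx, m, keep = TRUE)
      Y <- onehot(y[batch], m)
      p_true <- fw$probs[cbind(y[batch], seq_len(m))]
      ep_loss <- ep_loss + sum(-log(pmax(p_true, 1e-12)))
      ep_correct <- ep_correct + sum(apply(fw$probs, 2, which.max) == y[batch])
      grads <- .backward(params, spec, fw, bx, Y, m)
      upd <- .adadelta_step(params, grads, state, config)
      params <- upd$params
      state <- upd$state
    }
    hist$loss[ep] <- ep_loss / length(train_idx)
    hist$accuracy[ep] <- ep_correct / length(train_idx)
    if (length(val_idx) > 0L) {
      v <- eval_set(val_idx)
      hist$val_loss[ep] <- v[1]
      hist$val_accuracy[ep] <- v[2]
    }
    log_info(sprintf(
      "stage=train epoch=%d/%d loss=%.4f acc=%.3f val_loss=%s val_acc=%s",
      ep, config$epochs, hist$loss[ep], hist$accuracy[ep],
      ifelse(is.na(hist$val_loss[ep]), "-", sprintf("%.4f", hist$val_loss[ep])),
      ifelse(is.na(hist$val_accuracy[ep]), "-",
             sprintf("%.3f", hist$val_accuracy[ep]))))
  }

  model$params <- params
  model$classes <- classes
  model$trained <- TRUE
  model$history <- hist
  model$config <- config
  model$n_train <- length(train_idx)
  model$n_val <- length(val_idx)
  model
}

#' Predict class probabilities or labels for scalogram images
#'
#' Softmax probabilities are non-negative and sum to one per image; the label
#' prediction is the probability argmax. Deterministic given fixed parameters.
#'
#' @param object a `"scalocnn_cnn"` model.
#' @param images images as in [cnn_fit()].
#' @param type `"class"` for labels (default) or `"prob"` for the probability
#'   matrix (images in rows, classes in columns).
#' @param ... unused.
#' @return Character vector of labels, or a numeric probability matrix.
#' @export
predict.scalocnn_cnn <- function(object, images, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  spec <- object$spec
  co <- .coerce_images(images, spec)
  x <- co$x
  n <- ncol(x)
  probs <- matrix(NA_real_, n, spec$n_classes)
  for (start in seq(1L, n, by = 32L)) {
    chunk <- start:min(start + 31L, n)
    m <- length(chunk)
    bx <- .batch_indices(object$indices, m)
    fw <- .forward(object$params, spec, as.vector(x[, chunk, drop = FALSE]),
                   bx, m)
    probs[chunk, ] <- t(fw$probs)
  }
  classes <- object$classes %||% as.character(seq_len(spec$n_classes))
  colnames(probs) <- classes
  if (type == "prob") return(probs)
  classes[max.col(probs, ties.method = "first")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scalocnn_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<scalocnn_cnn> %s, %d classes, %s parameters\n",
              if (isTRUE(x$trained)) "trained" else "untrained",
              s$n_classes, format(s$n_params, big.mark = ",")))
  tr <- s$shape_trace
  cat(sprintf("  %dx%d -> %d@%dx%d -> %d@%dx%d -> %d@%dx%d -> %d@%dx%d -> %d -> %d -> %d\n",
              s$input_size[1], s$input_size[2],
              tr$conv1[1], tr$conv1[2], tr$conv1[3],
              tr$pool1[1], tr$pool1[2], tr$pool1[3],
              tr$conv2[1], tr$conv2[2], tr$conv2[3],
              tr$pool2[1], tr$pool2[2], tr$pool2[3],
              s$flat, s$fc_units, s$n_classes))
  if (isTRUE(x$trained)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final epoch %d: loss %.4f, accuracy %.3f", h$epoch, h$loss,
                h$accuracy))
    if (!is.na(h$val_accuracy)) {
      cat(sprintf(", val accuracy %.3f", h$val_accuracy))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.scalocnn_cnn <- function(object, ...) {
  print(object)
  s <- object$spec
  k <- s$kernel
  layers <- data.frame(
    layer = c("conv1", "pool1", "conv2", "pool2", "flatten", "fc", "output"),
    output = c(sprintf("%d@%dx%d", s$conv1_filters, s$conv1_out, s$conv1_out),
               sprintf("%d@%dx%d", s$conv1_filters, s$pool1_out, s$pool1_out),
               sprintf("%d@%dx%d", s$conv2_filters, s$conv2_out, s$conv2_out),
               sprintf("%d@%dx%d", s$conv2_filters, s$pool2_out, s$pool2_out),
               as.character(s$flat), as.character(s$fc_units),
               as.character(s$n_classes)),
    parameters = c(s$conv1_filters * (k^2 * s$channels + 1), 0,
                   s$conv2_filters * (k^2 * s$conv1_filters + 1), 0, 0,
                   s$fc_units * (s$flat + 1),
                   s$n_classes * (s$fc_units + 1)))
  print(layers, row.names = FALSE)
  invisible(layers)
}

#' Plot the training history of a fitted classifier
#'
#' @param x a trained `"scalocnn_cnn"`.
#' @param ... passed to [matplot()].
#' @export
plot.scalocnn_cnn <- function(x, ...) {
  if (!isTRUE(x$trained)) stop("model is untrained; nothing to plot")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$accuracy, h$val_accuracy), type = "l",
                    lty = 1, lwd = 2, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", ylim = c(0, 1), ...)
  graphics::legend("bottomright", c("training", "validation"), lty = 1,
                   lwd = 2, col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted classifier
#'
#' The archive is a single RDS file holding parameters, architecture spec,
#' training configuration, class levels and history.
#'
#' @param model a `"scalocnn_cnn"`.
#' @param path archive file path.
#' @return `save_cnn` returns `path` invisibly; `load_cnn` returns the model.
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "scalocnn_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "scalocnn_cnn"))
  model
}
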