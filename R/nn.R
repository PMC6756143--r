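# Trainable 1-D CNN: a compact, CPU-only, matrix-based implementation of the
# architecture in modified_lenet5_spec(). Convolutions are computed by
# unfolding the input into an im2col matrix and multiplying by the filter
# bank; gradients flow back through the same index maps. Optimization is
# Adam on minibatches of the categorical cross-entropy.

CLASS_LEVELS <- c("N", "A")  # output unit 1 = normal, unit 2 = apnea

conv1d_forward <- function(x, w, b, kernel, stride) {
  n <- dim(x)[1]; l <- dim(x)[2]; ch <- dim(x)[3]
  l_out <- (l - kernel) %/% stride + 1L
  starts <- (seq_len(l_out) - 1L) * stride
  tidx <- as.vector(outer(seq_len(kernel), starts, "+"))
  xs <- x[, tidx, , drop = FALSE]
  dim(xs) <- c(n, kernel, l_out, ch)
  xs <- aperm(xs, c(1, 3, 2, 4))
  dim(xs) <- c(n * l_out, kernel * ch)
  y <- xs %*% w
  y <- sweep(y, 2, b, "+")
  dim(y) <- c(n, l_out, ncol(w))
  list(y = y, xcol = xs, starts = starts, in_dim = c(n, l, ch))
}

conv1d_backward <- function(dy, cache, w, kernel) {
  n <- cache$in_dim[1]; l <- cache$in_dim[2]; ch <- cache$in_dim[3]
  l_out <- dim(dy)[2]; f <- dim(dy)[3]
  dym <- dy
  dim(dym) <- c(n * l_out, f)
  dw <- crossprod(cache$xcol, dym)
  db <- colSums(dym)
  dxcol <- dym %*% t(w)
  dim(dxcol) <- c(n, l_out, kernel, ch)
  dx <- array(0, dim = c(n, l, ch))
  for (j in seq_len(kernel)) {
    idx <- cache$starts + j
    dx[, idx, ] <- dx[, idx, ] + dxcol[, , j, ]
  }
  list(dx = dx, dw = dw, db = db)
}

maxpool1d_forward <- function(x, size, stride) {
  n <- dim(x)[1]; l <- dim(x)[2]; ch <- dim(x)[3]
  l_out <- (l - size) %/% stride + 1L
  starts <- (seq_len(l_out) - 1L) * stride
  m <- x[, starts + 1L, , drop = FALSE]
  jstar <- array(1L, dim = dim(m))
  for (j in 2:size) {
    a <- x[, starts + j, , drop = FALSE]
    upd <- a > m
    m[upd] <- a[upd]
    jstar[upd] <- j
  }
  list(y = m, jstar = jstar, starts = starts, in_dim = c(n, l, ch))
}

maxpool1d_backward <- function(dy, cache, size) {
  dx <- array(0, dim = cache$in_dim)
  for (j in seq_len(size)) {
    idx <- cache$starts + j
    sl <- dx[, idx, , drop = FALSE]
    mask <- cache$jstar == j
    sl[mask] <- sl[mask] + dy[mask]
    dx[, idx, ] <- sl
  }
  dx
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build a trainable CNN from an architecture specification
#'
#' Allocates seeded He-initialized weights for every learnable layer of the
#' specification. The resulting handle supports [train_cnn()] and
#' [predict_proba()]; its reported parameter count always equals
#' [count_parameters()] on the same spec.
#'
#' @param spec a `model_spec`, e.g. [modified_lenet5_spec()].
#' @param seed RNG seed for the initialization.
#' @return An object of class `apnea_cnn`.
#' @export
build_model <- function(spec, seed = 1L) {
  shapes <- model_shapes(spec)
  params <- list()
  with_seed(seed, {
    len <- spec$input_length
    ch <- spec$input_channels
    flat <- FALSE
    fan_in <- NULL
    for (ly in spec$layers) {
      if (ly$kind == "conv1d") {
        k <- ly$kernel * ch
        params[[ly$name]] <- list(w = he_init(k, ly$filters, k),
                                  b = numeric(ly$filters))
        len <- layer_output_length(len, ly$kernel, ly$stride, ly$pad)
        ch <- ly$filters
      } else if (ly$kind == "maxpool1d") {
        len <- layer_output_length(len, ly$kernel, ly$stride, ly$pad)
      } else if (ly$kind == "dense") {
        if (!flat) {
          fan_in <- len * ch
          flat <- TRUE
        }
        # softmax head starts near-zero so the untrained network predicts
        # close to the uniform distribution (pre-training loss ~ log K)
        w <- if (identical(ly$activation, "softmax")) {
          matrix(rnorm(fan_in * ly$filters, sd = 0.01), fan_in, ly$filters)
        } else {
          he_init(fan_in, ly$filters, fan_in)
        }
        params[[ly$name]] <- list(w = w, b = numeric(ly$filters))
        fan_in <- ly$filters
      }
    }
  })
  structure(list(spec = spec, params = params, norm = NULL,
                 history = NULL, trained = FALSE, shapes = shapes),
            class = "apnea_cnn")
}

#' @export
print.apnea_cnn <- function(x, ...) {
  pc <- count_parameters(x$spec)
  cat(sprintf("<apnea_cnn> %d-layer 1-D CNN, %d parameters, %s\n",
              length(x$spec$layers), pc$total,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of trainable parameters actually allocated in a model
#'
#' @param model an `apnea_cnn`.
#' @return Integer total over all weight and bias arrays.
#' @export
n_allocated_parameters <- function(model) {
  sum(vapply(model$params,
             function(p) length(p$w) + length(p$b), numeric(1)))
}

apply_norm <- function(model, x) {
  if (is.null(model$norm)) return(x)
  for (c_i in seq_len(dim(x)[3])) {
    x[, , c_i] <- (x[, , c_i] - model$norm$mean[c_i]) / model$norm$sd[c_i]
  }
  x
}

# Forward pass. training = TRUE samples dropout masks from the current RNG
# stream (inverted dropout); otherwise dropout is the identity.
forward_cnn <- function(model, x, training = FALSE, keep_cache = FALSE) {
  caches <- list()
  h <- x
  flat <- FALSE
  for (i in seq_along(model$spec$layers)) {
    ly <- model$spec$layers[[i]]
    cache <- list(kind = ly$kind)
    if (ly$kind == "conv1d") {
      p <- model$params[[ly$name]]
      fw <- conv1d_forward(h, p$w, p$b, ly$kernel, ly$stride)
      cache$conv <- fw[c("xcol", "starts", "in_dim")]
      h <- fw$y
      if (identical(ly$activation, "relu")) {
        cache$pre <- h
        h <- relu(h)
      }
    } else if (ly$kind == "maxpool1d") {
      fw <- maxpool1d_forward(h, ly$kernel, ly$stride)
      cache$pool <- fw[c("jstar", "starts", "in_dim")]
      h <- fw$y
    } else if (ly$kind == "dropout") {
      if (!flat) {
        cache$unflat_dim <- dim(h)
        dim(h) <- c(dim(h)[1], prod(dim(h)[-1]))
        flat <- TRUE
      }
      if (training && ly$rate > 0) {
        mask <- matrix(runif(length(h)) >= ly$rate, nrow(h), ncol(h)) /
          (1 - ly$rate)
        cache$mask <- mask
        h <- h * mask
      }
    } else if (ly$kind == "dense") {
      if (!flat) {
        cache$unflat_dim <- dim(h)
        dim(h) <- c(dim(h)[1], prod(dim(h)[-1]))
        flat <- TRUE
      }
      p <- model$params[[ly$name]]
      cache$x <- h
      h <- sweep(h %*% p$w, 2, p$b, "+")
      if (identical(ly$activation, "relu")) {
        cache$pre <- h
        h <- relu(h)
      } else if (identical(ly$activation, "softmax")) {
        h <- softmax(h)
      }
    }
    if (keep_cache) caches[[i]] <- cache
  }
  list(probs = h, caches = caches)
}

# Backward pass from softmax + cross-entropy: dlogits = (P - Y) * w / N.
backward_cnn <- function(model, caches, probs, y_onehot, sample_w) {
  grads <- list()
  dz <- (probs - y_onehot) * sample_w / nrow(probs)
  layers <- model$spec$layers
  d <- dz
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cache <- caches[[i]]
    if (ly$kind == "dense") {
      if (identical(ly$activation, "relu")) d <- d * (cache$pre > 0)
      p <- model$params[[ly$name]]
      grads[[ly$name]] <- list(w = crossprod(cache$x, d), b = colSums(d))
      d <- d %*% t(p$w)
      if (!is.null(cache$unflat_dim)) dim(d) <- cache$unflat_dim
    } else if (ly$kind == "dropout") {
      if (!is.null(cache$mask)) d <- d * cache$mask
      if (!is.null(cache$unflat_dim)) dim(d) <- cache$unflat_dim
    } else if (ly$kind == "maxpool1d") {
      d <- maxpool1d_backward(d, cache$pool, ly$kernel)
    } else if (ly$kind == "conv1d") {
      if (identical(ly$activation, "relu")) d <- d * (cache$pre > 0)
      p <- model$params[[ly$name]]
      bw <- conv1d_backward(d, cache$conv, p$w, ly$kernel)
      grads[[ly$name]] <- list(w = bw$dw, b = bw$db)
      d <- bw$dx
    }
  }
  grads
}

labels_to_onehot <- function(y) {
  m <- matrix(0, length(y), 2)
  m[cbind(seq_along(y), match(y, CLASS_LEVELS))] <- 1
  m
}

#' Train the CNN by minibatch backpropagation
#'
#' Minimizes the categorical cross-entropy with Adam. Input channels are
#' standardized with training-set means/SDs (stored on the model and applied
#' at prediction time). Dropout is active only during training. With
#' `validation_split > 0` a seeded holdout is used for early stopping; the
#' best-validation-loss weights are restored. The whole run (initial
#' shuffling, dropout masks) is a pure function of `cfg$seed`.
#'
#' @param model an `apnea_cnn` from [build_model()].
#' @param windows a list of `window_tensor`s, or a list with `x`
#'   (`N x L x C` array) and `y` (labels in `c("A", "N")`).
#' @param cfg a [train_config()].
#' @param verbose print a line per epoch.
#' @return The trained model; `model$history` holds per-epoch training (and
#'   validation) losses, with epoch 0 the pre-training loss.
#' @export
train_cnn <- function(model, windows, cfg = train_config(),
                      verbose = FALSE) {
  xy <- if (!is.null(windows$x)) windows else windows_to_array(windows)
  x <- xy$x
  y <- xy$y
  if (length(unique(y)) < 2) {
    stop_validation("training set must contain both classes")
  }
  n <- dim(x)[1]
  with_seed(cfg$seed, {
    model$norm <- list(mean = apply(x, 3, mean),
                       sd = pmax(apply(x, 3, sd), 1e-8))
    xs <- apply_norm(model, x)
    perm <- sample.int(n)
    n_val <- floor(cfg$validation_split * n)
    val_idx <- if (n_val >= 2) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    # guard: keep both classes in the training partition
    if (length(unique(y[tr_idx])) < 2) {
      tr_idx <- perm
      val_idx <- integer(0)
    }
    xtr <- xs[tr_idx, , , drop = FALSE]
    ytr <- y[tr_idx]
    y1h_tr <- labels_to_onehot(ytr)
    w_tr <- if (cfg$class_weights) {
      tab <- table(factor(ytr, levels = CLASS_LEVELS))
      as.numeric(length(ytr) / (2 * tab[ytr]))
    } else rep(1, length(ytr))

    eval_loss <- function(idx_x, idx_y) {
      p <- forward_cnn(model, idx_x, training = FALSE)$probs
      cross_entropy_loss(labels_to_onehot(idx_y), p)
    }

    adam <- list()
    t_step <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    hist_train <- eval_loss(xtr, ytr)
    hist_val <- if (length(val_idx)) eval_loss(xs[val_idx, , , drop = FALSE],
                                               y[val_idx]) else NA_real_
    best_val <- hist_val[1]
    best_params <- model$params
    stall <- 0L

    n_tr <- length(tr_idx)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      batch_starts <- seq(1L, n_tr, by = cfg$batch_size)
      ep_loss <- 0
      for (bs in batch_starts) {
        be <- min(bs + cfg$batch_size - 1L, n_tr)
        bi <- ord[bs:be]
        xb <- xtr[bi, , , drop = FALSE]
        yb <- y1h_tr[bi, , drop = FALSE]
        wb <- w_tr[bi]
        fw <- forward_cnn(model, xb, training = TRUE, keep_cache = TRUE)
        ep_loss <- ep_loss + cross_entropy_loss(yb, fw$probs) * length(bi)
        grads <- backward_cnn(model, fw$caches, fw$probs, yb, wb)
        t_step <- t_step + 1
        for (nm in names(grads)) {
          for (part in c("w", "b")) {
            g <- grads[[nm]][[part]]
            key <- paste0(nm, ".", part)
            if (is.null(adam[[key]])) {
              adam[[key]] <- list(m = g * 0, v = g * 0)
            }
            st <- adam[[key]]
            st$m <- b1 * st$m + (1 - b1) * g
            st$v <- b2 * st$v + (1 - b2) * g^2
            adam[[key]] <- st
            mhat <- st$m / (1 - b1^t_step)
            vhat <- st$v / (1 - b2^t_step)
            model$params[[nm]][[part]] <- model$params[[nm]][[part]] -
              cfg$learning_rate * mhat / (sqrt(vhat) + eps)
          }
        }
      }
      hist_train <- c(hist_train, ep_loss / n_tr)
      if (length(val_idx)) {
        vl <- eval_loss(xs[val_idx, , , drop = FALSE], y[val_idx])
        hist_val <- c(hist_val, vl)
        if (vl < best_val - 1e-6) {
          best_val <- vl
          best_params <- model$params
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$patience) {
            if (verbose) message(sprintf("early stop at epoch %d", epoch))
            break
          }
        }
      }
      if (verbose) {
        message(sprintf("epoch %d: train loss %.4f%s", epoch,
                        hist_train[length(hist_train)],
                        if (length(val_idx))
                          sprintf(", val loss %.4f",
                                  hist_val[length(hist_val)]) else ""))
      }
    }
    if (length(val_idx)) model$params <- best_params
  })
  model$history <- list(epoch = seq_along(hist_train) - 1L,
                        train_loss = hist_train,
                        val_loss = hist_val)
  model$trained <- TRUE
  model$config <- cfg
  model
}

#' Predict per-window apnea probabilities
#'
#' Runs the network in evaluation mode (dropout disabled), so repeated calls
#' give identical output. Hard labels use the 0.5 threshold.
#'
#' @param model a (trained) `apnea_cnn`.
#' @param windows list of `window_tensor`s or a list with `x` array.
#' @return A data.frame of class `prediction_set` with columns `prob_apnea`,
#'   `label`.
#' @export
predict_proba <- function(model, windows) {
  if (length(windows) == 0) {
    return(structure(data.frame(prob_apnea = numeric(0),
                                label = character(0)),
                     class = c("prediction_set", "data.frame")))
  }
  xy <- if (!is.null(windows$x)) windows else windows_to_array(windows)
  x <- apply_norm(model, xy$x)
  p <- forward_cnn(model, x, training = FALSE)$probs
  prob_apnea <- p[, match(APNEA, CLASS_LEVELS)]
  structure(data.frame(prob_apnea = prob_apnea,
                       label = ifelse(prob_apnea >= 0.5, APNEA, NORMAL)),
            class = c("prediction_set", "data.frame"))
}
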