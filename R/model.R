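# The VGG-16-style transfer-learning classifier: 13 convolutional layers
# (3x3, stride 1, ReLU) in five blocks separated by 2x2 stride-2 max-pools,
# the first ten convolutions frozen and the last three fine-tuned, followed
# by a head of three dense+dropout blocks and a 2-way softmax. For a
# 144x144x3 input the pre-flatten feature map is 4x4x512
# (144 -> 72 -> 36 -> 18 -> 9 -> 4).

VGG_FILTERS <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
VGG_POOL_AFTER <- c(2, 4, 7, 10, 13)  # pool follows these conv indices

#' Classifier architecture specification
#'
#' @param input_side input image side in pixels (default 144).
#' @param channels input channels (default 3; grayscale inputs are
#'   replicated).
#' @param frozen_conv number of leading convolutional layers excluded from
#'   optimization (default 10).
#' @param trainable_conv number of trailing fine-tuned convolutional layers;
#'   must satisfy `frozen_conv + trainable_conv = 13`.
#' @param head_widths widths of the three dense layers (default
#'   `c(512, 256, 64)`), each followed by dropout.
#' @param dropout_rate dropout probability after each dense layer
#'   (default 0.5).
#' @param n_classes output classes (default 2: no tumor / tumor).
#' @param width_multiplier scales every convolutional filter count (e.g.
#'   `1/16` builds a reduced model with identical topology for CPU-scale
#'   experiments).
#' @return a `model_spec` list.
#' @export
model_spec <- function(input_side = 144, channels = 3,
                       frozen_conv = 10, trainable_conv = 13 - frozen_conv,
                       head_widths = c(512, 256, 64), dropout_rate = 0.5,
                       n_classes = 2, width_multiplier = 1) {
  n_conv <- length(VGG_FILTERS)
  if (frozen_conv + trainable_conv != n_conv) {
    stop(sprintf("frozen (%d) + trainable (%d) convolutional layers must equal %d",
                 frozen_conv, trainable_conv, n_conv), call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (length(head_widths) != 3L) {
    stop("the head has exactly three dense layers", call. = FALSE)
  }
  if (input_side %/% 2^5 < 1) stop("input too small for five pools", call. = FALSE)
  structure(list(input_side = as.integer(input_side),
                 channels = as.integer(channels),
                 filters = pmax(1L, round(VGG_FILTERS * width_multiplier)),
                 pool_after = VGG_POOL_AFTER,
                 frozen_conv = as.integer(frozen_conv),
                 trainable_conv = as.integer(trainable_conv),
                 head_widths = as.integer(head_widths),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 width_multiplier = width_multiplier),
            class = "model_spec")
}

#' Build the classifier
#'
#' Initializes weights with seeded He-normal draws, or from a saved weight
#' list (e.g. convolutional weights exported from a pretrained backbone of
#' identical layout) via `weights`.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the random initialization.
#' @param weights optional named list of layer weights as produced by
#'   [save_weights()]; layers present in the list are initialized from it.
#' @return a `contourtl_net` object.
#' @export
build_contourtl_net <- function(spec = model_spec(), seed = 0, weights = NULL) {
  layers <- list()
  side <- spec$input_side
  in_ch <- spec$channels
  with_seed(seed, {
    for (i in seq_along(spec$filters)) {
      out_ch <- spec$filters[i]
      fan_in <- 9 * in_ch
      layers[[length(layers) + 1L]] <-
        list(type = "conv", name = paste0("conv", i),
             Wt = matrix(stats::rnorm(fan_in * out_ch, 0, sqrt(2 / fan_in)),
                         fan_in, out_ch),
             b = numeric(out_ch),
             in_ch = in_ch, out_ch = out_ch,
             kernel = c(3L, 3L), stride = 1L,
             trainable = i > spec$frozen_conv)
      in_ch <- out_ch
      if (i %in% spec$pool_after) {
        layers[[length(layers) + 1L]] <-
          list(type = "pool", name = paste0("pool", match(i, spec$pool_after)),
               window = c(2L, 2L), stride = 2L)
        side <- side %/% 2L
      }
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten", name = "flatten",
                                          feature_dim = c(side, side, in_ch))
    n_in <- side * side * in_ch
    for (j in seq_along(spec$head_widths)) {
      n_out <- spec$head_widths[j]
      layers[[length(layers) + 1L]] <-
        list(type = "dense", name = paste0("dense", j),
             W = matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
             b = numeric(n_out), activation = "relu", trainable = TRUE)
      layers[[length(layers) + 1L]] <-
        list(type = "dropout", name = paste0("dropout", j),
             rate = spec$dropout_rate)
      n_in <- n_out
    }
    layers[[length(layers) + 1L]] <-
      list(type = "dense", name = "output",
           W = matrix(stats::rnorm(spec$n_classes * n_in, 0, sqrt(2 / n_in)),
                      spec$n_classes, n_in),
           b = numeric(spec$n_classes), activation = "softmax",
           trainable = TRUE)
  })
  if (!is.null(weights)) {
    for (i in seq_along(layers)) {
      nm <- layers[[i]]$name
      if (!is.null(weights[[nm]])) {
        for (f in intersect(names(weights[[nm]]), c("Wt", "W", "b"))) {
          if (!identical(dim(weights[[nm]][[f]]), dim(layers[[i]][[f]])) &&
              length(weights[[nm]][[f]]) != length(layers[[i]][[f]])) {
            stop("weight shape mismatch for layer ", nm, call. = FALSE)
          }
          layers[[i]][[f]] <- weights[[nm]][[f]]
        }
      }
    }
  }
  structure(list(spec = spec, layers = layers, history = NULL),
            class = "contourtl_net")
}

#' Extract / save model weights
#'
#' @param model a `contourtl_net`.
#' @return named list of layer weight lists.
#' @export
save_weights <- function(model) {
  w <- list()
  for (l in model$layers) {
    if (l$type == "conv") w[[l$name]] <- list(Wt = l$Wt, b = l$b)
    if (l$type == "dense") w[[l$name]] <- list(W = l$W, b = l$b)
  }
  w
}

first_trainable_index <- function(model) {
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (!is.null(l$trainable) && l$trainable) return(i)
  }
  length(model$layers) + 1L
}

# Prepare one image for the network: replicate grayscale to the spec's
# channel count, validate the side, scale to [0, 1].
prep_input <- function(model, img) {
  side <- model$spec$input_side
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (dim(img)[1] != side || dim(img)[2] != side) {
    stop(sprintf("image is %dx%d but the model expects %dx%d",
                 dim(img)[1], dim(img)[2], side, side), call. = FALSE)
  }
  ch <- model$spec$channels
  if (dim(img)[3] == 1L && ch > 1L) {
    img <- array(rep(img, ch), c(dim(img)[1:2], ch))
  } else if (dim(img)[3] != ch) {
    stop(sprintf("image has %d channel(s) but the model expects %d",
                 dim(img)[3], ch), call. = FALSE)
  }
  img / 255
}

# Forward through layers [from, to]; `x` is the input to layer `from`.
# When train = TRUE, dropout is active and caches are kept for layers that
# need gradients.
forward_layers <- function(model, x, from = 1L, to = length(model$layers),
                           train = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq(from, to)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      r <- conv_forward(x, l$Wt, l$b, keep_cache = train)
      x <- r$out
      if (train) caches[[i]] <- r
    } else if (l$type == "pool") {
      r <- pool_forward(x, keep_cache = train)
      x <- r$out
      if (train) caches[[i]] <- r
    } else if (l$type == "flatten") {
      caches[[i]] <- list(in_dim = dim(x))
      x <- as.vector(x)
    } else if (l$type == "dropout") {
      if (train && l$rate > 0) {
        mask <- dropout_mask(length(x), l$rate)
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      }
    } else if (l$type == "dense") {
      r <- dense_forward(x, l$W, l$b, l$activation, keep_cache = train)
      x <- r$out
      if (train) caches[[i]] <- r
    }
  }
  list(out = x, caches = caches)
}

# Backward from the softmax output down to (and including) layer `to`.
# `dz` is the gradient on the output-layer pre-activation (p - onehot).
backward_layers <- function(model, dz, caches, to) {
  n <- length(model$layers)
  grads <- vector("list", n)
  # output dense layer (softmax): gradient arrives on pre-activation
  l <- model$layers[[n]]
  grads[[n]] <- list(dW = tcrossprod(dz, caches[[n]]$a_in), db = dz)
  dx <- drop(crossprod(l$W, dz))
  if (to >= n) return(grads)
  for (i in seq(n - 1L, to)) {
    l <- model$layers[[i]]
    if (l$type == "dense") {
      g <- dense_backward(dx, caches[[i]], l$W, l$activation)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dx <- g$dx
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]])) dx <- dx * caches[[i]]$mask
    } else if (l$type == "flatten") {
      dx <- array(dx, caches[[i]]$in_dim)
    } else if (l$type == "pool") {
      dx <- pool_backward(dx, caches[[i]])
    } else if (l$type == "conv") {
      g <- conv_backward(dx, caches[[i]], l$Wt, need_dx = i > to)
      grads[[i]] <- list(dW = g$dWt, db = g$db)
      dx <- g$dx
    }
  }
  grads
}

#' Predict class probabilities
#'
#' @param object a `contourtl_net`.
#' @param images a single image or a list of images, each `input_side` x
#'   `input_side` with 1 or `channels` channels, 8-bit values.
#' @param type `"prob"` for an n x 2 probability matrix (columns `p_no`,
#'   `p_yes`), `"class"` for hard 0/1 labels.
#' @param ... unused.
#' @return probability matrix or integer labels; deterministic for fixed
#'   weights (dropout is inactive at inference).
#' @export
predict.contourtl_net <- function(object, images, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  if (!is.list(images)) images <- list(images)
  probs <- matrix(NA_real_, length(images), object$spec$n_classes)
  for (i in seq_along(images)) {
    x <- prep_input(object, images[[i]])
    probs[i, ] <- forward_layers(object, x)$out
  }
  colnames(probs) <- if (object$spec$n_classes == 2L) c("p_no", "p_yes") else
    paste0("p_", seq_len(object$spec$n_classes) - 1L)
  if (type == "class") max.col(probs) - 1L else probs
}

#' Layer census of a classifier
#'
#' @param object a `contourtl_net`.
#' @param ... unused.
#' @return data.frame with one row per layer: type, name, output/kernel
#'   info, parameter count, trainable flag.
#' @export
summary.contourtl_net <- function(object, ...) {
  rows <- lapply(object$layers, function(l) {
    n_par <- switch(l$type,
                    conv = length(l$Wt) + length(l$b),
                    dense = length(l$W) + length(l$b),
                    0L)
    data.frame(name = l$name, type = l$type,
               params = n_par,
               trainable = isTRUE(l$trainable),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  structure(list(layers = df, spec = object$spec,
                 total_params = sum(df$params),
                 trainable_params = sum(df$params[df$trainable])),
            class = "summary.contourtl_net")
}

#' @export
print.summary.contourtl_net <- function(x, ...) {
  print(x$layers, row.names = FALSE)
  cat(sprintf("total params: %s | trainable: %s\n",
              format(x$total_params, big.mark = ","),
              format(x$trainable_params, big.mark = ",")))
  invisible(x)
}

#' @export
print.contourtl_net <- function(x, ...) {
  s <- x$spec
  n_conv <- sum(vapply(x$layers, function(l) l$type == "conv", logical(1)))
  cat(sprintf("contourtl_net: %dx%dx%d input, %d conv layers (%d frozen), %d pools, head %s, %d classes\n",
              s$input_side, s$input_side, s$channels, n_conv, s$frozen_conv,
              sum(vapply(x$layers, function(l) l$type == "pool", logical(1))),
              paste(s$head_widths, collapse = "-"), s$n_classes))
  if (!is.null(x$history)) {
    cat(sprintf("fitted: %d epoch(s), best epoch %d (val loss %.4f)\n",
                nrow(x$history$epochs), x$history$best_epoch,
                min(x$history$epochs$val_loss)))
  }
  invisible(x)
}

#' Plot training curves
#'
#' @param x a fitted `contourtl_net` (or its `$history`).
#' @param ... passed to `matplot`.
#' @export
plot.contourtl_net <- function(x, ...) {
  h <- if (inherits(x, "contourtl_net")) x$history else x
  if (is.null(h)) stop("model has no training history", call. = FALSE)
  e <- h$epochs
  graphics::matplot(e$epoch, cbind(e$loss, e$val_loss), type = "b", pch = 1:2,
                    xlab = "epoch", ylab = "loss", lty = 1, ...)
  graphics::legend("topright", c("train", "validation"), pch = 1:2,
                   col = 1:2, lty = 1)
  graphics::abline(v = h$best_epoch, lty = 3)
  invisible(x)
}
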