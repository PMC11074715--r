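# Training regime: RMSprop on sparse categorical cross-entropy, dropout in
# the head, early stopping on validation loss with best-weight restoration.
# Only trainable parameters are optimized; the frozen convolutional prefix
# is evaluated once per image and its feature maps reused every epoch.

#' Training configuration
#'
#' @param learning_rate RMSprop learning rate (default 2e-5, the fine-tuning
#'   rate used with pretrained weights; randomly initialized reduced models
#'   train faster with a larger rate such as 1e-3).
#' @param rho,epsilon RMSprop decay and stabilizer.
#' @param max_epochs maximum epochs (default 30).
#' @param batch_size minibatch size (default 32).
#' @param patience early-stopping patience in epochs (>= 1, default 5).
#' @param seed seed governing shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-5, rho = 0.9, epsilon = 1e-7,
                         max_epochs = 30, batch_size = 32, patience = 5,
                         seed = 0) {
  if (learning_rate < 0) stop("`learning_rate` must be >= 0", call. = FALSE)
  if (patience < 1) stop("`patience` must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = seed),
            class = "train_config")
}

load_split_images <- function(rows) {
  imgs <- lapply(rows$path, read_image)
  list(images = imgs, labels = as.integer(rows$label))
}

#' Train the classifier
#'
#' `data` is either a `partition` (as from [split_dataset()]; images are
#' loaded from the manifests) or a list
#' `list(train = list(images, labels), validation = list(images, labels))`
#' of in-memory images. Optimizes only trainable parameters with RMSprop on
#' sparse categorical cross-entropy; stops early when validation loss fails
#' to improve for `patience` consecutive epochs and restores the
#' best-validation-loss weights.
#'
#' @param model a `contourtl_net`.
#' @param data training/validation data (see above); both parts must be
#'   non-empty.
#' @param config a [train_config()].
#' @return the fitted model, with `$history` holding a `train_history`:
#'   per-epoch `epochs` data.frame (loss/acc, val_loss/val_acc),
#'   `stopped_epoch` and `best_epoch`.
#' @export
train_model <- function(model, data, config = train_config()) {
  if (inherits(data, "partition")) {
    data <- list(train = load_split_images(data$train),
                 validation = load_split_images(data$validation))
  }
  tr <- data$train; va <- data$validation
  if (length(tr$images) == 0L || length(va$images) == 0L) {
    stop("train and validation sets must be non-empty", call. = FALSE)
  }
  stopifnot(length(tr$images) == length(tr$labels),
            length(va$images) == length(va$labels))

  ft <- first_trainable_index(model)
  prefix_end <- ft - 1L
  feat <- function(img) {
    x <- prep_input(model, img)
    if (prefix_end >= 1L) forward_layers(model, x, 1L, prefix_end)$out else x
  }
  tr_x <- lapply(tr$images, feat)
  va_x <- lapply(va$images, feat)
  tr_y <- tr$labels; va_y <- va$labels
  n <- length(tr_x)
  k <- model$spec$n_classes

  opt_state <- list()
  best_loss <- Inf; best_epoch <- 0L; best_w <- NULL
  wait <- 0L; stopped_epoch <- 0L
  hist <- vector("list", config$max_epochs)

  model <- with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, n)]
        acc_grads <- NULL
        for (s in batch) {
          fw <- forward_layers(model, tr_x[[s]], from = ft, train = TRUE)
          p <- fw$out
          y <- tr_y[s]
          ep_loss <- ep_loss - log(max(p[y + 1L], 1e-12))
          ep_correct <- ep_correct + as.integer(which.max(p) - 1L == y)
          dz <- p
          dz[y + 1L] <- dz[y + 1L] - 1
          g <- backward_layers(model, dz, fw$caches, to = ft)
          acc_grads <- if (is.null(acc_grads)) g else
            mapply(function(a, b) {
              if (is.null(b)) return(a)
              list(dW = a$dW + b$dW, db = a$db + b$db)
            }, acc_grads, g, SIMPLIFY = FALSE)
        }
        scale <- 1 / length(batch)
        for (i in seq_along(model$layers)) {
          l <- model$layers[[i]]
          if (is.null(acc_grads[[i]]) || !isTRUE(l$trainable)) next
          wf <- if (l$type == "conv") "Wt" else "W"
          key <- as.character(i)
          if (is.null(opt_state[[key]])) {
            opt_state[[key]] <- list(vW = 0 * l[[wf]], vb = 0 * l$b)
          }
          uW <- rmsprop_update(l[[wf]], acc_grads[[i]]$dW * scale,
                               opt_state[[key]]$vW, config$learning_rate,
                               config$rho, config$epsilon)
          ub <- rmsprop_update(l$b, drop(acc_grads[[i]]$db) * scale,
                               opt_state[[key]]$vb, config$learning_rate,
                               config$rho, config$epsilon)
          model$layers[[i]][[wf]] <- uW$w
          model$layers[[i]]$b <- ub$w
          opt_state[[key]] <- list(vW = uW$v, vb = ub$v)
        }
      }

      val <- evaluate_on(model, va_x, va_y, ft)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  loss = ep_loss / n, acc = ep_correct / n,
                                  val_loss = val$loss, val_acc = val$acc)
      if (val$loss < best_loss) {
        best_loss <- val$loss; best_epoch <- epoch
        best_w <- save_weights(model); wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) { stopped_epoch <- epoch; break }
      }
    }
    model
  })

  if (!is.null(best_w)) {
    for (i in seq_along(model$layers)) {
      nm <- model$layers[[i]]$name
      if (!is.null(best_w[[nm]])) {
        for (f in names(best_w[[nm]])) model$layers[[i]][[f]] <- best_w[[nm]][[f]]
      }
    }
  }
  epochs <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$history <- structure(list(epochs = epochs,
                                  stopped_epoch = stopped_epoch,
                                  best_epoch = best_epoch),
                             class = "train_history")
  model
}

evaluate_on <- function(model, feats, labels, ft) {
  loss <- 0; correct <- 0L
  for (s in seq_along(feats)) {
    p <- forward_layers(model, feats[[s]], from = ft)$out
    loss <- loss - log(max(p[labels[s] + 1L], 1e-12))
    correct <- correct + as.integer(which.max(p) - 1L == labels[s])
  }
  list(loss = loss / length(feats), acc = correct / length(feats))
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("training history: %d epoch(s), best epoch %d%s\n",
              nrow(x$epochs), x$best_epoch,
              if (x$stopped_epoch > 0)
                sprintf(", stopped early at epoch %d", x$stopped_epoch) else ""))
  print(utils::tail(x$epochs, 3), row.names = FALSE)
  invisible(x)
}
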