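# Dataset splitting, model construction (bundled small CNN or a pluggable
# pretrained feature-extractor backbone with a replaced head), and the
# training loop: minibatch rmsprop with per-epoch validation and
# validation-accuracy early stopping.

#' Train/validation/test split specification
#'
#' @param ratios three nonnegative fractions summing to 1; default the
#'   64:16:20 protocol.
#' @param seed integer; the same seed always reproduces the same split.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(0.64, 0.16, 0.20), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0)) {
    stop("ratios must be three nonnegative numbers")
  }
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  structure(list(ratios = as.double(ratios), seed = as.integer(seed)),
            class = "split_spec")
}

# Largest-remainder apportionment of n into shares.
apportion <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Split items into train / validation / test subsets
#'
#' Subset sizes are the largest-remainder shares of the ratios. When `labels`
#' are supplied the split is stratified: items of each class are apportioned
#' separately (so every class appears in every subset whenever counts allow)
#' and then reconciled to the global subset sizes. The same seed always
#' yields the same assignment.
#'
#' @param items vector or list to split.
#' @param spec a [split_spec()].
#' @param labels optional class label per item for stratification.
#' @return list with `train`, `validation`, `test` subsets and an `indices`
#'   attribute holding the three index vectors.
#' @export
split_dataset <- function(items, spec = split_spec(), labels = NULL) {
  n <- length(items)
  if (n == 0L) stop("cannot split an empty item set")
  stopifnot(inherits(spec, "split_spec"))
  target <- apportion(n, spec$ratios)
  assign_idx <- with_seed(spec$seed, {
    groups <- list(integer(0), integer(0), integer(0))
    if (is.null(labels)) {
      perm <- sample.int(n)
      bounds <- cumsum(c(0L, target))
      for (s in 1:3) {
        groups[[s]] <- sort(perm[(bounds[s] + 1L):bounds[s + 1L]])
        if (target[s] == 0L) groups[[s]] <- integer(0)
      }
    } else {
      stopifnot(length(labels) == n)
      for (cls in unique(labels)) {
        ci <- which(labels == cls)
        perm <- ci[sample.int(length(ci))]
        share <- apportion(length(ci), spec$ratios)
        bounds <- cumsum(c(0L, share))
        for (s in 1:3) {
          if (share[s] > 0L) {
            groups[[s]] <- c(groups[[s]], perm[(bounds[s] + 1L):bounds[s + 1L]])
          }
        }
      }
      # reconcile per-class rounding drift with the global subset sizes
      repeat {
        sizes <- lengths(groups)
        over <- which(sizes > target)
        under <- which(sizes < target)
        if (length(over) == 0L) break
        s <- over[[1L]]; t <- under[[1L]]
        moved <- groups[[s]][length(groups[[s]])]
        groups[[s]] <- groups[[s]][-length(groups[[s]])]
        groups[[t]] <- c(groups[[t]], moved)
      }
      groups <- lapply(groups, sort)
    }
    groups
  })
  out <- list(train = items[assign_idx[[1L]]],
              validation = items[assign_idx[[2L]]],
              test = items[assign_idx[[3L]]])
  attr(out, "indices") <- assign_idx
  out
}

#' Training configuration
#'
#' Defaults follow the transfer-learning recipe: rmsprop, learning rate 1e-4,
#' minibatch 64, at most 105 epochs, early stopping after 10 validation
#' checks without improvement. When training the bundled small CNN from
#' random initialisation a larger learning rate (1e-3) is the conventional
#' choice; the pipeline preset uses it.
#'
#' @param optimizer optimiser name; `"rmsprop"` is implemented.
#' @param learning_rate positive step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param patience consecutive validation checks without improvement before
#'   stopping (>= 1).
#' @param gradient_threshold L2 gradient clipping threshold; `Inf` disables
#'   clipping.
#' @param seed integer seed for shuffling and initialisation.
#' @return object of class `train_config`.
#' @export
train_config <- function(optimizer = "rmsprop", learning_rate = 1e-4,
                         batch_size = 64L, max_epochs = 105L, patience = 10L,
                         gradient_threshold = Inf, seed = 1L) {
  if (optimizer != "rmsprop") stop("only the rmsprop optimizer is implemented")
  if (learning_rate < 0) stop("learning_rate must be nonnegative")
  stopifnot(batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(
    list(optimizer = optimizer, learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         gradient_threshold = gradient_threshold, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Build a classifier model
#'
#' With `backbone_spec = "small"` constructs the bundled small CNN (two 3x3
#' convolution blocks of 16 and 32 filters with relu and 2x2 max pooling,
#' then a fully-connected softmax head, on zero-centred inputs); all
#' parameters are trainable. Alternatively pass a
#' pretrained backbone as `list(features = function(images) ..., n_features =
#' <int>, name = <chr>)`: the backbone is frozen and the final three stages
#' (fully-connected layer, softmax, class decision) are replaced with a fresh
#' head of width `n_classes` — only the head is trainable.
#'
#' @param backbone_spec `"small"` or a pretrained-backbone list.
#' @param n_classes number of classes (>= 2).
#' @param input_size image side length in pixels (square inputs).
#' @param class_names optional class names attached to score columns.
#' @param seed seed for weight initialisation.
#' @return object of class `afw_model`.
#' @export
build_model <- function(backbone_spec = "small", n_classes = 4L,
                        input_size = 64L, class_names = NULL, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be at least 2")
  if (identical(backbone_spec, "small")) {
    model <- new_small_cnn(input_size, n_classes, seed = seed)
  } else if (is.list(backbone_spec) && is.function(backbone_spec$features)) {
    nf <- as.integer(backbone_spec$n_features)
    weights <- with_seed(seed, list(
      Wfc = matrix(stats::rnorm(nf * n_classes, sd = sqrt(2 / nf)),
                   nf, n_classes),
      bfc = numeric(n_classes)))
    model <- structure(
      list(kind = "head_only", input_size = as.integer(input_size),
           n_channels = 3L, n_classes = n_classes, weights = weights,
           geo = NULL, class_names = NULL, backbone = backbone_spec),
      class = "afw_model")
  } else {
    stop("backbone_spec must be \"small\" or a backbone list")
  }
  model$class_names <- class_names
  model
}

#' @export
print.afw_model <- function(x, ...) {
  cat(sprintf("<afw_model %s: input %dx%dx%d, %d classes, %d trainable parameters>\n",
              x$kind, x$input_size, x$input_size, x$n_channels, x$n_classes,
              n_trainable_params(x)))
  invisible(x)
}

#' Count of trainable parameters
#'
#' For a pretrained backbone only the replaced head counts; for the small CNN
#' every layer is trainable.
#'
#' @param model an `afw_model`.
#' @return integer parameter count.
#' @export
n_trainable_params <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

# Coerce supported image containers to an (h, w, 3, n) array in [0, 1].
as_image_array <- function(images, input_size = NULL) {
  if (is.list(images) && length(images) &&
      inherits(images[[1L]], "scalogram_image")) {
    arrs <- lapply(images, function(im) im$pixels / 255)
    images <- array(unlist(arrs), dim = c(dim(arrs[[1L]]), length(arrs)))
  }
  if (!is.array(images) || length(dim(images)) != 4L) {
    stop("images must be an (h, w, 3, n) array or list of scalogram_image")
  }
  if (!is.null(input_size) &&
      (dim(images)[1] != input_size || dim(images)[2] != input_size)) {
    stop(sprintf("image size %dx%d does not match model input %dx%d",
                 dim(images)[1], dim(images)[2], input_size, input_size))
  }
  images
}

labels_to_index <- function(labels, class_names) {
  idx <- match(labels, class_names)
  if (anyNA(idx)) {
    stop("labels outside the model's class set: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Train a classifier with rmsprop and early stopping
#'
#' Runs at most `max_epochs` epochs of shuffled minibatch rmsprop, evaluates
#' validation accuracy once per epoch, and stops early when accuracy has not
#' improved over `patience` consecutive checks. The returned model carries
#' the weights from the best validation check.
#'
#' @param model an [build_model()] result.
#' @param train_set,val_set lists with `images` (array `(h, w, 3, n)` in
#'   `[0, 1]` or list of `scalogram_image`) and `labels`.
#' @param config a [train_config()].
#' @param verbose log per-epoch progress.
#' @return list with `model` (best weights) and `history` (class
#'   `train_history`: data.frame of epoch, train_loss, val_accuracy, plus a
#'   `stop_reason` attribute, `"early_stop"` or `"max_epochs"`).
#' @export
train <- function(model, train_set, val_set, config = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "afw_model"), inherits(config, "train_config"))
  if (length(train_set$labels) == 0L || length(val_set$labels) == 0L) {
    stop("training and validation sets must be non-empty")
  }
  if (length(unique(train_set$labels)) < 2L) {
    stop("degenerate training set: a single class cannot be learned")
  }
  if (is.null(model$class_names)) {
    model$class_names <- sort(unique(c(train_set$labels, val_set$labels)))
  }
  if (length(model$class_names) != model$n_classes) {
    stop(sprintf("model expects %d classes but data has %d",
                 model$n_classes, length(model$class_names)))
  }
  missing_cls <- setdiff(model$class_names, unique(train_set$labels))
  if (length(missing_cls)) {
    warning("classes absent from the training set: ",
            paste(missing_cls, collapse = ", "))
  }
  x_tr <- as_image_array(train_set$images, model$input_size)
  x_va <- as_image_array(val_set$images, model$input_size)
  y_tr <- labels_to_index(train_set$labels, model$class_names)
  y_va <- labels_to_index(val_set$labels, model$class_names)
  n_tr <- length(y_tr)

  cache <- rmsprop_init(model$weights)
  best <- list(weights = model$weights, val_acc = -Inf)
  lag <- 0L
  hist <- list()
  stop_reason <- "max_epochs"
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n_tr)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq.int(1L, n_tr, by = config$batch_size)) {
        take <- perm[start:min(start + config$batch_size - 1L, n_tr)]
        bg <- if (model$kind == "small_cnn") {
          small_cnn_batch_grads(model, x_tr[, , , take, drop = FALSE],
                                y_tr[take])
        } else {
          head_only_batch_grads(model, x_tr[, , , take, drop = FALSE],
                                y_tr[take])
        }
        step <- rmsprop_step(model$weights, bg$grads, cache,
                             lr = config$learning_rate,
                             gradient_threshold = config$gradient_threshold)
        model$weights <- step$weights
        cache <- step$cache
        epoch_loss <- epoch_loss + bg$loss
        n_batches <- n_batches + 1L
      }
      scores <- model_scores(model, x_va)
      val_acc <- mean(max.col(scores, ties.method = "first") == y_va)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = epoch_loss / n_batches,
                                  val_accuracy = val_acc)
      if (verbose) {
        afw_log("train", sprintf("epoch %d loss %.4f val_acc %.4f",
                                 epoch, epoch_loss / n_batches, val_acc))
      }
      if (val_acc > best$val_acc) {
        best <- list(weights = model$weights, val_acc = val_acc)
        lag <- 0L
      } else {
        lag <- lag + 1L
        if (lag >= config$patience) {
          stop_reason <- "early_stop"
          break
        }
      }
    }
  })
  model$weights <- best$weights
  history <- do.call(rbind, hist)
  attr(history, "stop_reason") <- stop_reason
  attr(history, "best_val_accuracy") <- best$val_acc
  class(history) <- c("train_history", class(history))
  list(model = model, history = history)
}

#' Class scores and decisions for a batch of images
#'
#' @param object a trained `afw_model`.
#' @param images image array or list of `scalogram_image`.
#' @param ... unused.
#' @return list with `scores` (rows are probability vectors) and `decisions`
#'   (argmax with lowest-index tie-break; class names when known).
#' @export
predict.afw_model <- function(object, images, ...) {
  x <- as_image_array(images, object$input_size)
  scores <- model_scores(object, x)
  if (!is.null(object$class_names)) colnames(scores) <- object$class_names
  dec_idx <- max.col(scores, ties.method = "first")
  decisions <- if (!is.null(object$class_names)) {
    object$class_names[dec_idx]
  } else {
    dec_idx
  }
  list(scores = scores, decisions = decisions)
}
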