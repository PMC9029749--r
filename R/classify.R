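# Image classifiers over time-frequency representations.
#
# Backbones are pluggable. The built-in `tiny-scratch` backbone is a small
# convolutional feature map (two fixed, seed-initialized conv + ReLU +
# 2x2 average-pool blocks) followed by a trainable multinomial softmax
# head. Freezing the convolutional stage keeps head training convex,
# deterministic and fast on a single CPU; it plays the role of the frozen
# pretrained trunk in the transfer-learning recipe, with the final layer
# replaced and retrained per task. The field-scale ImageNet backbones
# (alexnet-class, vgg16-class, resnet50-class) are resolved at runtime via
# [register_backbone()]; without a registered plug-in their pretrained
# weights are unavailable and construction fails with a resolvable error.

.backbone_registry <- new.env(parent = emptyenv())

#' Register a backbone plug-in
#'
#' A plug-in is a function `(spec, n_classes) -> handle` returning an
#' object implementing the classifier contract (see
#' [build_classifier()]). Used to attach externally provided pretrained
#' networks.
#'
#' @param name Backbone name.
#' @param loader Function `(spec, n_classes)` returning a classifier
#'   handle.
#' @return `name`, invisibly.
#' @export
register_backbone <- function(name, loader) {
  stopifnot(is.character(name), is.function(loader))
  assign(name, loader, envir = .backbone_registry)
  invisible(name)
}

#' Backbone specification
#'
#' @param name Backbone identifier. `"tiny-scratch"` is built in; the
#'   ImageNet backbones `"alexnet-class"`, `"vgg16-class"` and
#'   `"resnet50-class"` must be supplied as plug-ins via
#'   [register_backbone()].
#' @param input_height,input_width Input image size expected by the
#'   backbone.
#' @param weights_origin `"pretrained_imagenet"` or `"random_init"`.
#' @param trainable_scope `"head_only"` or `"all_layers"`.
#' @return A list of class `backbone_spec`.
#' @export
backbone_spec <- function(name = "tiny-scratch",
                          input_height = 64L, input_width = 64L,
                          weights_origin = c("random_init",
                                             "pretrained_imagenet"),
                          trainable_scope = c("head_only", "all_layers")) {
  weights_origin <- match.arg(weights_origin)
  trainable_scope <- match.arg(trainable_scope)
  structure(
    list(name = name, input_height = as.integer(input_height),
         input_width = as.integer(input_width),
         weights_origin = weights_origin,
         trainable_scope = trainable_scope),
    class = "backbone_spec"
  )
}

#' Training configuration
#'
#' Hyperparameters for the softmax head: mini-batch stochastic gradient
#' descent with momentum on the cross-entropy loss with L2 weight decay.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Step size.
#' @param optimizer Currently `"sgd"` (momentum SGD).
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty on the head weights.
#' @param seed Seed controlling shuffling; identical seed and inputs give
#'   identical trained heads.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L,
                         learning_rate = 0.1, optimizer = "sgd",
                         momentum = 0.9, weight_decay = 1e-4, seed = 1L) {
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  optimizer <- match.arg(optimizer, "sgd")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer = optimizer,
         momentum = momentum, weight_decay = weight_decay,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# fixed internal seed for the frozen convolutional trunk: every build loads
# the same "checkpoint", mirroring how a pretrained trunk is always the
# same network
.TRUNK_SEED <- 909L

.init_conv <- function(n_in_ch, n_filters, seed_offset) {
  .with_seed(.TRUNK_SEED + seed_offset, {
    matrix(stats::rnorm(9L * n_in_ch * n_filters) / sqrt(9 * n_in_ch),
           9L * n_in_ch, n_filters)
  })
}

#' Build a classifier from a backbone spec
#'
#' Loads the backbone per `weights_origin` and replaces its final
#' classification layer with a freshly initialized `n_classes`-way softmax
#' layer. The returned handle is untrained; see [train_classifier()].
#'
#' @param spec A [backbone_spec()].
#' @param n_classes Number of output classes (>= 2).
#' @return An object of class `roar_classifier`.
#' @export
build_classifier <- function(spec, n_classes) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (exists(spec$name, envir = .backbone_registry, inherits = FALSE)) {
    loader <- get(spec$name, envir = .backbone_registry)
    return(loader(spec, as.integer(n_classes)))
  }
  if (spec$name %in% c("alexnet-class", "vgg16-class", "resnet50-class")) {
    stop("pretrained weights for backbone '", spec$name, "' are not ",
         "available offline; register a plug-in with register_backbone() ",
         "or use backbone 'tiny-scratch'", call. = FALSE)
  }
  stop("unknown backbone name: '", spec$name, "'", call. = FALSE)
}

# built-in backbone; registered at load time
.tiny_scratch_loader <- function(spec, n_classes) {
  structure(
    list(spec = spec, n_classes = n_classes,
         conv1 = .init_conv(1L, 8L, 1L),
         conv2 = .init_conv(8L, 8L, 2L),
         head = NULL, class_labels = NULL,
         feat_center = NULL, feat_scale = NULL, loss_history = NULL),
    class = "roar_classifier"
  )
}

#' @export
print.roar_classifier <- function(x, ...) {
  cat(sprintf("<roar_classifier> backbone=%s, %d classes, %s\n",
              x$spec$name, x$n_classes,
              if (is.null(x$head)) "untrained" else "trained"))
  invisible(x)
}

# shift a matrix by (di, dj) with zero fill ('same' padding convolution)
.shift_mat <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  src_r <- max(1, 1 + di):min(h, h + di)
  src_c <- max(1, 1 + dj):min(w, w + dj)
  out[src_r - di, src_c - dj] <- m[src_r, src_c]
  out
}

# 3x3 'same' convolution over a stack of channel matrices via column
# binding of shifted copies; returns list of n_filters matrices
.conv3x3 <- function(channels, weights) {
  h <- nrow(channels[[1]]); w <- ncol(channels[[1]])
  cols <- vector("list", 9L * length(channels))
  k <- 0L
  for (ch in channels) {
    for (dj in -1:1) {
      for (di in -1:1) {
        k <- k + 1L
        cols[[k]] <- as.numeric(.shift_mat(ch, di, dj))
      }
    }
  }
  patch <- do.call(cbind, cols)
  resp <- patch %*% weights
  lapply(seq_len(ncol(weights)), function(f) matrix(resp[, f], h, w))
}

.avgpool2 <- function(m) {
  h <- nrow(m) %/% 2L * 2L
  w <- ncol(m) %/% 2L * 2L
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (m[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
            m[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
            m[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
            m[seq(2, h, 2), seq(2, w, 2), drop = FALSE])
}

# frozen trunk: image array -> feature vector
.featurize_one <- function(handle, img) {
  gray <- if (length(dim(img)) == 3L) {
    (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  } else {
    img
  }
  gray <- gray / 255
  b1 <- .conv3x3(list(gray), handle$conv1)
  b1 <- lapply(b1, function(m) .avgpool2(pmax(m, 0)))
  b2 <- .conv3x3(b1, handle$conv2)
  b2 <- lapply(b2, function(m) .avgpool2(pmax(m, 0)))
  unlist(lapply(b2, as.numeric))
}

#' Extract frozen-trunk features for a batch of images
#'
#' The trunk is fixed at build time, so features can be computed once and
#' reused across cross-validation folds (only the head is retrained per
#' fold).
#'
#' @param handle A [build_classifier()] handle.
#' @param images List of image arrays (height x width x 3, values in
#'   \[0, 255\]).
#' @return Numeric matrix, one row per image.
#' @export
backbone_features <- function(handle, images) {
  stopifnot(inherits(handle, "roar_classifier"))
  t(vapply(images, function(im) .featurize_one(handle, im),
           numeric(length(.featurize_one(handle, images[[1]])))))
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# multinomial softmax head trained by mini-batch SGD with momentum;
# zero-initialized (convex objective, no symmetry to break) so training is
# deterministic given the shuffle seed
.train_head <- function(feats, y_int, n_classes, cfg,
                        feat_center = NULL, feat_scale = NULL) {
  n <- nrow(feats)
  if (is.null(feat_center)) {
    feat_center <- colMeans(feats)
    feat_scale <- pmax(apply(feats, 2L, stats::sd), 1e-8)
  }
  xs <- sweep(sweep(feats, 2L, feat_center), 2L, feat_scale, "/")
  xs <- cbind(1, xs)
  d <- ncol(xs)
  w <- matrix(0, d, n_classes)
  vel <- matrix(0, d, n_classes)
  yh <- matrix(0, n, n_classes)
  yh[cbind(seq_len(n), y_int)] <- 1
  loss_history <- numeric(cfg$epochs)
  objective <- function(w) {
    p_all <- .softmax_rows(xs %*% w)
    -mean(log(pmax(p_all[cbind(seq_len(n), y_int)], 1e-300))) +
      cfg$weight_decay / 2 * sum(w^2)
  }
  .with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      loss_history[ep] <- objective(w)
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- xs[idx, , drop = FALSE]
        p <- .softmax_rows(xb %*% w)
        grad <- crossprod(xb, p - yh[idx, , drop = FALSE]) / length(idx) +
          cfg$weight_decay * w
        vel <- cfg$momentum * vel - cfg$learning_rate * grad
        w <- w + vel
      }
    }
  })
  list(w = w, feat_center = feat_center, feat_scale = feat_scale,
       loss_history = loss_history)
}

#' Train a classifier
#'
#' Retrains the replaced softmax head on the given images and labels. The
#' frozen trunk is untouched (its weights stay bit-identical to the loaded
#' backbone); training is deterministic given `cfg$seed`.
#'
#' @param handle A [build_classifier()] handle.
#' @param images List of image arrays sized to the backbone spec.
#' @param labels Vector of class labels; every one of the handle's
#'   `n_classes` classes must be present.
#' @param cfg A [train_config()].
#' @return The trained handle (with `loss_history` attached).
#' @export
train_classifier <- function(handle, images, labels,
                             cfg = train_config()) {
  stopifnot(inherits(handle, "roar_classifier"))
  labels <- as.character(labels)
  if (length(images) != length(labels)) {
    stop("`images` and `labels` must have equal length", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) != handle$n_classes) {
    stop("degenerate fold: training labels cover ", length(classes),
         " of ", handle$n_classes, " classes", call. = FALSE)
  }
  if (length(images) < handle$n_classes) {
    stop("need at least one training image per class", call. = FALSE)
  }
  feats <- backbone_features(handle, images)
  fit <- .train_head(feats, match(labels, classes), handle$n_classes, cfg)
  handle$head <- fit$w
  handle$class_labels <- classes
  handle$feat_center <- fit$feat_center
  handle$feat_scale <- fit$feat_scale
  handle$loss_history <- fit$loss_history
  handle
}

.scores_from_feats <- function(handle, feats) {
  xs <- sweep(sweep(feats, 2L, handle$feat_center), 2L,
              handle$feat_scale, "/")
  .softmax_rows(cbind(1, xs) %*% handle$head)
}

#' Predict class scores
#'
#' @param handle A trained [train_classifier()] handle.
#' @param images List of image arrays, in the order scores are wanted.
#' @param sample_ids Character ids, one per image.
#' @return A [score_matrix()]: softmax rows summing to 1 in input order.
#' @export
predict_scores <- function(handle, images, sample_ids = NULL) {
  stopifnot(inherits(handle, "roar_classifier"))
  if (is.null(handle$head)) stop("classifier is untrained", call. = FALSE)
  if (length(images) < 1L) stop("`images` must be nonempty", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_along(images))
  if (length(sample_ids) != length(images)) {
    stop("`sample_ids` and `images` must have equal length", call. = FALSE)
  }
  feats <- backbone_features(handle, images)
  score_matrix(.scores_from_feats(handle, feats), sample_ids,
               handle$class_labels)
}

#' Construct a score matrix
#'
#' Per-sample posterior scores over classes; each row is a probability
#' vector. The interchange unit between classification, fusion and
#' evaluation.
#'
#' @param values `n_samples x n_classes` numeric matrix; rows must be
#'   nonnegative and sum to 1 (tolerance 1e-6).
#' @param sample_ids Unique character ids, one per row.
#' @param class_labels Class labels, one per column (>= 2).
#' @return A list of class `score_matrix`.
#' @export
score_matrix <- function(values, sample_ids, class_labels) {
  values <- as.matrix(values)
  if (length(class_labels) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (ncol(values) != length(class_labels) ||
      nrow(values) != length(sample_ids)) {
    stop("score matrix dimensions do not match ids/labels", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("`sample_ids` must be unique", call. = FALSE)
  }
  if (any(values < -1e-9) || any(abs(rowSums(values) - 1) > 1e-6)) {
    stop("rows must be probability vectors", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, class_labels)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         class_labels = as.character(class_labels)),
    class = "score_matrix"
  )
}

#' Write a score matrix as CSV
#'
#' Columns: `sample_id`, optional `true_label`, one column per class.
#'
#' @param scores A [score_matrix()].
#' @param path Output CSV path.
#' @param true_labels Optional vector of true labels to store alongside.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, true_labels = NULL) {
  stopifnot(inherits(scores, "score_matrix"))
  df <- data.frame(sample_id = scores$sample_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(true_labels)) df$true_label <- as.character(true_labels)
  df <- cbind(df, as.data.frame(scores$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix written by [write_scores()]
#'
#' @param path CSV path.
#' @return A list with `scores` (a [score_matrix()]) and `true_labels`
#'   (or `NULL`).
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  has_truth <- "true_label" %in% names(df)
  class_cols <- setdiff(names(df), c("sample_id", "true_label"))
  list(
    scores = score_matrix(as.matrix(df[, class_cols, drop = FALSE]),
                          df$sample_id, class_cols),
    true_labels = if (has_truth) df$true_label
  )
}
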