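# End-to-end runners: representation extraction, per-fold training over a
# fold plan, and the one-vs-many EER protocol.

#' Render every sample of a dataset as a network-ready image
#'
#' @param dataset A `roar_dataset`.
#' @param representation Representation name (see
#'   [compute_representation()]).
#' @param cfg A [rep_config()].
#' @param scaling `"raw"` or one of the [apply_scaling()] modes.
#' @param scaling_constant Constant for `box_n`.
#' @param target_height,target_width Network input size.
#' @param embedder Optional embedder for the embedding representation.
#' @return Named list of image arrays, keyed by `sample_id`.
#' @export
extract_images <- function(dataset, representation, cfg = rep_config(),
                           scaling = "min_max", scaling_constant = 1000,
                           target_height = 64L, target_width = 64L,
                           embedder = NULL) {
  stopifnot(inherits(dataset, "roar_dataset"))
  imgs <- lapply(dataset$samples, function(s) {
    img <- compute_representation(s$clip, representation, cfg, embedder)
    if (scaling != "raw") {
      img <- apply_scaling(img, scaling, scaling_constant)
    }
    to_network_image(img, target_height, target_width)
  })
  names(imgs) <- vapply(dataset$samples, `[[`, character(1), "sample_id")
  imgs
}

.sample_labels <- function(dataset, binary = FALSE) {
  field <- if (binary) "binary_label" else "individual_id"
  labs <- vapply(dataset$samples, `[[`, character(1), field)
  names(labs) <- vapply(dataset$samples, `[[`, character(1), "sample_id")
  labs
}

.fold_seed <- function(master_seed, fold_index) {
  as.integer((as.numeric(master_seed) + fold_index * 10007) %% 2147483647)
}

#' Run a fold plan end to end
#'
#' Builds the backbone once, extracts its frozen-trunk features for every
#' image once (the trunk does not change across folds), then per fold
#' retrains the replaced softmax head from scratch on the training samples
#' (fold seed derived deterministically from the master seed) and scores
#' the held-out samples. Pooled held-out scores and per-fold accuracies
#' are returned.
#'
#' @param images Named list of image arrays from [extract_images()].
#' @param labels Named character vector of true labels (names =
#'   sample ids).
#' @param plan A `fold_plan` whose sample ids all appear in `images`.
#' @param spec A [backbone_spec()].
#' @param cfg A [train_config()]; `cfg$seed` is the master seed.
#' @return List of class `eval_result`: `scheme`, `per_fold` (data.frame
#'   `fold_index`, `n_test`, `n_correct`), `overall_accuracy`, and
#'   `scores`, the pooled held-out [score_matrix()] (row order follows
#'   the order samples were held out).
#' @export
run_scheme <- function(images, labels, plan, spec = backbone_spec(),
                       cfg = train_config()) {
  stopifnot(inherits(plan, "fold_plan"))
  handle <- build_classifier(spec, n_classes = length(unique(labels)))
  classes <- sort(unique(labels))
  cached <- inherits(handle, "roar_classifier")
  feats <- if (cached) backbone_features(handle, images)
  if (cached) rownames(feats) <- names(images)

  pooled_values <- NULL
  pooled_ids <- character(0)
  per_fold <- vector("list", length(plan$folds))
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    fold_cfg <- cfg
    fold_cfg$seed <- .fold_seed(cfg$seed, i)
    train_labs <- labels[f$train]
    if (length(unique(train_labs)) != length(classes)) {
      stop("degenerate fold ", i, ": a class is missing from training",
           call. = FALSE)
    }
    if (cached) {
      fit <- .train_head(feats[f$train, , drop = FALSE],
                         match(train_labs, classes),
                         length(classes), fold_cfg)
      fold_handle <- handle
      fold_handle$head <- fit$w
      fold_handle$class_labels <- classes
      fold_handle$feat_center <- fit$feat_center
      fold_handle$feat_scale <- fit$feat_scale
      sc <- .scores_from_feats(fold_handle,
                               feats[f$test, , drop = FALSE])
    } else {
      fold_handle <- train_classifier(handle, images[f$train],
                                      train_labs, fold_cfg)
      sc <- predict_scores(fold_handle, images[f$test], f$test)$values
    }
    pooled_values <- rbind(pooled_values, sc)
    pooled_ids <- c(pooled_ids, f$test)
    n_correct <- sum(classes[apply(sc, 1L, which.max)] == labels[f$test])
    per_fold[[i]] <- data.frame(fold_index = i, n_test = length(f$test),
                                n_correct = n_correct)
  }
  per_fold <- do.call(rbind, per_fold)
  structure(
    list(scheme = plan$scheme, per_fold = per_fold,
         overall_accuracy = sum(per_fold$n_correct) / sum(per_fold$n_test),
         scores = score_matrix(pooled_values, pooled_ids, classes)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> scheme=%s, %d folds, overall accuracy %.4f\n",
              x$scheme, nrow(x$per_fold), x$overall_accuracy))
  invisible(x)
}

#' Run the one-vs-many EER protocol for one target individual
#'
#' Relabels the dataset (target = class "1", rest = class "2"), builds the
#' EER fold plan on the requested base scheme, retrains the binary head
#' per fold, and pools the held-out target-class posteriors across folds
#' into genuine (true class 1) and impostor (true class 2) score lists
#' before a single EER computation.
#'
#' @param images Named list of image arrays from [extract_images()].
#' @param dataset A `roar_dataset`.
#' @param target Target individual id.
#' @param base_scheme `"day"` or `"bout"`.
#' @param spec A [backbone_spec()].
#' @param cfg A [train_config()].
#' @return An `eer_result` (see [compute_eer()]).
#' @export
run_eer_protocol <- function(images, dataset, target,
                             base_scheme = "day",
                             spec = backbone_spec(),
                             cfg = train_config()) {
  view <- relabel_one_vs_many(dataset, target)
  labels <- .sample_labels(view, binary = TRUE)
  plan <- make_eer_folds(dataset, target, base_scheme)
  handle <- build_classifier(spec, n_classes = 2L)
  cached <- inherits(handle, "roar_classifier")
  feats <- if (cached) backbone_features(handle, images)
  if (cached) rownames(feats) <- names(images)

  genuine <- numeric(0)
  impostor <- numeric(0)
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    fold_cfg <- cfg
    fold_cfg$seed <- .fold_seed(cfg$seed, i)
    train_labs <- labels[f$train]
    if (length(unique(train_labs)) != 2L) {
      message("skipping fold ", i, ": one binary class missing from ",
              "training")
      next
    }
    if (cached) {
      fit <- .train_head(feats[f$train, , drop = FALSE],
                         match(train_labs, c("1", "2")), 2L, fold_cfg)
      fold_handle <- handle
      fold_handle$head <- fit$w
      fold_handle$class_labels <- c("1", "2")
      fold_handle$feat_center <- fit$feat_center
      fold_handle$feat_scale <- fit$feat_scale
      sc <- .scores_from_feats(fold_handle,
                               feats[f$test, , drop = FALSE])
    } else {
      fold_handle <- train_classifier(handle, images[f$train],
                                      train_labs, fold_cfg)
      sc <- predict_scores(fold_handle, images[f$test], f$test)$values
    }
    s1 <- sc[, 1L]
    genuine <- c(genuine, s1[labels[f$test] == "1"])
    impostor <- c(impostor, s1[labels[f$test] == "2"])
  }
  compute_eer(genuine, impostor, target_individual = target)
}

#' Mean pooled EER over every individual as target
#'
#' @inheritParams run_eer_protocol
#' @return List with `per_target` (list of `eer_result`) and
#'   `mean_eer_percent`.
#' @export
run_eer_all_targets <- function(images, dataset, base_scheme = "day",
                                spec = backbone_spec(),
                                cfg = train_config()) {
  targets <- dataset$class_labels
  per_target <- lapply(targets, function(tg) {
    run_eer_protocol(images, dataset, tg, base_scheme, spec, cfg)
  })
  names(per_target) <- targets
  list(per_target = per_target,
       mean_eer_percent = mean(vapply(per_target, `[[`, numeric(1),
                                      "eer_percent")))
}
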