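# Grouped leave-one-out designs, accuracy, and Equal Error Rate.
#
# Four schemes are supported: `day` (hold out one (individual, day)
# group), `bout` (hold out one roar bout), and their one-vs-many
# counterparts `eer_day` / `eer_bout` used for Equal Error Rate scoring.
# A "day" is an (individual, day-label) pair, not a calendar date shared
# across animals: five lions recorded on 4-10 days each is what yields ~20
# groups.

.as_manifest <- function(dataset) {
  if (inherits(dataset, "roar_dataset")) dataset_manifest(dataset)
  else as.data.frame(dataset, stringsAsFactors = FALSE)
}

.fold_plan <- function(scheme, folds, target_individual = NULL) {
  structure(
    list(scheme = scheme, folds = folds,
         target_individual = target_individual),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> scheme=%s, %d folds%s\n", x$scheme,
              length(x$folds),
              if (is.null(x$target_individual)) ""
              else paste0(", target=", x$target_individual)))
  invisible(x)
}

#' Day-wise leave-one-out fold plan
#'
#' One fold per (individual, day) group: that group's samples are the test
#' set, all remaining samples the training set. A class recorded on only
#' one day would be absent from its fold's training set; that is a
#' degenerate design and an error naming the class.
#'
#' @param dataset A `roar_dataset` or a manifest data.frame with columns
#'   `sample_id`, `individual_id`, `day_id`, `bout_id`.
#' @return A `fold_plan` with scheme `"day"`.
#' @export
make_day_folds <- function(dataset) {
  m <- .as_manifest(dataset)
  grp <- paste(m$individual_id, m$day_id, sep = "|")
  groups <- sort(unique(grp))
  if (length(groups) < 2L) {
    stop("need >= 2 (individual, day) groups", call. = FALSE)
  }
  days_per_ind <- tapply(m$day_id, m$individual_id,
                         function(d) length(unique(d)))
  if (any(days_per_ind < 2L)) {
    stop("degenerate fold: class '",
         names(days_per_ind)[which(days_per_ind < 2L)[1]],
         "' was recorded on a single day", call. = FALSE)
  }
  folds <- lapply(groups, function(g) {
    test <- m$sample_id[grp == g]
    list(train = m$sample_id[grp != g], test = test)
  })
  .fold_plan("day", folds)
}

#' Bout-wise leave-one-out fold plan
#'
#' One fold per bout (1-3 samples held out). A class with a single bout
#' would be untrainable in its fold; that is an error naming the class.
#'
#' @inheritParams make_day_folds
#' @return A `fold_plan` with scheme `"bout"`.
#' @export
make_bout_folds <- function(dataset) {
  m <- .as_manifest(dataset)
  bouts <- sort(unique(m$bout_id))
  if (length(bouts) < 2L) stop("need >= 2 bouts", call. = FALSE)
  bouts_per_ind <- tapply(m$bout_id, m$individual_id,
                          function(b) length(unique(b)))
  if (any(bouts_per_ind < 2L)) {
    stop("degenerate fold: class '",
         names(bouts_per_ind)[which(bouts_per_ind < 2L)[1]],
         "' has a single bout", call. = FALSE)
  }
  folds <- lapply(bouts, function(b) {
    list(train = m$sample_id[m$bout_id != b],
         test = m$sample_id[m$bout_id == b])
  })
  .fold_plan("bout", folds)
}

#' Naive per-sample leave-one-out fold plan
#'
#' One fold per sample, ignoring bout and day grouping. This design leaks
#' bout-level correlation between train and test; it exists to demonstrate
#' that leakage against the grouped designs, not for reporting.
#'
#' @inheritParams make_day_folds
#' @return A `fold_plan` with scheme `"sample"`.
#' @export
make_sample_folds <- function(dataset) {
  m <- .as_manifest(dataset)
  folds <- lapply(m$sample_id, function(s) {
    list(train = setdiff(m$sample_id, s), test = s)
  })
  .fold_plan("sample", folds)
}

#' One-vs-many relabelling
#'
#' Tags the target individual's samples as class `"1"` and every other
#' individual's samples as class `"2"`, preserving all grouping metadata.
#' The basis of the Equal Error Rate protocol; also what lets the system
#' flag animals from outside the known set.
#'
#' @param dataset A `roar_dataset`.
#' @param target An individual id from `dataset$class_labels`.
#' @return A `roar_dataset` whose samples carry a `binary_label` field and
#'   whose `class_labels` are `c("1", "2")`; the original individual ids
#'   remain on the samples.
#' @export
relabel_one_vs_many <- function(dataset, target) {
  stopifnot(inherits(dataset, "roar_dataset"))
  base_labels <- attr(dataset, "base_class_labels")
  known <- if (is.null(base_labels)) dataset$class_labels else base_labels
  if (!target %in% known) {
    stop("unknown target individual: ", target, call. = FALSE)
  }
  out <- dataset
  out$samples <- lapply(dataset$samples, function(s) {
    s$binary_label <- if (s$individual_id == target) "1" else "2"
    s
  })
  out$class_labels <- c("1", "2")
  attr(out, "base_class_labels") <- known
  attr(out, "target_individual") <- target
  out
}

#' One-vs-many EER fold plan
#'
#' Builds the base scheme's groups (days or bouts) on the relabelled view
#' and, per fold, holds out one sample from each binary class: the held-out
#' group contributes the sample of its own class, and the partner sample of
#' the opposite class is drawn from the other groups in deterministic
#' rotation. Both samples' whole groups are excluded from training, so the
#' base scheme's group-integrity holds. Folds whose held-out group offers
#' no usable pair are skipped with a message.
#'
#' @param dataset A `roar_dataset`.
#' @param target Target individual id (class `"1"`).
#' @param base_scheme `"day"` or `"bout"`.
#' @return A `fold_plan` with scheme `"eer_day"` or `"eer_bout"` and
#'   `target_individual` set. Each fold additionally carries
#'   `test_labels`, the binary labels of its two test samples.
#' @export
make_eer_folds <- function(dataset, target, base_scheme = c("day", "bout")) {
  base_scheme <- match.arg(base_scheme)
  view <- relabel_one_vs_many(dataset, target)
  m <- .as_manifest(view)
  lab <- vapply(view$samples, `[[`, character(1), "binary_label")
  names(lab) <- m$sample_id
  grp <- if (base_scheme == "day") {
    paste(m$individual_id, m$day_id, sep = "|")
  } else {
    m$bout_id
  }
  groups <- sort(unique(grp))
  group_label <- vapply(groups, function(g) lab[m$sample_id[grp == g][1]],
                        character(1))
  folds <- list()
  for (i in seq_along(groups)) {
    g <- groups[i]
    own_ids <- sort(m$sample_id[grp == g])
    own <- own_ids[1]
    opp_groups <- groups[group_label != group_label[i]]
    if (length(opp_groups) == 0L) {
      message("skipping fold for group ", g,
              ": no group of the opposite class available")
      next
    }
    partner_grp <- opp_groups[(length(folds) %% length(opp_groups)) + 1L]
    partner <- sort(m$sample_id[grp == partner_grp])[1]
    test <- c(own, partner)
    excluded <- m$sample_id[grp %in% c(g, partner_grp)]
    folds[[length(folds) + 1L]] <- list(
      train = setdiff(m$sample_id, excluded),
      test = test,
      test_labels = unname(lab[test])
    )
  }
  .fold_plan(paste0("eer_", base_scheme), folds, target_individual = target)
}

#' Check the structural invariants of a fold plan
#'
#' Per fold, train and test are disjoint; for the exhaustive schemes
#' (day, bout, sample) the test sets partition the sample ids; grouped
#' schemes never split a group across train and test.
#'
#' @param plan A `fold_plan`.
#' @param dataset The dataset (or manifest) the plan was built from.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_fold_plan <- function(plan, dataset) {
  m <- .as_manifest(dataset)
  all_ids <- m$sample_id
  grp <- switch(plan$scheme,
                day = paste(m$individual_id, m$day_id, sep = "|"),
                eer_day = paste(m$individual_id, m$day_id, sep = "|"),
                bout = m$bout_id,
                eer_bout = m$bout_id,
                sample = m$sample_id)
  names(grp) <- m$sample_id
  test_union <- character(0)
  for (f in plan$folds) {
    if (length(intersect(f$train, f$test)) > 0L) {
      stop("train/test overlap in a fold", call. = FALSE)
    }
    if (!all(c(f$train, f$test) %in% all_ids)) {
      stop("fold references unknown sample ids", call. = FALSE)
    }
    if (length(intersect(grp[f$train], grp[f$test])) > 0L) {
      stop("a ", plan$scheme, " group spans train and test", call. = FALSE)
    }
    test_union <- c(test_union, f$test)
  }
  if (plan$scheme %in% c("day", "bout", "sample")) {
    if (anyDuplicated(test_union) ||
        !setequal(test_union, all_ids)) {
      stop("test sets do not partition the dataset", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Classification accuracy of a score matrix
#'
#' Prediction is the row argmax; ties break toward the lowest class index
#' (a fixed, documented convention so results are deterministic).
#'
#' @param scores A [score_matrix()].
#' @param true_labels True labels aligned with `scores$sample_ids`; every
#'   label must be one of the score matrix's class labels.
#' @return List with `n_test`, `n_correct`, `accuracy`.
#' @export
accuracy <- function(scores, true_labels) {
  stopifnot(inherits(scores, "score_matrix"))
  true_labels <- as.character(true_labels)
  if (length(true_labels) != length(scores$sample_ids)) {
    stop("`true_labels` must align with the score rows", call. = FALSE)
  }
  if (!all(true_labels %in% scores$class_labels)) {
    stop("true labels outside the score matrix's classes", call. = FALSE)
  }
  pred <- scores$class_labels[apply(scores$values, 1L, which.max)]
  list(n_test = length(pred), n_correct = sum(pred == true_labels),
       accuracy = mean(pred == true_labels))
}

#' Equal Error Rate of genuine vs impostor score lists
#'
#' Scores are posteriors for the target class. `FAR(t)` is the fraction of
#' impostor scores `>= t` and `FRR(t)` the fraction of genuine scores
#' `< t`; thresholds sweep the midpoints of adjacent sorted distinct
#' scores plus sentinels below and above all scores. The EER is the value
#' at the FAR/FRR crossing, linearly interpolated between the bracketing
#' thresholds when the curves never exactly meet. Reported in percent.
#'
#' @param genuine_scores Nonempty numeric vector of target-class scores
#'   for genuine (target) samples.
#' @param impostor_scores Nonempty numeric vector of target-class scores
#'   for impostor (non-target) samples.
#' @param target_individual Optional label stored on the result.
#' @return List of class `eer_result`: `eer_percent` in \[0, 50\],
#'   `threshold_at_eer`, `n_genuine`, `n_impostor`, `target_individual`.
#' @export
compute_eer <- function(genuine_scores, impostor_scores,
                        target_individual = NA_character_) {
  if (length(genuine_scores) < 1L || length(impostor_scores) < 1L) {
    stop("both score lists must be nonempty", call. = FALSE)
  }
  all_scores <- sort(unique(c(genuine_scores, impostor_scores)))
  mids <- if (length(all_scores) > 1L) {
    (all_scores[-1] + all_scores[-length(all_scores)]) / 2
  } else {
    numeric(0)
  }
  thresholds <- c(min(all_scores) - 1, mids, max(all_scores) + 1)
  far <- vapply(thresholds,
                function(t) mean(impostor_scores >= t), numeric(1))
  frr <- vapply(thresholds,
                function(t) mean(genuine_scores < t), numeric(1))
  diffv <- far - frr  # nonincreasing from +? : far falls, frr rises with t
  eq <- which(abs(diffv) < 1e-12)
  if (length(eq) > 0L) {
    i <- eq[1]
    eer <- far[i]
    thr <- thresholds[i]
  } else {
    # first index where FAR drops below FRR; interpolate on the segment
    j <- which(diffv < 0)[1]
    i <- j - 1L
    s <- diffv[i] / (diffv[i] - diffv[j])
    eer <- far[i] + s * (far[j] - far[i])
    thr <- thresholds[i] + s * (thresholds[j] - thresholds[i])
  }
  structure(
    list(target_individual = target_individual,
         eer_percent = 100 * eer, threshold_at_eer = thr,
         n_genuine = length(genuine_scores),
         n_impostor = length(impostor_scores)),
    class = "eer_result"
  )
}

#' @export
print.eer_result <- function(x, ...) {
  cat(sprintf("<eer_result> %sEER = %.2f%% (threshold %.4f; %d genuine, %d impostor)\n",
              if (is.na(x$target_individual)) ""
              else paste0(x$target_individual, ": "),
              x$eer_percent, x$threshold_at_eer, x$n_genuine, x$n_impostor))
  invisible(x)
}

#' Export a fold plan as a long-format data.frame
#'
#' @param plan A `fold_plan`.
#' @return data.frame with columns `fold_index`, `sample_id`, `role`.
#' @export
fold_plan_table <- function(plan) {
  do.call(rbind, lapply(seq_along(plan$folds), function(i) {
    f <- plan$folds[[i]]
    data.frame(
      fold_index = i,
      sample_id = c(f$train, f$test),
      role = c(rep("train", length(f$train)), rep("test", length(f$test))),
      stringsAsFactors = FALSE
    )
  }))
}
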