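# Score-level sum-rule fusion and exhaustive ensemble search.

#' Sum-rule fusion of score matrices
#'
#' Adds the members' per-class scores elementwise and renormalizes each row
#' to sum to 1. All members must carry identical sample ids (same order)
#' and identical class labels. Order of the member list does not matter.
#'
#' @param matrices List of [score_matrix()] objects (>= 1).
#' @return The fused [score_matrix()].
#' @export
sum_rule <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L) {
    stop("`matrices` must be a nonempty list", call. = FALSE)
  }
  ref <- matrices[[1]]
  for (m in matrices) {
    stopifnot(inherits(m, "score_matrix"))
    if (!identical(m$sample_ids, ref$sample_ids) ||
        !identical(m$class_labels, ref$class_labels)) {
      stop("alignment error: members differ in sample ids or class labels",
           call. = FALSE)
    }
  }
  total <- Reduce(`+`, lapply(matrices, `[[`, "values"))
  total <- total / rowSums(total)
  score_matrix(total, ref$sample_ids, ref$class_labels)
}

#' Exhaustive search over 2- or 3-member sum-rule ensembles
#'
#' Evaluates every size-`k` combination of the stored members by sum-rule
#' fusion and the requested metric, and returns them ranked (descending
#' for accuracy, ascending for EER). Ties are broken lexicographically by
#' the joined member names, so rankings are deterministic.
#'
#' @param score_store Named list of [score_matrix()] objects, one per
#'   member (names identify the member, e.g.
#'   `"tiny-scratch|lm|min_max"`).
#' @param k Ensemble size, 2 or 3.
#' @param metric `"accuracy"` (multiclass) or `"eer"` (binary one-vs-many
#'   stores whose class labels are `"1"` = target, `"2"` = other).
#' @param true_labels True labels aligned with every member's
#'   `sample_ids`.
#' @return A data.frame with columns `rank`, `members`
#'   (`" + "`-joined names), and `metric`.
#' @export
search_ensembles <- function(score_store, k, metric = c("accuracy", "eer"),
                             true_labels) {
  metric <- match.arg(metric)
  if (!k %in% c(2L, 3L)) stop("`k` must be 2 or 3", call. = FALSE)
  if (is.null(names(score_store)) || anyDuplicated(names(score_store))) {
    stop("`score_store` must have unique names", call. = FALSE)
  }
  m <- length(score_store)
  if (k > m) stop("`k` exceeds the number of stored members", call. = FALSE)
  combos <- utils::combn(sort(names(score_store)), k, simplify = FALSE)
  vals <- vapply(combos, function(members) {
    fused <- sum_rule(score_store[members])
    ensemble_metric(fused, true_labels, metric)
  }, numeric(1))
  names_joined <- vapply(combos, paste, character(1), collapse = " + ")
  ord <- order(if (metric == "accuracy") -vals else vals, names_joined)
  data.frame(rank = seq_along(ord), members = names_joined[ord],
             metric = vals[ord], stringsAsFactors = FALSE)
}

#' Metric used by the ensemble search
#'
#' @param scores A [score_matrix()].
#' @param true_labels True labels aligned with `scores$sample_ids`.
#' @param metric `"accuracy"` or `"eer"` (EER in percent; requires binary
#'   class labels `"1"`/`"2"` with `"1"` the target class).
#' @return The metric value.
#' @export
ensemble_metric <- function(scores, true_labels,
                            metric = c("accuracy", "eer")) {
  metric <- match.arg(metric)
  if (metric == "accuracy") {
    accuracy(scores, true_labels)$accuracy
  } else {
    if (!identical(scores$class_labels, c("1", "2"))) {
      stop("EER metric requires binary class labels \"1\"/\"2\"",
           call. = FALSE)
    }
    s1 <- scores$values[, "1"]
    compute_eer(s1[true_labels == "1"], s1[true_labels != "1"])$eer_percent
  }
}
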