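# Fold designs, accuracy conventions, and the Equal Error Rate.

test_that("the field-shaped dataset yields exactly 20 day folds", {
  ds <- fixture_dataset()
  plan <- make_day_folds(ds)
  expect_equal(length(plan$folds), 20L)
  expect_true(validate_fold_plan(plan, ds))
})

test_that("a 2x2x1-sample design gives 4 singleton day folds", {
  m <- expand.grid(individual_id = c("a", "b"), day_id = c("d1", "d2"),
                   stringsAsFactors = FALSE)
  m$sample_id <- sprintf("s%d", seq_len(nrow(m)))
  m$bout_id <- sprintf("bout%d", seq_len(nrow(m)))
  m$index_in_bout <- 1L
  plan <- make_day_folds(m)
  expect_equal(length(plan$folds), 4L)
  expect_true(all(vapply(plan$folds, function(f) length(f$test),
                         integer(1)) == 1L))
})

test_that("bout folds: one fold per bout, test sets of 1-3", {
  ds <- fixture_dataset()
  m <- dataset_manifest(ds)
  plan <- make_bout_folds(ds)
  expect_equal(length(plan$folds), length(unique(m$bout_id)))
  sizes <- vapply(plan$folds, function(f) length(f$test), integer(1))
  expect_true(all(sizes %in% 1:3))
  expect_true(validate_fold_plan(plan, ds))
})

test_that("two bouts give two mutually complementary folds", {
  m <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    individual_id = c("a", "a", "b"),
    day_id = c("d1", "d2", "d1"),
    bout_id = c("b1", "b2", "b3"),
    index_in_bout = 1L
  )
  # b requires >= 2 bouts per class; build a compliant 2-class case
  m2 <- data.frame(
    sample_id = sprintf("s%d", 1:4),
    individual_id = rep(c("a", "b"), each = 2),
    day_id = rep(c("d1", "d2"), 2),
    bout_id = sprintf("b%d", 1:4),
    index_in_bout = 1L
  )
  plan <- make_bout_folds(m2)
  expect_equal(length(plan$folds), 4L)
  f <- plan$folds[[1]]
  expect_setequal(c(f$train, f$test), m2$sample_id)
})

test_that("degenerate designs are rejected with the class named", {
  m <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    individual_id = c("a", "a", "a", "a", "solo", "solo"),
    day_id = c("d1", "d1", "d2", "d2", "d9", "d9"),
    bout_id = c("b1", "b1", "b2", "b2", "b9", "b9"),
    index_in_bout = c(1L, 2L, 1L, 2L, 1L, 2L)
  )
  expect_error(make_day_folds(m), "solo")
  expect_error(make_bout_folds(m), "solo")
})

test_that("fold plans hold their invariants over 100 random datasets", {
  for (s in 1:100) {
    m <- random_manifest(s)
    day <- make_day_folds(m)
    bout <- make_bout_folds(m)
    expect_true(validate_fold_plan(day, m))
    expect_true(validate_fold_plan(bout, m))
    expect_equal(length(day$folds),
                 nrow(unique(m[, c("individual_id", "day_id")])))
    expect_equal(length(bout$folds), length(unique(m$bout_id)))
  }
})

test_that("one-vs-many relabelling partitions the samples and is idempotent", {
  ds <- fixture_dataset()
  target <- ds$class_labels[1]
  v <- relabel_one_vs_many(ds, target)
  labs <- vapply(v$samples, `[[`, character(1), "binary_label")
  inds <- vapply(ds$samples, `[[`, character(1), "individual_id")
  expect_equal(sum(labs == "1"), sum(inds == target))
  expect_equal(sum(labs == "2"), sum(inds != target))
  expect_identical(v$class_labels, c("1", "2"))
  expect_identical(relabel_one_vs_many(v, target), v)
  expect_error(relabel_one_vs_many(ds, "ghost"), "unknown target")
})

test_that("EER folds pair one sample of each class without group leakage", {
  ds <- fixture_dataset()
  target <- ds$class_labels[2]
  for (base in c("day", "bout")) {
    plan <- make_eer_folds(ds, target, base)
    n_groups <- if (base == "day") 20L else
      length(unique(dataset_manifest(ds)$bout_id))
    expect_lte(length(plan$folds), n_groups)
    expect_true(validate_fold_plan(plan, ds))
    for (f in plan$folds) {
      expect_length(f$test, 2L)
      expect_setequal(f$test_labels, c("1", "2"))
    }
  }
})

test_that("accuracy counts argmax matches with ties toward the lower index", {
  onehot <- score_matrix(diag(3), sprintf("s%d", 1:3),
                         c("a", "b", "c"))
  expect_equal(accuracy(onehot, c("a", "b", "c"))$accuracy, 1.0)

  half <- score_matrix(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                       c("s1", "s2"), c("a", "b"))
  expect_equal(accuracy(half, c("a", "a"))$accuracy, 0.5)

  tie <- score_matrix(matrix(c(0.5, 0.5), 1), "s1", c("a", "b"))
  expect_equal(accuracy(tie, "a")$n_correct, 1L)
  expect_equal(accuracy(tie, "b")$n_correct, 0L)
  expect_error(accuracy(tie, "zz"), "outside")
})

test_that("perfect separation gives EER 0 and the worked example 33.3 %", {
  expect_equal(compute_eer(c(0.9, 0.8), c(0.1, 0.2))$eer_percent, 0)
  r <- compute_eer(c(0.9, 0.7, 0.6), c(0.8, 0.3, 0.1))
  expect_equal(r$eer_percent, 100 / 3, tolerance = 1e-9)
  expect_gt(r$threshold_at_eer, 0.6)
  expect_lte(r$threshold_at_eer, 0.75)
  expect_error(compute_eer(numeric(0), 0.5), "nonempty")
})

test_that("EER matches the exhaustive threshold-sweep oracle on short lists", {
  set.seed(30)
  for (rep_i in 1:60) {
    ng <- sample(1:20, 1)
    ni <- sample(1:20, 1)
    # mix continuous scores and heavy ties
    pool <- if (rep_i %% 2 == 0) runif(ng + ni) else
      sample(seq(0, 1, 0.25), ng + ni, replace = TRUE)
    g <- pool[seq_len(ng)] + rep_i %% 3 * 0.1
    im <- pool[ng + seq_len(ni)]
    expect_equal(compute_eer(g, im)$eer_percent, oracle_eer(g, im),
                 tolerance = 1e-9)
  }
})

test_that("EER is invariant under joint strictly increasing transforms", {
  set.seed(31)
  g <- runif(15)
  im <- runif(12)
  base <- compute_eer(g, im)$eer_percent
  for (f in list(function(x) 2 * x + 3, function(x) x^3,
                 function(x) exp(x), stats::plogis)) {
    expect_equal(compute_eer(f(g), f(im))$eer_percent, base,
                 tolerance = 1e-9)
  }
})

test_that("identically distributed scores give EER near 50 %", {
  set.seed(32)
  g <- runif(1e4)
  im <- runif(1e4)
  expect_lt(abs(compute_eer(g, im)$eer_percent - 50), 2)
})

test_that("pooled accuracy equals the sample-weighted mean of fold accuracies", {
  ds <- fixture_dataset()
  images <- fixture_images("lm")
  labels <- fixture_labels()
  res <- run_scheme(images, labels, make_day_folds(ds), backbone_spec(),
                    train_config(seed = 7L))
  weighted <- sum(res$per_fold$n_correct) / sum(res$per_fold$n_test)
  expect_equal(res$overall_accuracy, weighted)
  per_fold_acc <- res$per_fold$n_correct / res$per_fold$n_test
  expect_equal(weighted,
               sum(per_fold_acc * res$per_fold$n_test) /
                 sum(res$per_fold$n_test))
  # pooled scores cover each sample exactly once
  expect_setequal(res$scores$sample_ids, names(labels))
})
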