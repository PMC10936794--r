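test_that("confusion counts partition the samples with pressure as positive", {
  cm <- confusion(rep(1, 10), rep(1, 10))
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 10, tn = 0, fp = 0, fn = 0))
  cm <- confusion_counts(tp = 121, tn = 12, fp = 2, fn = 10)
  expect_equal(cm$total, 145)
  # swapping the positive-class convention swaps tp<->tn and fp<->fn
  y <- c(1, 1, 0, 0, 1, 0); p <- c(1, 0, 0, 1, 1, 1)
  a <- confusion(y, p)
  b <- confusion(1 - y, 1 - p)
  expect_equal(c(a$tp, a$fn, a$fp), c(b$tn, b$fp, b$fn))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metric formulas agree with a brute-force recount on fuzzed labels", {
  set.seed(202)
  for (case in 1:1000) {
    n <- sample(2:60, 1)
    y <- stats::rbinom(n, 1, 0.5)
    p <- stats::rbinom(n, 1, runif(1))
    m <- metrics(confusion(y, p))
    o <- brute_metrics(y, p)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$precision, o$precision)
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
    # accuracy is the prevalence-weighted mean of sensitivity and specificity
    P <- sum(y == 1); N <- sum(y == 0)
    if (P > 0 && N > 0) {
      expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
    }
  }
})

test_that("degenerate confusion matrices are flagged, not fabricated", {
  m <- metrics(confusion_counts(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(all(c("precision", "sensitivity") %in% m$undefined))
  expect_true(is.na(m$f1))
  m2 <- metrics(confusion_counts(tp = 0, tn = 5, fp = 3, fn = 2))
  expect_equal(m2$f1, 0)            # precision = sensitivity = 0
  m3 <- metrics(confusion_counts(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(m3$accuracy, 0.5)
  # harmonic-mean fixed point: precision = sensitivity = p gives F1 = p
  m4 <- metrics(confusion_counts(tp = 30, tn = 50, fp = 10, fn = 10))
  expect_equal(m4$precision, m4$sensitivity)
  expect_equal(m4$f1, m4$precision)
  expect_error(confusion_counts(0, 0, 0, 0), "empty")
})

test_that("k-fold plans are balanced partitions with each sample validated once", {
  plan <- kfold(145, k = 5, seed = 1)
  expect_true(all(lengths(plan$folds) == 29))
  all_idx <- unlist(plan$folds)
  expect_equal(sort(all_idx), 1:145)       # disjoint union = everything
  plan2 <- kfold(17, k = 5, seed = 2)
  expect_true(max(lengths(plan2$folds)) - min(lengths(plan2$folds)) <= 1)
  expect_identical(kfold(50, 5, seed = 3)$folds, kfold(50, 5, seed = 3)$folds)
  expect_error(kfold(10, k = 1), ">= 2")
  expect_error(kfold(4, k = 5), "exceed")
})

test_that("ROC endpoints, extremes and the permutation null behave", {
  y <- c(rep(0, 50), rep(1, 50))
  perfect <- roc(y, as.numeric(y))
  expect_equal(perfect$auc, 1)
  expect_equal(roc(y, -as.numeric(y))$auc, 0)
  expect_equal(perfect$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(perfect$points[nrow(perfect$points), ]),
               c(fpr = 1, tpr = 1))
  set.seed(77)
  yb <- stats::rbinom(10000, 1, 0.5)
  null_auc <- roc(yb, stats::runif(10000))$auc
  expect_lt(abs(null_auc - 0.5), 0.02)
  expect_error(roc(rep(1, 5), runif(5)), "both classes")
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(5)
  y <- stats::rbinom(200, 1, 0.4)
  s <- stats::rnorm(200) + y
  base <- roc(y, s)
  expect_equal(roc(y, exp(s))$auc, base$auc)
  expect_equal(roc(y, 3 * s - 7)$points, base$points)
})

test_that("the hand-built ROC matches an independent reference", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- stats::rbinom(300, 1, 0.5)
  s <- stats::rnorm(300, mean = y)
  expect_equal(roc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("rule network reproduces its stated classification rules", {
  net <- rule_network()
  r0 <- evaluate_rule_network(list(I2 = 0, I7 = 0, I4 = 1, I6 = 1), net)
  expect_equal(r0$class, 0L)
  expect_true(r0$matched)
  r1 <- evaluate_rule_network(list(I2 = 0, I7 = 0, I5 = 0), net)
  expect_equal(r1$class, 1L)
  expect_true(r1$matched)
  # hidden layer: I2 = I7 = 0 forces H2 = 0; I5 = 0 forces H3 = -1
  expect_equal(unname(r1$hidden["H2"]), 0)
  expect_equal(unname(r1$hidden["H3"]), -1)
  expect_equal(unname(r1$output), c(1, 0))  # H2 = 0 and H3 = -1 fires O1
})

test_that("rule network totalizes via the default-class policy", {
  miss <- evaluate_rule_network(list(I1 = 1, I2 = 1, I3 = 0, I4 = 0, I5 = 1,
                                     I6 = 0, I7 = 1), rule_network())
  expect_false(miss$matched)
  expect_equal(miss$class, 0L)
  expect_equal(evaluate_rule_network(list(I2 = 1), rule_network(1L))$class, 1L)
  expect_error(evaluate_rule_network(list(I2 = 2), rule_network()), "domain")
  # every binary input vector maps to exactly one class
  grid <- expand.grid(rep(list(0:1), 7))
  names(grid) <- paste0("I", 1:7)
  cls <- apply(grid, 1, function(row)
    evaluate_rule_network(as.list(row), rule_network())$class)
  expect_true(all(cls %in% c(0L, 1L)))
})

test_that("the benchmark is deterministic and reports every requested family", {
  tab <- generate_breaths(dataset_config(n_rows = 240, seed = 31,
                                         effect_size = 2))
  grids <- list(DT = data.frame(cp = 0.01), NBT = data.frame(laplace = 0))
  r1 <- run_benchmark(tab, families = c("DT", "NBT"), k = 3, seed = 9,
                      grids = grids)
  r2 <- run_benchmark(tab, families = c("DT", "NBT"), k = 3, seed = 9,
                      grids = grids)
  expect_identical(r1$summary[setdiff(names(r1$summary), "train_seconds")],
                   r2$summary[setdiff(names(r2$summary), "train_seconds")])
  expect_setequal(names(r1$families), c("DT", "NBT"))
  m <- r1$families$DT$metrics
  expect_true(all(unlist(m[c("accuracy", "precision", "sensitivity",
                             "specificity", "f1")]) >= 0))
  expect_error(run_benchmark(tab, families = "DT", grids = list()),
               "empty hyperparameter grid")
})
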