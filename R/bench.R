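#' Binary confusion matrix
#'
#' Counts true/false positives/negatives with the pressure mode (label 1) as
#' the positive class: tp = (true 1, pred 1), tn = (0, 0), fp = (0, 1),
#' fn = (1, 0).
#'
#' @param y_true,y_pred Equal-length binary (0/1) label vectors, or the four
#'   counts directly via \code{confusion_counts}.
#' @return An object of class \code{confusion_matrix} with fields \code{tp},
#'   \code{tn}, \code{fp}, \code{fn}, \code{total}.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(y_true), length(y_pred)), call. = FALSE)
  }
  if (length(y_true) < 1) stop("empty label vectors", call. = FALSE)
  y_true <- as.integer(as.character(y_true))
  y_pred <- as.integer(as.character(y_pred))
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  confusion_counts(tp = sum(y_true == 1L & y_pred == 1L),
                   tn = sum(y_true == 0L & y_pred == 0L),
                   fp = sum(y_true == 0L & y_pred == 1L),
                   fn = sum(y_true == 1L & y_pred == 0L))
}

#' @rdname confusion
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  structure(as.list(c(counts, total = total)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("1 (pressure)", "0 (volume)"),
                              predicted = c("1", "0")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' accuracy = (tp + tn) / total; precision = tp / (tp + fp);
#' sensitivity (recall) = tp / (tp + fn); specificity = tn / (tn + fp);
#' F1 = 2 precision recall / (precision + recall). A metric whose
#' denominator is zero is reported as NA with its name listed in
#' \code{undefined}; F1 is 0 when precision and recall are both 0.
#'
#' @param cm A \code{\link{confusion_matrix}}.
#' @return An object of class \code{metrics_report}: the five metrics in
#'   [0, 1], \code{accuracy_pct} (accuracy as a percentage rounded to 1
#'   decimal, the table convention), and \code{undefined}.
#' @export
#' @examples
#' metrics(confusion_counts(tp = 121, tn = 12, fp = 2, fn = 10))
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  accuracy <- (cm$tp + cm$tn) / cm$total
  precision <- safe(cm$tp, cm$tp + cm$fp, "precision")
  sensitivity <- safe(cm$tp, cm$tp + cm$fn, "sensitivity")
  specificity <- safe(cm$tn, cm$tn + cm$fp, "specificity")
  f1 <- if (isTRUE(precision == 0) && isTRUE(sensitivity == 0)) 0
        else if (is.na(precision) || is.na(sensitivity)) {
          undefined <- c(undefined, "f1"); NA_real_
        } else 2 * precision * sensitivity / (precision + sensitivity)
  structure(list(accuracy = accuracy,
                 accuracy_pct = round(100 * accuracy, 1),
                 precision = precision, sensitivity = sensitivity,
                 specificity = specificity, f1 = f1,
                 undefined = undefined, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  precision %.4f  sensitivity %.4f  specificity %.4f  F1 %.4f\n",
              x$accuracy_pct, x$precision, x$sensitivity, x$specificity,
              x$f1))
  if (length(x$undefined)) {
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' k-fold cross-validation plan
#'
#' Seeded shuffle of the indices followed by contiguous fold slicing; fold
#' sizes differ by at most one, the folds are pairwise disjoint and their
#' union is all indices. Each fold serves once as the validation set while
#' the remaining k - 1 train.
#'
#' @param n Sample count.
#' @param k Fold count (default 5); must satisfy 2 <= k <= n.
#' @param seed Integer seed.
#' @return An object of class \code{cv_plan}: \code{k}, \code{seed}, and
#'   \code{folds}, a list of k validation index vectors.
#' @export
#' @examples
#' kfold(145, k = 5, seed = 1) # five folds of 29
kfold <- function(n, k = 5, seed = 1L) {
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  if (k > n) stop("'k' must not exceed the sample count", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, ends[-k] + 1)
  folds <- lapply(seq_len(k), function(i) sort(idx[starts[i]:ends[i]]))
  structure(list(k = as.integer(k), seed = as.integer(seed), folds = folds),
            class = "cv_plan")
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (predicting positive
#' when score >= threshold), collects (false positive rate, true positive
#' rate) pairs from (0, 0) to (1, 1), and integrates by the trapezoid rule.
#'
#' @param y_true Binary 0/1 labels containing both classes.
#' @param scores Real-valued scores, larger meaning more positive.
#' @return An object of class \code{roc_curve}: \code{points} (data.frame
#'   \code{fpr}, \code{tpr}, ordered) and \code{auc}.
#' @export
#' @examples
#' roc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc
roc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("labels and scores differ in length", call. = FALSE)
  }
  y_true <- as.integer(as.character(y_true))
  P <- sum(y_true == 1L); N <- sum(y_true == 0L)
  if (P == 0 || N == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & y_true == 0L) / N, tpr = sum(pred & y_true == 1L) / P)
  }, numeric(2))
  points <- data.frame(fpr = c(0, pts["fpr", ], 1),
                       tpr = c(0, pts["tpr", ], 1))
  points <- unique(points)
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                 utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' Rule-based neural classifier
#'
#' A small fixed-topology network stated as explicit rules: seven discrete
#' inputs I1..I7, three hidden nodes with activation sets
#' H1 in \{-1, 0, 1\}, H2 in \{0, 1\}, H3 in \{-1, 0.24, 1\}, and the output
#' pair (O1, O2). The shipped rule set is:
#' \itemize{
#'   \item IF I2 = 0 AND I7 = 0 THEN H2 = 0
#'   \item IF I4 = 1 AND I6 = 1 THEN H3 = -1; IF I5 = 0 THEN H3 = -1
#'   \item IF (H2 = 0 AND H3 = -1) OR (H1 = -1 AND H2 = 1 AND H3 = -1) OR
#'     (H1 = -1 AND H2 = 0 AND H3 = 0.24) THEN (O1, O2) = (1, 0) ELSE (0, 1)
#'   \item classification: IF I2 = 0 AND I7 = 0 AND I4 = 1 AND I6 = 1 THEN
#'     class 0; IF I2 = 0 AND I7 = 0 AND I5 = 0 THEN class 1 (first match
#'     wins)
#' }
#' The rule list does not cover every input combination; inputs firing no
#' classification rule receive \code{default_class} and are flagged.
#'
#' @param default_class Class returned when no rule fires (default 0).
#' @return An object of class \code{rule_network}.
#' @export
rule_network <- function(default_class = 0L) {
  if (!default_class %in% c(0L, 1L)) {
    stop("'default_class' must be 0 or 1", call. = FALSE)
  }
  structure(list(
    hidden_domains = list(H1 = c(-1, 0, 1), H2 = c(0, 1),
                          H3 = c(-1, 0.24, 1)),
    default_class = as.integer(default_class)
  ), class = "rule_network")
}

#' Evaluate the rule network on one input assignment
#'
#' @param inputs Named list or vector with entries I1..I7, each 0 or 1.
#' @param net A \code{\link{rule_network}}.
#' @return A list: \code{class} (0 or 1), \code{matched} (FALSE when the
#'   default-class policy fired), \code{hidden} (the derived H2/H3 values,
#'   NA where no hidden rule fired) and \code{output} (the (O1, O2) pair, NA
#'   when hidden values are incomplete).
#' @export
#' @examples
#' evaluate_rule_network(list(I2 = 0, I7 = 0, I4 = 1, I6 = 1), rule_network())
evaluate_rule_network <- function(inputs, net = rule_network()) {
  stopifnot(inherits(net, "rule_network"))
  inputs <- as.list(inputs)
  get_in <- function(nm) {
    if (is.null(inputs[[nm]])) return(NA_real_)
    v <- inputs[[nm]]
    if (!v %in% c(0, 1)) {
      stop("input ", nm, " outside its declared domain {0, 1}", call. = FALSE)
    }
    v
  }
  I <- vapply(paste0("I", 1:7), get_in, numeric(1))
  names(I) <- paste0("I", 1:7)
  # input -> hidden rules
  H2 <- if (isTRUE(I["I2"] == 0 && I["I7"] == 0)) 0 else NA_real_
  H3 <- if (isTRUE(I["I4"] == 1 && I["I6"] == 1) || isTRUE(I["I5"] == 0))
    -1 else NA_real_
  H1 <- NA_real_                       # no input rule assigns H1
  # hidden -> output rules
  fire <- isTRUE(H2 == 0 && H3 == -1) ||
    isTRUE(H1 == -1 && H2 == 1 && H3 == -1) ||
    isTRUE(H1 == -1 && H2 == 0 && H3 == 0.24)
  output <- if (fire) c(O1 = 1, O2 = 0) else c(O1 = 0, O2 = 1)
  # classification rules, first match wins
  if (isTRUE(I["I2"] == 0 && I["I7"] == 0 && I["I4"] == 1 && I["I6"] == 1)) {
    cls <- 0L; matched <- TRUE
  } else if (isTRUE(I["I2"] == 0 && I["I7"] == 0 && I["I5"] == 0)) {
    cls <- 1L; matched <- TRUE
  } else {
    cls <- net$default_class; matched <- FALSE
  }
  list(class = cls, matched = matched,
       hidden = c(H1 = H1, H2 = H2, H3 = H3), output = output)
}

# ---- classifier families ---------------------------------------------------

VENTILAB_FAMILIES <- c("DT", "OBT", "NBT", "NeNT", "ET", "NNT")

# Default hyperparameter grids searched inside the CV loop. Kept small so a
# full six-family run stays interactive.
default_grids <- function() {
  list(
    DT   = expand.grid(cp = c(0.01, 0.001)),
    OBT  = expand.grid(cp = c(0.02, 0.005, 0.001),
                       minsplit = c(10, 40), maxdepth = c(4, 12)),
    NBT  = expand.grid(laplace = c(0, 1)),
    NeNT = expand.grid(k = c(3, 7, 15)),
    ET   = expand.grid(nrounds = c(30, 80), max_depth = c(2, 4)),
    NNT  = expand.grid(size = c(4, 8), decay = c(0.1, 0.01))
  )
}

# Design matrix for distance/margin-based learners: one-hot the factors.
bench_model_matrix <- function(table) {
  feats <- setdiff(names(table), "label")
  for (cn in feats) {
    if (is.factor(table[[cn]]) || is.character(table[[cn]])) {
      table <- one_hot(table, cn)$table
    }
  }
  as.matrix(table[, setdiff(names(table), "label"), drop = FALSE])
}

# Fit one family with fixed hyperparameters; returns a score function
# (posterior probability of class 1) over new tables.
fit_family <- function(family, train, pars, seed) {
  set.seed(seed)
  y <- factor(train$label, levels = c(0, 1))
  feats <- setdiff(names(train), "label")
  form <- stats::as.formula(paste("label01 ~", paste(feats, collapse = "+")))
  df <- train[feats]
  df$label01 <- y
  switch(family,
    DT = {
      fit <- rpart::rpart(form, df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(cp = pars$cp))
      function(newdata) {
        stats::predict(fit, newdata[feats], type = "prob")[, "1"]
      }
    },
    OBT = {
      fit <- rpart::rpart(form, df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(
                            cp = pars$cp, minsplit = pars$minsplit,
                            maxdepth = pars$maxdepth))
      function(newdata) {
        stats::predict(fit, newdata[feats], type = "prob")[, "1"]
      }
    },
    NBT = {
      fit <- e1071::naiveBayes(form, df, laplace = pars$laplace)
      function(newdata) {
        stats::predict(fit, newdata[feats], type = "raw")[, "1"]
      }
    },
    NeNT = {
      Xtr <- bench_model_matrix(train)
      ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, stats::sd)
      scl[scl == 0] <- 1
      Xtr <- scale(Xtr, ctr, scl)
      k <- pars$k
      function(newdata) {
        Xte <- scale(bench_model_matrix(newdata), ctr, scl)
        pred <- class::knn(Xtr, Xte, cl = y, k = k, prob = TRUE)
        pwin <- attr(pred, "prob")
        ifelse(pred == "1", pwin, 1 - pwin)
      }
    },
    ET = {
      Xtr <- bench_model_matrix(train)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = pars$max_depth,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(Xtr, label = train$label),
        nrounds = pars$nrounds, verbose = 0)
      function(newdata) {
        stats::predict(fit, xgboost::xgb.DMatrix(bench_model_matrix(newdata)))
      }
    },
    NNT = {
      Xtr <- bench_model_matrix(train)
      ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, stats::sd)
      scl[scl == 0] <- 1
      Xtr <- scale(Xtr, ctr, scl)
      fit <- nnet::nnet(Xtr, nnet::class.ind(y), size = pars$size,
                        decay = pars$decay, softmax = TRUE, maxit = 200,
                        trace = FALSE)
      function(newdata) {
        Xte <- scale(bench_model_matrix(newdata), ctr, scl)
        stats::predict(fit, Xte)[, "1"]
      }
    },
    stop("unknown classifier family: ", family, call. = FALSE)
  )
}

#' Benchmark classifier families on a breath table
#'
#' Splits the table 70/30 (stratified), grid-searches each family's
#' hyperparameters by k-fold cross-validation on the training part, refits
#' the best setting on the full training part, and evaluates on the held-out
#' part: confusion matrix, the five classification metrics, ROC/AUC, and
#' wall-clock training time (informational only). Fully seeded.
#'
#' @param table A \code{breath_table} (or any data.frame with a binary
#'   \code{label} column).
#' @param families Subset of \code{c("DT", "OBT", "NBT", "NeNT", "ET",
#'   "NNT")}: Gini decision tree, grid-optimized tree, Gaussian naive Bayes,
#'   Euclidean k-nearest-neighbours, boosted tree ensemble, feed-forward
#'   neural network.
#' @param k Cross-validation folds (default 5).
#' @param seed Integer seed governing the split, fold plan and every fit.
#' @param train_fraction Training share of the 70/30 split.
#' @param grids Named list of hyperparameter grids (data.frames), one per
#'   requested family; defaults to the packaged grids.
#' @return An object of class \code{benchmark_report}: per-family list with
#'   \code{metrics} (\code{metrics_report}), \code{roc}, \code{auc},
#'   \code{best_pars}, \code{cv_accuracy}, \code{train_seconds}; plus the
#'   fold plan and a \code{summary} data.frame.
#' @export
run_benchmark <- function(table, families = VENTILAB_FAMILIES, k = 5,
                          seed = 1L, train_fraction = 0.7,
                          grids = default_grids()) {
  families <- match.arg(families, VENTILAB_FAMILIES, several.ok = TRUE)
  for (f in families) {
    if (is.null(grids[[f]]) || nrow(grids[[f]]) == 0) {
      stop("empty hyperparameter grid for family ", f, call. = FALSE)
    }
  }
  sp <- split_table(table, train_fraction = train_fraction, seed = seed)
  plan <- kfold(nrow(sp$train), k = k, seed = seed + 1L)
  out <- list()
  for (f in families) {
    grid <- grids[[f]]
    cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
      accs <- vapply(seq_len(plan$k), function(i) {
        val <- plan$folds[[i]]
        scorer <- fit_family(f, sp$train[-val, , drop = FALSE],
                             as.list(grid[g, , drop = FALSE]),
                             seed = seed + 100L * g + i)
        pred <- as.integer(scorer(sp$train[val, , drop = FALSE]) >= 0.5)
        mean(pred == sp$train$label[val])
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    best <- which.max(cv_acc)
    t0 <- proc.time()[["elapsed"]]
    scorer <- fit_family(f, sp$train, as.list(grid[best, , drop = FALSE]),
                         seed = seed + 7L)
    train_seconds <- proc.time()[["elapsed"]] - t0
    scores <- scorer(sp$test)
    pred <- as.integer(scores >= 0.5)
    cm <- confusion(sp$test$label, pred)
    rc <- roc(sp$test$label, scores)
    out[[f]] <- list(family = f, metrics = metrics(cm), confusion = cm,
                     roc = rc, auc = rc$auc,
                     best_pars = as.list(grid[best, , drop = FALSE]),
                     cv_accuracy = cv_acc[best],
                     train_seconds = train_seconds)
  }
  summary <- do.call(rbind, lapply(out, function(r) {
    m <- r$metrics
    data.frame(family = r$family, accuracy_pct = m$accuracy_pct,
               precision = round(m$precision, 4),
               sensitivity = round(m$sensitivity, 4),
               specificity = round(m$specificity, 4),
               f1 = round(m$f1, 4), auc = round(r$auc, 4),
               train_seconds = round(r$train_seconds, 3),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(families = out, plan = plan, seed = seed,
                 summary = summary),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
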