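# Shared test oracles, independent of the implementation paths they check.

# Analytic response of tau y' + y = K u, y(0) = 0, to u = sin(w t).
analytic_sine_response <- function(t, K, tau, w) {
  K / (1 + (w * tau)^2) * (sin(w * t) - w * tau * cos(w * t) +
                             w * tau * exp(-t / tau))
}

# Brute-force metric recount straight from prediction pairs.
brute_metrics <- function(y_true, y_pred) {
  list(
    accuracy = mean(y_true == y_pred),
    precision = {
      d <- sum(y_pred == 1); if (d == 0) NA_real_ else
        sum(y_true == 1 & y_pred == 1) / d
    },
    sensitivity = {
      d <- sum(y_true == 1); if (d == 0) NA_real_ else
        sum(y_true == 1 & y_pred == 1) / d
    },
    specificity = {
      d <- sum(y_true == 0); if (d == 0) NA_real_ else
        sum(y_true == 0 & y_pred == 0) / d
    })
}

# Nearest-centroid baseline on the z-scored numeric features: the weakest
# reasonable learner, used to show the synthetic signal exists.
nearest_centroid_accuracy <- function(train, test) {
  num <- names(train)[vapply(train, is.numeric, logical(1))]
  num <- setdiff(num, "label")
  z <- zscore(train, columns = num)
  ztest <- zscore(test, fit = z$fit)$table
  c0 <- colMeans(z$table[z$table$label == 0, num])
  c1 <- colMeans(z$table[z$table$label == 1, num])
  X <- as.matrix(ztest[, num])
  d0 <- rowSums(sweep(X, 2, c0)^2)
  d1 <- rowSums(sweep(X, 2, c1)^2)
  mean(as.integer(d1 < d0) == ztest$label)
}

quiet_scenario <- function(...) suppressWarnings(run_scenario(...))
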