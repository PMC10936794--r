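# The 28 per-breath features emulated by the generator: ventilator waveform
# summaries, pressures, demographics and laboratory fillers. `shift` is the
# mode-conditional mean shift in SD units applied to pressure-mode rows
# (scaled by the config's effect_size), making classes learnable but
# overlapping.
VENTILAB_FEATURES <- list(
  tidal_volume          = list(mean = 450,  sd = 60,   shift = -0.8),
  ie_ratio              = list(mean = 0.5,  sd = 0.08, shift = 0.3),
  resp_rate             = list(mean = 15,   sd = 2.5,  shift = 0),
  peak_pressure         = list(mean = 22,   sd = 3,    shift = 1.0),
  mean_airway_pressure  = list(mean = 12,   sd = 2,    shift = 0.8),
  plateau_pressure      = list(mean = 18,   sd = 2.5,  shift = 0.6),
  reduced_pressure      = list(mean = 20,   sd = 2.5,  shift = 0.9),
  peep                  = list(mean = 7,    sd = 1.5,  shift = 0.4),
  minute_ventilation    = list(mean = 6.8,  sd = 1.0,  shift = -0.5),
  insp_time             = list(mean = 1.6,  sd = 0.2,  shift = 0),
  exp_time              = list(mean = 2.4,  sd = 0.3,  shift = 0),
  insp_flow             = list(mean = 480,  sd = 60,   shift = -0.6),
  compliance            = list(mean = 55,   sd = 10,   shift = 0),
  resistance            = list(mean = 8,    sd = 2,    shift = 0),
  fio2                  = list(mean = 45,   sd = 10,   shift = 0),
  spo2                  = list(mean = 95,   sd = 2,    shift = 0),
  etco2                 = list(mean = 38,   sd = 4,    shift = 0),
  heart_rate            = list(mean = 88,   sd = 12,   shift = 0),
  resp_effort           = list(mean = 5,    sd = 1.5,  shift = 0.7),
  leak_fraction         = list(mean = 0.05, sd = 0.02, shift = 0),
  age                   = list(mean = 62,   sd = 14,   shift = 0),
  weight                = list(mean = 72,   sd = 12,   shift = 0),
  height                = list(mean = 168,  sd = 9,    shift = 0),
  urine_output          = list(mean = 1400, sd = 350,  shift = 0),
  lactate               = list(mean = 1.8,  sd = 0.6,  shift = 0),
  creatinine            = list(mean = 1.1,  sd = 0.3,  shift = 0),
  gender                = list(levels = c("F", "M"), probs = c(0.45, 0.55)),
  sedation_level        = list(levels = c("light", "moderate", "deep"),
                               probs = c(0.3, 0.45, 0.25))
)

#' Synthetic breath-record dataset configuration
#'
#' Describes one emulated recording: row count (the emulated recordings hold
#' roughly 6000-8000 rows each), class balance, class separability and the
#' per-feature distribution spec for the 28 breath/demographic features.
#'
#' @param n_rows Number of breath records (default 7000).
#' @param class_balance Fraction of rows labeled pressure mode (class 1),
#'   in (0, 1).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param effect_size Multiplier on the mode-conditional mean shifts
#'   (default 1: learnable but overlapping classes; larger values separate
#'   the classes).
#' @param feature_spec Named list describing each feature's distribution;
#'   defaults to the packaged 28-feature spec. Must contain every declared
#'   feature.
#' @return An object of class \code{dataset_config}.
#' @export
dataset_config <- function(n_rows = 7000, class_balance = 0.5, seed = 1L,
                           effect_size = 1, feature_spec = VENTILAB_FEATURES) {
  if (n_rows < 1) stop("'n_rows' must be >= 1", call. = FALSE)
  if (class_balance <= 0 || class_balance >= 1) {
    stop("'class_balance' must lie in (0, 1)", call. = FALSE)
  }
  missing <- setdiff(names(VENTILAB_FEATURES), names(feature_spec))
  if (length(missing)) {
    stop("feature_spec omits declared feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(n_rows = as.integer(n_rows), class_balance = class_balance,
                 seed = as.integer(seed), effect_size = effect_size,
                 feature_spec = feature_spec,
                 label_rule = paste(
                   "rows are drawn from mode-conditional distributions;",
                   "label 0 = volume mode, 1 = pressure mode")),
            class = "dataset_config")
}

#' Generate a synthetic breath-record table
#'
#' Draws \code{n_rows} records with 28 features plus a binary \code{label}
#' column (0 = volume mode, 1 = pressure mode). Class counts hit
#' \code{class_balance} exactly (rounded); pressure-mode rows draw the
#' pressure-linked features from mean-shifted distributions so the classes
#' are learnable but overlapping. Deterministic given the config seed.
#'
#' @param cfg A \code{\link{dataset_config}}.
#' @return A data.frame (class \code{breath_table}) with 28 feature columns
#'   and an integer \code{label} column; no missing values.
#' @export
#' @examples
#' tab <- generate_breaths(dataset_config(n_rows = 200, seed = 7))
#' table(tab$label)
generate_breaths <- function(cfg = dataset_config()) {
  stopifnot(inherits(cfg, "dataset_config"))
  n <- cfg$n_rows
  n1 <- round(n * cfg$class_balance)
  if (n1 < 1 || n1 > n - 1) {
    stop("class balance leaves an empty class at this n_rows", call. = FALSE)
  }
  label <- c(rep(0L, n - n1), rep(1L, n1))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  label <- sample(label)              # shuffle row order, counts unchanged
  cols <- lapply(names(cfg$feature_spec), function(nm) {
    sp <- cfg$feature_spec[[nm]]
    if (!is.null(sp$levels)) {
      factor(sample(sp$levels, n, replace = TRUE, prob = sp$probs),
             levels = sp$levels)
    } else {
      mu <- sp$mean + label * cfg$effect_size * sp$shift * sp$sd
      stats::rnorm(n, mean = mu, sd = sp$sd)
    }
  })
  names(cols) <- names(cfg$feature_spec)
  out <- as.data.frame(cols)
  out$label <- label
  class(out) <- c("breath_table", "data.frame")
  out
}

#' Z-score standardization
#'
#' Centers and scales the chosen numeric columns to mean 0 and unit sample
#' standard deviation (divisor n - 1). The fitted means and SDs are returned
#' so held-out data can be transformed with the training statistics.
#'
#' @param table A data.frame.
#' @param columns Column names to standardize; default all numeric columns
#'   except \code{label}.
#' @param fit Optional previously fitted \code{zscore_fit}; when supplied,
#'   its means/SDs are applied instead of refitting (no peeking at the new
#'   data's statistics).
#' @return A list of class \code{zscore_result}: \code{table} (transformed),
#'   and \code{fit} (\code{zscore_fit} with \code{center} and \code{scale}).
#' @export
#' @examples
#' z <- zscore(data.frame(x = c(1, 2, 3)))
#' z$table$x # -1 0 1
zscore <- function(table, columns = NULL, fit = NULL) {
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
    columns <- setdiff(columns, "label")
  }
  if (is.null(fit)) {
    center <- vapply(columns, function(cn) mean(table[[cn]]), numeric(1))
    scale <- vapply(columns, function(cn) stats::sd(table[[cn]]), numeric(1))
    degenerate <- columns[!is.finite(scale) | scale == 0]
    if (length(degenerate)) {
      stop("constant column(s) cannot be z-scored: ",
           paste(degenerate, collapse = ", "), call. = FALSE)
    }
    fit <- structure(list(columns = columns, center = center, scale = scale),
                     class = "zscore_fit")
  } else {
    stopifnot(inherits(fit, "zscore_fit"))
    columns <- fit$columns
  }
  for (cn in columns) {
    table[[cn]] <- (table[[cn]] - fit$center[[cn]]) / fit$scale[[cn]]
  }
  list(table = table, fit = fit)
}

#' Invert a z-score transform
#'
#' @param table A transformed data.frame.
#' @param fit The \code{zscore_fit} used for the forward transform.
#' @return The data.frame on the original scale.
#' @export
zscore_invert <- function(table, fit) {
  stopifnot(inherits(fit, "zscore_fit"))
  for (cn in fit$columns) {
    table[[cn]] <- table[[cn]] * fit$scale[[cn]] + fit$center[[cn]]
  }
  table
}

#' One-hot encode a categorical column
#'
#' Expands one categorical column into one binary column per level
#' (\code{<column>_<level>}); each encoded row has exactly one 1 across the
#' new columns. The level registry is returned so held-out data is encoded
#' against the training levels; unseen categories raise an error.
#'
#' @param table A data.frame.
#' @param column Name of the categorical column.
#' @param registry Optional level registry from a previous fit.
#' @return A list of class \code{one_hot_result}: \code{table} (column
#'   replaced by its indicators) and \code{registry} (character vector of
#'   levels).
#' @export
#' @examples
#' one_hot(data.frame(mode = c("CPAP", "PAV")), "mode")$table
one_hot <- function(table, column, registry = NULL) {
  if (!column %in% names(table)) {
    stop("no such column: ", column, call. = FALSE)
  }
  x <- as.character(table[[column]])
  if (is.null(registry)) {
    registry <- unique(x)
    if (length(registry) < 1) stop("column has no levels", call. = FALSE)
  } else {
    unseen <- setdiff(unique(x), registry)
    if (length(unseen)) {
      stop("unseen categor", if (length(unseen) > 1) "ies: " else "y: ",
           paste(unseen, collapse = ", "), " in column '", column, "'",
           call. = FALSE)
    }
  }
  ind <- vapply(registry, function(lv) as.integer(x == lv),
                integer(nrow(table)))
  if (nrow(table) == 1L) ind <- matrix(ind, nrow = 1)
  colnames(ind) <- paste(column, registry, sep = "_")
  pos <- match(column, names(table))
  out <- cbind(table[seq_len(pos - 1)], as.data.frame(ind),
               table[seq_len(ncol(table) - pos) + pos])
  list(table = out, registry = registry)
}

#' Stratified train/test split
#'
#' Splits by the \code{label} column, stratified so each class contributes
#' proportionally; train size is \code{round(n * train_fraction)} overall.
#' Deterministic given the seed; train and test are disjoint and their union
#' is the input.
#'
#' @param table A data.frame with a binary \code{label} column.
#' @param train_fraction Fraction assigned to training, in (0, 1);
#'   default 0.7.
#' @param seed Integer seed.
#' @return A list with \code{train} and \code{test} data.frames.
#' @export
#' @examples
#' sp <- split_table(generate_breaths(dataset_config(n_rows = 100, seed = 3)))
#' nrow(sp$train) # 70
split_table <- function(table, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must lie in (0, 1)", call. = FALSE)
  }
  if (!"label" %in% names(table)) {
    stop("table has no 'label' column", call. = FALSE)
  }
  n <- nrow(table)
  classes <- sort(unique(table$label))
  counts <- table(table$label)
  if (any(counts < 2)) {
    stop("every class needs >= 2 rows for a stratified split", call. = FALSE)
  }
  target <- round(n * train_fraction)
  base <- floor(counts * train_fraction)
  rem <- target - sum(base)
  if (rem > 0) {   # distribute the rounding remainder by fractional part
    frac <- counts * train_fraction - base
    ord <- order(frac, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  train_idx <- unlist(lapply(seq_along(classes), function(i) {
    idx <- which(table$label == classes[i])
    sample(idx, base[[as.character(classes[i])]])
  }))
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[setdiff(seq_len(n), train_idx), , drop = FALSE])
}
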