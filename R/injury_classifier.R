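#' Stratified train/validation/test split
#'
#' Partitions a labelled feature dataset into disjoint, label-stratified
#' subsets, deterministically for a given seed. The published split quotes
#' "75%, 15%, and 15%", which sums to 105%; the default here keeps the 15/15
#' validation/test shares and assigns the typo to the training share
#' (70/15/15). Per-class subset sizes use largest-remainder rounding, so 100
#' samples at `c(0.70, 0.15, 0.15)` yield exactly 70/15/15.
#'
#' @param dataset A tibble with a `label` factor (e.g. from
#'   [build_dataset()]).
#' @param fractions Length-3 nonnegative weights for train/validation/test;
#'   normalised to sum to 1.
#' @param seed RNG seed making the partition reproducible.
#' @return A named list of tibbles: `train`, `validation`, `test`.
#' @export
split_dataset <- function(dataset, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  stopifnot("label" %in% names(dataset), length(fractions) == 3,
            all(fractions >= 0), sum(fractions) > 0)
  fractions <- fractions / sum(fractions)
  set.seed(seed)
  parts <- list(train = integer(), validation = integer(), test = integer())
  for (lv in levels(factor(dataset$label))) {
    idx <- sample(which(dataset$label == lv))
    n <- length(idx)
    sizes <- floor(fractions * n)
    rem <- n - sum(sizes)
    if (rem > 0) {
      extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    cuts <- cumsum(c(0L, sizes))
    for (k in 1:3) {
      parts[[k]] <- c(parts[[k]], idx[seq_len(sizes[k]) + cuts[k]])
    }
  }
  lapply(parts, function(ix) dataset[sort(ix), , drop = FALSE])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

new_ann_model <- function(w_hidden, b_hidden, w_out, b_out, scaler,
                          features, training_record) {
  structure(
    list(w_hidden = w_hidden, b_hidden = b_hidden, w_out = w_out,
         b_out = b_out, scaler = scaler, features = features,
         training_record = training_record),
    class = "pq_ann"
  )
}

#' Train the injury classifier
#'
#' Fits the two-layer feed-forward network — nine texture-feature inputs, 18
#' sigmoid hidden units, one sigmoid output — that separates injured from
#' noninjured lung tissue. Features are z-scored by training-set statistics
#' (the scaler is stored with the model); fitting uses [nnet::nnet()] with
#' cross-entropy loss and an iteration cap of 5000, and the validation split
#' selects the weight-decay setting by validation cross-entropy. The fitted
#' weights are extracted into an explicit weight/bias representation that
#' [predict.pq_ann()] evaluates directly.
#'
#' @param data Either a labelled tibble (split internally via
#'   [split_dataset()]) or a list with `train`/`validation`/`test` tibbles.
#' @param hidden Number of hidden units (default 18).
#' @param max_iter Iteration cap (default 5000).
#' @param seed RNG seed for the split and the weight initialisation.
#' @param decay_grid Weight-decay values scored on the validation split.
#' @param fractions Split fractions when `data` is unsplit.
#' @param features Feature column names (default the nine texture features).
#' @return A `pq_ann` model object.
#' @export
train_injury_ann <- function(data, hidden = 18, max_iter = 5000, seed = 1L,
                             decay_grid = c(1e-4, 1e-3, 1e-2),
                             fractions = c(0.70, 0.15, 0.15),
                             features = FEATURE_NAMES) {
  if (!is.data.frame(data)) {
    splits <- data
  } else {
    splits <- split_dataset(data, fractions = fractions, seed = seed)
  }
  train <- splits$train
  val <- splits$validation
  if (is.null(train) || nrow(train) == 0) stop("empty training split",
                                               call. = FALSE)
  if (nlevels(droplevels(factor(train$label))) < 2) {
    stop("training split must contain both classes", call. = FALSE)
  }
  xtr <- as.matrix(train[, features])
  if (!all(is.finite(xtr))) stop("non-finite feature values", call. = FALSE)
  ctr <- colMeans(xtr)
  scl <- apply(xtr, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  zt <- sweep(sweep(xtr, 2, ctr), 2, scl, "/")
  yt <- as.numeric(train$label == "injured")
  use_val <- !is.null(val) && nrow(val) > 0 &&
    nlevels(droplevels(factor(val$label))) == 2
  zv <- NULL
  if (use_val) {
    xv <- as.matrix(val[, features])
    zv <- sweep(sweep(xv, 2, ctr), 2, scl, "/")
    yv <- as.numeric(val$label == "injured")
  }
  best <- NULL
  for (decay in decay_grid) {
    set.seed(seed)
    fit <- nnet::nnet(zt, yt, size = hidden, decay = decay,
                      maxit = max_iter, entropy = TRUE, trace = FALSE,
                      MaxNWts = 10000)
    p <- as.numeric(fit$fitted.values)
    loss <- if (use_val) {
      pv <- as.numeric(stats::predict(fit, zv))
      pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
      -mean(yv * log(pv) + (1 - yv) * log(1 - pv))
    } else {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(yt * log(p) + (1 - yt) * log(1 - p))
    }
    if (is.null(best) || loss < best$loss) {
      best <- list(fit = fit, loss = loss, decay = decay)
    }
    if (!use_val) break  # nothing to select on
  }
  fit <- best$fit
  nin <- ncol(zt)
  # nnet weight layout: per hidden unit (bias, nin weights), then output
  # unit (bias, hidden weights)
  wts <- fit$wts
  wh <- matrix(NA_real_, nrow = nin, ncol = hidden)
  bh <- numeric(hidden)
  for (j in seq_len(hidden)) {
    blk <- wts[((j - 1) * (nin + 1) + 1):(j * (nin + 1))]
    bh[j] <- blk[1]
    wh[, j] <- blk[-1]
  }
  out_blk <- wts[(hidden * (nin + 1) + 1):length(wts)]
  conv_flag <- is.null(fit$convergence) || fit$convergence != 0
  if (conv_flag) {
    # nnet reports nonzero convergence when the iteration cap was reached
    message("iteration cap reached before convergence; model returned as-is")
  }
  new_ann_model(
    w_hidden = wh, b_hidden = bh, w_out = out_blk[-1], b_out = out_blk[1],
    scaler = list(center = ctr, scale = scl),
    features = features,
    training_record = list(
      n_train = nrow(train),
      n_validation = if (use_val) nrow(val) else 0L,
      n_test = if (!is.null(splits$test)) nrow(splits$test) else 0L,
      max_iter = max_iter, hidden = hidden, decay = best$decay,
      selection_loss = best$loss, final_value = fit$value,
      hit_iteration_cap = conv_flag, seed = seed)
  )
}

#' @export
print.pq_ann <- function(x, ...) {
  tr <- x$training_record
  cat(sprintf("<pq_ann> %d-%d-1 sigmoid feed-forward network\n",
              nrow(x$w_hidden), ncol(x$w_hidden)))
  cat(sprintf("  trained on %d samples (val %d), decay %.4g, seed %d\n",
              tr$n_train, tr$n_validation, tr$decay, tr$seed))
  invisible(x)
}

#' Predict injury probabilities
#'
#' Evaluates `sigmoid(b_out + w_out . sigmoid(b_h + W' z))` with `z` the
#' stored-scaler standardisation of the nine features. Output lies strictly
#' in (0, 1); a batch prediction equals element-wise single predictions.
#'
#' @param object A `pq_ann` model.
#' @param newdata A tibble/data frame containing the model's feature columns,
#'   or a numeric matrix with one column per feature.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the `injured` class.
#' @export
predict.pq_ann <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else
    as.matrix(as.data.frame(newdata)[, object$features])
  if (ncol(x) != nrow(object$w_hidden)) {
    stop("feature dimensionality does not match the model", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  z <- sweep(sweep(x, 2, object$scaler$center), 2, object$scaler$scale, "/")
  hmat <- sigmoid(sweep(z %*% object$w_hidden, 2, object$b_hidden, "+"))
  p <- as.numeric(sigmoid(hmat %*% object$w_out + object$b_out))
  # keep the output strictly inside (0, 1) even when the logit saturates
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Classify every in-lung pixel of a volume
#'
#' Extracts the nine texture features for all pixels of the lung mask,
#' applies the trained network, and thresholds the probabilities into an
#' injured-candidate mask (a subset of the lung by construction).
#'
#' @param model A `pq_ann` model.
#' @param volume A [ct_volume()] (usually the smoothed volume).
#' @param lung A [binary_mask()] with role `"lung"`.
#' @param threshold Probability cutoff (default 0.5); 0 marks the whole lung,
#'   above 1 marks nothing.
#' @param rco_method Passed to [extract_feature_table()].
#' @return A [binary_mask()] with role `"injured_candidate"` and an attribute
#'   `probabilities` (tibble of per-pixel scores).
#' @export
classify_volume <- function(model, volume, lung, threshold = 0.5,
                            rco_method = "product") {
  bits <- mask_bits(lung)
  if (!any(bits)) stop("empty lung mask", call. = FALSE)
  feats <- extract_feature_table(volume, lung, rco_method = rco_method)
  p <- predict(model, feats)
  out <- array(FALSE, dim = dim(bits))
  sel <- p >= threshold
  out[cbind(feats$slice, feats$row, feats$col)[sel, , drop = FALSE]] <- TRUE
  m <- binary_mask(out, role = "injured_candidate",
                   spacing_mm = volume$spacing_mm,
                   source_scan_id = volume$scan_id)
  attr(m, "probabilities") <- tibble(
    slice = feats$slice, row = feats$row, col = feats$col, probability = p)
  m
}

#' Evaluate the classifier on a labelled test set
#'
#' Computes the full ROC curve (one operating point per distinct score), the
#' area under it by the trapezoid rule, and the confusion matrix at a chosen
#' probability threshold.
#'
#' @param model A `pq_ann` model.
#' @param test Labelled feature tibble with both classes present.
#' @param threshold Probability cutoff for the confusion matrix.
#' @return A `pq_eval` object: `roc` (tibble of `threshold`, `fpr`, `tpr`),
#'   `auc`, `confusion` (2 × 2 table), `threshold`, `n`.
#' @export
evaluate_classifier <- function(model, test, threshold = 0.5) {
  stopifnot("label" %in% names(test))
  y <- test$label == "injured"
  if (!any(y) || all(y)) {
    stop("ROC undefined: test set must contain both classes", call. = FALSE)
  }
  p <- predict(model, test)
  roc <- roc_points(p, y)
  auc <- trapezoid_auc(roc$fpr, roc$tpr)
  pred <- factor(ifelse(p >= threshold, "injured", "noninjured"),
                 levels = c("noninjured", "injured"))
  truth <- factor(ifelse(y, "injured", "noninjured"),
                  levels = c("noninjured", "injured"))
  structure(
    list(roc = roc, auc = auc, confusion = table(truth = truth, pred = pred),
         threshold = threshold, n = length(y)),
    class = "pq_eval"
  )
}

roc_points <- function(scores, truth) {
  np <- sum(truth)
  nn <- sum(!truth)
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(ths, function(t) sum(scores >= t & truth) / np, 0)
  fpr <- vapply(ths, function(t) sum(scores >= t & !truth) / nn, 0)
  tibble(threshold = ths, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                          utils::tail(tpr[ord], -1)) / 2)
}

#' @export
print.pq_eval <- function(x, ...) {
  cat(sprintf("<pq_eval> n = %d, AUC = %.4f (threshold %.2f)\n",
              x$n, x$auc, x$threshold))
  print(x$confusion)
  invisible(x)
}

# broom-style accessors --------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the ROC curve of an evaluation report
#' @param x A `pq_eval` object.
#' @param ... Unused.
#' @return A tibble of ROC operating points.
#' @export
tidy.pq_eval <- function(x, ...) x$roc

#' One-row evaluation summary
#' @param x A `pq_eval` object.
#' @param ... Unused.
#' @return A tibble with `n`, `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `threshold`.
#' @export
glance.pq_eval <- function(x, ...) {
  cm <- x$confusion
  tibble(
    n = x$n, auc = x$auc,
    accuracy = sum(diag(cm)) / sum(cm),
    sensitivity = cm["injured", "injured"] / sum(cm["injured", ]),
    specificity = cm["noninjured", "noninjured"] / sum(cm["noninjured", ]),
    threshold = x$threshold
  )
}

#' Tidy the network weights
#' @param x A `pq_ann` model.
#' @param ... Unused.
#' @return A tibble with one row per weight/bias (`layer`, `from`, `to`,
#'   `estimate`).
#' @export
tidy.pq_ann <- function(x, ...) {
  hid <- ncol(x$w_hidden)
  dplyr::bind_rows(
    tibble(layer = "hidden",
           from = rep(c("bias", x$features), hid),
           to = rep(sprintf("h%02d", seq_len(hid)),
                    each = nrow(x$w_hidden) + 1),
           estimate = as.numeric(rbind(x$b_hidden, x$w_hidden))),
    tibble(layer = "output", from = c("bias", sprintf("h%02d", seq_len(hid))),
           to = "output", estimate = c(x$b_out, x$w_out))
  )
}

#' One-row model summary
#' @param x A `pq_ann` model.
#' @param ... Unused.
#' @return A tibble summarising architecture and training record.
#' @export
glance.pq_ann <- function(x, ...) {
  tr <- x$training_record
  tibble(n_inputs = nrow(x$w_hidden), n_hidden = ncol(x$w_hidden),
         n_train = tr$n_train, n_validation = tr$n_validation,
         decay = tr$decay, max_iter = tr$max_iter,
         hit_iteration_cap = tr$hit_iteration_cap, seed = tr$seed)
}

#' Save or load a trained model
#'
#' Serialises the explicit weight representation, scaler and training record
#' to a portable JSON file.
#'
#' @param model A `pq_ann` model.
#' @param path Output path (`.json`).
#' @return `write_ann_model()` returns `path` invisibly; `read_ann_model()`
#'   the model.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "pq_ann"))
  payload <- list(
    w_hidden = model$w_hidden, b_hidden = model$b_hidden,
    w_out = model$w_out, b_out = model$b_out,
    scaler = model$scaler, features = model$features,
    training_record = model$training_record)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_ann_model(
    w_hidden = matrix(p$w_hidden, nrow = length(p$features)),
    b_hidden = as.numeric(p$b_hidden),
    w_out = as.numeric(p$w_out), b_out = as.numeric(p$b_out),
    scaler = list(center = stats::setNames(as.numeric(p$scaler$center),
                                           p$features),
                  scale = stats::setNames(as.numeric(p$scaler$scale),
                                          p$features)),
    features = p$features, training_record = p$training_record)
}
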