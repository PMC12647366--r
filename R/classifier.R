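# Subtype classifier: a single-hidden-layer feedforward network (6 logistic
# units, softmax output) over standardized hub-gene expression, trained by
# full-batch gradient descent on the cross-entropy. The step is halved
# whenever it would increase the loss, so the training loss is non-increasing
# by construction and training is bit-reproducible under a fixed seed.

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

nn_forward <- function(model, X) {
  H <- stats::plogis(X %*% model$W1 + matrix(model$b1, nrow(X),
                                             length(model$b1), byrow = TRUE))
  P <- softmax_rows(H %*% model$W2 + matrix(model$b2, nrow(X),
                                            length(model$b2), byrow = TRUE))
  list(H = H, P = P)
}

nn_loss <- function(P, Y1h) {
  -mean(rowSums(Y1h * log(pmax(P, 1e-12))))
}

nn_fit <- function(X, y, k, hidden = 6, epochs = 2000, lr = 0.01, seed = 1) {
  n <- nrow(X); d <- ncol(X)
  Y1h <- matrix(0, n, k)
  Y1h[cbind(seq_len(n), y)] <- 1
  set.seed(derive_seed(seed, 51L))
  model <- list(
    W1 = matrix(stats::runif(d * hidden, -0.5, 0.5), d, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::runif(hidden * k, -0.5, 0.5), hidden, k),
    b2 = rep(0, k))
  fw <- nn_forward(model, X)
  loss <- nn_loss(fw$P, Y1h)
  trace <- numeric(epochs + 1)
  trace[1] <- loss
  step <- lr
  for (ep in seq_len(epochs)) {
    dZ2 <- (fw$P - Y1h) / n                       # n x k
    gW2 <- t(fw$H) %*% dZ2
    gb2 <- colSums(dZ2)
    dH <- dZ2 %*% t(model$W2) * fw$H * (1 - fw$H) # logistic derivative
    gW1 <- t(X) %*% dH
    gb1 <- colSums(dH)
    repeat {
      cand <- list(W1 = model$W1 - step * gW1, b1 = model$b1 - step * gb1,
                   W2 = model$W2 - step * gW2, b2 = model$b2 - step * gb2)
      cand_fw <- nn_forward(cand, X)
      cand_loss <- nn_loss(cand_fw$P, Y1h)
      if (cand_loss <= loss || step < 1e-10) break
      step <- step / 2
    }
    if (cand_loss <= loss) {
      model <- cand; fw <- cand_fw; loss <- cand_loss
      if (step < lr) step <- min(lr, step * 2)
    }
    trace[ep + 1] <- loss
  }
  model$loss_trace <- trace
  model
}

stratified_split <- function(y, frac, seed) {
  set.seed(derive_seed(seed, 52L))
  train <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    n_tr <- max(1L, round(frac * length(idx)))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

stratified_folds <- function(y, folds, seed) {
  set.seed(derive_seed(seed, 53L))
  fold <- integer(length(y))
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  fold
}

#' Train the subtype classifier on hub-gene expression
#'
#' Splits samples stratified by class (default 8:2), standardizes each gene
#' with training-set mean and SD (the scalers are frozen into the model),
#' and fits the 6-unit single-hidden-layer softmax network by monotone
#' full-batch gradient descent. The held-out split is scored immediately.
#'
#' @param hub_expr Gene x sample expression matrix (hub genes).
#' @param labels Subtype labels per sample.
#' @param split Training fraction (default 0.8).
#' @param hidden Hidden units (default 6).
#' @param epochs,lr Training schedule (defaults 2000 and 0.01).
#' @param seed Integer seed; training is bit-reproducible given the seed.
#' @return A `subtype_classifier` with the weights, scalers, gene list,
#'   class levels, config, loss trace and `holdout` evaluation
#'   report.
#' @export
train_classifier <- function(hub_expr, labels, split = 0.8, hidden = 6,
                             epochs = 2000, lr = 0.01, seed = 1) {
  assert_that(length(labels) == ncol(hub_expr), "labels must match samples")
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  k <- length(classes)
  tr <- stratified_split(y, split, seed)
  te <- setdiff(seq_along(y), tr)
  if (length(unique(y[tr])) < k) {
    stop("a class is absent from the training split; provide more data",
         call. = FALSE)
  }
  Xall <- t(log2(hub_expr + 1))
  mu <- colMeans(Xall[tr, , drop = FALSE])
  sd_ <- apply(Xall[tr, , drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Ztr <- scale(Xall[tr, , drop = FALSE], center = mu, scale = sd_)
  net <- nn_fit(Ztr, y[tr], k, hidden = hidden, epochs = epochs, lr = lr,
                seed = seed)
  model <- structure(list(
    genes = rownames(hub_expr), classes = classes,
    center = mu, scale = sd_,
    W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
    loss_trace = net$loss_trace,
    config = list(split = split, hidden = hidden, epochs = epochs, lr = lr,
                  seed = seed)), class = "subtype_classifier")
  holdout <- NULL
  if (length(te) > 0) {
    Zte <- scale(Xall[te, , drop = FALSE], center = mu, scale = sd_)
    P <- nn_forward(model, Zte)$P
    holdout <- eval_metrics(y[te], max.col(P, "first"), P, classes)
    holdout$test_samples <- colnames(hub_expr)[te]
  }
  model$holdout <- holdout
  model
}

#' @export
print.subtype_classifier <- function(x, ...) {
  cat(sprintf("subtype_classifier: %d genes -> %d hidden -> %d classes\n",
              length(x$genes), length(x$b1), length(x$classes)))
  if (!is.null(x$holdout))
    cat(sprintf("  held-out accuracy %.3f, macro F1 %.3f\n",
                x$holdout$accuracy, x$holdout$macro_f1))
  invisible(x)
}

#' Predict subtypes for an external expression cohort
#'
#' Harmonization is a per-gene z-score computed within the external dataset
#' (cross-platform scale differences cancel). Model genes missing from the
#' cohort are imputed at the standardized mean (0) and logged; fewer than
#' 80% present is rejected with the missing list.
#'
#' @param model A `subtype_classifier`.
#' @param expr_external Gene x sample matrix of the external cohort.
#' @param harmonize "zscore" (default, within-dataset) or "model_scalers"
#'   (reuse the training scalers; appropriate for same-platform data).
#' @return List with `labels` (predicted class per sample), `probabilities`
#'   (sample x class, rows sum to 1) and `missing_genes`.
#' @export
predict_subtypes <- function(model, expr_external,
                             harmonize = c("zscore", "model_scalers")) {
  harmonize <- match.arg(harmonize)
  present <- intersect(model$genes, rownames(expr_external))
  missing <- setdiff(model$genes, present)
  if (length(present) < 0.8 * length(model$genes)) {
    stop("fewer than 80% of model genes present; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(missing) > 0) {
    message("imputing ", length(missing), " missing gene(s) at 0: ",
            paste(missing, collapse = ", "))
  }
  X <- t(log2(expr_external[present, , drop = FALSE] + 1))
  Z <- if (harmonize == "zscore") {
    s <- apply(X, 2, stats::sd); s[s == 0] <- 1
    scale(X, center = colMeans(X), scale = s)
  } else {
    scale(X, center = model$center[present], scale = model$scale[present])
  }
  Zfull <- matrix(0, nrow(Z), length(model$genes),
                  dimnames = list(rownames(Z), model$genes))
  Zfull[, present] <- Z
  P <- nn_forward(model, Zfull)$P
  colnames(P) <- as.character(model$classes)
  list(labels = model$classes[max.col(P, "first")],
       probabilities = P, missing_genes = missing)
}

# Shared evaluation metrics: accuracy, confusion, per-class/macro/weighted
# F1, one-vs-rest AUC by the Mann-Whitney rank statistic.
eval_metrics <- function(y_true, y_pred, P, classes) {
  k <- length(classes)
  conf <- table(factor(y_true, levels = seq_len(k)),
                factor(y_pred, levels = seq_len(k)))
  dimnames(conf) <- list(true = classes, predicted = classes)
  acc <- sum(diag(conf)) / sum(conf)
  f1 <- vapply(seq_len(k), function(c) {
    tp <- conf[c, c]; fp <- sum(conf[-c, c]); fn <- sum(conf[c, -c])
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  names(f1) <- classes
  auc <- vapply(seq_len(k), function(c) {
    pos <- y_true == c
    if (all(pos) || !any(pos)) return(NA_real_)
    rank_auc(P[, c], pos)
  }, 0)
  names(auc) <- classes
  weights <- as.vector(table(factor(y_true, levels = seq_len(k)))) / length(y_true)
  list(accuracy = acc, confusion = conf, f1 = f1,
       macro_f1 = mean(f1), weighted_f1 = sum(weights * f1),
       auc = auc, macro_auc = mean(auc, na.rm = TRUE))
}

#' One-vs-rest AUC from the rank statistic
#'
#' Mann-Whitney formulation: the probability a random positive outranks a
#' random negative (ties counted half).
#'
#' @param score Numeric scores.
#' @param positive Logical vector marking positives.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  assert_that(n1 > 0 && n0 > 0, "need both classes")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated evaluation of the subtype classifier
#'
#' Stratified k-fold cross-validation, retraining from the given config on
#' each training fold and scoring the left-out fold; metrics are pooled over
#' folds and also reported per fold. Classes smaller than the fold count
#' shrink the fold count with a warning.
#'
#' @param hub_expr Gene x sample matrix.
#' @param labels Subtype labels.
#' @param folds Number of folds (default 5).
#' @param hidden,epochs,lr Network config passed to the trainer.
#' @param seed Integer seed.
#' @return List with pooled metrics (as in the held-out report), `per_fold`
#'   accuracy, and `fold_assignment`.
#' @export
evaluate_classifier <- function(hub_expr, labels, folds = 5, hidden = 6,
                                epochs = 2000, lr = 0.01, seed = 1) {
  assert_that(folds >= 2, "folds must be >= 2")
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  min_class <- min(table(y))
  if (min_class < folds) {
    warning(sprintf("smallest class (%d) < folds; reducing folds to %d",
                    min_class, min_class))
    folds <- max(2L, min_class)
  }
  fold <- stratified_folds(y, folds, seed)
  Xall <- t(log2(hub_expr + 1))
  pred <- integer(length(y))
  P <- matrix(NA_real_, length(y), length(classes))
  per_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    mu <- colMeans(Xall[tr, , drop = FALSE])
    sd_ <- apply(Xall[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    net <- nn_fit(scale(Xall[tr, , drop = FALSE], mu, sd_), y[tr],
                  length(classes), hidden = hidden, epochs = epochs,
                  lr = lr, seed = derive_seed(seed, 60L + f))
    model <- list(W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2)
    Pf <- nn_forward(model, scale(Xall[te, , drop = FALSE], mu, sd_))$P
    pred[te] <- max.col(Pf, "first")
    P[te, ] <- Pf
    per_fold[f] <- mean(pred[te] == y[te])
  }
  out <- eval_metrics(y, pred, P, classes)
  out$per_fold <- per_fold
  out$fold_assignment <- fold
  out
}

#' Serialize / restore a subtype classifier as JSON
#'
#' The artifact records the gene list, scalers, weight matrices, class
#' levels and training config, so a model can be shipped as plain text.
#'
#' @param model A `subtype_classifier`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_classifier_json <- function(model, path) {
  payload <- list(
    genes = model$genes, classes = model$classes,
    center = as.list(model$center), scale = as.list(model$scale),
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    config = model$config)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    genes = p$genes, classes = p$classes,
    center = unlist(p$center), scale = unlist(p$scale),
    W1 = as.matrix(p$W1), b1 = as.numeric(p$b1),
    W2 = as.matrix(p$W2), b2 = as.numeric(p$b2),
    config = p$config), class = "subtype_classifier")
}
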