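# LASSO model-building protocol: kNN-median imputation, stratified holdout,
# 10-fold cross-validated penalty tuning (binomial deviance), and evaluation
# with exact trapezoidal ROC / Mann-Whitney AUC.

#' k-nearest-neighbour median imputation of missing dosages
#'
#' Each missing cell is filled with the median dosage of the `k` samples
#' nearest in Euclidean distance (computed over mutually non-missing SNPs)
#' among samples with an observed call at that SNP, rounded to the nearest
#' value in `{0, 1, 2}` (halves round up).
#'
#' @param x numeric matrix (samples by SNPs) with `NA` for missing, or a
#'   [genotype_data] object.
#' @param k number of neighbours.
#' @return Same type as the input, with no missing cells.
#' @export
impute_missing <- function(x, k = 5) {
  if (inherits(x, "genotype_data")) {
    x$dosage <- impute_missing(x$dosage, k = k)
    return(x)
  }
  if (!anyNA(x)) return(x)
  all_miss <- colSums(!is.na(x)) == 0
  if (any(all_miss))
    abort(sprintf("SNP(s) entirely missing, cannot impute: %s",
                  paste(colnames(x)[all_miss], collapse = ", ")))
  A <- x; A[is.na(A)] <- 0
  O <- (!is.na(x)) * 1
  D2 <- (A^2) %*% t(O) + O %*% t(A^2) - 2 * A %*% t(A)
  diag(D2) <- Inf
  out <- x
  for (j in which(colSums(is.na(x)) > 0)) {
    obs <- which(!is.na(x[, j]))
    for (i in which(is.na(x[, j]))) {
      nb <- obs[order(D2[i, obs])][seq_len(min(k, length(obs)))]
      v <- median(x[nb, j])
      out[i, j] <- min(2, max(0, floor(v + 0.5)))
    }
  }
  out
}

#' Stratified train/test split
#'
#' Deterministic under `seed`; the partition is exact (disjoint and
#' exhaustive) and stratified by phenotype, with `round(n_class *
#' test_fraction)` test members per class.
#'
#' @param data a [genotype_data] object (phenotypes must be 1/2).
#' @param test_fraction share of each class held out.
#' @param seed optional integer seed.
#' @return A list with `train` and `test` individual-ID vectors.
#' @export
split_holdout <- function(data, test_fraction = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- phenotype_labels(data)
  if (anyNA(y)) abort("phenotypes must be resolved before splitting")
  ids <- split(data$samples$iid, y)
  if (length(ids) < 2) abort("both classes must be present")
  if (any(lengths(ids) < 2)) abort("each class needs at least 2 members")
  test <- unlist(lapply(ids, function(v) {
    nt <- round(length(v) * test_fraction)
    if (nt < 1 || nt >= length(v))
      abort("test_fraction leaves an empty train or test class")
    sample(v, nt)
  }), use.names = FALSE)
  all_ids <- data$samples$iid
  list(train = all_ids[!all_ids %in% test], test = all_ids[all_ids %in% test])
}

stratified_foldid <- function(y, folds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  foldid
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit an L1-regularized logistic model with cross-validated penalty
#'
#' Dosages over the SNP pool are standardized to zero mean / unit variance
#' on the training set, the penalty grid is log-spaced over four decades
#' down from the smallest value that zeroes every coefficient, the
#' per-penalty mean binomial deviance is estimated by stratified k-fold
#' cross-validation, and the final model is the full-training-set fit at
#' the deviance-minimizing penalty (the optimizer is glmnet).
#' Out-of-fold predicted probabilities at the chosen penalty are kept —
#' they are the unbiased performance read-out for small sets that cannot
#' afford a holdout.
#'
#' @param data a [genotype_data] object, already imputed (no missing cells
#'   within the pool).
#' @param pool character vector of SNP IDs to offer the model.
#' @param folds number of CV folds; each class must have at least `folds`
#'   members.
#' @param n_lambda penalty-grid size.
#' @param seed optional integer seed (fold assignment).
#' @return An object of class `missnp_model`: intercept and per-SNP
#'   coefficients on the standardized scale, their de-standardized
#'   equivalents, the tuned penalty, the input pool, the selected
#'   (nonzero) SNPs, CV curve, out-of-fold scores, and a training-set
#'   fingerprint (sample IDs hash + seed).
#' @export
fit_lasso_cv <- function(data, pool, folds = 10, n_lambda = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing_pool <- setdiff(pool, data$snps$id)
  if (length(missing_pool))
    abort(sprintf("pool SNPs absent from data: %s",
                  paste(head(missing_pool, 3), collapse = ", ")))
  X <- data$dosage[, pool, drop = FALSE]
  if (anyNA(X)) abort("pool dosages contain missing values; impute first")
  y <- phenotype_labels(data)
  if (anyNA(y)) abort("phenotypes must be 1/2")
  if (folds < 2) abort("cross-validation needs at least 2 folds")
  if (min(table(y)) < max(folds, 2))
    abort(sprintf("a class has fewer than %d members; reduce `folds`", folds))

  # glmnet needs >= 2 columns; pad a constant pseudo-SNP for 1-SNP pools
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, `..pad..` = 0)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- nrow(Xs)
  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  if (lambda_max <= 0) lambda_max <- 1e-3
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                  length.out = n_lambda))

  foldid <- stratified_foldid(y, folds)
  dev <- matrix(NA_real_, folds, n_lambda)
  oof_by_lambda <- matrix(NA_real_, n, n_lambda)
  for (f in seq_len(folds)) {
    tr <- foldid != f
    # glmnet warns about small fold classes; our own guards handle sizing
    fit <- suppressWarnings(
      glmnet::glmnet(Xs[tr, , drop = FALSE], y[tr], family = "binomial",
                     lambda = grid, standardize = FALSE))
    pr <- predict(fit, Xs[!tr, , drop = FALSE], type = "response")
    # pad in case glmnet drops path tail
    pr <- pr[, match(grid, fit$lambda), drop = FALSE]
    oof_by_lambda[!tr, ] <- pr
    dev[f, ] <- apply(pr, 2, function(p)
      if (anyNA(p)) NA_real_ else binomial_deviance(y[!tr], p))
  }
  cvm <- colMeans(dev)
  best <- which.min(cvm)
  lambda <- grid[best]

  full <- suppressWarnings(
    glmnet::glmnet(Xs, y, family = "binomial", lambda = grid,
                   standardize = FALSE))
  b <- as.numeric(coef(full, s = lambda, exact = FALSE))
  intercept <- b[1]
  coefs <- setNames(b[-1], colnames(X))
  if (padded) {
    coefs <- coefs[pool]
    ctr <- ctr[pool]; scl <- scl[pool]
  }
  selected <- names(coefs)[coefs != 0]
  coef_raw <- coefs / scl
  intercept_raw <- intercept - sum(coefs * ctr / scl)

  structure(list(
    intercept = intercept, coefficients = coefs,
    intercept_raw = intercept_raw, coefficients_raw = coef_raw,
    lambda = lambda, cv = tibble(lambda = grid, deviance = cvm),
    pool = pool, selected = selected, center = ctr, scale = scl,
    folds = folds,
    oof_scores = setNames(oof_by_lambda[, best], data$samples$iid),
    fingerprint = list(sample_ids = data$samples$iid,
                       hash = rlang::hash(sort(data$samples$iid)),
                       seed = seed)),
    class = "missnp_model")
}

#' @export
print.missnp_model <- function(x, ...) {
  cat(sprintf("<missnp_model> %d/%d SNPs selected, lambda = %.4g, n_train = %d\n",
              length(x$selected), length(x$pool), x$lambda,
              length(x$fingerprint$sample_ids)))
  invisible(x)
}

#' @describeIn fit_lasso_cv one row per input-pool SNP: standardized and
#'   de-standardized coefficients and selection status.
#' @param x,object a `missnp_model`.
#' @param ... unused.
#' @method tidy missnp_model
#' @export
tidy.missnp_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)),
         estimate_raw = c(x$intercept_raw, unname(x$coefficients_raw)),
         selected = c(NA, unname(x$coefficients) != 0))
}

#' @describeIn fit_lasso_cv one-row model summary (pool size, model
#'   length, tuned penalty, CV deviance).
#' @method glance missnp_model
#' @export
glance.missnp_model <- function(x, ...) {
  tibble(n_pool = length(x$pool), model_length = length(x$selected),
         lambda = x$lambda,
         cv_deviance = x$cv$deviance[which.min(x$cv$deviance)],
         n_train = length(x$fingerprint$sample_ids))
}

#' Predict case probabilities from a fitted model
#'
#' @param object a `missnp_model`.
#' @param newdata a [genotype_data] object or dosage matrix containing all
#'   pool SNPs (imputed).
#' @param ... unused.
#' @return Named vector of predicted case probabilities.
#' @export
predict.missnp_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "genotype_data")) newdata$dosage else newdata
  if (!all(object$pool %in% colnames(X)))
    abort("newdata is missing model pool SNPs")
  X <- X[, object$pool, drop = FALSE]
  if (anyNA(X)) abort("newdata contains missing dosages; impute first")
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  eta <- object$intercept + as.numeric(Xs %*% object$coefficients)
  setNames(stats::plogis(eta), rownames(X))
}

#' Exact ROC AUC
#'
#' `auc_trapezoid()` integrates the exact ROC traced over the sorted
#' unique scores by the trapezoidal rule (score ties produce diagonal
#' segments); `auc_mann_whitney()` computes the equivalent rank statistic
#' `U / (n_case * n_ctrl)` with the mid-rank tie convention.  The two are
#' mathematically identical.
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels binary truth, 1 = case.
#' @return The AUC, or `NA` if one class is absent.
#' @export
auc_trapezoid <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  roc <- roc_points(scores, labels)
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' @rdname auc_trapezoid
#' @export
auc_mann_whitney <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# exact ROC polyline from (0,0) to (1,1), thresholds at unique scores
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(threshold = c(Inf, s[last]),
         tpr = c(0, tp[last] / sum(y)),
         fpr = c(0, fp[last] / sum(1 - y)))
}

#' Evaluate a fitted model on a dataset
#'
#' Scores every sample with the model's predicted case probability,
#' classifies at the 0.5 threshold (a score exactly at 0.5 is called a
#' case), and reports the confusion matrix (case = positive), accuracy,
#' sensitivity, specificity, exact trapezoidal AUC, per-sample scores and
#' the identities of misclassified samples split by true class.  With a
#' single-class evaluation set the AUC is undefined and reported as `NA`.
#'
#' @param model a `missnp_model`, or `NULL` if `scores` are supplied
#'   directly.
#' @param data a [genotype_data] object (imputed over the model pool).
#' @param scores optional named score vector overriding model prediction
#'   (used e.g. for out-of-fold CV scores).
#' @return An object of class `missnp_eval`.
#' @export
evaluate <- function(model, data, scores = NULL) {
  y <- phenotype_labels(data)
  if (anyNA(y)) abort("phenotypes must be 1/2 in the evaluation set")
  if (is.null(scores)) scores <- predict(model, data)
  scores <- scores[data$samples$iid]
  if (anyNA(scores)) abort("scores missing for some samples")
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  auc <- auc_trapezoid(scores, y)
  tab <- tibble(iid = data$samples$iid, truth = as.integer(y),
                score = unname(scores), predicted = pred)
  mis <- tab[tab$truth != tab$predicted, c("iid", "truth")]
  structure(list(
    scores = tab,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = auc,
    roc = roc_points(scores, y),
    misclassified = mis), class = "missnp_eval")
}

#' @export
print.missnp_eval <- function(x, ...) {
  cat(sprintf(
    "<missnp_eval> n = %d | acc %.3f, sens %.3f, spec %.3f, AUC %s | missed %d (%d cases, %d controls)\n",
    nrow(x$scores), x$accuracy, x$sensitivity, x$specificity,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
    nrow(x$misclassified), sum(x$misclassified$truth == 1),
    sum(x$misclassified$truth == 0)))
  invisible(x)
}

#' @describeIn evaluate per-sample scores and calls.
#' @param x,object a `missnp_eval`.
#' @param ... unused.
#' @method tidy missnp_eval
#' @export
tidy.missnp_eval <- function(x, ...) x$scores

#' @describeIn evaluate one-row metric summary.
#' @method glance missnp_eval
#' @export
glance.missnp_eval <- function(x, ...) {
  tibble(n = nrow(x$scores), TP = x$confusion[["TP"]], FP = x$confusion[["FP"]],
         TN = x$confusion[["TN"]], FN = x$confusion[["FN"]],
         accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, auc = x$auc,
         n_misclassified = nrow(x$misclassified))
}

#' Repeated-holdout evaluation
#'
#' Repeats the stratified split / fit / test cycle and summarizes the
#' spread of the metrics: an alternative reading of internal
#' cross-validation in which the 80/20 split itself is resampled, useful
#' for judging how much a single-split result owes to the particular
#' holdout.
#'
#' @param data imputed [genotype_data] (both classes present).
#' @param pool SNP pool offered to every fit.
#' @param repeats number of resplits.
#' @param test_fraction held-out share per resplit.
#' @param folds,n_lambda passed to [fit_lasso_cv()].
#' @param seed integer seed governing all resplits.
#' @return A list: `metrics` (one row per repeat: accuracy, sensitivity,
#'   specificity, auc, model_length) and `summary` (mean and sd per
#'   metric).
#' @export
repeated_holdout <- function(data, pool, repeats = 20, test_fraction = 0.2,
                             folds = 10, n_lambda = 100, seed = 1) {
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, repeats)
  rows <- purrr::map_dfr(seq_len(repeats), function(r) {
    sp <- split_holdout(data, test_fraction, seed = sub_seeds[r])
    fit <- fit_lasso_cv(data[sp$train, ], pool, folds = folds,
                        n_lambda = n_lambda)
    ev <- evaluate(fit, data[sp$test, ])
    tibble(repeat_ = r, accuracy = ev$accuracy,
           sensitivity = ev$sensitivity, specificity = ev$specificity,
           auc = ev$auc, model_length = length(fit$selected))
  })
  summ <- dplyr::summarise(
    tidyr::pivot_longer(rows, -"repeat_", names_to = "metric"),
    mean = mean(.data$value), sd = sd(.data$value), .by = "metric")
  list(metrics = rows, summary = summ)
}
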