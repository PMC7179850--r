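test_that("imputation is the identity on complete data and fills simple cases", {
  x <- matrix(sample(0:2, 50, TRUE), 10, 5)
  expect_identical(impute_missing(x), x)

  # one missing cell among identical samples: imputed to the shared value
  y <- matrix(2, 5, 3)
  y[1, 2] <- NA
  out <- impute_missing(y, k = 3)
  expect_identical(out[1, 2], 2)
  expect_false(anyNA(out))

  z <- matrix(NA_real_, 4, 2)
  z[, 1] <- 1
  colnames(z) <- c("ok", "gone")
  expect_error(impute_missing(z), "gone")
})

test_that("masked genotypes are recovered well at moderate allele frequency", {
  # families give the neighbour search something to find: siblings share
  # half their dosage variance, unrelated LD-free SNPs carry no signal
  for (s in 1:3) {
    co <- tiny_cohort(seed = 800 + s, n_cases = 120, n_controls = 120,
                      n_snps = 400, maf_range = c(0.05, 0.3),
                      relatives_per_case = 2)
    truth <- co$data$dosage
    set.seed(s)
    mask <- matrix(runif(length(truth)) < 0.01, nrow(truth))
    x <- truth; x[mask] <- NA
    imp <- impute_missing(x, k = 3)
    expect_false(anyNA(imp))
    expect_gte(mean(imp[mask] == truth[mask]), 0.70)
  }
})

test_that("the holdout split is stratified, exact and seeded", {
  co <- tiny_cohort(seed = 30, n_cases = 400, n_controls = 600, n_snps = 50,
                    n_causal_main = 5, n_causal_sub = 5)
  # force exact class sizes for the arithmetic check
  co$data$samples$phenotype <- rep(c(2L, 1L, 1L, 2L, 1L), 200)[1:1000]
  co$data$samples$phenotype <- c(rep(2L, 400), rep(1L, 600))
  sp <- split_holdout(co$data, 0.2, seed = 1)
  y <- phenotype_labels(co$data)
  expect_identical(sum(y[sp$test] == 1), 80L)
  expect_identical(sum(y[sp$test] == 0), 120L)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), co$data$samples$iid)
  expect_identical(split_holdout(co$data, 0.2, seed = 1), sp)
  expect_error(split_holdout(co$data, 0), "empty")
})

test_that("LASSO on null labels selects little and classifies at chance", {
  for (s in 1:3) {
    co <- tiny_cohort(seed = 900 + s, n_cases = 150, n_controls = 150,
                      n_snps = 300, beta_main = 0, beta_sub = 0,
                      subclass_fraction = 0)
    pool <- co$data$snps$id[1:100]
    m <- fit_lasso_cv(co$data, pool, seed = s)
    expect_lte(length(m$selected), 10)
    oof_auc <- auc_trapezoid(m$oof_scores, phenotype_labels(co$data))
    expect_lt(abs(oof_auc - 0.5), 0.12)
  }
})

test_that("the strongest penalty gives an intercept-only model", {
  co <- tiny_cohort(seed = 31, n_cases = 100, n_controls = 100, n_snps = 100,
                    n_causal_main = 5, n_causal_sub = 5)
  pool <- co$data$snps$id[1:50]
  m <- fit_lasso_cv(co$data, pool, seed = 1)
  # the top of the tuned grid zeroes every coefficient by construction
  y <- phenotype_labels(co$data)
  X <- scale(co$data$dosage[, pool])
  lmax <- max(abs(crossprod(X, y - mean(y)))) / length(y)
  top <- glmnet::glmnet(X, y, family = "binomial", lambda = lmax * 1.001,
                        standardize = FALSE)
  expect_identical(sum(abs(as.numeric(coef(top))[-1]) > 0), 0L)
})

test_that("LASSO recovers most of the causal SNPs offered to it", {
  hits <- sapply(1:3, function(s) {
    co <- tiny_cohort(seed = 950 + s, n_cases = 500, n_controls = 500,
                      n_snps = 600, subclass_fraction = 0)
    pool <- union(co$truth$main_causal_snps, co$data$snps$id[1:100])
    m <- fit_lasso_cv(co$data, pool, seed = s)
    mean(co$truth$main_causal_snps %in% m$selected)
  })
  expect_true(all(hits >= 0.6))
})

test_that("model predictions honour standardization and de-standardization", {
  co <- tiny_cohort(seed = 32, n_cases = 200, n_controls = 200, n_snps = 200)
  pool <- co$data$snps$id[1:80]
  m <- fit_lasso_cv(co$data, pool, seed = 2)
  pr <- predict(m, co$data)
  Xr <- co$data$dosage[, m$pool]
  eta_raw <- m$intercept_raw + as.numeric(Xr %*% m$coefficients_raw)
  expect_equal(unname(pr), plogis(eta_raw), tolerance = 1e-10)
  expect_true(all(m$selected %in% m$pool))
  td <- tidy(m)
  expect_identical(nrow(td), length(pool) + 1L)
  expect_identical(glance(m)$model_length, length(m$selected))
  expect_error(fit_lasso_cv(co$data, pool, folds = 1000), "reduce")
})

test_that("evaluation metrics match the confusion matrix identities", {
  ev <- eval_with_confusion(fn = 3, fp = 2, tp = 10, tn = 15)
  cm <- ev$confusion
  expect_equal(ev$accuracy, (cm["TP"] + cm["TN"]) / sum(cm),
               ignore_attr = TRUE)
  expect_equal(ev$sensitivity, cm["TP"] / (cm["TP"] + cm["FN"]),
               ignore_attr = TRUE)
  expect_equal(ev$specificity, cm["TN"] / (cm["TN"] + cm["FP"]),
               ignore_attr = TRUE)
  expect_identical(unname(cm), c(10L, 2L, 15L, 3L))
  g <- glance(ev)
  expect_equal(g$accuracy, ev$accuracy)
})

test_that("evaluation handles perfect, tied and degenerate scores", {
  gd <- toy_genotype_data(matrix(0, 4, 1), phenotype = c(2L, 2L, 1L, 1L))
  ids <- gd$samples$iid
  perfect <- evaluate(NULL, gd, scores = setNames(c(1, 1, 0, 0), ids))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)

  tied <- evaluate(NULL, gd, scores = setNames(rep(0.5, 4), ids))
  expect_equal(tied$auc, 0.5)              # tie convention
  expect_true(all(tied$scores$predicted == 1))  # 0.5 classified as case

  one_class <- toy_genotype_data(matrix(0, 3, 1), phenotype = rep(2L, 3))
  ev1 <- evaluate(NULL, one_class,
                  scores = setNames(c(0.2, 0.6, 0.9), one_class$samples$iid))
  expect_true(is.na(ev1$auc))
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  gd <- toy_genotype_data(matrix(0, 3, 1), phenotype = c(2L, 1L, 2L))
  ev <- evaluate(NULL, gd,
                 scores = setNames(c(0.9, 0.8, 0.4), gd$samples$iid))
  # pairs (case, ctrl): (0.9 > 0.8) concordant, (0.4 < 0.8) discordant -> 0.5
  expect_equal(ev$auc, 0.5)

  # exhaustive oracle on random vectors
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- sample(seq(0, 1, 0.1), n, TRUE)   # heavy ties
    conc <- 0; half <- 0; tot <- 0
    for (a in which(y == 1)) for (b in which(y == 0)) {
      tot <- tot + 1
      if (s[a] > s[b]) conc <- conc + 1
      else if (s[a] == s[b]) half <- half + 1
    }
    expect_equal(auc_trapezoid(s, y), (conc + half / 2) / tot)
  }
})

test_that("trapezoidal and Mann-Whitney AUC agree exactly", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # varying tie structure
    expect_equal(auc_trapezoid(s, y), auc_mann_whitney(s, y),
                 tolerance = 1e-12)
  }
})

test_that("repeated holdout summarizes metric spread over resplits", {
  co <- tiny_cohort(seed = 33, n_cases = 120, n_controls = 120, n_snps = 200)
  out <- repeated_holdout(co$data, co$data$snps$id[1:40], repeats = 3,
                          folds = 5, seed = 4)
  expect_identical(nrow(out$metrics), 3L)
  expect_true(all(c("auc", "accuracy") %in% out$summary$metric))
  expect_true(all(is.finite(out$summary$mean)))
  # seeded: identical on rerun
  out2 <- repeated_holdout(co$data, co$data$snps$id[1:40], repeats = 3,
                           folds = 5, seed = 4)
  expect_identical(out$metrics, out2$metrics)
})
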