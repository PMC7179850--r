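# Misclassified-sample feedback: identify the samples a model got wrong,
# build a second model on them, and merge the two marker sets (SNPs Mix =
# union of input pools, Models Mix = union of selected SNPs).

#' Misclassified samples of an evaluation
#'
#' @param report a `missnp_eval` (from [evaluate()]).
#' @return A tibble `iid`, `truth` (1 = case) of samples whose predicted
#'   label differs from the truth, with a `breakdown` attribute
#'   `c(cases, controls)`.
#' @export
misclassified_samples <- function(report) {
  stopifnot(inherits(report, "missnp_eval"))
  mis <- report$misclassified
  attr(mis, "breakdown") <- c(cases = sum(mis$truth == 1),
                              controls = sum(mis$truth == 0))
  mis
}

#' Re-model the misclassified samples
#'
#' Runs the kinship-corrected association scan restricted to the
#' misclassified samples (by default together with all members of their
#' families from the full cohort, using the kinship submatrix),
#' pre-selects SNPs at `p < p_threshold`, and fits a LASSO model on the
#' misclassified samples over that pool.  CV folds auto-reduce to the
#' smallest class size.  The returned evaluation is taken from the
#' out-of-fold CV predictions on the missed set by default; it is still
#' optimistically biased (the pool was chosen on overlapping samples) and
#' is stamped accordingly.
#'
#' @param missed_ids individual IDs of the misclassified samples.
#' @param cohort_data the full familial [genotype_data] (QC-passed).
#' @param kinship kinship matrix covering the cohort.
#' @param p_threshold pre-selection threshold (strict); 1 selects every
#'   SNP (degenerate, allowed with a warning).
#' @param folds maximum CV folds.
#' @param impute_k neighbours for [impute_missing()].
#' @param include_family include the missed samples' family members in the
#'   association scan (the familial set is what the scan corrects for).
#' @param eval_mode `"cv"` (out-of-fold scores) or `"resubstitution"`.
#' @param seed optional integer seed.
#' @return A list of class `missnp_remodel`: `model`, `pool`, `eval`
#'   (`missnp_eval` on the missed set), `assoc_samples`, `optimistic`
#'   (always `TRUE`).
#' @export
remodel_missed <- function(missed_ids, cohort_data, kinship = NULL,
                           p_threshold = 1e-3, folds = 10, impute_k = 5,
                           include_family = TRUE,
                           eval_mode = c("cv", "resubstitution"),
                           seed = NULL) {
  eval_mode <- match.arg(eval_mode)
  if (!is.null(seed)) set.seed(seed)
  if (p_threshold >= 1)
    warn("p_threshold >= 1 selects every SNP; the remodeled pool is degenerate")
  samp <- cohort_data$samples
  missed_ids <- intersect(samp$iid, missed_ids)
  y_missed <- phenotype_labels(cohort_data)[missed_ids]
  if (length(unique(y_missed)) < 2)
    abort("misclassified set contains a single class; remodeling undefined")
  if (min(table(y_missed)) < 2)
    abort("remodeling needs at least two misclassified subjects per class")
  assoc_ids <- if (include_family) {
    fams <- unique(samp$fid[samp$iid %in% missed_ids])
    samp$iid[samp$fid %in% fams]
  } else missed_ids
  sub <- cohort_data[assoc_ids, ]
  K <- if (is.null(kinship)) NULL else kinship_subset(kinship, assoc_ids)
  tab <- assoc_scan(sub, K)
  pool <- preselect(tab, "p_threshold", alpha = p_threshold)
  if (!length(pool))
    abort("no SNP passes the remodeling pre-selection threshold")
  missed <- impute_missing(cohort_data[missed_ids, pool], k = impute_k)
  folds_used <- max(2, min(folds, min(table(y_missed))))
  model <- fit_lasso_cv(missed, pool, folds = folds_used)
  ev <- if (eval_mode == "cv")
    evaluate(NULL, missed, scores = model$oof_scores)
  else evaluate(model, missed)
  structure(list(model = model, pool = pool, eval = ev,
                 assoc_samples = assoc_ids, eval_mode = eval_mode,
                 optimistic = TRUE),
            class = "missnp_remodel")
}

order_by_position <- function(ids, snps) {
  hit <- snps[match(ids, snps$id), ]
  ids[order(hit$chrom, hit$pos, ids)]
}

#' Merge marker sets from two models
#'
#' `mix_snp_pools()` is the "SNPs Mix" strategy: the union of the two
#' models' *input* pools.  `mix_model_snps()` is the "Models Mix"
#' strategy: the union of the two models' *selected* (nonzero-coefficient)
#' SNP sets.  Both return the union ordered by genomic position.
#'
#' @param base_pool,missed_pool input SNP pools (character).
#' @param snps SNP map (`id`, `chrom`, `pos`) used for ordering.
#' @return Character vector of SNP IDs.
#' @export
mix_snp_pools <- function(base_pool, missed_pool, snps) {
  if (!length(base_pool) || !length(missed_pool))
    abort("both input pools must be non-empty")
  order_by_position(union(base_pool, missed_pool), snps)
}

#' @rdname mix_snp_pools
#' @param base_model,missed_model fitted `missnp_model` objects.
#' @export
mix_model_snps <- function(base_model, missed_model, snps) {
  stopifnot(inherits(base_model, "missnp_model"),
            inherits(missed_model, "missnp_model"))
  order_by_position(union(base_model$selected, missed_model$selected), snps)
}

#' Refit a merged pool and compare with the base model
#'
#' Fits a LASSO model on the *same* training samples restricted to the
#' merged pool, evaluates it on the *same* held-out test set, and reports
#' the AUC change versus the base model.
#'
#' @param pool merged SNP pool.
#' @param train_data,test_data imputed [genotype_data] for the original
#'   split (must contain the pool SNPs).
#' @param base_eval the base model's `missnp_eval` on `test_data`.
#' @param strategy label, `"snps_mix"` or `"models_mix"`.
#' @param folds,n_lambda,seed passed to [fit_lasso_cv()].
#' @param test_informed stamp recording whether any test-sample
#'   information entered the pool construction.
#' @return A list of class `mix_report`: `strategy`, `input_pool_size`,
#'   `model_length`, `model`, `eval`, `base_auc`, `delta_auc`,
#'   `test_informed_selection`.
#' @export
refit_and_compare <- function(pool, train_data, test_data, base_eval,
                              strategy = "models_mix", folds = 10,
                              n_lambda = 100, seed = NULL,
                              test_informed = FALSE) {
  model <- fit_lasso_cv(train_data, pool, folds = folds,
                        n_lambda = n_lambda, seed = seed)
  ev <- evaluate(model, test_data)
  structure(list(strategy = strategy, input_pool_size = length(pool),
                 model_length = length(model$selected), model = model,
                 eval = ev, base_auc = base_eval$auc,
                 delta_auc = ev$auc - base_eval$auc,
                 test_informed_selection = test_informed),
            class = "mix_report")
}

#' @export
print.mix_report <- function(x, ...) {
  cat(sprintf(
    "<mix_report:%s> pool %d -> model %d SNPs | AUC %.3f (base %.3f, delta %+.3f)%s\n",
    x$strategy, x$input_pool_size, x$model_length, x$eval$auc, x$base_auc,
    x$delta_auc,
    if (isTRUE(x$test_informed_selection)) " [test-informed selection]" else ""))
  invisible(x)
}

#' @describeIn refit_and_compare one-row summary of a mixing experiment.
#' @param x a `mix_report`.
#' @param ... unused.
#' @method glance mix_report
#' @export
glance.mix_report <- function(x, ...) {
  tibble(strategy = x$strategy, input_pool_size = x$input_pool_size,
         model_length = x$model_length, auc = x$eval$auc,
         accuracy = x$eval$accuracy, sensitivity = x$eval$sensitivity,
         specificity = x$eval$specificity,
         base_auc = x$base_auc, delta_auc = x$delta_auc,
         test_informed_selection = x$test_informed_selection)
}

#' Compare the SNP content of several models
#'
#' Counts pairwise shared selected SNPs between models, each model's
#' specific SNPs (selected by it alone), and — within each model's
#' selected set — the SNP pairs whose dosages are nearly collinear
#' (squared Pearson correlation above `r2_threshold`), which flag
#' interchangeable markers from linkage disequilibrium.
#'
#' @param models named list of `missnp_model` objects.
#' @param data [genotype_data] providing dosages for the correlations.
#' @param r2_threshold redundancy threshold on r-squared (strict >).
#' @return A list of class `overlap_report`: `shared` (symmetric count
#'   matrix), `specific` (named counts), `redundant_pairs` (tibble
#'   `model`, `snp1`, `snp2`, `r2`).
#' @export
model_overlap <- function(models, data, r2_threshold = 0.95) {
  if (length(models) < 2) abort("need at least two models to compare")
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  sets <- lapply(models, function(m) m$selected)
  k <- length(sets)
  shared <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    shared[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  specific <- vapply(seq_len(k), function(i)
    length(setdiff(sets[[i]], unlist(sets[-i]))), integer(1))
  names(specific) <- names(sets)
  pairs <- purrr::map_dfr(names(sets), function(nm) {
    sel <- intersect(sets[[nm]], data$snps$id)
    if (length(sel) < 2) return(NULL)
    r <- suppressWarnings(cor(data$dosage[, sel, drop = FALSE],
                              use = "pairwise.complete.obs"))
    r2 <- r^2
    hit <- which(upper.tri(r2) & r2 > r2_threshold, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    tibble(model = nm, snp1 = sel[hit[, 1]], snp2 = sel[hit[, 2]],
           r2 = r2[hit])
  })
  if (nrow(pairs) == 0)
    pairs <- tibble(model = character(), snp1 = character(),
                    snp2 = character(), r2 = numeric())
  structure(list(shared = shared, specific = specific,
                 redundant_pairs = pairs, r2_threshold = r2_threshold),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> shared selected-SNP counts:\n")
  print(x$shared)
  cat("model-specific:", paste(names(x$specific), x$specific, sep = "=",
                               collapse = ", "), "\n")
  cat(sprintf("redundant pairs (r2 > %.2f): %d\n", x$r2_threshold,
              nrow(x$redundant_pairs)))
  invisible(x)
}
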