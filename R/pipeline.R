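# End-to-end protocol: simulate/load -> subject QC -> SNP QC -> kinship ->
# pre-selection -> base LASSO -> misclassified re-modeling -> mixing ->
# comparison. One master seed determines everything.

#' Pipeline options
#'
#' @param test_fraction held-out share of the unrelated set.
#' @param top_k size of the Top-k pre-selection pool.
#' @param preselect_alpha p-threshold for the main pre-selection pool (the
#'   pool the base model is built on).
#' @param remodel_alpha p-threshold for the misclassified-sample
#'   pre-selection.
#' @param folds,n_lambda LASSO CV settings.
#' @param impute_k neighbours for imputation.
#' @param ancestry_filter run the PCA ancestry stage (disable for cohorts
#'   known to be single-population).
#' @param pca_snps SNPs sampled for the PCA stage.
#' @param min_call_rate,hwe_alpha,hwe_on SNP QC settings, see [snp_qc()].
#' @param missed_sources which evaluations feed the re-modeling step:
#'   `"train"` (clean: no test information enters any selection) and/or
#'   `"test"` (misclassification read off the test set; stamped as
#'   test-informed).
#' @param strategies mixing strategies to run.
#' @param missed_eval `"cv"` or `"resubstitution"`, see [remodel_missed()].
#' @param include_family include missed samples' families in the
#'   re-modeling association scan.
#' @return A list of options for [run_full_pipeline()].
#' @export
pipeline_config <- function(test_fraction = 0.2, top_k = 100,
                            preselect_alpha = 1e-3, remodel_alpha = 1e-3,
                            folds = 10, n_lambda = 100, impute_k = 5,
                            ancestry_filter = TRUE, pca_snps = 100000,
                            min_call_rate = 0.98, hwe_alpha = 1e-5,
                            hwe_on = "controls",
                            missed_sources = c("train", "test"),
                            strategies = c("snps_mix", "models_mix"),
                            missed_eval = "cv", include_family = TRUE) {
  as.list(environment())
}

#' Run the full analysis pipeline
#'
#' Executes the whole protocol under one master seed: cohort simulation
#' (or PLINK input), phenotype and ancestry subject QC, the SNP QC
#' cascade, pedigree kinship, the kinship-corrected association scan with
#' Top-k and p-threshold pre-selection, one-member-per-family reduction,
#' a stratified holdout, the base LASSO model, re-modeling of the
#' misclassified samples (from training predictions, from test
#' predictions, or both), both marker-merging strategies with refits on
#' the identical split, and a model-overlap comparison.
#'
#' Information flow: the pre-selection scan always excludes the held-out
#' test subjects, so in `"train"` mode no test-sample genotype or label
#' influences any selection or coefficient.  `"test"`-mode mixes reuse the
#' test-informed variant (misclassification read off the test set) and their
#' reports carry `test_informed_selection = TRUE`.
#'
#' @param input a [sim_config()] (cohort is simulated) or a list
#'   `list(prefix = , pedigree = )` naming PLINK files.
#' @param seed master seed; fixed seed gives byte-identical summaries.
#' @param opts a [pipeline_config()].
#' @param out_dir optional directory: writes `summary.json`, the
#'   association table TSV, model JSONs and ROC-point TSVs.
#' @return A list of class `missnp_pipeline` with elements `cohort`,
#'   `qc_report`, `assoc`, `pools`, `kinship`, `split`, `base`
#'   (model/train/test evals), `missed`, `mixes`, `overlap`, `summary`.
#' @export
run_full_pipeline <- function(input, seed = 1, opts = pipeline_config(),
                              out_dir = NULL) {
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1, 8)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s (check the stage inputs)",
                    name, conditionMessage(e))))
  }

  # --- data ----------------------------------------------------------------
  if (inherits(input, "sim_config")) {
    input$seed <- stage_seeds[1]
    cohort <- stage("simulate", simulate_cohort(input))
    data <- cohort$data; pedigree <- cohort$pedigree
  } else {
    cohort <- NULL
    data <- stage("load", read_plink(input$prefix))
    pedigree <- if (!is.null(input$pedigree))
      stage("load", read_pedigree(input$pedigree)) else pedigree_of(data)
  }

  # --- subject QC ----------------------------------------------------------
  qc_stages <- list()
  ph <- stage("phenotype_filter", filter_phenotype(data))
  qc_stages$phenotype <- ph$report; data <- ph$data
  pca <- NULL
  if (isTRUE(opts$ancestry_filter)) {
    pca <- stage("ancestry_pca",
                 pca_ancestry_filter(data, n_snps = opts$pca_snps,
                                     seed = stage_seeds[2]))
    qc_stages$ancestry <- pca$report; data <- pca$data
  }

  # --- SNP QC (on the full familial set, the WADS analogue) ---------------
  sq <- stage("snp_qc",
              snp_qc(data, min_call_rate = opts$min_call_rate,
                     hwe_alpha = opts$hwe_alpha, hwe_on = opts$hwe_on))
  qc_stages$snp <- sq$report; wads <- sq$data
  qc_report <- new_qc_report(dplyr::bind_rows(qc_stages))

  # --- kinship + unrelated subset + split ---------------------------------
  kin <- stage("kinship", kinship_from_pedigree(pedigree))
  unr <- stage("one_per_family",
               select_unrelated(wads, seed = stage_seeds[3]))
  unrads <- unr$data
  split <- stage("split", split_holdout(unrads, opts$test_fraction,
                                        seed = stage_seeds[4]))

  # --- pre-selection (excluding held-out test subjects) -------------------
  wads_no_test <- wads[which(!wads$samples$iid %in% split$test), ]
  assoc <- stage("assoc",
                 assoc_scan(wads_no_test,
                            kinship_subset(kin, wads_no_test$samples$iid)))
  pools <- list(top_k = preselect(assoc, "top_k", k = opts$top_k),
                p_threshold = preselect(assoc, "p_threshold",
                                        alpha = opts$preselect_alpha))
  pool <- pools$p_threshold
  if (length(pool) < 2) pool <- pools$top_k  # fall back on sparse scans

  # --- base model ----------------------------------------------------------
  unrads_imp <- stage("impute", impute_missing(unrads[, pool],
                                               k = opts$impute_k))
  train <- unrads_imp[split$train, ]
  test <- unrads_imp[split$test, ]
  base_model <- stage("base_fit",
                      fit_lasso_cv(train, pool, folds = opts$folds,
                                   n_lambda = opts$n_lambda,
                                   seed = stage_seeds[5]))
  base_train_eval <- evaluate(base_model, train)
  base_test_eval <- evaluate(base_model, test)

  # --- misclassified re-modeling + mixing ---------------------------------
  wads_clean <- wads_no_test      # remodeling input for the clean branch
  missed <- list(); mixes <- list()
  for (src in opts$missed_sources) {
    ev <- if (src == "train") base_train_eval else base_test_eval
    mis <- misclassified_samples(ev)
    informed <- src == "test"
    rm_data <- if (informed) wads else wads_clean
    res <- tryCatch(
      remodel_missed(mis$iid, rm_data, kin,
                     p_threshold = opts$remodel_alpha,
                     folds = opts$folds, impute_k = opts$impute_k,
                     include_family = opts$include_family,
                     eval_mode = opts$missed_eval,
                     seed = stage_seeds[6] + (src == "test")),
      error = function(e) e)
    if (inherits(res, "error")) {
      # a branch whose missed set cannot support a model is recorded and
      # skipped; the other branch still runs
      warn(sprintf("re-modeling skipped for source '%s': %s", src,
                   conditionMessage(res)))
      missed[[src]] <- list(ids = mis$iid,
                            breakdown = attr(mis, "breakdown"),
                            skipped = conditionMessage(res))
      next
    }
    missed[[src]] <- c(res, list(ids = mis$iid,
                                 breakdown = attr(mis, "breakdown")))
    for (strat in opts$strategies) {
      mix_pool <- if (strat == "snps_mix")
        mix_snp_pools(pool, res$pool, wads$snps)
      else mix_model_snps(base_model, res$model, wads$snps)
      extra <- setdiff(mix_pool, colnames(unrads_imp$dosage))
      mix_imp <- if (length(extra)) {
        add <- impute_missing(unrads[, union(pool, mix_pool)],
                              k = opts$impute_k)
        add
      } else unrads_imp
      mixes[[paste(src, strat, sep = "_")]] <- stage(
        paste0("mix_", src, "_", strat),
        refit_and_compare(mix_pool, mix_imp[split$train, ],
                          mix_imp[split$test, ], base_test_eval,
                          strategy = strat, folds = opts$folds,
                          n_lambda = opts$n_lambda,
                          seed = stage_seeds[7],
                          test_informed = informed))
    }
  }

  # --- model comparison ----------------------------------------------------
  fitted_missed <- missed[!vapply(missed, function(m)
    is.null(m$model), logical(1))]
  models <- c(list(base = base_model),
              setNames(lapply(fitted_missed, `[[`, "model"),
                       paste0("missed_", names(fitted_missed))),
              setNames(lapply(mixes, `[[`, "model"), names(mixes)))
  overlap <- if (length(models) >= 2)
    stage("overlap", model_overlap(models, unrads)) else NULL

  out <- structure(list(cohort = cohort, qc_report = qc_report,
                        assoc = assoc, pools = pools, kinship = kin,
                        split = split, pca = pca,
                        base = list(model = base_model,
                                    train_eval = base_train_eval,
                                    test_eval = base_test_eval,
                                    pool = pool),
                        missed = missed, mixes = mixes, overlap = overlap,
                        seed = seed, opts = opts),
                   class = "missnp_pipeline")
  out$summary <- pipeline_summary(out)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

pipeline_summary <- function(pl) {
  ev_row <- function(ev) list(
    n = nrow(ev$scores), accuracy = ev$accuracy,
    sensitivity = ev$sensitivity, specificity = ev$specificity,
    auc = ev$auc, n_misclassified = nrow(ev$misclassified))
  list(
    seed = pl$seed,
    qc = lapply(seq_len(nrow(pl$qc_report)), function(i) list(
      stage = pl$qc_report$stage[i], unit = pl$qc_report$unit[i],
      n_in = pl$qc_report$n_in[i], n_removed = pl$qc_report$n_removed[i],
      n_out = pl$qc_report$n_out[i])),
    pools = list(top_k = length(pl$pools$top_k),
                 p_threshold = length(pl$pools$p_threshold)),
    n_train = length(pl$split$train), n_test = length(pl$split$test),
    base = c(list(input_snps = length(pl$base$pool),
                  model_length = length(pl$base$model$selected)),
             train = ev_row(pl$base$train_eval),
             test = ev_row(pl$base$test_eval)),
    missed = lapply(pl$missed, function(m) {
      if (!is.null(m$skipped))
        return(list(n_missed = length(m$ids),
                    breakdown = as.list(m$breakdown), skipped = m$skipped))
      c(list(n_missed = length(m$ids),
             breakdown = as.list(m$breakdown),
             input_snps = length(m$pool),
             model_length = length(m$model$selected),
             eval_mode = m$eval_mode, optimistic = m$optimistic),
        ev_row(m$eval))
    }),
    mixes = lapply(pl$mixes, function(x) c(
      list(strategy = x$strategy, input_snps = x$input_pool_size,
           model_length = x$model_length, base_auc = x$base_auc,
           delta_auc = x$delta_auc,
           test_informed_selection = x$test_informed_selection),
      ev_row(x$eval))),
    overlap = if (!is.null(pl$overlap)) list(
      shared = as.data.frame(pl$overlap$shared),
      specific = as.list(pl$overlap$specific),
      n_redundant_pairs = nrow(pl$overlap$redundant_pairs)) else NULL)
}

write_pipeline_outputs <- function(pl, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(pl$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(pl$assoc, file.path(out_dir, "assoc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dump_model <- function(m, path) jsonlite::write_json(
    list(intercept = m$intercept_raw,
         coefficients = as.list(m$coefficients_raw[m$selected]),
         lambda = m$lambda, pool = m$pool,
         seed = m$fingerprint$seed, hash = m$fingerprint$hash),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dump_model(pl$base$model, file.path(out_dir, "model_base.json"))
  for (nm in names(pl$missed))
    if (!is.null(pl$missed[[nm]]$model))
      dump_model(pl$missed[[nm]]$model,
                 file.path(out_dir, sprintf("model_missed_%s.json", nm)))
  for (nm in names(pl$mixes)) {
    dump_model(pl$mixes[[nm]]$model,
               file.path(out_dir, sprintf("model_%s.json", nm)))
    write.table(pl$mixes[[nm]]$eval$roc,
                file.path(out_dir, sprintf("roc_%s.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(pl$base$test_eval$roc, file.path(out_dir, "roc_base_test.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.missnp_pipeline <- function(x, ...) {
  cat(sprintf("<missnp_pipeline> seed %s | base AUC %.3f (test)\n",
              format(x$seed), x$base$test_eval$auc))
  for (nm in names(x$mixes))
    cat(sprintf("  %-22s AUC %.3f (delta %+.3f, %d SNPs)\n", nm,
                x$mixes[[nm]]$eval$auc, x$mixes[[nm]]$delta_auc,
                x$mixes[[nm]]$model_length))
  invisible(x)
}
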