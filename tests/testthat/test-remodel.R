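test_that("misclassified samples are identified with their class breakdown", {
  perfect <- eval_with_confusion(fn = 0, fp = 0, tp = 5, tn = 5)
  expect_identical(nrow(misclassified_samples(perfect)), 0L)

  # a reference confusion pattern: 56 missed cases + 33 missed controls of 448
  ev <- eval_with_confusion(fn = 56, fp = 33, tp = 107, tn = 252)
  mis <- misclassified_samples(ev)
  expect_identical(nrow(mis), 89L)
  expect_identical(unname(attr(mis, "breakdown")), c(56L, 33L))
})

test_that("pool mixing obeys union cardinalities and set identities", {
  snps <- tibble::tibble(id = sprintf("rs%05d", 1:2000),
                         chrom = rep(1:20, each = 100),
                         pos = rep(seq_len(100) * 1000L, 20))
  a <- snps$id[1:1106]
  b <- snps$id[1107:(1106 + 461)]
  expect_length(mix_snp_pools(a, b, snps), 1567)
  sel_a <- snps$id[1:433]
  sel_b <- snps$id[434:482]
  expect_length(union(sel_a, sel_b), 482)
  expect_identical(mix_snp_pools(a, a, snps), sort(a))  # idempotent
  ov <- snps$id[1000:1200]
  expect_length(mix_snp_pools(a, ov, snps),
                length(a) + length(ov) - length(intersect(a, ov)))
  # output is position-ordered
  mixed <- mix_snp_pools(b, a, snps)
  hit <- match(mixed, snps$id)
  expect_true(!is.unsorted(order(snps$chrom[hit], snps$pos[hit])))
})

test_that("models-mix pools are unions of selected SNP sets", {
  co <- tiny_cohort(seed = 40, n_cases = 200, n_controls = 200, n_snps = 300)
  pool1 <- co$data$snps$id[1:60]
  pool2 <- co$data$snps$id[50:120]
  m1 <- fit_lasso_cv(co$data, pool1, seed = 1)
  m2 <- fit_lasso_cv(co$data, pool2, seed = 2)
  mix <- mix_model_snps(m1, m2, co$data$snps)
  expect_setequal(mix, union(m1$selected, m2$selected))
  expect_lte(length(mix), length(m1$selected) + length(m2$selected))
  # base superset of missed: pool equals the base selected set
  mix_same <- mix_model_snps(m1, m1, co$data$snps)
  expect_setequal(mix_same, m1$selected)
})

test_that("refitting the base pool with the base seed reproduces the model", {
  co <- tiny_cohort(seed = 41, n_cases = 200, n_controls = 200, n_snps = 300)
  sp <- split_holdout(co$data, 0.2, seed = 5)
  train <- co$data[sp$train, ]; test <- co$data[sp$test, ]
  pool <- co$data$snps$id[1:80]
  base <- fit_lasso_cv(train, pool, seed = 7)
  base_eval <- evaluate(base, test)
  rep <- refit_and_compare(pool, train, test, base_eval,
                           strategy = "snps_mix", seed = 7)
  expect_equal(rep$model$coefficients, base$coefficients)
  expect_equal(rep$model$lambda, base$lambda)
  expect_equal(rep$delta_auc, 0)
  g <- glance(rep)
  expect_identical(g$strategy, "snps_mix")
  expect_false(g$test_informed_selection)
})

test_that("a single-SNP pool yields a valid degenerate model", {
  co <- tiny_cohort(seed = 42, n_cases = 100, n_controls = 100, n_snps = 100)
  sp <- split_holdout(co$data, 0.2, seed = 1)
  base_eval <- evaluate(NULL, co$data[sp$test, ],
                        scores = setNames(rep(0.6, length(sp$test)), sp$test))
  rep <- refit_and_compare(co$data$snps$id[1], co$data[sp$train, ],
                           co$data[sp$test, ], base_eval, seed = 1)
  expect_lte(rep$model_length, 1)
})

test_that("remodeling the missed set needs both classes and honours thresholds", {
  co <- tiny_cohort(seed = 43, n_cases = 150, n_controls = 150, n_snps = 400)
  ids_case <- co$data$samples$iid[co$data$samples$phenotype == 2][1:10]
  expect_error(remodel_missed(ids_case, co$data), "single class")

  ids <- c(co$data$samples$iid[co$data$samples$phenotype == 2][1:15],
           co$data$samples$iid[co$data$samples$phenotype == 1][1:15])
  expect_warning(
    res <- remodel_missed(ids, co$data, p_threshold = 1, seed = 1,
                          include_family = FALSE),
    "degenerate")
  expect_identical(length(res$pool), n_snps(co$data))
  # small missed sets auto-reduce the fold count and still run
  res2 <- remodel_missed(ids, co$data, p_threshold = 0.05, seed = 1,
                         include_family = FALSE)
  expect_lte(res2$model$folds, 10)
  expect_s3_class(res2$eval, "missnp_eval")
  expect_true(res2$optimistic)
})

test_that("remodeling a planted sub-class recovers its causal SNPs", {
  # sub-class large and strong enough for single-SNP power at p < 1e-3
  co <- simulate_cohort(sim_config(
    n_founder_cases = 1200, n_founder_controls = 1200, n_snps = 4000,
    subclass_fraction = 0.4, beta_sub = 0.8, n_causal_sub = 15, seed = 44))
  mis <- co$truth$subclass_members
  res <- remodel_missed(mis, co$data, include_family = FALSE, seed = 3)
  overlap <- length(intersect(res$pool, co$truth$sub_causal_snps))
  # permutation oracle: overlap of a random same-size draw with the truth
  set.seed(3)
  null_overlap <- replicate(1000, length(intersect(
    sample(co$data$snps$id, length(res$pool)), co$truth$sub_causal_snps)))
  p_perm <- (1 + sum(null_overlap >= overlap)) / 1001
  expect_lt(p_perm, 0.01)
})

test_that("model overlap counts shared, specific and redundant SNPs", {
  co <- tiny_cohort(seed = 45, n_cases = 250, n_controls = 250, n_snps = 300)
  pool <- co$data$snps$id[1:60]
  m1 <- fit_lasso_cv(co$data, pool, seed = 1)
  ov <- model_overlap(list(a = m1, b = m1), co$data)
  expect_identical(ov$shared["a", "b"], length(m1$selected))
  expect_identical(unname(ov$specific), c(0L, 0L))
  expect_true(isSymmetric(ov$shared))

  # duplicated SNP column in the data: one pair at r^2 = 1
  d <- co$data$dosage
  d[, pool[2]] <- d[, pool[1]]
  dup <- genotype_data(d, co$data$snps, co$data$samples)
  m_dup <- list(a = m1, b = m1)
  m_dup$a$selected <- pool[1:2]
  ov2 <- model_overlap(m_dup, dup)
  hit <- ov2$redundant_pairs[ov2$redundant_pairs$model == "a", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$r2, 1)

  # independent simulated SNPs at n >= 500: no pairs above 0.95
  for (s in 1:2) {
    coN <- tiny_cohort(seed = 46 + s, n_cases = 260, n_controls = 260,
                       n_snps = 200)
    mN <- list(a = m1, b = m1)
    mN$a$selected <- coN$data$snps$id[1:100]
    mN$b$selected <- character(0)
    ovN <- model_overlap(mN, coN$data)
    expect_identical(nrow(ovN$redundant_pairs), 0L)
  }
})

test_that("the pipeline is deterministic and leak-free in train mode", {
  cfg <- sim_config(n_founder_cases = 150, n_founder_controls = 150,
                    n_snps = 2500, relatives_per_case = 1,
                    missing_rate = 0.002, n_monomorphic = 5, n_no_rsid = 4,
                    beta_main = 0.5, beta_sub = 0.8, seed = 1)
  opts <- pipeline_config(ancestry_filter = FALSE)
  p1 <- run_full_pipeline(cfg, seed = 77, opts = opts)
  p2 <- run_full_pipeline(cfg, seed = 77, opts = opts)
  j1 <- jsonlite::toJSON(p1$summary, auto_unbox = TRUE, digits = NA)
  j2 <- jsonlite::toJSON(p2$summary, auto_unbox = TRUE, digits = NA)
  expect_identical(j1, j2)

  # information flow: in train mode nothing was fit on test samples
  test_ids <- p1$split$test
  expect_length(intersect(p1$base$model$fingerprint$sample_ids, test_ids), 0)
  expect_length(intersect(p1$missed$train$model$fingerprint$sample_ids,
                          test_ids), 0)
  for (nm in grep("^train_", names(p1$mixes), value = TRUE)) {
    expect_false(p1$mixes[[nm]]$test_informed_selection)
    expect_length(intersect(p1$mixes[[nm]]$model$fingerprint$sample_ids,
                            test_ids), 0)
  }
  # the test-informed branch is stamped
  for (nm in grep("^test_", names(p1$mixes), value = TRUE))
    expect_true(p1$mixes[[nm]]$test_informed_selection)
  # remodeling in train mode never saw a test subject
  expect_length(intersect(p1$missed$train$assoc_samples, test_ids), 0)
})

test_that("pipeline artifacts are written when requested", {
  cfg <- sim_config(n_founder_cases = 100, n_founder_controls = 100,
                    n_snps = 1200, beta_main = 0.8, beta_sub = 1, seed = 2)
  dir <- withr::local_tempdir()
  pl <- run_full_pipeline(cfg, seed = 3,
                          opts = pipeline_config(ancestry_filter = FALSE,
                                                 missed_sources = "train"),
                          out_dir = dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(file.exists(file.path(dir, "assoc.tsv")))
  expect_true(file.exists(file.path(dir, "model_base.json")))
  expect_true(any(grepl("^roc_", list.files(dir))))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_identical(js$seed, 3L)
  expect_true(all(c("qc", "pools", "base", "missed", "mixes") %in% names(js)))
})
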