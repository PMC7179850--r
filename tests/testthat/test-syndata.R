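test_that("allele frequencies follow the divergence model", {
  cfg0 <- sim_config(n_snps = 5000, fst = 0, seed = 1)
  set.seed(1)
  f0 <- draw_allele_frequencies(cfg0)
  expect_identical(f0$p1, f0$ancestral)   # fst = 0: exact
  expect_identical(f0$p2, f0$ancestral)

  cfg_deg <- sim_config(n_snps = 100, maf_range = c(0.5, 0.5), seed = 1)
  set.seed(1)
  expect_true(all(draw_allele_frequencies(cfg_deg)$ancestral == 0.5))

  # divergence grows with fst (oracle: Var(p1 - p2) = 2 fst p (1-p))
  gap <- sapply(1:10, function(s) {
    set.seed(s)
    hi <- draw_allele_frequencies(sim_config(n_snps = 10000, fst = 0.05))
    set.seed(s + 100)
    lo <- draw_allele_frequencies(sim_config(n_snps = 10000, fst = 0.005))
    c(hi = mean(abs(hi$p1 - hi$p2)), lo = mean(abs(lo$p1 - lo$p2)))
  })
  expect_true(all(gap["hi", ] > gap["lo", ]))
})

test_that("founder genotypes have binomial moments and degenerate limits", {
  cfg <- sim_config(n_founder_cases = 5000, n_founder_controls = 5000,
                    n_snps = 10, n_causal_main = 2, n_causal_sub = 2, seed = 2)
  freqs <- tibble::tibble(ancestral = c(0, rep(0.5, 9)),
                          p1 = c(0, rep(0.5, 9)), p2 = c(0, rep(0.5, 9)))
  set.seed(2)
  sim <- simulate_genotypes(freqs, cfg)
  expect_true(all(sim$data$dosage[, 1] == 0))          # p = 0
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_true(all(abs(colMeans(sim$data$dosage[, -1]) - 1) < 3 * se))
})

test_that("a fixed seed reproduces the cohort bit-for-bit", {
  a <- tiny_cohort(seed = 9, relatives_per_case = 1, missing_rate = 0.01,
                   n_monomorphic = 3, fst = 0.03, pop2_fraction = 0.3)
  b <- tiny_cohort(seed = 9, relatives_per_case = 1, missing_rate = 0.01,
                   n_monomorphic = 3, fst = 0.03, pop2_fraction = 0.3)
  expect_identical(a$data$dosage, b$data$dosage)
  expect_identical(a$truth, b$truth)
  expect_identical(a$pedigree, b$pedigree)
})

test_that("families obey Mendelian transmission and the kinship manifest", {
  co <- tiny_cohort(seed = 6, n_cases = 150, n_controls = 150, n_snps = 3000,
                    relatives_per_case = 2)
  K <- co$truth$kinship_true
  expect_true(Matrix::isSymmetric(K))
  expect_true(all(Matrix::diag(K) == 0.5))
  off <- K; Matrix::diag(off) <- 0
  expect_true(all(off@x %in% c(0, 0.25)))

  # sib dosage correlation ~ 2 * phi = 0.5 (Cov(Xi,Xj) = 4 phi p(1-p))
  samp <- co$data$samples
  sibs <- samp$iid[grepl("-S1$", samp$iid)]
  fid_of_sib <- samp$fid[match(sibs, samp$iid)]
  founder_ids <- samp$iid[match(fid_of_sib, samp$fid)]
  x <- co$data$dosage[founder_ids, ]
  z <- co$data$dosage[sibs, ]
  # per-SNP correlation across founder-sib pairs, averaged over SNPs
  xs <- scale(x); zs <- scale(z)
  ok <- !is.na(colSums(xs)) & !is.na(colSums(zs))
  cors <- colSums(xs[, ok] * zs[, ok]) / (nrow(x) - 1)
  expect_lt(abs(mean(cors) - 0.5), 0.05)

  # no relatives: singleton families, identity-like kinship
  co0 <- tiny_cohort(seed = 6, relatives_per_case = 0)
  expect_true(all(table(co0$pedigree$fid) == 1))
  expect_identical(Matrix::nnzero(co0$truth$kinship_true), n_samples(co0$data))
})

test_that("offspring of dosage-0 parents are dosage 0", {
  # at allele frequency 0 every parental allele is absent, so the whole
  # family must be dosage 0 by Mendelian transmission
  freqs <- tibble::tibble(ancestral = 0, p1 = 0, p2 = 0)
  cfg1 <- sim_config(n_founder_cases = 20, n_founder_controls = 20,
                     n_snps = 1, relatives_per_case = 2, n_causal_main = 0,
                     n_causal_sub = 0, subclass_fraction = 0, seed = 8)
  set.seed(8)
  sim <- simulate_genotypes(freqs, cfg1)
  ph <- assign_phenotypes(sim, cfg1)
  fam <- simulate_families(ph, sim$population, freqs, cfg1)
  expect_true(all(fam$data$dosage == 0))
})

test_that("phenotype assignment hits the configured balance and truth sets", {
  co <- tiny_cohort(seed = 10, n_cases = 400, n_controls = 400, n_snps = 1000,
                    subclass_fraction = 0)
  expect_identical(length(co$truth$subclass_members), 0L)
  # expected case share calibrated to 0.5; realized within binomial noise
  expect_lt(abs(mean(co$data$samples$phenotype == 2) - 0.5), 3 * sqrt(0.25 / 800))
  expect_length(co$truth$main_causal_snps, 20)
  expect_length(intersect(co$truth$main_causal_snps,
                          co$truth$sub_causal_snps), 0)

  co2 <- tiny_cohort(seed = 11, n_cases = 300, n_controls = 700, n_snps = 500)
  expect_lt(abs(mean(co2$data$samples$phenotype == 2) - 0.3),
            3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("the true main-effect predictor separates cases at the designed level", {
  cfg <- sim_config(n_founder_cases = 1000, n_founder_controls = 1000,
                    n_snps = 2000, subclass_fraction = 0, beta_main = 0.4,
                    n_causal_main = 20, seed = 12)
  co <- simulate_cohort(cfg)
  lp <- true_linear_predictor(co, "main")
  auc <- auc_mann_whitney(lp, phenotype_labels(co$data))
  expect_gt(auc, 0.75)
})

test_that("null genotype effects give chance-level separation", {
  cfg <- sim_config(n_founder_cases = 300, n_founder_controls = 300,
                    n_snps = 500, beta_main = 0, beta_sub = 0, seed = 13)
  co <- simulate_cohort(cfg)
  lp <- true_linear_predictor(co, "main")
  expect_lt(abs(auc_mann_whitney(lp, phenotype_labels(co$data)) - 0.5), 0.07)
})

test_that("planted QC failures match their manifest exactly", {
  co <- tiny_cohort(seed = 14, n_cases = 250, n_controls = 250, n_snps = 1000,
                    n_monomorphic = 50, n_hwe_violating = 10,
                    n_high_missing = 8, n_no_rsid = 6, missing_rate = 0)
  pf <- co$truth$planted_failures
  expect_length(pf$monomorphic, 50)
  d <- co$data$dosage
  one_value <- vapply(pf$monomorphic, function(s)
    length(unique(d[!is.na(d[, s]), s])) <= 1, logical(1))
  expect_true(all(one_value))
  n_single <- sum(apply(d, 2, function(x) length(unique(x[!is.na(x)])) <= 1))
  expect_identical(n_single, 50L)          # exactly the planted ones
  expect_true(all(!grepl("^rs", pf$no_rsid)))
  expect_true(all(colMeans(is.na(d[, pf$high_missing, drop = FALSE])) > 0.02))
  expect_length(intersect(unlist(pf),
                          c(co$truth$main_causal_snps,
                            co$truth$sub_causal_snps)), 0)
})

test_that("hwe_inbreeding = 1 plants zero heterozygotes", {
  co <- tiny_cohort(seed = 15, n_cases = 100, n_controls = 100, n_snps = 300,
                    n_hwe_violating = 5, hwe_inbreeding = 1)
  hw <- co$truth$planted_failures$hwe
  expect_true(all(colSums(co$data$dosage[, hw, drop = FALSE] == 1) == 0))
})

test_that("background missingness matches its binomial rate", {
  co <- tiny_cohort(seed = 16, n_cases = 250, n_controls = 250, n_snps = 2000,
                    missing_rate = 0.01)
  frac <- mean(is.na(co$data$dosage))
  se <- sqrt(0.01 * 0.99 / (500 * 2000))
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("an exchangeable null cohort yields uniform association p-values", {
  rejected <- logical(5)
  for (s in 1:5) {
    cfg <- sim_config(n_founder_cases = 500, n_founder_controls = 500,
                      n_snps = 5000, beta_main = 0, beta_sub = 0,
                      subclass_fraction = 0, fst = 0, seed = 100 + s)
    co <- simulate_cohort(cfg)
    tab <- assoc_scan(co$data)
    rejected[s] <- suppressWarnings(stats::ks.test(tab$p.value, "punif"))$p.value < 0.01
  }
  expect_true(all(!rejected))
})

test_that("configuration errors are caught", {
  expect_error(sim_config(fst = 0.6), "fst")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(subclass_fraction = 1), "subclass_fraction")
  expect_error(sim_config(n_snps = 10, n_causal_main = 8, n_causal_sub = 8),
               "exceed")
  expect_error(sim_config(relatives_per_case = 3), "relatives_per_case")
  # unattainable balance
  cfg <- sim_config(n_founder_cases = 1, n_founder_controls = 999,
                    n_snps = 50, beta_main = 50, n_causal_main = 10,
                    n_causal_sub = 2, seed = 1)
  expect_error(simulate_cohort(cfg), "balance|unattainable")
})
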