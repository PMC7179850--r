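# Synthetic GWAS cohort generator: two ancestry clusters (Balding-Nichols),
# nuclear families (full siblings of affected founders), a majority disease
# signal plus a hidden genetic sub-class, and planted QC failures with a
# ground-truth manifest for every planted feature.

#' Configure a synthetic cohort
#'
#' Returns a validated configuration for [simulate_cohort()].  The defaults
#' describe the package's reference validation cohort: ~2,000 unrelated
#' subjects from one homogeneous population, 20,000 biallelic autosomal
#' SNPs, a majority signal of 20 SNPs at log-odds 0.4 per dosage unit, and
#' a hidden sub-class (15% of subjects) whose status is instead driven by
#' 15 different SNPs at log-odds 0.6.  Families, stratification and QC
#' failures are off by default and switched on explicitly where a study
#' needs them.
#'
#' @param n_founder_cases,n_founder_controls target numbers of case and
#'   control founders; their ratio sets the case share the phenotype model
#'   is calibrated to.
#' @param relatives_per_case full siblings generated per affected founder
#'   (0, 1 or 2).
#' @param n_snps number of SNPs.
#' @param maf_range range the ancestral minor-allele frequencies are drawn
#'   from, within (0, 0.5].
#' @param n_causal_main,beta_main size and per-dosage log-odds of the
#'   majority causal SNP set.
#' @param n_causal_sub,beta_sub size and per-dosage log-odds of the
#'   sub-class causal SNP set.
#' @param subclass_fraction share of subjects whose phenotype follows the
#'   sub-class SNPs instead of the majority set, in [0, 1).
#' @param fst Balding-Nichols divergence between the two populations, in
#'   [0, 0.5).
#' @param pop2_fraction share of subjects drawn from population 2.
#' @param missing_rate background completely-at-random missingness.
#' @param n_monomorphic,n_hwe_violating,n_high_missing,n_no_rsid counts of
#'   planted QC failures (disjoint SNP sets, never causal SNPs).
#' @param hwe_inbreeding inbreeding coefficient used for the planted
#'   Hardy-Weinberg violations, in (0, 1].
#' @param seed integer seed; a fixed seed makes [simulate_cohort()] output
#'   bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founder_cases = 1000, n_founder_controls = 1000,
                       relatives_per_case = 0, n_snps = 20000,
                       maf_range = c(0.05, 0.5),
                       n_causal_main = 20, beta_main = 0.4,
                       n_causal_sub = 15, beta_sub = 0.6,
                       subclass_fraction = 0.15,
                       fst = 0, pop2_fraction = 0,
                       missing_rate = 0,
                       n_monomorphic = 0, n_hwe_violating = 0,
                       hwe_inbreeding = 0.8, n_high_missing = 0,
                       n_no_rsid = 0, seed = 1L) {
  cfg <- list(n_founder_cases = n_founder_cases,
              n_founder_controls = n_founder_controls,
              relatives_per_case = relatives_per_case, n_snps = n_snps,
              maf_range = maf_range, n_causal_main = n_causal_main,
              beta_main = beta_main, n_causal_sub = n_causal_sub,
              beta_sub = beta_sub, subclass_fraction = subclass_fraction,
              fst = fst, pop2_fraction = pop2_fraction,
              missing_rate = missing_rate, n_monomorphic = n_monomorphic,
              n_hwe_violating = n_hwe_violating,
              hwe_inbreeding = hwe_inbreeding,
              n_high_missing = n_high_missing, n_no_rsid = n_no_rsid,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_founder_cases < 1 || n_founder_controls < 1)
      abort("need at least one case and one control founder")
    if (!relatives_per_case %in% 0:2)
      abort("relatives_per_case must be 0, 1 or 2")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      abort("maf_range must lie within (0, 0.5]")
    if (fst < 0 || fst >= 0.5)
      abort("fst must lie in [0, 0.5)")
    if (subclass_fraction < 0 || subclass_fraction >= 1)
      abort("subclass_fraction must lie in [0, 1)")
    for (p in c(pop2_fraction, missing_rate))
      if (p < 0 || p > 1) abort("proportions must lie in [0, 1]")
    if (hwe_inbreeding <= 0 || hwe_inbreeding > 1)
      abort("hwe_inbreeding must lie in (0, 1]")
    if (n_causal_main + n_causal_sub + n_monomorphic + n_hwe_violating +
        n_high_missing + n_no_rsid > n_snps)
      abort("causal and planted-failure SNP counts exceed n_snps")
  })
  invisible(cfg)
}

#' Draw per-population allele frequencies (Balding-Nichols model)
#'
#' Ancestral frequencies are uniform on `maf_range`; each population's
#' frequency is a Beta draw with mean equal to the ancestral frequency `p`
#' and shape parameters `p(1-fst)/fst` and `(1-p)(1-fst)/fst`, so the
#' cross-population variance is `fst * p * (1-p)`.  With `fst = 0` both
#' populations carry the ancestral frequency exactly.
#'
#' Uses the current RNG state; [simulate_cohort()] seeds once from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A tibble with one row per SNP: `ancestral`, `p1`, `p2`.
#' @export
draw_allele_frequencies <- function(config) {
  m <- config$n_snps
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  if (config$fst == 0) {
    p1 <- p2 <- p
  } else {
    a <- p * (1 - config$fst) / config$fst
    b <- (1 - p) * (1 - config$fst) / config$fst
    p1 <- rbeta(m, a, b)
    p2 <- rbeta(m, a, b)
  }
  tibble(ancestral = p, p1 = p1, p2 = p2)
}

# deterministic SNP map: 22 autosomes with sizes decaying like real
# chromosomes, 1 kb marker spacing
make_snp_map <- function(m) {
  w <- (23 - 1:22); quota <- floor(m * w / sum(w))
  rem <- m - sum(quota)
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  chrom <- rep.int(1:22, quota)
  pos <- unlist(lapply(quota, function(k) seq_len(k) * 1000L), use.names = FALSE)
  tibble(chrom = as.integer(chrom), id = sprintf("rs%07d", seq_len(m)),
         cm = 0, pos = as.integer(pos), a1 = "A", a2 = "B")
}

#' Simulate founder genotypes
#'
#' Founders are assigned to population 2 with probability `pop2_fraction`
#' and their dosages drawn binomial(2, p) from that population's SNP
#' frequencies.
#'
#' @param freqs output of [draw_allele_frequencies()].
#' @param config a [sim_config()].
#' @return A list: `data` (a [genotype_data] with phenotypes still unset)
#'   and `population` (integer vector, 1 or 2, per founder).
#' @export
simulate_genotypes <- function(freqs, config) {
  n <- config$n_founder_cases + config$n_founder_controls
  m <- config$n_snps
  population <- 1L + (runif(n) < config$pop2_fraction)
  dos <- matrix(0, n, m)
  for (pop in 1:2) {
    idx <- which(population == pop)
    if (!length(idx)) next
    pp <- if (pop == 1) freqs$p1 else freqs$p2
    dos[idx, ] <- rbinom(length(idx) * m, 2L, rep(pp, each = length(idx)))
  }
  ids <- sprintf("S%05d", seq_len(n))
  samples <- tibble(fid = sprintf("F%05d", seq_len(n)), iid = ids,
                    father = "0", mother = "0", sex = 0L, phenotype = 0L)
  list(data = new_genotype_data(dos, make_snp_map(m), samples),
       population = population)
}

# solve the intercept so that mean(plogis(alpha + score)) hits `target`,
# by bisection to 1e-6 on the expected case share
solve_intercept <- function(score, target, tol = 1e-6) {
  f <- function(a) mean(stats::plogis(a + score)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    abort("case:control balance unattainable for the configured effect sizes")
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Assign case/control phenotypes with a hidden sub-class
#'
#' Picks disjoint majority and sub-class causal SNP sets (never the planted
#' QC-failure positions, which are reserved last in SNP order), flags a
#' `subclass_fraction` share of subjects as sub-class members, and draws
#' phenotypes from per-group logistic models: majority subjects from
#' `logistic(alpha_main + beta_main * sum(dosages over main set))`,
#' sub-class subjects from the analogous model over the sub-class set.
#' Each group's intercept is solved by bisection so its expected case share
#' equals the configured case:control balance.
#'
#' @param sim output of [simulate_genotypes()] (or any list with `data`).
#' @param config a [sim_config()].
#' @return A list: `data` with phenotypes filled in, `subclass_members`,
#'   `main_causal_snps`, `sub_causal_snps`, `alpha_main`, `alpha_sub`.
#' @export
assign_phenotypes <- function(sim, config) {
  data <- sim$data
  n <- n_samples(data); m <- n_snps(data)
  target <- config$n_founder_cases /
    (config$n_founder_cases + config$n_founder_controls)
  n_reserved <- config$n_monomorphic + config$n_hwe_violating +
    config$n_high_missing + config$n_no_rsid
  eligible <- seq_len(m - n_reserved)
  causal <- sample(eligible, config$n_causal_main + config$n_causal_sub)
  main_idx <- causal[seq_len(config$n_causal_main)]
  sub_idx <- setdiff(causal, main_idx)
  sub_members <- sample(n, round(config$subclass_fraction * n))
  is_sub <- seq_len(n) %in% sub_members

  score_main <- config$beta_main *
    rowSums(data$dosage[, main_idx, drop = FALSE])
  score_sub <- if (length(sub_idx)) config$beta_sub *
    rowSums(data$dosage[, sub_idx, drop = FALSE]) else numeric(n)

  alpha_main <- solve_intercept(score_main[!is_sub], target)
  alpha_sub <- if (any(is_sub)) solve_intercept(score_sub[is_sub], target) else NA_real_

  pr <- numeric(n)
  pr[!is_sub] <- stats::plogis(alpha_main + score_main[!is_sub])
  if (any(is_sub)) pr[is_sub] <- stats::plogis(alpha_sub + score_sub[is_sub])
  data$samples$phenotype <- ifelse(runif(n) < pr, 2L, 1L)

  list(data = data,
       subclass_members = data$samples$iid[is_sub],
       main_causal_snps = data$snps$id[main_idx],
       sub_causal_snps = data$snps$id[sub_idx],
       alpha_main = alpha_main, alpha_sub = alpha_sub)
}

#' Add full-sibling relatives of affected founders
#'
#' For each case founder, two parents are drawn from their exact posterior
#' given the founder's genotype under Hardy-Weinberg (transmitted alleles
#' recovered from the founder, untransmitted alleles drawn Bernoulli from
#' the founder's population frequency), and `relatives_per_case` full
#' siblings are generated by Mendelian transmission from those parents.
#' The founder's own genotype is therefore preserved along with its
#' phenotype association.  Siblings receive phenotypes from the same
#' per-group logistic models (intercepts reused from the founder fit;
#' sub-class membership drawn independently at `subclass_fraction`).
#' Parents are latent: they appear in the pedigree but carry no genotype
#' row.
#'
#' @param pheno output of [assign_phenotypes()].
#' @param population founder population assignments.
#' @param freqs output of [draw_allele_frequencies()].
#' @param config a [sim_config()].
#' @return A list: `data` (founders + siblings), `pedigree` (tibble
#'   including latent parent rows), `kinship_true` (sparse symmetric
#'   matrix over genotyped samples: 0.5 diagonal, 0.25 within a sibship),
#'   `subclass_members` (updated), `population` (per genotyped sample).
#' @export
simulate_families <- function(pheno, population, freqs, config) {
  data <- pheno$data
  n <- n_samples(data); m <- n_snps(data)
  k <- config$relatives_per_case
  aff <- which(data$samples$phenotype == 2L)
  ped_extra <- NULL
  sub_members <- pheno$subclass_members
  fam_members <- lapply(seq_len(n), function(i) i)  # genotyped members per family

  if (k > 0 && length(aff) > 0) {
    na <- length(aff)
    pp <- cbind(freqs$p1, freqs$p2)
    q <- pp[, population[aff], drop = FALSE]      # m x na
    q <- t(q)                                     # na x m
    gc <- data$dosage[aff, , drop = FALSE]
    # transmitted alleles: gc=0 -> (0,0); gc=2 -> (1,1); gc=1 -> random split
    am <- (gc == 2) + (gc == 1) * (runif(na * m) < 0.5)
    af <- gc - am
    # untransmitted alleles ~ Bernoulli(q)
    gm <- am + (runif(na * m) < q)
    gf <- af + (runif(na * m) < q)

    fid <- data$samples$fid[aff]
    p1_id <- paste0(fid, "-P1"); p2_id <- paste0(fid, "-P2")
    data$samples$father[aff] <- p1_id
    data$samples$mother[aff] <- p2_id

    main_idx <- match(pheno$main_causal_snps, data$snps$id)
    sub_idx <- match(pheno$sub_causal_snps, data$snps$id)
    target_sub <- config$subclass_fraction

    sib_dos <- vector("list", k)
    sib_samples <- vector("list", k)
    new_sub <- character(0)
    for (s in seq_len(k)) {
      d <- (runif(na * m) < gm / 2) + (runif(na * m) < gf / 2)
      dim(d) <- c(na, m)
      sib_id <- sprintf("%s-S%d", fid, s)
      is_sub <- runif(na) < target_sub
      sc_main <- config$beta_main * rowSums(d[, main_idx, drop = FALSE])
      sc_sub <- if (length(sub_idx)) config$beta_sub *
        rowSums(d[, sub_idx, drop = FALSE]) else numeric(na)
      pr <- ifelse(is_sub, stats::plogis(pheno$alpha_sub + sc_sub),
                   stats::plogis(pheno$alpha_main + sc_main))
      ph <- ifelse(runif(na) < pr, 2L, 1L)
      sib_dos[[s]] <- d
      sib_samples[[s]] <- tibble(fid = fid, iid = sib_id, father = p1_id,
                                 mother = p2_id, sex = 0L, phenotype = ph)
      new_sub <- c(new_sub, sib_id[is_sub])
    }
    sub_members <- c(sub_members, new_sub)
    all_dos <- rbind(data$dosage, do.call(rbind, sib_dos))
    all_samples <- dplyr::bind_rows(data$samples, sib_samples)
    data <- new_genotype_data(all_dos, data$snps, all_samples)
    population <- c(population, rep(population[aff], k))
    ped_extra <- tibble(fid = rep(fid, 2), iid = c(p1_id, p2_id),
                        father = "0", mother = "0")
    # sibship membership for kinship
    for (jj in seq_along(aff)) {
      i <- aff[jj]
      fam_members[[i]] <- c(i, n + jj + na * (seq_len(k) - 1))
    }
  }

  ped <- dplyr::bind_rows(pedigree_of(data), ped_extra)
  nn <- n_samples(data)
  ii <- unlist(lapply(fam_members, function(mem)
    rep(mem, each = length(mem))), use.names = FALSE)
  jj <- unlist(lapply(fam_members, function(mem)
    rep(mem, times = length(mem))), use.names = FALSE)
  vv <- ifelse(ii == jj, 0.5, 0.25)
  kin <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nn, nn),
                              dimnames = list(data$samples$iid,
                                              data$samples$iid))
  list(data = data, pedigree = ped,
       kinship_true = methods::as(Matrix::forceSymmetric(kin), "CsparseMatrix"),
       subclass_members = sub_members, population = population)
}

#' Overwrite designated SNPs with planted quality-control failures
#'
#' Failure SNPs are taken from the reserved tail of the SNP map (never
#' causal), pairwise disjoint: monomorphic SNPs are set to all-zero dosage;
#' Hardy-Weinberg violations are redrawn at frequency 0.5 with inbreeding
#' coefficient `hwe_inbreeding` (het probability `2p(1-p)(1-F)`);
#' high-missingness SNPs get a per-SNP missing rate drawn uniformly from
#' 5-15%; no-rsID SNPs keep their genotypes but lose their "rs" identifier.
#' Background missingness `missing_rate` is applied to all remaining SNPs.
#'
#' @param fam output of [simulate_families()] (or any list with `data`).
#' @param config a [sim_config()].
#' @return The input list with `data` modified and `planted_failures`
#'   added (a list of SNP-ID sets keyed by failure kind).
#' @export
plant_qc_failures <- function(fam, config) {
  data <- fam$data
  n <- n_samples(data); m <- n_snps(data)
  counts <- c(monomorphic = config$n_monomorphic,
              hwe = config$n_hwe_violating,
              high_missing = config$n_high_missing,
              no_rsid = config$n_no_rsid)
  n_reserved <- sum(counts)
  idx <- if (n_reserved > 0) (m - n_reserved + 1):m else integer(0)
  sets <- split(idx, rep(names(counts), counts[c("monomorphic", "hwe",
                                                 "high_missing", "no_rsid")]))
  sets <- sets[intersect(c("monomorphic", "hwe", "high_missing", "no_rsid"),
                         names(sets))]
  mono <- sets$monomorphic; hwe <- sets$hwe
  himiss <- sets$high_missing; norsid <- sets$no_rsid

  if (length(mono)) data$dosage[, mono] <- 0
  if (length(hwe)) {
    p <- 0.5; F <- config$hwe_inbreeding
    probs <- c(`2` = p^2 + F * p * (1 - p), `1` = 2 * p * (1 - p) * (1 - F),
               `0` = (1 - p)^2 + F * p * (1 - p))
    draws <- sample(c(2, 1, 0), n * length(hwe), replace = TRUE, prob = probs)
    data$dosage[, hwe] <- matrix(draws, n, length(hwe))
  }
  if (length(himiss)) {
    rate <- runif(length(himiss), 0.05, 0.15)
    mask <- matrix(runif(n * length(himiss)) <
                     matrix(rate, n, length(himiss), byrow = TRUE),
                   n, length(himiss))
    block <- data$dosage[, himiss, drop = FALSE]
    block[mask] <- NA
    data$dosage[, himiss] <- block
  }
  if (length(norsid)) {
    data$snps$id[norsid] <- sub("^rs", "var", data$snps$id[norsid])
    colnames(data$dosage) <- data$snps$id
  }
  if (config$missing_rate > 0) {
    rest <- setdiff(seq_len(m), c(mono, hwe, himiss, norsid))
    mask <- matrix(runif(n * length(rest)) < config$missing_rate,
                   n, length(rest))
    block <- data$dosage[, rest, drop = FALSE]
    block[mask] <- NA
    data$dosage[, rest] <- block
  }
  fam$data <- data
  fam$planted_failures <- list(
    monomorphic = data$snps$id[mono], hwe = data$snps$id[hwe],
    high_missing = data$snps$id[himiss], no_rsid = data$snps$id[norsid])
  fam
}

# orient every SNP to minor-allele dosage on observed calls (strict > 0.5
# flips; exact ties keep "A" as allele1, matching the text-dialect reader's
# alphabetical tie-break) so PLINK text round-trips are lossless
canonicalize_minor <- function(data) {
  frq <- colMeans(data$dosage, na.rm = TRUE) / 2
  flip <- which(!is.nan(frq) & frq > 0.5)
  if (length(flip)) {
    data$dosage[, flip] <- 2 - data$dosage[, flip]
    a1 <- data$snps$a1[flip]
    data$snps$a1[flip] <- data$snps$a2[flip]
    data$snps$a2[flip] <- a1
  }
  list(data = data, flipped = data$snps$id[flip])
}

#' Simulate a complete cohort with ground truth
#'
#' Runs the full generator under `config$seed`: allele frequencies,
#' founder genotypes and populations, phenotypes with a hidden sub-class,
#' sibling relatives of affected founders, planted QC failures, and a
#' final reorientation of every SNP to minor-allele dosage.  Output is
#' bit-reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return A list of class `missnp_cohort`: `data` (a [genotype_data]),
#'   `pedigree`, and `truth` — the manifest with `main_causal_snps`,
#'   `sub_causal_snps`, `subclass_members`, `population_of` (named
#'   integer vector), `planted_failures`, `kinship_true` (sparse),
#'   `flipped_snps`, and the solved intercepts.
#' @examples
#' cohort <- simulate_cohort(sim_config(
#'   n_founder_cases = 60, n_founder_controls = 60, n_snps = 300, seed = 7))
#' cohort$data
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  freqs <- draw_allele_frequencies(config)
  sim <- simulate_genotypes(freqs, config)
  pheno <- assign_phenotypes(sim, config)
  fam <- simulate_families(pheno, sim$population, freqs, config)
  fam <- plant_qc_failures(fam, config)
  can <- canonicalize_minor(fam$data)
  truth <- list(
    main_causal_snps = pheno$main_causal_snps,
    sub_causal_snps = pheno$sub_causal_snps,
    subclass_members = fam$subclass_members,
    population_of = setNames(fam$population, can$data$samples$iid),
    planted_failures = fam$planted_failures,
    kinship_true = fam$kinship_true,
    flipped_snps = can$flipped,
    alpha_main = pheno$alpha_main, alpha_sub = pheno$alpha_sub,
    beta_main = config$beta_main, beta_sub = config$beta_sub,
    allele_freqs = freqs)
  structure(list(data = can$data, pedigree = fam$pedigree, truth = truth,
                 config = config),
            class = "missnp_cohort")
}

#' @export
print.missnp_cohort <- function(x, ...) {
  cat("<missnp_cohort>\n")
  print(x$data)
  cat(sprintf("  causal SNPs: %d main / %d sub-class; sub-class members: %d\n",
              length(x$truth$main_causal_snps),
              length(x$truth$sub_causal_snps),
              length(x$truth$subclass_members)))
  invisible(x)
}

#' True genetic linear predictor of a cohort
#'
#' The oracle score used to benchmark classifiers: for each subject, the
#' linear predictor of the generating logistic model (majority model for
#' majority subjects, sub-class model for sub-class members), computed
#' from the manifest with the post-reorientation dosage scale handled.
#'
#' @param cohort a `missnp_cohort`.
#' @param group `"auto"` (per-subject true group), `"main"` or `"sub"`
#'   (force one model for everybody).
#' @return Named numeric vector of linear predictor values.
#' @export
true_linear_predictor <- function(cohort, group = c("auto", "main", "sub")) {
  group <- match.arg(group)
  tr <- cohort$truth
  d <- cohort$data$dosage
  orient <- function(ids) {
    x <- d[, ids, drop = FALSE]
    fl <- intersect(ids, tr$flipped_snps)
    if (length(fl)) x[, fl] <- 2 - x[, fl]
    x
  }
  sc_main <- tr$alpha_main + tr$beta_main * rowSums(orient(tr$main_causal_snps))
  sc_sub <- if (length(tr$sub_causal_snps))
    tr$alpha_sub + tr$beta_sub * rowSums(orient(tr$sub_causal_snps))
  else rep(NA_real_, nrow(d))
  out <- switch(group, main = sc_main, sub = sc_sub,
                auto = ifelse(cohort$data$samples$iid %in% tr$subclass_members,
                              sc_sub, sc_main))
  setNames(out, cohort$data$samples$iid)
}
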