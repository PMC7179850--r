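# Subject- and SNP-level quality control: phenotype clean-up, ancestry PCA
# (EIGENSTRAT normalization), one-member-per-family selection, and the SNP
# filter cascade (autosomes, rs IDs, call rate, monomorphism,
# Hardy-Weinberg).

qc_stage <- function(stage, unit, n_in, removed_ids) {
  tibble(stage = stage, unit = unit, n_in = n_in,
         n_removed = length(removed_ids), n_out = n_in - length(removed_ids),
         removed = list(removed_ids))
}

new_qc_report <- function(stages) {
  out <- dplyr::bind_rows(stages)
  class(out) <- c("qc_report", class(out))
  out
}

#' Remove subjects with unclear phenotype
#'
#' Keeps subjects coded 1 (control) or 2 (case); anything else (0, -9, ...)
#' is an unclear phenotype and is removed.
#'
#' @param data a [genotype_data] object.
#' @return A list: `data` (filtered) and `report` (one-stage QC report).
#' @export
filter_phenotype <- function(data) {
  bad <- !data$samples$phenotype %in% c(1L, 2L)
  report <- new_qc_report(qc_stage("phenotype", "subjects", n_samples(data),
                                   data$samples$iid[bad]))
  if (all(bad)) abort("no subjects remain after phenotype filtering")
  if (!any(bad)) return(list(data = data, report = report))
  list(data = data[which(!bad), ], report = report)
}

#' Ancestry filtering by principal components
#'
#' EIGENSTRAT-style detection of population structure: up to `n_snps` SNPs
#' are sampled without replacement with per-chromosome quotas proportional
#' to each chromosome's SNP count, dosages are normalized per SNP to
#' `(g - mu) / sqrt(p(1-p))` with `p = mu/2` (missing cells set to 0 after
#' centering), and the top principal components of the samples are
#' computed.  Within each phenotype group (when `per_group`), the side of
#' `pc1_threshold` holding the majority of that group is retained, so a
#' minority ancestry cluster separated along PC1 is removed separately in
#' cases and in controls.
#'
#' @param data a [genotype_data] object.
#' @param n_snps number of SNPs to sample for the decomposition (all SNPs
#'   if fewer are available).
#' @param n_pcs number of components to return.
#' @param pc1_threshold split point on PC1 (the cluster gap is commonly
#'   close to zero).
#' @param per_group apply the majority rule within cases and controls
#'   separately.
#' @param min_eigen_ratio structure gate: the PC1 split is only applied
#'   when the top two eigenvalues satisfy `lambda1 / lambda2 >
#'   min_eigen_ratio`.  Without genuine stratification PC1 is exchangeable
#'   noise centred on zero and a threshold split would discard half the
#'   cohort; under the Balding-Nichols model the ratio sits near 1 for a
#'   homogeneous cohort and well above 2 once clusters exist.
#' @param seed optional integer seed for the SNP sampling.
#' @return A list: `data` (retained subjects), `coords` (tibble of class
#'   `missnp_pca`: `iid`, `phenotype`, `PC1..PCk`, `retained`), and
#'   `report` (one-stage QC report).
#' @export
pca_ancestry_filter <- function(data, n_snps = 100000, n_pcs = 2,
                                pc1_threshold = 0, per_group = TRUE,
                                min_eigen_ratio = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples(data); m <- n_snps(data)
  if (n < n_pcs) abort("fewer samples than requested components")
  idx <- if (m <= n_snps) seq_len(m) else {
    counts <- table(factor(data$snps$chrom, levels = sort(unique(data$snps$chrom))))
    quota <- floor(n_snps * as.numeric(counts) / m)
    rem <- n_snps - sum(quota)
    if (rem > 0) {
      extra <- order(n_snps * as.numeric(counts) / m - quota,
                     decreasing = TRUE)[seq_len(rem)]
      quota[extra] <- quota[extra] + 1L
    }
    unlist(purrr::map2(split(seq_len(m), factor(data$snps$chrom,
                                                levels = names(counts))),
                       quota,
                       function(snps, q) sort(sample(snps, min(q, length(snps))))),
           use.names = FALSE)
  }
  G <- data$dosage[, idx, drop = FALSE]
  mu <- colMeans(G, na.rm = TRUE)
  p <- mu / 2
  usable <- which(!is.nan(p) & p > 0 & p < 1)
  if (!length(usable)) abort("all sampled SNPs are monomorphic")
  G <- G[, usable, drop = FALSE]
  M <- sweep(G, 2, mu[usable])
  M[is.na(M)] <- 0
  M <- sweep(M, 2, sqrt(p[usable] * (1 - p[usable])), "/")
  eg <- eigen(tcrossprod(M) / ncol(M), symmetric = TRUE)
  coords <- eg$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(n_pcs)], 0)), n_pcs)
  colnames(coords) <- paste0("PC", seq_len(n_pcs))
  structured <- eg$values[1] > min_eigen_ratio * max(eg$values[2], 1e-12)

  ph <- data$samples$phenotype
  groups <- if (per_group) split(seq_len(n), ph) else list(seq_len(n))
  keep <- logical(n)
  for (g in groups) {
    if (!structured) { keep[g] <- TRUE; next }
    upper <- coords[g, 1] >= pc1_threshold
    keep[g] <- if (mean(upper) >= 0.5) upper else !upper
  }
  coord_tab <- dplyr::bind_cols(
    tibble(iid = data$samples$iid, phenotype = ph),
    as_tibble(coords))
  coord_tab$retained <- keep
  class(coord_tab) <- c("missnp_pca", class(coord_tab))
  report <- new_qc_report(qc_stage("ancestry_pca", "subjects", n,
                                   data$samples$iid[!keep]))
  list(data = data[which(keep), ], coords = coord_tab, report = report)
}

#' Select one subject per family
#'
#' Retains exactly one individual per family ID, chosen uniformly at
#' random, turning a familial cohort into an unrelated subset.
#'
#' @param data a [genotype_data] object.
#' @param pedigree optional pedigree table supplying family IDs for the
#'   samples (defaults to the `fid` stored in `data`).
#' @param seed optional integer seed for the random choice.
#' @return A list: `data` (one member per family, input order preserved)
#'   and `report` (one-stage QC report).
#' @export
select_unrelated <- function(data, pedigree = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fid <- data$samples$fid
  if (!is.null(pedigree)) {
    pedigree <- as_tibble(pedigree)
    hit <- match(data$samples$iid, pedigree$iid)
    if (anyNA(hit)) abort("pedigree does not cover all samples")
    fid <- as.character(pedigree$fid[hit])
  }
  picked <- unlist(lapply(split(seq_len(n_samples(data)), fid),
                          function(i) if (length(i) == 1) i else sample(i, 1)),
                   use.names = FALSE)
  keep <- sort(picked)
  removed <- data$samples$iid[setdiff(seq_len(n_samples(data)), keep)]
  report <- new_qc_report(qc_stage("one_per_family", "subjects",
                                   n_samples(data), removed))
  if (!length(removed)) return(list(data = data, report = report))
  list(data = data[keep, ], report = report)
}

#' SNP-level quality-control cascade
#'
#' Applies, in order: (1) autosomes only (chromosome code <= 22); (2)
#' require an "rs" identifier; (3) call rate — the fraction of non-missing
#' calls computed within cases and within controls separately, SNP removed
#' if strictly below `min_call_rate` in either group; (4) monomorphic
#' SNPs (a single observed genotype value among non-missing calls); (5)
#' Hardy-Weinberg — test in the `hwe_on` group, remove if p strictly below
#' `hwe_alpha`.  A SNP with call rate exactly at the threshold is
#' retained, and HWE p exactly at `hwe_alpha` is retained: both bounds are
#' strict, matching the conventional "lower than" phrasing.
#'
#' @param data a [genotype_data] object.
#' @param autosomes_only,require_rsid,drop_monomorphic logical switches
#'   for the corresponding filters.
#' @param min_call_rate call-rate threshold (strict).
#' @param hwe_alpha Hardy-Weinberg p-value threshold (strict); `0`
#'   disables the filter.
#' @param hwe_on `"controls"` (default, the field standard — avoids
#'   removing true case-only association signals), `"cases"` or `"all"`.
#' @param hwe_method `"chisq"` or `"exact"`, see [hwe_test()].
#' @return A list: `data` (filtered, SNP order preserved) and `report`
#'   (QC report tibble, one row per filter with removed SNP IDs).
#' @export
snp_qc <- function(data, autosomes_only = TRUE, require_rsid = TRUE,
                   min_call_rate = 0.98, hwe_alpha = 1e-5,
                   drop_monomorphic = TRUE,
                   hwe_on = c("controls", "cases", "all"),
                   hwe_method = c("chisq", "exact")) {
  hwe_on <- match.arg(hwe_on)
  hwe_method <- match.arg(hwe_method)
  stages <- list()
  drop_stage <- function(name, bad_ids) {
    stages[[length(stages) + 1]] <<- qc_stage(name, "snps", n_snps(data), bad_ids)
    if (length(bad_ids)) data <<- data[, setdiff(data$snps$id, bad_ids)]
  }

  if (autosomes_only)
    drop_stage("autosomes", data$snps$id[data$snps$chrom > 22])
  if (require_rsid)
    drop_stage("rsid", data$snps$id[!grepl("^rs", data$snps$id)])

  ph <- data$samples$phenotype
  grp_rate <- function(rows) {
    if (!length(rows)) return(rep(1, n_snps(data)))
    colMeans(!is.na(data$dosage[rows, , drop = FALSE]))
  }
  low <- grp_rate(which(ph == 2)) < min_call_rate |
    grp_rate(which(ph == 1)) < min_call_rate
  drop_stage("call_rate", data$snps$id[low])

  if (drop_monomorphic) {
    nAA <- colSums(data$dosage == 2, na.rm = TRUE)
    nAa <- colSums(data$dosage == 1, na.rm = TRUE)
    naa <- colSums(data$dosage == 0, na.rm = TRUE)
    mono <- (nAA > 0) + (nAa > 0) + (naa > 0) <= 1
    drop_stage("monomorphic", data$snps$id[mono])
  }

  if (hwe_alpha > 0) {
    rows <- switch(hwe_on, controls = which(ph == 1), cases = which(ph == 2),
                   all = seq_along(ph))
    d <- data$dosage[rows, , drop = FALSE]
    nAA <- colSums(d == 2, na.rm = TRUE)
    nAa <- colSums(d == 1, na.rm = TRUE)
    naa <- colSums(d == 0, na.rm = TRUE)
    tot <- nAA + nAa + naa
    pv <- rep(1, n_snps(data))
    ok <- tot > 0
    pv[ok] <- hwe_test(nAA[ok], nAa[ok], naa[ok], method = hwe_method)$p.value
    drop_stage("hwe", data$snps$id[pv < hwe_alpha])
  }

  list(data = data, report = new_qc_report(stages))
}
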