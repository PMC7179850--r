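# Kinship estimation from pedigrees, Hardy-Weinberg tests, and the
# kinship-corrected chi-square association scan used for SNP pre-selection.

#' Kinship coefficients from a pedigree
#'
#' Recursive tabular method: individuals are processed in generation order
#' within each family; founders are unrelated with self-kinship 0.5;
#' `phi(j,j) = 0.5 * (1 + phi(father, mother))` and
#' `phi(i,j) = 0.5 * (phi(i, father(j)) + phi(i, mother(j)))`.
#' Parents referenced but not listed get implicit founder rows.  Families
#' (distinct `fid`) are assumed unrelated, which keeps the result sparse.
#'
#' @param ped data frame with columns `fid`, `iid`, `father`, `mother`
#'   (`"0"` = unknown/founder).
#' @return A sparse symmetric kinship matrix (`Matrix::dsCMatrix`) with
#'   one row/column per pedigree individual, dimnames set to `iid`.
#' @examples
#' ped <- data.frame(fid = "F1", iid = c("dad", "mum", "kid1", "kid2"),
#'                   father = c("0", "0", "dad", "dad"),
#'                   mother = c("0", "0", "mum", "mum"))
#' kinship_from_pedigree(ped)  # full sibs: 0.25
#' @export
kinship_from_pedigree <- function(ped) {
  ped <- as_tibble(ped)
  ped$iid <- as.character(ped$iid)
  ped$father <- as.character(ped$father)
  ped$mother <- as.character(ped$mother)
  # implicit founder rows for referenced-only parents
  refs <- setdiff(unique(c(ped$father, ped$mother)), c("0", ped$iid))
  if (length(refs)) {
    fid_of <- ped$fid[match(refs, ped$father)]
    fid_of[is.na(fid_of)] <- ped$fid[match(refs[is.na(fid_of)], ped$mother)]
    ped <- dplyr::bind_rows(ped, tibble(fid = fid_of, iid = refs,
                                        father = "0", mother = "0"))
  }
  if (anyDuplicated(ped$iid)) abort("duplicate individual IDs in pedigree")
  fams <- split(seq_len(nrow(ped)), ped$fid)
  ii <- jj <- integer(0); vv <- numeric(0)
  for (rows in fams) {
    sub <- ped[rows, ]
    k <- nrow(sub)
    phi <- matrix(0, k, k, dimnames = list(sub$iid, sub$iid))
    fa <- match(sub$father, sub$iid)  # NA = founder side
    mo <- match(sub$mother, sub$iid)
    done <- rep(FALSE, k)
    while (!all(done)) {
      ok_fa <- is.na(fa) | vapply(fa, function(i) !is.na(i) && done[i], logical(1))
      ok_mo <- is.na(mo) | vapply(mo, function(i) !is.na(i) && done[i], logical(1))
      ready <- which(!done & ok_fa & ok_mo)
      if (!length(ready))
        abort(sprintf("pedigree cycle detected in family %s", sub$fid[1]))
      for (j in ready) {
        pf <- fa[j]; pm <- mo[j]
        phi_fm <- if (!is.na(pf) && !is.na(pm)) phi[pf, pm] else 0
        prev <- which(done)
        if (length(prev)) {
          contrib <- 0.5 * ((if (!is.na(pf)) phi[prev, pf] else 0) +
                              (if (!is.na(pm)) phi[prev, pm] else 0))
          phi[prev, j] <- contrib
          phi[j, prev] <- contrib
        }
        phi[j, j] <- 0.5 * (1 + phi_fm)
        done[j] <- TRUE
      }
    }
    nz <- which(phi != 0, arr.ind = TRUE)
    ii <- c(ii, rows[nz[, 1]]); jj <- c(jj, rows[nz[, 2]])
    vv <- c(vv, phi[nz])
  }
  ord <- ped$iid
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(nrow(ped), nrow(ped)),
                            dimnames = list(ord, ord))
  methods::as(Matrix::forceSymmetric(K), "CsparseMatrix")
}

#' Subset a kinship matrix to a set of individuals
#'
#' @param K kinship matrix with dimnames.
#' @param ids individual IDs (must all be present).
#' @return The kinship submatrix in the order of `ids`.
#' @export
kinship_subset <- function(K, ids) {
  if (!all(ids %in% rownames(K))) abort("kinship matrix is missing some individuals")
  K[ids, ids, drop = FALSE]
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Goodness-of-fit chi-square (1 df) of observed genotype counts against
#' the proportions `p^2, 2p(1-p), (1-p)^2` implied by the observed allele
#' frequency `p = (2*n_AA + n_Aa) / (2n)`.  A monomorphic site returns
#' statistic 0 and p-value 1 by convention.  `method = "exact"` gives the
#' conditional exact test (sum of heterozygote-count probabilities no more
#' likely than the observed one).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors recycle together).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return A tibble with columns `statistic` (NA for the exact test) and
#'   `p.value`.
#' @examples
#' hwe_test(30, 40, 30)  # statistic 4
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be non-negative")
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, k); n_Aa <- rep_len(n_Aa, k); n_aa <- rep_len(n_aa, k)
  n <- n_AA + n_Aa + n_aa
  if (any(n == 0)) abort("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  mono <- p == 0 | p == 1
  if (method == "chisq") {
    eAA <- n * p^2; eAa <- 2 * n * p * (1 - p); eaa <- n * (1 - p)^2
    stat <- numeric(k)
    ok <- !mono
    stat[ok] <- (n_AA[ok] - eAA[ok])^2 / eAA[ok] +
      (n_Aa[ok] - eAa[ok])^2 / eAa[ok] + (n_aa[ok] - eaa[ok])^2 / eaa[ok]
    pv <- ifelse(mono, 1, pchisq(stat, df = 1, lower.tail = FALSE))
    tibble(statistic = stat, p.value = pv)
  } else {
    pv <- vapply(seq_len(k), function(i)
      hwe_exact_p(n_AA[i], n_Aa[i], n_aa[i]), numeric(1))
    tibble(statistic = NA_real_, p.value = pv)
  }
}

# conditional exact HWE p-value (two-sided, probability-ordering)
hwe_exact_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  n1 <- 2 * nAA + nAa               # minor-allele count (either orientation)
  if (n1 == 0 || n1 == 2 * n) return(1)
  hets <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  logp <- vapply(hets, function(h) {
    a <- (n1 - h) / 2; b <- (2 * n - n1 - h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(n1 + 1) + lgamma(2 * n - n1 + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Kinship-corrected chi-square association test
#'
#' The dosage-trend statistic with a quasi-likelihood variance correction
#' for relatedness.  With case/control contrast weights `w` (`1/n_case`
#' for cases, `-1/n_ctrl` for controls), allele-frequency difference
#' `D = w'x`, pooled frequency `p = mean(x)/2`, and dosage covariance
#' `Cov(x_i, x_j) = 4 phi_ij p (1-p)` implied by kinship, the statistic is
#' `T = D^2 / (2 p (1-p) w' (2 Phi) w)`, referred to chi-square with 1 df.
#' With `Phi = 0.5 I` (unrelated samples) this is exactly the classical
#' allelic trend test.  Missing dosages are excluded per SNP, with the
#' contrast and the kinship submatrix restricted to observed samples.
#' A monomorphic SNP (pooled frequency 0 or 1) returns statistic 0,
#' p-value 1.
#'
#' @param dosages numeric vector (one SNP) or samples-by-SNPs matrix.
#' @param labels binary vector, 1 = case, 0 = control; both classes must
#'   be present.
#' @param kinship kinship matrix over the samples (dense or sparse), or
#'   `NULL` for unrelated samples (`0.5 * I`).
#' @return A tibble with one row per SNP: `statistic`, `p.value`,
#'   `freq_case`, `freq_ctrl`, `n_used`.
#' @export
corrected_chi2 <- function(dosages, labels, kinship = NULL) {
  X <- if (is.matrix(dosages)) dosages else matrix(dosages, ncol = 1)
  n <- nrow(X)
  if (length(labels) != n) abort("labels do not match number of samples")
  if (!all(labels %in% 0:1)) abort("labels must be 0/1")
  if (!any(labels == 1) || !any(labels == 0))
    abort("both classes must be present")
  S <- if (is.null(kinship)) Matrix::Diagonal(n) else 2 * kinship
  if (nrow(S) != n) abort("kinship matrix does not cover all samples")

  case <- labels == 1
  m <- ncol(X)
  stat <- pv <- fc <- fr <- rep(NA_real_, m)
  nu <- integer(m)
  na_count <- colSums(is.na(X))
  w_full <- ifelse(case, 1 / sum(case), -1 / sum(!case))
  q_full <- as.numeric(Matrix::crossprod(w_full, S %*% w_full))

  cc <- which(na_count == 0)
  if (length(cc)) {
    Xc <- X[, cc, drop = FALSE]
    D <- as.numeric(crossprod(Xc, w_full))
    ph <- colMeans(Xc) / 2
    v <- 2 * ph * (1 - ph) * q_full
    s <- ifelse(ph <= 0 | ph >= 1, 0, D^2 / v)
    stat[cc] <- s
    pv[cc] <- ifelse(ph <= 0 | ph >= 1, 1, pchisq(s, 1, lower.tail = FALSE))
    fc[cc] <- colMeans(Xc[case, , drop = FALSE]) / 2
    fr[cc] <- colMeans(Xc[!case, , drop = FALSE]) / 2
    nu[cc] <- n
  }
  for (j in which(na_count > 0)) {
    obs <- which(!is.na(X[, j]))
    yo <- case[obs]
    nu[j] <- length(obs)
    if (!any(yo) || all(yo)) next  # one class absent at this SNP: NA
    w <- ifelse(yo, 1 / sum(yo), -1 / sum(!yo))
    x <- X[obs, j]
    D <- sum(w * x)
    ph <- mean(x) / 2
    fc[j] <- mean(x[yo]) / 2; fr[j] <- mean(x[!yo]) / 2
    if (ph <= 0 || ph >= 1) { stat[j] <- 0; pv[j] <- 1; next }
    Sv <- as.numeric(S[obs, obs, drop = FALSE] %*% w)
    v <- 2 * ph * (1 - ph) * sum(w * Sv)
    stat[j] <- D^2 / v
    pv[j] <- pchisq(stat[j], 1, lower.tail = FALSE)
  }
  tibble(statistic = stat, p.value = pv, freq_case = fc, freq_ctrl = fr,
         n_used = nu)
}

#' Genome-wide association scan
#'
#' Runs [corrected_chi2()] on every SNP of a dataset, using phenotype
#' labels from the sample records (subjects with missing phenotype are
#' dropped).
#'
#' @param data a [genotype_data] object.
#' @param kinship kinship matrix covering the samples (by `iid` dimnames),
#'   or `NULL` for unrelated samples.
#' @return A tibble of class `missnp_assoc`: `snp`, `chrom`, `pos`,
#'   `statistic`, `p.value`, `freq_case`, `freq_ctrl`, `n_used`.
#' @export
assoc_scan <- function(data, kinship = NULL) {
  y <- phenotype_labels(data)
  keep <- which(!is.na(y))
  if (length(keep) < n_samples(data)) data <- data[keep, ]
  y <- y[keep]
  K <- if (is.null(kinship)) NULL else kinship_subset(kinship, data$samples$iid)
  res <- corrected_chi2(data$dosage, as.numeric(y), K)
  out <- dplyr::bind_cols(tibble(snp = data$snps$id, chrom = data$snps$chrom,
                                 pos = data$snps$pos), res)
  class(out) <- c("missnp_assoc", class(out))
  out
}

#' Pre-select SNPs from an association table
#'
#' @param table an association table ([assoc_scan()] output or any data
#'   frame with `snp`, `chrom`, `pos`, `p.value`).
#' @param mode `"top_k"` (the `k` smallest p-values) or `"p_threshold"`
#'   (all SNPs with `p.value < alpha`, strict).
#' @param k,alpha selection parameters for the respective modes.
#' @return Character vector of SNP IDs in ascending-p order, ties broken
#'   by genomic position (chromosome, then base pair).  SNPs with
#'   undefined p-values are never selected.  If `k` exceeds the table
#'   size, all SNPs are returned with a warning.
#' @export
preselect <- function(table, mode = c("top_k", "p_threshold"),
                      k = 100, alpha = 1e-3) {
  mode <- match.arg(mode)
  if (nrow(table) == 0) abort("association table is empty")
  tab <- dplyr::arrange(dplyr::filter(as_tibble(table), !is.na(.data$p.value)),
                        .data$p.value, .data$chrom, .data$pos)
  if (mode == "top_k") {
    if (k > nrow(tab)) {
      warn(sprintf("k = %d exceeds table size %d; returning all SNPs",
                   k, nrow(tab)))
      k <- nrow(tab)
    }
    tab$snp[seq_len(k)]
  } else if (alpha >= 1) {
    tab$snp                       # degenerate threshold: everything
  } else {
    tab$snp[tab$p.value < alpha]
  }
}
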