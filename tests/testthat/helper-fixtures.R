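# Shared fixture builders. Everything is generated in code at test time.

# small labelled dosage set built by hand
toy_genotype_data <- function(dosage, phenotype = NULL, chrom = NULL,
                              pos = NULL, ids = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(phenotype)) phenotype <- rep(c(2L, 1L), length.out = n)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ids)) ids <- sprintf("rs%03d", seq_len(m))
  genotype_data(
    dosage,
    snps = data.frame(chrom = chrom, id = ids, cm = 0, pos = pos,
                      a1 = "A", a2 = "B"),
    samples = data.frame(fid = sprintf("F%03d", seq_len(n)),
                         iid = sprintf("I%03d", seq_len(n)),
                         father = "0", mother = "0", sex = 0L,
                         phenotype = phenotype))
}

# small cohort with adjustable structure
tiny_cohort <- function(seed = 1, n_cases = 60, n_controls = 60,
                        n_snps = 400, ...) {
  simulate_cohort(sim_config(n_founder_cases = n_cases,
                             n_founder_controls = n_controls,
                             n_snps = n_snps, seed = seed, ...))
}

# an evaluation object with a prescribed confusion pattern
eval_with_confusion <- function(fn, fp, tp, tn) {
  n <- fn + fp + tp + tn
  truth <- c(rep(2L, tp + fn), rep(1L, tn + fp))
  scores <- c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp))
  gd <- toy_genotype_data(matrix(0, n, 1), phenotype = truth)
  evaluate(NULL, gd, scores = setNames(scores, gd$samples$iid))
}

# brute-force corrected chi-square: explicit sums, no linear algebra
brute_force_chi2 <- function(x, y, Phi) {
  obs <- which(!is.na(x))
  x <- x[obs]; y <- y[obs]; Phi <- Phi[obs, obs, drop = FALSE]
  w <- ifelse(y == 1, 1 / sum(y == 1), -1 / sum(y == 0))
  D <- 0
  for (i in seq_along(x)) D <- D + w[i] * x[i]
  p <- sum(x) / (2 * length(x))
  if (p <= 0 || p >= 1) return(0)
  q <- 0
  for (i in seq_along(x)) for (j in seq_along(x))
    q <- q + w[i] * 2 * Phi[i, j] * w[j]
  D^2 / (2 * p * (1 - p) * q)
}

# concordant-label sib-pair cohort for calibration studies: 2*n_fam sibs,
# genotypes by Mendelian transmission from latent HWE parents, both sibs
# share the family's case/control status
sibpair_cohort <- function(n_fam, n_snps, maf_range = c(0.1, 0.5)) {
  q <- runif(n_snps, maf_range[1], maf_range[2])
  gm <- matrix(rbinom(n_fam * n_snps, 2L, rep(q, each = n_fam)), n_fam)
  gf <- matrix(rbinom(n_fam * n_snps, 2L, rep(q, each = n_fam)), n_fam)
  sib <- function() (runif(n_fam * n_snps) < gm / 2) +
    (runif(n_fam * n_snps) < gf / 2)
  d <- rbind(sib(), sib())
  fam <- rep(sprintf("F%04d", seq_len(n_fam)), 2)
  iid <- paste0(fam, c(rep("-a", n_fam), rep("-b", n_fam)))
  pheno <- rep(rep(c(2L, 1L), length.out = n_fam), 2)  # concordant sibs
  ped <- tibble::tibble(
    fid = c(fam, rep(sprintf("F%04d", seq_len(n_fam)), 2)),
    iid = c(iid, paste0(sprintf("F%04d", seq_len(n_fam)), "-P1"),
            paste0(sprintf("F%04d", seq_len(n_fam)), "-P2")),
    father = c(rep(paste0(sprintf("F%04d", seq_len(n_fam)), "-P1"), 2),
               rep("0", 2 * n_fam)),
    mother = c(rep(paste0(sprintf("F%04d", seq_len(n_fam)), "-P2"), 2),
               rep("0", 2 * n_fam)))
  gd <- genotype_data(
    d,
    snps = data.frame(chrom = 1L, id = sprintf("rs%05d", seq_len(n_snps)),
                      cm = 0, pos = seq_len(n_snps) * 1000L,
                      a1 = "A", a2 = "B"),
    samples = data.frame(fid = fam, iid = iid,
                         father = paste0(fam, "-P1"),
                         mother = paste0(fam, "-P2"),
                         sex = 0L, phenotype = pheno))
  list(data = gd, pedigree = ped)
}
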