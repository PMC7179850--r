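#' Assemble a genotype dataset
#'
#' The central container: a samples-by-SNPs minor-allele dosage matrix plus
#' the SNP map and the sample records that PLINK files carry.  Dosages are
#' 0/1/2 copies of `allele1` (the minor allele by convention) with `NA` for
#' missing calls — missingness is always out-of-band, never coded 0, so
#' monomorphism detection is unaffected by missing data.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; values in
#'   `{0, 1, 2, NA}`.
#' @param snps data frame with one row per SNP: `chrom` (integer 1-26,
#'   PLINK codes: 23=X, 24=Y, 25=XY, 26=MT), `id`, `cm` genetic distance,
#'   `pos` base-pair position, `a1`, `a2` allele labels.
#' @param samples data frame with one row per subject: `fid`, `iid`,
#'   `father`, `mother` (`"0"` = founder), `sex` (0/1/2), `phenotype`
#'   (1 = control, 2 = case, 0 or -9 = missing).
#'
#' @return An object of class `genotype_data`.  `snps` and `samples` are
#'   stored as tibbles; `dosage` keeps sample IDs as rownames and SNP IDs as
#'   colnames.
#' @examples
#' gd <- genotype_data(
#'   matrix(c(0, 1, 2, 1), 2, 2),
#'   snps = data.frame(chrom = 1L, id = c("rs1", "rs2"), cm = 0,
#'                     pos = c(100L, 200L), a1 = "A", a2 = "B"),
#'   samples = data.frame(fid = c("F1", "F2"), iid = c("I1", "I2"),
#'                        father = "0", mother = "0", sex = 0L,
#'                        phenotype = c(2L, 1L))
#' )
#' n_samples(gd)
#' @export
genotype_data <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  snps <- as_tibble(snps)
  samples <- as_tibble(samples)
  samples$fid <- as.character(samples$fid)
  samples$iid <- as.character(samples$iid)
  if (!all(c("chrom", "id", "cm", "pos", "a1", "a2") %in% names(snps)))
    abort("`snps` needs columns chrom, id, cm, pos, a1, a2")
  if (!all(c("fid", "iid", "father", "mother", "sex", "phenotype") %in% names(samples)))
    abort("`samples` needs columns fid, iid, father, mother, sex, phenotype")
  if (nrow(samples) != nrow(dosage) || nrow(snps) != ncol(dosage))
    abort("dosage dimensions do not match `samples`/`snps`")
  if (length(dosage)) {
    rng <- suppressWarnings(range(dosage, na.rm = TRUE))
    if (is.finite(rng[1]) &&
        (rng[1] < 0 || rng[2] > 2 || any(dosage %% 1 > 0, na.rm = TRUE)))
      abort("non-missing dosages must be 0, 1 or 2")
  }
  if (anyDuplicated(snps$id))
    abort("SNP identifiers must be unique")
  if (anyDuplicated(samples$iid))
    abort("individual IDs must be globally unique")
  new_genotype_data(dosage, snps, samples)
}

# internal fast path: structural assembly of already-validated pieces
new_genotype_data <- function(dosage, snps, samples) {
  rownames(dosage) <- samples$iid
  colnames(dosage) <- snps$id
  structure(list(dosage = dosage, snps = snps, samples = samples),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  ph <- x$samples$phenotype
  cat(sprintf(
    "<genotype_data> %d samples x %d SNPs (%d cases, %d controls, %d unknown)\n",
    nrow(x$dosage), ncol(x$dosage),
    sum(ph == 2), sum(ph == 1), sum(!ph %in% c(1, 2))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.3g%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / SNPs in a genotype dataset
#' @param x a `genotype_data` object.
#' @return An integer count.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(x) ncol(x$dosage)

#' Subset a genotype dataset
#'
#' `i` selects samples (logical, integer, or individual IDs), `j` selects
#' SNPs (logical, integer, or SNP IDs).  Order is preserved as given.
#'
#' @param x a `genotype_data` object.
#' @param i,j sample / SNP selectors.
#' @param ... unused.
#' @return A `genotype_data` with the selected rows/columns.
#' @export
`[.genotype_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$samples$iid)
  if (is.character(j)) j <- match(j, x$snps$id)
  if (anyNA(i)) abort("unknown sample ID in subset")
  if (anyNA(j)) abort("unknown SNP ID in subset")
  new_genotype_data(x$dosage[i, j, drop = FALSE], x$snps[j, ], x$samples[i, ])
}

#' Case/control indicators
#'
#' @param x a `genotype_data` object.
#' @return `phenotype_labels()` returns a 0/1 vector (1 = case, `NA` for
#'   missing phenotype) named by individual ID.
#' @export
phenotype_labels <- function(x) {
  ph <- x$samples$phenotype
  y <- ifelse(ph == 2, 1, ifelse(ph == 1, 0, NA_real_))
  setNames(y, x$samples$iid)
}

#' Extract the pedigree table of a cohort
#'
#' @param x a `genotype_data` object.
#' @return A tibble with columns `fid`, `iid`, `father`, `mother`
#'   (`"0"` marks a founder).
#' @export
pedigree_of <- function(x) {
  dplyr::select(x$samples, "fid", "iid", "father", "mother")
}
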