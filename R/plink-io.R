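# PLINK 1.9 text/binary codec. No installed package reads this format, so
# the 2-bit .bed layout is implemented directly against the format
# definition:
# SNP-major, 3-byte header 0x6c 0x1b 0x01, each SNP packed 4 samples/byte
# (low bits first), codes 0b00 = 2 copies of allele1, 0b01 = missing,
# 0b10 = het, 0b11 = 0 copies; final byte per SNP zero-padded.

.bed_magic <- as.raw(c(0x6c, 0x1b))
.bed_mode_snp_major <- as.raw(0x01)

# 256 x 4 lookup: byte value -> dosages of the 4 packed samples
.bed_decode_tab <- local({
  code2dos <- c(2, NA, 1, 0)  # 2-bit values 0,1,2,3
  b <- 0:255
  cbind(code2dos[b %% 4 + 1], code2dos[(b %/% 4) %% 4 + 1],
        code2dos[(b %/% 16) %% 4 + 1], code2dos[(b %/% 64) %% 4 + 1])
})

#' Read PLINK genotype files
#'
#' Reads either the binary dialect (`.bed`/`.bim`/`.fam`, SNP-major) or the
#' text dialect (`.ped`/`.map`), auto-detected from the files present unless
#' forced with `text`.  Binary dosages count allele1 exactly as stored in
#' the `.bim` (PLINK's A1, minor by convention).  Text files carry no allele
#' order, so dosages count the rarer observed allele; an exact frequency tie
#' is broken toward the alphabetically smaller allele, and a monomorphic
#' SNP is coded all-0 dosage with its single allele as allele2.
#'
#' @param prefix path prefix (without extension).
#' @param text `NA` (auto), `TRUE` (force `.ped/.map`) or `FALSE` (force
#'   binary).
#' @return A [genotype_data] object.  SNP and sample order follow the files.
#' @seealso [write_plink()]
#' @export
read_plink <- function(prefix, text = NA) {
  if (is.na(text)) {
    if (file.exists(paste0(prefix, ".bed"))) text <- FALSE
    else if (file.exists(paste0(prefix, ".ped"))) text <- TRUE
    else abort(sprintf("neither %s.bed nor %s.ped exists", prefix, prefix))
  }
  if (text) read_plink_text(prefix) else read_plink_bed(prefix)
}

read_plink_bed <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  fam <- read_ws_table(paste0(prefix, ".fam"),
                       c("fid", "iid", "father", "mother", "sex", "phenotype"))
  bim <- read_ws_table(paste0(prefix, ".bim"),
                       c("chrom", "id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:2], .bed_magic))
    abort(sprintf("%s: bad magic bytes, not a PLINK .bed file", bed_path))
  if (raw[3] != .bed_mode_snp_major)
    abort(sprintf("%s: mode byte 0x%02x unsupported; only SNP-major (0x01) is",
                  bed_path, as.integer(raw[3])))
  bpn <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpn * m)
    abort(sprintf("%s: truncated or oversized body (%d bytes, expected %d)",
                  bed_path, length(body), bpn * m))
  dos <- matrix(0, nrow = n, ncol = m)
  if (m > 0 && n > 0) {
    vals <- .bed_decode_tab[as.integer(body) + 1L, , drop = FALSE]
    arr <- matrix(as.vector(t(vals)), nrow = 4L * bpn)
    dos <- arr[seq_len(n), , drop = FALSE]
  }
  genotype_data(dos, snps = bim, samples = fam)
}

read_plink_text <- function(prefix) {
  map <- read_ws_table(paste0(prefix, ".map"), c("chrom", "id", "cm", "pos"))
  ped <- read_ws_table(paste0(prefix, ".ped"), NULL, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    abort(sprintf(".ped has %d columns, expected %d for %d SNPs",
                  ncol(ped), 6 + 2 * m, m))
  samples <- tibble(fid = ped[[1]], iid = ped[[2]], father = ped[[3]],
                    mother = ped[[4]], sex = as.integer(ped[[5]]),
                    phenotype = as.integer(ped[[6]]))
  n <- nrow(ped)
  dos <- matrix(NA_real_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- ped[[6 + 2 * j - 1]]; x2 <- ped[[6 + 2 * j]]
    obs <- x1 != "0"
    if (any(obs != (x2 != "0")))
      abort(sprintf("SNP %s: half-missing genotype in .ped", map$id[j]))
    alleles <- sort(unique(c(x1[obs], x2[obs])))
    if (length(alleles) > 2)
      abort(sprintf("SNP %s: more than two alleles in .ped", map$id[j]))
    if (length(alleles) == 0) {            # fully missing SNP
      a1[j] <- "0"; a2[j] <- "0"
      next
    }
    if (length(alleles) == 1) {            # monomorphic: single allele = major
      a1[j] <- "0"; a2[j] <- alleles
      dos[obs, j] <- 0
      next
    }
    cnt1 <- sum(x1[obs] == alleles[1]) + sum(x2[obs] == alleles[1])
    # minor = rarer allele; exact tie -> alphabetically first (alleles[1])
    minor <- if (cnt1 <= length(x1[obs]) + length(x2[obs]) - cnt1)
      alleles[1] else alleles[2]
    a1[j] <- minor; a2[j] <- setdiff(alleles, minor)
    dos[obs, j] <- (x1[obs] == minor) + (x2[obs] == minor)
  }
  snps <- tibble(chrom = as.integer(map$chrom), id = as.character(map$id),
                 cm = as.numeric(map$cm), pos = as.integer(map$pos),
                 a1 = a1, a2 = a2)
  genotype_data(dos, snps = snps, samples = samples)
}

#' Write PLINK genotype files
#'
#' Writes the dataset as stored — allele1 dosages, SNP and sample order
#' unchanged.  Binary mode produces bit-exact PLINK 1.9 (SNP-major, final
#' byte per SNP zero-padded); text mode writes whitespace-delimited
#' `.ped`/`.map` with missing genotypes as `0 0`.
#'
#' @param x a [genotype_data] object.
#' @param prefix output path prefix.
#' @param text write `.ped`/`.map` instead of `.bed`/`.bim`/`.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(x, prefix, text = FALSE) {
  stopifnot(inherits(x, "genotype_data"))
  if (text) write_plink_text(x, prefix) else write_plink_bed(x, prefix)
  invisible(prefix)
}

write_plink_bed <- function(x, prefix) {
  n <- n_samples(x); m <- n_snps(x)
  fam <- x$samples[, c("fid", "iid", "father", "mother", "sex", "phenotype")]
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  write.table(x$snps[, c("chrom", "id", "cm", "pos", "a1", "a2")],
              paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  bpn <- ceiling(n / 4)
  bytes <- raw(0)
  if (m > 0 && n > 0) {
    dos2code <- function(d) {
      code <- integer(length(d))          # dosage 2 -> 0b00
      code[is.na(d)] <- 1L                # missing  -> 0b01
      code[!is.na(d) & d == 1] <- 2L      # het      -> 0b10
      code[!is.na(d) & d == 0] <- 3L      # dosage 0 -> 0b11
      code
    }
    codes <- matrix(0L, 4L * bpn, m)
    codes[seq_len(n), ] <- dos2code(x$dosage)
    q <- matrix(codes, nrow = 4L)
    bytes <- as.raw(q[1, ] + 4L * q[2, ] + 16L * q[3, ] + 64L * q[4, ])
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(.bed_magic, .bed_mode_snp_major, bytes), con)
}

write_plink_text <- function(x, prefix) {
  write.table(x$snps[, c("chrom", "id", "cm", "pos")],
              paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  n <- n_samples(x); m <- n_snps(x)
  g1 <- g2 <- matrix("0", n, m)
  if (m > 0 && n > 0) {
    a1 <- matrix(x$snps$a1, n, m, byrow = TRUE)
    a2 <- matrix(x$snps$a2, n, m, byrow = TRUE)
    d <- x$dosage
    ok <- !is.na(d)
    g1[ok] <- ifelse(d[ok] >= 1, a1[ok], a2[ok])
    g2[ok] <- ifelse(d[ok] == 2, a1[ok], a2[ok])
  }
  geno <- matrix("", n, 2 * m)
  if (m > 0) {
    geno[, seq(1, 2 * m, by = 2)] <- g1
    geno[, seq(2, 2 * m, by = 2)] <- g2
  }
  out <- cbind(as.matrix(x$samples[, c("fid", "iid", "father", "mother",
                                       "sex", "phenotype")]), geno)
  write.table(out, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
}

#' Read / write a pedigree table
#'
#' Tab- or space-delimited, four columns: family ID, individual ID, father
#' ID, mother ID (`0` = founder).  A header line is detected and skipped.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a tibble with columns `fid`, `iid`,
#'   `father`, `mother`.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("fid|family", first, ignore.case = TRUE)
  ped <- read_ws_table(path, c("fid", "iid", "father", "mother"),
                       colClasses = "character", skip = as.integer(has_header))
  as_tibble(ped)
}

#' @rdname read_pedigree
#' @param ped pedigree data frame (`fid`, `iid`, `father`, `mother`).
#' @export
write_pedigree <- function(ped, path) {
  write.table(ped[, c("fid", "iid", "father", "mother")], path,
              quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

# whitespace-tolerant table reader (tabs and/or spaces)
read_ws_table <- function(path, col_names, ...) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(col_names)))
    names(out) <- col_names
    return(tibble::as_tibble(out))
  }
  out <- read.table(path, header = FALSE, stringsAsFactors = FALSE, ...)
  if (!is.null(col_names)) {
    if (ncol(out) != length(col_names))
      abort(sprintf("%s: expected %d columns, found %d",
                    path, length(col_names), ncol(out)))
    names(out) <- col_names
  }
  tibble::as_tibble(out)
}
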