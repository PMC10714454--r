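# Readers and writers for the plain-text formats used across the
# pipeline: count matrices (TSV / MatrixMarket), dosage matrices (TSV and
# PLINK bed/bim/fam), expression and GRM tables, and metadata/phenotypes.

#' Read a gene x sample count table from TSV
#'
#' @param path TSV with gene ids in the first column and samples in
#'   header.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  count_matrix(as.matrix(df))
}

#' Write counts to TSV
#' @param cm a [count_matrix()].
#' @param path output path.
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read counts from MatrixMarket (.mtx with row/column sidecar files)
#'
#' @param mtx path to the .mtx file; `<path>.rownames` and
#'   `<path>.colnames` hold the gene and sample ids, one per line.
#' @return a [count_matrix()].
#' @export
read_counts_mtx <- function(mtx) {
  M <- as.matrix(Matrix::readMM(mtx))
  rn <- readLines(paste0(mtx, ".rownames"))
  cn <- readLines(paste0(mtx, ".colnames"))
  dimnames(M) <- list(rn, cn)
  count_matrix(M)
}

#' Write counts to MatrixMarket with id sidecars
#' @inheritParams write_counts_tsv
#' @export
write_counts_mtx <- function(cm, path) {
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
  writeLines(rownames(cm$counts), paste0(path, ".rownames"))
  writeLines(colnames(cm$counts), paste0(path, ".colnames"))
  invisible(path)
}

#' Read a dosage matrix from TSV
#'
#' @param path TSV with animal ids in the first column, SNPs in header;
#'   entries 0/1/2 or NA.
#' @return numeric matrix animals x SNPs.
#' @export
read_dosages_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' Write a dosage matrix to TSV
#' @param dosages matrix animals x SNPs.
#' @param path output path.
#' @export
write_dosages_tsv <- function(dosages, path) {
  df <- data.frame(animal_id = rownames(dosages), dosages,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# -- PLINK bed/bim/fam ----------------------------------------------------
# Minimal SNP-major bed support (magic 0x6c 0x1b 0x01; two bits per
# genotype: 00 hom A1, 01 missing, 10 het, 11 hom A2).  Dosage counts the
# A2 allele.

#' Write genotypes as PLINK .bed/.bim/.fam
#'
#' @param dosages matrix animals x SNPs (0/1/2/NA), dimnames required.
#' @param prefix output path prefix (writes prefix.bed/.bim/.fam).
#' @param chrom,pos optional per-SNP chromosome and position for the .bim.
#' @export
write_plink <- function(dosages, prefix, chrom = NULL, pos = NULL) {
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep(1, m)
  if (is.null(pos)) pos <- seq_len(m)
  fam <- data.frame(fid = rownames(dosages), iid = rownames(dosages),
                    pat = 0, mat = 0, sex = 0, phe = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = chrom, id = colnames(dosages), cm = 0,
                    pos = pos, a1 = "A", a2 = "B")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  code <- matrix(0L, n, m)                      # 0 -> 00 (hom A1)
  code[is.na(dosages)] <- 1L                    # missing -> 01
  code[!is.na(dosages) & dosages == 1] <- 2L    # het -> 10
  code[!is.na(dosages) & dosages == 2] <- 3L    # hom A2 -> 11
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(m)) {
    v <- c(code[, j], rep(0L, pad))
    q <- matrix(v, nrow = 4)
    byte <- q[1, ] + q[2, ] * 4L + q[3, ] * 16L + q[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read genotypes from PLINK .bed/.bim/.fam
#'
#' @param prefix path prefix of the fileset.
#' @return list: `dosages` (animals x SNPs, A2-allele counts), `bim`,
#'   `fam` data frames.
#' @export
read_plink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"),
                    col.names = c("fid", "iid", "pat", "mat", "sex", "phe"))
  bim <- read.table(paste0(prefix, ".bim"),
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + m * ceiling(n / 4))
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK bed file")
  }
  body <- as.integer(raw[-(1:3)])
  bytes_per_snp <- ceiling(n / 4)
  lut <- c(0, NA, 1, 2)  # 00, 01, 10, 11 -> dosage
  D <- matrix(NA_real_, n, m, dimnames = list(fam$iid, bim$id))
  for (j in seq_len(m)) {
    b <- body[(j - 1) * bytes_per_snp + seq_len(bytes_per_snp)]
    two_bits <- c(rbind(b %% 4, (b %/% 4) %% 4,
                        (b %/% 16) %% 4, (b %/% 64) %% 4))
    D[, j] <- lut[two_bits[seq_len(n)] + 1]
  }
  list(dosages = D, bim = bim, fam = fam)
}

#' Write a GRM with id sidecar
#' @param G symmetric matrix with animal ids as dimnames.
#' @param path output TSV path.
#' @export
write_grm_tsv <- function(G, path) {
  df <- data.frame(animal_id = rownames(G), G, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GRM written by [write_grm_tsv()]
#' @param path TSV path.
#' @return symmetric matrix.
#' @export
read_grm_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' Write an expression matrix and its normalization factors
#' @param em an `expr_matrix` from [normalize_log2()].
#' @param path output TSV (values); factors go to `<path>.factors`.
#' @export
write_expr_tsv <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fdf <- data.frame(sample_id = names(em$factors), factor = em$factors,
                    lib_size = em$lib_size)
  write.table(fdf, paste0(path, ".factors"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
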