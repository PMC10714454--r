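# SNP quality control and company-blocked VanRaden genomic relationships.
#
# The relationship matrix is built separately within each company from
# within-company allele frequencies (method 1: Z Z' / (2 sum p(1-p)) with
# Z the 2p-centered dosages), then assembled block-diagonally so that
# relationships between companies are exactly zero.  This targets pooled
# within-company variance components, the relevant quantity for closed
# breeding populations.

#' Construct a genotype set
#'
#' @param dosages numeric matrix, animals x SNPs, entries 0/1/2 or `NA`.
#' @param company character/factor vector of per-animal company labels.
#' @param qc_group optional per-animal grouping used for marker QC (the
#'   intersection rule applies across groups); defaults to `company`.
#' @return object of class `genotype_set`.
#' @export
genotype_set <- function(dosages, company, qc_group = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("animal", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  }
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  company <- as.character(company)
  if (length(company) != nrow(dosages)) {
    stop("one company label per animal is required")
  }
  if (is.null(qc_group)) qc_group <- company
  qc_group <- as.character(qc_group)
  if (length(qc_group) != nrow(dosages)) {
    stop("one qc_group label per animal is required")
  }
  structure(list(dosages = dosages, company = company, qc_group = qc_group),
            class = "genotype_set")
}

#' Marker and individual quality control
#'
#' Keeps SNPs whose minor allele frequency and call rate exceed the
#' thresholds (strict inequalities) in *every* QC group, then drops animals
#' whose individual call rate over the surviving SNPs does not exceed
#' `ind_call_min`.
#'
#' @param gs a [genotype_set()].
#' @param maf_min,snp_call_min,ind_call_min thresholds; SNPs/animals must
#'   be strictly above them.
#' @return list with the filtered `genotype_set` and a `report` of removal
#'   counts by reason.
#' @export
snp_qc <- function(gs, maf_min = 0.05, snp_call_min = 0.90,
                   ind_call_min = 0.90) {
  stopifnot(inherits(gs, "genotype_set"))
  D <- gs$dosages
  groups <- unique(gs$qc_group)
  keep_snp <- rep(TRUE, ncol(D))
  fail_maf <- rep(FALSE, ncol(D))
  fail_call <- rep(FALSE, ncol(D))
  for (g in groups) {
    Dg <- D[gs$qc_group == g, , drop = FALSE]
    call_rate <- colMeans(!is.na(Dg))
    p <- colMeans(Dg, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    maf[is.nan(maf)] <- 0
    fail_maf <- fail_maf | !(maf > maf_min)
    fail_call <- fail_call | !(call_rate > snp_call_min)
  }
  keep_snp <- !(fail_maf | fail_call)
  if (!any(keep_snp)) stop("no SNPs survive quality control")
  D2 <- D[, keep_snp, drop = FALSE]
  ind_call <- rowMeans(!is.na(D2))
  keep_ind <- ind_call > ind_call_min
  report <- list(
    n_snp_in = ncol(D), n_snp_out = sum(keep_snp),
    snp_fail_maf = sum(fail_maf), snp_fail_call = sum(fail_call & !fail_maf),
    n_ind_in = nrow(D), n_ind_out = sum(keep_ind),
    ind_fail_call = sum(!keep_ind)
  )
  out <- genotype_set(D2[keep_ind, , drop = FALSE],
                      gs$company[keep_ind], gs$qc_group[keep_ind])
  list(genotypes = out, report = report)
}

#' VanRaden (method 1) relationship block for one company
#'
#' Centers dosages by twice the within-company allele frequency and scales
#' the cross-product by \eqn{2\sum_j p_j(1-p_j)} over SNPs polymorphic in
#' the company.  Missing dosages are mean-imputed to \eqn{2p}.
#'
#' @param gs a [genotype_set()].
#' @param company company label selecting the animals.
#' @return symmetric relationship matrix for the company's animals, with
#'   the scaling sum attached as attribute `sum2pq`.
#' @export
vanraden_grm <- function(gs, company) {
  stopifnot(inherits(gs, "genotype_set"))
  idx <- which(gs$company == company)
  if (length(idx) == 0) stop("unknown company: ", company)
  D <- gs$dosages[idx, , drop = FALSE]
  p <- colMeans(D, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.nan(p)
  if (!any(poly)) stop("all SNPs monomorphic within company ", company)
  D <- D[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(D, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation: dosage 2p => centered value 0
  denom <- 2 * sum(p * (1 - p))
  Gb <- tcrossprod(Z) / denom
  dimnames(Gb) <- list(rownames(gs$dosages)[idx], rownames(gs$dosages)[idx])
  attr(Gb, "sum2pq") <- denom
  Gb
}

#' Assemble a block-diagonal GRM across companies
#'
#' @param blocks named list of per-company relationship blocks (square,
#'   with animal ids as dimnames).
#' @param animal_order character vector giving the output row/column order;
#'   must be exactly the union of the blocks' animals.
#' @return full GRM with cross-company entries exactly zero.
#' @export
combine_block_grm <- function(blocks, animal_order = NULL) {
  ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
  if (anyDuplicated(ids)) stop("blocks overlap: duplicated animal ids")
  if (is.null(animal_order)) animal_order <- ids
  if (!setequal(animal_order, ids) || length(animal_order) != length(ids)) {
    stop("animal_order must be a permutation of the blocks' animals")
  }
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(animal_order, animal_order))
  for (b in blocks) {
    G[rownames(b), colnames(b)] <- b
  }
  G
}

#' Full pipeline: QC then blocked GRM
#'
#' @param gs a [genotype_set()].
#' @param qc apply [snp_qc()] first?
#' @param ... passed to [snp_qc()].
#' @return the combined GRM over all animals, in the input animal order.
#' @export
build_grm <- function(gs, qc = TRUE, ...) {
  if (qc) gs <- snp_qc(gs, ...)$genotypes
  blocks <- lapply(unique(gs$company), function(cc) vanraden_grm(gs, cc))
  combine_block_grm(blocks, rownames(gs$dosages))
}

#' Diagonal ridge for near-singular relationship matrices
#'
#' Adds `eps` to the diagonal when the smallest eigenvalue falls below
#' `tol`, restoring positive definiteness ahead of REML.
#'
#' @param G symmetric matrix.
#' @param eps ridge size.
#' @param tol eigenvalue threshold triggering the ridge.
#' @return `G`, possibly ridged, with attribute `ridged` set accordingly.
#' @export
grm_ridge <- function(G, eps = 1e-6, tol = 1e-8) {
  lam <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  ridged <- lam < tol
  if (ridged) diag(G) <- diag(G) + eps
  attr(G, "ridged") <- ridged
  G
}
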