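# Count filtering and normalization for 3' mRNA-seq gene counts.
#
# Filtering removes globin genes (which dominate whole-blood libraries even
# with globin blocking) and genes with zero counts in more than a set
# fraction of samples.  Between-sample normalization uses TMM factors; the
# expression matrix used downstream is log2(normalized count + 1), with
# counts rescaled to the geometric-mean effective library size so values
# stay on a count-like scale.

#' Construct a count matrix container
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @param gene_ids,sample_ids optional ids; taken from dimnames otherwise.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")
  structure(list(counts = counts), class = "count_matrix")
}

#' Remove excluded genes and genes with excess zero counts
#'
#' A gene is removed when listed in `exclude_ids`, or when its fraction of
#' zero-count samples is strictly greater than `zero_fraction_max` (so a
#' gene with zeros in exactly that fraction of samples is retained).
#'
#' @param cm a [count_matrix()].
#' @param exclude_ids gene ids to drop regardless of counts (e.g. the
#'   globin genes HBA, HBB); ids not present are warned about, not fatal.
#' @param zero_fraction_max maximum tolerated zero-count fraction.
#' @return list with the filtered `count_matrix` and a `report` data frame
#'   (gene, reason) of removals.
#' @export
filter_genes <- function(cm, exclude_ids = character(),
                         zero_fraction_max = 0.80) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  missing_ids <- setdiff(exclude_ids, rownames(counts))
  if (length(missing_ids) > 0) {
    warning("exclude ids not found: ", paste(missing_ids, collapse = ", "))
  }
  excluded <- rownames(counts) %in% exclude_ids
  zero_frac <- rowMeans(counts == 0)
  too_zero <- zero_frac > zero_fraction_max
  drop <- excluded | too_zero
  if (all(drop)) stop("all genes removed by filtering")
  reason <- ifelse(excluded, "excluded",
                   ifelse(too_zero, "zero_fraction", NA))
  report <- data.frame(gene = rownames(counts)[drop],
                       reason = reason[drop],
                       zero_fraction = zero_frac[drop],
                       stringsAsFactors = FALSE)
  list(counts = count_matrix(counts[!drop, , drop = FALSE]),
       report = report)
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors with the published defaults (30%
#' two-sided trim on M, 5% on A, precision weighting, reference chosen by
#' the upper-quartile rule), rescaled so their geometric mean is 1.
#'
#' @param cm a [count_matrix()].
#' @param ref reference sample id, or `NULL` for automatic choice.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(cm, ref = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  if (any(colSums(counts) == 0)) stop("zero-library sample(s) present")
  refCol <- if (is.null(ref)) NULL else match(ref, colnames(counts))
  if (!is.null(ref) && is.na(refCol)) stop("unknown reference sample: ", ref)
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = refCol)
  names(f) <- colnames(counts)
  f
}

#' Normalize counts and transform to log2 scale
#'
#' Each sample's counts are rescaled to a common target library size
#' (default: the geometric mean of the effective library sizes, i.e.
#' library size times TMM factor), then transformed as
#' log2(normalized count + 1).  Passing an explicit `target_lib` keeps the
#' scaling reference fixed across datasets, which makes the per-sample
#' normalization exactly invariant to rescaling any one sample's depth;
#' the automatic geometric-mean target is itself a function of all
#' libraries and is recomputed per dataset.
#'
#' @param cm a [count_matrix()].
#' @param factors per-sample normalization factors from [tmm_factors()].
#' @param target_lib target effective library size, or `NULL` for the
#'   geometric mean of the effective library sizes.
#' @return object of class `expr_matrix`: list with `values` (genes x
#'   samples, log2 scale), `factors`, `lib_size`, `target_lib`, and a
#'   `provenance` character vector describing the scaling convention and
#'   filters.
#' @export
normalize_log2 <- function(cm, factors, target_lib = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  factors <- factors[colnames(counts)]
  if (anyNA(factors)) stop("factors do not cover all samples")
  if (any(factors <= 0)) stop("normalization factors must be positive")
  lib <- colSums(counts)
  eff <- lib * factors
  target <- if (is.null(target_lib)) exp(mean(log(eff))) else target_lib
  if (target <= 0) stop("target library size must be positive")
  norm <- sweep(counts, 2, target / eff, `*`)
  values <- log2(norm + 1)
  structure(list(values = values, factors = factors, lib_size = lib,
                 target_lib = target,
                 provenance = c(
                   sprintf("scaling: common effective library size %s",
                           if (is.null(target_lib)) {
                             "(geometric mean of effective library sizes)"
                           } else format(target_lib)),
                   "transform: log2(normalized count + 1)")),
            class = "expr_matrix")
}

#' One-step filter + TMM + log2 normalization
#'
#' @inheritParams filter_genes
#' @inheritParams tmm_factors
#' @return an `expr_matrix` with the filter report attached as attribute
#'   `filter_report`.
#' @export
normalize_counts <- function(cm, exclude_ids = character(),
                             zero_fraction_max = 0.80, ref = NULL) {
  fl <- filter_genes(cm, exclude_ids, zero_fraction_max)
  f <- tmm_factors(fl$counts, ref = ref)
  em <- normalize_log2(fl$counts, f)
  attr(em, "filter_report") <- fl$report
  em
}
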