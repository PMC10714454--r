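# Single-trait animal model for gene expression:
#
#   y = Batch + Enrich + Age + RIN + (log2 WBC proportions) + Pen + Litter
#       + u + e,
#   Pen ~ N(0, I sP2), Litter ~ N(0, I sL2), u ~ N(0, G sA2), e ~ N(0, I se2)
#
# The WI model includes the six white-blood-cell composition covariates,
# the WO model omits them.  Heritability and the litter-effect proportion
# are reported against the total of all four components; significance is a
# boundary-corrected likelihood-ratio test against the model without the
# corresponding random term.

WBC_TYPES <- c("lymphocyte", "neutrophil", "monocyte",
               "basophil", "eosinophil", "luc")

#' Log2 transform for WBC proportions
#'
#' A small offset keeps zero proportions finite; the transform is monotone
#' and the offset only matters for rare zero counts of a cell type.
#' @param p proportions in \[0, 1\].
#' @param offset additive offset before log2.
#' @return log2(p + offset)
#' @export
log2_wbc <- function(p, offset = 0.001) log2(p + offset)

#' Build the fixed design and random-term incidence structures
#'
#' @param metadata data frame with one row per animal: `batch`, `pen`,
#'   `litter`, optionally `enrich`, `age`, `rin`, and (for the WI model)
#'   WBC proportion columns `wbc_<type>` for the six cell types.
#' @param wbc include the six log2 WBC composition covariates (WI model)?
#' @param y optional response vector; rows with missing covariates or
#'   response are dropped (with a message) and the reduced response is
#'   returned alongside.
#' @return list with `X` (fixed design, full column rank), `Z_pen`,
#'   `Z_litter` (incidence matrices), `keep` (logical row filter applied),
#'   and `y` (if supplied).
#' @export
build_design <- function(metadata, wbc = FALSE, y = NULL) {
  md <- as.data.frame(metadata)
  need <- c("batch", "pen", "litter")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  covs <- intersect(c("age", "rin"), names(md))
  wbc_cols <- paste0("wbc_", WBC_TYPES)
  if (wbc) {
    lack <- setdiff(wbc_cols, names(md))
    if (length(lack) > 0) stop("WI model needs WBC columns: ", paste(lack, collapse = ", "))
  }
  used <- c(need, intersect("enrich", names(md)), covs, if (wbc) wbc_cols)
  keep <- complete.cases(md[used])
  if (!is.null(y)) keep <- keep & !is.na(y)
  if (sum(keep) < length(keep)) {
    message(sum(!keep), " animal(s) dropped for missing covariates/response")
  }
  md <- md[keep, , drop = FALSE]

  md$batch <- factor(md$batch)
  # pen coded within batch
  pen_f <- factor(paste(md$batch, md$pen, sep = ":"))
  litter_f <- factor(md$litter)

  terms <- c("batch")
  if ("enrich" %in% names(md) && length(unique(md$enrich)) > 1) {
    md$enrich <- factor(md$enrich)
    terms <- c(terms, "enrich")
  }
  terms <- c(terms, covs)
  if (wbc) {
    for (cl in wbc_cols) md[[paste0("l2_", cl)]] <- log2_wbc(md[[cl]])
    terms <- c(terms, paste0("l2_", wbc_cols))
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- model.matrix(fml, data = md)
  # drop collinear columns
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[-qx$pivot[seq_len(qx$rank)]]
    warning("dropping collinear fixed-effect columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  Zp <- model.matrix(~ 0 + pen_f)
  Zl <- model.matrix(~ 0 + litter_f)
  list(X = X, Z_pen = Zp, Z_litter = Zl, keep = keep,
       y = if (!is.null(y)) as.numeric(y[keep]) else NULL)
}

#' Boundary-corrected likelihood-ratio p-value
#'
#' For a variance component tested on its lower boundary the LRT null
#' distribution is the 50:50 mixture of a point mass at zero and chi-square
#' with 1 df; for an unconstrained (covariance) parameter it is plain
#' chi-square 1.
#'
#' @param logL_full,logL_reduced restricted log-likelihoods.
#' @param boundary is the tested parameter on the boundary of its space?
#' @param tol tolerated negative likelihood difference (optimizer noise).
#' @return p-value.
#' @export
lrt_pvalue <- function(logL_full, logL_reduced, boundary = TRUE, tol = 1e-4) {
  lr <- 2 * (logL_full - logL_reduced)
  if (lr < -tol) stop("logL(full) < logL(reduced): optimizer failure")
  lr <- max(lr, 0)
  if (boundary) {
    if (lr == 0) 1 else 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  } else {
    pchisq(lr, df = 1, lower.tail = FALSE)
  }
}

#' Fit the animal model for one response by AI-REML
#'
#' @param y response vector (one gene's expression).
#' @param X fixed design matrix.
#' @param G genomic relationship matrix aligned to `y`.
#' @param Z_pen,Z_litter incidence matrices for pen and litter random
#'   effects, or `NULL` to omit the term.
#' @param lrt compute boundary-mixture likelihood-ratio tests for the
#'   additive and litter components (requires refits)?
#' @param include_pen_in_total include the pen variance in the
#'   denominator of h2 and c2 (default) or exclude it.
#' @param ... passed to [aireml()].
#' @return object of class `vcfit`: variance components, `h2`, `c2`, their
#'   delta-method standard errors, log-likelihood, LRT p-values (when
#'   requested), convergence and boundary information.
#' @export
reml_fit <- function(y, X, G, Z_pen = NULL, Z_litter = NULL,
                     lrt = TRUE, include_pen_in_total = TRUE, ...) {
  n <- length(y)
  Klist <- list(additive = G)
  if (!is.null(Z_pen)) Klist$pen <- tcrossprod(Z_pen)
  if (!is.null(Z_litter)) Klist$litter <- tcrossprod(Z_litter)
  Klist$residual <- diag(n)
  fit <- aireml(y, X, Klist, ...)
  theta <- fit$theta

  denom_terms <- names(theta)
  if (!include_pen_in_total) denom_terms <- setdiff(denom_terms, "pen")
  total <- sum(theta[denom_terms])
  h2 <- unname(theta["additive"] / total)
  c2 <- if ("litter" %in% names(theta)) unname(theta["litter"] / total) else NA_real_

  ratio_se <- function(num_name) {
    C <- fit$cov_theta
    if (anyNA(diag(C)[denom_terms])) return(NA_real_)
    g <- setNames(rep(0, length(theta)), names(theta))
    g[denom_terms] <- -theta[num_name] / total^2
    g[num_name] <- g[num_name] + 1 / total
    v <- as.numeric(t(g) %*% C %*% g)
    if (is.na(v) || v < 0) NA_real_ else sqrt(v)
  }
  h2_se <- ratio_se("additive")
  c2_se <- if ("litter" %in% names(theta)) ratio_se("litter") else NA_real_

  p_h2 <- p_c2 <- NA_real_
  if (lrt) {
    fit0 <- aireml(y, X, Klist, fixed = c(additive = 0), ...)
    p_h2 <- lrt_pvalue(fit$logL, fit0$logL, boundary = TRUE)
    if ("litter" %in% names(theta)) {
      fitL <- aireml(y, X, Klist, fixed = c(litter = 0), ...)
      p_c2 <- lrt_pvalue(fit$logL, fitL$logL, boundary = TRUE)
    }
  }
  # Wald z as a cheap alternative significance measure
  wald_z <- unname(theta["additive"] / fit$se["additive"])
  p_wald <- if (is.na(wald_z)) NA_real_ else pnorm(wald_z, lower.tail = FALSE)

  structure(list(
    components = theta, se = fit$se, h2 = h2, c2 = c2,
    h2_se = h2_se, c2_se = c2_se,
    logL = fit$logL, p_h2 = p_h2, p_c2 = p_c2, p_wald = p_wald,
    converged = fit$converged, boundary = fit$boundary,
    non_identifiable = fit$non_identifiable,
    iterations = fit$iterations
  ), class = "vcfit")
}

#' @export
print.vcfit <- function(x, ...) {
  cat("Animal-model REML fit\n")
  cat("  components:", paste(sprintf("%s=%.4g", names(x$components),
                                     x$components), collapse = ", "), "\n")
  cat(sprintf("  h2 = %.3f (SE %.3f, LRT p = %.3g)\n",
              x$h2, x$h2_se, x$p_h2))
  if (!is.na(x$c2)) {
    cat(sprintf("  c2 = %.3f (SE %.3f, LRT p = %.3g)\n",
                x$c2, x$c2_se, x$p_c2))
  }
  cat("  converged:", x$converged,
      if (x$non_identifiable) " [non-identifiable]" else "", "\n")
  invisible(x)
}

#' Scan all genes under the WI and/or WO model
#'
#' Fits [reml_fit()] to every row of the expression matrix under the
#' requested model(s) and tabulates heritability, litter effect and their
#' significance.  Per-gene failures are recorded and the scan continues.
#'
#' @param expr an `expr_matrix` (or plain genes x samples matrix).
#' @param metadata per-animal metadata aligned to the columns of `expr`.
#' @param G genomic relationship matrix aligned to the columns of `expr`.
#' @param model "wi", "wo", or "both".
#' @param genes optional subset of gene ids.
#' @param lrt compute LRT p-values (two extra refits per gene).
#' @param threads number of worker processes (forked; results are
#'   order-independent and identical to a serial run).
#' @return data frame, one row per gene x model, of class `h2scan`; when
#'   both models are fitted, attribute `wi_wo_cor` holds the Pearson
#'   correlations of the h2 and c2 vectors between models.
#' @export
scan_transcriptome <- function(expr, metadata, G, model = c("both", "wi", "wo"),
                               genes = NULL, lrt = TRUE, threads = 1) {
  model <- match.arg(model)
  vals <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (!is.null(genes)) vals <- vals[intersect(genes, rownames(vals)), , drop = FALSE]
  models <- switch(model, both = c("wo", "wi"), wi = "wi", wo = "wo")

  fit_one <- function(gene, mod) {
    y <- vals[gene, ]
    ds <- build_design(metadata, wbc = (mod == "wi"), y = y)
    Gk <- G[ds$keep, ds$keep, drop = FALSE]
    res <- tryCatch(
      reml_fit(ds$y, ds$X, Gk, ds$Z_pen, ds$Z_litter, lrt = lrt),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(gene = gene, model = toupper(mod),
                        sigma2_A = NA, sigma2_P = NA, sigma2_L = NA,
                        sigma2_e = NA, h2 = NA, h2_se = NA, c2 = NA,
                        c2_se = NA, p_h2 = NA, p_c2 = NA, p_wald = NA,
                        logL = NA, converged = FALSE,
                        error = conditionMessage(res)))
    }
    data.frame(gene = gene, model = toupper(mod),
               sigma2_A = unname(res$components["additive"]),
               sigma2_P = unname(res$components["pen"]),
               sigma2_L = unname(res$components["litter"]),
               sigma2_e = unname(res$components["residual"]),
               h2 = res$h2, h2_se = res$h2_se,
               c2 = res$c2, c2_se = res$c2_se,
               p_h2 = res$p_h2, p_c2 = res$p_c2, p_wald = res$p_wald,
               logL = res$logL, converged = res$converged,
               error = NA_character_)
  }

  tasks <- expand.grid(gene = rownames(vals), model = models,
                       stringsAsFactors = FALSE)
  run <- function(i) fit_one(tasks$gene[i], tasks$model[i])
  rows <- if (threads > 1) {
    parallel::mclapply(seq_len(nrow(tasks)), run, mc.cores = threads)
  } else {
    lapply(seq_len(nrow(tasks)), run)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (model == "both") {
    wi <- out[out$model == "WI", ]
    wo <- out[out$model == "WO", ]
    wi <- wi[match(wo$gene, wi$gene), ]
    attr(out, "wi_wo_cor") <- c(
      h2 = suppressWarnings(cor(wi$h2, wo$h2, use = "complete.obs")),
      c2 = suppressWarnings(cor(wi$c2, wo$c2, use = "complete.obs")))
  }
  class(out) <- c("h2scan", "data.frame")
  out
}

#' Best per-gene heritability across models
#'
#' For genome-window summaries each gene carries the higher of its WI and
#' WO heritability estimates together with the matching p-value.
#'
#' @param scan an `h2scan` from [scan_transcriptome()].
#' @param model take the maximum over models (default) or restrict to one.
#' @return data frame gene, h2, p.
#' @export
best_h2 <- function(scan, model = c("max", "WI", "WO")) {
  model <- match.arg(model)
  if (model != "max") {
    sub <- scan[scan$model == model, c("gene", "h2", "p_h2")]
    names(sub) <- c("gene", "h2", "p")
    return(sub)
  }
  sp <- split(scan, scan$gene)
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[!is.na(d$h2), , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    i <- which.max(d$h2)
    data.frame(gene = d$gene[i], h2 = d$h2[i], p = d$p_h2[i])
  }))
  rownames(out) <- NULL
  out
}
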