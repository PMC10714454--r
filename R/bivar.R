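# Bivariate REML for the genetic correlation between a gene's expression
# and a phenotype, with unbalanced records: expression is observed on the
# transcriptomed subset only, phenotypes on the (larger) genotyped set.
#
# The genetic (co)variance structure is the 2x2 trait matrix Kronecker the
# GRM; residual covariance is estimable only over animals with both
# records and is fixed to zero when that overlap is small.  Two code paths
# produce identical results where both apply: a general dense path (any
# missingness pattern, pen/litter terms per trait) built on aireml(), and
# an eigen-rotation fast path for complete, additive+residual designs in
# which every per-iteration quantity reduces to 2x2 block algebra.

#' Bivariate REML fit
#'
#' @param y1,y2 numeric vectors over the same animal universe as `G`;
#'   `NA` marks an animal without a record for that trait.
#' @param G genomic relationship matrix over the animal universe.
#' @param X1,X2 fixed-effect design matrices over the universe rows
#'   (default: intercept only).
#' @param Z_pen1,Z_litter1,Z_pen2,Z_litter2 optional incidence matrices
#'   (universe rows) for trait-specific pen/litter random effects.
#' @param min_overlap minimum number of animals with both records for the
#'   residual covariance to be estimated; below it the parameter is fixed
#'   at zero.
#' @param lrt likelihood-ratio test of zero genetic covariance (one refit).
#' @param method "auto" picks the eigen fast path when the design allows
#'   it (same record set for both traits, no pen/litter terms).
#' @param ... passed to the optimizer.
#' @return object of class `gcfit`: 2x2 genetic and residual matrices,
#'   `rg`, `rg_se`, `p` (LRT for zero genetic covariance), per-trait
#'   variance components, convergence flags, and `psd_projected` when the
#'   genetic matrix had to be projected back to the PSD cone.
#' @export
bivar_reml <- function(y1, y2, G, X1 = NULL, X2 = NULL,
                       Z_pen1 = NULL, Z_litter1 = NULL,
                       Z_pen2 = NULL, Z_litter2 = NULL,
                       min_overlap = 30, lrt = TRUE,
                       method = c("auto", "eigen", "dense"), ...) {
  method <- match.arg(method)
  n <- nrow(G)
  stopifnot(length(y1) == n, length(y2) == n)
  if (is.null(X1)) X1 <- matrix(1, n, 1)
  if (is.null(X2)) X2 <- matrix(1, n, 1)
  i1 <- which(!is.na(y1)); i2 <- which(!is.na(y2))
  if (length(i1) < 3 || length(i2) < 3) stop("too few records")
  balanced <- identical(i1, i2)
  no_env <- is.null(Z_pen1) && is.null(Z_litter1) &&
    is.null(Z_pen2) && is.null(Z_litter2)
  use_eigen <- switch(method,
    auto = balanced && no_env,
    eigen = { if (!(balanced && no_env)) stop(
      "eigen path needs a balanced additive+residual design"); TRUE },
    dense = FALSE)
  overlap <- length(intersect(i1, i2))
  est_e12 <- overlap >= min_overlap

  fit <- if (use_eigen) {
    .bivar_eigen(y1[i1], y2[i1], X1[i1, , drop = FALSE],
                 X2[i1, , drop = FALSE], G[i1, i1], est_e12 = est_e12,
                 lrt = lrt, ...)
  } else {
    .bivar_dense(y1, y2, G, X1, X2, i1, i2,
                 Z_pen1, Z_litter1, Z_pen2, Z_litter2,
                 est_e12 = est_e12, lrt = lrt, ...)
  }
  fit$n1 <- length(i1); fit$n2 <- length(i2); fit$overlap <- overlap
  fit$residual_cov_estimated <- est_e12
  class(fit) <- "gcfit"
  fit
}

#' @export
print.gcfit <- function(x, ...) {
  cat("Bivariate REML fit\n")
  cat(sprintf("  rg = %s (SE %s, LRT p = %.3g)\n",
              format(x$rg, digits = 3), format(x$rg_se, digits = 3), x$p))
  cat("  genetic:", paste(sprintf("%.4g", x$genetic), collapse = " "), "\n")
  cat("  residual:", paste(sprintf("%.4g", x$residual), collapse = " "), "\n")
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

# shared post-processing: rg, SE, PSD projection
.gc_summarize <- function(theta, cov_theta, logL, logL0, converged,
                          boundary, lrt) {
  A <- matrix(c(theta["a11"], theta["a12"], theta["a12"], theta["a22"]), 2)
  E <- matrix(c(theta["e11"], theta["e12"], theta["e12"], theta["e22"]), 2)
  psd_projected <- FALSE
  ev <- eigen(A, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values), 1)) {
    lam <- pmax(ev$values, 0)
    A <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    psd_projected <- TRUE
  }
  rg <- rg_se <- NA_real_
  reason <- NA_character_
  if (A[1, 1] <= 0 || A[2, 2] <= 0) {
    reason <- "zero genetic variance for one trait"
  } else {
    rg <- A[1, 2] / sqrt(A[1, 1] * A[2, 2])
    rg <- max(min(rg, 1), -1)
    if (!is.null(cov_theta) && !anyNA(diag(cov_theta)[c("a11", "a12", "a22")])) {
      g <- setNames(rep(0, nrow(cov_theta)), rownames(cov_theta))
      g["a12"] <- 1 / sqrt(A[1, 1] * A[2, 2])
      g["a11"] <- -rg / (2 * A[1, 1])
      g["a22"] <- -rg / (2 * A[2, 2])
      v <- as.numeric(t(g) %*% cov_theta %*% g)
      if (!is.na(v) && v >= 0) rg_se <- sqrt(v)
    }
  }
  p <- if (lrt && !is.null(logL0)) {
    lrt_pvalue(logL, logL0, boundary = FALSE)
  } else NA_real_
  list(genetic = A, residual = E, rg = rg, rg_se = rg_se, p = p,
       components = theta, logL = logL, logL_null = logL0,
       converged = converged, boundary = boundary,
       psd_projected = psd_projected, rg_missing_reason = reason)
}

# -- general dense path --------------------------------------------------

.bivar_dense <- function(y1, y2, G, X1, X2, i1, i2,
                         Z_pen1, Z_litter1, Z_pen2, Z_litter2,
                         est_e12, lrt, ...) {
  n1 <- length(i1); n2 <- length(i2); nt <- n1 + n2
  b1 <- seq_len(n1); b2 <- n1 + seq_len(n2)
  zero <- matrix(0, nt, nt)
  blk <- function(rows, cols, M) { K <- zero; K[rows, cols] <- M; K }
  Ka11 <- blk(b1, b1, G[i1, i1])
  Ka22 <- blk(b2, b2, G[i2, i2])
  Ka12 <- zero; Ka12[b1, b2] <- G[i1, i2]; Ka12[b2, b1] <- G[i2, i1]
  Ke11 <- blk(b1, b1, diag(n1))
  Ke22 <- blk(b2, b2, diag(n2))
  Ke12 <- zero
  m12 <- outer(i1, i2, `==`)
  Ke12[b1, b2] <- m12 * 1; Ke12[b2, b1] <- t(m12) * 1

  Klist <- list(a11 = Ka11, a12 = Ka12, a22 = Ka22,
                e11 = Ke11, e12 = Ke12, e22 = Ke22)
  nonneg <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  addZ <- function(Z, idx, rows, nm) {
    if (!is.null(Z)) {
      Klist[[nm]] <<- blk(rows, rows, tcrossprod(Z[idx, , drop = FALSE]))
      nonneg <<- c(nonneg, TRUE)
    }
  }
  addZ(Z_pen1, i1, b1, "pen1"); addZ(Z_litter1, i1, b1, "litter1")
  addZ(Z_pen2, i2, b2, "pen2"); addZ(Z_litter2, i2, b2, "litter2")

  y <- c(y1[i1], y2[i2])
  X <- rbind(cbind(X1[i1, , drop = FALSE],
                   matrix(0, n1, ncol(X2))),
             cbind(matrix(0, n2, ncol(X1)),
                   X2[i2, , drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]

  v1 <- var(y1[i1]); v2 <- var(y2[i2])
  start <- c(a11 = v1 / 2, a12 = 0, a22 = v2 / 2,
             e11 = v1 / 2, e12 = 0, e22 = v2 / 2)
  start <- c(start, setNames(rep((v1 + v2) / 20,
                                 length(Klist) - 6),
                             names(Klist)[-(1:6)]))
  fixed <- if (est_e12) NULL else c(e12 = 0)
  fit <- aireml(y, X, Klist, nonneg = nonneg, start = start,
                fixed = fixed, ...)
  logL0 <- NULL
  if (lrt) {
    fixed0 <- c(fixed, c(a12 = 0))
    fit0 <- aireml(y, X, Klist, nonneg = nonneg, start = start,
                   fixed = fixed0, ...)
    logL0 <- fit0$logL
  }
  .gc_summarize(fit$theta, fit$cov_theta, fit$logL, logL0,
                fit$converged, fit$boundary, lrt)
}

# -- eigen-rotation fast path --------------------------------------------
#
# With complete records on one animal set and only additive + residual
# terms, rotating both traits by the eigenvectors of G turns V into n
# independent 2x2 blocks  V_i = A d_i + E,  so each AI-REML iteration is
# O(n p^2).

.bivar_eigen <- function(y1, y2, X1, X2, G, est_e12 = TRUE, lrt = TRUE,
                         max_iter = 200, tol = 1e-8) {
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  y1r <- as.numeric(crossprod(U, y1))
  y2r <- as.numeric(crossprod(U, y2))
  X1r <- crossprod(U, X1); X2r <- crossprod(U, X2)
  n <- length(d); p1 <- ncol(X1r); p2 <- ncol(X2r)

  v1 <- var(y1); v2 <- var(y2)
  theta <- c(a11 = v1 / 2, a12 = 0, a22 = v2 / 2,
             e11 = v1 / 2, e12 = 0, e22 = v2 / 2)
  pnames <- names(theta)
  is_fixed <- setNames(rep(FALSE, 6), pnames)
  if (!est_e12) { theta["e12"] <- 0; is_fixed["e12"] <- TRUE }

  eval_state <- function(th) {
    V11 <- th["a11"] * d + th["e11"]
    V12 <- th["a12"] * d + th["e12"]
    V22 <- th["a22"] * d + th["e22"]
    det <- V11 * V22 - V12^2
    if (any(det <= 0) || any(V11 <= 0)) return(NULL)
    Vi11 <- V22 / det; Vi22 <- V11 / det; Vi12 <- -V12 / det
    B11 <- crossprod(X1r, Vi11 * X1r)
    B12 <- crossprod(X1r, Vi12 * X2r)
    B22 <- crossprod(X2r, Vi22 * X2r)
    B <- rbind(cbind(B11, B12), cbind(t(B12), B22))
    cholB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cholB)) return(NULL)
    ViY1 <- Vi11 * y1r + Vi12 * y2r
    ViY2 <- Vi12 * y1r + Vi22 * y2r
    rhs <- c(crossprod(X1r, ViY1), crossprod(X2r, ViY2))
    beta <- backsolve(cholB, forwardsolve(t(cholB), rhs))
    Xb1 <- as.numeric(X1r %*% beta[seq_len(p1)])
    Xb2 <- as.numeric(X2r %*% beta[p1 + seq_len(p2)])
    w1 <- ViY1 - (Vi11 * Xb1 + Vi12 * Xb2)
    w2 <- ViY2 - (Vi12 * Xb1 + Vi22 * Xb2)
    ll <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(cholB))) +
                    sum(y1r * w1 + y2r * w2))
    list(ll = as.numeric(ll), Vi11 = Vi11, Vi12 = Vi12, Vi22 = Vi22,
         cholB = cholB, w1 = w1, w2 = w2)
  }

  # apply P to a stacked block vector (t1, t2)
  applyP <- function(st, t1, t2) {
    Vt1 <- st$Vi11 * t1 + st$Vi12 * t2
    Vt2 <- st$Vi12 * t1 + st$Vi22 * t2
    rhs <- c(crossprod(X1r, Vt1), crossprod(X2r, Vt2))
    cc <- backsolve(st$cholB, forwardsolve(t(st$cholB), rhs))
    Xc1 <- as.numeric(X1r %*% cc[seq_len(p1)])
    Xc2 <- as.numeric(X2r %*% cc[p1 + seq_len(p2)])
    list(u1 = Vt1 - (st$Vi11 * Xc1 + st$Vi12 * Xc2),
         u2 = Vt2 - (st$Vi12 * Xc1 + st$Vi22 * Xc2))
  }

  # M_k entries (as functions of d) for dV/dtheta_k
  Mk <- function(k) switch(k,
    a11 = list(m11 = d, m12 = 0 * d, m22 = 0 * d),
    a12 = list(m11 = 0 * d, m12 = d, m22 = 0 * d),
    a22 = list(m11 = 0 * d, m12 = 0 * d, m22 = d),
    e11 = list(m11 = rep(1, n), m12 = rep(0, n), m22 = rep(0, n)),
    e12 = list(m11 = rep(0, n), m12 = rep(1, n), m22 = rep(0, n)),
    e22 = list(m11 = rep(0, n), m12 = rep(0, n), m22 = rep(1, n)))

  run_fit <- function(theta, is_fixed) {
    st <- eval_state(theta)
    if (is.null(st)) {
      theta[c("a11", "a22")] <- c(v1, v2) * 0.3
      theta[c("e11", "e22")] <- c(v1, v2) * 0.7
      theta[c("a12", "e12")][!is_fixed[c("a12", "e12")]] <- 0
      st <- eval_state(theta)
      if (is.null(st)) stop("no positive-definite start")
    }
    free <- pnames[!is_fixed]
    boundary <- setNames(rep(FALSE, 6), pnames)
    floor_val <- 1e-8 * (v1 + v2)
    converged <- FALSE
    cov_theta <- NULL
    for (iter in seq_len(max_iter)) {
      ll_enter <- st$ll
      w1 <- st$w1; w2 <- st$w2
      Binv <- chol2inv(st$cholB)
      score <- setNames(numeric(6), pnames)
      tlist <- list()
      for (k in pnames) {
        M <- Mk(k)
        # t_k = K_k w
        t1 <- M$m11 * w1 + M$m12 * w2
        t2 <- M$m12 * w1 + M$m22 * w2
        tlist[[k]] <- list(t1 = t1, t2 = t2)
        wKw <- sum(w1 * t1 + w2 * t2)
        trViK <- sum(M$m11 * st$Vi11 + 2 * M$m12 * st$Vi12 +
                       M$m22 * st$Vi22)
        # N = Vi M Vi
        a <- M$m11 * st$Vi11 + M$m12 * st$Vi12
        b <- M$m12 * st$Vi11 + M$m22 * st$Vi12
        a2 <- M$m11 * st$Vi12 + M$m12 * st$Vi22
        b2 <- M$m12 * st$Vi12 + M$m22 * st$Vi22
        N11 <- st$Vi11 * a + st$Vi12 * b
        N12 <- st$Vi11 * a2 + st$Vi12 * b2
        N22 <- st$Vi12 * a2 + st$Vi22 * b2
        S11 <- crossprod(X1r, N11 * X1r)
        S12 <- crossprod(X1r, N12 * X2r)
        S22 <- crossprod(X2r, N22 * X2r)
        S <- rbind(cbind(S11, S12), cbind(t(S12), S22))
        trPK <- trViK - sum(Binv * S)
        score[k] <- -0.5 * (trPK - wKw)
      }
      # active-set release of components previously fixed at zero
      release <- pnames[boundary & score > 0 & !is_fixed]
      if (length(release) > 0) {
        boundary[release] <- FALSE
        free <- pnames[pnames %in% c(free, release)]
      }
      ulist <- lapply(tlist, function(t) applyP(st, t$t1, t$t2))
      AI <- matrix(0, 6, 6, dimnames = list(pnames, pnames))
      for (k in pnames) for (l in pnames) {
        AI[k, l] <- 0.5 * sum(tlist[[k]]$t1 * ulist[[l]]$u1 +
                                tlist[[k]]$t2 * ulist[[l]]$u2)
      }
      AI <- (AI + t(AI)) / 2
      aif <- AI[free, free, drop = FALSE]
      delta <- tryCatch(solve(aif, score[free]), error = function(e)
        score[free] / (abs(diag(aif)) + 1))
      step <- 1; improved <- FALSE
      for (h in 1:30) {
        cand <- theta
        cand[free] <- theta[free] + step * delta
        nn <- c("a11", "a22", "e11", "e22")
        cand[nn][cand[nn] < 0] <- 0
        st_new <- eval_state(cand)
        if (!is.null(st_new) && st_new$ll >= st$ll - 1e-10) {
          theta <- cand; st <- st_new; improved <- TRUE; break
        }
        step <- step / 2
      }
      hit <- intersect(free, c("a11", "a22", "e11", "e22"))
      hit <- hit[theta[hit] < floor_val & theta[hit] >= 0 &
                   score[hit] < 0]
      if (length(hit) > 0) {
        theta[hit] <- 0; boundary[hit] <- TRUE
        free <- setdiff(free, hit)
        st2 <- eval_state(theta)
        if (!is.null(st2)) st <- st2
        next
      }
      if (abs(st$ll - ll_enter) < tol * (abs(st$ll) + 1)) {
        converged <- TRUE
        inv <- tryCatch(solve(aif), error = function(e) NULL)
        if (!is.null(inv)) {
          cov_theta <- matrix(NA_real_, 6, 6,
                              dimnames = list(pnames, pnames))
          cov_theta[free, free] <- inv
        }
        break
      }
    }
    list(theta = theta, logL = st$ll, cov_theta = cov_theta,
         converged = converged, boundary = boundary)
  }

  fit <- run_fit(theta, is_fixed)
  logL0 <- NULL
  if (lrt) {
    isf0 <- is_fixed; isf0["a12"] <- TRUE
    th0 <- theta; th0["a12"] <- 0
    fit0 <- run_fit(th0, isf0)
    logL0 <- fit0$logL
  }
  .gc_summarize(fit$theta, fit$cov_theta, fit$logL, logL0,
                fit$converged, fit$boundary, lrt)
}

#' Benjamini-Hochberg q-values
#'
#' @param p vector of p-values in \[0, 1\].
#' @return step-up q-values, monotone in p-value rank.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Genetic-correlation scan over genes and traits
#'
#' Restricts genes to those with nominally significant heritability under
#' the WI *or* WO model, applies the survivor-dataset convention to the
#' phenotypes, and fits [bivar_reml()] for every gene x trait pair under
#' the requested expression model(s).
#'
#' @param expr an `expr_matrix` or matrix (genes x transcriptomed animals).
#' @param pheno data frame with `animal_id`, `survived`, and trait columns
#'   over the genotyped universe.
#' @param traits character vector of trait columns to analyze.
#' @param scan an `h2scan` from [scan_transcriptome()] used for the gene
#'   filter (`NULL` to skip filtering).
#' @param metadata expression-model metadata (rows = transcriptomed
#'   animals, aligned to `expr` columns).
#' @param G GRM over the union of animals; dimnames must cover
#'   `pheno$animal_id` and the columns of `expr`.
#' @param model expression model for the fixed effects: "wo" or "wi".
#' @param alpha significance threshold on the heritability p-value.
#' @param apply_survivor apply [survivor_filter()] to the phenotypes.
#' @param ... passed to [bivar_reml()].
#' @return data frame (class `gctable`): gene, trait, model, rg, rg_se, p,
#'   q (BH within trait x model), components and convergence flags.
#' @export
gc_scan <- function(expr, pheno, traits, scan = NULL, metadata = NULL,
                    G, model = "wo", alpha = 0.05,
                    apply_survivor = TRUE, ...) {
  vals <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  genes <- rownames(vals)
  if (!is.null(scan)) {
    sig <- unique(scan$gene[!is.na(scan$p_h2) & scan$p_h2 < alpha])
    genes <- intersect(genes, sig)
  }
  if (length(genes) == 0) stop("no genes pass the heritability filter")
  if (apply_survivor && "survived" %in% names(pheno)) {
    pheno <- survivor_filter(pheno)
  }
  ids <- rownames(G)
  stopifnot(!is.null(ids))
  expr_ids <- colnames(vals)

  # expression fixed design over the universe (NA rows outside subset)
  X1 <- matrix(1, nrow(G), 1)
  if (!is.null(metadata)) {
    ds <- build_design(metadata, wbc = (model == "wi"))
    X1 <- matrix(0, nrow(G), ncol(ds$X))
    X1[match(expr_ids[ds$keep], ids), ] <- ds$X
    X1[, 1][X1[, 1] == 0] <- 1  # keep intercept defined everywhere
  }

  rows <- list()
  for (g in genes) {
    y1 <- rep(NA_real_, nrow(G))
    y1[match(expr_ids, ids)] <- vals[g, ]
    for (tr in traits) {
      y2 <- rep(NA_real_, nrow(G))
      y2[match(pheno$animal_id, ids)] <- pheno[[tr]]
      res <- tryCatch(bivar_reml(y1, y2, G, X1 = X1, ...),
                      error = function(e) e)
      rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
        data.frame(gene = g, trait = tr, model = toupper(model),
                   rg = NA, rg_se = NA, p = NA,
                   sigma2_A_gene = NA, sigma2_A_trait = NA,
                   converged = FALSE, error = conditionMessage(res))
      } else {
        data.frame(gene = g, trait = tr, model = toupper(model),
                   rg = res$rg, rg_se = res$rg_se, p = res$p,
                   sigma2_A_gene = res$genetic[1, 1],
                   sigma2_A_trait = res$genetic[2, 2],
                   converged = res$converged, error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (tr in unique(out$trait)) {
    sel <- out$trait == tr
    out$q[sel] <- fdr_adjust(out$p[sel])
  }
  rownames(out) <- NULL
  class(out) <- c("gctable", "data.frame")
  out
}
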