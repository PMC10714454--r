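# Shared fixtures: small genotype/GRM builders used across test files.

make_G <- function(n, m = 500, n_companies = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  company <- sort(rep_len(paste0("c", seq_len(n_companies)), n))
  p <- runif(m, 0.1, 0.5)
  D <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(D) <- paste0("a", seq_len(n))
  colnames(D) <- paste0("s", seq_len(m))
  gs <- genotype_set(D, company)
  build_grm(gs, qc = FALSE)
}

# MVN draw with covariance s2 * G (via eigendecomposition)
mvn_from_G <- function(G, s2 = 1) {
  eg <- eigen(G, symmetric = TRUE)
  as.numeric(eg$vectors %*% (sqrt(pmax(eg$values, 0) * s2) *
                               rnorm(nrow(G))))
}

# independent profile-likelihood oracle for the additive+residual model:
# grid search over h2 after rotating by the eigenvectors of G
profile_h2_grid <- function(y, X, G, grid = seq(0, 0.999, by = 0.001)) {
  eg <- eigen(G, symmetric = TRUE)
  yr <- as.numeric(crossprod(eg$vectors, y))
  Xr <- crossprod(eg$vectors, X)
  n <- length(y); p <- qr(X)$rank
  ll <- vapply(grid, function(h) {
    w <- h * eg$values + (1 - h)
    if (any(w <= 0)) return(-Inf)
    Xw <- Xr / w
    B <- crossprod(Xr, Xw)
    bc <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(bc)) return(-Inf)
    beta <- backsolve(bc, forwardsolve(t(bc), crossprod(Xw, yr)))
    r <- yr - Xr %*% beta
    s2 <- sum(r^2 / w) / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(w)) +
              2 * sum(log(diag(bc))) + (n - p))
  }, 0)
  grid[which.max(ll)]
}

# small demo count matrix
toy_counts <- function(ngene = 8, nsamp = 5, seed = 3) {
  set.seed(seed)
  m <- matrix(rnbinom(ngene * nsamp, mu = 50, size = 5), ngene, nsamp)
  count_matrix(m)
}
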