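# Average-information REML for a linear mixed model with an arbitrary set of
# (co)variance structures:
#
#   y = X beta + sum_k  (component k),   V = sum_k theta_k * K_k
#
# Each K_k is an n x n symmetric matrix (GRM, Z Z' incidence products, the
# identity for the residual, or signed cross-trait blocks in bivariate
# models).  Variance parameters are constrained >= 0; covariance parameters
# (nonneg = FALSE) are unconstrained apart from keeping V positive definite.
#
# Updates are AI steps with step-halving on the restricted log-likelihood,
# falling back to EM-type multiplicative updates for nonnegative components
# when the AI step fails.  Components driven to the lower boundary are fixed
# at zero and the fit re-converges over the remaining parameters.

#' Restricted log-likelihood machinery for one parameter vector
#' @noRd
.reml_eval <- function(theta, y, X, Klist, ridge = 0) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (k in seq_along(Klist)) V <- V + theta[k] * Klist[[k]]
  if (ridge > 0) diag(V) <- diag(V) + ridge
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(NULL)
  Vi <- chol2inv(cholV)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cholB <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cholB)) return(NULL)
  beta <- backsolve(cholB, forwardsolve(t(cholB), crossprod(ViX, y)))
  Py <- Vi %*% y - ViX %*% beta
  logdetV <- 2 * sum(log(diag(cholV)))
  logdetB <- 2 * sum(log(diag(cholB)))
  ll <- -0.5 * (logdetV + logdetB + sum(y * Py))
  list(ll = as.numeric(ll), Vi = Vi, ViX = ViX, cholB = cholB,
       beta = as.numeric(beta), Py = as.numeric(Py))
}

#' Apply the projection matrix P to a vector without forming P
#' @noRd
.apply_P <- function(st, v) {
  as.numeric(st$Vi %*% v - st$ViX %*%
    backsolve(st$cholB, forwardsolve(t(st$cholB), crossprod(st$ViX, v))))
}

#' Fit variance components by average-information REML
#'
#' Maximizes the restricted log-likelihood
#' \eqn{-\tfrac12(\log|V| + \log|X'V^{-1}X| + y'Py)} over the
#' (co)variance parameters of \eqn{V = \sum_k \theta_k K_k}.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param Klist named list of symmetric n x n matrices, one per variance
#'   parameter; include the identity for the residual.
#' @param nonneg logical vector, one per parameter; `TRUE` (default)
#'   constrains the parameter to be nonnegative, `FALSE` marks a covariance
#'   parameter free in sign.
#' @param start optional numeric start values.
#' @param fixed optional named numeric vector of parameters held fixed
#'   (e.g. `c(gen_cov = 0)` for a likelihood-ratio null fit).
#' @param max_iter,tol iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param ridge diagonal ridge added to V when a Cholesky fails.
#' @param restarts number of additional spread starting points (each
#'   concentrating most of the variance in one nonnegative component);
#'   the fit with the highest restricted likelihood is returned.  Guards
#'   against multimodal restricted likelihoods, which occur for weakly
#'   identified designs.
#' @return list with `theta`, `logL`, `beta`, `se` (from the inverse AI
#'   matrix; `NA` for boundary/fixed parameters), `ai` (AI matrix over free
#'   parameters), `converged`, `iterations`, `boundary` (logical per
#'   parameter), and `non_identifiable`.
#' @export
aireml <- function(y, X, Klist, nonneg = rep(TRUE, length(Klist)),
                   start = NULL, fixed = NULL,
                   max_iter = 200, tol = 1e-8, ridge = 0, restarts = 0) {
  if (restarts > 0) {
    m <- length(Klist)
    vy <- stats::var(as.numeric(y))
    starts <- list(start)
    ks <- which(nonneg)
    for (k in ks[seq_len(min(restarts, length(ks)))]) {
      s <- rep(0.2 * vy / max(1, m - 1), m)
      s[!nonneg] <- 0
      s[k] <- 0.8 * vy
      starts <- c(starts, list(s))
    }
    fits <- lapply(starts, function(s0) {
      tryCatch(aireml(y, X, Klist, nonneg = nonneg, start = s0,
                      fixed = fixed, max_iter = max_iter, tol = tol,
                      ridge = ridge, restarts = 0),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0) stop("all REML starts failed")
    return(fits[[which.max(vapply(fits, `[[`, 0, "logL"))]])
  }
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, length(Klist) >= 1)
  m <- length(Klist)
  if (is.null(names(Klist))) names(Klist) <- paste0("vc", seq_len(m))
  vy <- stats::var(y)
  floor_val <- 1e-8 * vy

  theta <- if (is.null(start)) {
    s <- rep(vy / m, m)
    s[!nonneg] <- 0
    s
  } else as.numeric(start)
  names(theta) <- names(Klist)

  is_fixed <- rep(FALSE, m); names(is_fixed) <- names(Klist)
  if (!is.null(fixed)) {
    idx <- match(names(fixed), names(Klist))
    if (anyNA(idx)) stop("unknown component in `fixed`")
    theta[idx] <- as.numeric(fixed)
    is_fixed[idx] <- TRUE
  }
  boundary <- rep(FALSE, m); names(boundary) <- names(Klist)
  free <- which(!is_fixed)
  non_identifiable <- FALSE

  st <- .reml_eval(theta, y, X, Klist)
  if (is.null(st)) {
    # fall back to a crude but PD start
    theta[nonneg & !is_fixed] <- vy / sum(nonneg & !is_fixed)
    theta[!nonneg & !is_fixed] <- 0
    st <- .reml_eval(theta, y, X, Klist, ridge = ridge)
    if (is.null(st)) stop("could not find a positive-definite starting V")
  }

  ai_free <- NULL
  iter <- 0
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1
    ll_enter <- st$ll
    Py <- st$Py
    Binv <- chol2inv(st$cholB)
    # score and AI over currently free parameters
    tvec <- lapply(Klist, function(K) as.numeric(K %*% Py))
    score <- numeric(m)
    trPK <- numeric(m)
    for (k in seq_len(m)) {
      PK_tr <- sum(st$Vi * Klist[[k]]) -
        sum(st$ViX * (Klist[[k]] %*% st$ViX %*% Binv))
      trPK[k] <- PK_tr
      score[k] <- -0.5 * (PK_tr - sum(Py * tvec[[k]]))
    }
    u <- lapply(tvec, function(t) .apply_P(st, t))
    AI <- matrix(0, m, m)
    for (k in seq_len(m)) for (l in k:m) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(tvec[[k]] * u[[l]])
    }
    dimnames(AI) <- list(names(Klist), names(Klist))

    # active-set release: a component fixed at the zero boundary whose
    # score has turned positive re-enters the free set
    release <- which(boundary & score > 0 & !is_fixed)
    if (length(release) > 0) {
      boundary[release] <- FALSE
      free <- sort(union(free, release))
    }
    ai_free <- AI[free, free, drop = FALSE]

    if (length(free) == 0) { converged <- TRUE; break }

    rc <- tryCatch(rcond(ai_free), error = function(e) 0)
    delta_free <- if (rc > 1e-12) {
      tryCatch(solve(ai_free, score[free]), error = function(e) NULL)
    } else NULL
    if (is.null(delta_free)) {
      non_identifiable <- TRUE
      delta_free <- score[free] / (abs(diag(ai_free)) + 1)
    }

    # step-halving on the restricted likelihood
    step <- 1
    improved <- FALSE
    for (h in 1:30) {
      cand <- theta
      cand[free] <- theta[free] + step * delta_free
      cand[free][nonneg[free] & cand[free] < 0] <- 0
      st_new <- .reml_eval(cand, y, X, Klist, ridge = if (h > 20) ridge else 0)
      if (!is.null(st_new) && st_new$ll >= st$ll - 1e-10) {
        theta <- cand; st <- st_new; improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      # EM-type multiplicative fallback for nonnegative components
      cand <- theta
      for (k in free) {
        if (nonneg[k] && trPK[k] > 0 && theta[k] > 0) {
          cand[k] <- theta[k] * sum(Py * tvec[[k]]) / trPK[k]
        }
      }
      st_new <- .reml_eval(cand, y, X, Klist, ridge = ridge)
      if (!is.null(st_new) && st_new$ll >= st$ll - 1e-10) {
        theta <- cand; st <- st_new; improved <- TRUE
      }
    }

    # boundary handling: fix tiny nonnegative components at exactly zero
    # when their score pushes them negative
    hit <- free[nonneg[free] & theta[free] < floor_val & score[free] < 0]
    if (length(hit) > 0) {
      theta[hit] <- 0
      boundary[hit] <- TRUE
      free <- setdiff(free, hit)
      st2 <- .reml_eval(theta, y, X, Klist)
      if (is.null(st2)) {
        # zeroing left V singular: hold the component at the floor instead
        st2 <- .reml_eval(theta, y, X, Klist,
                          ridge = max(ridge, floor_val))
      }
      if (is.null(st2)) {
        theta[hit] <- floor_val
        boundary[hit] <- FALSE
        free <- sort(union(free, hit))
      } else {
        st <- st2
      }
      next
    }

    # convergence on relative log-likelihood change within the iteration
    if (abs(st$ll - ll_enter) < tol * (abs(st$ll) + 1)) {
      converged <- TRUE
      break
    }
  }

  # standard errors from the inverse AI matrix over free parameters
  se <- rep(NA_real_, m); names(se) <- names(Klist)
  cov_theta <- matrix(NA_real_, m, m, dimnames = list(names(Klist), names(Klist)))
  if (length(free) > 0 && !is.null(ai_free) &&
      ncol(ai_free) == length(free)) {
    inv <- tryCatch(solve(ai_free), error = function(e) NULL)
    if (is.null(inv)) {
      non_identifiable <- TRUE
    } else {
      se[free] <- sqrt(pmax(diag(inv), 0))
      cov_theta[free, free] <- inv
    }
  }
  se[boundary] <- NA_real_

  list(theta = theta, logL = st$ll, beta = st$beta, se = se,
       cov_theta = cov_theta, ai = ai_free,
       converged = converged, iterations = iter,
       boundary = boundary, non_identifiable = non_identifiable)
}
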