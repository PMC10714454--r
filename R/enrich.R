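# Functional enrichment: over-representation of highly heritable genes,
# pre-ranked GSEA on signed genetic-correlation significance, and the
# signed-significance trait x pathway matrix with hierarchical clustering.

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, genes; tab-separated).
#' @return named list of character vectors; descriptions kept as the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[`, "", 2)
  if (any(lengths(sets) == 0)) stop("GMT contains empty set(s)")
  sets
}

#' Write gene sets to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Restrict gene sets to a universe and filter by size
#'
#' Keeps sets whose intersection with the universe is strictly between
#' `min_size` and `max_size` genes.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of analyzable genes.
#' @param min_size,max_size exclusive size bounds.
#' @return filtered list of intersected sets.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 10, max_size = 500) {
  sets <- lapply(sets, intersect, universe)
  keep <- lengths(sets) > min_size & lengths(sets) < max_size
  sets[keep]
}

#' Over-representation analysis (one-sided hypergeometric)
#'
#' @param query gene list of interest (must be a subset of `universe`).
#' @param universe background gene list.
#' @param sets named list of gene sets (intersected with the universe).
#' @return data frame per set: overlap counts, odds ratio, one-sided
#'   hypergeometric p, BH q.
#' @export
ora_fisher <- function(query, universe, sets) {
  query <- unique(query); universe <- unique(universe)
  if (length(query) == 0 || length(universe) == 0) {
    stop("query and universe must be non-empty")
  }
  if (!all(query %in% universe)) stop("query must be a subset of universe")
  N <- length(universe); nq <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(s, query))
    # P(X >= k), X ~ Hypergeom(N, K, nq)
    p <- phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    or <- (k * (N - K - nq + k)) / max(1, (K - k) * (nq - k))
    data.frame(set = nm, set_size = K, overlap = k,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out
}

#' Rank genes by signed genetic-correlation significance
#'
#' Score = sign(rg) x (-log10 p), ordered from the most significant
#' positive to the most significant negative genetic correlation.  Ties
#' are broken by |rg| (larger first) and then gene id.
#'
#' @param gc data frame with columns gene, rg, p (one row per gene).
#' @param cap absolute score cap applied when p underflows to 0.
#' @return object of class `ranked_list`: data frame gene, score in rank
#'   order.
#' @export
rank_genes <- function(gc, cap = 320) {
  stopifnot(all(c("gene", "rg", "p") %in% names(gc)))
  if (anyDuplicated(gc$gene)) stop("one row per gene required")
  score <- sign(gc$rg) * (-log10(gc$p))
  zero_p <- !is.na(gc$p) & gc$p == 0
  if (any(zero_p)) {
    message(sum(zero_p), " zero p-value(s) capped at +/-", cap)
    score[zero_p] <- sign(gc$rg[zero_p]) * cap
  }
  score[is.infinite(score)] <- sign(score[is.infinite(score)]) * cap
  ord <- order(-score, -abs(gc$rg), gc$gene)
  structure(data.frame(gene = gc$gene[ord], score = score[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# weighted Kolmogorov-Smirnov-like enrichment score for hit positions
# `hits` (sorted, 1-based) in a list of length N with |score|^w weights
# `absw` (full-length vector).  Returns the signed maximum deviation of
# the running sum.
.es_stat <- function(absw, hits, N) {
  m <- length(hits)
  a <- absw[hits]
  A <- sum(a)
  if (A == 0) return(list(es = 0, peak = 0L))
  Wk <- cumsum(a) / A
  miss <- 1 / (N - m)
  k <- seq_len(m)
  at_hit <- Wk - (hits - k) * miss          # just after each hit
  before <- c(0, Wk[-m]) - (hits - k) * miss # just before each hit
  i_hi <- which.max(at_hit); i_lo <- which.min(before)
  if (at_hit[i_hi] >= -before[i_lo]) {
    list(es = at_hit[i_hi], peak = hits[i_hi])
  } else {
    list(es = before[i_lo], peak = hits[i_lo])
  }
}

#' Pre-ranked gene set enrichment analysis
#'
#' Weighted running-sum enrichment scores against a ranked list, with a
#' gene-label permutation null: for each permutation the set's positions
#' are redrawn uniformly from the list.  NES divides ES by the mean of
#' same-sign permutation ES; nominal p is the same-sign permutation tail
#' fraction; FDR is the sign-stratified ratio of pooled-null to observed
#' NES tail fractions.
#'
#' @param rl a [rank_genes()] result (or data frame gene, score, already
#'   ordered).
#' @param sets named list of gene sets; filtered against the list with
#'   [filter_gene_sets()] bounds.
#' @param weight exponent on |score| for hit increments (1 = weighted,
#'   0 = classical Kolmogorov-Smirnov).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @param min_size,max_size set-size filter bounds (exclusive).
#' @return data frame per set: size, ES, NES, nominal p, FDR q, leading
#'   edge (comma-separated core genes).
#' @export
gsea_preranked <- function(rl, sets, weight = 1, n_perm = 1000, seed = 1,
                           min_size = 10, max_size = 500) {
  genes <- rl$gene
  N <- length(genes)
  absw <- abs(rl$score)^weight
  sets <- filter_gene_sets(sets, genes, min_size, max_size)
  sets <- sets[lengths(sets) < N]  # a set covering the list is degenerate
  if (length(sets) == 0) stop("no gene sets pass the size filter")
  set.seed(seed)

  res <- lapply(names(sets), function(nm) {
    hits <- sort(match(sets[[nm]], genes))
    m <- length(hits)
    obs <- .es_stat(absw, hits, N)
    null_es <- vapply(seq_len(n_perm), function(i) {
      .es_stat(absw, sort(sample.int(N, m)), N)$es
    }, 0)
    list(set = nm, size = m, es = obs$es, peak = obs$peak,
         hits = hits, null = null_es)
  })

  es <- vapply(res, `[[`, 0, "es")
  nes <- numeric(length(res))
  pval <- numeric(length(res))
  null_nes <- vector("list", length(res))
  for (i in seq_along(res)) {
    nl <- res[[i]]$null
    pos <- nl[nl >= 0]; neg <- nl[nl < 0]
    mp <- if (length(pos) > 0) mean(pos) else NA
    mn <- if (length(neg) > 0) mean(abs(neg)) else NA
    nes[i] <- if (es[i] >= 0) es[i] / mp else es[i] / mn
    pval[i] <- if (es[i] >= 0) {
      (1 + sum(pos >= es[i])) / (1 + length(pos))
    } else {
      (1 + sum(neg <= es[i])) / (1 + length(neg))
    }
    nn <- nl
    nn[nl >= 0] <- if (is.na(mp)) 0 else nl[nl >= 0] / mp
    nn[nl < 0] <- if (is.na(mn)) 0 else nl[nl < 0] / mn
    null_nes[[i]] <- nn
  }
  pool <- unlist(null_nes)
  fdr <- vapply(seq_along(res), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num_d <- sum(pool >= 0)
      num <- if (num_d == 0) 1 else sum(pool >= nes[i]) / num_d
      den_d <- sum(nes >= 0)
      den <- sum(nes >= nes[i]) / den_d
    } else {
      num_d <- sum(pool < 0)
      num <- if (num_d == 0) 1 else sum(pool <= nes[i]) / num_d
      den_d <- sum(nes < 0)
      den <- sum(nes <= nes[i]) / den_d
    }
    min(1, num / den)
  }, 0)

  lead <- vapply(seq_along(res), function(i) {
    r <- res[[i]]
    core <- if (r$es >= 0) r$hits[r$hits <= r$peak] else r$hits[r$hits >= r$peak]
    paste(genes[core], collapse = ",")
  }, "")

  data.frame(set = vapply(res, `[[`, "", "set"),
             size = vapply(res, `[[`, 0L, "size"),
             es = es, nes = nes, p = pval, fdr = fdr,
             leading_edge = lead, stringsAsFactors = FALSE)
}

#' Signed-significance matrix across traits with set clustering
#'
#' Builds the set x trait matrix of signed enrichment significance,
#' entry = -log10(FDR) with a positive sign when the direction of the
#' enrichment (sign of NES times the trait's favorable direction) is
#' favorable and negative otherwise, and clusters the sets by
#' hierarchical agglomeration on their profiles.
#'
#' @param gsea_by_trait named list (by trait) of [gsea_preranked()]
#'   results.
#' @param favorable named numeric (+1/-1) per trait: the favorable
#'   direction of an increase in the trait.
#' @param dist_method,linkage clustering choices.
#' @return list: `matrix` (sets x traits), `set_order` (dendrogram leaf
#'   order), `hclust` object.
#' @export
signed_significance_matrix <- function(gsea_by_trait, favorable,
                                       dist_method = "euclidean",
                                       linkage = "complete") {
  traits <- names(gsea_by_trait)
  lack <- setdiff(traits, names(favorable))
  if (length(lack) > 0) {
    stop("no favorable direction declared for trait(s): ",
         paste(lack, collapse = ", "))
  }
  all_sets <- sort(unique(unlist(lapply(gsea_by_trait,
                                        function(d) d$set))))
  M <- matrix(0, length(all_sets), length(traits),
              dimnames = list(all_sets, traits))
  for (tr in traits) {
    d <- gsea_by_trait[[tr]]
    sig <- -log10(pmax(d$fdr, 1e-320))
    s <- ifelse(sign(d$nes) * favorable[tr] >= 0, 1, -1)
    M[d$set, tr] <- sig * s
  }
  hc <- if (nrow(M) > 2) {
    hclust(dist(M, method = dist_method), method = linkage)
  } else NULL
  ord <- if (is.null(hc)) rownames(M) else rownames(M)[hc$order]
  list(matrix = M, set_order = ord, hclust = hc)
}
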