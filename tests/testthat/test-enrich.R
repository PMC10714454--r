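test_that("ORA p-values match hypergeometric tail sums from first principles", {
  # direct oracle: sum of C(K,j) C(N-K, n-j) / C(N,n) over j >= k
  oracle <- function(k, K, n, N) {
    j <- max(k, 0):min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  set.seed(41)
  for (i in 1:200) {
    N <- sample(5:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    p_pkg <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p_pkg, oracle(k, K, n, N), tolerance = 1e-12)
  }
  # worked 2x2 example: 10 in set&query, margins (15, 25) of N = 1000
  universe <- paste0("g", 1:1000)
  query <- universe[1:25]
  sets <- list(S = universe[c(1:10, 26:30)])  # 10 overlap, size 15
  res <- ora_fisher(query, universe, sets)
  expect_equal(res$overlap, 10)
  expect_equal(res$p, oracle(10, 15, 25, 1000), tolerance = 1e-12)

  # saturation and disjointness give p = 1
  res2 <- ora_fisher(universe, universe, sets)
  expect_equal(res2$p, 1)
  sets3 <- list(S = universe[900:950])
  expect_equal(ora_fisher(universe[1:20], universe, sets3)$p, 1)
  expect_error(ora_fisher(character(), universe, sets), "non-empty")
  expect_error(ora_fisher("not_there", universe, sets), "subset")
})

test_that("gene ranking orders by signed significance with documented tie-breaks", {
  gc <- data.frame(gene = c("gA", "gB", "gC", "gD", "gE"),
                   rg = c(0.5, 0.5, -0.5, -0.2, 0.5),
                   p = c(0.01, 0.1, 0.001, 0.5, 0.1))
  rl <- rank_genes(gc)
  expect_equal(rl$gene[1], "gA")            # most significant positive
  expect_equal(rl$gene[nrow(rl)], "gC")     # most significant negative last
  # tie between gB and gE (same rg, p): alphabetical gene id
  ties <- rl$gene[rl$score == -log10(0.1)]
  expect_equal(ties, c("gB", "gE"))
  # zero p-values are capped, not infinite
  gc$p[1] <- 0
  expect_message(rl2 <- rank_genes(gc), "capped")
  expect_equal(rl2$score[1], 320)
})

test_that("enrichment scores match hand-evaluated running sums", {
  # N = 5, single-gene set at rank 1, weight 0:
  # steps +1 at the hit then -1/4 per miss; max deviation = 1
  rl <- data.frame(gene = paste0("g", 1:5), score = c(5, 4, 3, 2, 1))
  class(rl) <- c("ranked_list", "data.frame")
  res <- gsea_preranked(rl, list(top = "g1"), weight = 0, n_perm = 10,
                        seed = 1, min_size = 0, max_size = 10)
  expect_equal(res$es, 1)
  # same set at the bottom: running sum dips to -(4/4) before the hit,
  # reaching +? at hit: before hit deviation = -4/4 + ... hand value:
  # 4 misses of -1/4 then +1 -> extreme deviation is -1 + 1e-... = -1
  res2 <- gsea_preranked(rl, list(bottom = "g5"), weight = 0, n_perm = 10,
                         seed = 1, min_size = 0, max_size = 10)
  expect_equal(res2$es, -1)
  # weighted: set {g1, g3} at weight 1 on scores (5,4,3,2,1):
  # A = 5 + 3 = 8; at g1: 5/8; before g3: 5/8 - 1/3; at g3: 1 - 1/3
  res3 <- gsea_preranked(rl, list(s = c("g1", "g3")), weight = 1,
                         n_perm = 10, seed = 1, min_size = 0,
                         max_size = 10)
  expect_equal(res3$es, 1 - 1/3, tolerance = 1e-12)
})

test_that("weight zero reduces to the classical KS statistic", {
  # independent direct implementation of the running sum over all ranks
  ks_direct <- function(N, hits) {
    m <- length(hits)
    inc <- rep(-1 / (N - m), N)
    inc[hits] <- 1 / m
    cs <- cumsum(inc)
    cs[which.max(abs(cs))]
  }
  set.seed(42)
  rl <- data.frame(gene = paste0("g", 1:100),
                   score = sort(rnorm(100), decreasing = TRUE))
  class(rl) <- c("ranked_list", "data.frame")
  for (i in 1:10) {
    hits <- sort(sample(100, sample(5:30, 1)))
    sets <- list(s = rl$gene[hits])
    res <- gsea_preranked(rl, sets, weight = 0, n_perm = 5, seed = 1,
                          min_size = 0, max_size = 99)
    expect_equal(res$es, ks_direct(100, hits), tolerance = 1e-12)
  }
})

test_that("GSEA agrees with an independent implementation and is deterministic", {
  set.seed(43)
  rl <- data.frame(gene = paste0("g", 1:200),
                   score = sort(rnorm(200, sd = 2), decreasing = TRUE))
  class(rl) <- c("ranked_list", "data.frame")
  sets <- simulate_gene_sets(rl$gene, n_sets = 8, size_range = c(15, 40),
                             seed = 44)
  res <- gsea_preranked(rl, sets, n_perm = 100, seed = 7)
  # ES bounds
  expect_true(all(res$es >= -1 & res$es <= 1))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
  # fixed seed reproduces p and FDR exactly
  res2 <- gsea_preranked(rl, sets, n_perm = 100, seed = 7)
  expect_identical(res, res2)
  # cross-check ES against fgsea
  stats <- setNames(rl$score, rl$gene)
  for (nm in names(sets)) {
    es_fgsea <- fgsea::calcGseaStat(stats, match(sets[[nm]], names(stats)),
                                    gseaParam = 1)
    expect_equal(res$es[res$set == nm], es_fgsea, tolerance = 1e-6)
  }
})

test_that("signed-significance matrix follows the favorable-direction rule", {
  gs1 <- data.frame(set = c("S1", "S2"), size = c(20, 30),
                    es = c(0.5, -0.4), nes = c(1.8, -1.5),
                    p = c(0.001, 0.02), fdr = c(0.01, 1),
                    leading_edge = "")
  gs2 <- gs1; gs2$nes <- c(-1.2, 2.0); gs2$fdr <- c(0.1, 0.05)
  out <- signed_significance_matrix(list(t1 = gs1, t2 = gs2),
                                    favorable = c(t1 = 1, t2 = 1))
  # FDR 0.01 with favorable direction -> +2
  expect_equal(out$matrix["S1", "t1"], 2)
  # FDR = 1 -> 0 regardless of direction
  expect_equal(out$matrix["S2", "t1"], 0)
  # flipping a trait's favorable sign negates its column exactly
  out2 <- signed_significance_matrix(list(t1 = gs1, t2 = gs2),
                                     favorable = c(t1 = 1, t2 = -1))
  expect_equal(out2$matrix[, "t2"], -out$matrix[, "t2"])
  expect_equal(out2$matrix[, "t1"], out$matrix[, "t1"])
  expect_error(signed_significance_matrix(list(t1 = gs1),
                                          favorable = c(zz = 1)),
               "favorable")
})

test_that("GMT round-trips and size filtering applies exclusive bounds", {
  sets <- list(A = paste0("g", 1:12), B = paste0("g", 1:5),
               C = paste0("g", 1:30))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$A, sets$A)
  expect_equal(names(back), names(sets))
  universe <- paste0("g", 1:25)
  filt <- filter_gene_sets(sets, universe, min_size = 10, max_size = 500)
  expect_setequal(names(filt), c("A", "C"))   # B too small; C clipped to 25
  expect_equal(length(filt$C), 25)
  filt2 <- filter_gene_sets(sets, universe, min_size = 12, max_size = 500)
  expect_false("A" %in% names(filt2))         # exactly 12 fails strict >
})
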