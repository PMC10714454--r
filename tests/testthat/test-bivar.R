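test_that("eigen fast path and dense path agree on a balanced design", {
  set.seed(21)
  n <- 40
  G <- make_G(n, m = 300)
  u <- mvn_from_G(G, 0.4)
  y1 <- 1 + u + rnorm(n, sd = sqrt(0.6))
  y2 <- 2 + 0.6 * u + rnorm(n, sd = sqrt(0.8))
  fe <- bivar_reml(y1, y2, G, method = "eigen")
  fd <- bivar_reml(y1, y2, G, method = "dense")
  expect_equal(fe$logL, fd$logL, tolerance = 1e-5)
  expect_equal(fe$components, fd$components, tolerance = 1e-3)
  expect_equal(fe$p, fd$p, tolerance = 1e-3)
})

test_that("a trait paired with itself gives a boundary genetic correlation of one", {
  set.seed(22)
  n <- 60
  G <- make_G(n, m = 300)
  u <- mvn_from_G(G, 0.5)
  y <- u + rnorm(n, sd = sqrt(0.5))
  fit <- bivar_reml(y, y, G)
  expect_equal(fit$rg, 1, tolerance = 0.02)
})

test_that("unbalanced records are handled with structural missingness", {
  set.seed(23)
  n <- 80
  G <- make_G(n, m = 300)
  u <- mvn_from_G(G, 0.5)
  y1 <- u + rnorm(n, sd = sqrt(0.5))
  y2 <- 0.7 * u + rnorm(n, sd = sqrt(0.51))
  y1[41:80] <- NA  # expression only on half the animals
  fit <- bivar_reml(y1, y2, G, method = "dense", lrt = FALSE)
  expect_equal(fit$n1, 40)
  expect_equal(fit$n2, 80)
  expect_equal(fit$overlap, 40)
  expect_true(is.finite(fit$logL))
  # overlap below the threshold fixes the residual covariance at zero
  y1b <- y1; y1b[1:30] <- NA
  fit2 <- bivar_reml(y1b, y2, G, method = "dense", lrt = FALSE,
                     min_overlap = 30)
  expect_false(fit2$residual_cov_estimated)
  expect_equal(unname(fit2$components["e12"]), 0)
})

test_that("gene-side components agree between bivariate and single-trait fits", {
  set.seed(24)
  n <- 150
  G <- make_G(n, m = 400)
  u <- mvn_from_G(G, 0.4)
  y1 <- u + rnorm(n, sd = sqrt(0.6))
  v <- mvn_from_G(G, 0.4)
  y2 <- 0.5 * u + sqrt(1 - 0.25) * v + rnorm(n, sd = sqrt(0.6))
  X <- matrix(1, n, 1)
  uni <- aireml(y1, X, list(additive = G, residual = diag(n)))
  biv <- bivar_reml(y1, y2, G, lrt = FALSE)
  expect_equal(unname(biv$components["a11"]), unname(uni$theta[1]),
               tolerance = 0.1 * max(uni$theta[1], 0.1))
  expect_equal(unname(biv$components["e11"]), unname(uni$theta[2]),
               tolerance = 0.1 * uni$theta[2])
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.01, 0.04, 0.5)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("gc_scan applies the WI-or-WO significance filter and fills the grid", {
  set.seed(25)
  cfg <- sim_config(n_companies = 1, n_batches = 3, animals_per_batch = 40,
                    pens_per_batch = 4, litters_per_batch = 6,
                    n_snps = 300, n_genes = 3, h2_by_gene = 0.5,
                    c2_by_gene = 0, pen_var_frac_by_gene = 0,
                    wbc_effect_scale = 0, n_traits = 2, trait_h2 = 0.4,
                    seed = 25)
  sim <- simulate_cohort(cfg)
  G <- build_grm(genotype_set(sim$genotypes$dosages, sim$metadata$company),
                 qc = FALSE)
  # fabricated scan: gene1 significant under WI only, gene2 under WO,
  # gene3 under neither
  scan <- data.frame(gene = rep(c("gene1", "gene2", "gene3"), 2),
                     model = rep(c("WI", "WO"), each = 3),
                     p_h2 = c(0.01, 0.5, 0.9, 0.2, 0.03, 0.4))
  class(scan) <- c("h2scan", "data.frame")
  gc <- gc_scan(sim$expr, sim$pheno, c("trait1", "trait2"), scan = scan,
                G = G, lrt = FALSE)
  expect_setequal(unique(gc$gene), c("gene1", "gene2"))
  expect_equal(nrow(gc), 4)  # 2 genes x 2 traits
  expect_true(all(!is.na(gc$q) | is.na(gc$p)))
})
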