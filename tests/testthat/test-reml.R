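test_that("boundary-mixture LRT p-values match closed forms", {
  expect_equal(lrt_pvalue(0, 0, boundary = TRUE), 1)
  expect_equal(lrt_pvalue(3.84 / 2, 0, boundary = TRUE),
               0.5 * pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(lrt_pvalue(3.84 / 2, 0, boundary = FALSE),
               pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(lrt_pvalue(3.84 / 2, 0, boundary = TRUE), 0.025,
               tolerance = 1e-3)
  expect_equal(lrt_pvalue(3.84 / 2, 0, boundary = FALSE), 0.05,
               tolerance = 1e-3)
  expect_error(lrt_pvalue(0, 1), "optimizer")
})

test_that("design builder codes factors, covariates and WBC columns", {
  set.seed(11)
  cfg <- sim_config(n_companies = 1, n_batches = 2, animals_per_batch = 20,
                    pens_per_batch = 2, litters_per_batch = 4,
                    n_snps = 10, n_genes = 1)
  md <- simulate_structure(cfg, seed = 1)
  ds_wo <- build_design(md, wbc = FALSE)
  ds_wi <- build_design(md, wbc = TRUE)
  # two batches -> one batch contrast given the intercept
  expect_equal(sum(grepl("batch", colnames(ds_wo$X))), 1)
  # the WI model adds exactly six covariate columns
  expect_equal(ncol(ds_wi$X) - ncol(ds_wo$X), 6)
  # zero WBC proportion stays finite through the offset transform
  expect_true(is.finite(log2_wbc(0)))
  # random-term incidence: every animal in exactly one pen and litter
  expect_true(all(rowSums(ds_wo$Z_pen) == 1))
  expect_true(all(rowSums(ds_wo$Z_litter) == 1))
  # missing covariates drop animals
  md2 <- md; md2$age[1] <- NA
  expect_message(ds2 <- build_design(md2), "dropped")
  expect_equal(sum(ds2$keep), nrow(md) - 1)
})

test_that("AI-REML matches the eigen-rotation profile-likelihood oracle", {
  set.seed(12)
  n <- 60
  # the fixed design spans the company means, matching the model the
  # block GRM is used with (otherwise the zero-eigenvalue company
  # contrast creates a degenerate boundary spike in the likelihood)
  company <- factor(rep(c("c1", "c2"), each = n / 2))
  X <- model.matrix(~ company)
  for (rep in 1:8) {
    G <- make_G(n, m = 200, n_companies = 2)
    h2_true <- runif(1, 0.1, 0.8)
    u <- mvn_from_G(G, h2_true)
    y <- 1 + u + rnorm(n, sd = sqrt(1 - h2_true))
    fit <- aireml(y, X, list(additive = G, residual = diag(n)),
                  restarts = 2, tol = 1e-12)
    # the grid represents a boundary optimum by its endpoint 0.999
    h2_hat <- min(unname(fit$theta[1] / sum(fit$theta)), 0.999)
    h2_grid <- profile_h2_grid(y, X, G)
    expect_lt(abs(h2_hat - h2_grid), 1e-3)
  }
})

test_that("degenerate and null fits are flagged sensibly", {
  set.seed(13)
  n <- 80
  # G = I: additive and residual unidentifiable
  y <- rnorm(n)
  fit <- aireml(y, matrix(1, n, 1), list(A = diag(n), E = diag(n)))
  expect_true(fit$non_identifiable)
  # pure-noise gene against a real G: h2 near zero
  G <- make_G(n, m = 400)
  f2 <- reml_fit(rnorm(n), matrix(1, n, 1), G, lrt = TRUE)
  expect_lt(f2$h2, 0.15)
  expect_gte(f2$p_h2, 0)
  # likelihood invariance to fixed-effect reparameterization
  x <- factor(rep(c("u", "v"), n / 2))
  X1 <- model.matrix(~ x)
  X2 <- model.matrix(~ relevel(x, "v"))
  fa <- aireml(y, X1, list(A = G, E = diag(n)))
  fb <- aireml(y, X2, list(A = G, E = diag(n)))
  expect_lt(abs(fa$logL - fb$logL), 1e-8)
})

test_that("transcriptome scan is consistent with single fits and chunking", {
  set.seed(14)
  cfg <- sim_config(n_companies = 1, n_batches = 3, animals_per_batch = 30,
                    pens_per_batch = 3, litters_per_batch = 5,
                    n_snps = 200, n_genes = 3, h2_by_gene = 0.4,
                    c2_by_gene = 0.1, pen_var_frac_by_gene = 0.05,
                    wbc_effect_scale = 0, seed = 14)
  sim <- simulate_cohort(cfg)
  G <- build_grm(genotype_set(sim$genotypes$dosages, sim$metadata$company),
                 qc = FALSE)
  scan <- scan_transcriptome(sim$expr, sim$metadata, G, model = "wo",
                             lrt = FALSE)
  expect_equal(nrow(scan), 3)
  # matches a direct single-gene fit
  ds <- build_design(sim$metadata, wbc = FALSE, y = sim$expr[1, ])
  single <- reml_fit(ds$y, ds$X, G[ds$keep, ds$keep], ds$Z_pen,
                     ds$Z_litter, lrt = FALSE)
  expect_equal(scan$h2[scan$gene == "gene1"], single$h2, tolerance = 1e-10)
  # chunked equals serial
  scan2 <- scan_transcriptome(sim$expr, sim$metadata, G, model = "wo",
                              lrt = FALSE, threads = 2)
  expect_equal(scan2$h2, scan$h2, tolerance = 1e-12)
  # both models: WI adds WBC columns, correlations attribute present
  scan3 <- scan_transcriptome(sim$expr, sim$metadata, G, model = "both",
                              lrt = FALSE)
  expect_equal(nrow(scan3), 6)
  expect_true(is.numeric(attr(scan3, "wi_wo_cor")["h2"]))
})

test_that("best_h2 takes the larger of the WI and WO estimates", {
  scan <- data.frame(gene = c("g1", "g1", "g2", "g2"),
                     model = c("WI", "WO", "WI", "WO"),
                     h2 = c(0.3, 0.5, 0.2, 0.1),
                     p_h2 = c(0.2, 0.01, 0.03, 0.6))
  class(scan) <- c("h2scan", "data.frame")
  bh <- best_h2(scan)
  expect_equal(bh$h2[bh$gene == "g1"], 0.5)
  expect_equal(bh$p[bh$gene == "g1"], 0.01)
  expect_equal(bh$h2[bh$gene == "g2"], 0.2)
})
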