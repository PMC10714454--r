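test_that("configuration validation enforces the documented invariants", {
  expect_error(sim_config(h2_by_gene = 0.6, c2_by_gene = 0.3,
                          pen_var_frac_by_gene = 0.2), "must be < 1")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(sim_config(n_genes = 2, n_traits = 1,
                          rg_matrix = matrix(c(1.2, 0), 2, 1)), "rg")
  expect_error(sim_config(n_genes = 1, n_traits = 1, h2_by_gene = 0,
                          rg_matrix = matrix(0.5, 1, 1)),
               "nonzero rg requires")
  expect_error(sim_config(binary_prevalence = 1.5), "prevalence")
  expect_error(sim_config(n_batches = 0), "counts")
})

test_that("genotypes are reproducible and in HWE at p = 0.5", {
  cfg <- sim_config(n_companies = 1, n_batches = 2,
                    animals_per_batch = 1500, pens_per_batch = 2,
                    litters_per_batch = 2, n_snps = 30,
                    maf_range = c(0.5, 0.5), n_genes = 1)
  md <- simulate_structure(cfg, seed = 31)
  g1 <- simulate_genotypes(cfg, md, seed = 32)
  g2 <- simulate_genotypes(cfg, md, seed = 32)
  expect_identical(g1$dosages, g2$dosages)
  tab <- table(g1$dosages) / length(g1$dosages)
  expect_equal(unname(tab[c("0", "1", "2")]), c(0.25, 0.5, 0.25),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("cohort labels nest as configured and breeding values center per company", {
  cfg <- sim_config(n_companies = 2, n_batches = 4, animals_per_batch = 20,
                    pens_per_batch = 4, litters_per_batch = 5,
                    n_snps = 100, n_genes = 2, h2_by_gene = 0.4,
                    seed = 33)
  sim <- simulate_cohort(cfg)
  md <- sim$metadata
  # litters and pens belong to exactly one batch
  expect_true(all(rowSums(table(md$litter, md$batch) > 0) == 1))
  expect_true(all(rowSums(table(paste(md$batch, md$pen), md$batch) > 0) == 1))
  # each animal has one company; batches nest in companies
  expect_true(all(rowSums(table(md$batch, md$company) > 0) == 1))
  for (cc in unique(md$company)) {
    mu <- colMeans(sim$truth$breeding_values[md$company == cc, ,
                                             drop = FALSE])
    expect_lt(max(abs(mu)), 1e-10)  # exact within-company centering
  }
})

test_that("realized variance fractions equal the configured fractions", {
  cfg <- sim_config(n_companies = 1, n_batches = 10,
                    animals_per_batch = 200, pens_per_batch = 10,
                    litters_per_batch = 20, n_snps = 200, n_genes = 3,
                    h2_by_gene = c(0.3, 0.1, 0), c2_by_gene = 0.1,
                    pen_var_frac_by_gene = 0.05, seed = 34)
  sim <- simulate_cohort(cfg)
  bv <- sim$truth$breeding_values
  for (g in 1:3) {
    expect_equal(var(bv[, g]), cfg$h2_by_gene[g], tolerance = 1e-10)
  }
})

test_that("cohort simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_companies = 1, n_batches = 2, animals_per_batch = 15,
                    pens_per_batch = 3, litters_per_batch = 3,
                    n_snps = 50, n_genes = 4, seed = 35)
  s1 <- simulate_cohort(cfg, counts = TRUE)
  s2 <- simulate_cohort(cfg, counts = TRUE)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$pheno, s2$pheno)
})

test_that("liability thresholding calibrates binary prevalence", {
  cfg <- sim_config(n_companies = 1, n_batches = 5,
                    animals_per_batch = 1000, pens_per_batch = 5,
                    litters_per_batch = 10, n_snps = 100, n_genes = 1,
                    h2_by_gene = 0.3, n_traits = 1, trait_h2 = 0.3,
                    binary_prevalence = 0.2, seed = 36)
  sim <- simulate_cohort(cfg)
  frac <- mean(sim$pheno$trait1)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
})

test_that("degenerate full-correlation limit reproduces the gene signal", {
  cfg <- sim_config(n_companies = 1, n_batches = 2,
                    animals_per_batch = 100, pens_per_batch = 2,
                    litters_per_batch = 4, n_snps = 100, n_genes = 1,
                    h2_by_gene = 0.99, c2_by_gene = 0,
                    pen_var_frac_by_gene = 0, n_traits = 1,
                    trait_h2 = 1, rg_matrix = matrix(1, 1, 1), seed = 37)
  sim <- simulate_cohort(cfg)
  r <- cor(sim$truth$breeding_values[, 1],
           sim$truth$trait_breeding_values[, 1])
  expect_gt(r, 0.999)
})

test_that("impossible joint genetic covariances are rejected", {
  # two copies of (nearly) the same gene cannot both correlate 0.9 / -0.9
  cfg <- sim_config(n_companies = 1, n_batches = 2,
                    animals_per_batch = 50, pens_per_batch = 2,
                    litters_per_batch = 4, n_snps = 100, n_genes = 2,
                    h2_by_gene = 0.5, n_traits = 1,
                    rg_matrix = matrix(c(0.99, -0.99), 2, 1), seed = 38)
  md <- simulate_structure(cfg, seed = 38)
  geno <- simulate_genotypes(cfg, md)
  ex <- simulate_expression(cfg, geno, md)
  # force near-duplicate breeding values to make the target infeasible
  ex$truth$breeding_values[, 2] <- ex$truth$breeding_values[, 1] +
    rnorm(nrow(md), sd = 1e-3)
  expect_error(simulate_phenotypes(cfg, geno, md, ex$truth), "PSD|singular")
})

test_that("generated counts exercise the normalization front end", {
  cfg <- sim_config(n_companies = 1, n_batches = 2, animals_per_batch = 20,
                    pens_per_batch = 2, litters_per_batch = 4,
                    n_snps = 50, n_genes = 30, seed = 39)
  sim <- simulate_cohort(cfg, counts = TRUE)
  expect_true(all(sim$counts >= 0))
  em <- normalize_counts(count_matrix(sim$counts))
  expect_equal(dim(em$values)[2], 40)
  # normalized log2 expression correlates with the simulated signal
  keep <- intersect(rownames(em$values), rownames(sim$expr))
  cors <- vapply(keep, function(g) cor(em$values[g, ], sim$expr[g, ]), 0)
  expect_gt(median(cors), 0.5)
})
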