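test_that("SNP QC applies strict thresholds in every group", {
  set.seed(1)
  D <- matrix(rbinom(40 * 6, 2, 0.3), 40, 6)
  grp <- rep(c("g1", "g2"), each = 20)
  # snp1: MAF 0.025 in g1, ~0.3 in g2 -> removed by the intersection rule
  D[1:20, 1] <- c(1, rep(0, 19))
  D[21:40, 1] <- rbinom(20, 2, 0.3)
  # snp2: MAF exactly 0.05 in g1 (2 alleles of 40) -> strict ">" removes
  D[1:20, 2] <- c(1, 1, rep(0, 18))
  D[21:40, 2] <- rbinom(20, 2, 0.3)
  # snp3: low call rate in g2
  D2 <- D
  D2[21:35, 3] <- NA                             # call rate 5/20 = 0.25
  gs <- genotype_set(D2, company = grp)
  qc <- snp_qc(gs)
  kept <- colnames(qc$genotypes$dosages)
  expect_false("snp1" %in% kept)
  expect_false("snp2" %in% kept)
  expect_false("snp3" %in% kept)
  expect_true(all(paste0("snp", 4:6) %in% kept))

  # complete data at healthy MAF: nothing removed
  set.seed(2)
  Dc <- matrix(rbinom(30 * 5, 2, 0.3), 30, 5)
  qc2 <- snp_qc(genotype_set(Dc, rep("g", 30)))
  expect_equal(dim(qc2$genotypes$dosages), c(30L, 5L))
  expect_error(snp_qc(genotype_set(matrix(2, 10, 2), rep("g", 10))),
               "no SNPs")
})

test_that("VanRaden block matches the hand-computed 1-SNP example", {
  D <- matrix(c(0, 2), 2, 1, dimnames = list(c("a1", "a2"), "s1"))
  gs <- genotype_set(D, c("c1", "c1"))
  B <- vanraden_grm(gs, "c1")
  expect_equal(unname(B), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(B, "sum2pq"), 0.5)

  # duplicate animals: off-diagonal equals diagonal
  set.seed(3)
  D2 <- matrix(rbinom(20, 2, 0.4), 2, 10, byrow = TRUE)
  D2[2, ] <- D2[1, ]
  D2 <- rbind(D2, matrix(rbinom(30, 2, 0.4), 3, 10))
  rownames(D2) <- paste0("a", 1:5)
  B2 <- vanraden_grm(genotype_set(D2, rep("c1", 5)), "c1")
  expect_equal(B2[1, 2], B2[1, 1], tolerance = 1e-12)

  expect_error(vanraden_grm(genotype_set(matrix(2, 4, 3), rep("c", 4)), "c"),
               "monomorphic")
})

test_that("HWE simulation gives mean GRM diagonal near one and centered Z", {
  set.seed(4)
  n <- 300
  G <- make_G(n, m = 10000)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  # column sums of centered dosages are zero within company <=> G rows sum ~ 0
  expect_lt(max(abs(rowSums(G))), 1e-8)
  expect_equal(G, t(G), tolerance = 1e-12)
})

test_that("block assembly zeroes cross-company cells and commutes with permutation", {
  set.seed(5)
  D <- rbind(matrix(rbinom(2 * 20, 2, 0.3), 2, 20),
             matrix(rbinom(3 * 20, 2, 0.4), 3, 20))
  rownames(D) <- paste0("a", 1:5)
  comp <- c("c1", "c1", "c2", "c2", "c2")
  gs <- genotype_set(D, comp)
  blocks <- list(vanraden_grm(gs, "c1"), vanraden_grm(gs, "c2"))
  G <- combine_block_grm(blocks)
  expect_equal(dim(G), c(5L, 5L))
  expect_true(all(G[1:2, 3:5] == 0))
  expect_true(all(G[3:5, 1:2] == 0))

  # single company: identity of the assembly
  G1 <- combine_block_grm(blocks[1])
  expect_equal(G1, blocks[[1]], ignore_attr = TRUE)

  # permutation equivariance
  ord <- c("a3", "a1", "a5", "a2", "a4")
  Gp <- combine_block_grm(blocks, ord)
  expect_equal(Gp[rownames(G), rownames(G)], G)

  expect_error(combine_block_grm(list(blocks[[1]], blocks[[1]])),
               "overlap")
  expect_error(combine_block_grm(blocks, c("a1", "a2", "a3", "a4", "zz")),
               "permutation")
})

test_that("ridge restores positive definiteness when needed", {
  G <- matrix(c(1, 1, 1, 1), 2)  # singular
  Gr <- grm_ridge(G)
  expect_true(attr(Gr, "ridged"))
  expect_gt(min(eigen(Gr, symmetric = TRUE, only.values = TRUE)$values), 0)
  Gok <- diag(2)
  expect_false(attr(grm_ridge(Gok), "ridged"))
})
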