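# Synthetic cohorts with the statistical structure the analyses assume:
# multi-company cohorts in batches, pens and litters nested in batches,
# SNP genotypes in Hardy-Weinberg equilibrium with company-specific allele
# frequencies, expression built gene by gene from genotype-weighted SNP
# effects (so the GRM constructed by the pipeline is consistent with the
# simulated truth), white-blood-cell composition covariate effects, and
# phenotypes sharing genetics with chosen genes at configured genetic
# correlations, with binary traits via a liability threshold.
#
# Random components are rescaled to their exact target variance fractions,
# which makes parameter-recovery experiments sharp: the configured h2/c2
# are realized variance fractions, not just expectations.

#' Simulation configuration
#'
#' Defaults mirror a large multi-herd challenge cohort: seven companies,
#' fifty batches of ~64 weaned pigs housed in pens, litters nested in
#' batches, dense SNP genotypes passing a MAF > 0.05 screen.  Tests and
#' examples use smaller explicit values.
#'
#' @param n_companies,n_batches,animals_per_batch,pens_per_batch,litters_per_batch
#'   cohort structure counts (batches are nested in companies; pens and
#'   litters in batches).
#' @param n_snps number of SNPs.
#' @param maf_range allele-frequency range (per company) for simulated SNPs.
#' @param n_genes number of genes.
#' @param h2_by_gene,c2_by_gene,pen_var_frac_by_gene per-gene variance
#'   fractions of the random part of expression (additive, litter, pen);
#'   scalars are recycled.
#' @param wbc_effect_scale SD of per-gene effects of the six log2 WBC
#'   composition covariates (0 disables cell-composition signal).
#' @param n_traits,trait_h2 phenotype count and heritabilities.
#' @param rg_matrix n_genes x n_traits genetic correlations between gene
#'   expression and traits (default all zero).
#' @param binary_prevalence per-trait prevalence for liability-threshold
#'   binary coding, or `NA` for a continuous trait.
#' @param nb_dispersion,lib_sd negative-binomial dispersion and log-normal
#'   library-size SD used when read counts are generated.
#' @param wbc_alpha Dirichlet concentration for the six WBC proportions
#'   (lymphocyte, neutrophil, monocyte, basophil, eosinophil, LUC).
#' @param seed default RNG seed for [simulate_cohort()].
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_companies = 7, n_batches = 50,
                       animals_per_batch = 64, pens_per_batch = 12,
                       litters_per_batch = 20,
                       n_snps = 5000, maf_range = c(0.05, 0.5),
                       n_genes = 100,
                       h2_by_gene = 0.07, c2_by_gene = 0.02,
                       pen_var_frac_by_gene = 0.05,
                       wbc_effect_scale = 0.2,
                       n_traits = 2, trait_h2 = 0.3,
                       rg_matrix = NULL, binary_prevalence = NULL,
                       nb_dispersion = 0.1, lib_sd = 0.3,
                       wbc_alpha = c(30, 55, 8, 1, 5, 1),
                       seed = 1) {
  counts <- c(n_companies = n_companies, n_batches = n_batches,
              animals_per_batch = animals_per_batch,
              pens_per_batch = pens_per_batch,
              litters_per_batch = litters_per_batch,
              n_snps = n_snps, n_genes = n_genes, n_traits = n_traits)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (n_batches < n_companies) stop("need at least one batch per company")
  if (length(maf_range) != 2 || any(maf_range <= 0) ||
      any(maf_range > 0.5) || maf_range[1] > maf_range[2]) {
    stop("maf_range must be increasing within (0, 0.5]")
  }
  h2 <- rep_len(h2_by_gene, n_genes)
  c2 <- rep_len(c2_by_gene, n_genes)
  pf <- rep_len(pen_var_frac_by_gene, n_genes)
  if (any(h2 < 0 | h2 >= 1 | c2 < 0 | pf < 0)) {
    stop("variance fractions must be in [0, 1)")
  }
  if (any(h2 + c2 + pf >= 1)) {
    stop("per gene h2 + c2 + pen fraction must be < 1")
  }
  th2 <- rep_len(trait_h2, n_traits)
  if (any(th2 < 0 | th2 > 1)) stop("trait_h2 must be in [0, 1]")
  if (is.null(rg_matrix)) rg_matrix <- matrix(0, n_genes, n_traits)
  rg_matrix <- as.matrix(rg_matrix)
  if (!all(dim(rg_matrix) == c(n_genes, n_traits))) {
    stop("rg_matrix must be n_genes x n_traits")
  }
  if (any(abs(rg_matrix) > 1)) stop("|rg| must be <= 1")
  if (any(rg_matrix != 0 & rep(h2 == 0, n_traits))) {
    stop("nonzero rg requires nonzero gene h2")
  }
  if (!is.null(binary_prevalence)) {
    bp <- rep_len(binary_prevalence, n_traits)
    if (any(!is.na(bp) & (bp <= 0 | bp >= 1))) {
      stop("binary prevalence must be in (0, 1)")
    }
  } else bp <- rep(NA_real_, n_traits)
  structure(list(
    n_companies = n_companies, n_batches = n_batches,
    animals_per_batch = animals_per_batch,
    pens_per_batch = pens_per_batch,
    litters_per_batch = litters_per_batch,
    n_snps = n_snps, maf_range = maf_range, n_genes = n_genes,
    h2_by_gene = h2, c2_by_gene = c2, pen_var_frac_by_gene = pf,
    wbc_effect_scale = wbc_effect_scale,
    n_traits = n_traits, trait_h2 = th2, rg_matrix = rg_matrix,
    binary_prevalence = bp, nb_dispersion = nb_dispersion,
    lib_sd = lib_sd, wbc_alpha = wbc_alpha, seed = seed
  ), class = "sim_config")
}

# scale a vector to an exact target SD around an exact zero mean
.scale_exact <- function(x, target_sd) {
  if (target_sd == 0) return(rep(0, length(x)))
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) stop("degenerate component: zero variance before scaling")
  x * (target_sd / s)
}

#' Cohort structure: batches, companies, pens, litters, covariates
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed (set only when non-NULL).
#' @return metadata data frame, one row per animal.
#' @export
simulate_structure <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  batch_company <- sort(rep_len(seq_len(cfg$n_companies), cfg$n_batches))
  n <- cfg$n_batches * cfg$animals_per_batch
  batch <- rep(seq_len(cfg$n_batches), each = cfg$animals_per_batch)
  pen <- unlist(lapply(seq_len(cfg$n_batches), function(b)
    rep_len(seq_len(cfg$pens_per_batch), cfg$animals_per_batch)))
  litter <- unlist(lapply(seq_len(cfg$n_batches), function(b)
    sort(rep_len(seq_len(cfg$litters_per_batch), cfg$animals_per_batch))))
  md <- data.frame(
    animal_id = sprintf("animal%04d", seq_len(n)),
    company = paste0("company", batch_company[batch]),
    batch = paste0("batch", batch),
    pen = paste0("pen", pen),
    litter = sprintf("batch%d_litter%d", batch, litter),
    enrich = ifelse(pen %% 2 == 0, "yes", "no"),
    age = round(rnorm(n, mean = 21, sd = 1.5)),
    rin = round(rnorm(n, mean = 8, sd = 0.5), 1),
    stringsAsFactors = FALSE
  )
  # Dirichlet WBC proportions
  A <- matrix(rgamma(n * 6, shape = rep(cfg$wbc_alpha, each = n)), n, 6)
  P <- A / rowSums(A)
  colnames(P) <- paste0("wbc_", WBC_TYPES)
  cbind(md, as.data.frame(P))
}

#' Simulate SNP dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP gets a company-specific allele frequency drawn uniformly from
#' `maf_range`; dosages are binomial(2, p) per animal.
#'
#' @param cfg a [sim_config()].
#' @param metadata from [simulate_structure()].
#' @param seed optional seed.
#' @return list: `dosages` (animals x SNPs), `freq` (company x SNP allele
#'   frequencies), `company` labels.
#' @export
simulate_genotypes <- function(cfg, metadata, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$n_snps < 1 || nrow(metadata) < 1) stop("invalid configuration")
  companies <- unique(metadata$company)
  freq <- matrix(runif(length(companies) * cfg$n_snps,
                       cfg$maf_range[1], cfg$maf_range[2]),
                 nrow = length(companies),
                 dimnames = list(companies,
                                 paste0("snp", seq_len(cfg$n_snps))))
  n <- nrow(metadata)
  D <- matrix(0L, n, cfg$n_snps,
              dimnames = list(metadata$animal_id, colnames(freq)))
  for (cc in companies) {
    idx <- which(metadata$company == cc)
    D[idx, ] <- matrix(rbinom(length(idx) * cfg$n_snps, 2,
                              rep(freq[cc, ], each = length(idx))),
                       length(idx), cfg$n_snps)
  }
  list(dosages = D, freq = freq, company = metadata$company)
}

# additive genetic values from genotype-weighted SNP effects, centered
# within company (exact, because dosages are centered within company)
.genetic_values <- function(dosages, company, n_draws = 1) {
  Zc <- dosages
  for (cc in unique(company)) {
    idx <- company == cc
    Zc[idx, ] <- scale(dosages[idx, , drop = FALSE], center = TRUE,
                       scale = FALSE)
  }
  b <- matrix(rnorm(ncol(Zc) * n_draws), ncol(Zc), n_draws)
  Zc %*% b
}

#' Simulate gene expression on the log2 scale (plus optional read counts)
#'
#' Expression of gene g is batch + enrichment + age and RIN covariate
#' effects + WBC-composition effects + pen + litter + additive genetic
#' value + residual.  The additive value is a genotype-weighted sum of SNP
#' effects rescaled so the realized variance fractions of (additive,
#' litter, pen) among the random terms equal the configured h2/c2/pen
#' fractions exactly; the total random variance is 1 per gene.
#'
#' @param cfg a [sim_config()].
#' @param geno from [simulate_genotypes()].
#' @param metadata from [simulate_structure()].
#' @param counts also generate negative-binomial read counts.
#' @param seed optional seed.
#' @return list: `expr` (genes x animals, log2 scale), `counts` (or NULL),
#'   `truth` (per-gene breeding-value matrix and configured fractions),
#'   `annotation` (gene positions on 18 autosomes).
#' @export
simulate_expression <- function(cfg, geno, metadata, counts = FALSE,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(metadata)
  if (nrow(geno$dosages) != n) stop("genotype/metadata dimension mismatch")
  ng <- cfg$n_genes
  gene_ids <- paste0("gene", seq_len(ng))

  batch_eff <- setNames(rnorm(cfg$n_batches, 0, 0.5),
                        paste0("batch", seq_len(cfg$n_batches)))
  enrich_eff <- 0.3
  wbc_l2 <- log2_wbc(as.matrix(
    metadata[paste0("wbc_", WBC_TYPES)]))

  U <- .genetic_values(geno$dosages, metadata$company, n_draws = ng)
  pen_key <- paste(metadata$batch, metadata$pen)
  litter_key <- metadata$litter
  mu <- runif(ng, 3, 9)

  expr <- matrix(0, ng, n, dimnames = list(gene_ids, metadata$animal_id))
  bv <- matrix(0, n, ng, dimnames = list(metadata$animal_id, gene_ids))
  for (g in seq_len(ng)) {
    h2 <- cfg$h2_by_gene[g]; c2 <- cfg$c2_by_gene[g]
    pf <- cfg$pen_var_frac_by_gene[g]
    u <- .scale_exact(U[, g], sqrt(h2))
    pen_e <- setNames(rnorm(length(unique(pen_key))), unique(pen_key))
    pen_v <- .scale_exact(pen_e[pen_key], sqrt(pf))
    lit_e <- setNames(rnorm(length(unique(litter_key))), unique(litter_key))
    lit_v <- .scale_exact(lit_e[litter_key], sqrt(c2))
    e <- .scale_exact(rnorm(n), sqrt(1 - h2 - c2 - pf))
    beta_wbc <- rnorm(6, 0, cfg$wbc_effect_scale)
    fixed <- batch_eff[metadata$batch] +
      enrich_eff * (metadata$enrich == "yes") +
      0.02 * (metadata$age - mean(metadata$age)) +
      0.10 * (metadata$rin - mean(metadata$rin)) +
      as.numeric(wbc_l2 %*% beta_wbc)
    expr[g, ] <- mu[g] + fixed + pen_v + lit_v + u + e
    bv[, g] <- u
  }

  cm <- NULL
  if (counts) {
    libf <- exp(rnorm(n, 0, cfg$lib_sd))
    mu_counts <- sweep(2^expr, 2, libf, `*`)
    cm <- matrix(rnbinom(length(mu_counts), mu = mu_counts,
                         size = 1 / cfg$nb_dispersion),
                 nrow = ng, dimnames = dimnames(expr))
  }

  annotation <- data.frame(
    gene_id = gene_ids,
    chrom = sample(paste0("chr", 1:18), ng, replace = TRUE),
    start = sample.int(150e6, ng),
    stringsAsFactors = FALSE
  )
  annotation$end <- annotation$start + sample(500:100000, ng, replace = TRUE)

  list(expr = expr, counts = cm,
       truth = list(breeding_values = bv, true_h2 = cfg$h2_by_gene,
                    true_c2 = cfg$c2_by_gene,
                    true_pen_frac = cfg$pen_var_frac_by_gene),
       annotation = annotation)
}

#' Simulate phenotypes genetically correlated with gene expression
#'
#' Trait breeding values are built as weighted sums of the standardized
#' gene breeding values plus an independent genotype-derived component,
#' with weights solved from the configured gene x trait genetic
#' correlations against the realized between-gene genetic correlation
#' matrix.  Binary traits are thresholded on the liability scale at the
#' quantile matching the configured prevalence.
#'
#' @param cfg a [sim_config()].
#' @param geno from [simulate_genotypes()].
#' @param metadata from [simulate_structure()].
#' @param expr_truth the `truth` element of [simulate_expression()].
#' @param seed optional seed.
#' @return list: `pheno` data frame (animal_id, survived, trait columns),
#'   `truth` (trait breeding values, liability thresholds, configured rg).
#' @export
simulate_phenotypes <- function(cfg, geno, metadata, expr_truth,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(metadata)
  bv <- expr_truth$breeding_values
  batch_eff <- setNames(rnorm(cfg$n_batches, 0, 0.3),
                        paste0("batch", seq_len(cfg$n_batches)))
  pheno <- data.frame(animal_id = metadata$animal_id,
                      survived = TRUE, stringsAsFactors = FALSE)
  tbv <- matrix(0, n, cfg$n_traits,
                dimnames = list(metadata$animal_id,
                                paste0("trait", seq_len(cfg$n_traits))))
  thresholds <- rep(NA_real_, cfg$n_traits)

  for (t in seq_len(cfg$n_traits)) {
    r <- cfg$rg_matrix[, t]
    h2t <- cfg$trait_h2[t]
    used <- which(r != 0)
    Ustd <- if (length(used) > 0) {
      scale(bv[, used, drop = FALSE])  # exact sd-1 gene breeding values
    } else NULL
    # independent genetic component, residualized against the used genes
    v <- as.numeric(.genetic_values(geno$dosages, metadata$company))
    shared <- rep(0, n); var_shared <- 0
    if (length(used) > 0) {
      C <- crossprod(Ustd) / (n - 1)
      w <- tryCatch(solve(C, r[used]), error = function(e)
        stop("rg_matrix incompatible with realized gene genetic ",
             "correlations (singular submatrix for trait ", t, ")"))
      var_shared <- sum(w * r[used])
      if (var_shared > 1 + 1e-8) {
        stop("rg_matrix does not yield a PSD joint genetic covariance ",
             "for trait ", t, " (implied shared variance ",
             round(var_shared, 3), " > 1)")
      }
      shared <- as.numeric(Ustd %*% w)
      v <- resid(lm(v ~ Ustd))
    }
    v <- .scale_exact(v, 1)
    a_std <- shared + sqrt(max(0, 1 - var_shared)) * v
    a <- .scale_exact(a_std, sqrt(h2t))
    e <- .scale_exact(rnorm(n), sqrt(1 - h2t))
    liab <- batch_eff[metadata$batch] + a + e
    tbv[, t] <- a
    prev <- cfg$binary_prevalence[t]
    if (!is.na(prev)) {
      z <- (liab - mean(liab)) / sd(liab)
      thresholds[t] <- qnorm(1 - prev)
      pheno[[paste0("trait", t)]] <- as.integer(z > thresholds[t])
    } else {
      pheno[[paste0("trait", t)]] <- liab
    }
  }
  list(pheno = pheno,
       truth = list(trait_breeding_values = tbv,
                    liability_thresholds = thresholds,
                    true_rg = cfg$rg_matrix, true_trait_h2 = cfg$trait_h2))
}

#' Simulate a full cohort
#'
#' Runs structure, genotype, expression and phenotype simulation under a
#' single seed and assembles the ground truth needed for recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param counts also generate read counts.
#' @param seed seed (defaults to `cfg$seed`).
#' @return object of class `sim_cohort`.
#' @export
simulate_cohort <- function(cfg, counts = FALSE, seed = cfg$seed) {
  set.seed(seed)
  md <- simulate_structure(cfg)
  geno <- simulate_genotypes(cfg, md)
  ex <- simulate_expression(cfg, geno, md, counts = counts)
  ph <- simulate_phenotypes(cfg, geno, md, ex$truth)
  structure(list(
    config = cfg, metadata = md, genotypes = geno,
    expr = ex$expr, counts = ex$counts, annotation = ex$annotation,
    pheno = ph$pheno,
    truth = c(ex$truth, ph$truth,
              list(litter_ids = md$litter,
                   pen_ids = paste(md$batch, md$pen),
                   batch_ids = md$batch, company_ids = md$company))
  ), class = "sim_cohort")
}

#' Random gene sets in GMT-style list form
#'
#' @param gene_ids universe of gene ids.
#' @param n_sets number of sets.
#' @param size_range inclusive range of set sizes.
#' @param seed optional seed.
#' @return named list of character vectors.
#' @export
simulate_gene_sets <- function(gene_ids, n_sets = 50,
                               size_range = c(15, 100), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample(size_range[1]:min(size_range[2], length(gene_ids)),
                  n_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(gene_ids, s))
  names(sets) <- paste0("SET_", seq_len(n_sets))
  sets
}
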