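# End-to-end orchestration: simulate (optional) -> normalize -> grm ->
# h2scan -> windows -> ora -> gcscan -> gsea -> heatmap matrix.  Stage
# outputs are plain TSV with a JSON manifest recording parameters, seeds
# and input/output hashes; a stage is skipped on re-run when its recorded
# input hashes still match and its outputs are intact, so corrupting an
# intermediate re-runs that stage and its descendants.

.hash_files <- function(paths) {
  h <- as.character(tools::md5sum(paths))
  names(h) <- basename(paths)
  h
}

.stage_current <- function(manifest, name, in_hash) {
  st <- manifest$stages[[name]]
  if (is.null(st)) return(FALSE)
  if (!identical(st$input_hash, as.list(in_hash))) return(FALSE)
  outs <- unlist(st$outputs)
  if (!all(file.exists(outs))) return(FALSE)
  identical(as.list(.hash_files(outs)), st$output_hash)
}

#' Default pipeline configuration
#'
#' @param sim arguments for [sim_config()] (the demo cohort), or `NULL`
#'   when inputs are provided externally.
#' @param traits trait columns to analyze for genetic correlations.
#' @param alpha heritability significance threshold.
#' @param ora_h2_cutoff heritability cutoff defining the ORA query list.
#' @param gc_fdr FDR threshold reported for genetic correlations.
#' @param window_size,min_genes window parameters.
#' @param n_perm,gsea_min_size,gsea_max_size GSEA parameters.
#' @param n_gene_sets simulated gene-set count for the demo.
#' @param seed pipeline seed.
#' @return config list.
#' @export
pipeline_config <- function(sim = list(), traits = NULL, alpha = 0.05,
                            ora_h2_cutoff = 0.2, gc_fdr = 0.20,
                            window_size = 5e5, min_genes = 5,
                            n_perm = 1000, gsea_min_size = 3,
                            gsea_max_size = 500, n_gene_sets = 20,
                            seed = 1) {
  stopifnot(alpha > 0, alpha < 1, gc_fdr > 0, gc_fdr <= 1,
            ora_h2_cutoff >= 0, ora_h2_cutoff < 1, window_size > 0)
  list(sim = sim, traits = traits, alpha = alpha,
       ora_h2_cutoff = ora_h2_cutoff, gc_fdr = gc_fdr,
       window_size = window_size, min_genes = min_genes,
       n_perm = n_perm, gsea_min_size = gsea_min_size,
       gsea_max_size = gsea_max_size, n_gene_sets = n_gene_sets,
       seed = seed)
}

#' Bundled demonstration configuration
#'
#' A small cohort (200 animals in 4 batches from 2 companies, 100 genes,
#' 2 traits, one gene genetically correlated with trait 1) that runs the
#' full pipeline in minutes on one CPU.
#'
#' @param seed pipeline seed.
#' @param n_perm GSEA permutations.
#' @return config list for [run_pipeline()].
#' @export
demo_pipeline_config <- function(seed = 1, n_perm = 1000) {
  pipeline_config(
    sim = list(n_companies = 2, n_batches = 4, animals_per_batch = 50,
               pens_per_batch = 5, litters_per_batch = 10, n_snps = 500,
               n_genes = 100, h2_by_gene = 0.3, c2_by_gene = 0.05,
               pen_var_frac_by_gene = 0.05, wbc_effect_scale = 0.1,
               n_traits = 2, trait_h2 = 0.4,
               rg_matrix = cbind(c(0.6, rep(0, 99)), rep(0, 100))),
    n_perm = n_perm, n_gene_sets = 25, seed = seed)
}

#' Check id alignment across pipeline inputs
#'
#' @param counts a [count_matrix()].
#' @param dosages dosage matrix (animals x SNPs).
#' @param metadata metadata data frame with `animal_id`.
#' @param pheno phenotype data frame with `animal_id`.
#' @param annotation gene annotation with `gene_id`.
#' @return report list of orphan ids per category (empty when aligned).
#' @export
validate_inputs <- function(counts = NULL, dosages = NULL,
                            metadata = NULL, pheno = NULL,
                            annotation = NULL) {
  rep <- list()
  samp <- if (!is.null(counts)) colnames(counts$counts) else NULL
  geno_ids <- if (!is.null(dosages)) rownames(dosages) else NULL
  meta_ids <- if (!is.null(metadata)) metadata$animal_id else NULL
  if (!is.null(samp) && !is.null(geno_ids)) {
    rep$no_genotype <- setdiff(samp, geno_ids)
  }
  if (!is.null(samp) && !is.null(meta_ids)) {
    rep$no_metadata <- setdiff(samp, meta_ids)
  }
  if (!is.null(pheno) && !is.null(geno_ids)) {
    rep$pheno_no_genotype <- setdiff(pheno$animal_id, geno_ids)
  }
  if (!is.null(counts) && !is.null(annotation)) {
    rep$no_annotation <- setdiff(rownames(counts$counts),
                                 annotation$gene_id)
    dup <- annotation$gene_id[duplicated(annotation$gene_id)]
    rep$duplicated_gene_id <- unique(dup)
  }
  rep[lengths(rep) > 0]
}

#' Run the full analysis pipeline on a (simulated) cohort
#'
#' @param config from [pipeline_config()], or the path of a YAML file
#'   whose keys are [pipeline_config()] arguments; must include `sim`
#'   settings for the bundled demo mode.
#' @param run_dir output directory.
#' @param resume skip stages whose inputs and outputs are unchanged.
#' @return the manifest (invisibly); stage outputs under `run_dir`.
#' @export
run_pipeline <- function(config, run_dir, resume = TRUE) {
  if (is.character(config) && length(config) == 1) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(run_dir, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list(created = format(Sys.time()), seed = config$seed,
              stages = list())
  pth <- function(...) file.path(run_dir, ...)

  run_stage <- function(name, inputs, outputs, fun) {
    in_hash <- .hash_files(inputs)
    if (resume && .stage_current(manifest, name, in_hash)) {
      message("stage ", name, ": up to date, skipped")
      return(invisible(FALSE))
    }
    message("stage ", name, ": running")
    fun()
    if (!all(file.exists(outputs))) {
      stop("stage ", name, " did not produce: ",
           paste(outputs[!file.exists(outputs)], collapse = ", "))
    }
    manifest$stages[[name]] <<- list(
      input_hash = as.list(in_hash),
      outputs = as.list(outputs),
      output_hash = as.list(.hash_files(outputs)),
      time = format(Sys.time()))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(TRUE)
  }

  # -- simulate ----------------------------------------------------------
  sim_files <- pth(c("counts.tsv", "metadata.tsv", "dosages.tsv",
                     "pheno.tsv", "annotation.tsv", "gene_sets.gmt"))
  run_stage("simulate", character(), sim_files, function() {
    cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    sim <- simulate_cohort(cfg, counts = TRUE)
    write_counts_tsv(count_matrix(sim$counts), pth("counts.tsv"))
    write.table(sim$metadata, pth("metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_dosages_tsv(sim$genotypes$dosages, pth("dosages.tsv"))
    write.table(sim$pheno, pth("pheno.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$annotation, pth("annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sets <- simulate_gene_sets(rownames(sim$expr),
                               n_sets = config$n_gene_sets,
                               size_range = c(5, 30),
                               seed = config$seed + 1)
    write_gmt(sets, pth("gene_sets.gmt"))
  })

  # -- normalize ---------------------------------------------------------
  run_stage("normalize", pth("counts.tsv"), pth("expr.tsv"), function() {
    cm <- read_counts_tsv(pth("counts.tsv"))
    em <- normalize_counts(cm)
    write_expr_tsv(em, pth("expr.tsv"))
  })

  # -- grm ---------------------------------------------------------------
  run_stage("grm", pth(c("dosages.tsv", "metadata.tsv")), pth("grm.tsv"),
            function() {
    D <- read_dosages_tsv(pth("dosages.tsv"))
    md <- read.table(pth("metadata.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    gs <- genotype_set(D, md$company[match(rownames(D), md$animal_id)])
    G <- build_grm(gs)
    write_grm_tsv(G, pth("grm.tsv"))
  })

  read_md <- function() read.table(pth("metadata.tsv"), header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)
  read_expr <- function() {
    as.matrix(read.table(pth("expr.tsv"), header = TRUE, sep = "\t",
                         row.names = 1, check.names = FALSE))
  }

  # -- h2scan ------------------------------------------------------------
  run_stage("h2scan", pth(c("expr.tsv", "grm.tsv", "metadata.tsv")),
            pth("h2scan.tsv"), function() {
    expr <- read_expr(); md <- read_md()
    G <- read_grm_tsv(pth("grm.tsv"))
    G <- G[colnames(expr), colnames(expr)]
    scan <- scan_transcriptome(expr, md, G, model = "both")
    wiwo <- attr(scan, "wi_wo_cor")
    write.table(scan, pth("h2scan.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(as.list(wiwo), pth("h2scan_wiwo.json"),
                         auto_unbox = TRUE)
  })

  # -- windows -----------------------------------------------------------
  run_stage("windows", pth(c("h2scan.tsv", "annotation.tsv")),
            pth("windows.tsv"), function() {
    scan <- read.table(pth("h2scan.tsv"), header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    class(scan) <- c("h2scan", "data.frame")
    ann <- read.table(pth("annotation.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    map <- assign_windows(ann, window_size = config$window_size)
    ws <- summarize_windows(map, best_h2(scan),
                            min_genes = config$min_genes,
                            alpha = config$alpha)
    write.table(ws, pth("windows.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  # -- ora ---------------------------------------------------------------
  run_stage("ora", pth(c("h2scan.tsv", "gene_sets.gmt")),
            pth("ora.tsv"), function() {
    scan <- read.table(pth("h2scan.tsv"), header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    class(scan) <- c("h2scan", "data.frame")
    bh <- best_h2(scan)
    query <- bh$gene[bh$h2 > config$ora_h2_cutoff]
    sets <- read_gmt(pth("gene_sets.gmt"))
    res <- if (length(query) == 0) {
      data.frame(set = character(), set_size = integer(),
                 overlap = integer(), odds_ratio = numeric(),
                 p = numeric(), q = numeric())
    } else ora_fisher(query, bh$gene, sets)
    write.table(res, pth("ora.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  # -- gcscan ------------------------------------------------------------
  run_stage("gcscan",
            pth(c("expr.tsv", "grm.tsv", "metadata.tsv", "pheno.tsv",
                  "h2scan.tsv")),
            pth("gcscan.tsv"), function() {
    expr <- read_expr(); md <- read_md()
    G <- read_grm_tsv(pth("grm.tsv"))
    pheno <- read.table(pth("pheno.tsv"), header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    scan <- read.table(pth("h2scan.tsv"), header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    class(scan) <- c("h2scan", "data.frame")
    traits <- config$traits
    if (is.null(traits)) {
      traits <- grep("^trait", names(pheno), value = TRUE)
    }
    gc <- gc_scan(expr, pheno, traits, scan = scan, metadata = md,
                  G = G, alpha = config$alpha)
    write.table(gc, pth("gcscan.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  # -- gsea --------------------------------------------------------------
  run_stage("gsea", pth(c("gcscan.tsv", "gene_sets.gmt")),
            pth("gsea.tsv"), function() {
    gc <- read.table(pth("gcscan.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    sets <- read_gmt(pth("gene_sets.gmt"))
    rows <- list()
    for (tr in unique(gc$trait)) {
      d <- gc[gc$trait == tr & !is.na(gc$p) & !is.na(gc$rg), ]
      if (nrow(d) < 3) next
      rl <- rank_genes(d[c("gene", "rg", "p")])
      res <- gsea_preranked(rl, sets, n_perm = config$n_perm,
                            seed = config$seed,
                            min_size = config$gsea_min_size,
                            max_size = config$gsea_max_size)
      res$trait <- tr
      rows[[tr]] <- res
    }
    out <- do.call(rbind, rows)
    write.table(out, pth("gsea.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  # -- heatmap matrix ----------------------------------------------------
  run_stage("heatmap_matrix", pth("gsea.tsv"),
            pth("signed_matrix.tsv"), function() {
    gs <- read.table(pth("gsea.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    by_trait <- split(gs, gs$trait)
    fav <- setNames(rep(1, length(by_trait)), names(by_trait))
    sm <- signed_significance_matrix(by_trait, fav)
    df <- data.frame(set = rownames(sm$matrix), sm$matrix,
                     check.names = FALSE)
    write.table(df, pth("signed_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(sm$set_order, pth("signed_matrix_order.txt"))
  })

  invisible(jsonlite::read_json(manifest_path))
}
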