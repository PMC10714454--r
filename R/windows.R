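# Heritability summaries over non-overlapping genomic windows.
#
# Genes are assigned to fixed 0.5-Mb windows (anchored at coordinate zero,
# 0-based half-open internally) by their midpoint.  A window is flagged as
# a heritable region when it holds at least `min_genes` genes and at least
# 80% of them have significantly heritable expression; a top region
# additionally has every gene significant and mean heritability above 0.2.

#' Read a gene annotation table
#'
#' Accepts a TSV with columns gene_id, chrom, start, end (1-based
#' inclusive coordinates, as in GFF/GTF) or a GFF3/GTF file (gene
#' features; requires the rtracklayer package).
#'
#' @param path file path.
#' @param exclude_scaffolds drop sequences whose name does not look like a
#'   chromosome (`chr*`, numerals, X, Y, MT)?
#' @return data frame gene_id, chrom, start, end.
#' @export
read_gene_annotation <- function(path, exclude_scaffolds = TRUE) {
  if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF/GTF requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else gr$ID
    ann <- data.frame(gene_id = as.character(ids),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  } else {
    ann <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(ann))) {
      stop("annotation must have columns: ", paste(need, collapse = ", "))
    }
    ann <- ann[need]
  }
  if (exclude_scaffolds) {
    ok <- grepl("^(chr)?([0-9]+|X|Y|MT?)$", ann$chrom, ignore.case = TRUE)
    ann <- ann[ok, , drop = FALSE]
  }
  if (any(ann$start > ann$end)) stop("annotation has start > end")
  ann
}

#' Assign genes to non-overlapping windows
#'
#' Converts 1-based inclusive gene coordinates to a 0-based half-open
#' system and assigns each gene to the window containing its midpoint
#' (`by = "midpoint"`) or its start.  A midpoint landing exactly on a
#' window boundary belongs to the right window (half-open convention).
#'
#' @param ann annotation data frame (gene_id, chrom, start, end).
#' @param window_size window width in base pairs.
#' @param by anchor point for assignment.
#' @return data frame gene_id, chrom, window (0-based index within
#'   chromosome), win_start, win_end (0-based half-open).
#' @export
assign_windows <- function(ann, window_size = 5e5,
                           by = c("midpoint", "start")) {
  by <- match.arg(by)
  missing_chrom <- is.na(ann$chrom) | ann$chrom == ""
  if (any(missing_chrom)) {
    message(sum(missing_chrom), " gene(s) without chromosome excluded")
    ann <- ann[!missing_chrom, , drop = FALSE]
  }
  start0 <- ann$start - 1          # 0-based
  end0 <- ann$end                  # half-open
  anchor <- if (by == "midpoint") floor((start0 + end0) / 2) else start0
  win <- anchor %/% window_size
  data.frame(gene_id = ann$gene_id, chrom = ann$chrom, window = win,
             win_start = win * window_size,
             win_end = (win + 1) * window_size,
             stringsAsFactors = FALSE)
}

#' Summarize per-gene heritability by window
#'
#' @param map gene-to-window map from [assign_windows()].
#' @param h2_table data frame with columns gene, h2, p (per-gene best
#'   heritability and its p-value, e.g. from [best_h2()]).
#' @param min_genes minimum gene count for a window to be flag-eligible.
#' @param sig_frac fraction of significant genes (>=) for the
#'   heritable-region flag.
#' @param alpha significance threshold on p.
#' @param top_mean_h2 mean-h2 threshold (>) for the top-region flag.
#' @return data frame per window: chrom, window, interval, n_genes,
#'   mean_h2, frac_sig, heritable_region, top_region.
#' @export
summarize_windows <- function(map, h2_table, min_genes = 5,
                              sig_frac = 0.80, alpha = 0.05,
                              top_mean_h2 = 0.2) {
  merged <- merge(map, h2_table, by.x = "gene_id", by.y = "gene")
  key <- interaction(merged$chrom, merged$window, drop = TRUE)
  sp <- split(merged, key)
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    frac <- mean(!is.na(d$p) & d$p < alpha)
    mh2 <- mean(d$h2, na.rm = TRUE)
    data.frame(chrom = d$chrom[1], window = d$window[1],
               win_start = d$win_start[1], win_end = d$win_end[1],
               n_genes = n, mean_h2 = mh2, frac_sig = frac,
               heritable_region = n >= min_genes && frac >= sig_frac,
               top_region = n >= min_genes && frac == 1 &&
                 mh2 > top_mean_h2,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$window), ]
}
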