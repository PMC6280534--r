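#' Classify differentially expressed genes
#'
#' Three-way classification at an adjusted-p threshold: `up` when
#' `padj < alpha` and `log2fc > 0`, `down` when `padj < alpha` and
#' `log2fc < 0`, otherwise `ns`. Rows with missing `padj` are rejected
#' with a warning.
#'
#' @param table DEG table (gene, log2fc, padj).
#' @param alpha adjusted-p threshold (default 0.01).
#' @return data.table: gene, log2fc, padj, class.
#' @export
classify_degs <- function(table, alpha = 0.01) {
  dt <- as.data.table(table)
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(dt))) {
    stop("DEG table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(dt$padj))
  if (length(bad)) {
    warning(length(bad), " row(s) with missing padj rejected", call. = FALSE)
    dt <- dt[-bad]
  }
  if (any(dt$padj < 0 | dt$padj > 1)) {
    stop("padj outside [0, 1]", call. = FALSE)
  }
  dt <- dt[, .(gene, log2fc, padj)]
  dt[, class := fifelse(padj < alpha & log2fc > 0, "up",
                        fifelse(padj < alpha & log2fc < 0, "down", "ns"))]
  dt[]
}

#' Flag hypomethylated DEGs and build the four-way partition
#'
#' A DEG is hypomethylated when at least one hypo-DMR overlaps its
#' strand-aware `[TSS - up, TES + down]` regulatory window. Returns the
#' four GO-analysis groups: hypo-up, hypo-down, nonhypo-up, nonhypo-down.
#' DEG genes absent from the annotation draw a warning and are flagged
#' `FALSE`.
#'
#' @param degs classified DEG table from [classify_degs()].
#' @param dmrs DMR table with a `direction` column.
#' @param genes gene annotation (chrom, start0, end, strand, id).
#' @param up,down regulatory window sizes (defaults 2000 bp).
#' @return list: `degs` (with `hypomethylated` flag and `group`),
#'   `groups` (list of gene-id vectors), `counts`.
#' @export
flag_hypomethylated_degs <- function(degs, dmrs, genes, up = 2000L, down = 2000L) {
  degs <- as.data.table(copy(degs))
  genes <- as.data.table(genes)
  dmrs <- as.data.table(dmrs)
  hypo <- dmrs[direction == "hypo"]
  assoc <- associate_dmrs_to_genes(hypo, genes, up = up, down = down)
  hypo_genes <- assoc$genes[dmr_associated == TRUE, id]
  missing <- setdiff(degs$gene, genes$id)
  if (length(missing)) {
    warning(length(missing), " DEG gene(s) absent from annotation; flagged FALSE",
            call. = FALSE)
  }
  degs[, hypomethylated := gene %in% hypo_genes]
  degs[, group := fifelse(class == "ns", "ns",
                          paste0(fifelse(hypomethylated, "hypo", "nonhypo"),
                                 "_", class))]
  grp_names <- c("hypo_up", "hypo_down", "nonhypo_up", "nonhypo_down")
  groups <- lapply(stats::setNames(grp_names, grp_names),
                   function(g) degs[group == g, gene])
  list(degs = degs[], groups = groups,
       counts = vapply(groups, length, integer(1)))
}

#' GO term enrichment by Fisher exact test
#'
#' For each term: `k` = genes of the set carrying the term, `n` = set
#' size, `K` = background genes carrying the term, `N` = background size;
#' `fold_enrichment = (k/n) / (K/N)` (observed over expected) and the
#' two-sided Fisher p-value of `[[k, n-k], [K-k, N-n-(K-k)]]`. A term is
#' flagged enriched under the combined criteria
#' `|log2(fold_enrichment)| > fold_gate` and `p < p_gate`. Terms with no
#' background annotation are skipped with a note. No multiple-testing
#' correction is applied by default; `adjust = TRUE` adds a BH column and
#' gates on it instead.
#'
#' @param gene_set character vector of genes (subset of `background`).
#' @param background character vector of all annotated genes.
#' @param go_map data.table/data.frame with columns `gene`, `term`.
#' @param fold_gate log2 fold-enrichment gate (default 1).
#' @param p_gate p-value gate (default 0.05).
#' @param adjust apply BH across terms (default FALSE).
#' @return data.table: term, k, n, K, N, fold_enrichment, log2_fold,
#'   p_value (and `fdr` when `adjust`), enriched.
#' @export
go_enrichment <- function(gene_set, background, go_map,
                          fold_gate = 1, p_gate = 0.05, adjust = FALSE) {
  go <- as.data.table(go_map)
  if (!all(c("gene", "term") %in% names(go))) {
    stop("go_map needs columns gene, term", call. = FALSE)
  }
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% background)) {
    stop("gene_set must be a subset of background", call. = FALSE)
  }
  go <- unique(go[gene %in% background])
  N <- length(background)
  n <- length(gene_set)
  terms <- unique(go$term)
  rows <- lapply(terms, function(tm) {
    tg <- go[term == tm, gene]
    K <- length(tg)
    if (K == 0L) {
      message("term ", tm, " has no background annotation; skipped")
      return(NULL)
    }
    k <- length(intersect(tg, gene_set))
    fold <- (k / n) / (K / N)
    p <- fisher_exact_2x2(k, n - k, K - k, N - n - (K - k))
    data.table(term = tm, k = k, n = n, K = K, N = N,
               fold_enrichment = fold, log2_fold = log2(fold), p_value = p)
  })
  out <- rbindlist(rows)
  if (!nrow(out)) return(out)
  if (adjust) {
    out[, fdr := bh_adjust(p_value)]
    out[, enriched := abs(log2_fold) > fold_gate & fdr < p_gate]
  } else {
    out[, enriched := abs(log2_fold) > fold_gate & p_value < p_gate]
  }
  setorder(out, p_value)
  out[]
}
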