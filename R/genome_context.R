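#' Read gene/TE features from GFF3 or BED
#'
#' Thin wrapper over `rtracklayer::import()` that returns the package's
#' internal feature representation (0-based half-open `start0`/`end`).
#' GFF3 `type` values containing "transposable" or "repeat" (and BED names
#' starting with "te") are classed as TEs, everything else as genes.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @return data.table: chrom, start0, end, strand, kind (`gene`/`TE`), id.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path)
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  dt[strand == "*", strand := "+"]
  meta <- S4Vectors::mcols(gr)
  type <- if ("type" %in% names(meta)) as.character(meta$type) else rep("gene", nrow(dt))
  id <- if ("ID" %in% names(meta)) as.character(meta$ID)
        else if ("name" %in% names(meta)) as.character(meta$name)
        else sprintf("feat%05d", seq_len(nrow(dt)))
  dt[, kind := ifelse(grepl("transposable|repeat", type, ignore.case = TRUE) |
                        grepl("^te", id, ignore.case = TRUE), "TE", "gene")]
  dt[, id := id]
  setkey(dt, chrom, start0)
  dt[]
}

# strand-aware regulatory window [TSS - up, TES + down] as half-open interval
.gene_windows <- function(genes, up = 2000L, down = 2000L) {
  g <- as.data.table(genes)
  w <- copy(g)
  w[, `:=`(
    start0 = pmax(0L, as.integer(ifelse(strand == "+", start0 - up, start0 - down))),
    end = as.integer(ifelse(strand == "+", end + down, end + up))
  )]
  w
}

#' Associate DMRs with genes
#'
#' A gene is DMR-associated when at least one DMR overlaps (>= 1 bp,
#' half-open) its strand-aware regulatory window `[TSS - up, TES + down]`.
#' Each DMR additionally records its closest gene and the signed distance
#' to it in gene orientation (negative upstream of the TSS side, positive
#' downstream, 0 when overlapping the gene body).
#'
#' @param dmrs DMR table (chrom, start0, end).
#' @param genes gene table (chrom, start0, end, strand, id).
#' @param up,down regulatory window sizes in bp (defaults 2000).
#' @return list: `pairs` (dmr_idx, gene_id), `genes` with
#'   `dmr_associated`, `dmrs` with `closest_gene` and `signed_distance`.
#' @export
associate_dmrs_to_genes <- function(dmrs, genes, up = 2000L, down = 2000L) {
  dmrs <- .check_intervals(as.data.table(dmrs), "dmrs")
  genes <- .check_intervals(as.data.table(genes), "genes")
  win <- .gene_windows(genes, up, down)
  hits <- GenomicRanges::findOverlaps(.as_granges(dmrs), .as_granges(win))
  pairs <- data.table(dmr_idx = S4Vectors::queryHits(hits),
                      gene_id = genes$id[S4Vectors::subjectHits(hits)])
  g_out <- copy(genes)[, dmr_associated := id %in% pairs$gene_id]
  d_out <- copy(dmrs)
  d_out[, `:=`(closest_gene = NA_character_, signed_distance = NA_integer_)]
  if (nrow(genes)) {
    near <- GenomicRanges::distanceToNearest(.as_granges(dmrs), .as_granges(genes))
    qi <- S4Vectors::queryHits(near)
    si <- S4Vectors::subjectHits(near)
    dist <- S4Vectors::mcols(near)$distance
    gstrand <- genes$strand[si]
    # sign: negative when the DMR lies on the gene's 5' (TSS) side
    before <- d_out$end[qi] <= genes$start0[si]   # DMR left of gene
    after <- d_out$start0[qi] >= genes$end[si]    # DMR right of gene
    sgn <- integer(length(qi))
    sgn[before] <- ifelse(gstrand[before] == "+", -1L, 1L)
    sgn[after] <- ifelse(gstrand[after] == "+", 1L, -1L)
    d_out[qi, `:=`(closest_gene = genes$id[si],
                   signed_distance = as.integer(sgn * dist))]
  }
  list(pairs = pairs, genes = g_out[], dmrs = d_out[])
}

#' Classify DMRs into genomic element classes
#'
#' Each DMR is assigned one class by the position of its midpoint, with
#' priority `gene_body > tss_up_2kb > tes_down_2kb > intergenic`. Genome
#' background proportions apply the same priority classification to every
#' base of the genome.
#'
#' @param dmrs DMR table.
#' @param genes gene table with strands.
#' @param chrom_lengths named contig lengths (for the background).
#' @param up,down flank sizes defining `tss_up` / `tes_down` (2000 bp).
#' @return list: `classes` (per-DMR class vector), `counts`, `fractions`,
#'   and `background` (genome-wide base fractions per class).
#' @export
classify_elements <- function(dmrs, genes, chrom_lengths, up = 2000L, down = 2000L) {
  dmrs <- .check_intervals(as.data.table(dmrs), "dmrs")
  genes <- as.data.table(genes)
  tss_up <- copy(genes)
  tss_up[, `:=`(s = ifelse(strand == "+", pmax(0L, start0 - up), end),
                e = ifelse(strand == "+", start0, end + up))]
  tes_down <- copy(genes)
  tes_down[, `:=`(s = ifelse(strand == "+", end, pmax(0L, start0 - down)),
                  e = ifelse(strand == "+", end + down, start0))]
  gr_gene <- GenomicRanges::reduce(.as_granges(genes))
  gr_tss <- GenomicRanges::reduce(GenomicRanges::GRanges(
    tss_up$chrom, IRanges::IRanges(tss_up$s + 1L, tss_up$e)))
  gr_tes <- GenomicRanges::reduce(GenomicRanges::GRanges(
    tes_down$chrom, IRanges::IRanges(tes_down$s + 1L, tes_down$e)))
  # priority resolution for the background partition
  gr_tss_x <- GenomicRanges::setdiff(gr_tss, gr_gene)
  gr_tes_x <- GenomicRanges::setdiff(GenomicRanges::setdiff(gr_tes, gr_gene), gr_tss)
  total <- sum(as.numeric(chrom_lengths))
  bp <- c(gene_body = sum(as.numeric(GenomicRanges::width(gr_gene))),
          tss_up_2kb = sum(as.numeric(GenomicRanges::width(gr_tss_x))),
          tes_down_2kb = sum(as.numeric(GenomicRanges::width(gr_tes_x))))
  background <- c(bp / total, intergenic = unname(1 - sum(bp) / total))
  # midpoint classification
  mid <- (dmrs$start0 + dmrs$end) %/% 2L
  mgr <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  cls <- rep("intergenic", nrow(dmrs))
  in_tes <- GenomicRanges::countOverlaps(mgr, gr_tes) > 0
  cls[in_tes] <- "tes_down_2kb"
  in_tss <- GenomicRanges::countOverlaps(mgr, gr_tss) > 0
  cls[in_tss] <- "tss_up_2kb"
  in_gene <- GenomicRanges::countOverlaps(mgr, gr_gene) > 0
  cls[in_gene] <- "gene_body"
  lev <- c("gene_body", "tss_up_2kb", "tes_down_2kb", "intergenic")
  counts <- table(factor(cls, levels = lev))
  list(classes = cls, counts = counts,
       fractions = if (nrow(dmrs)) counts / nrow(dmrs) else counts,
       background = background[lev])
}

#' Sample length-matched random region sets
#'
#' Each draw emits one region per input DMR with the identical length
#' multiset, placed uniformly on the genome (contigs weighted by the number
#' of valid start positions); regions never extend past a contig end.
#' Reproducible by seed.
#'
#' @param dmrs DMR table supplying the length multiset.
#' @param chrom_lengths named contig lengths.
#' @param seed integer seed.
#' @param n_draws number of region sets (default 1).
#' @return data.table: draw, chrom, start0, end.
#' @export
sample_random_regions <- function(dmrs, chrom_lengths, seed = 1L, n_draws = 1L) {
  dmrs <- .check_intervals(as.data.table(dmrs), "dmrs")
  set.seed(as.integer(seed))
  widths <- dmrs$end - dmrs$start0
  if (length(widths) && max(widths) > max(chrom_lengths)) {
    stop("a region is longer than every contig", call. = FALSE)
  }
  chroms <- names(chrom_lengths)
  out <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    valid <- outer(unlist(chrom_lengths), widths, FUN = function(L, w) pmax(0, L - w + 1))
    ch_i <- vapply(seq_along(widths), function(j) {
      sample.int(length(chroms), 1L, prob = valid[, j])
    }, integer(1))
    s <- vapply(seq_along(widths), function(j) {
      as.integer(runif(1, 0, chrom_lengths[[ch_i[j]]] - widths[j]))
    }, integer(1))
    out[[d]] <- data.table(draw = d, chrom = chroms[ch_i], start0 = s,
                           end = s + widths)
  }
  rbindlist(out)
}

#' Fisher enrichment of a predicate in observed versus random regions
#'
#' Builds the 2x2 table (observed hits/misses vs random hits/misses) and
#' returns the cross-product odds ratio with the two-sided
#' [fisher_exact_2x2()] p-value.
#'
#' @param observed,random interval tables.
#' @param predicate function mapping an interval table to a logical
#'   hit/miss vector.
#' @return list: `odds_ratio`, `p_value`, `table` (2x2 matrix),
#'   `observed_fraction`, `random_fraction`.
#' @export
enrichment_test <- function(observed, random, predicate) {
  ho <- predicate(observed)
  hr <- predicate(random)
  a <- sum(ho); b <- sum(!ho); c <- sum(hr); d <- sum(!hr)
  or <- if (b * c > 0) (a * d) / (b * c) else NA_real_
  list(odds_ratio = or,
       p_value = fisher_exact_2x2(a, b, c, d),
       table = matrix(c(a, b, c, d), 2, byrow = TRUE,
                      dimnames = list(c("observed", "random"),
                                      c("hit", "miss"))),
       observed_fraction = a / max(1, a + b),
       random_fraction = c / max(1, c + d))
}

# shared binning: assigns genomic positions (0-based) around stranded
# features to metagene bins. Returns data.table(feature_idx, bin).
# Bins: 1..nf upstream flank, nf+1..nf+body body, then downstream flank.
.metagene_bins <- function(pos0, feat_idx, features, flank, body_bins, flank_bin) {
  nf <- as.integer(flank / flank_bin)
  fs <- features$start0[feat_idx]
  fe <- features$end[feat_idx]
  fstrand <- features$strand[feat_idx]
  L <- fe - fs
  d <- ifelse(fstrand == "+", pos0 - fs, fe - 1L - pos0)
  bin <- integer(length(pos0))
  up <- d < 0
  bin[up] <- nf + floor(d[up] / flank_bin) + 1L
  body <- d >= 0 & d < L
  bin[body] <- nf + 1L + floor(d[body] / L[body] * body_bins)
  bin[body] <- pmin(bin[body], nf + body_bins)
  down <- d >= L
  bin[down] <- nf + body_bins + 1L + floor((d[down] - L[down]) / flank_bin)
  keep <- bin >= 1L & bin <= 2L * nf + body_bins
  data.table(feature_idx = feat_idx[keep], bin = bin[keep],
             row = which(keep))
}

#' Metagene profile of a per-position signal or of interval density
#'
#' Features are oriented 5' to 3' (minus-strand features are reversed), the
#' body is length-normalised into `body_bins` bins and each flank is cut
#' into fixed `flank_bin`-bp bins. For per-position signals (mode
#' `"level"`) each bin reports the weighted mean of `value`; for interval
#' inputs (mode `"density"`) each bin reports the number of interval
#' midpoints per feature.
#'
#' @param signal for `"level"`: data.table(chrom, pos, value, weight)
#'   (weight defaults to 1), or a named list of such tables (one column per
#'   sample in the result); for `"density"`: an interval table
#'   (chrom, start0, end).
#' @param features stranded feature table (chrom, start0, end, strand).
#' @param flank flank size in bp (default 2000).
#' @param body_bins number of body bins (default 20).
#' @param flank_bin flank bin width in bp (default 100).
#' @param mode `"level"` or `"density"`.
#' @return data.table with `bin`, `zone` (`upstream`/`body`/`downstream`)
#'   and one value column per signal table.
#' @export
metagene_profile <- function(signal, features, flank = 2000L, body_bins = 20L,
                             flank_bin = 100L, mode = c("level", "density")) {
  mode <- match.arg(mode)
  features <- .check_intervals(as.data.table(features), "features")
  nf <- as.integer(flank / flank_bin)
  nbins <- 2L * nf + body_bins
  zone <- rep(c("upstream", "body", "downstream"), c(nf, body_bins, nf))
  out <- data.table(bin = seq_len(nbins), zone = zone)
  ext <- copy(features)[, `:=`(xstart = start0 - flank + 1L, xend = end + flank,
                               feature_idx = .I)]
  setkey(ext, chrom, xstart, xend)
  if (mode == "density") {
    iv <- .check_intervals(as.data.table(signal), "signal")
    mid <- (iv$start0 + iv$end) %/% 2L
    pts <- data.table(chrom = iv$chrom, xstart = mid + 1L, xend = mid + 1L)
    exty <- ext[, .(chrom, xstart, xend, feature_idx)]
    setkey(exty, chrom, xstart, xend)
    ov <- foverlaps(pts, exty, by.x = c("chrom", "xstart", "xend"),
                    type = "within", nomatch = NULL)
    bins <- .metagene_bins(ov$i.xstart - 1L, ov$feature_idx, features,
                           flank, body_bins, flank_bin)
    cnt <- bins[, .N, by = bin]
    out[, density := 0]
    out[cnt$bin, density := cnt$N / max(1L, nrow(features))]
    return(out[])
  }
  sigs <- if (is.data.frame(signal)) list(value = signal) else signal
  for (nm in names(sigs)) {
    sg <- as.data.table(sigs[[nm]])
    if (!"weight" %in% names(sg)) sg <- copy(sg)[, weight := 1]
    pts <- data.table(chrom = sg$chrom, xstart = sg$pos, xend = sg$pos,
                      value = sg$value, weight = sg$weight)
    exty <- ext[, .(chrom, xstart, xend, feature_idx)]
    setkey(exty, chrom, xstart, xend)
    ov <- foverlaps(pts, exty, by.x = c("chrom", "xstart", "xend"),
                    type = "within", nomatch = NULL)
    bins <- .metagene_bins(ov$i.xstart - 1L, ov$feature_idx, features,
                           flank, body_bins, flank_bin)
    vals <- data.table(bin = bins$bin, value = ov$value[bins$row],
                       weight = ov$weight[bins$row])
    prof <- vals[, .(v = sum(value * weight) / sum(weight)), by = bin]
    out[, (nm) := NA_real_]
    out[prof$bin, (nm) := prof$v]
  }
  out[]
}

#' Per-gene methylation-change matrix across metagene bins
#'
#' For every feature (row) and metagene bin (column), the difference of
#' pooled weighted methylation levels, condition B minus condition A.
#' Bins without covered cytosines are `NA`.
#'
#' @param table_a,table_b condition-pooled [methylome_table()]s.
#' @param features stranded features (typically DMR-associated genes).
#' @param context optional context filter.
#' @inheritParams metagene_profile
#' @param path optional TSV output path.
#' @return numeric matrix, rows = features (named by `id` when present),
#'   columns = bins.
#' @export
methylation_change_matrix <- function(table_a, table_b, features,
                                      context = NULL, flank = 2000L,
                                      body_bins = 20L, flank_bin = 100L,
                                      path = NULL) {
  features <- .check_intervals(as.data.table(features), "features")
  nf <- as.integer(flank / flank_bin)
  nbins <- 2L * nf + body_bins
  per_gene_bin <- function(tab) {
    dt <- as.data.table(tab)
    if (!is.null(context)) {
      ctx <- context
      dt <- dt[dt$context %in% ctx]
    }
    ext <- copy(features)[, `:=`(xstart = start0 - flank + 1L,
                                 xend = end + flank, feature_idx = .I)]
    setkey(ext, chrom, xstart, xend)
    pts <- data.table(chrom = dt$chrom, xstart = dt$pos, xend = dt$pos,
                      cc = dt$c_count, ct = dt$ct_count)
    exty <- ext[, .(chrom, xstart, xend, feature_idx)]
    setkey(exty, chrom, xstart, xend)
    ov <- foverlaps(pts, exty, by.x = c("chrom", "xstart", "xend"),
                    type = "within", nomatch = NULL)
    bins <- .metagene_bins(ov$i.xstart - 1L, ov$feature_idx, features,
                           flank, body_bins, flank_bin)
    cbind(bins, cc = ov$cc[bins$row], ct = ov$ct[bins$row])[
      , .(level = sum(cc) / sum(ct)), by = .(feature_idx, bin)]
  }
  la <- per_gene_bin(table_a)
  lb <- per_gene_bin(table_b)
  m <- matrix(NA_real_, nrow(features), nbins)
  both <- merge(la, lb, by = c("feature_idx", "bin"), suffixes = c("_a", "_b"))
  m[cbind(both$feature_idx, both$bin)] <- both$level_b - both$level_a
  rownames(m) <- if ("id" %in% names(features)) features$id else NULL
  if (!is.null(path)) {
    fwrite(as.data.table(m, keep.rownames = "id"), path, sep = "\t", na = "NA")
  }
  m
}
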