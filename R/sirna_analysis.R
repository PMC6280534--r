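#' Length-filter small RNAs and build a size histogram
#'
#' Discards reads shorter than `min_len` or longer than `max_len`, then
#' tabulates count-weighted length fractions per sample (fractions sum to
#' 1 within each sample).
#'
#' @param records small-RNA summary table
#'   (sample, length_nt, first_nt, chrom, start0, end, count).
#' @param min_len,max_len retained length range (defaults 18 and 30 nt).
#' @return list: `records` (filtered), `histogram`
#'   (sample, length_nt, count, fraction).
#' @export
length_filter_and_histogram <- function(records, min_len = 18L, max_len = 30L) {
  rec <- as.data.table(records)[length_nt >= min_len & length_nt <= max_len]
  hist <- rec[, .(count = sum(count)), by = .(sample, length_nt)]
  hist[, fraction := count / sum(count), by = sample]
  setkey(hist, sample, length_nt)
  list(records = rec[], histogram = hist[])
}

#' 5'-terminal nucleotide composition
#'
#' Count-weighted fractions of the first nucleotide among reads of one
#' length class (24 nt by default, the RdDM-associated siRNA class).
#' `U` and `T` are reported together under `"U"`.
#'
#' @param records small-RNA summary table.
#' @param length_nt read length class (default 24).
#' @return named numeric vector over `A`, `C`, `G`, `U` summing to 1.
#' @export
five_prime_composition <- function(records, length_nt = 24L) {
  ln <- length_nt
  rec <- as.data.table(records)[length_nt == ln]
  if (!nrow(rec)) stop("no reads of length ", ln, " nt", call. = FALSE)
  rec[, nt := ifelse(first_nt %in% c("T", "U"), "U", first_nt)]
  tab <- rec[, .(count = sum(count)), by = nt]
  out <- stats::setNames(rep(0, 4), c("A", "C", "G", "U"))
  out[tab$nt] <- tab$count
  out / sum(out)
}

#' Reads-per-million normalisation
#'
#' `count * 1e6 / total`, invariant under proportional rescaling of both
#' arguments.
#'
#' @param count raw mapped read count(s).
#' @param total total cleaned reads of the library.
#' @return RPM value(s).
#' @export
normalize_rpm <- function(count, total) {
  if (any(total <= 0)) stop("total cleaned reads must be > 0", call. = FALSE)
  count * 1e6 / total
}

#' Exclude siRNA clusters inside long TE bodies
#'
#' Clusters fully contained in a TE body of length >= `min_te_len` are
#' flagged `in_long_te` and removed from the canonical RdDM set (long-TE
#' body siRNAs persist independently of canonical RdDM targeting; partial
#' overlaps are retained).
#'
#' @param clusters cluster table (chrom, start0, end, ...).
#' @param tes TE feature table (chrom, start0, end).
#' @param min_te_len "long TE" threshold in bp (default 4000); `Inf`
#'   retains everything.
#' @return list: `clusters` (all, with `in_long_te`), `canonical`
#'   (retained subset).
#' @export
filter_long_te_clusters <- function(clusters, tes, min_te_len = 4000L) {
  cl <- .check_intervals(as.data.table(copy(clusters)), "clusters")
  te <- .check_intervals(as.data.table(tes), "tes")
  long_te <- te[end - start0 >= min_te_len]
  cl[, in_long_te := FALSE]
  if (nrow(long_te) && nrow(cl)) {
    hits <- GenomicRanges::findOverlaps(.as_granges(cl), .as_granges(long_te),
                                        type = "within")
    cl[unique(S4Vectors::queryHits(hits)), in_long_te := TRUE]
  }
  list(clusters = cl[], canonical = cl[in_long_te == FALSE][])
}

#' Overlap of DMRs with siRNA clusters
#'
#' A DMR is a hit when it intersects (>= 1 bp, half-open intervals) at
#' least one cluster. The hit fraction feeds [enrichment_test()] against
#' length-matched random regions.
#'
#' @param dmrs DMR table.
#' @param clusters cluster table (typically the canonical set from
#'   [filter_long_te_clusters()]).
#' @return list: `hits` (logical per DMR), `fraction`.
#' @export
cluster_dmr_overlap <- function(dmrs, clusters) {
  dmrs <- .check_intervals(as.data.table(dmrs), "dmrs")
  clusters <- .check_intervals(as.data.table(clusters), "clusters")
  hits <- rep(FALSE, nrow(dmrs))
  if (nrow(dmrs) && nrow(clusters)) {
    ov <- GenomicRanges::findOverlaps(.as_granges(dmrs), .as_granges(clusters))
    hits[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  list(hits = hits, fraction = if (nrow(dmrs)) mean(hits) else NA_real_)
}

#' siRNA abundance metaprofile around anchor regions
#'
#' Cluster abundance is spread uniformly over each cluster's bases and
#' averaged into bins around the anchors: the anchor body is scaled into
#' `body_bins` bins and each flank is cut into fixed `flank_bin`-bp bins.
#' One column is returned per abundance column, so a ripe-minus-immature
#' change profile is a column difference.
#'
#' @param clusters cluster table with one or more abundance columns.
#' @param anchors anchor interval table (e.g. hypo-DMRs).
#' @param abundance_cols names of abundance columns (default: all columns
#'   starting with `"rpm_"`).
#' @param flank flank size in bp (default 2000).
#' @param body_bins anchor-body bins (default 10).
#' @param flank_bin flank bin width in bp (default 200).
#' @return data.table with `bin`, `zone` and mean per-bp abundance per
#'   sample column.
#' @export
sirna_metaprofile <- function(clusters, anchors, abundance_cols = NULL,
                              flank = 2000L, body_bins = 10L,
                              flank_bin = 200L) {
  anchors <- .check_intervals(as.data.table(anchors), "anchors")
  if (!nrow(anchors)) stop("empty anchor set", call. = FALSE)
  cl <- .check_intervals(as.data.table(clusters), "clusters")
  if (is.null(abundance_cols)) {
    abundance_cols <- grep("^rpm_", names(cl), value = TRUE)
  }
  if (!length(abundance_cols)) stop("no abundance columns found", call. = FALSE)
  nf <- as.integer(flank / flank_bin)
  nbins <- 2L * nf + body_bins
  # anchor bin intervals, all half-open; anchors are treated as unstranded
  an <- copy(anchors)[, feature_idx := .I]
  bins_list <- lapply(seq_len(nrow(an)), function(i) {
    s <- an$start0[i]; e <- an$end[i]; L <- e - s
    ups <- s - flank + flank_bin * (seq_len(nf) - 1L)
    body_edges <- s + round(L * (0:body_bins) / body_bins)
    dns <- e + flank_bin * (seq_len(nf) - 1L)
    data.table(
      chrom = an$chrom[i],
      bstart = c(ups, head(body_edges, -1L), dns),
      bend = c(ups + flank_bin, tail(body_edges, -1L), dns + flank_bin),
      bin = seq_len(nbins)
    )
  })
  bins <- rbindlist(bins_list)
  bins <- bins[bstart < bend & bend > 0]
  bins[, bstart := pmax(0L, bstart)]
  bins[, bin_id := .I]
  setkey(bins, chrom, bstart, bend)
  clx <- cl[, c("chrom", "start0", "end", abundance_cols), with = FALSE]
  setnames(clx, c("start0", "end"), c("bstart", "bend"))
  binsy <- bins[, .(chrom, bstart, bend, bin, bin_id)]
  setkey(binsy, chrom, bstart, bend)
  ov <- foverlaps(clx, binsy, by.x = c("chrom", "bstart", "bend"),
                  type = "any", nomatch = NULL)
  out <- data.table(bin = seq_len(nbins),
                    zone = rep(c("upstream", "body", "downstream"),
                               c(nf, body_bins, nf)))
  n_anchor <- nrow(an)
  for (colnm in abundance_cols) {
    out[, (colnm) := 0]
    if (nrow(ov)) {
      ovl_w <- pmin(ov$bend, ov$i.bend) - pmax(ov$bstart, ov$i.bstart)
      per_bp <- ov[[colnm]] / (ov$i.bend - ov$i.bstart)
      contrib <- data.table(bin = ov$bin,
                            v = per_bp * ovl_w / pmax(1L, ov$bend - ov$bstart))
      agg <- contrib[, .(v = sum(v)), by = bin]
      out[agg$bin, (colnm) := agg$v / n_anchor]
    }
  }
  out[]
}

#' Naive 24-nt cluster caller for synthetic pipelines
#'
#' Merges 24-nt read intervals lying within `max_gap` bp of each other and
#' keeps merged groups with at least `min_reads` reads. This is a
#' convenience for fully synthetic runs only -- it is *not* the dedicated
#' small-RNA cluster discovery performed by tools such as ShortStack, and
#' real analyses should supply externally called clusters as BED.
#'
#' @param records small-RNA summary table.
#' @param max_gap merge distance in bp (default 100).
#' @param min_reads minimum summed count per cluster (default 5).
#' @return cluster interval table (chrom, start0, end, n_reads).
#' @export
call_sirna_clusters_naive <- function(records, max_gap = 100L, min_reads = 5L) {
  rec <- as.data.table(records)[length_nt == 24L]
  if (!nrow(rec)) {
    return(data.table(chrom = character(), start0 = integer(),
                      end = integer(), n_reads = integer()))
  }
  gr <- .as_granges(rec)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, red)
  cnt <- data.table(grp = S4Vectors::subjectHits(hits),
                    count = rec$count[S4Vectors::queryHits(hits)])
  tot <- cnt[, .(n_reads = sum(count)), by = grp]
  out <- data.table(chrom = as.character(GenomicRanges::seqnames(red)),
                    start0 = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red))[tot$grp]
  out[, n_reads := tot$n_reads]
  out[n_reads >= min_reads][order(chrom, start0)][]
}

#' Read siRNA clusters from BED with an abundance sidecar
#'
#' @param bed_path BED6 cluster intervals (name column = cluster id).
#' @param abundance_path optional TSV with `cluster_id` plus per-sample
#'   abundance columns, joined by id.
#' @return cluster data.table (chrom, start0, end, cluster_id, ...).
#' @export
read_sirna_clusters <- function(bed_path, abundance_path = NULL) {
  gr <- rtracklayer::import(bed_path)
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start0 = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   cluster_id = if (!is.null(gr$name)) as.character(gr$name)
                                else sprintf("cl%06d", seq_along(gr)))
  if (!is.null(abundance_path)) {
    ab <- fread(abundance_path)
    keep <- c("cluster_id", grep("^rpm_", names(ab), value = TRUE))
    dt <- merge(dt, ab[, keep, with = FALSE], by = "cluster_id", sort = FALSE)
    setcolorder(dt, c("chrom", "start0", "end", "cluster_id"))
  }
  setkey(dt, chrom, start0)
  dt[]
}
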