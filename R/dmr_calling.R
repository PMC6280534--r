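#' Call differentially methylated cytosines (DMCs)
#'
#' A cytosine is a DMC when it passes the all-library depth mask and its
#' methylated/unmethylated counts, pooled per condition, give a two-sided
#' Fisher exact p below `alpha`.
#'
#' @param pooled_a,pooled_b condition-pooled [methylome_table()]s on an
#'   identical cytosine catalogue (see [pool_replicates()]).
#' @param mask logical depth mask from [filter_by_depth()] (default: all).
#' @param alpha DMC significance threshold (default 0.05).
#' @return data.table of DMCs: chrom, pos, strand, context, `level_a`,
#'   `level_b`, `p_value`.
#' @export
call_dmcs <- function(pooled_a, pooled_b, mask = NULL, alpha = 0.05) {
  .check_aligned(list(pooled_a, pooled_b))
  if (is.null(mask)) mask <- rep(TRUE, nrow(pooled_a))
  dt <- data.table(
    chrom = pooled_a$chrom, pos = pooled_a$pos, strand = pooled_a$strand,
    context = pooled_a$context,
    ca = pooled_a$c_count, cta = pooled_a$ct_count,
    cb = pooled_b$c_count, ctb = pooled_b$ct_count
  )[mask & (pooled_a$ct_count + pooled_b$ct_count) > 0]
  if (!nrow(dt)) return(dt[, .(chrom, pos, strand, context,
                               level_a = numeric(0), level_b = numeric(0),
                               p_value = numeric(0))])
  dt[, p_value := fisher_exact_2x2(ca, cta - ca, cb, ctb - cb)]
  out <- dt[p_value < alpha,
            .(chrom, pos, strand, context,
              level_a = ca / cta, level_b = cb / ctb, p_value)]
  setkey(out, chrom, pos, strand)
  out[]
}

#' Sliding-window Fisher scan
#'
#' Tiles every chromosome with windows of `window` bp advanced by `step`
#' bp, pools methylated/unmethylated counts of the depth-passing cytosines
#' of each context inside each window, applies the two-sided Fisher exact
#' test between conditions, and Benjamini-Hochberg-adjusts the p-values
#' genome-wide within each context. Windows containing no covered cytosine
#' of a context are not tested (and do not enter that context's BH family).
#'
#' @inheritParams call_dmcs
#' @param window window width in bp (default 200).
#' @param step step size in bp (default 50).
#' @param chrom_lengths named contig lengths; defaults to the last covered
#'   position per contig.
#' @return data.table of tested windows: chrom, start0, end, context,
#'   pooled counts `ma, ua, mb, ub`, `p_value`, `fdr`.
#' @export
scan_windows <- function(pooled_a, pooled_b, mask = NULL,
                         window = 200L, step = 50L, chrom_lengths = NULL) {
  .check_aligned(list(pooled_a, pooled_b))
  if (is.null(mask)) mask <- rep(TRUE, nrow(pooled_a))
  cyt <- data.table(
    chrom = pooled_a$chrom, pos = pooled_a$pos, context = pooled_a$context,
    ca = pooled_a$c_count, cta = pooled_a$ct_count,
    cb = pooled_b$c_count, ctb = pooled_b$ct_count
  )[mask & (pooled_a$ct_count + pooled_b$ct_count) > 0]
  if (is.null(chrom_lengths)) {
    cl <- cyt[, .(len = max(pos)), by = chrom]
    chrom_lengths <- stats::setNames(cl$len, cl$chrom)
  }
  window <- as.integer(window); step <- as.integer(step)
  res <- list()
  for (ch in names(chrom_lengths)) {
    sub <- cyt[chrom == ch]
    if (!nrow(sub)) next
    L <- as.integer(chrom_lengths[[ch]])
    w_max <- if (L >= window) (L - window) %/% step else 0L
    pos0 <- sub$pos - 1L
    # window index range covering each cytosine
    lo <- pmax(0L, as.integer(ceiling((pos0 - window + 1L) / step)))
    hi <- pmin(w_max, pos0 %/% step)
    k <- hi - lo + 1L
    ok <- k > 0L
    if (!any(ok)) next
    idx <- rep(which(ok), k[ok])
    wi <- rep(lo[ok], k[ok]) + sequence(k[ok]) - 1L
    ex <- sub[idx][, wstart := wi * step]
    agg <- ex[, .(ma = sum(ca), ua = sum(cta - ca),
                  mb = sum(cb), ub = sum(ctb - cb)),
              by = .(context, wstart)]
    agg[, `:=`(chrom = ch, start0 = wstart,
               end = pmin(wstart + window, L))]
    res[[ch]] <- agg[, .(chrom, start0, end, context, ma, ua, mb, ub)]
  }
  win <- rbindlist(res)
  if (!nrow(win)) {
    return(data.table(chrom = character(), start0 = integer(),
                      end = integer(), context = character(),
                      ma = integer(), ua = integer(), mb = integer(),
                      ub = integer(), p_value = numeric(), fdr = numeric()))
  }
  win <- win[ma + ua + mb + ub > 0]
  win[, p_value := fisher_exact_2x2(ma, ua, mb, ub)]
  win[, fdr := bh_adjust(p_value), by = context]
  setkey(win, chrom, start0, context)
  win[]
}

#' Merge candidate windows across contexts and shrink to bounding DMCs
#'
#' Candidate windows (FDR below `fdr_cutoff` in any context) that overlap
#' or are book-ended are unioned into maximal regions; each region is then
#' trimmed to the span from its first to its last DMC (1-based inclusive
#' positions; `start0`/`end` half-open accordingly). Regions containing no
#' DMC are discarded.
#'
#' @param windows window table from [scan_windows()].
#' @param dmcs DMC table from [call_dmcs()].
#' @param fdr_cutoff candidate threshold (default 0.05).
#' @return data.table of candidate regions: chrom, start0, end, `n_dmc`,
#'   `min_fdr` (smallest window FDR inside the region).
#' @export
merge_and_shrink <- function(windows, dmcs, fdr_cutoff = 0.05) {
  cand <- as.data.table(windows)[fdr < fdr_cutoff]
  empty <- data.table(chrom = character(), start0 = integer(),
                      end = integer(), n_dmc = integer(), min_fdr = numeric())
  if (!nrow(cand)) return(empty)
  gr <- .as_granges(cand)
  red <- GenomicRanges::reduce(gr)  # merges overlapping and book-ended
  reg <- data.table(chrom = as.character(GenomicRanges::seqnames(red)),
                    start0 = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    region_id = seq_along(red))
  # smallest candidate-window FDR per merged region
  hits <- GenomicRanges::findOverlaps(gr, red)
  cand[, region_id := NA_integer_]
  cand[S4Vectors::queryHits(hits), region_id := S4Vectors::subjectHits(hits)]
  fdrs <- cand[, .(min_fdr = min(fdr)), by = region_id]
  # DMCs inside each merged region
  dm <- as.data.table(copy(dmcs))
  if (!nrow(dm)) return(empty)
  dm[, `:=`(xstart = pos, xend = pos)]
  rg <- copy(reg)[, `:=`(xstart = start0 + 1L, xend = end)]
  setkey(rg, chrom, xstart, xend)
  ov <- foverlaps(dm, rg, by.x = c("chrom", "xstart", "xend"),
                  type = "within", nomatch = NULL)
  if (!nrow(ov)) return(empty)
  shr <- ov[, .(start0 = min(pos) - 1L, end = max(pos), n_dmc = .N),
            by = .(chrom, region_id)]
  out <- shr[fdrs, on = "region_id", nomatch = NULL]
  setkey(out, chrom, start0)
  out[, region_id := NULL]
  out[]
}

#' Filter candidate regions into DMRs
#'
#' Keeps regions with at least `min_dmc` DMCs (the "more than 3" rule) and
#' an absolute mean methylation difference above `min_diff`, where the mean
#' difference is the pooled count-weighted level difference (condition B
#' minus condition A) over all depth-passing cytosines of all contexts in
#' the region. Direction is `hypo` when condition B is lower.
#'
#' @param regions output of [merge_and_shrink()].
#' @param pooled_a,pooled_b condition-pooled methylomes.
#' @param mask depth mask aligned to the pooled tables.
#' @param min_dmc minimum DMC count (default 4, i.e. `n_dmc > 3`).
#' @param min_diff minimum absolute pooled level difference (default 0.15,
#'   strict inequality).
#' @return data.table of DMRs: chrom, start0, end, n_dmc, min_fdr,
#'   mean_diff, direction, and per-context per-condition weighted levels
#'   (`lev_CG_a`, `lev_CG_b`, ...).
#' @export
filter_dmrs <- function(regions, pooled_a, pooled_b, mask = NULL,
                        min_dmc = 4L, min_diff = 0.15) {
  reg <- as.data.table(copy(regions))
  if (!nrow(reg)) {
    return(cbind(reg, data.table(mean_diff = numeric(), direction = character())))
  }
  .check_aligned(list(pooled_a, pooled_b))
  if (is.null(mask)) mask <- rep(TRUE, nrow(pooled_a))
  cyt <- data.table(
    chrom = pooled_a$chrom, pos = pooled_a$pos, context = pooled_a$context,
    ca = pooled_a$c_count, cta = pooled_a$ct_count,
    cb = pooled_b$c_count, ctb = pooled_b$ct_count
  )[mask]
  reg[, region_id := .I]
  rg <- copy(reg)[, `:=`(xstart = start0 + 1L, xend = end)]
  setkey(rg, chrom, xstart, xend)
  cyt[, `:=`(xstart = pos, xend = pos)]
  rgy <- rg[, .(chrom, xstart, xend, region_id)]
  setkey(rgy, chrom, xstart, xend)
  ov <- foverlaps(cyt, rgy, by.x = c("chrom", "xstart", "xend"),
                  type = "within", nomatch = NULL)
  stats_all <- ov[, .(
    mean_diff = sum(cb) / sum(ctb) - sum(ca) / sum(cta)
  ), by = region_id]
  lev <- ov[, .(lev_a = sum(ca) / sum(cta), lev_b = sum(cb) / sum(ctb)),
            by = .(region_id, context)]
  levw <- dcast(lev, region_id ~ context, value.var = c("lev_a", "lev_b"))
  nm <- setdiff(names(levw), "region_id")
  setnames(levw, nm, sub("^lev_(a|b)_(.*)$", "lev_\\2_\\1", nm))
  out <- reg[stats_all, on = "region_id", nomatch = NULL]
  out <- levw[out, on = "region_id"]
  out <- out[n_dmc >= min_dmc & abs(mean_diff) > min_diff]
  out[, direction := ifelse(mean_diff < 0, "hypo", "hyper")]
  out[, region_id := NULL]
  setcolorder(out, c("chrom", "start0", "end", "n_dmc", "min_fdr",
                     "mean_diff", "direction"))
  setkey(out, chrom, start0)
  out[]
}

#' Replicate-consistency robust index
#'
#' `|log2FC1 - log2FC2| / |log2FC1 + log2FC2|` across the two replicates of
#' a DMR, where `FCi` is the replicate's differential methylation fold
#' change. Identical replicate fold changes give 0; a zero denominator
#' (opposite fold changes) gives `NA`. Lower values are more credible.
#'
#' @param log2fc1,log2fc2 per-replicate log2 fold changes (vectorised).
#' @return numeric vector of robust indices (`NA` where undefined).
#' @export
#' @examples
#' robust_index(log2(0.5), log2(0.5)) # 0
#' robust_index(-2, -1)               # 1/3
#' robust_index(1, -1)                # NA
robust_index <- function(log2fc1, log2fc2) {
  den <- abs(log2fc1 + log2fc2)
  out <- abs(log2fc1 - log2fc2) / den
  out[den == 0 & abs(log2fc1 - log2fc2) > 0] <- NA_real_
  out[den == 0 & abs(log2fc1 - log2fc2) == 0] <- 0
  out
}

#' Attach per-replicate fold changes and robust indices to DMRs
#'
#' For each DMR and replicate pair, computes the replicate's weighted level
#' in each condition over the DMR, the fold change
#' `FCi = (level_B_i + epsilon) / (level_A_i + epsilon)`, and the
#' [robust_index()]. DMRs where any single library's mean depth over the
#' region falls below `depth_floor` get `NA` (low-depth rule).
#'
#' @param dmrs DMR table from [filter_dmrs()].
#' @param tables_a,tables_b lists of replicate methylomes per condition.
#' @param epsilon pseudocount on levels before the ratio (default 0.01).
#' @param depth_floor minimum mean `ct_count` per replicate over the DMR
#'   (default 4, echoing the DMC depth filter).
#' @return `dmrs` with added `log2fc_rep1`, `log2fc_rep2`, `robust_index`.
#' @export
annotate_robust_index <- function(dmrs, tables_a, tables_b,
                                  epsilon = 0.01, depth_floor = 4) {
  out <- as.data.table(copy(dmrs))
  if (!nrow(out)) {
    out[, `:=`(log2fc_rep1 = numeric(0), log2fc_rep2 = numeric(0),
               robust_index = numeric(0))]
    return(out[])
  }
  n_rep <- length(tables_a)
  stopifnot(n_rep == length(tables_b), n_rep >= 2L)
  out[, region_id := .I]
  rg <- out[, .(chrom, xstart = start0 + 1L, xend = end, region_id)]
  setkey(rg, chrom, xstart, xend)
  rep_stats <- function(tab) {
    dt <- data.table(chrom = tab$chrom, xstart = tab$pos, xend = tab$pos,
                     cc = tab$c_count, ct = tab$ct_count)
    ov <- foverlaps(dt, rg, by.x = c("chrom", "xstart", "xend"),
                    type = "within", nomatch = NULL)
    st <- ov[, .(level = sum(cc) / sum(ct), mean_depth = mean(ct)),
             by = region_id]
    full <- st[data.table(region_id = out$region_id), on = "region_id"]
    full[is.na(mean_depth), mean_depth := 0]
    full
  }
  l2fc <- matrix(NA_real_, nrow(out), n_rep)
  low <- rep(FALSE, nrow(out))
  for (r in seq_len(n_rep)) {
    sa <- rep_stats(tables_a[[r]])
    sb <- rep_stats(tables_b[[r]])
    bad <- sa$mean_depth < depth_floor | sb$mean_depth < depth_floor |
      is.na(sa$level) | is.na(sb$level)
    low <- low | bad
    okr <- !bad
    l2fc[okr, r] <- log2((sb$level[okr] + epsilon) / (sa$level[okr] + epsilon))
  }
  out[, `:=`(log2fc_rep1 = l2fc[, 1], log2fc_rep2 = l2fc[, 2])]
  out[, region_id := NULL]
  out[, robust_index := robust_index(log2fc_rep1, log2fc_rep2)]
  out[low, robust_index := NA_real_]
  out[]
}

#' Rank DMRs by robust index
#'
#' Ascending robust index (lower = more credible replicate agreement), `NA`
#' last; ties broken by smaller window FDR, then genomic order.
#'
#' @param dmrs DMR table carrying `robust_index` and `min_fdr`.
#' @param top optional `k`: return only the `k` most credible DMRs.
#' @return the reordered (optionally truncated) table.
#' @export
rank_dmrs <- function(dmrs, top = NULL) {
  out <- as.data.table(copy(dmrs))
  setorder(out, robust_index, min_fdr, chrom, start0, na.last = TRUE)
  if (!is.null(top)) out <- head(out, top)
  out[]
}

#' Full DMC/DMR calling pipeline
#'
#' Runs depth filtering, replicate pooling, DMC calling, the sliding-window
#' Fisher scan with per-context BH control, cross-context merging, DMC
#' shrinking, the DMC-count and effect-size filters, robust-index
#' annotation and ranking in one call.
#'
#' @param tables_a,tables_b lists of replicate [methylome_table()]s for
#'   condition A (e.g. immature) and condition B (e.g. ripe); all tables
#'   must share one cytosine catalogue.
#' @param window,step sliding-window geometry (defaults 200/50).
#' @param min_depth all-library depth filter (default 4).
#' @param dmc_alpha DMC Fisher threshold (default 0.05).
#' @param fdr window FDR candidate threshold (default 0.05).
#' @param min_dmc minimum DMCs per DMR (default 4).
#' @param min_diff minimum absolute pooled methylation difference (0.15).
#' @param epsilon fold-change pseudocount (default 0.01).
#' @param chrom_lengths named contig lengths for window tiling.
#' @param exclude_chroms contigs dropped before calling (e.g. the
#'   unmethylated conversion-control contig).
#' @param verbose emit per-stage counts via `message()`.
#' @return ranked DMR data.table; stage counts in `attr(, "stages")`,
#'   window and DMC tables in `attr(, "windows")` / `attr(, "dmcs")`,
#'   parameters in `attr(, "params")`.
#' @export
call_dmrs <- function(tables_a, tables_b, window = 200L, step = 50L,
                      min_depth = 4L, dmc_alpha = 0.05, fdr = 0.05,
                      min_dmc = 4L, min_diff = 0.15, epsilon = 0.01,
                      chrom_lengths = NULL, exclude_chroms = NULL,
                      verbose = FALSE) {
  drop_ctl <- function(t) {
    if (is.null(exclude_chroms)) return(t)
    methylome_table(as.data.table(t)[!chrom %in% exclude_chroms],
                    sample_id = attr(t, "sample_id"),
                    condition = attr(t, "condition"),
                    replicate = attr(t, "replicate"))
  }
  tables_a <- lapply(tables_a, drop_ctl)
  tables_b <- lapply(tables_b, drop_ctl)
  all_tabs <- c(tables_a, tables_b)
  mask <- filter_by_depth(all_tabs, min_depth = min_depth)
  pooled_a <- pool_replicates(tables_a)
  pooled_b <- pool_replicates(tables_b)
  say <- function(...) if (verbose) message(sprintf(...))
  say("depth filter: %d / %d cytosines pass (min_depth=%d in all %d libraries)",
      sum(mask), length(mask), min_depth, length(all_tabs))
  dmcs <- call_dmcs(pooled_a, pooled_b, mask, alpha = dmc_alpha)
  say("DMCs: %d at p < %g", nrow(dmcs), dmc_alpha)
  wins <- scan_windows(pooled_a, pooled_b, mask, window = window,
                       step = step, chrom_lengths = chrom_lengths)
  n_cand <- sum(wins$fdr < fdr)
  say("windows: %d tested, %d candidates at FDR < %g", nrow(wins), n_cand, fdr)
  regions <- merge_and_shrink(wins, dmcs, fdr_cutoff = fdr)
  say("merged+shrunk candidate regions: %d", nrow(regions))
  dmrs <- filter_dmrs(regions, pooled_a, pooled_b, mask,
                      min_dmc = min_dmc, min_diff = min_diff)
  say("DMRs after n_dmc >= %d and |diff| > %g: %d (%d hypo / %d hyper)",
      min_dmc, min_diff, nrow(dmrs), sum(dmrs$direction == "hypo"),
      sum(dmrs$direction == "hyper"))
  dmrs <- annotate_robust_index(dmrs, tables_a, tables_b, epsilon = epsilon,
                                depth_floor = min_depth)
  dmrs <- rank_dmrs(dmrs)
  setattr(dmrs, "stages", list(
    n_positions = length(mask), n_pass_depth = sum(mask),
    n_dmc = nrow(dmcs), n_windows_tested = nrow(wins),
    n_candidate_windows = n_cand, n_regions = nrow(regions),
    n_dmrs = nrow(dmrs),
    n_hypo = sum(dmrs$direction == "hypo"),
    n_hyper = sum(dmrs$direction == "hyper")))
  setattr(dmrs, "windows", wins)
  setattr(dmrs, "dmcs", dmcs)
  setattr(dmrs, "params", list(window = window, step = step,
                               min_depth = min_depth, dmc_alpha = dmc_alpha,
                               fdr = fdr, min_dmc = min_dmc,
                               min_diff = min_diff, epsilon = epsilon))
  dmrs[]
}

#' Compare called DMRs with a planted ground truth
#'
#' A planted DMR counts as recovered when at least one called DMR of the
#' same direction overlaps it (half-open, >= 1 bp); a called DMR counts as
#' a true positive when it overlaps a same-direction planted DMR.
#'
#' @param called called DMR table (chrom, start0, end, direction).
#' @param truth planted DMR table (chrom, start0, end, direction).
#' @return list with `sensitivity`, `precision`, `n_called`, `n_truth`,
#'   `hypo_hyper_ratio` of the calls.
#' @export
evaluate_dmr_calls <- function(called, truth) {
  called <- as.data.table(called)
  truth <- as.data.table(truth)
  ov_dir <- function(q, s) {
    if (!nrow(q) || !nrow(s)) return(rep(FALSE, nrow(q)))
    hit <- rep(FALSE, nrow(q))
    for (d in unique(q$direction)) {
      qi <- which(q$direction == d)
      si <- s[direction == d]
      if (!nrow(si)) next
      h <- GenomicRanges::findOverlaps(.as_granges(q[qi]), .as_granges(si))
      hit[qi[unique(S4Vectors::queryHits(h))]] <- TRUE
    }
    hit
  }
  sens <- if (nrow(truth)) mean(ov_dir(truth, called)) else NA_real_
  prec <- if (nrow(called)) mean(ov_dir(called, truth)) else NA_real_
  n_hypo <- sum(called$direction == "hypo")
  n_hyper <- sum(called$direction == "hyper")
  list(sensitivity = sens, precision = prec,
       n_called = nrow(called), n_truth = nrow(truth),
       hypo_hyper_ratio = if (n_hyper > 0) n_hypo / n_hyper else Inf)
}

#' Write DMRs as BED6+ and as a TSV report
#'
#' BED columns: chrom, start0, end, name, robust index (score slot), strand
#' `"."`, then n_dmc, mean_diff, direction, min window FDR and the
#' per-context levels. Output is byte-deterministic for identical inputs.
#'
#' @param dmrs ranked DMR table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dt <- as.data.table(dmrs)
  extra <- setdiff(names(dt), c("chrom", "start0", "end"))
  bed <- data.table(chrom = dt$chrom, start0 = dt$start0, end = dt$end,
                    name = sprintf("DMR%05d", seq_len(nrow(dt))),
                    score = dt$robust_index, strand = ".")
  bed <- cbind(bed, dt[, setdiff(extra, "robust_index"), with = FALSE])
  fwrite(bed, path, sep = "\t", col.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
write_dmr_tsv <- function(dmrs, path) {
  fwrite(as.data.table(dmrs), path, sep = "\t", na = "NA")
  invisible(path)
}
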