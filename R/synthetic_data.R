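#' Parameters of a synthetic two-condition methylome study
#'
#' Bundles and validates every tunable of the synthetic generator: genome
#' size and composition, context-specific methylation baselines, coverage,
#' bisulfite conversion failure, replicate structure, the planted-DMR plan,
#' the siRNA cluster plan and the DEG plan. Identical specs (same seed)
#' produce byte-identical outputs.
#'
#' Defaults describe the emulated study: genome-average methylation
#' baselines of 40/11/2 percent for CG/CHG/CHH, ~10 reads per strand of
#' coverage, >99.6 percent bisulfite conversion (failure 0.004), and two
#' replicates per condition. Hypomethylated DMRs are planted as RdDM-like
#' islands: regions that in the immature condition are methylated well above
#' the genome average in all three contexts (`dmr_baseline_levels`) and lose
#' `delta` of methylation in every context in the ripe condition.
#' Hypermethylated DMRs start at the genome baselines and gain `delta`.
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param genome_length total fruit-genome length in bp (>= 10 kb),
#'   split evenly across `n_chromosomes`.
#' @param n_chromosomes number of fruit chromosomes.
#' @param gc_content genome GC fraction.
#' @param baseline_levels named fractions, per-context genome baselines.
#' @param dmr_baseline_levels named fractions, immature-condition methylation
#'   inside planted hypo-DMRs (RdDM-target-like levels).
#' @param mean_coverage mean reads per strand per cytosine (Poisson).
#' @param conversion_failure probability an unmethylated C escapes
#'   conversion and reads as methylated.
#' @param n_replicates biological replicates per condition.
#' @param dispersion beta-binomial overdispersion `rho` in `[0, 1)` shared
#'   across contexts; 0 gives pure binomial sampling.
#' @param dmr_plan either a list
#'   `list(n_hypo=, n_hyper=, delta=, width_range=, placement=)` or an
#'   explicit data.frame of planted DMRs
#'   (`chrom, start0, end, direction, delta, placement, gene_id`).
#' @param sirna_plan list: `cluster_density` (clusters per bp of background
#'   genome), `frac_colocated` (fraction of planted hypo-DMRs that overlap a
#'   cluster), `fold_decrease` (immature/ripe abundance ratio at co-located
#'   clusters), `cluster_width` range, `mean_rpm`, `five_prime_A` (5'-A bias
#'   of 24-nt reads), `n_reads` (small-RNA summary rows per sample).
#' @param deg_plan list: `n_up`, `n_down`, `frac_hypo_linked` (fraction of
#'   DEGs carrying a planted promoter/body hypo-DMR).
#' @param gene_density,gene_width,te_density,te_width annotation layout.
#' @param control_length,control_chrom unmethylated control contig used only
#'   for conversion QC.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            genome_length = 2e6,
                            n_chromosomes = 2L,
                            gc_content = 0.4,
                            baseline_levels = c(CG = 0.40, CHG = 0.11, CHH = 0.02),
                            dmr_baseline_levels = c(CG = 0.90, CHG = 0.65, CHH = 0.35),
                            mean_coverage = 10,
                            conversion_failure = 0.004,
                            n_replicates = 2L,
                            dispersion = 0.02,
                            dmr_plan = list(n_hypo = 200L, n_hyper = 20L,
                                            delta = 0.3,
                                            width_range = c(300L, 1500L),
                                            placement = c(promoter = 0.6,
                                                          body = 0.2,
                                                          intergenic = 0.2)),
                            sirna_plan = list(cluster_density = 1 / 7000,
                                              frac_colocated = 0.7,
                                              fold_decrease = 4,
                                              cluster_width = c(150L, 400L),
                                              mean_rpm = 30,
                                              five_prime_A = 0.5,
                                              n_reads = 400L),
                            deg_plan = list(n_up = 50L, n_down = 50L,
                                            frac_hypo_linked = 0.4),
                            gene_density = 1 / 6000,
                            gene_width = c(1000L, 3000L),
                            te_density = 1 / 12000,
                            te_width = c(500L, 8000L),
                            control_length = 20000L,
                            control_chrom = "chloroplast_control") {
  stopifnot(.is_whole(seed), length(seed) == 1L)
  if (genome_length < 1e4) stop("genome_length must be >= 10 kb", call. = FALSE)
  if (mean_coverage <= 0) stop("mean_coverage must be > 0", call. = FALSE)
  fracs <- c(gc_content, baseline_levels, dmr_baseline_levels,
             conversion_failure, dispersion)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]", call. = FALSE)
  if (!all(c("CG", "CHG", "CHH") %in% names(baseline_levels))) {
    stop("baseline_levels must name CG, CHG and CHH", call. = FALSE)
  }
  if (is.list(dmr_plan) && !is.data.frame(dmr_plan)) {
    if (dmr_plan$delta < 0 || dmr_plan$delta > 1) {
      stop("dmr_plan delta must lie in [0, 1]", call. = FALSE)
    }
    need_bp <- (dmr_plan$n_hypo + dmr_plan$n_hyper) *
      (max(dmr_plan$width_range) + 1000L)
    if (need_bp > 0.8 * genome_length) {
      stop("genome too short to host dmr_plan", call. = FALSE)
    }
  }
  if (sirna_plan$frac_colocated > 1 || sirna_plan$frac_colocated < 0) {
    stop("sirna_plan frac_colocated must lie in [0, 1]", call. = FALSE)
  }
  spec <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
               n_chromosomes = as.integer(n_chromosomes), gc_content = gc_content,
               baseline_levels = baseline_levels,
               dmr_baseline_levels = dmr_baseline_levels,
               mean_coverage = mean_coverage,
               conversion_failure = conversion_failure,
               n_replicates = as.integer(n_replicates),
               dispersion = dispersion, dmr_plan = dmr_plan,
               sirna_plan = sirna_plan, deg_plan = deg_plan,
               gene_density = gene_density, gene_width = gene_width,
               te_density = te_density, te_width = te_width,
               control_length = as.integer(control_length),
               control_chrom = control_chrom)
  class(spec) <- "simulation_spec"
  spec
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "simulation_spec: %.2f Mb on %d chromosome(s) + control contig, seed %d\n",
    x$genome_length / 1e6, x$n_chromosomes, x$seed))
  cat(sprintf("  baselines CG/CHG/CHH = %.2f/%.2f/%.2f, coverage %.1fx/strand, conversion failure %.3f\n",
              x$baseline_levels["CG"], x$baseline_levels["CHG"],
              x$baseline_levels["CHH"], x$mean_coverage, x$conversion_failure))
  invisible(x)
}

#' Generate the reference sequence and cytosine catalogue
#'
#' Draws i.i.d. bases at the requested GC content for each fruit chromosome
#' and for the unmethylated control contig, then catalogues every cytosine
#' on both strands with its CG/CHG/CHH context. The catalogue is the
#' substrate of [simulate_methylome()].
#'
#' @param spec a [simulation_spec()].
#' @return list of class `sim_reference` with elements `spec`, `sequences`
#'   (named character vector), `chrom_lengths`, and `cytosines`
#'   (data.table: chrom, pos, strand, context).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(.subseed(spec$seed, 0L))
  gc <- spec$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  per <- rep(spec$genome_length %/% spec$n_chromosomes, spec$n_chromosomes)
  per[1] <- per[1] + spec$genome_length %% spec$n_chromosomes
  lens <- c(stats::setNames(per, paste0("chr", seq_len(spec$n_chromosomes))),
            stats::setNames(spec$control_length, spec$control_chrom))
  seqs <- character(length(lens))
  names(seqs) <- names(lens)
  cat_list <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    chars <- sample(names(probs), lens[i], replace = TRUE, prob = probs)
    seqs[i] <- paste(chars, collapse = "")
    cp <- which(chars == "C")
    gp <- which(chars == "G")
    dt <- data.table(
      chrom = names(lens)[i],
      pos = c(cp, gp),
      strand = rep(c("+", "-"), c(length(cp), length(gp)))
    )
    dt[, context := .classify_chars(chars, pos, strand)]
    cat_list[[i]] <- dt
  }
  cyt <- rbindlist(cat_list)
  setkey(cyt, chrom, pos, strand)
  structure(list(spec = spec, sequences = seqs, chrom_lengths = lens,
                 cytosines = cyt),
            class = "sim_reference")
}

#' Generate a gene/TE annotation for a synthetic reference
#'
#' Genes and transposable elements are laid out non-overlapping along each
#' fruit chromosome by stick-breaking the free space, with random strands.
#'
#' @param spec a [simulation_spec()].
#' @param reference result of [generate_reference()].
#' @return list with data.tables `genes` and `tes`
#'   (chrom, start0, end, strand, kind, id).
#' @export
generate_annotation <- function(spec, reference) {
  set.seed(.subseed(spec$seed, 1L))
  fruit <- setdiff(names(reference$chrom_lengths), spec$control_chrom)
  feats <- list()
  for (ch in fruit) {
    len <- reference$chrom_lengths[[ch]]
    n_g <- max(1L, round(len * spec$gene_density))
    n_t <- max(1L, round(len * spec$te_density))
    widths <- c(
      as.integer(runif(n_g, spec$gene_width[1], spec$gene_width[2])),
      as.integer(runif(n_t, spec$te_width[1], spec$te_width[2]))
    )
    kinds <- rep(c("gene", "TE"), c(n_g, n_t))
    o <- sample(length(widths))
    widths <- widths[o]; kinds <- kinds[o]
    free <- len - sum(widths)
    if (free < (length(widths) + 1L) * 200L) {
      stop("annotation does not fit on ", ch, "; lower densities", call. = FALSE)
    }
    # stick-breaking: distribute the free space into n+1 gaps
    cuts <- sort(sample.int(free - (length(widths) + 1L) * 100L,
                            length(widths), replace = TRUE))
    gaps <- diff(c(0L, cuts)) + 100L
    starts <- cumsum(gaps) + cumsum(c(0L, head(widths, -1L)))
    feats[[ch]] <- data.table(chrom = ch, start0 = starts,
                              end = starts + widths,
                              strand = sample(c("+", "-"), length(widths),
                                              replace = TRUE),
                              kind = kinds)
  }
  all <- rbindlist(feats)
  setkey(all, chrom, start0)
  all[, id := sprintf("%s%05d", ifelse(kind == "gene", "gene", "te"),
                      seq_len(.N)), by = kind]
  list(genes = all[kind == "gene"][], tes = all[kind == "TE"][])
}

#' Resolve the planted-DMR plan to genomic coordinates
#'
#' Places the requested numbers of hypo- and hyper-DMRs with widths uniform
#' in `width_range`, preferentially near genes: `promoter` placements sit in
#' the 2 kb upstream of a gene TSS (strand-aware), `body` placements inside
#' a gene, `intergenic` placements in open space. Planted DMRs are mutually
#' separated by at least 1 kb so that calls remain attributable.
#'
#' @param spec a [simulation_spec()].
#' @param reference result of [generate_reference()].
#' @param annotation result of [generate_annotation()].
#' @return data.table of planted DMRs: `dmr_id, chrom, start0, end,
#'   direction, delta, placement, gene_id` (the ground-truth table).
#' @export
plan_dmrs <- function(spec, reference, annotation) {
  if (is.data.frame(spec$dmr_plan)) {
    pl <- as.data.table(spec$dmr_plan)
    .check_intervals(pl, "dmr_plan")
    if (!"dmr_id" %in% names(pl)) pl[, dmr_id := sprintf("pdmr%04d", .I)]
    if (!"gene_id" %in% names(pl)) pl[, gene_id := NA_character_]
    return(pl[])
  }
  set.seed(.subseed(spec$seed, 2L))
  plan <- spec$dmr_plan
  n_all <- plan$n_hypo + plan$n_hyper
  if (n_all == 0L) {
    return(data.table(dmr_id = character(), chrom = character(),
                      start0 = integer(), end = integer(),
                      direction = character(), delta = numeric(),
                      placement = character(), gene_id = character()))
  }
  dirs <- rep(c("hypo", "hyper"), c(plan$n_hypo, plan$n_hyper))
  place <- sample(names(plan$placement), n_all, replace = TRUE,
                  prob = plan$placement)
  widths <- as.integer(runif(n_all, plan$width_range[1], plan$width_range[2]))
  genes <- annotation$genes
  fruit <- setdiff(names(reference$chrom_lengths), spec$control_chrom)
  # planted DMRs emulate canonical RdDM targets, which live outside long TE
  # bodies; keep them clear of TEs >= 4 kb so their siRNA clusters stay in
  # the canonical set
  long_te <- annotation$tes[end - start0 >= 4000L]
  occupied <- data.table(chrom = character(), start0 = integer(), end = integer())
  gene_pool <- sample(seq_len(nrow(genes)))
  gp_i <- 1L
  rows <- vector("list", n_all)
  min_gap <- 1000L
  for (i in seq_len(n_all)) {
    w <- widths[i]
    done <- FALSE
    for (attempt in seq_len(300L)) {
      gid <- NA_character_
      if (place[i] == "promoter") {
        if (gp_i > nrow(genes)) { place[i] <- "intergenic"; next }
        g <- genes[gene_pool[gp_i]]; gp_i <- gp_i + 1L
        off <- as.integer(runif(1, 0, 500))
        if (g$strand == "+") {
          e <- g$start0 - off; s <- e - w
        } else {
          s <- g$end + off; e <- s + w
        }
        ch <- g$chrom; gid <- g$id
      } else if (place[i] == "body") {
        g <- genes[sample.int(nrow(genes), 1L)]
        s <- g$start0 + as.integer(runif(1, 0, max(1, g$end - g$start0 - w)))
        e <- s + w; ch <- g$chrom; gid <- g$id
      } else {
        ch <- sample(fruit, 1L,
                     prob = reference$chrom_lengths[fruit])
        s <- as.integer(runif(1, 0, reference$chrom_lengths[[ch]] - w))
        e <- s + w
      }
      if (s < 0L || e > reference$chrom_lengths[[ch]]) next
      clash <- occupied[chrom == ch & start0 < e + min_gap & end > s - min_gap]
      if (nrow(clash)) next
      if (nrow(long_te[chrom == ch & start0 < e & end > s])) next
      occupied <- rbind(occupied,
                        data.table(chrom = ch, start0 = as.integer(s),
                                   end = as.integer(e)))
      rows[[i]] <- data.table(chrom = ch, start0 = as.integer(s),
                              end = as.integer(e), direction = dirs[i],
                              delta = plan$delta, placement = place[i],
                              gene_id = gid)
      done <- TRUE
      break
    }
    if (!done) stop("genome too short to host dmr_plan", call. = FALSE)
  }
  out <- rbindlist(rows)
  setkey(out, chrom, start0)
  out[, dmr_id := sprintf("pdmr%04d", .I)]
  setcolorder(out, c("dmr_id", "chrom", "start0", "end", "direction",
                     "delta", "placement", "gene_id"))
  out[]
}

#' Simulate one bisulfite-sequenced methylome
#'
#' Per catalogued cytosine: total depth is Poisson(`mean_coverage`),
#' truncated at >= 1 inside planted DMRs so the planted signal is always
#' observable; the true methylation level is the context baseline (or the
#' planted level inside a DMR), perturbed per replicate by a beta
#' distribution with overdispersion `dispersion`; observed methylated counts
#' are binomial, with conversion failure adding false-methylated reads at
#' rate `conversion_failure`. The control contig is fully unmethylated, so
#' its apparent methylation estimates the conversion failure rate.
#'
#' Planted level model: hypo-DMRs are methylated at `dmr_baseline_levels`
#' in the immature condition and at `dmr_baseline_levels - delta` (clamped
#' to `[0, 1]`) when ripe; hyper-DMRs are at genome baselines when immature
#' and gain `delta` when ripe.
#'
#' @param spec a [simulation_spec()].
#' @param reference result of [generate_reference()].
#' @param plan planted-DMR table from [plan_dmrs()].
#' @param condition `"immature"` or `"ripe"`.
#' @param replicate replicate index in `1..n_replicates`.
#' @return a [methylome_table()].
#' @export
simulate_methylome <- function(spec, reference, plan,
                               condition = c("immature", "ripe"),
                               replicate = 1L) {
  condition <- match.arg(condition)
  if (!(replicate %in% seq_len(spec$n_replicates))) {
    stop("replicate out of range", call. = FALSE)
  }
  ci <- match(condition, c("immature", "ripe"))
  set.seed(.subseed(spec$seed, 10L + 4L * (ci - 1L) + as.integer(replicate)))
  cyt <- copy(reference$cytosines)
  base <- spec$baseline_levels
  dmrb <- spec$dmr_baseline_levels
  mu <- unname(base[cyt$context])
  mu[cyt$chrom == spec$control_chrom] <- 0
  in_dmr <- rep(FALSE, nrow(cyt))
  if (nrow(plan)) {
    pp <- data.table(chrom = plan$chrom, xstart = plan$start0 + 1L,
                     xend = plan$end, j = seq_len(nrow(plan)))
    setkey(pp, chrom, xstart, xend)
    cy <- data.table(chrom = cyt$chrom, xstart = cyt$pos, xend = cyt$pos,
                     i = seq_len(nrow(cyt)))
    ov <- foverlaps(cy, pp, by.x = c("chrom", "xstart", "xend"),
                    type = "within", nomatch = NULL)
    if (nrow(ov)) {
      in_dmr[ov$i] <- TRUE
      hyp <- plan$direction[ov$j] == "hypo"
      ctx <- cyt$context[ov$i]
      lvl <- ifelse(hyp, unname(dmrb[ctx]), unname(base[ctx]))
      if (condition == "ripe") {
        lvl <- lvl + ifelse(hyp, -1, 1) * plan$delta[ov$j]
      }
      mu[ov$i] <- pmin(1, pmax(0, lvl))
    }
  }
  lam <- spec$mean_coverage
  n <- rpois(nrow(cyt), lam)
  if (any(in_dmr)) {
    # zero-truncated Poisson inside planted DMRs
    u <- runif(sum(in_dmr), min = ppois(0, lam), max = 1)
    n[in_dmr] <- qpois(u, lam)
  }
  rho <- spec$dispersion
  p_true <- mu
  if (rho > 0) {
    r <- (1 - rho) / rho
    mid <- mu > 0 & mu < 1
    p_true[mid] <- rbeta(sum(mid), mu[mid] * r, (1 - mu[mid]) * r)
  }
  p_obs <- p_true + (1 - p_true) * spec$conversion_failure
  cyt[, ct_count := n]
  cyt[, c_count := rbinom(.N, n, p_obs)]
  methylome_table(cyt,
                  sample_id = sprintf("%s_rep%d", condition, replicate),
                  condition = condition, replicate = as.integer(replicate))
}

#' Simulate siRNA clusters, small-RNA summaries, DEGs and a GO map
#'
#' Places 24-nt siRNA clusters so that exactly
#' `round(frac_colocated * n_hypo)` planted hypo-DMRs overlap at least one
#' cluster; background clusters are laid down at `cluster_density` away from
#' all planted DMRs (500 bp margin), so the non-selected hypo-DMRs stay
#' cluster-free and the planted co-location fraction is exactly recoverable.
#' Co-located clusters lose `fold_decrease`-fold abundance in the ripe
#' condition. The DEG table contains exactly `n_up + n_down` genes with
#' adjusted p < 0.01, of which `frac_hypo_linked` carry a planted hypo-DMR
#' in their regulatory window; remaining annotated genes are emitted as
#' non-significant rows. A GO map plants the term `GO:0009718`
#' (anthocyanin-biosynthesis-like) at ~5x enrichment among hypo-linked
#' up-DEGs over a 5 percent background rate.
#'
#' @param spec a [simulation_spec()].
#' @param reference result of [generate_reference()].
#' @param plan planted-DMR table from [plan_dmrs()].
#' @param annotation result of [generate_annotation()].
#' @return list with data.tables `clusters` (chrom, start0, end, cluster_id,
#'   colocated, dmr_id, and one RPM abundance column per sample),
#'   `smallrna` (sample, length_nt, first_nt, chrom, start0, end, count),
#'   `degs` (gene, log2fc, padj), `go_map` (gene, term), and ground truth
#'   `truth_degs`, `truth_clusters`.
#' @export
simulate_sirna_and_deg <- function(spec, reference, plan, annotation) {
  set.seed(.subseed(spec$seed, 3L))
  sp <- spec$sirna_plan
  hypo <- plan[direction == "hypo"]
  n_h <- nrow(hypo)
  k <- round(sp$frac_colocated * n_h)
  sel <- if (n_h) sort(sample.int(n_h, k)) else integer(0)
  cl <- list()
  # co-located clusters: centred strictly inside the selected hypo-DMRs
  if (k) {
    w <- as.integer(runif(k, sp$cluster_width[1], sp$cluster_width[2]))
    ctr <- hypo$start0[sel] +
      as.integer(runif(k, 1, hypo$end[sel] - hypo$start0[sel] - 1))
    cl[[1]] <- data.table(chrom = hypo$chrom[sel],
                          start0 = pmax(0L, ctr - w %/% 2L),
                          end = ctr + w %/% 2L + 1L,
                          colocated = TRUE, dmr_id = hypo$dmr_id[sel])
  }
  # background clusters, kept >= 500 bp away from every planted DMR
  fruit <- setdiff(names(reference$chrom_lengths), spec$control_chrom)
  bg <- list()
  for (ch in fruit) {
    len <- reference$chrom_lengths[[ch]]
    n_bg <- round(len * sp$cluster_density)
    if (!n_bg) next
    w <- as.integer(runif(n_bg, sp$cluster_width[1], sp$cluster_width[2]))
    s <- as.integer(runif(n_bg, 0, len - w))
    keep <- rep(TRUE, n_bg)
    pch <- plan[chrom == ch]
    if (nrow(pch)) {
      for (j in seq_len(nrow(pch))) {
        keep <- keep & !(s < pch$end[j] + 500L & s + w > pch$start0[j] - 500L)
      }
    }
    bg[[ch]] <- data.table(chrom = ch, start0 = s[keep], end = (s + w)[keep],
                           colocated = FALSE, dmr_id = NA_character_)
  }
  clusters <- rbindlist(c(cl, bg), use.names = TRUE)
  setkey(clusters, chrom, start0)
  clusters[, cluster_id := sprintf("cl%06d", .I)]
  n_cl <- nrow(clusters)
  base_rpm <- rlnorm(n_cl, log(sp$mean_rpm), 0.5)
  samples <- as.vector(outer(c("immature", "ripe"),
                             seq_len(spec$n_replicates),
                             function(co, r) sprintf("%s_rep%d", co, r)))
  for (s in samples) {
    ripe <- startsWith(s, "ripe")
    mu <- base_rpm
    if (ripe) mu <- ifelse(clusters$colocated, base_rpm / sp$fold_decrease, base_rpm)
    clusters[, (paste0("rpm_", s)) := mu * rlnorm(n_cl, 0, 0.1)]
  }
  # small-RNA read summaries per sample (size histogram / 5'-nt substrate)
  len_levels <- 18:30
  len_prob <- c(0.03, 0.03, 0.05, 0.25, 0.08, 0.07, 0.40, 0.02, 0.02,
                0.02, 0.01, 0.01, 0.01)
  smallrna <- rbindlist(lapply(samples, function(s) {
    nr <- sp$n_reads
    ln <- sample(len_levels, nr, replace = TRUE, prob = len_prob)
    nt <- ifelse(ln == 24L,
                 sample(c("A", "C", "G", "T"), nr, replace = TRUE,
                        prob = c(sp$five_prime_A,
                                 rep((1 - sp$five_prime_A) / 3, 3))),
                 sample(c("A", "C", "G", "T"), nr, replace = TRUE))
    src <- clusters[sample.int(max(n_cl, 1L), nr, replace = TRUE)]
    s0 <- src$start0 + as.integer(runif(nr, 0, pmax(1, src$end - src$start0 - ln)))
    data.table(sample = s, length_nt = ln, first_nt = nt, chrom = src$chrom,
               start0 = s0, end = s0 + ln, count = 1L + rpois(nr, 3))
  }))
  # DEG table
  dp <- spec$deg_plan
  genes <- annotation$genes
  linked_pool <- unique(hypo$gene_id[!is.na(hypo$gene_id)])
  n_up_l <- round(dp$frac_hypo_linked * dp$n_up)
  n_dn_l <- round(dp$frac_hypo_linked * dp$n_down)
  if (length(linked_pool) < n_up_l + n_dn_l) {
    stop("not enough hypo-DMR-linked genes for deg_plan; plant more promoter DMRs",
         call. = FALSE)
  }
  linked <- sample(linked_pool, n_up_l + n_dn_l)
  # genes whose regulatory window touches any planted hypo-DMR are never
  # used as "unlinked" DEGs, keeping the truth labels clean
  gwin <- copy(genes)[, `:=`(start0 = pmax(0L, start0 - 2000L), end = end + 2000L)]
  touch <- unique(gwin[hypo, on = .(chrom, start0 < end, end > start0),
                       nomatch = NULL]$id)
  free_pool <- setdiff(genes$id, touch)
  n_up_f <- dp$n_up - n_up_l
  n_dn_f <- dp$n_down - n_dn_l
  if (length(free_pool) < n_up_f + n_dn_f) {
    stop("not enough unlinked genes for deg_plan", call. = FALSE)
  }
  free <- sample(free_pool, n_up_f + n_dn_f)
  up_genes <- c(head(linked, n_up_l), head(free, n_up_f))
  dn_genes <- c(tail(linked, n_dn_l), tail(free, n_dn_f))
  deg_genes <- c(up_genes, dn_genes)
  other <- setdiff(genes$id, deg_genes)
  degs <- rbindlist(list(
    data.table(gene = up_genes, log2fc = runif(length(up_genes), 1.2, 4),
               padj = 10^runif(length(up_genes), -8, log10(0.009))),
    data.table(gene = dn_genes, log2fc = -runif(length(dn_genes), 1.2, 4),
               padj = 10^runif(length(dn_genes), -8, log10(0.009))),
    data.table(gene = other, log2fc = rnorm(length(other), 0, 0.25),
               padj = runif(length(other), 0.05, 1))
  ))
  truth_degs <- data.table(gene = degs$gene,
                           truth_class = c(rep("up", length(up_genes)),
                                           rep("down", length(dn_genes)),
                                           rep("ns", length(other))),
                           truth_hypo_linked = degs$gene %in% linked)
  # GO map: planted term enriched among hypo-linked up-DEGs
  planted_term <- "GO:0009718"
  terms <- c(planted_term, sprintf("GO:%07d", 1:19))
  hypo_up <- intersect(up_genes, linked)
  p_bg <- 0.05
  n_bg <- max(1L, round(p_bg * nrow(genes)))
  rows <- list()
  for (tm in terms) {
    gset <- sample(genes$id, n_bg)
    if (tm == planted_term) {
      # plant the term in an exact 25% of hypo-linked up-DEGs (5x background)
      n_pl <- ceiling(0.25 * length(hypo_up))
      gset <- union(setdiff(gset, hypo_up),
                    if (length(hypo_up)) sample(hypo_up, n_pl) else character(0))
    }
    if (length(gset)) rows[[tm]] <- data.table(gene = gset, term = tm)
  }
  go_map <- rbindlist(rows)
  list(clusters = clusters[], smallrna = smallrna, degs = degs,
       go_map = go_map, truth_degs = truth_degs,
       truth_clusters = data.table(dmr_id = hypo$dmr_id,
                                   colocated = seq_len(n_h) %in% sel))
}

#' Generate a complete synthetic study, optionally writing it to disk
#'
#' Orchestrates [generate_reference()], [generate_annotation()],
#' [plan_dmrs()], [simulate_methylome()] for every condition x replicate,
#' and [simulate_sirna_and_deg()]. When `dir` is given, all artifacts are
#' written as plain-text files (FASTA reference, GFF3 annotation, native TSV
#' methylomes, BED6 clusters plus abundance TSV, DEG/GO/truth TSVs) together
#' with a JSON manifest echoing the spec and every path.
#'
#' @param spec a [simulation_spec()].
#' @param dir optional output directory.
#' @return list of class `sim_study` with all in-memory objects (and
#'   `paths`/`manifest` when written).
#' @export
simulate_study <- function(spec, dir = NULL) {
  ref <- generate_reference(spec)
  annot <- generate_annotation(spec, ref)
  plan <- plan_dmrs(spec, ref, annot)
  conds <- c("immature", "ripe")
  meth <- list()
  for (co in conds) {
    for (r in seq_len(spec$n_replicates)) {
      meth[[sprintf("%s_rep%d", co, r)]] <-
        simulate_methylome(spec, ref, plan, co, r)
    }
  }
  aux <- simulate_sirna_and_deg(spec, ref, plan, annot)
  study <- c(list(spec = spec, reference = ref, annotation = annot,
                  truth_dmrs = plan, methylomes = meth), aux)
  class(study) <- "sim_study"
  if (!is.null(dir)) {
    study$paths <- .write_study(study, dir)
  }
  study
}

.write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  seqs <- Biostrings::DNAStringSet(study$reference$sequences)
  p$reference <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(seqs, p$reference)
  p$annotation <- file.path(dir, "annotation.gff3")
  feats <- rbind(study$annotation$genes, study$annotation$tes)
  gr <- GenomicRanges::GRanges(feats$chrom,
                               IRanges::IRanges(feats$start0 + 1L, feats$end),
                               strand = feats$strand)
  gr$type <- ifelse(feats$kind == "gene", "gene", "transposable_element")
  gr$ID <- feats$id
  rtracklayer::export(gr, p$annotation, format = "gff3")
  for (nm in names(study$methylomes)) {
    p[[paste0("methylome_", nm)]] <- file.path(dir, paste0("meth_", nm, ".tsv"))
    write_methylation_calls(study$methylomes[[nm]], p[[paste0("methylome_", nm)]])
  }
  p$clusters_bed <- file.path(dir, "sirna_clusters.bed")
  cl <- study$clusters
  bed <- data.table(cl$chrom, cl$start0, cl$end, cl$cluster_id, 0L, ".")
  fwrite(bed, p$clusters_bed, sep = "\t", col.names = FALSE)
  p$clusters_abundance <- file.path(dir, "sirna_cluster_abundance.tsv")
  fwrite(cl, p$clusters_abundance, sep = "\t")
  p$smallrna <- file.path(dir, "smallrna_reads.tsv")
  fwrite(study$smallrna, p$smallrna, sep = "\t")
  p$degs <- file.path(dir, "degs.tsv")
  fwrite(study$degs, p$degs, sep = "\t")
  p$go_map <- file.path(dir, "go_map.tsv")
  fwrite(study$go_map, p$go_map, sep = "\t")
  p$truth_dmrs <- file.path(dir, "truth_dmrs.tsv")
  fwrite(study$truth_dmrs, p$truth_dmrs, sep = "\t")
  p$truth_degs <- file.path(dir, "truth_degs.tsv")
  fwrite(study$truth_degs, p$truth_degs, sep = "\t")
  p$truth_clusters <- file.path(dir, "truth_clusters.tsv")
  fwrite(study$truth_clusters, p$truth_clusters, sep = "\t")
  manifest <- list(package = "rddmr",
                   spec = study$spec[setdiff(names(study$spec), character(0))],
                   paths = p)
  p$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  p
}
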