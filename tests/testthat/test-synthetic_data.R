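test_that("generation is deterministic by seed and sensitive to it", {
  spec <- simulation_spec(seed = 21L, genome_length = 5e4, n_chromosomes = 1L,
                          dmr_plan = list(n_hypo = 4L, n_hyper = 1L, delta = 0.3,
                                          width_range = c(300L, 800L),
                                          placement = c(promoter = 0.5, body = 0.25,
                                                        intergenic = 0.25)))
  r1 <- generate_reference(spec)
  r2 <- generate_reference(spec)
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(r1$cytosines, r2$cytosines)
  a1 <- generate_annotation(spec, r1)
  p1 <- plan_dmrs(spec, r1, a1)
  m1 <- simulate_methylome(spec, r1, p1, "ripe", 1)
  m2 <- simulate_methylome(spec, r1, p1, "ripe", 1)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  spec2 <- simulation_spec(seed = 22L, genome_length = 5e4, n_chromosomes = 1L,
                           dmr_plan = spec$dmr_plan)
  r3 <- generate_reference(spec2)
  expect_false(identical(r1$sequences, r3$sequences))
})

test_that("cytosine catalogue matches context re-classification from sequence", {
  spec <- simulation_spec(seed = 4L, genome_length = 2e4, n_chromosomes = 1L,
                          dmr_plan = list(n_hypo = 2L, n_hyper = 0L, delta = 0.3,
                                          width_range = c(300L, 500L),
                                          placement = c(promoter = 0, body = 0,
                                                        intergenic = 1)),
                          control_length = 5000L)
  ref <- generate_reference(spec)
  cyt <- ref$cytosines[chrom == "chr1"]
  redo <- classify_context(ref$sequences["chr1"], cyt$pos, cyt$strand,
                           chrom = rep("chr1", nrow(cyt)))
  expect_identical(cyt$context, redo)
  # every genuine cytosine is catalogued on both strands
  chars <- strsplit(ref$sequences[["chr1"]], "")[[1]]
  expect_equal(sum(cyt$strand == "+"), sum(chars == "C"))
  expect_equal(sum(cyt$strand == "-"), sum(chars == "G"))
})

test_that("base composition honours the requested GC content", {
  spec <- simulation_spec(seed = 8L, genome_length = 1e5, n_chromosomes = 1L,
                          gc_content = 0.4,
                          dmr_plan = list(n_hypo = 1L, n_hyper = 0L, delta = 0.3,
                                          width_range = c(300L, 500L),
                                          placement = c(promoter = 0, body = 0,
                                                        intergenic = 1)))
  ref <- generate_reference(spec)
  chars <- strsplit(ref$sequences[["chr1"]], "")[[1]]
  gc <- mean(chars %in% c("C", "G"))
  expect_lt(abs(gc - 0.4), 0.02)
})

test_that("control contig is perfectly converted when failure rate is zero", {
  spec <- simulation_spec(seed = 5L, genome_length = 2e4, n_chromosomes = 1L,
                          conversion_failure = 0,
                          dmr_plan = list(n_hypo = 1L, n_hyper = 0L, delta = 0.3,
                                          width_range = c(300L, 500L),
                                          placement = c(promoter = 0, body = 0,
                                                        intergenic = 1)))
  ref <- generate_reference(spec)
  ann <- generate_annotation(spec, ref)
  plan <- plan_dmrs(spec, ref, ann)
  m <- simulate_methylome(spec, ref, plan, "immature", 1)
  expect_equal(conversion_rate(m)$rate, 1.0)
})

test_that("simulated levels track baselines and the planted DMR model", {
  st <- tiny_study()
  spec <- st$spec
  m_imm <- st$methylomes$immature_rep1
  m_ripe <- st$methylomes$ripe_rep1
  plan <- st$truth_dmrs
  # CHH outside planted DMRs stays near its 2% baseline (+ conversion failure)
  outside <- as.data.table(m_imm)[chrom == "chr1" & context == "CHH"]
  pp <- plan[, .(chrom, start0, end)]
  ingr <- rep(FALSE, nrow(outside))
  for (j in seq_len(nrow(pp))) {
    ingr <- ingr | (outside$pos > pp$start0[j] & outside$pos <= pp$end[j])
  }
  lev_out <- sum(outside$c_count[!ingr]) / sum(outside$ct_count[!ingr])
  expect_lt(abs(lev_out - 0.02), 0.01)
  # planted hypo-DMRs: immature CG near dmr baseline, ripe CG reduced by delta
  hypo <- plan[direction == "hypo"]
  lv <- function(tab, ctx) {
    dt <- as.data.table(tab)[context == ctx]
    hit <- rep(FALSE, nrow(dt))
    for (j in seq_len(nrow(hypo))) {
      hit <- hit | (dt$chrom == hypo$chrom[j] & dt$pos > hypo$start0[j] &
                      dt$pos <= hypo$end[j])
    }
    sum(dt$c_count[hit]) / sum(dt$ct_count[hit])
  }
  expect_lt(abs(lv(m_imm, "CG") - spec$dmr_baseline_levels[["CG"]]), 0.03)
  expect_lt(abs(lv(m_ripe, "CG") -
                  (spec$dmr_baseline_levels[["CG"]] - 0.3)), 0.03)
})

test_that("genome-wide weighted levels converge to the context baselines", {
  # calibration at 2 Mb with no planted signal: within 0.5 percentage points
  spec <- simulation_spec(seed = 31L, genome_length = 2e6, n_chromosomes = 2L,
                          conversion_failure = 0,
                          dmr_plan = list(n_hypo = 0L, n_hyper = 0L, delta = 0.3,
                                          width_range = c(300L, 500L),
                                          placement = c(promoter = 0, body = 0,
                                                        intergenic = 1)))
  ref <- generate_reference(spec)
  plan <- plan_dmrs(spec, ref, generate_annotation(spec, ref))
  m <- simulate_methylome(spec, ref, plan, "immature", 1)
  fruit <- as.data.table(m)[chrom != spec$control_chrom]
  for (ctx in c("CG", "CHG", "CHH")) {
    lev <- fruit[context == ctx, sum(c_count) / sum(ct_count)]
    expect_lt(abs(lev - spec$baseline_levels[[ctx]]), 0.005)
  }
})

test_that("spec validation catches impossible worlds", {
  expect_error(simulation_spec(genome_length = 5e3), ">= 10 kb")
  expect_error(simulation_spec(mean_coverage = 0), "> 0")
  expect_error(simulation_spec(
    genome_length = 2e4,
    dmr_plan = list(n_hypo = 100L, n_hyper = 0L, delta = 0.3,
                    width_range = c(300L, 1500L),
                    placement = c(promoter = 0, body = 0, intergenic = 1))),
    "too short")
  expect_error(simulation_spec(
    sirna_plan = list(cluster_density = 1 / 7000, frac_colocated = 1.3,
                      fold_decrease = 4, cluster_width = c(150L, 400L),
                      mean_rpm = 30, five_prime_A = 0.5, n_reads = 10L)),
    "frac_colocated")
  expect_error(simulate_methylome(tiny_study()$spec, tiny_study()$reference,
                                  tiny_study()$truth_dmrs, "overripe", 1))
})

test_that("siRNA/DEG simulation honours its plan exactly", {
  st <- tiny_study()
  spec <- st$spec
  n_hypo <- sum(st$truth_dmrs$direction == "hypo")
  k <- round(spec$sirna_plan$frac_colocated * n_hypo)
  expect_equal(sum(st$truth_clusters$colocated), k)
  # exactly the selected hypo-DMRs overlap a cluster
  hypo <- st$truth_dmrs[direction == "hypo"]
  ov <- cluster_dmr_overlap(hypo, st$clusters)
  expect_equal(sum(ov$hits), k)
  expect_equal(ov$hits, st$truth_clusters$colocated)
  # co-located clusters drop ~fold_decrease in the ripe condition
  cl <- st$clusters
  ratio <- (cl$rpm_immature_rep1 + cl$rpm_immature_rep2) /
    (cl$rpm_ripe_rep1 + cl$rpm_ripe_rep2)
  expect_gt(median(ratio[cl$colocated]), 3)
  expect_lt(median(ratio[!cl$colocated]), 1.3)
  # DEG table: exactly n_up + n_down significant rows, linked fraction exact
  dp <- spec$deg_plan
  sig <- st$degs[padj < 0.01]
  expect_equal(nrow(sig), dp$n_up + dp$n_down)
  expect_equal(sum(sig$log2fc > 0), dp$n_up)
  tr <- st$truth_degs
  expect_equal(sum(tr$truth_hypo_linked & tr$truth_class != "ns"),
               round(dp$frac_hypo_linked * dp$n_up) +
                 round(dp$frac_hypo_linked * dp$n_down))
})

test_that("simulate_study writes a readable, manifest-described file set", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(seed = 13L, genome_length = 8e4, n_chromosomes = 1L,
                          dmr_plan = list(n_hypo = 5L, n_hyper = 1L, delta = 0.3,
                                          width_range = c(300L, 600L),
                                          placement = c(promoter = 1, body = 0,
                                                        intergenic = 0)),
                          deg_plan = list(n_up = 2L, n_down = 2L,
                                          frac_hypo_linked = 0.5))
  st <- simulate_study(spec, dir = dir)
  expect_true(all(file.exists(unlist(st$paths))))
  man <- jsonlite::read_json(st$paths$manifest)
  expect_equal(man$spec$seed, 13L)
  # methylome TSV round-trips
  back <- read_methylation_calls(st$paths$methylome_immature_rep1)
  expect_equal(as.data.frame(back)[, -1],
               as.data.frame(st$methylomes$immature_rep1)[, -1])
  expect_equal(back$chrom, st$methylomes$immature_rep1$chrom)
  # annotation round-trips through the GFF3 reader
  feats <- read_features(st$paths$annotation)
  expect_equal(sum(feats$kind == "gene"), nrow(st$annotation$genes))
  expect_equal(sum(feats$kind == "TE"), nrow(st$annotation$tes))
  expect_setequal(feats[kind == "gene", id], st$annotation$genes$id)
  # cluster BED + abundance sidecar round-trips
  cl <- read_sirna_clusters(st$paths$clusters_bed, st$paths$clusters_abundance)
  expect_equal(nrow(cl), nrow(st$clusters))
  expect_true(all(grepl("^rpm_", setdiff(names(cl),
                                         c("chrom", "start0", "end", "cluster_id")))))
})
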