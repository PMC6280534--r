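test_that("gene association respects the strand-aware 2 kb windows", {
  genes <- data.table(chrom = "chr1", start0 = 5000L, end = 7000L,
                      strand = "+", id = "g1")
  # 1.5 kb upstream of the TSS: associated
  a1 <- associate_dmrs_to_genes(
    data.table(chrom = "chr1", start0 = 3300L, end = 3600L), genes)
  expect_true(a1$genes$dmr_associated)
  # 2.5 kb upstream: not associated
  a2 <- associate_dmrs_to_genes(
    data.table(chrom = "chr1", start0 = 2400L, end = 2500L), genes)
  expect_false(a2$genes$dmr_associated)
  expect_equal(a2$dmrs$closest_gene, "g1")
  expect_lt(a2$dmrs$signed_distance, 0)  # upstream of the TSS
  # minus-strand gene: just beyond the right coordinate end is upstream
  genes_m <- data.table(chrom = "chr1", start0 = 5000L, end = 7000L,
                        strand = "-", id = "g1")
  a3 <- associate_dmrs_to_genes(
    data.table(chrom = "chr1", start0 = 7100L, end = 7200L), genes_m)
  expect_true(a3$genes$dmr_associated)
  expect_lt(a3$dmrs$signed_distance, 0)
})

test_that("association is symmetric under strand flip plus coordinate mirror", {
  set.seed(12)
  L <- 100000L
  genes <- data.table(chrom = "chr1",
                      start0 = as.integer(runif(15, 0, L - 4000)),
                      strand = sample(c("+", "-"), 15, TRUE),
                      id = sprintf("g%02d", 1:15))
  genes[, end := start0 + as.integer(runif(15, 500, 3000))]
  dmrs <- data.table(chrom = "chr1",
                     start0 = as.integer(runif(40, 0, L - 1000)))
  dmrs[, end := start0 + as.integer(runif(40, 100, 900))]
  mirror <- function(x) {
    y <- copy(x)[, `:=`(start0 = L - end, end = L - start0)]
    if ("strand" %in% names(y)) {
      y[, strand := ifelse(strand == "+", "-", "+")]
    }
    y
  }
  a <- associate_dmrs_to_genes(dmrs, genes)
  b <- associate_dmrs_to_genes(mirror(dmrs), mirror(genes))
  expect_equal(a$genes[order(id), dmr_associated],
               b$genes[order(id), dmr_associated])
  expect_equal(sort(paste(a$pairs$dmr_idx, a$pairs$gene_id)),
               sort(paste(b$pairs$dmr_idx, b$pairs$gene_id)))
})

test_that("element classification uses midpoints with the stated priority", {
  genes <- data.table(chrom = "chr1",
                      start0 = c(10000L, 16000L), end = c(12000L, 18000L),
                      strand = c("+", "-"), id = c("g1", "g2"))
  lens <- c(chr1 = 50000L)
  # midpoint inside a gene body
  r1 <- classify_elements(data.table(chrom = "chr1", start0 = 10500L,
                                     end = 11500L), genes, lens)
  expect_equal(r1$classes, "gene_body")
  # region between the genes: tss_up of g1? No: between g1 end (12000) and
  # g2 start; g2 is minus strand so its TSS flank is right of 18000; the
  # interval [12000,14000) is tes_down of g1 and tes_down of g2 -> tes class;
  # [14000,16000) is tes_down of g2 only
  r2 <- classify_elements(data.table(chrom = "chr1", start0 = 12100L,
                                     end = 12300L), genes, lens)
  expect_equal(r2$classes, "tes_down_2kb")
  # upstream of g1 (plus strand): tss_up beats tes_down when both apply
  genes2 <- data.table(chrom = "chr1",
                       start0 = c(10000L, 5000L), end = c(12000L, 7000L),
                       strand = c("+", "+"), id = c("g1", "g0"))
  r3 <- classify_elements(data.table(chrom = "chr1", start0 = 8400L,
                                     end = 8600L), genes2, lens)
  expect_equal(r3$classes, "tss_up_2kb")
  # fractions and background each sum to 1
  many <- data.table(chrom = "chr1",
                     start0 = seq(0L, 45000L, by = 5000L))
  many[, end := start0 + 400L]
  r4 <- classify_elements(many, genes, lens)
  expect_equal(sum(r4$fractions), 1)
  expect_equal(sum(r4$background), 1)
  expect_true(all(r4$background >= 0))
})

test_that("random regions match the DMR length multiset and the seed", {
  dmrs <- data.table(chrom = "chr1", start0 = c(0L, 1000L, 5000L),
                     end = c(700L, 1900L, 5100L))
  lens <- c(chr1 = 40000L, chr2 = 20000L)
  r1 <- sample_random_regions(dmrs, lens, seed = 9L, n_draws = 3L)
  r2 <- sample_random_regions(dmrs, lens, seed = 9L, n_draws = 3L)
  expect_identical(r1, r2)
  for (d in 1:3) {
    expect_setequal(r1[draw == d, end - start0], dmrs$end - dmrs$start0)
  }
  expect_true(all(r1$start0 >= 0))
  expect_true(all(r1$end <= lens[r1$chrom]))
  expect_error(sample_random_regions(
    data.table(chrom = "chr1", start0 = 0L, end = 90000L), lens, seed = 1),
    "longer than every contig")
})

test_that("random placement hits TSS flanks at their analytic genome fraction", {
  set.seed(5)
  lens <- c(chr1 = 200000L)
  genes <- data.table(chrom = "chr1", start0 = seq(10000L, 190000L, 20000L))
  genes[, `:=`(end = start0 + 2000L, strand = "+",
               id = sprintf("g%02d", .I))]
  # point-like query regions; hit = midpoint in a tss_up flank
  dmrs <- data.table(chrom = "chr1", start0 = rep(0L, 50), end = rep(2L, 50))
  draws <- sample_random_regions(dmrs, lens, seed = 33L, n_draws = 40L)
  cls <- classify_elements(draws, genes, lens)
  got <- mean(cls$classes == "tss_up_2kb")
  expected <- cls$background[["tss_up_2kb"]]
  se <- sqrt(expected * (1 - expected) / nrow(draws))
  expect_lt(abs(got - expected), 3 * se)
})

test_that("enrichment_test reproduces the cross-product odds ratio", {
  obs <- data.table(chrom = "chr1", start0 = 0:99 * 10L, end = 0:99 * 10L + 5L)
  hit_obs <- c(rep(TRUE, 67), rep(FALSE, 33))
  hit_rnd <- c(rep(TRUE, 17), rep(FALSE, 83))
  fake_pred <- local({
    i <- 0L
    function(x) {
      i <<- i + 1L
      if (i == 1L) hit_obs else hit_rnd
    }
  })
  r <- enrichment_test(obs, obs, fake_pred)
  expect_equal(r$odds_ratio, (67 * 83) / (33 * 17), tolerance = 1e-12)
  expect_equal(r$p_value, oracle_fisher_p(67, 33, 17, 83), tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)
  # identical compositions: OR 1, p 1
  r2 <- enrichment_test(obs, obs, function(x) c(rep(TRUE, 50), rep(FALSE, 50)))
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_value, 1)
})

test_that("metagene profiles are flat for uniform signal and oriented 5'->3'", {
  genes <- data.table(chrom = "chr1", start0 = c(5000L, 20000L),
                      end = c(9000L, 24000L), strand = c("+", "-"),
                      id = c("g1", "g2"))
  sig <- data.table(chrom = "chr1", pos = 1:30000, value = 0.5, weight = 1)
  prof <- metagene_profile(sig, genes)
  expect_equal(max(prof$value) - min(prof$value), 0, tolerance = 1e-13)
  expect_equal(nrow(prof), 60L)  # 20 + 20 + 20 bins
  # minus-strand gene with signal only at its TSS-proximal (right) end
  sig2 <- data.table(chrom = "chr1", pos = 1:30000, value = 0, weight = 1)
  sig2[pos >= 23800 & pos < 24000, value := 1]
  gm <- genes[id == "g2"]
  prof2 <- metagene_profile(sig2, gm)
  body <- prof2[zone == "body"]
  expect_equal(which.max(body$value), 1L)  # peak at the 5' body edge
})

test_that("DMR density profiles peak upstream when planted in promoters", {
  spec <- simulation_spec(seed = 17L, genome_length = 3e5, n_chromosomes = 1L,
                          dmr_plan = list(n_hypo = 15L, n_hyper = 0L, delta = 0.3,
                                          width_range = c(300L, 800L),
                                          placement = c(promoter = 1, body = 0,
                                                        intergenic = 0)))
  ref <- generate_reference(spec)
  ann <- generate_annotation(spec, ref)
  plan <- plan_dmrs(spec, ref, ann)
  prof <- metagene_profile(plan, ann$genes, mode = "density")
  expect_equal(prof$zone[which.max(prof$density)], "upstream")
})

test_that("methylation change matrix is zero for identical conditions", {
  st <- tiny_study()
  genes <- st$annotation$genes[1:10]
  m <- methylation_change_matrix(st$methylomes$immature_rep1,
                                 st$methylomes$immature_rep1, genes)
  expect_equal(nrow(m), 10L)
  expect_true(all(m[!is.na(m)] == 0))
  # hypo-planted promoters: upstream bins go negative between conditions
  assoc_genes <- st$annotation$genes[
    id %in% st$truth_dmrs[direction == "hypo" & placement == "promoter", gene_id]]
  pa <- pool_replicates(st$methylomes[c("immature_rep1", "immature_rep2")])
  pb <- pool_replicates(st$methylomes[c("ripe_rep1", "ripe_rep2")])
  m2 <- methylation_change_matrix(pa, pb, assoc_genes)
  up_cols <- 1:20
  expect_lt(min(m2[, up_cols], na.rm = TRUE), -0.2)
})
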