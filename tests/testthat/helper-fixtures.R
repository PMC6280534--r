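# Fixture builders shared across test files. Everything is generated in
# code; no data files are read.

suppressMessages(library(data.table))

# tiny methylome table from parallel vectors
make_calls <- function(chrom = "chr1", pos, strand = "+", context = "CG",
                       c_count, ct_count, sample_id = "s",
                       condition = NA_character_, replicate = NA_integer_) {
  n <- length(pos)
  methylome_table(
    data.table(chrom = rep_len(chrom, n), pos = pos,
               strand = rep_len(strand, n), context = rep_len(context, n),
               c_count = rep_len(c_count, n), ct_count = rep_len(ct_count, n)),
    sample_id = sample_id, condition = condition, replicate = replicate
  )
}

# one small synthetic study, generated once per test session
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- simulation_spec(
        seed = 11L, genome_length = 3e5, n_chromosomes = 1L,
        dmr_plan = list(n_hypo = 20L, n_hyper = 4L, delta = 0.3,
                        width_range = c(300L, 1500L),
                        placement = c(promoter = 0.6, body = 0.2,
                                      intergenic = 0.2)),
        sirna_plan = list(cluster_density = 1 / 7000, frac_colocated = 0.7,
                          fold_decrease = 4, cluster_width = c(150L, 400L),
                          mean_rpm = 30, five_prime_A = 0.5, n_reads = 400L),
        deg_plan = list(n_up = 8L, n_down = 8L, frac_hypo_linked = 0.5))
      cache <<- simulate_study(spec)
    }
    cache
  }
})

tiny_dmr_call <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- tiny_study()
      cache <<- call_dmrs(
        st$methylomes[c("immature_rep1", "immature_rep2")],
        st$methylomes[c("ripe_rep1", "ripe_rep2")],
        exclude_chroms = st$spec$control_chrom)
    }
    cache
  }
})

# independent brute-force two-sided Fisher p for one table, via log-choose
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || k == m + n2) return(1)
  js <- max(0, k - n2):min(k, m)
  logdens <- lchoose(m, js) + lchoose(n2, k - js) - lchoose(m + n2, k)
  dens <- exp(logdens)
  min(1, sum(dens[dens <= dens[js == a] * (1 + 1e-7)]))
}

# independent BH oracle: sequential step-up from the largest p
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  adj[m] <- min(1, ps[m])
  if (m > 1) {
    for (i in (m - 1):1) adj[i] <- min(adj[i + 1], ps[i] * m / i)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
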