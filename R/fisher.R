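#' Two-sided Fisher exact test for 2x2 tables
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]`, computed by
#' summing all hypergeometric point probabilities that do not exceed the
#' probability of the observed table (with the customary `1 + 1e-7` relative
#' tolerance for floating-point ties). This is the probability-ordering
#' definition used throughout the DMC/DMR caller and the enrichment tests.
#'
#' All four arguments are recycled to a common length; duplicate tables are
#' computed once, so the function is cheap to call on genome-scale vectors.
#'
#' @param a,b,c,d non-negative integer counts; `a`,`b` form the first row
#'   (e.g. methylated/unmethylated in condition A) and `c`,`d` the second.
#' @return numeric vector of two-sided p-values.
#' @export
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10) # 2 / choose(20, 10)
#' fisher_exact_2x2(5, 5, 5, 5)   # 1
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  if (n == 0L) return(numeric(0))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  for (v in list(a, b, c, d)) {
    if (!.is_whole(v)) stop("table entries must be non-negative integers", call. = FALSE)
    if (any(v < 0)) stop("table entries must be non-negative", call. = FALSE)
  }
  if (any(a + b + c + d == 0)) {
    stop("at least one margin must be nonzero", call. = FALSE)
  }
  dt <- data.table(a = as.integer(round(a)), b = as.integer(round(b)),
                   c = as.integer(round(c)), d = as.integer(round(d)))
  u <- unique(dt)
  u[, p_value := vapply(seq_len(.N), function(i) {
    .fisher_p1(u$a[i], u$b[i], u$c[i], u$d[i])
  }, numeric(1))]
  # join u back onto dt so the result follows dt's row order
  u[dt, on = c("a", "b", "c", "d"), x.p_value]
}

# single-table worker; margins: m = a+b, n2 = c+d, k = a+c
.fisher_p1 <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  if (m == 0L || n2 == 0L || k == 0L || k == m + n2) return(1)
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n2, k)
  p <- sum(dens[dens <= dens[a - lo + 1L] * (1 + 1e-7)])
  min(1, p)
}
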