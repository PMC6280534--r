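# Internal helpers shared across modules.
#
# Positions (`pos`) are 1-based; intervals (`start0`, `end`) are 0-based
# half-open. These two helpers are the only place the conversion happens.

pos_to_start0 <- function(pos) as.integer(pos) - 1L

start0_to_pos <- function(start0) as.integer(start0) + 1L

# data.table(chrom, start0, end) -> GRanges (1-based closed, as GRanges wants)
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start0 + 1L, end = x$end)
  )
}

.check_intervals <- function(x, what = "interval table") {
  need <- c("chrom", "start0", "end")
  if (!all(need %in% names(x))) {
    stop(what, " must have columns chrom, start0, end", call. = FALSE)
  }
  if (nrow(x) && any(x$start0 >= x$end)) {
    stop(what, " has start0 >= end (0-based half-open expected)", call. = FALSE)
  }
  invisible(x)
}

.is_whole <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < 1e-8)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted p-values are multiplied by `m / rank` and
#' a running minimum is taken from the largest p downwards, capped at 1.
#' Identical in value to `stats::p.adjust(method = "BH")`; re-exposed here so
#' the window-scan FDR is an explicit, testable primitive.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of BH-adjusted p-values, same order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (anyNA(p)) stop("NA p-values are not supported", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]", call. = FALSE)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1L)))
  adj[ro]
}

# deterministic small sub-seed derived from a user seed; keeps within 2^31
.subseed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
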