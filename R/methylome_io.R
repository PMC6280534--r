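#' Construct a per-cytosine methylome table
#'
#' A `MethylomeTable` is a `data.table` with columns `chrom`, `pos`
#' (1-based), `strand` (`+`/`-`), `context` (`CG`/`CHG`/`CHH`), `c_count`
#' (methylated reads) and `ct_count` (total informative reads), sorted by
#' `(chrom, pos, strand)`, carrying `sample_id`, `condition` and `replicate`
#' attributes.
#'
#' @param calls data.frame with the six columns above.
#' @param sample_id sample identifier.
#' @param condition condition label (e.g. `"immature"` or `"ripe"`).
#' @param replicate replicate index.
#' @return a `MethylomeTable` (also a `data.table`).
#' @export
methylome_table <- function(calls, sample_id = "sample", condition = NA_character_,
                            replicate = NA_integer_) {
  dt <- as.data.table(calls)
  need <- c("chrom", "pos", "strand", "context", "c_count", "ct_count")
  if (!all(need %in% names(dt))) {
    stop("methylation calls need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  dt <- dt[, need, with = FALSE]
  bad <- .validate_calls(dt)
  if (length(bad)) {
    stop("invalid methylation calls at row(s): ",
         paste(head(bad, 20L), collapse = ", "),
         if (length(bad) > 20L) " ..." else "", call. = FALSE)
  }
  dt[, `:=`(pos = as.integer(pos), c_count = as.integer(c_count),
            ct_count = as.integer(ct_count),
            chrom = as.character(chrom), strand = as.character(strand),
            context = as.character(context))]
  setkey(dt, chrom, pos, strand)
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand"))) {
    stop("duplicated (chrom, pos, strand) in methylation calls", call. = FALSE)
  }
  setattr(dt, "sample_id", sample_id)
  setattr(dt, "condition", condition)
  setattr(dt, "replicate", replicate)
  setattr(dt, "class", c("MethylomeTable", class(dt)))
  dt[]
}

# returns indices of invalid rows
.validate_calls <- function(dt) {
  bad <- dt[, which(
    is.na(pos) | pos < 1 |
      !(strand %in% c("+", "-")) |
      !(context %in% c("CG", "CHG", "CHH")) |
      is.na(c_count) | is.na(ct_count) |
      c_count < 0 | ct_count < 0 | c_count > ct_count
  )]
  bad
}

#' @export
print.MethylomeTable <- function(x, ...) {
  cat(sprintf(
    "MethylomeTable '%s' (condition=%s, replicate=%s): %d cytosines on %d contig(s)\n",
    attr(x, "sample_id"), attr(x, "condition"), attr(x, "replicate"),
    nrow(x), length(unique(x$chrom))
  ))
  NextMethod()
}

#' Read per-cytosine methylation calls
#'
#' Reads a methylation call file into a validated, sorted [methylome_table()].
#' Two dialects are supported: `"native"`, a tab-separated file with header
#' `chrom pos strand context c_count ct_count`, and `"cx"`, a CX-report-like
#' headerless file with columns
#' `chrom pos strand count_methylated count_unmethylated context trinucleotide`.
#' Malformed rows (counts inconsistent, unknown context or strand token) are
#' rejected with their file line numbers.
#'
#' @param path file path (plain text or gzip, anything `fread` accepts).
#' @param dialect `"native"` or `"cx"`.
#' @param sample_id,condition,replicate metadata stored on the result.
#' @return a `MethylomeTable`.
#' @export
read_methylation_calls <- function(path, dialect = c("native", "cx"),
                                   sample_id = basename(path),
                                   condition = NA_character_,
                                   replicate = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "native") {
    dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = 1))
    need <- c("chrom", "pos", "strand", "context", "c_count", "ct_count")
    if (!all(need %in% names(dt))) {
      stop("native dialect expects header: ", paste(need, collapse = " "), call. = FALSE)
    }
    offset <- 1L  # header line
  } else {
    dt <- fread(path, sep = "\t", header = FALSE,
                col.names = c("chrom", "pos", "strand", "c_count", "u_count",
                              "context", "tri"))
    dt[, ct_count := c_count + u_count]
    dt[, c("u_count", "tri") := NULL]
    offset <- 0L
  }
  bad <- .validate_calls(dt)
  if (length(bad)) {
    stop("rejected ", length(bad), " malformed row(s) in ", path, " at line(s): ",
         paste(head(bad + offset, 20L), collapse = ", "),
         if (length(bad) > 20L) " ..." else "", call. = FALSE)
  }
  methylome_table(dt, sample_id = sample_id, condition = condition,
                  replicate = replicate)
}

#' Write a methylome table in the native TSV dialect
#'
#' @param table a `MethylomeTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(table, path) {
  cols <- c("chrom", "pos", "strand", "context", "c_count", "ct_count")
  fwrite(as.data.table(table)[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Classify the sequence context of a cytosine
#'
#' Determines CG/CHG/CHH (H = A, C or T) from the two bases 3' of the
#' cytosine on its own strand. On the minus strand the reference is read
#' reverse-complemented, i.e. the cytosine sits where the plus strand shows
#' a G and its downstream bases are the complements of the plus-strand bases
#' immediately to its left. Cytosines within 2 bp of a contig end whose
#' missing downstream bases make the call ambiguous are classified CHH
#' (a site that cannot be shown to be CG or CHG is treated as asymmetric).
#'
#' @param reference a single sequence as a character string, a named
#'   character vector of sequences, or a `Biostrings::DNAStringSet`.
#' @param pos 1-based position(s) of the cytosine.
#' @param strand `"+"` or `"-"`, recycled.
#' @param chrom contig name(s) when `reference` holds several sequences.
#' @return character vector of `"CG"`, `"CHG"`, `"CHH"`.
#' @export
#' @examples
#' classify_context("TACGT", 3, "+") # "CG"
#' classify_context("TACAG", 3, "+") # "CHG"
classify_context <- function(reference, pos, strand, chrom = NULL) {
  seqs <- .as_seq_list(reference)
  n <- max(length(pos), length(strand), length(chrom %||% character(0)), 1L)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  if (is.null(chrom)) {
    if (length(seqs) != 1L) stop("chrom is required for a multi-sequence reference", call. = FALSE)
    chrom <- rep_len(names(seqs), n)
  } else {
    chrom <- rep_len(as.character(chrom), n)
  }
  out <- character(n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(seqs)) stop("unknown contig: ", ch, call. = FALSE)
    chars <- strsplit(seqs[[ch]], "", fixed = TRUE)[[1]]
    idx <- which(chrom == ch)
    out[idx] <- .classify_chars(chars, pos[idx], strand[idx])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_seq_list <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference)) {
    seqs <- reference
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else if (is.list(reference)) {
    seqs <- unlist(reference)
  } else {
    stop("unsupported reference representation", call. = FALSE)
  }
  toupper(seqs)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# vectorised worker on a character vector of bases
.classify_chars <- function(chars, pos, strand) {
  L <- length(chars)
  if (any(pos < 1L | pos > L)) stop("position outside contig bounds", call. = FALSE)
  plus <- strand == "+"
  base_here <- chars[pos]
  if (any(plus & base_here != "C")) {
    stop("base at position is not C on the + strand", call. = FALSE)
  }
  if (any(!plus & base_here != "G")) {
    stop("base at position is not C on the - strand (no G on +)", call. = FALSE)
  }
  b1 <- character(length(pos))
  b2 <- character(length(pos))
  # + strand: downstream bases are pos+1, pos+2
  i1 <- pos + 1L; i2 <- pos + 2L
  b1[plus] <- ifelse(i1[plus] <= L, chars[pmin(i1[plus], L)], NA_character_)
  b2[plus] <- ifelse(i2[plus] <= L, chars[pmin(i2[plus], L)], NA_character_)
  # - strand: downstream bases are complements of pos-1, pos-2
  j1 <- pos - 1L; j2 <- pos - 2L
  b1[!plus] <- ifelse(j1[!plus] >= 1L, .COMPLEMENT[chars[pmax(j1[!plus], 1L)]], NA_character_)
  b2[!plus] <- ifelse(j2[!plus] >= 1L, .COMPLEMENT[chars[pmax(j2[!plus], 1L)]], NA_character_)
  ctx <- rep("CHH", length(pos))
  ctx[!is.na(b1) & b1 == "G"] <- "CG"
  ctx[!is.na(b1) & b1 != "G" & !is.na(b2) & b2 == "G"] <- "CHG"
  ctx
}

#' Bisulfite conversion rate from an unmethylated control contig
#'
#' Estimates the conversion rate as `1 - sum(c_count) / sum(ct_count)` over
#' all cytosines of a control contig known to be unmethylated (the
#' chloroplast in a plant WGBS library), and flags QC failure below a
#' threshold. The threshold comparison is `rate >= threshold`.
#'
#' @param table a `MethylomeTable` containing the control contig.
#' @param control_chrom name of the unmethylated control contig.
#' @param threshold QC pass threshold (default 0.996).
#' @return list with `rate`, `pass`, `n_reads`.
#' @export
conversion_rate <- function(table, control_chrom = "chloroplast_control",
                            threshold = 0.996) {
  ctl <- as.data.table(table)[chrom == control_chrom]
  if (!nrow(ctl)) stop("control contig '", control_chrom, "' absent", call. = FALSE)
  tot <- sum(as.numeric(ctl$ct_count))
  if (tot == 0) stop("zero informative reads on control contig", call. = FALSE)
  rate <- 1 - sum(as.numeric(ctl$c_count)) / tot
  list(rate = rate, pass = rate >= threshold, n_reads = tot)
}

#' Weighted methylation level
#'
#' Pooled-count ("weighted") methylation level `sum(c_count) / sum(ct_count)`
#' over the selected cytosines -- not the mean of per-site ratios, so deep
#' and shallow sites contribute proportionally to their coverage.
#'
#' @param table a `MethylomeTable` (or plain data.frame of calls).
#' @param context optional context filter (`"CG"`, `"CHG"`, `"CHH"` or a
#'   vector of these).
#' @param region optional region as `list(chrom=, start0=, end=)`
#'   (0-based half-open).
#' @param min_depth optional minimum `ct_count` per site.
#' @return the pooled methylation level in `[0, 1]`.
#' @export
weighted_methylation_level <- function(table, context = NULL, region = NULL,
                                       min_depth = 0L) {
  dt <- as.data.table(table)
  if (!is.null(context)) {
    ctx <- context
    dt <- dt[dt$context %in% ctx]
  }
  if (!is.null(region)) {
    dt <- dt[chrom == region$chrom & pos > region$start0 & pos <= region$end]
  }
  dt <- dt[ct_count >= min_depth]
  tot <- sum(as.numeric(dt$ct_count))
  if (!nrow(dt) || tot == 0) {
    stop("no cytosines with informative reads in selection", call. = FALSE)
  }
  sum(as.numeric(dt$c_count)) / tot
}

#' Per-position depth mask across libraries
#'
#' Keeps positions whose informative read count (`ct_count`) is at least
#' `min_depth` in *every* supplied library. All tables must share one
#' cytosine catalogue (same `(chrom, pos, strand)` in the same order).
#'
#' @param tables list of `MethylomeTable`s.
#' @param min_depth minimum depth (default 4).
#' @return logical vector, one entry per catalogue position.
#' @export
filter_by_depth <- function(tables, min_depth = 4L) {
  if (!length(tables)) stop("at least one table required", call. = FALSE)
  .check_aligned(tables)
  mask <- rep(TRUE, nrow(tables[[1]]))
  for (t in tables) mask <- mask & (t$ct_count >= min_depth)
  mask
}

.check_aligned <- function(tables) {
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (nrow(t) != nrow(ref) ||
        !identical(t$chrom, ref$chrom) ||
        !identical(t$pos, ref$pos) ||
        !identical(t$strand, ref$strand)) {
      stop("mismatched cytosine catalogues across libraries", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Pool replicate methylomes of one condition
#'
#' Per-position `c_count` and `ct_count` are summed across replicates. The
#' pooled weighted level of any region equals the count-weighted mean of the
#' replicate levels by construction.
#'
#' @param tables list of `MethylomeTable`s from the same condition, on an
#'   identical cytosine catalogue.
#' @return a pooled `MethylomeTable`.
#' @export
pool_replicates <- function(tables) {
  if (!length(tables)) stop("no tables to pool", call. = FALSE)
  conds <- unique(vapply(tables, function(t) as.character(attr(t, "condition")), ""))
  if (length(conds) > 1L) stop("tables come from different conditions", call. = FALSE)
  .check_aligned(tables)
  out <- copy(as.data.table(tables[[1]]))
  if (length(tables) > 1L) {
    for (t in tables[-1]) {
      out[, `:=`(c_count = c_count + t$c_count, ct_count = ct_count + t$ct_count)]
    }
  }
  methylome_table(out,
                  sample_id = paste0(conds, "_pooled"),
                  condition = conds, replicate = NA_integer_)
}
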