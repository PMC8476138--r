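`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single integer seed; each stage
#' draws from its own substream so that toggling one stage does not shift the
#' draws of another. Substreams are derived by hashing the master seed with a
#' stage offset, kept below 2^31 so the result is a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param k integer stage offset (each stage uses a distinct constant).
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647)
}

## intervals are data.frames with chrom, start, end in 0-based half-open
## coordinates throughout the package; conversion to 1-based conventions
## happens only in formats-io.R.

new_intervals <- function(chrom = character(), start = integer(),
                          end = integer(), strand = ".", kind = NA_character_,
                          parent = NA_character_, phase = NA_integer_) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), strand = strand, kind = kind,
                   parent = parent, phase = phase, stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (nrow(df) && any(df$start < 0 | df$end <= df$start))
    stop("invalid interval: need 0 <= start < end")
  invisible(df)
}

#' Merge (union) intervals per chromosome
#'
#' @param intervals data.frame with chrom/start/end (0-based half-open).
#' @return data.frame with disjoint, sorted intervals covering the union.
#' @keywords internal
merge_intervals <- function(intervals) {
  if (!nrow(intervals))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## total bp of the union of `intervals` falling inside [start, end) on one
## chromosome; intervals must already be merged (disjoint).
overlap_bp <- function(start, end, iv_start, iv_end) {
  if (!length(iv_start)) return(0)
  sum(pmax(0, pmin(end, iv_end) - pmax(start, iv_start)))
}

## per-window overlap of a merged interval set: windows and intervals on one
## chromosome, both 0-based half-open; vectorized over windows via IRanges.
windowed_overlap_bp <- function(win_start, win_end, iv_start, iv_end) {
  if (!length(win_start)) return(numeric(0))
  if (!length(iv_start)) return(numeric(length(win_start)))
  w <- IRanges::IRanges(start = win_start + 1, end = win_end)
  iv <- IRanges::IRanges(start = iv_start + 1, end = iv_end)
  hits <- IRanges::findOverlaps(w, iv)
  out <- numeric(length(w))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(win_end[qi], iv_end[si]) - pmax(win_start[qi], iv_start[si])
    agg <- tapply(ov, qi, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

## complement of a merged interval set within [0, chrom_length)
complement_intervals <- function(merged, chrom, chrom_length) {
  d <- merged[merged$chrom == chrom, , drop = FALSE]
  if (!nrow(d))
    return(data.frame(chrom = chrom, start = 0, end = chrom_length,
                      stringsAsFactors = FALSE))
  d <- d[order(d$start), , drop = FALSE]
  starts <- c(0, d$end)
  ends <- c(d$start, chrom_length)
  keep <- ends > starts
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

## fast (chrom, pos) join: numeric keys, exact for pos < 2^33
match_chrom_pos <- function(a, b) {
  lev <- unique(c(a$chrom, b$chrom))
  ka <- (match(a$chrom, lev) - 1) * 2^33 + a$pos
  kb <- (match(b$chrom, lev) - 1) * 2^33 + b$pos
  match(ka, kb)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name))
  invisible(x)
}
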