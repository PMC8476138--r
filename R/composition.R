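## Windowed GC / repeat / coding-density profiles and fusion-centred
## normalized coordinates.

#' Windowed composition profile
#'
#' Tiles each chromosome with non-overlapping windows and computes GC% (over
#' non-N bases), repeat% and coding% per window. Coverage is computed on the
#' merged (union) interval set per kind so overlapping features are not
#' double-counted. Terminal windows shorter than half the window size are
#' dropped (count reported via the `"n_dropped_short"` attribute).
#'
#' @param genome a [kf_genome()] with sequences.
#' @param repeats repeat intervals (BED-derived data.frame).
#' @param annotation feature data.frame; coding density uses CDS intervals by
#'   default (`coding_kind = "exon"` switches to exons).
#' @param window_size window size in bp (>= 1000; 100 kb default).
#' @param coding_kind `"CDS"` or `"exon"`.
#' @return data.frame chrom, start, end, gc, repeat_pct, coding, norm_pos
#'   (NA until [normalized_profile()] is applied).
#' @export
window_composition <- function(genome, repeats, annotation,
                               window_size = 1e5, coding_kind = c("CDS", "exon")) {
  coding_kind <- match.arg(coding_kind)
  if (window_size < 1000) stop("window_size must be >= 1 kb")
  known <- genome$info$id
  bad <- setdiff(unique(c(repeats$chrom, annotation$chrom)), known)
  if (length(bad)) stop("intervals on chromosomes absent from genome: ",
                        paste(bad, collapse = ", "))
  rep_m <- merge_intervals(repeats)
  cds_m <- merge_intervals(annotation[annotation$kind == coding_kind, , drop = FALSE])
  n_dropped <- 0L
  out <- lapply(known, function(ch) {
    L <- genome$info$length[genome$info$id == ch]
    starts <- seq(0, L - 1, by = window_size)
    ends <- pmin(starts + window_size, L)
    keep <- (ends - starts) >= window_size / 2
    n_dropped <<- n_dropped + sum(!keep)
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    wlen <- ends - starts
    v <- Biostrings::Views(Biostrings::DNAString(genome$seq[[ch]]),
                           start = starts + 1, end = ends)
    lf <- Biostrings::letterFrequency(v, c("G", "C", "N"))
    nonN <- wlen - lf[, "N"]
    gc <- ifelse(nonN > 0, 100 * (lf[, "G"] + lf[, "C"]) / nonN, NA_real_)
    rm_ <- rep_m[rep_m$chrom == ch, , drop = FALSE]
    cm_ <- cds_m[cds_m$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch, start = starts, end = ends, gc = gc,
               repeat_pct = 100 * windowed_overlap_bp(starts, ends, rm_$start, rm_$end) / wlen,
               coding = 100 * windowed_overlap_bp(starts, ends, cm_$start, cm_$end) / wlen,
               norm_pos = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "n_dropped_short") <- n_dropped
  out
}

#' Fusion-centred normalized positions and binned profile
#'
#' Maps window midpoints to [0, 1]: unfused chromosomes linearly, fused
#' chromosomes piecewise-linearly so the fusion point lands at exactly 0.5
#' (left component onto [0, 0.5], right onto [0.5, 1]). Bins the windows and
#' returns per-bin mean and SD of each metric.
#'
#' @param windows output of [window_composition()].
#' @param lengths named chromosome lengths (bp).
#' @param fusions fusion events (NULL or empty for unfused sets); only single
#'   fusions per chromosome are supported by the 0.5-centred map.
#' @param n_bins number of bins (>= 3).
#' @param metrics metric columns to summarize.
#' @return list with `windows` (norm_pos filled) and `bins` (bin, bin_mid,
#'   metric, mean, sd, n).
#' @export
normalized_profile <- function(windows, lengths, fusions = NULL, n_bins = 20,
                               metrics = c("gc", "repeat_pct", "coding")) {
  if (n_bins < 3) stop("n_bins must be >= 3")
  bp <- stats::setNames(rep(NA_real_, length(lengths)), names(lengths))
  if (!is.null(fusions) && nrow(fusions)) {
    one <- fusions[!duplicated(fusions$derived_chrom), , drop = FALSE]
    bp[one$derived_chrom] <- one$breakpoint
  }
  mid <- (windows$start + windows$end) / 2
  L <- lengths[windows$chrom]
  b <- bp[windows$chrom]
  windows$norm_pos <- ifelse(is.na(b), mid / L,
                             ifelse(mid < b, 0.5 * mid / b,
                                    0.5 + 0.5 * (mid - b) / (L - b)))
  bin <- pmin(n_bins, floor(windows$norm_pos * n_bins) + 1L)
  rows <- lapply(metrics, function(m) {
    agg_mean <- tapply(windows[[m]], bin, mean, na.rm = TRUE)
    agg_sd <- tapply(windows[[m]], bin, stats::sd, na.rm = TRUE)
    agg_n <- tapply(windows[[m]], bin, function(x) sum(!is.na(x)))
    data.frame(bin = as.integer(names(agg_mean)),
               bin_mid = (as.integer(names(agg_mean)) - 0.5) / n_bins,
               metric = m, mean = as.numeric(agg_mean),
               sd = as.numeric(agg_sd), n = as.integer(agg_n),
               stringsAsFactors = FALSE)
  })
  list(windows = windows, bins = do.call(rbind, rows))
}

#' One-sided rank-sum contrasts between chromosome classes
#'
#' For each metric and each ordered pair of classes, a one-sided
#' Wilcoxon-Mann-Whitney rank-sum test with alternative "less" (the first
#' class of the pair tends to smaller values). Significance is called at a
#' stringent alpha (default 0.005). Classes with fewer than 3 members give
#' NA.
#'
#' @param metrics_table data.frame with a `homolog` column and one column per
#'   metric.
#' @param class_table output of [classify_chromosomes()].
#' @param metrics metric columns to test (default: all numeric columns).
#' @param alpha significance threshold.
#' @return data.frame metric, class_a, class_b, alternative, statistic, p,
#'   significant.
#' @export
class_contrasts <- function(metrics_table, class_table,
                            metrics = NULL, alpha = 0.005) {
  cls <- stats::setNames(class_table$class, class_table$homolog)
  g <- cls[metrics_table$homolog]
  if (is.null(metrics))
    metrics <- setdiff(names(metrics_table)[vapply(metrics_table, is.numeric, logical(1))],
                       "homolog")
  classes <- c("NFC", "LFC", "SFC")
  pairs <- expand.grid(class_a = classes, class_b = classes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$class_a != pairs$class_b, ]
  out <- lapply(metrics, function(m) {
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      xa <- metrics_table[[m]][g == pairs$class_a[i] & !is.na(g)]
      xb <- metrics_table[[m]][g == pairs$class_b[i] & !is.na(g)]
      if (length(xa) < 3 || length(xb) < 3) {
        w <- NA_real_; p <- NA_real_
      } else {
        wt <- suppressWarnings(stats::wilcox.test(xa, xb, alternative = "less"))
        w <- unname(wt$statistic); p <- wt$p.value
      }
      data.frame(metric = m, class_a = pairs$class_a[i],
                 class_b = pairs$class_b[i], alternative = "less",
                 statistic = w, p = p,
                 significant = !is.na(p) & p <= alpha,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-chromosome repeat scaling of intronic versus intergenic regions
#'
#' For every chromosome, totals intron bp and repeat bp falling inside
#' introns (one point per chromosome), and likewise for intergenic regions
#' (complement of merged gene spans); fits an SMA line per region kind on
#' log10 scales, and compares elevations by permutation. Chromosomes with no
#' intron bp or zero repeat overlap in a region are excluded (counted in the
#' `"n_excluded"` attribute).
#'
#' @param annotation feature data.frame (introns synthesized by
#'   [read_gff3()] or provided).
#' @param repeats repeat intervals.
#' @param lengths named chromosome lengths.
#' @param n_permutations,seed passed to [sma_group_compare()].
#' @return list with `points`, `fits` (per kind) and `compare`.
#' @export
region_repeat_scaling <- function(annotation, repeats, lengths,
                                  n_permutations = 999, seed = 1) {
  rep_m <- merge_intervals(repeats)
  introns_m <- merge_intervals(annotation[annotation$kind == "intron", , drop = FALSE])
  genes_m <- merge_intervals(annotation[annotation$kind == "gene", , drop = FALSE])
  pts <- lapply(names(lengths), function(ch) {
    im <- introns_m[introns_m$chrom == ch, , drop = FALSE]
    ig <- complement_intervals(genes_m, ch, lengths[[ch]])
    rm_ <- rep_m[rep_m$chrom == ch, , drop = FALSE]
    rbp <- function(reg) sum(windowed_overlap_bp(reg$start, reg$end,
                                                 rm_$start, rm_$end))
    data.frame(chrom = ch,
               kind = c("intron", "intergenic"),
               region_bp = c(sum(im$end - im$start), sum(ig$end - ig$start)),
               repeat_bp = c(rbp(im), rbp(ig)), stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, pts)
  ok <- pts$region_bp > 0 & pts$repeat_bp > 0
  n_excluded <- sum(!ok)
  pts <- pts[ok, , drop = FALSE]
  groups <- lapply(split(pts, pts$kind), function(d)
    list(x = log10(d$region_bp), y = log10(d$repeat_bp)))
  fits <- lapply(groups, function(g) sma_fit(g$x, g$y))
  cmp <- sma_group_compare(groups, n_permutations = n_permutations, seed = seed)
  out <- list(points = pts, fits = fits, compare = cmp)
  attr(out, "n_excluded") <- n_excluded
  out
}
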