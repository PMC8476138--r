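## Evolutionary turnover of functional elements (CREs, exons): reciprocal
## best hits, per-chromosome conservation, and its dependence on chromosome
## length and divergence time.

#' Reciprocal best hits
#'
#' Per query, the best hit has the lowest e-value, ties broken by highest
#' bitscore then lexicographic subject id (deterministic). A pair is retained
#' iff each side is the other's best and both e-values pass the threshold.
#'
#' @param hits_forward,hits_reverse 12-column hit tables (element vs target
#'   genome and back).
#' @param evalue_max inclusive e-value threshold (default 1e-10).
#' @return data.frame query, subject, evalue_fwd, evalue_rev.
#' @export
reciprocal_best_hits <- function(hits_forward, hits_reverse,
                                 evalue_max = 1e-10) {
  best_of <- function(h) {
    if (!nrow(h)) return(h[0, c("query_id", "subject_id", "evalue")])
    h <- h[order(h$query_id, h$evalue, -h$bitscore, h$subject_id), , drop = FALSE]
    h[!duplicated(h$query_id), c("query_id", "subject_id", "evalue")]
  }
  bf <- best_of(hits_forward)
  br <- best_of(hits_reverse)
  if (!nrow(bf) || !nrow(br))
    return(data.frame(query = character(), subject = character(),
                      evalue_fwd = numeric(), evalue_rev = numeric(),
                      stringsAsFactors = FALSE))
  m <- match(bf$subject_id, br$query_id)
  ok <- !is.na(m) & br$subject_id[m] == bf$query_id &
    bf$evalue <= evalue_max & br$evalue[m] <= evalue_max
  out <- data.frame(query = bf$query_id[ok], subject = bf$subject_id[ok],
                    evalue_fwd = bf$evalue[ok], evalue_rev = br$evalue[m][ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-chromosome conservation of functional elements
#'
#' Conservation C is the percentage of a chromosome's source elements with a
#' reciprocal best hit in the target. To score conservation per ancestral
#' homolog segment of fused chromosomes, relabel the elements through
#' [split_chromosomes()] first and supply segment lengths.
#'
#' @param elements data.frame with `chrom` and unique `id` per element.
#' @param rbh pairs from [reciprocal_best_hits()].
#' @param lengths named chromosome (or segment) lengths in bp.
#' @return data.frame chrom, n_elements, n_conserved, conservation (%),
#'   length_bp; chromosomes with elements but length NA are kept with NA
#'   length, chromosomes without elements are returned with NA conservation.
#' @export
conservation_by_chromosome <- function(elements, rbh, lengths) {
  if (anyDuplicated(elements$id)) stop("element ids must be unique")
  conserved <- elements$id %in% rbh$query
  chroms <- names(lengths)
  n_el <- as.integer(table(factor(elements$chrom, levels = chroms)))
  n_co <- as.integer(tapply(conserved, factor(elements$chrom, levels = chroms),
                            sum, default = 0))
  data.frame(chrom = chroms, n_elements = n_el, n_conserved = n_co,
             conservation = ifelse(n_el > 0, 100 * n_co / n_el, NA_real_),
             length_bp = as.numeric(lengths), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Correlation of conservation with chromosome length
#'
#' Pearson correlation of per-chromosome conservation against chromosome
#' length (signed; a negative value means longer chromosomes retain fewer
#' elements).
#'
#' @param results data.frame from [conservation_by_chromosome()] (optionally
#'   with extra grouping columns handled by the caller).
#' @return list rho, p, n (NA when conservation is constant).
#' @export
conservation_length_correlation <- function(results) {
  ok <- is.finite(results$conservation) & is.finite(results$length_bp)
  if (sum(ok) < 5) stop("need at least 5 chromosomes")
  x <- results$length_bp[ok]; y <- results$conservation[ok]
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Multiple regression of conservation on length and divergence time
#'
#' Ordinary least squares of conservation (%) on chromosome length (Mb) and
#' divergence time (Myr) with intercept, pooling per-chromosome points across
#' target comparisons; also retains the simple per-comparison length slopes
#' used for effect-size comparisons.
#'
#' @param results data.frame with columns conservation, length_bp and
#'   time_myr (one row per chromosome x target comparison).
#' @return list: coefficients (intercept, beta_length per Mb, beta_time per
#'   Myr), r2, per_comparison (data.frame time_myr, length_slope), fit (the
#'   `lm` object).
#' @export
turnover_multiple_regression <- function(results) {
  d <- data.frame(C = results$conservation, L = results$length_bp / 1e6,
                  T_ = results$time_myr)
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 5) stop("need at least 5 observations")
  single_time <- length(unique(d$T_)) < 2
  if (single_time) {
    warning("single divergence time: time coefficient not estimable")
    fit <- stats::lm(C ~ L, data = d)
    co <- c(stats::coef(fit), NA_real_)
  } else {
    fit <- stats::lm(C ~ L + T_, data = d)
    co <- stats::coef(fit)
  }
  per <- lapply(split(d, d$T_), function(dd)
    data.frame(time_myr = dd$T_[1],
               length_slope = unname(stats::coef(stats::lm(C ~ L, data = dd))["L"])))
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(coefficients = c(intercept = unname(co[1]), beta_length = unname(co[2]),
                        beta_time = unname(co[3])),
       r2 = summary(fit)$r.squared, per_comparison = per, fit = fit)
}

#' Compare chromosome-length effect sizes between two element sources
#'
#' Paired t-test on per-comparison length slopes (paired by target
#' comparison), plus the ratio of mean absolute slopes.
#'
#' @param slopes_a,slopes_b numeric vectors of length slopes, paired by
#'   position (same target comparisons in the same order), length >= 2.
#' @return list: t, p, df, ratio (mean |a| / mean |b|), n.
#' @export
compare_effect_sizes <- function(slopes_a, slopes_b) {
  if (length(slopes_a) != length(slopes_b))
    stop("slope vectors must be paired (equal length)")
  if (length(slopes_a) < 2)
    stop("paired t-test needs at least 2 paired comparisons")
  d <- slopes_a - slopes_b
  if (stats::sd(d) == 0) {
    tt <- list(statistic = if (all(d == 0)) 0 else sign(d[1]) * Inf,
               p.value = if (all(d == 0)) 1 else 0,
               parameter = length(d) - 1)
  } else tt <- stats::t.test(slopes_a, slopes_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       ratio = mean(abs(slopes_a)) / mean(abs(slopes_b)),
       n = length(slopes_a))
}
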