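## Standardized major axis (SMA) regression for allometric scaling, with
## permutation-based common-slope and elevation tests. SMA treats x and y
## symmetrically: slope = sign(r) * sd(y) / sd(x), so slope(x, y) *
## slope(y, x) = 1 whenever r != 0.

#' Fit a standardized major axis line
#'
#' @param x,y numeric vectors (n >= 3).
#' @param log_transform if `TRUE`, both variables are log10-transformed
#'   first (all values must be positive).
#' @param group optional group label stored on the fit.
#' @return object of class `kf_sma`: slope, intercept, r, n, group.
#' @export
sma_fit <- function(x, y, log_transform = FALSE, group = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("SMA needs at least 3 points")
  if (log_transform) {
    if (any(x <= 0 | y <= 0)) stop("log transform requires positive values")
    x <- log10(x); y <- log10(y)
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  s <- if (r < 0) -1 else 1
  slope <- s * sy / sx
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r = r, n = length(x), group = group),
            class = "kf_sma")
}

#' @export
print.kf_sma <- function(x, ...) {
  cat(sprintf("SMA fit%s: slope = %.4g, intercept = %.4g, r = %.3f, n = %d\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

## pooled common SMA slope after within-group centring
common_sma_slope <- function(groups) {
  xc <- unlist(lapply(groups, function(g) g$x - mean(g$x)))
  yc <- unlist(lapply(groups, function(g) g$y - mean(g$y)))
  r <- stats::cor(xc, yc)
  s <- if (r < 0) -1 else 1
  s * stats::sd(yc) / stats::sd(xc)
}

#' Permutation tests for common slope and elevation between SMA groups
#'
#' The common-slope test permutes group labels over all points and uses the
#' variance of group SMA slopes as the statistic. The pairwise elevation
#' test computes residual scores `y - b_common * x` under the pooled common
#' slope (fitted on within-group-centred data) and permutes the scores
#' between the two groups, with the absolute difference in group means as the
#' statistic. Elevation P values are Holm-adjusted across pairs.
#'
#' @param groups named list; each element a list with numeric `x` and `y`
#'   (each n >= 3). Supplying a single group compares it with itself (P = 1).
#' @param n_permutations number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return list: slopes, b_common, common_slope_p, elevation (data.frame
#'   group_a, group_b, diff, p, p_adj).
#' @export
sma_group_compare <- function(groups, n_permutations = 999, seed = 1) {
  if (n_permutations < 99) stop("need at least 99 permutations")
  if (!length(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, function(g) length(g$x) < 3, logical(1))))
    stop("each group needs at least 3 points")
  single <- length(groups) == 1
  if (single) groups <- c(groups, groups)   # self-comparison: P = 1 by symmetry
  set.seed(seed)
  slopes <- vapply(groups, function(g) sma_fit(g$x, g$y)$slope, numeric(1))
  b_common <- common_sma_slope(groups)

  ## common-slope test
  all_x <- unlist(lapply(groups, `[[`, "x"))
  all_y <- unlist(lapply(groups, `[[`, "y"))
  glab <- rep(seq_along(groups), vapply(groups, function(g) length(g$x), integer(1)))
  stat_obs <- stats::var(slopes)
  perm_stat <- function(lab) {
    s <- vapply(split(seq_along(lab), lab), function(i) {
      if (length(i) < 3 || stats::sd(all_x[i]) == 0 || stats::sd(all_y[i]) == 0)
        return(NA_real_)
      sma_fit(all_x[i], all_y[i])$slope
    }, numeric(1))
    stats::var(s, na.rm = TRUE)
  }
  perm <- replicate(n_permutations, perm_stat(sample(glab)))
  common_slope_p <- (1 + sum(perm >= stat_obs, na.rm = TRUE)) / (n_permutations + 1)

  ## pairwise elevation tests
  nm <- names(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  elev <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ri <- groups[[i]]$y - b_common * groups[[i]]$x
    rj <- groups[[j]]$y - b_common * groups[[j]]$x
    obs <- abs(mean(ri) - mean(rj))
    pooled <- c(ri, rj); ni <- length(ri)
    perm <- replicate(n_permutations, {
      idx <- sample(length(pooled), ni)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    p <- (1 + sum(perm >= obs)) / (n_permutations + 1)
    data.frame(group_a = nm[i], group_b = nm[j],
               diff = mean(ri) - mean(rj), p = p, stringsAsFactors = FALSE)
  })
  elev <- do.call(rbind, elev)
  if (single) elev$p <- 1
  elev$p_adj <- stats::p.adjust(elev$p, method = "holm")
  list(slopes = slopes, b_common = b_common,
       common_slope_p = common_slope_p, elevation = elev)
}
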