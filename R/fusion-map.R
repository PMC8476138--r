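## Fusion-point detection from ortholog synteny anchors, chromosome
## splitting, and NFC/LFC/SFC classification.

#' Build an ordered anchor map
#'
#' Anchors tie positions on a derived (possibly fused) chromosome to
#' ancestral homolog labels. Input is either a ready-made anchor table or a
#' pair of element table + similarity hits against the derived assembly, in
#' which case each element's best placement is used and ambiguous placements
#' (a second placement with equal e-value or within 2 bits of bitscore) are
#' dropped with a logged count.
#'
#' @param anchors data.frame with columns chrom (derived), pos (bp), homolog,
#'   and optionally anchor_id; or `NULL` when building from hits.
#' @param elements when building from hits: data.frame of source elements
#'   with columns id and homolog (the ancestral chromosome each element comes
#'   from).
#' @param hits 12-column hit table of elements against the derived assembly
#'   (subject = derived chromosome).
#' @param ambiguity_bits bitscore margin within which two placements are
#'   considered ambiguous (default 2).
#' @return anchor data.frame sorted by chrom and position, with attributes
#'   `"n_dropped_ambiguous"` and `"multi_homolog"` (derived chromosomes whose
#'   anchors come from more than two homologs).
#' @export
build_anchor_map <- function(anchors = NULL, elements = NULL, hits = NULL,
                             ambiguity_bits = 2) {
  n_dropped <- 0L
  if (is.null(anchors)) {
    stopifnot(!is.null(elements), !is.null(hits))
    if (!nrow(hits)) {
      am <- data.frame(chrom = character(), pos = numeric(),
                       homolog = character(), anchor_id = character(),
                       stringsAsFactors = FALSE)
      attr(am, "n_dropped_ambiguous") <- 0L
      attr(am, "multi_homolog") <- character()
      return(am)
    }
    rows <- lapply(split(hits, hits$query_id), function(h) {
      h <- h[order(h$evalue, -h$bitscore, h$subject_id), , drop = FALSE]
      if (nrow(h) > 1 &&
          (h$evalue[2] == h$evalue[1] ||
           h$bitscore[1] - h$bitscore[2] < ambiguity_bits))
        return(NULL)
      ## hit coordinates are 1-based inclusive; midpoint in 0-based coords
      data.frame(chrom = h$subject_id[1],
                 pos = floor((h$s_start[1] - 1 + h$s_end[1]) / 2),
                 anchor_id = h$query_id[1], stringsAsFactors = FALSE)
    })
    kept <- !vapply(rows, is.null, logical(1))
    n_dropped <- sum(!kept)
    anchors <- do.call(rbind, rows[kept])
    anchors$homolog <- elements$homolog[match(anchors$anchor_id, elements$id)]
  }
  if (!("anchor_id" %in% names(anchors)))
    anchors$anchor_id <- paste0("a", seq_len(nrow(anchors)))
  anchors <- anchors[order(anchors$chrom, anchors$pos),
                     c("chrom", "pos", "homolog", "anchor_id")]
  rownames(anchors) <- NULL
  multi <- names(which(vapply(split(anchors$homolog, anchors$chrom),
                              function(h) length(unique(h)) > 2, logical(1))))
  attr(anchors, "n_dropped_ambiguous") <- n_dropped
  attr(anchors, "multi_homolog") <- multi
  anchors
}

## minimal-misassignment partition of sorted anchor labels into k contiguous
## blocks with fixed block labels; returns cut indices (anchor index after
## which each cut falls) and the total number of discordant anchors
changepoint_partition <- function(labels, positions, block_labels) {
  n <- length(labels)
  k <- length(block_labels)
  mismatch <- outer(labels, block_labels, FUN = "!=") * 1L
  cum <- rbind(0, apply(mismatch, 2, cumsum))   # cum[i+1, j] = cost of 1..i in block j
  ## dp[i+1, j]: min cost of assigning anchors 1..i to blocks 1..j, each block
  ## non-empty
  dp <- matrix(Inf, n + 1, k)
  choice <- matrix(NA_integer_, n + 1, k)
  dp[, 1] <- cum[, 1]
  if (k > 1) for (j in 2:k) {
    for (i in j:n) {
      prev <- dp[j:i, j - 1] + (cum[i + 1, j] - cum[j:i, j])
      b <- which.min(prev)
      dp[i + 1, j] <- prev[b]
      choice[i + 1, j] <- (j:i)[b] - 1L   # last anchor index of block j-1
    }
  }
  cuts <- integer(k - 1)
  i <- n
  if (k > 1) for (j in k:2) {
    cuts[j - 1] <- choice[i + 1, j]
    i <- cuts[j - 1]
  }
  list(cuts = cuts, cost = dp[n + 1, k])
}

#' Detect chromosome fusions from an anchor map
#'
#' For each derived chromosome carrying anchors from two (or more) ancestral
#' homologs, finds the contiguous-block changepoint(s) minimizing the number
#' of anchors on the wrong side (ties broken toward the cut with the largest
#' flanking gap). The breakpoint is the floor of the midpoint between the two
#' anchors flanking the cut, and the flanking gap is retained as the
#' breakpoint's uncertainty. Chromosomes whose anchors all belong to one
#' homolog yield no event. An event where the minimal misassignment exceeds
#' 10% of the chromosome's anchors is flagged low-confidence.
#'
#' @param anchor_map output of [build_anchor_map()].
#' @return data.frame of fusion events: derived_chrom, left_homolog,
#'   right_homolog, breakpoint, flanking_gap, n_discordant, confidence.
#' @export
detect_fusions <- function(anchor_map) {
  if (!nrow(anchor_map)) stop("empty anchor map")
  events <- lapply(split(anchor_map, anchor_map$chrom), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    tab <- table(d$homolog)
    claim <- names(tab)[tab >= 2]
    if (length(claim) < 2) return(NULL)
    med <- vapply(claim, function(h) stats::median(d$pos[d$homolog == h]),
                  numeric(1))
    block_labels <- claim[order(med)]
    ## enumerate optimal partitions; for k = 2 resolve gap ties explicitly
    part <- changepoint_partition(d$homolog, d$pos, block_labels)
    cuts <- part$cuts
    if (length(block_labels) == 2) {
      n <- nrow(d)
      cost <- vapply(1:(n - 1), function(i)
        sum(d$homolog[1:i] != block_labels[1]) +
          sum(d$homolog[(i + 1):n] != block_labels[2]), numeric(1))
      best <- which(cost == min(cost))
      gaps <- d$pos[best + 1] - d$pos[best]
      cuts <- best[which.max(gaps)]
    }
    n_disc <- part$cost
    out <- lapply(seq_along(cuts), function(ci) {
      i <- cuts[ci]
      data.frame(derived_chrom = d$chrom[1],
                 left_homolog = block_labels[ci],
                 right_homolog = block_labels[ci + 1],
                 breakpoint = floor((d$pos[i] + d$pos[i + 1]) / 2),
                 flanking_gap = d$pos[i + 1] - d$pos[i],
                 n_discordant = n_disc,
                 confidence = if (n_disc > 0.1 * nrow(d)) "low" else "high",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, events)
  if (is.null(out))
    out <- data.frame(derived_chrom = character(), left_homolog = character(),
                      right_homolog = character(), breakpoint = numeric(),
                      flanking_gap = numeric(), n_discordant = integer(),
                      confidence = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ancestral-homolog segment table for a derived genome
#'
#' Cuts every fused chromosome at its breakpoints; unfused chromosomes form a
#' single segment labeled by their homology group.
#'
#' @param genome derived [kf_genome()].
#' @param fusions fusion events from [detect_fusions()] (or the generator's
#'   truth table with the same columns).
#' @return data.frame derived_chrom, homolog, start, end.
#' @export
fusion_segments <- function(genome, fusions) {
  L <- chrom_lengths(genome)
  segs <- list()
  fused <- unique(fusions$derived_chrom)
  for (ch in genome$info$id) {
    len <- L[[ch]]
    ev <- fusions[fusions$derived_chrom == ch, , drop = FALSE]
    if (!nrow(ev)) {
      segs[[ch]] <- data.frame(derived_chrom = ch,
                               homolog = genome$info$homology_group[genome$info$id == ch],
                               start = 0, end = len, stringsAsFactors = FALSE)
      next
    }
    ev <- ev[order(ev$breakpoint), , drop = FALSE]
    if (any(ev$breakpoint <= 0 | ev$breakpoint >= len))
      stop("breakpoint outside chromosome ", ch)
    bounds <- c(0, ev$breakpoint, len)
    homologs <- c(ev$left_homolog, ev$right_homolog[nrow(ev)])
    segs[[ch]] <- data.frame(derived_chrom = ch, homolog = homologs,
                             start = bounds[-length(bounds)],
                             end = bounds[-1], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Relabel positions and intervals to ancestral coordinates
#'
#' Points are assigned to the segment containing them (a point exactly at a
#' breakpoint belongs to the right-hand segment); intervals are assigned by
#' midpoint, with a midpoint exactly at the breakpoint going left, and
#' intervals spanning a breakpoint are flagged. The right-hand component's
#' offset is subtracted so coordinates are relative to the ancestral
#' chromosome start.
#'
#' @param x data.frame with `chrom` and either `pos` (points) or
#'   `start`/`end` (intervals).
#' @param segments segment table from [fusion_segments()].
#' @return `x` with chrom replaced by the homolog label, coordinates shifted,
#'   and (for intervals) a logical `spans_breakpoint` column.
#' @export
split_chromosomes <- function(x, segments) {
  is_point <- "pos" %in% names(x)
  ref <- if (is_point) x$pos else (x$start + x$end) / 2
  out <- x
  if (!is_point) out$spans_breakpoint <- FALSE
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    on_chrom <- x$chrom == s$derived_chrom
    inseg <- if (is_point) {
      on_chrom & ref >= s$start & ref < s$end
    } else {
      ## midpoint exactly at a breakpoint goes left: include end boundary
      ## unless this is the chromosome start
      on_chrom & ref > s$start & ref <= s$end | (on_chrom & s$start == 0 & ref == 0)
    }
    if (!any(inseg)) next
    out$chrom[inseg] <- s$homolog
    if (is_point) {
      out$pos[inseg] <- x$pos[inseg] - s$start
    } else {
      ## full extent kept, shifted into the assigned segment's coordinates;
      ## spanning features are flagged rather than clipped
      out$start[inseg] <- x$start[inseg] - s$start
      out$end[inseg] <- x$end[inseg] - s$start
      out$spans_breakpoint[inseg] <-
        x$start[inseg] < s$start | x$end[inseg] > s$end
    }
  }
  out
}

#' Classify homologs as NFC, LFC or SFC
#'
#' Per fusion, the component with the smaller ancestral (outgroup) length is
#' the short-fused chromosome (SFC), the other the long-fused chromosome
#' (LFC); homologs not involved in a fusion are not-fused (NFC). Equal
#' component lengths are broken by lexicographic homolog label with a
#' warning.
#'
#' @param fusions fusion events (detected or truth).
#' @param lengths_anc named vector of ancestral homolog lengths (bp), e.g.
#'   outgroup chromosome lengths.
#' @param homologs all homolog labels (defaults to those in `lengths_anc`).
#' @return data.frame homolog, class, derived_chrom (NA for NFC).
#' @export
classify_chromosomes <- function(fusions, lengths_anc,
                                 homologs = names(lengths_anc)) {
  cls <- data.frame(homolog = homologs, class = "NFC",
                    derived_chrom = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(fusions))) {
    a <- fusions$left_homolog[i]; b <- fusions$right_homolog[i]
    la <- lengths_anc[a]; lb <- lengths_anc[b]
    if (is.na(la) || is.na(lb))
      stop("missing ancestral length for ", if (is.na(la)) a else b)
    if (la == lb) {
      warning("equal component lengths for ", a, "/", b,
              "; tie broken lexicographically")
      sfc <- min(a, b)
    } else sfc <- if (la < lb) a else b
    lfc <- setdiff(c(a, b), sfc)
    cls$class[cls$homolog == sfc] <- "SFC"
    cls$class[cls$homolog == lfc] <- "LFC"
    cls$derived_chrom[cls$homolog %in% c(a, b)] <- fusions$derived_chrom[i]
  }
  cls
}
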