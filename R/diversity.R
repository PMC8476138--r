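## Nucleotide diversity at 4-fold degenerate third codon positions (pi_4D).
##
## The 4D-site caller is deliberately conservative: a codon is only used if at
## most one of its three positions carries an observed variant, and the third
## position must be 4-fold degenerate under *every* observed allele at that
## one variant position. This mirrors the fact that a substitution elsewhere
## in the codon can move it out of a 4-fold family even when the reference
## codon belongs to one.

fourfold_env <- new.env(parent = emptyenv())

## the 16 dinucleotide prefixes scanned against the standard genetic code;
## exactly 8 are 4-fold degenerate (Leu-CTN, Val, Ser-TCN, Pro, Thr, Ala,
## Arg-CGN, Gly)
fourfold_prefixes <- function() {
  if (is.null(fourfold_env$prefixes)) {
    gc <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    pre <- as.vector(outer(bases, bases, paste0))
    is4 <- vapply(pre, function(p)
      length(unique(gc[paste0(p, bases)])) == 1L, logical(1))
    fourfold_env$prefixes <- pre[is4]
  }
  fourfold_env$prefixes
}

complement_bases <- function(x) chartr("ACGTN", "TGCAN", x)

#' Non-overlapping coding intervals
#'
#' Selects one transcript per gene (longest total CDS, ties broken by
#' transcript id) and removes every CDS interval that overlaps a CDS of a
#' *different* gene, so that no retained codon is ambiguous about its reading
#' frame.
#'
#' @param features annotation data.frame from [read_gff3()] (kinds gene,
#'   mRNA, exon, CDS; CDS carry `parent` transcript ids and phases).
#' @return data.frame of CDS intervals with columns chrom, start, end,
#'   strand, phase, transcript, gene; attribute `"n_removed_overlap"` counts
#'   intervals dropped for inter-gene overlap.
#' @export
nonoverlapping_coding_intervals <- function(features) {
  cds <- features[features$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("annotation contains no CDS features")
  mrna <- features[features$kind == "mRNA", , drop = FALSE]
  tx2gene <- stats::setNames(mrna$parent, mrna$id)
  cds$transcript <- cds$parent
  cds$gene <- tx2gene[cds$transcript]
  cds$gene[is.na(cds$gene)] <- cds$transcript[is.na(cds$gene)]

  ## longest-CDS transcript per gene, ties by transcript id
  len_by_tx <- tapply(cds$end - cds$start, cds$transcript, sum)
  tx <- names(len_by_tx)
  gene_of_tx <- cds$gene[match(tx, cds$transcript)]
  ord <- order(gene_of_tx, -as.numeric(len_by_tx), tx)
  chosen <- tx[ord][!duplicated(gene_of_tx[ord])]
  cds <- cds[cds$transcript %in% chosen, , drop = FALSE]

  ## remove intervals overlapping a CDS of a different gene (both copies go)
  ir <- IRanges::IRanges(cds$start + 1, cds$end)
  hits <- IRanges::findOverlaps(ir, ir)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  clash <- qh != sh & cds$chrom[qh] == cds$chrom[sh] & cds$gene[qh] != cds$gene[sh]
  drop <- unique(qh[clash])
  out <- if (length(drop)) cds[-drop, , drop = FALSE] else cds
  rownames(out) <- NULL
  out <- out[, c("chrom", "start", "end", "strand", "phase", "transcript", "gene")]
  attr(out, "n_removed_overlap") <- length(drop)
  out
}

## per-chromosome table of observed variant positions and their observed
## alleles (reference plus every alternate allele carried by a called
## genotype)
observed_variant_alleles <- function(variants) {
  if (is.null(variants) || nrow(variants$sites) == 0)
    return(list(pos = list(), alleles = list()))
  s <- variants$sites
  alt_list <- strsplit(s$alts, ",", fixed = TRUE)
  a1 <- sub("/.*", "", variants$gt)
  a2 <- sub(".*/", "", variants$gt)
  obs <- lapply(seq_len(nrow(s)), function(i) {
    idx <- unique(c(a1[i, ], a2[i, ]))
    idx <- suppressWarnings(as.integer(idx[idx != "."]))
    idx <- idx[!is.na(idx) & idx > 0]
    unique(c(s$ref[i], alt_list[[i]][idx]))
  })
  has_alt <- lengths(obs) > 1
  s <- s[has_alt, , drop = FALSE]
  obs <- obs[has_alt]
  pos <- split(s$pos, s$chrom)
  alle <- split(obs, s$chrom)
  list(pos = pos, alleles = alle)
}

#' Call 4-fold degenerate third codon positions
#'
#' Walks every retained codon strand- and phase-aware (minus-strand CDS are
#' reverse-complemented). Codons containing N are discarded; codons with more
#' than one position carrying an observed variant are discarded; otherwise
#' the third codon position is a 4D site if and only if it is 4-fold
#' degenerate under the reference codon and under every observed allele at
#' the (at most one) variant position.
#'
#' @param genome a [kf_genome()] with sequences.
#' @param coding output of [nonoverlapping_coding_intervals()].
#' @param variants a [kf_variants()] (already genotype-filtered as desired),
#'   or `NULL` for a reference-only call.
#' @return list with `sites` (data.frame chrom, pos, gene, codon_index,
#'   strand) and `counts` (provenance: codons scanned and reasons for
#'   rejection).
#' @export
call_fourfold_sites <- function(genome, coding, variants = NULL) {
  if (is.null(genome$seq)) stop("genome carries no sequence")
  pre4 <- fourfold_prefixes()
  vinfo <- observed_variant_alleles(variants)
  counts <- c(codons_scanned = 0, rejected_multi_variant = 0,
              rejected_non_4d = 0, rejected_N = 0, trailing_dropped = 0)
  ord <- order(coding$transcript, coding$start)
  co_chrom <- coding$chrom[ord]; co_start <- coding$start[ord]
  co_end <- coding$end[ord]; co_strand <- coding$strand[ord]
  co_phase <- coding$phase[ord]; co_gene <- coding$gene[ord]
  tx_idx <- split(seq_along(ord), coding$transcript[ord])
  out_chrom <- vector("list", length(tx_idx))
  out_pos <- vector("list", length(tx_idx))
  out_codon <- vector("list", length(tx_idx))
  out_gene <- character(length(tx_idx))
  out_strand <- character(length(tx_idx))
  k <- 0L
  for (ii in tx_idx) {
    minus <- co_strand[ii[1]] == "-"
    seqs <- substring(genome$seq[[co_chrom[ii[1]]]], co_start[ii] + 1, co_end[ii])
    cds <- paste(seqs, collapse = "")
    pos <- sequence(as.integer(co_end[ii] - co_start[ii]),
                    from = as.integer(co_start[ii]))
    if (minus) {   # reverse complement; positions follow
      cds <- complement_bases(intToUtf8(rev(utf8ToInt(cds))))
      pos <- rev(pos)
    }
    ph <- co_phase[ii[if (minus) length(ii) else 1L]]
    ph <- if (is.na(ph)) 0L else as.integer(ph)
    if (ph > 0) { cds <- substring(cds, ph + 1); pos <- pos[-seq_len(ph)] }
    nc <- nchar(cds)
    n_codons <- nc %/% 3L
    if (n_codons == 0L) next
    if (nc %% 3L != 0L) counts["trailing_dropped"] <- counts["trailing_dropped"] + 1
    counts["codons_scanned"] <- counts["codons_scanned"] + n_codons
    i3 <- seq_len(3L * n_codons)
    pos <- pos[i3]
    codons <- substring(cds, i3[c(TRUE, FALSE, FALSE)], i3[c(FALSE, FALSE, TRUE)])

    chrom <- co_chrom[ii[1]]
    vp <- vinfo$pos[[chrom]]
    vi <- if (length(vp)) match(pos, vp) else rep(NA_integer_, length(pos))
    vm <- matrix(!is.na(vi), nrow = 3L)
    nvar <- colSums(vm)

    hasN <- grepl("N", codons, fixed = TRUE)
    counts["rejected_N"] <- counts["rejected_N"] + sum(hasN)
    counts["rejected_multi_variant"] <-
      counts["rejected_multi_variant"] + sum(nvar > 1 & !hasN)

    keep <- !hasN & nvar <= 1
    ok4 <- substring(codons, 1, 2) %in% pre4
    ## re-check codons with one variant position under every observed allele
    one <- which(keep & nvar == 1 & ok4)
    for (ci in one) {
      j <- which(vm[, ci])
      p <- pos[3L * (ci - 1L) + j]
      alleles <- vinfo$alleles[[chrom]][[match(p, vp)]]
      if (minus) alleles <- complement_bases(alleles)
      if (j < 3L) {
        cod <- codons[ci]
        variants_ok <- vapply(alleles, function(a) {
          substr(cod, j, j) <- a
          substring(cod, 1, 2) %in% pre4
        }, logical(1))
        if (!all(variants_ok)) ok4[ci] <- FALSE
      }
      ## j == 3: the prefix is unchanged by any allele, ok4 stands
    }
    counts["rejected_non_4d"] <- counts["rejected_non_4d"] + sum(keep & !ok4)
    sel <- which(keep & ok4)
    if (length(sel)) {
      k <- k + 1L
      out_chrom[[k]] <- chrom
      out_pos[[k]] <- pos[3L * sel]
      out_codon[[k]] <- sel
      out_gene[k] <- co_gene[ii[1]]
      out_strand[k] <- co_strand[ii[1]]
    }
  }
  sites <- if (k) {
    ns <- lengths(out_pos[seq_len(k)])
    data.frame(chrom = rep(unlist(out_chrom[seq_len(k)]), ns),
               pos = unlist(out_pos[seq_len(k)]),
               gene = rep(out_gene[seq_len(k)], ns),
               codon_index = unlist(out_codon[seq_len(k)]),
               strand = rep(out_strand[seq_len(k)], ns),
               stringsAsFactors = FALSE)
  } else
    data.frame(chrom = character(), pos = numeric(), gene = character(),
               codon_index = integer(), strand = character(),
               stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  lev <- unique(sites$chrom)
  if (anyDuplicated((match(sites$chrom, lev) - 1) * 2^33 + sites$pos))
    stop("internal error: duplicated 4D site")
  rownames(sites) <- NULL
  list(sites = sites, counts = counts)
}

#' Apply depth and quality filters to genotypes
#'
#' A genotype is kept if and only if DP > `min_dp` AND GQ > `min_gq` (strict
#' inequalities); failing genotypes are set to missing. The default profile
#' is (10, 30); the `"low-coverage"` profile uses (5, 20).
#'
#' @param variants a [kf_variants()].
#' @param min_dp,min_gq strict lower thresholds.
#' @param profile `"default"` or `"low-coverage"`; overridden by explicit
#'   `min_dp`/`min_gq`.
#' @return the filtered [kf_variants()].
#' @export
filter_genotypes <- function(variants, min_dp = NULL, min_gq = NULL,
                             profile = c("default", "low-coverage")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "default") c(10, 30) else c(5, 20)
  min_dp <- min_dp %||% defaults[1]
  min_gq <- min_gq %||% defaults[2]
  fail <- !(variants$dp > min_dp & variants$gq > min_gq)
  variants$gt[fail] <- "./."
  variants
}

## per-site allele bookkeeping: returns allele count k and the pairwise
## heterozygosity pi = (# differing pairs) / (# pairs) over all called alleles
site_pi_from_gt <- function(gt_rows) {
  a1 <- sub("/.*", "", gt_rows)
  a2 <- sub(".*/", "", gt_rows)
  alle <- matrix(c(a1, a2), nrow = nrow(gt_rows))
  called <- alle != "." & alle != ""
  k <- rowSums(called)
  symbols <- sort(unique(as.vector(alle[called])))
  same_pairs <- numeric(nrow(alle))
  for (s in symbols) {
    cs <- rowSums(alle == s & called)
    same_pairs <- same_pairs + cs * (cs - 1) / 2
  }
  tot_pairs <- k * (k - 1) / 2
  pi <- ifelse(tot_pairs > 0, 1 - same_pairs / tot_pairs, NA_real_)
  list(k = k, pi = pi)
}

#' Windowed nucleotide diversity over 4D sites
#'
#' Sites are taken in chromosome order and grouped into windows of
#' `sites_per_window` consecutive 4D sites. Per site, diversity is the mean
#' pairwise difference over all called alleles (two per called diploid
#' genotype). 4D sites with no record in `variants` are monomorphic and
#' contribute 0. Sites whose called-allele fraction falls below
#' `min_called_fraction` are excluded from the window mean. A trailing window
#' is kept if at least half full.
#'
#' @param fourfold output of [call_fourfold_sites()] (or its `sites`).
#' @param variants a filtered [kf_variants()].
#' @param sites_per_window window size in 4D sites (default 500).
#' @param min_called_fraction minimum fraction of callable alleles for a site
#'   to enter the window mean (default 0.5).
#' @return data.frame with chrom, window, start, end, n_sites,
#'   n_sites_included, pi.
#' @export
pi_windows <- function(fourfold, variants, sites_per_window = 500,
                       min_called_fraction = 0.5) {
  sites <- if (is.data.frame(fourfold)) fourfold else fourfold$sites
  if (!nrow(sites)) {
    warning("no 4D sites called")
    return(data.frame(chrom = character(), window = integer(),
                      start = numeric(), end = numeric(), n_sites = integer(),
                      n_sites_included = integer(), pi = numeric()))
  }
  n_samples <- length(variants$samples)
  hit <- match_chrom_pos(sites, variants$sites)

  pi_site <- numeric(nrow(sites))
  frac <- rep(1, nrow(sites))
  has <- which(!is.na(hit))
  included <- rep(TRUE, nrow(sites))
  if (length(has)) {
    sp <- site_pi_from_gt(variants$gt[hit[has], , drop = FALSE])
    defined <- !is.na(sp$pi)
    pi_site[has] <- ifelse(defined, sp$pi, 0)
    frac[has] <- sp$k / (2 * n_samples)
    ## sites with < 2 called alleles have undefined pi and are excluded
    included[has[!defined]] <- FALSE
  }
  included <- included & frac >= min_called_fraction
  windows_from_sites(sites, pi_site, included, sites_per_window)
}

windows_from_sites <- function(sites, pi_site, included, spw) {
  out <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
    idx <- idx[order(sites$pos[idx])]
    n <- length(idx)
    w <- (seq_len(n) - 1L) %/% spw + 1L
    full <- tabulate(w)
    keep_w <- which(full >= spw / 2)
    rows <- lapply(keep_w, function(wi) {
      ii <- idx[w == wi]
      inc <- ii[included[ii]]
      data.frame(chrom = sites$chrom[ii[1]], window = wi,
                 start = min(sites$pos[ii]), end = max(sites$pos[ii]) + 1,
                 n_sites = length(ii), n_sites_included = length(inc),
                 pi = if (length(inc)) mean(pi_site[inc]) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise diversity between two samples
#'
#' Per site, the mean proportion of differing alleles across the four
#' between-sample allele pairs (the mode used when within-population samples
#' are unsuitable, e.g. a bottlenecked population). Windows as in
#' [pi_windows()].
#'
#' @inheritParams pi_windows
#' @param samples exactly two sample names.
#' @return data.frame as [pi_windows()].
#' @export
pairwise_pi <- function(fourfold, variants, samples,
                        sites_per_window = 500) {
  if (length(samples) != 2) stop("pairwise mode needs exactly two samples")
  missing <- setdiff(samples, variants$samples)
  if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
  sites <- if (is.data.frame(fourfold)) fourfold else fourfold$sites
  hit <- match_chrom_pos(sites, variants$sites)

  pi_site <- numeric(nrow(sites))
  included <- rep(TRUE, nrow(sites))
  has <- which(!is.na(hit))
  if (length(has)) {
    gt <- variants$gt[hit[has], samples, drop = FALSE]
    a1 <- sub("/.*", "", gt); a2 <- sub(".*/", "", gt)
    ok <- a1[, 1] != "." & a2[, 1] != "." & a1[, 2] != "." & a2[, 2] != "."
    diffs <- (a1[, 1] != a1[, 2]) + (a1[, 1] != a2[, 2]) +
             (a2[, 1] != a1[, 2]) + (a2[, 1] != a2[, 2])
    pi_site[has] <- ifelse(ok, diffs / 4, 0)
    included[has] <- ok
  }
  windows_from_sites(sites, pi_site, included, sites_per_window)
}

#' Per-ancestral-chromosome diversity summary
#'
#' Maps windows (by midpoint) onto ancestral homolog segments, averages
#' window pi per homolog (unweighted), and normalizes by the mean over
#' not-fused (NFC) homologs so species with different effective population
#' sizes are comparable.
#'
#' @param windows output of [pi_windows()] or [pairwise_pi()].
#' @param segments segment table from [fusion_segments()] (derived_chrom,
#'   homolog, start, end); windows on chromosomes absent from the table keep
#'   their own chromosome id as homolog.
#' @param class_table classification from [classify_chromosomes()].
#' @return data.frame homolog, n_windows, pi, pi_norm, class.
#' @export
chromosome_diversity_summary <- function(windows, segments, class_table) {
  mid <- (windows$start + windows$end) / 2
  homolog <- windows$chrom
  if (!is.null(segments) && nrow(segments)) {
    for (i in seq_len(nrow(segments))) {
      inseg <- windows$chrom == segments$derived_chrom[i] &
        mid >= segments$start[i] & mid < segments$end[i]
      homolog[inseg] <- segments$homolog[i]
    }
  }
  agg <- stats::aggregate(windows$pi, list(homolog = homolog),
                          function(x) mean(x, na.rm = TRUE))
  names(agg)[2] <- "pi"
  agg$n_windows <- as.integer(table(homolog)[agg$homolog])
  cls <- stats::setNames(class_table$class, class_table$homolog)
  agg$class <- unname(cls[agg$homolog])
  nfc_mean <- mean(agg$pi[agg$class == "NFC"], na.rm = TRUE)
  if (!is.finite(nfc_mean) || nfc_mean <= 0)
    stop("cannot normalize: no NFC diversity available")
  agg$pi_norm <- agg$pi / nfc_mean
  agg[, c("homolog", "n_windows", "pi", "pi_norm", "class")]
}

#' Relative change in normalized diversity between an extant species and its
#' inferred ancestor
#'
#' `dpi_rel = (pi_norm_extant - pi_norm_ancestor) / pi_norm_ancestor`, per
#' homolog. The ratio form mirrors the relative recombination-rate change;
#' the choice of formula is recorded in the `"definition"` attribute.
#'
#' @param extant,ancestor summaries from [chromosome_diversity_summary()].
#' @return data.frame homolog, class, pi_norm_extant, pi_norm_ancestor,
#'   dpi_rel.
#' @export
relative_diversity_change <- function(extant, ancestor) {
  m <- merge(extant[, c("homolog", "class", "pi_norm")],
             ancestor[, c("homolog", "pi_norm")],
             by = "homolog", suffixes = c("_extant", "_ancestor"))
  m$dpi_rel <- (m$pi_norm_extant - m$pi_norm_ancestor) / m$pi_norm_ancestor
  attr(m, "definition") <- "ratio: (extant - ancestor) / ancestor on NFC-normalized pi_4D"
  m
}

#' Recombination-rate change under a fixed map length per chromosome
#'
#' Assumes one obligate crossover per bivalent per meiosis, i.e. a genetic
#' map length of 50 cM per chromosome regardless of physical length. The
#' per-base rate is r = M / L (cM/Mb); for a homolog that is now part of a
#' fused chromosome, the extant length is the length of the whole fused
#' chromosome. The relative decrease is `dr_rel = 1 - r_extant / r_anc`
#' (negative values mean the rate increased, e.g. after genome shrinkage of
#' unfused chromosomes).
#'
#' @param lengths_anc named vector: ancestral (outgroup) length in bp per
#'   homolog.
#' @param lengths_extant named vector: length in bp of the extant chromosome
#'   each homolog now resides on (the fused chromosome for fused homologs).
#' @param map_anc,map_extant map lengths in cM: scalar default 50, or named
#'   vectors (e.g. observed map lengths from [read_linkage_map()] +
#'   [map_lengths()]).
#' @return data.frame homolog, L_anc, L_extant, M_anc, M_extant, r_anc,
#'   r_extant (cM/Mb), dr_rel.
#' @export
recombination_model <- function(lengths_anc, lengths_extant,
                                map_anc = 50, map_extant = 50) {
  homologs <- names(lengths_anc)
  if (is.null(homologs)) stop("lengths_anc must be named by homolog")
  le <- lengths_extant[homologs]
  expand <- function(m) if (length(m) == 1 && is.null(names(m)))
    rep(m, length(homologs)) else as.numeric(m[homologs])
  M_anc <- expand(map_anc); M_extant <- expand(map_extant)
  r_anc <- M_anc / (lengths_anc / 1e6)
  r_extant <- M_extant / (le / 1e6)
  data.frame(homolog = homologs,
             L_anc = as.numeric(lengths_anc), L_extant = as.numeric(le),
             M_anc = M_anc, M_extant = M_extant,
             r_anc = r_anc, r_extant = r_extant,
             dr_rel = 1 - r_extant / r_anc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlation between diversity change and recombination-rate change
#'
#' Spearman rank correlation of the per-homolog relative diversity change
#' against the relative recombination-rate decrease. `stats::cor.test`
#' supplies the exact permutation distribution for small tie-free samples and
#' the large-sample approximation otherwise; ties get average ranks.
#'
#' @param dpi_rel,dr_rel paired per-homolog values.
#' @param use_magnitude if `TRUE`, correlate `|dpi_rel|` with `dr_rel`
#'   (larger rate decrease predicting larger diversity loss gives positive
#'   rho); if `FALSE`, use signed values (expected rho negative).
#' @param alternative passed to [stats::cor.test()] (`"two.sided"`,
#'   `"greater"`, `"less"`).
#' @return list with rho, p, n and the orientation used.
#' @export
diversity_recombination_correlation <- function(dpi_rel, dr_rel,
                                                use_magnitude = FALSE,
                                                alternative = "two.sided") {
  ok <- is.finite(dpi_rel) & is.finite(dr_rel)
  if (sum(ok) < 5) stop("need at least 5 paired homolog values")
  x <- dr_rel[ok]
  y <- if (use_magnitude) abs(dpi_rel[ok]) else dpi_rel[ok]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = alternative))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       orientation = if (use_magnitude)
       "|dpi_rel| vs dr_rel (positive rho = more rate decrease, more diversity loss)"
       else "signed dpi_rel vs dr_rel (negative rho expected)")
}
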