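## Synthetic two-species system with known ground truth: an ancestral
## 31-chromosome genome and a derived genome in which the 10 shortest
## ancestral chromosomes have each fused onto a distinct longer one. Repeat
## and GC density are enriched at chromosome tails; per-chromosome diversity
## decreases with chromosome length; functional-element retention in a target
## species decreases with chromosome length and divergence time. Every
## realization is reproducible from (config, seed), and each stage draws from
## its own substream so toggling one stage does not shift another's draws.

#' Simulation configuration
#'
#' Defaults mirror the karyotype studied by the pipeline: 31 ancestral
#' chromosomes, 10 fusions each joining a short chromosome to a longer one,
#' tail-enriched GC and repeats, a diversity gradient
#' `pi(L) = pi_a - pi_b * log10(L)` (floored at `pi_floor`), 6 resequenced
#' diploid individuals, and element-retention probability
#' `plogis(c0 - c_len * L_Mb - c_time * T_Myr)` at divergence times 26, 65
#' and 85 Myr. Chromosome lengths are drawn log-uniform from `length_range`;
#' the default range is scaled down from real lepidopteran chromosomes to
#' keep Monte-Carlo replication tractable.
#'
#' @param seed master integer seed; every stage derives a substream from it.
#' @param n_chromosomes number of ancestral chromosomes.
#' @param length_range bp range for log-uniform chromosome lengths.
#' @param n_fusions number of fusions (<= floor(n_chromosomes/2)).
#' @param random_pairing if `TRUE`, fusion partners are drawn at random
#'   instead of pairing the shortest with longer chromosomes (null model).
#' @param tail_enrichment repeat-intensity multiplier at chromosome ends
#'   (>= 1); position intensity is
#'   `lambda0 * (1 + (tail_enrichment - 1) * (2|x/L - 0.5|)^2)`.
#' @param gc_base baseline GC fraction of non-repeat sequence.
#' @param gc_tail_amp added GC fraction at the extreme tails (same quadratic
#'   profile as repeats).
#' @param repeat_density genome fraction covered by repeats (before merging)
#'   on the longest chromosome.
#' @param repeat_size_effect relative repeat-density excess of the shortest
#'   chromosome over the longest (densities interpolate on log-length);
#'   emulates the higher repeat load of small chromosomes.
#' @param gc_size_effect GC-fraction excess of the shortest chromosome over
#'   the longest.
#' @param repeat_mean_len mean repeat length (bp).
#' @param coding_density genome fraction covered by CDS.
#' @param exons_per_gene,exon_length,intron_length gene-model shape (bp).
#' @param pi_a,pi_b,pi_floor diversity model pi(L) = pi_a - pi_b*log10(L),
#'   floored.
#' @param n_individuals diploid individuals carried in the VCF.
#' @param dp_mean mean read depth; `gq_low_rate` fraction of genotypes drawn
#'   with low GQ to exercise the filters.
#' @param gq_low_rate see above.
#' @param c0,c_len,c_time element-retention logistic coefficients (c_len per
#'   Mb, c_time per Myr).
#' @param divergence_times target divergence times (Myr).
#' @param elements_per_mb functional elements (per kind) per Mb.
#' @param decoy_rate fraction of lost elements that still produce a
#'   one-directional decoy hit.
#' @param discordant_rate fraction of anchors relabeled to a random wrong
#'   homolog (0 by default: anchors represent curated orthology).
#' @return a list of class `kf_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 31,
                       length_range = c(1.5e5, 6e5),
                       n_fusions = 10,
                       random_pairing = FALSE,
                       tail_enrichment = 3,
                       gc_base = 0.34,
                       gc_tail_amp = 0.08,
                       repeat_density = 0.20,
                       repeat_size_effect = 0.5,
                       gc_size_effect = 0.04,
                       repeat_mean_len = 400,
                       coding_density = 0.10,
                       exons_per_gene = 5,
                       exon_length = 150,
                       intron_length = 200,
                       pi_a = 0.12, pi_b = 0.018, pi_floor = 1e-4,
                       n_individuals = 6,
                       dp_mean = 30, gq_low_rate = 0.05,
                       c0 = 4.5, c_len = 10, c_time = 0.03,
                       divergence_times = c(26, 65, 85),
                       elements_per_mb = 200,
                       decoy_rate = 0.3,
                       discordant_rate = 0) {
  if (n_fusions > floor(n_chromosomes / 2))
    stop("n_fusions must be <= floor(n_chromosomes/2)")
  if (tail_enrichment < 1) stop("tail_enrichment must be >= 1")
  cfg <- as.list(environment())
  class(cfg) <- "kf_sim_config"
  cfg
}

pi_of_length <- function(L, config) {
  out <- pmax(config$pi_floor, config$pi_a - config$pi_b * log10(L))
  names(out) <- names(L)
  out
}

random_bases <- function(n, gc) {
  bases <- charToRaw("ACGT")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rawToChar(bases[sample.int(4L, n, replace = TRUE, prob = p)])
}

## random sequence with a tail-elevated GC profile, generated in 10 kb blocks
random_sequence <- function(L, gc_base, gc_tail_amp, block = 10000) {
  nb <- ceiling(L / block)
  starts <- (seq_len(nb) - 1) * block
  sizes <- pmin(block, L - starts)
  relpos <- (starts + sizes / 2) / L
  gc <- pmin(0.95, gc_base + gc_tail_amp * (2 * abs(relpos - 0.5))^2)
  chunks <- vapply(seq_len(nb), function(i) random_bases(sizes[i], gc[i]),
                   character(1))
  paste(chunks, collapse = "")
}

## sequence only within gene spans (flat GC), N elsewhere: cheap stand-in for
## runs where only coding sequence matters (diversity-only experiments)
genic_sequence <- function(L, gene_start, gene_end, gc) {
  if (!length(gene_start)) return(strrep("N", L))
  o <- order(gene_start)
  gene_start <- gene_start[o]; gene_end <- gene_end[o]
  gaps <- c(gene_start, L) - c(0, gene_end)
  chunks <- character(2 * length(gene_start) + 1)
  chunks[seq(1, length(chunks), 2)] <- strrep("N", gaps)
  chunks[seq(2, length(chunks), 2)] <-
    vapply(gene_end - gene_start, random_bases, character(1), gc = gc)
  paste(chunks, collapse = "")
}

## repeat intervals with per-position intensity
## lambda(x) = lambda0 * (1 + (te - 1) * (2|x/L - 0.5|)^2), sampled by
## rejection from the envelope te * lambda0
place_repeats <- function(L, density, mean_len, te) {
  m <- round(L * density / mean_len)
  if (m == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  xs <- numeric(0)
  while (length(xs) < m) {
    cand <- stats::runif(2 * m, 0, L)
    w <- (1 + (te - 1) * (2 * abs(cand / L - 0.5))^2) / max(1, te)
    xs <- c(xs, cand[stats::runif(2 * m) < w])
  }
  xs <- xs[seq_len(m)]
  len <- pmax(50, round(stats::rexp(m, 1 / mean_len)))
  start <- pmax(0, round(xs - len / 2))
  end <- pmin(L, start + len)
  ok <- end > start
  data.frame(start = start[ok], end = end[ok])
}

## non-overlapping gene placement avoiding repeats; returns start positions
place_genes <- function(L, n, span, repeats) {
  if (n == 0) return(numeric(0))
  placed <- numeric(0)
  ir <- if (nrow(repeats)) IRanges::IRanges(repeats$start + 1, repeats$end)
  for (batch in 1:6) {
    cand <- floor(stats::runif(6 * n, 0, max(1, L - span)))
    if (!is.null(ir)) {
      cr <- IRanges::IRanges(cand + 1, cand + span)
      cand <- cand[IRanges::countOverlaps(cr, ir) == 0]
    }
    cand <- sort(c(placed, cand))
    keep <- numeric(0)
    last_end <- -Inf
    for (s in cand) {
      if (s >= last_end) { keep <- c(keep, s); last_end <- s + span }
      if (length(keep) == n) break
    }
    placed <- keep
    if (length(placed) == n) break
  }
  if (length(placed) < n / 2)
    stop("infeasible packing: gene + repeat densities too high; lower them")
  placed
}

## all gene-model rows for one chromosome at once (gene/mRNA/exon/CDS with
## phases); exon sizes jittered so phases other than 0 occur, total CDS
## length kept divisible by 3
gene_models_for_chrom <- function(chrom, gstart, strands, config) {
  n <- length(gstart)
  if (!n) return(NULL)
  ne <- config$exons_per_gene
  S <- matrix(config$exon_length +
                sample(c(-2L, -1L, 0L, 1L, 2L), ne * n, replace = TRUE), ne, n)
  S[ne, ] <- S[ne, ] - colSums(S) %% 3L
  gaps <- rbind(0, S[-ne, , drop = FALSE] + config$intron_length)
  starts <- sweep(apply(gaps, 2, cumsum), 2, gstart, `+`)
  ends <- starts + S
  gene_id <- sprintf("%s_g%03d", chrom, seq_len(n))
  tx_id <- paste0(gene_id, ".t1")
  ## phase: bases to skip to reach the first full codon, in transcription order
  St <- S
  minus <- strands == "-"
  St[, minus] <- S[rev(seq_len(ne)), minus, drop = FALSE]
  cb <- rbind(0, apply(St[-ne, , drop = FALSE], 2, cumsum))
  ph <- (3 - cb %% 3) %% 3
  ph[, minus] <- ph[rev(seq_len(ne)), minus, drop = FALSE]
  gene_end <- ends[ne, ]
  strand_rep <- rep(strands, each = ne)
  rbind(
    data.frame(chrom = chrom, start = rep(gstart, 2), end = rep(gene_end, 2),
               strand = rep(strands, 2),
               kind = rep(c("gene", "mRNA"), each = n),
               parent = c(rep(NA_character_, n), gene_id),
               phase = NA_integer_, id = c(gene_id, tx_id),
               stringsAsFactors = FALSE),
    data.frame(chrom = chrom, start = c(as.vector(starts), as.vector(starts)),
               end = c(as.vector(ends), as.vector(ends)),
               strand = c(strand_rep, strand_rep),
               kind = rep(c("exon", "CDS"), each = ne * n),
               parent = rep(rep(tx_id, each = ne), 2),
               phase = c(rep(NA_integer_, ne * n), as.integer(as.vector(ph))),
               id = NA_character_, stringsAsFactors = FALSE)
  )
}

#' Simulate the ancestral genome
#'
#' Draws chromosome lengths log-uniform over `length_range` (labelled
#' anc01..ancNN in decreasing length order), places repeats with
#' tail-enriched intensity, generates tail-elevated GC sequence, and places
#' multi-exon genes on both strands outside repeats.
#'
#' @param config a [sim_config()].
#' @param with_sequence `TRUE` for full sequence, `FALSE` for a
#'   lengths-and-annotation-only genome (sufficient for anchor/fusion work),
#'   or `"genic"` for sequence inside gene spans only with N elsewhere
#'   (sufficient for diversity work; composition profiles need full
#'   sequence).
#' @return list: genome ([kf_genome()]), features (gene models + synthesized
#'   introns), repeats, truth (list with per-chromosome true pi).
#' @export
simulate_ancestral_genome <- function(config, with_sequence = TRUE) {
  genic <- identical(with_sequence, "genic")
  set.seed(substream_seed(config$seed, 101))
  n <- config$n_chromosomes
  L <- sort(round(10^stats::runif(n, log10(config$length_range[1]),
                                  log10(config$length_range[2]))),
            decreasing = TRUE)
  ids <- sprintf("anc%02d", seq_len(n))
  ## upper bound on a gene's genomic span (exon sizes are jittered by <= 2 bp)
  gene_span <- config$exons_per_gene * (config$exon_length + 2) +
    (config$exons_per_gene - 1) * config$intron_length
  cds_per_gene <- config$exons_per_gene * config$exon_length

  feats <- vector("list", n)
  reps <- vector("list", n)
  want_seq <- genic || isTRUE(with_sequence)
  seqs <- if (want_seq) character(n) else NULL
  ## smaller chromosomes carry denser repeats and higher GC, interpolated on
  ## log-length (0 = longest, 1 = shortest)
  lg <- log10(L)
  smallness <- if (max(lg) > min(lg)) (max(lg) - lg) / (max(lg) - min(lg)) else
    rep(0, n)
  rep_density <- config$repeat_density * (1 + config$repeat_size_effect * smallness)
  gc_chrom <- config$gc_base + config$gc_size_effect * smallness
  for (i in seq_len(n)) {
    r <- place_repeats(L[i], rep_density[i], config$repeat_mean_len,
                       config$tail_enrichment)
    r <- if (nrow(r)) merge_intervals(cbind(chrom = ids[i], r)) else
      data.frame(chrom = character(), start = numeric(), end = numeric())
    n_genes <- round(L[i] * config$coding_density / cds_per_gene)
    gstart <- place_genes(L[i], n_genes, gene_span, r)
    strands <- sample(c("+", "-"), length(gstart), replace = TRUE)
    feats[[i]] <- gene_models_for_chrom(ids[i], gstart, strands, config)
    reps[[i]] <- r
    if (genic) {
      gn <- feats[[i]][feats[[i]]$kind == "gene", , drop = FALSE]
      seqs[i] <- genic_sequence(L[i], gn$start, gn$end, gc_chrom[i])
    } else if (want_seq) {
      seqs[i] <- random_sequence(L[i], gc_chrom[i],
                                 if (config$tail_enrichment > 1) config$gc_tail_amp else 0)
    }
  }
  features <- do.call(rbind, feats)
  features <- rbind(features, synthesize_introns(features))
  repeats <- do.call(rbind, reps)
  repeats$strand <- "."; repeats$kind <- "repeat"
  repeats$parent <- NA_character_; repeats$phase <- NA_integer_
  if (want_seq) names(seqs) <- ids
  genome <- kf_genome(data.frame(id = ids, species = "ancestor", length = L,
                                 homology_group = ids, stringsAsFactors = FALSE),
                      seq = seqs)
  truth <- list(pi = data.frame(homolog = ids, length = L,
                                pi_true = pi_of_length(L, config),
                                stringsAsFactors = FALSE))
  list(genome = genome, features = features, repeats = repeats, truth = truth)
}

#' Apply fusions to an ancestral genome
#'
#' The `n_fusions` shortest chromosomes are each concatenated onto a distinct
#' longer partner (head or tail at random, recorded); with
#' `random_pairing = TRUE` partners are drawn without regard to length.
#' Sequences, gene models and repeats are carried over unchanged (the
#' ancestral-concatenation state, i.e. no post-fusion repeat turnover; see
#' [resample_repeats()] for the post-selection regime).
#'
#' @param ancestral output of [simulate_ancestral_genome()].
#' @param config the same [sim_config()].
#' @return list: genome (derived [kf_genome()]), features, repeats, truth
#'   (fusion table with breakpoints + segment table + per-chromosome pi), and
#'   anchors (gene-midpoint anchor table for [build_anchor_map()]).
#' @export
apply_fusions <- function(ancestral, config) {
  set.seed(substream_seed(config$seed, 102))
  info <- ancestral$genome$info
  nf <- config$n_fusions
  if (nf > floor(nrow(info) / 2)) stop("too many fusions for chromosome count")
  if (config$random_pairing) {
    picked <- sample(info$id, 2 * nf)
    shorts <- picked[seq_len(nf)]
    partners <- picked[nf + seq_len(nf)]
  } else {
    ord <- order(info$length)
    shorts <- info$id[ord][seq_len(nf)]
    partners <- sample(setdiff(info$id, shorts), nf)
  }
  short_at_head <- sample(c(TRUE, FALSE), nf, replace = TRUE)

  lens <- stats::setNames(info$length, info$id)
  comp <- list()
  for (k in seq_len(nf)) {
    pair <- if (short_at_head[k]) c(shorts[k], partners[k]) else
      c(partners[k], shorts[k])
    comp[[length(comp) + 1]] <- pair
  }
  for (id in setdiff(info$id, c(shorts, partners)))
    comp[[length(comp) + 1]] <- id

  dlen <- vapply(comp, function(p) sum(lens[p]), numeric(1))
  ord2 <- order(dlen, decreasing = TRUE)
  comp <- comp[ord2]; dlen <- dlen[ord2]
  dids <- sprintf("chr%02d", seq_along(comp))

  segs <- list(); fus <- list()
  seqs <- if (!is.null(ancestral$genome$seq)) character(length(comp)) else NULL
  for (i in seq_along(comp)) {
    p <- comp[[i]]
    offs <- cumsum(c(0, lens[p][-length(p)]))
    segs[[i]] <- data.frame(derived_chrom = dids[i], homolog = p,
                            start = offs, end = offs + lens[p],
                            stringsAsFactors = FALSE)
    if (length(p) == 2) {
      sfc <- if (lens[p[1]] < lens[p[2]]) p[1] else p[2]
      fus[[length(fus) + 1]] <-
        data.frame(derived_chrom = dids[i], left_homolog = p[1],
                   right_homolog = p[2], breakpoint = offs[2],
                   sfc = sfc, lfc = setdiff(p, sfc),
                   short_at_head = p[1] == sfc, stringsAsFactors = FALSE)
    }
    if (!is.null(seqs)) seqs[i] <- paste(ancestral$genome$seq[p], collapse = "")
  }
  segments <- do.call(rbind, segs)
  ## shift all annotations at once: ancestral chrom -> (derived chrom, offset)
  off <- stats::setNames(segments$start, segments$homolog)
  dchr <- stats::setNames(segments$derived_chrom, segments$homolog)
  shift <- function(df) {
    df$start <- df$start + off[df$chrom]
    df$end <- df$end + off[df$chrom]
    df$chrom <- unname(dchr[df$chrom])
    df
  }
  features <- shift(ancestral$features)
  repeats <- shift(ancestral$repeats)
  fusions <- do.call(rbind, fus)
  if (!is.null(seqs)) names(seqs) <- dids
  hg <- vapply(comp, paste, character(1), collapse = "+")
  genome <- kf_genome(data.frame(id = dids, species = "derived", length = dlen,
                                 homology_group = hg, stringsAsFactors = FALSE),
                      seq = seqs)
  rownames(segments) <- rownames(fusions) <- rownames(features) <-
    rownames(repeats) <- NULL

  anchors <- make_anchors(features, segments, config)
  truth <- ancestral$truth
  truth$fusions <- fusions
  truth$segments <- segments
  list(genome = genome, features = features, repeats = repeats,
       truth = truth, anchors = anchors)
}

## gene-midpoint anchors labeled with the true ancestral homolog; an optional
## fraction is relabeled to a random wrong homolog (translocation noise)
make_anchors <- function(features, segments, config) {
  genes <- features[features$kind == "gene", , drop = FALSE]
  pos <- floor((genes$start + genes$end) / 2)
  homolog <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    hit <- genes$chrom == s$derived_chrom & pos >= s$start & pos < s$end
    homolog[hit] <- s$homolog
  }
  anchors <- data.frame(chrom = genes$chrom, pos = pos, homolog = homolog,
                        anchor_id = genes$id, stringsAsFactors = FALSE)
  if (config$discordant_rate > 0) {
    flip <- stats::runif(nrow(anchors)) < config$discordant_rate
    pool <- unique(segments$homolog)
    anchors$homolog[flip] <- vapply(anchors$homolog[flip], function(h)
      sample(setdiff(pool, h), 1), character(1))
  }
  anchors[order(anchors$chrom, anchors$pos), ]
}

#' Resample repeats under the current karyotype
#'
#' Places a fresh repeat landscape whose tail-enriched intensity profile
#' follows the *current* chromosomes (for a fused genome, tails of the fused
#' chromosome, with no relic enrichment at the fusion point). This is the
#' post-selection regime in which central repeats have been purged after a
#' fusion; contrast with the carried-over repeats from [apply_fusions()].
#'
#' @param genome a [kf_genome()].
#' @param config a [sim_config()].
#' @param stream substream offset (change to decorrelate from other stages).
#' @return repeat interval data.frame.
#' @export
resample_repeats <- function(genome, config, stream = 103) {
  set.seed(substream_seed(config$seed, stream))
  lg <- log10(genome$info$length)
  smallness <- if (max(lg) > min(lg)) (max(lg) - lg) / (max(lg) - min(lg)) else
    rep(0, length(lg))
  dens <- config$repeat_density * (1 + config$repeat_size_effect * smallness)
  out <- lapply(seq_len(nrow(genome$info)), function(i) {
    r <- place_repeats(genome$info$length[i], dens[i],
                       config$repeat_mean_len, config$tail_enrichment)
    if (!nrow(r)) return(NULL)
    merge_intervals(cbind(chrom = genome$info$id[i], r))
  })
  out <- do.call(rbind, out)
  out$strand <- "."; out$kind <- "repeat"
  out$parent <- NA_character_; out$phase <- NA_integer_
  rownames(out) <- NULL
  out
}

#' Simulate resequencing variants
#'
#' Plants segregating sites only at 4D-eligible third codon positions
#' (enumerated from the reference gene models) so the diversity stage's
#' estimate is directly interpretable against truth. Per chromosome, the
#' expected per-site heterozygosity equals `pi(L)` of the chromosome the site
#' resides on (for a fused genome, the fused chromosome's length — the
#' recombination-driven diversity shift). A site is segregating with
#' probability `pi(L) / hbar` where `hbar` is the mean heterozygosity of a
#' segregating site under a uniform allele-count spectrum; genotypes are
#' binomial draws at the site frequency. DP is Poisson around `dp_mean`; GQ
#' is 99 except for a `gq_low_rate` fraction drawn low to exercise filters.
#'
#' @param genome a [kf_genome()] with sequence.
#' @param features its gene models.
#' @param config a [sim_config()].
#' @param stream substream offset (use different values for different
#'   species).
#' @param eligible optional precomputed 4D-eligible site table (from
#'   [call_fourfold_sites()] with no variants), e.g. the ancestral set mapped
#'   through known fusion segments; enumerated from `features` when `NULL`.
#' @return list: variants ([kf_variants()]), truth (per-chromosome expected
#'   pi), n_eligible (4D-eligible site count per chromosome).
#' @export
simulate_variants <- function(genome, features, config, stream = 104,
                              eligible = NULL) {
  set.seed(substream_seed(config$seed, stream))
  if (is.null(eligible)) {
    coding <- nonoverlapping_coding_intervals(features)
    eligible <- call_fourfold_sites(genome, coding, variants = NULL)$sites
  }
  n_ind <- config$n_individuals
  n_all <- 2L * n_ind
  counts <- seq_len(n_all - 1)
  hbar <- mean(2 * (counts / n_all) * (1 - counts / n_all))

  lens <- chrom_lengths(genome)
  pi_target <- pi_of_length(lens, config)
  q <- pi_target / hbar
  if (any(q > 1)) stop("pi target too high for the site-frequency model")

  qe <- q[eligible$chrom]
  if (anyNA(qe)) stop("internal error: eligible site on unknown chromosome")
  seg <- stats::runif(nrow(eligible)) < qe
  sites <- eligible[seg, , drop = FALSE]
  n <- nrow(sites)
  samples <- sprintf("ind%02d", seq_len(n_ind))
  if (n == 0) {
    v <- kf_variants(data.frame(chrom = character(), pos = numeric(),
                                ref = character(), alts = character(),
                                stringsAsFactors = FALSE),
                     matrix(character(), 0, n_ind, dimnames = list(NULL, samples)),
                     matrix(integer(), 0, n_ind), matrix(integer(), 0, n_ind))
  } else {
    f <- sample(counts, n, replace = TRUE) / n_all
    ## reference base per site, read from its own chromosome (vectorized)
    ref <- substring(genome$seq[sites$chrom], sites$pos + 1, sites$pos + 1)
    ## one random non-reference base per site
    bases <- c("A", "C", "G", "T")
    alt_table <- t(vapply(bases, function(b) setdiff(bases, b), character(3)))
    alt <- alt_table[cbind(match(ref, bases), sample.int(3L, n, replace = TRUE))]
    a1 <- matrix(stats::rbinom(n * n_ind, 1, f), n, n_ind)
    a2 <- matrix(stats::rbinom(n * n_ind, 1, f), n, n_ind)
    gt <- matrix(paste0(a1, "/", a2), n, n_ind,
                 dimnames = list(NULL, samples))
    dp <- matrix(stats::rpois(n * n_ind, config$dp_mean), n, n_ind)
    gq <- matrix(ifelse(stats::runif(n * n_ind) < config$gq_low_rate,
                        sample(0:30, n * n_ind, replace = TRUE), 99L), n, n_ind)
    v <- kf_variants(data.frame(chrom = sites$chrom, pos = sites$pos,
                                ref = unname(ref), alts = unname(alt),
                                stringsAsFactors = FALSE),
                     gt, dp, gq)
  }
  list(variants = v,
       truth = data.frame(chrom = names(lens), length = as.numeric(lens),
                          pi_true = as.numeric(pi_target),
                          stringsAsFactors = FALSE),
       n_eligible = table(eligible$chrom))
}

#' Simulate functional elements and similarity-hit tables
#'
#' Places CRE and exon element sets along each chromosome and, for each
#' divergence time, retains each element in the target with probability
#' `plogis(c0 - c_len * L_Mb - c_time * T_Myr)` (L = length of the
#' chromosome the element sits on). Retained elements yield reciprocal best
#' hits with e-value well below 1e-10; a fraction of lost elements yield a
#' one-directional decoy hit that must not survive the reciprocal filter.
#' Divergence is bookkept at the hit-table level (retention indicators +
#' synthetic hit rows), not by mutating sequence.
#'
#' @param genome a [kf_genome()] (sequence not required).
#' @param config a [sim_config()].
#' @param stream substream offset.
#' @param kinds element kinds to simulate (subset of `c("CRE", "exon")`).
#' @return list: elements (list CRE/exon of data.frames with id, chrom, start,
#'   end), hits (`hits[[kind]][[as.character(T)]]` = list(forward, reverse)),
#'   retention (truth: element id, kind, time_myr, retained).
#' @export
simulate_elements_and_hits <- function(genome, config, stream = 105,
                                       kinds = c("CRE", "exon")) {
  set.seed(substream_seed(config$seed, stream))
  info <- genome$info
  kinds <- c(CRE = 200L, exon = 300L)[kinds]   # element lengths by kind
  elements <- list()
  for (k in names(kinds)) {
    per <- lapply(seq_len(nrow(info)), function(i) {
      n <- max(1L, round(info$length[i] / 1e6 * config$elements_per_mb))
      start <- sort(round(stats::runif(n, 0, info$length[i] - kinds[[k]])))
      data.frame(id = sprintf("%s_%s_e%04d", k, info$id[i], seq_len(n)),
                 chrom = info$id[i], start = start, end = start + kinds[[k]],
                 stringsAsFactors = FALSE)
    })
    elements[[k]] <- do.call(rbind, per)
  }
  L_mb <- stats::setNames(info$length / 1e6, info$id)
  hits <- list(); retention <- list()
  for (k in names(kinds)) {
    el <- elements[[k]]
    hits[[k]] <- list()
    for (T_ in config$divergence_times) {
      p <- stats::plogis(config$c0 - config$c_len * L_mb[el$chrom] -
                           config$c_time * T_)
      kept <- stats::runif(nrow(el)) < p
      region <- sprintf("tgt%s_%s_r%05d", T_, el$chrom, seq_len(nrow(el)))
      mk_hit <- function(q, s, ev) {
        n <- length(q)
        data.frame(
          query_id = q, subject_id = s,
          percent_identity = round(stats::runif(n, 80, 100), 1),
          alignment_length = rep(kinds[[k]], n), mismatch = rep(0L, n),
          gapopen = rep(0L, n), q_start = rep(1L, n),
          q_end = rep(kinds[[k]], n), s_start = rep(1L, n),
          s_end = rep(kinds[[k]], n), evalue = ev,
          bitscore = round(stats::runif(n, 100, 500), 1),
          stringsAsFactors = FALSE)
      }
      ev_f <- 10^-stats::runif(sum(kept), 15, 60)
      ev_r <- 10^-stats::runif(sum(kept), 15, 60)
      fwd <- mk_hit(el$id[kept], region[kept], ev_f)
      rv <- mk_hit(region[kept], el$id[kept], ev_r)
      lost <- which(!kept)
      decoy <- lost[stats::runif(length(lost)) < config$decoy_rate]
      if (length(decoy)) {
        fwd <- rbind(fwd, mk_hit(el$id[decoy],
                                 sprintf("tgt%s_decoy_r%05d", T_, decoy),
                                 10^-stats::runif(length(decoy), 11, 30)))
      }
      hits[[k]][[as.character(T_)]] <- list(forward = fwd, reverse = rv)
      retention[[length(retention) + 1]] <-
        data.frame(id = el$id, kind = k, time_myr = T_, retained = kept,
                   chrom = el$chrom, stringsAsFactors = FALSE)
    }
  }
  list(elements = elements, hits = hits,
       retention = do.call(rbind, retention))
}

#' Write a full synthetic dataset to disk
#'
#' Writes FASTA, GFF3, repeat BED, VCF, anchor TSV, element BEDs, hit tables
#' and the truth tables for one simulated system, echoing the configuration
#' into a log file.
#'
#' @param sim output of [apply_fusions()] (derived system).
#' @param variants output of [simulate_variants()].
#' @param turnover output of [simulate_elements_and_hits()].
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, variants = NULL, turnover = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$genome$seq)) write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff3(sim$features, file.path(dir, "annotation.gff3"))
  write_bed(sim$repeats, file.path(dir, "repeats.bed"))
  utils::write.table(sim$anchors, file.path(dir, "anchors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$fusions, file.path(dir, "truth_fusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(variants)) {
    write_vcf(variants$variants, file.path(dir, "calls.vcf"))
    utils::write.table(variants$truth, file.path(dir, "truth_pi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(turnover)) {
    for (k in names(turnover$elements))
      write_bed(stats::setNames(turnover$elements[[k]],
                                c("parent", "chrom", "start", "end")),
                file.path(dir, paste0("elements_", k, ".bed")))
    for (k in names(turnover$hits))
      for (T_ in names(turnover$hits[[k]])) {
        write_hits(turnover$hits[[k]][[T_]]$forward,
                   file.path(dir, sprintf("hits_%s_T%s_fwd.tsv", k, T_)))
        write_hits(turnover$hits[[k]][[T_]]$reverse,
                   file.path(dir, sprintf("hits_%s_T%s_rev.tsv", k, T_)))
      }
    utils::write.table(turnover$retention, file.path(dir, "truth_retention.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
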