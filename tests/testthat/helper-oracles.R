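# Independent brute-force oracles used across the suite. They re-derive the
# quantities from first principles (translation tables, exhaustive pair
# enumeration, exhaustive changepoint scans) and share no code path with the
# implementation they check.

GC_TABLE <- Biostrings::GENETIC_CODE

# Is the third position of this codon 4-fold degenerate under every observed
# allele combination? `alleles` is a list of 3 character vectors (observed
# bases per codon position, reference included). A codon fails if any combo
# contains N or if any combo's four third-base variants translate to more
# than one amino acid.
oracle_codon_4d <- function(codon, alleles = NULL) {
  b <- strsplit(codon, "")[[1]]
  if (is.null(alleles))
    alleles <- list(b[1], b[2], b[3])
  combos <- expand.grid(alleles[[1]], alleles[[2]], alleles[[3]],
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cb <- unlist(combos[i, ])
    if (any(cb == "N")) return(FALSE)
    aas <- GC_TABLE[paste0(cb[1], cb[2], c("A", "C", "G", "T"))]
    if (length(unique(aas)) != 1) return(FALSE)
  }
  TRUE
}

# mean pairwise difference over all called alleles at one site
oracle_pi_site <- function(alleles) {
  alleles <- alleles[alleles != "."]
  k <- length(alleles)
  if (k < 2) return(NA_real_)
  diff <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    diff <- diff + (alleles[i] != alleles[j])
  diff / (k * (k - 1) / 2)
}

# exhaustive single-changepoint scan over sorted anchors with two homolog
# block labels (both orientations); returns minimal misassignment, the cut
# (largest flanking gap among ties) and the implied breakpoint
oracle_changepoint <- function(pos, labels) {
  o <- order(pos)
  pos <- pos[o]; labels <- labels[o]
  homs <- unique(labels)
  n <- length(pos)
  best <- NULL
  for (left in homs) for (i in 1:(n - 1)) {
    right_set <- setdiff(homs, left)
    for (right in right_set) {
      cost <- sum(labels[1:i] != left) + sum(labels[(i + 1):n] != right)
      gap <- pos[i + 1] - pos[i]
      if (is.null(best) || cost < best$cost ||
          (cost == best$cost && gap > best$gap)) {
        best <- list(cost = cost, gap = gap,
                     breakpoint = floor((pos[i] + pos[i + 1]) / 2),
                     left = left, right = right)
      }
    }
  }
  best
}

# all-pairs brute-force reciprocal best hits
oracle_rbh <- function(fwd, rev, emax) {
  best <- function(h, q) {
    d <- h[h$query_id == q, , drop = FALSE]
    d <- d[order(d$evalue, -d$bitscore, d$subject_id), , drop = FALSE]
    d[1, , drop = FALSE]
  }
  pairs <- character(0)
  for (q in unique(fwd$query_id)) {
    bf <- best(fwd, q)
    if (bf$evalue > emax) next
    if (!(bf$subject_id %in% rev$query_id)) next
    br <- best(rev, bf$subject_id)
    if (br$subject_id == q && br$evalue <= emax)
      pairs <- c(pairs, paste(q, bf$subject_id))
  }
  sort(pairs)
}

# SMA via the major axis (first eigenvector) of the standardized data,
# back-transformed to the original scales
oracle_sma_slope <- function(x, y) {
  xs <- scale(x); ys <- scale(y)
  v <- eigen(stats::cov(cbind(xs, ys)))$vectors[, 1]
  (v[2] / v[1]) * stats::sd(y) / stats::sd(x)
}

# random 12-column hit table
random_hits <- function(n, n_q, n_s, seed) {
  set.seed(seed)
  data.frame(query_id = sprintf("q%03d", sample.int(n_q, n, TRUE)),
             subject_id = sprintf("s%03d", sample.int(n_s, n, TRUE)),
             percent_identity = round(runif(n, 70, 100), 1),
             alignment_length = sample(50:500, n, TRUE),
             mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = 100L,
             s_start = 1L, s_end = 100L,
             evalue = 10^-sample(0:40, n, TRUE),  # ties on purpose
             bitscore = sample(seq(50, 500, by = 10), n, TRUE),
             stringsAsFactors = FALSE)
}

# tiny genome: one chromosome per entry of `seqs` (named character vector)
toy_genome <- function(seqs, species = "toy") {
  kf_genome(data.frame(id = names(seqs), species = species,
                       length = nchar(seqs),
                       homology_group = names(seqs),
                       stringsAsFactors = FALSE),
            seq = seqs)
}

# one plus-strand single-exon transcript covering [start, end) of `chrom`
toy_cds_annotation <- function(chrom, start, end, strand = "+", gene = "g1") {
  tx <- paste0(gene, ".t1")
  data.frame(chrom = chrom, start = c(start, start, start, start),
             end = c(end, end, end, end), strand = strand,
             kind = c("gene", "mRNA", "exon", "CDS"),
             parent = c(NA, gene, tx, tx),
             phase = c(NA, NA, NA, 0L),
             id = c(gene, tx, NA, NA), stringsAsFactors = FALSE)
}

# variants object from parallel vectors; gt is a character matrix
toy_variants <- function(chrom, pos, ref, alts, gt, dp = NULL, gq = NULL) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(pos))
  n <- nrow(gt); m <- ncol(gt)
  if (is.null(dp)) dp <- matrix(99L, n, m)
  if (is.null(gq)) gq <- matrix(99L, n, m)
  colnames(gt) <- sprintf("ind%02d", seq_len(m))
  kf_variants(data.frame(chrom = chrom, pos = pos, ref = ref, alts = alts,
                         stringsAsFactors = FALSE), gt, dp, gq)
}

mk_hits <- function(q, s, ev, bs = 200) {
  data.frame(query_id = q, subject_id = s, percent_identity = 95,
             alignment_length = 100L, mismatch = 0L, gapopen = 0L,
             q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
             evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
}

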