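# 4D-site calling, genotype filters, pi estimation, the 50 cM recombination
# model and the diversity~recombination correlation

test_that("one transcript per gene is kept and inter-gene CDS overlap is removed", {
  # gA has two isoforms (CDS lengths 300 and 450); gB one
  ann <- rbind(toy_cds_annotation("c", 0, 300, gene = "gA"),
               data.frame(chrom = "c", start = 1000, end = 1450, strand = "+",
                          kind = c("mRNA", "exon", "CDS"),
                          parent = c("gA", "gA.t2", "gA.t2"),
                          phase = c(NA, NA, 0L), id = c("gA.t2", NA, NA)),
               toy_cds_annotation("c", 2000, 2300, gene = "gB"))
  ci <- nonoverlapping_coding_intervals(ann)
  expect_setequal(unique(ci$transcript), c("gA.t2", "gB.t1"))  # 450 beats 300

  # two genes overlapping by one CDS interval: both copies removed
  ann2 <- rbind(toy_cds_annotation("c", 0, 300, gene = "g1"),
                toy_cds_annotation("c", 200, 500, gene = "g2"))
  ci2 <- nonoverlapping_coding_intervals(ann2)
  expect_equal(nrow(ci2), 0)
  expect_equal(attr(ci2, "n_removed_overlap"), 2)

  ann3 <- rbind(toy_cds_annotation("c", 0, 300, gene = "g1"),
                toy_cds_annotation("c", 400, 700, gene = "g2"))
  expect_equal(nrow(nonoverlapping_coding_intervals(ann3)), 2)
})

test_that("reference-only 4D calls pick exactly the third positions of 4-fold families", {
  # GGA: Gly family -> third position is 4D; ATG (Met) is not
  g <- toy_genome(c(c = "GGAATG"))
  ann <- toy_cds_annotation("c", 0, 6)
  res <- call_fourfold_sites(g, nonoverlapping_coding_intervals(ann))
  expect_equal(res$sites$pos, 2)
  expect_equal(res$counts[["codons_scanned"]], 2)

  # all 64 codons in a row: exactly the 32 codons of the 8 families qualify
  bases <- c("A", "C", "G", "T")
  all64 <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste, collapse = "")
  g2 <- toy_genome(c(c = paste(all64, collapse = "")))
  ann2 <- toy_cds_annotation("c", 0, 192)
  res2 <- call_fourfold_sites(g2, nonoverlapping_coding_intervals(ann2))
  expect_equal(nrow(res2$sites), 32)
  called_codons <- substring(g2$seq[["c"]], res2$sites$pos - 1, res2$sites$pos + 1)
  fams <- vapply(called_codons, function(cd) {
    aa <- Biostrings::GENETIC_CODE[paste0(substr(cd, 1, 2), bases)]
    length(unique(aa)) == 1
  }, logical(1))
  expect_true(all(fams))
})

test_that("observed variants make the caller conservative exactly as specified", {
  # CTA is Leu (4-fold), but a C->T variant at position 1 makes TTA (Leu2
  # family, third position NOT 4D): the codon must be discarded
  g <- toy_genome(c(c = "CTAGGA"))
  ann <- toy_cds_annotation("c", 0, 6)
  v <- toy_variants("c", 0, "C", "T", matrix(c("0/1", "0/0"), 1))
  res <- call_fourfold_sites(g, nonoverlapping_coding_intervals(ann), v)
  expect_equal(res$sites$pos, 5)   # only the GGA site survives
  expect_equal(res$counts[["rejected_non_4d"]], 1)

  # variants at two positions of one codon: automatic discard
  v2 <- toy_variants("c", c(0, 2), c("C", "A"), c("T", "G"),
                     matrix(c("0/1", "0/0", "0/1", "0/0"), 2, byrow = TRUE))
  res2 <- call_fourfold_sites(g, nonoverlapping_coding_intervals(ann), v2)
  expect_equal(res2$counts[["rejected_multi_variant"]], 1)
  expect_equal(res2$sites$pos, 5)

  # a third-position variant in a 4-fold codon is harmless (synonymous)
  v3 <- toy_variants("c", 2, "A", "G", matrix(c("0/1", "0/0"), 1))
  res3 <- call_fourfold_sites(g, nonoverlapping_coding_intervals(ann), v3)
  expect_equal(res3$sites$pos, c(2, 5))

  # an allele only present in uncalled genotypes is not "observed"
  v4 <- toy_variants("c", 0, "C", "T", matrix(c("./.", "./."), 1))
  res4 <- call_fourfold_sites(g, nonoverlapping_coding_intervals(ann), v4)
  expect_equal(res4$sites$pos, c(2, 5))

  # codons containing N are discarded
  g5 <- toy_genome(c(c = "GGNGGA"))
  res5 <- call_fourfold_sites(g5, nonoverlapping_coding_intervals(ann))
  expect_equal(res5$counts[["rejected_N"]], 1)
  expect_equal(res5$sites$pos, 5)
})

test_that("4D calling is strand-invariant", {
  cfg <- sim_config(seed = 23, n_chromosomes = 2, length_range = c(4e4, 6e4),
                    n_fusions = 1)
  anc <- simulate_ancestral_genome(cfg, with_sequence = "genic")
  v <- simulate_variants(anc$genome, anc$features, cfg)
  s1 <- call_fourfold_sites(anc$genome,
                            nonoverlapping_coding_intervals(anc$features),
                            v$variants)
  # reverse-complement every chromosome and flip all annotations/variants
  lens <- chrom_lengths(anc$genome)
  rc <- vapply(anc$genome$seq, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  g2 <- kf_genome(anc$genome$info, rc)
  f2 <- anc$features
  L <- lens[f2$chrom]
  new_start <- L - f2$end
  f2$end <- L - f2$start
  f2$start <- new_start
  f2$strand <- ifelse(f2$strand == "+", "-", "+")
  v2 <- v$variants
  v2$sites$pos <- lens[v2$sites$chrom] - 1 - v2$sites$pos
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v2$sites$ref <- unname(comp[v2$sites$ref])
  v2$sites$alts <- unname(comp[v2$sites$alts])
  s2 <- call_fourfold_sites(g2, nonoverlapping_coding_intervals(f2), v2)
  expect_equal(nrow(s2$sites), nrow(s1$sites))
  expect_setequal(lens[s2$sites$chrom] - 1 - s2$sites$pos, s1$sites$pos)
  # per-site diversity (windows of one site) is the same multiset
  w1 <- pi_windows(s1, v$variants, sites_per_window = 1)
  w2 <- pi_windows(s2, v2, sites_per_window = 1)
  expect_equal(sort(w1$pi), sort(w2$pi))
  expect_equal(mean(w1$pi), mean(w2$pi))
})

test_that("genotype filters apply strict DP/GQ thresholds and profiles", {
  v <- toy_variants("c", c(0, 1, 2), rep("A", 3), rep("G", 3),
                    matrix("0/1", 3, 1),
                    dp = matrix(c(10L, 11L, 6L), 3, 1),
                    gq = matrix(c(99L, 31L, 25L), 3, 1))
  f <- filter_genotypes(v)
  expect_equal(unname(f$gt[, 1]), c("./.", "0/1", "./."))  # DP=10 fails strict >10
  f2 <- filter_genotypes(v, profile = "low-coverage")
  expect_equal(unname(f2$gt[3, 1]), "0/1")                  # DP=6 GQ=25 passes (5, 20)
})

test_that("window pi matches the worked examples", {
  # one site, genotypes 0/0 and 0/1: alleles {0,0,0,1} -> pi = 0.5
  g <- toy_genome(c(c = strrep("GGA", 600)))
  ann <- toy_cds_annotation("c", 0, 1800)
  s4 <- call_fourfold_sites(g, nonoverlapping_coding_intervals(ann))
  expect_equal(nrow(s4$sites), 600)
  v <- toy_variants("c", 2, "A", "G", matrix(c("0/0", "0/1"), 1))
  w <- pi_windows(s4, v, sites_per_window = 500)
  expect_equal(nrow(w), 1)   # 600 sites: one full window + dropped 100-site tail
  expect_equal(w$pi, 0.5 / 500)   # exactly 0.001
  expect_equal(w$n_sites, 500)

  # all sites monomorphic -> pi exactly 0
  v0 <- toy_variants(character(0), numeric(0), character(0), character(0),
                     matrix(character(0), 0, 2))
  w0 <- pi_windows(s4, v0, sites_per_window = 300)
  expect_equal(w0$pi, c(0, 0))
})

test_that("pairwise mode enumerates the four cross pairs", {
  g <- toy_genome(c(c = strrep("GGA", 10)))
  ann <- toy_cds_annotation("c", 0, 30)
  s4 <- call_fourfold_sites(g, nonoverlapping_coding_intervals(ann))
  v <- toy_variants("c", c(2, 5, 8), rep("A", 3), rep("G", 3),
                    matrix(c("0/0", "0/1", "0/0",
                             "1/1", "0/1", "0/0"), 3))
  w <- pairwise_pi(s4, v, samples = c("ind01", "ind02"), sites_per_window = 10)
  # site 1: 0/0 vs 1/1 -> 1.0; site 2: 0/1 vs 0/1 -> 0.5; site 3: identical -> 0
  expect_equal(w$pi, (1 + 0.5 + 0) / 10)
  expect_error(pairwise_pi(s4, v, samples = c("ind01", "ind02", "x")), "two")
})

test_that("per-homolog summaries normalize by the NFC mean and difference correctly", {
  w <- data.frame(chrom = c("a1", "a2", "a3", "a4"), window = 1,
                  start = 0, end = 100,
                  n_sites = 500, n_sites_included = 500,
                  pi = c(0.01, 0.02, 0.03, 0.01))
  cls <- data.frame(homolog = c("a1", "a2", "a3", "a4"),
                    class = c("NFC", "NFC", "NFC", "SFC"))
  sm <- chromosome_diversity_summary(w, NULL, cls)
  expect_equal(sm$pi_norm[sm$homolog == "a4"], 0.5)
  expect_equal(mean(sm$pi_norm[sm$class == "NFC"]), 1)

  anc <- sm; ext <- sm
  ext$pi_norm[ext$homolog == "a4"] <- 0.4
  d <- relative_diversity_change(ext, anc)
  expect_equal(d$dpi_rel[d$homolog == "a4"], (0.4 - 0.5) / 0.5)
})

test_that("the 50 cM recombination model reproduces the stated arithmetic", {
  r <- recombination_model(c(sfc = 5e6, nfc = 10e6, same = 7e6),
                           c(sfc = 20e6, nfc = 8e6, same = 7e6))
  expect_equal(r$r_anc[r$homolog == "sfc"], 10)     # 50 cM / 5 Mb
  expect_equal(r$r_extant[r$homolog == "sfc"], 2.5) # 50 cM / 20 Mb
  expect_equal(r$dr_rel[r$homolog == "sfc"], 0.75)
  expect_equal(r$dr_rel[r$homolog == "nfc"], -0.25) # rate increase
  expect_equal(r$dr_rel[r$homolog == "same"], 0)
  # observed map lengths override the 50 cM default
  r2 <- recombination_model(c(a = 5e6), c(a = 5e6), map_extant = c(a = 55))
  expect_equal(r2$dr_rel, 1 - 55 / 50)
})

test_that("the diversity-recombination correlation behaves at the extremes", {
  dr <- 1:8 / 10
  dpi <- -(1:8) / 5
  res <- diversity_recombination_correlation(dpi, dr)
  expect_equal(res$rho, -1)
  res2 <- diversity_recombination_correlation(dpi, dr, use_magnitude = TRUE)
  expect_equal(res2$rho, 1)
  expect_error(diversity_recombination_correlation(dpi[1:3], dr[1:3]), "at least 5")
})
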