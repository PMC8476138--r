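test_that("anchor maps are built from hits with the ambiguity rule", {
  elements <- data.frame(id = c("e1", "e2", "e3"),
                         homolog = c("ancA", "ancA", "ancB"),
                         stringsAsFactors = FALSE)
  hits <- data.frame(
    query_id = c("e1", "e2", "e2", "e3"),
    subject_id = c("chr1", "chr1", "chr2", "chr1"),
    percent_identity = 95, alignment_length = 100, mismatch = 0, gapopen = 0,
    q_start = 1, q_end = 100,
    s_start = c(101, 201, 150, 301), s_end = c(200, 300, 249, 400),
    evalue = c(1e-40, 1e-30, 1e-30, 1e-50),   # e2 ambiguous: equal e-values
    bitscore = c(200, 150, 150, 300), stringsAsFactors = FALSE)
  am <- build_anchor_map(elements = elements, hits = hits)
  expect_equal(nrow(am), 2)
  expect_equal(attr(am, "n_dropped_ambiguous"), 1)
  expect_equal(am$homolog, c("ancA", "ancB"))
  # 1-based inclusive hit span [101, 200] -> 0-based midpoint floor((100+200)/2)
  expect_equal(am$pos[1], 150)

  empty <- build_anchor_map(elements = elements, hits = hits[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(detect_fusions(empty), "empty")
})

test_that("fusion detection follows the midpoint rule on clean and interleaved anchors", {
  clean <- data.frame(chrom = "chr1",
                      pos = c(1e6, 2e6, 3e6, 5e6, 6e6),
                      homolog = c("ancA", "ancA", "ancA", "ancB", "ancB"),
                      stringsAsFactors = FALSE)
  ev <- detect_fusions(build_anchor_map(anchors = clean))
  expect_equal(ev$breakpoint, 4e6)
  expect_equal(ev$n_discordant, 0L)
  expect_equal(ev$flanking_gap, 2e6)
  expect_equal(c(ev$left_homolog, ev$right_homolog), c("ancA", "ancB"))

  inter <- data.frame(chrom = "chr1",
                      pos = c(1, 2, 5, 3, 4, 6, 7) * 1e6,
                      homolog = c("ancA", "ancA", "ancA",
                                  "ancB", "ancB", "ancB", "ancB"),
                      stringsAsFactors = FALSE)
  ev2 <- detect_fusions(build_anchor_map(anchors = inter))
  expect_equal(ev2$breakpoint, 2.5e6)
  expect_equal(ev2$n_discordant, 1L)

  one <- data.frame(chrom = "chr2", pos = c(1e5, 2e5), homolog = "ancC",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(detect_fusions(build_anchor_map(anchors = one))), 0)
})

test_that("fusion detection matches an exhaustive changepoint scan on random anchor sets", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    pos <- sort(sample.int(1e6, n))
    cut_true <- sample(2:(n - 2), 1)
    labels <- c(rep("ancA", cut_true), rep("ancB", n - cut_true))
    flip <- runif(n) < 0.15   # discordant noise
    labels[flip] <- ifelse(labels[flip] == "ancA", "ancB", "ancA")
    if (length(unique(labels)) < 2) next
    if (min(table(labels)) < 2) next
    am <- build_anchor_map(anchors = data.frame(chrom = "chrX", pos = pos,
                                                homolog = labels,
                                                stringsAsFactors = FALSE))
    ev <- detect_fusions(am)
    orc <- oracle_changepoint(pos, labels)
    expect_equal(ev$n_discordant, orc$cost)
    expect_equal(ev$breakpoint, orc$breakpoint)
  }
})

test_that("splitting relabels points and intervals with the stated conventions", {
  genome <- kf_genome(data.frame(id = "chr1", species = "d", length = 10e6,
                                 homology_group = "ancL+ancR",
                                 stringsAsFactors = FALSE))
  fus <- data.frame(derived_chrom = "chr1", left_homolog = "ancL",
                    right_homolog = "ancR", breakpoint = 6e6,
                    stringsAsFactors = FALSE)
  segs <- fusion_segments(genome, fus)
  expect_equal(segs$end - segs$start, c(6e6, 4e6))

  pt <- split_chromosomes(data.frame(chrom = "chr1", pos = 7.5e6), segs)
  expect_equal(pt$chrom, "ancR")
  expect_equal(pt$pos, 1.5e6)
  # point exactly at the breakpoint belongs to the right segment
  pt0 <- split_chromosomes(data.frame(chrom = "chr1", pos = 6e6), segs)
  expect_equal(pt0$chrom, "ancR")
  expect_equal(pt0$pos, 0)

  # interval with midpoint exactly at the breakpoint goes left, flagged
  iv <- split_chromosomes(data.frame(chrom = "chr1", start = 5.9e6, end = 6.1e6),
                          segs)
  expect_equal(iv$chrom, "ancL")
  expect_true(iv$spans_breakpoint)

  # no fusions: the identity view
  g0 <- kf_genome(data.frame(id = "chr2", species = "d", length = 1e6,
                             homology_group = "anc02",
                             stringsAsFactors = FALSE))
  segs0 <- fusion_segments(g0, fus[0, ])
  idp <- split_chromosomes(data.frame(chrom = "chr2", pos = 123), segs0)
  expect_equal(idp$chrom, "anc02")
  expect_equal(idp$pos, 123)

  bad <- data.frame(derived_chrom = "chr1", left_homolog = "a",
                    right_homolog = "b", breakpoint = 20e6)
  expect_error(fusion_segments(genome, bad), "outside")
})

test_that("splitting then re-applying segment offsets is a bijection on anchors", {
  cfg <- sim_config(seed = 9)
  der <- apply_fusions(simulate_ancestral_genome(cfg, with_sequence = FALSE), cfg)
  segs <- der$truth$segments
  a <- der$anchors
  split <- split_chromosomes(a[, c("chrom", "pos")], segs)
  off <- stats::setNames(segs$start, segs$homolog)
  dchr <- stats::setNames(segs$derived_chrom, segs$homolog)
  expect_equal(unname(dchr[split$chrom]), a$chrom)
  expect_equal(split$pos + unname(off[split$chrom]), a$pos)
})

test_that("classification follows the shorter-ancestral-component rule", {
  fus <- data.frame(derived_chrom = "chr6", left_homolog = "anc06",
                    right_homolog = "anc31", breakpoint = 9e6,
                    stringsAsFactors = FALSE)
  lens <- c(anc06 = 9e6, anc31 = 3e6, anc01 = 12e6)
  cls <- classify_chromosomes(fus, lens)
  expect_equal(cls$class[cls$homolog == "anc31"], "SFC")
  expect_equal(cls$class[cls$homolog == "anc06"], "LFC")
  expect_equal(cls$class[cls$homolog == "anc01"], "NFC")

  expect_error(classify_chromosomes(fus, lens[-2]), "missing ancestral length")

  lens_tied <- c(anc06 = 5e6, anc31 = 5e6)
  expect_warning(cls2 <- classify_chromosomes(fus, lens_tied), "tie")
  expect_equal(cls2$class[cls2$homolog == "anc06"], "SFC")

  # all-unfused: everything NFC
  cls3 <- classify_chromosomes(fus[0, ], lens)
  expect_true(all(cls3$class == "NFC"))
})

test_that("class counts satisfy #SFC == #LFC == #fusions and #NFC == n - 2*#fusions", {
  cfg <- sim_config(seed = 13)
  anc <- simulate_ancestral_genome(cfg, with_sequence = FALSE)
  der <- apply_fusions(anc, cfg)
  fus <- detect_fusions(build_anchor_map(anchors = der$anchors))
  cls <- classify_chromosomes(fus, chrom_lengths(anc$genome))
  expect_equal(sum(cls$class == "SFC"), nrow(fus))
  expect_equal(sum(cls$class == "LFC"), nrow(fus))
  expect_equal(sum(cls$class == "NFC"), 31 - 2 * nrow(fus))
})
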