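test_that("window composition computes GC over non-N bases and union coverage", {
  g <- toy_genome(c(chr1 = paste0(strrep("G", 1e5), strrep("A", 1e5))))
  repeats <- data.frame(chrom = "chr1", start = c(0, 20e3), end = c(30e3, 50e3))
  cds <- data.frame(chrom = "chr1", start = c(110e3, 130e3),
                    end = c(160e3, 170e3), strand = "+", kind = "CDS",
                    parent = "t1", phase = 0L, stringsAsFactors = FALSE)
  w <- window_composition(g, repeats, cds, window_size = 1e5)
  expect_equal(w$gc, c(100, 0))
  # merged repeats cover [0, 50e3): 50% of window 1
  expect_equal(w$repeat_pct, c(50, 0))
  # two CDS overlapping by 30 kb span 60 kb: union not sum
  expect_equal(w$coding, c(0, 60))

  expect_error(window_composition(g, data.frame(chrom = "zz", start = 0, end = 1),
                                  cds, 1e5), "absent")
  expect_error(window_composition(g, repeats, cds, window_size = 500), ">= 1 kb")
})

test_that("N-only stretches are excluded from the GC denominator", {
  g <- toy_genome(c(chr1 = paste0(strrep("N", 50e3), strrep("G", 25e3),
                                  strrep("T", 25e3))))
  w <- window_composition(g, data.frame(chrom = character(), start = numeric(),
                                        end = numeric()),
                          data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), kind = character()),
                          window_size = 1e5)
  expect_equal(w$gc, 50)   # 25k G over 50k non-N
})

test_that("window repeat bp totals equal the merged repeat bp per chromosome", {
  cfg <- sim_config(seed = 4, n_chromosomes = 3, length_range = c(1e5, 2e5),
                    n_fusions = 1)
  anc <- simulate_ancestral_genome(cfg)
  # exact tiling: no terminal remainder is dropped below half window
  w <- window_composition(anc$genome, anc$repeats, anc$features,
                          window_size = 1e4)
  merged <- merge_intervals(anc$repeats)
  for (ch in anc$genome$info$id) {
    L <- anc$genome$info$length[anc$genome$info$id == ch]
    ww <- w[w$chrom == ch, ]
    covered <- sum(ww$repeat_pct / 100 * (ww$end - ww$start))
    mg <- merged[merged$chrom == ch, ]
    in_windows <- sum(pmin(mg$end, max(ww$end)) - pmin(mg$start, max(ww$end)))
    expect_equal(covered, in_windows, tolerance = 1e-12)
  }
})

test_that("normalized positions centre the fusion point at 0.5 and are measure-preserving", {
  g <- kf_genome(data.frame(id = c("chr1", "chr2"), species = "d",
                            length = c(10e6, 4e6),
                            homology_group = c("a+b", "c"),
                            stringsAsFactors = FALSE))
  fus <- data.frame(derived_chrom = "chr1", breakpoint = 6e6)
  win <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                    start = c(5.95e6, 2.95e6, 7.95e6, 0.95e6),
                    end = c(6.05e6, 3.05e6, 8.05e6, 1.05e6),
                    gc = 1, repeat_pct = 1, coding = 1)
  pr <- normalized_profile(win, chrom_lengths(g), fus, n_bins = 10)
  np <- pr$windows$norm_pos
  expect_equal(np[1], 0.5)         # window centred at the breakpoint
  expect_equal(np[2], 0.25)        # left-component midpoint
  expect_equal(np[3], 0.75)        # right-component midpoint
  expect_equal(np[4], 0.25)        # unfused: linear map
  # measure-preserving per component: equal-bp steps map to equal widths
  steps <- data.frame(chrom = "chr1", start = seq(0, 5e6, 1e6),
                      end = seq(1e6, 6e6, 1e6), gc = 0, repeat_pct = 0, coding = 0)
  nps <- normalized_profile(steps, chrom_lengths(g), fus, n_bins = 10)$windows$norm_pos
  expect_equal(diff(nps), rep(diff(nps)[1], 5))
  expect_error(normalized_profile(win, chrom_lengths(g), fus, n_bins = 2),
               "n_bins")
})

test_that("carried-over repeats leave a relic peak at the fusion point; resampled repeats do not", {
  wins_mid_tail <- function(genome, repeats, fus) {
    w <- window_composition(genome, repeats,
                            data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), kind = character()),
                            window_size = 1e4)
    pr <- normalized_profile(w, chrom_lengths(genome), fus, n_bins = 20)
    b <- pr$bins[pr$bins$metric == "repeat_pct", ]
    mid <- mean(b$mean[b$bin %in% 10:11])            # around 0.5
    shoulder <- mean(b$mean[b$bin %in% c(5, 16)])    # component centres
    mid - shoulder
  }
  hits <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = 300 + s, n_chromosomes = 12, n_fusions = 6,
                      length_range = c(1e5, 3e5), tail_enrichment = 3,
                      repeat_size_effect = 0)
    der <- apply_fusions(simulate_ancestral_genome(cfg), cfg)
    fused_ids <- der$truth$fusions$derived_chrom
    keep <- der$genome$info$id %in% fused_ids
    gsub_ <- kf_genome(der$genome$info[keep, ], der$genome$seq[keep])
    fus <- der$truth$fusions
    relic <- wins_mid_tail(gsub_, der$repeats[der$repeats$chrom %in% fused_ids, ], fus)
    res <- resample_repeats(gsub_, cfg)
    purged <- wins_mid_tail(gsub_, res, fus)
    hits <- hits + (relic > purged)
  }
  expect_gte(hits, 4)
})

test_that("class contrasts use exact one-sided rank-sum tests", {
  met <- data.frame(homolog = c(paste0("s", 1:3), paste0("n", 1:3), paste0("l", 1:3)),
                    value = c(1, 2, 3, 4, 5, 6, 4.5, 5.5, 6.5))
  cls <- data.frame(homolog = met$homolog,
                    class = rep(c("SFC", "NFC", "LFC"), each = 3))
  res <- class_contrasts(met, cls, metrics = "value")
  p_sn <- res$p[res$class_a == "SFC" & res$class_b == "NFC"]
  expect_equal(p_sn, 0.05)   # exact: 1 / C(6,3) = 1/20
  expect_true(res$significant[res$class_a == "SFC" & res$class_b == "NFC"] == FALSE)

  # identical distributions: far from significant
  met2 <- met; met2$value <- rep(c(1, 2, 3), 3)
  res2 <- class_contrasts(met2, cls, metrics = "value")
  expect_true(all(res2$p > 0.005, na.rm = TRUE))

  # class with < 3 members gives NA
  cls3 <- cls; cls3$class[1] <- "NFC"
  res3 <- class_contrasts(met, cls3, metrics = "value")
  expect_true(all(is.na(res3$p[res3$class_a == "SFC" | res3$class_b == "SFC"])))
})

test_that("a planted SFC repeat excess is detected by the 'greater' contrast", {
  hits <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = 400 + s)
    anc <- simulate_ancestral_genome(cfg, with_sequence = FALSE)
    der <- apply_fusions(anc, cfg)
    cls <- classify_chromosomes(der$truth$fusions, chrom_lengths(anc$genome))
    merged <- merge_intervals(anc$repeats)
    rep_pct <- vapply(anc$genome$info$id, function(ch)
      100 * sum(merged$end[merged$chrom == ch] - merged$start[merged$chrom == ch]) /
        anc$genome$info$length[anc$genome$info$id == ch], numeric(1))
    met <- data.frame(homolog = anc$genome$info$id, repeat_pct = rep_pct)
    res <- class_contrasts(met, cls, metrics = "repeat_pct")
    # NFC less-than-SFC is the one-sided "SFC greater" contrast
    p <- res$p[res$class_a == "NFC" & res$class_b == "SFC"]
    hits <- hits + (p <= 0.005)
  }
  expect_gte(hits, 4)
})

test_that("a wholly repeat-covered single intron gives the degenerate scaling point", {
  mk <- function(chrom, ex2_start) {
    a <- rbind(toy_cds_annotation(chrom, 100, 200, gene = paste0("g_", chrom)),
               data.frame(chrom = chrom, start = ex2_start,
                          end = ex2_start + 100, strand = "+", kind = "exon",
                          parent = paste0("g_", chrom, ".t1"), phase = NA,
                          id = NA))
    a$end[a$kind %in% c("gene", "mRNA")] <- ex2_start + 100
    a
  }
  ann <- rbind(mk("chr1", 300), mk("chr2", 500), mk("chr3", 800))
  ann <- rbind(ann, karyofuse:::synthesize_introns(ann))
  # chr1's single intron [200, 300) wholly covered by a repeat
  repeats <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr3"),
                        start = c(200, 500, 250, 700, 300, 900),
                        end = c(300, 600, 330, 800, 450, 990))
  rr <- region_repeat_scaling(ann, repeats,
                              c(chr1 = 1000, chr2 = 1000, chr3 = 1100),
                              n_permutations = 99, seed = 1)
  p1 <- rr$points[rr$points$chrom == "chr1" & rr$points$kind == "intron", ]
  expect_equal(p1$region_bp, 100)
  expect_equal(p1$repeat_bp, 100)   # -> (log10 intron bp, log10 intron bp)
})

test_that("region repeat scaling separates planted intergenic repeat excess", {
  # the generator keeps genes repeat-free, so place annotation-independent
  # uniform repeats here: 20% density, 200 bp elements
  # the generator keeps genes repeat-free, so lay down an
  # annotation-independent repeat grid (20 bp every 100 bp: 20% density with
  # negligible sampling noise, so the fitted common slope is ~1)
  cfg <- sim_config(seed = 17, n_chromosomes = 10, length_range = c(1e5, 3e5),
                    n_fusions = 0)
  anc <- simulate_ancestral_genome(cfg, with_sequence = FALSE)
  lens <- chrom_lengths(anc$genome)
  grid <- do.call(rbind, lapply(names(lens), function(ch) {
    s <- seq(0, lens[[ch]] - 100, by = 100)
    data.frame(chrom = ch, start = s, end = s + 20)
  }))
  # uniform density: intron and intergenic elevations essentially equal
  rr <- region_repeat_scaling(anc$features, grid, lens, seed = 1)
  expect_lt(abs(rr$compare$elevation$diff[1]), 0.05)
  expect_lt(abs(rr$fits$intron$intercept - rr$fits$intergenic$intercept), 0.06)
  # planted ~2x intergenic density: drop every other in-gene repeat
  genes <- merge_intervals(anc$features[anc$features$kind == "gene", ])
  in_gene <- rep(FALSE, nrow(grid))
  for (ch in names(lens)) {
    gi <- genes[genes$chrom == ch, ]
    on <- grid$chrom == ch
    ov <- IRanges::countOverlaps(IRanges::IRanges(grid$start[on] + 1, grid$end[on]),
                                 IRanges::IRanges(gi$start + 1, gi$end))
    in_gene[on] <- ov > 0
  }
  drop <- in_gene & (seq_len(nrow(grid)) %% 2 == 0)
  rr2 <- region_repeat_scaling(anc$features, grid[!drop, ], lens, seed = 1)
  expect_lte(rr2$compare$elevation$p[1], 0.005)
  expect_gt(rr2$fits$intergenic$intercept, rr2$fits$intron$intercept)
  # the planted factor ~2 appears as a ~log10(2) elevation drop for introns
  expect_equal(rr2$fits$intergenic$intercept - rr2$fits$intron$intercept,
               log10(2), tolerance = 0.25)
})
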