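## End-to-end orchestration on a synthetic system: generate -> fusion map ->
## composition -> diversity -> recombination model -> turnover -> report.

#' Run the full pipeline on a synthetic system
#'
#' Generates the ancestral and derived genomes, detects fusions from the
#' anchor map, classifies chromosomes, profiles composition, computes pi_4D
#' for both species, applies the 50 cM recombination model, correlates
#' diversity change with recombination-rate change, and scores functional
#' element turnover. Stages can be toggled; all randomness derives from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param stages character vector of stages to run (subset of
#'   `c("composition", "diversity", "turnover")`; the fusion map always
#'   runs).
#' @param window_size composition window size in bp.
#' @param sites_per_window 4D sites per diversity window.
#' @param out_dir if non-NULL, TSV/JSON outputs are written there.
#' @return list with per-stage outputs and a flat `report` (see
#'   [make_report()]).
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = c("composition", "diversity", "turnover"),
                         window_size = 1e5, sites_per_window = 500,
                         out_dir = NULL) {
  with_seq <- if ("composition" %in% stages) TRUE else
    if ("diversity" %in% stages) "genic" else FALSE
  anc <- simulate_ancestral_genome(config, with_sequence = with_seq)
  der <- apply_fusions(anc, config)

  ## fusion map
  amap <- build_anchor_map(anchors = der$anchors)
  fusions <- detect_fusions(amap)
  segments <- fusion_segments(der$genome, fusions)
  anc_lengths <- chrom_lengths(anc$genome)
  classes <- classify_chromosomes(fusions, anc_lengths)
  stage_out <- list(config = config, truth = der$truth, fusions = fusions,
                    segments = segments, classes = classes)
  report <- list(
    n_ancestral_chromosomes = nrow(anc$genome$info),
    n_derived_chromosomes = nrow(der$genome$info),
    n_fusions_detected = nrow(fusions),
    n_sfc = sum(classes$class == "SFC"),
    n_lfc = sum(classes$class == "LFC"),
    n_nfc = sum(classes$class == "NFC"),
    mean_breakpoint_error_bp = mean(abs(
      fusions$breakpoint[match(der$truth$fusions$derived_chrom,
                               fusions$derived_chrom)] -
        der$truth$fusions$breakpoint))
  )

  if ("composition" %in% stages) {
    ## derived-genome windows; repeats carried over from the ancestor
    win <- window_composition(der$genome, der$repeats, der$features,
                              window_size = window_size)
    prof <- normalized_profile(win, chrom_lengths(der$genome), fusions)
    ## per-homolog metrics on the ancestral genome for class contrasts
    anc_win <- window_composition(anc$genome, anc$repeats, anc$features,
                                  window_size = window_size)
    met <- stats::aggregate(anc_win[, c("gc", "repeat_pct")],
                            list(homolog = anc_win$chrom), mean, na.rm = TRUE)
    met$length <- anc_lengths[met$homolog]
    contrasts <- class_contrasts(met, classes)
    sma_len_rep <- sma_fit(log10(met$length),
                           log10(pmax(1e-3, met$repeat_pct * met$length / 100)))
    stage_out$composition <- list(windows = win, profile = prof,
                                  metrics = met, contrasts = contrasts,
                                  sma_length_repeat = sma_len_rep)
    getp <- function(a, b, m) {
      r <- contrasts[contrasts$class_a == a & contrasts$class_b == b &
                       contrasts$metric == m, ]
      r$p[1]
    }
    report <- c(report, list(
      sma_length_repeat_slope = sma_len_rep$slope,
      length_repeat_pearson_r = sma_len_rep$r,
      p_sfc_smaller_than_nfc = getp("SFC", "NFC", "length"),
      p_nfc_repeat_less_than_sfc = getp("NFC", "SFC", "repeat_pct")
    ))
  }

  if ("diversity" %in% stages) {
    ## plant variants on both species; the derived genome's 4D-eligible set
    ## is the ancestral one mapped through the true segments (concatenation
    ## does not change codons)
    coding_anc <- nonoverlapping_coding_intervals(anc$features)
    eligible_anc <- call_fourfold_sites(anc$genome, coding_anc, NULL)$sites
    tseg <- der$truth$segments
    eligible_der <- eligible_anc
    si <- match(eligible_anc$chrom, tseg$homolog)
    eligible_der$chrom <- tseg$derived_chrom[si]
    eligible_der$pos <- eligible_anc$pos + tseg$start[si]
    va <- simulate_variants(anc$genome, anc$features, config, stream = 104,
                            eligible = eligible_anc)
    vd <- simulate_variants(der$genome, der$features, config, stream = 114,
                            eligible = eligible_der)
    f_anc <- filter_genotypes(va$variants)
    f_der <- filter_genotypes(vd$variants)
    sites_anc <- call_fourfold_sites(anc$genome, coding_anc, f_anc)
    sites_der <- call_fourfold_sites(der$genome,
                                     nonoverlapping_coding_intervals(der$features),
                                     f_der)
    w_anc <- pi_windows(sites_anc, f_anc, sites_per_window = sites_per_window)
    w_der <- pi_windows(sites_der, f_der, sites_per_window = sites_per_window)
    none <- segments[0, ]
    sum_anc <- chromosome_diversity_summary(w_anc, none, classes)
    sum_der <- chromosome_diversity_summary(w_der, segments, classes)
    dpi <- relative_diversity_change(sum_der, sum_anc)
    ## extant length of each homolog = the derived chromosome it now sits on
    ext_len <- stats::setNames(
      chrom_lengths(der$genome)[segments$derived_chrom], segments$homolog)
    recomb <- recombination_model(anc_lengths, ext_len[names(anc_lengths)])
    m <- merge(dpi, recomb, by = "homolog")
    corr <- diversity_recombination_correlation(m$dpi_rel, m$dr_rel,
                                                use_magnitude = TRUE)
    fit <- stats::lm(pi ~ I(log10(length)),
                     data = merge(sum_anc, data.frame(homolog = names(anc_lengths),
                                                      length = as.numeric(anc_lengths)),
                                  by = "homolog"))
    stage_out$diversity <- list(summary_anc = sum_anc, summary_der = sum_der,
                                dpi = dpi, recomb = recomb, correlation = corr,
                                pi_length_fit = fit)
    report <- c(report, list(
      pi_length_r2 = summary(fit)$r.squared,
      pi_length_slope = unname(stats::coef(fit)[2]),
      dpi_dr_spearman_rho = corr$rho,
      dpi_dr_spearman_p = corr$p,
      mean_dpi_rel_sfc = mean(m$dpi_rel[m$class == "SFC"]),
      mean_dr_rel_sfc = mean(m$dr_rel[m$class == "SFC"])
    ))
  }

  if ("turnover" %in% stages) {
    tv <- simulate_elements_and_hits(anc$genome, config)
    res <- list()
    for (k in names(tv$hits))
      for (T_ in names(tv$hits[[k]])) {
        rbh <- reciprocal_best_hits(tv$hits[[k]][[T_]]$forward,
                                    tv$hits[[k]][[T_]]$reverse)
        cc <- conservation_by_chromosome(tv$elements[[k]], rbh, anc_lengths)
        cc$kind <- k
        cc$time_myr <- as.numeric(T_)
        res[[length(res) + 1]] <- cc
      }
    res <- do.call(rbind, res)
    corr_by <- lapply(split(res, list(res$kind, res$time_myr)),
                      conservation_length_correlation)
    reg <- turnover_multiple_regression(res)
    stage_out$turnover <- list(results = res, correlations = corr_by,
                               regression = reg)
    rhos <- vapply(corr_by, `[[`, numeric(1), "rho")
    report <- c(report, list(
      conservation_length_rho_min = min(rhos),
      conservation_length_rho_max = max(rhos),
      turnover_r2 = reg$r2,
      turnover_beta_length_per_mb = unname(reg$coefficients["beta_length"]),
      turnover_beta_time_per_myr = unname(reg$coefficients["beta_time"])
    ))
  }

  stage_out$report <- make_report(list(report), config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(fusions, file.path(out_dir, "fusions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(classes, file.path(out_dir, "classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(stage_out$report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage_out
}

#' Merge stage outputs into one flat report
#'
#' Produces a flat key space of named statistics; duplicate keys across
#' stages are an error. A hash of the configuration is included so reruns
#' are detectable.
#'
#' @param stage_reports list of named lists of scalar statistics.
#' @param config the run's [sim_config()] (hashed into the report).
#' @return named list (flat).
#' @export
make_report <- function(stage_reports, config = NULL) {
  keys <- unlist(lapply(stage_reports, names))
  dup <- keys[duplicated(keys)]
  if (length(dup)) stop("conflicting duplicate report keys: ",
                        paste(unique(dup), collapse = ", "))
  out <- do.call(c, stage_reports)
  if (is.null(out)) out <- list()
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(paste(names(config), vapply(config, paste, character(1),
                                           collapse = ","), sep = "="), tf)
    out$config_hash <- unname(tools::md5sum(tf))
    out$seed <- config$seed
  }
  out
}
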