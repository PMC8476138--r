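## Format boundaries. Everything in memory is 0-based half-open; GFF3 and VCF
## are 1-based on disk, BED is already 0-based half-open, and the 12-column
## hit table keeps its native 1-based inclusive coordinates inside the hit
## records (they are never used as genomic intervals downstream).

#' Read a FASTA file into a genome object
#'
#' Lowercase (soft-masked) bases are uppercased; any character outside
#' A/C/G/T/N is replaced by N and the substitution count is reported via a
#' message and the `"n_substituted"` attribute. Masking state is not retained:
#' repeat evidence enters the pipeline only as BED intervals.
#'
#' @param path FASTA file.
#' @param species species tag stored on every record.
#' @param homology_group optional named vector mapping chromosome id to
#'   ancestral homolog label; defaults to the chromosome id itself.
#' @return a [kf_genome()].
#' @export
read_fasta <- function(path, species = "unknown", homology_group = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  n_sub <- sum(vapply(seqs, function(s)
    sum(charToRaw(s) %in% charToRaw("RYSWKMBDHVU")), numeric(1)))
  ## readDNAStringSet already restricts to the IUPAC alphabet; map every
  ## ambiguity code (and U) to N.
  seqs <- chartr("RYSWKMBDHVU", "NNNNNNNNNNN", seqs)
  if (n_sub > 0)
    message(sprintf("read_fasta: %d non-ACGTN base(s) replaced by N", n_sub))
  names(seqs) <- ids
  hg <- if (is.null(homology_group)) stats::setNames(ids, ids) else homology_group
  g <- kf_genome(data.frame(id = ids, species = species,
                            length = nchar(seqs),
                            homology_group = as.character(hg[ids]),
                            stringsAsFactors = FALSE),
                 seq = seqs)
  attr(g, "n_substituted") <- n_sub
  g
}

#' Write a genome to FASTA
#' @param genome a [kf_genome()] with sequences.
#' @param path output file.
#' @param width line-wrap width (bp).
#' @export
write_fasta <- function(genome, path, width = 70) {
  if (is.null(genome$seq)) stop("genome carries no sequence")
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

gff_kind_map <- c(gene = "gene", mRNA = "mRNA", transcript = "mRNA",
                  exon = "exon", CDS = "CDS",
                  five_prime_UTR = "UTR", three_prime_UTR = "UTR", UTR = "UTR",
                  intron = "intron")

#' Read a GFF3 annotation
#'
#' Coordinates are converted from the on-disk 1-based inclusive convention to
#' the package's 0-based half-open convention. Introns are synthesized per
#' transcript from the gaps between consecutive exons.
#'
#' @param path GFF3 file.
#' @return feature data.frame with columns chrom, start, end, strand, kind,
#'   parent, phase.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% names(gff_kind_map)
  gr <- gr[keep]
  type <- type[keep]
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  feats <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      start = BiocGenerics::start(gr) - 1,
                      end = BiocGenerics::end(gr),
                      strand = as.character(BiocGenerics::strand(gr)),
                      kind = unname(gff_kind_map[type]),
                      parent = parent,
                      phase = if (!is.null(gr$phase)) as.integer(as.character(gr$phase))
                              else NA_integer_,
                      id = id,
                      stringsAsFactors = FALSE)
  feats$strand[feats$strand == "*"] <- "."
  if (any(feats$kind == "CDS" & is.na(feats$parent)))
    stop("CDS feature without a parent transcript")
  validate_intervals(feats)
  ## introns synthesized from exon gaps unless the file already carries them
  if (!any(feats$kind == "intron"))
    feats <- rbind(feats, synthesize_introns(feats))
  feats
}

## gaps between consecutive exons of each transcript, inheriting strand
synthesize_introns <- function(feats) {
  ex <- feats[feats$kind == "exon" & !is.na(feats$parent), , drop = FALSE]
  if (nrow(ex) < 2) return(feats[0, , drop = FALSE])
  ex <- ex[order(ex$parent, ex$start), , drop = FALSE]
  n <- nrow(ex)
  same <- ex$parent[-1] == ex$parent[-n]
  out <- data.frame(chrom = ex$chrom[-n][same], start = ex$end[-n][same],
                    end = ex$start[-1][same], strand = ex$strand[-n][same],
                    kind = "intron", parent = ex$parent[-n][same],
                    phase = NA_integer_, id = NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write features to GFF3
#' @param feats feature data.frame (0-based half-open).
#' @param path output file.
#' @param source source column value.
#' @export
write_gff3 <- function(feats, path, source = "karyofuse") {
  kind_out <- feats$kind
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- character(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    a <- character(0)
    if (!is.null(feats$id) && !is.na(feats$id[i]))
      a <- c(a, paste0("ID=", feats$id[i]))
    if (!is.na(feats$parent[i])) a <- c(a, paste0("Parent=", feats$parent[i]))
    attrs[i] <- if (length(a)) paste(a, collapse = ";") else "."
  }
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   feats$chrom, source, kind_out,
                   as.integer(feats$start + 1), as.integer(feats$end),
                   feats$strand,
                   ifelse(is.na(feats$phase), ".", as.character(feats$phase)),
                   attrs)
  writeLines(lines, con)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED3+ file.
#' @param kind feature kind to stamp on every interval (e.g. "repeat", "CRE").
#' @return feature data.frame (BED is natively 0-based half-open; kept as-is).
#' @export
read_bed <- function(path, kind = "repeat") {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED needs at least 3 columns")
  df <- data.frame(chrom = as.character(tab[[1]]), start = as.numeric(tab[[2]]),
                   end = as.numeric(tab[[3]]), strand = ".", kind = kind,
                   parent = if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_,
                   phase = NA_integer_, stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Write intervals to BED
#' @param feats feature data.frame.
#' @param path output file.
#' @export
write_bed <- function(feats, path) {
  name <- if (!is.null(feats$parent)) ifelse(is.na(feats$parent), ".", feats$parent) else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", feats$chrom, as.integer(feats$start),
                     as.integer(feats$end), name), path)
  invisible(path)
}

#' Construct a variant-set object
#'
#' @param sites data.frame with chrom, pos (0-based), ref, alts
#'   (comma-separated alternate alleles, `""` if none).
#' @param gt character matrix (sites x samples) of unphased genotypes
#'   `"0/1"`, `"./."` for missing; allele indices index into `c(ref, alts)`.
#' @param dp,gq integer matrices of per-genotype depth and quality.
#' @return object of class `kf_variants`.
#' @export
kf_variants <- function(sites, gt, dp, gq) {
  stopifnot(nrow(sites) == nrow(gt), all(dim(gt) == dim(dp)),
            all(dim(gt) == dim(gq)))
  if (is.null(colnames(gt))) colnames(gt) <- paste0("s", seq_len(ncol(gt)))
  colnames(dp) <- colnames(gq) <- colnames(gt)
  structure(list(sites = sites, gt = gt, dp = dp, gq = gq,
                 samples = colnames(gt)), class = "kf_variants")
}

#' @export
print.kf_variants <- function(x, ...) {
  cat(sprintf("<kf_variants> %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Read genotypes from a VCF
#'
#' Requires GT, DP and GQ FORMAT fields. VCF POS (1-based) is converted to
#' 0-based; multiallelic sites are retained with the full alternate list.
#'
#' @param path VCF file.
#' @param samples samples to keep (default all); an absent sample is an error.
#' @return a [kf_variants()].
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  all_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- all_samples
  missing <- setdiff(samples, all_samples)
  if (length(missing)) stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")[, samples, drop = FALSE]
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))[, samples, drop = FALSE]
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))[, samples, drop = FALSE]
  gt[is.na(gt)] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  alts <- fix[, "ALT"]
  alts[is.na(alts) | alts == "."] <- ""
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]) - 1,
                      ref = fix[, "REF"], alts = alts, stringsAsFactors = FALSE)
  storage <- function(m) { m[is.na(m)] <- 0L; matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m)) }
  kf_variants(sites, gt, storage(dp), storage(gq))
}

#' Write a variant set to VCF
#' @param variants a [kf_variants()].
#' @param path output file.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", variants$samples), collapse = "\t")), con)
  s <- variants$sites
  geno <- vapply(seq_len(nrow(s)), function(i)
    paste(sprintf("%s:%d:%d", variants$gt[i, ], variants$dp[i, ],
                  variants$gq[i, ]), collapse = "\t"), character(1))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:GQ\t%s",
                     s$chrom, as.integer(s$pos + 1), s$ref,
                     ifelse(s$alts == "", ".", s$alts), geno), con)
  invisible(path)
}

hit_columns <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatch", "gapopen", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

#' Read a 12-column tabular similarity-hit table
#'
#' The standard tab-separated hit format (query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore). Hit
#' coordinates stay in their native 1-based inclusive dialect inside the
#' record; they are not used as genomic intervals downstream.
#'
#' @param path hit table file.
#' @return data.frame with the 12 named columns.
#' @export
read_hits <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0)
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 12)), hit_columns))
  bad <- which(nf != 12)
  if (length(bad))
    stop(sprintf("malformed hit table: line %d has %d columns (expected 12)",
                 bad[1], nf[bad[1]]))
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(tab) <- hit_columns
  if (any(tab$evalue < 0)) stop("negative e-value in hit table")
  if (any(tab$alignment_length <= 0)) stop("non-positive alignment length")
  tab
}

#' Write a hit table
#' @param hits data.frame with the 12 standard columns.
#' @param path output file.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, hit_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a linkage-map marker table
#'
#' TSV with columns marker_id, chrom, pos_bp, cM. Within each chromosome the
#' genetic position must be non-decreasing with physical position.
#'
#' @param path TSV file (with header).
#' @return data.frame of markers.
#' @export
read_linkage_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("linkage map needs 4 columns: marker_id, chrom, pos_bp, cM")
  names(tab)[1:4] <- c("marker_id", "chrom", "pos_bp", "cM")
  for (d in split(tab, tab$chrom)) {
    d <- d[order(d$pos_bp), ]
    if (is.unsorted(d$cM))
      stop("cM decreases with bp on chromosome ", d$chrom[1])
  }
  tab
}

#' Per-chromosome genetic map lengths
#' @param map a linkage-map data.frame from [read_linkage_map()].
#' @return named numeric vector of map lengths (max cM - min cM) per chromosome.
#' @export
map_lengths <- function(map) {
  vapply(split(map$cM, map$chrom), function(x) max(x) - min(x), numeric(1))
}
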