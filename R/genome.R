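#' Construct a genome object
#'
#' A genome is the package's container for one species' chromosome set: a
#' table of chromosome metadata plus (optionally) the nucleotide sequences.
#' The `homology_group` column ties every extant chromosome (or, after a
#' fusion, every chromosome component) to an ancestral chromosome label such
#' as `"anc01"`; for fused chromosomes it holds the component labels joined
#' by `"+"` in head-to-tail order.
#'
#' @param info data.frame with columns `id`, `species`, `length`,
#'   `homology_group`.
#' @param seq named character vector of sequences (A/C/G/T/N), or `NULL` for
#'   a sequence-free genome (lengths only).
#' @return an object of class `kf_genome`.
#' @export
kf_genome <- function(info, seq = NULL) {
  stopifnot(is.data.frame(info),
            all(c("id", "species", "length", "homology_group") %in% names(info)))
  if (anyDuplicated(info$id)) stop("duplicate chromosome ids")
  if (any(info$length <= 0)) stop("chromosome lengths must be positive")
  if (!is.null(seq)) {
    seq <- seq[info$id]
    if (anyNA(names(seq))) stop("sequence missing for some chromosomes")
    if (!all(nchar(seq) == info$length))
      stop("sequence length disagrees with declared chromosome length")
  }
  structure(list(info = info, seq = seq), class = "kf_genome")
}

#' @export
print.kf_genome <- function(x, ...) {
  cat(sprintf("<kf_genome> %s: %d chromosomes, %.2f Mb total%s\n",
              x$info$species[1], nrow(x$info), sum(x$info$length) / 1e6,
              if (is.null(x$seq)) " (no sequence)" else ""))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `kf_genome`.
#' @return named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(genome$info$length, genome$info$id)
}
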