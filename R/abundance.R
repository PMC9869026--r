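## Depth-based community composition: minimizer read assignment, mean
## coverage depth per genome, and depth-weighted relative abundance
## aggregated by taxonomic rank.

#' Assign reads to genomes by shared minimizers
#'
#' Each read goes to the genome with which it shares the most (k, w)
#' minimizers, provided the count reaches `min_hits`; the covered
#' reference interval is estimated from the outermost matched minimizer
#' positions.  Ties are deterministic: genomes are indexed in
#' lexicographic id order and the first best wins.
#'
#' @param reads character vector of read sequences.
#' @param genomes named character vector of genome sequences.
#' @param k minimizer k-mer size (default 17).
#' @param w minimizer window (default 11).
#' @param min_hits minimum shared minimizers (default 10).
#' @param read_ids identifiers (defaults to names of `reads`).
#' @return data.frame: read_id, genome (NA = unassigned), hits,
#'   ref_start (0-based), ref_end (half-open), read_length.
#' @export
assign_reads <- function(reads, genomes, k = 17L, w = 11L, min_hits = 10L,
                         read_ids = names(reads)) {
  if (is.null(read_ids)) read_ids <- sprintf("read%06d", seq_along(reads))
  genomes <- genomes[order(names(genomes))]
  res <- assign_reads_cpp(as.character(reads), as.character(genomes),
                          as.integer(k), as.integer(w), as.integer(min_hits),
                          as.double(MH_DEFAULT_SEED))
  data.frame(read_id = read_ids,
             genome = names(genomes)[res$genome],
             hits = res$hits, ref_start = res$ref_start,
             ref_end = res$ref_end, read_length = nchar(reads))
}

#' Mean coverage depth per genome
#'
#' `mean_depth = sum(assigned interval lengths) / genome length`; interval
#' lengths are clipped to the genome (assignments to circular genomes may
#' wrap, which the minimizer intervals already fold in).
#'
#' @param assignments an [assign_reads()] table.
#' @param genome_lengths named numeric vector of genome lengths.
#' @return data.frame: genome_id, mean_depth_x, bases_assigned, n_reads;
#'   attribute `total_assigned_fraction` gives the fraction of read bases
#'   assigned anywhere.
#' @export
mean_depth <- function(assignments, genome_lengths) {
  ok <- !is.na(assignments$genome)
  a <- assignments[ok, , drop = FALSE]
  spans <- pmin(a$ref_end - a$ref_start, a$read_length)
  agg <- if (nrow(a)) {
    s <- rowsum(data.frame(bases = spans, n = 1L), a$genome)
    data.frame(genome_id = rownames(s), bases_assigned = s$bases,
               n_reads = s$n)
  } else data.frame(genome_id = character(), bases_assigned = numeric(),
                    n_reads = integer())
  out <- data.frame(genome_id = names(genome_lengths))
  out <- merge(out, agg, by = "genome_id", all.x = TRUE, sort = TRUE)
  out$bases_assigned[is.na(out$bases_assigned)] <- 0
  out$n_reads[is.na(out$n_reads)] <- 0L
  out$mean_depth_x <- out$bases_assigned /
    genome_lengths[out$genome_id]
  out <- out[, c("genome_id", "mean_depth_x", "bases_assigned", "n_reads")]
  attr(out, "total_assigned_fraction") <-
    if (sum(assignments$read_length) > 0)
      sum(a$read_length) / sum(assignments$read_length) else 0
  out
}

#' Depth-weighted relative abundance by taxonomic rank
#'
#' `abundance(taxon) = sum(depth of genomes in taxon) / sum(all depths)`.
#' Genomes without taxonomy are grouped under `"unclassified"` with a
#' warning.  A secondary base-fraction column (depth x length weighting)
#' is included.
#'
#' @param depths a [mean_depth()] table.
#' @param taxonomy named character vector: genome_id -> `d;p;c;o;f;g`
#'   lineage.
#' @param rank one of `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`.
#' @return data.frame: taxon, relative_abundance (sums to 1),
#'   base_fraction.
#' @export
rank_profile <- function(depths, taxonomy, rank = "phylum") {
  rank <- match.arg(rank, TAXON_RANKS)
  paths <- taxonomy[depths$genome_id]
  miss <- is.na(paths)
  if (any(miss))
    warning(sum(miss), " genome(s) without taxonomy grouped as unclassified")
  taxa <- ifelse(miss, "unclassified",
                 vapply(paths, function(p) {
                   r <- taxon_rank(p, rank)
                   if (is.na(r)) "unclassified" else r
                 }, ""))
  dtot <- sum(depths$mean_depth_x)
  if (dtot <= 0) stop("no coverage depth to aggregate")
  rel <- rowsum(depths$mean_depth_x, taxa)
  bf <- rowsum(depths$bases_assigned, taxa)
  out <- data.frame(taxon = rownames(rel),
                    relative_abundance = rel[, 1] / dtot,
                    base_fraction = bf[, 1] / sum(depths$bases_assigned))
  rownames(out) <- NULL
  out[order(-out$relative_abundance), , drop = FALSE]
}
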