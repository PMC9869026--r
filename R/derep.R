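## Dereplication: MinHash sketches and Mash distance for fast grouping,
## fragment-based ANI with mutual coverage for the species decision, and
## greedy score-based representative selection.

MH_DEFAULT_SEED <- 42

#' MinHash sketch of a genome
#'
#' Bottom-s sketch of the 64-bit hashes (masked to 53 bits) of canonical
#' k-mers; multi-contig genomes are pooled into one sketch.  Canonical
#' means the lexicographic minimum of a k-mer and its reverse complement,
#' so a genome and its reverse complement sketch identically.
#'
#' @param seq character vector of sequence(s).
#' @param genome_id identifier stored in the sketch.
#' @param k k-mer size (default 21).
#' @param s sketch size (default 1000).
#' @param hash_seed hash seed recorded in the sketch (sketches are only
#'   comparable at equal k, s and seed).
#' @return object of class `mh_sketch`.
#' @export
minhash_sketch <- function(seq, genome_id = "genome", k = 21L, s = 1000L,
                           hash_seed = MH_DEFAULT_SEED) {
  if (sum(nchar(seq)) < k) stop("sequence shorter than k")
  hashes <- mh_sketch_cpp(as.character(seq), as.integer(k), as.integer(s),
                          as.double(hash_seed))
  structure(list(genome_id = genome_id, k = as.integer(k), s = as.integer(s),
                 hash_seed = hash_seed, hashes = hashes),
            class = "mh_sketch")
}

#' Mash distance between two sketches
#'
#' Jaccard is estimated on the bottom-s sketch of the union of the two
#' hash sets; the distance is `-(1/k) * ln(2j / (1 + j))`, 0 for identical
#' sketches and capped at 1 when no hashes are shared.
#'
#' @param a,b [minhash_sketch()] objects with equal k, s and hash seed.
#' @return numeric distance in \[0, 1\].
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "mh_sketch"), inherits(b, "mh_sketch"))
  if (a$k != b$k || a$s != b$s || !identical(a$hash_seed, b$hash_seed))
    stop("sketches are not comparable (k, s or hash seed differ)")
  merged <- sort(unique(c(a$hashes, b$hashes)))
  merged <- merged[seq_len(min(a$s, length(merged)))]
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  j <- shared / length(merged)
  if (j <= 0) return(1)
  min(1, -log(2 * j / (1 + j)) / a$k)
}

#' Estimated Jaccard index between two sketches
#'
#' @inheritParams mash_distance
#' @return numeric Jaccard estimate in \[0, 1\].
#' @export
sketch_jaccard <- function(a, b) {
  merged <- sort(unique(c(a$hashes, b$hashes)))
  merged <- merged[seq_len(min(a$s, length(merged)))]
  sum(merged %in% a$hashes & merged %in% b$hashes) / length(merged)
}

#' Single-linkage clustering of sketches
#'
#' Connected components of the graph joining every pair at Mash distance
#' `<= d_max`.  Cluster ids are deterministic: clusters are numbered by
#' their lexicographically smallest member.
#'
#' @param sketches list of [minhash_sketch()] objects.
#' @param d_max distance threshold (default 0.05).
#' @return data.frame `genome_id`, `cluster`.
#' @export
cluster_sketches <- function(sketches, d_max = 0.05) {
  if (length(sketches) == 0) stop("need at least one sketch")
  ids <- vapply(sketches, function(s) s$genome_id, "")
  n <- length(ids)
  edges <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (mash_distance(sketches[[i]], sketches[[j]]) <= d_max)
        edges[[length(edges) + 1]] <- c(ids[i], ids[j])
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) do.call(rbind, edges) else
      data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership
  lead <- vapply(split(names(memb), memb), function(m) sort(m)[1], "")
  ord <- rank(lead)
  data.frame(genome_id = names(memb),
             cluster = as.integer(ord[as.character(memb)]))
}

#' Fragment-based ANI between two genomes
#'
#' The query is cut into consecutive `frag_bp` fragments; each fragment is
#' anchored by shared k-mer seeds to its best diagonal in the reference
#' (leftmost on ties) and extended with a banded alignment (half band
#' `band_frac * frag_bp`).  Fragments with alignment coverage >= 70% of
#' the fragment and identity >= 30% are retained; ANI is the mean identity
#' of retained fragments and query coverage the retained fraction.  The
#' reported ANI of the pair is the mean of the two directional ANIs; both
#' coverages are kept.
#'
#' @param query,ref genome sequences (single characters; concatenate
#'   multi-contig genomes with "N" separators upstream if needed).
#' @param query_id,ref_id identifiers for the report.
#' @param frag_bp fragment size (default 1020).
#' @param k seed k-mer size (default 21).
#' @param band_frac band half-width as a fraction of `frag_bp`.
#' @param min_seeds minimum seed k-mers to accept an anchor (default 2).
#' @param min_frag_cov,min_frag_ident fragment retention thresholds.
#' @return object of class `ani_result`: list with `query_id`, `ref_id`,
#'   `ani_pct` (NA when no fragment aligns in either direction),
#'   `query_cov_pct`, `ref_cov_pct`, `n_fragments_aligned`.
#' @export
fragment_ani <- function(query, ref, query_id = "query", ref_id = "ref",
                         frag_bp = 1020L, k = 21L, band_frac = 0.1,
                         min_seeds = 2L, min_frag_cov = 70,
                         min_frag_ident = 30) {
  if (nchar(query) < frag_bp || nchar(ref) < frag_bp)
    stop("both genomes must be at least frag_bp long")
  dir1 <- ani_direction(query, ref, frag_bp, k, band_frac, min_seeds,
                        min_frag_cov, min_frag_ident)
  dir2 <- ani_direction(ref, query, frag_bp, k, band_frac, min_seeds,
                        min_frag_cov, min_frag_ident)
  ani <- if (is.na(dir1$ani) && is.na(dir2$ani)) NA_real_ else
    mean(c(dir1$ani, dir2$ani), na.rm = TRUE)
  structure(list(query_id = query_id, ref_id = ref_id, ani_pct = ani,
                 query_cov_pct = dir1$cov, ref_cov_pct = dir2$cov,
                 n_fragments_aligned = dir1$n_aligned + dir2$n_aligned),
            class = "ani_result")
}

ani_direction <- function(query, ref, frag_bp, k, band_frac, min_seeds,
                          min_frag_cov, min_frag_ident) {
  fr <- ani_fragments_cpp(query, ref, as.integer(frag_bp), as.integer(k),
                          band_frac, as.integer(min_seeds))
  keep <- !is.na(fr$identity) & fr$coverage >= min_frag_cov &
    fr$identity >= min_frag_ident
  n_tot <- nrow(fr)
  list(ani = if (any(keep)) mean(fr$identity[keep]) else NA_real_,
       cov = if (n_tot) 100 * sum(keep) / n_tot else 0,
       n_aligned = sum(keep))
}

#' Same-species decision rule
#'
#' Two genomes belong to one species when their ANI is at least `ani_min`
#' and the coverage of *both* genomes is at least `cov_min`.
#'
#' @param ani an [fragment_ani()] result (or a list with `ani_pct`,
#'   `query_cov_pct`, `ref_cov_pct`).
#' @param ani_min ANI threshold in percent (default 95).
#' @param cov_min mutual coverage threshold in percent (default 50).
#' @return logical.
#' @export
same_species <- function(ani, ani_min = 95, cov_min = 50) {
  if (is.na(ani$ani_pct)) return(FALSE)
  ani$ani_pct >= ani_min && ani$query_cov_pct >= cov_min &&
    ani$ref_cov_pct >= cov_min
}

#' Dereplicate genomes to species representatives
#'
#' Genomes are first grouped by single-linkage Mash clustering
#' (`d_max`).  Within each cluster, genomes are taken greedily by
#' descending quality score (ties: higher Cp, then lexicographic id): the
#' best unassigned genome becomes a representative and absorbs every
#' unassigned genome that passes [same_species()] against it; this repeats
#' until all genomes are assigned.
#'
#' @param genomes named character vector/list of genome sequences.
#' @param quality data.frame with `genome_id`, `Cp`, `Ct`, `score` (as
#'   from [genome_quality_report()]).
#' @param d_max Mash clustering threshold (default 0.05).
#' @param ani_min,cov_min species decision thresholds.
#' @param k,s sketch parameters.
#' @return list with `representatives` (character ids), `membership`
#'   (data.frame genome_id/representative), `pairs` (evaluated ANI pairs).
#' @export
dereplicate <- function(genomes, quality, d_max = 0.05, ani_min = 95,
                        cov_min = 50, k = 21L, s = 1000L) {
  ids <- names(genomes)
  if (!all(ids %in% quality$genome_id))
    stop("quality scores missing for some genomes")
  q <- quality[match(ids, quality$genome_id), , drop = FALSE]
  sketches <- lapply(ids, function(id)
    minhash_sketch(genomes[[id]], id, k = k, s = s))
  cl <- cluster_sketches(sketches, d_max = d_max)
  rep_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  pairs <- list()
  for (cid in sort(unique(cl$cluster))) {
    members <- cl$genome_id[cl$cluster == cid]
    while (any(is.na(rep_of[members]))) {
      open <- members[is.na(rep_of[members])]
      qi <- q[match(open, q$genome_id), , drop = FALSE]
      ord <- order(-qi$score, -qi$Cp, qi$genome_id)
      best <- open[ord[1]]
      rep_of[best] <- best
      for (other in setdiff(open, best)) {
        res <- fragment_ani(genomes[[best]], genomes[[other]],
                            query_id = best, ref_id = other)
        pairs[[length(pairs) + 1]] <- data.frame(
          a = best, b = other, ani = res$ani_pct,
          cov_a = res$query_cov_pct, cov_b = res$ref_cov_pct,
          same_species = same_species(res, ani_min, cov_min))
        if (same_species(res, ani_min, cov_min)) rep_of[other] <- best
      }
    }
  }
  list(representatives = sort(unique(unname(rep_of))),
       membership = data.frame(genome_id = ids,
                               representative = unname(rep_of[ids])),
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL)
}
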