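## Novelty assessment: ANI matching of representative genomes against a
## reference catalog, and genus/species novelty from full-length 16S
## identity thresholds.

#' Match representatives against a reference catalog by ANI
#'
#' For each representative the best catalog ANI is computed (Mash-sketch
#' prefilter at distance `d_prefilter`, then [fragment_ani()] on the
#' surviving pairs); a genome is `matched` when its best ANI reaches
#' `ani_min`, otherwise `novel`.
#'
#' @param representatives named character vector of genome sequences.
#' @param catalog named character vector of reference genome sequences.
#' @param ani_min match threshold in percent (default 95).
#' @param d_prefilter Mash distance prefilter (default 0.1).
#' @return data.frame: genome_id, catalog_id (best match or NA), ani
#'   (best, NA if no pair survived the prefilter), status.
#' @export
match_catalog <- function(representatives, catalog, ani_min = 95,
                          d_prefilter = 0.1) {
  if (length(catalog) == 0) {
    warning("empty catalog: all representatives reported novel")
    return(data.frame(genome_id = names(representatives),
                      catalog_id = NA_character_, ani = NA_real_,
                      status = "novel"))
  }
  sk_rep <- lapply(names(representatives), function(id)
    minhash_sketch(representatives[[id]], id))
  sk_cat <- lapply(names(catalog), function(id)
    minhash_sketch(catalog[[id]], id))
  rows <- lapply(seq_along(sk_rep), function(i) {
    best_ani <- NA_real_; best_id <- NA_character_
    for (j in seq_along(sk_cat)) {
      if (mash_distance(sk_rep[[i]], sk_cat[[j]]) > d_prefilter) next
      res <- fragment_ani(representatives[[i]], catalog[[j]],
                          query_id = names(representatives)[i],
                          ref_id = names(catalog)[j])
      if (!is.na(res$ani_pct) &&
          (is.na(best_ani) || res$ani_pct > best_ani)) {
        best_ani <- res$ani_pct; best_id <- names(catalog)[j]
      }
    }
    data.frame(genome_id = names(representatives)[i],
               catalog_id = if (!is.na(best_ani) && best_ani >= ani_min)
                 best_id else NA_character_,
               ani = best_ani,
               status = if (!is.na(best_ani) && best_ani >= ani_min)
                 "matched" else "novel")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise identity of two full-length 16S genes
#'
#' Semi-global (end-gap-free) alignment with match +1, mismatch -1 and
#' affine gaps (open 4, extend 2, so a gap is never preferred over a
#' substitution); identity is matches divided by alignment columns
#' spanning the shorter sequence, in percent.  Both sequences must look
#' full-length (1200-1700 bp).
#'
#' @param a,b 16S gene sequences.
#' @return identity percent.
#' @export
ssu_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la < 1200 || la > 1700 || lb < 1200 || lb > 1700)
    stop("ssu_identity expects full-length genes (1200-1700 bp)")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}

#' Genus/species novelty from best 16S identity
#'
#' Below `genus_thr` the gene indicates a novel genus; in
#' `[genus_thr, species_thr)` a novel species; at or above `species_thr`
#' a known species.
#'
#' @param best_identity best identity (percent) against a 16S reference
#'   collection; NA means the genome had no assessable gene.
#' @param genus_thr genus demarcation threshold (default 95).
#' @param species_thr species demarcation threshold (default 97).
#' @return one of `"novel_genus"`, `"novel_species"`, `"known"`,
#'   `"unassessed"` (vectorized).
#' @export
taxon_novelty <- function(best_identity, genus_thr = 95, species_thr = 97) {
  ifelse(is.na(best_identity), "unassessed",
         ifelse(best_identity < genus_thr, "novel_genus",
                ifelse(best_identity < species_thr, "novel_species",
                       "known")))
}

#' Extract 16S genes from an assembled genome
#'
#' Reuses the read-level anchor detector (same anchors, no qualities) and
#' keeps full-length candidates only.
#'
#' @param seq genome sequence.
#' @param genome_id identifier.
#' @return character vector of 16S gene sequences (template orientation).
#' @export
extract_ssu_genes <- function(seq, genome_id = "genome") {
  cand <- detect_ssu(stats::setNames(seq, genome_id))
  cand <- cand[cand$length_bp >= 1200 & cand$length_bp <= 1700, ,
               drop = FALSE]
  cand$sequence
}

#' Full novelty call for representative genomes
#'
#' Combines the catalog ANI call with 16S-based taxon novelty: for each
#' genome the best identity of any of its 16S genes against the 16S
#' reference collection decides novelty (maximum over gene copies — the
#' most conservative choice against false novelty); genomes without a 16S
#' gene are `unassessed`.
#'
#' @param representatives named character vector of genome sequences.
#' @param catalog named character vector of catalog genome sequences.
#' @param ssu_refs named character vector of reference 16S genes.
#' @param ani_min,genus_thr,species_thr thresholds.
#' @return data.frame per genome: catalog call columns plus `ssu_best_id`,
#'   `ssu_best_identity`, `taxon_novelty`.
#' @export
novelty_report <- function(representatives, catalog, ssu_refs,
                           ani_min = 95, genus_thr = 95, species_thr = 97) {
  base <- match_catalog(representatives, catalog, ani_min = ani_min)
  extra <- lapply(names(representatives), function(id) {
    genes <- extract_ssu_genes(representatives[[id]], id)
    if (!length(genes) || !length(ssu_refs))
      return(data.frame(ssu_best_id = NA_character_,
                        ssu_best_identity = NA_real_))
    best <- -Inf; best_id <- NA_character_
    for (g in genes) for (r in names(ssu_refs)) {
      idn <- ssu_identity(g, ssu_refs[[r]])
      if (idn > best) { best <- idn; best_id <- r }
    }
    data.frame(ssu_best_id = best_id, ssu_best_identity = best)
  })
  extra <- do.call(rbind, extra)
  out <- cbind(base, extra)
  out$taxon_novelty <- taxon_novelty(out$ssu_best_identity,
                                     genus_thr, species_thr)
  out
}
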