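## Genome quality scoring: a declared single-copy-marker surrogate for
## completeness/contamination, the quality ranks used to admit genomes, the
## composite score used to pick representatives, and rRNA-operon / tRNA
## metrics.  Marker weighting is uniform (no collocation sets) — a stated
## simplification relative to lineage-specific marker workflows.

#' Completeness and contamination from marker hits
#'
#' With a marker set of M single-copy markers,
#' `Cp = 100 * |markers present at least once| / M` and
#' `Ct = 100 * sum(max(0, count - 1)) / M`.
#'
#' @param hits named integer vector of per-marker copy counts (zeros may be
#'   omitted).
#' @param marker_set_size M, the total number of markers in the set;
#'   defaults to the packaged synthetic marker set size.
#' @return named numeric vector `c(Cp = , Ct = )`.
#' @export
estimate_cp_ct <- function(hits, marker_set_size = length(marker_genes())) {
  if (marker_set_size < 1) stop("empty marker set")
  if (any(hits < 0)) stop("marker counts must be >= 0")
  cp <- 100 * sum(hits >= 1) / marker_set_size
  ct <- 100 * sum(pmax(0, hits - 1)) / marker_set_size
  c(Cp = cp, Ct = ct)
}

#' Genome quality rank
#'
#' `near_complete` if Cp >= 90 and Ct < 5; else `high` if Cp >= 70 and
#' Ct < 10; else `medium` if Cp >= 50 and Ct < 10; else `fail`.
#'
#' @param cp completeness percent (0-100).
#' @param ct contamination percent (>= 0).
#' @return character rank (vectorized).
#' @export
quality_rank <- function(cp, ct) {
  stopifnot(all(cp >= 0 & cp <= 100), all(ct >= 0))
  ifelse(cp >= 90 & ct < 5, "near_complete",
         ifelse(cp >= 70 & ct < 10, "high",
                ifelse(cp >= 50 & ct < 10, "medium", "fail")))
}

#' Composite quality score
#'
#' The score `Cp - 5 * Ct` used to choose between redundant genomes; may
#' be negative.
#'
#' @param cp completeness percent.
#' @param ct contamination percent.
#' @return numeric score.
#' @export
checkm_score <- function(cp, ct) {
  stopifnot(all(cp >= 0 & cp <= 100), all(ct >= 0))
  cp - 5 * ct
}

#' Count complete rRNA operons in an annotation table
#'
#' One operon is counted per 16S gene whose 23S and 5S genes lie on the
#' same strand, in 16S -> 23S -> 5S order (strand-aware downstream), with
#' both starting within `max_span_bp` of the 16S start.  16S genes without
#' a complete same-strand cluster are reported as partial.
#'
#' @param annotations data.frame with columns `type` (`16S_rRNA`,
#'   `23S_rRNA`, `5S_rRNA`), `start`, `end`, `strand`.
#' @param max_span_bp colocation window (default 10000).
#' @return list with `operons` and `partial` counts.
#' @export
count_rrna_operons <- function(annotations, max_span_bp = 10000) {
  need <- c("type", "start", "end", "strand")
  stopifnot(all(need %in% names(annotations)))
  g16 <- annotations[annotations$type == "16S_rRNA", , drop = FALSE]
  g23 <- annotations[annotations$type == "23S_rRNA", , drop = FALSE]
  g5 <- annotations[annotations$type == "5S_rRNA", , drop = FALSE]
  n_op <- 0L; n_part <- 0L
  for (i in seq_len(nrow(g16))) {
    s <- g16$strand[i]
    anchor <- if (s == "+") g16$start[i] else g16$end[i]
    downstream <- function(tab) {
      same <- tab[tab$strand == s, , drop = FALSE]
      pos <- if (s == "+") same$start else same$end
      d <- if (s == "+") pos - anchor else anchor - pos
      d[d > 0 & d <= max_span_bp]
    }
    d23 <- downstream(g23); d5 <- downstream(g5)
    ok <- length(d23) > 0 && length(d5) > 0 && min(d23) < min(d5)
    if (ok) n_op <- n_op + 1L else n_part <- n_part + 1L
  }
  list(operons = n_op, partial = n_part)
}

#' Count distinct standard tRNA isotypes
#'
#' Redundant copies collapse; labels outside the 20 standard isotypes are
#' dropped with a warning.
#'
#' @param annotations data.frame with columns `type` and `id` (`id` holds
#'   the isotype for tRNA rows).
#' @return integer 0-20.
#' @export
count_trna_types <- function(annotations) {
  tr <- annotations[annotations$type == "tRNA", , drop = FALSE]
  iso <- unique(tr$id)
  unknown <- setdiff(iso, TRNA_ISOTYPES)
  if (length(unknown))
    warning("ignoring unknown tRNA isotypes: ",
            paste(unknown, collapse = ", "))
  length(intersect(iso, TRNA_ISOTYPES))
}

#' Detect single-copy markers in a genome sequence
#'
#' Built-in marker search against the packaged synthetic marker set: each
#' marker is seeded by exact occurrences of its central 31-mer (either
#' strand) and a hit is counted where the full-length identity at the
#' seeded position reaches `min_identity` (gap-free comparison).
#'
#' @param seq genome sequence(s) (character vector; multi-contig genomes
#'   pass all contigs).
#' @param markers named character vector of marker genes (defaults to the
#'   packaged set).
#' @param min_identity minimum full-length identity (default 0.95).
#' @return named integer vector of per-marker copy counts.
#' @export
detect_markers <- function(seq, markers = marker_genes(),
                           min_identity = 0.95) {
  ## one dictionary holding every marker's central 31-mer on both strands,
  ## matched in a single pass per contig
  mlen <- vapply(markers, nchar, 0L)
  c0 <- as.integer((mlen - 31) / 2)
  seedf <- substring(markers, c0 + 1, c0 + 31)
  seedr <- revcomp(seedf)
  dict <- Biostrings::PDict(unname(c(seedf, seedr)))
  n <- length(markers)
  qry <- c(markers, revcomp(unlist(markers)))
  offset <- c(c0, mlen - 31L - c0)
  counts <- stats::setNames(integer(n), names(markers))
  for (contig in as.character(seq)) {
    hits <- Biostrings::matchPDict(dict, Biostrings::DNAString(contig))
    st <- Biostrings::startIndex(hits)
    for (i in which(lengths(st) > 0)) {
      m <- ((i - 1) %% n) + 1
      for (p in st[[i]]) {
        gstart <- p - offset[i]
        if (gstart < 1 || gstart + mlen[m] - 1 > nchar(contig)) next
        window <- substring(contig, gstart, gstart + mlen[m] - 1)
        if (hamming_identity(window, qry[[i]]) >= min_identity)
          counts[m] <- counts[m] + 1L
      }
    }
  }
  counts
}

## Gap-free identity between two equal-length strings.
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  x <- utf8ToInt(a) == utf8ToInt(b)
  mean(x)
}

#' Full quality report for a set of genomes
#'
#' Runs marker detection (or consumes a precomputed hit table), assigns
#' ranks and scores, and computes operon/tRNA metrics from an annotation
#' table when one is supplied.
#'
#' @param genomes named list/vector; each element the sequence(s) of one
#'   genome.
#' @param hits optional named list of per-genome marker hit vectors (skips
#'   the built-in detector).
#' @param annotations optional annotation data.frame with a `genome`
#'   column (plus the columns of [count_rrna_operons()] and
#'   [count_trna_types()]).
#' @return data.frame: genome_id, Cp, Ct, rank, score, n_operons,
#'   n_partial_operons, n_trna_types.
#' @export
genome_quality_report <- function(genomes, hits = NULL, annotations = NULL) {
  ids <- names(genomes)
  rows <- lapply(ids, function(id) {
    h <- if (!is.null(hits)) hits[[id]] else detect_markers(genomes[[id]])
    q <- estimate_cp_ct(h)
    n_op <- NA_integer_; n_part <- NA_integer_; n_trna <- NA_integer_
    if (!is.null(annotations)) {
      ann <- annotations[annotations$genome == id, , drop = FALSE]
      op <- count_rrna_operons(ann)
      n_op <- op$operons; n_part <- op$partial
      n_trna <- suppressWarnings(count_trna_types(ann))
    }
    data.frame(genome_id = id, Cp = q[["Cp"]], Ct = q[["Ct"]],
               rank = quality_rank(q[["Cp"]], q[["Ct"]]),
               score = checkm_score(q[["Cp"]], q[["Ct"]]),
               n_operons = n_op, n_partial_operons = n_part,
               n_trna_types = n_trna)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
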