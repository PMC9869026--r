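## Read-level full-length 16S profiling: conserved-anchor detection of 16S
## genes on HiFi reads, the length and Phred-accuracy filters, a
## naive-Bayes 8-mer bootstrap classifier, and copy-number-adjusted
## community profiles.

#' Detect full-length 16S genes on reads (or genomes)
#'
#' A candidate is reported where at least `min_anchors` conserved-region
#' anchors co-occur on one strand, in template order, with pairwise
#' spacing within +/-`spacing_tol` of the spacing on the packaged 16S
#' template.  Boundaries are taken from the outermost anchors extended to
#' the template ends and clipped to the read.  Reverse-strand candidates
#' are reverse-complemented (qualities reversed), so all reported genes
#' are in template orientation.
#'
#' @param seqs character vector of read (or genome) sequences.
#' @param ids sequence identifiers.
#' @param quals optional Phred+33 quality strings (same lengths as
#'   `seqs`).
#' @param max_mismatch anchor mismatch tolerance (default 1).
#' @param min_anchors minimum chained anchors (default 3).
#' @param spacing_tol relative spacing tolerance (default 0.2).
#' @return data.frame of candidates: read_id, start, end (1-based on the
#'   read as sequenced), strand, length_bp, n_anchors, sequence, qual,
#'   mean_error_prob.
#' @export
detect_ssu <- function(seqs, ids = names(seqs), quals = NULL,
                       max_mismatch = 1L, min_anchors = 3L,
                       spacing_tol = 0.2) {
  if (is.null(ids)) ids <- sprintf("seq%06d", seq_along(seqs))
  anc <- ssu_anchors()
  len16 <- nchar(rrna_templates()[["16S_rRNA"]])
  hits <- scan_anchors_cpp(as.character(seqs), anc$anchor_seq,
                           as.integer(max_mismatch))
  out <- list()
  if (nrow(hits)) hits_by_seq <- split(hits, hits$seq) else hits_by_seq <- list()
  for (si in names(hits_by_seq)) {
    i <- as.integer(si)
    slen <- nchar(seqs[[i]])
    h <- hits_by_seq[[si]]
    for (strand in c(1L, -1L)) {
      hs <- h[h$strand == strand, , drop = FALSE]
      if (nrow(hs) < min_anchors) next
      ## work in gene orientation: for "-" hits, flip read coordinates
      pos <- if (strand == 1L) hs$pos else slen - (hs$pos + 14L) + 1L
      toff <- anc$anchor_offset[hs$anchor]
      ord <- order(pos)
      pos <- pos[ord]; toff <- toff[ord]
      chains <- chain_anchors(pos, toff, spacing_tol)
      for (ch in chains) {
        if (length(ch) < min_anchors) next
        p1 <- pos[ch[1]]; t1 <- toff[ch[1]]
        pL <- pos[ch[length(ch)]]; tL <- toff[ch[length(ch)]]
        gstart <- max(1L, p1 - t1 + 1L)
        gend <- min(slen, pL + (len16 - tL))
        sq <- if (strand == 1L) substring(seqs[[i]], gstart, gend) else
          revcomp(substring(seqs[[i]], slen - gend + 1L, slen - gstart + 1L))
        ql <- NA_character_
        if (!is.null(quals)) {
          qfull <- quals[[i]]
          ql <- if (strand == 1L) substring(qfull, gstart, gend) else
            reverse_chars(substring(qfull, slen - gend + 1L,
                                    slen - gstart + 1L))
        }
        out[[length(out) + 1]] <- data.frame(
          read_id = ids[i],
          start = if (strand == 1L) gstart else slen - gend + 1L,
          end = if (strand == 1L) gend else slen - gstart + 1L,
          strand = if (strand == 1L) "+" else "-",
          length_bp = gend - gstart + 1L, n_anchors = length(ch),
          sequence = sq, qual = ql,
          mean_error_prob = if (is.na(ql)) NA_real_ else
            qual_mean_error_cpp(ql))
      }
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      length_bp = integer(), n_anchors = integer(),
                      sequence = character(), qual = character(),
                      mean_error_prob = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Greedy chaining of anchors sorted by read position: extend while the
## template offset increases and the read spacing matches the template
## spacing within the relative tolerance.
chain_anchors <- function(pos, toff, tol) {
  chains <- list()
  cur <- integer(0)
  for (i in seq_along(pos)) {
    if (length(cur) == 0) { cur <- i; next }
    l <- cur[length(cur)]
    dt <- toff[i] - toff[l]
    dp <- pos[i] - pos[l]
    ok <- dt > 0 && dp > 0 && abs(dp - dt) <= tol * dt
    if (ok) cur <- c(cur, i) else { chains[[length(chains) + 1]] <- cur; cur <- i }
  }
  if (length(cur)) chains[[length(chains) + 1]] <- cur
  chains
}

reverse_chars <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

#' Length and quality filter for detected 16S genes
#'
#' Keeps genes with `min_bp <= length <= max_bp` and Phred-implied mean
#' accuracy `1 - mean_error_prob >= min_accuracy` (Q20 corresponds to
#' 99%).
#'
#' @param candidates a [detect_ssu()] table with quality strings.
#' @param min_bp,max_bp length bounds (defaults 1200 and 1700).
#' @param min_accuracy minimum mean accuracy (default 0.99).
#' @return the retained subset of `candidates`.
#' @export
filter_ssu <- function(candidates, min_bp = 1200, max_bp = 1700,
                       min_accuracy = 0.99) {
  keep <- candidates$length_bp >= min_bp & candidates$length_bp <= max_bp &
    (1 - candidates$mean_error_prob) >= min_accuracy
  candidates[keep & !is.na(keep), , drop = FALSE]
}

#' Train the naive-Bayes 8-mer 16S classifier
#'
#' Per-genus word (8-mer) presence priors with the classical smoothing
#' `(n_sequences_with_word + 0.5) / (n_sequences + 1)`.
#'
#' @param ref_seqs named character vector of reference 16S sequences.
#' @param taxon_paths character vector (same names/order) of
#'   `domain;...;genus` lineages.
#' @param word_size word length (default 8).
#' @return object of class `ssu_classifier`.
#' @export
train_classifier <- function(ref_seqs, taxon_paths, word_size = 8L) {
  if (is.null(names(ref_seqs)) || anyDuplicated(names(ref_seqs)))
    stop("reference sequences need unique ids")
  if (length(taxon_paths) != length(ref_seqs))
    stop("need one taxon path per reference sequence")
  genera <- vapply(taxon_paths, taxon_rank, "", rank = "genus")
  if (length(unique(genera)) < 2)
    stop("training needs at least two genera")
  x <- Biostrings::DNAStringSet(ref_seqs)
  freq <- Biostrings::oligonucleotideFrequency(x, width = word_size)
  pres <- freq > 0
  glist <- sort(unique(genera))
  logp <- sapply(glist, function(g) {
    rows <- pres[genera == g, , drop = FALSE]
    n <- nrow(rows)
    log((colSums(rows) + 0.5) / (n + 1))
  })
  taxmat <- do.call(rbind, lapply(glist, function(g) {
    p <- taxon_paths[match(g, genera)]
    parts <- strsplit(p, ";", fixed = TRUE)[[1]]
    length(parts) <- length(TAXON_RANKS)
    parts
  }))
  colnames(taxmat) <- TAXON_RANKS
  rownames(taxmat) <- glist
  structure(list(logp = logp, genera = glist, taxonomy = taxmat,
                 word_size = as.integer(word_size)),
            class = "ssu_classifier")
}

#' Save / load a trained classifier
#'
#' @param model an [train_classifier()] model.
#' @param path file path.
#' @return `write_classifier` returns `path` invisibly; `read_classifier`
#'   the model.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "ssu_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "ssu_classifier"))
  m
}

#' Classify 16S genes with bootstrap confidence
#'
#' The genus call is the maximum joint log-likelihood over the gene's
#' distinct words; confidence is the fraction of `n_bootstrap` trials
#' (each scoring a random 1/8 subsample of the words, drawn with
#' replacement) agreeing with that call.  Ranks above genus inherit the
#' aggregated trial agreement of their descendant genera.  The assigned
#' taxon is rolled up to the deepest rank whose confidence reaches
#' `conf_min`; a gene confident at no rank is `unclassified`.
#'
#' @param seqs character vector of 16S gene sequences (template
#'   orientation).
#' @param model an [train_classifier()] model.
#' @param n_bootstrap bootstrap trials (default 100).
#' @param conf_min minimum confidence to report a rank (default 0.8).
#' @param seed integer seed for the bootstrap.
#' @return data.frame: one row per gene with `genus`..`domain` calls,
#'   per-rank confidences, and the rolled-up `assigned_rank` /
#'   `assigned_taxon`.
#' @export
classify_ssu <- function(seqs, model, n_bootstrap = 100L, conf_min = 0.8,
                         seed = 1L) {
  stopifnot(inherits(model, "ssu_classifier"))
  if (any(nchar(seqs) < model$word_size))
    stop("gene shorter than the classifier word size")
  x <- Biostrings::DNAStringSet(as.character(seqs))
  freq <- Biostrings::oligonucleotideFrequency(x, width = model$word_size)
  G <- length(model$genera)
  rows <- with_seed(child_seed(seed, "classify"), {
    lapply(seq_along(seqs), function(i) {
      words <- which(freq[i, ] > 0)
      W <- model$logp[words, , drop = FALSE]
      full <- colSums(W)
      ml <- model$genera[which.max(full)]
      m <- max(1L, ceiling(length(words) / 8))
      wins <- character(n_bootstrap)
      for (t in seq_len(n_bootstrap)) {
        sub <- sample.int(length(words), m, replace = TRUE)
        sc <- colSums(W[sub, , drop = FALSE])
        ## a subsample scoring all genera equally carries no signal
        wins[t] <- if (max(sc) - min(sc) < 1e-9) NA_character_ else
          model$genera[which.max(sc)]
      }
      conf <- numeric(length(TAXON_RANKS))
      names(conf) <- TAXON_RANKS
      call <- character(length(TAXON_RANKS))
      names(call) <- TAXON_RANKS
      win_tax <- model$taxonomy[wins, , drop = FALSE]
      for (r in TAXON_RANKS) {
        call[r] <- model$taxonomy[ml, r]
        agree <- !is.na(wins) & win_tax[, r] == call[r]
        agree[is.na(agree)] <- FALSE
        conf[r] <- mean(agree)
      }
      ok <- which(conf >= conf_min)
      if (length(ok)) {
        deepest <- max(ok)
        arank <- TAXON_RANKS[deepest]
        ataxon <- call[deepest]
      } else { arank <- "unclassified"; ataxon <- NA_character_ }
      data.frame(t(call), t(stats::setNames(conf, paste0("conf_",
                                                         TAXON_RANKS))),
                 assigned_rank = arank, assigned_taxon = ataxon)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Copy-number-adjusted community profile
#'
#' Divides per-taxon gene counts by 16S copies per genome so abundances
#' reflect cells rather than gene copies:
#' `abundance(t) = (count_t / copies_t) / sum_u(count_u / copies_u)`.
#' Copy numbers are looked up at the stated rank; unlisted taxa fall back
#' to `default_copies`.
#'
#' @param taxa character vector of per-gene taxon calls (NA = dropped).
#' @param copy_table data.frame with columns naming the taxon (first
#'   column) and `copies`.
#' @param default_copies fallback copy number (default 2).
#' @return named numeric vector of relative abundances summing to 1.
#' @export
copy_adjusted_profile <- function(taxa, copy_table = rrn_copy_table(),
                                  default_copies = 2) {
  taxa <- taxa[!is.na(taxa)]
  if (!length(taxa)) stop("no classified genes to profile")
  counts <- table(taxa)
  key <- copy_table[[1]]
  copies <- copy_table$copies[match(names(counts), key)]
  copies[is.na(copies)] <- default_copies
  if (any(copies <= 0)) stop("copy numbers must be positive")
  w <- as.numeric(counts) / copies
  stats::setNames(w / sum(w), names(counts))
}
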