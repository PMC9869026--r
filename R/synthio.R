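## Synthetic community generation: replicon specs, community specs, genome
## synthesis with planted rRNA operons / tRNA genes / marker genes, HiFi-like
## read simulation with Phred-consistent substitution noise, and GFA
## construction — all with a machine-readable truth manifest.

#' Describe a replicon to simulate
#'
#' A replicon spec fixes the identity, size, topology and planted gene
#' content of one simulated replicon.  Chromosomes must be at least 1 Mb;
#' plasmid and virus replicons must be smaller than 1 Mb (the same size
#' split used when judging whether a circular contig can be a complete
#' genome).
#'
#' @param id replicon identifier.
#' @param length_bp replicon length (>= 1000).
#' @param topology `"circular"` or `"linear"`.
#' @param replicon_class `"chromosome"`, `"plasmid"` or `"virus"`.
#' @param gc_fraction backbone GC fraction in (0, 1).
#' @param rrn_operon_copies number of planted 16S-23S-5S operons (0-15).
#' @param trna_types character vector of standard tRNA isotypes to plant.
#' @param taxon_path semicolon-separated lineage
#'   `domain;phylum;class;order;family;genus` (may be `NA` for viruses).
#' @param plant_markers plant the packaged single-copy marker set once
#'   (default: chromosomes only).
#' @return object of class `replicon_spec`.
#' @export
replicon_spec <- function(id, length_bp, topology = c("circular", "linear"),
                          replicon_class = c("chromosome", "plasmid", "virus"),
                          gc_fraction = 0.5, rrn_operon_copies = 2,
                          trna_types = TRNA_ISOTYPES, taxon_path = NA_character_,
                          plant_markers = NULL) {
  topology <- match.arg(topology)
  replicon_class <- match.arg(replicon_class)
  length_bp <- as.integer(length_bp)
  if (length_bp < 1000L)
    stop("replicon '", id, "': length_bp must be >= 1000")
  if (replicon_class == "chromosome" && length_bp < 1e6)
    stop("replicon '", id, "': chromosome specs must be >= 1 Mb")
  if (replicon_class != "chromosome" && length_bp >= 1e6)
    stop("replicon '", id, "': plasmid/virus specs must be < 1 Mb")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  if (rrn_operon_copies < 0 || rrn_operon_copies > 15)
    stop("rrn_operon_copies must be between 0 and 15")
  bad <- setdiff(trna_types, TRNA_ISOTYPES)
  if (length(bad))
    stop("unknown tRNA isotypes: ", paste(bad, collapse = ", "))
  if (is.null(plant_markers)) plant_markers <- replicon_class == "chromosome"
  structure(list(id = id, length_bp = length_bp, topology = topology,
                 replicon_class = replicon_class, gc_fraction = gc_fraction,
                 rrn_operon_copies = as.integer(rrn_operon_copies),
                 trna_types = trna_types, taxon_path = taxon_path,
                 plant_markers = plant_markers),
            class = "replicon_spec")
}

#' Describe a synthetic community
#'
#' @param replicons list of [replicon_spec()] objects.
#' @param abundances positive weights, one per replicon, summing to 1.
#' @param strain_variants optional data.frame with columns `base_id`,
#'   `n_variants`, `divergence` and `weight_frac`: each base replicon gains
#'   `n_variants` substitution-mutated variants; each variant receives
#'   `weight_frac` of the base abundance.
#' @param seed integer seed fixing the realized community.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(replicons, abundances, strain_variants = NULL,
                           seed = 1L) {
  ids <- vapply(replicons, function(r) r$id, "")
  if (anyDuplicated(ids)) stop("duplicate replicon ids")
  if (length(abundances) != length(replicons))
    stop("need one abundance per replicon")
  if (any(abundances <= 0)) stop("abundances must be positive")
  if (abs(sum(abundances) - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", sum(abundances), ")")
  if (!is.null(strain_variants)) {
    need <- c("base_id", "n_variants", "divergence", "weight_frac")
    if (!all(need %in% names(strain_variants)))
      stop("strain_variants needs columns ", paste(need, collapse = ", "))
    if (!all(strain_variants$base_id %in% ids))
      stop("strain_variants reference unknown replicons")
  }
  structure(list(replicons = replicons,
                 abundances = stats::setNames(abundances, ids),
                 strain_variants = strain_variants, seed = as.integer(seed)),
            class = "community_spec")
}

#' HiFi read model
#'
#' Length and accuracy model of simulated HiFi reads.  Read lengths are
#' drawn from a normal distribution truncated to
#' `[min_length_bp, max_length_bp]` whose mean is calibrated so that the
#' expected read-set N50 equals `length_n50_bp`.  Per-read base quality is
#' drawn from a two-point integer Phred distribution calibrated so the
#' expected per-base error rate equals `1 - mean_accuracy`, then jittered
#' by +/-`quality_jitter` per base.  Substitution errors are drawn at the
#' Phred-implied rate of each base, so quality strings are an unbiased
#' accuracy estimate by construction.
#'
#' @param length_n50_bp target read N50 (default 14254).
#' @param min_length_bp minimum emitted read length (default 1000).
#' @param max_length_bp truncation upper bound (default 30000).
#' @param length_sd_bp standard deviation of the length distribution.
#' @param mean_accuracy expected per-base accuracy (> 0.99; default 0.9994).
#' @param quality_jitter per-base quality jitter half-width (default 2).
#' @return object of class `read_model`.
#' @export
read_model <- function(length_n50_bp = 14254L, min_length_bp = 1000L,
                       max_length_bp = 30000L, length_sd_bp = 2800,
                       mean_accuracy = 0.9994, quality_jitter = 2L) {
  if (mean_accuracy <= 0.99)
    stop("mean_accuracy must exceed 0.99 for HiFi-like reads")
  if (min_length_bp >= length_n50_bp)
    stop("min_length_bp must be below length_n50_bp")
  m <- structure(list(length_n50_bp = as.integer(length_n50_bp),
                      min_length_bp = as.integer(min_length_bp),
                      max_length_bp = as.integer(max_length_bp),
                      length_sd_bp = length_sd_bp,
                      mean_accuracy = mean_accuracy,
                      quality_jitter = as.integer(quality_jitter)),
                 class = "read_model")
  m$length_mu <- calibrate_length_mu(m)
  m$quality_dist <- calibrate_quality(mean_accuracy, quality_jitter)
  m
}

## Mean of the truncated-normal length distribution such that the expected
## N50 (base-weighted upper median) hits the target.
calibrate_length_mu <- function(model) {
  lb <- model$min_length_bp; ub <- model$max_length_bp
  sd <- model$length_sd_bp; target <- model$length_n50_bp
  n50_of <- function(mu) {
    wtot <- integrate(function(t) t * dnorm(t, mu, sd), lb, ub)$value
    f <- function(x)
      integrate(function(t) t * dnorm(t, mu, sd), x, ub)$value / wtot - 0.5
    uniroot(f, c(lb, ub))$root
  }
  uniroot(function(mu) n50_of(mu) - target,
          c(lb + sd / 2, ub - sd / 2))$root
}

## Two-point integer Phred distribution {q, q+1} with mixing weight chosen
## so that E[10^(-(q+J)/10)] (J uniform on -j..j) equals 1 - mean_accuracy.
calibrate_quality <- function(mean_accuracy, jitter) {
  target <- 1 - mean_accuracy
  jfac <- mean(10^(-(-jitter:jitter) / 10))
  qreal <- -10 * log10(target / jfac)
  qlo <- floor(qreal)
  e <- function(q) 10^(-q / 10) * jfac
  w <- (e(qlo) - target) / (e(qlo) - e(qlo + 1))
  list(q = c(qlo, qlo + 1), prob = c(1 - w, w))
}

#' Synthesize one replicon with planted genes
#'
#' Generates the replicon backbone at the requested GC, plants
#' `rrn_operon_copies` ordered 16S-23S-5S operons (one strand each, within
#' a <= 10 kb window), one gene per requested tRNA isotype and (for
#' chromosomes) one copy of every packaged single-copy marker gene, at
#' random non-overlapping positions.  All coordinates are recorded in the
#' truth annotation table.
#'
#' @param spec a [replicon_spec()].
#' @param seed integer seed; identical (spec, seed) gives byte-identical
#'   output.
#' @return list with elements `spec`, `seq` (character) and `annotations`
#'   (data.frame: replicon, type, id, start, end, strand, operon).
#' @export
generate_replicon <- function(spec, seed) {
  stopifnot(inherits(spec, "replicon_spec"))
  genus <- taxon_rank(spec$taxon_path, "genus")
  genes <- list()
  if (spec$rrn_operon_copies > 0) {
    if (is.na(genus))
      stop("replicon '", spec$id, "': rRNA operons need a taxon_path")
    rr <- genus_rrna_genes(genus)
    for (i in seq_len(spec$rrn_operon_copies))
      genes[[length(genes) + 1]] <- list(kind = "operon", idx = i, genes = rr)
  }
  for (iso in spec$trna_types)
    genes[[length(genes) + 1]] <- list(kind = "tRNA", idx = iso,
                                       seq = trna_gene(iso))
  if (spec$plant_markers) {
    mk <- marker_genes()
    for (i in seq_along(mk))
      genes[[length(genes) + 1]] <- list(kind = "marker", idx = names(mk)[i],
                                         seq = mk[[i]])
  }
  with_seed(child_seed(seed, paste0("replicon/", spec$id)), {
    spacer <- function(n) random_dna(n, spec$gc_fraction)
    ## realize each element as (sequence, relative gene table)
    elements <- lapply(genes, function(g) {
      if (g$kind == "operon") {
        sp1 <- sample(60:120, 1); sp2 <- sample(40:80, 1)
        s16 <- g$genes[["16S"]]; s23 <- g$genes[["23S"]]; s5 <- g$genes[["5S"]]
        seqf <- paste0(s16, spacer(sp1), s23, spacer(sp2), s5)
        o16 <- 1L
        o23 <- nchar(s16) + sp1 + 1L
        o5 <- o23 + nchar(s23) + sp2
        tab <- data.frame(type = c("16S_rRNA", "23S_rRNA", "5S_rRNA"),
                          id = paste0("operon", g$idx),
                          rel_start = c(o16, o23, o5),
                          rel_end = c(nchar(s16), o23 + nchar(s23) - 1L,
                                      o5 + nchar(s5) - 1L),
                          operon = g$idx)
        list(seq = seqf, tab = tab)
      } else {
        list(seq = g$seq,
             tab = data.frame(type = if (g$kind == "tRNA") "tRNA" else "marker",
                              id = as.character(g$idx), rel_start = 1L,
                              rel_end = nchar(g$seq), operon = NA_integer_))
      }
    })
    el_len <- vapply(elements, function(e) nchar(e$seq), 0)
    free <- spec$length_bp - sum(el_len)
    n_el <- length(elements)
    if (free < n_el + 1)
      stop("replicon '", spec$id, "': planted genes exceed available length")
    ## random order, random strand, random gap sizes
    ord <- if (n_el > 1) sample(n_el) else seq_len(n_el)
    strands <- if (n_el) sample(c("+", "-"), n_el, replace = TRUE) else character()
    gaps <- if (n_el) {
      w <- runif(n_el + 1)
      floor(free * w / sum(w))
    } else free
    gaps[1] <- gaps[1] + (free - sum(gaps))
    pieces <- character(0)
    ann <- list()
    pos <- 0L
    for (j in seq_len(n_el)) {
      pieces <- c(pieces, spacer(gaps[j]))
      pos <- pos + gaps[j]
      e <- elements[[ord[j]]]
      el <- nchar(e$seq)
      strand <- strands[j]
      sq <- if (strand == "+") e$seq else revcomp(e$seq)
      tab <- e$tab
      if (strand == "+") {
        tab$start <- pos + tab$rel_start
        tab$end <- pos + tab$rel_end
      } else {
        tab$start <- pos + el - tab$rel_end + 1L
        tab$end <- pos + el - tab$rel_start + 1L
      }
      tab$strand <- strand
      pieces <- c(pieces, sq)
      pos <- pos + el
      ann[[j]] <- tab[, c("type", "id", "start", "end", "strand", "operon")]
    }
    pieces <- c(pieces, spacer(gaps[n_el + 1]))
    seqfull <- paste(pieces, collapse = "")
    stopifnot(nchar(seqfull) == spec$length_bp)
    annotations <- if (length(ann)) cbind(replicon = spec$id,
                                          do.call(rbind, ann)) else
      data.frame(replicon = character(), type = character(),
                 id = character(), start = integer(), end = integer(),
                 strand = character(), operon = integer())
    annotations <- annotations[order(annotations$start), , drop = FALSE]
    rownames(annotations) <- NULL
    list(spec = spec, seq = seqfull, annotations = annotations)
  })
}

#' Derive a strain variant of a realized replicon
#'
#' Applies uniform substitutions at the given divergence rate.  Annotation
#' coordinates are inherited unchanged (the noise model is
#' substitution-only).
#'
#' @param replicon a realized replicon from [generate_replicon()].
#' @param divergence substitution rate in (0, 0.5).
#' @param variant_id identifier of the new replicon.
#' @param seed integer seed.
#' @return a realized replicon list.
#' @export
make_strain_variant <- function(replicon, divergence, variant_id, seed) {
  stopifnot(divergence > 0, divergence < 0.5)
  seqv <- with_seed(child_seed(seed, paste0("variant/", variant_id)),
                    mutate_sequence(replicon$seq, divergence))
  ann <- replicon$annotations
  if (nrow(ann)) ann$replicon <- variant_id
  spec <- replicon$spec
  spec$id <- variant_id
  list(spec = spec, seq = seqv, annotations = ann,
       base_id = replicon$spec$id, divergence = divergence)
}

## Extract one rank from a "d;p;c;o;f;g" lineage string.
taxon_rank <- function(taxon_path, rank) {
  if (is.na(taxon_path)) return(NA_character_)
  parts <- strsplit(taxon_path, ";", fixed = TRUE)[[1]]
  i <- match(rank, TAXON_RANKS)
  if (i > length(parts)) NA_character_ else trimws(parts[i])
}

#' Realize a community: sequences, variants and truth tables
#'
#' Generates every replicon of a [community_spec()] (plus requested strain
#' variants), and assembles the truth manifest: per-replicon taxonomy and
#' abundance, gene annotations, and the realized 16S copy-number table.
#'
#' @param cspec a [community_spec()].
#' @return object of class `synthetic_community`: list with `replicons`
#'   (named list of realized replicons), `abundances` (per realized
#'   replicon, sums to 1), `taxonomy` (data.frame replicon/taxon_path/
#'   base_id), `annotations` (combined truth gene table) and `copy_table`.
#' @export
build_community <- function(cspec) {
  stopifnot(inherits(cspec, "community_spec"))
  reps <- list()
  ab <- numeric(0)
  tax <- list()
  for (i in seq_along(cspec$replicons)) {
    sp <- cspec$replicons[[i]]
    r <- generate_replicon(sp, cspec$seed)
    w <- cspec$abundances[[sp$id]]
    sv <- cspec$strain_variants
    if (!is.null(sv) && sp$id %in% sv$base_id) {
      v <- sv[sv$base_id == sp$id, , drop = FALSE]
      for (j in seq_len(nrow(v))) {
        for (m in seq_len(v$n_variants[j])) {
          vid <- sprintf("%s_v%d", sp$id, m + 1L)
          vr <- make_strain_variant(r, v$divergence[j], vid,
                                    cspec$seed + m)
          reps[[vid]] <- vr
          ab[vid] <- w * v$weight_frac[j] / v$n_variants[j]
          tax[[vid]] <- data.frame(replicon = vid, taxon_path = sp$taxon_path,
                                   base_id = sp$id,
                                   replicon_class = sp$replicon_class)
        }
        w <- w * (1 - v$weight_frac[j])
      }
    }
    reps[[sp$id]] <- r
    ab[sp$id] <- w
    tax[[sp$id]] <- data.frame(replicon = sp$id, taxon_path = sp$taxon_path,
                               base_id = sp$id,
                               replicon_class = sp$replicon_class)
  }
  taxonomy <- do.call(rbind, tax)
  rownames(taxonomy) <- NULL
  annotations <- do.call(rbind, lapply(reps, function(r) r$annotations))
  rownames(annotations) <- NULL
  copy_table <- copy_table_from(reps, taxonomy)
  structure(list(spec = cspec, replicons = reps, abundances = ab / sum(ab),
                 taxonomy = taxonomy, annotations = annotations,
                 copy_table = copy_table),
            class = "synthetic_community")
}

## Genus-level 16S copy numbers realized in a community (base replicons).
copy_table_from <- function(reps, taxonomy) {
  base <- taxonomy[taxonomy$replicon == taxonomy$base_id, , drop = FALSE]
  genus <- vapply(base$taxon_path, taxon_rank, "", rank = "genus")
  copies <- vapply(base$replicon, function(id)
    reps[[id]]$spec$rrn_operon_copies, 0L)
  keep <- !is.na(genus) & copies > 0
  df <- data.frame(genus = genus[keep], copies = copies[keep])
  df[!duplicated(df$genus), , drop = FALSE]
}

#' The default synthetic digester community
#'
#' Twelve bacterial/archaeal taxa with log-normal abundance skew
#' (sigma = 1.5) and one dominant taxon fixed at 70% to mimic a
#' *Defluviitoga*-dominated anaerobic-digester profile; the dominant taxon
#' carries a small plasmid and a strain variant, one archaeon
#' (*Methanothrix*) carries a second strain variant, and a small virus
#' replicon is included.  Chromosome sizes are 1.0-2.05 Mb and 16S operon
#' copy numbers follow the packaged per-genus copy table.
#'
#' @param seed integer seed; abundances of the non-dominant taxa are
#'   resampled per seed, the dominant weight stays fixed at 0.70.
#' @return a [community_spec()].
#' @export
default_community <- function(seed = 1L) {
  taxa <- data.frame(
    genus = c("Defluviitoga", "Methanothrix", "Fermentimonas", "Petrimonas",
              "Syntrophomonas", "Clostridium", "Anaerolinea", "Thermovirga",
              "Desulfovibrio", "Olsenella", "Sebaldella", "Phycisphaera"),
    path = c(
      "Bacteria;Thermotogae;Thermotogae_c;Petrotogales;Petrotogaceae;Defluviitoga",
      "Archaea;Euryarchaeota;Methanomicrobia;Methanotrichales;Methanotrichaceae;Methanothrix",
      "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Dysgonomonadaceae;Fermentimonas",
      "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Dysgonomonadaceae;Petrimonas",
      "Bacteria;Firmicutes;Clostridia;Eubacteriales;Syntrophomonadaceae;Syntrophomonas",
      "Bacteria;Firmicutes;Clostridia;Eubacteriales;Clostridiaceae;Clostridium",
      "Bacteria;Chloroflexi;Anaerolineae;Anaerolineales;Anaerolineaceae;Anaerolinea",
      "Bacteria;Synergistetes;Synergistia;Synergistales;Synergistaceae;Thermovirga",
      "Bacteria;Desulfobacterota;Desulfovibrionia;Desulfovibrionales;Desulfovibrionaceae;Desulfovibrio",
      "Bacteria;Actinobacteria;Coriobacteriia;Coriobacteriales;Atopobiaceae;Olsenella",
      "Bacteria;Fusobacteriota;Fusobacteriia;Fusobacteriales;Leptotrichiaceae;Sebaldella",
      "Bacteria;Planctomycetes;Phycisphaerae;Phycisphaerales;Phycisphaeraceae;Phycisphaera"),
    length = c(2050000L, 1300000L, 1250000L, 1100000L, 1150000L, 1400000L,
               1050000L, 1000000L, 1200000L, 1000000L, 1350000L, 1100000L),
    gc = c(0.31, 0.52, 0.38, 0.41, 0.45, 0.30, 0.54, 0.48, 0.58, 0.64,
           0.33, 0.55))
  copies <- rrn_copy_table()
  taxa$copies <- copies$copies[match(taxa$genus, copies$genus)]
  reps <- lapply(seq_len(nrow(taxa)), function(i)
    replicon_spec(id = sprintf("chr_%s", taxa$genus[i]),
                  length_bp = taxa$length[i], topology = "circular",
                  replicon_class = "chromosome", gc_fraction = taxa$gc[i],
                  rrn_operon_copies = taxa$copies[i],
                  taxon_path = taxa$path[i]))
  reps <- c(reps, list(
    replicon_spec("pDefluviitoga", 45000L, "circular", "plasmid",
                  gc_fraction = 0.33, rrn_operon_copies = 0L,
                  trna_types = character(),
                  taxon_path = taxa$path[1]),
    replicon_spec("virus_phi1", 35000L, "circular", "virus",
                  gc_fraction = 0.42, rrn_operon_copies = 0L,
                  trna_types = character(),
                  taxon_path = "Viruses;Uroviricota;Caudoviricetes;Caudovirales;Unclassified_f;Unclassified_g")))
  ## weights: dominant taxon 0.70 total (chromosome + variant + plasmid),
  ## virus 0.005, the rest log-normal over the remaining taxa
  w_dom <- 0.70 - 0.01          # chromosome + variant share; plasmid 0.01
  w_vir <- 0.005
  w_rest <- with_seed(child_seed(seed, "abundances"), {
    x <- rlnorm(nrow(taxa) - 1, meanlog = 0, sdlog = 1.5)
    x / sum(x) * (1 - 0.70 - w_vir)
  })
  ab <- c(w_dom, w_rest, 0.01, w_vir)
  sv <- data.frame(
    base_id = c("chr_Defluviitoga", "chr_Methanothrix"),
    n_variants = c(2L, 1L),
    divergence = c(0.01, 0.005),
    weight_frac = c(0.05 / w_dom, 0.2))
  community_spec(reps, ab, strain_variants = sv, seed = seed)
}

#' Simulate HiFi reads from a realized community
#'
#' Reads are drawn from each replicon in proportion to abundance x length,
#' i.e. replicon i receives `depth_target * abundance_i` fold coverage.
#' Start positions are uniform; circular replicons yield origin-spanning
#' reads; minus-strand reads are reverse-complemented before noise.
#' Substitution errors are drawn per base at the Phred-implied rate of the
#' base's quality.  The truth manifest records every read's source
#' interval, strand and substitution count, plus the read-coordinate
#' intervals of every fully contained 16S gene.
#'
#' @param community a [build_community()] result.
#' @param model a [read_model()].
#' @param depth_target community depth multiplier (> 0): replicon i is
#'   covered at `depth_target * abundance_i` fold.
#' @param seed integer seed.
#' @return object of class `hifi_simulation`: list with `reads`
#'   (data.frame id/seq/qual), `truth` (per-read table), `truth_ssu`
#'   (per-read fully contained 16S intervals), `model`, `depth_target`.
#' @export
simulate_hifi_reads <- function(community, model, depth_target, seed) {
  stopifnot(inherits(community, "synthetic_community"),
            inherits(model, "read_model"), depth_target > 0)
  ids_all <- character(); seqs_all <- character(); quals_all <- character()
  truth <- list(); truth_ssu <- list()
  qd <- model$quality_dist
  for (rid in names(community$replicons)) {
    rep <- community$replicons[[rid]]
    L <- nchar(rep$seq)
    a <- community$abundances[[rid]]
    target_bases <- depth_target * a * L
    res <- with_seed(child_seed(seed, paste0("reads/", rid)), {
      n_guess <- ceiling(target_bases / model$length_mu * 1.3) + 10
      lens <- integer(0)
      while (sum(lens) < target_bases) {
        x <- as.integer(round(rnorm(n_guess, model$length_mu,
                                    model$length_sd_bp)))
        x <- x[x >= model$min_length_bp & x <= model$max_length_bp]
        x <- pmin(x, L)
        lens <- c(lens, x)
      }
      lens <- lens[seq_len(which(cumsum(lens) >= target_bases)[1])]
      n <- length(lens)
      circ <- rep$spec$topology == "circular"
      starts <- if (circ) sample.int(L, n, replace = TRUE) - 1L else {
        vapply(lens, function(l) sample.int(L - l + 1L, 1) - 1L, 0L)
      }
      seq2 <- if (circ) paste0(rep$seq, substring(rep$seq, 1, model$max_length_bp))
              else rep$seq
      raw <- substring(seq2, starts + 1L, starts + lens)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      neg <- strand == "-"
      if (any(neg)) raw[neg] <- revcomp(raw[neg])
      q0 <- sample(qd$q, n, replace = TRUE, prob = qd$prob)
      noise <- simulate_noise_cpp(raw, as.integer(q0), model$quality_jitter)
      list(lens = lens, starts = starts, strand = strand, noise = noise)
    })
    n <- length(res$lens)
    if (n == 0) next
    ids <- sprintf("%s_read%06d", rid, seq_len(n))
    ids_all <- c(ids_all, ids)
    seqs_all <- c(seqs_all, as.character(res$noise$seq))
    quals_all <- c(quals_all, as.character(res$noise$qual))
    truth[[rid]] <- data.frame(
      read_id = ids, replicon = rid, start = res$starts,
      end = res$starts + res$lens, strand = res$strand, length = res$lens,
      n_subs = res$noise$n_err)
    truth_ssu[[rid]] <- ssu_truth_intervals(rep, res$starts, res$lens,
                                            res$strand, ids)
  }
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  truth_ssu <- do.call(rbind, truth_ssu)
  if (!is.null(truth_ssu)) rownames(truth_ssu) <- NULL
  structure(list(reads = data.frame(id = ids_all, seq = seqs_all,
                                    qual = quals_all),
                 truth = truth, truth_ssu = truth_ssu, model = model,
                 depth_target = depth_target, seed = as.integer(seed)),
            class = "hifi_simulation")
}

## Read-coordinate intervals of 16S genes fully contained in reads.
## starts are 0-based genome offsets; reads on "-" were reverse-complemented.
ssu_truth_intervals <- function(rep, starts, lens, strand, ids) {
  g <- rep$annotations[rep$annotations$type == "16S_rRNA", , drop = FALSE]
  if (nrow(g) == 0 || length(starts) == 0) return(NULL)
  L <- nchar(rep$seq)
  circ <- rep$spec$topology == "circular"
  out <- list()
  for (i in seq_len(nrow(g))) {
    gs <- g$start[i] - 1L; glen <- g$end[i] - g$start[i] + 1L
    for (shift in if (circ) c(0L, L) else 0L) {
      off <- gs + shift - starts
      keep <- off >= 0L & off + glen <= lens
      if (!any(keep)) next
      offk <- off[keep]; lk <- lens[keep]
      neg <- strand[keep] == "-"
      rs <- ifelse(neg, lk - (offk + glen) + 1L, offk + 1L)
      gstrand <- ifelse(neg, chartr("+-", "-+", g$strand[i]), g$strand[i])
      out[[length(out) + 1]] <- data.frame(
        read_id = ids[keep], replicon = rep$spec$id, operon = g$operon[i],
        r_start = rs, r_end = rs + glen - 1L, gene_strand = gstrand)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Write a simulation to FASTQ plus truth tables
#'
#' @param sim a [simulate_hifi_reads()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`fastq`, `truth`, `truth_ssu`).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fq <- file.path(dir, "reads.fastq")
  write_fastq(sim$reads$id, sim$reads$seq, sim$reads$qual, fq)
  tr <- file.path(dir, "truth_reads.tsv")
  write.table(sim$truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  ts <- file.path(dir, "truth_ssu.tsv")
  if (!is.null(sim$truth_ssu))
    write.table(sim$truth_ssu, ts, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(fastq = fq, truth = tr, truth_ssu = ts))
}

#' Build a GFA1 assembly graph from a realized community
#'
#' Each layout row turns one replicon into one graph component:
#' `circular` emits a single segment with a head-to-tail self-link;
#' `tangled_circular` splits the replicon (and, if `variant_ids` are
#' given, each listed variant) into `n_segments` overlapping pieces whose
#' links form a cycle; `linear` emits one isolated segment.
#'
#' @param community a [build_community()] result.
#' @param layout data.frame with columns `replicon`, `topology`,
#'   `n_segments` (1 for circular/linear), `overlap_bp`, and optionally a
#'   list-column `variant_ids` naming additional realized replicons whose
#'   segments join the tangle.
#' @param path output GFA file.
#' @param seed integer seed (controls nothing today; reserved).
#' @return list with `path` and `labels` (data.frame component/segment/
#'   topology/replicon).
#' @export
build_gfa <- function(community, layout, path, seed = 1L) {
  stopifnot(all(c("replicon", "topology", "n_segments", "overlap_bp") %in%
                  names(layout)))
  lines <- "H\tVN:Z:1.0"
  labels <- list()
  for (i in seq_len(nrow(layout))) {
    rid <- layout$replicon[i]
    topo <- layout$topology[i]
    nseg <- layout$n_segments[i]
    ov <- layout$overlap_bp[i]
    rep <- community$replicons[[rid]]
    if (is.null(rep)) stop("layout references unknown replicon '", rid, "'")
    comp <- paste0("comp_", rid)
    if (topo %in% c("circular", "linear")) {
      if (nseg != 1L)
        stop("topology '", topo, "' requires exactly one segment (replicon '",
             rid, "')")
      seg <- paste0(rid, "_s1")
      sq <- rep$seq
      if (topo == "circular" && ov > 0)
        sq <- paste0(sq, substring(sq, 1, ov))   # duplicated head at tail
      lines <- c(lines, sprintf("S\t%s\t%s\tLN:i:%d", seg, sq, nchar(sq)))
      if (topo == "circular")
        lines <- c(lines, sprintf("L\t%s\t+\t%s\t+\t%dM", seg, seg, ov))
      labels[[length(labels) + 1]] <-
        data.frame(component = comp, segment = seg, topology = topo,
                   replicon = rid)
    } else if (topo == "tangled_circular") {
      if (nseg < 2L) stop("tangled components need >= 2 segments")
      sources <- rid
      if ("variant_ids" %in% names(layout)) {
        v <- layout$variant_ids[[i]]
        if (!is.null(v) && length(v)) sources <- c(rid, v)
      }
      seg_of <- list()
      for (src in sources) {
        sq <- community$replicons[[src]]$seq
        L <- nchar(sq)
        bnd <- floor(seq(0, L, length.out = nseg + 1))
        segs <- character(nseg)
        for (s in seq_len(nseg)) {
          from <- bnd[s] + 1L
          to <- min(L, bnd[s + 1] + ov)
          segs[s] <- substring(sq, from, to)
        }
        names(segs) <- sprintf("%s_s%d", src, seq_len(nseg))
        seg_of[[src]] <- segs
        for (s in seq_len(nseg))
          lines <- c(lines, sprintf("S\t%s\t%s\tLN:i:%d", names(segs)[s],
                                    segs[s], nchar(segs[s])))
      }
      for (src in sources) {
        nm <- names(seg_of[[src]])
        for (dst in sources) {
          nm2 <- names(seg_of[[dst]])
          for (s in seq_len(nseg)) {
            nxt <- if (s == nseg) 1L else s + 1L
            lines <- c(lines, sprintf("L\t%s\t+\t%s\t+\t%dM",
                                      nm[s], nm2[nxt], ov))
          }
        }
      }
      labels[[length(labels) + 1]] <- data.frame(
        component = comp,
        segment = unlist(lapply(seg_of, names), use.names = FALSE),
        topology = topo,
        replicon = rep(sources, each = nseg))
    } else stop("unknown topology '", topo, "'")
  }
  writeLines(lines, path)
  labels <- if (length(labels)) do.call(rbind, labels) else
    data.frame(component = character(), segment = character(),
               topology = character(), replicon = character())
  rownames(labels) <- NULL
  list(path = path, labels = labels)
}

#' Default graph layout for a community
#'
#' Chromosomes, plasmids and virus replicons become circular components,
#' except: a replicon with strain variants whose variants should stay
#' unassembled can be rendered as a tangle via `tangled`, and replicons
#' listed in `linear` are emitted as single linear segments.
#'
#' @param community a [build_community()] result.
#' @param tangled named list: base replicon id -> character vector of
#'   variant ids to tangle together with it.
#' @param linear character vector of replicon ids to emit as linear.
#' @param overlap_bp link overlap used for circular self-links and tangles.
#' @return layout data.frame for [build_gfa()].
#' @export
default_layout <- function(community, tangled = list(), linear = character(),
                           overlap_bp = 100L) {
  ids <- names(community$replicons)
  tangle_members <- unlist(tangled, use.names = FALSE)
  rows <- list()
  for (rid in ids) {
    if (rid %in% tangle_members) next
    if (rid %in% names(tangled)) {
      rows[[rid]] <- data.frame(replicon = rid, topology = "tangled_circular",
                                n_segments = 4L, overlap_bp = overlap_bp)
      rows[[rid]]$variant_ids <- list(tangled[[rid]])
    } else {
      topo <- if (rid %in% linear) "linear" else "circular"
      rows[[rid]] <- data.frame(replicon = rid, topology = topo,
                                n_segments = 1L,
                                overlap_bp = if (topo == "circular")
                                  overlap_bp else 0L)
      rows[[rid]]$variant_ids <- list(character(0))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
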