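## End-to-end orchestration: read QC -> graph triage -> genome quality ->
## dereplication -> novelty -> depth profiles -> read-level 16S profile ->
## run report.  Every stage is also callable on its own; run_all() wires
## them together with one config and one seed.

#' Read quality control
#'
#' Keeps reads with length >= `min_bp` and Phred-implied mean accuracy
#' >= `min_accuracy`.
#'
#' @param reads either a path to a FASTQ file or a data.frame with
#'   columns `id`, `seq`, `qual`.
#' @param min_bp minimum read length (default 1000).
#' @param min_accuracy minimum mean accuracy (default 0.99).
#' @return list: `reads` (kept data.frame), `n_in`, `n_kept`, `n_removed`.
#' @export
qc_reads <- function(reads, min_bp = 1000, min_accuracy = 0.99) {
  if (is.character(reads) && length(reads) == 1) reads <- as.data.frame(read_fastq(reads))
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  len_ok <- nchar(reads$seq) >= min_bp
  acc <- 1 - qual_mean_error_cpp(reads$qual)
  keep <- len_ok & acc >= min_accuracy
  list(reads = reads[keep, , drop = FALSE], n_in = nrow(reads),
       n_kept = sum(keep), n_removed = sum(!keep))
}

#' Pipeline configuration
#'
#' All stage thresholds with their standard defaults: read QC at 1 kb and
#' 99% accuracy, binning floor 2 kb, Mash clustering at d 0.05, species
#' rule ANI >= 95% with mutual coverage >= 50%, 16S length window
#' 1200-1700 bp with Q20 accuracy, and 16S novelty thresholds 95%/97%.
#'
#' @param fastq path to HiFi reads (FASTQ), or a reads data.frame.
#' @param gfa path to the GFA1 assembly graph.
#' @param taxonomy named character vector or 2-column data.frame mapping
#'   genome id to lineage (optional; needed for rank profiles).
#' @param ssu_refs named character vector of reference 16S genes
#'   (optional; needed for the 16S profile stage).
#' @param ssu_taxa lineages of `ssu_refs` (same order).
#' @param copy_table copy-number data.frame (default packaged table).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param ... threshold overrides (see defaults in the source).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(fastq, gfa, taxonomy = NULL, ssu_refs = NULL,
                            ssu_taxa = NULL, copy_table = NULL,
                            out_dir = tempfile("hifimag_run_"), seed = 1L,
                            ...) {
  cfg <- list(fastq = fastq, gfa = gfa, taxonomy = taxonomy,
              ssu_refs = ssu_refs, ssu_taxa = ssu_taxa,
              copy_table = copy_table, out_dir = out_dir,
              seed = as.integer(seed),
              read_min_bp = 1000, read_min_accuracy = 0.99,
              min_contig_bp = 2000, min_circular_bp = 0,
              mash_d = 0.05, ani_min = 95, cov_min = 50,
              ssu_min_bp = 1200, ssu_max_bp = 1700, ssu_min_accuracy = 0.99,
              genus_thr = 95, species_thr = 97,
              assign_k = 17L, assign_w = 11L, assign_min_hits = 10L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  ## normalize numeric storage so file round-trips hash identically
  for (f in c("read_min_bp", "read_min_accuracy", "min_contig_bp",
              "min_circular_bp", "mash_d", "ani_min", "cov_min",
              "ssu_min_bp", "ssu_max_bp", "ssu_min_accuracy", "genus_thr",
              "species_thr"))
    cfg[[f]] <- as.double(cfg[[f]])
  for (f in c("seed", "assign_k", "assign_w", "assign_min_hits"))
    cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(cfg$read_min_bp >= 0, "read_min_bp must be >= 0")
  chk(cfg$read_min_accuracy > 0 && cfg$read_min_accuracy <= 1,
      "read_min_accuracy must be in (0, 1]")
  chk(cfg$ani_min > 0 && cfg$ani_min <= 100, "ani_min must be in (0, 100]")
  chk(cfg$cov_min >= 0 && cfg$cov_min <= 100, "cov_min must be in [0, 100]")
  chk(cfg$mash_d >= 0 && cfg$mash_d <= 1, "mash_d must be in [0, 1]")
  chk(cfg$ssu_min_bp < cfg$ssu_max_bp, "ssu length window is empty")
  chk(cfg$genus_thr <= cfg$species_thr,
      "genus_thr must not exceed species_thr")
  invisible(TRUE)
}

#' Write / read a pipeline config file
#'
#' Round-trips a path-based config through YAML.  Only configs whose
#' inputs are file paths (not in-memory objects) can be written.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   reconstructed config.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (f in c("fastq", "gfa"))
    if (!is.character(cfg[[f]]))
      stop("only path-based configs can be written (field '", f, "')")
  flat <- cfg[!vapply(cfg, is.null, TRUE)]
  keep <- vapply(flat, function(x)
    is.character(x) || is.numeric(x) || is.logical(x), TRUE)
  yaml::write_yaml(flat[keep], path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Semantic hash of a pipeline config
#'
#' Hash over every field except `out_dir`; changes iff a semantic field
#' changes.
#'
#' @param cfg a [pipeline_config()].
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  sem <- cfg[setdiff(names(cfg), "out_dir")]
  sprintf("%013.0f", fnv1a_cpp(paste(deparse(sem), collapse = "\n")))
}

#' Run the full pipeline
#'
#' Stages: read QC; GFA triage (circular contigs become single-contig
#' candidates, linear contigs pass the binning floor); marker-based
#' quality ranking (rank `fail` drops a candidate); Mash + ANI
#' dereplication picking max-score representatives; depth profiles by
#' minimizer read assignment; read-level 16S detection, filtering,
#' classification and copy-number-adjusted profiling.  Stage outputs are
#' written under `out_dir`; the returned run report summarizes counts.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `run_report` (also written as JSON to
#'   `out_dir/report.json`).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config_hash = config_hash(cfg), seed = cfg$seed)

  ## stage 1: read QC
  qc <- qc_reads(cfg$fastq, cfg$read_min_bp, cfg$read_min_accuracy)
  report$reads <- list(n_in = qc$n_in, n_kept = qc$n_kept,
                       n_removed = qc$n_removed)
  reads <- qc$reads

  ## stage 2: graph triage
  graph <- parse_gfa(cfg$gfa)
  calls <- classify_components(graph)
  write_component_table(calls, file.path(cfg$out_dir, "components.tsv"))
  circ <- extract_circular(graph, calls, cfg$min_circular_bp)
  lin <- prebinning_filter(graph, calls, cfg$min_contig_bp)
  report$components <- as.list(table(calls$topology))
  candidates <- c(circ, lin)
  names(candidates) <- sub("_s[0-9]+$", "", names(candidates))
  report$candidates <- length(candidates)

  ## stage 3: genome quality
  quality <- genome_quality_report(as.list(candidates))
  write.table(quality, file.path(cfg$out_dir, "quality.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$quality_ranks <- as.list(table(quality$rank))
  keep <- quality$genome_id[quality$rank != "fail"]
  genomes <- candidates[keep]

  ## stage 4: dereplication
  if (length(genomes)) {
    dr <- dereplicate(genomes, quality, d_max = cfg$mash_d,
                      ani_min = cfg$ani_min, cov_min = cfg$cov_min)
    write.table(dr$membership, file.path(cfg$out_dir, "membership.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    reps <- genomes[dr$representatives]
    write_fasta(reps, file.path(cfg$out_dir, "representatives.fasta"))
  } else { dr <- NULL; reps <- character(0) }
  report$genomes <- list(candidates = length(candidates),
                         quality_pass = length(genomes),
                         representatives = length(reps),
                         absorbed = length(genomes) - length(reps))

  ## stage 5: depth profiles
  taxonomy <- as_taxonomy_vector(cfg$taxonomy)
  if (length(reps) && nrow(reads)) {
    asn <- assign_reads(reads$seq, unlist(reps), k = cfg$assign_k,
                        w = cfg$assign_w, min_hits = cfg$assign_min_hits,
                        read_ids = reads$id)
    depths <- mean_depth(asn, vapply(reps, nchar, 0)[order(names(reps))])
    write.table(depths, file.path(cfg$out_dir, "depth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$depth <- list(
      assigned_fraction = attr(depths, "total_assigned_fraction"))
    profiles <- list()
    if (!is.null(taxonomy)) {
      for (r in TAXON_RANKS) {
        pr <- rank_profile(depths, taxonomy, r)
        profiles[[r]] <- pr
        write.table(pr, file.path(cfg$out_dir,
                                  sprintf("profile_depth_%s.tsv", r)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  } else { depths <- NULL; profiles <- list() }

  ## stage 6: read-level 16S profile
  ssu <- NULL
  if (!is.null(cfg$ssu_refs) && nrow(reads)) {
    cand <- detect_ssu(reads$seq, ids = reads$id, quals = reads$qual)
    kept <- filter_ssu(cand, cfg$ssu_min_bp, cfg$ssu_max_bp,
                       cfg$ssu_min_accuracy)
    report$ssu <- list(candidates = nrow(cand), kept = nrow(kept))
    if (nrow(kept)) {
      model <- train_classifier(cfg$ssu_refs, cfg$ssu_taxa)
      cls <- classify_ssu(kept$sequence, model, seed = cfg$seed)
      kept <- cbind(kept[, c("read_id", "start", "end", "strand",
                             "length_bp", "mean_error_prob")],
                    cls[, c("genus", "conf_genus", "assigned_rank",
                            "assigned_taxon")])
      write.table(kept, file.path(cfg$out_dir, "ssu_classifications.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ct <- if (is.null(cfg$copy_table)) rrn_copy_table() else cfg$copy_table
      genus_calls <- ifelse(cls$conf_genus >= 0.8, cls$genus, NA)
      prof <- copy_adjusted_profile(genus_calls, ct)
      ssu <- list(classifications = kept, profile = prof)
      write.table(data.frame(genus = names(prof), relative_abundance = prof),
                  file.path(cfg$out_dir, "profile_ssu_genus.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$ssu$classified <- sum(!is.na(genus_calls))
    }
  }

  report_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(list(report = report, quality = quality, derep = dr,
                 depths = depths, profiles = profiles, ssu = ssu,
                 representatives = names(reps), out_dir = cfg$out_dir),
            class = "run_report")
}

as_taxonomy_vector <- function(taxonomy) {
  if (is.null(taxonomy)) return(NULL)
  if (is.data.frame(taxonomy))
    return(stats::setNames(taxonomy[[2]], taxonomy[[1]]))
  taxonomy
}

#' Build the full default synthetic scenario
#'
#' Realizes the default community, simulates reads, writes the GFA (the
#' dominant taxon's two strain variants form one tangled component; one
#' chromosome is emitted as a linear contig to exercise the binning path)
#' and assembles a ready-to-run [pipeline_config()].
#'
#' @param seed integer seed driving community, reads and pipeline.
#' @param depth_target community depth multiplier for the read simulation.
#' @param dir working directory for the GFA and pipeline outputs.
#' @return list: `community`, `sim`, `gfa`, `config`.
#' @export
synthetic_scenario <- function(seed, depth_target = 250, dir = tempfile("scen_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  com <- build_community(default_community(seed = seed))
  sim <- simulate_hifi_reads(com, read_model(), depth_target = depth_target,
                             seed = seed)
  lay <- default_layout(
    com, tangled = list(chr_Defluviitoga_v2 = "chr_Defluviitoga_v3"),
    linear = "chr_Phycisphaera")
  gfa <- build_gfa(com, lay, file.path(dir, "assembly.gfa"))
  refs <- community_ssu_refs(com)
  cfg <- pipeline_config(
    fastq = sim$reads, gfa = gfa$path,
    taxonomy = stats::setNames(com$taxonomy$taxon_path,
                               com$taxonomy$replicon),
    ssu_refs = refs$seqs, ssu_taxa = refs$taxa,
    copy_table = com$copy_table,
    out_dir = file.path(dir, "run"), seed = seed)
  list(community = com, sim = sim, gfa = gfa, config = cfg)
}

#' Reference 16S set of a synthetic community
#'
#' One reference gene per genus realized in the community (the exact
#' per-genus gene the simulator plants), with its lineage — the natural
#' training set for the read-level classifier.
#'
#' @param community a [build_community()] result.
#' @return list with `seqs` (named character) and `taxa` (lineages).
#' @export
community_ssu_refs <- function(community) {
  base <- community$taxonomy[community$taxonomy$replicon ==
                               community$taxonomy$base_id, , drop = FALSE]
  seqs <- character(0); taxa <- character(0)
  for (i in seq_len(nrow(base))) {
    rep <- community$replicons[[base$replicon[i]]]
    if (rep$spec$rrn_operon_copies == 0) next
    genus <- taxon_rank(base$taxon_path[i], "genus")
    if (is.na(genus) || genus %in% names(seqs)) next
    seqs[genus] <- genus_rrna_genes(genus)[["16S"]]
    taxa[genus] <- base$taxon_path[i]
  }
  list(seqs = seqs, taxa = taxa)
}
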