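## Loaders for the packaged synthetic reference data.  All of it is
## generated (see data-raw/), deterministic, and labelled synthetic: the
## 16S/23S/5S gene templates with their conserved-region table, the
## single-copy marker gene set, and the per-genus rrn operon copy table.

.ref_cache <- new.env(parent = emptyenv())

ref_file <- function(name) {
  p <- system.file("extdata", name, package = "hifimag")
  if (!nzchar(p)) stop("packaged reference file not found: ", name)
  p
}

#' Synthetic rRNA gene templates
#'
#' The packaged 16S (1512 bp), 23S and 5S gene templates from which all
#' simulated rRNA operons are derived.  Per-genus gene variants are made by
#' mutating the variable (non-conserved) positions of these templates.
#'
#' @return named character vector with elements `16S_rRNA`, `23S_rRNA`,
#'   `5S_rRNA`.
#' @export
rrna_templates <- function() {
  if (is.null(.ref_cache$templates))
    .ref_cache$templates <- read_fasta(ref_file("synthetic_rrna_templates.fasta"))
  .ref_cache$templates
}

#' Conserved-region anchor table of the 16S template
#'
#' Eight 20 bp conserved blocks on the packaged 16S template together with
#' the 15-mer anchor extracted from each block.  The anchors drive the
#' read-level 16S detector; the blocks are held fixed when per-genus
#' variants are simulated.
#'
#' @return data.frame with columns `block`, `start`, `end`,
#'   `anchor_offset` (1-based template position of the anchor) and
#'   `anchor_seq`.
#' @export
ssu_anchors <- function() {
  if (is.null(.ref_cache$anchors))
    .ref_cache$anchors <- read.delim(
      ref_file("synthetic_16s_conserved_regions.tsv"),
      stringsAsFactors = FALSE)
  .ref_cache$anchors
}

#' Synthetic single-copy marker gene set
#'
#' Forty 480 bp synthetic ubiquitous single-copy marker genes.  The
#' simulator plants one copy of every marker on each chromosome, and the
#' built-in marker detector searches genomes against this set to estimate
#' completeness and contamination.
#'
#' @return named character vector of marker sequences.
#' @export
marker_genes <- function() {
  if (is.null(.ref_cache$markers))
    .ref_cache$markers <- read_fasta(ref_file("synthetic_marker_genes.fasta"))
  .ref_cache$markers
}

#' Per-genus rrn operon copy numbers
#'
#' The copy-number table for the default synthetic community, in the style
#' of an rrnDB extract: 16S gene copies per genome at genus rank.
#'
#' @return data.frame with columns `genus` and `copies`.
#' @export
rrn_copy_table <- function() {
  if (is.null(.ref_cache$copies))
    .ref_cache$copies <- read.delim(ref_file("synthetic_rrn_copy_numbers.tsv"),
                                    stringsAsFactors = FALSE)
  .ref_cache$copies
}

## Variable (non-conserved) 1-based positions of the 16S template.
ssu_variable_positions <- function() {
  if (is.null(.ref_cache$varpos)) {
    len <- nchar(rrna_templates()[["16S_rRNA"]])
    anc <- ssu_anchors()
    cons <- unlist(mapply(seq, anc$start, anc$end, SIMPLIFY = FALSE))
    .ref_cache$varpos <- setdiff(seq_len(len), cons)
  }
  .ref_cache$varpos
}

## Deterministic per-genus rRNA gene variants: mutate variable positions of
## the 16S (conserved blocks untouched) and all positions of 23S/5S at the
## given rates.  Seeded from the genus name only, so every run of the
## simulator agrees on what a genus' genes look like.
genus_rrna_genes <- function(genus, rate16 = 0.10, rate_other = 0.05) {
  tpl <- rrna_templates()
  seed <- child_seed(0, paste0("genus-rrna/", genus))
  with_seed(seed, {
    g16 <- mutate_positions(tpl[["16S_rRNA"]], ssu_variable_positions(), rate16)
    g23 <- mutate_positions(tpl[["23S_rRNA"]],
                            seq_len(nchar(tpl[["23S_rRNA"]])), rate_other)
    g5 <- mutate_positions(tpl[["5S_rRNA"]],
                           seq_len(nchar(tpl[["5S_rRNA"]])), rate_other)
    c("16S" = g16, "23S" = g23, "5S" = g5)
  })
}

## Substitute a fraction `rate` of the given positions with a different base.
mutate_positions <- function(seq, positions, rate) {
  if (rate <= 0 || length(positions) == 0) return(seq)
  n <- rbinom(1, length(positions), rate)
  if (n == 0) return(seq)
  pos <- sort(sample(positions, n))
  v <- utf8ToInt(seq)
  codes <- c(65L, 67L, 71L, 84L)                # A C G T
  cur <- match(v[pos], codes)
  shift <- sample.int(3L, n, replace = TRUE)    # one of the other 3 bases
  v[pos] <- codes[((cur - 1L + shift) %% 4L) + 1L]
  intToUtf8(v)
}

## Uniform substitution of a whole sequence at the given rate; returns the
## mutated sequence and the number of substitutions actually made.
mutate_sequence <- function(seq, rate) {
  n <- nchar(seq)
  mutate_positions(seq, seq_len(n), rate)
}

## Deterministic 76 bp synthetic tRNA gene per isotype.
trna_gene <- function(isotype) {
  with_seed(child_seed(0, paste0("trna/", isotype)), random_dna(76, 0.5))
}
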