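# Shared fixtures.  Everything is generated in code; heavier objects are
# cached per session so multiple test files can reuse them.

.fx <- new.env(parent = emptyenv())

fx_path <- function(genus = "Testus",
                    phylum = "Testophyta") {
  sprintf("Bacteria;%s;C_c;O_o;F_f;%s", phylum, genus)
}

## A small realized chromosome (1 Mb) with 2 operons, cached.
fx_chromosome <- function() {
  if (is.null(.fx$chrom)) {
    sp <- replicon_spec("chrT", 1e6, "circular", "chromosome",
                        gc_fraction = 0.45, rrn_operon_copies = 2,
                        taxon_path = fx_path("Defluviitoga", "Thermotogae"))
    .fx$chrom <- generate_replicon(sp, 101)
  }
  .fx$chrom
}

## Random DNA under a local seed (does not disturb test RNG state).
fx_dna <- function(n, seed, gc = 0.5) {
  hifimag:::with_seed(seed, hifimag:::random_dna(n, gc))
}

fx_mutate <- function(seq, rate, seed) {
  hifimag:::with_seed(seed, hifimag:::mutate_sequence(seq, rate))
}

## Exhaustive canonical k-mer set of a sequence, as strings.  Independent
## of the package's hashing path (plain substring + reverse complement).
fx_canonical_kmers <- function(seq, k = 21) {
  n <- nchar(seq)
  starts <- seq_len(n - k + 1)
  fwd <- substring(seq, starts, starts + k - 1)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fwd)))
  unique(pmin(fwd, rev))
}

fx_exact_jaccard <- function(a, b, k = 21) {
  ka <- fx_canonical_kmers(a, k)
  kb <- fx_canonical_kmers(b, k)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

## Uniform quality string.
fx_qual <- function(len, q) strrep(intToUtf8(q + 33), len)

## A tiny multi-taxon community of sub-Mb replicons for fast end-to-end
## style tests (plasmid class permits small sizes).
fx_small_community <- function(seed = 5, n_taxa = 5, len = 60000,
                               copies = c(2, 1, 4, 2, 3)) {
  genera <- paste0("Genus", LETTERS[seq_len(n_taxa)])
  reps <- lapply(seq_len(n_taxa), function(i)
    replicon_spec(paste0("rep", i), len, "circular", "plasmid",
                  rrn_operon_copies = copies[i],
                  trna_types = character(),
                  taxon_path = fx_path(genera[i], paste0("Phy", i)),
                  plant_markers = FALSE))
  w <- hifimag:::with_seed(seed, {
    x <- rlnorm(n_taxa, 0, 1)
    x / sum(x)
  })
  build_community(community_spec(reps, w, seed = seed))
}
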