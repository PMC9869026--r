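# Builds the synthetic reference data shipped under inst/extdata.
# Everything here is generated, fixed-seed, and plainly labelled synthetic:
# the package never ships real database content.
#
# Run from the package root:  Rscript data-raw/build_reference_data.R

set.seed(20260901)

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## --- rRNA gene templates ---------------------------------------------------
## A 1512 bp 16S template with eight 20 bp conserved blocks placed at
## positions that echo the classic universally conserved regions of the real
## gene; the rest of the gene is "variable" and is what per-genus mutation
## acts on.  23S and 5S templates are plain random genes of typical length.
len16s <- 1512
blocks <- data.frame(
  block = paste0("C", 1:8),
  start = c(10, 340, 520, 790, 910, 1065, 1230, 1480),
  end   = c(29, 359, 539, 809, 929, 1084, 1249, 1499)
)

t16s <- random_dna(len16s, gc = 0.54)
t23s <- random_dna(2900, gc = 0.53)
t5s  <- random_dna(115,  gc = 0.55)

## 15-mer anchors sit 2 bp inside each conserved block
blocks$anchor_offset <- blocks$start + 2          # 1-based template position
blocks$anchor_seq <- substring(t16s, blocks$anchor_offset,
                               blocks$anchor_offset + 14)

writeLines(c(">16S_rRNA synthetic template", t16s,
             ">23S_rRNA synthetic template", t23s,
             ">5S_rRNA synthetic template",  t5s),
           "inst/extdata/synthetic_rrna_templates.fasta")

write.table(blocks, "inst/extdata/synthetic_16s_conserved_regions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## --- single-copy marker genes ----------------------------------------------
## 40 synthetic ubiquitous single-copy marker genes, 480 bp each.
n_marker <- 40
markers <- vapply(seq_len(n_marker), function(i) random_dna(480, 0.5), "")
ids <- sprintf("MK%03d", seq_len(n_marker))
writeLines(as.vector(rbind(paste0(">", ids, " synthetic single-copy marker"),
                           markers)),
           "inst/extdata/synthetic_marker_genes.fasta")

## --- rrn operon copy numbers ----------------------------------------------
## Copy numbers per genus for the default synthetic community (the simulator
## plants exactly these); values are typical of the respective lineages.
copies <- data.frame(
  genus = c("Defluviitoga", "Methanothrix", "Fermentimonas", "Petrimonas",
            "Syntrophomonas", "Clostridium", "Anaerolinea", "Thermovirga",
            "Desulfovibrio", "Olsenella", "Sebaldella", "Phycisphaera"),
  copies = c(2, 2, 4, 4, 5, 8, 2, 2, 4, 3, 5, 2)
)
write.table(copies, "inst/extdata/synthetic_rrn_copy_numbers.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("reference data written to inst/extdata\n")
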