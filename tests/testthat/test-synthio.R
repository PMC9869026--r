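# Synthetic community generator: spec validation, planted-gene truth,
# read simulation statistics and reproducibility.

test_that("replicon specs enforce the size and content invariants", {
  expect_error(replicon_spec("x", 500, "linear", "plasmid"), ">= 1000")
  expect_error(replicon_spec("x", 5e5, "circular", "chromosome"), ">= 1 Mb")
  expect_error(replicon_spec("x", 2e6, "circular", "plasmid"), "< 1 Mb")
  expect_error(replicon_spec("x", 2e6, "circular", "chromosome",
                             rrn_operon_copies = 16), "between 0 and 15")
  expect_error(replicon_spec("x", 1e4, "linear", "plasmid",
                             trna_types = "Xyz"), "unknown tRNA")
})

test_that("community specs validate abundances and variant references", {
  sp <- replicon_spec("a", 1e4, "linear", "plasmid",
                      rrn_operon_copies = 0, trna_types = character())
  expect_error(community_spec(list(sp), c(0.5)), "sum to 1")
  expect_error(community_spec(list(sp, sp), c(0.5, 0.5)), "duplicate")
  expect_error(
    community_spec(list(sp), 1, strain_variants = data.frame(
      base_id = "zzz", n_variants = 1, divergence = 0.01,
      weight_frac = 0.1)),
    "unknown replicons")
  expect_silent(community_spec(list(sp), 1))
})

test_that("generated replicons carry the requested planted genes", {
  r <- fx_chromosome()
  ann <- r$annotations
  expect_equal(nchar(r$seq), 1e6)
  expect_equal(sum(ann$type == "16S_rRNA"), 2)
  expect_equal(sum(ann$type == "23S_rRNA"), 2)
  expect_equal(sum(ann$type == "5S_rRNA"), 2)
  expect_gte(sum(ann$type == "tRNA"), 20)
  expect_equal(sum(ann$type == "marker"), length(marker_genes()))
  expect_lt(abs(hifimag:::gc_fraction(r$seq) - 0.45), 0.02)
  ## operons sit within a 10 kb window in 16S-23S-5S order
  expect_equal(count_rrna_operons(ann)$operons, 2)
})

test_that("a replicon without operons plants no 16S interval", {
  sp <- replicon_spec("p0", 20000, "circular", "plasmid",
                      rrn_operon_copies = 0, trna_types = c("Ala", "Gly"),
                      taxon_path = fx_path())
  r <- generate_replicon(sp, 3)
  expect_false(any(r$annotations$type == "16S_rRNA"))
  expect_equal(sum(r$annotations$type == "tRNA"), 2)
})

test_that("replicon generation is byte-identical for identical spec+seed", {
  sp <- replicon_spec("d", 30000, "circular", "plasmid",
                      rrn_operon_copies = 1, trna_types = c("Ala"),
                      taxon_path = fx_path())
  r1 <- generate_replicon(sp, 11)
  r2 <- generate_replicon(sp, 11)
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- generate_replicon(sp, 12)
  expect_false(identical(r1$seq, r3$seq))
})

test_that("truth annotations map back onto the replicon sequence", {
  r <- fx_chromosome()
  genus_genes <- hifimag:::genus_rrna_genes("Defluviitoga")
  g16 <- r$annotations[r$annotations$type == "16S_rRNA", ]
  for (i in seq_len(nrow(g16))) {
    sq <- substring(r$seq, g16$start[i], g16$end[i])
    if (g16$strand[i] == "-") sq <- hifimag:::revcomp(sq)
    expect_identical(sq, unname(genus_genes[["16S"]]))
  }
  mk <- r$annotations[r$annotations$type == "marker", ][1:5, ]
  for (i in seq_len(nrow(mk))) {
    sq <- substring(r$seq, mk$start[i], mk$end[i])
    if (mk$strand[i] == "-") sq <- hifimag:::revcomp(sq)
    expect_identical(sq, unname(marker_genes()[[mk$id[i]]]))
  }
})

test_that("oversized gene content raises a sizing error", {
  sp <- replicon_spec("tiny", 1500, "linear", "plasmid",
                      rrn_operon_copies = 1, taxon_path = fx_path())
  expect_error(generate_replicon(sp, 1), "exceed")
})

## One simulation reused by the following read-model tests: a single 1 Mb
## chromosome at 70x (~5000 reads, ~70 Mb).
sim_for_stats <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      com <- build_community(community_spec(list(replicon_spec(
        "chrS", 1e6, "circular", "chromosome", rrn_operon_copies = 2,
        taxon_path = fx_path())), 1, seed = 2))
      cache <<- simulate_hifi_reads(com, read_model(), depth_target = 70,
                                    seed = 21)
    }
    cache
  }
})

test_that("simulated coverage depth matches the requested target", {
  sim <- sim_for_stats()
  depth <- sum(sim$truth$length) / 1e6
  expect_gte(depth, 68)
  expect_lte(depth, 72)
})

test_that("no emitted read is shorter than the model minimum", {
  sim <- sim_for_stats()
  expect_gte(min(nchar(sim$reads$seq)), 1000)
  expect_identical(nchar(sim$reads$seq), sim$truth$length)
})

test_that("read-length N50 lands within 10% of the model target", {
  sim <- sim_for_stats()
  expect_gte(nrow(sim$reads), 5000)
  n50 <- read_stats(nchar(sim$reads$seq))$N50
  expect_lt(abs(n50 - 14254) / 14254, 0.10)
})

test_that("realized error rate matches the Phred-implied model accuracy", {
  sim <- sim_for_stats()
  expect_gte(sum(sim$truth$length), 1e7)
  emp_acc <- 1 - sum(sim$truth$n_subs) / sum(sim$truth$length)
  expect_lt(abs(emp_acc - 0.9994), 5e-4)
  ## and the quality strings are an unbiased estimate of that same rate
  phred_err <- qual_mean_error(sim$reads$qual)
  implied <- sum(phred_err * nchar(sim$reads$seq)) / sum(sim$truth$length)
  expect_lt(abs(implied - (1 - 0.9994)), 5e-5)
})

test_that("identical community/model/seed reproduce identical reads", {
  com <- build_community(community_spec(list(replicon_spec(
    "p", 50000, "circular", "plasmid", rrn_operon_copies = 1,
    trna_types = character(), taxon_path = fx_path())), 1, seed = 4))
  s1 <- simulate_hifi_reads(com, read_model(), 20, seed = 9)
  s2 <- simulate_hifi_reads(com, read_model(), 20, seed = 9)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_hifi_reads(com, read_model(), 20, seed = 10)
  expect_false(identical(s1$reads$seq, s3$reads$seq))
})

test_that("per-read truth intervals reproduce reads up to recorded errors", {
  sim <- sim_for_stats()
  com_seq <- NULL
  chr <- build_community(community_spec(list(replicon_spec(
    "chrS", 1e6, "circular", "chromosome", rrn_operon_copies = 2,
    taxon_path = fx_path())), 1, seed = 2))$replicons$chrS$seq
  doubled <- paste0(chr, substring(chr, 1, 40000))
  idx <- hifimag:::with_seed(1, sample.int(nrow(sim$truth), 50))
  for (i in idx) {
    tr <- sim$truth[i, ]
    clean <- substring(doubled, tr$start + 1, tr$end)
    if (tr$strand == "-") clean <- hifimag:::revcomp(clean)
    noisy <- sim$reads$seq[sim$reads$id == tr$read_id]
    d <- sum(utf8ToInt(clean) != utf8ToInt(noisy))
    expect_identical(d, tr$n_subs)
  }
})

test_that("strain variants diverge at the requested rate with intact truth", {
  r <- fx_chromosome()
  v <- make_strain_variant(r, 0.01, "chrT_v2", 7)
  d <- mean(utf8ToInt(r$seq) != utf8ToInt(v$seq))
  expect_lt(abs(d - 0.01), 0.001)
  expect_identical(v$annotations$start, r$annotations$start)
  expect_identical(unique(v$annotations$replicon), "chrT_v2")
})

test_that("the default community fixes the dominant taxon at 70%", {
  com <- build_community(default_community(seed = 3))
  expect_lt(abs(sum(com$abundances) - 1), 1e-9)
  dom <- grepl("Defluviitoga", com$taxonomy$taxon_path)
  expect_equal(sum(com$abundances[com$taxonomy$replicon[dom]]), 0.70,
               tolerance = 1e-9)
  expect_equal(nrow(com$copy_table), 12)
})

test_that("built GFA honours the requested component structure", {
  com <- fx_small_community()
  lay <- data.frame(replicon = c("rep1", "rep2", "rep3"),
                    topology = c("circular", "tangled_circular", "linear"),
                    n_segments = c(1L, 4L, 1L), overlap_bp = c(100L, 50L, 0L))
  gfa <- build_gfa(com, lay, file.path(tempdir(), "fx.gfa"))
  ln <- readLines(gfa$path)
  expect_equal(sum(startsWith(ln, "S")), 6)      # 1 + 4 + 1 segments
  expect_equal(sum(startsWith(ln, "L")), 5)      # self-link + 4-cycle
  expect_error(build_gfa(com, data.frame(replicon = "rep1",
                                         topology = "circular",
                                         n_segments = 2L, overlap_bp = 0L),
                         tempfile()), "exactly one segment")
  ## empty request is a valid header-only GFA
  g0 <- build_gfa(com, lay[0, ], file.path(tempdir(), "fx0.gfa"))
  expect_identical(readLines(g0$path), "H\tVN:Z:1.0")
})

test_that("tangle segments from strain variants stay near-identical to base", {
  com <- build_community(community_spec(
    list(replicon_spec("b", 40000, "circular", "plasmid",
                       rrn_operon_copies = 0, trna_types = character(),
                       taxon_path = fx_path())),
    1,
    strain_variants = data.frame(base_id = "b", n_variants = 2,
                                 divergence = 0.02, weight_frac = 0.3),
    seed = 8))
  lay <- data.frame(replicon = "b", topology = "tangled_circular",
                    n_segments = 3L, overlap_bp = 0L)
  lay$variant_ids <- list(c("b_v2", "b_v3"))
  gfa <- build_gfa(com, lay, tempfile(fileext = ".gfa"))
  graph <- parse_gfa(gfa$path)
  base <- com$replicons$b$seq
  for (seg in graph$segments$id) {
    src <- sub("_s[0-9]+$", "", seg)
    piece <- graph$seqs[[seg]]
    ## locate the piece on its own source, then compare to the base
    pos <- regexpr(substring(piece, 1, 30), com$replicons[[src]]$seq,
                   fixed = TRUE)
    expect_gte(pos, 1)
    base_piece <- substring(base, pos, pos + nchar(piece) - 1)
    ident <- mean(utf8ToInt(piece) == utf8ToInt(base_piece))
    expect_gte(ident, 0.80)
  }
})
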