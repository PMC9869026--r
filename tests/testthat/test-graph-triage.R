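# GFA parsing and topology triage.

gfa_lines <- function(..., path = tempfile(fileext = ".gfa")) {
  writeLines(c("H\tVN:Z:1.0", ...), path)
  path
}

test_that("parse_gfa reads S/L records and validates link endpoints", {
  p <- gfa_lines("S\ta\tACGTACGT\tLN:i:8\tdp:f:12.5",
                 "S\tb\tTTTT",
                 "L\ta\t+\tb\t-\t0M")
  g <- parse_gfa(p)
  expect_equal(nrow(g$segments), 2)
  expect_equal(g$segments$length, c(8L, 4L))
  expect_equal(g$segments$depth[1], 12.5)
  expect_equal(nrow(g$links), 1)

  expect_error(parse_gfa(gfa_lines("S\ta\tACGT", "L\ta\t+\tzz\t+\t0M")),
               "missing segment at line 3")
  expect_warning(parse_gfa(gfa_lines("S\ta\tACGT", "P\tp1\ta+\t*")),
                 "ignoring GFA record types")
  ## header-only file parses to an empty graph
  g0 <- parse_gfa(gfa_lines())
  expect_equal(nrow(g0$segments), 0)
  expect_error(parse_gfa(tempfile()), "not found")
})

test_that("component classification follows the three-topology rule", {
  p <- gfa_lines(
    "S\tcircA\tACGTACGTACGT", "L\tcircA\t+\tcircA\t+\t0M",
    "S\tcircB\tGGGGCCCCAAAA", "L\tcircB\t-\tcircB\t-\t0M",
    "S\tpal\tACGTACGTACGT", "L\tpal\t+\tpal\t-\t0M",
    "S\tlin\tTTTTTTTT",
    "S\tt1\tAAAACCCC", "S\tt2\tCCCCGGGG", "S\tt3\tGGGGTTTT",
    "L\tt1\t+\tt2\t+\t0M", "L\tt2\t+\tt3\t+\t0M", "L\tt3\t+\tt1\t+\t0M")
  calls <- classify_components(parse_gfa(p))
  topo <- setNames(calls$topology, vapply(calls$members, `[`, "", 1))
  expect_equal(topo[["circA"]], "circular")     # head-to-tail, + orientation
  expect_equal(topo[["circB"]], "circular")     # head-to-tail, - orientation
  expect_equal(topo[["pal"]], "tangled_circular") # palindromic self-link
  expect_equal(topo[["lin"]], "linear")
  expect_equal(topo[["t1"]], "tangled_circular")
  expect_true(calls$has_cycle[vapply(calls$members, `[`, "", 1) == "t1"])
  ## components partition the segments
  expect_setequal(unlist(calls$members),
                  parse_gfa(p)$segments$id)
  expect_equal(sum(calls$n_segments), 7)
})

test_that("multi-segment acyclic components are tangled without has_cycle", {
  p <- gfa_lines("S\ta\tACGT", "S\tb\tTTTT", "L\ta\t+\tb\t+\t0M")
  calls <- classify_components(parse_gfa(p))
  expect_equal(calls$topology, "tangled_circular")
  expect_false(calls$has_cycle)
})

test_that("link orientation does not change component membership", {
  p1 <- gfa_lines("S\ta\tACGT", "S\tb\tTTTT", "S\tc\tGGGG",
                  "L\ta\t+\tb\t+\t0M", "L\tb\t+\tc\t+\t0M")
  p2 <- gfa_lines("S\ta\tACGT", "S\tb\tTTTT", "S\tc\tGGGG",
                  "L\ta\t-\tb\t+\t0M", "L\tc\t-\tb\t-\t0M")
  c1 <- classify_components(parse_gfa(p1))
  c2 <- classify_components(parse_gfa(p2))
  expect_identical(c1$members, c2$members)
  expect_identical(c1$topology, c2$topology)
})

test_that("circular extraction trims the self-link overlap exactly", {
  com <- fx_small_community()
  truth_seq <- com$replicons$rep1$seq
  lay <- data.frame(replicon = "rep1", topology = "circular",
                    n_segments = 1L, overlap_bp = 100L)
  gfa <- build_gfa(com, lay, tempfile(fileext = ".gfa"))
  g <- parse_gfa(gfa$path)
  calls <- classify_components(g)
  circ <- extract_circular(g, calls)
  expect_length(circ, 1)
  expect_identical(unname(circ[[1]]), truth_seq)   # overlap removed

  expect_identical(extract_circular(g, calls, min_length_bp = 1e9),
                   character(0))
  ## malformed overlap CIGARs raise rather than guess
  bad <- gfa_lines("S\tx\tACGTACGT", "L\tx\t+\tx\t+\t4S4M")
  gb <- parse_gfa(bad)
  expect_error(extract_circular(gb, classify_components(gb)),
               "CIGAR")
})

test_that("tangle members are emitted completely, other requests error", {
  p <- gfa_lines("S\tt1\tAAAACCCC", "S\tt2\tCCCCGGGG", "S\tt3\tGGGGTTTT",
                 "S\tt4\tTTTTAAAA",
                 "L\tt1\t+\tt2\t+\t0M", "L\tt2\t+\tt3\t+\t0M",
                 "L\tt3\t+\tt4\t+\t0M", "L\tt4\t+\tt1\t+\t0M",
                 "S\tc\tACACACAC", "L\tc\t+\tc\t+\t0M")
  g <- parse_gfa(p)
  calls <- classify_components(g)
  tid <- calls$component_id[calls$topology == "tangled_circular"]
  mem <- members_for_reassembly(g, calls, tid)
  expect_length(mem, 4)
  expect_equal(sum(nchar(mem)),
               calls$total_bp[calls$component_id == tid])
  cid <- calls$component_id[calls$topology == "circular"]
  expect_error(members_for_reassembly(g, calls, cid), "not tangled")
  expect_error(members_for_reassembly(g, calls, "nope"), "unknown")
})

test_that("pre-binning filter keeps only linear contigs above the floor", {
  p <- gfa_lines(
    "S\tcirc\tACGTACGT", "L\tcirc\t+\tcirc\t+\t0M",
    "S\tt1\tAAAA", "S\tt2\tCCCC", "S\tt3\tGGGG",
    "L\tt1\t+\tt2\t+\t0M", "L\tt2\t+\tt3\t+\t0M", "L\tt3\t+\tt1\t+\t0M",
    sprintf("S\tlinS\t%s", strrep("A", 1500)),
    sprintf("S\tlinM\t%s", strrep("C", 2500)),
    sprintf("S\tlinL\t%s", strrep("G", 9000)))
  g <- parse_gfa(p)
  calls <- classify_components(g)
  kept <- prebinning_filter(g, calls)
  expect_setequal(names(kept), c("linM", "linL"))
  expect_setequal(names(prebinning_filter(g, calls, 0)),
                  c("linS", "linM", "linL"))
  ## a graph of only circles yields an empty set without error
  p2 <- gfa_lines("S\tc\tACGT", "L\tc\t+\tc\t+\t0M")
  g2 <- parse_gfa(p2)
  expect_length(prebinning_filter(g2, classify_components(g2)), 0)
})

test_that("topology labels of simulator-built graphs are fully recovered", {
  com <- fx_small_community()
  lay <- data.frame(
    replicon = c("rep1", "rep2", "rep3", "rep4", "rep5"),
    topology = c("circular", "circular", "tangled_circular", "linear",
                 "linear"),
    n_segments = c(1L, 1L, 4L, 1L, 1L),
    overlap_bp = c(100L, 0L, 60L, 0L, 0L))
  gfa <- build_gfa(com, lay, tempfile(fileext = ".gfa"))
  g <- parse_gfa(gfa$path)
  calls <- classify_components(g)
  truth <- unique(gfa$labels[, c("component", "topology")])
  expect_equal(nrow(calls), nrow(truth))
  for (i in seq_len(nrow(calls))) {
    seg1 <- calls$members[[i]][1]
    want <- gfa$labels$topology[gfa$labels$segment == seg1]
    expect_equal(calls$topology[i], want)
  }
})
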