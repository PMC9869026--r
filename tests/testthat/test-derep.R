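# MinHash sketching, Mash distance, clustering, fragment ANI and
# representative selection.

test_that("sketches are deterministic and strand-canonical", {
  g <- fx_dna(10000, seed = 1)
  s1 <- minhash_sketch(g, "g")
  s2 <- minhash_sketch(g, "g")
  expect_identical(s1$hashes, s2$hashes)
  src <- minhash_sketch(hifimag:::revcomp(g), "grc")
  expect_identical(s1$hashes, src$hashes)
  expect_error(minhash_sketch("ACGT", k = 21), "shorter than k")
  ## multi-contig genomes pool into one sketch
  sp <- minhash_sketch(c(substring(g, 1, 6000), substring(g, 6001, 10000)))
  expect_gt(length(intersect(sp$hashes, s1$hashes)), 900)
})

test_that("sketch Jaccard tracks the exhaustive k-mer Jaccard", {
  a <- fx_dna(10000, seed = 2)
  b <- fx_mutate(a, 0.02, seed = 3)
  est <- sketch_jaccard(minhash_sketch(a, "a"), minhash_sketch(b, "b"))
  exact <- fx_exact_jaccard(a, b)
  expect_lt(abs(est - exact), 0.05)
})

test_that("mash distance obeys its boundary conventions and symmetry", {
  a <- fx_dna(20000, seed = 4)
  sa <- minhash_sketch(a, "a")
  expect_equal(mash_distance(sa, sa), 0)
  b <- fx_dna(20000, seed = 5)
  sb <- minhash_sketch(b, "b")
  expect_equal(mash_distance(sa, sb), 1)       # disjoint hash sets cap at 1
  expect_equal(mash_distance(sa, sb), mash_distance(sb, sa))
  s8 <- minhash_sketch(a, "a8", k = 15)
  expect_error(mash_distance(sa, s8), "not comparable")
  ## 1% substitution pair lands in the expected distance band
  c2 <- fx_mutate(a, 0.01, seed = 6)
  d <- mash_distance(sa, minhash_sketch(c2, "c"))
  expect_gte(d, 0.005)
  expect_lte(d, 0.02)
})

test_that("single-linkage clustering joins chains and splits strangers", {
  base <- fx_dna(50000, seed = 7)
  b <- fx_mutate(base, 0.03, seed = 8)
  c <- fx_mutate(b, 0.03, seed = 9)
  other <- fx_dna(50000, seed = 10)
  sks <- list(minhash_sketch(base, "A"), minhash_sketch(b, "B"),
              minhash_sketch(c, "C"), minhash_sketch(other, "D"))
  ## chain premise: A~B and B~C are inside d_max, A~C outside
  expect_lte(mash_distance(sks[[1]], sks[[2]]), 0.05)
  expect_lte(mash_distance(sks[[2]], sks[[3]]), 0.05)
  expect_gt(mash_distance(sks[[1]], sks[[3]]), 0.05)
  cl <- cluster_sketches(sks)
  expect_equal(cl$cluster[cl$genome_id %in% c("A", "B", "C")],
               rep(1L, 3))
  expect_equal(cl$cluster[cl$genome_id == "D"], 2L)
  ## trivial cases
  one <- cluster_sketches(list(minhash_sketch(base, "x"),
                               minhash_sketch(base, "y"),
                               minhash_sketch(base, "z")))
  expect_equal(length(unique(one$cluster)), 1)
})

test_that("fragment ANI recovers identity, coverage and random-pair limits", {
  g <- fx_dna(200000, seed = 11)
  self <- fragment_ani(g, g)
  expect_equal(self$ani_pct, 100)
  expect_gte(self$query_cov_pct, 99)
  expect_gte(self$ref_cov_pct, 99)

  g2 <- fx_mutate(g, 0.02, seed = 12)
  r <- fragment_ani(g, g2)
  expect_gte(r$ani_pct, 97.5)
  expect_lte(r$ani_pct, 98.5)

  rnd <- fragment_ani(g, fx_dna(200000, seed = 13))
  expect_true(is.na(rnd$ani_pct))
  expect_lt(rnd$query_cov_pct, 5)
  expect_lt(rnd$ref_cov_pct, 5)
  expect_error(fragment_ani("ACGT", g), "at least frag_bp")
})

test_that("ANI is recovered within 0.5 points across substitution rates", {
  g <- fx_dna(150000, seed = 14)
  for (rate in c(0.005, 0.02, 0.04)) {
    m <- fx_mutate(g, rate, seed = 15 + round(rate * 1000))
    ## oracle: Hamming identity on the known gap-free alignment
    truth <- 100 * mean(utf8ToInt(g) == utf8ToInt(m))
    r <- fragment_ani(g, m)
    expect_lt(abs(r$ani_pct - truth), 0.5)
    expect_lt(abs(r$ani_pct - 100 * (1 - rate)), 0.6)
  }
})

test_that("ANI detects reverse-complemented homology", {
  g <- fx_dna(120000, seed = 30)
  r <- fragment_ani(g, hifimag:::revcomp(fx_mutate(g, 0.01, seed = 31)))
  expect_gte(r$ani_pct, 98.4)
  expect_gte(r$query_cov_pct, 99)
})

test_that("the same-species rule needs ANI and both coverages", {
  mk <- function(ani, ca, cb) list(ani_pct = ani, query_cov_pct = ca,
                                   ref_cov_pct = cb)
  expect_true(same_species(mk(96, 60, 55)))
  expect_false(same_species(mk(96, 60, 40)))    # both coverages required
  expect_false(same_species(mk(94.9, 100, 100)))
  expect_true(same_species(mk(95, 50, 50)))     # thresholds are inclusive
  expect_false(same_species(mk(NA, 0, 0)))
})

test_that("dereplication keeps the best-scoring genome per species", {
  A <- fx_dna(60000, seed = 16)
  B <- fx_mutate(A, 0.01, seed = 17)
  C <- fx_dna(60000, seed = 18)
  q <- data.frame(genome_id = c("A", "B", "C"), Cp = c(90, 85, 70),
                  Ct = c(1, 1, 0), score = c(85, 80, 70))
  dr <- dereplicate(c(A = A, B = B, C = C), q)
  expect_setequal(dr$representatives, c("A", "C"))
  expect_equal(dr$membership$representative[dr$membership$genome_id == "B"],
               "A")
  ## mutually distinct genomes are all their own representative
  D <- fx_dna(60000, seed = 19)
  q2 <- data.frame(genome_id = c("C", "D"), Cp = c(70, 60), Ct = 0,
                   score = c(70, 60))
  dr2 <- dereplicate(c(C = C, D = D), q2)
  expect_setequal(dr2$representatives, c("C", "D"))
  ## idempotence: dereplicating the representatives changes nothing
  dr3 <- dereplicate(c(A = A, C = C), q[q$genome_id != "B", ])
  expect_setequal(dr3$representatives, c("A", "C"))
})

test_that("species x variant panels collapse to max-score representatives", {
  set.seed(20)
  n_sp <- 5
  genomes <- list(); quality <- list(); want <- character(n_sp)
  for (s in seq_len(n_sp)) {
    base <- fx_dna(80000, seed = 100 + s)
    scores <- c(80, 90, 70) + s
    for (v in 1:2) {
      id <- sprintf("sp%d_v%d", s, v)
      genomes[[id]] <- if (v == 1) base else
        fx_mutate(base, 0.005, seed = 200 + s)
      quality[[id]] <- data.frame(genome_id = id, Cp = scores[v], Ct = 0,
                                  score = scores[v])
    }
    want[s] <- sprintf("sp%d_v2", s)     # v2 always scores highest
  }
  dr <- dereplicate(unlist(genomes), do.call(rbind, quality))
  expect_setequal(dr$representatives, want)
})
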