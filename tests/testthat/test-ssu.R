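# Read-level 16S detection, filtering, classification and copy-number
# adjusted profiles.

ssu_gene <- function(genus = "Defluviitoga")
  unname(hifimag:::genus_rrna_genes(genus)[["16S"]])

test_that("a planted full-length gene is detected with exact boundaries", {
  gene <- ssu_gene()
  read <- paste0(fx_dna(2000, seed = 1), gene, fx_dna(2000, seed = 2))
  qual <- fx_qual(nchar(read), 30)
  cand <- detect_ssu(read, ids = "r1", quals = qual)
  expect_equal(nrow(cand), 1)
  expect_lte(abs(cand$start - 2001), 25)
  expect_lte(abs(cand$end - (2000 + nchar(gene))), 25)
  expect_identical(cand$sequence, gene)
  expect_equal(cand$mean_error_prob, 1e-3, tolerance = 1e-9)
  ## random sequence yields no candidate
  expect_equal(nrow(detect_ssu(fx_dna(8000, seed = 3))), 0)
})

test_that("reverse-strand genes come back reverse-complemented", {
  gene <- ssu_gene()
  read <- paste0(fx_dna(1500, seed = 4), hifimag:::revcomp(gene),
                 fx_dna(1500, seed = 5))
  qual <- paste0(fx_qual(1500, 20), fx_qual(nchar(gene), 35),
                 fx_qual(1500, 20))
  cand <- detect_ssu(read, ids = "r1", quals = qual)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$strand, "-")
  expect_identical(cand$sequence, gene)
  ## the quality slice follows the gene, not the flanks
  expect_equal(cand$mean_error_prob, 10^(-3.5), tolerance = 1e-6)
})

test_that("a read spanning two operons yields two candidates", {
  g1 <- ssu_gene("Defluviitoga")
  g2 <- ssu_gene("Methanothrix")
  read <- paste0(fx_dna(500, seed = 6), g1, fx_dna(800, seed = 7), g2,
                 fx_dna(500, seed = 8))
  cand <- detect_ssu(read, ids = "r1", quals = fx_qual(nchar(read), 30))
  expect_equal(nrow(cand), 2)
  expect_setequal(cand$sequence, c(g1, g2))
})

test_that("detection tolerates read-level substitution noise", {
  gene <- ssu_gene()
  read0 <- paste0(fx_dna(1000, seed = 9), gene, fx_dna(1000, seed = 10))
  read <- fx_mutate(read0, 0.001, seed = 11)
  cand <- detect_ssu(read, ids = "r", quals = fx_qual(nchar(read), 30))
  expect_equal(nrow(cand), 1)
  expect_lte(abs(cand$start - 1001), 25)
})

test_that("the length and accuracy filters follow the stated thresholds", {
  cand <- data.frame(read_id = sprintf("r%d", 1:5),
                     length_bp = c(1512, 1100, 1750, 1200, 1512),
                     mean_error_prob = c(10^-3, 10^-3, 10^-3, 10^-2,
                                         10^-1.3))
  kept <- filter_ssu(cand)
  ## 1512 bp Q30 kept; 1100 too short; 1750 too long; 1200 bp at exactly
  ## Q20 kept (accuracy 0.99 passes >=); 1512 bp Q13 fails (error 0.0501)
  expect_setequal(kept$read_id, c("r1", "r4"))
  ## brute-force re-scan agrees on a random candidate batch
  big <- data.frame(read_id = sprintf("q%d", 1:200),
                    length_bp = hifimag:::with_seed(1,
                      sample(1000:1900, 200, TRUE)),
                    mean_error_prob = hifimag:::with_seed(2,
                      10^-runif(200, 1, 4)))
  kept2 <- filter_ssu(big)
  brute <- big[sapply(seq_len(200), function(i)
    big$length_bp[i] >= 1200 && big$length_bp[i] <= 1700 &&
      (1 - big$mean_error_prob[i]) >= 0.99), ]
  expect_identical(kept2$read_id, brute$read_id)
})

fx_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genera <- rrn_copy_table()$genus
      refs <- vapply(genera, ssu_gene, "")
      taxa <- sprintf("Bacteria;Phy_%s;C;O;F;%s", genera, genera)
      cache <<- train_classifier(refs, taxa)
    }
    cache
  }
})

test_that("training sequences classify to their own genus with certainty", {
  model <- fx_model()
  refs <- vapply(model$genera, ssu_gene, "")
  cls <- classify_ssu(refs, model, seed = 3)
  expect_identical(cls$genus, model$genera)
  expect_true(all(cls$conf_genus == 1))
  expect_error(train_classifier(c(a = ssu_gene()), "Bacteria;P;C;O;F;G"),
               "two genera")
  expect_error(train_classifier(setNames(rep(ssu_gene(), 2), c("a", "a")),
                                rep("Bacteria;P;C;O;F;G", 2)), "unique ids")
})

test_that("the classifier round-trips through serialization unchanged", {
  model <- fx_model()
  p <- tempfile(fileext = ".rds")
  write_classifier(model, p)
  expect_identical(read_classifier(p), model)
})

test_that("classification is deterministic for a fixed seed", {
  model <- fx_model()
  q <- fx_mutate(ssu_gene(), 0.02, seed = 12)
  c1 <- classify_ssu(q, model, seed = 7)
  c2 <- classify_ssu(q, model, seed = 7)
  expect_identical(c1, c2)
})

test_that("confidence decays along the divergence ladder", {
  model <- fx_model()
  confs <- vapply(c(0, 0.02, 0.05, 0.10), function(rate) {
    g <- if (rate == 0) ssu_gene() else
      fx_mutate(ssu_gene(), rate, seed = round(rate * 1000))
    mean(vapply(1:3, function(s)
      classify_ssu(g, model, seed = s)$conf_genus, 0))
  }, 0)
  expect_equal(confs[1], 1)
  expect_gte(confs[2], 0.95)      # 2% diverged, genera ~15% apart
  for (i in 2:4) expect_lte(confs[i], confs[i - 1] + 0.05)
})

test_that("random sequences stay unclassified at genus rank", {
  model <- fx_model()
  rnd <- vapply(1:20, function(i) fx_dna(1500, seed = 500 + i), "")
  cls <- classify_ssu(rnd, model, seed = 9)
  expect_true(all(cls$conf_genus < 0.8))
  expect_true(all(cls$assigned_rank != "genus"))
})

test_that("copy-number adjustment rescales counts to cell proportions", {
  tab <- data.frame(genus = c("A", "B"), copies = c(4, 1))
  prof <- copy_adjusted_profile(c(rep("A", 40), rep("B", 10)), tab)
  expect_equal(unname(prof[c("A", "B")]), c(0.5, 0.5))
  tab1 <- data.frame(genus = c("A", "B"), copies = c(1, 1))
  prof1 <- copy_adjusted_profile(c(rep("A", 40), rep("B", 10)), tab1)
  expect_equal(unname(prof1[c("A", "B")]), c(0.8, 0.2))
  tab2 <- data.frame(genus = c("A", "B"), copies = c(3, 2))
  prof2 <- copy_adjusted_profile(c(rep("A", 30), rep("B", 10)), tab2)
  expect_equal(unname(prof2[c("A", "B")]), c(2 / 3, 1 / 3))
  expect_error(copy_adjusted_profile("A", data.frame(genus = "A",
                                                     copies = 0)),
               "positive")
  ## unlisted taxa fall back to the default copy number
  prof3 <- copy_adjusted_profile(c(rep("A", 8), rep("Zz", 4)),
                                 data.frame(genus = "A", copies = 4),
                                 default_copies = 2)
  expect_equal(unname(prof3[c("A", "Zz")]), c(0.5, 0.5))
})

test_that("profiles are invariant to reverse-complementing every read", {
  com <- fx_small_community()
  sim <- simulate_hifi_reads(com, read_model(), depth_target = 15, seed = 4)
  fwd <- filter_ssu(detect_ssu(sim$reads$seq, ids = sim$reads$id,
                               quals = sim$reads$qual))
  rc_seq <- hifimag:::revcomp(sim$reads$seq)
  rc_qual <- hifimag:::reverse_chars(sim$reads$qual)
  rev <- filter_ssu(detect_ssu(rc_seq, ids = sim$reads$id, quals = rc_qual))
  expect_equal(nrow(fwd), nrow(rev))
  expect_setequal(paste(fwd$read_id, fwd$sequence),
                  paste(rev$read_id, rev$sequence))
  expect_equal(sort(fwd$mean_error_prob), sort(rev$mean_error_prob),
               tolerance = 1e-12)
})
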