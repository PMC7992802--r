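test_that("presence patterns tally correctly for simple cases", {
  tabs <- list(
    gA = busco_records(c("b1", "b2"), c("Complete", "Missing")),
    gB = busco_records(c("b1", "b2"), c("Duplicated", "Missing")),
    gC = busco_records(c("b1", "b2"), c("Complete", "Fragmented"))
  )
  pm <- presence_matrix(tabs)
  expect_equal(unname(pm$pattern_tally["111"]), 1L)  # b1 everywhere
  expect_equal(unname(pm$pattern_tally["000"]), 1L)  # b2: F counts absent
  expect_equal(pm$missing_in_all, "b2")
  expect_equal(sum(pm$pattern_tally), length(pm$genes))

  # Fragmented can be counted present when asked
  pm2 <- presence_matrix(tabs, present_statuses = c("Complete",
                                                    "Duplicated",
                                                    "Fragmented"))
  expect_equal(unname(pm2$matrix["b2", "gC"]), 1L)
})

test_that("planted pattern frequencies are reproduced exactly", {
  freqs <- c("111" = 50, "011" = 20, "110" = 8, "000" = 5)
  fx <- gen_busco_tables(freqs, seed = 6, dup_fraction = 0.3)
  pm <- presence_matrix(fx$tables)
  expect_equal(pm$pattern_tally[names(freqs)], freqs,
               ignore_attr = TRUE)
  expect_equal(length(pm$missing_in_all), 5L)
  expect_equal(pm$top_patterns$pattern[1], "111")
  # tally from the manifest agrees
  expect_equal(sort(unname(pm$pattern_tally)),
               sort(unname(table(fx$manifest$genes$pattern))),
               ignore_attr = TRUE)
})

test_that("reciprocal best hits require mutual best bitscores", {
  fwd <- blast_hits(c("a", "a", "b"), c("x", "y", "x"),
                    80, 100, 1e-30, c(200, 150, 180))
  rev <- blast_hits(c("x", "y"), c("a", "c"),
                    80, 100, 1e-30, c(210, 90))
  pairs <- reciprocal_best_hits(fwd, rev)
  expect_equal(pairs$query_id, "a")
  expect_equal(pairs$subject_id, "x")

  # fwd best(a)=x but rev best(x) points elsewhere: no pair
  rev2 <- blast_hits("x", "c", 80, 100, 1e-30, 500)
  expect_equal(nrow(reciprocal_best_hits(fwd, rev2)), 0L)

  # e-value cutoff is strict
  fwd3 <- blast_hits("a", "x", 80, 100, 1e-4, 200)
  rev3 <- blast_hits("x", "a", 80, 100, 1e-4, 200)
  expect_equal(nrow(reciprocal_best_hits(fwd3, rev3)), 0L)
  expect_equal(nrow(reciprocal_best_hits(fwd3, rev3,
                                         max_evalue = 1e-3)), 1L)
})

test_that("RBH matches the double-loop oracle on planted fixtures", {
  fx <- gen_blast_tables(200, 200, 0.4, seed = 19)
  pairs <- reciprocal_best_hits(fx$fwd, fx$rev)
  got <- sort(paste(pairs$query_id, pairs$subject_id), method = "radix")
  expect_identical(got, brute_rbh(fx$fwd, fx$rev))
  # planted pairs recovered, sub-threshold pairs excluded
  planted <- sort(paste(fx$manifest$planted_pairs$query_id,
                        fx$manifest$planted_pairs$subject_id),
                  method = "radix")
  expect_identical(got, planted)
  expect_false(any(fx$manifest$subthreshold_pairs$query_id %in%
                     pairs$query_id))
})

test_that("RBH is symmetric under direction swap", {
  fx <- gen_blast_tables(80, 80, 0.5, seed = 27)
  ab <- reciprocal_best_hits(fx$fwd, fx$rev)
  ba <- reciprocal_best_hits(fx$rev, fx$fwd)
  expect_setequal(paste(ab$query_id, ab$subject_id),
                  paste(ba$subject_id, ba$query_id))
})

test_that("rescue reports RBH-supported missing-in-all genes", {
  tabs <- list(
    g1 = busco_records("b1", "Missing"),
    g2 = busco_records("b1", "Missing"),
    g3 = busco_records("b1", "Missing")
  )
  pm <- presence_matrix(tabs)
  pair <- function(q, s) data.frame(query_id = q, subject_id = s,
                                    stringsAsFactors = FALSE)
  rbh_all <- list(g1 = pair("p1", "x1"), g2 = pair("p1", "x2"),
                  g3 = pair("p1", "x3"))
  rep1 <- rescue_missing(pm, rbh_all, c(b1 = "p1"))
  expect_equal(rep1$n_rescued_all, 1L)
  expect_equal(rep1$fraction, 1.0)

  # support in only 2 of 3 genomes counts as partial, not rescued
  rbh_part <- list(g1 = pair("p1", "x1"), g2 = pair("p1", "x2"),
                   g3 = pair("other", "x3"))
  rep2 <- rescue_missing(pm, rbh_part, c(b1 = "p1"))
  expect_equal(rep2$n_rescued_all, 0L)
  expect_equal(rep2$n_partial, 1L)

  # unmapped genes come out of the denominator with a warning
  expect_warning(rep3 <- rescue_missing(pm, rbh_all, c(zz = "p9")),
                 "without protein mapping")
  expect_equal(rep3$n_missing_all, 0L)
  expect_equal(rep3$unmapped, "b1")
})

test_that("rescue recovers a planted fraction on generated fixtures", {
  # 20 genes missing in all 3 genomes; 9 get planted RBH support everywhere
  fx <- gen_busco_tables(c("111" = 30, "000" = 20), seed = 8)
  pm <- presence_matrix(fx$tables)
  missing <- pm$missing_in_all
  expect_equal(length(missing), 20L)
  prots <- stats::setNames(paste0("prot_", pm$genes), pm$genes)
  supported <- missing[1:9]
  rbh <- lapply(pm$genomes, function(g) {
    data.frame(query_id = prots[supported],
               subject_id = paste0(g, "_tgt"), stringsAsFactors = FALSE)
  })
  names(rbh) <- pm$genomes
  # one gene additionally supported in just one genome
  rbh[[1]] <- rbind(rbh[[1]],
                    data.frame(query_id = prots[missing[10]],
                               subject_id = "partial_tgt",
                               stringsAsFactors = FALSE))
  report <- rescue_missing(pm, rbh, prots)
  expect_equal(report$n_missing_all, 20L)
  expect_equal(report$n_rescued_all, 9L)
  expect_equal(report$fraction, 9 / 20)
  expect_equal(report$n_partial, 1L)
  expect_lte(report$n_rescued_all, report$n_missing_all)
})

test_that("metric matrices implement the documented formulas", {
  hits <- list(
    g1 = blast_hits(c("q1", "q2"), c("s1", "s2"), c(90, 70),
                    c(100, 90), 1e-30, c(200, 120))
  )
  lens <- c(q1 = 110, q2 = 100)
  mm <- metric_matrices(hits, lens, list(core = c("q1", "q2", "q3")))
  m <- mm$core
  expect_equal(m$normalized_bitscore["q1", "g1"], 2.0)
  expect_equal(m$aligned_proportion["q2", "g1"], 0.9)
  expect_true(is.na(m$bitscore["q3", "g1"]))   # absent, never zero

  expect_error(metric_matrices(hits, c(q1 = 110),
                               list(core = c("q1", "q2"))), "q2")
})

test_that("metric matrices equal cell-wise recomputation on fixtures", {
  fx <- gen_blast_tables(100, 100, 0.6, seed = 33)
  hits <- list(gen1 = fx$fwd)
  lens <- fx$manifest$query_lengths
  genes <- sort(unique(fx$fwd$query_id))
  mm <- metric_matrices(hits, lens, list(all = genes))$all
  for (g in genes) {
    rows <- fx$fwd[fx$fwd$query_id == g, ]
    rows <- rows[order(-rows$bitscore, rows$evalue, rows$subject_id,
                       method = "radix"), ]
    best <- rows[1, ]
    expect_equal(mm$bitscore[g, "gen1"], best$bitscore)
    expect_equal(mm$aln_len[g, "gen1"], best$aln_len)
    expect_equal(mm$pct_identity[g, "gen1"], best$pct_identity)
    expect_equal(mm$normalized_bitscore[g, "gen1"],
                 best$bitscore / best$aln_len)
    expect_equal(mm$aligned_proportion[g, "gen1"],
                 best$aln_len / lens[[g]])
  }
})

test_that("matched downsampling is reproducible and bounded", {
  genes <- sprintf("g%04d", 1:500)
  expect_error(subsample_matched(genes, 501, 2, seed = 1),
               "exceeds")
  full <- subsample_matched(genes, 500, 3, seed = 1)
  expect_true(all(vapply(full, function(s) setequal(s, genes), TRUE)))
  a <- subsample_matched(genes, 101, 50, seed = 7)
  b <- subsample_matched(genes, 101, 50, seed = 7)
  expect_identical(a, b)
  expect_true(all(lengths(a) == 101L))
  expect_true(all(vapply(a, anyDuplicated, 0L) == 0L))
})
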