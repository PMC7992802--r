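mk_model <- function(id, exon_spans, strand = "+", seq_id = "chrI",
                     evidence = "transcript") {
  gene_model(id, seq_id, strand,
             do.call(rbind, exon_spans), evidence = evidence)
}

# three well-separated exons of total length 3*aa so orf_len_aa == aa
spans_for_orf <- function(start, aa, k = 3) {
  total <- 3 * aa
  len <- total %/% k
  lens <- c(rep(len, k - 1), total - len * (k - 1))
  s <- start
  out <- list()
  for (l in lens) {
    out[[length(out) + 1L]] <- cbind(s, s + l - 1)
    s <- s + l + 150
  }
  out
}

test_that("window coverage counts every exon boundary once", {
  m <- mk_model("m1", list(cbind(101, 190), cbind(301, 360),
                           cbind(501, 512)))
  w <- build_windows(annotation_set(list(m)))
  expect_equal(w$window, c(1L, 3L, 5L))
  expect_equal(w$count, c(2L, 2L, 2L))
  expect_equal(sum(w$count), 2L * 3L)

  # both boundaries of one short exon land in the same window
  w2 <- build_windows(annotation_set(list(mk_model("m2",
                                                   list(cbind(150, 160))))))
  expect_equal(w2$count, 2L)
  expect_equal(w2$window, 1L)
})

test_that("window coverage equals a brute-force boundary tally", {
  set <- random_set(500, seed = 13, n_seqs = 3)
  w <- build_windows(set)
  want <- brute_window_tally(set)
  expect_equal(nrow(w), length(want))
  for (i in seq_len(nrow(w))) {
    key <- paste(w$seq_id[i], w$strand[i], w$window[i])
    expect_equal(w$count[i], want[[key]])
  }
  expect_equal(sum(w$count), 2L * nrow(set$exons))
})

test_that("the longest eligible ORF wins and overlaps are discarded", {
  a <- mk_model("a", spans_for_orf(1000, 100))
  b <- mk_model("b", spans_for_orf(1100, 80))
  res <- select_nonredundant(annotation_set(list(a, b)))
  expect_equal(res$selected$models$model_id, "a")
  expect_equal(res$discarded$model_id, "b")
  expect_equal(res$discarded$reason, "overlap_with_selected")
})

test_that("filters exclude short-ORF and few-exon models", {
  two_exon <- mk_model("x", spans_for_orf(1000, 200, k = 2))
  res <- select_nonredundant(annotation_set(list(two_exon)))
  expect_equal(length(res$selected), 0L)
  expect_equal(res$discarded$reason, "filter_exons")

  short_orf <- mk_model("y", spans_for_orf(1000, 30, k = 3))
  res2 <- select_nonredundant(annotation_set(list(short_orf)))
  expect_equal(res2$discarded$reason, "filter_orf_len")
})

test_that("non-overlapping models coexist and strands are independent", {
  a <- mk_model("a", spans_for_orf(1000, 100))
  b <- mk_model("b", spans_for_orf(9000, 90))
  res <- select_nonredundant(annotation_set(list(a, b)))
  expect_setequal(res$selected$models$model_id, c("a", "b"))

  plus <- mk_model("p", spans_for_orf(1000, 100), strand = "+")
  minus <- mk_model("m", spans_for_orf(1000, 100), strand = "-")
  res2 <- select_nonredundant(annotation_set(list(plus, minus)))
  expect_setequal(res2$selected$models$model_id, c("p", "m"))
})

test_that("generated loci are resolved to their planted winners", {
  for (seed in c(1, 2)) {
    fx <- gen_locus_set(120, seed = seed, tie_mode = seed == 2)
    res <- select_nonredundant(fx$merged)
    expect_setequal(res$selected$models$model_id, fx$manifest$winners)
  }
})

test_that("selection output satisfies its structural invariants", {
  fx <- gen_locus_set(80, seed = 5, tie_mode = TRUE)
  res <- select_nonredundant(fx$merged)
  sel <- res$selected$models
  # partition
  expect_equal(sort(c(sel$model_id, res$discarded$model_id)),
               sort(fx$merged$models$model_id))
  # filter soundness
  expect_true(all(sel$n_exons >= 3))
  expect_true(all(sel$orf_len_aa >= 60))
  # exon-level pairwise disjointness per (seq, strand)
  for (key in unique(paste(sel$seq_id, sel$strand))) {
    ids <- sel$model_id[paste(sel$seq_id, sel$strand) == key]
    ex <- res$selected$exons[res$selected$exons$model_id %in% ids, ]
    ex <- ex[radix_order(ex$start), ]
    if (nrow(ex) > 1) {
      expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
    }
  }
})

test_that("re-selecting a selected set changes nothing", {
  for (seed in 1:10) {
    fx <- gen_locus_set(20, seed = seed)
    once <- select_nonredundant(fx$merged)
    twice <- select_nonredundant(once$selected)
    expect_equal(nrow(twice$discarded), 0L)
    expect_setequal(twice$selected$models$model_id,
                    once$selected$models$model_id)
  }
})

test_that("repeated runs produce identical audit logs", {
  fx <- gen_locus_set(40, seed = 12, tie_mode = TRUE)
  r1 <- select_nonredundant(fx$merged)
  r2 <- select_nonredundant(fx$merged)
  expect_identical(r1$audit, r2$audit)
  expect_identical(r1$selected$models, r2$selected$models)
})

test_that("the selector agrees with the naive re-implementation", {
  # varied shapes: generator loci, plain random sets, tie mode
  for (seed in 1:6) {
    fx <- gen_locus_set(25, seed = seed, tie_mode = seed %% 2 == 0)
    expect_selector_matches_oracle(fx$merged)
  }
  for (seed in 7:10) {
    expect_selector_matches_oracle(random_set(60, seed = seed))
  }
  # non-default thresholds
  expect_selector_matches_oracle(random_set(50, seed = 99),
                                 window_size = 50, min_orf_aa = 20,
                                 min_exons = 2)
})

test_that("lowering the ORF threshold never shrinks selected ORF mass", {
  for (seed in c(3, 14)) {
    fx <- gen_locus_set(50, seed = seed)
    strict <- select_nonredundant(fx$merged, min_orf_aa = 60)
    lax <- select_nonredundant(fx$merged, min_orf_aa = 20)
    expect_gte(sum(lax$selected$models$orf_len_aa),
               sum(strict$selected$models$orf_len_aa))
  }
})

test_that("window discard scope keeps the partition invariant", {
  fx <- gen_locus_set(40, seed = 6)
  res <- select_nonredundant(fx$merged, discard_scope = "window")
  expect_equal(sort(c(res$selected$models$model_id,
                      res$discarded$model_id)),
               sort(fx$merged$models$model_id))
  expect_true(all(res$selected$models$n_exons >= 3))
  expect_true(all(res$selected$models$orf_len_aa >= 60))
})

test_that("evidence merging unions sets and preserves labels", {
  hom <- annotation_set(lapply(1:10, function(i) {
    mk_model(sprintf("h%d", i), spans_for_orf(i * 5000, 80),
             evidence = "homology")
  }))
  tra <- annotation_set(lapply(1:15, function(i) {
    mk_model(sprintf("t%d", i), spans_for_orf(i * 5000 + 2000, 70),
             evidence = "transcript")
  }))
  merged <- merge_evidence(hom, tra)
  expect_equal(length(merged), 25L)
  expect_true(all(grepl("^(homology|transcript):", merged$models$model_id)))

  # empty homology set: identity on the transcript side
  id_merge <- merge_evidence(annotation_set(), tra, prefix = FALSE)
  expect_equal(id_merge$models, tra$models)

  dup <- merge_evidence(hom, tra, prefix = FALSE)
  expect_equal(length(dup), 25L)
  expect_error(merge_evidence(hom, hom, prefix = FALSE), "duplicate")
})

test_that("selection counts by evidence match a direct tally", {
  fx <- gen_locus_set(60, seed = 44)
  res <- select_nonredundant(fx$merged)
  s <- summary(res)
  ev <- fx$merged$models$evidence[
    match(res$selected$models$model_id, fx$merged$models$model_id)]
  expect_equal(s$selected_by_evidence$homology,
               unname(table(factor(ev, c("homology", "transcript")))[1]),
               ignore_attr = TRUE)
  expect_equal(s$n_input, length(fx$merged))
  expect_equal(s$n_selected + s$n_discarded, s$n_input)
})

test_that("an empty input yields an empty, well-formed result", {
  res <- select_nonredundant(annotation_set())
  expect_equal(length(res$selected), 0L)
  expect_equal(nrow(res$discarded), 0L)
  expect_equal(nrow(res$audit), 0L)
})
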