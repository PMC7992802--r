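make_gff3 <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("read_gff3 builds one model per mRNA with CDS-derived ORF", {
  p <- make_gff3(c(
    "chrI\ttest\tgene\t101\t512\t.\t+\t.\tID=gene:m1",
    "chrI\ttest\tmRNA\t101\t512\t.\t+\t.\tID=m1;Parent=gene:m1",
    "chrI\ttest\tCDS\t101\t190\t.\t+\t0\tID=cds:m1;Parent=m1",
    "chrI\ttest\tCDS\t301\t360\t.\t+\t0\tID=cds:m1;Parent=m1",
    "chrI\ttest\tCDS\t501\t512\t.\t+\t0\tID=cds:m1;Parent=m1"
  ))
  set <- read_gff3(p, evidence = "transcript")
  expect_equal(length(set), 1L)
  expect_equal(set$models$n_exons, 3L)
  expect_equal(set$models$orf_len_aa, 54L)
  expect_equal(set$models$evidence, "transcript")
})

test_that("header-only and malformed GFF3 inputs behave as contracted", {
  empty <- make_gff3(character())
  expect_equal(length(read_gff3(empty)), 0L)

  bad_coord <- make_gff3("chrI\tt\tCDS\t200\t100\t.\t+\t0\tID=c;Parent=m")
  expect_error(read_gff3(bad_coord), "line 2.*start > end")

  bad_strand <- make_gff3("chrI\tt\tCDS\t1\t9\t.\t?\t0\tID=c;Parent=m")
  expect_error(read_gff3(bad_strand), "line 2.*strand")

  not_int <- make_gff3("chrI\tt\tCDS\tx\t9\t.\t+\t0\tID=c;Parent=m")
  expect_error(read_gff3(not_int), "line 2.*coordinate")

  childless <- make_gff3(c(
    "chrI\tt\tgene\t1\t99\t.\t+\t.\tID=gene:m1",
    "chrI\tt\tmRNA\t1\t99\t.\t+\t.\tID=m1;Parent=gene:m1"
  ))
  expect_warning(set <- read_gff3(childless), "no CDS/exon")
  expect_equal(length(set), 0L)
})

test_that("GFF3 write -> read round-trips model lists exactly", {
  set <- random_set(50, seed = 3)
  p <- tempfile(fileext = ".gff3")
  write_gff3(set, p)
  back <- read_gff3(p)
  expect_sets_equal(back, set)
  # evidence and source protein survive the trip
  expect_equal(
    back$models$evidence[match(set$models$model_id,
                               back$models$model_id)],
    set$models$evidence)
  expect_equal(
    back$models$source_protein_id[match(set$models$model_id,
                                        back$models$model_id)],
    set$models$source_protein_id)
  # writing twice is byte-identical
  p2 <- tempfile(fileext = ".gff3")
  write_gff3(set, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
  # empty set -> header only
  pe <- tempfile()
  write_gff3(annotation_set(), pe)
  expect_identical(readLines(pe), "##gff-version 3")
})

test_that("readers tolerate CRLF line endings", {
  set <- random_set(5, seed = 8)
  p <- tempfile()
  write_gff3(set, p)
  crlf <- tempfile()
  writeLines(readLines(p), crlf, sep = "\r\n")
  expect_sets_equal(read_gff3(crlf), set)
})

exonerate_fixture <- function() {
  p <- tempfile(fileext = ".exgff")
  writeLines(c(
    "Command line: [exonerate --model protein2genome query.fa target.fa]",
    "# --- START OF GFF DUMP ---",
    "#",
    paste("chrI\texonerate:protein2genome:local\tgene\t1000\t2400\t655",
          "\t+\t.\tgene_id 1 ; sequence protA ; gene_orientation +",
          sep = ""),
    "chrI\texonerate:protein2genome:local\texon\t1000\t1200\t.\t+\t.\tinsertions 0",
    "chrI\texonerate:protein2genome:local\tsplice5\t1201\t1202\t.\t+\t.\tintron_id 1",
    "chrI\texonerate:protein2genome:local\texon\t1400\t1600\t.\t+\t.\tinsertions 0",
    "chrI\texonerate:protein2genome:local\texon\t2000\t2400\t.\t+\t.\tinsertions 2",
    "chrI\texonerate:protein2genome:local\tsimilarity\t1000\t2400\t655\t+\t.\talignment_id 1",
    "# --- END OF GFF DUMP ---",
    "  Some alignment text outside the dump",
    "# --- START OF GFF DUMP ---",
    paste("chrII\texonerate:protein2genome:local\tgene\t500\t1900\t321",
          "\t-\t.\tgene_id 2 ; sequence protB ; gene_orientation +",
          sep = ""),
    "chrII\texonerate:protein2genome:local\texon\t500\t700\t.\t-\t.\tinsertions 0",
    "chrII\texonerate:protein2genome:local\texon\t900\t1100\t.\t-\t.\tinsertions 0",
    "chrII\texonerate:protein2genome:local\texon\t1300\t1500\t.\t-\t.\tinsertions 0",
    "chrII\texonerate:protein2genome:local\texon\t1700\t1900\t.\t-\t.\tinsertions 0",
    "# --- END OF GFF DUMP ---"
  ), p)
  p
}

test_that("exonerate dialect parses genes, exons and query ids", {
  set <- read_exonerate_gff(exonerate_fixture())
  expect_equal(length(set), 2L)
  m <- set$models[radix_order(set$models$model_id), ]
  expect_equal(m$model_id, c("protA.g1", "protB.g2"))
  expect_equal(m$n_exons, c(3L, 4L))
  expect_equal(m$source_protein_id, c("protA", "protB"))
  expect_equal(m$evidence, c("homology", "homology"))
})

test_that("exonerate degenerate inputs warn instead of failing", {
  no_dump <- tempfile()
  writeLines("exonerate alignment text only", no_dump)
  expect_warning(set <- read_exonerate_gff(no_dump), "no GFF dump")
  expect_equal(length(set), 0L)

  empty_gene <- tempfile()
  writeLines(c(
    "# --- START OF GFF DUMP ---",
    "chrI\tex\tgene\t100\t500\t10\t+\t.\tgene_id 1 ; sequence pX",
    "# --- END OF GFF DUMP ---"
  ), empty_gene)
  expect_warning(set <- read_exonerate_gff(empty_gene), "zero exon")
  expect_equal(length(set), 0L)
})

test_that("the same structures parse identically from GFF3 and dialect", {
  set.seed(21)
  models <- lapply(1:20, function(i) {
    k <- sample(2:5, 1)
    lens <- sample(30:200, k, replace = TRUE)
    gaps <- sample(50:200, k - 1, replace = TRUE)
    start <- sample(1:30000, 1)
    starts <- start + cumsum(c(0L, lens[-k] + gaps))
    gene_model(sprintf("prot%02d.g%d", i, i), "chrI",
               sample(c("+", "-"), 1), cbind(starts, starts + lens - 1L),
               evidence = "homology",
               source_protein_id = sprintf("prot%02d", i))
  })
  set <- annotation_set(models)
  p3 <- tempfile(); pex <- tempfile()
  write_gff3(set, p3)
  write_exonerate_gff(set, pex)
  from_gff3 <- read_gff3(p3)
  from_ex <- read_exonerate_gff(pex)
  expect_sets_equal(from_gff3, from_ex)
  expect_sets_equal(from_ex, set)
})

test_that("longest isoform filtering keeps the per-gene maximum", {
  aa <- Biostrings::AAStringSet(c(
    g1.t1 = paste(rep("A", 120), collapse = ""),
    g1.t2 = paste(rep("A", 200), collapse = ""),
    g2.t1 = paste(rep("K", 50), collapse = "")
  ))
  kept <- longest_isoform_filter(aa)
  expect_equal(names(kept), c("g1.t2", "g2.t1"))

  # single-isoform input is untouched
  single <- aa[c(2, 3)]
  expect_equal(names(longest_isoform_filter(single)), names(single))

  # ties break toward the lexicographically smallest id
  tie <- Biostrings::AAStringSet(c(g9.b = "MKV", g9.a = "MKL"))
  expect_equal(names(longest_isoform_filter(tie)), "g9.a")

  expect_error(longest_isoform_filter(
    Biostrings::AAStringSet(c(nodot = "MK"))), "nodot")
})

test_that("longest isoform filtering matches a brute-force maximum", {
  set.seed(5)
  recs <- character(); genes <- character()
  for (g in 1:100) {
    n_iso <- sample(1:4, 1)
    for (t in seq_len(n_iso)) {
      recs <- c(recs, paste(rep("M", sample(50:500, 1)), collapse = ""))
      genes <- c(genes, sprintf("gene%03d", g))
    }
  }
  names(recs) <- sprintf("%s.t%d", genes, stats::ave(
    seq_along(genes), genes, FUN = seq_along))
  aa <- Biostrings::AAStringSet(recs)
  kept <- longest_isoform_filter(aa)
  expect_equal(length(kept), 100L)
  by_gene <- split(nchar(recs), genes)
  kept_gene <- sub("\\.t\\d+$", "", names(kept))
  expect_equal(unname(Biostrings::width(kept)),
               unname(vapply(by_gene[kept_gene], max, 0)))
})

test_that("BUSCO tables parse all statuses, CRLF and generator output", {
  p <- tempfile()
  writeLines(c(
    "# BUSCO version is: 4.1.1",
    "b1\tComplete\tseqA\t512.2\t300",
    "b2\tDuplicated\tseqB\t300.0\t210",
    "b3\tFragmented\tseqC\t55.5\t60",
    "b4\tMissing"
  ), p)
  r <- read_busco_table(p)
  expect_equal(r$status,
               c("Complete", "Duplicated", "Fragmented", "Missing"))
  expect_equal(r$score[1], 512.2)
  expect_true(is.na(r$sequence[4]))

  crlf <- tempfile()
  writeLines(readLines(p), crlf, sep = "\r\n")
  expect_equal(read_busco_table(crlf), r)

  bad <- tempfile()
  writeLines(c("b1\tComplete\ts\t1.0\t10", "b2\tGone"), bad)
  expect_error(read_busco_table(bad), "line 2")

  fx <- gen_busco_tables(c("101" = 30, "000" = 10), seed = 4,
                         out_dir = tempfile())
  parsed <- read_busco_table(fx$files[[1]])
  expect_equal(parsed, fx$tables[[1]], ignore_attr = TRUE)
})

test_that("BLAST tabular parsing is exact and strict on column count", {
  p <- tempfile()
  writeLines(paste("qA\tsB\t85.0\t100\t15\t0\t1\t100\t1\t100",
                   "\t1e-50\t200", sep = ""), p)
  h <- read_blast_tab(p)
  expect_equal(h$pct_identity, 85.0)
  expect_equal(h$aln_len, 100L)
  expect_equal(h$bitscore, 200)
  expect_equal(h$evalue, 1e-50)

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_blast_tab(empty)), 0L)

  bad <- tempfile()
  writeLines(c(readLines(p), "qA\tsB\t85.0"), bad)
  expect_error(read_blast_tab(bad), "line 2")

  fx <- gen_blast_tables(30, 30, 0.5, seed = 9, out_dir = tempfile())
  parsed <- read_blast_tab(fx$files[["fwd"]])
  expect_equal(parsed, fx$fwd, ignore_attr = TRUE)
})
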