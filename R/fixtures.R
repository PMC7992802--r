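# Seeded generators of self-contained test inputs with known ground truth:
# redundant gene-model sets over toy sequences (a unique intended winner
# per locus plus decoys), BUSCO full_table files realizing planted
# presence/absence pattern frequencies, and bipartite BLAST tables with
# planted reciprocal-best-hit structure plus confounders. Regenerating with
# the same seed reproduces byte-identical files.
#
# Layout guarantees that make the locus ground truth unambiguous by
# construction: every decoy competing for a locus is nested inside the
# winner's gene span (so every covered window at the locus intersects the
# winner, which carries the strictly longest eligible ORF, or wins the
# documented tie-breaks in tie mode), and consecutive loci are separated by
# at least two window widths.

split_len <- function(total, k, min_each = 20L) {
  # random composition of `total` into k parts each >= min_each
  slack <- total - k * min_each
  stopifnot(slack >= 0L)
  cuts <- sort(sample.int(slack + 1L, k - 1L, replace = TRUE) - 1L)
  parts <- diff(c(0L, cuts, slack))
  as.integer(parts + min_each)
}

# Exon matrix of k exons with given lengths starting at `start`, introns
# drawn from intron_range.
make_exons <- function(start, lens, intron_range = c(50L, 300L)) {
  k <- length(lens)
  introns <- if (k > 1L) {
    sample(seq(intron_range[1], intron_range[2]), k - 1L, replace = TRUE)
  } else integer()
  starts <- start + cumsum(c(0L, lens[-k] + introns))
  cbind(start = as.integer(starts), end = as.integer(starts + lens - 1L))
}

# Exons for a model with `orf_aa` amino acids over `k` exons, nested so the
# span fits inside [lo, hi] when possible.
nested_exons <- function(lo, hi, orf_aa, k) {
  total <- 3L * orf_aa
  width_budget <- hi - lo + 1L
  # shrink introns until the model fits inside the host span
  for (max_intron in c(300L, 120L, 60L, 20L, 5L)) {
    lens <- split_len(total, k, min_each = max(10L, total %/% (2L * k)))
    need <- total + (k - 1L) * max_intron
    if (need <= width_budget) {
      off <- sample.int(width_budget - need + 1L, 1L) - 1L
      return(make_exons(lo + off, lens, c(5L, max_intron)))
    }
  }
  make_exons(lo, split_len(total, k, min_each = 5L), c(5L, 5L))
}

#' Generate a redundant gene-model fixture with known winners
#'
#' Builds `n_loci` non-overlapping loci over up to three toy sequences and
#' both strands. Each locus holds one intended winner (3-6 exons, ORF of
#' 100-400 aa, so always eligible) plus 1-5 decoys drawn from: an eligible
#' isoform with a strictly shorter ORF, a 2-exon model with a long ORF, a
#' sub-60-aa model, and a duplicate homology placement; with `tie_mode` an
#' extra eligible decoy with exactly the winner's ORF length but a larger
#' gene start exercises the documented tie-breaks. Competing decoys are
#' nested inside the winner span; occasionally an ineligible decoy is
#' placed beside the winner (non-overlapping) so filter-reason discards
#' occur. Consecutive loci are separated by at least `2 * window_size` bp,
#' making the per-locus ground truth exact by construction.
#'
#' @param n_loci Number of loci (>= 1).
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @param tie_mode Plant exact ORF-length ties (default `FALSE`).
#' @param window_size Window width the layout respects (default 100).
#' @param out_dir If non-`NULL`, write `homology.gff3`, `transcript.gff3`
#'   and `manifest.json` there.
#' @return List with `homology` and `transcript` [annotation_set()]s (model
#'   ids disjoint by construction), `merged` (their union), and `manifest`:
#'   a list with `seed`, a per-locus data frame `loci` (`locus`, `seq_id`,
#'   `strand`, `winner_id`, `n_models`), the winner id vector `winners`,
#'   and per-model ground truth `models` (`model_id`, `locus`, `role`,
#'   `eligible`). If `out_dir` was given, also `files`.
#' @export
gen_locus_set <- function(n_loci, seed = 1, tie_mode = FALSE,
                          window_size = 100, out_dir = NULL) {
  stopifnot(n_loci >= 1)
  with_seed(seed, {
    n_seqs <- min(3L, n_loci)
    seq_ids <- c("chrI", "chrII", "chrIII")[seq_len(n_seqs)]
    cursor <- stats::setNames(rep(1000L, n_seqs), seq_ids)
    models <- list()
    rows <- list()
    model_rows <- list()

    for (locus in seq_len(n_loci)) {
      sid <- seq_ids[((locus - 1L) %% n_seqs) + 1L]
      strand <- if (locus %% 2L == 1L) "+" else "-"
      w_orf <- sample(100:400, 1L)
      w_k <- sample(3:6, 1L)
      w_ex <- make_exons(cursor[[sid]], split_len(3L * w_orf, w_k))
      w_id <- sprintf("l%05d.m0", locus)
      lo <- min(w_ex[, "start"])
      hi <- max(w_ex[, "end"])
      w_ev <- sample(c("homology", "transcript"), 1L)
      w_src <- if (w_ev == "homology") sprintf("PPA%05d", locus)
               else NA_character_
      models[[w_id]] <- gene_model(w_id, sid, strand, w_ex,
                                   evidence = w_ev,
                                   source_protein_id = w_src)
      model_rows[[length(model_rows) + 1L]] <-
        list(w_id, locus, "winner", TRUE)
      locus_end <- hi

      n_dec <- sample(1:5, 1L)
      kinds <- sample(c("short_isoform", "two_exon", "tiny_orf",
                        "homology_dup"), n_dec, replace = TRUE)
      if (tie_mode) kinds <- c(kinds, "tie")
      for (d in seq_along(kinds)) {
        d_id <- sprintf("l%05d.m%d", locus, d)
        kind <- kinds[d]
        offside <- kind %in% c("two_exon", "tiny_orf") &&
          stats::runif(1) < 0.3
        spec <- switch(
          kind,
          short_isoform = list(orf = sample(60:(w_orf - 1L), 1L),
                               k = sample(3:5, 1L), elig = TRUE),
          homology_dup = list(orf = w_orf - sample(1:20, 1L),
                              k = w_k, elig = TRUE),
          two_exon = list(orf = sample(80:300, 1L), k = 2L, elig = FALSE),
          tiny_orf = list(orf = sample(20:59, 1L), k = sample(3:4, 1L),
                          elig = FALSE),
          tie = list(orf = w_orf, k = sample(3:5, 1L), elig = TRUE)
        )
        ex <- if (offside) {
          st <- locus_end + sample(10:50, 1L)
          make_exons(st, split_len(3L * spec$orf, spec$k, min_each = 10L),
                     c(5L, 40L))
        } else if (kind == "tie") {
          # same ORF length, strictly larger gene start: loses the tie
          repeat {
            e <- nested_exons(lo + 1L, hi, spec$orf, spec$k)
            if (min(e[, "start"]) > lo) break
          }
          e
        } else {
          nested_exons(lo, hi, spec$orf, spec$k)
        }
        d_ev <- if (kind == "homology_dup") "homology"
                else sample(c("homology", "transcript"), 1L)
        d_src <- if (d_ev == "homology") {
          if (kind == "homology_dup") w_src %||% sprintf("PPA%05d", locus)
          else sprintf("PPB%05d", locus)
        } else NA_character_
        if (kind == "homology_dup" && is.na(d_src)) {
          d_src <- sprintf("PPA%05d", locus)
        }
        models[[d_id]] <- gene_model(d_id, sid, strand, ex,
                                     evidence = d_ev,
                                     source_protein_id = d_src)
        model_rows[[length(model_rows) + 1L]] <-
          list(d_id, locus, kind, spec$elig)
        locus_end <- max(locus_end, max(ex[, "end"]))
      }
      rows[[locus]] <- list(locus, sid, strand, w_id, length(kinds) + 1L)
      cursor[[sid]] <- locus_end + 2L * window_size + 100L +
        sample(0:100, 1L)
    }

    loci <- data.frame(
      locus = vapply(rows, `[[`, 0L, 1L),
      seq_id = vapply(rows, `[[`, "", 2L),
      strand = vapply(rows, `[[`, "", 3L),
      winner_id = vapply(rows, `[[`, "", 4L),
      n_models = vapply(rows, function(r) as.integer(r[[5L]]), 0L),
      stringsAsFactors = FALSE
    )
    mtab <- data.frame(
      model_id = vapply(model_rows, `[[`, "", 1L),
      locus = vapply(model_rows, function(r) as.integer(r[[2L]]), 0L),
      role = vapply(model_rows, `[[`, "", 3L),
      eligible = vapply(model_rows, `[[`, TRUE, 4L),
      stringsAsFactors = FALSE
    )
    ev <- vapply(models, `[[`, "", "evidence")
    hom <- annotation_set(unname(models[ev == "homology"]), "toy")
    tra <- annotation_set(unname(models[ev == "transcript"]), "toy")
    merged <- merge_evidence(hom, tra, prefix = FALSE)
    manifest <- list(seed = seed, tie_mode = tie_mode,
                     window_size = window_size, n_loci = n_loci,
                     loci = loci, winners = loci$winner_id, models = mtab)
    out <- list(homology = hom, transcript = tra, merged = merged,
                manifest = manifest)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- c(homology = file.path(out_dir, "homology.gff3"),
                 transcript = file.path(out_dir, "transcript.gff3"),
                 manifest = file.path(out_dir, "manifest.json"))
      write_gff3(hom, files[["homology"]])
      write_gff3(tra, files[["transcript"]])
      jsonlite::write_json(manifest, files[["manifest"]],
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out$files <- files
    }
    out
  })
}

#' Generate BUSCO full_table fixtures with planted patterns
#'
#' Realizes the requested presence/absence pattern frequencies across a set
#' of genomes as per-genome full_table files. Present cells are written as
#' `Complete` rows (a configurable fraction as duplicated pairs of
#' `Duplicated` rows); absent cells as `Missing` rows (a configurable
#' fraction as `Fragmented`, which the default presence rule also treats as
#' absent).
#'
#' @param pattern_freqs Named integer vector: pattern bitstring (one
#'   character per genome, `"1"` = present) -> number of genes.
#' @param seed RNG seed.
#' @param genome_ids Optional genome names; default `genome01`, ...
#' @param dup_fraction Fraction of present cells rendered as Duplicated.
#' @param frag_fraction Fraction of absent cells rendered as Fragmented.
#' @param out_dir If non-`NULL`, write `full_table_<genome>.tsv` files.
#' @return List with `tables` (named list of [busco_records()]),
#'   `manifest` (`seed`, `genes` data frame with `busco_id` and `pattern`,
#'   `pattern_freqs`), and `files` when written.
#' @export
gen_busco_tables <- function(pattern_freqs, seed = 1, genome_ids = NULL,
                             dup_fraction = 0.1, frag_fraction = 0.2,
                             out_dir = NULL) {
  pats <- names(pattern_freqs)
  stopifnot(!is.null(pats), all(grepl("^[01]+$", pats)))
  if (length(unique(nchar(pats))) != 1L) {
    stopf("inconsistent pattern bitstring lengths: %s",
          paste(unique(nchar(pats)), collapse = ", "))
  }
  n_genomes <- nchar(pats[1L])
  if (is.null(genome_ids)) genome_ids <- sprintf("genome%02d", 1:n_genomes)
  stopifnot(length(genome_ids) == n_genomes)
  with_seed(seed, {
    gene_pattern <- sample(rep(pats, times = pattern_freqs))
    genes <- sprintf("busco%05d", seq_along(gene_pattern))
    tables <- list()
    for (j in seq_len(n_genomes)) {
      present <- substring(gene_pattern, j, j) == "1"
      rows <- list()
      for (i in seq_along(genes)) {
        if (present[i]) {
          dup <- stats::runif(1) < dup_fraction
          score <- round(stats::runif(1, 200, 900), 1)
          len <- sample(100:2000, 1L)
          if (dup) {
            rows[[length(rows) + 1L]] <- list(genes[i], "Duplicated",
                                              sprintf("%s_p1", genes[i]),
                                              score, len)
            rows[[length(rows) + 1L]] <- list(genes[i], "Duplicated",
                                              sprintf("%s_p2", genes[i]),
                                              score - 1, len)
          } else {
            rows[[length(rows) + 1L]] <- list(genes[i], "Complete",
                                              sprintf("%s_p1", genes[i]),
                                              score, len)
          }
        } else if (stats::runif(1) < frag_fraction) {
          rows[[length(rows) + 1L]] <- list(genes[i], "Fragmented",
                                            sprintf("%s_p1", genes[i]),
                                            round(stats::runif(1, 50, 199),
                                                  1),
                                            sample(30:99, 1L))
        } else {
          rows[[length(rows) + 1L]] <- list(genes[i], "Missing",
                                            NA_character_, NA_real_,
                                            NA_integer_)
        }
      }
      tables[[genome_ids[j]]] <- busco_records(
        busco_id = vapply(rows, `[[`, "", 1L),
        status = vapply(rows, `[[`, "", 2L),
        sequence = vapply(rows, `[[`, "", 3L),
        score = vapply(rows, function(r) as.numeric(r[[4L]]), 0),
        length = vapply(rows, function(r) as.integer(r[[5L]]), 0L)
      )
    }
    manifest <- list(seed = seed,
                     genes = data.frame(busco_id = genes,
                                        pattern = gene_pattern,
                                        stringsAsFactors = FALSE),
                     pattern_freqs = as.list(pattern_freqs))
    out <- list(tables = tables, manifest = manifest)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- stats::setNames(
        file.path(out_dir, sprintf("full_table_%s.tsv", genome_ids)),
        genome_ids)
      for (g in genome_ids) {
        write_busco_table(tables[[g]], files[[g]])
      }
      out$files <- files
    }
    out
  })
}

# full_table writer used by the fixture generator (protein-mode layout).
write_busco_table <- function(records, path) {
  hdr <- c("# BUSCO was run in mode: proteins",
           "# Busco id\tStatus\tSequence\tScore\tLength")
  fmt <- function(r) {
    if (r$status == "Missing") {
      paste(r$busco_id, r$status, sep = "\t")
    } else {
      paste(r$busco_id, r$status, r$sequence,
            sprintf("%.1f", r$score), r$length, sep = "\t")
    }
  }
  body <- vapply(seq_len(nrow(records)),
                 function(i) fmt(records[i, ]), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con = con, sep = "\n")
  invisible(path)
}

#' Generate bipartite BLAST tables with planted RBH structure
#'
#' Emits forward (reference -> target) and reverse (target -> reference)
#' BLASTP tabular fixtures in which a chosen fraction of reference proteins
#' has a planted mutual-best partner whose bitscore is a strict maximum in
#' both directions. Confounders: one-way bests (the reverse best points at
#' a different, planted reference), mutual pairs below the e-value cutoff
#' (`evalue = 1e-3`), extra lower-bitscore HSP rows for some planted pairs,
#' and background hits that are never best in the reverse direction.
#'
#' @param n_ref,n_target Proteome sizes.
#' @param rbh_fraction Fraction of reference proteins with a planted
#'   reciprocal-best partner.
#' @param seed RNG seed.
#' @param n_subthreshold Planted mutual pairs at `evalue = 1e-3` (excluded
#'   at the default cutoff).
#' @param n_oneway Planted one-way bests.
#' @param n_background Background hit rows per direction.
#' @param out_dir If non-`NULL`, write `fwd.tsv` and `rev.tsv`.
#' @return List with `fwd`, `rev` (`blast_hits` data frames), `manifest`
#'   (`planted_pairs`, `subthreshold_pairs`, `oneway`, `query_lengths`),
#'   and `files` when written.
#' @export
gen_blast_tables <- function(n_ref = 200, n_target = 200,
                             rbh_fraction = 0.5, seed = 1,
                             n_subthreshold = 5, n_oneway = 10,
                             n_background = 300, out_dir = NULL) {
  stopifnot(rbh_fraction >= 0, rbh_fraction <= 1)
  with_seed(seed, {
    refs <- sprintf("ref%04d", seq_len(n_ref))
    tgts <- sprintf("tgt%04d", seq_len(n_target))
    ref_len <- stats::setNames(sample(120:1200, n_ref, replace = TRUE),
                               refs)
    m <- round(rbh_fraction * n_ref)
    m <- min(m, n_target)
    paired_ref <- sample(refs, m)
    paired_tgt <- sample(tgts, m)

    mk_row <- function(q, s, bit, evalue, qlen) {
      aln <- max(30L, as.integer(round(qlen * stats::runif(1, 0.5, 1))))
      pid <- round(stats::runif(1, 35, 98), 1)
      list(q, s, pid, aln, as.integer(round(aln * (1 - pid / 100))),
           sample(0:3, 1L), 1L, aln, 1L, aln, evalue, bit)
    }
    fwd <- list()
    rev <- list()
    add <- function(side, row) {
      if (side == "fwd") fwd[[length(fwd) + 1L]] <<- row
      else rev[[length(rev) + 1L]] <<- row
    }
    rnd_evalue <- function() 10^-sample(20:80, 1L)

    planted_bit <- numeric(m)
    for (i in seq_len(m)) {
      bit <- round(stats::runif(1, 250, 600), 1)
      planted_bit[i] <- bit
      add("fwd", mk_row(paired_ref[i], paired_tgt[i], bit, rnd_evalue(),
                        ref_len[[paired_ref[i]]]))
      add("rev", mk_row(paired_tgt[i], paired_ref[i],
                        round(bit + stats::runif(1, -5, 5), 1),
                        rnd_evalue(), ref_len[[paired_ref[i]]]))
      if (stats::runif(1) < 0.15) {  # extra lower-bitscore HSP row
        add("fwd", mk_row(paired_ref[i], paired_tgt[i],
                          round(bit * stats::runif(1, 0.3, 0.7), 1),
                          rnd_evalue(), ref_len[[paired_ref[i]]]))
      }
    }

    free_ref <- setdiff(refs, paired_ref)
    free_tgt <- setdiff(tgts, paired_tgt)
    ns <- min(n_subthreshold, length(free_ref), length(free_tgt))
    sub_ref <- utils::head(free_ref, ns)
    sub_tgt <- utils::head(free_tgt, ns)
    for (i in seq_len(ns)) {
      bit <- round(stats::runif(1, 100, 200), 1)
      add("fwd", mk_row(sub_ref[i], sub_tgt[i], bit, 1e-3,
                        ref_len[[sub_ref[i]]]))
      add("rev", mk_row(sub_tgt[i], sub_ref[i], bit, 1e-3,
                        ref_len[[sub_ref[i]]]))
    }
    free_ref <- setdiff(free_ref, sub_ref)
    free_tgt <- setdiff(free_tgt, sub_tgt)

    no <- min(n_oneway, length(free_ref), length(free_tgt),
              length(paired_ref))
    ow_ref <- utils::head(free_ref, no)
    ow_tgt <- utils::head(free_tgt, no)
    ow_back <- if (no > 0L) sample(paired_ref, no) else character()
    for (i in seq_len(no)) {
      bit <- round(stats::runif(1, 150, 240), 1)
      add("fwd", mk_row(ow_ref[i], ow_tgt[i], bit, rnd_evalue(),
                        ref_len[[ow_ref[i]]]))
      add("rev", mk_row(ow_tgt[i], ow_ref[i],
                        round(bit * 0.8, 1), rnd_evalue(),
                        ref_len[[ow_ref[i]]]))
      add("rev", mk_row(ow_tgt[i], ow_back[i],
                        round(bit * 1.2, 1), rnd_evalue(),
                        ref_len[[ow_back[i]]]))
    }

    if (n_background > 0L && m > 0L) {
      bg_floor <- min(c(planted_bit,
                        rep(Inf, as.integer(m == 0L)))) * 0.4
      for (i in seq_len(n_background)) {
        q <- sample(refs, 1L)
        s <- sample(tgts, 1L)
        bit <- round(stats::runif(1, 30, max(31, bg_floor)), 1)
        add("fwd", mk_row(q, s, bit, rnd_evalue(), ref_len[[q]]))
        # reverse background only from planted targets, below their best
        qt <- sample(paired_tgt, 1L)
        st <- sample(refs, 1L)
        add("rev", mk_row(qt, st, round(stats::runif(1, 30, 60), 1),
                          rnd_evalue(), ref_len[[st]]))
      }
    }

    as_hits <- function(rows) {
      if (length(rows) == 0L) {
        h <- data.frame(matrix(nrow = 0L, ncol = 12L,
                               dimnames = list(NULL, blast_tab_columns)))
        class(h) <- c("blast_hits", "data.frame")
        return(h)
      }
      m2 <- do.call(rbind, lapply(rows, function(r) {
        data.frame(query_id = r[[1]], subject_id = r[[2]],
                   pct_identity = r[[3]], aln_len = r[[4]],
                   mismatch = r[[5]], gapopen = r[[6]], qstart = r[[7]],
                   qend = r[[8]], sstart = r[[9]], send = r[[10]],
                   evalue = r[[11]], bitscore = r[[12]],
                   stringsAsFactors = FALSE)
      }))
      rownames(m2) <- NULL
      class(m2) <- c("blast_hits", "data.frame")
      m2
    }
    fwd_df <- as_hits(fwd)
    rev_df <- as_hits(rev)
    manifest <- list(
      seed = seed,
      planted_pairs = data.frame(query_id = paired_ref,
                                 subject_id = paired_tgt,
                                 stringsAsFactors = FALSE),
      subthreshold_pairs = data.frame(query_id = sub_ref,
                                      subject_id = sub_tgt,
                                      stringsAsFactors = FALSE),
      oneway = data.frame(query_id = ow_ref, subject_id = ow_tgt,
                          stringsAsFactors = FALSE),
      query_lengths = ref_len
    )
    out <- list(fwd = fwd_df, rev = rev_df, manifest = manifest)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- c(fwd = file.path(out_dir, "fwd.tsv"),
                 rev = file.path(out_dir, "rev.tsv"))
      write_blast_tab(fwd_df, files[["fwd"]])
      write_blast_tab(rev_df, files[["rev"]])
      out$files <- files
    }
    out
  })
}

#' Generate random transcript sequences
#'
#' Random `A/C/G/T` transcripts (with an optional sprinkling of `N`) for
#' exercising the ORF extractor; sequence realism is unnecessary for the
#' coordinate-driven selector, so these are only used on the six-frame
#' translation path.
#'
#' @param n Number of transcripts.
#' @param len_range Length range in nt.
#' @param seed RNG seed.
#' @param n_fraction Per-base probability of an `N`.
#' @return Named [Biostrings::DNAStringSet].
#' @export
gen_transcripts <- function(n, len_range = c(1000, 2000), seed = 1,
                            n_fraction = 0.002) {
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      len <- sample(len_range[1]:len_range[2], 1L)
      base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      nn <- stats::runif(len) < n_fraction
      base[nn] <- "N"
      paste(base, collapse = "")
    }, "")
    names(seqs) <- sprintf("tx%04d", seq_len(n))
    Biostrings::DNAStringSet(seqs)
  })
}
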