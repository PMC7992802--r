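# Independent oracle implementations used to validate the package: a naive
# re-implementation of the greedy selector (recomputes candidate and
# overlap sets from scratch at every step, no incremental state), a
# hand-coded six-frame translator/ORF enumerator, a double-loop
# reciprocal-best-hit finder, and a brute-force window tally. These share
# no logic with the package beyond reading its plain data frames.

radix_order <- function(...) order(..., method = "radix")

# ---- naive greedy selector ------------------------------------------------

naive_select <- function(set, window_size = 100, min_orf_aa = 60,
                         min_exons = 3) {
  m <- set$models
  ex <- set$exons
  n <- nrow(m)
  # recompute per-model facts from the exon table alone
  exl <- split(ex, ex$model_id)
  lo <- hi <- nex <- orf <- integer(n)
  for (i in seq_len(n)) {
    e <- exl[[m$model_id[i]]]
    lo[i] <- min(e$start); hi[i] <- max(e$end)
    nex[i] <- nrow(e)
    orf[i] <- floor(sum(e$end - e$start + 1) / 3)
  }
  seqs <- m$seq_id; strands <- m$strand; ids <- m$model_id

  # window tally over every exon boundary of every model
  wkey <- character(); wcount <- integer()
  tal <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    e <- exl[[ids[i]]]
    for (coord in c(e$start, e$end)) {
      k <- paste(seqs[i], strands[i], floor((coord - 1) / window_size),
                 sep = "\t")
      tal[[k]] <- (if (is.null(tal[[k]])) 0L else tal[[k]]) + 1L
    }
  }
  keys <- ls(tal)
  parts <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
  wdf <- data.frame(seq = parts[, 1], strand = parts[, 2],
                    win = as.integer(parts[, 3]),
                    count = vapply(keys, function(k) tal[[k]], 0L),
                    stringsAsFactors = FALSE)
  wdf <- wdf[radix_order(-wdf$count, wdf$seq, wdf$win,
                         match(wdf$strand, c("+", "-"))), , drop = FALSE]

  state <- rep("open", n)
  reason <- rep(NA_character_, n)
  chosen_log <- character()
  eligible <- nex >= min_exons & orf >= min_orf_aa
  for (r in seq_len(nrow(wdf))) {
    ws <- wdf$win[r] * window_size + 1L
    we <- ws + window_size - 1L
    cand <- which(state == "open" & seqs == wdf$seq[r] &
                    strands == wdf$strand[r] &
                    lo <= we & hi >= ws & eligible)
    if (length(cand) == 0L) next
    pick <- cand[radix_order(-orf[cand], lo[cand], ids[cand])][1L]
    state[pick] <- "selected"
    victims <- which(state == "open" & seqs == seqs[pick] &
                       strands == strands[pick] &
                       lo <= hi[pick] & hi >= lo[pick])
    state[victims] <- "discarded"
    reason[victims] <- "overlap_with_selected"
    chosen_log <- c(chosen_log, ids[pick])
  }
  left <- which(state == "open")
  state[left] <- "discarded"
  reason[left] <- ifelse(nex[left] < min_exons, "filter_exons",
                         "filter_orf_len")
  sel <- sort(ids[state == "selected"], method = "radix")
  disc <- data.frame(model_id = ids[state == "discarded"],
                     reason = reason[state == "discarded"],
                     stringsAsFactors = FALSE)
  disc <- disc[radix_order(disc$model_id), , drop = FALSE]
  rownames(disc) <- NULL
  list(selected = sel, discarded = disc, chosen = chosen_log)
}

expect_selector_matches_oracle <- function(set, ...) {
  got <- select_nonredundant(set, ...)
  want <- naive_select(set, ...)
  expect_identical(sort(got$selected$models$model_id, method = "radix"),
                   want$selected)
  got_disc <- got$discarded[radix_order(got$discarded$model_id), ,
                            drop = FALSE]
  rownames(got_disc) <- NULL
  expect_identical(got_disc, want$discarded)
  expect_identical(got$audit$chosen, want$chosen)
  invisible(got)
}

# ---- hand-coded six-frame ORF enumerator ----------------------------------

.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- character(64)
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

brute_translate <- function(nt) {
  n_codons <- nchar(nt) %/% 3L
  if (n_codons == 0L) return("")
  out <- character(n_codons)
  for (j in seq_len(n_codons)) {
    codon <- substr(nt, 3L * j - 2L, 3L * j)
    out[j] <- if (grepl("N", codon)) "X"
              else .codon_table[[codon]]
  }
  paste(out, collapse = "")
}

brute_revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "")[[1]]),
        collapse = "")
}

# All maximal stop-free stretches >= min_len across six frames; run bounds
# found with rle over the per-codon stop indicator.
brute_orfs <- function(seqs, min_len = 40) {
  out <- list()
  for (id in names(seqs)) {
    for (strand in c("+", "-")) {
      nt <- if (strand == "+") seqs[[id]] else brute_revcomp(seqs[[id]])
      for (frame in 0:2) {
        aa <- brute_translate(substring(nt, frame + 1L))
        if (nchar(aa) == 0L) next
        is_stop <- strsplit(aa, "")[[1]] == "*"
        r <- rle(is_stop)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in seq_along(r$values)) {
          if (r$values[k] || r$lengths[k] < min_len) next
          out[[length(out) + 1L]] <- data.frame(
            transcript_id = id, strand = strand, frame = frame,
            aa_start = starts[k] - 1L, aa_end = ends[k],
            sequence = substr(aa, starts[k], ends[k]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), aa_start = integer(),
                      aa_end = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[radix_order(res$transcript_id, res$strand, res$frame,
                  res$aa_start), , drop = FALSE]
}

normalize_orfs <- function(orfs) {
  df <- as.data.frame(orfs)[, c("transcript_id", "strand", "frame",
                                "aa_start", "aa_end", "sequence")]
  df <- df[radix_order(df$transcript_id, df$strand, df$frame,
                       df$aa_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- double-loop reciprocal best hits -------------------------------------

brute_best <- function(hits, max_evalue) {
  hits <- hits[hits$evalue < max_evalue, , drop = FALSE]
  best <- list()
  for (i in seq_len(nrow(hits))) {
    q <- hits$query_id[i]
    b <- best[[q]]
    if (is.null(b)) { best[[q]] <- hits[i, ]; next }
    better <- hits$bitscore[i] > b$bitscore ||
      (hits$bitscore[i] == b$bitscore && hits$evalue[i] < b$evalue) ||
      (hits$bitscore[i] == b$bitscore && hits$evalue[i] == b$evalue &&
         hits$subject_id[i] < b$subject_id)
    if (better) best[[q]] <- hits[i, ]
  }
  best
}

brute_rbh <- function(fwd, rev, max_evalue = 1e-4) {
  fb <- brute_best(fwd, max_evalue)
  rb <- brute_best(rev, max_evalue)
  pairs <- character()
  for (q in names(fb)) {
    s <- fb[[q]]$subject_id
    if (!is.null(rb[[s]]) && rb[[s]]$subject_id == q) {
      pairs <- c(pairs, paste(q, s))
    }
  }
  sort(pairs, method = "radix")
}

# ---- misc -----------------------------------------------------------------

brute_window_tally <- function(set, window_size = 100) {
  counts <- list()
  for (i in seq_len(nrow(set$exons))) {
    mid <- set$exons$model_id[i]
    row <- set$models[set$models$model_id == mid, ]
    for (coord in c(set$exons$start[i], set$exons$end[i])) {
      key <- paste(row$seq_id, row$strand,
                   floor((coord - 1) / window_size))
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random annotation set independent of the locus generator's layout
# guarantees (models may overlap arbitrarily): used for I/O round trips and
# index checks.
random_set <- function(n_models, seed, n_seqs = 2, max_coord = 50000) {
  set.seed(seed)
  models <- lapply(seq_len(n_models), function(i) {
    k <- sample(1:6, 1)
    lens <- sample(10:300, k, replace = TRUE)
    gaps <- if (k > 1) sample(1:500, k - 1, replace = TRUE) else integer()
    start <- sample(1:max_coord, 1)
    starts <- start + cumsum(c(0L, lens[-k] + gaps))
    ev <- sample(c("homology", "transcript"), 1)
    gene_model(sprintf("rm%04d", i),
               sprintf("seq%d", sample(n_seqs, 1)),
               sample(c("+", "-"), 1),
               cbind(starts, starts + lens - 1L),
               evidence = ev,
               source_protein_id = if (ev == "homology")
                 sprintf("P%04d", i) else NA_character_)
  })
  annotation_set(models, genome_id = "rand")
}

# Model-level equality of annotation sets (ids, structure, evidence).
expect_sets_equal <- function(a, b) {
  norm <- function(s) {
    m <- s$models[radix_order(s$models$model_id), , drop = FALSE]
    rownames(m) <- NULL
    e <- s$exons[radix_order(s$exons$model_id, s$exons$start), ,
                 drop = FALSE]
    rownames(e) <- NULL
    list(models = m, exons = e)
  }
  expect_equal(norm(a), norm(b))
}
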