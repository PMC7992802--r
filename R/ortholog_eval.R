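# Comparative evaluation toolkit: BUSCO presence/absence patterns across
# genomes, best-reciprocal BLASTP hits, rescue of genes a completeness
# pipeline reports missing, and alignment-metric matrices with matched
# downsampling.

#' Presence/absence pattern matrix from BUSCO tables
#'
#' Summarizes per-genome BUSCO classifications into a binary gene-by-genome
#' presence matrix and tallies the row patterns. A gene counts as present
#' in a genome when any of its records there has a status in
#' `present_statuses` (default Complete or Duplicated; Fragmented counts as
#' absent). The gene universe is the union of BUSCO ids across tables.
#'
#' @param tables Named list, one [busco_records()] data frame per genome;
#'   names are the genome ids and define column order.
#' @param present_statuses Statuses treated as presence.
#' @param top_k How many most-abundant patterns to report (default 20).
#' @return Object of class `pattern_matrix`:
#' \describe{
#'   \item{genomes, genes}{ordered ids (genes in C-locale sort order).}
#'   \item{matrix}{binary integer matrix, genes x genomes.}
#'   \item{pattern_tally}{named integer vector, pattern bitstring -> count,
#'     sorted by decreasing count then pattern; sums to the gene count.}
#'   \item{top_patterns}{data frame of the `top_k` most abundant patterns.}
#'   \item{missing_in_all}{genes with the all-zeros pattern.}
#' }
#' @export
presence_matrix <- function(tables,
                            present_statuses = c("Complete", "Duplicated"),
                            top_k = 20) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  present_statuses <- canonical_busco_status(present_statuses)
  genomes <- names(tables)
  genes <- unique(unlist(lapply(tables, function(tb) tb$busco_id)))
  genes <- genes[c_order(genes)]
  mat <- matrix(0L, nrow = length(genes), ncol = length(genomes),
                dimnames = list(genes, genomes))
  for (g in genomes) {
    tb <- tables[[g]]
    present <- unique(tb$busco_id[tb$status %in% present_statuses])
    mat[match(present, genes), g] <- 1L
  }
  patterns <- apply(mat, 1L, paste, collapse = "")
  tally <- table(patterns)
  counts <- as.integer(tally)
  names(counts) <- names(tally)
  counts <- counts[c_order(-counts, names(counts))]
  top <- utils::head(
    data.frame(pattern = names(counts), count = unname(counts),
               stringsAsFactors = FALSE),
    top_k)
  structure(
    list(genomes = genomes, genes = genes, matrix = mat,
         pattern_tally = counts, top_patterns = top,
         missing_in_all = genes[rowSums(mat) == 0L]),
    class = "pattern_matrix"
  )
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat(sprintf("<pattern_matrix> %d genes x %d genomes; %d pattern(s)\n",
              length(x$genes), length(x$genomes), length(x$pattern_tally)))
  all_ones <- x$pattern_tally[strrep("1", length(x$genomes))]
  cat(sprintf("  present in all: %d; missing in all: %d\n",
              if (is.na(all_ones)) 0L else unname(all_ones),
              length(x$missing_in_all)))
  invisible(x)
}

#' Best-reciprocal BLASTP hits between two proteomes
#'
#' Filters both hit tables at a strict e-value cutoff, keeps per query the
#' single best hit by bitscore (ties: lower e-value, then lexicographically
#' smaller subject id), and emits a pair when the two directions agree.
#' When one query has several HSP rows to the same subject, the
#' highest-bitscore row represents the pair.
#'
#' @param fwd Hits reference -> target (`blast_hits` data frame).
#' @param rev Hits target -> reference.
#' @param max_evalue Strict e-value cutoff: hits with
#'   `evalue >= max_evalue` are removed (default 1e-4).
#' @return Data frame of class `ortholog_pairs`, sorted by `query_id`, with
#'   columns `query_id`, `subject_id` and the bitscore/e-value of the two
#'   supporting hits (`fwd_bitscore`, `fwd_evalue`, `rev_bitscore`,
#'   `rev_evalue`).
#' @export
reciprocal_best_hits <- function(fwd, rev, max_evalue = 1e-4) {
  best_by_query <- function(hits) {
    hits <- hits[hits$evalue < max_evalue, , drop = FALSE]
    if (nrow(hits) == 0L) return(hits)
    ord <- c_order(hits$query_id, -hits$bitscore, hits$evalue,
                   hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    hits[!duplicated(hits$query_id), , drop = FALSE]
  }
  fb <- best_by_query(fwd)
  rb <- best_by_query(rev)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      fwd_bitscore = numeric(), fwd_evalue = numeric(),
                      rev_bitscore = numeric(), rev_evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(fb) == 0L || nrow(rb) == 0L) {
    class(empty) <- c("ortholog_pairs", "data.frame")
    return(empty)
  }
  back <- rb$subject_id[match(fb$subject_id, rb$query_id)]
  mutual <- !is.na(back) & back == fb$query_id
  fb <- fb[mutual, , drop = FALSE]
  if (nrow(fb) == 0L) {
    class(empty) <- c("ortholog_pairs", "data.frame")
    return(empty)
  }
  ri <- match(fb$subject_id, rb$query_id)
  out <- data.frame(query_id = fb$query_id, subject_id = fb$subject_id,
                    fwd_bitscore = fb$bitscore, fwd_evalue = fb$evalue,
                    rev_bitscore = rb$bitscore[ri],
                    rev_evalue = rb$evalue[ri],
                    stringsAsFactors = FALSE)
  out <- out[c_order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}

#' Rescue genes reported missing everywhere via reciprocal best hits
#'
#' For the genes whose presence pattern is all-zeros (missing in every
#' genome), counts how many have a best-reciprocal-hit ortholog in every
#' genome — evidence that the gene is present but eluded the completeness
#' pipeline. Genes without a protein mapping are listed as unmapped and
#' excluded from the denominator with a warning.
#'
#' @param pattern A [presence_matrix()] result.
#' @param rbh_by_genome Named list, one [reciprocal_best_hits()] pair table
#'   per genome (names must cover `pattern$genomes`).
#' @param busco_to_protein Named character vector (or two-column data
#'   frame `busco_id`, `protein_id`) mapping BUSCO gene ids to reference
#'   protein ids, as used for the `query_id` side of the pair tables.
#' @return Object of class `rescue_report`: per-gene table (`busco_id`,
#'   `protein_id`, `n_genomes_rbh`, `rescued_all`), plus `n_missing_all`,
#'   `n_rescued_all`, `n_partial`, `fraction` (unrounded) and `unmapped`.
#' @export
rescue_missing <- function(pattern, rbh_by_genome, busco_to_protein) {
  stopifnot(inherits(pattern, "pattern_matrix"))
  missing_genomes <- setdiff(pattern$genomes, names(rbh_by_genome))
  if (length(missing_genomes) > 0L) {
    stopf("no RBH table for genome(s): %s",
          paste(missing_genomes, collapse = ", "))
  }
  if (is.data.frame(busco_to_protein)) {
    map <- stats::setNames(as.character(busco_to_protein[[2L]]),
                           as.character(busco_to_protein[[1L]]))
  } else {
    map <- busco_to_protein
  }
  miss <- pattern$missing_in_all
  prot <- unname(map[miss])
  unmapped <- miss[is.na(prot)]
  if (length(unmapped) > 0L) {
    warnf("%d missing-in-all gene(s) without protein mapping excluded: %s",
          length(unmapped), paste(unmapped, collapse = ", "))
  }
  keep <- !is.na(prot)
  miss <- miss[keep]
  prot <- prot[keep]
  n_hit <- vapply(prot, function(p) {
    sum(vapply(pattern$genomes, function(g) {
      p %in% rbh_by_genome[[g]]$query_id
    }, TRUE))
  }, 0L)
  per_gene <- data.frame(busco_id = miss, protein_id = prot,
                         n_genomes_rbh = n_hit,
                         rescued_all = n_hit == length(pattern$genomes),
                         stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  structure(
    list(per_gene = per_gene,
         n_missing_all = length(miss),
         n_rescued_all = sum(per_gene$rescued_all),
         n_partial = sum(n_hit > 0L & !per_gene$rescued_all),
         fraction = if (length(miss)) sum(per_gene$rescued_all) /
           length(miss) else NA_real_,
         unmapped = unmapped),
    class = "rescue_report"
  )
}

#' @export
print.rescue_report <- function(x, ...) {
  cat(sprintf(paste0("<rescue_report> %d missing in all genomes; ",
                     "%d (%.1f%%) with RBH support in every genome; ",
                     "%d partial\n"),
              x$n_missing_all, x$n_rescued_all,
              100 * (x$fraction %||% NA_real_), x$n_partial))
  invisible(x)
}

metric_names <- c("bitscore", "aln_len", "pct_identity",
                  "normalized_bitscore", "aligned_proportion")

#' Alignment-metric matrices for gene sets across genomes
#'
#' For each named gene set, builds five gene-by-genome matrices from the
#' best BLASTP hit of each gene in each genome: raw `bitscore`, alignment
#' length `aln_len`, `pct_identity`, length-normalized bitscore
#' (`bitscore / aln_len`) and `aligned_proportion`
#' (`aln_len / query protein length`). Cells without a hit are `NA`, never
#' zero. When a query has several rows in a table, the highest-bitscore
#' row is used.
#'
#' @param hits Named list, one `blast_hits` data frame per genome (query
#'   ids are reference protein/gene ids).
#' @param query_lengths Named numeric vector: reference protein lengths in
#'   amino acids. A gene with hits but no length is an error naming it.
#' @param gene_sets Named list of character vectors of query ids (e.g. the
#'   completeness-pipeline orthologs vs the reciprocal-best-hit rescues).
#' @return Object of class `metric_matrices`: per gene set, a list of the
#'   five matrices.
#' @export
metric_matrices <- function(hits, query_lengths, gene_sets) {
  stopifnot(!is.null(names(hits)), !is.null(names(gene_sets)))
  genomes <- names(hits)
  best <- lapply(hits, function(h) {
    ord <- c_order(h$query_id, -h$bitscore, h$evalue, h$subject_id)
    h <- h[ord, , drop = FALSE]
    h[!duplicated(h$query_id), , drop = FALSE]
  })
  out <- lapply(gene_sets, function(genes) {
    mats <- lapply(metric_names, function(nm) {
      matrix(NA_real_, nrow = length(genes), ncol = length(genomes),
             dimnames = list(genes, genomes))
    })
    names(mats) <- metric_names
    for (g in genomes) {
      h <- best[[g]]
      idx <- match(genes, h$query_id)
      hit <- !is.na(idx)
      if (!any(hit)) next
      no_len <- genes[hit][!(genes[hit] %in% names(query_lengths))]
      if (length(no_len) > 0L) {
        stopf("query length missing for gene(s) with hits: %s",
              paste(unique(no_len), collapse = ", "))
      }
      hi <- idx[hit]
      mats$bitscore[hit, g] <- h$bitscore[hi]
      mats$aln_len[hit, g] <- h$aln_len[hi]
      mats$pct_identity[hit, g] <- h$pct_identity[hi]
      mats$normalized_bitscore[hit, g] <- h$bitscore[hi] / h$aln_len[hi]
      mats$aligned_proportion[hit, g] <-
        h$aln_len[hi] / query_lengths[genes[hit]]
    }
    mats
  })
  structure(out, class = "metric_matrices")
}

#' Matched downsampling of a gene set
#'
#' Draws `n_reps` uniform without-replacement samples of `target_size`
#' genes, reproducibly from `seed`. Used to compare metric distributions of
#' a large gene set against a smaller one at equal sample size.
#'
#' @param genes Character vector.
#' @param target_size Sample size; must not exceed `length(genes)`.
#' @param n_reps Number of replicates.
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return List of `n_reps` character vectors.
#' @export
subsample_matched <- function(genes, target_size, n_reps, seed) {
  if (target_size > length(genes)) {
    stopf("target_size (%d) exceeds gene set size (%d)",
          target_size, length(genes))
  }
  with_seed(seed, lapply(seq_len(n_reps), function(i) {
    sample(genes, target_size, replace = FALSE)
  }))
}
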