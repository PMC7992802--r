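#' Construct a single gene model
#'
#' A gene model is one candidate gene structure: an ordered set of exons
#' (CDS spans) on one strand of one genomic sequence, together with the
#' evidence track it came from. The ORF length in amino acids is always
#' derived from the spans as `floor(total CDS length / 3)`; this single rule
#' makes homology- and transcript-derived models directly comparable and is
#' the quantity the non-redundant selector maximizes. Stop codons are not
#' subtracted.
#'
#' @param model_id Unique model identifier.
#' @param seq_id Genomic sequence (chromosome/contig) identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of 1-based inclusive
#'   `(start, end)` coordinates. Rows are sorted by start and must not
#'   overlap.
#' @param evidence `"homology"` or `"transcript"`.
#' @param source_protein_id Optional identifier of the protein whose spliced
#'   alignment produced a homology model.
#' @return An object of class `gene_model`: a list with fields `model_id`,
#'   `seq_id`, `strand`, `exons` (integer matrix with columns `start`,
#'   `end`), `evidence`, `orf_len_aa`, `source_protein_id`.
#' @examples
#' gm <- gene_model("m1", "chrI", "+",
#'                  cbind(start = c(101, 301, 501), end = c(190, 360, 512)),
#'                  evidence = "transcript")
#' gm$orf_len_aa  # floor((90 + 60 + 12) / 3) = 54
#' @export
gene_model <- function(model_id, seq_id, strand, exons,
                       evidence = c("transcript", "homology"),
                       source_protein_id = NA_character_) {
  evidence <- match.arg(evidence)
  if (!strand %in% c("+", "-")) {
    stopf("gene model '%s': strand must be '+' or '-', got '%s'",
          model_id, strand)
  }
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L || nrow(exons) < 1L) {
    stopf("gene model '%s': exons must be a non-empty 2-column matrix",
          model_id)
  }
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  exons <- exons[c_order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "start"] > exons[, "end"])) {
    stopf("gene model '%s': exon start > end", model_id)
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] <= exons[-nrow(exons), "end"])) {
    stopf("gene model '%s': exons overlap", model_id)
  }
  structure(
    list(
      model_id = as.character(model_id),
      seq_id = as.character(seq_id),
      strand = strand,
      exons = exons,
      evidence = evidence,
      orf_len_aa = orf_len_from_spans(exons),
      source_protein_id = as.character(source_protein_id)
    ),
    class = "gene_model"
  )
}

orf_len_from_spans <- function(exons) {
  as.integer(sum(exons[, "end"] - exons[, "start"] + 1L) %/% 3L)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s%s  %d exon(s)  ORF %d aa  [%s]\n",
              x$model_id, x$seq_id, x$strand, nrow(x$exons), x$orf_len_aa,
              x$evidence))
  invisible(x)
}

#' Build an annotation set from gene models
#'
#' An annotation set is a queryable collection of [gene_model()] objects
#' over one genome, stored column-wise (a model table and an exon table)
#' with an interval index per `(seq_id, strand)` so overlap queries scale.
#' Model identifiers must be unique.
#'
#' @param models List of `gene_model` objects (may be empty).
#' @param genome_id Label for the genome the models annotate.
#' @return An object of class `annotation_set` with components:
#' \describe{
#'   \item{genome_id}{the label.}
#'   \item{models}{data frame, one row per model: `model_id`, `seq_id`,
#'     `strand`, `evidence`, `n_exons`, `orf_len_aa`, `span_start`,
#'     `span_end`, `source_protein_id`.}
#'   \item{exons}{data frame, one row per exon: `model_id`, `start`, `end`.}
#' }
#' @seealso [query_models()], [merge_evidence()], [read_gff3()]
#' @export
annotation_set <- function(models = list(), genome_id = "genome") {
  if (inherits(models, "gene_model")) models <- list(models)
  ids <- vapply(models, `[[`, "", "model_id")
  if (anyDuplicated(ids)) {
    stopf("duplicate model_id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(models) == 0L) {
    mdf <- data.frame(
      model_id = character(), seq_id = character(), strand = character(),
      evidence = character(), n_exons = integer(), orf_len_aa = integer(),
      span_start = integer(), span_end = integer(),
      source_protein_id = character(), stringsAsFactors = FALSE
    )
    edf <- data.frame(model_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  } else {
    mdf <- data.frame(
      model_id = ids,
      seq_id = vapply(models, `[[`, "", "seq_id"),
      strand = vapply(models, `[[`, "", "strand"),
      evidence = vapply(models, `[[`, "", "evidence"),
      n_exons = vapply(models, function(m) nrow(m$exons), 0L),
      orf_len_aa = vapply(models, `[[`, 0L, "orf_len_aa"),
      span_start = vapply(models, function(m) min(m$exons[, "start"]), 0L),
      span_end = vapply(models, function(m) max(m$exons[, "end"]), 0L),
      source_protein_id = vapply(models, `[[`, "", "source_protein_id"),
      stringsAsFactors = FALSE
    )
    edf <- do.call(rbind, lapply(models, function(m) {
      data.frame(model_id = m$model_id, start = m$exons[, "start"],
                 end = m$exons[, "end"], stringsAsFactors = FALSE)
    }))
    rownames(edf) <- NULL
  }
  structure(list(genome_id = genome_id, models = mdf, exons = edf),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> genome '%s': %d model(s), %d exon(s)\n",
              x$genome_id, nrow(x$models), nrow(x$exons)))
  if (nrow(x$models) > 0L) {
    ev <- table(x$models$evidence)
    cat("  evidence:", paste(sprintf("%s=%d", names(ev), ev),
                             collapse = ", "), "\n")
    cat("  seqs:", paste(sort(unique(x$models$seq_id)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
length.annotation_set <- function(x) nrow(x$models)

# Rebuild the gene_model list from the column store (inverse of
# annotation_set()).
as_model_list <- function(set) {
  if (nrow(set$models) == 0L) return(list())
  exon_split <- split(set$exons[c("start", "end")], set$exons$model_id)
  lapply(seq_len(nrow(set$models)), function(i) {
    r <- set$models[i, ]
    gene_model(r$model_id, r$seq_id, r$strand,
               as.matrix(exon_split[[r$model_id]]),
               evidence = r$evidence,
               source_protein_id = r$source_protein_id)
  })
}

# Subset an annotation set to the given model ids (order of `ids`).
subset_set <- function(set, ids) {
  keep <- set$models[match(ids, set$models$model_id), , drop = FALSE]
  if (anyNA(keep$model_id)) stopf("subset_set: unknown model id")
  rownames(keep) <- NULL
  ex <- set$exons[set$exons$model_id %in% ids, , drop = FALSE]
  ex <- ex[c_order(match(ex$model_id, ids), ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  structure(list(genome_id = set$genome_id, models = keep, exons = ex),
            class = "annotation_set")
}

#' Query models overlapping a genomic interval
#'
#' Returns exactly the models with at least one exon intersecting the
#' 1-based inclusive interval `[start, end]` on the given sequence and
#' strand. Strands are fully independent throughout the package. The lookup
#' is backed by an `IRanges` overlap query.
#'
#' @param set An [annotation_set()].
#' @param seq_id,strand Sequence and strand to query.
#' @param start,end 1-based inclusive interval bounds.
#' @return Character vector of model ids, in C-locale sorted order.
#' @export
query_models <- function(set, seq_id, strand, start, end) {
  m <- set$models
  on_target <- m$model_id[m$seq_id == seq_id & m$strand == strand]
  if (length(on_target) == 0L) return(character())
  ex <- set$exons[set$exons$model_id %in% on_target, , drop = FALSE]
  ir <- IRanges::IRanges(start = ex$start, end = ex$end)
  hits <- IRanges::overlapsAny(ir, IRanges::IRanges(start, end))
  ids <- unique(ex$model_id[hits])
  ids[c_order(ids)]
}

#' Create BUSCO classification records
#'
#' Canonical container for one BUSCO gene classification: one of
#' `Complete`, `Duplicated`, `Fragmented`, `Missing` (parsed
#' case-insensitively, stored canonically). Mostly produced by
#' [read_busco_table()] and the fixture generators.
#'
#' @param busco_id Character vector of BUSCO gene ids.
#' @param status Character vector of statuses (recycled rules apply as in
#'   `data.frame`).
#' @param sequence,score,length Optional per-row annotations (sequence hit,
#'   BUSCO score, gene length).
#' @return Data frame of class `busco_records`.
#' @export
busco_records <- function(busco_id, status, sequence = NA_character_,
                          score = NA_real_, length = NA_integer_) {
  status <- canonical_busco_status(status)
  out <- data.frame(busco_id = as.character(busco_id), status = status,
                    sequence = as.character(sequence),
                    score = as.numeric(score),
                    length = as.integer(length), stringsAsFactors = FALSE)
  class(out) <- c("busco_records", "data.frame")
  out
}

busco_status_levels <- c("Complete", "Duplicated", "Fragmented", "Missing")

canonical_busco_status <- function(status) {
  idx <- match(tolower(status), tolower(busco_status_levels))
  if (anyNA(idx)) {
    bad <- unique(status[is.na(idx)])
    stopf("unknown BUSCO status literal(s): %s", paste(bad, collapse = ", "))
  }
  busco_status_levels[idx]
}

#' Create BLAST tabular hit records
#'
#' Container for rows of BLASTP tabular output (outfmt-6 column order).
#' Mostly produced by [read_blast_tab()] and the fixture generators.
#'
#' @param query_id,subject_id Sequence identifiers.
#' @param pct_identity Percent identity in `[0, 100]`.
#' @param aln_len Alignment length (>= 1).
#' @param evalue Expectation value (>= 0).
#' @param bitscore Bit score.
#' @return Data frame of class `blast_hits` with those five columns.
#' @export
blast_hits <- function(query_id, subject_id, pct_identity, aln_len,
                       evalue, bitscore) {
  aln_len <- as.integer(aln_len)
  pct_identity <- as.numeric(pct_identity)
  if (any(aln_len < 1L)) stopf("blast_hits: aln_len must be >= 1")
  if (any(pct_identity < 0 | pct_identity > 100)) {
    stopf("blast_hits: pct_identity must lie in [0, 100]")
  }
  if (any(as.numeric(evalue) < 0)) stopf("blast_hits: evalue must be >= 0")
  out <- data.frame(query_id = as.character(query_id),
                    subject_id = as.character(subject_id),
                    pct_identity = pct_identity, aln_len = aln_len,
                    evalue = as.numeric(evalue),
                    bitscore = as.numeric(bitscore),
                    stringsAsFactors = FALSE)
  class(out) <- c("blast_hits", "data.frame")
  out
}
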