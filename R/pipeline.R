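# High-level runners behind the command-line interface. Every runner writes
# its artifacts deterministically, can emit a machine-readable stats JSON
# (configuration, input checksums, seed, headline counts), logs to stderr,
# and removes partial outputs if it fails midway.

pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[genewinnow] ", fmt), ...))
}

input_checksums <- function(paths) {
  paths <- unlist(paths, use.names = TRUE)
  as.list(tools::md5sum(paths))
}

write_stats_json <- function(stats, path) {
  if (is.null(path)) return(invisible(NULL))
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Run `expr`; on error remove the declared output paths and rethrow.
with_cleanup <- function(outputs, expr) {
  tryCatch(expr, error = function(e) {
    for (p in unlist(outputs)) {
      if (!is.null(p) && file.exists(p)) unlink(p)
    }
    stop(e)
  })
}

require_files <- function(...) {
  paths <- unlist(list(...))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  invisible(paths)
}

#' Consolidate homology and transcript GFF files into a non-redundant GFF3
#'
#' Reads the two evidence tracks (GFF3, or the exonerate dialect when the
#' file contains a GFF dump section), merges them, runs
#' [select_nonredundant()], and writes the selected models as GFF3. The
#' optional audit TSV records one row per selection event; the stats JSON
#' holds the configuration, input checksums and counts by evidence.
#'
#' @param homology_gff,transcript_gff Input model files.
#' @param out_gff Output GFF3 of selected models.
#' @param audit_tsv,stats_json Optional report paths.
#' @param window_size,min_orf_aa,min_exons,discard_scope Passed to
#'   [select_nonredundant()].
#' @return Invisibly, the stats list.
#' @export
run_select <- function(homology_gff, transcript_gff, out_gff,
                       audit_tsv = NULL, stats_json = NULL,
                       window_size = 100, min_orf_aa = 60, min_exons = 3,
                       discard_scope = "model") {
  require_files(homology_gff, transcript_gff)
  with_cleanup(list(out_gff, audit_tsv, stats_json), {
    read_models <- function(path, evidence) {
      if (any(grepl("START OF GFF DUMP",
                    read_lines_clean(path), fixed = TRUE))) {
        read_exonerate_gff(path, evidence = evidence)
      } else {
        read_gff3(path, evidence = evidence)
      }
    }
    hom <- read_models(homology_gff, "homology")
    tra <- read_models(transcript_gff, "transcript")
    merged <- merge_evidence(hom, tra, prefix = TRUE)
    pipeline_log("select: %d homology + %d transcript models",
                 length(hom), length(tra))
    res <- select_nonredundant(merged, window_size = window_size,
                               min_orf_aa = min_orf_aa,
                               min_exons = min_exons,
                               discard_scope = discard_scope)
    write_gff3(res$selected, out_gff)
    if (!is.null(audit_tsv)) {
      utils::write.table(res$audit, audit_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    stats <- c(summary(res),
               list(inputs = input_checksums(
                 c(homology = homology_gff, transcript = transcript_gff))))
    write_stats_json(stats, stats_json)
    pipeline_log("select: kept %d of %d models -> %s",
                 stats$n_selected, stats$n_input, out_gff)
    invisible(stats)
  })
}

#' Extract ORFs from a transcript FASTA to a protein FASTA
#'
#' @param transcripts_fasta Input nucleotide FASTA.
#' @param out_fasta Output protein FASTA ([write_orf_fasta()] headers).
#' @param min_len Minimum ORF length in amino acids (default 40).
#' @param stats_json Optional stats path.
#' @return Invisibly, the stats list.
#' @export
run_extract_orfs <- function(transcripts_fasta, out_fasta, min_len = 40,
                             stats_json = NULL) {
  require_files(transcripts_fasta)
  with_cleanup(list(out_fasta, stats_json), {
    orfs <- extract_orfs(transcripts_fasta, min_len = min_len)
    write_orf_fasta(orfs, out_fasta)
    stats <- list(min_len = min_len, n_orfs = nrow(orfs),
                  n_transcripts_with_orf =
                    length(unique(orfs$transcript_id)),
                  inputs = input_checksums(
                    c(transcripts = transcripts_fasta)))
    write_stats_json(stats, stats_json)
    pipeline_log("extract-orfs: %d ORFs (>= %d aa) -> %s", nrow(orfs),
                 min_len, out_fasta)
    invisible(stats)
  })
}

write_pattern_tsv <- function(pattern, path) {
  df <- data.frame(busco_id = pattern$genes, pattern$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_pattern_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- df$busco_id
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  patterns <- apply(mat, 1L, paste, collapse = "")
  tally <- table(patterns)
  counts <- as.integer(tally)
  names(counts) <- names(tally)
  counts <- counts[c_order(-counts, names(counts))]
  structure(
    list(genomes = colnames(mat), genes = genes, matrix = mat,
         pattern_tally = counts,
         top_patterns = utils::head(
           data.frame(pattern = names(counts), count = unname(counts),
                      stringsAsFactors = FALSE), 20L),
         missing_in_all = genes[rowSums(mat) == 0L]),
    class = "pattern_matrix"
  )
}

#' Summarize BUSCO tables into a presence/absence pattern report
#'
#' @param tables Named character vector of full_table paths (names are the
#'   genome ids, in column order).
#' @param out_tsv Per-gene binary presence matrix (TSV).
#' @param top_tsv Optional table of the `top_k` most abundant patterns.
#' @param top_k,present_statuses Passed to [presence_matrix()].
#' @param stats_json Optional stats path.
#' @return Invisibly, the stats list.
#' @export
run_patterns <- function(tables, out_tsv, top_tsv = NULL, top_k = 20,
                         present_statuses = c("Complete", "Duplicated"),
                         stats_json = NULL) {
  stopifnot(!is.null(names(tables)))
  require_files(tables)
  with_cleanup(list(out_tsv, top_tsv, stats_json), {
    recs <- lapply(tables, read_busco_table)
    pm <- presence_matrix(recs, present_statuses = present_statuses,
                          top_k = top_k)
    write_pattern_tsv(pm, out_tsv)
    if (!is.null(top_tsv)) {
      utils::write.table(pm$top_patterns, top_tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    stats <- list(genomes = pm$genomes, n_genes = length(pm$genes),
                  n_patterns = length(pm$pattern_tally),
                  n_missing_in_all = length(pm$missing_in_all),
                  present_statuses = present_statuses,
                  inputs = input_checksums(tables))
    write_stats_json(stats, stats_json)
    pipeline_log("patterns: %d genes x %d genomes, %d patterns -> %s",
                 length(pm$genes), length(pm$genomes),
                 length(pm$pattern_tally), out_tsv)
    invisible(stats)
  })
}

#' Compute best-reciprocal hits from two BLAST tabular files
#'
#' @param fwd_tab,rev_tab BLAST outfmt-6 files (reference -> target and
#'   target -> reference).
#' @param out_tsv Output pair table.
#' @param max_evalue Strict e-value cutoff (default 1e-4).
#' @param stats_json Optional stats path.
#' @return Invisibly, the stats list.
#' @export
run_rbh <- function(fwd_tab, rev_tab, out_tsv, max_evalue = 1e-4,
                    stats_json = NULL) {
  require_files(fwd_tab, rev_tab)
  with_cleanup(list(out_tsv, stats_json), {
    pairs <- reciprocal_best_hits(read_blast_tab(fwd_tab),
                                  read_blast_tab(rev_tab),
                                  max_evalue = max_evalue)
    utils::write.table(pairs, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stats <- list(max_evalue = max_evalue, n_pairs = nrow(pairs),
                  inputs = input_checksums(c(fwd = fwd_tab,
                                             rev = rev_tab)))
    write_stats_json(stats, stats_json)
    pipeline_log("rbh: %d reciprocal best pairs -> %s", nrow(pairs),
                 out_tsv)
    invisible(stats)
  })
}

#' Rescue missing-in-all genes from pattern and RBH pair files
#'
#' @param pattern_tsv Presence matrix written by [run_patterns()].
#' @param pair_tsvs Named character vector of pair tables (one per genome,
#'   as written by [run_rbh()]); names must match the pattern's genomes.
#' @param mapping_tsv Two-column TSV `busco_id` -> reference protein id
#'   (header optional).
#' @param out_json,out_tsv Report destinations (either may be `NULL`).
#' @return Invisibly, the [rescue_missing()] report.
#' @export
run_rescue <- function(pattern_tsv, pair_tsvs, mapping_tsv,
                       out_json = NULL, out_tsv = NULL) {
  stopifnot(!is.null(names(pair_tsvs)))
  require_files(pattern_tsv, pair_tsvs, mapping_tsv)
  with_cleanup(list(out_json, out_tsv), {
    pm <- read_pattern_tsv(pattern_tsv)
    rbh <- lapply(pair_tsvs, function(p) {
      utils::read.delim(p, stringsAsFactors = FALSE)
    })
    map <- utils::read.delim(mapping_tsv, header = FALSE,
                             stringsAsFactors = FALSE,
                             comment.char = "#")
    if (identical(tolower(map[1, 1]), "busco_id")) {
      map <- map[-1L, , drop = FALSE]
    }
    report <- rescue_missing(pm, rbh, map)
    if (!is.null(out_json)) {
      jsonlite::write_json(
        list(n_missing_all = report$n_missing_all,
             n_rescued_all = report$n_rescued_all,
             n_partial = report$n_partial, fraction = report$fraction,
             unmapped = report$unmapped, per_gene = report$per_gene),
        out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (!is.null(out_tsv)) {
      utils::write.table(report$per_gene, out_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    pipeline_log("rescue: %d/%d missing-in-all genes with full RBH support",
                 report$n_rescued_all, report$n_missing_all)
    invisible(report)
  })
}

#' Compute alignment-metric matrices as a long-format TSV
#'
#' @param hit_tabs Named character vector of BLAST tabular files (one per
#'   genome).
#' @param lengths_tsv Two-column TSV: reference protein id, length in aa.
#' @param out_tsv Long-format output (`gene_set`, `metric`, `gene`,
#'   `genome`, `value`), suitable for heatmap plotting; absent cells are
#'   omitted.
#' @param gene_set_files Optional named character vector of files with one
#'   gene id per line; default is one set (`all`) holding every query seen.
#' @return Invisibly, the [metric_matrices()] object.
#' @export
run_metrics <- function(hit_tabs, lengths_tsv, out_tsv,
                        gene_set_files = NULL) {
  stopifnot(!is.null(names(hit_tabs)))
  require_files(hit_tabs, lengths_tsv,
                if (is.null(gene_set_files)) character()
                else gene_set_files)
  with_cleanup(list(out_tsv), {
    hits <- lapply(hit_tabs, read_blast_tab)
    lt <- utils::read.delim(lengths_tsv, header = FALSE,
                            stringsAsFactors = FALSE,
                            comment.char = "#")
    lens <- stats::setNames(as.numeric(lt[[2L]]), as.character(lt[[1L]]))
    gene_sets <- if (is.null(gene_set_files)) {
      all <- unique(unlist(lapply(hits, function(h) h$query_id)))
      list(all = all[c_order(all)])
    } else {
      lapply(gene_set_files, function(p) read_lines_clean(p))
    }
    mm <- metric_matrices(hits, lens, gene_sets)
    long <- do.call(rbind, lapply(names(mm), function(set_name) {
      do.call(rbind, lapply(metric_names, function(met) {
        m <- mm[[set_name]][[met]]
        idx <- which(!is.na(m), arr.ind = TRUE)
        if (nrow(idx) == 0L) return(NULL)
        data.frame(gene_set = set_name, metric = met,
                   gene = rownames(m)[idx[, 1L]],
                   genome = colnames(m)[idx[, 2L]],
                   value = m[idx], stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(long)) {
      long <- data.frame(gene_set = character(), metric = character(),
                         gene = character(), genome = character(),
                         value = numeric())
    }
    long <- long[c_order(long$gene_set, long$metric, long$gene,
                         long$genome), , drop = FALSE]
    utils::write.table(long, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pipeline_log("metrics: %d cells across %d gene set(s) -> %s",
                 nrow(long), length(gene_sets), out_tsv)
    invisible(mm)
  })
}
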