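# Readers/writers for the formats the pipeline touches: GFF3, the exonerate
# protein2genome GFF dump dialect, FASTA (via Biostrings), BUSCO full_table
# TSV and BLAST tabular (outfmt 6). All readers tolerate CRLF endings and
# trailing blank lines. External coordinates are 1-based inclusive.

# Line-level validation shared by the GFF readers, so malformed input is
# reported with its line number before any heavier parsing runs.
validate_gff_line <- function(fields, lineno) {
  if (!is_wholenumber(fields[4]) || !is_wholenumber(fields[5])) {
    stopf("line %d: non-integer coordinate ('%s', '%s')",
          lineno, fields[4], fields[5])
  }
  if (as.integer(fields[4]) > as.integer(fields[5])) {
    stopf("line %d: start > end (%s > %s)", lineno, fields[4], fields[5])
  }
  if (!fields[7] %in% c("+", "-")) {
    stopf("line %d: unknown strand symbol '%s'", lineno, fields[7])
  }
  invisible(TRUE)
}

#' Read gene models from a GFF3 file
#'
#' Expects the conventional gene -> mRNA -> CDS/exon hierarchy expressed via
#' `Parent` attributes. One [gene_model()] is built per mRNA (or per
#' top-level feature that directly parents CDS/exon rows). CDS children are
#' preferred over exon children when both are present; the ORF length is
#' derived from the CDS spans. mRNAs with no CDS/exon children are skipped
#' with a warning. Parsing is done with [rtracklayer::readGFF()] after a
#' line-level validation pass that reports malformed coordinates or strand
#' symbols with their line number.
#'
#' @param path GFF3 file.
#' @param evidence Evidence label to stamp on every model (`"homology"` or
#'   `"transcript"`), or `NULL` (default) to take it from the GFF source
#'   column (column 2) where that column holds one of the two labels,
#'   falling back to `"transcript"`.
#' @param genome_id Genome label for the returned set.
#' @return An [annotation_set()].
#' @seealso [write_gff3()], [read_exonerate_gff()]
#' @export
read_gff3 <- function(path, evidence = NULL, genome_id = "genome") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- read_lines_clean(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L) {
      stopf("line %d: expected 9 tab-separated fields, found %d",
            i, length(fields))
    }
    validate_gff_line(fields, i)
  }
  if (length(body) == 0L) return(annotation_set(genome_id = genome_id))

  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  g$type <- as.character(g$type)
  parent_of <- function(i) {
    p <- g$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }
  g$parent1 <- vapply(seq_len(nrow(g)), parent_of, "")

  is_child <- g$type %in% c("CDS", "exon")
  kids <- g[is_child & !is.na(g$parent1), , drop = FALSE]
  if (nrow(kids) == 0L) {
    warnf("%s: no CDS/exon features with Parent attributes; empty set", path)
    return(annotation_set(genome_id = genome_id))
  }
  # Prefer CDS rows when a parent has both CDS and exon children.
  has_cds <- unique(kids$parent1[kids$type == "CDS"])
  kids <- kids[kids$type == "CDS" | !(kids$parent1 %in% has_cds), ,
               drop = FALSE]

  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  childless <- setdiff(mrna$ID, kids$parent1)
  if (length(childless) > 0L) {
    warnf("%s: skipping %d model(s) with no CDS/exon children: %s", path,
          length(childless), paste(childless, collapse = ", "))
  }

  models <- lapply(split(seq_len(nrow(kids)), kids$parent1), function(idx) {
    rows <- kids[idx, , drop = FALSE]
    mid <- rows$parent1[1L]
    meta <- g[!is.na(g$ID) & g$ID == mid, , drop = FALSE]
    src <- NA_character_
    ev <- evidence
    if (nrow(meta) > 0L) {
      if ("source_protein" %in% names(meta) &&
          !is.na(meta$source_protein[1L])) {
        src <- as.character(meta$source_protein[1L])
      }
      if (is.null(ev)) {
        s <- as.character(meta$source[1L])
        ev <- if (s %in% c("homology", "transcript")) s else "transcript"
      }
    }
    gene_model(mid, as.character(rows$seqid[1L]),
               as.character(rows$strand[1L]),
               cbind(start = rows$start, end = rows$end),
               evidence = ev %||% "transcript", source_protein_id = src)
  })
  ids <- vapply(models, `[[`, "", "model_id")
  annotation_set(models[c_order(ids)], genome_id = genome_id)
}

#' Read gene models from an exonerate GFF dump
#'
#' Parses the GFF2-style output of exonerate's `protein2genome` model: only
#' `gene` and `exon` rows inside sections bracketed by
#' `# --- START OF GFF DUMP ---` / `# --- END OF GFF DUMP ---` are
#' consumed; `similarity`, `splice5`, `splice3`, `cds` and `intron` rows and
#' all alignment text outside dump sections are ignored. The aligned query
#' identifier (the `sequence` attribute of the `gene` row) becomes
#' `source_protein_id`, and the model id is `<query>.g<gene_id>` (a running
#' counter when the `gene_id` attribute is absent). A `gene` row with zero
#' `exon` rows is skipped with a warning; a file with no dump section
#' yields an empty set with a warning.
#'
#' @param path exonerate GFF output file.
#' @param evidence Evidence label for the models (default `"homology"`:
#'   spliced protein-to-genome alignments).
#' @param genome_id Genome label for the returned set.
#' @return An [annotation_set()].
#' @export
read_exonerate_gff <- function(path, evidence = "homology",
                               genome_id = "genome") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- read_lines_clean(path)
  in_dump <- FALSE
  saw_dump <- FALSE
  models <- list()
  cur <- NULL   # list(id, seq, strand, src, exons, lineno)
  skipped <- character()

  flush_model <- function() {
    if (is.null(cur)) return()
    if (nrow(cur$exons) == 0L) {
      skipped <<- c(skipped, cur$id)
    } else {
      models[[length(models) + 1L]] <<- gene_model(
        cur$id, cur$seq, cur$strand, cur$exons,
        evidence = evidence, source_protein_id = cur$src)
    }
    cur <<- NULL
  }

  n_genes <- 0L
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("START OF GFF DUMP", line, fixed = TRUE)) {
      in_dump <- TRUE
      saw_dump <- TRUE
      next
    }
    if (grepl("END OF GFF DUMP", line, fixed = TRUE)) {
      flush_model()
      in_dump <- FALSE
      next
    }
    if (!in_dump || grepl("^#", line) || !nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9L) {
      stopf("line %d: expected >= 9 tab-separated fields, found %d",
            i, length(fields))
    }
    type <- fields[3]
    if (!type %in% c("gene", "exon")) next
    validate_gff_line(fields, i)
    if (type == "gene") {
      flush_model()
      n_genes <- n_genes + 1L
      attrs <- parse_gff2_attrs(fields[9])
      src <- attrs[["sequence"]] %||% NA_character_
      gid <- attrs[["gene_id"]] %||% as.character(n_genes)
      cur <- list(
        id = sprintf("%s.g%s", src %||% "gene", gid),
        seq = fields[1], strand = fields[7], src = src,
        exons = cbind(start = integer(), end = integer())
      )
    } else if (!is.null(cur)) {
      cur$exons <- rbind(cur$exons,
                         c(start = as.integer(fields[4]),
                           end = as.integer(fields[5])))
    }
  }
  flush_model()
  if (!saw_dump) {
    warnf("%s: no GFF dump section found; empty set", path)
  }
  if (length(skipped) > 0L) {
    warnf("%s: skipping %d gene(s) with zero exon rows: %s", path,
          length(skipped), paste(skipped, collapse = ", "))
  }
  ids <- vapply(models, `[[`, "", "model_id")
  if (anyDuplicated(ids)) {
    warnf("%s: duplicate model ids made unique", path)
    ids2 <- make.unique(ids, sep = "_dup")
    models <- lapply(seq_along(models), function(j) {
      m <- models[[j]]; m$model_id <- ids2[j]; m
    })
    ids <- ids2
  }
  annotation_set(models[c_order(ids)], genome_id = genome_id)
}

# "key value ; key value" GFF2-style attribute string -> named list.
parse_gff2_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(trimws(p), "[ \t]+")[[1]]
    if (length(kv) >= 2L) out[[kv[1]]] <- paste(kv[-1L], collapse = " ")
  }
  out
}

#' Write an annotation set as GFF3
#'
#' Deterministic writer: features are sorted by `(seq_id, span_start,
#' model_id)` in C-locale order and emitted as a gene -> mRNA -> CDS
#' hierarchy with 1-based inclusive coordinates, the evidence label in the
#' source column, `source_protein` as an mRNA attribute where known, and
#' CDS phase computed in translation order. Two writes of the same set are
#' byte-identical, and [read_gff3()] on the output reproduces the set.
#'
#' @param set An [annotation_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  m <- set$models
  ord <- c_order(m$seq_id, m$span_start, m$model_id)
  out <- "##gff-version 3"
  exons_by_id <- split(set$exons, set$exons$model_id)
  for (i in ord) {
    r <- m[i, ]
    ex <- exons_by_id[[r$model_id]]
    ex <- ex[c_order(ex$start), , drop = FALSE]
    gid <- paste0("gene:", r$model_id)
    out <- c(out, paste(r$seq_id, r$evidence, "gene", r$span_start,
                        r$span_end, ".", r$strand, ".",
                        paste0("ID=", gid), sep = "\t"))
    attrs <- paste0("ID=", r$model_id, ";Parent=", gid)
    if (!is.na(r$source_protein_id) && nzchar(r$source_protein_id) &&
        r$source_protein_id != "NA") {
      attrs <- paste0(attrs, ";source_protein=", r$source_protein_id)
    }
    out <- c(out, paste(r$seq_id, r$evidence, "mRNA", r$span_start,
                        r$span_end, ".", r$strand, ".", attrs, sep = "\t"))
    phases <- cds_phases(ex$start, ex$end, r$strand)
    for (j in seq_len(nrow(ex))) {
      out <- c(out, paste(r$seq_id, r$evidence, "CDS", ex$start[j],
                          ex$end[j], ".", r$strand, phases[j],
                          paste0("ID=cds:", r$model_id, ";Parent=",
                                 r$model_id), sep = "\t"))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con = con, sep = "\n")
  invisible(path)
}

# GFF3 CDS phases in ascending-coordinate row order; translation runs
# right-to-left on the minus strand.
cds_phases <- function(starts, ends, strand) {
  lens <- ends - starts + 1L
  n <- length(lens)
  order_tr <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  cum <- c(0L, cumsum(lens[order_tr]))[seq_len(n)]
  ph <- (3L - (cum %% 3L)) %% 3L
  ph[order(order_tr)]
}

#' Write an annotation set in the exonerate GFF dump dialect
#'
#' Emits one GFF dump section per model (`gene` + `exon` rows with
#' GFF2-style attributes), as produced by spliced protein-to-genome
#' alignment, primarily so fixtures can exercise [read_exonerate_gff()]
#' against the same structures encoded as GFF3. Model ids must follow the
#' `<query>.g<n>` form that the reader derives from the `sequence` and
#' `gene_id` attributes, and `source_protein_id`, where set, must equal
#' the `<query>` part; otherwise the encoding could not round-trip and an
#' error is raised.
#'
#' @param set An [annotation_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_exonerate_gff <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  m <- set$models
  ok <- grepl("^.+\\.g[^.]+$", m$model_id)
  if (!all(ok)) {
    stopf("model id(s) not encodable as <query>.g<n>: %s",
          paste(m$model_id[!ok], collapse = ", "))
  }
  src <- sub("^(.+)\\.g[^.]+$", "\\1", m$model_id)
  gid <- sub("^.+\\.g([^.]+)$", "\\1", m$model_id)
  has_sp <- !is.na(m$source_protein_id) & m$source_protein_id != "NA" &
    nzchar(m$source_protein_id)
  if (any(has_sp & m$source_protein_id != src)) {
    bad <- m$model_id[has_sp & m$source_protein_id != src]
    stopf("source_protein_id does not match model id prefix for: %s",
          paste(bad, collapse = ", "))
  }
  exons_by_id <- split(set$exons, set$exons$model_id)
  out <- character()
  ord <- c_order(m$seq_id, m$span_start, m$model_id)
  for (i in ord) {
    r <- m[i, ]
    ex <- exons_by_id[[r$model_id]]
    ex <- ex[c_order(ex$start), , drop = FALSE]
    out <- c(out, "# --- START OF GFF DUMP ---", "#")
    out <- c(out, paste(r$seq_id, "exonerate:protein2genome:local", "gene",
                        r$span_start, r$span_end, "500", r$strand, ".",
                        sprintf("gene_id %s ; sequence %s ; gene_orientation +",
                                gid[i], src[i]), sep = "\t"))
    for (j in seq_len(nrow(ex))) {
      out <- c(out, paste(r$seq_id, "exonerate:protein2genome:local",
                          "exon", ex$start[j], ex$end[j], ".", r$strand,
                          ".", "insertions 0 ; deletions 0", sep = "\t"))
    }
    out <- c(out, "# --- END OF GFF DUMP ---")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con = con, sep = "\n")
  invisible(path)
}

#' Keep the longest isoform per gene
#'
#' Reduces a proteome with multiple isoforms per gene to one representative
#' record per gene: the longest sequence, ties broken by the
#' lexicographically smallest record id. The gene behind each record is
#' derived from its id by `id_pattern` (a regex whose first capture group is
#' the gene id; the default strips a final dot-suffix, so `g27.t2` maps to
#' gene `g27`), or supplied directly via `gene_ids`.
#'
#' @param proteins An [Biostrings::AAStringSet] (or any XStringSet) whose
#'   names are record ids, optionally followed by a description.
#' @param gene_ids Optional character vector of gene ids parallel to
#'   `proteins`, or a function mapping record ids to gene ids. Overrides
#'   `id_pattern`.
#' @param id_pattern Regex with one capture group extracting the gene id
#'   from a record id. Records whose id does not match raise an error that
#'   lists the offending ids.
#' @return The subset of `proteins`, in input order, with exactly one record
#'   per gene.
#' @export
longest_isoform_filter <- function(proteins, gene_ids = NULL,
                                   id_pattern = "^(.+)\\.[^.]+$") {
  ids <- sub("\\s.*$", "", names(proteins))
  if (is.null(gene_ids)) {
    ok <- grepl(id_pattern, ids)
    if (!all(ok)) {
      stopf("no gene id derivable for record(s): %s",
            paste(ids[!ok], collapse = ", "))
    }
    gene_ids <- sub(id_pattern, "\\1", ids)
  } else if (is.function(gene_ids)) {
    gene_ids <- vapply(ids, gene_ids, "")
  }
  if (length(gene_ids) != length(proteins)) {
    stopf("gene_ids length (%d) != number of records (%d)",
          length(gene_ids), length(proteins))
  }
  lens <- Biostrings::width(proteins)
  keep <- vapply(split(seq_along(ids), gene_ids), function(idx) {
    best <- idx[lens[idx] == max(lens[idx])]
    best[c_order(ids[best])][1L]
  }, 0L)
  proteins[sort(keep)]
}

#' Read a BUSCO full_table file
#'
#' Parses BUSCO's per-gene tab-separated result file. Lines starting with
#' `#` are comments; `Missing` rows may carry only the id and status;
#' `Duplicated` genes may appear on several rows (presence queries in
#' [presence_matrix()] collapse them). Statuses are parsed
#' case-insensitively and stored canonically; an unknown status literal is
#' an error naming the line. Both protein-mode (5-column) and genome-mode
#' (8-column) layouts are understood.
#'
#' @param path full_table file.
#' @return A [busco_records()] data frame, one row per table row.
#' @export
read_busco_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- read_lines_clean(path)
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^#", line) || !nzchar(trimws(line))) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      stopf("line %d: expected at least busco_id and status", i)
    }
    st <- tryCatch(canonical_busco_status(f[2]), error = function(e) {
      stopf("line %d: %s", i, conditionMessage(e))
    })
    nf <- length(f)
    sequence <- if (nf >= 3L) f[3] else NA_character_
    score <- NA_real_
    len <- NA_integer_
    if (nf >= 8L) {           # genome mode: ... Strand Score Length
      score <- suppressWarnings(as.numeric(f[7]))
      len <- suppressWarnings(as.integer(f[8]))
    } else if (nf >= 4L) {    # protein mode: Sequence Score [Length]
      score <- suppressWarnings(as.numeric(f[4]))
      if (nf >= 5L) len <- suppressWarnings(as.integer(f[5]))
    }
    rows[[length(rows) + 1L]] <- list(f[1], st, sequence, score, len)
  }
  if (length(rows) == 0L) {
    return(busco_records(character(), character()))
  }
  busco_records(
    busco_id = vapply(rows, `[[`, "", 1L),
    status = vapply(rows, `[[`, "", 2L),
    sequence = vapply(rows, `[[`, "", 3L),
    score = vapply(rows, function(r) as.numeric(r[[4L]]), 0),
    length = vapply(rows, function(r) as.integer(r[[5L]]), 0L)
  )
}

blast_tab_columns <- c("query_id", "subject_id", "pct_identity", "aln_len",
                       "mismatch", "gapopen", "qstart", "qend", "sstart",
                       "send", "evalue", "bitscore")

#' Read BLAST tabular output (outfmt 6)
#'
#' Expects the default 12-column order `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`. Hits are
#' returned in file order; scientific-notation e-values are accepted; a row
#' with the wrong column count is an error naming the line.
#'
#' @param path BLAST tabular file.
#' @return A `blast_hits` data frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- read_lines_clean(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^#", lines))
  empty <- data.frame(matrix(nrow = 0L, ncol = 12L,
                             dimnames = list(NULL, blast_tab_columns)))
  if (length(keep) == 0L) {
    class(empty) <- c("blast_hits", "data.frame")
    return(empty)
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stopf("line %d: expected 12 tab-separated columns, found %d",
          keep[bad], nf[bad])
  }
  m <- do.call(rbind, parts)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("blast_hits", "data.frame")
  out
}

# Write blast_hits back out in outfmt-6 layout (used by the fixture
# generators; deterministic formatting).
write_blast_tab <- function(hits, path) {
  fmt_num <- function(x) {
    vapply(x, function(v) {
      if (v == floor(v) && abs(v) < 1e15) sprintf("%.1f", v)
      else format(v, scientific = FALSE)
    }, "")
  }
  lines <- paste(hits$query_id, hits$subject_id,
                 sprintf("%.1f", hits$pct_identity), hits$aln_len,
                 hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
                 hits$sstart, hits$send, sprintf("%.2e", hits$evalue),
                 fmt_num(hits$bitscore), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con = con, sep = "\n")
  invisible(path)
}
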