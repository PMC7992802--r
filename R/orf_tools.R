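# Six-frame ORF extraction from assembled transcripts: the preparation step
# for the transcript evidence track. An ORF here is a maximal stop-free
# stretch of a frame translation; "partial" means truncated at a transcript
# edge, so ORFs need not start with ATG nor end at a stop. Standard genetic
# code throughout (nematode nuclear genes).

#' Extract partial and complete ORFs from transcripts
#'
#' Scans all six reading frames of each nucleotide record and reports every
#' maximal stop-free stretch of at least `min_len` amino acids. Codons
#' containing `N` translate to `X` and do not terminate an ORF. Reported
#' coordinates are 0-based half-open positions within the frame translation
#' (`aa_start`/`aa_end`). The completeness flags record, per end, whether
#' the ORF could be a biologically complete one: `complete5p` is true when
#' the ORF starts with methionine or runs to the transcript edge, and
#' `complete3p` when it ends at a stop codon or runs to the edge (for
#' maximal ORFs the 3' condition always holds; the flag is kept for
#' symmetry and downstream filtering on `starts_with_met`).
#'
#' @param transcripts A [Biostrings::DNAStringSet], a named character
#'   vector of nucleotide sequences over `A,C,G,T,N` (case-insensitive), or
#'   a path to a FASTA file.
#' @param min_len Minimum ORF length in amino acids (stop excluded);
#'   default 40.
#' @return Data frame of class `orf_records` with columns `transcript_id`,
#'   `strand` (`+`/`-`), `frame` (0, 1, 2), `aa_start`, `aa_end`,
#'   `sequence` (no `*`), `starts_with_met`, `complete5p`, `complete3p`.
#' @examples
#' extract_orfs(c(t1 = "ATGAAATAA"), min_len = 2)
#' @export
extract_orfs <- function(transcripts, min_len = 40) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  }
  if (!inherits(transcripts, "DNAStringSet")) {
    bad <- grepl("[^ACGTNacgtn]", transcripts)
    if (any(bad)) {
      stopf("non-IUPAC nucleotide character in record(s): %s",
            paste(names(transcripts)[bad] %||%
                    which(bad), collapse = ", "))
    }
    transcripts <- Biostrings::DNAStringSet(toupper(transcripts))
  } else {
    letters <- Biostrings::uniqueLetters(transcripts)
    if (length(setdiff(letters, c("A", "C", "G", "T", "N"))) > 0L) {
      freq <- Biostrings::alphabetFrequency(transcripts)
      extra <- setdiff(colnames(freq), c("A", "C", "G", "T", "N"))
      bad <- rowSums(freq[, extra, drop = FALSE]) > 0
      stopf("non-IUPAC nucleotide character in record(s): %s",
            paste(names(transcripts)[bad] %||% which(bad),
                  collapse = ", "))
    }
  }
  stopifnot(min_len >= 1)
  ids <- names(transcripts) %||% as.character(seq_along(transcripts))
  ids <- sub("\\s.*$", "", ids)

  out <- list()
  for (i in seq_along(transcripts)) {
    seq_fwd <- transcripts[[i]]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fwd else
        Biostrings::reverseComplement(seq_fwd)
      n <- length(s)
      for (frame in 0:2) {
        n_codons <- (n - frame) %/% 3L
        if (n_codons < 1L) next
        aa <- as.character(Biostrings::translate(
          Biostrings::subseq(s, start = frame + 1L,
                             width = n_codons * 3L),
          no.init.codon = TRUE, if.fuzzy.codon = "X"))
        runs <- stop_free_runs(aa)
        if (nrow(runs) == 0L) next
        keep <- runs$len >= min_len
        if (!any(keep)) next
        runs <- runs[keep, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = ids[i], strand = strand, frame = frame,
          aa_start = runs$start0, aa_end = runs$start0 + runs$len,
          sequence = runs$seq,
          starts_with_met = substring(runs$seq, 1L, 1L) == "M",
          complete5p = substring(runs$seq, 1L, 1L) == "M" |
            runs$start0 == 0L,
          complete3p = runs$hits_stop |
            (runs$start0 + runs$len) == nchar(aa),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(out) == 0L) {
    data.frame(transcript_id = character(), strand = character(),
               frame = integer(), aa_start = integer(), aa_end = integer(),
               sequence = character(), starts_with_met = logical(),
               complete5p = logical(), complete3p = logical(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  rownames(res) <- NULL
  class(res) <- c("orf_records", "data.frame")
  res
}

# Maximal '*'-free runs of an amino-acid string: data frame with 0-based
# start, length, the run sequence, and whether a stop follows the run.
stop_free_runs <- function(aa) {
  n <- nchar(aa)
  if (n == 0L) {
    return(data.frame(start0 = integer(), len = integer(),
                      seq = character(), hits_stop = logical()))
  }
  pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
  # trailing stops drop empty pieces; reconstruct positions from lengths
  lens <- nchar(pieces)
  starts0 <- cumsum(c(0L, lens + 1L))[seq_along(pieces)]
  keep <- lens > 0L
  data.frame(start0 = as.integer(starts0[keep]), len = as.integer(lens[keep]),
             seq = pieces[keep],
             hits_stop = (starts0[keep] + lens[keep]) < n,
             stringsAsFactors = FALSE)
}

#' Write ORF records as protein FASTA
#'
#' Headers follow `transcriptID|strand|frame|start-end|flags`, where flags
#' are `5c`/`5p` and `3c`/`3p` for complete/partial ends.
#'
#' @param orfs An `orf_records` data frame from [extract_orfs()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_orf_fasta <- function(orfs, path) {
  headers <- sprintf("%s|%s|%d|%d-%d|%s%s", orfs$transcript_id, orfs$strand,
                     orfs$frame, orfs$aa_start, orfs$aa_end,
                     ifelse(orfs$complete5p, "5c", "5p"),
                     ifelse(orfs$complete3p, "3c", "3p"))
  aa <- Biostrings::AAStringSet(orfs$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
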