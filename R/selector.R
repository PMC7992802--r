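# The consolidation heuristic at the heart of the package: reduce a
# redundant joint annotation (homology placements + transcribed ORFs,
# possibly several models per locus) to one representative model per locus.
#
# Procedure, per (seq_id, strand):
#   1. every exon start and end coordinate is assigned to a fixed-size
#      window (100 bp by default) and each window's coverage is the number
#      of boundary features assigned to it (a start and an end falling in
#      the same window both count);
#   2. windows are visited in order of decreasing coverage;
#   3. at each window, among the still-available models whose gene span
#      intersects the window and that pass the eligibility filters
#      (>= min_exons exons, ORF >= min_orf_aa), the model with the longest
#      ORF is selected and every other still-available model overlapping
#      the chosen model's gene span is discarded;
#   4. once selected, a model is never displaced (greedy, no backtracking).
#
# Coverage is computed from ALL models, including ones failing the filters;
# the filters apply only when choosing. Strands never interact.

#' Build a window coverage map of exon boundaries
#'
#' Assigns every exon start and every exon end coordinate to a window of
#' `window_size` bp on its (sequence, strand) and counts boundary features
#' per window. A boundary at 1-based coordinate c falls in window
#' `floor((c - 1) / window_size)`; both boundaries of an exon contained in
#' one window count twice. The total count over all windows is exactly
#' twice the number of exons.
#'
#' @param set An [annotation_set()].
#' @param window_size Window width in bp (default 100).
#' @return Data frame of class `window_coverage` with columns `seq_id`,
#'   `strand`, `window` (0-based index) and `count`, sorted by
#'   `(seq_id, strand, window)`; attribute `window_size`.
#' @export
build_windows <- function(set, window_size = 100) {
  stopifnot(inherits(set, "annotation_set"), window_size >= 1)
  ex <- set$exons
  key <- match(ex$model_id, set$models$model_id)
  seq_id <- set$models$seq_id[key]
  strand <- set$models$strand[key]
  b <- data.frame(
    seq_id = c(seq_id, seq_id), strand = c(strand, strand),
    window = c(window_index(ex$start, window_size),
               window_index(ex$end, window_size)),
    stringsAsFactors = FALSE
  )
  if (nrow(b) == 0L) {
    out <- data.frame(seq_id = character(), strand = character(),
                      window = integer(), count = integer())
  } else {
    agg <- stats::aggregate(
      list(count = rep(1L, nrow(b))),
      by = list(seq_id = b$seq_id, strand = b$strand, window = b$window),
      FUN = sum)
    out <- agg[c_order(agg$seq_id, agg$strand, agg$window), , drop = FALSE]
    out$count <- as.integer(out$count)
    rownames(out) <- NULL
  }
  attr(out, "window_size") <- window_size
  class(out) <- c("window_coverage", "data.frame")
  out
}

#' Select a non-redundant set of gene models
#'
#' Greedy window-coverage selection: windows (built over all input models
#' with [build_windows()]) are processed from most to least covered; at
#' each window the intersecting eligible model with the longest ORF is
#' chosen and all other still-available models overlapping it are
#' discarded. Eligibility requires at least `min_exons` exons and an ORF of
#' at least `min_orf_aa` amino acids; ineligible models never get selected
#' but do contribute coverage. The run is fully deterministic: window
#' ties break by (seq_id, window index, '+' before '-') and candidate ties
#' by (longest ORF, smaller gene start, smaller model id), all in C locale.
#'
#' @param set An [annotation_set()], typically from [merge_evidence()].
#' @param window_size Window width in bp (default 100).
#' @param min_orf_aa Minimum ORF length in amino acids for a model to be
#'   selectable (default 60).
#' @param min_exons Minimum exon count for a model to be selectable
#'   (default 3).
#' @param discard_scope What "other intersecting models are discarded"
#'   ranges over once a model is chosen: `"model"` (default) discards
#'   still-available models whose gene span overlaps the chosen model's
#'   gene span; `"window"` discards only those overlapping the triggering
#'   window.
#' @return Object of class `selection_result`:
#' \describe{
#'   \item{selected}{[annotation_set()] of representative models, pairwise
#'     exon-disjoint per (seq_id, strand).}
#'   \item{discarded}{data frame `model_id`, `reason` with reason one of
#'     `overlap_with_selected`, `filter_exons`, `filter_orf_len`. Together
#'     with the selected ids this partitions the input ids.}
#'   \item{audit}{data frame of selection events in processing order:
#'     `seq_id`, `strand`, `window`, `count`, `chosen`, `n_discarded`.}
#'   \item{params}{the thresholds used.}
#' }
#' @examples
#' a <- gene_model("a", "c1", "+", cbind(c(1, 201, 401), c(100, 300, 500)))
#' b <- gene_model("b", "c1", "+", cbind(c(51, 251, 451), c(130, 330, 480)))
#' select_nonredundant(annotation_set(list(a, b)))$selected$models$model_id
#' @export
select_nonredundant <- function(set, window_size = 100, min_orf_aa = 60,
                                min_exons = 3,
                                discard_scope = c("model", "window")) {
  stopifnot(inherits(set, "annotation_set"),
            window_size >= 1, min_orf_aa >= 0, min_exons >= 0)
  discard_scope <- match.arg(discard_scope)
  m <- set$models
  n <- nrow(m)
  params <- list(window_size = window_size, min_orf_aa = min_orf_aa,
                 min_exons = min_exons, discard_scope = discard_scope)
  empty_audit <- data.frame(seq_id = character(), strand = character(),
                            window = integer(), count = integer(),
                            chosen = character(), n_discarded = integer(),
                            stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(selected = set,
                          discarded = data.frame(model_id = character(),
                                                 reason = character(),
                                                 stringsAsFactors = FALSE),
                          audit = empty_audit, params = params),
                     class = "selection_result"))
  }

  eligible <- m$n_exons >= min_exons & m$orf_len_aa >= min_orf_aa
  wins <- build_windows(set, window_size)
  ord <- c_order(-wins$count, wins$seq_id, wins$window,
                 match(wins$strand, c("+", "-")))
  wins <- wins[ord, , drop = FALSE]

  group_key <- paste(m$seq_id, m$strand, sep = "\r")
  groups <- split(seq_len(n), group_key)
  status <- rep("open", n)      # open | selected | discarded
  reason <- rep(NA_character_, n)
  audit <- vector("list", nrow(wins))
  n_events <- 0L

  for (w in seq_len(nrow(wins))) {
    g <- groups[[paste(wins$seq_id[w], wins$strand[w], sep = "\r")]]
    open <- g[status[g] == "open"]
    if (length(open) == 0L) next
    ws <- window_span(wins$window[w], window_size)
    in_win <- open[m$span_start[open] <= ws$end &
                     m$span_end[open] >= ws$start]
    cand <- in_win[eligible[in_win]]
    if (length(cand) == 0L) next
    pick <- cand[c_order(-m$orf_len_aa[cand], m$span_start[cand],
                         m$model_id[cand])][1L]
    status[pick] <- "selected"
    victims <- if (discard_scope == "model") {
      open[m$span_start[open] <= m$span_end[pick] &
             m$span_end[open] >= m$span_start[pick] & open != pick]
    } else {
      setdiff(in_win, pick)
    }
    status[victims] <- "discarded"
    reason[victims] <- "overlap_with_selected"
    n_events <- n_events + 1L
    audit[[n_events]] <- data.frame(
      seq_id = wins$seq_id[w], strand = wins$strand[w],
      window = wins$window[w], count = wins$count[w],
      chosen = m$model_id[pick], n_discarded = length(victims),
      stringsAsFactors = FALSE)
  }

  # Leftover open models failed a filter and overlap nothing selected.
  left <- which(status == "open")
  if (length(left) > 0L) {
    still_eligible <- left[eligible[left]]
    if (length(still_eligible) > 0L) {
      # Unreachable for model scope (every model's own boundaries define
      # windows); defensive: keep such models rather than dropping them.
      status[still_eligible] <- "selected"
      left <- setdiff(left, still_eligible)
    }
    status[left] <- "discarded"
    reason[left] <- ifelse(m$n_exons[left] < min_exons, "filter_exons",
                           "filter_orf_len")
  }

  sel_ids <- m$model_id[status == "selected"]
  disc <- data.frame(model_id = m$model_id[status == "discarded"],
                     reason = reason[status == "discarded"],
                     stringsAsFactors = FALSE)
  rownames(disc) <- NULL
  structure(
    list(selected = subset_set(set, sel_ids[c_order(sel_ids)]),
         discarded = disc[c_order(disc$model_id), , drop = FALSE],
         audit = if (n_events) do.call(rbind, audit[seq_len(n_events)])
                 else empty_audit,
         params = params),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("<selection_result> %d selected, %d discarded ",
                     "(window %d bp, ORF >= %d aa, >= %d exons)\n"),
              nrow(x$selected$models), nrow(x$discarded),
              x$params$window_size, x$params$min_orf_aa,
              x$params$min_exons))
  if (nrow(x$discarded) > 0L) {
    tab <- table(x$discarded$reason)
    cat("  discard reasons:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a selection result
#'
#' @method summary selection_result
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return Named list with input/selected/discarded counts, discards by
#'   reason, and selected counts by evidence track (the homology vs
#'   RNA-seq breakdown of the final annotation).
#' @export
summary.selection_result <- function(object, ...) {
  ev <- table(factor(object$selected$models$evidence,
                     levels = c("homology", "transcript")))
  rs <- table(factor(object$discarded$reason,
                     levels = c("overlap_with_selected", "filter_exons",
                                "filter_orf_len")))
  list(n_input = nrow(object$selected$models) + nrow(object$discarded),
       n_selected = nrow(object$selected$models),
       n_discarded = nrow(object$discarded),
       discarded_by_reason = as.list(rs),
       selected_by_evidence = as.list(ev),
       params = object$params)
}

#' Merge homology and transcript evidence into a joint annotation
#'
#' Unions two annotation sets ahead of [select_nonredundant()]. Evidence
#' labels are preserved so the final report can count how many selected
#' models came from each track. With `prefix = TRUE` (default) model ids
#' are namespaced as `<evidence>:<model_id>` to keep the two tracks
#' disjoint; a duplicate id after prefixing is an error.
#'
#' @param homology,transcript [annotation_set()] objects.
#' @param prefix Prefix each model id with its evidence label.
#' @return The union [annotation_set()].
#' @export
merge_evidence <- function(homology, transcript, prefix = TRUE) {
  stopifnot(inherits(homology, "annotation_set"),
            inherits(transcript, "annotation_set"))
  relabel <- function(set) {
    if (!prefix || nrow(set$models) == 0L) return(set)
    old <- set$models$model_id
    new <- paste0(set$models$evidence, ":", old)
    set$models$model_id <- new
    set$exons$model_id <- new[match(set$exons$model_id, old)]
    set
  }
  h <- relabel(homology)
  tr <- relabel(transcript)
  ids <- c(h$models$model_id, tr$models$model_id)
  if (anyDuplicated(ids)) {
    stopf("duplicate model_id(s) after merging: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  models <- rbind(h$models, tr$models)
  exons <- rbind(h$exons, tr$exons)
  rownames(models) <- rownames(exons) <- NULL
  structure(list(genome_id = homology$genome_id, models = models,
                 exons = exons),
            class = "annotation_set")
}
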