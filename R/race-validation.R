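#' Map RLM-RACE fragments onto transcripts
#'
#' Each adaptor-trimmed fragment is matched by exact full-length substring
#' search against every transcript. A fragment counts iff it occurs exactly
#' once across the whole transcript set; its 5'-end position (1-based) marks
#' the inferred cleavage site. Fragments occurring more than once are
#' ambiguous; fragments occurring nowhere are unmapped; both are excluded
#' from per-transcript totals but tallied so that
#' mapped + ambiguous + unmapped equals the number of input fragments.
#'
#' @param fragments Named character vector of fragment sequences (DNA).
#' @param transcripts Named character vector of transcript sequences.
#' @param max_mismatch Mismatches tolerated in the substring match
#'   (default 0, exact; a small tolerance accommodates Sanger base-call
#'   errors in real clone sets).
#' @return A `CleavageReport` set: list with `reports` (per transcript: list
#'   with `transcript_id`, `position_counts` named integer vector, `total`),
#'   `ambiguous`, `unmapped`, `n_fragments`.
#' @export
map_fragments <- function(fragments, transcripts, max_mismatch = 0) {
  if (any(nchar(fragments) == 0)) stop("empty RACE fragment")
  stopifnot(length(transcripts) > 0, !is.null(names(transcripts)))
  txset <- Biostrings::DNAStringSet(unname(toupper(transcripts)))
  names(txset) <- names(transcripts)
  reports <- lapply(names(transcripts), function(id) {
    list(transcript_id = id, position_counts = integer(0), total = 0L)
  })
  names(reports) <- names(transcripts)
  ambiguous <- 0L; unmapped <- 0L
  for (fr in toupper(fragments)) {
    counts <- Biostrings::vcountPattern(fr, txset, max.mismatch = max_mismatch)
    tot <- sum(counts)
    if (tot == 0) { unmapped <- unmapped + 1L; next }
    if (tot > 1) { ambiguous <- ambiguous + 1L; next }
    ti <- which(counts == 1)
    pos <- BiocGenerics::start(Biostrings::matchPattern(
      fr, txset[[ti]], max.mismatch = max_mismatch))[1]
    key <- as.character(pos)
    pc <- reports[[ti]]$position_counts
    pc[key] <- if (key %in% names(pc)) pc[[key]] + 1L else 1L
    reports[[ti]]$position_counts <- pc
    reports[[ti]]$total <- reports[[ti]]$total + 1L
  }
  structure(list(reports = reports, ambiguous = ambiguous,
                 unmapped = unmapped, n_fragments = length(fragments)),
            class = "CleavageReportSet")
}

#' Annotate cleavage reports with predicted sites
#'
#' Sets each transcript's predicted cleavage position from the accepted
#' duplex hits (best-penalty hit when several), computes the Fig.-5-style
#' fraction string "fragments at the predicted site / total sequenced
#' fragments", and makes an advisory VALIDATED call when at least
#' `min_clones` fragments fall exactly on the predicted position. Transcripts
#' with RACE data but no prediction are reported as unpredicted.
#'
#' @param report_set A `CleavageReportSet` from [map_fragments()].
#' @param hits Accepted hits from [scan_transcriptome()].
#' @param min_clones Minimum at-site clone count for the VALIDATED call
#'   (default 2); the fraction itself is the primary output.
#' @return data.frame: `transcript_id`, `predicted_pos`, `at_site`, `total`,
#'   `fraction`, `validated`, `predicted` (logical).
#' @export
confirm_cleavage <- function(report_set, hits, min_clones = 2) {
  stopifnot(inherits(report_set, "CleavageReportSet"))
  acc <- hits[hits$accepted, , drop = FALSE]
  rows <- lapply(report_set$reports, function(rep) {
    h <- acc[acc$transcript_id == rep$transcript_id, , drop = FALSE]
    predicted <- nrow(h) > 0
    ppos <- if (predicted) h$cleavage_pos[which.min(h$penalty)] else NA_integer_
    at_site <- if (predicted) {
      n <- rep$position_counts[as.character(ppos)]
      if (is.na(n)) 0L else as.integer(n)
    } else NA_integer_
    data.frame(
      transcript_id = rep$transcript_id,
      predicted_pos = ppos,
      at_site = at_site,
      total = rep$total,
      fraction = if (predicted) paste0(at_site, "/", rep$total) else NA_character_,
      validated = predicted && !is.na(at_site) && at_site >= min_clones,
      predicted = predicted,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
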