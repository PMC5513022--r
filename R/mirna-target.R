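#' Classify one miRNA:target base pair
#'
#' The duplex convention is antiparallel and ungapped: miRNA position 1 is the
#' 5' end. Watson-Crick pairs (A:U, U:A, G:C, C:G) are class `M`; G:U wobbles
#' (miRNA G against target U, or miRNA U against target G) are class `W`;
#' everything else is a mismatch `X`. DNA targets are read as RNA (T = U).
#'
#' @param mirna_base,target_base Single RNA/DNA bases.
#' @return `"M"`, `"W"` or `"X"`.
#' @export
classify_pair <- function(mirna_base, target_base) {
  m <- chartr("Tacgut", "UACGUU", mirna_base)
  t <- chartr("Tacgut", "UACGUU", target_base)
  if (!m %in% c("A", "C", "G", "U") || !t %in% c("A", "C", "G", "U")) {
    stop("ambiguity codes are not allowed in duplex classification: ",
         mirna_base, ":", target_base)
  }
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  if (wc[[m]] == t) return("M")
  if ((m == "G" && t == "U") || (m == "U" && t == "G")) return("W")
  "X"
}

# vectorised pair-class lookup: 16 combinations, miRNA base x target base
.pair_class_table <- local({
  b <- c("A", "C", "G", "U")
  tab <- matrix("X", 4, 4, dimnames = list(b, b))
  tab["A", "U"] <- "M"; tab["U", "A"] <- "M"
  tab["G", "C"] <- "M"; tab["C", "G"] <- "M"
  tab["G", "U"] <- "W"; tab["U", "G"] <- "W"
  tab
})

as_rna_chars <- function(seq) {
  x <- strsplit(chartr("acgtuT", "ACGUUU", seq), "", fixed = TRUE)[[1]]
  if (any(!x %in% c("A", "C", "G", "U"))) {
    stop("sequence contains non-ACGT/U characters")
  }
  x
}

#' Score one miRNA:target window
#'
#' The window is the target subsequence written 5' to 3' with the same length
#' L as the miRNA; miRNA position i pairs with window position L - i + 1.
#' Penalty is 1.0 per mismatch plus 0.5 per G:U wobble. The predicted cleavage
#' coordinate is the transcript position paired with miRNA position 10 (the
#' 5' nucleotide of the 3' cleavage fragment that RLM-RACE sequences).
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA letters).
#' @param window Target window, 5' to 3', same length as the miRNA.
#' @param window_start 1-based transcript coordinate of the window's first
#'   base (used for the cleavage coordinate; default 1).
#' @param transcript_id Optional id carried into the hit.
#' @return A one-row data.frame (a `DuplexHit`): `transcript_id`, `start`,
#'   `end`, `pair_classes`, `penalty`, `cleavage_pos`.
#' @export
score_window <- function(mirna, window, window_start = 1L,
                         transcript_id = NA_character_) {
  m <- as_rna_chars(mirna)
  w <- as_rna_chars(window)
  L <- length(m)
  if (length(w) != L) stop("window length ", length(w),
                           " does not match miRNA length ", L)
  cls <- vapply(seq_len(L), function(i) {
    .pair_class_table[m[i], w[L - i + 1L]]
  }, character(1))
  data.frame(
    transcript_id = transcript_id,
    start = as.integer(window_start),
    end = as.integer(window_start + L - 1L),
    pair_classes = paste(cls, collapse = ""),
    penalty = sum(cls == "X") * 1.0 + sum(cls == "W") * 0.5,
    cleavage_pos = as.integer(window_start + L - 10L),
    stringsAsFactors = FALSE
  )
}

#' Apply positional duplex rules to a scored hit
#'
#' Rules, indexed by miRNA position (1 = 5' end): at most one mismatch within
#' positions 1-9 (`SEED`), no mismatch at positions 10-11 (`SITE`), no run of
#' more than two consecutive mismatches after position 11 (`RUN`), and total
#' penalty at most `threshold` (`PENALTY`, boundary inclusive). G:U wobbles
#' count as pairs for all positional rules but contribute 0.5 to the penalty.
#'
#' @param hit A one-row data.frame from [score_window()].
#' @param threshold Penalty threshold (default 2.5).
#' @param strict_site Also reject wobbles at positions 10-11 (default FALSE).
#' @return The hit with `accepted` (logical) and `reasons` (comma-separated
#'   codes, empty when accepted) columns added.
#' @export
apply_rules <- function(hit, threshold = 2.5, strict_site = FALSE) {
  cls <- strsplit(hit$pair_classes, "", fixed = TRUE)[[1]]
  L <- length(cls)
  reasons <- character(0)
  if (sum(cls[1:9] == "X") > 1) reasons <- c(reasons, "SEED")
  site_bad <- any(cls[10:11] == "X") ||
    (strict_site && any(cls[10:11] == "W"))
  if (site_bad) reasons <- c(reasons, "SITE")
  if (L >= 12) {
    tail_x <- cls[12:L] == "X"
    runs <- rle(tail_x)
    if (any(runs$values & runs$lengths > 2)) reasons <- c(reasons, "RUN")
  }
  if (hit$penalty > threshold) reasons <- c(reasons, "PENALTY")
  hit$accepted <- length(reasons) == 0
  hit$reasons <- paste(reasons, collapse = ",")
  hit
}

#' Scan transcripts for miRNA target sites
#'
#' Evaluates every ungapped window of miRNA length on the sense strand of
#' every transcript, scores it, applies the positional rules and returns hits.
#' Transcripts shorter than the miRNA are skipped with a warning.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param transcripts Named character vector of transcript sequences.
#' @param threshold Penalty threshold (default 2.5, inclusive).
#' @param strict_site See [apply_rules()].
#' @param report_rejected Also return rejected windows with reason codes.
#' @return data.frame of hits sorted by (transcript, penalty, position), with
#'   the columns of [score_window()] plus `accepted`, `reasons`.
#' @export
scan_transcriptome <- function(mirna, transcripts, threshold = 2.5,
                               strict_site = FALSE, report_rejected = FALSE) {
  if (length(transcripts) == 0) return(empty_hits())
  stopifnot(!is.null(names(transcripts)))
  m <- as_rna_chars(mirna)
  L <- length(m)
  res <- vector("list", length(transcripts))
  for (ti in seq_along(transcripts)) {
    tx <- transcripts[[ti]]
    tchars <- as_rna_chars(tx)
    n <- length(tchars)
    if (n < L) {
      warning("transcript '", names(transcripts)[ti],
              "' shorter than the miRNA; skipped")
      next
    }
    starts <- seq_len(n - L + 1L)
    # class matrix: rows = miRNA positions, cols = window starts
    cls <- matrix("X", nrow = L, ncol = length(starts))
    for (i in seq_len(L)) {
      cls[i, ] <- .pair_class_table[m[i], tchars[starts + (L - i)]]
    }
    is_x <- cls == "X"
    penalty <- colSums(is_x) + 0.5 * colSums(cls == "W")
    seed_ok <- colSums(is_x[1:9, , drop = FALSE]) <= 1
    site_ok <- !is_x[10, ] & !is_x[11, ]
    if (strict_site) site_ok <- site_ok & cls[10, ] != "W" & cls[11, ] != "W"
    run_ok <- rep(TRUE, length(starts))
    if (L >= 14) {
      for (j in 12:(L - 2)) {
        run_ok <- run_ok & !(is_x[j, ] & is_x[j + 1, ] & is_x[j + 2, ])
      }
    }
    accepted <- seed_ok & site_ok & run_ok & (penalty <= threshold)
    keep <- if (report_rejected) rep(TRUE, length(starts)) else accepted
    if (!any(keep)) next
    ks <- starts[keep]
    reasons <- vapply(which(keep), function(j) {
      r <- character(0)
      if (!seed_ok[j]) r <- c(r, "SEED")
      if (!site_ok[j]) r <- c(r, "SITE")
      if (!run_ok[j]) r <- c(r, "RUN")
      if (penalty[j] > threshold) r <- c(r, "PENALTY")
      paste(r, collapse = ",")
    }, character(1))
    res[[ti]] <- data.frame(
      transcript_id = names(transcripts)[ti],
      start = ks,
      end = ks + L - 1L,
      pair_classes = apply(cls[, keep, drop = FALSE], 2, paste, collapse = ""),
      penalty = penalty[keep],
      cleavage_pos = ks + L - 10L,
      accepted = accepted[keep],
      reasons = reasons,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) return(empty_hits())
  out <- out[order(out$transcript_id, out$penalty, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(transcript_id = character(0), start = integer(0),
             end = integer(0), pair_classes = character(0),
             penalty = numeric(0), cleavage_pos = integer(0),
             accepted = logical(0), reasons = character(0),
             stringsAsFactors = FALSE)
}
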