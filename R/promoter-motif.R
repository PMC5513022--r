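#' Built-in MYB cis-element consensus motifs
#'
#' `MBS` (MYB binding site) = `YAACWAMC`, i.e. (C/T)AAC(A/T)A(A/C)C;
#' `MBSIIG` (SMRE, secondary wall MYB-responsive element) = `YACCWAMC`,
#' i.e. (C/T)ACC(A/T)A(A/C)C. Each degenerate 8-mer expands to exactly 8
#' concrete words (2 x 1 x 1 x 1 x 2 x 1 x 2 x 1).
#'
#' @export
myb_motifs <- function() c(MBS = "YAACWAMC", MBSIIG = "YACCWAMC")

#' Extract a proximal promoter from a genome
#'
#' The anchor is the annotated translation start (CDS start), since
#' UTR/TSS annotation is typically unavailable: on the + strand the promoter
#' is the `length` bases at genomic coordinates
#' `[cds_start - length, cds_start - 1]` reported 5' to 3'; on the - strand
#' it is the reverse complement of `[cds_end + 1, cds_end + length]`.
#' Promoters running off the scaffold edge are truncated with a warning.
#'
#' @param genome Named character vector of scaffold sequences.
#' @param gene One row of a gene-model data.frame ([read_gff3()]).
#' @param length Promoter length in bp (default 500).
#' @return Character scalar: the promoter sequence, 5' to 3' on the gene's
#'   coding strand, with attribute `actual_length`.
#' @export
extract_promoter <- function(genome, gene, length = 500) {
  stopifnot(gene$strand %in% c("+", "-"))
  scaf <- genome[[gene$seq_id]]
  if (is.null(scaf)) stop("scaffold '", gene$seq_id, "' not in genome")
  slen <- nchar(scaf)
  if (gene$strand == "+") {
    from <- max(1L, gene$cds_start - length)
    to <- gene$cds_start - 1L
    if (to < from) stop("gene '", gene$gene_id, "': promoter has length 0")
    p <- substr(scaf, from, to)
  } else {
    from <- gene$cds_end + 1L
    to <- min(slen, gene$cds_end + length)
    if (to < from) stop("gene '", gene$gene_id, "': promoter has length 0")
    p <- revcomp_dna(substr(scaf, from, to))
  }
  if (nchar(p) < length) {
    warning("gene '", gene$gene_id, "': promoter truncated to ",
            nchar(p), " bp at scaffold edge")
  }
  attr(p, "actual_length") <- nchar(p)
  p
}

#' Scan a promoter for degenerate consensus motifs on both strands
#'
#' All overlapping occurrences are reported. A minus-strand hit is a match of
#' the reverse complement of the consensus against the given sequence; its
#' position is the 5'-most plus-strand coordinate. Positions are reported
#' both promoter-local (1-based) and anchor-relative, where the anchor (ATG)
#' sits just 3' of the promoter's last base, so local position p in a
#' promoter of length L maps to `p - L - 1` (in [-500, -8] for a full-length
#' promoter and 8-nt motif).
#'
#' @param promoter DNA sequence (character scalar) as from
#'   [extract_promoter()].
#' @param motifs Named character vector of IUPAC consensus strings
#'   (default [myb_motifs()]).
#' @param gene_id Optional id carried into the hits.
#' @return data.frame of `MotifHit`s: `gene_id`, `motif`, `strand`, `pos`
#'   (1-based local), `pos_rel_anchor`, `match` (the matched word).
#' @export
scan_motifs <- function(promoter, motifs = myb_motifs(),
                        gene_id = NA_character_) {
  L <- nchar(promoter)
  subj <- Biostrings::DNAString(promoter)
  rows <- list()
  for (mn in names(motifs)) {
    pat <- Biostrings::DNAString(motifs[[mn]])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subj, fixed = "subject")
      st <- BiocGenerics::start(m)
      if (length(st) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, motif = mn, strand = strand, pos = st,
        pos_rel_anchor = st - L - 1L,
        match = as.character(Biostrings::DNAStringSet(m)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), motif = character(0),
                      strand = character(0), pos = integer(0),
                      pos_rel_anchor = integer(0), match = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$motif, out$pos, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Per-gene motif presence table over a cohort
#'
#' Extracts each gene's proximal promoter and scans it for every motif,
#' returning a wide presence table plus the full hit list. Extraction errors
#' for single genes are downgraded to warnings and that gene is skipped.
#'
#' @param genes Gene-model data.frame ([read_gff3()]).
#' @param genome Named character vector of scaffolds.
#' @param motifs Named character vector of IUPAC consensus strings.
#' @param length Promoter length (default 500).
#' @return List with `presence` (data.frame gene_id x motif logical) and
#'   `hits` (all `MotifHit`s).
#' @export
motif_presence_table <- function(genes, genome, motifs = myb_motifs(),
                                 length = 500) {
  hits <- list()
  pres <- matrix(NA, nrow(genes), base::length(motifs),
                 dimnames = list(genes$gene_id, names(motifs)))
  for (i in seq_len(nrow(genes))) {
    p <- tryCatch(extract_promoter(genome, genes[i, ], length = length),
                  error = function(e) {
                    warning("skipping gene '", genes$gene_id[i], "': ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(p)) next
    h <- scan_motifs(p, motifs, gene_id = genes$gene_id[i])
    hits[[i]] <- h
    pres[i, ] <- names(motifs) %in% h$motif
  }
  all_hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(all_hits)) all_hits <- scan_motifs("", motifs)[0, ]
  presence <- data.frame(gene_id = rownames(pres), pres,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(presence = presence, hits = all_hits)
}
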