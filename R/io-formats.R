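#' Read a (multi-record) FASTA file
#'
#' Sequences are uppercased on input and validated against the nucleotide
#' alphabet `A,C,G,T,U,N`. Records containing `U` are flagged as RNA, all
#' others as DNA. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences with an `alphabet` attribute
#'   (character vector, `"DNA"` or `"RNA"` per record). An empty file yields
#'   an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    out <- character(0)
    attr(out, "alphabet") <- character(0)
    return(out)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], " in ", path)
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) {
    stop("sequence '", ids[bad][1], "' contains characters outside A,C,G,T,U,N")
  }
  names(seqs) <- ids
  attr(seqs, "alphabet") <- ifelse(grepl("U", seqs, fixed = TRUE), "RNA", "DNA")
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(names(seqs) != ""))
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Only `gene` and `CDS` features are consulted. Per gene the CDS span is
#' collapsed to `cds_start = min(CDS start)`, `cds_end = max(CDS end)`;
#' coordinates stay GFF3-style 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `seq_id`, `strand`,
#'   `cds_start`, `cds_end`, `family` (NA when not annotated).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  cds <- gr[type == "CDS"]
  if (length(genes) == 0) stop("no gene features in ", path)
  gid <- as.character(genes$ID)
  gstrand <- as.character(BiocGenerics::strand(genes))
  if (any(gstrand == "*")) {
    stop("gene '", gid[gstrand == "*"][1],
         "' has no strand; promoter extraction requires one")
  }
  if (length(cds) > 0 && is.null(cds$Parent)) {
    stop("CDS feature without a parent gene in ", path)
  }
  parent <- vapply(cds$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  if (any(is.na(parent)) || !all(parent %in% gid)) {
    stop("CDS feature without a parent gene in ", path)
  }
  fam <- if (!is.null(genes$family)) as.character(genes$family) else {
    rep(NA_character_, length(genes))
  }
  out <- data.frame(
    gene_id = gid,
    seq_id = as.character(GenomicRanges::seqnames(genes)),
    strand = gstrand,
    cds_start = NA_integer_,
    cds_end = NA_integer_,
    family = fam,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    mine <- which(parent == out$gene_id[i])
    if (length(mine) == 0) stop("gene '", out$gene_id[i], "' has no CDS")
    out$cds_start[i] <- min(BiocGenerics::start(cds)[mine])
    out$cds_end[i] <- max(BiocGenerics::end(cds)[mine])
  }
  out
}

write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr_g <- paste0("ID=", g$gene_id)
    if (!is.na(g$family)) attr_g <- paste0(attr_g, ";family=", g$family)
    writeLines(sprintf("%s\tlignoreg\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$seq_id, g$cds_start, g$cds_end, g$strand, attr_g), con)
    writeLines(sprintf("%s\tlignoreg\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                       g$seq_id, g$cds_start, g$cds_end, g$strand,
                       g$gene_id, g$gene_id), con)
  }
  invisible(path)
}

#' Read a Cq table from a 96.96 dynamic-array export
#'
#' Expects a TSV with header columns `assay`, `sample`, `condition`,
#' `replicate`, `cq`. A Cq of `"ND"` (not detected) is kept as missing, never
#' imputed to zero; assays that are ND in every observation are flagged
#' undetectable.
#'
#' @param path Path to the TSV.
#' @return A list of class `CqMatrix`: `observations` (data.frame with `cq`
#'   numeric, NA = undetected), `detectable` (named logical per assay),
#'   `efficiencies` (empty until [estimate_efficiency()]), `reference_assays`.
#' @export
read_cq_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty Cq table: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("assay", "sample", "condition", "replicate", "cq")
  if (!all(need %in% header)) {
    stop("Cq table must have columns: ", paste(need, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_bad <- which(lengths(parts) != length(header))
  if (length(n_bad) > 0) {
    stop("malformed Cq row at line ", n_bad[1] + 1L, " of ", path)
  }
  mat <- do.call(rbind, parts)
  colnames(mat) <- header
  cq_raw <- mat[, "cq"]
  cq <- suppressWarnings(as.numeric(cq_raw))
  bad <- is.na(cq) & cq_raw != "ND"
  if (any(bad)) {
    stop("non-numeric Cq (not 'ND') at line ", which(bad)[1] + 1L, " of ", path)
  }
  obs <- data.frame(
    assay = mat[, "assay"],
    sample = mat[, "sample"],
    condition = mat[, "condition"],
    replicate = as.integer(mat[, "replicate"]),
    cq = cq,
    stringsAsFactors = FALSE
  )
  detectable <- tapply(!is.na(obs$cq), obs$assay, any)
  structure(list(
    observations = obs,
    detectable = setNames(as.logical(detectable), names(detectable)),
    efficiencies = numeric(0),
    reference_assays = character(0)
  ), class = "CqMatrix")
}

#' Write hits as BED-like 6-column TSV
#'
#' Columns: `seq_id`, `start0`, `end0` (0-based half-open), `name`, `score`,
#' `strand`.
#'
#' @param hits data.frame with 1-based inclusive `start`, `end` plus `seq_id`,
#'   `name`, `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(hits, path) {
  z <- to_zero_based(hits$start, hits$end)
  write_tsv(data.frame(seq_id = hits$seq_id, start0 = z$start, end0 = z$end,
                       name = hits$name, score = hits$score,
                       strand = hits$strand), path)
}
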