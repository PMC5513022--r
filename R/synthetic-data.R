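#' @name synthetic_data
#' @title Synthetic-data generators with ground-truth manifests
#' @description Every pipeline input can be generated with planted,
#'   manifest-recorded ground truth: promoters carrying MYB cis-elements,
#'   transcripts carrying miRNA target duplexes of controlled pair-class
#'   structure, Cq matrices with planted fold changes and stable reference
#'   genes, RACE read sets concentrated at planted cleavage positions, and
#'   expression profiles with planted co-expression clusters. Identical
#'   seeds give identical outputs; every planted element is recoverable by
#'   the corresponding analysis module (the planting contract).
NULL

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

expand_iupac <- function(consensus) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  words <- ""
  for (ch in chars) {
    words <- as.vector(outer(words, codes[[ch]], paste0))
  }
  sort(words)
}

#' Generate a genome with planted promoter motifs
#'
#' Emits one scaffold per gene (500 bp promoter + 600 bp CDS + 500 bp
#' flank, uniform ACGT background), genes alternating between strands, and
#' plants the requested degenerate-consensus motif instances into the
#' proximal promoters. The generator re-scans every promoter: if background
#' sequence creates an unintended instance overlapping a planted one, the
#' background is redrawn; accidental instances elsewhere are recorded in the
#' manifest.
#'
#' @param n_genes Number of genes (>= 1).
#' @param promoter_motif_spec A list, one element per gene (recycled names
#'   `gene1`..`geneN`), each a data.frame with columns `motif`
#'   (name in `motifs`), `offset` (anchor-relative position of the planted
#'   word's 5' end, in `[-500, -motif length]`) and optionally `strand`;
#'   may be NULL / empty for no planting.
#' @param seed Integer seed.
#' @param motifs Named IUPAC consensus vector (default [myb_motifs()]).
#' @return List with `genome` (named character), `genes` (gene-model
#'   data.frame), `manifest` (planted and accidental motifs, seed).
#' @export
make_genome <- function(n_genes, promoter_motif_spec = NULL, seed = 0,
                        motifs = myb_motifs()) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  plen <- 500L
  withr::with_seed(seed, {
    genome <- character(0)
    genes <- list()
    planted <- list()
    accidental <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%d", g)
      strand <- if (g %% 2 == 1) "+" else "-"
      spec <- if (!is.null(promoter_motif_spec) &&
                  length(promoter_motif_spec) >= g) {
        promoter_motif_spec[[g]]
      } else NULL
      spans <- NULL
      if (!is.null(spec) && nrow(spec) > 0) {
        wlen <- nchar(motifs[spec$motif])
        if (any(is.na(wlen))) stop("unknown motif name in spec for ", gid)
        if (any(spec$offset < -plen | spec$offset > -wlen)) {
          stop(gid, ": planted offset outside the ", plen, " bp promoter")
        }
        if (is.null(spec$strand)) {
          spec$strand <- sample(c("+", "-"), nrow(spec), replace = TRUE)
        }
        p1 <- spec$offset + plen + 1L      # promoter-local 1-based start
        spans <- cbind(p1, p1 + wlen - 1L)
        o <- order(p1)
        if (nrow(spans) > 1 &&
            any(spans[o, 1][-1] <= spans[o, 2][-nrow(spans)])) {
          stop(gid, ": planted motif instances overlap each other")
        }
      }
      # redraw background until no unintended instance overlaps a planted one
      for (attempt in seq_len(200)) {
        prom <- strsplit(random_dna(plen), "", fixed = TRUE)[[1]]
        if (!is.null(spans)) {
          for (i in seq_len(nrow(spans))) {
            word <- sample(expand_iupac(motifs[[spec$motif[i]]]), 1)
            if (spec$strand[i] == "-") word <- revcomp_dna(word)
            prom[spans[i, 1]:spans[i, 2]] <- strsplit(word, "", fixed = TRUE)[[1]]
          }
        }
        prom_s <- paste(prom, collapse = "")
        hits <- scan_motifs(prom_s, motifs, gene_id = gid)
        ok <- TRUE
        if (!is.null(spans)) {
          on_plant <- rep(FALSE, nrow(hits))
          matched <- logical(nrow(spec))
          for (i in seq_len(nrow(spans))) {
            ov <- hits$pos <= spans[i, 2] & (hits$pos + nchar(motifs[hits$motif]) - 1L) >= spans[i, 1]
            exact <- ov & hits$pos == spans[i, 1] & hits$motif == spec$motif[i] &
              hits$strand == spec$strand[i]
            matched[i] <- any(exact)
            if (any(ov & !exact)) ok <- FALSE
            on_plant <- on_plant | ov
          }
          if (!all(matched)) ok <- FALSE
          acc <- hits[!on_plant, , drop = FALSE]
        } else {
          acc <- hits
        }
        if (ok) break
        if (attempt == 200) stop(gid, ": could not realize motif planting")
      }
      cds <- random_dna(600L)
      flank <- random_dna(500L)
      if (strand == "+") {
        scaf <- paste0(prom_s, cds, flank)
        cds_start <- plen + 1L
      } else {
        scaf <- paste0(flank, cds, revcomp_dna(prom_s))
        cds_start <- 501L
      }
      sid <- sprintf("scaffold%d", g)
      genome[sid] <- scaf
      genes[[g]] <- data.frame(gene_id = gid, seq_id = sid, strand = strand,
                               cds_start = cds_start,
                               cds_end = cds_start + 599L,
                               family = NA_character_,
                               stringsAsFactors = FALSE)
      if (!is.null(spec) && nrow(spec) > 0) {
        planted[[g]] <- data.frame(gene_id = gid, motif = spec$motif,
                                   strand = spec$strand,
                                   pos_rel_anchor = spec$offset,
                                   stringsAsFactors = FALSE)
      }
      if (nrow(acc) > 0) {
        accidental[[g]] <- data.frame(gene_id = gid, motif = acc$motif,
                                      strand = acc$strand,
                                      pos_rel_anchor = acc$pos_rel_anchor,
                                      stringsAsFactors = FALSE)
      }
    }
    list(genome = genome,
         genes = do.call(rbind, genes),
         manifest = list(
           seed = seed,
           planted_motifs = if (length(planted)) do.call(rbind, planted) else NULL,
           accidental_motifs = if (length(accidental)) do.call(rbind, accidental) else NULL))
  })
}

wc_partner <- c(A = "T", U = "A", G = "C", C = "G")
wobble_partner <- c(G = "T", U = "G")   # target DNA letters

#' Generate transcripts with planted miRNA target duplexes
#'
#' For each site specification (a string over `M` = Watson-Crick pair,
#' `W` = G:U wobble, `X` = mismatch, one character per miRNA position
#' 5' to 3'), emits one transcript embedding exactly one window realizing
#' that pair-class pattern, built backwards from the miRNA sequence.
#' Decoy transcripts are verified to contain no window of penalty <= 2.5.
#' Flanks are redrawn if they would create additional rule-satisfying
#' windows.
#'
#' @param mirna Mature miRNA, 5' to 3' (RNA letters).
#' @param site_specs Character vector of pair-class strings, each of the
#'   miRNA's length.
#' @param n_decoys Number of target-free decoy transcripts.
#' @param seed Integer seed.
#' @param flank Flank length around each planted window (default 120).
#' @return List with `transcripts` (named character, DNA), `manifest`
#'   (`planted_targets` data.frame with window coordinates, pair classes,
#'   expected penalty, expected cleavage position, rule verdict and reasons;
#'   `decoys`; seed).
#' @export
make_targets <- function(mirna, site_specs, n_decoys = 0, seed = 0,
                         flank = 120L) {
  m <- as_rna_chars(mirna)
  L <- length(m)
  if (L < 12) stop("miRNA must be at least 12 nt for the positional rules")
  withr::with_seed(seed, {
    txs <- character(0)
    planted <- list()
    for (s in seq_along(site_specs)) {
      cls <- strsplit(site_specs[[s]], "", fixed = TRUE)[[1]]
      if (length(cls) != L || any(!cls %in% c("M", "W", "X"))) {
        stop("site spec ", s, " must be a length-", L, " string over M/W/X")
      }
      target <- character(L)
      for (i in seq_len(L)) {
        b <- m[i]
        target[L - i + 1L] <- switch(cls[i],
          M = wc_partner[[b]],
          W = {
            if (!b %in% names(wobble_partner)) {
              stop("site spec ", s, ": position ", i, " requests a wobble but ",
                   "miRNA base ", b, " cannot wobble (only G or U can)")
            }
            wobble_partner[[b]]
          },
          X = {
            excl <- wc_partner[[b]]
            if (b %in% names(wobble_partner)) excl <- c(excl, wobble_partner[[b]])
            sample(setdiff(DNA_BASES, excl), 1)
          })
      }
      window <- paste(target, collapse = "")
      tid <- sprintf("tx_site%d", s)
      for (attempt in seq_len(200)) {
        tx <- paste0(random_dna(flank), window, random_dna(flank))
        hits <- scan_transcriptome(mirna, setNames(tx, tid))
        site_ok <- apply_rules(score_window(mirna, window))$accepted
        want <- if (site_ok) 1L else 0L
        extra <- hits[!(hits$start == flank + 1L), , drop = FALSE]
        if (nrow(extra) == 0 && sum(hits$start == flank + 1L) == want) break
        if (attempt == 200) stop(tid, ": could not realize planted window")
      }
      txs[tid] <- tx
      scored <- apply_rules(score_window(mirna, window,
                                         window_start = flank + 1L,
                                         transcript_id = tid))
      planted[[s]] <- data.frame(
        transcript_id = tid, window_start = flank + 1L,
        pair_classes = paste(cls, collapse = ""),
        expected_penalty = scored$penalty,
        expected_cleavage_pos = scored$cleavage_pos,
        rule_ok = scored$accepted, reasons = scored$reasons,
        stringsAsFactors = FALSE)
    }
    decoys <- character(0)
    if (n_decoys > 0) {
      for (d in seq_len(n_decoys)) {
        tid <- sprintf("tx_decoy%d", d)
        for (attempt in seq_len(200)) {
          tx <- random_dna(300L)
          all_w <- scan_transcriptome(mirna, setNames(tx, tid),
                                      threshold = Inf, report_rejected = TRUE)
          if (min(all_w$penalty) > 2.5) break
          if (attempt == 200) stop(tid, ": could not draw a clean decoy")
        }
        txs[tid] <- tx
        decoys <- c(decoys, tid)
      }
    }
    list(transcripts = txs,
         manifest = list(seed = seed,
                         planted_targets = do.call(rbind, planted),
                         decoys = decoys))
  })
}

#' Generate a Cq dataset with planted fold changes
#'
#' Emulates a 96.96 dynamic-array design: each assay is measured in every
#' condition on `n_bio` biological samples, each in `n_tech` technical
#' replicates (default 3 x 3, n = 9 values per condition). Cq values follow
#' `Cq = baseline - log_E(true quantity) + Normal(0, noise_sd)`; reference
#' assays have true fold 1 everywhere. A noise-free dilution series
#' (1, 0.1, 0.01) is emitted per assay with the same efficiency.
#'
#' @param conditions Character vector of condition names; the first is the
#'   implicit calibrator (true quantity 1).
#' @param fold_changes Numeric matrix assay x condition of true quantities
#'   relative to the first condition (reference assays must be all 1).
#' @param efficiencies Named numeric vector per assay, in (1, 2.2].
#' @param reference_assays Character vector naming the stable assays.
#' @param noise_sd Gaussian Cq noise, cycles (default 0.15).
#' @param n_bio,n_tech Replicate structure (default 3 and 3).
#' @param seed Integer seed.
#' @return List with `cq` (a `CqMatrix` with efficiencies and references
#'   set), `cq_table` / `dilution_table` (data.frames as written to TSV),
#'   `manifest`.
#' @export
make_cq_dataset <- function(conditions, fold_changes, efficiencies,
                            reference_assays, noise_sd = 0.15,
                            n_bio = 3, n_tech = 3, seed = 0) {
  stopifnot(is.matrix(fold_changes),
            identical(colnames(fold_changes), conditions),
            all(rownames(fold_changes) %in% names(efficiencies)))
  if (any(efficiencies <= 1 | efficiencies > 2.2)) {
    stop("efficiencies must lie in (1, 2.2]")
  }
  if (any(fold_changes[reference_assays, ] != 1)) {
    stop("reference assays must have fold change 1 in every condition")
  }
  assays <- rownames(fold_changes)
  withr::with_seed(seed, {
    baseline <- setNames(round(runif(length(assays), 18, 26), 2), assays)
    rows <- list()
    for (a in assays) {
      for (ci in seq_along(conditions)) {
        q <- fold_changes[a, ci]
        true_cq <- baseline[[a]] - log(q) / log(efficiencies[[a]])
        for (b in seq_len(n_bio)) {
          for (t in seq_len(n_tech)) {
            rows[[length(rows) + 1L]] <- data.frame(
              assay = a, sample = paste0(conditions[ci], b),
              condition = conditions[ci], replicate = t,
              cq = true_cq + rnorm(1, 0, noise_sd),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    cq_table <- do.call(rbind, rows)
    dil <- expand.grid(assay = assays, dilution = c(1, 0.1, 0.01),
                       stringsAsFactors = FALSE)
    dil$cq <- baseline[dil$assay] -
      log10(dil$dilution) / log10(efficiencies[dil$assay])
    dil <- dil[order(dil$assay, -dil$dilution), ]
    rownames(dil) <- NULL
    cq <- structure(list(
      observations = cq_table,
      detectable = setNames(rep(TRUE, length(assays)), assays),
      efficiencies = efficiencies,
      reference_assays = reference_assays
    ), class = "CqMatrix")
    list(cq = cq, cq_table = cq_table, dilution_table = dil,
         manifest = list(seed = seed, planted_fold_changes = fold_changes,
                         efficiencies = efficiencies,
                         reference_assays = reference_assays,
                         noise_sd = noise_sd, baseline = baseline))
  })
}

#' Generate RACE reads concentrated at a planted cleavage site
#'
#' `n_at_site` reads are exact transcript substrings starting at
#' `cleavage_pos`; `n_background` reads start uniformly at other positions.
#' Every read is checked to occur exactly once in the transcript set (drawn
#' again otherwise) so that [map_fragments()] counts it unambiguously.
#'
#' @param transcripts Named character vector (the read donor must be the
#'   first element or named by `transcript_id`).
#' @param transcript_id Donor transcript id.
#' @param cleavage_pos 1-based cleavage position (read 5' end).
#' @param n_at_site,n_background Read counts.
#' @param read_len Read length (default 40); `cleavage_pos + read_len - 1`
#'   must not exceed the transcript length.
#' @param seed Integer seed.
#' @return List with `fragments` (named character) and `manifest`.
#' @export
make_race_reads <- function(transcripts, transcript_id, cleavage_pos,
                            n_at_site, n_background, read_len = 40L,
                            seed = 0) {
  tx <- transcripts[[transcript_id]]
  if (is.null(tx)) stop("transcript '", transcript_id, "' not found")
  n <- nchar(tx)
  if (cleavage_pos + read_len - 1L > n) {
    stop("read of length ", read_len, " at position ", cleavage_pos,
         " runs past the transcript end (", n, " nt)")
  }
  occurs_once <- function(read) {
    sum(vapply(transcripts, function(t) {
      length(gregexpr(read, t, fixed = TRUE)[[1]]) *
        (gregexpr(read, t, fixed = TRUE)[[1]][1] != -1)
    }, numeric(1))) == 1
  }
  withr::with_seed(seed, {
    frs <- character(0)
    site_read <- substr(tx, cleavage_pos, cleavage_pos + read_len - 1L)
    if (!occurs_once(site_read)) stop("at-site read is not unique")
    for (i in seq_len(n_at_site)) frs[sprintf("read_site%d", i)] <- site_read
    starts_pool <- setdiff(seq_len(n - read_len + 1L), cleavage_pos)
    for (i in seq_len2(n_background)) {
      for (attempt in seq_len(100)) {
        st <- sample(starts_pool, 1)
        rd <- substr(tx, st, st + read_len - 1L)
        if (occurs_once(rd)) break
        if (attempt == 100) stop("could not draw a unique background read")
      }
      frs[sprintf("read_bg%d", i)] <- rd
    }
    list(fragments = frs,
         manifest = list(seed = seed, transcript_id = transcript_id,
                         cleavage_pos = cleavage_pos, n_at_site = n_at_site,
                         n_background = n_background, read_len = read_len))
  })
}

seq_len2 <- function(n) if (n > 0) seq_len(n) else integer(0)

#' Generate expression profiles with planted clusters
#'
#' Cluster archetypes are centered condition indicators scaled by
#' `separation` (pairwise Pearson correlation below zero for distinct
#' archetypes whenever `separation > 0`); each member profile is its
#' archetype plus i.i.d. Gaussian noise. With `separation = 0` the labels
#' are unidentifiable but still recorded in the manifest.
#'
#' @param k Number of clusters (requires `k <= n_conditions`).
#' @param genes_per_cluster Genes per cluster.
#' @param separation Archetype scale (log2 units; default 4).
#' @param noise_sd Per-value Gaussian noise (default 0.5).
#' @param n_conditions Number of conditions (default 10).
#' @param seed Integer seed.
#' @return List with `profiles` (matrix genes x conditions) and `manifest`
#'   (`planted_clusters` named integer vector, seed).
#' @export
make_profiles <- function(k, genes_per_cluster = 8, separation = 4,
                          noise_sd = 0.5, n_conditions = 10, seed = 0) {
  if (k < 1) stop("k must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  if (k > n_conditions) stop("need k <= n_conditions for distinct archetypes")
  withr::with_seed(seed, {
    arch <- matrix(0, k, n_conditions)
    for (j in seq_len(k)) {
      e <- rep(0, n_conditions); e[j] <- 1
      arch[j, ] <- separation * (e - mean(e))
    }
    n <- k * genes_per_cluster
    labels <- rep(seq_len(k), each = genes_per_cluster)
    profiles <- arch[labels, , drop = FALSE] +
      matrix(rnorm(n * n_conditions, 0, noise_sd), n, n_conditions)
    rownames(profiles) <- sprintf("g%02d_%02d", labels,
                                  sequence(rep(genes_per_cluster, k)))
    colnames(profiles) <- sprintf("cond%02d", seq_len(n_conditions))
    list(profiles = profiles,
         manifest = list(seed = seed,
                         planted_clusters = setNames(labels,
                                                     rownames(profiles))))
  })
}
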