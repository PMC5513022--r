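#' Default pipeline configuration
#'
#' One flat list drives [run_all()]: the root seed (all stage randomness is
#' derived from it via named substreams), generator sizes, and every
#' analysis threshold. The synthetic cohort plants six bona fide candidate
#' genes (higher in stem, root and inner stem tissue), one
#' hypolignified-pattern decoy (up in stem/root and in the *outer* tissue),
#' flat null genes, three stable reference assays, miRNA target sites of
#' controlled structure and one RACE-supported cleavage site.
#'
#' @param seed Integer root seed.
#' @param out_dir Output directory.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 0, out_dir = tempfile("lignoreg_run_")) {
  list(
    seed = seed, out_dir = out_dir,
    n_genes = 12, n_positive = 6, planted_fold = 8,
    mirna = "UCAUUGAGUGCAGCGUUGAUG",       # 21-nt laccase-targeting miRNA
    site_specs = NULL,                     # NULL = built-in panel
    n_decoys = 3,
    race_at_site = 7, race_background = 3,
    noise_sd = 0.15, n_bio = 3, n_tech = 3,
    alpha = 0.01, min_lfc = 1.0, penalty_threshold = 2.5,
    k = 2, restarts = 5, promoter_length = 500
  )
}

#' Run the whole synthetic pipeline end to end
#'
#' Stage order: simulate, qpcr, cluster, mirna-target, racemap,
#' promoter-scan, prioritize. Every stage reads its inputs from the files
#' the simulate stage wrote (FASTA/GFF3/TSV), so the run exercises the full
#' I/O surface; all outputs plus `truth.json`, the serialized config and an
#' md5 checksum manifest land in `config$out_dir`. Identical configurations
#' give byte-identical outputs.
#'
#' @param config List from [default_config()] (possibly modified).
#' @return Invisibly, a list with the key in-memory results
#'   (`candidates`, `calls`, `clusters`, `hits`, `cleavage`, `motifs`,
#'   `truth`) and `out_dir`.
#' @export
run_all <- function(config = default_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$out_dir, f)
  log_stage <- function(s) message("[lignoreg] stage: ", s)

  ## ---- simulate ----
  log_stage("simulate")
  gene_ids <- sprintf("gene%d", seq_len(cfg$n_genes))
  positives <- gene_ids[seq_len(cfg$n_positive)]
  decoy <- gene_ids[cfg$n_positive + 1L]
  refs <- c("ref1", "ref2", "ref3")
  # plant MBSIIG in every positive promoter; MBS in a couple of others
  mspec <- setNames(vector("list", cfg$n_genes), gene_ids)
  for (i in seq_len(cfg$n_genes)) {
    if (gene_ids[i] %in% positives) {
      mspec[[i]] <- data.frame(motif = "MBSIIG", offset = -100L,
                               strand = "+", stringsAsFactors = FALSE)
    } else if (i %% 3 == 0) {
      mspec[[i]] <- data.frame(motif = "MBS", offset = -250L,
                               strand = "-", stringsAsFactors = FALSE)
    }
  }
  gen <- make_genome(cfg$n_genes, mspec,
                     seed = derive_seed(cfg$seed, "genome"))
  write_fasta(gen$genome, pth("genome.fa"))
  write_gff3(gen$genes, pth("genes.gff3"))

  conditions <- c("leaf", "stem", "root", "OT", "IT")
  folds <- matrix(1, cfg$n_genes + length(refs), length(conditions),
                  dimnames = list(c(gene_ids, refs), conditions))
  folds[positives, c("stem", "root", "IT")] <- cfg$planted_fold
  folds[positives, "OT"] <- 1
  folds[decoy, c("stem", "root", "OT")] <- cfg$planted_fold  # hypolignified pattern
  eff <- setNames(rep(c(2.0, 1.95, 1.9), length.out = nrow(folds)),
                  rownames(folds))
  qd <- make_cq_dataset(conditions, folds, eff, refs,
                        noise_sd = cfg$noise_sd, n_bio = cfg$n_bio,
                        n_tech = cfg$n_tech,
                        seed = derive_seed(cfg$seed, "cq"))
  write_tsv(qd$cq_table, pth("cq.tsv"))
  write_tsv(qd$dilution_table, pth("dilutions.tsv"))

  site_specs <- cfg$site_specs
  if (is.null(site_specs)) {
    L <- nchar(cfg$mirna)
    all_m <- strrep("M", L)
    site_specs <- c(
      all_m,                                               # perfect
      paste0(substr(all_m, 1, 4), "X", substr(all_m, 6, L)),   # 1 seed mm, ok
      paste0(substr(all_m, 1, 9), "X", substr(all_m, 11, L)),  # X at 10: reject
      paste0("X", substr(all_m, 2, 4), "X", substr(all_m, 6, L)) # 2 seed mm: reject
    )
  }
  tg <- make_targets(cfg$mirna, site_specs, n_decoys = cfg$n_decoys,
                     seed = derive_seed(cfg$seed, "targets"))
  write_fasta(tg$transcripts, pth("transcripts.fa"))

  pt <- tg$manifest$planted_targets
  donor <- pt[pt$rule_ok, ][1, ]
  rr <- make_race_reads(tg$transcripts, donor$transcript_id,
                        donor$expected_cleavage_pos,
                        n_at_site = cfg$race_at_site,
                        n_background = cfg$race_background,
                        seed = derive_seed(cfg$seed, "race"))
  write_fasta(rr$fragments, pth("race.fa"))

  truth <- list(seed = cfg$seed,
                genome = gen$manifest, cq = qd$manifest,
                targets = tg$manifest, race = rr$manifest,
                positives = positives, decoy = decoy)
  jsonlite::write_json(truth, pth("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  ## ---- qpcr ----
  log_stage("qpcr")
  cq <- read_cq_table(pth("cq.tsv"))
  cq$efficiencies <- estimate_efficiency(pth("dilutions.tsv"))
  cq$reference_assays <- refs
  nrq <- normalize_cq(cq)
  design <- data.frame(condition = c("stem", "root", "IT"),
                       control = c("leaf", "leaf", "OT"),
                       stringsAsFactors = FALSE)
  cr <- condition_ratios(nrq, design, alpha = cfg$alpha)
  write_tsv(data.frame(assay = rownames(nrq$nrq),
                       round(log2(nrq$nrq), 6), check.names = FALSE),
            pth("nrq_log2.tsv"))
  calls_out <- cr$calls
  calls_out$log2_ratio <- round(calls_out$log2_ratio, 6)
  write_tsv(calls_out, pth("calls.tsv"))
  write_tsv(data.frame(assay = rownames(cr$heatmap),
                       round(cr$heatmap, 6), check.names = FALSE),
            pth("heatmap.tsv"))

  ## ---- cluster ----
  log_stage("cluster")
  expr <- log2(nrq$nrq[!rownames(nrq$nrq) %in% refs, , drop = FALSE])
  cl <- consensus_over_restarts(expr, k = cfg$k, n_restarts = cfg$restarts,
                                seed = derive_seed(cfg$seed, "cluster"))
  write_tsv(data.frame(gene_id = names(cl$labels), cluster = cl$labels,
                       row.names = NULL), pth("clusters.tsv"))

  ## ---- mirna-target ----
  log_stage("mirna-target")
  txs <- read_fasta(pth("transcripts.fa"))
  hits <- scan_transcriptome(cfg$mirna, txs,
                             threshold = cfg$penalty_threshold)
  write_tsv(hits, pth("hits.tsv"))

  ## ---- racemap ----
  log_stage("racemap")
  frs <- read_fasta(pth("race.fa"))
  rep_set <- map_fragments(frs, txs)
  cleavage <- confirm_cleavage(rep_set, hits)
  write_tsv(cleavage, pth("cleavage.tsv"))

  ## ---- promoter-scan ----
  log_stage("promoter-scan")
  genome <- read_fasta(pth("genome.fa"))
  genes <- read_gff3(pth("genes.gff3"))
  mt <- motif_presence_table(genes, genome, length = cfg$promoter_length)
  write_tsv(mt$hits, pth("motif_hits.tsv"))
  write_tsv(mt$presence, pth("motif_presence.tsv"))

  ## ---- prioritize ----
  log_stage("prioritize")
  candidates <- call_candidates(cr$calls, cl$labels, mt$presence,
                                min_lfc = cfg$min_lfc, alpha = cfg$alpha)
  cand_out <- candidates
  num <- vapply(cand_out, is.numeric, logical(1))
  cand_out[num] <- lapply(cand_out[num], function(x) round(x, 6))
  write_tsv(cand_out, pth("candidates.tsv"))

  jsonlite::write_json(cfg[order(names(cfg))], pth("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- sort(setdiff(list.files(cfg$out_dir), "checksums.json"))
  sums <- tools::md5sum(file.path(cfg$out_dir, outputs))
  names(sums) <- outputs
  jsonlite::write_json(as.list(sums), pth("checksums.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(out_dir = cfg$out_dir, candidates = candidates,
                 calls = cr$calls, clusters = cl, hits = hits,
                 cleavage = cleavage, motifs = mt, truth = truth,
                 nrq = nrq))
}
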