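test_that("consensus motifs expand to exactly 8 concrete words each", {
  for (m in myb_motifs()) {
    expect_length(oracle_expand(m), 8)
  }
  expect_true("CAACAAAC" %in% oracle_expand(myb_motifs()[["MBS"]]))
  expect_true("TACCTAAC" %in% oracle_expand(myb_motifs()[["MBSIIG"]]))
})

test_that("promoter extraction honours strand, anchor and scaffold edges", {
  scaf <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")  # 1000 bp
  genome <- c(scf = scaf)
  plus <- data.frame(gene_id = "g+", seq_id = "scf", strand = "+",
                     cds_start = 1001 - 0, cds_end = 1000)
  plus$cds_start <- 1001  # promoter would be genomic 501..1000
  # make scaffold long enough for that gene
  genome2 <- c(scf = paste0(scaf, scaf))
  p <- extract_promoter(genome2, plus)
  expect_equal(p[1], substr(genome2[["scf"]], 501, 1000),
               ignore_attr = TRUE)
  minus <- data.frame(gene_id = "g-", seq_id = "scf", strand = "-",
                      cds_start = 1, cds_end = 400)
  pm <- extract_promoter(genome, minus)
  expect_equal(pm[1], lignoreg:::revcomp_dna(substr(scaf, 401, 900)),
               ignore_attr = TRUE)
  short <- data.frame(gene_id = "gs", seq_id = "scf", strand = "+",
                      cds_start = 300, cds_end = 500)
  expect_warning(ps <- extract_promoter(genome, short), "truncated")
  expect_equal(attr(ps, "actual_length"), 299)
  zero <- data.frame(gene_id = "gz", seq_id = "scf", strand = "+",
                     cds_start = 1, cds_end = 100)
  expect_error(extract_promoter(genome, zero), "length 0")
})

test_that("literal 8-mers hit on the expected strand at position 1", {
  h <- scan_motifs("CAACAAAC")
  expect_equal(nrow(h), 1)
  expect_equal(h$motif, "MBS")
  expect_equal(h$strand, "+")
  expect_equal(h$pos, 1)
  expect_equal(h$pos_rel_anchor, -8)
  h2 <- scan_motifs("GTTTGTTG")  # reverse complement of CAAACAAC? no: of CAACAAAC
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$pos, 1)
})

test_that("scanner equals the word-expansion oracle on random promoters", {
  withr::local_seed(202)
  for (i in 1:50) {
    seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    got <- scan_motifs(seq)
    want <- oracle_motif_scan(seq, myb_motifs())
    got <- got[order(got$motif, got$pos, got$strand), ]
    expect_equal(got$motif, want$motif)
    expect_equal(got$pos, want$pos)
    expect_equal(got$strand, want$strand)
  }
})

test_that("strand involution: scanning the reverse complement mirrors hits", {
  withr::local_seed(203)
  for (i in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    fwd <- scan_motifs(seq)
    rev <- scan_motifs(lignoreg:::revcomp_dna(seq))
    # 1-based mirror of an 8-mer starting at p in a length-L sequence
    key <- function(h, L) paste(h$motif,
                                ifelse(h$strand == "+", "-", "+"),
                                L - h$pos - 6)
    expect_setequal(key(fwd, 300), paste(rev$motif, rev$strand, rev$pos))
  }
})

test_that("planting contract: presence table equals the manifest", {
  spec <- list(
    data.frame(motif = "MBSIIG", offset = -100L, strand = "+"),
    data.frame(motif = "MBS", offset = -250L, strand = "-"),
    NULL,
    data.frame(motif = c("MBS", "MBSIIG"), offset = c(-400L, -60L),
               strand = c("+", "+")))
  gen <- make_genome(4, spec, seed = 77)
  mt <- motif_presence_table(gen$genes, gen$genome)
  tr <- gen$manifest
  for (g in seq_len(4)) {
    gid <- sprintf("gene%d", g)
    for (mn in names(myb_motifs())) {
      planted <- !is.null(tr$planted_motifs) &&
        any(tr$planted_motifs$gene_id == gid & tr$planted_motifs$motif == mn)
      accidental <- !is.null(tr$accidental_motifs) &&
        any(tr$accidental_motifs$gene_id == gid &
              tr$accidental_motifs$motif == mn)
      expect_equal(mt$presence[mt$presence$gene_id == gid, mn],
                   planted || accidental,
                   info = paste(gid, mn))
    }
  }
  # planted positions are reported at their anchor-relative offsets
  for (r in seq_len(nrow(tr$planted_motifs))) {
    pm <- tr$planted_motifs[r, ]
    sub <- mt$hits[mt$hits$gene_id == pm$gene_id & mt$hits$motif == pm$motif, ]
    expect_true(pm$pos_rel_anchor %in% sub$pos_rel_anchor)
  }
})

test_that("make_genome validates input and is deterministic", {
  expect_error(make_genome(0), "n_genes")
  bad <- list(data.frame(motif = "MBS", offset = -3L, strand = "+"))
  expect_error(make_genome(1, bad), "outside")
  ovl <- list(data.frame(motif = c("MBS", "MBS"), offset = c(-100L, -104L),
                         strand = c("+", "+")))
  expect_error(make_genome(1, ovl), "overlap")
  a <- make_genome(3, seed = 12)
  b <- make_genome(3, seed = 12)
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes, b$genes)
})

test_that("background hit rate matches the 2^-13 closed form", {
  withr::local_seed(31)
  n <- 2e6  # positions scanned (x 2 motifs x 2 strands)
  seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  hits <- scan_motifs(seq)
  trials <- (n - 7) * 2 * 2
  p <- 8 / 4^8
  expect_lt(abs(nrow(hits) - trials * p), 5 * sqrt(trials * p * (1 - p)))
})
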