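MIR <- "UCAUUGAGUGCAGCGUUGAUG"  # 21 nt
L <- nchar(MIR)

test_that("classify_pair follows Watson-Crick / wobble / mismatch classes", {
  expect_equal(classify_pair("G", "C"), "M")
  expect_equal(classify_pair("A", "U"), "M")
  expect_equal(classify_pair("A", "T"), "M")  # DNA target read as RNA
  expect_equal(classify_pair("G", "U"), "W")
  expect_equal(classify_pair("U", "G"), "W")
  expect_equal(classify_pair("A", "G"), "X")
  expect_equal(classify_pair("C", "U"), "X")
  expect_error(classify_pair("N", "A"), "ambiguity")
})

test_that("score_window scores the reverse complement as a perfect duplex", {
  win <- lignoreg:::revcomp_dna(chartr("U", "T", MIR))
  h <- score_window(MIR, win)
  expect_equal(h$penalty, 0)
  expect_equal(h$pair_classes, strrep("M", L))
  # one wobble: miRNA position 3 is A -> cannot wobble; use position 1 (U:G)
  w2 <- win
  substr(w2, L, L) <- "G"   # pairs miRNA position 1 (U)
  h2 <- score_window(MIR, w2)
  expect_equal(h2$penalty, 0.5)
  expect_equal(substr(h2$pair_classes, 1, 1), "W")
  expect_error(score_window(MIR, "ACGT"), "length")
})

test_that("cleavage coordinate pairs with miRNA position 10", {
  tg <- make_targets(MIR, strrep("M", L), seed = 3)
  hit <- scan_transcriptome(MIR, tg$transcripts)
  expect_equal(nrow(hit), 1)
  # recompute the pairing index: window position L-10+1 pairs miRNA pos 10
  expect_equal(hit$cleavage_pos, hit$start + L - 10)
  tx_base <- substr(tg$transcripts[[1]], hit$cleavage_pos, hit$cleavage_pos)
  mir10 <- substr(MIR, 10, 10)
  expect_equal(classify_pair(mir10, tx_base), "M")
})

test_that("positional rules reject with the stated reason codes", {
  m <- strrep("M", L)
  put <- function(pos, ch) {
    s <- strsplit(m, "")[[1]]; s[pos] <- ch; paste(s, collapse = "")
  }
  mk <- function(spec) {
    tg <- make_targets(MIR, spec, seed = 7)
    w <- substr(tg$transcripts[[1]], 121, 120 + L)
    apply_rules(score_window(MIR, w))
  }
  expect_equal(mk(put(10, "X"))$reasons, "SITE")
  h <- mk(put(c(1, 5), "X"))
  expect_equal(h$reasons, "SEED")
  h <- mk(put(13:15, "X"))
  expect_true(grepl("RUN", h$reasons))
  expect_true(grepl("PENALTY", h$reasons))
  expect_equal(h$penalty, 3.0)
  # wobbles are pairs, not mismatches: W at 13-15 is accepted at penalty 1.5
  hw <- mk(put(which(strsplit(MIR, "")[[1]] %in% c("G", "U"))[
    which(strsplit(MIR, "")[[1]] %in% c("G", "U")) >= 13][1:3], "W"))
  expect_true(hw$accepted)
  expect_equal(hw$penalty, 1.5)
})

test_that("penalty monotonicity under M->W and M->X edits", {
  base <- score_window(MIR, lignoreg:::revcomp_dna(chartr("U", "T", MIR)))
  mchars <- strsplit(MIR, "")[[1]]
  for (i in seq_len(L)) {
    spec <- strsplit(strrep("M", L), "")[[1]]
    spec[i] <- "X"
    tg <- make_targets(MIR, paste(spec, collapse = ""), seed = 11 + i)
    w <- substr(tg$transcripts[[1]], 121, 120 + L)
    expect_equal(score_window(MIR, w)$penalty, base$penalty + 1.0)
    if (mchars[i] %in% c("G", "U")) {
      spec[i] <- "W"
      tgw <- make_targets(MIR, paste(spec, collapse = ""), seed = 211 + i)
      ww <- substr(tgw$transcripts[[1]], 121, 120 + L)
      expect_equal(score_window(MIR, ww)$penalty, base$penalty + 0.5)
    }
  }
})

test_that("scan_transcriptome equals the brute-force oracle on random data", {
  withr::local_seed(42)
  mirnas <- vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  }, "")
  txs <- setNames(
    vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    }, ""),
    sprintf("tx%02d", 1:20))
  # random sequence alone rarely yields hits; also plant near-complements
  for (mir in mirnas) {
    extra <- make_targets(mir, c(strrep("M", 21),
                                 paste0("MMMMXMMMM", strrep("M", 12)),
                                 paste0(strrep("M", 11), "XXMMXXMMMM")),
                          n_decoys = 0, seed = 99)$transcripts
    all_tx <- c(txs, extra)
    got <- scan_transcriptome(mir, all_tx)
    want <- oracle_scan(mir, all_tx)
    got <- got[order(got$transcript_id, got$start), ]
    expect_equal(got$transcript_id, want$transcript_id)
    expect_equal(got$start, want$start)
    expect_equal(got$penalty, want$penalty)
    expect_equal(got$pair_classes, want$pair_classes)
    expect_equal(got$cleavage_pos, want$cleavage_pos)
  }
  expect_equal(nrow(scan_transcriptome(mirnas[1], character(0))), 0)
  expect_warning(scan_transcriptome(mirnas[1], c(short = "ACGT")), "skipped")
})

test_that("planting contract: accepted set is exactly the rule-satisfying plants", {
  m <- strrep("M", L)
  put <- function(pos, ch) {
    s <- strsplit(m, "")[[1]]; s[pos] <- ch; paste(s, collapse = "")
  }
  specs <- c(m,                        # perfect, accept
             put(5, "X"),             # one seed mismatch, accept
             put(10, "X"),            # SITE violation
             put(c(1, 5), "X"),       # SEED violation
             put(13:15, "X"))         # RUN violation
  tg <- make_targets(MIR, specs, n_decoys = 5, seed = 17)
  hits <- scan_transcriptome(MIR, tg$transcripts)
  truth <- tg$manifest$planted_targets
  good <- truth[truth$rule_ok, ]
  expect_setequal(hits$transcript_id, good$transcript_id)
  expect_equal(hits$start[match(good$transcript_id, hits$transcript_id)],
               good$window_start)
  expect_equal(hits$penalty[match(good$transcript_id, hits$transcript_id)],
               good$expected_penalty)
  bad <- truth[!truth$rule_ok, ]
  expect_equal(bad$reasons, c("SITE", "SEED", "RUN,PENALTY"))
  expect_false(any(bad$transcript_id %in% hits$transcript_id))
  expect_false(any(grepl("decoy", hits$transcript_id)))
})

test_that("make_targets validates wobble feasibility and determinism", {
  # miRNA position with base C can never wobble
  cpos <- which(strsplit(MIR, "")[[1]] == "C")[1]
  spec <- strsplit(strrep("M", L), "")[[1]]; spec[cpos] <- "W"
  expect_error(make_targets(MIR, paste(spec, collapse = "")),
               "cannot wobble")
  a <- make_targets(MIR, strrep("M", L), n_decoys = 2, seed = 8)
  b <- make_targets(MIR, strrep("M", L), n_decoys = 2, seed = 8)
  expect_identical(a$transcripts, b$transcripts)
})

test_that("antisense strand carries no mirrored hit", {
  tg <- make_targets(MIR, strrep("M", L), seed = 23)
  rc <- setNames(lignoreg:::revcomp_dna(tg$transcripts[[1]]),
                 names(tg$transcripts))
  expect_equal(nrow(scan_transcriptome(MIR, rc)), 0)
})
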