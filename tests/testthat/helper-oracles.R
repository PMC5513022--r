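# Independent brute-force oracles. These deliberately re-derive every rule
# from scratch (different data structures, no shared helpers with the
# package) so that agreement is a genuine cross-check.

# -- duplex oracle: re-classify, re-score and re-filter every window --------
oracle_pair <- function(mb, tb) {
  mb <- sub("T", "U", toupper(mb)); tb <- sub("T", "U", toupper(tb))
  pair <- paste0(mb, tb)
  if (pair %in% c("AU", "UA", "GC", "CG")) return("M")
  if (pair %in% c("GU", "UG")) return("W")
  "X"
}

oracle_scan <- function(mirna, transcripts, threshold = 2.5) {
  m <- strsplit(toupper(mirna), "")[[1]]
  L <- length(m)
  out <- list()
  for (tid in names(transcripts)) {
    tx <- strsplit(toupper(transcripts[[tid]]), "")[[1]]
    if (length(tx) < L) next
    for (st in 1:(length(tx) - L + 1)) {
      win <- tx[st:(st + L - 1)]
      cls <- character(L)
      for (i in 1:L) cls[i] <- oracle_pair(m[i], win[L - i + 1])
      pen <- sum(cls == "X") + 0.5 * sum(cls == "W")
      ok <- TRUE
      if (sum(cls[1:9] == "X") > 1) ok <- FALSE
      if (cls[10] == "X" || cls[11] == "X") ok <- FALSE
      run <- 0
      for (i in 12:L) {
        run <- if (cls[i] == "X") run + 1 else 0
        if (run > 2) ok <- FALSE
      }
      if (pen > threshold) ok <- FALSE
      if (ok) {
        out[[length(out) + 1]] <- data.frame(
          transcript_id = tid, start = st, penalty = pen,
          pair_classes = paste(cls, collapse = ""),
          cleavage_pos = st + L - 10, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      penalty = numeric(0), pair_classes = character(0),
                      cleavage_pos = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$transcript_id, res$start), , drop = FALSE]
}

# -- motif oracle: expand the consensus into words, substring-search --------
oracle_expand <- function(consensus) {
  tab <- list(A = "A", C = "C", G = "G", T = "T", Y = c("C", "T"),
              W = c("A", "T"), M = c("A", "C"))
  words <- ""
  for (ch in strsplit(consensus, "")[[1]]) {
    words <- as.vector(outer(words, tab[[ch]], paste0))
  }
  words
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

oracle_motif_scan <- function(seq, motifs) {
  out <- list()
  for (mn in names(motifs)) {
    for (strand in c("+", "-")) {
      words <- oracle_expand(motifs[[mn]])
      if (strand == "-") words <- vapply(words, oracle_revcomp, "")
      for (w in words) {
        # overlapping occurrences via lookahead-free stepping
        st <- 1
        repeat {
          p <- regexpr(w, substr(seq, st, nchar(seq)), fixed = TRUE)
          if (p == -1) break
          pos <- st + p - 1
          out[[length(out) + 1]] <- data.frame(
            motif = mn, strand = strand, pos = pos, stringsAsFactors = FALSE)
          st <- pos + 1
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif = character(0), strand = character(0),
                      pos = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  res[order(res$motif, res$pos, res$strand), , drop = FALSE]
}

# -- Mann-Whitney oracle: full enumeration over label assignments -----------
oracle_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  v <- c(x, y)
  r <- rank(v)
  mu <- n1 * n2 / 2
  U_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  U_obs <- U_of(seq_len(n1))
  sets <- combn(N, n1)
  devs <- apply(sets, 2, function(idx) abs(U_of(idx) - mu))
  sum(devs >= abs(U_obs - mu) - 1e-9) / ncol(sets)
}

# -- clustering helpers -----------------------------------------------------
# all partitions of n items into at most k non-empty groups (canonical form)
all_partitions <- function(n, k) {
  labs <- list(1L)
  for (i in 2:n) {
    labs <- unlist(lapply(labs, function(l) {
      mx <- max(l)
      lapply(seq_len(min(mx + 1L, k)), function(c) c(l, c))
    }), recursive = FALSE)
  }
  labs
}

partition_objective <- function(profiles, labels) {
  tot <- 0
  for (c in unique(labels)) {
    mem <- profiles[labels == c, , drop = FALSE]
    ctr <- apply(mem, 2, median)
    for (i in seq_len(nrow(mem))) {
      d <- if (sd(ctr) == 0) 1 else 1 - cor(mem[i, ], ctr)
      tot <- tot + d
    }
  }
  tot
}

random_profiles <- function(n, p, seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    rownames(m) <- sprintf("g%d", seq_len(n))
    m
  })
}
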