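#' Estimate amplification efficiencies from a dilution series
#'
#' Fits, per assay, the least-squares slope of Cq against log10 relative
#' input and returns `E = 10^(-1/slope)` (fold amplification per cycle; 2 is
#' perfect doubling). Efficiencies outside (1.6, 2.2] trigger a warning but
#' are kept, since published assays report no hard QC rule.
#'
#' @param dilution_table data.frame with columns `assay`, `dilution`
#'   (relative input, e.g. 1, 0.1, 0.01) and `cq`, or a path to such a TSV.
#' @return Named numeric vector of efficiencies per assay.
#' @export
estimate_efficiency <- function(dilution_table) {
  if (is.character(dilution_table)) {
    dilution_table <- read.delim(dilution_table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("assay", "dilution", "cq") %in% names(dilution_table)))
  out <- vapply(split(dilution_table, dilution_table$assay), function(d) {
    pts <- unique(d$dilution)
    if (length(pts) < 3) {
      stop("assay '", d$assay[1], "': need >= 3 dilution points, got ",
           length(pts))
    }
    if (log10(max(pts) / min(pts)) < 2 - 1e-9) {
      stop("assay '", d$assay[1], "': dilution series spans < 2 log10 units")
    }
    slope <- stats::coef(stats::lm(cq ~ log10(dilution), data = d))[[2]]
    if (slope >= 0) {
      stop("assay '", d$assay[1], "': non-negative dilution slope (",
           signif(slope, 3), "); corrupt series")
    }
    10^(-1 / slope)
  }, numeric(1))
  low <- out <= 1.6 | out > 2.2
  if (any(low)) {
    warning("efficiency outside (1.6, 2.2] for: ",
            paste(names(out)[low], collapse = ", "))
  }
  out
}

#' qBase-style multi-reference normalization of a Cq matrix
#'
#' Per assay g and sample s, the relative quantity is
#' `RQ[g,s] = E_g^(meanCq_g - Cq[g,s])` with `meanCq_g` the across-sample
#' arithmetic mean Cq (the qBase calibrator). The normalization factor
#' `NF_s` is the geometric mean of the reference assays' RQ in sample s, and
#' `NRQ = RQ / NF`. Undetected (NA) observations are excluded, not imputed.
#'
#' @param cq A `CqMatrix` from [read_cq_table()] with `efficiencies` and
#'   `reference_assays` filled in (see [estimate_efficiency()]).
#' @param average_technical Average technical replicates to one Cq per
#'   (assay, biological sample) before normalizing. Requires a
#'   `bio_sample` column in the observations; default FALSE treats each
#'   replicate row as its own sample (the pooled n = 9 convention).
#' @return An `NRQMatrix`: list with `nrq` (matrix assay x sample),
#'   `sample_condition` (named character), `reference_assays`.
#' @export
normalize_cq <- function(cq, average_technical = FALSE) {
  stopifnot(inherits(cq, "CqMatrix"))
  obs <- cq$observations
  if (length(cq$efficiencies) == 0) stop("no efficiencies set; run estimate_efficiency")
  if (length(cq$reference_assays) == 0) stop("no reference assays set")
  if (average_technical) {
    # the `sample` column is the biological unit; `replicate` the technical rep
    if (is.null(obs$bio_sample)) obs$bio_sample <- obs$sample
    key <- interaction(obs$assay, obs$bio_sample, obs$condition, drop = TRUE)
    obs <- do.call(rbind, lapply(split(obs, key), function(d) {
      data.frame(assay = d$assay[1], sample = d$bio_sample[1],
                 condition = d$condition[1], replicate = 1L,
                 cq = mean(d$cq, na.rm = TRUE), stringsAsFactors = FALSE)
    }))
  } else {
    # each (sample, replicate) row is a normalization unit
    obs$sample <- paste(obs$sample, obs$replicate, sep = ".")
  }
  obs <- obs[!is.na(obs$cq), , drop = FALSE]
  assays <- unique(obs$assay)
  samples <- unique(obs$sample)
  miss_e <- setdiff(assays, names(cq$efficiencies))
  if (length(miss_e) > 0) stop("missing efficiency for assay: ", miss_e[1])
  if (any(cq$efficiencies[assays] <= 1)) stop("non-positive log-efficiency")
  cqm <- matrix(NA_real_, length(assays), length(samples),
                dimnames = list(assays, samples))
  cqm[cbind(obs$assay, obs$sample)] <- obs$cq
  for (r in cq$reference_assays) {
    if (!r %in% assays) stop("reference assay '", r, "' absent from data")
    bad <- samples[is.na(cqm[r, ])]
    if (length(bad) > 0) {
      stop("reference assay '", r, "' missing in sample '", bad[1], "'")
    }
  }
  E <- cq$efficiencies[assays]
  mean_cq <- rowMeans(cqm, na.rm = TRUE)
  rq <- E^(mean_cq - cqm)           # recycles by column
  nf <- exp(colMeans(log(rq[cq$reference_assays, , drop = FALSE])))
  nrq <- sweep(rq, 2, nf, "/")
  cond <- setNames(obs$condition[!duplicated(obs$sample)],
                   obs$sample[!duplicated(obs$sample)])[samples]
  structure(list(nrq = nrq, sample_condition = cond,
                 reference_assays = cq$reference_assays),
            class = "NRQMatrix")
}

#' Exact Mann-Whitney (Wilcoxon rank-sum) test with mid-ranks
#'
#' Computes the exact permutation p-value of the Mann-Whitney U statistic
#' under random relabeling, assigning mid-ranks to ties. Two-sided p is the
#' fraction of the C(n1+n2, n1) label assignments whose U deviates from the
#' null mean n1*n2/2 at least as much as observed. The exact distribution is
#' obtained by a subset-sum count over doubled mid-ranks (exact for ties);
#' when either group exceeds 12 observations a normal approximation with tie
#' correction is used and flagged.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param alternative Only `"two_sided"` is implemented.
#' @return List with `p_value`, `U` (for `x`), `exact` (logical).
#' @export
mann_whitney_exact <- function(x, y, alternative = "two_sided") {
  stopifnot(alternative == "two_sided")
  if (length(x) == 0 || length(y) == 0) stop("empty group in Mann-Whitney test")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                    # mid-ranks
  W_obs <- sum(r[seq_len(n1)])
  U_obs <- W_obs - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= 12 && n2 <= 12) {
    d <- as.integer(round(2 * r))       # doubled mid-ranks are integers
    # counts[k, s+1] = number of size-k subsets of d with sum s
    maxs <- sum(sort(d, decreasing = TRUE)[seq_len(n1)])
    counts <- matrix(0, n1 + 1, maxs + 1)
    counts[1, 1] <- 1
    for (v in d) {
      kmax <- n1
      for (k in kmax:1) {
        idx <- seq_len(maxs + 1 - v)
        counts[k + 1, idx + v] <- counts[k + 1, idx + v] + counts[k, idx]
      }
    }
    sums <- (0:maxs) / 2                               # back to rank scale
    Uvals <- sums - n1 * (n1 + 1) / 2
    cnt <- counts[n1 + 1, ]
    dev <- abs(Uvals - mu)
    p <- sum(cnt[dev >= abs(U_obs - mu) - 1e-9]) / choose(N, n1)
    list(p_value = p, U = U_obs, exact = TRUE)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U_obs - mu) / sqrt(sigma2)
    list(p_value = min(1, 2 * pnorm(-abs(z))), U = U_obs, exact = FALSE)
  }
}

#' Condition ratios and differential calls from normalized quantities
#'
#' For each assay and each (condition, control) comparison in the design,
#' computes `log2(mean NRQ_condition / mean NRQ_control)` and an exact
#' Mann-Whitney p-value on the per-sample NRQs. Assays undetected in either
#' condition are marked not testable and excluded from the heatmap table.
#'
#' @param nrq An `NRQMatrix` from [normalize_cq()].
#' @param design data.frame with columns `condition`, `control` (one row per
#'   comparison, e.g. stem vs leaf, root vs leaf, IT vs OT).
#' @param alpha Significance level (default 0.01).
#' @return List with `calls` (data.frame: assay, condition, control,
#'   log2_ratio, p_value, significant, testable) and `heatmap` (matrix of
#'   log2 ratios, assays x comparisons, reference assays excluded).
#' @export
condition_ratios <- function(nrq, design, alpha = 0.01) {
  stopifnot(inherits(nrq, "NRQMatrix"),
            all(c("condition", "control") %in% names(design)))
  conds <- nrq$sample_condition
  missing_ctrl <- setdiff(design$control, conds)
  if (length(missing_ctrl) > 0) {
    stop("control condition '", missing_ctrl[1], "' absent from samples")
  }
  assays <- rownames(nrq$nrq)
  rows <- list()
  for (i in seq_len(nrow(design))) {
    cc <- design$condition[i]; ctl <- design$control[i]
    if (!cc %in% conds) stop("condition '", cc, "' absent from samples")
    a_cols <- conds == cc; b_cols <- conds == ctl
    for (a in assays) {
      va <- nrq$nrq[a, a_cols]; vb <- nrq$nrq[a, b_cols]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      testable <- length(va) > 0 && length(vb) > 0
      if (testable) {
        lr <- log2(mean(va) / mean(vb))
        p <- mann_whitney_exact(va, vb)$p_value
      } else {
        lr <- NA_real_; p <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        assay = a, condition = cc, control = ctl, log2_ratio = lr,
        p_value = p, significant = testable && !is.na(p) && p < alpha,
        testable = testable, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  keep <- !calls$assay %in% nrq$reference_assays & calls$testable
  hm_calls <- calls[keep, , drop = FALSE]
  cmp <- paste(hm_calls$condition, hm_calls$control, sep = "_vs_")
  heatmap <- tapply(hm_calls$log2_ratio,
                    list(factor(hm_calls$assay, unique(hm_calls$assay)),
                         factor(cmp, unique(cmp))), mean)
  list(calls = calls, heatmap = heatmap)
}
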