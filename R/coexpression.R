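#' Pearson correlation distance between two expression profiles
#'
#' `d = 1 - r`, in [0, 2]; 0 for perfectly correlated profiles, 2 for
#' perfectly anti-correlated ones. Requires length >= 3 and nonzero variance
#' in both vectors (Pearson is undefined for constant profiles, which callers
#' must filter out first).
#'
#' @param a,b Numeric vectors of equal length.
#' @return Distance in [0, 2].
#' @export
pearson_distance <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero-variance profile: Pearson distance undefined")
  }
  1 - cor(a, b)
}

# distances from all profiles (rows) to one center; a degenerate
# zero-variance center is treated as uncorrelated (d = 1)
.dist_to_center <- function(mat, center) {
  if (sd(center) == 0) return(rep(1, nrow(mat)))
  1 - as.vector(cor(t(mat), center))
}

#' k-means-medians clustering under Pearson distance
#'
#' MeV-style KMC: starting from a seeded random partition into k groups,
#' iterate (1) centers = element-wise median of members, (2) reassign each
#' profile to the nearest center by Pearson correlation distance, refilling
#' any emptied cluster with the profile farthest from its own center.
#' Nearest-center ties go to the lowest cluster index. Iteration stops at a
#' stable assignment, at `max_iter`, or if a full iteration would increase
#' the total within-cluster distance (in which case the previous assignment
#' is kept; element-wise medians do not exactly minimize summed Pearson
#' distance, and this rule makes the objective non-increasing by
#' construction).
#'
#' @param profiles Numeric matrix, genes x conditions, rownames = gene ids.
#'   Zero-variance rows are excluded with a warning.
#' @param k Number of clusters (default 10, the MeV KMC default).
#' @param max_iter Maximum iterations (default 50, the MeV default).
#' @param seed Integer seed for the random initial partition.
#' @param init Optional integer vector of initial labels (overrides the
#'   seeded random partition; used for deterministic restarts).
#' @return A `ClusterAssignment`: list with `labels` (named integer vector,
#'   contiguous 1..k), `centers` (k x conditions matrix), `objective`
#'   (total within-cluster distance), `objective_trace`, `n_iterations`,
#'   `converged`, `excluded` (zero-variance gene ids).
#' @export
kmedians_cluster <- function(profiles, k = 10, max_iter = 50, seed = 0,
                             init = NULL) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  const <- apply(profiles, 1, sd) == 0
  excluded <- rownames(profiles)[const]
  if (any(const)) {
    warning("excluding ", sum(const), " zero-variance profile(s): ",
            paste(excluded, collapse = ", "))
    profiles <- profiles[!const, , drop = FALSE]
  }
  n <- nrow(profiles)
  if (k < 1 || k > n) stop("k must be between 1 and the number of profiles (", n, ")")
  labels <- if (is.null(init)) {
    withr::with_seed(seed, {
      l <- sample(rep_len(seq_len(k), n))   # every cluster non-empty
      l
    })
  } else {
    stopifnot(length(init) == n, all(init %in% seq_len(k)))
    as.integer(init)
  }
  centers <- matrix(NA_real_, k, ncol(profiles))
  objective <- function(lab, cen) {
    sum(vapply(seq_len(n), function(i) {
      .dist_to_center(profiles[i, , drop = FALSE], cen[lab[i], ])
    }, numeric(1)))
  }
  update_centers <- function(lab) {
    t(vapply(seq_len(k), function(c) {
      apply(profiles[lab == c, , drop = FALSE], 2, median)
    }, numeric(ncol(profiles))))
  }
  centers <- update_centers(labels)
  obj <- objective(labels, centers)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    dmat <- matrix(vapply(seq_len(k),
                          function(c) .dist_to_center(profiles, centers[c, ]),
                          numeric(n)), nrow = n, ncol = k)
    new_labels <- max.col(-dmat, ties.method = "first")  # lowest index on ties
    # refill emptied clusters with the profile farthest from its own center
    for (c in seq_len(k)) {
      if (!any(new_labels == c)) {
        dcur <- dmat[cbind(seq_len(n), new_labels)]
        dcur[tabulate(new_labels, k)[new_labels] <= 1] <- -Inf
        new_labels[which.max(dcur)] <- c
      }
    }
    if (all(new_labels == labels)) { converged <- TRUE; break }
    new_centers <- update_centers(new_labels)
    new_obj <- objective(new_labels, new_centers)
    if (new_obj > obj + 1e-12) { converged <- TRUE; break }
    labels <- new_labels
    centers <- new_centers
    obj <- new_obj
    trace <- c(trace, obj)
  }
  # relabel to contiguous 1..k in first-appearance order
  map <- match(labels, unique(labels))
  centers <- centers[unique(labels), , drop = FALSE]
  structure(list(
    labels = setNames(as.integer(map), rownames(profiles)),
    centers = centers, objective = obj, objective_trace = trace,
    n_iterations = iter, converged = converged, excluded = excluded,
    k = length(unique(map))
  ), class = "ClusterAssignment")
}

#' Best-of-restarts consensus clustering
#'
#' Runs [kmedians_cluster()] from `n_restarts` seeded initial partitions,
#' returns the run with minimal total within-cluster distance, and reports a
#' stability score: the mean pairwise adjusted Rand index across restarts
#' (1 = every restart found the same partition).
#'
#' @inheritParams kmedians_cluster
#' @param n_restarts Number of restarts (default 10).
#' @param seed Root seed; restart r uses a derived sub-seed.
#' @return The best `ClusterAssignment`, with `stability` added.
#' @export
consensus_over_restarts <- function(profiles, k = 10, n_restarts = 10,
                                    seed = 0, max_iter = 50) {
  stopifnot(n_restarts >= 1)
  runs <- lapply(seq_len(n_restarts), function(r) {
    kmedians_cluster(profiles, k = k, max_iter = max_iter,
                     seed = derive_seed(seed, paste0("restart", r)))
  })
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- runs[[which.min(objs)]]
  if (n_restarts > 1) {
    pairs <- combn(n_restarts, 2)
    aris <- apply(pairs, 2, function(p) {
      mclust::adjustedRandIndex(runs[[p[1]]]$labels, runs[[p[2]]]$labels)
    })
    best$stability <- mean(aris)
  } else {
    best$stability <- 1
  }
  best
}
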