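#' Consensus purity (sc1A ensemble)
#'
#' The median of the input purities (mean of the middle two for an even
#' number of inputs).
#'
#' @param purities numeric vector of purity estimates.
#' @return Consensus purity.
#' @export
ensemble_1a <- function(purities) {
  if (length(purities) < 1L) stop("no input purities")
  stats::median(purities)
}

#' Consensus subclone count (sc1B ensemble)
#'
#' The floor of the median of the input counts.
#'
#' @param counts integer vector of subclone-count predictions.
#' @return Consensus integer count.
#' @export
ensemble_1b <- function(counts) {
  if (length(counts) < 1L) stop("no input counts")
  as.integer(floor(stats::median(counts)))
}

# weighted median with the even-count tie convention: when the half-weight
# point falls exactly on a boundary, average the two bracketing values.
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  i <- which(cw >= 0.5 - 1e-12)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1]) / 2
  else x[i]
}

#' WeMe consensus of cluster profiles (sc1C ensemble)
#'
#' Weighted-median consensus of cellular-prevalence location profiles,
#' ignoring individual SNV assignments. Each input profile is rendered as an
#' inverse CDF of SNV mass over CP (CP as a step function of the mass
#' quantile); on a shared grid of mass quantiles the consensus inverse CDF is
#' the pointwise weighted median across methods, and consensus clusters are
#' read off as its steps. Per-cluster masses are converted back to SNV counts
#' summing to `total_ssms` by largest-remainder rounding.
#'
#' @param profiles list of [cluster_profile()] data.frames.
#' @param weights per-method weights (default equal).
#' @param total_ssms total SNV count of the consensus (default: the median of
#'   the input totals, rounded).
#' @param grid_n number of mass quantiles (default 1001).
#' @return A consensus [cluster_profile()].
#' @export
weme_consensus <- function(profiles, weights = NULL, total_ssms = NULL,
                           grid_n = 1001) {
  if (length(profiles) < 1L) stop("no input profiles")
  if (is.null(weights)) weights <- rep(1, length(profiles))
  stopifnot(length(weights) == length(profiles), all(weights > 0))
  if (is.null(total_ssms))
    total_ssms <- round(stats::median(vapply(profiles,
                                             function(p) sum(p$n_ssms),
                                             numeric(1))))
  q <- (seq_len(grid_n) - 0.5) / grid_n   # interior mass quantiles
  # inverse CDF of each profile at the grid quantiles
  inv <- vapply(profiles, function(p) {
    ord <- order(p$cp)
    cp <- p$cp[ord]
    cw <- cumsum(p$n_ssms[ord]) / sum(p$n_ssms)
    cp[vapply(q, function(x) which(cw >= x - 1e-12)[1], integer(1))]
  }, numeric(grid_n))
  cons <- vapply(seq_len(grid_n),
                 function(i) weighted_median(inv[i, ], weights),
                 numeric(1))
  # steps of the consensus inverse CDF -> clusters with mass = run length
  runs <- rle(cons)
  mass <- runs$lengths / grid_n
  cp <- runs$values
  counts <- largest_remainder_round(mass * total_ssms, total_ssms)
  keep <- counts > 0
  cluster_profile(seq_len(sum(keep)), counts[keep], cp[keep])
}

largest_remainder_round <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' CICC consensus of hard assignments (sc2A ensemble)
#'
#' Consensus clustering of mutations from the coassignment behaviour of the
#' input methods. The distance between two SNVs is one minus the fraction of
#' methods coassigning them; average-linkage hierarchical clustering on this
#' distance is cut at `k` clusters. By default `k` is the floor-of-median of
#' the input methods' cluster counts.
#'
#' @param assignments list of hard label vectors over the same SNV set.
#' @param k target cluster count (default: [ensemble_1b()] of the inputs'
#'   cluster counts).
#' @return Integer consensus label vector.
#' @export
cicc_consensus <- function(assignments, k = NULL) {
  if (length(assignments) < 1L) stop("no input assignments")
  n <- length(assignments[[1]])
  if (any(vapply(assignments, length, integer(1)) != n))
    stop("assignments cover inconsistent SNV sets")
  if (is.null(k))
    k <- ensemble_1b(vapply(assignments,
                            function(a) length(unique(a)), numeric(1)))
  stopifnot(k >= 1, k <= n)
  co <- matrix(0, n, n)
  for (a in assignments) {
    lab <- canonicalize_labels(a)
    co <- co + outer(lab, lab, "==")
  }
  co <- co / length(assignments)
  if (k == n) return(seq_len(n))
  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  canonicalize_labels(stats::cutree(hc, k = k))
}

#' Enumerate or sample method combinations
#'
#' All size-`n` subsets of the input methods when their number is within the
#' cap, otherwise `cap` distinct subsets sampled uniformly without
#' replacement (cap 200 by default).
#'
#' @param methods character vector of method ids.
#' @param n subset size.
#' @param cap maximum number of subsets (default 200).
#' @param seed optional integer seed for the sampling branch.
#' @return A list of character vectors, each one subset.
#' @export
combination_protocol <- function(methods, n, cap = 200, seed = NULL) {
  m <- length(methods)
  if (n < 1 || n > m) stop("subset size must be between 1 and ", m)
  total <- choose(m, n)
  if (total <= cap) {
    combos <- utils::combn(methods, n, simplify = FALSE)
    return(combos)
  }
  if (!is.null(seed)) set.seed(seed)
  seen <- new.env(hash = TRUE)
  out <- vector("list", cap)
  got <- 0L
  while (got < cap) {
    s <- sort(sample(methods, n))
    key <- paste(s, collapse = "\r")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- s
    }
  }
  out
}
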