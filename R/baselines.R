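#' Random purity baseline (sc1A)
#'
#' Draws a purity uniformly between 0.2 and 0.99, mirroring the random
#' reference method run alongside participant algorithms.
#'
#' @param seed optional integer seed for reproducibility.
#' @param n number of draws.
#' @return Numeric vector in `[0.2, 0.99]`.
#' @export
random_1a <- function(seed = NULL, n = 1) {
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, 0.2, 0.99)
}

#' Random subclone-count baseline (sc1B)
#'
#' Draws from the four integer values 1-4 with probabilities
#' `{0.2, 0.3, 0.3, 0.2}`.
#'
#' @inheritParams random_1a
#' @return Integer vector with values in `{1, 2, 3, 4}`.
#' @export
random_1b <- function(seed = NULL, n = 1) {
  if (!is.null(seed)) set.seed(seed)
  sample(1:4, n, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
}

#' Random cluster-profile baseline (sc1C)
#'
#' Places one cluster at cancer cell fraction (CCF) 1; any additional clusters
#' get CCFs drawn uniformly from `[0.2, 0.9]`. Each cluster receives an SNV
#' count drawn uniformly from 1 to 10. CCFs are converted to cellular
#' prevalences by multiplying by `purity` (CCF = CP / purity); the default
#' `purity = 1` leaves the profile on the CCF scale.
#'
#' @param k number of clusters (e.g. a [random_1b()] draw).
#' @param purity purity used to convert CCF to CP at the output boundary.
#' @param seed optional integer seed.
#' @return A [cluster_profile()] data.frame.
#' @export
random_1c <- function(k, purity = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(k >= 1)
  ccf <- c(1, if (k > 1) stats::runif(k - 1, 0.2, 0.9))
  n_ssms <- sample(1:10, k, replace = TRUE)
  cluster_profile(seq_len(k), n_ssms, ccf * purity)
}

#' Random hard-assignment baseline (sc2A)
#'
#' Draws a per-cluster weight uniformly from 1 to 10, then assigns each SNV to
#' a cluster multinomially with the normalized weights.
#'
#' @param n_snvs number of SNVs to label.
#' @param k number of clusters (e.g. a [random_1b()] draw).
#' @param seed optional integer seed.
#' @return Integer label vector of length `n_snvs`.
#' @export
random_2a <- function(n_snvs, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_snvs >= 1, k >= 1)
  w <- sample(1:10, k, replace = TRUE)
  sample(seq_len(k), n_snvs, replace = TRUE, prob = w)
}

#' Random coclustering-matrix baseline (sc2B)
#'
#' Generates `n_vectors` random assignment vectors (cluster count per vector
#' drawn as in [random_1b()], labels as in [random_2a()]) and returns the
#' proportion of vectors coassigning each SNV pair. The generating vectors are
#' attached as the `"vectors"` attribute (one row per vector) so the matrix
#' can be recounted.
#'
#' @param n_snvs number of SNVs.
#' @param seed optional integer seed.
#' @param n_vectors number of random assignment vectors (default 100).
#' @return Symmetric `n_snvs x n_snvs` matrix with unit diagonal.
#' @export
random_2b <- function(n_snvs, seed = NULL, n_vectors = 100) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_snvs >= 1, n_vectors >= 1)
  vecs <- t(vapply(seq_len(n_vectors), function(i) {
    random_2a(n_snvs, random_1b())
  }, integer(n_snvs)))
  cc <- matrix(0, n_snvs, n_snvs)
  for (i in seq_len(n_vectors)) {
    lab <- vecs[i, ]
    cc <- cc + outer(lab, lab, "==")
  }
  cc <- cc / n_vectors
  diag(cc) <- 1
  attr(cc, "vectors") <- vecs
  cc
}

#' One-cluster baseline predictor
#'
#' The naive reference method that places all SNVs in a single cluster at the
#' variant allele frequency (VAF) mode. The mode is estimated by the maximum
#' of a Gaussian kernel density (Silverman's bandwidth) on `[0, 1]`; assuming
#' diploid heterozygous SNVs, the cluster's cellular prevalence is twice the
#' mode, clipped to 1, and doubles as the purity estimate. The predicted
#' phylogeny is a single somatic clone under the germline root.
#'
#' @param vafs per-SNV variant allele fractions in `[0, 1]`.
#' @return A list with one element per subchallenge (`sc1A`, `sc1B`, `sc1C`,
#'   `sc2A`, `sc2B`, `sc3A`, `sc3B`) plus `vaf_mode`.
#' @export
onecluster_predict <- function(vafs) {
  if (length(vafs) < 1L) stop("empty VAF vector")
  if (any(!is.finite(vafs)) || any(vafs < 0) || any(vafs > 1))
    stop("VAFs must lie in [0, 1]")
  n <- length(vafs)
  if (length(unique(vafs)) == 1L) {
    mode <- vafs[1]
  } else {
    d <- stats::density(vafs, bw = "nrd0", from = 0, to = 1, n = 512)
    mode <- d$x[which.max(d$y)]
  }
  cp <- min(1, 2 * mode)
  tree <- data.frame(id = 1L, parent = 0L)
  labels <- rep(1L, n)
  list(sc1A = cp,
       sc1B = 1L,
       sc1C = cluster_profile(1L, n, cp),
       sc2A = labels,
       sc2B = build_cocluster(labels),
       sc3A = list(tree = tree, assignment = labels),
       sc3B = build_relationship_matrices(tree, labels),
       vaf_mode = mode)
}
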