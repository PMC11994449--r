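#' Construct a cluster profile
#'
#' A cluster profile summarizes a subclonal reconstruction as a set of
#' mutation clusters, each with an SNV count and a cellular prevalence. It is
#' the input to the cellular-prevalence distribution metric.
#'
#' @param cluster cluster ids.
#' @param n_ssms positive SNV counts per cluster (zero allowed only for the
#'   reconciliation-added cluster).
#' @param cp cellular prevalences in `[0, 1]`.
#' @return A `data.frame` with columns `cluster`, `n_ssms`, `cp`.
#' @export
cluster_profile <- function(cluster, n_ssms, cp) {
  stopifnot(length(cluster) == length(n_ssms), length(cluster) == length(cp))
  if (length(cluster) < 1L) stop("empty cluster profile")
  if (any(!is.finite(cp)) || any(cp < 0) || any(cp > 1))
    stop("cluster cp must lie in [0, 1]")
  if (any(n_ssms < 0) || sum(n_ssms) <= 0)
    stop("cluster SNV counts must be non-negative with positive total")
  data.frame(cluster = cluster, n_ssms = as.numeric(n_ssms),
             cp = as.numeric(cp))
}

#' Purity score (sc1A)
#'
#' `1 - |rho - c|` where `rho` is the true and `c` the predicted cellularity,
#' both required to lie in `[0, 1]`.
#'
#' @param rho true purity.
#' @param c_pred predicted purity.
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' score_1a(0.8, 0.6)  # 0.8
score_1a <- function(rho, c_pred) {
  if (!is.numeric(rho) || !is.finite(rho) || rho < 0 || rho > 1)
    stop("true purity must lie in [0, 1]")
  if (!is.numeric(c_pred) || !is.finite(c_pred) || c_pred < 0 || c_pred > 1)
    stop("predicted purity must lie in [0, 1]")
  1 - abs(rho - c_pred)
}

#' Subclone-count score (sc1B)
#'
#' `(L - d + 1) / (L + 1)` with `d = min(|kappa - L|, L + 1)`, where `L >= 1`
#' is the true number of subclonal lineages and `kappa` the predicted count.
#' Capping `d` at `L + 1` keeps the score non-negative no matter how far off
#' the prediction is.
#'
#' @param L true number of lineages (integer, `>= 1`).
#' @param kappa predicted number of lineages (integer, `>= 0`).
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' score_1b(4, 2)  # 0.6
score_1b <- function(L, kappa) {
  if (!is.numeric(L) || L < 1) stop("true lineage count L must be >= 1")
  if (!is.numeric(kappa) || kappa < 0) stop("predicted count must be >= 0")
  d <- pmin(abs(kappa - L), L + 1)
  (L - d + 1) / (L + 1)
}

# Exact first-Wasserstein distance between two discrete distributions on
# [0, 1] via the integrated absolute CDF difference. Masses are normalized.
profile_emd <- function(truth, pred) {
  w1 <- truth$n_ssms / sum(truth$n_ssms)
  w2 <- pred$n_ssms / sum(pred$n_ssms)
  support <- sort(unique(c(truth$cp, pred$cp)))
  f1 <- vapply(support, function(x) sum(w1[truth$cp <= x]), numeric(1))
  f2 <- vapply(support, function(x) sum(w2[pred$cp <= x]), numeric(1))
  if (length(support) == 1L) return(0)
  dx <- diff(support)
  sum(abs(f1[-length(f1)] - f2[-length(f2)]) * dx)
}

#' Cellular-prevalence profile score (sc1C)
#'
#' `1 - EMD`, where EMD is the earth mover's (first Wasserstein) distance
#' between the SNV-mass-weighted discrete cellular-prevalence distributions of
#' the true and predicted cluster profiles, with ground distance `|x - y|` on
#' the unit interval. Because prevalences live on `[0, 1]` and masses are
#' normalized, the distance is at most 1 and the score lies in `[0, 1]`.
#'
#' @param truth,pred cluster profiles (see [cluster_profile()]).
#' @return A `metric_breakdown` whose `score` is `1 - EMD`.
#' @export
#' @examples
#' tr <- cluster_profile(1, 100, 0.8)
#' pr <- cluster_profile(1, 100, 0.6)
#' score_1c(tr, pr)$score  # 0.8
score_1c <- function(truth, pred) {
  truth <- cluster_profile(truth$cluster, truth$n_ssms, truth$cp)
  pred <- cluster_profile(pred$cluster, pred$n_ssms, pred$cp)
  emd <- profile_emd(truth, pred)
  metric_breakdown(score = 1 - emd, emd = emd)
}

metric_breakdown <- function(score, emd = NA_real_, aupr_raw = NA_real_,
                             aupr_norm = NA_real_, ajsd_raw = NA_real_,
                             ajsd_norm = NA_real_, pcc = NA_real_,
                             flags = character(0)) {
  structure(list(score = score, emd = emd, aupr_raw = aupr_raw,
                 aupr_norm = aupr_norm, ajsd_raw = ajsd_raw,
                 ajsd_norm = ajsd_norm, pcc = pcc, flags = flags),
            class = "metric_breakdown")
}

#' @export
print.metric_breakdown <- function(x, ...) {
  cat(sprintf("score: %.6f\n", x$score))
  parts <- unlist(x[c("emd", "aupr_raw", "aupr_norm", "ajsd_raw",
                      "ajsd_norm", "pcc")])
  parts <- parts[!is.na(parts)]
  if (length(parts))
    cat(paste(sprintf("  %s: %.6f", names(parts), parts), collapse = "\n"),
        "\n", sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Area under the precision-recall curve as average precision: pairs sorted by
# decreasing predicted score, ties grouped at a single threshold, and
# precision summed over recall increments.
aupr <- function(scores, labels) {
  pos <- sum(labels)
  if (pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / pos
  sum(diff(c(0, rec)) * prec)
}

# Binary entropy in bits, with 0 log 0 = 0.
bernoulli_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h
}

# Jensen-Shannon divergence (base 2) between Bernoulli(p) and Bernoulli(q),
# vectorized; lies in [0, 1].
jsd_bernoulli <- function(p, q) {
  m <- (p + q) / 2
  pmax(bernoulli_entropy(m) - (bernoulli_entropy(p) + bernoulli_entropy(q)) / 2,
       0)
}

upper_tri <- function(m) m[upper.tri(m)]

# Raw AUPR and AJSD of a predicted cocluster matrix against the true one,
# over unordered off-diagonal pairs.
cocluster_components <- function(truth_cc, pred_cc) {
  y <- upper_tri(truth_cc)
  p <- upper_tri(pred_cc)
  list(aupr = aupr(p, y), ajsd = mean(jsd_bernoulli(p, y)))
}

#' Mutation coclustering score (sc2A / sc2B)
#'
#' `(AUPR + AJSD) / 2` after normalization, computed on the off-diagonal
#' unordered pairs of the predicted versus true coclustering matrices. AUPR is
#' the area under the precision-recall curve for pairwise coclustering; AJSD
#' is the average per-pair Jensen-Shannon divergence (base 2) between the
#' Bernoulli coclustering probabilities. Each component is normalized so that
#' the worse of two extreme reference predictions (all SNVs in one cluster;
#' every SNV its own cluster) maps to 0 and a perfect prediction maps to 1,
#' clamped below at 0. The hard task passes a label vector, the soft task a
#' soft-assignment or coclustering matrix.
#'
#' @param truth hard assignment label vector for the truth.
#' @param pred hard label vector, soft SNV x cluster assignment matrix, or an
#'   SNV x SNV coclustering probability matrix (symmetric, unit diagonal).
#' @return A `metric_breakdown` with raw and normalized components.
#' @export
score_2 <- function(truth, pred) {
  truth_cc <- build_cocluster(truth)
  n <- nrow(truth_cc)
  pred_cc <- as_cocluster(pred, n)
  if (nrow(pred_cc) != n)
    stop("prediction covers ", nrow(pred_cc), " SNVs but truth has ", n,
         "; reconcile first")
  comp <- cocluster_components(truth_cc, pred_cc)
  one <- cocluster_components(truth_cc, matrix(1, n, n))
  single <- cocluster_components(truth_cc, diag(n))
  flags <- character(0)
  if (is.na(comp$aupr)) {
    # no positive pair in the truth: PR curve undefined
    aupr_norm <- 0
    flags <- c(flags, "aupr_undefined")
  } else {
    worst_aupr <- min(one$aupr, single$aupr)
    aupr_norm <- if (1 - worst_aupr < 1e-12) as.numeric(comp$aupr >= worst_aupr)
                 else (comp$aupr - worst_aupr) / (1 - worst_aupr)
    aupr_norm <- min(max(aupr_norm, 0), 1)
  }
  worst_ajsd <- max(one$ajsd, single$ajsd)
  ajsd_norm <- if (worst_ajsd < 1e-12) as.numeric(comp$ajsd < 1e-12)
               else 1 - comp$ajsd / worst_ajsd
  ajsd_norm <- min(max(ajsd_norm, 0), 1)
  metric_breakdown(score = (aupr_norm + ajsd_norm) / 2,
                   aupr_raw = comp$aupr, aupr_norm = aupr_norm,
                   ajsd_raw = comp$ajsd, ajsd_norm = ajsd_norm, flags = flags)
}

# Coerce hard labels / soft assignment / cocluster matrix to a cocluster
# matrix. A square matrix matching the SNV count is taken as a cocluster
# matrix already; any other matrix is treated as a soft assignment.
as_cocluster <- function(pred, n_snvs) {
  if (is.matrix(pred)) {
    if (nrow(pred) == ncol(pred) && nrow(pred) == n_snvs &&
        max(abs(pred - t(pred))) < 1e-6) {
      cc <- (pred + t(pred)) / 2
      diag(cc) <- 1
      return(cc)
    }
    return(build_cocluster(pred))
  }
  build_cocluster(pred)
}

#' Phylogeny score (sc3A / sc3B)
#'
#' The Pearson correlation between the predicted and true values of the
#' coclustering matrix, the cousin matrix, the ancestor-descendant matrix and
#' its transpose, stacked into one vector over off-diagonal entries. The hard
#' task derives the prediction's matrices from a tree plus hard assignment;
#' the soft task uses submitted probability matrices. A stacked vector with
#' zero variance on either side yields a score of 0 (flagged).
#'
#' @param truth a `phylogeny_truth` or `relationship_matrices` object.
#' @param pred a `relationship_matrices` object (see
#'   [build_relationship_matrices()] and [relationship_from_soft()]).
#' @return A `metric_breakdown` whose `score` is the correlation.
#' @export
score_3 <- function(truth, pred) {
  if (inherits(truth, "phylogeny_truth"))
    truth <- build_relationship_matrices(truth)
  stopifnot(inherits(truth, "relationship_matrices"),
            inherits(pred, "relationship_matrices"))
  if (nrow(truth$cocluster) != nrow(pred$cocluster))
    stop("prediction covers ", nrow(pred$cocluster),
         " SNVs but truth has ", nrow(truth$cocluster), "; reconcile first")
  stack <- function(m) {
    off <- !diag(nrow(m$cocluster))
    c(m$cocluster[off], m$ancestor_descendant[off],
      t(m$ancestor_descendant)[off], m$cousin[off])
  }
  a <- stack(truth); b <- stack(pred)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(metric_breakdown(score = 0, pcc = NA_real_,
                            flags = "zero_variance"))
  pcc <- stats::cor(a, b)
  metric_breakdown(score = pcc, pcc = pcc)
}

#' Reconcile a prediction's SNV universe with the truth
#'
#' Truth SNVs absent from the prediction (false negatives) are added as a
#' single new cluster with a cellular prevalence of zero, derived from the
#' normal: its SNVs cocluster with each other, are ancestors/descendants of
#' nothing, and are cousins of every somatic SNV. Prediction-only SNVs (false
#' positives) are dropped. The result covers exactly the truth SNV set, in
#' truth order.
#'
#' @param pred a prediction: hard label vector (2A), soft/cocluster matrix
#'   (2B), `relationship_matrices` (3A/3B) or cluster profile (1C).
#' @param pred_snv_ids SNV ids covered by the prediction, in its row order
#'   (ignored for cluster profiles).
#' @param truth_snv_ids the truth SNV ids, in truth order.
#' @return The reconciled prediction of the same kind.
#' @export
reconcile_prediction <- function(pred, pred_snv_ids, truth_snv_ids) {
  if (is.data.frame(pred)) {  # cluster profile: reconcile by SNV mass
    n_truth <- length(truth_snv_ids)
    n_pred <- sum(pred$n_ssms)
    if (n_pred < n_truth) {
      pred <- rbind(pred, data.frame(cluster = max(pred$cluster) + 1,
                                     n_ssms = n_truth - n_pred, cp = 0))
    }
    return(pred)
  }
  keep <- pred_snv_ids %in% truth_snv_ids
  if (!any(keep)) stop("prediction covers none of the truth SNVs")
  fn_ids <- setdiff(truth_snv_ids, pred_snv_ids)
  kept_ids <- pred_snv_ids[keep]
  out_ids <- c(kept_ids, fn_ids)   # truth set; reordered to truth order below
  ord <- match(truth_snv_ids, out_ids)
  n_fn <- length(fn_ids)
  if (inherits(pred, "relationship_matrices")) {
    grow <- function(m, fn_diag_block) {
      m <- m[keep, keep, drop = FALSE]
      k <- nrow(m)
      out <- matrix(0, k + n_fn, k + n_fn)
      out[seq_len(k), seq_len(k)] <- m
      if (n_fn > 0) {
        blk <- matrix(fn_diag_block$fn_fn, n_fn, n_fn)
        diag(blk) <- fn_diag_block$diag
        out[k + seq_len(n_fn), k + seq_len(n_fn)] <- blk
        out[seq_len(k), k + seq_len(n_fn)] <- fn_diag_block$cross
        out[k + seq_len(n_fn), seq_len(k)] <- fn_diag_block$cross
      }
      out[ord, ord, drop = FALSE]
    }
    cc <- grow(pred$cocluster, list(fn_fn = 1, diag = 1, cross = 0))
    ad <- grow(pred$ancestor_descendant, list(fn_fn = 0, diag = 0, cross = 0))
    cs <- grow(pred$cousin, list(fn_fn = 0, diag = 0, cross = 1))
    dimnames(cc) <- dimnames(ad) <- dimnames(cs) <-
      list(truth_snv_ids, truth_snv_ids)
    return(structure(list(cocluster = cc, ancestor_descendant = ad,
                          cousin = cs), class = "relationship_matrices"))
  }
  if (is.matrix(pred)) {  # cocluster matrix
    m <- pred[keep, keep, drop = FALSE]
    k <- nrow(m)
    out <- matrix(0, k + n_fn, k + n_fn)
    out[seq_len(k), seq_len(k)] <- m
    if (n_fn > 0) out[k + seq_len(n_fn), k + seq_len(n_fn)] <- 1
    diag(out) <- 1
    out <- out[ord, ord, drop = FALSE]
    dimnames(out) <- list(truth_snv_ids, truth_snv_ids)
    return(out)
  }
  # hard label vector
  lab <- canonicalize_labels(pred)[keep]
  if (n_fn > 0) lab <- c(lab, rep(max(lab) + 1L, n_fn))
  stats::setNames(lab[ord], truth_snv_ids)
}
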