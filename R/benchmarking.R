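#' Assemble a score table
#'
#' A score table holds one row per `{tumor, algorithm, subchallenge}` with the
#' raw metric value; normalization adds `s_minmax`. Missing outputs are rows
#' with `NA` raw scores (missingness is not penalized by default).
#'
#' @param tumor,algorithm character ids.
#' @param subchallenge one of `"1A" "1B" "1C" "2A" "2B" "3A" "3B"`.
#' @param s_raw raw metric values (may contain `NA` for missing outputs).
#' @param titration_group optional shared id for multi-depth versions of one
#'   tumor; such tumors are normalized jointly.
#' @return A `data.frame` of class `score_table`.
#' @export
score_table <- function(tumor, algorithm, subchallenge, s_raw,
                        titration_group = NA_character_) {
  sc <- as.character(subchallenge)
  bad <- setdiff(unique(sc), c("1A", "1B", "1C", "2A", "2B", "3A", "3B"))
  if (length(bad)) stop("unknown subchallenge: ", paste(bad, collapse = ", "))
  out <- data.frame(tumor = as.character(tumor),
                    algorithm = as.character(algorithm),
                    subchallenge = sc, s_raw = as.numeric(s_raw),
                    titration_group = as.character(titration_group))
  class(out) <- c("score_table", "data.frame")
  out
}

norm_group_key <- function(records) {
  grp <- ifelse(is.na(records$titration_group) | records$titration_group == "",
                paste0("tumor:", records$tumor),
                paste0("titration:", records$titration_group))
  paste(grp, records$subchallenge, sep = "|")
}

#' Min-max normalize scores within tumor and subchallenge
#'
#' Within each `{tumor, subchallenge}` group the lowest raw score maps to 0
#' and the highest to 1: `(s - min(s)) / (max(s) - min(s))`. Tumors belonging
#' to a titration series (same tumor sequenced at several depths) share one
#' min and max across all depths. A degenerate group in which every method
#' scored the same normalizes to 1 for all (everyone is equally best).
#'
#' @param records a [score_table()].
#' @return The table with an `s_minmax` column added (NA raw stays NA).
#' @export
minmax_normalize <- function(records) {
  key <- norm_group_key(records)
  s <- records$s_raw
  out <- rep(NA_real_, length(s))
  for (k in unique(key)) {
    i <- which(key == k & !is.na(s))
    if (!length(i)) next
    lo <- min(s[i]); hi <- max(s[i])
    out[i] <- if (hi - lo < .Machine$double.eps * 4) 1
              else (s[i] - lo) / (hi - lo)
  }
  records$s_minmax <- out
  records
}

# algorithm x tumor matrix of normalized scores for one subchallenge
score_matrix_for <- function(records, subchallenge) {
  r <- records[records$subchallenge == subchallenge, , drop = FALSE]
  if (!nrow(r)) stop("no records for subchallenge ", subchallenge)
  if (is.null(r$s_minmax)) stop("records must be normalized first")
  algs <- unique(r$algorithm); tums <- unique(r$tumor)
  m <- matrix(NA_real_, length(algs), length(tums),
              dimnames = list(algs, tums))
  m[cbind(match(r$algorithm, algs), match(r$tumor, tums))] <- r$s_minmax
  m
}

rank_from_medians <- function(med) {
  rank(-med, ties.method = "min", na.last = "keep")
}

#' Rank algorithms by median normalized score
#'
#' Algorithms are ranked by their median min-max-normalized score across all
#' tumors for which they produced a valid output; tied algorithms share the
#' minimum rank. Optionally, missing outputs can be zero-filled instead of
#' excluded.
#'
#' @param records a normalized [score_table()].
#' @param subchallenge which subchallenge to rank.
#' @param zero_fill if `TRUE`, missing `{tumor, algorithm}` scores count as 0.
#' @return A `data.frame` with columns `algorithm`, `median_score`, `rank`,
#'   `n_tumors`, ordered best first.
#' @export
rank_algorithms <- function(records, subchallenge, zero_fill = FALSE) {
  m <- score_matrix_for(records, subchallenge)
  if (zero_fill) m[is.na(m)] <- 0
  med <- apply(m, 1, stats::median, na.rm = TRUE)
  rk <- rank_from_medians(med)
  out <- data.frame(algorithm = rownames(m), median_score = med, rank = rk,
                    n_tumors = rowSums(!is.na(m)), row.names = NULL)
  out[order(out$rank, out$algorithm), , drop = FALSE]
}

#' Bootstrap test of rank differences against the best method
#'
#' Resamples tumors with replacement and recomputes the median-score ranking
#' in each resample to test whether an entry's rank is genuinely worse than
#' the best method's (null hypothesis: the ranks are equal). The P value for
#' an entry is the fraction of resamples in which its recomputed rank is at
#' most the original best method's recomputed rank; entries with `P > 0.1`
#' are flagged statistically indistinguishable from the best.
#'
#' @param records a normalized [score_table()].
#' @param subchallenge which subchallenge to test.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param zero_fill treat missing outputs as 0 rather than excluding them.
#' @return A `data.frame` with columns `algorithm`, `rank`, `p_value`,
#'   `indistinguishable`.
#' @export
bootstrap_rank_pvalue <- function(records, subchallenge, n_boot = 10000,
                                  seed = NULL, zero_fill = FALSE) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  m <- score_matrix_for(records, subchallenge)
  if (zero_fill) m[is.na(m)] <- 0
  if (nrow(m) < 2) stop("need at least 2 algorithms")
  if (ncol(m) < 2) stop("need at least 2 tumors")
  med0 <- apply(m, 1, stats::median, na.rm = TRUE)
  rk0 <- rank_from_medians(med0)
  best <- rownames(m)[which.min(rk0)]
  hits <- matrix(0, nrow(m), 1, dimnames = list(rownames(m), NULL))
  n_t <- ncol(m)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(n_t, n_t, replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    medb <- apply(mb, 1, stats::median, na.rm = TRUE)
    rkb <- rank_from_medians(medb)
    hits <- hits + (rkb <= rkb[best])
  }
  p <- as.numeric(hits) / n_boot
  data.frame(algorithm = rownames(m), rank = rk0, p_value = p,
             indistinguishable = p > 0.1, row.names = NULL)
}

# weighted mean ignoring NA, weights renormalized over the observed entries
wmean <- function(x, w) {
  ok <- !is.na(x)
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

# Collapse a tumor x algorithm x subchallenge score array to an
# algorithm x subchallenge matrix of tumor-weighted means.
aggregate_scores <- function(scores, tumor_weights = NULL) {
  stopifnot(length(dim(scores)) == 3)
  n_t <- dim(scores)[1]
  if (is.null(tumor_weights)) tumor_weights <- rep(1, n_t)
  apply(scores, c(2, 3), wmean, w = tumor_weights)
}

#' Project algorithms and subchallenges into a decision space
#'
#' Performs a principal component analysis on the algorithm x subchallenge
#' matrix of tumor-weighted mean scores, projecting algorithms, subchallenge
#' axes and a decision axis (the direction of the subchallenge-weighted mean
#' score) onto the leading components. Projection of the algorithms onto the
#' decision axis yields a ranking; with equal weights this equals ranking by
#' unweighted mean score.
#'
#' @param scores either a tumor x algorithm x subchallenge array of normalized
#'   scores or an already-aggregated algorithm x subchallenge matrix.
#' @param subchallenge_weights weights over subchallenges (default equal).
#' @param tumor_weights weights over tumors (default equal; ignored for
#'   pre-aggregated matrices).
#' @return A list of class `decision_space` with elements `score_matrix`,
#'   `pca`, `algorithm_proj`, `subchallenge_proj`, `decision_axis`,
#'   `decision_scores` and `ranking`.
#' @export
decision_projection <- function(scores, subchallenge_weights = NULL,
                                tumor_weights = NULL) {
  m <- if (length(dim(scores)) == 3) aggregate_scores(scores, tumor_weights)
       else as.matrix(scores)
  if (nrow(m) < 2) stop("need at least 2 algorithms")
  if (anyNA(m)) stop("score matrix must be complete (impute or zero-fill)")
  k <- ncol(m)
  w <- if (is.null(subchallenge_weights)) rep(1, k) else subchallenge_weights
  stopifnot(length(w) == k, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  d <- min(2, ncol(pca$rotation))
  alg_proj <- pca$x[, seq_len(d), drop = FALSE]
  sub_proj <- pca$rotation[, seq_len(d), drop = FALSE]
  axis <- drop(crossprod(pca$rotation[, seq_len(d), drop = FALSE], w))
  dec <- drop(m %*% w)
  structure(list(score_matrix = m, pca = pca, algorithm_proj = alg_proj,
                 subchallenge_proj = sub_proj, decision_axis = axis,
                 decision_scores = dec,
                 ranking = rank(-dec, ties.method = "min")),
            class = "decision_space")
}

#' @export
print.decision_space <- function(x, ...) {
  ve <- x$pca$sdev^2 / sum(x$pca$sdev^2)
  cat(sprintf("Decision space over %d algorithms x %d subchallenges\n",
              nrow(x$score_matrix), ncol(x$score_matrix)))
  cat(sprintf("  PC1+PC2 variance: %.1f%%\n", 100 * sum(ve[seq_len(min(2, length(ve)))])))
  ord <- order(x$ranking)
  cat("  top of decision-axis ranking:\n")
  top <- utils::head(ord, 5)
  for (i in top)
    cat(sprintf("    %d. %s (%.4f)\n", x$ranking[i],
                rownames(x$score_matrix)[i], x$decision_scores[i]))
  invisible(x)
}

#' Stability of rankings under weight perturbation
#'
#' Two complementary analyses of how sensitive the decision-axis ranking is to
#' the choice of weights: (1) `n_axes` perturbed decision axes obtained by
#' adding uniform -50% to +50% changes to the subchallenge weights, projected
#' into the PCA plane (a density cloud around the equal-weight axis); and (2)
#' `n_weight_sets` random uniform weight vectors over tumors crossed with
#' `n_weight_sets` over subchallenges, yielding `n_weight_sets^2` independent
#' rankings (200 x 200 = 40,000 at the defaults), from which per-algorithm
#' rank distributions and ever-ranked-first flags are derived.
#'
#' @param scores tumor x algorithm x subchallenge array of normalized scores.
#' @param n_axes number of perturbed decision axes (default 3000).
#' @param n_weight_sets number of random weight draws per dimension
#'   (default 200).
#' @param perturbation relative perturbation half-width (default 0.5).
#' @param seed integer seed.
#' @return A list with `axes` (n_axes x 2 matrix of axis coordinates),
#'   `ranks` (algorithm x n_weight_sets^2 matrix), `ever_first` (named
#'   logical) and `first_fraction`.
#' @export
weight_perturbation_study <- function(scores, n_axes = 3000,
                                      n_weight_sets = 200,
                                      perturbation = 0.5, seed = NULL) {
  stopifnot(length(dim(scores)) == 3)
  if (!is.null(seed)) set.seed(seed)
  n_t <- dim(scores)[1]; n_a <- dim(scores)[2]; n_s <- dim(scores)[3]
  algs <- dimnames(scores)[[2]]
  if (is.null(algs)) algs <- paste0("alg", seq_len(n_a))
  base <- decision_projection(scores)
  rot <- base$pca$rotation[, seq_len(min(2, ncol(base$pca$rotation))),
                           drop = FALSE]
  w0 <- rep(1 / n_s, n_s)
  axes <- matrix(NA_real_, n_axes, ncol(rot))
  for (i in seq_len(n_axes)) {
    w <- w0 * (1 + stats::runif(n_s, -perturbation, perturbation))
    w <- w / sum(w)
    axes[i, ] <- drop(crossprod(rot, w))
  }
  tw <- matrix(stats::runif(n_weight_sets * n_t), n_weight_sets, n_t)
  sw <- matrix(stats::runif(n_weight_sets * n_s), n_weight_sets, n_s)
  tw <- tw / rowSums(tw); sw <- sw / rowSums(sw)
  ranks <- matrix(NA_integer_, n_a, n_weight_sets^2,
                  dimnames = list(algs, NULL))
  col <- 0L
  for (i in seq_len(n_weight_sets)) {
    agg <- aggregate_scores(scores, tw[i, ])       # algorithm x subchallenge
    agg0 <- agg; agg0[is.na(agg0)] <- 0
    for (j in seq_len(n_weight_sets)) {
      col <- col + 1L
      dec <- drop(agg0 %*% sw[j, ])
      ranks[, col] <- rank(-dec, ties.method = "min")
    }
  }
  first <- rowSums(ranks == 1L) / ncol(ranks)
  list(axes = axes, ranks = ranks,
       ever_first = stats::setNames(first > 0, algs),
       first_fraction = stats::setNames(first, algs))
}

#' Drop highly correlated submissions from the same team
#'
#' Documented filter utility: within each team and subchallenge, submissions
#' whose scores across tumors correlate above the threshold with a
#' better-ranked teammate are removed, retaining the algorithm with the
#' highest median score. No inferential claim is attached.
#'
#' @param records a normalized [score_table()].
#' @param teams named character vector mapping algorithm -> team id.
#' @param threshold correlation threshold (default 0.75).
#' @return The filtered score table.
#' @export
filter_correlated_submissions <- function(records, teams, threshold = 0.75) {
  drop <- character(0)
  for (sc in unique(records$subchallenge)) {
    m <- score_matrix_for(records, sc)
    algs <- rownames(m)
    med <- apply(m, 1, stats::median, na.rm = TRUE)
    for (team in unique(teams[algs])) {
      members <- algs[teams[algs] == team & !is.na(teams[algs])]
      members <- members[order(-med[members])]
      kept <- character(0)
      for (a in members) {
        r <- if (length(kept)) suppressWarnings(
          vapply(kept, function(b) stats::cor(m[a, ], m[b, ],
                                              use = "pairwise.complete.obs"),
                 numeric(1))) else numeric(0)
        if (any(!is.na(r) & r > threshold))
          drop <- c(drop, paste(sc, a, sep = "|"))
        else kept <- c(kept, a)
      }
    }
  }
  keep <- !(paste(records$subchallenge, records$algorithm, sep = "|") %in% drop)
  records[keep, , drop = FALSE]
}
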