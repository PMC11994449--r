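# Independent oracles used to pin the metric implementations.

# Exact 1-D optimal transport cost by greedy mass matching on sorted
# supports (provably optimal for the |x - y| ground distance); independent
# of the CDF-area route used by the package.
transport_emd_oracle <- function(truth, pred) {
  o1 <- order(truth$cp); o2 <- order(pred$cp)
  x <- truth$cp[o1]; wx <- truth$n_ssms[o1] / sum(truth$n_ssms)
  y <- pred$cp[o2]; wy <- pred$n_ssms[o2] / sum(pred$n_ssms)
  i <- 1L; j <- 1L; cost <- 0
  while (i <= length(x) && j <= length(y)) {
    m <- min(wx[i], wy[j])
    cost <- cost + m * abs(x[i] - y[j])
    wx[i] <- wx[i] - m; wy[j] <- wy[j] - m
    if (wx[i] <= 1e-15) i <- i + 1L
    if (j <= length(y) && wy[j] <= 1e-15) j <- j + 1L
  }
  cost
}

random_profile <- function(max_clusters = 6) {
  k <- sample.int(max_clusters, 1)
  cluster_profile(seq_len(k), sample.int(50, k, replace = TRUE),
                  round(runif(k), 3))
}

# Pairwise enumeration oracle for the coclustering components: explicit
# loops over unordered pairs and thresholds.
pair_components_oracle <- function(truth_labels, pred_cc) {
  n <- length(truth_labels)
  y <- c(); p <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    y <- c(y, as.numeric(truth_labels[i] == truth_labels[j]))
    p <- c(p, pred_cc[i, j])
  }
  jsd <- function(a, b) {
    h <- function(q) if (q <= 0 || q >= 1) 0 else -q * log2(q) - (1 - q) * log2(1 - q)
    h((a + b) / 2) - (h(a) + h(b)) / 2
  }
  ajsd <- mean(mapply(jsd, p, y))
  if (sum(y) == 0) return(list(aupr = NA_real_, ajsd = ajsd))
  # PR curve: one operating point per distinct threshold, ties grouped
  thr <- sort(unique(p), decreasing = TRUE)
  prec <- rec <- numeric(length(thr))
  for (t in seq_along(thr)) {
    sel <- p >= thr[t]
    prec[t] <- sum(y[sel]) / sum(sel)
    rec[t] <- sum(y[sel]) / sum(y)
  }
  aupr <- sum(diff(c(0, rec)) * prec)
  list(aupr = aupr, ajsd = ajsd)
}

# Ordered-pair enumeration oracle for the phylogeny correlation metric.
phylogeny_pcc_oracle <- function(tree_t, lab_t, tree_p, lab_p) {
  is_anc <- function(tree, a, b) {  # is cluster a a strict ancestor of b?
    cur <- tree$parent[tree$id == b]
    while (cur != 0) {
      if (cur == a) return(TRUE)
      cur <- tree$parent[tree$id == cur]
    }
    FALSE
  }
  vecs <- function(tree, lab) {
    n <- length(lab)
    cc <- ad <- ta <- cs <- c()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      same <- lab[i] == lab[j]
      aij <- !same && is_anc(tree, lab[i], lab[j])
      aji <- !same && is_anc(tree, lab[j], lab[i])
      cc <- c(cc, as.numeric(same)); ad <- c(ad, as.numeric(aij))
      ta <- c(ta, as.numeric(aji))
      cs <- c(cs, as.numeric(!same && !aij && !aji))
    }
    c(cc, ad, ta, cs)
  }
  stats::cor(vecs(tree_t, lab_t), vecs(tree_p, lab_p))
}

# all partitions of n items into exactly 2 non-empty blocks
two_partitions <- function(n) {
  out <- list()
  for (code in 1:(2^(n - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    out[[length(out) + 1L]] <- bits + 1L
  }
  out
}

mean_intra_distance <- function(labels, d) {
  tot <- 0; cnt <- 0
  n <- length(labels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) { tot <- tot + d[i, j]; cnt <- cnt + 1 }
  }
  if (cnt == 0) 0 else tot / cnt
}

# small deterministic truth used across tests
tiny_truth <- function(n_snvs = 6) {
  lab <- rep(c(1L, 2L, 3L), length.out = n_snvs)
  names(lab) <- paste0("s", seq_len(n_snvs))
  phylogeny_truth(
    0.8,
    data.frame(id = 1:3, parent = c(0L, 1L, 1L), cp = c(0.8, 0.4, 0.3),
               n_ssms = tabulate(lab, 3)),
    lab)
}
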