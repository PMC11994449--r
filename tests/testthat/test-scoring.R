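test_that("purity score is one minus the absolute error", {
  expect_equal(score_1a(0.7, 0.7), 1)
  expect_equal(score_1a(1.0, 0.0), 0)
  expect_equal(score_1a(0.8, 0.6), 0.8)
  expect_error(score_1a(1.2, 0.5), "\\[0, 1\\]")
  expect_error(score_1a(0.5, -0.1), "\\[0, 1\\]")
})

test_that("subclone-count score caps the error at L + 1", {
  expect_equal(score_1b(3, 3), 1)
  expect_equal(score_1b(2, 100), 0)
  expect_equal(score_1b(4, 2), 0.6)
  expect_error(score_1b(0, 1), ">= 1")
})

test_that("subclone-count score is non-increasing in |kappa - L| and flat past L+1", {
  for (L in 1:6) {
    s <- vapply(0:(3 * L + 5), function(k) score_1b(L, k), numeric(1))
    above <- s[(L + 1):length(s)]           # kappa >= L
    expect_true(all(diff(above) <= 1e-12))
    below <- s[seq_len(L + 1)]              # kappa 0..L
    expect_true(all(diff(below) >= -1e-12))
    capped <- vapply((2 * L + 1):(3 * L + 5), function(k) score_1b(L, k),
                     numeric(1))
    expect_true(all(abs(capped - capped[1]) < 1e-12))
    expect_true(all(s >= 0))
  }
})

test_that("cellular-prevalence score equals one minus the CDF-area distance", {
  p <- cluster_profile(1:2, c(10, 5), c(0.9, 0.4))
  expect_equal(score_1c(p, p)$score, 1)
  expect_equal(score_1c(cluster_profile(1, 100, 0.8),
                        cluster_profile(1, 100, 0.6))$score, 0.8)
  expect_equal(score_1c(cluster_profile(1:2, c(50, 50), c(1.0, 0.5)),
                        cluster_profile(1, 100, 0.75))$score, 0.75)
  expect_error(score_1c(p, cluster_profile(1, 0, 0.5)), "positive total")
})

test_that("CDF-area distance agrees with the greedy transport oracle", {
  set.seed(7)
  for (rep in 1:200) {
    a <- random_profile(); b <- random_profile()
    expect_equal(score_1c(a, b)$score, 1 - transport_emd_oracle(a, b),
                 tolerance = 1e-9)
  }
})

test_that("coclustering score is 1 for a perfect prediction and 0 at the anchor", {
  truth <- c(1L, 1L, 2L, 2L, 3L)
  perfect <- score_2(truth, truth)
  expect_equal(perfect$score, 1)
  expect_equal(perfect$aupr_raw, 1)
  expect_equal(perfect$ajsd_raw, 0)
  # the worse extreme normalizes to component 0
  one <- score_2(truth, rep(1L, 5))
  single <- score_2(truth, 1:5)
  worse_ajsd <- if (one$ajsd_raw >= single$ajsd_raw) one else single
  expect_equal(worse_ajsd$ajsd_norm, 0)
  worse_aupr <- if (one$aupr_raw <= single$aupr_raw) one else single
  expect_equal(worse_aupr$aupr_norm, 0)
})

test_that("coclustering components match explicit pairwise enumeration", {
  # the 6 pairs of a 4-SNV instance with a maximally wrong prediction
  truth <- c(1L, 1L, 2L, 2L)
  pred <- c(1L, 2L, 1L, 2L)
  res <- score_2(truth, pred)
  oracle <- pair_components_oracle(truth, build_cocluster(pred))
  expect_equal(res$aupr_raw, oracle$aupr)
  expect_equal(res$ajsd_raw, oracle$ajsd)
  expect_equal(res$aupr_raw, 1 / 3)
  expect_equal(res$ajsd_raw, 2 / 3)
  expect_equal(res$score, 0)
  # random soft instances
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    tl <- sample(1:3, n, replace = TRUE)
    w <- matrix(runif(n * 3), n, 3); w <- w / rowSums(w)
    cc <- build_cocluster(w)
    res <- score_2(tl, cc)
    oracle <- pair_components_oracle(tl, cc)
    expect_equal(res$aupr_raw, oracle$aupr, tolerance = 1e-12)
    expect_equal(res$ajsd_raw, oracle$ajsd, tolerance = 1e-12)
  }
})

test_that("hard and soft coclustering paths agree on indicator matrices", {
  truth <- c(1L, 2L, 1L, 3L, 2L, 3L)
  pred <- c(1L, 1L, 2L, 2L, 3L, 3L)
  hard <- score_2(truth, pred)
  k <- max(pred)
  w <- matrix(0, length(pred), k); w[cbind(seq_along(pred), pred)] <- 1
  soft <- score_2(truth, build_cocluster(w))
  expect_equal(hard$score, soft$score, tolerance = 1e-12)
})

test_that("coclustering score is invariant to SNV order and relabeling", {
  set.seed(3)
  truth <- sample(1:3, 10, replace = TRUE)
  pred <- sample(1:4, 10, replace = TRUE)
  base <- score_2(truth, pred)$score
  perm <- sample(10)
  expect_equal(score_2(truth[perm], pred[perm])$score, base)
  relab <- c(4L, 1L, 3L, 2L)[pred]
  expect_equal(score_2(truth, relab)$score, base)
})

test_that("phylogeny score is 1 for perfect or relabeled predictions", {
  tr <- tiny_truth(8)
  mats <- build_relationship_matrices(tr)
  expect_equal(score_3(tr, mats)$score, 1, tolerance = 1e-12)
  # relabeled clusters, same structure
  tree2 <- data.frame(id = c(10L, 20L, 30L), parent = c(0L, 10L, 10L))
  lab2 <- c(10L, 20L, 30L)[as.integer(tr$assignment)]
  mats2 <- build_relationship_matrices(tree2, lab2)
  expect_equal(score_3(tr, mats2)$score, 1, tolerance = 1e-12)
})

test_that("phylogeny score matches the enumeration oracle", {
  tree_t <- data.frame(id = 1:3, parent = c(0L, 1L, 1L))
  lab_t <- c(1L, 1L, 2L, 2L, 3L, 3L)
  tr <- phylogeny_truth(0.8, data.frame(id = 1:3, parent = c(0, 1, 1),
                                        cp = c(0.8, 0.4, 0.3),
                                        n_ssms = c(2, 2, 2)),
                        stats::setNames(lab_t, paste0("s", 1:6)))
  tree_p <- data.frame(id = 1L, parent = 0L)
  lab_p <- rep(1L, 6)
  got <- score_3(tr, build_relationship_matrices(tree_p, lab_p))$score
  want <- phylogeny_pcc_oracle(tree_t, lab_t, tree_p, lab_p)
  expect_equal(got, want, tolerance = 1e-12)
  # random instances
  set.seed(21)
  for (rep in 1:10) {
    t1 <- simulate_tree(sample(2:4, 1), "branching", 0.9, n_snvs = 6)
    t2 <- simulate_tree(sample(2:4, 1), "linear", 0.9, n_snvs = 6)
    got <- score_3(build_relationship_matrices(t1),
                   build_relationship_matrices(t2))$score
    want <- phylogeny_pcc_oracle(t1$subclones, as.integer(t1$assignment),
                                 t2$subclones, as.integer(t2$assignment))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("zero-variance phylogeny comparisons score 0 and are flagged", {
  # a soft prediction spreading probability equally over all four relations
  # has a constant stacked vector, hence no variance to correlate against
  n <- 4
  cc <- matrix(0.25, n, n); diag(cc) <- 1
  ad <- matrix(0.25, n, n); diag(ad) <- 0
  flat <- relationship_from_soft(cc, ad)
  res <- score_3(tiny_truth(4), flat)
  expect_equal(res$score, 0)
  expect_true("zero_variance" %in% res$flags)
})

test_that("reconciliation adds one zero-CP cluster and drops false positives", {
  truth_ids <- paste0("s", 1:5)
  pred_ids <- c(paste0("s", 1:4), "s6")
  lab <- c(1L, 1L, 2L, 2L, 3L)
  rec <- reconcile_prediction(lab, pred_ids, truth_ids)
  expect_equal(names(rec), truth_ids)
  expect_equal(length(rec), 5)
  # the truth-only SNV gets a fresh cluster of its own
  expect_false(rec[["s5"]] %in% rec[paste0("s", 1:4)])
  # identity when SNV sets agree
  expect_equal(unname(reconcile_prediction(lab, truth_ids, truth_ids)),
               canonicalize_labels(lab))
  # multiple missing SNVs share ONE zero-CP cluster
  rec2 <- reconcile_prediction(c(1L), "s1", paste0("s", 1:3))
  expect_equal(unname(rec2[c("s2", "s3")]), rep(rec2[["s2"]], 2))
  expect_equal(length(unique(rec2)), 2)
  expect_error(reconcile_prediction(lab, paste0("x", 1:5), truth_ids),
               "none of the truth")
})

test_that("reconciled matrices treat missing SNVs as a normal-derived leaf", {
  truth_ids <- paste0("s", 1:4)
  tree <- data.frame(id = 1:2, parent = c(0L, 1L))
  mats <- build_relationship_matrices(tree, c(1L, 2L))
  rec <- reconcile_prediction(mats, c("s1", "s2"), truth_ids)
  expect_equal(dim(rec$cocluster), c(4, 4))
  # FN SNVs cocluster with each other, are cousins of all somatic SNVs
  expect_equal(rec$cocluster["s3", "s4"], 1)
  expect_equal(rec$cousin["s3", "s1"], 1)
  expect_equal(rec$ancestor_descendant["s1", "s3"], 0)
  # partition invariant still holds
  tot <- rec$cocluster + rec$ancestor_descendant +
    t(rec$ancestor_descendant) + rec$cousin
  expect_equal(tot[upper.tri(tot)], rep(1, 6))
})

test_that("cluster-profile reconciliation adds the SNV-mass shortfall at CP 0", {
  prof <- cluster_profile(1, 80, 0.7)
  rec <- reconcile_prediction(prof, NULL, paste0("s", 1:100))
  expect_equal(nrow(rec), 2)
  expect_equal(rec$cp[2], 0)
  expect_equal(rec$n_ssms[2], 20)
  same <- reconcile_prediction(cluster_profile(1, 100, 0.7), NULL,
                               paste0("s", 1:100))
  expect_equal(nrow(same), 1)
})
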