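make_records <- function(mat, subchallenge = "1C", titration = NULL) {
  # mat: algorithm x tumor raw scores
  rows <- expand.grid(algorithm = rownames(mat), tumor = colnames(mat),
                      stringsAsFactors = FALSE)
  tg <- if (is.null(titration)) NA_character_ else titration[rows$tumor]
  score_table(rows$tumor, rows$algorithm, subchallenge,
              mat[cbind(rows$algorithm, rows$tumor)], titration_group = tg)
}

test_that("min-max normalization maps group extremes to 0 and 1", {
  m <- rbind(a = c(t1 = 0.2), b = c(t1 = 0.5), c = c(t1 = 0.8))
  r <- minmax_normalize(make_records(m))
  expect_equal(sort(r$s_minmax), c(0, 0.5, 1))
  # degenerate group: everyone equally best
  m2 <- rbind(a = c(t1 = 0.4), b = c(t1 = 0.4))
  expect_equal(minmax_normalize(make_records(m2))$s_minmax, c(1, 1))
})

test_that("titration tumors share one min and max across depths", {
  m <- rbind(a = c(d8 = 0.1, d64 = 0.5), b = c(d8 = 0.3, d64 = 0.9))
  r <- minmax_normalize(make_records(m, titration = c(d8 = "T1", d64 = "T1")))
  # global min 0.1 -> 0, global max 0.9 -> 1; within-depth extremes do not
  expect_equal(sort(r$s_minmax), (sort(as.numeric(m)) - 0.1) / 0.8)
  # without the shared group each depth would normalize to {0, 1}
  r2 <- minmax_normalize(make_records(m))
  expect_equal(sort(r2$s_minmax), c(0, 0, 1, 1))
})

test_that("normalization is idempotent", {
  set.seed(5)
  m <- matrix(runif(12), 3, 4, dimnames = list(letters[1:3], paste0("t", 1:4)))
  r1 <- minmax_normalize(make_records(m))
  r2 <- r1; r2$s_raw <- r2$s_minmax
  expect_equal(minmax_normalize(r2)$s_minmax, r1$s_minmax)
})

test_that("normalization is invariant to affine rescaling within groups", {
  set.seed(8)
  m <- matrix(runif(15), 3, 5, dimnames = list(letters[1:3], paste0("t", 1:5)))
  r1 <- minmax_normalize(make_records(m))
  r2 <- minmax_normalize(make_records(3.7 * m - 0.4))
  expect_equal(r1$s_minmax, r2$s_minmax)
  # a non-affine monotone transform still preserves within-group ordering
  r3 <- minmax_normalize(make_records(exp(2 * m)))
  key <- paste(r1$tumor, r1$subchallenge)
  for (k in unique(key)) {
    i <- key == k
    expect_equal(order(r1$s_minmax[i]), order(r3$s_minmax[i]))
  }
})

test_that("tied algorithms share the minimum rank; dominators rank first", {
  m <- rbind(a = c(t1 = 0.9, t2 = 0.8), b = c(t1 = 0.9, t2 = 0.8),
             c = c(t1 = 0.1, t2 = 0.2))
  r <- rank_algorithms(minmax_normalize(make_records(m)), "1C")
  expect_equal(r$rank[r$algorithm %in% c("a", "b")], c(1L, 1L))
  expect_equal(r$rank[r$algorithm == "c"], 3L)
})

test_that("missing tumors are excluded from medians unless zero-filled", {
  m <- rbind(a = c(t1 = 0.9, t2 = NA, t3 = NA),
             b = c(t1 = 0.5, t2 = 0.5, t3 = 0.5))
  r <- rank_algorithms(minmax_normalize(make_records(m)), "1C")
  expect_equal(r$n_tumors[r$algorithm == "a"], 1)
  expect_equal(r$rank[r$algorithm == "a"], 1L)
  rz <- rank_algorithms(minmax_normalize(make_records(m)), "1C",
                        zero_fill = TRUE)
  expect_equal(rz$rank[rz$algorithm == "b"], 1L)
})

test_that("bootstrap rank test gives P = 1 for the best and its duplicate", {
  set.seed(2)
  m <- matrix(runif(40, 0.3, 0.7), 4, 10,
              dimnames = list(c("best", "clone", "mid", "low"),
                              paste0("t", 1:10)))
  m["best", ] <- runif(10, 0.8, 1)
  m["clone", ] <- m["best", ]
  m["low", ] <- runif(10, 0, 0.2)
  r <- minmax_normalize(make_records(m))
  p <- bootstrap_rank_pvalue(r, "1C", n_boot = 500, seed = 99)
  expect_equal(p$p_value[p$algorithm == "best"], 1)
  expect_equal(p$p_value[p$algorithm == "clone"], 1)
  expect_true(p$indistinguishable[p$algorithm == "clone"])
  # strictly dominated on every tumor: never catches up in any resample
  expect_equal(p$p_value[p$algorithm == "low"], 0)
  expect_false(p$indistinguishable[p$algorithm == "low"])
})

test_that("bootstrap P does not increase with the margin of dominance", {
  ps <- vapply(c(0.05, 0.2, 0.5), function(gap) {
    m <- rbind(best = rep(0.8, 8), entry = rep(0.8 - gap, 8))
    colnames(m) <- paste0("t", 1:8)
    r <- make_records(m); r$s_minmax <- r$s_raw
    bootstrap_rank_pvalue(r, "1C", n_boot = 300,
                          seed = 1)$p_value[2]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("decision projection reduces to mean-score ranking at equal weights", {
  set.seed(13)
  m <- matrix(runif(12), 4, 3,
              dimnames = list(paste0("alg", 1:4), c("1A", "1B", "1C")))
  d <- decision_projection(m)
  expect_equal(unname(d$ranking),
               unname(rank(-rowMeans(m), ties.method = "min")))
  # identical algorithms collapse to a single projected point
  m2 <- matrix(0.5, 3, 2, dimnames = list(letters[1:3], c("1A", "1B")))
  d2 <- decision_projection(m2)
  expect_lt(max(dist(d2$algorithm_proj)), 1e-12)
})

test_that("projections match the explicit eigendecomposition of a 3x2 matrix", {
  m <- matrix(c(0.9, 0.5, 0.1, 0.8, 0.4, 0.3), 3, 2,
              dimnames = list(c("a", "b", "c"), c("1C", "2A")))
  d <- decision_projection(m)
  cm <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(cm) / (nrow(m) - 1))
  got <- abs(d$algorithm_proj)            # eigenvector sign is arbitrary
  want <- abs(cm %*% eig$vectors)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("weight perturbation keeps a dominating algorithm first everywhere", {
  set.seed(4)
  scores <- array(runif(5 * 3 * 4, 0.2, 0.6), dim = c(5, 3, 4),
                  dimnames = list(paste0("t", 1:5), c("dom", "x", "y"),
                                  c("1A", "1B", "1C", "2A")))
  scores[, "dom", ] <- runif(20, 0.8, 1)
  res <- weight_perturbation_study(scores, n_axes = 50, n_weight_sets = 20,
                                   seed = 3)
  expect_equal(ncol(res$ranks), 400)
  expect_true(res$ever_first[["dom"]])
  expect_equal(res$first_fraction[["dom"]], 1)
  expect_true(all(res$ranks["dom", ] == 1))
  # zero perturbation leaves every axis at the equal-weight axis
  res0 <- weight_perturbation_study(scores, n_axes = 10, n_weight_sets = 2,
                                    perturbation = 0, seed = 3)
  expect_lt(max(dist(res0$axes)), 1e-12)
})

test_that("correlated same-team submissions are pruned to the best one", {
  set.seed(17)
  base <- runif(8)
  m <- rbind(a1 = base + 0.1, a2 = base + 0.05, b = runif(8))
  colnames(m) <- paste0("t", 1:8)
  r <- minmax_normalize(make_records(m))
  out <- filter_correlated_submissions(r, teams = c(a1 = "A", a2 = "A", b = "B"))
  kept <- unique(out$algorithm)
  expect_true("a1" %in% kept)    # best of the correlated pair survives
  expect_false("a2" %in% kept)
  expect_true("b" %in% kept)
})
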