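test_that("all seven prediction dialects round-trip", {
  tr <- simulate_tree(3, "branching", 0.8, n_snvs = 15, seed = 81)
  pred <- degrade_truth(tr, noise_spec(misassign_rate = 0.2, cp_sd = 0.03,
                                       seed = 82))
  d <- withr::local_tempdir()
  for (sc in c("1A", "1B", "1C", "2A", "2B", "3A", "3B")) {
    f <- file.path(d, paste0("sc", sc, ".tsv"))
    write_prediction(pred[[paste0("sc", sc)]], f, sc)
    back <- read_prediction(f, sc)
    orig <- pred[[paste0("sc", sc)]]
    switch(sc,
      "1A" = expect_equal(back, orig, tolerance = 1e-9),
      "1B" = expect_identical(back, as.integer(orig)),
      "1C" = expect_equal(back, orig, tolerance = 1e-7, ignore_attr = TRUE),
      "2A" = expect_equal(back, unname(as.integer(orig))),
      "2B" = expect_equal(back, unname(orig[, ]), tolerance = 1e-7,
                          ignore_attr = TRUE),
      "3A" = expect_equal(back, orig$tree, ignore_attr = TRUE),
      "3B" = expect_equal(back, unname(orig$ancestor_descendant),
                          tolerance = 1e-7, ignore_attr = TRUE))
  }
})

test_that("validators reject malformed predictions with a located error", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.tsv")
  m <- matrix(c(1, 0.2, 0.7, 1), 2, 2)   # asymmetric
  write.table(m, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(read_prediction(f, "2B"), "asymmetric")
  writeLines("1.4", f)
  expect_error(read_prediction(f, "1A"), "\\[0, 1\\]")
  writeLines("-2", f)
  expect_error(read_prediction(f, "1B"), "non-negative")
  writeLines(c("1\t0", "2\t3"), f)       # orphan parent
  expect_error(read_prediction(f, "3A"), "orphan")
  m2 <- matrix(c(0.9, 0.2, 0.2, 1), 2, 2)  # off-unit diagonal
  write.table(m2, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(read_prediction(f, "2B"), "diagonal")
})

test_that("truth bundles round-trip and enforce invariants on load", {
  tr <- simulate_tree(4, "linear", 0.77, n_snvs = 25, seed = 91)
  d <- withr::local_tempdir()
  write_truth(tr, d)
  back <- read_truth(d)
  expect_equal(back$purity, tr$purity)
  expect_equal(back$subclones, tr$subclones, tolerance = 1e-9)
  expect_equal(back$assignment, tr$assignment)
  # corrupt the bundle: child cp above parent cp
  cl <- read.table(file.path(d, "clusters.tsv"), header = TRUE, sep = "\t")
  cl$cp[2] <- cl$cp[1] + 0.2
  write.table(cl, file.path(d, "clusters.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(read_truth(d), "pigeonhole")
  # missing assignment row
  write_truth(tr, d)
  a <- read.table(file.path(d, "assignments.tsv"), header = TRUE, sep = "\t")
  a$cluster[3] <- NA
  write.table(a, file.path(d, "assignments.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_truth(d), a$snv[3])
})

test_that("an on-disk cohort scores end to end with failures kept as missing", {
  design <- cohort_design(n_tumors = 2, snv_range = c(20, 30), seed = 321)
  algs <- list(a1 = noise_spec(), a2 = noise_spec(misassign_rate = 0.3))
  d <- withr::local_tempdir()
  co <- generate_cohort(design, algs, out_dir = d, titration = FALSE)
  scores <- score_command(file.path(d, "truth"), d)
  expect_equal(nrow(scores), 2 * 2 * 7)
  expect_true(all(is.finite(scores$s_raw)))
  # zero-noise algorithm scores 1 everywhere
  expect_equal(scores$s_raw[scores$algorithm == "a1"], rep(1, 14))
  # rerun is deterministic
  scores2 <- score_command(file.path(d, "truth"), d)
  expect_identical(scores, scores2)
  # corrupt one file: its row goes missing with a reason, others still score
  victim <- file.path(d, "predictions", "T01", "a2", "sc1A.tsv")
  writeLines("not-a-number", victim)
  scores3 <- score_command(file.path(d, "truth"), d)
  bad <- scores3$tumor == "T01" & scores3$algorithm == "a2" &
    scores3$subchallenge == "1A"
  expect_true(is.na(scores3$s_raw[bad]))
  expect_match(scores3$reason[bad], "purity")
  expect_equal(sum(is.na(scores3$s_raw)), 1)
  # CSV export round-trips the table shape
  csv <- file.path(d, "scores.csv")
  score_command(file.path(d, "truth"), d, out_csv = csv)
  expect_equal(nrow(read.csv(csv)), 28)
})

test_that("in-memory cohort scoring matches the on-disk path", {
  design <- cohort_design(n_tumors = 2, snv_range = c(15, 25), seed = 654)
  algs <- list(x = noise_spec(cp_sd = 0.05, misassign_rate = 0.2, seed = 1))
  d <- withr::local_tempdir()
  co <- generate_cohort(design, algs, out_dir = d, titration = FALSE)
  mem <- score_cohort(co, normalize = FALSE)
  disk <- score_command(file.path(d, "truth"), d, normalize = FALSE)
  key <- function(x) paste(x$tumor, x$algorithm, x$subchallenge)
  disk <- disk[match(key(mem), key(disk)), ]
  expect_equal(mem$s_raw, disk$s_raw, tolerance = 1e-6)
})
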