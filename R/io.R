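SUBCHALLENGES <- c("1A", "1B", "1C", "2A", "2B", "3A", "3B")

pred_filename <- function(subchallenge) paste0("sc", subchallenge, ".tsv")

# stream a dense numeric matrix as TSV in row chunks, avoiding a full
# character copy in memory (dense dialects grow as O(N^2))
write_dense_matrix <- function(m, con, chunk = 256L) {
  n <- nrow(m)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    block <- m[lo:hi, , drop = FALSE]
    lines <- apply(formatC(block, format = "fg", digits = 8, width = 1),
                   1, paste, collapse = "\t")
    writeLines(lines, con)
  }
}

#' Write a prediction file
#'
#' Serializes one subchallenge prediction in the benchmark's TSV dialects:
#' `1A` a single purity value; `1B` a single non-negative integer; `1C`
#' headerless rows `(cluster_id, n_ssms, cp)`; `2A` one 1-based cluster label
#' per line in SNV-index order; `2B` a dense symmetric coclustering matrix
#' with unit diagonal; `3A` headerless rows `(cluster_id, parent_id)` with 0
#' denoting the germline root; `3B` a dense ancestor-probability matrix.
#'
#' @param pred the prediction object for that subchallenge (as produced by
#'   [degrade_truth()] or the baselines).
#' @param path output file path.
#' @param subchallenge one of `"1A" ... "3B"`.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(pred, path, subchallenge) {
  subchallenge <- match.arg(subchallenge, SUBCHALLENGES)
  con <- file(path, "w")
  on.exit(close(con))
  switch(subchallenge,
    "1A" = writeLines(format(pred, digits = 10), con),
    "1B" = writeLines(format(as.integer(pred)), con),
    "1C" = utils::write.table(pred[, c("cluster", "n_ssms", "cp")], con,
                              sep = "\t", row.names = FALSE,
                              col.names = FALSE, quote = FALSE),
    "2A" = writeLines(as.character(as.integer(pred)), con),
    "2B" = write_dense_matrix(pred, con),
    "3A" = {
      tree <- if (is.list(pred) && !is.data.frame(pred)) pred$tree else pred
      utils::write.table(tree[, c("id", "parent")], con, sep = "\t",
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    },
    "3B" = {
      m <- if (inherits(pred, "relationship_matrices"))
        pred$ancestor_descendant else pred
      write_dense_matrix(m, con)
    })
  invisible(path)
}

validation_error <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, line, msg), call. = FALSE)
}

read_matrix_file <- function(path, max_snvs) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    validation_error(path, 1, sprintf("matrix is %d x %d, not square",
                                      nrow(m), ncol(m)))
  if (nrow(m) > max_snvs)
    validation_error(path, 1, sprintf(
      "matrix covers %d SNVs, above the %d cap (dense O(N^2) memory)",
      nrow(m), max_snvs))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    validation_error(path, bad[1, 1], "non-finite matrix entry")
  if (any(m < -1e-9) || any(m > 1 + 1e-9))
    validation_error(path, which(m < 0 | m > 1, arr.ind = TRUE)[1, 1],
                     "matrix entries must lie in [0, 1]")
  pmin(pmax(m, 0), 1)
}

#' Read and validate a prediction file
#'
#' Parses one subchallenge prediction under its dialect (see
#' [write_prediction()]) and validates it: finite values, symmetry and unit
#' diagonal (within 1e-6) for coclustering matrices, probability ranges for
#' soft matrices, parsable tree rows for phylogenies. Violations raise a
#' validation error naming the file and line.
#'
#' @param path prediction file.
#' @param subchallenge one of `"1A" ... "3B"`.
#' @param max_snvs size cap for dense matrices (default 20000).
#' @return The typed prediction: numeric (1A), integer (1B), cluster profile
#'   (1C), integer labels (2A), matrix (2B/3B) or tree data.frame (3A).
#' @export
read_prediction <- function(path, subchallenge, max_snvs = 20000) {
  subchallenge <- match.arg(subchallenge, SUBCHALLENGES)
  if (!file.exists(path)) stop("no such prediction file: ", path)
  switch(subchallenge,
    "1A" = {
      x <- suppressWarnings(as.numeric(readLines(path, warn = FALSE)[1]))
      if (!is.finite(x) || x < 0 || x > 1)
        validation_error(path, 1, "purity must be a single value in [0, 1]")
      x
    },
    "1B" = {
      x <- suppressWarnings(as.numeric(readLines(path, warn = FALSE)[1]))
      if (!is.finite(x) || x < 0 || x != round(x))
        validation_error(path, 1, "subclone count must be a non-negative integer")
      as.integer(x)
    },
    "1C" = {
      d <- utils::read.table(path, sep = "\t", header = FALSE)
      if (ncol(d) != 3)
        validation_error(path, 1, "expected 3 columns (cluster, n_ssms, cp)")
      names(d) <- c("cluster", "n_ssms", "cp")
      bad <- which(!is.finite(d$cp) | d$cp < 0 | d$cp > 1)
      if (length(bad))
        validation_error(path, bad[1], "cluster cp must lie in [0, 1]")
      cluster_profile(d$cluster, d$n_ssms, d$cp)
    },
    "2A" = {
      lab <- suppressWarnings(as.integer(readLines(path, warn = FALSE)))
      bad <- which(is.na(lab) | lab < 1)
      if (length(bad))
        validation_error(path, bad[1], "labels must be positive integers")
      lab
    },
    "2B" = {
      m <- read_matrix_file(path, max_snvs)
      asym <- max(abs(m - t(m)))
      if (asym > 1e-6)
        validation_error(path, which(abs(m - t(m)) > 1e-6,
                                     arr.ind = TRUE)[1, 1],
                         sprintf("coclustering matrix asymmetric (max %.2g)",
                                 asym))
      if (max(abs(diag(m) - 1)) > 1e-6)
        validation_error(path, which.max(abs(diag(m) - 1)),
                         "coclustering diagonal must be 1")
      m
    },
    "3A" = {
      d <- utils::read.table(path, sep = "\t", header = FALSE)
      if (ncol(d) != 2)
        validation_error(path, 1, "expected 2 columns (cluster_id, parent_id)")
      names(d) <- c("id", "parent")
      tryCatch(validate_tree(d$id, d$parent),
               error = function(e) validation_error(path, 1, conditionMessage(e)))
      d
    },
    "3B" = read_matrix_file(path, max_snvs))
}

#' Write a truth bundle
#'
#' A truth bundle is a directory with `purity.txt` (single value),
#' `clusters.tsv` (`id`, `parent`, `cp`, `n_ssms`; parent 0 is the germline
#' root) and `assignments.tsv` (`snv`, `cluster`), plus `ploidy.txt`.
#'
#' @param truth a [phylogeny_truth()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "phylogeny_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(format(truth$purity, digits = 10), file.path(dir, "purity.txt"))
  writeLines(format(truth$psi, digits = 10), file.path(dir, "ploidy.txt"))
  utils::write.table(truth$subclones, file.path(dir, "clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(snv = names(truth$assignment),
                                cluster = as.integer(truth$assignment)),
                     file.path(dir, "assignments.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read and validate a truth bundle
#'
#' Loads a truth written by [write_truth()]; all `phylogeny_truth` invariants
#' (single clonal node carrying the purity, pigeonhole consistency, complete
#' assignment) are enforced at load.
#'
#' @param dir truth bundle directory.
#' @return A [phylogeny_truth()].
#' @export
read_truth <- function(dir) {
  purity <- as.numeric(readLines(file.path(dir, "purity.txt"), warn = FALSE)[1])
  psi_file <- file.path(dir, "ploidy.txt")
  psi <- if (file.exists(psi_file))
    as.numeric(readLines(psi_file, warn = FALSE)[1]) else 2
  clusters <- utils::read.table(file.path(dir, "clusters.tsv"), sep = "\t",
                                header = TRUE)
  assign_df <- utils::read.table(file.path(dir, "assignments.tsv"), sep = "\t",
                                 header = TRUE,
                                 colClasses = c("character", "integer"))
  if (anyNA(assign_df$cluster))
    stop("missing cluster for SNV ",
         assign_df$snv[which(is.na(assign_df$cluster))[1]])
  phylogeny_truth(purity, clusters,
                  stats::setNames(assign_df$cluster, assign_df$snv),
                  psi = psi)
}

#' Score a full prediction set against a truth
#'
#' Applies the seven subchallenge metrics to a `prediction_set` (see
#' [degrade_truth()]), reconciling the prediction's SNV universe with the
#' truth first: truth-only SNVs join a single zero-CP cluster derived from
#' the normal, prediction-only SNVs are excluded.
#'
#' @param truth a [phylogeny_truth()].
#' @param pred a `prediction_set`.
#' @param subchallenges which metrics to compute (default all seven).
#' @return Named numeric vector of raw scores.
#' @export
score_prediction_set <- function(truth, pred,
                                 subchallenges = SUBCHALLENGES) {
  stopifnot(inherits(truth, "phylogeny_truth"))
  truth_ids <- names(truth$assignment)
  pred_ids <- pred$snv_ids
  if (is.null(pred_ids)) pred_ids <- truth_ids
  truth_lab <- stats::setNames(canonicalize_labels(truth$assignment),
                               truth_ids)
  out <- stats::setNames(rep(NA_real_, length(subchallenges)), subchallenges)
  for (sc in subchallenges) {
    out[sc] <- switch(sc,
      "1A" = score_1a(truth$purity, pred$sc1A),
      "1B" = score_1b(nrow(truth$subclones), pred$sc1B),
      "1C" = {
        tp <- cluster_profile(truth$subclones$id, truth$subclones$n_ssms,
                              truth$subclones$cp)
        pp <- reconcile_prediction(pred$sc1C, pred_ids, truth_ids)
        score_1c(tp, pp)$score
      },
      "2A" = {
        rec <- reconcile_prediction(as.integer(pred$sc2A), pred_ids, truth_ids)
        score_2(truth_lab, rec)$score
      },
      "2B" = {
        rec <- reconcile_prediction(pred$sc2B, pred_ids, truth_ids)
        score_2(truth_lab, rec)$score
      },
      "3A" = {
        mats <- build_relationship_matrices(pred$sc3A$tree,
                                            as.integer(pred$sc3A$assignment))
        rec <- reconcile_prediction(mats, pred_ids, truth_ids)
        score_3(truth, rec)$score
      },
      "3B" = {
        mats <- pred$sc3B
        if (!inherits(mats, "relationship_matrices"))
          mats <- relationship_from_soft(as_cocluster(pred$sc2B,
                                                      length(pred_ids)), mats)
        rec <- reconcile_prediction(mats, pred_ids, truth_ids)
        score_3(truth, rec)$score
      })
  }
  out
}

#' Score every prediction in a synthetic cohort
#'
#' Runs [score_prediction_set()] over all `{tumor, algorithm}` pairs of an
#' in-memory cohort and returns the normalized score table. Failures are
#' recorded as missing scores (with the reason attached as an attribute),
#' not zero.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param subchallenges which metrics to compute (default all seven).
#' @param normalize add min-max normalized scores (default TRUE).
#' @return A [score_table()].
#' @export
score_cohort <- function(cohort, subchallenges = SUBCHALLENGES,
                         normalize = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- list(); failures <- list()
  for (tid in names(cohort$predictions)) {
    truth <- cohort$truths[[tid]]
    tg <- cohort$meta[[tid]]$titration_group
    for (alg in names(cohort$predictions[[tid]])) {
      s <- tryCatch(
        score_prediction_set(truth, cohort$predictions[[tid]][[alg]],
                             subchallenges),
        error = function(e) {
          failures[[paste(tid, alg)]] <<- conditionMessage(e)
          stats::setNames(rep(NA_real_, length(subchallenges)), subchallenges)
        })
      rows[[length(rows) + 1L]] <-
        score_table(tid, alg, subchallenges, as.numeric(s),
                    titration_group = tg)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("score_table", "data.frame")
  if (normalize) out <- minmax_normalize(out)
  attr(out, "failures") <- failures
  out
}

# ---- on-disk cohort ------------------------------------------------------

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tid in names(cohort$truths))
    write_truth(cohort$truths[[tid]], file.path(out_dir, "truth", tid))
  man <- cohort$manifest
  man$path <- NA_character_
  for (i in seq_len(nrow(man))) {
    tid <- man$tumor[i]; alg <- man$algorithm[i]; sc <- man$subchallenge[i]
    pdir <- file.path(out_dir, "predictions", tid, alg)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    pred <- cohort$predictions[[tid]][[alg]]
    rel <- file.path("predictions", tid, alg, pred_filename(sc))
    write_prediction(pred[[paste0("sc", sc)]], file.path(out_dir, rel), sc)
    snv_file <- file.path(pdir, "snvs.txt")
    if (!file.exists(snv_file)) writeLines(pred$snv_ids, snv_file)
    man$path[i] <- rel
  }
  utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Score an on-disk cohort
#'
#' Reads `manifest.tsv` from a prediction directory, loads each truth bundle
#' and prediction file, reconciles and scores it, and returns (optionally
#' writing as CSV) the score table. Malformed or missing predictions are
#' recorded as missing scores with a reason; the run continues.
#'
#' @param truth_dir directory of truth bundles (one subdirectory per tumor).
#' @param pred_dir directory containing `manifest.tsv` and prediction files.
#' @param out_csv optional path for the score table CSV.
#' @param normalize add min-max normalized scores (default TRUE).
#' @return A [score_table()] with a `reason` column for missing scores.
#' @export
score_command <- function(truth_dir, pred_dir, out_csv = NULL,
                          normalize = TRUE) {
  man <- utils::read.table(file.path(pred_dir, "manifest.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character")
  if (!nrow(man)) stop("empty manifest")
  truths <- new.env()
  get_truth <- function(tid) {
    if (!exists(tid, envir = truths, inherits = FALSE))
      truths[[tid]] <- read_truth(file.path(truth_dir, tid))
    truths[[tid]]
  }
  n <- nrow(man)
  s_raw <- rep(NA_real_, n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sc <- man$subchallenge[i]
    res <- tryCatch({
      truth <- get_truth(man$tumor[i])
      pred <- read_prediction(file.path(pred_dir, man$path[i]), sc)
      pdir <- dirname(file.path(pred_dir, man$path[i]))
      snv_file <- file.path(pdir, "snvs.txt")
      snv_ids <- if (file.exists(snv_file))
        readLines(snv_file, warn = FALSE) else names(truth$assignment)
      pset <- list(snv_ids = snv_ids)
      pset[[paste0("sc", sc)]] <- typed_prediction(pred, sc, pdir, snv_ids)
      score_prediction_set(truth, pset, sc)[[sc]]
    }, error = function(e) structure(NA_real_, reason = conditionMessage(e)))
    s_raw[i] <- as.numeric(res)
    if (!is.null(attr(res, "reason"))) reason[i] <- attr(res, "reason")
  }
  out <- score_table(man$tumor, man$algorithm, man$subchallenge, s_raw,
                     titration_group = if ("titration_group" %in% names(man))
                       man$titration_group else NA_character_)
  out$reason <- reason
  if (normalize) out <- minmax_normalize(out)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

# lift a parsed prediction file into the prediction_set slot expected by the
# scorer; 3A needs the sibling 2A labels, 3B the sibling 2B cocluster matrix
typed_prediction <- function(pred, sc, pdir, snv_ids) {
  if (sc == "3A") {
    lab_file <- file.path(pdir, pred_filename("2A"))
    if (!file.exists(lab_file))
      stop("sc3A requires the sc2A assignment file alongside the tree")
    lab <- read_prediction(lab_file, "2A")
    if (length(lab) != length(snv_ids))
      stop("sc2A labels cover ", length(lab), " SNVs but snvs.txt lists ",
           length(snv_ids))
    return(list(tree = pred, assignment = lab))
  }
  if (sc == "3B") {
    cc_file <- file.path(pdir, pred_filename("2B"))
    cc <- if (file.exists(cc_file)) read_prediction(cc_file, "2B")
          else {
            lab_file <- file.path(pdir, pred_filename("2A"))
            if (!file.exists(lab_file))
              stop("sc3B requires an sc2B matrix or sc2A labels for coclustering")
            build_cocluster(read_prediction(lab_file, "2A"))
          }
    if (nrow(cc) != nrow(pred))
      stop("sc3B matrix and coclustering matrix disagree on SNV count")
    return(relationship_from_soft(cc, pred))
  }
  pred
}
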