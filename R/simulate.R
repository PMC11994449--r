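# sample() without its scalar-x surprise
resample <- function(x, ...) x[sample.int(length(x), ...)]

#' Cohort design parameters
#'
#' Describes the design space of a synthetic cohort: number of tumors,
#' subclone counts, tree topology mix, purity, sequencing depth levels, SNV
#' burden and whole-genome doubling probability. The defaults mirror the
#' benchmark's design space: 1-5 subclones, purities 0.3-0.95, depths
#' 8x-128x, 500-5,000 SNVs, and a balanced mix of linear and branching
#' topologies.
#'
#' @param n_tumors number of tumors.
#' @param subclone_range integer interval of subclone counts.
#' @param topology_mix fraction of branching (versus linear) topologies.
#' @param purity_range purity interval.
#' @param depth_levels sequencing depths; also used for the titration subset.
#' @param snv_range SNV-count interval.
#' @param wgd_probability probability of whole-genome doubling (ploidy 4).
#' @param seed integer seed for cohort generation.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_tumors = 20, subclone_range = c(1, 5),
                          topology_mix = 0.5, purity_range = c(0.3, 0.95),
                          depth_levels = c(8, 16, 32, 64, 128),
                          snv_range = c(500, 5000), wgd_probability = 0.3,
                          seed = NULL) {
  stopifnot(n_tumors >= 1, length(subclone_range) == 2,
            subclone_range[1] >= 1, diff(subclone_range) >= 0,
            topology_mix >= 0, topology_mix <= 1,
            purity_range[1] > 0, purity_range[2] <= 1,
            length(depth_levels) >= 1, snv_range[1] >= 1,
            wgd_probability >= 0, wgd_probability <= 1)
  structure(list(n_tumors = n_tumors, subclone_range = subclone_range,
                 topology_mix = topology_mix, purity_range = purity_range,
                 depth_levels = depth_levels, snv_range = snv_range,
                 wgd_probability = wgd_probability, seed = seed),
            class = "cohort_design")
}

#' Noise specification for a synthetic "algorithm"
#'
#' Describes how a truth is degraded into a prediction, standing in for a
#' participant algorithm of known relative quality. All rates lie in
#' `[0, 1]`; a zero-noise spec reproduces the truth exactly.
#'
#' @param merge_prob probability that a non-clonal cluster is merged into its
#'   parent.
#' @param split_prob probability that a cluster is split in two.
#' @param cp_sd standard deviation of Gaussian jitter added to cluster CPs.
#' @param misassign_rate per-SNV probability of relabeling to a random
#'   cluster.
#' @param purity_sd standard deviation of Gaussian jitter on the purity.
#' @param fn_rate per-SNV probability of dropping the SNV (false negative).
#' @param fp_rate number of spurious SNVs added, as a fraction of the truth
#'   SNV count (false positives).
#' @param seed integer seed.
#' @param name optional algorithm label.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(merge_prob = 0, split_prob = 0, cp_sd = 0,
                       misassign_rate = 0, purity_sd = 0, fn_rate = 0,
                       fp_rate = 0, seed = NULL, name = NULL) {
  rates <- c(merge_prob, split_prob, misassign_rate, fn_rate, fp_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), cp_sd >= 0, purity_sd >= 0)
  structure(list(merge_prob = merge_prob, split_prob = split_prob,
                 cp_sd = cp_sd, misassign_rate = misassign_rate,
                 purity_sd = purity_sd, fn_rate = fn_rate, fp_rate = fp_rate,
                 seed = seed, name = name),
            class = "noise_spec")
}

#' Simulate a ground-truth tumor phylogeny
#'
#' Draws a rooted clone tree with the requested number of subclones and
#' topology, respecting the pigeonhole principle: cellular prevalences are
#' allocated by stick-breaking within each parent's CP budget with a minimum
#' gap of `min_gap` between parent and child and among siblings, so the
#' generated truths are resolvable. SNVs are distributed over the nodes with
#' a prescribed subclonal fraction, at least one per node.
#'
#' @param n_subclones number of nodes including the clonal one (`>= 1`).
#' @param topology `"linear"` (each node has at most one child) or
#'   `"branching"`.
#' @param purity clonal cellular prevalence in `(0, 1]`.
#' @param n_snvs total number of SNVs (default 100).
#' @param frac_subclonal fraction of SNVs on non-clonal nodes (default drawn
#'   uniformly from `[0.1, 0.6]`; forced to 0 when `n_subclones == 1`).
#' @param wgd whole-genome doubling flag; sets ploidy 4 instead of 2.
#' @param seed optional integer seed.
#' @param min_gap minimum CP separation (default 0.05).
#' @param max_tries bounded retries for the CP allocation.
#' @return A [phylogeny_truth()].
#' @export
simulate_tree <- function(n_subclones, topology = c("branching", "linear"),
                          purity, n_snvs = 100, frac_subclonal = NULL,
                          wgd = FALSE, seed = NULL, min_gap = 0.05,
                          max_tries = 500) {
  topology <- match.arg(topology)
  stopifnot(n_subclones >= 1, purity > 0, purity <= 1,
            n_snvs >= n_subclones)
  if (!is.null(seed)) set.seed(seed)
  min_cp <- min_gap
  for (try in seq_len(max_tries)) {
    id <- 1L; parent <- 0L; cp <- purity
    ok <- TRUE
    for (i in seq_len(n_subclones - 1L)) {
      new_id <- i + 1L
      kid_sum <- vapply(id, function(p) sum(cp[parent == p]), numeric(1))
      budget <- cp - kid_sum
      cand <- if (topology == "linear") utils::tail(id, 1) else id
      cand <- cand[budget[match(cand, id)] >= min_cp + min_gap]
      if (!length(cand)) { ok <- FALSE; break }
      # in branching trees, open a branch as soon as one is possible
      if (topology == "branching" && all(tabulate(parent, nbins = new_id) <= 1)) {
        with_child <- cand[cand %in% parent]
        if (length(with_child) && length(id) > 1) cand <- with_child
      }
      p <- resample(cand, 1)
      hi <- (cp[match(p, id)] - sum(cp[parent == p])) - min_gap
      cp_new <- stats::runif(1, min_cp, hi)
      id <- c(id, new_id); parent <- c(parent, p); cp <- c(cp, cp_new)
    }
    if (ok) break
    if (try == max_tries)
      stop("could not allocate cellular prevalences after ", max_tries,
           " attempts")
  }
  if (is.null(frac_subclonal))
    frac_subclonal <- if (n_subclones > 1) stats::runif(1, 0.1, 0.6) else 0
  if (n_subclones == 1) frac_subclonal <- 0
  n_clonal <- max(1L, round(n_snvs * (1 - frac_subclonal)))
  n_clonal <- min(n_clonal, n_snvs - (n_subclones - 1L))
  counts <- c(n_clonal, distribute_counts(n_snvs - n_clonal, n_subclones - 1L))
  lab <- sample(rep(id, counts))
  names(lab) <- paste0("s", seq_len(n_snvs))
  phylogeny_truth(purity,
                  data.frame(id = id, parent = parent, cp = cp,
                             n_ssms = counts),
                  lab, psi = if (wgd) 4 else 2)
}

# split total into k parts, each >= 1, roughly multinomial
distribute_counts <- function(total, k) {
  if (k == 0L) return(integer(0))
  stopifnot(total >= k)
  counts <- as.integer(stats::rmultinom(1, total - k, rep(1 / k, k))) + 1L
  counts
}

#' Simulate read counts for each SNV
#'
#' Binomial read sampling over the truth: total depth per SNV is Poisson with
#' the given mean; the alternate count is binomial with the expected VAF
#' `cp * multiplicity / (rho * tumor_copies + 2 * (1 - rho))` under the
#' diploid heterozygous default.
#'
#' @param truth a [phylogeny_truth()].
#' @param depth mean read depth, `> 0`.
#' @param seed optional integer seed.
#' @param tumor_copies,multiplicity local copy number and mutation
#'   multiplicity (defaults 2 and 1).
#' @return A `data.frame` with columns `snv`, `cluster`, `cp`, `alt`,
#'   `total`, `vaf`.
#' @export
simulate_reads <- function(truth, depth, seed = NULL, tumor_copies = 2,
                           multiplicity = 1) {
  stopifnot(inherits(truth, "phylogeny_truth"), depth > 0)
  if (!is.null(seed)) set.seed(seed)
  cp <- truth$subclones$cp[match(truth$assignment, truth$subclones$id)]
  rho <- truth$purity
  evaf <- cp * multiplicity / (rho * tumor_copies + 2 * (1 - rho))
  n <- length(cp)
  total <- stats::rpois(n, depth)
  alt <- stats::rbinom(n, total, pmin(evaf, 1))
  data.frame(snv = names(truth$assignment),
             cluster = as.integer(truth$assignment), cp = cp, alt = alt,
             total = total, vaf = ifelse(total > 0, alt / total, 0))
}

#' Degrade a truth into a full prediction set
#'
#' Produces the seven subchallenge outputs of one synthetic "algorithm" by
#' perturbing the truth according to a [noise_spec()]: cluster merges and
#' splits alter the subclone count, CP jitter moves cluster locations, SNV
#' misassignment relabels mutations, and false-negative/false-positive rates
#' shrink or inflate the reported SNV universe (exercising reconciliation).
#' With zero noise the prediction reproduces the truth exactly and scores 1
#' on all seven metrics.
#'
#' @param truth a [phylogeny_truth()].
#' @param noise a [noise_spec()].
#' @return A list of class `prediction_set` with elements `sc1A`, `sc1B`,
#'   `sc1C`, `sc2A`, `sc2B`, `sc3A`, `sc3B` and `snv_ids`.
#' @export
degrade_truth <- function(truth, noise = noise_spec()) {
  stopifnot(inherits(truth, "phylogeny_truth"), inherits(noise, "noise_spec"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  clus <- truth$subclones
  lab <- truth$assignment
  clonal <- clus$id[clus$parent == 0L]
  # merges: fold a non-clonal cluster into its parent
  for (cl in resample(setdiff(clus$id, clonal))) {
    if (!(cl %in% clus$id) || stats::runif(1) >= noise$merge_prob) next
    p <- clus$parent[clus$id == cl]
    lab[lab == cl] <- p
    clus$parent[clus$parent == cl] <- p
    clus <- clus[clus$id != cl, , drop = FALSE]
  }
  # splits: carve a child off a cluster, taking half its SNVs
  for (cl in clus$id) {
    if (stats::runif(1) >= noise$split_prob) next
    members <- names(lab)[lab == cl]
    if (length(members) < 2L) next
    new_id <- max(clus$id) + 1L
    moved <- sample(members, floor(length(members) / 2))
    lab[moved] <- new_id
    clus <- rbind(clus, data.frame(id = new_id, parent = cl,
                                   cp = clus$cp[clus$id == cl] *
                                     stats::runif(1, 0.4, 0.9),
                                   n_ssms = 0L))
  }
  # CP jitter (clonal node carries the purity estimate)
  if (noise$cp_sd > 0)
    clus$cp <- pmin(pmax(clus$cp + stats::rnorm(nrow(clus), 0, noise$cp_sd),
                         0.01), 1)
  purity_pred <- min(max(truth$purity +
                           if (noise$purity_sd > 0)
                             stats::rnorm(1, 0, noise$purity_sd) else 0,
                         0.01), 1)
  if (noise$cp_sd > 0 || noise$purity_sd > 0)
    clus$cp[clus$id == clonal] <- purity_pred
  # SNV misassignment
  if (noise$misassign_rate > 0) {
    hit <- stats::runif(length(lab)) < noise$misassign_rate
    if (any(hit))
      lab[hit] <- resample(clus$id, sum(hit), replace = TRUE)
  }
  # false negatives / false positives
  if (noise$fn_rate > 0) {
    keep <- stats::runif(length(lab)) >= noise$fn_rate
    if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
    lab <- lab[keep]
  }
  n_fp <- round(noise$fp_rate * length(truth$assignment))
  if (n_fp > 0) {
    fp <- stats::setNames(resample(clus$id, n_fp, replace = TRUE),
                          paste0("fp", seq_len(n_fp)))
    lab <- c(lab, fp)
  }
  # drop emptied clusters from the reported clustering (keep tree consistent)
  counts <- table(factor(lab, levels = clus$id))
  empty <- clus$id[counts == 0]
  for (e in empty) {
    p <- clus$parent[clus$id == e]
    clus$parent[clus$parent == e] <- p
  }
  clus <- clus[counts > 0, , drop = FALSE]
  clus$n_ssms <- as.integer(counts[counts > 0])
  labels <- stats::setNames(match(lab, clus$id), names(lab))
  tree <- data.frame(id = seq_len(nrow(clus)),
                     parent = match(clus$parent, clus$id))
  tree$parent[is.na(tree$parent)] <- 0L
  profile <- cluster_profile(seq_len(nrow(clus)), clus$n_ssms, clus$cp)
  structure(list(
    sc1A = purity_pred,
    sc1B = nrow(clus),
    sc1C = profile,
    sc2A = labels,
    sc2B = build_cocluster(as.integer(labels)),
    sc3A = list(tree = tree, assignment = labels),
    sc3B = build_relationship_matrices(tree, labels),
    snv_ids = names(lab)), class = "prediction_set")
}

#' Generate a synthetic cohort with degraded predictions
#'
#' Draws `n_tumors` truths from the design space and, for each, runs every
#' supplied noise specification as a synthetic "algorithm" to produce a full
#' prediction set. The first tumor is replicated across all depth levels as a
#' titration series sharing one truth (and one normalization group).
#' Optionally writes the cohort to disk in the package's file dialects with a
#' manifest.
#'
#' @param design a [cohort_design()].
#' @param algorithms named list of [noise_spec()] objects.
#' @param out_dir optional directory; when given, truth bundles, prediction
#'   files and `manifest.tsv` are written there.
#' @param titration include the multi-depth titration subset (default TRUE).
#' @return A list of class `synthetic_cohort` with `truths` (named list),
#'   `predictions` (`predictions[[tumor]][[algorithm]]`), `manifest`
#'   (data.frame with tumor, algorithm, subchallenge, depth,
#'   titration_group) and `design`.
#' @export
generate_cohort <- function(design, algorithms, out_dir = NULL,
                            titration = TRUE) {
  stopifnot(inherits(design, "cohort_design"), length(algorithms) >= 1)
  if (is.null(names(algorithms)))
    names(algorithms) <- paste0("alg", seq_along(algorithms))
  if (!is.null(design$seed)) set.seed(design$seed)
  base_seed <- if (is.null(design$seed)) 7L else design$seed %% 100000L
  truths <- list(); meta <- list()
  for (t in seq_len(design$n_tumors)) {
    n_sub <- resample(seq(design$subclone_range[1], design$subclone_range[2]), 1)
    topo <- if (stats::runif(1) < design$topology_mix) "branching" else "linear"
    rho <- stats::runif(1, design$purity_range[1], design$purity_range[2])
    n_snvs <- resample(seq(design$snv_range[1], design$snv_range[2]), 1)
    wgd <- stats::runif(1) < design$wgd_probability
    depth <- resample(design$depth_levels, 1)
    tid <- sprintf("T%02d", t)
    truths[[tid]] <- simulate_tree(n_sub, topo, rho, n_snvs, wgd = wgd,
                                   seed = base_seed * 1000L + t)
    meta[[tid]] <- list(depth = depth, titration_group = NA_character_)
  }
  if (titration) {
    for (d in design$depth_levels) {
      tid <- sprintf("T01_d%d", d)
      truths[[tid]] <- truths[["T01"]]
      meta[[tid]] <- list(depth = d, titration_group = "T01")
    }
  }
  predictions <- list()
  rows <- list()
  subs <- c("1A", "1B", "1C", "2A", "2B", "3A", "3B")
  ai <- 0L
  for (alg in names(algorithms)) {
    ai <- ai + 1L
    spec <- algorithms[[alg]]
    ti <- 0L
    for (tid in names(truths)) {
      ti <- ti + 1L
      spec_t <- spec
      spec_t$seed <- (base_seed * 7919L + ai * 611L + ti) %% .Machine$integer.max
      predictions[[tid]][[alg]] <- degrade_truth(truths[[tid]], spec_t)
      rows[[length(rows) + 1L]] <-
        data.frame(tumor = tid, algorithm = alg, subchallenge = subs,
                   depth = meta[[tid]]$depth,
                   titration_group = meta[[tid]]$titration_group)
    }
  }
  manifest <- do.call(rbind, rows)
  cohort <- structure(list(truths = truths, predictions = predictions,
                           manifest = manifest, design = design,
                           meta = meta),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d tumors x %d algorithms\n",
              length(x$truths), length(x$predictions[[1]])))
  invisible(x)
}
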