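#' Construct a subclone table
#'
#' A subclone table describes the nodes of a rooted tumor phylogeny. Each row
#' is one subclone (mutation cluster) with a positive integer `id`, a `parent`
#' id (`0` is the germline root sentinel), a cellular prevalence `cp` (the
#' fraction of all sampled cells carrying the clone's mutations) and the number
#' of SNVs assigned to the node, `n_ssms`.
#'
#' @param id integer vector of positive cluster labels.
#' @param parent integer vector of parent labels; 0 denotes the germline root.
#' @param cp numeric vector of cellular prevalences in `[0, 1]`.
#' @param n_ssms non-negative integer vector of SNV counts per node.
#' @return A `data.frame` with columns `id`, `parent`, `cp`, `n_ssms`.
#' @export
#' @examples
#' subclone_table(id = c(1, 2), parent = c(0, 1), cp = c(0.8, 0.4),
#'                n_ssms = c(50, 30))
subclone_table <- function(id, parent, cp, n_ssms = rep(0L, length(id))) {
  stopifnot(length(id) == length(parent), length(id) == length(cp),
            length(id) == length(n_ssms))
  id <- as.integer(id); parent <- as.integer(parent)
  if (anyNA(id) || any(id < 1L)) stop("subclone ids must be positive integers")
  if (anyDuplicated(id)) stop("duplicate subclone ids")
  if (any(!is.finite(cp)) || any(cp < 0) || any(cp > 1))
    stop("cellular prevalence must lie in [0, 1]")
  if (any(n_ssms < 0)) stop("n_ssms must be non-negative")
  if (!all(parent %in% c(0L, id))) stop("parent refers to a missing node")
  data.frame(id = id, parent = parent, cp = as.numeric(cp),
             n_ssms = as.integer(n_ssms))
}

#' Construct a ground-truth tumor phylogeny
#'
#' Bundles the tumor purity, the subclone tree and the SNV-to-subclone
#' assignment that a prediction is scored against. The constructor enforces the
#' structural invariants of a single-sample truth: the tree is connected and
#' acyclic, exactly one clonal node hangs off the germline root and carries
#' `cp` equal to the purity, and every node satisfies the pigeonhole
#' constraint (its children's prevalences cannot sum beyond its own).
#'
#' @param purity tumor purity `rho` in `(0, 1]`: the fraction of sampled cells
#'   that are tumor cells.
#' @param subclones a subclone table (see [subclone_table()]).
#' @param assignment integer vector of cluster ids, one per SNV; names are SNV
#'   ids (generated as `s1, s2, ...` when unnamed). The vector order is the
#'   binding SNV index for all matrix representations.
#' @param psi tumor ploidy (average copies per tumor cell); metadata used by
#'   feature computations, default 2.
#' @param pigeonhole_tol slack allowed when checking that children prevalences
#'   sum to at most the parent's.
#' @return An object of class `phylogeny_truth`.
#' @export
phylogeny_truth <- function(purity, subclones, assignment, psi = 2,
                            pigeonhole_tol = 1e-8) {
  if (!is.numeric(purity) || length(purity) != 1 || !is.finite(purity) ||
      purity <= 0 || purity > 1)
    stop("purity must be a single value in (0, 1]")
  subclones <- subclone_table(subclones$id, subclones$parent, subclones$cp,
                              subclones$n_ssms)
  validate_tree(subclones$id, subclones$parent)
  clonal <- subclones$id[subclones$parent == 0L]
  if (length(clonal) != 1L)
    stop("truth must have exactly one clonal node (child of the germline root)")
  if (abs(subclones$cp[subclones$id == clonal] - purity) > pigeonhole_tol)
    stop("clonal node cp must equal the purity")
  cp <- stats::setNames(subclones$cp, subclones$id)
  kid_sum <- tapply(subclones$cp, subclones$parent, sum)
  for (p in names(kid_sum)) {
    if (p == "0") next
    if (kid_sum[[p]] > cp[[p]] + pigeonhole_tol)
      stop("pigeonhole violation: children of node ", p,
           " have cp summing to ", signif(kid_sum[[p]], 6),
           " > parent cp ", signif(cp[[p]], 6))
  }
  assignment <- as.integer_assignment(assignment)
  if (!all(assignment %in% subclones$id))
    stop("assignment refers to a missing subclone id")
  counts <- table(factor(assignment, levels = subclones$id))
  subclones$n_ssms <- as.integer(counts)
  structure(list(purity = purity, subclones = subclones,
                 assignment = assignment, psi = psi),
            class = "phylogeny_truth")
}

as.integer_assignment <- function(assignment) {
  x <- as.integer(assignment)
  if (length(x) < 1L) stop("assignment must cover at least one SNV")
  if (anyNA(x)) stop("assignment contains missing cluster ids")
  nm <- names(assignment)
  if (is.null(nm)) nm <- paste0("s", seq_along(x))
  if (anyDuplicated(nm)) stop("duplicate SNV ids in assignment")
  stats::setNames(x, nm)
}

# Connectivity/acyclicity check by walking parent pointers to the root.
validate_tree <- function(id, parent) {
  parent_of <- stats::setNames(as.integer(parent), id)
  for (node in id) {
    seen <- integer(0)
    cur <- node
    while (cur != 0L) {
      if (cur %in% seen) stop("malformed tree: cycle involving node ", node)
      seen <- c(seen, cur)
      if (!as.character(cur) %in% names(parent_of))
        stop("malformed tree: orphan cluster ", cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  invisible(TRUE)
}

#' @export
print.phylogeny_truth <- function(x, ...) {
  cat("Tumor phylogeny truth\n")
  cat(sprintf("  purity: %.4g   ploidy: %.4g\n", x$purity, x$psi))
  cat(sprintf("  %d subclones, %d SNVs\n", nrow(x$subclones),
              length(x$assignment)))
  print(x$subclones, row.names = FALSE)
  invisible(x)
}

#' Canonicalize cluster labels
#'
#' Remaps arbitrary cluster labels to 1-based contiguous integers in order of
#' first appearance. All scoring metrics are invariant to relabeling; the
#' canonical form is used by the file dialects.
#'
#' @param labels vector of cluster labels (any atomic type).
#' @return Integer vector of the same length with labels `1..k`.
#' @export
canonicalize_labels <- function(labels) {
  if (length(labels) < 1L) stop("empty assignment")
  match(labels, unique(labels))
}

#' Pairwise coclustering matrix from a hard or soft assignment
#'
#' For a hard assignment (vector of cluster labels), entry `(i, j)` is 1 when
#' SNVs `i` and `j` share a cluster and 0 otherwise. For a soft assignment
#' (an SNV-by-cluster matrix of probabilities with rows summing to 1), entry
#' `(i, j)` is the probability that the two SNVs co-occur in a cluster: the dot
#' product of rows `i` and `j`. The diagonal is 1 by definition.
#'
#' @param assignment either a vector of labels or an SNV x cluster probability
#'   matrix.
#' @param row_tol tolerance for soft-assignment row sums.
#' @return A symmetric SNV x SNV matrix with unit diagonal.
#' @export
#' @examples
#' build_cocluster(c("a", "a", "b"))
build_cocluster <- function(assignment, row_tol = 1e-8) {
  if (is.matrix(assignment)) {
    w <- assignment
    if (nrow(w) < 1L) stop("empty assignment")
    if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
      stop("soft assignment entries must lie in [0, 1]")
    if (any(abs(rowSums(w) - 1) > row_tol))
      stop("soft assignment rows must sum to 1")
    cc <- tcrossprod(w)
    diag(cc) <- 1
    cc
  } else {
    if (length(assignment) < 1L) stop("empty assignment")
    lab <- canonicalize_labels(assignment)
    cc <- 1 * outer(lab, lab, "==")
    cc
  }
}

# Cluster-level strict-ancestor matrix from parent pointers (0 = germline).
cluster_ancestry <- function(id, parent) {
  validate_tree(id, parent)
  k <- length(id)
  parent_of <- stats::setNames(as.integer(parent), id)
  anc <- matrix(0, k, k, dimnames = list(id, id))
  for (j in seq_len(k)) {
    cur <- parent_of[[as.character(id[j])]]
    while (cur != 0L) {
      anc[as.character(cur), as.character(id[j])] <- 1
      cur <- parent_of[[as.character(cur)]]
    }
  }
  anc
}

#' Pairwise SNV relationship matrices from a phylogeny
#'
#' Expands a clone tree plus a hard SNV assignment into the three pairwise
#' relation encodings the phylogeny metrics consume: the coclustering matrix
#' (same cluster), the ancestor-descendant matrix (entry `(i, j)` is 1 when
#' the cluster of SNV `i` is a strict ancestor of the cluster of SNV `j`) and
#' the cousin matrix (distinct clusters on diverged branches). Off the
#' diagonal the four indicators `cocluster`, `ancestor_descendant`, its
#' transpose and `cousin` partition all ordered SNV pairs. The germline root
#' (id 0) never enters the matrices; only somatic clones are scored.
#'
#' @param tree a data.frame with columns `id` and `parent` (0 = germline), or
#'   a `phylogeny_truth` (in which case `assignment` is taken from it).
#' @param assignment vector of cluster ids per SNV (ignored for truths).
#' @return An object of class `relationship_matrices`: a list with elements
#'   `cocluster`, `ancestor_descendant`, `cousin`.
#' @export
build_relationship_matrices <- function(tree, assignment = NULL) {
  if (inherits(tree, "phylogeny_truth")) {
    assignment <- tree$assignment
    tree <- tree$subclones
  }
  if (is.null(assignment)) stop("assignment required when tree is not a truth")
  assignment <- as.integer_assignment(assignment)
  if (!all(assignment %in% tree$id))
    stop("assignment refers to a cluster missing from the tree")
  anc <- cluster_ancestry(tree$id, tree$parent)
  idx <- match(assignment, tree$id)
  cc <- 1 * outer(idx, idx, "==")
  ad <- anc[idx, idx, drop = FALSE]
  dimnames(ad) <- NULL
  diag(ad) <- 0
  cousin <- 1 - cc - ad - t(ad)
  diag(cousin) <- 0
  nm <- names(assignment)
  dimnames(cc) <- dimnames(ad) <- dimnames(cousin) <- list(nm, nm)
  structure(list(cocluster = cc, ancestor_descendant = ad, cousin = cousin),
            class = "relationship_matrices")
}

#' Assemble relationship matrices from submitted probability matrices
#'
#' The probabilistic phylogeny task submits an ancestor-descendant probability
#' matrix directly; the coclustering matrix comes from the coclustering task.
#' The cousin matrix is completed as the remaining probability mass,
#' `1 - cocluster - AD - t(AD)`, clamped to `[0, 1]`.
#'
#' @param cocluster symmetric SNV x SNV coclustering probability matrix.
#' @param ancestry SNV x SNV ancestor-descendant probability matrix.
#' @return A `relationship_matrices` object.
#' @export
relationship_from_soft <- function(cocluster, ancestry) {
  stopifnot(is.matrix(cocluster), is.matrix(ancestry),
            all(dim(cocluster) == dim(ancestry)))
  cousin <- 1 - cocluster - ancestry - t(ancestry)
  cousin <- pmin(pmax(cousin, 0), 1)
  diag(cousin) <- 0
  structure(list(cocluster = cocluster, ancestor_descendant = ancestry,
                 cousin = cousin),
            class = "relationship_matrices")
}

#' @export
print.relationship_matrices <- function(x, ...) {
  cat(sprintf("Pairwise SNV relationship matrices (%d SNVs)\n",
              nrow(x$cocluster)))
  invisible(x)
}
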