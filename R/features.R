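#' Number of reads per chromosome copy (NRPCC)
#'
#' `rho * d / (rho * psi + 2 * (1 - rho))`: the mean read depth adjusted for
#' tumor purity and ploidy, a power proxy for subclonal reconstruction from a
#' single sample.
#'
#' @param rho tumor purity in `(0, 1]`.
#' @param psi tumor ploidy (copies per tumor cell), `> 0`.
#' @param depth mean read depth, `>= 0`.
#' @return Reads per chromosome copy.
#' @export
#' @examples
#' nrpcc(1, 2, 64)    # 32
#' nrpcc(0.5, 2, 60)  # 15
nrpcc <- function(rho, psi, depth) {
  if (any(rho <= 0) || any(rho > 1)) stop("purity must lie in (0, 1]")
  if (any(psi <= 0)) stop("ploidy must be positive")
  if (any(depth < 0)) stop("depth must be non-negative")
  rho * depth / (rho * psi + 2 * (1 - rho))
}

#' Percentage of the genome altered (PGA)
#'
#' Fraction of genome bases lying in copy-number segments whose total copy
#' number deviates from the integer tumor ploidy (`round(psi)`). Subclonal
#' segments count their full length. Coordinates are 1-based inclusive.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`, `major`,
#'   `minor` (allele-specific integer copies).
#' @param ploidy tumor ploidy.
#' @param genome_size total bases in the genome considered.
#' @return Fraction in `[0, 1]`.
#' @export
pga <- function(segments, ploidy, genome_size) {
  if (!nrow(segments)) return(0)
  stopifnot(all(segments$end >= segments$start),
            all(segments$major >= 0), all(segments$minor >= 0))
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on ", chr)
  }
  total_cn <- segments$major + segments$minor
  dev <- total_cn != round(ploidy)
  sum((segments$end - segments$start + 1)[dev]) / genome_size
}

#' Clonal fraction (CF)
#'
#' The proportion of mutations assigned to the clonal (truncal) node:
#' mutation count in the clonal node over the total count.
#'
#' @param truth a [phylogeny_truth()].
#' @return Fraction in `[0, 1]`.
#' @export
clonal_fraction <- function(truth) {
  stopifnot(inherits(truth, "phylogeny_truth"))
  total <- sum(truth$subclones$n_ssms)
  if (total == 0) stop("truth carries no mutations")
  clonal <- truth$subclones$id[truth$subclones$parent == 0L]
  truth$subclones$n_ssms[truth$subclones$id == clonal] / total
}

#' Subclone peak overlap in CCF space
#'
#' Fits a Gaussian kernel density (Silverman's bandwidth) to each subclone's
#' CNA- and purity-adjusted CCF values on a shared grid and quantifies how
#' much of CCF space is covered by more than one subclone: the trapezoidal
#' integral of the second-largest density envelope divided by the trapezoidal
#' integral of the summed densities. Well-separated subclones give values
#' near 0; identical subclone densities give `1 / n_subclones` of the mass to
#' each extra layer (0.5 for two identical subclones). A single subclone has
#' no overlap and returns 0.
#'
#' @param subclone_ccfs list of numeric vectors, one per subclone (each with
#'   at least 2 values when more than one subclone is given).
#' @param grid_n grid resolution (default 512).
#' @param grid_max upper CCF grid bound (default 1.25).
#' @return Fraction in `[0, 1]`.
#' @export
peak_overlap <- function(subclone_ccfs, grid_n = 512, grid_max = 1.25) {
  if (!length(subclone_ccfs)) stop("no subclone CCF values supplied")
  if (length(subclone_ccfs) == 1L) return(0)
  if (any(vapply(subclone_ccfs, length, integer(1)) < 2))
    stop("each subclone needs at least 2 CCF values")
  grid <- seq(0, grid_max, length.out = grid_n)
  dens <- vapply(subclone_ccfs, function(x) {
    d <- stats::density(x, bw = "nrd0", from = 0, to = grid_max, n = grid_n)
    d$y
  }, numeric(grid_n))
  second <- apply(dens, 1, function(v) sort(v, decreasing = TRUE)[2])
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
  num <- trapz(second)
  den <- trapz(rowSums(dens))
  if (den == 0) return(0)
  min(max(num / den, 0), 1)
}

#' Convert VAF to cancer cell fraction
#'
#' `CCF = vaf * (rho * tumor_copies + (1 - rho) * normal_copies) /
#' (rho * multiplicity)`: adjusts a variant allele fraction for purity and
#' local copy number. With the defaults (diploid tumor and normal, mutation on
#' one copy) a clonal heterozygous SNV at purity `rho` has VAF `rho / 2` and
#' CCF 1.
#'
#' @param vaf variant allele fraction in `[0, 1]`.
#' @param rho tumor purity in `(0, 1]`.
#' @param tumor_copies total tumor copy number at the locus (default 2).
#' @param normal_copies normal copy number (default 2).
#' @param multiplicity copies bearing the mutation (default 1).
#' @return Cancer cell fraction.
#' @export
#' @examples
#' vaf_to_ccf(0.4, 0.8)  # 1
vaf_to_ccf <- function(vaf, rho, tumor_copies = 2, normal_copies = 2,
                       multiplicity = 1) {
  if (any(multiplicity <= 0)) stop("multiplicity must be positive")
  if (any(rho <= 0) || any(rho > 1)) stop("purity must lie in (0, 1]")
  vaf * (rho * tumor_copies + (1 - rho) * normal_copies) / (rho * multiplicity)
}

#' Compute the feature set for one synthetic tumor
#'
#' Convenience wrapper collecting the data-intrinsic features used in the
#' determinant analyses for a truth with known depth and CNA segments.
#'
#' @param truth a [phylogeny_truth()].
#' @param depth mean read depth.
#' @param segments optional CNA segment data.frame (see [pga()]).
#' @param genome_size genome size in bases for PGA (default 3e9).
#' @return A one-row `data.frame` of features.
#' @export
tumor_features <- function(truth, depth, segments = NULL, genome_size = 3e9) {
  stopifnot(inherits(truth, "phylogeny_truth"))
  data.frame(
    rho = truth$purity,
    psi = truth$psi,
    depth = depth,
    nrpcc = nrpcc(truth$purity, truth$psi, depth),
    pga = if (is.null(segments)) 0 else pga(segments, truth$psi, genome_size),
    cf = clonal_fraction(truth),
    m = sum(truth$subclones$n_ssms),
    n_subclones = nrow(truth$subclones))
}
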