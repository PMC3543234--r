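#' Loiselle pairwise kinship coefficients
#'
#' Multilocus Loiselle et al. (1995) kinship between all pairs of
#' individuals, relative to the allele frequencies of the analyzed sample
#' itself.  Per locus and allele the contribution for a pair (i, j) is
#' \deqn{(p_{ia} - \bar p_a)(p_{ja} - \bar p_a) + \bar p_a (1 - \bar p_a)/(n_l - 1)}
#' where \eqn{p_{ia}} is individual i's allele dosage (0, 1/2, 1),
#' \eqn{\bar p_a} the sample frequency and \eqn{n_l} the number of gene
#' copies typed at the locus; the multilocus coefficient is the ratio of
#' numerators summed over co-typed loci to the summed per-locus weights
#' \eqn{\sum_a \bar p_a (1 - \bar p_a)}.
#'
#' @param x a [genotype_data] object; the reference allele frequencies are
#'   those of `x` itself, so subset to the analysis unit (whole estuary or
#'   deme) before calling.
#' @return An object of class `kinship_matrix`: `F` (individuals x
#'   individuals, `NA` on the diagonal and for pairs with no co-typed locus)
#'   plus the per-locus numerators/denominators needed for delete-one-locus
#'   jackknifing downstream.
#' @export
loiselle_kinship <- function(x) {
  n <- length(x$ind)
  L <- length(x$loci)
  num <- array(NA_real_, dim = c(n, n, L))
  den <- numeric(L)
  typed <- !is.na(x$a1)
  informative <- logical(L)
  for (l in seq_len(L)) {
    g1 <- x$a1[, l]; g2 <- x$a2[, l]
    keep <- typed[, l]
    alleles <- sort(unique(c(g1[keep], g2[keep])))
    if (length(alleles) < 2) next
    nl <- 2 * sum(keep)
    dos <- (outer(g1, alleles, "==") + outer(g2, alleles, "==")) / 2
    pbar <- colSums(dos[keep, , drop = FALSE]) / sum(keep)
    den[l] <- sum(pbar * (1 - pbar))
    cent <- sweep(dos, 2, pbar, "-")
    cent[!keep, ] <- NA
    num[, , l] <- tcrossprod(cent) + den[l] / (nl - 1)
    informative[l] <- TRUE
  }
  if (!any(informative)) stop("undefined: reference sample monomorphic at all loci")
  num <- num[, , informative, drop = FALSE]
  den <- den[informative]
  typed <- typed[, informative, drop = FALSE]
  Fm <- kinship_from_parts(num, den, typed)
  diag(Fm) <- NA
  dimnames(Fm) <- list(x$ind, x$ind)
  structure(list(F = Fm, num = num, den = den, typed = typed,
                 loci = x$loci[informative], estimator = "loiselle"),
            class = "kinship_matrix")
}

# combine per-locus numerators into the multilocus ratio, restricted to
# co-typed loci per pair
kinship_from_parts <- function(num, den, typed) {
  n <- dim(num)[1]; L <- dim(num)[3]
  num_s <- matrix(0, n, n)
  den_s <- matrix(0, n, n)
  for (l in seq_len(L)) {
    co <- tcrossprod(typed[, l] * 1)          # 1 when both typed
    nl <- num[, , l]
    nl[co == 0] <- 0
    num_s <- num_s + nl
    den_s <- den_s + den[l] * co
  }
  out <- num_s / den_s
  out[den_s == 0] <- NA
  out
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix (", x$estimator, "): ", nrow(x$F), " individuals, ",
      length(x$den), " informative loci\n", sep = "")
  ut <- upper.tri(x$F)
  cat(sprintf("  mean pairwise coefficient = %.5f\n", mean(x$F[ut], na.rm = TRUE)))
  invisible(x)
}

#' Organelle kinship analogue
#'
#' Distance-based haploid analogue of a kinship coefficient for a maternally
#' inherited marker: pairwise similarity \eqn{1 - d_{ij}/\bar d}, where
#' \eqn{d_{ij}} is the mutational distance between the two individuals'
#' haplotypes and \eqn{\bar d} the mean over all pairs in the sample, so the
#' all-pairs mean is exactly zero.
#'
#' @param x a [haplotype_data] object with at least two distinct haplotypes.
#' @return A `kinship_matrix` (single haploid locus; no locus jackknife is
#'   possible downstream).
#' @export
organelle_kinship_analogue <- function(x) {
  if (length(unique(x$haplotype)) < 2)
    stop("undefined: sample monomorphic (single haplotype)")
  hid <- as.character(x$haplotype)
  d <- x$dist[hid, hid]
  ut <- upper.tri(d)
  dbar <- mean(d[ut])
  if (dbar == 0) stop("undefined: all pairwise haplotype distances zero")
  Fm <- 1 - d / dbar
  diag(Fm) <- NA
  dimnames(Fm) <- list(x$ind, x$ind)
  n <- length(x$ind)
  structure(list(F = Fm, num = array(Fm, c(n, n, 1)), den = 1,
                 typed = matrix(TRUE, n, 1), loci = "organelle",
                 estimator = "distance-analogue"),
            class = "kinship_matrix")
}
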