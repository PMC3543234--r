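#' Per-population diversity summary
#'
#' Number of alleles, observed heterozygosity (fraction of heterozygous
#' typed individuals) and expected heterozygosity (gene diversity
#' \eqn{H_e = 1 - \sum p^2}, uncorrected) per population and locus.
#'
#' @param x a [genotype_data] object.
#' @return Data frame with columns `pop`, `locus`, `n` (typed individuals),
#'   `n_alleles`, `H_o`, `H_e`.  Cells with no typed individuals are absent.
#' @export
summary_diversity <- function(x) {
  res <- list()
  for (p in unique(x$pop)) {
    idx <- x$pop == p
    for (l in x$loci) {
      g1 <- x$a1[idx, l]; g2 <- x$a2[idx, l]
      keep <- !is.na(g1)
      if (!any(keep)) next
      g1 <- g1[keep]; g2 <- g2[keep]
      pfreq <- table(c(g1, g2)) / (2 * length(g1))
      res[[length(res) + 1L]] <- data.frame(
        pop = p, locus = l, n = length(g1),
        n_alleles = length(pfreq),
        H_o = mean(g1 != g2),
        H_e = 1 - sum(pfreq^2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# Weir-Cockerham (1984) variance components per locus.
# Returns a data.frame locus/a/b/c; loci with no information (monomorphic or
# <2 populations typed) get zero components.
wc_components <- function(a1, a2, pop) {
  pop <- as.character(pop)
  L <- ncol(a1)
  out <- data.frame(locus = colnames(a1), a = 0, b = 0, cc = 0,
                    stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    g1 <- a1[, l]; g2 <- a2[, l]
    keep <- !is.na(g1)
    if (sum(keep) < 2) next
    g1 <- g1[keep]; g2 <- g2[keep]
    pf <- factor(pop[keep])
    n_i <- as.numeric(table(pf))
    r <- length(n_i)
    if (r < 2) next
    alleles <- sort(unique(c(g1, g2)))
    if (length(alleles) < 2) next
    n_tot <- sum(n_i)
    nbar <- n_tot / r
    if (nbar <= 1) next
    n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
    f1 <- factor(g1, levels = alleles); f2 <- factor(g2, levels = alleles)
    cnt <- table(pf, f1) + table(pf, f2)          # pops x alleles gene copies
    het <- g1 != g2
    hcnt <- table(pf[het], f1[het]) + table(pf[het], f2[het])
    # align het counts to all pops (table drops nothing since pf keeps levels)
    p_ia <- sweep(cnt, 1, 2 * n_i, "/")
    h_ia <- sweep(hcnt, 1, n_i, "/")
    pbar <- colSums(cnt) / (2 * n_tot)
    hbar <- colSums(hcnt) / n_tot
    s2 <- colSums(n_i * sweep(p_ia, 2, pbar, "-")^2) / ((r - 1) * nbar)
    pq <- pbar * (1 - pbar)
    a_v <- (nbar / n_c) * (s2 - (pq - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_v <- (nbar / (nbar - 1)) * (pq - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_v <- hbar / 2
    out$a[l] <- sum(a_v); out$b[l] <- sum(b_v); out$cc[l] <- sum(c_v)
  }
  out
}

# multilocus theta/f from summed components
wc_ratios <- function(comp) {
  tot <- comp$a + comp$b + comp$cc
  list(theta = sum(comp$a) / sum(tot),
       f = 1 - sum(comp$cc) / sum(comp$b + comp$cc))
}

jackknife_se <- function(values) {
  L <- length(values)
  if (L < 2) return(NA_real_)
  sqrt((L - 1) / L * sum((values - mean(values))^2))
}

#' Weir-Cockerham F-statistics
#'
#' Multilocus and per-locus Weir & Cockerham (1984) \eqn{\theta}{theta}
#' (F_ST) and \eqn{f} (F_IS), estimated from among-population (a),
#' among-individual (b) and within-individual (c) variance components.
#' Multilocus estimates are ratios of summed components
#' (\eqn{\sum a / \sum (a+b+c)} and \eqn{\sum b / \sum(b+c)}), never means of
#' per-locus ratios.  Standard errors come from the delete-one-locus
#' jackknife, \eqn{SE = \sqrt{(L-1)/L \sum_l (\hat\theta_{(-l)} - \bar\theta)^2}}.
#' The equilibrium outcrossing rate `t` is derived from the multilocus F_IS
#' via [outcrossing_rate()].
#'
#' Missing data are handled per locus by complete cases (an individual is
#' excluded only at loci where it is untyped).
#'
#' @param x a [genotype_data] object with at least two populations and one
#'   polymorphic locus.
#' @param by grouping: `"pop"` or `"subpop"`.
#' @return An object of class `fstats_result` with elements `F_ST`, `F_IS`,
#'   `SE_FST`, `SE_FIS`, `t`, `per_locus` (data frame with components and
#'   per-locus ratios), `n_loci_used`.
#' @export
wc_f_statistics <- function(x, by = c("pop", "subpop")) {
  by <- match.arg(by)
  grp <- if (by == "pop") x$pop else x$subpop
  if (is.null(grp)) stop("no subpopulation labels in dataset")
  if (length(unique(grp)) < 2) stop("need at least 2 populations")
  comp <- wc_components(x$a1, x$a2, grp)
  used <- comp$a + comp$b + comp$cc > 0
  if (!any(used)) stop("undefined statistic: all loci monomorphic")
  comp_u <- comp[used, , drop = FALSE]
  est <- wc_ratios(comp_u)
  L <- nrow(comp_u)
  th_jk <- fis_jk <- numeric(L)
  for (l in seq_len(L)) {
    r <- wc_ratios(comp_u[-l, , drop = FALSE])
    th_jk[l] <- r$theta; fis_jk[l] <- r$f
  }
  per_locus <- data.frame(
    locus = comp$locus, a = comp$a, b = comp$b, c = comp$cc,
    theta = ifelse(used, comp$a / (comp$a + comp$b + comp$cc), NA_real_),
    f = ifelse(used, 1 - comp$cc / (comp$b + comp$cc), NA_real_),
    stringsAsFactors = FALSE)
  structure(list(F_ST = est$theta, F_IS = est$f,
                 SE_FST = jackknife_se(th_jk), SE_FIS = jackknife_se(fis_jk),
                 t = if (is.finite(est$f)) outcrossing_rate(est$f) else NA_real_,
                 per_locus = per_locus, n_loci_used = L, grouping = by),
            class = "fstats_result")
}

#' @export
print.fstats_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F-statistics (%d informative loci)\n", x$n_loci_used))
  cat(sprintf("  F_ST = %.4f (SE %.4f)\n", x$F_ST, x$SE_FST))
  cat(sprintf("  F_IS = %.4f (SE %.4f)\n", x$F_IS, x$SE_FIS))
  cat(sprintf("  outcrossing rate t = %.4f\n", x$t))
  invisible(x)
}

#' Pairwise F_ST with permutation tests
#'
#' Weir-Cockerham \eqn{\theta}{theta} for every population pair, with a
#' permutation test that shuffles individuals between the two populations.
#' The p-value convention includes the observed value:
#' \eqn{p = (1 + \#\{\theta^{perm} \ge \theta^{obs}\}) / (n_{perm} + 1)},
#' so \eqn{p \in (0, 1]}.
#'
#' @param x a [genotype_data] object.
#' @param n_perm number of permutations (>= 1).
#' @param seed optional RNG seed.
#' @return An object of class `pairwise_fst` with symmetric matrices `fst`
#'   and `p` (diagonal `NA`) and the permutation count.
#' @export
pairwise_fst <- function(x, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pops <- unique(x$pop)
  sizes <- table(x$pop)
  if (any(sizes < 2)) stop("population with <2 individuals: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  k <- length(pops)
  fst <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    idx <- which(x$pop %in% pops[c(i, j)])
    a1 <- x$a1[idx, , drop = FALSE]; a2 <- x$a2[idx, , drop = FALSE]
    labs <- x$pop[idx]
    obs <- wc_ratios(wc_components(a1, a2, labs))$theta
    ge <- 0L
    for (b in seq_len(n_perm)) {
      pl <- sample(labs)
      th <- wc_ratios(wc_components(a1, a2, pl))$theta
      if (!is.na(th) && th >= obs - 1e-12) ge <- ge + 1L
    }
    fst[i, j] <- fst[j, i] <- obs
    p[i, j] <- p[j, i] <- (1 + ge) / (n_perm + 1)
  }
  structure(list(fst = fst, p = p, n_perm = n_perm), class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("Pairwise Weir-Cockerham F_ST (lower) / permutation p (upper),",
      x$n_perm, "permutations\n")
  m <- x$fst
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, 4))
  invisible(x)
}

#' Outcrossing rate from the inbreeding coefficient
#'
#' At inbreeding equilibrium under mixed mating, the selfing rate \eqn{s}
#' satisfies \eqn{F_{IS} = s/(2-s)}; solving for the outcrossing rate
#' \eqn{t = 1 - s} gives \eqn{t = (1 - F_{IS})/(1 + F_{IS})}.
#'
#' @param f_is inbreeding coefficient, must exceed -1.
#' @param clamp clamp the result to `[0, 1]` for reporting (default), which
#'   only matters when `F_IS < 0`.
#' @return Outcrossing rate `t`; `t(0) = 1`.
#' @export
outcrossing_rate <- function(f_is, clamp = TRUE) {
  if (any(f_is <= -1)) stop("F_IS must be > -1")
  t <- (1 - f_is) / (1 + f_is)
  if (clamp) t <- pmin(pmax(t, 0), 1)
  t
}

#' Brookfield (method 1) null allele frequency
#'
#' Estimates the frequency of a non-amplifying (null) allele from the
#' heterozygote deficit: \eqn{q = (H_e - H_o)/(1 + H_e)}.  Negative values
#' (observed heterozygosity above expectation) are passed through unchanged.
#'
#' @param h_e expected heterozygosity in `[0, 1]` (vectorized).
#' @param h_o observed heterozygosity in `[0, 1]` (vectorized).
#' @return Estimated null allele frequency (may be slightly negative).
#' @export
brookfield_null_frequency <- function(h_e, h_o) {
  if (any(h_e < 0 | h_e > 1 | h_o < 0 | h_o > 1, na.rm = TRUE))
    stop("heterozygosities must lie in [0, 1]")
  (h_e - h_o) / (1 + h_e)
}

#' Haploid Weir-Cockerham theta
#'
#' F_ST for haploid data (e.g. organelle haplotypes treated as alleles of a
#' single locus), from the among/within-population analysis of variance of
#' allele-indicator variables with the unequal-sample-size coefficient
#' \eqn{n_c}.  For balanced identity (0/1) distances this equals the
#' distance-based AMOVA Phi_ST exactly.
#'
#' @param alleles vector of haploid allele (haplotype) labels.
#' @param pop population labels, same length.
#' @return Estimate of theta (can be slightly negative near zero
#'   differentiation).
#' @export
wc_theta_haploid <- function(alleles, pop) {
  keep <- !is.na(alleles)
  alleles <- alleles[keep]; pop <- factor(pop[keep])
  n_i <- as.numeric(table(pop))
  r <- length(n_i)
  if (r < 2) stop("need at least 2 populations")
  n <- sum(n_i)
  n_c <- (n - sum(n_i^2) / n) / (r - 1)
  f <- factor(alleles)
  cnt <- table(pop, f)
  p_ia <- sweep(cnt, 1, n_i, "/")
  pbar <- colSums(cnt) / n
  if (all(pbar %in% c(0, 1))) stop("undefined statistic: monomorphic sample")
  ssp <- sum(colSums(n_i * sweep(p_ia, 2, pbar, "-")^2))
  ssw <- sum(sweep(p_ia * (1 - p_ia), 1, n_i, "*"))
  msp <- ssp / (r - 1)
  msw <- ssw / (n - r)
  a <- (msp - msw) / n_c
  a / (a + msw)
}
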