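# One-level analysis of molecular variance (among vs within populations).
#
# Both entry points reduce to the same machinery: per stratum, sums of
# squared inter-unit distances give SS_within and SS_total
# (SS = (1/n) sum_{i<j} d^2_ij), the unequal-n coefficient
# n0 = (N - sum n_k^2 / N)/(P - 1) converts mean squares to variance
# components, and Phi_ST = sigma2_among / (sigma2_among + sigma2_within).
# Significance comes from permuting whole individuals among populations.

# squared-distance sums of squares from group counts over a finite state
# space: counts = groups x states, d2 = states x states squared distances.
ss_from_counts <- function(counts, d2) {
  apply(counts, 1, function(cn) {
    n <- sum(cn)
    if (n < 1) return(0)
    as.numeric(cn %*% d2 %*% cn) / (2 * n)
  })
}

amova_components_counts <- function(counts, d2) {
  n_k <- rowSums(counts)
  keep <- n_k > 0
  counts <- counts[keep, , drop = FALSE]; n_k <- n_k[keep]
  P <- nrow(counts); n <- sum(n_k)
  ss_w <- sum(ss_from_counts(counts, d2))
  ss_t <- ss_from_counts(matrix(colSums(counts), 1), d2)
  ss_t <- as.numeric(ss_t)
  ss_a <- ss_t - ss_w
  df_a <- P - 1; df_w <- n - P
  n0 <- (n - sum(n_k^2) / n) / (P - 1)
  msw <- ss_w / df_w
  msa <- ss_a / df_a
  c(sigma_a = (msa - msw) / n0, sigma_w = msw, ss_t = ss_t, df_t = n - 1)
}

# per-locus gene-copy components for diploid allele-identity distances
amova_nuclear_components <- function(a1, a2, pop) {
  L <- ncol(a1)
  sa <- sw <- sst <- dft <- 0
  for (l in seq_len(L)) {
    g1 <- a1[, l]; g2 <- a2[, l]
    keep <- !is.na(g1)
    if (sum(keep) < 2) next
    pf <- factor(pop[keep])
    if (nlevels(pf) < 2) next
    alleles <- sort(unique(c(g1[keep], g2[keep])))
    if (length(alleles) < 2) next
    f1 <- factor(g1[keep], levels = alleles)
    f2 <- factor(g2[keep], levels = alleles)
    counts <- table(pf, f1) + table(pf, f2)
    d2 <- 1 - diag(length(alleles))           # allele mismatch, F_ST-based
    cmp <- amova_components_counts(unclass(counts), d2)
    sa <- sa + cmp["sigma_a"]; sw <- sw + cmp["sigma_w"]
    sst <- sst + cmp["ss_t"]; dft <- dft + cmp["df_t"]
  }
  c(sigma_a = unname(sa), sigma_w = unname(sw), ss_t = unname(sst), df_t = unname(dft))
}

make_amova_result <- function(obs, phi_perm, n_perm) {
  sa <- obs[["sigma_a"]]; sw <- obs[["sigma_w"]]
  phi <- sa / (sa + sw)
  sa_f <- max(sa, 0)
  tot <- sa_f + sw
  p <- if (n_perm > 0)
    (1 + sum(phi_perm >= phi - 1e-12, na.rm = TRUE)) / (n_perm + 1) else NA_real_
  structure(list(sigma2_among = sa, sigma2_within = sw,
                 percent_among = 100 * sa_f / tot,
                 percent_within = 100 * sw / tot,
                 Phi_ST = phi, p_value = p, n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (among vs within populations)\n")
  cat(sprintf("  sigma2 among  = %.4f (%5.2f%%)\n", x$sigma2_among, x$percent_among))
  cat(sprintf("  sigma2 within = %.4f (%5.2f%%)\n", x$sigma2_within, x$percent_within))
  cat(sprintf("  Phi_ST = %.4f, p = %s (%d permutations)\n", x$Phi_ST,
              format.pval(x$p_value), x$n_perm))
  invisible(x)
}

#' AMOVA on diploid genotypes (allele-identity distances)
#'
#' F_ST-style one-level AMOVA at the gene-copy level: within each locus the
#' squared distance between two gene copies is 0 for identical allele labels
#' and 1 otherwise (allele identity, not repeat-size differences).  Variance
#' components are summed over loci; significance permutes whole individuals
#' (their diploid multilocus genotypes move together) among populations.
#'
#' @param x a [genotype_data] object.
#' @param by grouping column, `"pop"` or `"subpop"`.
#' @param n_perm number of permutations (default 10,000).
#' @param seed optional RNG seed.
#' @return An object of class `amova_result`: raw variance components
#'   (`sigma2_among` may be negative), percentages (computed with
#'   `sigma2_among` floored at zero), `Phi_ST` (raw ratio), permutation
#'   `p_value` in (0, 1].
#' @export
amova_nuclear <- function(x, by = c("pop", "subpop"), n_perm = 10000, seed = NULL) {
  by <- match.arg(by)
  grp <- if (by == "pop") x$pop else x$subpop
  if (is.null(grp)) stop("no subpopulation labels in dataset")
  sizes <- table(grp)
  if (length(sizes) < 2) stop("need at least 2 populations")
  if (any(sizes < 2)) stop("population with <2 individuals: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  obs <- amova_nuclear_components(x$a1, x$a2, grp)
  if (obs[["df_t"]] == 0) stop("undefined statistic: all loci monomorphic")
  phi_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    cmp <- amova_nuclear_components(x$a1, x$a2, sample(grp))
    phi_perm[b] <- cmp[["sigma_a"]] / (cmp[["sigma_a"]] + cmp[["sigma_w"]])
  }
  make_amova_result(obs, phi_perm, n_perm)
}

#' AMOVA on organelle haplotypes (mutational-step distances)
#'
#' Same machinery as [amova_nuclear()] with the squared inter-individual
#' distance equal to the squared number of differing sites between their
#' haplotypes.
#'
#' @param x a [haplotype_data] object.
#' @param n_perm number of permutations (default 10,000).
#' @param seed optional RNG seed.
#' @return An `amova_result`; raises an error when every individual carries
#'   the same haplotype (total diversity zero, Phi_ST undefined).
#' @export
amova_haplotype <- function(x, n_perm = 10000, seed = NULL) {
  sizes <- table(x$pop)
  if (length(sizes) < 2) stop("need at least 2 populations")
  if (any(sizes < 2)) stop("population with <2 individuals: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  if (length(unique(x$haplotype)) < 2)
    stop("undefined statistic: all individuals share one haplotype")
  if (!is.null(seed)) set.seed(seed)
  haps <- sort(unique(x$haplotype))
  d2 <- x$dist[as.character(haps), as.character(haps)]^2
  hf <- factor(x$haplotype, levels = haps)
  comp_for <- function(pop) {
    counts <- unclass(table(factor(pop), hf))
    amova_components_counts(counts, d2)
  }
  obs <- comp_for(x$pop)
  phi_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    cmp <- comp_for(sample(x$pop))
    phi_perm[b] <- cmp[["sigma_a"]] / (cmp[["sigma_a"]] + cmp[["sigma_w"]])
  }
  make_amova_result(obs, phi_perm, n_perm)
}
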