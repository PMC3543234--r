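#' Haplotype diversity per population
#'
#' Nei's unbiased gene (haplotype) diversity
#' \eqn{H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} per population.
#'
#' @param x a [haplotype_data] object.
#' @return Data frame with columns `pop`, `n` (individuals), `k` (haplotype
#'   count) and `H_d`.  `H_d = 0` exactly when a population is fixed for one
#'   haplotype; populations with fewer than 2 individuals raise an error.
#' @export
haplotype_diversity <- function(x) {
  res <- lapply(unique(x$pop), function(p) {
    h <- x$haplotype[x$pop == p]
    n <- length(h)
    if (n < 2) stop("population '", p, "' has fewer than 2 individuals")
    pf <- table(h) / n
    data.frame(pop = p, n = n, k = length(pf),
               H_d = n / (n - 1) * (1 - sum(pf^2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Nei's G_ST for organelle haplotypes
#'
#' Haplotype-frequency differentiation \eqn{G_{ST} = (H_T - H_S)/H_T} with
#' unbiased diversities: \eqn{H_S} is the sample-size-weighted mean of the
#' per-population unbiased diversities \eqn{\frac{n_k}{n_k-1}(1-\sum p^2)},
#' and \eqn{H_T} the pooled-frequency diversity with the same correction.
#' The SE comes from the delete-one-population jackknife (organelle data
#' form one combined locus, so a locus jackknife is impossible); the
#' reported confidence interval is estimate +/- 2 SE and may extend beyond
#' [0, 1].
#'
#' @param x a [haplotype_data] object with at least two populations and
#'   overall polymorphism.
#' @return List with `G_ST`, `SE`, `CI` (+/- 2 SE), `H_S`, `H_T`.
#' @export
nei_gst_haplotypes <- function(x) {
  pops <- unique(x$pop)
  if (length(pops) < 2) stop("need at least 2 populations")
  gst_of <- function(sel_pops) {
    idx <- x$pop %in% sel_pops
    h <- x$haplotype[idx]; pp <- x$pop[idx]
    n_k <- table(pp)
    N <- sum(n_k)
    hs <- sum(vapply(names(n_k), function(p) {
      ph <- table(h[pp == p]) / n_k[[p]]
      n_k[[p]] / N * n_k[[p]] / (n_k[[p]] - 1) * (1 - sum(ph^2))
    }, numeric(1)))
    pbar <- table(h) / N
    ht <- N / (N - 1) * (1 - sum(pbar^2))
    c(gst = if (ht > 0) (ht - hs) / ht else NA_real_, hs = hs, ht = ht)
  }
  obs <- gst_of(pops)
  if (is.na(obs[["gst"]]))
    stop("undefined statistic: no haplotype polymorphism (H_T = 0)")
  se <- NA_real_
  if (length(pops) >= 3) {          # deleting 1 of 2 pops leaves no contrast
    jk <- vapply(seq_along(pops),
                 function(k) gst_of(pops[-k])[["gst"]], numeric(1))
    se <- jackknife_se(jk[!is.na(jk)])
  }
  list(G_ST = obs[["gst"]], SE = se,
       CI = obs[["gst"]] + c(-2, 2) * se,
       H_S = obs[["hs"]], H_T = obs[["ht"]])
}

#' Expected maternal F_ST under equal pollen and seed migration
#'
#' Converts the biparentally inherited (nuclear) F_ST into the F_ST expected
#' for a maternally inherited marker if pollen and seed migrate at the same
#' rate:
#' \deqn{F_{ST}^{mat} = \frac{a_b F_{ST}^{bipar}}{a_m + (a_b - a_m) F_{ST}^{bipar}}}
#' with \eqn{a_m = 2} (maternal haploid transmission) and
#' \eqn{a_b = 4 + 2t}, where `t` is the outcrossing rate: selfing lowers the
#' effective number of independent nuclear gene lineages moved per dispersal
#' event.  The function is strictly increasing in both arguments with fixed
#' points at 0 and 1.
#'
#' @param f_st_bipar nuclear multilocus F_ST in [0, 1].
#' @param t outcrossing rate in [0, 1].
#' @return Expected maternal F_ST.
#' @export
expected_maternal_fst <- function(f_st_bipar, t) {
  if (any(f_st_bipar < 0 | f_st_bipar > 1)) stop("F_ST must lie in [0, 1]")
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  a_b <- 4 + 2 * t
  a_m <- 2
  a_b * f_st_bipar / (a_m + (a_b - a_m) * f_st_bipar)
}

#' Ennos pollen-to-seed migration ratio
#'
#' Ratio \eqn{r = m_p / m_s} of pollen to seed migration rates inferred from
#' the contrast between biparental (nuclear) and maternal (organelle)
#' structure:
#' \deqn{r = \frac{(1/F_{ST}^{bipar} - 1)(1 + F_{IS}) - 2 (1/G_{ST}^{mat} - 1)}{1/G_{ST}^{mat} - 1}}
#' Negative estimates are passed through unchanged (they indicate pollen
#' flow indistinguishable from zero relative to seed flow).
#'
#' @param f_st_bipar nuclear multilocus F_ST, strictly inside (0, 1).
#' @param f_is nuclear inbreeding coefficient.
#' @param g_st_mat organelle G_ST, strictly inside (0, 1).
#' @return The migration-rate ratio `r`.
#' @export
ennos_ratio <- function(f_st_bipar, f_is, g_st_mat) {
  if (any(f_st_bipar <= 0 | f_st_bipar >= 1))
    stop("F_ST must lie strictly inside (0, 1)")
  if (any(g_st_mat <= 0 | g_st_mat >= 1))
    stop("G_ST must lie strictly inside (0, 1)")
  A <- (1 / f_st_bipar - 1) * (1 + f_is)
  B <- 1 / g_st_mat - 1
  (A - 2 * B) / B
}

#' Hamilton-Miller overlap test of equal pollen and seed migration
#'
#' Compares the expected maternal F_ST (from nuclear markers, assuming
#' m_pollen = m_seed) with the observed organelle G_ST.  Each value gets a
#' +/- 2 SE confidence interval -- the expected value inherits the SE of the
#' nuclear F_ST untransformed -- and the null hypothesis of equal migration
#' rates is rejected exactly when the two closed intervals fail to overlap
#' (touching endpoints still overlap).
#'
#' @param expected expected maternal F_ST point estimate.
#' @param se_expected SE attached to the expected value (the nuclear F_ST
#'   jackknife SE).
#' @param observed observed organelle G_ST.
#' @param se_observed SE of the observed G_ST.
#' @return List with `H0_rejected`, `expected_ci`, `observed_ci`.
#' @export
hamilton_miller_test <- function(expected, se_expected, observed, se_observed) {
  if (isTRUE(se_expected < 0) || isTRUE(se_observed < 0))
    stop("SEs must be non-negative")
  eci <- expected + c(-2, 2) * se_expected
  oci <- observed + c(-2, 2) * se_observed
  if (anyNA(c(eci, oci)))               # an SE was unavailable (e.g. 2 pops)
    return(list(H0_rejected = NA, expected_ci = eci, observed_ci = oci))
  overlap <- max(eci[1], oci[1]) <= min(eci[2], oci[2])
  list(H0_rejected = !overlap, expected_ci = eci, observed_ci = oci)
}

#' Pollen-versus-seed gene-flow inference from summary statistics
#'
#' Runs the full derived-quantity chain from already-estimated nuclear and
#' organelle statistics: outcrossing rate `t` from F_IS, the expected
#' maternal F_ST with its +/- 2 SE interval, the observed G_ST interval, the
#' Hamilton-Miller verdict, and the Ennos ratio `r`.  This is the "replay"
#' entry point: it reproduces a published comparison table from its printed
#' inputs without genotype data.
#'
#' @param f_st nuclear multilocus F_ST.
#' @param se_f_st its SE.
#' @param f_is nuclear multilocus F_IS.
#' @param g_st observed organelle G_ST.
#' @param se_g_st its SE.
#' @return An object of class `gene_flow_result` with fields `F_ST_bipar`,
#'   `SE_FST_bipar`, `F_IS`, `t`, `G_ST_mat`, `SE_GST_mat`, `G_ST_mat_CI`,
#'   `F_ST_mat_expected`, `F_ST_mat_expected_CI`, `a_mat`, `a_bipar`, `r`,
#'   `H0_rejected`.
#' @export
replay_gene_flow <- function(f_st, se_f_st, f_is, g_st, se_g_st) {
  t <- outcrossing_rate(f_is)
  expected <- expected_maternal_fst(f_st, t)
  hm <- hamilton_miller_test(expected, se_f_st, g_st, se_g_st)
  r <- ennos_ratio(f_st, f_is, g_st)
  structure(list(F_ST_bipar = f_st, SE_FST_bipar = se_f_st, F_IS = f_is,
                 t = t, G_ST_mat = g_st, SE_GST_mat = se_g_st,
                 G_ST_mat_CI = hm$observed_ci,
                 F_ST_mat_expected = expected,
                 F_ST_mat_expected_CI = hm$expected_ci,
                 a_mat = 2, a_bipar = 4 + 2 * t, r = r,
                 H0_rejected = hm$H0_rejected),
            class = "gene_flow_result")
}

#' Pollen-versus-seed gene-flow inference from data
#'
#' Estimates the nuclear side ([wc_f_statistics()]) and the organelle side
#' ([nei_gst_haplotypes()]) and feeds both into [replay_gene_flow()].
#'
#' @param genotypes a [genotype_data] object.
#' @param haplotypes a [haplotype_data] object on the same populations.
#' @param by grouping for the nuclear F-statistics.
#' @return A `gene_flow_result` (see [replay_gene_flow()]) with the
#'   underlying `fstats_result` and G_ST list attached as attributes
#'   `"fstats"` and `"gst"`.
#' @export
gene_flow_analysis <- function(genotypes, haplotypes, by = "pop") {
  fs <- wc_f_statistics(genotypes, by = by)
  gst <- nei_gst_haplotypes(haplotypes)
  out <- replay_gene_flow(fs$F_ST, fs$SE_FST, fs$F_IS, gst$G_ST, gst$SE)
  attr(out, "fstats") <- fs
  attr(out, "gst") <- gst
  out
}

#' @export
print.gene_flow_result <- function(x, ...) {
  cat("Pollen vs seed gene flow\n")
  cat(sprintf("  nuclear  F_ST = %.4f (SE %.4f), F_IS = %.4f, t = %.4f\n",
              x$F_ST_bipar, x$SE_FST_bipar, x$F_IS, x$t))
  cat(sprintf("  expected maternal F_ST = %.4f  [%.4f, %.4f]\n",
              x$F_ST_mat_expected, x$F_ST_mat_expected_CI[1],
              x$F_ST_mat_expected_CI[2]))
  cat(sprintf("  observed organelle G_ST = %.4f  [%.4f, %.4f]\n",
              x$G_ST_mat, x$G_ST_mat_CI[1], x$G_ST_mat_CI[2]))
  cat(sprintf("  Ennos r (pollen/seed) = %.2f\n", x$r))
  cat("  H0 (equal pollen and seed migration):",
      if (is.na(x$H0_rejected)) "undetermined (no SE available)"
      else if (x$H0_rejected) "REJECTED" else "not rejected", "\n")
  invisible(x)
}
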