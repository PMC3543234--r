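#' Simulation configuration
#'
#' Parameters of the forward-time metapopulation simulator
#' ([simulate_metapopulation()]).  Defaults describe a desk-scale
#' hermaphroditic plant metapopulation: four demes of 100 diploids, 10
#' stepwise-mutating microsatellite loci, one maternally inherited
#' infinite-alleles organelle locus, full outcrossing, and symmetric 1%
#' pollen and seed migration.
#'
#' @param n_demes number of demes (island mode) (default 4).
#' @param N diploid individuals per deme (default 100).
#' @param generations non-overlapping generations to run (default 200).
#' @param s selfing probability per offspring in [0, 1] (default 0).
#' @param m_p pollen migration probability per outcross event (default 0.01).
#' @param m_s seed migration probability per offspring (default 0.01).
#' @param n_loci microsatellite loci (default 10).
#' @param mu_nuc stepwise (+/-1 repeat) mutation rate per allele copy per
#'   generation (default 1e-3).
#' @param mu_org organelle mutation rate to a brand-new haplotype
#'   (infinite alleles; default 3e-4).
#' @param spatial_mode `"island"` (discrete demes) or `"linear"` (continuous
#'   1-D habitat with Gaussian dispersal, produces isolation by distance).
#' @param sigma_s seed dispersal scale in meters, linear mode (default 250).
#' @param sigma_p pollen dispersal scale in meters, linear mode (default 500).
#' @param habitat_length 1-D habitat length in meters (default 10,000, the
#'   spatial scale over which SGS is usually summarized).
#' @param q_null per-locus null-allele injection frequency applied to the
#'   output (default 0 = none); see [inject_null_alleles()].
#' @param n_founder_alleles distinct starting repeat sizes per locus
#'   (default 8).
#' @param n_founder_haplotypes distinct starting organelle haplotypes
#'   (default 6).
#' @param rng_seed optional RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 4, N = 100, generations = 200, s = 0,
                       m_p = 0.01, m_s = 0.01, n_loci = 10, mu_nuc = 1e-3,
                       mu_org = 3e-4, spatial_mode = c("island", "linear"),
                       sigma_s = 250, sigma_p = 500, habitat_length = 10000,
                       q_null = 0, n_founder_alleles = 8,
                       n_founder_haplotypes = 6, rng_seed = NULL) {
  spatial_mode <- match.arg(spatial_mode)
  probs <- c(s = s, m_p = m_p, m_s = m_s, mu_nuc = mu_nuc, mu_org = mu_org,
             q_null = q_null)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (q_null >= 1) stop("q_null must lie in [0, 1)")
  if (N < 2) stop("N must be >= 2")
  if (n_demes < 1 || generations < 1 || n_loci < 1) stop("invalid sizes")
  structure(as.list(environment()), class = "sim_config")
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  lo + ifelse(x > span, 2 * span - x, x)
}

#' Forward-time simulation of a mixed-mating plant metapopulation
#'
#' Non-overlapping generations, constant deme sizes (soft selection).  Each
#' offspring in deme k draws (1) a mother from deme j, with j = k with
#' probability `1 - m_s` and uniform among the other demes otherwise (seed
#' migration moves the diploid zygote and the maternal organelle); (2) with
#' probability `s` both nuclear gametes from the mother (selfing), otherwise
#' a pollen parent from the mother's deme with probability `1 - m_p` and
#' uniform among the other demes otherwise (pollen moves one outcrossed
#' nuclear gamete only; the donor is never the mother herself).  Nuclear
#' alleles mutate stepwise +/-1 repeat with probability `mu_nuc`; the
#' organelle is copied from the mother and mutates to a brand-new haplotype
#' with probability `mu_org`.  In linear mode deme draws are replaced by
#' Gaussian dispersal kernels (`sigma_s`, `sigma_p`) along a 1-D habitat and
#' every individual carries a coordinate.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_output`: `genotypes` ([genotype_data]),
#'   `haplotypes` ([haplotype_data], unit mutational distances), and
#'   `config`.
#' @export
simulate_metapopulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  if (!is.null(cf$rng_seed)) set.seed(cf$rng_seed)
  linear <- cf$spatial_mode == "linear"
  D <- if (linear) 1L else cf$n_demes
  Ntot <- cf$n_demes * cf$N
  L <- cf$n_loci
  # founders: distinct repeat-size windows per locus, shared across demes
  base <- 100L
  a1 <- matrix(sample.int(cf$n_founder_alleles, Ntot * L, replace = TRUE) + base,
               Ntot, L)
  a2 <- matrix(sample.int(cf$n_founder_alleles, Ntot * L, replace = TRUE) + base,
               Ntot, L)
  hap <- sample.int(cf$n_founder_haplotypes, Ntot, replace = TRUE)
  next_hap <- cf$n_founder_haplotypes + 1L
  deme <- rep(seq_len(cf$n_demes), each = cf$N)
  pos <- if (linear) runif(Ntot, 0, cf$habitat_length) else NULL

  draw_other <- function(k, D) {            # uniform over demes != k
    o <- sample.int(D - 1L, length(k), replace = TRUE)
    o + (o >= k)
  }
  gamete <- function(parent_idx) {
    pick <- matrix(runif(length(parent_idx) * L) < 0.5, ncol = L)
    g <- ifelse(pick, a1[parent_idx, , drop = FALSE], a2[parent_idx, , drop = FALSE])
    mut <- matrix(runif(length(g)) < cf$mu_nuc, ncol = L)
    if (any(mut)) {
      step <- sample(c(-1L, 1L), sum(mut), replace = TRUE)
      g[mut] <- pmax(g[mut] + step, 2L)     # repeat sizes stay positive
    }
    g
  }

  for (gen in seq_len(cf$generations)) {
    if (!linear) {
      mig_s <- runif(Ntot) < cf$m_s & cf$n_demes > 1L
      m_deme <- deme
      if (any(mig_s)) m_deme[mig_s] <- draw_other(deme[mig_s], cf$n_demes)
      mother <- (m_deme - 1L) * cf$N + sample.int(cf$N, Ntot, replace = TRUE)
      selfed <- runif(Ntot) < cf$s
      mig_p <- runif(Ntot) < cf$m_p & cf$n_demes > 1L
      p_deme <- m_deme
      if (any(mig_p)) p_deme[mig_p] <- draw_other(m_deme[mig_p], cf$n_demes)
      father <- (p_deme - 1L) * cf$N + sample.int(cf$N, Ntot, replace = TRUE)
      clash <- !selfed & father == mother
      while (any(clash)) {                 # outcross donor is never the mother
        father[clash] <- (p_deme[clash] - 1L) * cf$N +
          sample.int(cf$N, sum(clash), replace = TRUE)
        clash <- !selfed & father == mother
      }
      new_pos <- NULL
    } else {
      mother <- sample.int(Ntot, Ntot, replace = TRUE)
      selfed <- runif(Ntot) < cf$s
      father <- integer(Ntot)
      out_idx <- which(!selfed)
      for (i in out_idx) {
        w <- exp(-((pos - pos[mother[i]])^2) / (2 * cf$sigma_p^2))
        w[mother[i]] <- 0
        father[i] <- sample.int(Ntot, 1L, prob = w)
      }
      new_pos <- reflect_into(pos[mother] + rnorm(Ntot, 0, cf$sigma_s),
                              0, cf$habitat_length)
    }
    father[selfed] <- mother[selfed]
    gm <- gamete(mother)
    gf <- gamete(father)
    new_hap <- hap[mother]
    hmut <- runif(Ntot) < cf$mu_org
    if (any(hmut)) {
      new_hap[hmut] <- next_hap + seq_len(sum(hmut)) - 1L
      next_hap <- next_hap + sum(hmut)
    }
    a1 <- gm; a2 <- gf; hap <- new_hap
    if (linear) pos <- new_pos
  }

  loci <- paste0("ssr", sprintf("%02d", seq_len(L)))
  colnames(a1) <- colnames(a2) <- loci
  ids <- paste0("ind", sprintf("%04d", seq_len(Ntot)))
  pops <- if (linear) rep("pop_1", Ntot) else paste0("deme", deme)
  coords <- if (linear) cbind(pos, 0) else NULL
  g <- genotype_data(ids, pops, a1, a2,
                     coords = coords,
                     coord_units = if (linear) "meters" else NA_character_,
                     loci = loci)
  if (cf$q_null > 0) g <- inject_null_alleles(g, cf$q_null)
  haps_seen <- sort(unique(hap))
  hap_rel <- match(hap, haps_seen)          # compact ids by sorted label
  h <- haplotype_data(ids, pops, hap_rel)
  structure(list(genotypes = g, haplotypes = h, config = cf),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output:", length(x$genotypes$ind), "individuals,",
      length(x$genotypes$loci), "loci,",
      length(unique(x$haplotypes$haplotype)), "organelle haplotypes\n")
  invisible(x)
}

#' Inject null alleles
#'
#' Masks allele lineages to emulate non-amplifying microsatellite alleles.
#' Per locus, a random set of allele labels with total sample frequency
#' close to `q_null` is masked: alleles are visited in random order and
#' accumulated while they fit under the target, with the boundary allele
#' admitted with the fractional probability that keeps the expected masked
#' frequency exactly `q_null`.  A heterozygote with one masked allele
#' appears homozygous for the visible allele; a genotype with both alleles
#' masked becomes missing.
#'
#' @param x a [genotype_data] object.
#' @param q_null masking probability in [0, 1).
#' @param seed optional RNG seed.
#' @return A modified [genotype_data]; the masked labels are attached as
#'   attribute `"masked_alleles"` (a list per locus).
#' @export
inject_null_alleles <- function(x, q_null, seed = NULL) {
  if (q_null < 0 || q_null > 1) stop("q_null must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (q_null == 0) return(x)
  a1 <- x$a1; a2 <- x$a2
  masked <- vector("list", length(x$loci))
  names(masked) <- x$loci
  for (l in seq_along(x$loci)) {
    al <- c(a1[, l], a2[, l])
    al <- al[!is.na(al)]
    frq <- table(al) / length(al)
    ord <- sample(length(frq))
    hit <- integer(0)
    left <- q_null
    for (k in ord) {
      f <- as.numeric(frq[k])
      if (left <= 0) break
      if (f <= left || runif(1) < left / f) {
        hit <- c(hit, as.integer(names(frq)[k]))
        left <- left - f
      }
    }
    masked[[l]] <- hit
    if (!length(hit)) next
    m1 <- a1[, l] %in% hit
    m2 <- a2[, l] %in% hit
    both <- m1 & m2
    a1[m1 & !both, l] <- a2[m1 & !both, l]   # visible allele shows twice
    a2[m2 & !both, l] <- a1[m2 & !both, l]
    a1[both, l] <- NA_integer_
    a2[both, l] <- NA_integer_
  }
  out <- genotype_data(x$ind, x$pop, a1, a2, subpop = x$subpop,
                       coords = x$coords, coord_units = x$coord_units,
                       loci = x$loci)
  attr(out, "masked_alleles") <- masked
  out
}
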