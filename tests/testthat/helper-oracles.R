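# Independent brute-force oracles and fixture builders.
# Every oracle follows the defining sums of squares / sums over alleles
# directly, with explicit loops, so it shares no code path with the package.

# random diploid dataset builder
rand_genotypes <- function(n_pops = 2, n_ind = 5, n_loci = 2, n_alleles = 3,
                           miss_rate = 0, coords = FALSE) {
  n <- n_pops * n_ind
  a1 <- matrix(sample.int(n_alleles, n * n_loci, TRUE), n, n_loci)
  a2 <- matrix(sample.int(n_alleles, n * n_loci, TRUE), n, n_loci)
  if (miss_rate > 0) {
    m <- matrix(runif(n * n_loci) < miss_rate, n, n_loci)
    a1[m] <- NA; a2[m] <- NA
  }
  genotype_data(paste0("i", seq_len(n)), rep(paste0("pop_", seq_len(n_pops)),
                                             each = n_ind),
                a1, a2,
                coords = if (coords) cbind(runif(n, 0, 5000), runif(n, 0, 5000)),
                coord_units = if (coords) "meters" else NA_character_)
}

# genotype_data from a compact list: pops = list(pop_name = matrix of
# genotype strings "a/b" with loci in columns)
gd_from_strings <- function(pops) {
  rows1 <- list(); rows2 <- list(); labs <- character(); ids <- character()
  for (p in names(pops)) {
    m <- pops[[p]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    for (i in seq_len(nrow(m))) {
      al <- t(vapply(m[i, ], function(s) {
        if (is.na(s)) return(c(NA_integer_, NA_integer_))
        as.integer(strsplit(s, "/")[[1]])
      }, integer(2)))
      rows1[[length(rows1) + 1]] <- al[, 1]
      rows2[[length(rows2) + 1]] <- al[, 2]
      labs <- c(labs, p)
      ids <- c(ids, paste0(p, "_", i))
    }
  }
  genotype_data(ids, labs, do.call(rbind, rows1), do.call(rbind, rows2))
}

# Weir-Cockerham via the indicator-variable nested ANOVA (mean squares),
# complete cases per locus
oracle_wc <- function(g) {
  A <- B <- C <- 0
  for (l in seq_along(g$loci)) {
    g1 <- g$a1[, l]; g2 <- g$a2[, l]
    keep <- !is.na(g1)
    if (sum(keep) < 2) next
    g1 <- g1[keep]; g2 <- g2[keep]; pop <- g$pop[keep]
    pops <- unique(pop)
    r <- length(pops)
    if (r < 2) next
    alleles <- sort(unique(c(g1, g2)))
    if (length(alleles) < 2) next
    n_i <- sapply(pops, function(p) sum(pop == p))
    n <- sum(n_i)
    n_c <- (n - sum(n_i^2) / n) / (r - 1)
    for (al in alleles) {
      x <- cbind(as.numeric(g1 == al), as.numeric(g2 == al))
      xbar_ind <- rowMeans(x)
      xbar_pop <- sapply(pops, function(p) mean(x[pop == p, ]))
      xbar <- mean(x)
      ssg <- sum((x - xbar_ind)^2)
      ssi <- 2 * sum((xbar_ind - xbar_pop[match(pop, pops)])^2)
      ssp <- 2 * sum(n_i * (xbar_pop - xbar)^2)
      msg <- ssg / n
      msi <- ssi / (n - r)
      msp <- ssp / (r - 1)
      C <- C + msg
      B <- B + (msi - msg) / 2
      A <- A + (msp - msi) / (2 * n_c)
    }
  }
  list(theta = A / (A + B + C), f = 1 - C / (B + C))
}

# distance-based AMOVA by explicit pair loops over units
oracle_amova_units <- function(d2, pop) {
  n <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d2[i, j]
  ss_t <- ss_t / n
  ss_w <- 0
  for (p in pops) {
    idx <- which(pop == p)
    s <- 0
    if (length(idx) > 1)
      for (ii in 1:(length(idx) - 1)) for (jj in (ii + 1):length(idx))
        s <- s + d2[idx[ii], idx[jj]]
    ss_w <- ss_w + s / length(idx)
  }
  n_k <- sapply(pops, function(p) sum(pop == p))
  msw <- ss_w / (n - P)
  msa <- (ss_t - ss_w) / (P - 1)
  n0 <- (n - sum(n_k^2) / n) / (P - 1)
  sigma_a <- (msa - msw) / n0
  list(sigma_a = sigma_a, sigma_w = msw, phi = sigma_a / (sigma_a + msw))
}

# nuclear AMOVA oracle: gene copies enumerated explicitly per locus
oracle_amova_nuclear <- function(g) {
  sa <- sw <- 0
  for (l in seq_along(g$loci)) {
    keep <- !is.na(g$a1[, l])
    if (sum(keep) < 2) next
    alleles <- c(g$a1[keep, l], g$a2[keep, l])
    pop <- rep(g$pop[keep], 2)
    if (length(unique(g$pop[keep])) < 2 || length(unique(alleles)) < 2) next
    d2 <- outer(alleles, alleles, "!=") * 1
    cmp <- oracle_amova_units(d2, pop)
    sa <- sa + cmp$sigma_a; sw <- sw + cmp$sigma_w
  }
  list(sigma_a = sa, sigma_w = sw, phi = sa / (sa + sw))
}

# Loiselle kinship for one pair by direct sums over alleles and loci
oracle_loiselle_pair <- function(g, i, j) {
  num <- den <- 0
  for (l in seq_along(g$loci)) {
    g1 <- g$a1[, l]; g2 <- g$a2[, l]
    keep <- !is.na(g1)
    if (!keep[i] || !keep[j]) next
    alleles <- sort(unique(c(g1[keep], g2[keep])))
    if (length(alleles) < 2) next
    nl <- 2 * sum(keep)
    for (al in alleles) {
      pbar <- (sum(g1[keep] == al) + sum(g2[keep] == al)) / nl
      pi_ <- ((g1[i] == al) + (g2[i] == al)) / 2
      pj_ <- ((g1[j] == al) + (g2[j] == al)) / 2
      num <- num + (pi_ - pbar) * (pj_ - pbar) + pbar * (1 - pbar) / (nl - 1)
      den <- den + pbar * (1 - pbar)
    }
  }
  num / den
}
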