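test_that("Loiselle kinship matches the sum-over-alleles oracle", {
  set.seed(13)
  for (rep in 1:20) {
    g <- rand_genotypes(n_pops = 1, n_ind = sample(4:6, 1),
                        n_loci = sample(1:3, 1), n_alleles = sample(2:3, 1),
                        miss_rate = sample(c(0, 0.2), 1))
    kin <- try(loiselle_kinship(g), silent = TRUE)
    if (inherits(kin, "try-error")) next  # all-monomorphic draw
    n <- length(g$ind)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      or <- oracle_loiselle_pair(g, i, j)
      if (is.finite(or)) expect_equal(kin$F[i, j], or, tolerance = 1e-12)
      else expect_true(is.na(kin$F[i, j]))
    }
  }
})

test_that("kinship centering: all-pairs mean is near zero on complete data", {
  set.seed(14)
  n <- 100
  a1 <- matrix(sample.int(6, n * 8, TRUE), n, 8)
  a2 <- matrix(sample.int(6, n * 8, TRUE), n, 8)
  g <- genotype_data(paste0("i", 1:n), rep("A", n), a1, a2)
  kin <- loiselle_kinship(g)
  expect_lt(abs(mean(kin$F[upper.tri(kin$F)])), 5e-3)
})

test_that("a clonal pair sits above the sample mean at every polymorphic locus", {
  set.seed(15)
  n <- 30
  a1 <- matrix(sample.int(5, n * 6, TRUE), n, 6)
  a2 <- matrix(sample.int(5, n * 6, TRUE), n, 6)
  a1[2, ] <- a1[1, ]; a2[2, ] <- a2[1, ]    # individual 2 clones individual 1
  g <- genotype_data(paste0("i", 1:n), rep("A", n), a1, a2)
  kin <- loiselle_kinship(g)
  m <- mean(kin$F[upper.tri(kin$F)])
  expect_gt(kin$F[1, 2], m)
  expect_gt(kin$F[1, 2], 0.2)               # clones approach F_ij ~ 1/2
})

test_that("organelle kinship analogue: centering and hand-computed toy", {
  h <- haplotype_data(c("a", "b", "c"), rep("p", 3), 1:3,
                      dist = matrix(c(0, 1, 2,
                                      1, 0, 3,
                                      2, 3, 0), 3, byrow = TRUE,
                                    dimnames = list(1:3, 1:3)))
  kin <- organelle_kinship_analogue(h)
  # dbar = 2 -> similarities 1 - d/2
  expect_equal(kin$F["a", "b"], 0.5)
  expect_equal(kin$F["a", "c"], 0)
  expect_equal(kin$F["b", "c"], -0.5)
  expect_equal(mean(kin$F[upper.tri(kin$F)]), 0)
  # identical haplotypes share the maximal similarity in the sample
  h2 <- haplotype_data(c("a", "b", "c"), rep("p", 3), c(1, 1, 2))
  k2 <- organelle_kinship_analogue(h2)
  expect_equal(unname(k2$F["a", "b"]), max(k2$F, na.rm = TRUE))
  hm <- haplotype_data(c("a", "b"), rep("p", 2), c(1, 1),
                       dist = matrix(0, 1, 1, dimnames = list(1, 1)))
  expect_error(organelle_kinship_analogue(hm), "monomorphic")
})

test_that("distance classes: equal counts, NN rule, degenerate geometry", {
  set.seed(16)
  x <- runif(80, 0, 5000)
  d <- as.matrix(dist(cbind(x, 0)))
  edges <- make_distance_classes(d, n_classes = 10, min_pairs = 100,
                                 max_distance = 1e9)
  pr <- d[upper.tri(d)]
  counts <- table(cut(pr, c(0, edges)))
  # equal-count bins before NN widening: later classes within +-1 of target
  expect_true(all(abs(counts[-1] - length(pr) / 10) <= length(pr) / 10))
  # >= 90% of nearest-neighbor pairs inside class 1
  dd <- d; diag(dd) <- Inf
  nn <- apply(dd, 1, min)
  expect_gte(mean(nn <= edges[1]), 0.9)

  # clustered transect geometry: NN rule must still hold
  x2 <- c(runif(40, 0, 100), runif(40, 4000, 4100))
  d2 <- as.matrix(dist(cbind(x2, 0)))
  e2 <- make_distance_classes(d2, n_classes = 6, min_pairs = 100,
                              max_distance = 1e9)
  dd2 <- d2; diag(dd2) <- Inf
  expect_gte(mean(apply(dd2, 1, min) <= e2[1]), 0.9)

  dsq <- matrix(1, 4, 4) - diag(4)
  expect_error(make_distance_classes(dsq * 100, min_pairs = 1),
               "equidistant")
})

test_that("regression recovers a perfectly linear kinship-distance signal", {
  set.seed(17)
  n <- 60
  x <- runif(n, 10, 9000)
  d <- as.matrix(dist(cbind(x, 0)))
  a <- 0.12; b <- -0.015
  Fm <- a + b * log(pmax(d, 1)); diag(Fm) <- NA
  res <- kinship_distance_regression(Fm, d, n_perm = 99, seed = 1,
                                     min_pairs = 50)
  expect_equal(res$b_ld, b, tolerance = 1e-9)
  expect_equal(res$R2_ld, 1, tolerance = 1e-9)
  expect_equal(res$Sp, -b / (1 - res$F_A), tolerance = 1e-12)
  expect_lt(res$p_perm, 0.05)
})

test_that("spatially random genotypes show no kinship-distance slope", {
  set.seed(18)
  n <- 80
  a1 <- matrix(sample.int(6, n * 6, TRUE), n, 6)
  a2 <- matrix(sample.int(6, n * 6, TRUE), n, 6)
  g <- genotype_data(paste0("i", 1:n), rep("A", n), a1, a2,
                     coords = cbind(runif(n, 0, 8000), runif(n, 0, 8000)),
                     coord_units = "meters")
  kin <- loiselle_kinship(g)
  d <- pairwise_geographic_distance(g)
  res <- kinship_distance_regression(kin, d, n_perm = 199, seed = 2,
                                     min_pairs = 100)
  expect_lt(abs(res$b_ld), 0.01)
  expect_gt(res$p_perm, 0.01)
})

test_that("locus jackknife SE of the slope is zero for duplicated loci", {
  set.seed(19)
  n <- 40
  a1 <- matrix(sample.int(4, n, TRUE), n, 1)
  a2 <- matrix(sample.int(4, n, TRUE), n, 1)
  g <- genotype_data(paste0("i", 1:n), rep("A", n),
                     cbind(a1, a1, a1), cbind(a2, a2, a2),
                     coords = cbind(runif(n, 0, 5000), 0),
                     coord_units = "meters")
  kin <- loiselle_kinship(g)
  d <- pairwise_geographic_distance(g)
  res <- kinship_distance_regression(kin, d, n_perm = 0, min_pairs = 50)
  expect_equal(res$SE_b, 0, tolerance = 1e-12)
})

test_that("co-located pairs are excluded and counted", {
  set.seed(20)
  n <- 30
  x <- c(rep(100, 2), runif(n - 2, 200, 3000))  # two trees on one GPS point
  Fm <- matrix(rnorm(n * n, 0, 0.01), n, n); Fm <- (Fm + t(Fm)) / 2
  d <- as.matrix(dist(cbind(x, 0)))
  res <- kinship_distance_regression(Fm, d, n_perm = 0, min_pairs = 20,
                                     nn_fraction = 0.5)
  expect_equal(res$n_zero_dropped, 1L)
})

test_that("Sp statistic formula and domain", {
  expect_equal(round(sp_statistic(-0.0217, 0.144), 3), 0.025)
  expect_equal(round(sp_statistic(-0.0308, 0.139), 3), 0.036)
  expect_equal(round(sp_statistic(-0.0095, 0.043), 3), 0.010)
  expect_equal(sp_statistic(0, 0.2), 0)
  expect_error(sp_statistic(-0.01, 1), "F_A")
})
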