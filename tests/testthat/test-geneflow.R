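test_that("haplotype diversity: fixed, two-of-two, and worked frequencies", {
  hfix <- haplotype_data(paste0("i", 1:10), rep("A", 10), rep(1, 10),
                         dist = matrix(0, 1, 1, dimnames = list(1, 1)))
  expect_equal(haplotype_diversity(hfix)$H_d, 0)

  h2 <- haplotype_data(c("a", "b"), c("A", "A"), c(1, 2))
  expect_equal(haplotype_diversity(h2)$H_d, 1)

  # n = 20, frequencies {0.5, 0.5}: (20/19) * 0.5 = 0.5263
  h3 <- haplotype_data(paste0("i", 1:20), rep("A", 20), rep(c(1, 2), 10))
  expect_equal(round(haplotype_diversity(h3)$H_d, 4), 0.5263)

  h1 <- haplotype_data("a", "A", 1, dist = matrix(0, 1, 1, dimnames = list(1, 1)))
  expect_error(haplotype_diversity(h1), "fewer than 2")
})

test_that("Nei G_ST: fixed difference, shared frequencies, hand computation", {
  hfix <- haplotype_data(paste0("i", 1:12), rep(c("A", "B"), each = 6),
                         rep(c(1, 2), each = 6))
  expect_equal(nei_gst_haplotypes(hfix)$G_ST, 1)

  set.seed(41)
  hap <- sample(1:3, 400, TRUE, prob = c(0.5, 0.3, 0.2))  # one common pool
  hsame <- haplotype_data(paste0("i", 1:400),
                          rep(c("A", "B", "C", "D"), each = 100), hap)
  expect_lt(abs(nei_gst_haplotypes(hsame)$G_ST), 0.05)

  # two populations, frequencies {0.75, 0.25} and {0.25, 0.75}, n = 8 each:
  # unbiased H_S = (8/7) * 0.375 = 0.4286..., pooled H_T = (16/15) * 0.5
  h <- haplotype_data(paste0("i", 1:16), rep(c("A", "B"), each = 8),
                      c(1, 1, 1, 1, 1, 1, 2, 2, 1, 1, 2, 2, 2, 2, 2, 2))
  gst <- nei_gst_haplotypes(h)
  hs <- 8 / 7 * (1 - 0.75^2 - 0.25^2)
  ht <- 16 / 15 * (1 - 2 * 0.5^2)
  expect_equal(gst$H_S, hs, tolerance = 1e-12)
  expect_equal(gst$H_T, ht, tolerance = 1e-12)
  expect_equal(gst$G_ST, (ht - hs) / ht, tolerance = 1e-12)

  hmono <- haplotype_data(paste0("i", 1:8), rep(c("A", "B"), each = 4), rep(1, 8),
                          dist = matrix(0, 1, 1, dimnames = list(1, 1)))
  expect_error(nei_gst_haplotypes(hmono), "H_T = 0")
})

test_that("G_ST is invariant to haplotype relabeling", {
  set.seed(42)
  hap <- sample.int(4, 30, TRUE)
  pop <- rep(c("A", "B", "C"), each = 10)
  h1 <- haplotype_data(paste0("i", 1:30), pop, hap)
  relab <- c(9L, 2L, 14L, 5L)
  h2 <- haplotype_data(paste0("i", 1:30), pop, relab[hap])
  expect_equal(nei_gst_haplotypes(h2)$G_ST, nei_gst_haplotypes(h1)$G_ST,
               tolerance = 1e-12)
})

test_that("expected maternal F_ST reproduces the published derived values", {
  t1 <- outcrossing_rate(0.1950)
  t2 <- outcrossing_rate(0.1327)
  expect_equal(round(expected_maternal_fst(0.3181, t1), 4), 0.5550)
  expect_equal(round(expected_maternal_fst(0.4001, t2), 4), 0.6485)
})

test_that("expected maternal F_ST: fixed points and monotonicity", {
  for (t in c(0, 0.3, 0.7, 1)) {
    expect_equal(expected_maternal_fst(0, t), 0)
    expect_equal(expected_maternal_fst(1, t), 1)
  }
  fb <- seq(0.05, 0.95, by = 0.05)
  for (t in c(0, 0.5, 1))
    expect_true(all(diff(expected_maternal_fst(fb, t)) > 0))
  for (f in c(0.2, 0.5, 0.8))
    expect_true(all(diff(expected_maternal_fst(f, seq(0, 1, 0.1))) > 0))
  expect_error(expected_maternal_fst(1.2, 0.5), "F_ST")
})

test_that("Ennos ratio reproduces the published values and its identities", {
  expect_equal(round(ennos_ratio(0.3181, 0.1950, 0.3469), 2), -0.64)
  expect_equal(round(ennos_ratio(0.4001, 0.1327, 0.8504), 2), 7.65)
  # r = 1 + F_IS exactly when G_ST sits at the equal-migration expectation
  for (fb in c(0.1, 0.3181, 0.6, 0.9)) for (fis in c(0, 0.1327, 0.5, 0.9)) {
    gm <- expected_maternal_fst(fb, outcrossing_rate(fis))
    expect_equal(ennos_ratio(fb, fis, gm), 1 + fis, tolerance = 1e-9)
  }
  # strictly increasing in G_ST for fixed nuclear inputs: stronger maternal
  # structure means less seed flow, hence a higher pollen/seed ratio
  r <- ennos_ratio(0.3, 0.2, seq(0.1, 0.9, 0.1))
  expect_true(all(diff(r) > 0))
  expect_error(ennos_ratio(0, 0.1, 0.5), "F_ST")
  expect_error(ennos_ratio(0.3, 0.1, 1), "G_ST")
})

test_that("Hamilton-Miller interval test: overlap conventions", {
  # published intervals: expected [0.4758, 0.6342] vs observed [0.1407, 0.5531]
  hm <- hamilton_miller_test(0.5550, 0.0396, 0.3469, 0.1031)
  expect_false(hm$H0_rejected)
  expect_equal(round(hm$expected_ci, 4), c(0.4758, 0.6342))

  expect_true(hamilton_miller_test(0.05, 0.025, 0.25, 0.025)$H0_rejected)
  # touching endpoints: closed intervals overlap -> not rejected
  expect_false(hamilton_miller_test(0.1, 0.05, 0.3, 0.05)$H0_rejected)
  expect_error(hamilton_miller_test(0.5, -0.1, 0.3, 0.1), "non-negative")
})

test_that("replay chain assembles the full published comparison", {
  res <- replay_gene_flow(0.3181, 0.0396, 0.1950, 0.3469, 0.1031)
  expect_equal(round(res$t, 4), 0.6736)
  expect_equal(round(res$F_ST_mat_expected, 4), 0.5550)
  expect_equal(round(res$F_ST_mat_expected_CI, 4), c(0.4758, 0.6342))
  expect_equal(round(res$r, 2), -0.64)
  expect_false(res$H0_rejected)
  expect_equal(res$a_mat, 2)
  expect_gte(res$a_bipar, 4); expect_lte(res$a_bipar, 6)
})

test_that("gene_flow_analysis wires estimates from data into the chain", {
  set.seed(43)
  cf <- sim_config(n_demes = 4, N = 40, generations = 80, m_p = 0.02,
                   m_s = 0.02, rng_seed = 9)
  sim <- simulate_metapopulation(cf)
  res <- gene_flow_analysis(sim$genotypes, sim$haplotypes)
  fs <- attr(res, "fstats"); gst <- attr(res, "gst")
  expect_equal(res$F_ST_bipar, fs$F_ST)
  expect_equal(res$G_ST_mat, gst$G_ST)
  expect_equal(res$F_ST_mat_expected,
               expected_maternal_fst(fs$F_ST, outcrossing_rate(fs$F_IS)))
  expect_equal(res$r, ennos_ratio(fs$F_ST, fs$F_IS, gst$G_ST))
  expect_type(res$H0_rejected, "logical")
})
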