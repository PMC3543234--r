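test_that("GENEPOP parsing handles 2/3-digit encodings and POP blocks", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("two-locus toy", "locA", "locB", "POP",
               "ind1 , 092092 110112",
               "ind2 , 000000 110110"), f)
  g <- read_genotype_table(f, dialect = "genepop")
  expect_equal(length(g$ind), 2L)
  expect_equal(g$loci, c("locA", "locB"))
  expect_equal(unname(g$a1[1, ]), c(92L, 110L))
  expect_equal(unname(g$a2[1, ]), c(92L, 112L))
  expect_true(is.na(g$a1[2, "locA"]) && is.na(g$a2[2, "locA"]))
  expect_equal(g$pop, c("pop_1", "pop_1"))

  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("2-digit", "locA", "POP", "a1 , 0912", "POP", "b1 , 1212"), f2)
  g2 <- read_genotype_table(f2, dialect = "genepop")
  expect_equal(unname(g2$a1[, 1]), c(9L, 12L))
  expect_equal(g2$pop, c("pop_1", "pop_2"))
})

test_that("CSV reader treats NA,NA as a missing genotype and validates format", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,pop,loc1_1,loc1_2,loc2_1,loc2_2",
               "i1,A,101,103,NA,NA",
               "i2,A,101,101,105,107"), f)
  g <- read_genotype_table(f, "csv")
  expect_true(is.na(g$a1[1, "loc2"]))
  expect_equal(g$a2[1, "loc1"], c(loc1 = 103L), ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,pop,loc1_1,loc1_2,loc2_1", "i1,A,1,2,3"), f2)
  expect_error(read_genotype_table(f2, "csv"), "odd|pair")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,pop,loc1_1,loc1_2", "i1,A,1,2", "i1,A,2,2"), f3)
  expect_error(read_genotype_table(f3, "csv"), "duplicate")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,pop,loc1_1,loc1_2", "i1,A,1,2", "i2,A,x7,2"), f4)
  expect_error(read_genotype_table(f4, "csv"), "line 3")
})

test_that("half-missing genotypes are rejected, not imputed", {
  expect_error(genotype_data("i1", "A", matrix(1L), matrix(NA_integer_)),
               "half-missing")
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "POP", "i1 , 0092"), f)
  expect_error(read_genotype_table(f, "genepop"), "half-missing")
})

test_that("write/read round trip is lossless for both dialects", {
  for (seed in 1:3) {
    set.seed(seed)
    g <- rand_genotypes(n_pops = 3, n_ind = 6, n_loci = 4, n_alleles = 5,
                        miss_rate = 0.1, coords = TRUE)
    f <- withr::local_tempfile(fileext = ".csv")
    write_genotype_table(g, f, "csv")
    g2 <- read_genotype_table(f, "csv")
    expect_equal(g2, g)

    fg <- withr::local_tempfile(fileext = ".gen")
    write_genotype_table(g, fg, "genepop")
    g3 <- read_genotype_table(fg, "genepop")
    expect_equal(g3$a1, g$a1)
    expect_equal(g3$a2, g$a2)
    expect_equal(g3$pop, g$pop)   # generator uses GENEPOP-style pop_k labels
  }
})

test_that("allele frequencies sum to one per population and locus", {
  set.seed(4)
  g <- rand_genotypes(n_pops = 3, n_ind = 8, n_loci = 3, miss_rate = 0.2)
  af <- allele_frequencies(g)
  sums <- tapply(af$freq, interaction(af$pop, af$locus, drop = TRUE), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # monomorphic locus: single frequency 1
  gm <- gd_from_strings(list(A = matrix(rep("7/7", 3), ncol = 1)))
  afm <- allele_frequencies(gm)
  expect_equal(afm$freq, 1)
  expect_equal(afm$n_copies, 6)
})

test_that("FASTA collapsing drops ambiguous columns globally and is order-invariant", {
  m <- rbind(s1 = strsplit("ACGT", "")[[1]], s2 = strsplit("ACGT", "")[[1]])
  pm <- data.frame(id = c("s1", "s2", "s3", "s4"), pop = "A")
  h <- collapse_fasta_to_haplotypes(m, pm)
  expect_equal(length(unique(h$haplotype)), 1L)
  expect_equal(unname(h$dist), matrix(0L, 1, 1))

  m2 <- rbind(s1 = strsplit("ACGT", "")[[1]], s2 = strsplit("ACCT", "")[[1]])
  h2 <- collapse_fasta_to_haplotypes(m2, pm)
  expect_equal(length(unique(h2$haplotype)), 2L)
  expect_equal(h2$dist[1, 2], 1L, ignore_attr = TRUE)

  # gap column dropped -> comparison on 3 columns, distance 0, one haplotype
  m3 <- rbind(s1 = strsplit("AC-T", "")[[1]], s2 = strsplit("ACTT", "")[[1]])
  h3 <- collapse_fasta_to_haplotypes(m3, pm)
  expect_equal(length(unique(h3$haplotype)), 1L)

  # order invariance: ids relabeled canonically by first occurrence
  m4 <- rbind(s1 = strsplit("AAAA", "")[[1]], s2 = strsplit("AATA", "")[[1]],
              s3 = strsplit("AAAA", "")[[1]])
  h4 <- collapse_fasta_to_haplotypes(m4, pm)
  h4r <- collapse_fasta_to_haplotypes(m4[c(2, 3, 1), ], pm)
  expect_equal(h4$haplotype, c(1L, 2L, 1L))
  expect_equal(h4r$haplotype, c(1L, 2L, 2L))
  expect_equal(sort(table(h4$haplotype)), sort(table(h4r$haplotype)),
               ignore_attr = TRUE)
})

test_that("FASTA collapsing via file IO and error paths", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "ACCT"), f)
  h <- collapse_fasta_to_haplotypes(f, data.frame(id = c("s1", "s2"), pop = "A"))
  expect_equal(length(unique(h$haplotype)), 2L)

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTA", ">s2", "ACCT"), f2)
  expect_error(collapse_fasta_to_haplotypes(f2, data.frame(id = c("s1", "s2"), pop = "A")),
               "unequal|aligned")

  m <- rbind(s1 = c("-", "N"), s2 = c("A", "C"))
  expect_error(collapse_fasta_to_haplotypes(m, data.frame(id = c("s1", "s2"), pop = "A")),
               "empty alignment")
})

test_that("geographic distances: haversine in meters, Euclidean passthrough", {
  expect_equal(pairwise_geographic_distance(rbind(c(10, 20), c(10, 20)))[1, 2], 0)
  d <- pairwise_geographic_distance(rbind(c(0, 0), c(0, 1)), units = "degrees")
  expect_equal(d[1, 2], 111195, tolerance = 1 / 111195)
  dp <- pairwise_geographic_distance(rbind(c(0, 0), c(3, 4)), units = "meters")
  expect_equal(dp[1, 2], 5)
  expect_error(pairwise_geographic_distance(rbind(c(NA, 0), c(0, 1))), "missing")
})

test_that("haplotype table round trip and distance-matrix validation", {
  h <- haplotype_data(paste0("i", 1:4), c("A", "A", "B", "B"), c(1, 2, 2, 3),
                      dist = matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
                                    dimnames = list(1:3, 1:3)))
  f <- withr::local_tempfile(fileext = ".csv")
  fd <- withr::local_tempfile(fileext = ".csv")
  write_haplotype_table(h, f, distances = fd)
  h2 <- read_haplotype_table(f, distances = fd)
  expect_equal(h2$haplotype, h$haplotype)
  expect_equal(unname(h2$dist), unname(h$dist))
  expect_error(haplotype_data("i1", "A", 5L,
                              dist = matrix(0, 1, 1, dimnames = list(1, 1))),
               "present in the distance matrix")
})
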