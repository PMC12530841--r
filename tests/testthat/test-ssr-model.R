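test_that("genotype CSV dialects parse and round-trip", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("accession_id,locus,allele1,allele2",
               "CY001,SSR13,182,",
               "CY001,SSR14,100,104",
               "CY002,SSR13,178,182",
               "CY002,SSR14,104,100"), path)
  gm <- read_genotypes(path)
  # single peak recorded as homozygous
  expect_equal(unname(c(gm$a1["CY001", "SSR13"], gm$a2["CY001", "SSR13"])),
               c(182L, 182L))
  # unordered pairs stored sorted
  expect_equal(unname(gm$a1[, "SSR14"]), c(100L, 100L))
  expect_equal(unname(gm$a2[, "SSR14"]), c(104L, 104L))

  # duplicate cell rejected
  writeLines(c("accession_id,locus,allele1,allele2",
               "CY001,SSR13,182,", "CY001,SSR13,178,"), path)
  expect_error(read_genotypes(path), "duplicate")

  # non-integer allele rejected
  writeLines(c("accession_id,locus,allele1,allele2",
               "CY001,SSR13,182.5,"), path)
  expect_error(read_genotypes(path), "non-integer")

  # synthetic panel round-trips bit-identically through both dialects
  sim <- simulate_populations(seed = 5)
  for (fmt in c("long", "wide")) {
    p2 <- tempfile(fileext = ".csv")
    write_genotypes(sim$gm, p2, format = fmt)
    back <- read_genotypes(p2)
    expect_identical(back$a1, sim$gm$a1)
    expect_identical(back$a2, sim$gm$a2)
  }
})

test_that("allele frequencies count copies over typed individuals", {
  gm <- make_gm(cbind(c(100L, 100L)), cbind(c(100L, 104L)))
  af <- allele_frequencies(gm, "L1")
  expect_equal(af$n_typed, 2L)
  expect_equal(unname(af$freqs), c(0.75, 0.25))

  gm2 <- make_gm(cbind(rep(100L, 4)), cbind(rep(100L, 4)))
  expect_equal(unname(allele_frequencies(gm2, "L1")$freqs), 1)

  # law of large numbers at N = 5000
  set.seed(6)
  p <- c(0.5, 0.3, 0.15, 0.05)
  sizes <- c(100L, 104L, 108L, 112L)
  draw <- function() sizes[sample.int(4, 5000, TRUE, p)]
  gm3 <- make_gm(cbind(draw()), cbind(draw()))
  af3 <- allele_frequencies(gm3, "L1")
  expect_lt(max(abs(af3$freqs[as.character(sizes)] - p)), 0.02)
})

test_that("locus summaries match closed forms and invariants", {
  # two alleles at p = q = 0.5
  gm <- make_gm(cbind(rep(c(100L, 104L), each = 10)),
                cbind(rep(c(100L, 104L), each = 10)))
  s <- locus_summary(gm, "L1")
  expect_equal(s$ne, 2)
  expect_equal(s$nei, 0.5)
  expect_equal(s$shannon_i, log(2))
  expect_equal(s$pic, 0.375)
  expect_equal(s$ho, 0)

  # every individual heterozygous
  gm2 <- make_gm(cbind(rep(100L, 6)), cbind(rep(104L, 6)))
  expect_equal(locus_summary(gm2, "L1")$ho, 1)

  # monomorphic locus
  gm3 <- make_gm(cbind(rep(100L, 6)), cbind(rep(100L, 6)))
  s3 <- locus_summary(gm3, "L1")
  expect_equal(c(s3$na, s3$ne, s3$nei, s3$pic, s3$shannon_i),
               c(1, 1, 0, 0, 0))

  # invariant chain on random panels: Ne <= Na, PIC < Nei < He, I >= ln Ne
  sim <- simulate_populations(group_sizes = c(40L, 40L), seed = 9)
  st <- summarize_loci(sim$gm)
  expect_true(all(st$ne <= st$na + 1e-12))
  expect_true(all(st$pic < st$nei))
  expect_true(all(st$nei < st$he))
  expect_true(all(st$shannon_i >= log(st$ne) - 1e-12))

  # allele relabeling and reordering leave statistics unchanged
  gm4 <- sim$gm
  perm <- sample(length(gm4$accessions))
  gm5 <- genotype_matrix(gm4$a1[perm, ] + 1000L, gm4$a2[perm, ] + 1000L)
  st5 <- summarize_loci(gm5)
  expect_equal(st5[, -1], st[, -1], tolerance = 1e-12)

  # removing and re-adding an individual restores statistics
  ids <- gm4$accessions
  st6 <- summarize_loci(subset_genotypes(gm4, ids))
  expect_identical(st6, st)
})

test_that("summary rows mirror the Mean/Total convention", {
  df <- data.frame(locus = c("A", "B"), na = c(4, 8), ne = c(2, 3),
                   pic = c(0.4, 0.6))
  su <- locus_stats_summary(df)
  expect_equal(unname(su$mean["na"]), 6)
  expect_equal(unname(su$total["ne"]), 5)
  expect_equal(su$n_pic_above_0.5, 1L)

  one <- df[1, ]
  su1 <- locus_stats_summary(one)
  expect_equal(unname(su1$mean["na"]), one$na)
})

test_that("Hardy-Weinberg chi-square follows its expectations", {
  # exact HW proportions: chi2 = 0, p = 1
  gm <- make_gm(cbind(c(rep(100L, 25), rep(100L, 50), rep(104L, 25))),
                cbind(c(rep(100L, 25), rep(104L, 50), rep(104L, 25))))
  h <- hwe_test(gm, "L1")
  expect_equal(h$chi2, 0, tolerance = 1e-12)
  expect_equal(h$p_value, 1)
  expect_equal(h$df, 1L)

  # monomorphic: not testable
  gmm <- make_gm(cbind(rep(100L, 10)), cbind(rep(100L, 10)))
  hm <- hwe_test(gmm, "L1")
  expect_equal(hm$df, 0L)
  expect_true(is.na(hm$p_value))

  # df = a(a-1)/2 for multiallelic loci
  set.seed(14)
  draw <- function() sample(c(100L, 104L, 108L, 112L), 80, TRUE)
  gm4 <- make_gm(cbind(draw()), cbind(draw()))
  expect_equal(hwe_test(gm4, "L1")$df, 6L)

  # Monte-Carlo p agrees broadly with the asymptotic p in a clean case
  set.seed(15)
  hmc <- hwe_test(gm4, "L1", monte_carlo = TRUE, n_perm = 499)
  expect_true(hmc$p_mc > 0 && hmc$p_mc <= 1)
})

test_that("STRUCTURE export writes two rows per individual", {
  sim <- simulate_populations(group_sizes = c(5L, 5L), n_loci = 3L,
                              seed = 2)
  path <- tempfile()
  write_genotypes(sim$gm, path, format = "structure")
  lines <- readLines(path)
  expect_length(lines, 1 + 2 * 10)
  expect_match(lines[1], "^accession_id\t")
})
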