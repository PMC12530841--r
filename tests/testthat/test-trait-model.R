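test_that("descriptive statistics use the population-SD convention", {
  tt <- one_trait_table(c(1L, 2L, 3L), class_codes = 1:3)
  s <- descriptive_stats(tt, "T1")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(2 / 3), tolerance = 1e-12)  # 0.8165
  expect_equal(s$cv_percent, 100 * sqrt(2 / 3) / 2, tolerance = 1e-12)
  expect_equal(s$range, s$max - s$min)

  # binary trait closed form: SD^2 = ab/(a+b)^2
  a <- 17L; b <- 96L
  tb <- one_trait_table(c(rep(0L, a), rep(1L, b)), class_codes = c(0L, 1L))
  sb <- descriptive_stats(tb, "T1")
  expect_equal(sb$sd^2, a * b / (a + b)^2, tolerance = 1e-12)

  # constant trait
  tc <- one_trait_table(rep(5L, 20), class_codes = c(3L, 5L, 7L))
  sc <- descriptive_stats(tc, "T1")
  expect_equal(sc$sd, 0)
  expect_equal(sc$cv_percent, 0)

  # order invariance
  set.seed(4)
  v <- sample(c(1L, 2L, 3L), 30, replace = TRUE)
  s1 <- descriptive_stats(one_trait_table(v, 1:3), "T1")
  s2 <- descriptive_stats(one_trait_table(sample(v), 1:3), "T1")
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sd, s2$sd)
  expect_equal(s1$shannon_h, s2$shannon_h)
})

test_that("Shannon-Weaver index follows its closed forms", {
  expect_equal(shannon_weaver(rep(1L, 50)), 0)
  for (k in c(2, 3, 5)) {
    v <- rep(seq_len(k), each = 10)
    expect_equal(shannon_weaver(v), log(k), tolerance = 1e-12)
  }
  # invariance under code relabeling
  v <- c(rep(1L, 30), rep(2L, 10), rep(3L, 5))
  expect_equal(shannon_weaver(v), shannon_weaver(10L * v + 3L))
  # frequencies sum to one and H' <= ln(#classes)
  tt <- one_trait_table(v, class_codes = 1:3)
  s <- descriptive_stats(tt, "T1")
  expect_equal(sum(s$class_frequencies), 1, tolerance = 1e-9)
  expect_lte(s$shannon_h, log(length(s$class_frequencies)) + 1e-12)
})

test_that("trait table round-trips through CSV and validates codes", {
  d1 <- trait_descriptor("T1", kind = "qualitative", class_codes = c(5L, 7L))
  d2 <- trait_descriptor("T2", kind = "qualitative", class_codes = c(5L, 7L))
  codes <- matrix(c(5L, 7L, 5L, 7L, 5L, NA), 3, 2,
                  dimnames = list(c("A1", "A2", "A3"), c("T1", "T2")))
  tt <- trait_table(codes, list(d1, d2))
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(accession_id = rownames(codes), codes), path,
            row.names = FALSE)
  back <- read_trait_table(path, list(d1, d2))
  expect_equal(back$codes, tt$codes)
  expect_true(is.na(back$codes["A3", "T2"]))  # missing preserved

  # code outside the descriptor set names trait and accession
  d3 <- trait_descriptor("T1", class_codes = c(3L, 5L, 7L))
  bad <- matrix(c(3L, 4L), 2, 1, dimnames = list(c("A1", "A2"), "T1"))
  expect_error(trait_table(bad, list(d3)), "T1.*A2.*4")
})

test_that("generated tables contain only descriptor-legal codes", {
  sim <- simulate_traits(n_accessions = 40L, seed = 11)
  # constructor validates every cell; rebuilding must not error
  expect_silent(trait_table(sim$table$codes, sim$table$traits))
  expect_equal(dim(sim$table$codes), c(40L, 50L))
})

test_that("LSD grading schemes follow the ANOVA arithmetic", {
  # degenerate: all values identical
  reps <- data.frame(accession_id = rep(c("a", "b"), each = 3),
                     value = 10)
  sc <- build_lsd_grading(reps, n_grades = 3L)
  expect_equal(sc$lsd_value, 0)
  expect_length(sc$codes, 1L)
  expect_equal(apply_grading(c(9, 10, 11), sc), rep(sc$codes, 3))

  # MSE = 0 with distinct accession means
  reps2 <- data.frame(accession_id = rep(c("a", "b"), each = 2),
                      value = c(1, 1, 3, 3))
  sc2 <- build_lsd_grading(reps2, n_grades = 3L)
  expect_equal(sc2$lsd_value, 0)
  expect_equal(sc2$center, 2)

  # LSD against an aov-based oracle
  set.seed(7)
  df <- data.frame(accession_id = rep(letters[1:5], each = 5),
                   value = rnorm(25, rep(c(10, 12, 9, 11, 13), each = 5), 1.5))
  sc3 <- build_lsd_grading(df, alpha = 0.05, n_grades = 5L)
  fit <- aov(value ~ factor(accession_id), data = df)
  mse <- sum(residuals(fit)^2) / fit$df.residual
  lsd_oracle <- qt(0.975, fit$df.residual) * sqrt(2 * mse / 5)
  expect_equal(sc3$lsd_value, lsd_oracle, tolerance = 1e-9)
  expect_gt(sc3$class_width, 2 * sc3$lsd_value)
  # center is the midpoint of the middle class
  expect_equal(mean(sc3$boundaries[2:3]), sc3$center, tolerance = 1e-9)

  # insufficient replication
  expect_error(build_lsd_grading(
    data.frame(accession_id = c("a", "a", "b"), value = 1:3)),
    "insufficient replication")
})

test_that("grading maps values to half-open intervals", {
  sc <- structure(list(trait_id = "T", boundaries = c(4, 6),
                       codes = c(3L, 5L, 7L), center = 5, class_width = 2,
                       lsd_alpha = 0.05, lsd_value = 0.5),
                  class = "grading_scheme")
  expect_equal(apply_grading(5.0, sc), 5L)
  expect_equal(apply_grading(6.0, sc), 7L)    # boundary goes up
  expect_equal(apply_grading(4.0, sc), 5L)
  expect_equal(apply_grading(-100, sc), 3L)
  expect_equal(apply_grading(100, sc), 7L)
  expect_true(is.na(apply_grading(NA_real_, sc)))

  # histogram of graded uniforms matches interval masses
  set.seed(21)
  u <- runif(20000, 0, 10)
  g <- apply_grading(u, sc)
  mass <- c(0.4, 0.2, 0.4)                    # [0,4), [4,6), [6,10)
  expect_equal(as.numeric(table(g)) / 20000, mass, tolerance = 0.02)

  # totality: grading built from replicates maps every mean to a code
  set.seed(3)
  df <- data.frame(accession_id = rep(sprintf("a%d", 1:8), each = 4),
                   value = rnorm(32, rep(1:8, each = 4), 0.4))
  sc2 <- build_lsd_grading(df, n_grades = 5L)
  means <- tapply(df$value, df$accession_id, mean)
  codes <- apply_grading(as.numeric(means), sc2)
  expect_true(all(codes %in% sc2$codes))
})

test_that("trait correlations carry t-test p-values and exclusions", {
  set.seed(5)
  n <- 113
  x <- sample(1:5, n, replace = TRUE)
  codes <- cbind(T1 = x, T2 = 2L * x,            # perfectly correlated
                 T3 = sample(1:5, n, replace = TRUE),
                 T4 = rep(3L, n))                # invariant
  rownames(codes) <- sprintf("A%03d", 1:n)
  descs <- lapply(colnames(codes), function(id)
    trait_descriptor(id, class_codes = sort(unique(codes[, id]))))
  tt <- trait_table(codes, descs)
  expect_warning(cm <- trait_correlation_matrix(tt), "zero-variance")
  expect_equal(cm$excluded, "T4")
  expect_equal(diag(cm$r)[1:3], c(T1 = 1, T2 = 1, T3 = 1))
  expect_equal(cm$r["T1", "T2"], 1, tolerance = 1e-12)
  expect_lt(cm$p["T1", "T2"], 1e-12)
  expect_true(all(is.na(cm$r["T4", ])))
  expect_equal(cm$r, t(cm$r))

  # type-I error of the significance flag on independent traits:
  # 40 independent columns give 780 pairs; about 1% flagged at 0.01
  set.seed(99)
  M <- matrix(sample(1:7, 113 * 40, replace = TRUE), 113, 40,
              dimnames = list(sprintf("A%03d", 1:113),
                              sprintf("T%d", 1:40)))
  dd <- lapply(colnames(M), function(id)
    trait_descriptor(id, class_codes = 1:7))
  cm2 <- trait_correlation_matrix(trait_table(M, dd), alpha = 0.01)
  flags <- cm2$significant
  diag(flags) <- FALSE
  rate <- sum(flags) / (40 * 39)
  expect_lt(rate, 0.03)
})
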