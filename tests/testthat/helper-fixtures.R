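# shared builders and brute-force oracles

make_codes <- function(values, trait_id = "T1",
                       ids = sprintf("A%03d", seq_along(values))) {
  matrix(as.integer(values), ncol = 1, dimnames = list(ids, trait_id))
}

# trait table with a single trait from a code vector
one_trait_table <- function(values, class_codes, trait_id = "T1",
                            kind = "qualitative") {
  d <- trait_descriptor(trait_id, kind = kind, class_codes = class_codes)
  trait_table(make_codes(values, trait_id), list(d))
}

# genotype matrix from two allele matrices with auto names
make_gm <- function(a1, a2) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  rownames(a1) <- rownames(a2) <- sprintf("I%02d", seq_len(nrow(a1)))
  colnames(a1) <- colnames(a2) <- sprintf("L%d", seq_len(ncol(a1)))
  genotype_matrix(a1, a2)
}

# brute-force diversity statistics by explicit enumeration of the
# frequency sums (independent of the closed forms in the package)
diversity_oracle <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  sp2 <- 0
  for (x in p) sp2 <- sp2 + x * x
  pic_cross <- 0
  k <- length(p)
  if (k >= 2) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        pic_cross <- pic_cross + 2 * p[i]^2 * p[j]^2
      }
    }
  }
  list(ne = unname(1 / sp2), nei = unname(1 - sp2),
       shannon_i = unname(-sum(p * log(p))),
       pic = unname(1 - sp2 - pic_cross))
}

# AMOVA sums of squares from explicit pairwise allele differences:
# SS of a copy set = sum of pairwise squared differences / set size
ss_pairwise_oracle <- function(copies) {
  n <- length(copies)
  if (n < 2) return(0)
  tot <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) tot <- tot + as.integer(copies[i] != copies[j])
  }
  tot / n
}

# genotype string key for duplicate matching (missing as its own token)
genotype_strings <- function(gm) {
  apply(cbind(gm$a1, gm$a2), 1, paste, collapse = "|")
}

# mean silhouette width of a labelled distance matrix
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
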