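#' Pairwise genetic distance matrix between accessions
#'
#' The default allele-sharing distance at one locus between genotypes
#' `{x1,x2}` and `{y1,y2}` is `1 - s/2` where `s` is the number of allele
#' copies shared counting multiplicity (multiset intersection size, 0-2);
#' the genetic distance is the average over loci typed in both
#' accessions.  It is 0 exactly for identical multilocus genotypes, which
#' makes a `GD = 0` duplicate criterion coincide with genotype identity.
#' `nei_individual` instead treats each individual as a population of two
#' allele copies and computes Nei's (1972) standard distance
#' `D = -ln(Jxy / sqrt(Jx Jy))`; it is offered for compatibility with
#' population-level usage but is degenerate for single individuals (it
#' can be 0 for non-identical heterozygote pairs).
#'
#' @param gm A [genotype_matrix()].
#' @param method `"allele_share"` (default) or `"nei_individual"`.
#' @return Symmetric numeric matrix with zero diagonal, accession ids as
#'   dimnames, and attribute `"method"`.
#' @export
genetic_distance_matrix <- function(gm,
                                    method = c("allele_share",
                                               "nei_individual")) {
  method <- match.arg(method)
  n <- length(gm$accessions)
  if (n < 2L) stop("need at least 2 accessions")
  d <- matrix(0, n, n, dimnames = list(gm$accessions, gm$accessions))
  a1 <- gm$a1; a2 <- gm$a2
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(a1[i, ]) & !is.na(a1[j, ])
      if (!any(ok)) {
        stop("accessions ", gm$accessions[i], " and ", gm$accessions[j],
             " share no typed locus")
      }
      x1 <- a1[i, ok]; x2 <- a2[i, ok]
      y1 <- a1[j, ok]; y2 <- a2[j, ok]
      if (method == "allele_share") {
        aligned <- (x1 == y1) + (x2 == y2)
        crossed <- (x1 == y2) + (x2 == y1)
        s <- pmax(aligned, crossed)     # multiset intersection of pairs
        d[i, j] <- d[j, i] <- mean(1 - s / 2)
      } else {
        jxy <- mean(((x1 == y1) + (x1 == y2) + (x2 == y1) + (x2 == y2)) / 4)
        jx <- mean(ifelse(x1 == x2, 1, 0.5))
        jy <- mean(ifelse(y1 == y2, 1, 0.5))
        d[i, j] <- d[j, i] <- if (jxy == 0) Inf else
          -log(jxy / sqrt(jx * jy))
      }
    }
  }
  attr(d, "method") <- method
  d
}

#' Euclidean trait distance matrix
#'
#' Euclidean distance between accessions on standardized graded codes
#' (invariant traits excluded).
#'
#' @param table A [trait_table()].
#' @return Symmetric matrix with attribute `"method" = "euclidean"`.
#' @export
trait_distance_matrix <- function(table) {
  X <- standardize_traits(table)
  d <- as.matrix(dist(X))
  attr(d, "method") <- "euclidean"
  d
}

#' Write / read a square distance matrix CSV
#'
#' @param d Square matrix with dimnames.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(d, path) {
  write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerates the closest pair of clusters, with the between-cluster
#' distance defined as the size-weighted average of member distances.
#' The recorded node height is half the merging distance, so root-to-leaf
#' path lengths are equal (the tree is ultrametric).  Ties are broken
#' deterministically: among equally close pairs, the pair whose sorted
#' minimum leaf labels are lexicographically smallest merges first.
#'
#' @param d Complete symmetric distance matrix with labels as dimnames.
#' @return Object of class `c("upgma", "hclust")` (compatible with
#'   [stats::cutree()]): `merge`, `height` (node depths), `order`,
#'   `labels`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1L) {
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), order = 1L,
                          labels = labels, method = "upgma"),
                     class = c("upgma", "hclust")))
  }
  if (anyNA(d)) stop("distance matrix is incomplete")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  D <- d
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  node <- -seq_len(n)                  # hclust convention: leaves negative
  minlab <- labels                     # smallest member label per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- Inf; bi <- bj <- 0L
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in (ii + 1L):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        dij <- D[i, j]
        if (dij < best - 1e-12) {
          best <- dij; bi <- i; bj <- j
        } else if (dij <= best + 1e-12) {
          key_new <- sort(c(minlab[i], minlab[j]))
          key_old <- sort(c(minlab[bi], minlab[bj]))
          if (key_new[1L] < key_old[1L] ||
              (key_new[1L] == key_old[1L] && key_new[2L] < key_old[2L])) {
            best <- min(best, dij); bi <- i; bj <- j
          }
        }
      }
    }
    merge[step, ] <- if (minlab[bi] <= minlab[bj]) {
      c(node[bi], node[bj])
    } else {
      c(node[bj], node[bi])
    }
    height[step] <- best / 2
    # weighted average distance to the merged cluster
    for (k in idx) {
      if (k != bi && k != bj) {
        D[bi, k] <- D[k, bi] <-
          (sizes[bi] * D[bi, k] + sizes[bj] * D[bj, k]) /
          (sizes[bi] + sizes[bj])
      }
    }
    sizes[bi] <- sizes[bi] + sizes[bj]
    active[bj] <- FALSE
    node[bi] <- step
    minlab[bi] <- min(minlab[bi], minlab[bj])
    members[[bi]] <- c(members[[bi]], members[[bj]])
  }
  leaf_order <- integer(0)
  expand <- function(k) {
    if (k < 0L) return(-k)
    c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  }
  leaf_order <- expand(n - 1L)
  structure(list(merge = merge, height = height, order = leaf_order,
                 labels = labels, method = "upgma"),
            class = c("upgma", "hclust"))
}

#' Serialize an ultrametric tree to Newick
#'
#' Branch lengths are differences of node depths (leaves at depth 0).
#' Labels containing Newick metacharacters or whitespace are single-quoted.
#'
#' @param tree An [upgma()] tree.
#' @param path Optional file to write (with trailing newline).
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 10L) {
  quote_label <- function(x) {
    if (grepl("[][(){}:;,'\" \t]", x)) {
      paste0("'", gsub("'", "''", x), "'")
    } else x
  }
  fmt <- function(x) sprintf("%.*g", digits, x)
  if (nrow(tree$merge) == 0L) {
    s <- paste0(quote_label(tree$labels[1L]), ";")
  } else {
    depth <- function(k) if (k < 0L) 0 else tree$height[k]
    node_str <- function(k, parent_depth) {
      if (k < 0L) {
        paste0(quote_label(tree$labels[-k]), ":", fmt(parent_depth))
      } else {
        h <- tree$height[k]
        paste0("(", node_str(tree$merge[k, 1L], h - depth(tree$merge[k, 1L])),
               ",", node_str(tree$merge[k, 2L], h - depth(tree$merge[k, 2L])),
               "):", fmt(parent_depth))
      }
    }
    root <- nrow(tree$merge)
    h <- tree$height[root]
    s <- paste0("(",
                node_str(tree$merge[root, 1L],
                         h - depth(tree$merge[root, 1L])),
                ",",
                node_str(tree$merge[root, 2L],
                         h - depth(tree$merge[root, 2L])),
                ");")
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Cut an UPGMA tree into k clusters
#'
#' Clusters are renumbered by decreasing size (ties by first accession in
#' input order).
#'
#' @param tree An [upgma()] tree.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector accession -> cluster.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$labels)
  stopifnot(k >= 1L, k <= n)
  if (n == 1L) {
    out <- 1L; names(out) <- tree$labels
    return(out)
  }
  raw <- cutree(tree, k = k)
  sizes <- table(raw)
  first <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.numeric(sizes), as.numeric(first))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- relabel[raw]
  names(out) <- tree$labels
  out
}

#' Detect duplicate (synonymous) accessions
#'
#' Groups accessions into connected components of the graph whose edges
#' join pairs with distance at or below the threshold (0 by default,
#' i.e. identical multilocus genotypes).  Reports groups of size >= 2,
#' the redundant-accession count, and the number of distinct genotypes.
#'
#' @param d Distance matrix (see [genetic_distance_matrix()]).
#' @param threshold Non-negative distance threshold (default 0).
#' @return Object of class `duplicate_report` with `groups`,
#'   `n_redundant`, `n_distinct`, `threshold`.
#' @export
find_duplicates <- function(d, threshold = 0) {
  if (threshold < 0) stop("threshold must be non-negative")
  d <- as.matrix(d)
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] <= threshold + 1e-12) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ids <- rownames(d)
  groups <- split(ids, comp)
  groups <- unname(groups[vapply(groups, length, integer(1)) >= 2L])
  n_distinct <- length(unique(comp))
  structure(list(groups = groups, n_redundant = n - n_distinct,
                 n_distinct = n_distinct, threshold = threshold),
            class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat("duplicate_report:", length(x$groups), "groups,",
      x$n_redundant, "redundant,", x$n_distinct, "distinct (threshold ",
      x$threshold, ")\n")
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' Flag homonymous accessions
#'
#' A homonym group is a set of accessions sharing a variety name whose
#' members are not all genetically identical (maximum pairwise distance
#' above 0).  Name grouping is an explicit input mapping; optional
#' normalization folds case and surrounding whitespace only.
#'
#' @param names Named character vector accession id -> variety name.
#' @param d Distance matrix covering all named accessions.
#' @param normalize Fold case/whitespace before grouping (default FALSE).
#' @return List with `name_groups` (name -> accession ids, >= 2 members)
#'   and `flagged` (the genetically heterogeneous subset).
#' @export
find_homonyms <- function(names, d, normalize = FALSE) {
  d <- as.matrix(d)
  miss <- setdiff(base::names(names), rownames(d))
  if (length(miss)) {
    stop("accessions missing from the distance matrix: ",
         paste(miss, collapse = ", "))
  }
  key <- if (normalize) tolower(trimws(names)) else as.character(names)
  grp <- split(base::names(names), key)
  grp <- grp[vapply(grp, length, integer(1)) >= 2L]
  flagged <- grp[vapply(grp, function(ids) {
    max(d[ids, ids]) > 1e-12
  }, logical(1))]
  list(name_groups = grp, flagged = flagged)
}

#' Principal coordinates of a genetic distance matrix
#'
#' Classical metric multidimensional scaling (PCoA, Gower double
#' centering) of the pairwise distance matrix.  Negative eigenvalues of a
#' non-Euclidean matrix are clipped to zero with a warning when computing
#' explained-variance fractions.
#'
#' @param x A [genotype_matrix()] or a distance matrix.
#' @param k Number of axes (default all positive).
#' @return List with `coordinates` (accessions x axes), `eigenvalues`,
#'   `explained` (fractions).
#' @export
genotype_pca <- function(x, k = NULL) {
  d <- if (inherits(x, "genotype_matrix")) {
    genetic_distance_matrix(x)
  } else as.matrix(x)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 accessions")
  if (is.null(k)) k <- n - 1L
  mds <- cmdscale(as.dist(d), k = k, eig = TRUE)
  eig <- mds$eig
  if (any(eig < -1e-8)) {
    warning("negative eigenvalues clipped to 0 (non-Euclidean distances)")
  }
  pos <- pmax(eig, 0)
  keep <- seq_len(ncol(mds$points))
  coords <- mds$points
  colnames(coords) <- paste0("Axis", keep)
  list(coordinates = coords, eigenvalues = eig,
       explained = pos / sum(pos))
}
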