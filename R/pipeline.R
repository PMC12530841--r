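#' Run the full two-arm characterization pipeline
#'
#' Orchestrates trait statistics, core-trait selection, morphological
#' clustering, locus summaries, Hardy-Weinberg tests, genetic
#' distances/UPGMA, duplicate and homonym detection, AMOVA and the
#' admixture K sweep, writing one output file per stage plus a manifest
#' with parameters, seed and content hashes.  Outputs are a pure
#' function of (inputs, config, seed).
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   * `out_dir` (required) output directory;
#'   * `seed` (required for stochastic stages);
#'   * inputs: either in-memory objects `traits` ([trait_table()]),
#'     `genotypes` ([genotype_matrix()]), `groups`, `names`, or file
#'     paths `traits_csv` (+ `descriptors`), `genotypes_csv`,
#'     `groups_csv`, `names_csv`;
#'   * `stages`: character subset of
#'     `c("traits", "core_selection", "trait_cluster", "ssr_stats",
#'        "hwe", "cluster", "duplicates", "amova", "structure")`
#'     (default: all whose inputs are present);
#'   * thresholds: `alpha` (0.05), `alpha_cor` (0.01), `p_enter` (0.05),
#'     `p_remove` (0.10), `gd_threshold` (0), `k_cut` (5), `k_min` (1),
#'     `k_max` (10), `replicates` (10), `burn_in` (100000),
#'     `iterations` (200000).
#' @return List of stage results, invisibly; files in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(alpha = 0.05, alpha_cor = 0.01, p_enter = 0.05,
                   p_remove = 0.10, gd_threshold = 0, k_cut = 5L,
                   k_min = 1L, k_max = 10L, replicates = 10L,
                   burn_in = 100000L, iterations = 200000L,
                   stages = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  traits <- config$traits
  if (is.null(traits) && !is.null(config$traits_csv)) {
    traits <- read_trait_table(config$traits_csv, config$descriptors)
  }
  gm <- config$genotypes
  if (is.null(gm) && !is.null(config$genotypes_csv)) {
    gm <- read_genotypes(config$genotypes_csv)
  }
  groups <- config$groups
  if (is.null(groups) && !is.null(config$groups_csv)) {
    df <- read.csv(config$groups_csv, stringsAsFactors = FALSE)
    groups <- stats::setNames(as.character(df[[2L]]),
                              as.character(df[[1L]]))
  }
  vnames <- config$names
  if (is.null(vnames) && !is.null(config$names_csv)) {
    df <- read.csv(config$names_csv, stringsAsFactors = FALSE)
    vnames <- stats::setNames(as.character(df[[2L]]),
                              as.character(df[[1L]]))
  }

  all_stages <- c("traits", "core_selection", "trait_cluster",
                  "ssr_stats", "hwe", "cluster", "duplicates", "amova",
                  "structure")
  stages <- config$stages
  if (is.null(stages)) {
    stages <- all_stages
    if (is.null(traits)) {
      stages <- setdiff(stages, c("traits", "core_selection",
                                  "trait_cluster"))
    }
    if (is.null(gm)) {
      stages <- setdiff(stages, c("ssr_stats", "hwe", "cluster",
                                  "duplicates", "amova", "structure"))
    }
    if (is.null(groups)) stages <- setdiff(stages, "amova")
  }
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))

  res <- list()
  log_line <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("traits" %in% stages) {
    run_stage("traits", function() {
      st <- trait_stats_table(traits)
      write.csv(st, out("trait_stats.csv"), row.names = FALSE)
      res$trait_stats <<- st
      log_line("traits", sprintf("%d traits, %d accessions",
                                 nrow(st), length(traits$accessions)))
    })
  }
  if ("core_selection" %in% stages) {
    run_stage("core_selection", function() {
      X <- standardize_traits(traits)
      pca <- trait_pca(X)
      eig <- data.frame(component = seq_along(pca$eigenvalues),
                        eigenvalue = pca$eigenvalues,
                        contribution = pca$contribution,
                        cumulative = pca$cumulative_contribution)
      write.csv(eig, out("pca_eigen.csv"), row.names = FALSE)
      cs <- composite_score(pca)
      jsonlite::write_json(as.list(cs$weights), out("weights.json"),
                           auto_unbox = TRUE, digits = NA)
      write.csv(data.frame(accession_id = names(cs$f_values),
                           f = cs$f_values),
                out("f_scores.csv"), row.names = FALSE)
      ct <- trait_f_correlation(X, cs)
      write.csv(ct, out("correlation_table.csv"), row.names = FALSE)
      sel <- stepwise_select(X, cs, p_enter = config$p_enter,
                             p_remove = config$p_remove)
      jsonlite::write_json(
        list(selected_traits = sel$selected_traits,
             coefficients = as.list(sel$coefficients),
             r_squared = sel$r_squared),
        out("core_set.json"), auto_unbox = TRUE, digits = NA)
      res$core_set <<- sel
      res$pca <<- pca
      res$composite <<- cs
      log_line("core_selection",
               sprintf("retained %d components, %d core traits",
                       pca$retained, length(sel$selected_traits)))
    })
  }
  if ("trait_cluster" %in% stages) {
    run_stage("trait_cluster", function() {
      d <- trait_distance_matrix(traits)
      tree <- upgma(d)
      write_newick(tree, out("trait_tree.newick"))
      cl <- cut_clusters(tree, min(3L, length(tree$labels)))
      write.csv(data.frame(accession_id = names(cl), cluster = cl),
                out("trait_clusters.csv"), row.names = FALSE)
      res$trait_clusters <<- cl
      log_line("trait_cluster", sprintf("%d accessions", nrow(d)))
    })
  }
  if ("ssr_stats" %in% stages) {
    run_stage("ssr_stats", function() {
      st <- summarize_loci(gm)
      summ <- locus_stats_summary(st)
      tot <- rbind(
        cbind(data.frame(locus = "Mean", n_typed = NA),
              as.data.frame(t(summ$mean))),
        cbind(data.frame(locus = "Total", n_typed = NA),
              as.data.frame(t(summ$total))))
      write.csv(rbind(st, tot), out("locus_stats.csv"), row.names = FALSE)
      res$locus_stats <<- st
      log_line("ssr_stats", sprintf("%d loci, %d with PIC > 0.5",
                                    nrow(st), summ$n_pic_above_0.5))
    })
  }
  if ("hwe" %in% stages) {
    run_stage("hwe", function() {
      hw <- hwe_all(gm)
      write.csv(hw, out("hwe.csv"), row.names = FALSE)
      res$hwe <<- hw
      log_line("hwe", sprintf("%d tests, %d significant at 0.05",
                              nrow(hw), sum(hw$sig_05, na.rm = TRUE)))
    })
  }
  gd <- NULL
  if (any(c("cluster", "duplicates", "structure") %in% stages) &&
      !is.null(gm)) {
    gd <- genetic_distance_matrix(gm)
  }
  if ("cluster" %in% stages) {
    run_stage("cluster", function() {
      write_distance_matrix(gd, out("gd_matrix.csv"))
      tree <- upgma(gd)
      write_newick(tree, out("tree.newick"))
      k <- min(config$k_cut, length(tree$labels))
      cl <- cut_clusters(tree, k)
      write.csv(data.frame(accession_id = names(cl), cluster = cl),
                out("clusters.csv"), row.names = FALSE)
      pc <- genotype_pca(gd)
      write.csv(data.frame(accession_id = rownames(pc$coordinates),
                           pc$coordinates[, seq_len(min(5L,
                             ncol(pc$coordinates))), drop = FALSE]),
                out("pcoa_coordinates.csv"), row.names = FALSE)
      res$genetic_clusters <<- cl
      log_line("cluster", sprintf("cut at k = %d", k))
    })
  }
  if ("duplicates" %in% stages) {
    run_stage("duplicates", function() {
      dup <- find_duplicates(gd, threshold = config$gd_threshold)
      jsonlite::write_json(
        list(groups = dup$groups, n_redundant = dup$n_redundant,
             n_distinct = dup$n_distinct, threshold = dup$threshold),
        out("duplicates.json"), auto_unbox = TRUE, digits = NA)
      res$duplicates <<- dup
      if (!is.null(vnames)) {
        hom <- find_homonyms(vnames, gd)
        jsonlite::write_json(
          list(name_groups = hom$name_groups,
               flagged = hom$flagged),
          out("homonyms.json"), auto_unbox = TRUE, digits = NA)
        res$homonyms <<- hom
      }
      log_line("duplicates",
               sprintf("%d groups, %d distinct genotypes",
                       length(dup$groups), dup$n_distinct))
    })
  }
  if ("amova" %in% stages) {
    run_stage("amova", function() {
      am <- amova(gm, groups)
      write.csv(am$table, out("amova.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(phi_st = am$phi_st, nm = am$nm,
             percentages = as.list(am$percentages)),
        out("amova.json"), auto_unbox = TRUE, digits = NA)
      res$amova <<- am
      log_line("amova", sprintf("Phi_ST = %.4f", am$phi_st))
    })
  }
  if ("structure" %in% stages) {
    run_stage("structure", function() {
      if (is.null(config$seed)) stop("seed required for structure stage")
      sw <- sweep_k(gm, config$k_min:config$k_max,
                    replicates = config$replicates, seed = config$seed,
                    burn_in = config$burn_in,
                    iterations = config$iterations)
      for (nm_run in names(sw$runs)) {
        q <- sw$runs[[nm_run]]$q
        write.csv(data.frame(accession_id = rownames(q), q),
                  out(sprintf("qmatrix_%s.csv", nm_run)),
                  row.names = FALSE)
      }
      ev <- tryCatch(evanno_delta_k(sw), error = function(e) NULL)
      tab <- if (is.null(ev)) sw$summary else ev$table
      write.csv(tab, out("sweep.csv"), row.names = FALSE)
      res$structure_sweep <<- sw
      res$evanno <<- ev
      log_line("structure",
               if (is.null(ev)) "sweep done (delta-K unavailable)"
               else sprintf("best K = %d", ev$best_k))
    })
  }

  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("germdiv")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("traits", "genotypes", "groups",
                                  "names", "descriptors"))],
    stages = stages,
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(out(f))))
    }))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

#' Cross-tabulate two accession partitions
#'
#' Counts accessions per pair of class labels, e.g. morphological
#' cluster versus genetic group.
#'
#' @param assignments_a,assignments_b Named vectors over the same
#'   accession set.
#' @return Contingency table (`table`).
#' @export
cross_tabulate <- function(assignments_a, assignments_b) {
  if (!setequal(names(assignments_a), names(assignments_b))) {
    stop("partitions cover different accession sets")
  }
  ids <- names(assignments_a)
  table(a = assignments_a[ids], b = assignments_b[ids])
}
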