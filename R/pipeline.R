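#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults: 20,000-UMI
#' depth filter and downsampling, gene/triplet posterior cutoffs 0.5/0.6,
#' transition-prior odds 5e-2, critical drive phi0 = 0.1, 10,000 coupling
#' samples, 1000 Markov steps, overexpression grid 0-2 by 0.1.  One master
#' seed is expanded deterministically per stage (see `stage_seed`).
#'
#' @param counts path to a count matrix, or an [expression_matrix()], or
#'   `NULL` to generate the default synthetic lineage dataset.
#' @param annot optional annotation path or data.frame ([load_annotation()]
#'   shape); when supplied the analysis is restricted to TFs.
#' @param out_dir output directory.
#' @param depth,gene_cutoff,triplet_cutoff,prior_odds,phi0,n_samples,n_steps,delta_grid
#'   stage parameters (defaults as above).
#' @param k_max,gap_B,nstart clustering parameters.
#' @param seed master seed.
#' @param stages character subset of
#'   `c("prep", "lineage", "modules", "grn", "perturb")`.
#' @param modules_file optional path to a module x state CSV (same shape as
#'   a deposited supplementary state table); when given, the lineage half
#'   is skipped and grn/perturb run standalone on it.
#' @param pathways optional named list of pathway gene sets.
#' @param perturb optional list(kind, state, module, target, clamp) driving
#'   the perturbation stage.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(counts = NULL, annot = NULL, out_dir = tempfile("statefate_"),
                            depth = 20000, gene_cutoff = 0.5, triplet_cutoff = 0.6,
                            prior_odds = 5e-2, phi0 = 0.1, n_samples = 10000,
                            n_steps = 1000, delta_grid = seq(0, 2, by = 0.1),
                            k_max = 20, gap_B = 10, nstart = 20, seed = 7,
                            stages = c("prep", "lineage", "modules", "grn", "perturb"),
                            modules_file = NULL, pathways = NULL, perturb = NULL) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full pipeline
#'
#' prep (filter, downsample, lognorm, optional TF restriction) -> lineage
#' (seed clustering, iterative triplet/re-clustering loop, tree assembly)
#' -> modules (binarization) -> grn (constraint system + coupling
#' ensemble) -> perturb (optional scans/dynamics).  Every artifact is
#' written under `config$out_dir` together with a JSON manifest recording
#' seeds, parameters and a config hash; outputs are fully determined by
#' (inputs, config).
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  priors <- triplet_priors(prior_odds_transition = config$prior_odds,
                           prior_odds_marker = config$prior_odds)
  manifest <- list(package = "statefate",
                   version = as.character(utils::packageVersion("statefate")),
                   seed = config$seed,
                   config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
                   stages = list())
  log_path <- file.path(config$out_dir, "pipeline.jsonl")
  log_line <- function(...) cat(jsonlite::toJSON(list(...), auto_unbox = TRUE),
                                "\n", file = log_path, append = TRUE)

  states <- NULL
  if (is.null(config$modules_file)) {
    ## ---- prep ----
    if ("prep" %in% config$stages) {
      mat <- if (is.null(config$counts)) {
        sim <- generate_lineage_dataset(lineage_config(),
                                        seed = stage_seed(config$seed, 1))
        res$truth <- sim$labels
        sim$mat
      } else if (inherits(config$counts, "ExpressionMatrix")) {
        config$counts
      } else load_expression(config$counts)
      mat <- filter_cells_min_depth(mat, config$depth)
      mat <- subsample_umis(mat, config$depth, seed = stage_seed(config$seed, 2))
      if (!is.null(config$annot)) {
        annot <- if (is.character(config$annot)) load_annotation(config$annot) else config$annot
        mat <- restrict_to_tfs(mat, annot)
      }
      mat <- lognorm(mat)
      res$prep <- mat
      write_expression_lognorm(mat, file.path(config$out_dir, "prep_lognorm.tsv"))
      manifest$stages$prep <- list(cells = nrow(mat$counts), genes = ncol(mat$counts))
      log_line(stage = "prep", cells = nrow(mat$counts))
    }
    ## ---- lineage ----
    if ("lineage" %in% config$stages) {
      seed_asgn <- seed_clusters(res$prep, seed = stage_seed(config$seed, 3),
                                 k_max = config$k_max, gap_B = config$gap_B,
                                 nstart = config$nstart)
      it <- run_iterations(res$prep, seed_asgn,
                           gene_cutoff = config$gene_cutoff,
                           triplet_cutoff = config$triplet_cutoff,
                           priors = priors, k_max = config$k_max,
                           gap_B = config$gap_B, nstart = config$nstart,
                           seed = stage_seed(config$seed, 4))
      tree <- assemble_tree(it$triplet_results, it$assignment$n_clusters)
      res$lineage <- list(iteration_state = it, tree = tree)
      utils::write.table(
        data.frame(cell_id = names(it$assignment$cluster),
                   cluster = it$assignment$cluster),
        file.path(config$out_dir, "assignment.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(as.data.frame(tree$edges),
                         file.path(config$out_dir, "tree_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(tree_newick(tree), file.path(config$out_dir, "tree.newick"))
      for (h in it$history) log_line(stage = "lineage", iteration = h$iteration,
                                     n_genes = h$n_genes, n_clusters = h$n_clusters)
      manifest$stages$lineage <- list(n_clusters = it$assignment$n_clusters,
                                      n_genes = length(it$gene_subspace),
                                      iterations = it$iteration,
                                      converged = it$converged,
                                      tree_score = tree$score)
    }
    ## ---- modules ----
    if ("modules" %in% config$stages) {
      st <- build_modules(res$prep, res$lineage$iteration_state$assignment,
                          res$lineage$iteration_state$triplet_results,
                          res$lineage$tree, gene_cutoff = config$gene_cutoff,
                          on_conflict = "drop")
      if (!is.null(config$pathways))
        st <- signaling_modules(st, res$prep,
                                res$lineage$iteration_state$assignment,
                                config$pathways)
      states <- st
      write_state_matrix(st, file.path(config$out_dir, "modules.csv"))
      manifest$stages$modules <- list(n_modules = nrow(st$values),
                                      aliases = as.list(st$aliases))
      log_line(stage = "modules", n_modules = nrow(st$values))
    }
  } else {
    states <- read_state_matrix(config$modules_file)
    res$modules_source <- config$modules_file
  }
  res$states <- states
  ## ---- grn ----
  if ("grn" %in% config$stages && !is.null(states)) {
    collapsed <- collapse_aliases(states)
    system <- fixed_point_constraints(collapsed$values,
                                      model_config(phi0 = config$phi0))
    ens <- sample_couplings(system, n_samples = config$n_samples,
                            seed = stage_seed(config$seed, 5))
    res$grn <- list(system = system, ensemble = ens)
    smry <- ensemble_summary(ens)
    utils::write.csv(smry$mean, file.path(config$out_dir, "coupling_mean.csv"))
    utils::write.csv(smry$cv, file.path(config$out_dir, "coupling_cv.csv"))
    manifest$stages$grn <- list(n_samples = config$n_samples,
                                n_inequalities = nrow(system$A),
                                n_parameters = ncol(system$A),
                                mean_retries = mean(ens$retries))
    log_line(stage = "grn", n_samples = config$n_samples)
  }
  ## ---- perturb ----
  if ("perturb" %in% config$stages && !is.null(config$perturb) && !is.null(res$grn)) {
    p <- config$perturb
    init <- states$values[rownames(res$grn$ensemble$states), p$state]
    if (identical(p$kind, "overexpress")) {
      scan <- overexpression_scan(res$grn$ensemble, init, p$module, p$target,
                                  delta_grid = config$delta_grid)
      utils::write.csv(scan, file.path(config$out_dir, "scan.csv"), row.names = FALSE)
      res$perturb <- scan
    } else {
      dist <- ensemble_markov(res$grn$ensemble, init, clamps = p$clamp,
                              n_steps = config$n_steps)
      cls <- classify_distribution(dist, binary_state_matrix(res$grn$ensemble$states),
                                   ignore = p$clamp)
      utils::write.csv(data.frame(state = names(cls), probability = cls),
                       file.path(config$out_dir, "dist.csv"), row.names = FALSE)
      res$perturb <- list(distribution = dist, classified = cls)
    }
    log_line(stage = "perturb", kind = p$kind)
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

# Lognorm matrices are not integer; write with full precision TSV.
write_expression_lognorm <- function(mat, path) {
  df <- data.frame(cell_id = mat$cell_ids, mat$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
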