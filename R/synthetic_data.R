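#' Default planted-lineage configuration
#'
#' Describes the synthetic world the generator emulates: 9 cell states on a
#' bifurcating lineage tree (a root state, a primed intermediate, two
#' branching progenitors and terminal fates), 32 cells per state (288
#' total), and a gene plan of state-specific marker genes, triplet
#' transition genes and housekeeping background genes.  Library sizes are
#' drawn above the 20,000-UMI retention threshold so the depth filter and
#' downsampler apply as they would to real CEL-seq wells.
#'
#' Marker genes have mean log2 expression `mu_hi` in their own state and
#' `mu_lo` elsewhere; a transition gene of direct triplet (a, m, b) with low
#' state a has `mu_hi` in m and b and `mu_lo` everywhere else, so that
#' within the triplet it is lowest in a.
#'
#' @param n_states number of states (default 9; tree shape fixed for 9,
#'   otherwise a chain).
#' @param n_cells_per_state cells per state (default 32).
#' @param n_genes total genes (default 300); markers and transition genes
#'   are planted first, the rest are background.
#' @param markers_per_state planted marker genes per state (default 12).
#' @param transitions_per_slot planted transition genes per (direct triplet,
#'   low state) slot (default 4).
#' @param mu_hi,mu_lo planted high/low mean log2 expression (default 5 / 1).
#' @param dispersion negative-binomial size parameter shared by all genes
#'   (default 10); `Inf` gives the Poisson limit.
#' @param depth_range library-size interval (default 30,000-60,000 UMIs).
#' @return a list of class `PlantedLineage`.
#' @export
lineage_config <- function(n_states = 9, n_cells_per_state = 32, n_genes = 300,
                           markers_per_state = 12, transitions_per_slot = 4,
                           mu_hi = 5, mu_lo = 1, dispersion = 10,
                           depth_range = c(30000, 60000)) {
  if (any(n_cells_per_state <= 0))
    abort_sf("n_cells_per_state must be positive for every state", "statefate_validation_error")
  if (depth_range[1] < 20000)
    abort_sf("depth_range minimum must be >= 20000", "statefate_validation_error")
  states <- paste0("C", seq_len(n_states) - 1)
  edges <- if (n_states == 9) {
    cbind(c("C0", "C1", "C1", "C2", "C4", "C4", "C3", "C3"),
          c("C1", "C2", "C3", "C4", "C7", "C8", "C5", "C6"))
  } else {
    cbind(states[-n_states], states[-1])
  }
  n_cells_per_state <- rep_len(n_cells_per_state, n_states)

  trips <- direct_triplets_of_tree(states, edges)
  plan <- list(); mu <- list()
  gid <- 0
  nxt <- function() { gid <<- gid + 1; sprintf("g%03d_%s", gid, plan_tag) }
  for (s in states) {
    for (i in seq_len(markers_per_state)) {
      plan_tag <- paste0("mk_", s)
      g <- nxt()
      plan[[g]] <- list(class = "marker", state = s)
      mu[[g]] <- ifelse(states == s, mu_hi, mu_lo)
    }
  }
  for (t in trips) {
    for (low in setdiff(t$members, t$center)) {
      hi_states <- setdiff(t$members, low)
      for (i in seq_len(transitions_per_slot)) {
        plan_tag <- paste0("tr_", low)
        g <- nxt()
        plan[[g]] <- list(class = "transition", triplet = t$members,
                          center = t$center, low_state = low)
        mu[[g]] <- ifelse(states %in% hi_states, mu_hi, mu_lo)
      }
    }
  }
  n_bg <- n_genes - gid
  if (n_bg < 0) abort_sf("n_genes too small for the planted plan", "statefate_validation_error")
  # Housekeeping background: constant across states, spanning moderate-to-
  # high expression so it carries most of the library mass (as in real
  # transcriptomes) and per-state library composition stays comparable.
  for (i in seq_len(n_bg)) {
    plan_tag <- "bg"
    g <- nxt()
    plan[[g]] <- list(class = "background")
    lvl <- 4 + 3 * (i - 1) / max(n_bg - 1, 1)
    mu[[g]] <- rep(lvl, n_states)
  }
  mu <- do.call(rbind, mu)
  colnames(mu) <- states
  structure(list(states = states, edges = edges, triplets = trips,
                 gene_plan = plan, mean_log2 = mu,
                 n_cells_per_state = n_cells_per_state,
                 dispersion = dispersion, depth_range = depth_range),
            class = "PlantedLineage")
}

# All triplets (a, m, b) of a tree where the center m is adjacent to both
# a and b: the "direct" triplets, skipping no state.
direct_triplets_of_tree <- function(states, edges) {
  adj <- lapply(stats::setNames(states, states), function(s)
    c(edges[edges[, 1] == s, 2], edges[edges[, 2] == s, 1]))
  out <- list()
  for (m in states) {
    nb <- adj[[m]]
    if (length(nb) < 2) next
    for (pair in utils::combn(sort(nb), 2, simplify = FALSE)) {
      out[[length(out) + 1]] <- list(members = sort(c(pair, m)), center = m)
    }
  }
  out
}

#' Generate a planted lineage dataset
#'
#' Draws a UMI count matrix under the configured world: per cell, a library
#' size from `depth_range`, and per gene a negative-binomial count with
#' mean proportional to `2^mu - 1` for the cell's state, normalized to the
#' library size.  Deterministic given `seed`.
#'
#' @param config a [lineage_config()].
#' @param seed RNG seed.
#' @return list with `mat` (raw [expression_matrix()]), `labels` (cell to
#'   state), and `config`.
#' @export
generate_lineage_dataset <- function(config = lineage_config(), seed = 1) {
  stopifnot(inherits(config, "PlantedLineage"))
  validate_gene_plan(config)
  set.seed(seed)
  states <- config$states
  labels <- rep(states, config$n_cells_per_state)
  n_cells <- length(labels)
  genes <- rownames(config$mean_log2)
  expr <- 2^config$mean_log2 - 1            # linear-scale expected expression
  prop <- sweep(expr, 2, colSums(expr), "/")
  depth <- sample(config$depth_range[1]:config$depth_range[2], n_cells, replace = TRUE)
  counts <- matrix(0L, n_cells, length(genes),
                   dimnames = list(sprintf("cell_%03d", seq_len(n_cells)), genes))
  for (i in seq_len(n_cells)) {
    mu_i <- depth[i] * prop[, labels[i]]
    counts[i, ] <- if (is.infinite(config$dispersion)) {
      stats::rpois(length(mu_i), mu_i)
    } else {
      stats::rnbinom(length(mu_i), mu = mu_i, size = config$dispersion)
    }
  }
  mat <- expression_matrix(counts,
                           cell_meta = data.frame(cell_id = rownames(counts),
                                                  state = labels),
                           layer = "raw")
  list(mat = mat, labels = stats::setNames(labels, rownames(counts)),
       config = config)
}

validate_gene_plan <- function(config) {
  mu <- config$mean_log2
  for (g in rownames(mu)) {
    p <- config$gene_plan[[g]]
    if (p$class == "marker" && any(mu[g, setdiff(colnames(mu), p$state)] >= mu[g, p$state]))
      abort_sf(sprintf("marker gene %s is not strictly highest in %s", g, p$state),
               "statefate_validation_error")
    if (p$class == "transition") {
      others <- setdiff(p$triplet, p$low_state)
      if (any(mu[g, others] <= mu[g, p$low_state]))
        abort_sf(sprintf("transition gene %s is not strictly lowest in %s", g, p$low_state),
                 "statefate_validation_error")
    }
  }
  invisible(TRUE)
}

#' Enumerate or search the fixed points of a threshold network
#'
#' A state m is a fixed point when one synchronous update
#' m_i <- H(sum_j J_ij m_j - phi0) leaves it unchanged (H(x) = 1 for
#' x >= 0).  Exhaustive enumeration over all 2^N binary states for
#' N <= `exhaustive_max`; otherwise synchronous iteration to convergence
#' from `n_starts` random binary starts (plus the observed corners).
#'
#' @param J coupling matrix (N x N).
#' @param phi0 critical drive.
#' @param include_zero keep the all-zero state (always fixed when
#'   phi0 > 0)?
#' @param exhaustive_max largest N for exhaustive enumeration (default 16).
#' @param n_starts random starts for the iterative search (default 2000).
#' @return binary matrix, one fixed point per row.
#' @export
find_fixed_points <- function(J, phi0 = 0.1, include_zero = FALSE,
                              exhaustive_max = 16, n_starts = 2000) {
  n <- nrow(J)
  if (n <= exhaustive_max) {
    B <- as.matrix(expand.grid(rep(list(0:1), n)))
    colnames(B) <- NULL
    D <- B %*% t(J)
    F <- (D - phi0 >= 0) + 0L
    fixed <- B[rowSums(F != B) == 0, , drop = FALSE]
  } else {
    starts <- matrix(stats::rbinom(n_starts * n, 1, 0.5), n_starts, n)
    seen <- new.env(parent = emptyenv())
    fixed <- matrix(0L, 0, n)
    for (i in seq_len(n_starts)) {
      s <- starts[i, ]
      for (it in 1:(4 * n)) {
        s2 <- as.integer(J %*% s - phi0 >= 0)
        if (all(s2 == s)) break
        s <- s2
      }
      if (all(as.integer(J %*% s - phi0 >= 0) == s)) {
        key <- paste(s, collapse = "")
        if (is.null(seen[[key]])) { seen[[key]] <- TRUE; fixed <- rbind(fixed, s) }
      }
    }
    rownames(fixed) <- NULL
  }
  if (!include_zero) fixed <- fixed[rowSums(fixed) > 0, , drop = FALSE]
  fixed
}

#' Generate a planted threshold-network instance
#'
#' Draws coupling matrices J uniformly entrywise in \[-1, 1\] until one has
#' at least `target_n_states` distinct nonzero fixed points whose
#' constraints hold with margin at least `min_margin` (so the instance is
#' guaranteed feasible for the coupling sampler, with J itself a witness).
#'
#' @param n_modules N (<= 20).
#' @param phi0 critical drive (default 0.1).
#' @param target_n_states required number of nonzero fixed points.
#' @param seed RNG seed.
#' @param min_margin required distance of every drive from phi0.
#' @param max_retries resampling budget.
#' @return list of class `PlantedGRN` with `J_true`, `phi0`, `states`
#'   (a [binary_state_matrix()]).
#' @export
generate_grn_instance <- function(n_modules, phi0 = 0.1, target_n_states = 2,
                                  seed = 1, min_margin = 1e-4,
                                  max_retries = 500) {
  if (n_modules > 20)
    abort_sf("n_modules must be <= 20", "statefate_validation_error")
  set.seed(seed)
  for (try in seq_len(max_retries)) {
    J <- matrix(stats::runif(n_modules^2, -1, 1), n_modules, n_modules)
    fp <- find_fixed_points(J, phi0)
    if (nrow(fp) < target_n_states) next
    fp <- fp[seq_len(min(nrow(fp), target_n_states * 2L)), , drop = FALSE]
    drives <- fp %*% t(J)
    if (min(abs(drives - phi0)) < min_margin) next
    states <- binary_state_matrix(t(fp),
                                  module_ids = paste0("M", seq_len(n_modules)),
                                  state_ids = paste0("S", seq_len(nrow(fp))))
    return(structure(list(J_true = J, phi0 = phi0, states = states),
                     class = "PlantedGRN"))
  }
  abort_sf(sprintf("no J with >= %d fixed points found in %d draws",
                   target_n_states, max_retries), "statefate_resource_error")
}
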