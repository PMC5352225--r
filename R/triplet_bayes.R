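#' Priors for triplet gene-class and topology inference
#'
#' @param prior_odds_transition prior odds that a gene is a transition gene
#'   for a given triplet (default 5e-2).
#' @param prior_odds_marker prior odds for the marker class; the published
#'   analysis states only the transition prior, so the marker prior reuses
#'   its value by default.
#' @param topology_prior prior over the three topologies (default uniform).
#' @return list of class `TripletPriors`.
#' @export
triplet_priors <- function(prior_odds_transition = 5e-2,
                           prior_odds_marker = 5e-2,
                           topology_prior = rep(1 / 3, 3)) {
  if (prior_odds_transition <= 0 || prior_odds_marker <= 0 || any(topology_prior <= 0))
    abort_sf("priors must be positive", "statefate_validation_error")
  structure(list(prior_odds_transition = prior_odds_transition,
                 prior_odds_marker = prior_odds_marker,
                 topology_prior = topology_prior / sum(topology_prior)),
            class = "TripletPriors")
}

# Vectorized 2-component (low/high) 1-D Gaussian mixture EM, one mixture
# per row of X (genes x pooled cells).  Returns the per-cell posterior of
# the high component, and a per-gene degeneracy flag.
fit_gmm2_rows <- function(X, n_iter = 30, sd_floor = 0.05) {
  G <- nrow(X); n <- ncol(X)
  degenerate <- apply(X, 1, function(v) stats::var(v) < 1e-10)
  med <- apply(X, 1, stats::median)
  lo_mask <- X <= med           # G x n logical
  nlo <- pmax(rowSums(lo_mask), 1); nhi <- pmax(n - rowSums(lo_mask), 1)
  mlo <- rowSums(X * lo_mask) / nlo
  mhi <- rowSums(X * !lo_mask) / nhi
  same <- mhi - mlo < 1e-8
  mhi[same] <- mlo[same] + 1            # arbitrary; gene is degenerate anyway
  slo <- shi <- pmax(sqrt(rowSums((X - med)^2) / n) / 2, sd_floor)
  w <- rep(0.5, G)
  for (it in seq_len(n_iter)) {
    # E step: responsibilities of the high component
    lhi <- -((X - mhi)^2) / (2 * shi^2) - log(shi) + log(w)
    llo <- -((X - mlo)^2) / (2 * slo^2) - log(slo) + log(1 - w)
    r <- 1 / (1 + exp(llo - lhi))
    # M step
    shi_sum <- pmax(rowSums(r), 1e-8); slo_sum <- pmax(rowSums(1 - r), 1e-8)
    w <- pmin(pmax(shi_sum / n, 1e-3), 1 - 1e-3)
    mhi <- rowSums(r * X) / shi_sum
    mlo <- rowSums((1 - r) * X) / slo_sum
    shi <- pmax(sqrt(rowSums(r * (X - mhi)^2) / shi_sum), sd_floor)
    slo <- pmax(sqrt(rowSums((1 - r) * (X - mlo)^2) / slo_sum), sd_floor)
    # keep the labelling low/high consistent
    flip <- mhi < mlo
    if (any(flip)) {
      tmp <- mhi[flip]; mhi[flip] <- mlo[flip]; mlo[flip] <- tmp
      tmp <- shi[flip]; shi[flip] <- slo[flip]; slo[flip] <- tmp
      w[flip] <- 1 - w[flip]
      r[flip, ] <- 1 - r[flip, , drop = FALSE]
    }
  }
  r <- pmin(pmax(r, 1e-12), 1 - 1e-12)
  list(resp_high = r, degenerate = degenerate, separation = mhi - mlo,
       mean_high = mhi, sd_within = pmax(slo, shi))
}

# Per-gene posteriors for one triplet, vectorized over genes.
# X: genes x cells lognorm matrix restricted to the triplet's cells;
# groups: integer vector (1, 2, 3) giving each cell's cluster.
# min_sep: minimum low/high component separation (log2 units) for a gene
# to count as "well separated"; below it the gene carries null mass only.
# This implements the definition that marker/transition distributions must
# be well separated between clusters, and keeps per-cell evidence products
# from turning compositional drift into spurious certainty.
triplet_gene_posteriors <- function(X, groups, priors = triplet_priors(),
                                    min_sep = 1, min_high_mean = 2.5) {
  G <- nrow(X)
  # cheap pre-filter: a gene whose total range is below the separation
  # gate can never be informative; skip its EM fit
  rng <- apply(X, 1, function(v) max(v) - min(v))
  active <- which(rng >= min_sep)
  r <- matrix(0.5, G, ncol(X))
  degenerate <- rep(TRUE, G)
  if (length(active)) {
    fit <- fit_gmm2_rows(X[active, , drop = FALSE])
    # A gene is informative only when its two components are well
    # separated AND its high component sits above the low-count
    # quantization regime (log2 units; 2.5 ~ 5 UMIs at 20k depth).
    degenerate[active] <- fit$degenerate | fit$separation < min_sep |
      fit$mean_high < min_high_mean
    r[active, ] <- fit$resp_high
  }
  # cluster-level probability q_k that cluster k's cells are collectively
  # "high": product of per-cell component posteriors, renormalized
  q <- matrix(0, G, 3)
  for (k in 1:3) {
    idx <- which(groups == k)
    lhi <- rowSums(log(r[, idx, drop = FALSE]))
    llo <- rowSums(log(1 - r[, idx, drop = FALSE]))
    q[, k] <- 1 / (1 + exp(llo - lhi))
  }
  fit <- list(degenerate = degenerate)
  q <- pmin(pmax(q, 1e-6), 1 - 1e-6)
  # joint high/low configurations over the three clusters partition unit
  # mass: marker-for-k = only k high; transition-low-in-k = only k low;
  # null = all high or all low.
  marker <- cbind(q[, 1] * (1 - q[, 2]) * (1 - q[, 3]),
                  (1 - q[, 1]) * q[, 2] * (1 - q[, 3]),
                  (1 - q[, 1]) * (1 - q[, 2]) * q[, 3])
  transi <- cbind((1 - q[, 1]) * q[, 2] * q[, 3],
                  q[, 1] * (1 - q[, 2]) * q[, 3],
                  q[, 1] * q[, 2] * (1 - q[, 3]))
  null <- q[, 1] * q[, 2] * q[, 3] + (1 - q[, 1]) * (1 - q[, 2]) * (1 - q[, 3])
  wm <- priors$prior_odds_marker * marker
  wt <- priors$prior_odds_transition * transi
  tot <- null + rowSums(wm) + rowSums(wt)
  p_marker <- wm / tot
  p_transition <- wt / tot
  p_null <- null / tot
  # degenerate genes carry no evidence
  if (any(fit$degenerate)) {
    p_marker[fit$degenerate, ] <- 0
    p_transition[fit$degenerate, ] <- 0
    p_null[fit$degenerate] <- 1
  }
  list(p_null = p_null, p_marker = p_marker, p_transition = p_transition)
}

#' Per-gene marker/transition posterior for one cluster triplet
#'
#' Pools the gene's log-expression values over the three clusters, fits a
#' two-component (low/high) Gaussian mixture, and turns the cluster-level
#' high/low posteriors q_k into class probabilities: a marker gene is high
#' in exactly one cluster, a transition gene low in exactly one, and the
#' all-high / all-low configurations carry the null mass.  Prior odds
#' reweight the classes; the result sums to one.
#'
#' @param expr numeric vector of lognorm expression values for one gene
#'   over the triplet's cells.
#' @param groups integer vector in \{1, 2, 3\}: each cell's cluster.
#' @param priors a [triplet_priors()].
#' @param min_cells minimum cells per cluster (default 5).
#' @param min_sep minimum low/high mixture-component separation (log2
#'   units, default 1) for the gene to count as well separated; below it
#'   the gene is treated as carrying no class evidence (null).
#' @param min_high_mean minimum high-component mean (log2 units, default
#'   2.5): genes whose "high" level is in the low-count quantization
#'   regime carry no class evidence.
#' @return list of class `GeneTripletPosterior` with `p_marker` (3),
#'   `p_transition` (3), `p_null`, `odds_transition` (3).
#' @export
gene_class_posterior <- function(expr, groups, priors = triplet_priors(),
                                 min_cells = 5, min_sep = 1,
                                 min_high_mean = 2.5) {
  if (any(tabulate(groups, 3) < min_cells))
    abort_sf(sprintf("every cluster needs >= %d cells", min_cells),
             "statefate_precondition_error")
  post <- triplet_gene_posteriors(matrix(expr, nrow = 1), groups, priors,
                                  min_sep = min_sep,
                                  min_high_mean = min_high_mean)
  p_t <- drop(post$p_transition)
  structure(list(p_marker = drop(post$p_marker), p_transition = p_t,
                 p_null = drop(post$p_null),
                 odds_transition = p_t / (1 - p_t)),
            class = "GeneTripletPosterior")
}

#' Posterior over the three triplet topologies
#'
#' For topology "k is intermediate", a gene's transition-low-in-k mass is
#' incompatible (a transition gene is expressed in the intermediate state),
#' so the gene's factor is `1 - p_transition_k`: each gene casts a log-vote
#' against its lowest cluster being intermediate, weighted by its odds of
#' being a transition gene.  Computed in log space and normalized.
#'
#' @param p_transition genes x 3 matrix of per-gene transition posteriors
#'   (or a list of [gene_class_posterior()] results).
#' @param priors a [triplet_priors()].
#' @return numeric 3-vector summing to 1.
#' @export
topology_posterior <- function(p_transition, priors = triplet_priors()) {
  if (is.list(p_transition) && !is.matrix(p_transition))
    p_transition <- do.call(rbind, lapply(p_transition, `[[`, "p_transition"))
  if (nrow(p_transition) == 0)
    abort_sf("no genes supplied", "statefate_precondition_error")
  logp <- log(priors$topology_prior) + colSums(log1p(-p_transition))
  logp <- logp - max(logp)
  exp(logp) / sum(exp(logp))
}

#' Full triplet analysis
#'
#' Runs [gene_class_posterior()] for every gene (vectorized) and
#' [topology_posterior()] over the results.
#'
#' @param mat lognorm-layer [expression_matrix()].
#' @param cells list of 3 integer vectors: cell indices per cluster.
#' @param cluster_ids labels of the three clusters.
#' @param priors a [triplet_priors()].
#' @param min_cells minimum cells per cluster.
#' @param min_sep,min_high_mean evidence gates, see
#'   [gene_class_posterior()].
#' @return list of class `TripletResult` with `cluster_ids`,
#'   `gene_posteriors` (data.frame), `p_topology`, `priors`.
#' @export
triplet_result <- function(mat, cells, cluster_ids = c("A", "B", "C"),
                           priors = triplet_priors(), min_cells = 5,
                           min_sep = 1, min_high_mean = 2.5) {
  stopifnot(inherits(mat, "ExpressionMatrix"), length(cells) == 3)
  sizes <- lengths(cells)
  if (any(sizes < min_cells))
    abort_sf(sprintf("every cluster needs >= %d cells (got %s)",
                     min_cells, paste(sizes, collapse = "/")),
             "statefate_precondition_error")
  idx <- unlist(cells)
  groups <- rep(1:3, sizes)
  X <- t(mat$counts[idx, , drop = FALSE])
  post <- triplet_gene_posteriors(X, groups, priors, min_sep = min_sep,
                                  min_high_mean = min_high_mean)
  gp <- data.frame(gene_id = mat$gene_ids,
                   p_null = post$p_null,
                   p_marker_1 = post$p_marker[, 1],
                   p_marker_2 = post$p_marker[, 2],
                   p_marker_3 = post$p_marker[, 3],
                   p_transition_1 = post$p_transition[, 1],
                   p_transition_2 = post$p_transition[, 2],
                   p_transition_3 = post$p_transition[, 3])
  structure(list(cluster_ids = cluster_ids, cells = cells,
                 gene_posteriors = gp,
                 p_topology = topology_posterior(post$p_transition, priors),
                 priors = priors),
            class = "TripletResult")
}

#' @export
print.TripletResult <- function(x, ...) {
  cat("TripletResult", paste(x$cluster_ids, collapse = "-"),
      "| P(topology):", paste(sprintf("%s=%.3f", x$cluster_ids, x$p_topology),
                              collapse = " "), "\n")
  invisible(x)
}

#' Label genes from a triplet result
#'
#' A gene is labelled `marker` or `transition` (for the cluster whose
#' posterior is largest) when that posterior strictly exceeds
#' `gene_cutoff`; otherwise `neither`.
#'
#' @param result a [triplet_result()].
#' @param gene_cutoff posterior cutoff (default 0.5, strict).
#' @return data.frame with `gene_id`, `class`, `cluster`, `posterior`.
#' @export
classify_genes <- function(result, gene_cutoff = 0.5) {
  gp <- result$gene_posteriors
  pm <- as.matrix(gp[, c("p_marker_1", "p_marker_2", "p_marker_3")])
  pt <- as.matrix(gp[, c("p_transition_1", "p_transition_2", "p_transition_3")])
  best_m <- max.col(pm, ties.method = "first")
  best_t <- max.col(pt, ties.method = "first")
  pm_best <- pm[cbind(seq_len(nrow(pm)), best_m)]
  pt_best <- pt[cbind(seq_len(nrow(pt)), best_t)]
  class <- rep("neither", nrow(gp))
  cluster <- rep(NA_character_, nrow(gp))
  posterior <- pmax(pm_best, pt_best)
  is_m <- pm_best > gene_cutoff & pm_best >= pt_best
  is_t <- pt_best > gene_cutoff & pt_best > pm_best
  class[is_m] <- "marker"; cluster[is_m] <- result$cluster_ids[best_m[is_m]]
  class[is_t] <- "transition"; cluster[is_t] <- result$cluster_ids[best_t[is_t]]
  data.frame(gene_id = gp$gene_id, class = class, cluster = cluster,
             posterior = posterior)
}

#' Serialize a TripletResult
#'
#' Writes the per-gene posterior table as TSV and the topology posterior
#' plus priors as a JSON sidecar (`<stem>.json`).
#'
#' @param result a [triplet_result()].
#' @param path TSV path.
#' @export
write_triplet_result <- function(result, path) {
  utils::write.table(result$gene_posteriors, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hdr <- list(cluster_ids = result$cluster_ids,
              p_topology = as.numeric(result$p_topology),
              priors = unclass(result$priors))
  jsonlite::write_json(hdr, paste0(sub("\\.tsv$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
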