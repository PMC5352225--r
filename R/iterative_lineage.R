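#' Construct a ClusterAssignment
#'
#' @param labels integer (or coercible) cluster label per cell; relabelled
#'   to contiguous integers 1..K preserving first-appearance order.
#' @param cell_ids optional names.
#' @export
cluster_assignment <- function(labels, cell_ids = NULL) {
  lv <- unique(labels)
  lab <- match(labels, lv)
  if (!is.null(cell_ids)) names(lab) <- cell_ids
  structure(list(cluster = lab, n_clusters = length(lv)),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters\n",
              length(x$cluster), x$n_clusters))
  invisible(x)
}

# Best-of k-means: random restarts plus one deterministic run initialized
# from Ward-linkage hierarchical centers, which stabilizes the within-sum
# against k-means local minima (important for the gap statistic, where an
# inflated W_k at the true k masks the gap maximum).
kmeans_best <- function(M, k, nstart = 10, hc = NULL) {
  if (k == 1)
    return(list(cluster = rep(1L, nrow(M)),
                tot.withinss = sum(scale(M, scale = FALSE)^2)))
  km <- stats::kmeans(M, k, nstart = nstart, iter.max = 50)
  if (is.null(hc)) hc <- stats::hclust(stats::dist(M), method = "ward.D2")
  cut <- stats::cutree(hc, k)
  centers <- rowsum(M, cut) / as.vector(table(cut))
  km2 <- tryCatch(stats::kmeans(M, centers, iter.max = 50),
                  error = function(e) NULL)
  if (!is.null(km2) && km2$tot.withinss < km$tot.withinss) km2 else km
}

# Gap statistic for k-means: compares log within-cluster dispersion with
# B uniform reference draws over the feature ranges; selects the smallest
# k with Gap(k) >= Gap(k+1) - s_{k+1} (the "firstSEmax"-style rule).
gap_statistic <- function(X, k_max = 20, B = 10, nstart = 10, seed = 1) {
  set.seed(seed)
  ks <- seq_len(k_max)
  hcX <- stats::hclust(stats::dist(X), method = "ward.D2")
  logW <- vapply(ks, function(k)
    log(kmeans_best(X, k, nstart, hcX)$tot.withinss), 0)
  rng_lo <- apply(X, 2, min); rng_hi <- apply(X, 2, max)
  logWstar <- matrix(0, B, k_max)
  for (b in seq_len(B)) {
    ref <- matrix(stats::runif(length(X), rep(rng_lo, each = nrow(X)),
                               rep(rng_hi, each = nrow(X))), nrow(X))
    hcr <- stats::hclust(stats::dist(ref), method = "ward.D2")
    logWstar[b, ] <- vapply(ks, function(k)
      log(kmeans_best(ref, k, nstart, hcr)$tot.withinss), 0)
  }
  gap <- colMeans(logWstar) - logW
  s <- apply(logWstar, 2, stats::sd) * sqrt(1 + 1 / B)
  k_hat <- k_max
  for (k in seq_len(k_max - 1)) {
    if (gap[k] >= gap[k + 1] - s[k + 1]) { k_hat <- k; break }
  }
  list(k = k_hat, gap = gap, se = s)
}

# Minimal density-based clustering (DBSCAN-style) on a 2-D embedding.
density_cluster <- function(Y, min_pts = 5, eps = NULL) {
  n <- nrow(Y)
  D <- as.matrix(stats::dist(Y))
  if (is.null(eps)) {
    knn <- apply(D, 1, function(d) sort(d)[min_pts + 1])
    eps <- stats::quantile(knn, 0.9)
  }
  labels <- integer(n)     # 0 = unvisited
  cl <- 0
  for (i in seq_len(n)) {
    if (labels[i] != 0) next
    nb <- which(D[i, ] <= eps)
    if (length(nb) < min_pts) { labels[i] <- -1; next }    # noise (for now)
    cl <- cl + 1
    queue <- nb
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1) labels[j] <- cl
      if (labels[j] != 0) next
      labels[j] <- cl
      nbj <- which(D[j, ] <= eps)
      if (length(nbj) >= min_pts) queue <- c(queue, nbj[labels[nbj] == 0])
    }
  }
  # attach residual noise points to the nearest cluster
  if (any(labels == -1)) {
    for (i in which(labels == -1)) {
      ok <- labels > 0
      labels[i] <- labels[ok][which.min(D[i, ok])]
    }
  }
  labels
}

#' Seed clustering of cells
#'
#' Two backends: `kmeans_gap` chooses k by the gap statistic (k = 1..k_max)
#' and runs k-means with multiple restarts; `embed_density` reduces to the
#' top 10 principal components, embeds in 2-D (t-SNE when the Rtsne package
#' is installed, otherwise the first two PCs) and density-clusters the
#' embedding.
#'
#' @param mat lognorm-layer [expression_matrix()] (typically TF-restricted).
#' @param method `"kmeans_gap"` (default) or `"embed_density"`.
#' @param seed RNG seed (determinism contract: same seed, same assignment).
#' @param k force the number of clusters (skips the gap statistic); used
#'   e.g. to produce a deliberately over-split seed.
#' @param k_max largest k considered by the gap statistic (default 20).
#' @param gap_B reference draws for the gap statistic.
#' @param nstart k-means restarts (default 20).
#' @return a [cluster_assignment()].
#' @export
seed_clusters <- function(mat, method = c("kmeans_gap", "embed_density"),
                          seed = 1, k = NULL, k_max = 20, gap_B = 10,
                          nstart = 20) {
  method <- match.arg(method)
  if (k_max < 1) abort_sf("k_max must be >= 1", "statefate_validation_error")
  X <- mat$counts
  set.seed(seed)
  if (method == "kmeans_gap") {
    if (is.null(k)) k <- gap_statistic(X, k_max = k_max, B = gap_B,
                                       nstart = max(nstart %/% 2, 5),
                                       seed = seed)$k
    lab <- kmeans_best(X, k, nstart = nstart)$cluster
  } else {
    npc <- min(10, ncol(X), nrow(X) - 1)
    pc <- stats::prcomp(X, rank. = npc)$x
    Y <- if (requireNamespace("Rtsne", quietly = TRUE) && nrow(X) > 30) {
      Rtsne::Rtsne(pc, perplexity = min(30, (nrow(X) - 1) %/% 3),
                   check_duplicates = FALSE)$Y
    } else pc[, 1:2, drop = FALSE]
    lab <- density_cluster(Y)
    if (!is.null(k) && max(lab) != k)
      warning("embed_density found ", max(lab), " clusters, not the requested ", k)
  }
  cluster_assignment(lab, mat$cell_ids)
}

# All triplet results for one assignment; triplets with any cluster below
# min_cells are skipped.
all_triplet_results <- function(mat, assignment, priors = triplet_priors(),
                                min_cells = 5) {
  K <- assignment$n_clusters
  cells_by <- split(seq_along(assignment$cluster), assignment$cluster)
  out <- list()
  for (trip in utils::combn(K, 3, simplify = FALSE)) {
    sizes <- lengths(cells_by[trip])
    if (any(sizes < min_cells)) next
    out[[paste(trip, collapse = "_")]] <-
      triplet_result(mat, cells_by[trip], cluster_ids = trip,
                     priors = priors, min_cells = min_cells)
  }
  out
}

# Marker-or-transition gene subspace over triplets passing the topology
# cutoff.
gene_subspace_from_triplets <- function(triplet_results, gene_ids,
                                        gene_cutoff = 0.5,
                                        triplet_cutoff = 0.6) {
  keep <- rep(FALSE, length(gene_ids))
  for (tr in triplet_results) {
    if (max(tr$p_topology) < triplet_cutoff) next
    gp <- tr$gene_posteriors
    pmax_gene <- pmax(gp$p_marker_1, gp$p_marker_2, gp$p_marker_3,
                      gp$p_transition_1, gp$p_transition_2, gp$p_transition_3)
    keep <- keep | (pmax_gene > gene_cutoff)
  }
  gene_ids[keep]
}

#' Iterate triplet inference and re-clustering to convergence
#'
#' Alternates (i) triplet marker/transition/topology inference over every
#' cluster triplet with enough cells and (ii) re-clustering of the cells in
#' the subspace of high-probability marker/transition genes, until the
#' cluster assignment is unchanged or the gene subspace stops changing
#' (Jaccard change < 0.10), or `max_iter` is hit (with a warning).
#'
#' @param mat lognorm-layer [expression_matrix()].
#' @param seed_assignment a [cluster_assignment()] with >= 3 clusters.
#' @param gene_cutoff posterior cutoff for a gene to enter the subspace
#'   (default 0.5).
#' @param triplet_cutoff topology-posterior cutoff for a triplet to count
#'   as a transition event (default 0.6).
#' @param max_iter iteration cap (default 20).
#' @param method re-clustering backend, as in [seed_clusters()].
#' @param priors a [triplet_priors()].
#' @param min_cells minimum cells per cluster in a triplet.
#' @param k_max,gap_B,nstart re-clustering parameters.
#' @param seed RNG seed for re-clustering.
#' @return list of class `IterationState`: `iteration`, `gene_subspace`,
#'   `assignment`, `triplet_results`, `converged`, `history`.
#' @export
run_iterations <- function(mat, seed_assignment, gene_cutoff = 0.5,
                           triplet_cutoff = 0.6, max_iter = 20,
                           method = "kmeans_gap", priors = triplet_priors(),
                           min_cells = 5, k_max = 20, gap_B = 10,
                           nstart = 20, seed = 1) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (seed_assignment$n_clusters < 3)
    abort_sf("seed must have >= 3 clusters", "statefate_precondition_error")
  assignment <- seed_assignment
  genes_prev <- character()
  history <- list()
  converged <- FALSE
  trs <- NULL
  for (it in seq_len(max_iter)) {
    trs <- all_triplet_results(mat, assignment, priors, min_cells)
    genes <- gene_subspace_from_triplets(trs, mat$gene_ids, gene_cutoff,
                                         triplet_cutoff)
    if (length(genes) == 0)
      abort_sf(sprintf(
        "gene subspace empty at iteration %d (%d triplets, max topology %.2f)",
        it, length(trs), max(vapply(trs, function(t) max(t$p_topology), 0))),
        "statefate_convergence_error")
    sub <- mat
    sub$counts <- mat$counts[, mat$gene_ids %in% genes, drop = FALSE]
    sub$gene_ids <- mat$gene_ids[mat$gene_ids %in% genes]
    new_assignment <- seed_clusters(sub, method = method, seed = seed + it,
                                    k_max = k_max, gap_B = gap_B,
                                    nstart = nstart)
    history[[it]] <- list(iteration = it, n_genes = length(genes),
                          n_clusters = new_assignment$n_clusters)
    ari <- adjusted_rand_index(assignment$cluster, new_assignment$cluster)
    gene_change <- 1 - jaccard_index(genes_prev, genes)
    stable_genes <- it > 1 && gene_change < 0.10
    assignment_prev <- assignment
    assignment <- new_assignment
    genes_prev <- genes
    if (ari == 1 || stable_genes) {
      converged <- TRUE
      if (ari == 1) assignment <- assignment_prev   # unchanged partition
      break
    }
  }
  if (!converged) warning("run_iterations hit max_iter without converging")
  # final triplet results on the converged assignment
  trs <- all_triplet_results(mat, assignment, priors, min_cells)
  genes <- gene_subspace_from_triplets(trs, mat$gene_ids, gene_cutoff,
                                       triplet_cutoff)
  structure(list(iteration = length(history), gene_subspace = genes,
                 assignment = assignment, triplet_results = trs,
                 converged = converged, history = history),
            class = "IterationState")
}

## ---- lineage tree assembly ----

tree_distances <- function(n, edges) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    D[edges[r, 1], edges[r, 2]] <- 1
    D[edges[r, 2], edges[r, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n))    # Floyd-Warshall (n small)
    D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  D
}

# Score of a spanning tree: sum over triplets whose median is one of the
# triplet members of log P(T = median) - log(1/3).  The log(1/3) reference
# makes triplets without an implied topology score-neutral, so trees are
# rewarded for confident consistent triplets and penalized for
# contradicted ones.
tree_score <- function(n, edges, trip_ids, trip_logp) {
  D <- tree_distances(n, edges)
  s <- 0
  for (q in seq_along(trip_ids)) {
    t3 <- trip_ids[[q]]
    a <- t3[1]; b <- t3[2]; c <- t3[3]
    if (!is.finite(D[a, b]) || !is.finite(D[a, c]) || !is.finite(D[b, c]))
      next                               # disconnected: no implied topology
    med <- 0
    if (D[a, b] == D[a, c] + D[c, b]) med <- 3
    else if (D[a, c] == D[a, b] + D[b, c]) med <- 2
    else if (D[b, c] == D[b, a] + D[a, c]) med <- 1
    if (med > 0) s <- s + trip_logp[[q]][med] - log(1 / 3)
  }
  s
}

prufer_to_edges <- function(pr, n) {
  avail <- rep(1L, n)
  for (v in pr) avail[v] <- avail[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (i in seq_along(pr)) {
    leaf <- which(avail == 1L)[1]
    edges[i, ] <- c(leaf, pr[i])
    avail[leaf] <- 0L
    avail[pr[i]] <- avail[pr[i]] - 1L
  }
  edges[n - 1, ] <- which(avail == 1L)
  edges
}

all_spanning_trees <- function(n) {
  if (n == 2) return(list(matrix(c(1L, 2L), 1)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  lapply(seq_len(nrow(seqs)), function(i) prufer_to_edges(seqs[i, ], n))
}

#' Assemble the most parsimonious lineage tree
#'
#' Searches spanning trees of the cluster set for the one maximizing the
#' summed log topology posterior of all triplets whose intermediate node
#' the tree determines (the member on the path between the other two).
#' Exhaustive search (via Prufer enumeration) for <= 7 clusters, otherwise
#' greedy hill climbing over edge exchanges started from the best chain.
#'
#' @param triplet_results list of [triplet_result()]s whose `cluster_ids`
#'   are integer cluster indices.
#' @param n_clusters number of clusters.
#' @param exhaustive_max largest size for exhaustive search (default 7).
#' @return list of class `LineageTree` with `nodes`, `edges`, `score`.
#' @export
assemble_tree <- function(triplet_results, n_clusters,
                          exhaustive_max = 7) {
  if (n_clusters < 3) {
    warning("fewer than 3 clusters: trivial tree returned")
    edges <- if (n_clusters == 2) matrix(c(1L, 2L), 1) else matrix(0L, 0, 2)
    return(structure(list(nodes = seq_len(n_clusters), edges = edges, score = 0),
                     class = "LineageTree"))
  }
  trip_ids <- lapply(triplet_results, function(t) as.integer(t$cluster_ids))
  trip_logp <- lapply(triplet_results, function(t) log(pmax(t$p_topology, 1e-300)))
  score_of <- function(edges) tree_score(n_clusters, edges, trip_ids, trip_logp)

  if (n_clusters <= exhaustive_max) {
    trees <- all_spanning_trees(n_clusters)
    scores <- vapply(trees, score_of, 0)
    best <- trees[[which.max(scores)]]
    return(structure(list(nodes = seq_len(n_clusters), edges = best,
                          score = max(scores)), class = "LineageTree"))
  }
  # greedy: steepest-ascent edge exchange (remove an edge, reconnect the
  # two components every possible way, take the single best improvement
  # per sweep), multi-started from the chain and from every star tree to
  # escape local optima of the rugged tree-score landscape
  climb <- function(edges) {
    score <- score_of(edges)
    repeat {
      sweep_best <- NULL; sweep_score <- score
      for (e in seq_len(nrow(edges))) {
        reduced <- edges[-e, , drop = FALSE]
        comp <- components_of(n_clusters, reduced)
        side <- comp == comp[edges[e, 1]]
        for (u in which(side))
          for (v in which(!side)) {
            cand <- rbind(reduced, c(u, v))
            s <- score_of(cand)
            if (s > sweep_score + 1e-12) {
              sweep_best <- cand; sweep_score <- s
            }
          }
      }
      if (is.null(sweep_best)) break
      edges <- sweep_best; score <- sweep_score
    }
    list(edges = edges, score = score)
  }
  starts <- c(list(cbind(seq_len(n_clusters - 1), 2:n_clusters)),
              lapply(seq_len(n_clusters), function(ctr)
                cbind(setdiff(seq_len(n_clusters), ctr), ctr)))
  best <- NULL; best_score <- -Inf
  for (st in starts) {
    res <- climb(st)
    if (res$score > best_score) { best <- res$edges; best_score <- res$score }
  }
  structure(list(nodes = seq_len(n_clusters), edges = best, score = best_score),
            class = "LineageTree")
}

components_of <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) { comp[comp == comp[a] | comp == comp[b]] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  comp
}

#' @export
print.LineageTree <- function(x, ...) {
  cat(sprintf("LineageTree: %d clusters, score %.3f\n", length(x$nodes), x$score))
  if (nrow(x$edges)) cat(paste(sprintf("  %s -- %s", x$edges[, 1], x$edges[, 2]),
                               collapse = "\n"), "\n")
  invisible(x)
}

#' Export a LineageTree as Newick text
#'
#' @param tree a [assemble_tree()] result.
#' @param root node to root at (default 1).
#' @param labels node labels (default `C<k-1>`).
#' @export
tree_newick <- function(tree, root = 1, labels = paste0("C", tree$nodes - 1)) {
  adj <- lapply(tree$nodes, function(v)
    c(tree$edges[tree$edges[, 1] == v, 2], tree$edges[tree$edges[, 2] == v, 1]))
  rec <- function(v, parent) {
    kids <- setdiff(adj[[v]], parent)
    if (length(kids) == 0) return(labels[v])
    paste0("(", paste(vapply(kids, rec, "", parent = v), collapse = ","),
           ")", labels[v])
  }
  paste0(rec(root, 0L), ";")
}

#' Within-cluster discreteness test
#'
#' For each cluster, compares the observed first-principal-component
#' variance of the cluster's cells with the maximum PC variance over
#' `n_rand` randomizations in which each gene's values are independently
#' permuted across cells (breaking gene-gene correlation but keeping
#' marginals).  A ratio above 1 flags residual structure (the cluster is
#' not a single homogeneous state).
#'
#' @param mat lognorm-layer [expression_matrix()].
#' @param assignment a [cluster_assignment()].
#' @param genes optional gene subset (e.g. the converged subspace).
#' @param n_rand randomizations (default 1000).
#' @param seed RNG seed.
#' @return data.frame with `cluster`, `pc1_var`, `null_max`,
#'   `pc1_variance_ratio`, `significant`.
#' @export
discreteness_test <- function(mat, assignment, genes = NULL, n_rand = 1000,
                              seed = 1) {
  set.seed(seed)
  X <- mat$counts
  if (!is.null(genes)) X <- X[, mat$gene_ids %in% genes, drop = FALSE]
  out <- data.frame()
  for (k in seq_len(assignment$n_clusters)) {
    idx <- which(assignment$cluster == k)
    if (length(idx) < 3) next
    Xc <- X[idx, , drop = FALSE]
    obs <- top_pc_var(Xc)
    if (obs < 1e-12) {
      out <- rbind(out, data.frame(cluster = k, pc1_var = 0, null_max = 0,
                                   pc1_variance_ratio = 0, significant = FALSE))
      next
    }
    null_max <- 0
    for (r in seq_len(n_rand)) {
      Xp <- apply(Xc, 2, sample)
      null_max <- max(null_max, top_pc_var(Xp))
    }
    ratio <- obs / null_max
    out <- rbind(out, data.frame(cluster = k, pc1_var = obs,
                                 null_max = null_max,
                                 pc1_variance_ratio = ratio,
                                 significant = ratio > 1))
  }
  out
}

# Largest eigenvalue of the sample covariance, via the n x n Gram matrix.
top_pc_var <- function(X) {
  Xc <- scale(X, scale = FALSE)
  n <- nrow(Xc)
  ev <- eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE, only.values = TRUE)
  max(ev$values[1], 0)
}
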