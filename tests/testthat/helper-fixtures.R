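# Shared fixtures, built in code (no binary files).  The medium lineage
# dataset and its derived objects are computed once per test run.

small_counts <- function() {
  m <- matrix(c(5L, 0L, 3L,
                1L, 2L, 0L,
                0L, 4L, 7L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:3)))
  m
}

# cached medium-size planted lineage world (288 cells, 300 genes)
lineage_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_lineage_dataset(lineage_config(), seed = 101)
      ln <- lognorm(subsample_umis(filter_cells_min_depth(sim$mat),
                                   seed = 102))
      asgn <- cluster_assignment(match(sim$labels, paste0("C", 0:8)),
                                 names(sim$labels))
      cache <<- list(sim = sim, lognorm = ln, truth = asgn)
    }
    cache
  }
})

# cached triplet sweep + tree on the truth labels
lineage_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- lineage_world()
      trs <- statefate:::all_triplet_results(w$lognorm, w$truth)
      tree <- assemble_tree(trs, w$truth$n_clusters)
      cache <<- list(triplets = trs, tree = tree)
    }
    cache
  }
})

# cached small planted GRN + ensemble
grn_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_grn_instance(8, target_n_states = 3, seed = 401)
      sys <- fixed_point_constraints(g$states)
      ens <- sample_couplings(sys, n_samples = 60, seed = 402)
      cache <<- list(grn = g, system = sys, ensemble = ens)
    }
    cache
  }
})

# dense 2^N ensemble transition matrix (oracle for lazy propagation)
dense_kernel <- function(ensemble, clamp_idx = integer(0)) {
  N <- dim(ensemble$samples)[1]; k <- dim(ensemble$samples)[3]
  phi0 <- ensemble$config$phi0
  B <- as.matrix(expand.grid(rep(list(0:1), N)))
  if (length(clamp_idx)) B[, clamp_idx] <- 1
  Tm <- matrix(0, 2^N, 2^N)
  for (q in seq_len(k)) {
    nxt <- (B %*% t(ensemble$samples[, , q]) - phi0 >= 0) + 0
    if (length(clamp_idx)) nxt[, clamp_idx] <- 1
    idx <- as.numeric(nxt %*% 2^(0:(N - 1))) + 1
    for (a in seq_len(2^N)) Tm[idx[a], a] <- Tm[idx[a], a] + 1 / k
  }
  Tm
}

dist_to_vector <- function(d, N) {
  v <- numeric(2^N)
  for (w in seq_along(d$probs)) {
    bits <- as.integer(strsplit(names(d$probs)[w], "")[[1]])
    v[sum(bits * 2^(0:(N - 1))) + 1] <- d$probs[w]
  }
  v
}

# draw lognormal-ish log2 expression for a 3-cluster triplet
triplet_expr <- function(means, n_per = 30, sd = 0.5) {
  list(values = rnorm(3 * n_per, rep(means, each = n_per), sd),
       groups = rep(1:3, each = n_per))
}
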