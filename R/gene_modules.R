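#' Direct triplets of a lineage tree
#'
#' A triplet of clusters is "direct" when its intermediate member is
#' adjacent in the tree to both others, so no cell state is skipped along
#' any pairwise path.  Returned as integer index triples with the center
#' identified.
#'
#' @param tree a [assemble_tree()] result.
#' @export
direct_triplets <- function(tree) {
  n <- length(tree$nodes)
  adj <- lapply(seq_len(n), function(v)
    c(tree$edges[tree$edges[, 1] == v, 2], tree$edges[tree$edges[, 2] == v, 1]))
  out <- list()
  for (m in seq_len(n)) {
    nb <- adj[[m]]
    if (length(nb) < 2) next
    for (pair in utils::combn(sort(nb), 2, simplify = FALSE))
      out[[length(out) + 1]] <- list(members = sort(c(pair, m)), center = m)
  }
  out
}

#' Genes supported by direct triplets only
#'
#' Keeps genes that are high-probability marker or transition genes in at
#' least one direct triplet of the tree; genes supported only by indirect
#' triplets (where a state is skipped) are removed.
#'
#' @param triplet_results named list of [triplet_result()]s with integer
#'   `cluster_ids`.
#' @param tree a [assemble_tree()] result over the same clusters.
#' @param gene_cutoff classification cutoff (default 0.5).
#' @return character vector of gene ids.
#' @export
direct_triplet_genes <- function(triplet_results, tree, gene_cutoff = 0.5) {
  calls <- local_calls(triplet_results, tree, gene_cutoff)
  rownames(calls$calls)[rowSums(!is.na(calls$calls)) > 0]
}

# Local binarization calls from direct triplets: a marker gene for cluster
# k is 1 in k and 0 in the other two members; a transition gene low in k is
# 0 in k and 1 in the other two.  Only direct triplets whose inferred
# topology agrees with the tree (the center wins the topology posterior)
# contribute: gene classes are defined conditional on the topology, so a
# disagreeing triplet's calls are not interpretable on the tree.
# Conflicting calls raise an error naming the triplets involved
# (on_conflict = "error"), or drop the offending genes with a warning
# (on_conflict = "drop").
local_calls <- function(triplet_results, tree, gene_cutoff = 0.5,
                        on_conflict = c("error", "drop")) {
  on_conflict <- match.arg(on_conflict)
  dts <- direct_triplets(tree)
  n_states <- length(tree$nodes)
  gene_ids <- triplet_results[[1]]$gene_posteriors$gene_id
  calls <- matrix(NA_integer_, length(gene_ids), n_states,
                  dimnames = list(gene_ids, NULL))
  call_src <- matrix("", length(gene_ids), n_states)
  conflicted <- character(0)
  for (dt in dts) {
    key <- paste(dt$members, collapse = "_")
    tr <- triplet_results[[key]]
    if (is.null(tr)) next
    if (dt$members[which.max(tr$p_topology)] != dt$center) next
    cls <- classify_genes(tr, gene_cutoff)
    hit <- cls$class != "neither"
    for (i in which(hit)) {
      g <- cls$gene_id[i]
      k <- as.integer(cls$cluster[i])
      vals <- if (cls$class[i] == "marker") {
        stats::setNames(c(1L, 0L, 0L), c(k, setdiff(dt$members, k)))
      } else {
        stats::setNames(c(0L, 1L, 1L), c(k, setdiff(dt$members, k)))
      }
      for (s in names(vals)) {
        si <- as.integer(s)
        v <- vals[[s]]
        if (!is.na(calls[g, si]) && calls[g, si] != v) {
          if (on_conflict == "error")
            abort_sf(sprintf(
              "conflicting local calls for gene %s in state %d (triplets %s vs %s)",
              g, si, call_src[match(g, gene_ids), si], key),
              "statefate_conflict_error")
          conflicted <- union(conflicted, g)
          next
        }
        calls[g, si] <- v
        call_src[match(g, gene_ids), si] <- key
      }
    }
  }
  if (length(conflicted)) {
    warning("dropping gene(s) with conflicting local calls: ",
            paste(conflicted, collapse = ", "))
    calls[conflicted, ] <- NA_integer_
  }
  list(calls = calls, triplets = dts)
}

#' Binarize one gene (or gene group) across all states
#'
#' Locally-called states keep their calls; every remaining state gets 1
#' when the (group) mean log expression there is within `tolerance`
#' (relatively) of — or higher than — the lower of the locally-high state
#' means, i.e. `mean >= (1 - tolerance) * min(high means)`, inclusive at
#' the boundary.  Three-level genes resolve naturally: medium and high
#' both clear the threshold and map to 1.
#'
#' @param local_calls integer vector over states with entries 0/1/NA (NA =
#'   no local call); at least one 1 required.
#' @param state_means mean log expression per state for the gene (or its
#'   local-pattern group).
#' @param tolerance comparability tolerance (default 0.10).
#' @return integer 0/1 vector over states.
#' @export
binarize_gene <- function(local_calls, state_means, tolerance = 0.10) {
  stopifnot(length(local_calls) == length(state_means))
  if (!any(local_calls == 1L, na.rm = TRUE))
    abort_sf("gene has no locally-high call; cannot set reference level",
             "statefate_precondition_error")
  ref <- min(state_means[which(local_calls == 1L)])
  out <- local_calls
  fill <- is.na(out)
  out[fill] <- as.integer(state_means[fill] >= (1 - tolerance) * ref)
  out
}

# Per-state mean lognorm expression, genes x states.
state_mean_profiles <- function(mat, assignment) {
  K <- assignment$n_clusters
  vapply(seq_len(K), function(k)
    colMeans(mat$counts[assignment$cluster == k, , drop = FALSE]),
    numeric(ncol(mat$counts)))
}

#' Group binary patterns into gene modules
#'
#' One module per distinct binary pattern; the representative name is the
#' lexicographically first member gene unless a curated name is supplied.
#' All-zero patterns (genes expressed nowhere) are dropped with a warning.
#'
#' @param patterns binary matrix, genes in rows, states in columns.
#' @param curated_names optional named character vector mapping a member
#'   gene to a module name.
#' @return a [binary_state_matrix()].
#' @export
group_modules <- function(patterns, curated_names = NULL) {
  if (nrow(patterns) == 0)
    abort_sf("no binary patterns supplied", "statefate_empty_result")
  zero <- rowSums(patterns) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero pattern gene(s) dropped (expressed nowhere)")
    patterns <- patterns[!zero, , drop = FALSE]
    if (nrow(patterns) == 0)
      abort_sf("all patterns were zero", "statefate_empty_result")
  }
  key <- apply(patterns, 1, paste, collapse = "")
  groups <- split(rownames(patterns), key)
  members <- lapply(groups, sort)
  reps <- unname(vapply(members, `[[`, "", 1))
  if (!is.null(curated_names)) {
    for (i in seq_along(members)) {
      hit <- intersect(names(curated_names), members[[i]])
      if (length(hit)) reps[i] <- curated_names[[hit[1]]]
    }
  }
  vals <- do.call(rbind, lapply(names(groups), function(k)
    as.integer(strsplit(k, "")[[1]])))
  ord <- order(reps)
  binary_state_matrix(vals[ord, , drop = FALSE], module_ids = reps[ord],
                      member_genes = stats::setNames(members[ord], reps[ord]))
}

#' Build TF gene modules from a converged lineage analysis
#'
#' Restricts to genes supported by direct triplets, applies local
#' binarization per triplet, groups genes with identical local patterns,
#' fills the remaining states by the threshold rule on the group's mean
#' expression profile, and merges identical final patterns into modules.
#'
#' @param mat lognorm-layer [expression_matrix()].
#' @param assignment converged [cluster_assignment()].
#' @param triplet_results named list of [triplet_result()]s.
#' @param tree the [assemble_tree()] result.
#' @param gene_cutoff classification cutoff (default 0.5).
#' @param tolerance threshold tolerance (default 0.10).
#' @param curated_names optional module renaming, see [group_modules()].
#' @param on_conflict `"error"` (default) raises on genes whose direct
#'   triplets give contradictory local calls; `"drop"` removes them with a
#'   warning (used by the pipeline, where occasional spurious calls on
#'   noisy data should not abort the run).
#' @return a [binary_state_matrix()].
#' @export
build_modules <- function(mat, assignment, triplet_results, tree,
                          gene_cutoff = 0.5, tolerance = 0.10,
                          curated_names = NULL,
                          on_conflict = c("error", "drop")) {
  lc <- local_calls(triplet_results, tree, gene_cutoff,
                    on_conflict = match.arg(on_conflict))
  calls <- lc$calls
  keep <- rowSums(!is.na(calls)) > 0
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) == 0)
    abort_sf("no direct-triplet genes to binarize", "statefate_empty_result")
  sm <- state_mean_profiles(mat, assignment)
  sm <- sm[rownames(calls), , drop = FALSE]
  sig <- apply(calls, 1, paste, collapse = ".")
  patterns <- matrix(0L, nrow(calls), ncol(calls),
                     dimnames = list(rownames(calls), NULL))
  for (grp in split(seq_len(nrow(calls)), sig)) {
    group_mean <- colMeans(sm[grp, , drop = FALSE])
    pat <- binarize_gene(calls[grp[1], ], group_mean, tolerance)
    patterns[grp, ] <- matrix(pat, length(grp), ncol(calls), byrow = TRUE)
  }
  group_modules(patterns, curated_names)
}

#' Append signalling-pathway modules
#'
#' Per pathway, averages the member genes' per-state mean expression and
#' binarizes the profile with the same threshold rule, anchored at the
#' pathway's highest state mean (signalling pathways carry no triplet
#' calls).  Rows are appended under the pathway name even when the pattern
#' duplicates an existing module; such duplicates are recorded as aliases.
#'
#' @param states a [binary_state_matrix()] of TF modules.
#' @param mat lognorm-layer [expression_matrix()].
#' @param assignment the converged [cluster_assignment()].
#' @param pathways named list of gene-id vectors (e.g. LIF/BMP/WNT/FGF).
#' @param tolerance threshold tolerance (default 0.10).
#' @return the extended [binary_state_matrix()].
#' @export
signaling_modules <- function(states, mat, assignment, pathways,
                              tolerance = 0.10) {
  sm <- state_mean_profiles(mat, assignment)
  vals <- states$values
  members <- states$member_genes
  aliases <- states$aliases
  for (pw in names(pathways)) {
    genes <- intersect(pathways[[pw]], mat$gene_ids)
    if (length(genes) == 0) {
      warning("pathway ", pw, " has no detected genes; row omitted")
      next
    }
    profile <- colMeans(sm[genes, , drop = FALSE])
    ref <- max(profile)
    pat <- as.integer(profile >= (1 - tolerance) * ref)
    name <- paste0("[", pw, "]")
    dup <- which(apply(vals, 1, function(v) all(v == pat)))
    if (length(dup))
      aliases <- c(aliases, stats::setNames(rownames(vals)[dup[1]], name))
    vals <- rbind(vals, stats::setNames(list(pat), name)[[1]])
    rownames(vals)[nrow(vals)] <- name
    members[[name]] <- genes
  }
  binary_state_matrix(vals, member_genes = members, aliases = aliases)
}
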