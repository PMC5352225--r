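#' One synchronous network update with optional clamping
#'
#' Applies m_i <- H(sum_j J_ij s_j - phi0) to every unclamped module, where
#' s is the current level vector; clamped modules keep their exogenous
#' level (1 for a signal clamp, 1 + delta_s for overexpression).  The clamp
#' level enters the drive on other modules but the clamped module itself is
#' not updated.
#'
#' @param J coupling matrix.
#' @param state current level vector (binary except clamped entries).
#' @param clamps named or index-addressed numeric vector of clamp levels
#'   (`NULL` for none).
#' @param config a [model_config()].
#' @return the next level vector.
#' @export
step_state <- function(J, state, clamps = NULL, config = model_config()) {
  s <- as.numeric(state)
  idx <- clamp_indices(clamps, rownames(J) %||% names(state), length(s))
  if (length(idx)) s[idx] <- clamps
  drive <- as.numeric(J %*% s)
  nxt <- as.numeric(drive - config$phi0 >= 0)
  if (length(idx)) nxt[idx] <- s[idx]
  nxt
}

# Resolve a clamp vector (named by module name or by integer index) to
# integer module indices.
clamp_indices <- function(clamps, mod_names, n) {
  if (is.null(clamps) || length(clamps) == 0) return(integer(0))
  nm <- names(clamps)
  if (is.null(nm) || !all(nzchar(nm)))
    abort_sf("clamps must be named by module name or index", "statefate_key_error")
  idx <- if (!is.null(mod_names) && all(nm %in% mod_names)) {
    match(nm, mod_names)
  } else {
    suppressWarnings(as.integer(nm))
  }
  if (anyNA(idx) || any(idx < 1) || any(idx > n))
    abort_sf(paste0("unknown clamp module(s): ", paste(nm, collapse = ", ")),
             "statefate_key_error")
  idx
}

#' Overexpression scan over an ensemble
#'
#' Clamps `module` at level 1 + delta_s in every sampled model, iterates
#' the deterministic dynamics from `initial_state` until the state repeats
#' (cycle detection) or `max_steps`, and reports per delta_s the fraction
#' of models in which `target` has shut off.  On a limit cycle the target
#' counts as down only when it is 0 on every cycle state.
#'
#' @param ensemble a [sample_couplings()] ensemble.
#' @param initial_state binary vector; must be a fixed point of every
#'   sampled model and express `module` (= 1).
#' @param module clamped (overexpressed) module, name or index.
#' @param target read-out module, name or index.
#' @param delta_grid overexpression increments (default 0 to 2 by 0.1).
#' @param max_steps iteration cap per trajectory (default 200).
#' @return data.frame with `delta_s`, `fraction_down`, `n_models`.
#' @export
overexpression_scan <- function(ensemble, initial_state, module, target,
                                delta_grid = seq(0, 2, by = 0.1),
                                max_steps = 200) {
  mods <- rownames(ensemble$states)
  mi <- if (is.character(module)) match(module, mods) else module
  ti <- if (is.character(target)) match(target, mods) else target
  if (is.na(mi) || is.na(ti)) abort_sf("unknown module", "statefate_key_error")
  if (initial_state[mi] != 1)
    abort_sf("overexpressed module must be expressed in the initial state",
             "statefate_precondition_error")
  k <- dim(ensemble$samples)[3]
  cfg <- ensemble$config
  for (q in seq_len(k)) {
    if (!verify_fixed_point(ensemble$samples[, , q], initial_state, cfg))
      abort_sf(sprintf("initial state is not a fixed point of sampled model %d", q),
               "statefate_precondition_error")
  }
  out <- data.frame(delta_s = delta_grid, fraction_down = NA_real_,
                    n_models = k)
  for (d in seq_along(delta_grid)) {
    clamp <- stats::setNames(1 + delta_grid[d], NULL)
    down <- logical(k)
    for (q in seq_len(k)) {
      J <- ensemble$samples[, , q]
      s <- as.numeric(initial_state)
      s[mi] <- 1 + delta_grid[d]
      seen <- character(0)
      traj <- list()
      for (step in seq_len(max_steps)) {
        key <- paste(s, collapse = ",")
        hit <- match(key, seen)
        if (!is.na(hit)) {
          cycle <- traj[hit:length(traj)]
          down[q] <- all(vapply(cycle, function(v) v[ti] == 0, TRUE))
          break
        }
        seen <- c(seen, key)
        traj[[length(traj) + 1]] <- s
        drive <- as.numeric(J %*% s)
        nxt <- as.numeric(drive - cfg$phi0 >= 0)
        nxt[mi] <- 1 + delta_grid[d]
        s <- nxt
      }
    }
    out$fraction_down[d] <- mean(down)
  }
  out
}

#' Ensemble Markov dynamics over network states
#'
#' Propagates a probability distribution over binary network states under
#' the ensemble-averaged one-step transition kernel: each sampled model
#' contributes weight 1/n_samples to the image of each support state, with
#' clamped modules held at 1.  The full 2^N transition matrix is never
#' materialized; the sparse distribution is propagated lazily over the
#' reachable support, which is mathematically identical on that support.
#' States whose mass falls below `prob_floor` are truncated and the
#' distribution renormalized (truncated mass is reported).  Propagation
#' stops early once the distribution is exactly stationary.
#'
#' @param ensemble a [sample_couplings()] ensemble.
#' @param initial_state binary vector (the starting cell state).
#' @param clamps character vector or indices of modules clamped at 1
#'   (signal addition), or `NULL`.
#' @param n_steps horizon (default 1000).
#' @param prob_floor truncation threshold (default 1e-8).
#' @param support_cap maximum support size before aborting (default 1e5).
#' @return list of class `StateDistribution`: `probs` (named by state
#'   bitstring), `step`, `truncated_mass`.
#' @export
ensemble_markov <- function(ensemble, initial_state, clamps = NULL,
                            n_steps = 1000, prob_floor = 1e-8,
                            support_cap = 1e5) {
  mods <- rownames(ensemble$states)
  ci <- if (is.character(clamps)) match(clamps, mods) else as.integer(clamps)
  if (anyNA(ci)) abort_sf("unknown clamp module", "statefate_key_error")
  k <- dim(ensemble$samples)[3]
  N <- dim(ensemble$samples)[1]
  cfg <- ensemble$config
  s0 <- as.numeric(initial_state)
  if (length(ci)) s0[ci] <- 1
  # states are encoded as integers (exact in doubles for N <= 50)
  if (N > 30)
    abort_sf("lazy propagation supports up to 30 modules", "statefate_resource_error")
  pow2 <- 2^(seq_len(N) - 1)
  Jflat <- as.numeric(ensemble$samples)
  codes <- sum(s0 * pow2); mass <- 1       # sparse distribution: parallel vectors
  truncated <- 0
  update_mask <- !(seq_len(N) %in% ci)
  step_done <- 0
  decode <- function(code) as.numeric(intToBits(as.integer(code)))[seq_len(N)]
  for (step in seq_len(n_steps)) {
    stepped <- .cpp_markov_step(Jflat, N, k, codes, mass,
                                as.integer(ci - 1L), cfg$phi0)
    ord <- order(stepped$codes)
    new_codes <- stepped$codes[ord]; new_mass <- stepped$mass[ord]
    drop <- new_mass < prob_floor
    truncated <- truncated + sum(new_mass[drop])
    new_codes <- new_codes[!drop]; new_mass <- new_mass[!drop] / sum(new_mass[!drop])
    if (length(new_codes) > support_cap)
      abort_sf("state support exceeded cap; raise prob_floor",
               "statefate_resource_error")
    step_done <- step
    same <- length(new_codes) == length(codes) && all(new_codes == codes) &&
      max(abs(new_mass - mass)) < 1e-15
    codes <- new_codes; mass <- new_mass
    if (same) break                      # deterministic kernel: stationary
  }
  keys <- vapply(codes, function(cd)
    paste(as.integer(intToBits(as.integer(cd)))[seq_len(N)], collapse = ""), "")
  structure(list(probs = stats::setNames(mass, keys), step = step_done,
                 horizon = n_steps, truncated_mass = truncated),
            class = "StateDistribution")
}

#' Attribute distribution mass to named cell states
#'
#' Exact-match mass per column of the binary state matrix (with clamped
#' modules ignored if `ignore` is given); residual mass is reported as
#' `other`.
#'
#' @param dist a [ensemble_markov()] result.
#' @param states a [binary_state_matrix()].
#' @param ignore module names/indices excluded from matching (e.g. clamped
#'   signal modules).
#' @return named numeric vector over state labels plus `other`; sums to 1.
#' @export
classify_distribution <- function(dist, states, ignore = NULL) {
  v <- states$values
  ig <- if (is.character(ignore)) match(ignore, rownames(v)) else as.integer(ignore)
  keep <- setdiff(seq_len(nrow(v)), ig)
  out <- stats::setNames(numeric(ncol(v) + 1), c(colnames(v), "other"))
  for (key in names(dist$probs)) {
    s <- as.integer(strsplit(key, "")[[1]])
    hit <- which(colSums(v[keep, , drop = FALSE] != s[keep]) == 0)
    lab <- if (length(hit)) colnames(v)[hit[1]] else "other"
    out[lab] <- out[lab] + dist$probs[[key]]
  }
  out
}
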