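#' Threshold-network model configuration
#'
#' Parameters of the hard-threshold (Heaviside) network: critical drive
#' phi0, coupling bound, and the slack used to encode strict inequalities
#' in the LP.  Module lifetime tau and basal rate r0 are fixed at 1 and 0
#' (a rescaling, not a restriction); the nonlinearity is the hard-threshold
#' limit.
#'
#' @param phi0 critical drive (default 0.1).
#' @param j_bound bound on |J_ij| (default 1).
#' @param margin strict-inequality slack epsilon (default 1e-6).
#' @return list of class `ModelConfig`.
#' @export
model_config <- function(phi0 = 0.1, j_bound = 1, margin = 1e-6) {
  if (j_bound <= 0 || margin <= 0 || !is.finite(phi0))
    abort_sf("invalid model config", "statefate_validation_error")
  structure(list(phi0 = phi0, j_bound = j_bound, margin = margin,
                 tau = 1, r0 = 0, mu = Inf),
            class = "ModelConfig")
}

# Collapse duplicate module rows (signalling aliases) to one modeling
# variable; returns the reduced matrix plus the expansion map.
collapse_aliases <- function(states) {
  v <- if (inherits(states, "BinaryStateMatrix")) states$values else as.matrix(states)
  key <- apply(v, 1, paste, collapse = "")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(values = v[first, , drop = FALSE], map = map,
       dropped = rownames(v)[!first])
}

#' Fixed-point inequality system for a binary state matrix
#'
#' For every state alpha and module i: if m_i^alpha = 1 the drive
#' sum_j J_ij m_j^alpha must be >= phi0 + margin, else <= phi0 - margin.
#' This yields N x S inequalities over the N^2 couplings (for instance, 29
#' modules and 9 states give 261 inequalities over 841 parameters).
#'
#' @param states a [binary_state_matrix()] (or plain binary modules x
#'   states matrix) with no duplicate module rows (collapse aliases first).
#' @param config a [model_config()].
#' @return list of class `ConstraintSystem` with sparse `A`
#'   (inequalities x N^2, column-major J indexing), `rhs`, `sense`,
#'   `n_modules`, `n_states`.
#' @export
fixed_point_constraints <- function(states, config = model_config()) {
  v <- if (inherits(states, "BinaryStateMatrix")) states$values else as.matrix(states)
  if (!all(v %in% c(0, 1)))
    abort_sf("state matrix entries must be 0/1", "statefate_validation_error")
  # Duplicate module rows are accepted: every inequality touches a single
  # row of J, so duplicates only replicate a row's constraint set.  Named
  # signalling aliases should still be collapsed upstream (see
  # collapse_aliases) because their couplings are not separately
  # identifiable.
  N <- nrow(v); S <- ncol(v)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  sense <- character(N * S); rhs <- numeric(N * S)
  row <- 0L
  for (alpha in seq_len(S)) {
    on <- which(v[, alpha] == 1)
    for (i in seq_len(N)) {
      row <- row + 1L
      if (length(on)) {
        ii <- c(ii, rep(row, length(on)))
        jj <- c(jj, (on - 1L) * N + i)       # J[i, j] column-major
        xx <- c(xx, rep(1, length(on)))
      }
      if (v[i, alpha] == 1) {
        sense[row] <- ">="; rhs[row] <- config$phi0 + config$margin
      } else {
        sense[row] <- "<="; rhs[row] <- config$phi0 - config$margin
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N * S, N * N))
  structure(list(A = A, rhs = rhs, sense = sense, n_modules = N,
                 n_states = S, config = config, states = v),
            class = "ConstraintSystem")
}

#' @export
print.ConstraintSystem <- function(x, ...) {
  cat(sprintf("ConstraintSystem: %d inequalities over %d couplings (%d modules, %d states)\n",
              nrow(x$A), ncol(x$A), x$n_modules, x$n_states))
  invisible(x)
}

# Dense <=-form base of the LP (constraints + box bounds), in the shifted
# variables x = J + j_bound >= 0; built once per ensemble.
lp_base <- function(system) {
  jb <- system$config$j_bound
  nv <- ncol(system$A)
  A <- as.matrix(system$A)
  sgn <- ifelse(system$sense == "<=", 1, -1)
  A_le <- rbind(A * sgn, diag(nv))
  b_le <- c((system$rhs + jb * rowSums(A)) * sgn, rep(2 * jb, nv))
  list(A_le = A_le, b_le = b_le, jb = jb, nv = nv)
}

# Solve max c'J  s.t.  system constraints, |J| <= j_bound, and optionally
# the cut sum(a * J) <= 0.
solve_coupling_lp <- function(system, objective, cut = FALSE, base = NULL) {
  if (is.null(base)) base <- lp_base(system)
  A_le <- base$A_le; b_le <- base$b_le
  if (cut) {
    A_le <- rbind(A_le, objective)
    b_le <- c(b_le, sum(objective) * base$jb)  # sum(a*J) <= 0, shifted
  }
  res <- .cpp_simplex(A_le, b_le, objective)
  if (res$status != 0) return(list(status = res$status))
  list(status = 0,
       J = matrix(res$x - base$jb, system$n_modules, system$n_modules))
}

#' Sample an ensemble of coupling matrices
#'
#' Repeatedly draws binary objective coefficients a_ij ~ Bernoulli(0.5) and
#' solves the linear program maximising U = sum a_ij J_ij subject to the
#' fixed-point inequalities, |J_ij| <= j_bound, and the fictitious cut
#' U <= 0 through the origin, which exposes an interior face of the
#' solution polytope so the sampler is not confined to its outer surface.
#' Draws whose cut excludes the whole polytope are redrawn (up to
#' `max_retries` per sample), so the ensemble always has `n_samples`
#' members.
#'
#' @param system a [fixed_point_constraints()] system.
#' @param n_samples number of coupling matrices (default 10,000).
#' @param seed RNG seed; the ensemble is reproducible given the seed.
#' @param max_retries redraw budget per sample (default 50).
#' @return list of class `CouplingEnsemble`: `samples` (N x N x n array),
#'   `config`, `states`, `retries`.
#' @export
sample_couplings <- function(system, n_samples = 10000, seed = 1,
                             max_retries = 50) {
  stopifnot(inherits(system, "ConstraintSystem"))
  N <- system$n_modules
  base <- lp_base(system)
  feas <- solve_coupling_lp(system, rep(0, N * N), cut = FALSE, base = base)
  if (feas$status != 0) {
    bad <- infeasible_modules(system)
    abort_sf(paste0("fixed-point system infeasible; irreducible infeasible module row(s): ",
                    paste(bad, collapse = ", ")),
             "statefate_infeasible_error")
  }
  set.seed(seed)
  samples <- array(0, c(N, N, n_samples))
  retries <- integer(n_samples)
  for (s in seq_len(n_samples)) {
    for (r in 0:max_retries) {
      a <- stats::rbinom(N * N, 1, 0.5)
      sol <- solve_coupling_lp(system, a, cut = TRUE, base = base)
      if (sol$status == 0) { samples[, , s] <- sol$J; retries[s] <- r; break }
      if (r == max_retries)
        abort_sf(sprintf("sample %d: %d cut redraws exhausted", s, max_retries),
                 "statefate_sampling_error")
    }
  }
  structure(list(samples = samples, config = system$config,
                 states = system$states, retries = retries, seed = seed),
            class = "CouplingEnsemble")
}

# Rows of J are constrained independently (each inequality touches one row
# only), so infeasibility can be localized: solve the per-module row LP and
# report the modules whose row system is infeasible.
infeasible_modules <- function(system) {
  N <- system$n_modules; S <- system$n_states
  v <- system$states
  bad <- integer(0)
  for (i in seq_len(N)) {
    # row-i system: variables J[i, 1..N]
    A <- t(v)                               # S x N, row alpha = m^alpha
    sgn <- ifelse(v[i, ] == 1, -1, 1)       # >= rows flipped to <=
    rhs <- ifelse(v[i, ] == 1,
                  system$config$phi0 + system$config$margin,
                  system$config$phi0 - system$config$margin)
    jb <- system$config$j_bound
    A_le <- A * sgn
    b_le <- (rhs + jb * rowSums(A)) * sgn
    A_le <- rbind(A_le, diag(N)); b_le <- c(b_le, rep(2 * jb, N))
    if (.cpp_simplex(A_le, b_le, rep(0, N))$status != 0) bad <- c(bad, i)
  }
  if (length(bad) == 0) bad <- "(coupled infeasibility)"
  bad
}

#' @export
print.CouplingEnsemble <- function(x, ...) {
  cat(sprintf("CouplingEnsemble: %d samples of %dx%d couplings (phi0 = %g)\n",
              dim(x$samples)[3], dim(x$samples)[1], dim(x$samples)[2],
              x$config$phi0))
  invisible(x)
}

#' Is a state a fixed point of a coupling matrix?
#'
#' True when one synchronous Heaviside update m_i <- H(sum_j J_ij m_j -
#' phi0) returns the state unchanged (H(x) = 1 for x >= 0).
#'
#' @param J coupling matrix.
#' @param state binary vector.
#' @param config a [model_config()].
#' @export
verify_fixed_point <- function(J, state, config = model_config()) {
  all(as.integer(as.numeric(J %*% state) - config$phi0 >= 0) == as.integer(state))
}

#' Elementwise ensemble summary
#'
#' Mean, coefficient of variation (sd / |mean|; reported as `NA` where the
#' mean is 0) and the fractions of samples in which each coupling is
#' negative, zero (within the LP margin) or positive.
#'
#' @param ensemble a [sample_couplings()] ensemble with >= 2 samples.
#' @return list with matrices `mean`, `cv`, `frac_neg`, `frac_zero`,
#'   `frac_pos`.
#' @export
ensemble_summary <- function(ensemble) {
  k <- dim(ensemble$samples)[3]
  if (is.na(k) || k < 2)
    abort_sf("ensemble must have >= 2 samples", "statefate_precondition_error")
  m <- apply(ensemble$samples, c(1, 2), mean)
  s <- apply(ensemble$samples, c(1, 2), stats::sd)
  cv <- s / abs(m)
  cv[m == 0] <- NA
  eps <- ensemble$config$margin
  list(mean = m, cv = cv,
       frac_neg = apply(ensemble$samples < -eps, c(1, 2), mean),
       frac_zero = apply(abs(ensemble$samples) <= eps, c(1, 2), mean),
       frac_pos = apply(ensemble$samples > eps, c(1, 2), mean))
}

#' Fraction of samples with a given coupling sign pattern
#'
#' `a_to_b` refers to the coupling through which module `a` drives module
#' `b`, i.e. the entry J\[b, a\].  `both_negative` / `both_positive` test
#' the two directed couplings between `a` and `b` jointly (e.g. mutual
#' inhibition).
#'
#' @param ensemble a [sample_couplings()] ensemble.
#' @param a,b module names or indices.
#' @param sense one of `both_negative`, `both_positive`, `a_to_b_negative`,
#'   `a_to_b_positive`, `b_to_a_negative`, `b_to_a_positive`.
#' @return fraction in \[0, 1\].
#' @export
mutual_sign_fraction <- function(ensemble, a, b,
                                 sense = c("both_negative", "both_positive",
                                           "a_to_b_negative", "a_to_b_positive",
                                           "b_to_a_negative", "b_to_a_positive")) {
  sense <- match.arg(sense)
  mods <- rownames(ensemble$states)
  ai <- if (is.character(a)) match(a, mods) else a
  bi <- if (is.character(b)) match(b, mods) else b
  if (is.na(ai) || is.na(bi)) abort_sf("unknown module", "statefate_key_error")
  j_ab <- ensemble$samples[bi, ai, ]     # a drives b
  j_ba <- ensemble$samples[ai, bi, ]     # b drives a
  mean(switch(sense,
              both_negative = j_ab < 0 & j_ba < 0,
              both_positive = j_ab > 0 & j_ba > 0,
              a_to_b_negative = j_ab < 0,
              a_to_b_positive = j_ab > 0,
              b_to_a_negative = j_ba < 0,
              b_to_a_positive = j_ba > 0))
}

#' Export a constraint system as sparse triplet CSV
#'
#' @param system a [fixed_point_constraints()] system.
#' @param path CSV path (columns row, col, value, plus sense/rhs table
#'   appended as `<stem>_rhs.csv`).
#' @export
write_constraints <- function(system, path) {
  tr <- Matrix::summary(system$A)
  utils::write.csv(data.frame(row = tr$i, col = tr$j, value = tr$x),
                   path, row.names = FALSE)
  utils::write.csv(data.frame(row = seq_along(system$rhs),
                              sense = system$sense, rhs = system$rhs),
                   paste0(sub("\\.csv$", "", path), "_rhs.csv"),
                   row.names = FALSE)
  invisible(path)
}
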