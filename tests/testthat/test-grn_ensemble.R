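test_that("constraint bookkeeping matches N x S over N^2", {
  set.seed(61)
  v <- matrix(rbinom(12, 1, 0.5), 4, 3)
  sys <- fixed_point_constraints(v)
  expect_equal(nrow(sys$A), 12)
  expect_equal(ncol(sys$A), 16)
  expect_equal(sum(sys$sense == ">="), sum(v))
  # every inequality touches exactly one row of J
  for (r in seq_len(nrow(sys$A))) {
    cols <- which(sys$A[r, ] != 0)
    if (length(cols)) expect_length(unique((cols - 1) %% 4 + 1), 1)
  }
  expect_error(fixed_point_constraints(matrix(c(0, 2), 1, 2)),
               class = "statefate_validation_error")
})

test_that("single-module null-state system is trivially satisfiable", {
  sys <- fixed_point_constraints(matrix(0L, 1, 1))
  ens <- sample_couplings(sys, n_samples = 5, seed = 1)
  expect_equal(dim(ens$samples), c(1, 1, 5))
  expect_true(all(abs(ens$samples) <= 1))
})

test_that("sampled feasible region matches a grid oracle on N = 2", {
  # one module driving itself and a partner; states: (1,0) and (1,1)
  v <- rbind(c(1, 1), c(0, 1))
  cfg <- model_config(phi0 = 0.1, margin = 1e-6)
  sys <- fixed_point_constraints(v, cfg)
  ens <- sample_couplings(sys, n_samples = 200, seed = 3)
  grid <- as.matrix(expand.grid(rep(list(seq(-1, 1, 0.25)), 4)))
  ok <- apply(grid, 1, function(j) {
    J <- matrix(j, 2, 2)
    all(apply(v, 2, function(st) verify_fixed_point(J, st, cfg)))
  })
  # every grid-feasible point satisfies the system and vice versa (margin
  # excludes only boundary points)
  Agrid <- as.matrix(sys$A)
  for (r in which(ok)) {
    lhs <- as.numeric(Agrid %*% grid[r, ])
    viol <- ifelse(sys$sense == ">=", lhs < cfg$phi0 - 1e-9,
                   lhs > cfg$phi0 + 1e-9)
    expect_false(any(viol))
  }
  # all samples verify all states
  for (q in 1:200)
    expect_true(all(apply(v, 2, function(st)
      verify_fixed_point(ens$samples[, , q], st, cfg))))
})

test_that("every sampled matrix satisfies every inequality (by-construction claim)", {
  gw <- grn_world()
  k <- dim(gw$ensemble$samples)[3]
  A <- as.matrix(gw$system$A)
  for (q in seq_len(k)) {
    lhs <- as.numeric(A %*% as.numeric(gw$ensemble$samples[, , q]))
    ge <- gw$system$sense == ">="
    expect_true(all(lhs[ge] >= gw$system$rhs[ge] - 1e-7))
    expect_true(all(lhs[!ge] <= gw$system$rhs[!ge] + 1e-7))
    expect_true(all(abs(gw$ensemble$samples[, , q]) <= 1 + 1e-9))
  }
})

test_that("sampling is reproducible and samples vary", {
  gw <- grn_world()
  again <- sample_couplings(gw$system, n_samples = 60, seed = 402)
  expect_identical(gw$ensemble$samples, again$samples)
  expect_gt(max(apply(gw$ensemble$samples, c(1, 2), sd)), 0.05)
})

test_that("infeasible systems raise a localized error; XOR-like patterns are rescued by the self bit", {
  # An XOR-like pattern (module 1 on when exactly one of modules 2, 3 is
  # on) is NOT infeasible at phi0 in (0, 1]: the module's own bit enters
  # its drive, and J = e_i separates any on/off split.  The sampler must
  # therefore succeed, matching a grid oracle that finds feasible rows.
  v <- rbind(c(1, 1, 0),
             c(1, 0, 1),
             c(0, 1, 1))
  ens <- sample_couplings(fixed_point_constraints(v), 5, seed = 1)
  expect_equal(dim(ens$samples)[3], 5)
  grid <- as.matrix(expand.grid(rep(list(seq(-1, 1, 0.5)), 3)))
  drives <- grid %*% v                    # candidate row-1 drives per state
  ok <- drives[, 1] >= 0.1 & drives[, 2] >= 0.1 & drives[, 3] < 0.1
  expect_true(any(ok))
  # Genuine infeasibility: phi0 above the reachable drive.  Each state
  # turns on a single module, so the on-drive is at most j_bound = 1 < 1.5.
  ident <- diag(3)
  err <- tryCatch(
    sample_couplings(fixed_point_constraints(ident, model_config(phi0 = 1.5)),
                     5, seed = 1),
    error = function(e) e)
  expect_s3_class(err, "statefate_infeasible_error")
  expect_match(conditionMessage(err), "1, 2, 3")
  # grid oracle agrees: no row 1 satisfies J11 >= 1.5 with |J| <= 1
  drives2 <- grid %*% ident
  expect_false(any(drives2[, 1] >= 1.5 &
                     drives2[, 2] < 1.5 & drives2[, 3] < 1.5))
})

test_that("phi0 scan preserves the qualitative block sign structure", {
  # two mutually exclusive 3-module blocks; states = each block fully on.
  # For every phi0 in the scan range the within-block drives must exceed
  # the cross-block drives, so the mean within-block coupling stays above
  # the mean cross-block coupling across the whole ensemble.
  v <- cbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  within <- outer(1:6, 1:6, function(i, j) (i <= 3) == (j <= 3))
  for (phi0 in c(-2, -1, 0.1, 1, 2)) {
    sys <- fixed_point_constraints(v, model_config(phi0 = phi0))
    ens <- sample_couplings(sys, n_samples = 40, seed = 7)
    m <- apply(ens$samples, c(1, 2), mean)
    expect_gt(mean(m[within]), mean(m[!within]))
    # and the per-row drive inequalities really flip with phi0
    for (q in c(1, 40)) {
      drives <- ens$samples[, , q] %*% v
      expect_true(all(drives[v == 1] >= phi0))
      expect_true(all(drives[v == 0] < phi0))
    }
  }
})

test_that("ensemble summary reports mean, cv and a sign partition", {
  gw <- grn_world()
  s <- ensemble_summary(gw$ensemble)
  expect_equal(s$frac_neg + s$frac_zero + s$frac_pos,
               matrix(1, 8, 8), tolerance = 1e-12)
  # recompute one entry directly
  expect_equal(s$mean[2, 3], mean(gw$ensemble$samples[2, 3, ]))
  expect_equal(s$cv[2, 3], sd(gw$ensemble$samples[2, 3, ]) /
                 abs(mean(gw$ensemble$samples[2, 3, ])))
  two <- gw$ensemble
  two$samples <- two$samples[, , c(1, 1)]
  expect_true(all(ensemble_summary(two)$cv == 0, na.rm = TRUE))
  one <- gw$ensemble; one$samples <- one$samples[, , 1, drop = FALSE]
  expect_error(ensemble_summary(one), class = "statefate_precondition_error")
})

test_that("mutual sign fractions agree with direct counting", {
  gw <- grn_world()
  mods <- rownames(gw$ensemble$states)
  f_both <- mutual_sign_fraction(gw$ensemble, mods[1], mods[2], "both_negative")
  j_ab <- gw$ensemble$samples[2, 1, ]; j_ba <- gw$ensemble$samples[1, 2, ]
  expect_equal(f_both, mean(j_ab < 0 & j_ba < 0))
  f_dir <- mutual_sign_fraction(gw$ensemble, mods[1], mods[2], "a_to_b_negative")
  expect_equal(f_dir, mean(j_ab < 0))
  expect_lte(f_both, min(f_dir, mutual_sign_fraction(gw$ensemble, mods[1],
                                                     mods[2], "b_to_a_negative")))
  expect_error(mutual_sign_fraction(gw$ensemble, "nope", mods[1]),
               class = "statefate_key_error")
})

test_that("alias collapse reduces duplicate rows and remembers the map", {
  v <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  col <- statefate:::collapse_aliases(v)
  expect_equal(nrow(col$values), 2)
  expect_equal(col$map, c(1, 1, 2))
  expect_identical(col$dropped, "b")
})

test_that("constraint export writes sparse triplets", {
  gw <- grn_world()
  dir <- withr::local_tempdir()
  write_constraints(gw$system, file.path(dir, "cons.csv"))
  tr <- read.csv(file.path(dir, "cons.csv"))
  A <- as.matrix(gw$system$A)
  expect_equal(nrow(tr), sum(A != 0))
  rhs <- read.csv(file.path(dir, "cons_rhs.csv"))
  expect_equal(nrow(rhs), nrow(A))
})
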