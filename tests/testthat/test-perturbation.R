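test_that("step_state applies the Heaviside update and honors clamps", {
  # 2-module hand case: J12 = 0.5, J21 = -0.5, phi0 = 0.1, state (1,1):
  # drive1 = J11*1 + J12*1 = 0 + 0.5 -> on; drive2 = -0.5 -> off
  J <- rbind(c(0, 0.5), c(-0.5, 0))
  expect_equal(step_state(J, c(1, 1)), c(1, 0))
  # fixed point, no clamps: unchanged
  gw <- grn_world()
  st <- gw$grn$states$values[, 1]
  expect_equal(step_state(gw$grn$J_true, st,
                          config = model_config(phi0 = gw$grn$phi0)),
               as.numeric(st))
  # all-zero state is fixed for any J at phi0 = 0.1
  expect_equal(step_state(J, c(0, 0)), c(0, 0))
  # clamped module keeps its exogenous level and feeds the drive
  rownames(J) <- colnames(J) <- c("A", "B")
  out <- step_state(J, c(0, 0), clamps = c(A = 1.5))
  expect_equal(out, c(1.5, 0))           # drive on B = -0.75 < 0.1
  out2 <- step_state(rbind(c(0, 0), c(0.5, 0)) |>
                       `dimnames<-`(list(c("A", "B"), c("A", "B"))),
                     c(0, 0), clamps = c(A = 1.5))
  expect_equal(out2[2], 1)               # drive on B = 0.75 >= 0.1
  expect_error(step_state(J, c(0, 0), clamps = c(Z = 1)),
               class = "statefate_key_error")
})

test_that("one-bit flips off a planted fixed point generically move", {
  gw <- grn_world()
  moved <- 0; total <- 0
  for (alpha in seq_len(ncol(gw$grn$states$values))) {
    st <- gw$grn$states$values[, alpha]
    for (i in seq_along(st)) {
      flipped <- st; flipped[i] <- 1 - flipped[i]
      total <- total + 1
      if (!verify_fixed_point(gw$grn$J_true, flipped,
                              model_config(phi0 = gw$grn$phi0)))
        moved <- moved + 1
    }
  }
  expect_gt(moved / total, 0.5)
})

test_that("overexpression scan is 0 at delta 0 and monotone for negative coupling", {
  # constructed ensemble: module 1 self-sustains, module 2 self-sustains,
  # coupling 1 -> 2 uniformly negative with graded strength; initial state
  # (1, 1) is fixed for every model at delta = 0
  k <- 30
  samples <- array(0, c(2, 2, k))
  for (q in 1:k) {
    w <- -0.2 - 0.6 * (q - 1) / (k - 1)          # J21 in [-0.8, -0.2]
    samples[, , q] <- rbind(c(0.5, 0), c(w, 0.5 - w))
  }
  rn <- c("A", "B")
  ens <- structure(list(samples = samples, config = model_config(),
                        states = matrix(1L, 2, 1,
                                        dimnames = list(rn, "S1"))),
                   class = "CouplingEnsemble")
  scan <- overexpression_scan(ens, c(1, 1), "A", "B",
                              delta_grid = seq(0, 2, 0.25))
  expect_equal(scan$fraction_down[1], 0)
  expect_true(all(diff(scan$fraction_down) >= 0))
  expect_gt(scan$fraction_down[nrow(scan)], 0)
  # clamped module must be expressed in the initial state
  expect_error(overexpression_scan(ens, c(0, 1), "A", "B"),
               class = "statefate_precondition_error")
  # an initial state that some model does not fix is rejected
  broken <- ens
  broken$samples[1, 1, 5] <- 0             # model 5 loses A's self-drive
  expect_error(overexpression_scan(broken, c(1, 1), "A", "B"),
               class = "statefate_precondition_error")
})

test_that("lazy ensemble dynamics equals the dense transition-matrix oracle", {
  gw <- grn_world()
  N <- 8
  init <- gw$grn$states$values[, 2]
  # unclamped and clamped kernels over 100 steps
  for (cl in list(integer(0), 1L)) {
    Tm <- dense_kernel(gw$ensemble, cl)
    s0 <- init; if (length(cl)) s0[cl] <- 1
    p <- numeric(2^N); p[sum(s0 * 2^(0:(N - 1))) + 1] <- 1
    for (s in 1:100) p <- Tm %*% p
    d <- ensemble_markov(gw$ensemble, init,
                         clamps = if (length(cl)) rownames(gw$grn$states$values)[cl],
                         n_steps = 100, prob_floor = 0)
    expect_lt(max(abs(dist_to_vector(d, N) - p)), 1e-9)
  }
})

test_that("a commonly fixed initial state is stationary at every horizon", {
  gw <- grn_world()
  init <- gw$grn$states$values[, 1]
  d <- ensemble_markov(gw$ensemble, init, n_steps = 500)
  expect_length(d$probs, 1)
  expect_equal(unname(d$probs[1]), 1)
  expect_lt(d$step, 5)     # early stationarity exit
  key <- paste(init, collapse = "")
  expect_identical(names(d$probs), key)
})

test_that("probability mass is conserved up to reported truncation", {
  gw <- grn_world()
  init <- gw$grn$states$values[, 2]
  d <- ensemble_markov(gw$ensemble, init, clamps = "M2", n_steps = 40,
                       prob_floor = 1e-4)
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
  expect_gte(d$truncated_mass, 0)
})

test_that("distribution classification tallies exact matches and conserves mass", {
  gw <- grn_world()
  init <- gw$grn$states$values[, 1]
  d <- ensemble_markov(gw$ensemble, init, n_steps = 10)
  cls <- classify_distribution(d, gw$grn$states)
  expect_equal(sum(cls), 1, tolerance = 1e-12)
  expect_equal(unname(cls["S1"]), 1)
  expect_equal(unname(cls[["other"]]), 0)
  # oracle tally on a clamped run
  d2 <- ensemble_markov(gw$ensemble, gw$grn$states$values[, 2], clamps = "M1",
                        n_steps = 30, prob_floor = 0)
  cls2 <- classify_distribution(d2, gw$grn$states, ignore = "M1")
  v <- gw$grn$states$values
  manual <- numeric(ncol(v) + 1); names(manual) <- c(colnames(v), "other")
  for (w in seq_along(d2$probs)) {
    bits <- as.integer(strsplit(names(d2$probs)[w], "")[[1]])
    hit <- which(colSums(v[-1, , drop = FALSE] != bits[-1]) == 0)
    lab <- if (length(hit)) colnames(v)[hit[1]] else "other"
    manual[lab] <- manual[lab] + d2$probs[w]
  }
  expect_equal(cls2, manual, tolerance = 1e-12)
})
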