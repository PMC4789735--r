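test_that("classify_frame implements the 12 A signature logic", {
  d <- function(tt, cc, ag1, ag2) c(TT = tt, CC = cc, AG1 = ag1, AG2 = ag2)
  expect_identical(classify_frame(d(8, 9, 20, 21)), "iso-I")
  expect_identical(classify_frame(d(20, 21, 8, 9)), "iso-II")
  expect_identical(classify_frame(d(20, 20, 20, 20)), "open")
  expect_identical(classify_frame(d(8, 8, 8, 8)), "ambiguous")
  # max-aggregation: one long signature distance vetoes the stacked call
  expect_identical(classify_frame(d(8, 13, 20, 21)), "open")
  # boundary: exactly at the cutoff counts as long
  expect_identical(classify_frame(d(12, 12, 20, 20)), "open")
  expect_error(classify_frame(d(NaN, 1, 1, 1)), "finite")
})

test_that("classify_frame agrees with the exhaustive truth-table oracle", {
  set.seed(101)
  n <- 2000
  dmat <- matrix(runif(4 * n, 2, 30), n, 4,
                 dimnames = list(NULL, c("TT", "CC", "AG1", "AG2")))
  got <- classify_frame(dmat)
  want <- vapply(seq_len(n), function(i)
    oracle_classify(dmat[i, 1], dmat[i, 2], dmat[i, 3], dmat[i, 4]),
    character(1))
  expect_identical(got, want)
})

test_that("core distances are rigid-motion invariant and site-validated", {
  topo <- toy_topology(3)
  tpl <- idealized_geometry(topo, "iso-II")
  d0 <- core_distances(tpl$coords, topo)
  shifted <- sweep(tpl$coords, 2L, c(-100, 0, 0))
  expect_equal(core_distances(shifted, topo), d0, tolerance = 1e-12)
  expect_equal(core_distances(random_rigid_motion(tpl$coords, 3), topo), d0,
               tolerance = 1e-9)
  expect_error(core_distances(tpl$coords[1:10, ], topo), "cover")
})

test_that("trajectory classification preserves times and is rotation invariant", {
  topo <- toy_topology(3)
  tpls <- template_set(topo)
  s <- simulate_state_series(kinetic_model(0.2, 1, 0.2, 1), 60, dt = 1, seed = 2)
  tr <- render_trajectory(s, tpls, sigma = 0, seed = 4)
  cs <- classify_trajectory(tr, topo)
  expect_identical(cs$states, s$states)
  expect_identical(cs$times, s$times)
  rot <- tr
  for (f in seq_len(dim(tr$coords)[3L]))
    rot$coords[, , f] <- random_rigid_motion(tr$coords[, , f], seed = f)
  expect_identical(classify_trajectory(rot, topo)$states, cs$states)
})

test_that("population fractions average members and sum to one", {
  mk <- function(states) structure(list(times = seq_along(states) - 1,
                                        states = states, dt = 1,
                                        initial = states[1],
                                        member = NA, seed = NA, jumps = NULL),
                                   class = "state_series")
  single <- population_fractions(mk(rep("iso-II", 10)))
  expect_equal(unname(single$fractions),  c(0, 0, 1, 0))
  members <- list(mk(rep("iso-I", 10)), mk(c(rep("open", 5), rep("iso-II", 5))))
  pop <- population_fractions(members)
  expect_equal(sum(pop$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(pop$fractions), c(0.25, 0.5, 0.25, 0))
  # member permutation invariance
  expect_equal(population_fractions(rev(members))$fractions, pop$fractions)
  # ensemble at stationarity recovers the analytic distribution
  m <- kinetic_model(0.2, 1.2, 0.2, 1.2)
  pi_cf <- stationary_distribution(m)
  ens <- simulate_ensemble(m, n_members = 60, duration = 400, seed = 8,
                           initial_dist = pi_cf)
  pop <- population_fractions(ens)
  ok <- abs(pop$fractions[1:3] - pi_cf) <= 3 * pmax(pop$se[1:3], 1e-6)
  expect_true(all(ok))
})

test_that("transition matrix counts pairs within members and handles ambiguity", {
  mk <- function(states) structure(list(times = seq_along(states) - 1,
                                        states = states, dt = 1,
                                        initial = states[1],
                                        member = NA, seed = NA, jumps = NULL),
                                   class = "state_series")
  tm <- transition_matrix(mk(c("open", "iso-I", "iso-I", "open", "iso-II")))
  expect_equal(unname(tm$probabilities["open", ]), c(0, 0.5, 0.5))
  expect_equal(unname(tm$probabilities["iso-I", ]), c(0.5, 0.5, 0))
  expect_identical(tm$n_transitions, 4L)
  # constant series: identity row for the occupied state
  tmc <- transition_matrix(mk(rep("iso-II", 5)))
  expect_equal(unname(tmc$probabilities["iso-II", ]), c(0, 0, 1))
  expect_identical(tmc$undefined_rows, c("open", "iso-I"))
  # ambiguous frames are excluded from pairing and counted
  tma <- transition_matrix(mk(c("open", "ambiguous", "open", "open")))
  expect_identical(tma$n_excluded_ambiguous, 2L)
  expect_identical(tma$n_transitions, 1L)
  # no cross-member pairs: two constant members give no off-diagonal counts
  tm2 <- transition_matrix(list(mk(rep("iso-I", 3)), mk(rep("iso-II", 3))))
  expect_identical(sum(tm2$counts) , 4L)
  expect_identical(tm2$counts["iso-I", "iso-II"], 0L)
  expect_error(transition_matrix(mk(c("open", "open")), lag = 2), "longer")
  # occupied rows always sum to 1
  m <- kinetic_model(0.3, 1, 0.3, 1)
  ens <- simulate_ensemble(m, n_members = 10, duration = 200, seed = 5)
  tme <- transition_matrix(ens)
  expect_equal(unname(rowSums(tme$probabilities)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("stationary transition counts satisfy detailed balance", {
  m <- kinetic_model(0.2, 1, 0.25, 1.3)
  pi_cf <- stationary_distribution(m)
  ens <- simulate_ensemble(m, n_members = 50, duration = 500, seed = 17,
                           initial_dist = pi_cf)
  cnt <- transition_matrix(ens)$counts
  for (pair in list(c("open", "iso-I"), c("open", "iso-II"),
                    c("iso-I", "iso-II"))) {
    nij <- cnt[pair[1L], pair[2L]]; nji <- cnt[pair[2L], pair[1L]]
    expect_lte(abs(nij - nji), 3 * sqrt(nij + nji) + 1e-9)
  }
})

test_that("every stacked-to-stacked inter-conversion passes through open", {
  m <- kinetic_model(0.3, 2, 0.3, 2)
  ens <- simulate_ensemble(m, n_members = 20, duration = 1000, seed = 23)
  for (s in ens) {
    j <- s$jumps$state
    expect_false(any(j[-length(j)] != "open" & j[-1L] != "open"))
  }
})

test_that("stage-1 and stage-2 seeded ensembles agree on populations", {
  m <- default_kinetic_model()
  e1 <- simulate_ensemble(m, n_members = 50, duration = 800, seed = 41)
  p1 <- population_fractions(e1)
  e2 <- simulate_ensemble(m, n_members = 50, duration = 800, seed = 42,
                          initial_dist = p1$fractions[1:3] / sum(p1$fractions[1:3]))
  p2 <- population_fractions(e2)
  comb_se <- sqrt(p1$se[1:3]^2 + p2$se[1:3]^2)
  expect_true(all(abs(p1$fractions[1:3] - p2$fractions[1:3]) <=
                  3 * pmax(comb_se, 1e-6)))
})

test_that("distance distributions are normalized and resolve the two peaks", {
  topo <- toy_topology(3)
  tpls <- template_set(topo)
  m <- default_kinetic_model()
  ens <- simulate_ensemble(m, n_members = 4, duration = 250, seed = 19,
                           templates = tpls, sigma = 1)
  h_ag <- distance_distribution(ens, topo, "AG")
  width <- h_ag$bin_right - h_ag$bin_left
  expect_equal(sum(h_ag$density * width), 1, tolerance = 1e-10)
  # bimodal: mass below and above the cutoff with a gap near 12 A
  expect_gt(sum(h_ag$density[h_ag$bin_right <= 9] * width[h_ag$bin_right <= 9]), 0.3)
  expect_gt(sum(h_ag$density[h_ag$bin_left >= 15] * width[h_ag$bin_left >= 15]), 0.2)
  near_cut <- h_ag$bin_left >= 10.5 & h_ag$bin_right <= 13.5
  expect_lt(max(h_ag$density[near_cut]), max(h_ag$density))
  # all-open ensemble: no mass below the cutoff
  s_open <- simulate_state_series(kinetic_model(0, 0, 0, 0), 100, dt = 1,
                                  initial = "open", seed = 1)
  tr_open <- render_trajectory(s_open, tpls, sigma = 1, seed = 2)
  h_open <- distance_distribution(tr_open, topo, "TTCC")
  expect_identical(sum(h_open$density[h_open$bin_right <= 12]), 0)
})

test_that("inter-duplex angle handles orthogonal, collinear and degenerate arms", {
  topo <- toy_topology(3)
  planar <- idealized_geometry(topo, "open-planar")
  expect_equal(inter_duplex_angle(planar$coords, topo, c("XR", "RH")), 90,
               tolerance = 1e-9)
  # opposite arms of the planar template are collinear
  expect_equal(inter_duplex_angle(planar$coords, topo, c("XR", "HB")), 180,
               tolerance = 1e-9)
  tetra <- idealized_geometry(topo, "open-tetrahedral")
  expect_equal(inter_duplex_angle(tetra$coords, topo),
               acos(-1 / 3) * 180 / pi, tolerance = 0.1)
  # degenerate arm: collapse the XR terminal pair onto the vertex
  degen <- planar$coords
  vertex <- colMeans(planar$coords[topo$core_markers$site, ])
  bp <- topo$base_pairs
  term <- bp[bp$arm == "XR" & bp$index_in_arm == topo$arm_length - 1L, ]
  degen[c(term$site_a, term$site_b), ] <- rep(vertex, each = 2L)
  expect_error(inter_duplex_angle(degen, topo), "degenerate")
  expect_error(inter_duplex_angle(planar$coords, topo, c("XR", "QQ")), "arm")
})

test_that("per-conformer IDA statistics recover means and respond to noise", {
  topo <- toy_topology(3)
  tpls <- template_set(topo, iso2_ida = 95.7)
  # pure iso-II at sigma = 0: mean equals the nominal IDA, zero spread
  s <- simulate_state_series(kinetic_model(0, 0, 0, 0), 200, dt = 1,
                             initial = "iso-II", seed = 1)
  tr <- render_trajectory(s, tpls, sigma = 0, seed = 2)
  st <- conformer_structure_stats(tr, s, topo)
  expect_equal(st$by_state[["iso-II"]]$mean, 95.7, tolerance = 1e-6)
  expect_equal(st$by_state[["iso-II"]]$sd, 0, tolerance = 1e-6)
  expect_null(st$by_state[["open"]])
  # mixture of two delta geometries recovers both means
  m <- kinetic_model(0.5, 1, 0.5, 1)
  smix <- simulate_state_series(m, 400, dt = 1, seed = 3)
  trmix <- render_trajectory(smix, tpls, sigma = 0, seed = 4)
  stm <- conformer_structure_stats(trmix, smix, topo)
  expect_equal(stm$by_state[["iso-I"]]$mean, 140, tolerance = 1e-6)
  expect_equal(stm$by_state[["iso-II"]]$mean, 95.7, tolerance = 1e-6)
  # IDA spread grows monotonically with site noise
  sds <- sapply(c(0, 1, 2), function(sg) {
    trn <- render_trajectory(s, tpls, sigma = sg, seed = 7)
    conformer_structure_stats(trn, s, topo)$by_state[["iso-II"]]$sd
  })
  expect_true(all(diff(sds) > 0))
  # equilibration discard drops early frames
  st2 <- conformer_structure_stats(tr, s, topo, discard_ns = 50)
  expect_identical(st2$n_frames, sum(s$times >= 50))
})
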