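test_that("a zero radical profile leaves the chain untouched", {
  sc <- bpa_scenario()
  zero_prof <- oh_profile(h2o2_poly(0, t_max_s = 18000), 1e-10,
                          sc$system$c0_mol_L)
  traj <- simulate_chain(sc$system, sc$rates, zero_prof,
                         seq(0, 18000, 3600))
  expect_equal(traj$states,
               matrix(rep(c(1, 0, 0, 0), each = 6), 6,
                      dimnames = list(NULL, sc$system$species)),
               tolerance = 1e-12)
})

test_that("numerical trajectories match the exposure-transform oracle", {
  sc <- bpa_scenario()
  prof <- scenario_profile(sc)
  grid <- seq(0, 18000, length.out = 13)
  traj <- simulate_chain(sc$system, sc$rates, prof, grid)
  u <- vapply(grid, function(t) oh_exposure(prof, 0, t), numeric(1))
  oracle <- bateman_chain(u, sc$rates, sc$system$initial_state)
  expect_lt(max(abs(traj$states - oracle)), 1e-6)
  # repeated-rate scenario through the same oracle
  rb <- rhb_scenario()
  prof_rb <- scenario_profile(rb)
  grid_rb <- seq(0, 10800, length.out = 7)
  traj_rb <- simulate_chain(rb$system, rb$rates, prof_rb, grid_rb)
  u_rb <- vapply(grid_rb, function(t) oh_exposure(prof_rb, 0, t), numeric(1))
  expect_lt(max(abs(traj_rb$states -
                      bateman_chain(u_rb, rb$rates,
                                    rb$system$initial_state))), 1e-6)
})

test_that("trajectories conserve mass and stay non-negative", {
  set.seed(31)
  for (i in 1:5) {
    ch <- random_chain(n = sample(3:5, 1))
    prof <- oh_profile(random_poly(), 10^runif(1, -11, -9.5), ch$system$c0_mol_L)
    traj <- simulate_chain(ch$system, ch$rates, prof,
                           seq(0, 18000, length.out = 9))
    expect_true(all(abs(rowSums(traj$states) - 1) < 1e-6))
    expect_true(all(traj$states >= 0))
    parent <- traj$states[, 1]
    expect_true(all(diff(parent) <= 1e-9))                 # non-increasing
    expect_true(all(diff(traj$states[, ncol(traj$states)]) >= -1e-9))
  }
})

test_that("removal and mineralization read the expected endpoints", {
  sc <- bpa_scenario()
  traj <- simulate_chain(sc$system, sc$rates, scenario_profile(sc),
                         seq(0, 18000, 600))
  expect_equal(removal_fraction(traj, t = 0), 0)
  r5h <- removal_fraction(traj, t = 18000)
  expect_gt(r5h, 0.90)
  expect_lt(r5h, 0.92)
  expect_equal(mineralization_fraction(traj, 0), 0)
  rb <- rhb_scenario()
  traj_rb <- simulate_chain(rb$system, rb$rates, scenario_profile(rb),
                            seq(0, 10800, 600))
  expect_equal(mineralization_fraction(traj_rb, 10800), 0.20,
               tolerance = 0.05)
  # full consumption at a tenfold radical dose
  hot <- oh_profile(sc$poly, 1e-9, sc$system$c0_mol_L)
  traj_hot <- simulate_chain(sc$system, sc$rates, hot, seq(0, 18000, 600))
  expect_equal(removal_fraction(traj_hot, t = 18000), 1, tolerance = 1e-6)
  expect_equal(mineralization_fraction(traj_hot, 18000), 1,
               tolerance = 1e-4)
  expect_error(removal_fraction(traj, pool = "P_tr", t = 18000),
               "zero initial")
})

test_that("formed-intermediate turnover distinguishes net level from throughput", {
  sc <- bpa_scenario()
  traj <- simulate_chain(sc$system, sc$rates, scenario_profile(sc),
                         seq(0, 18000, 600))
  expect_error(formed_intermediate_turnover(traj, "P_tr", 0), "inflow")
  expect_error(formed_intermediate_turnover(traj, "BPA", 18000),
               "intermediate")
  # fast downstream step: everything formed is immediately processed
  fast <- simulate_chain(sc$system, c(1e10, 1e13, 1e13),
                         scenario_profile(sc), seq(0, 18000, 600))
  expect_gt(formed_intermediate_turnover(fast, "P_tr", 18000), 0.999)
  # at 10 mA/cm^2 over 90% of the formed two-ring pool has been processed
  prof10 <- oh_profile(sc$poly, k_of_j(sc$law, 10), sc$system$c0_mol_L)
  traj10 <- simulate_chain(sc$system, sc$rates, prof10, seq(0, 18000, 600))
  expect_gt(formed_intermediate_turnover(traj10, "P_tr", 18000), 0.9)
})

test_that("current-density sweeps scale monotonically and match direct runs", {
  sc <- bpa_scenario()
  j <- c(2.5, 5, 10, 15, 20)
  sweeps <- sweep_current_density(sc$system, sc$rates, sc$poly, sc$law, j,
                                  seq(0, 18000, 1800))
  expect_length(sweeps, 5)
  removal <- vapply(sweeps, removal_fraction, numeric(1), t = 18000)
  expect_true(all(diff(removal) > 0))
  expect_lt(removal[["2.5"]], 0.60)
  # a single-j sweep equals the direct simulate_chain call
  direct <- simulate_chain(sc$system, sc$rates,
                           oh_profile(sc$poly, k_of_j(sc$law, 15),
                                      sc$system$c0_mol_L),
                           seq(0, 18000, 1800))
  expect_equal(sweeps[["15"]]$states, direct$states, tolerance = 1e-12)
  summ <- sweep_summary(sweeps, t = 18000)
  expect_equal(summ$removal, unname(removal), tolerance = 1e-12)
})
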