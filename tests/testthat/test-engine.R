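# Engine: pair potentials, force-energy consistency, minimizer contracts,
# integrator conservation laws, thermostat/barostat behaviour, determinism.

test_that("shifted LJ is zero at the cutoff and -eps at the minimum", {
  expect_equal(pair_energy_lj_shifted(1.1, 0.47, 2.35, cutoff = 1.1), 0)
  expect_equal(pair_energy_lj_shifted(1.5, 0.47, 2.35, cutoff = 1.1), 0)
  rmin <- 2^(1 / 6) * 0.47
  expect_equal(pair_energy_lj_shifted(rmin, 0.47, 2.35, cutoff = 1e6),
               -2.35, tolerance = 1e-9)
  # frozen value from an independent scalar evaluation of the formula
  expect_equal(pair_energy_lj_shifted(0.5, 0.47, 2.35, cutoff = 1.1),
               -1.9542778825, tolerance = 1e-9)
  expect_error(pair_energy_lj_shifted(0, 0.47, 1), "positive")
})

test_that("reaction-field energy is shifted, screened and zero for neutral pairs", {
  expect_equal(pair_energy_reaction_field(0.7, 0), 0)
  expect_equal(pair_energy_reaction_field(1.1, -1, 15, 1.1), 0,
               tolerance = 1e-12)
  # frozen value from an independently coded textbook RF expression
  expect_equal(pair_energy_reaction_field(0.5, -1, 15, 1.1),
               -6.7641004346, tolerance = 1e-8)
  expect_error(pair_energy_reaction_field(-1, 1), "positive")
})

test_that("an isolated LJ dimer at the minimum feels no net force", {
  rmin <- 2^(1 / 6) * 0.47
  sys <- make_bead_system(rbind(c(2, 2, 2), c(2 + rmin, 2, 2)), box = 20)
  f <- compute_forces(sys, interaction_matrix("v3"),
                      sim_config(cutoff = 5))
  expect_lt(max(abs(f$forces)), 1e-8)
})

test_that("forces equal the negative finite-difference energy gradient", {
  m <- interaction_matrix("v3")
  cfg <- sim_config()
  set.seed(99)
  worst <- 0
  for (rep in 1:50) {
    # 10 beads incl. charged ones, random but not badly overlapping
    repeat {
      pos <- matrix(runif(30, 0, 3), ncol = 3)
      if (min(cgpep:::cpp_pair_dists(pos, 3)) > 0.3) break
    }
    sys <- make_bead_system(pos, box = 3, type = "W")
    sys$beads$type[1:2] <- "Q5"
    sys$beads$charge[1:2] <- c(1, -1)
    f <- compute_forces(sys, m, cfg)
    h <- 1e-6
    for (k in sample(30, 6)) {
      i <- (k - 1) %% 10 + 1; d <- (k - 1) %/% 10 + 1
      up <- sys; up$positions[i, d] <- up$positions[i, d] + h
      dn <- sys; dn$positions[i, d] <- dn$positions[i, d] - h
      num <- -(compute_forces(up, m, cfg)$energy -
                 compute_forces(dn, m, cfg)$energy) / (2 * h)
      scale <- max(abs(f$forces[i, d]), 1)
      worst <- max(worst, abs(num - f$forces[i, d]) / scale)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("molecules separated beyond the cutoff in all images do not interact", {
  sys <- make_bead_system(rbind(c(1, 1, 1), c(4, 4, 4)), box = 9)
  f <- compute_forces(sys, interaction_matrix("v3"), sim_config())
  expect_equal(f$energy, 0)
  expect_equal(max(abs(f$forces)), 0)
})

test_that("a clashed LJ dimer minimizes to the analytic minimum distance", {
  sys <- make_bead_system(rbind(c(2, 2, 2), c(2.3, 2, 2)), box = 20)
  # localizing a single-pair minimum needs a much tighter force threshold
  # than the production default
  cfg <- sim_config(cutoff = 5, minimize_fmax = 0.5)
  out <- minimize(sys, interaction_matrix("v3"), cfg)
  d <- sqrt(sum((out$positions[1, ] - out$positions[2, ])^2))
  expect_lt(abs(d - 2^(1 / 6) * 0.47) / (2^(1 / 6) * 0.47), 0.01)
})

test_that("an already-converged state returns unchanged almost immediately", {
  rmin <- 2^(1 / 6) * 0.47
  sys <- make_bead_system(rbind(c(2, 2, 2), c(2 + rmin, 2, 2)), box = 20)
  out <- minimize(sys, interaction_matrix("v3"), sim_config(cutoff = 5))
  expect_lte(attr(out, "steps"), 1)
  expect_true(attr(out, "converged"))
  expect_equal(out$positions, sys$positions, tolerance = 1e-9)
})

test_that("minimizing a random gas meets the stopping contract", {
  sys <- make_lj_gas(100, box = 2.3, seed = 4)  # dense, clashes likely
  cfg <- sim_config()
  out <- minimize(sys, interaction_matrix("v3"), cfg)
  expect_true(attr(out, "converged") || attr(out, "steps") >= 5000)
  if (attr(out, "converged"))
    expect_lt(attr(out, "fmax_pN"), cfg$minimize_fmax)
})

test_that("NVE total energy is conserved at reduced time step", {
  # a moderate-well LJ liquid (eps 2 kJ/mol, kT < eps) isolates integrator
  # error from the hard-collision stiffness of the deepest CG wells; drift
  # is the fitted slope of E(t) times the duration, the standard measure,
  # which separates secular loss from the bounded shadow-energy oscillation
  sys <- make_lj_gas(100, box = 3.0, seed = 1)
  m <- override_interactions(interaction_matrix("v3"),
                             data.frame(a = "W", b = "W", epsilon = 2.0,
                                        sigma = 0.47))
  cfg <- sim_config(dt = 5, thermostat = FALSE, barostat = FALSE, T0 = 100,
                    remove_com = TRUE, stride = 250L)
  sys <- minimize(sys, m, cfg)
  traj <- run_md(sys, m, cfg, seed = 1, n_steps = 10000L)
  e <- traj$energies
  ii <- 2:nrow(e)  # skip the t=0 half-step offset
  slope <- unname(coef(lm(e$etot[ii] ~ e$time_ps[ii]))[2])
  drift <- abs(slope) * (max(e$time_ps) - e$time_ps[2])
  expect_lt(drift / mean(abs(e$epot[ii])), 1e-3)
})

test_that("the V-rescale thermostat holds the temperature set point", {
  sys <- make_lj_gas(100, box = 3.4, seed = 2)
  m <- interaction_matrix("v3")
  cfg <- sim_config(barostat = FALSE, stride = 1000L)
  sys <- minimize(sys, m, cfg)
  traj <- run_md(sys, m, cfg, seed = 5, n_steps = 100000L)
  temps <- traj$energies$temperature
  second_half <- temps[seq(ceiling(length(temps) / 2), length(temps))]
  expect_lt(abs(mean(second_half) - 303), 3)
})

test_that("net linear momentum stays zero with COM removal", {
  sys <- make_lj_gas(60, box = 3.0, seed = 3)
  m <- interaction_matrix("v3")
  cfg <- sim_config(stride = 500L)
  sys <- minimize(sys, m, cfg)
  traj <- run_md(sys, m, cfg, seed = 2, n_steps = 2000L)
  for (f in seq_along(traj$frames)) {
    p <- colSums(traj$velocities[[f]] * traj$beads$mass)
    expect_lt(max(abs(p)), 1e-6)
  }
})

test_that("constraints hold at every output frame", {
  traj <- make_ff_run("v3", n_mol = 6, box = 3.6, n_steps = 1500L,
                      stride = 300L)
  tol <- sim_config()$constraint_tol
  for (f in seq_along(traj$frames)) {
    pos <- traj$frames[[f]]; box <- traj$boxes[f]
    d <- traj$constraints
    for (p in seq_len(nrow(d))) {
      dx <- pos[d$i[p], ] - pos[d$j[p], ]
      dx <- dx - box * round(dx / box)
      expect_lt(abs(sum(dx^2) - d$d[p]^2) / d$d[p]^2, 2 * tol)
    }
  }
})

test_that("box volume responds with the correct sign to a pressure offset", {
  sys <- make_lj_gas(150, box = 3.0, seed = 6)
  m <- interaction_matrix("v3")
  base <- sim_config(stride = 500L, n_steps = 3000L)
  sys <- minimize(sys, m, base)
  hi <- base; hi$P0 <- 500   # strong compression demand
  lo <- base; lo$P0 <- -500  # expansion demand
  v_hi <- tail(run_md(sys, m, hi, seed = 3)$energies$volume, 1)
  v_lo <- tail(run_md(sys, m, lo, seed = 3)$energies$volume, 1)
  expect_lt(v_hi, v_lo)
})

test_that("runs are deterministic under a fixed seed", {
  a <- make_ff_run("v3", n_mol = 5, box = 3.5, seed = 9, n_steps = 800L)
  b <- make_ff_run("v3", n_mol = 5, box = 3.5, seed = 9, n_steps = 800L)
  expect_identical(a$frames[[length(a$frames)]],
                   b$frames[[length(b$frames)]])
  c <- make_ff_run("v3", n_mol = 5, box = 3.5, seed = 10, n_steps = 800L)
  expect_false(identical(a$frames[[length(a$frames)]],
                         c$frames[[length(c$frames)]]))
})

test_that("pair potentials approach zero continuously at the cutoff", {
  r <- 1.1 - 10^seq(-7, -4)
  expect_true(all(abs(pair_energy_lj_shifted(r, 0.47, 5, 1.1)) < 1e-4))
  expect_true(all(abs(pair_energy_reaction_field(r, 1, 15, 1.1)) < 1e-4))
  expect_lt(abs(pair_energy_lj_shifted(1.1 - 1e-9, 0.47, 5, 1.1)), 1e-7)
})

test_that("config files round-trip through the MDP-style format", {
  cfg <- sim_config(cutoff = 1.2, epsilon_r = 12, dt = 20, n_steps = 1234L,
                    T0 = 310, tau_T = 0.5, P0 = 2, tau_P = 4,
                    barostat = FALSE)
  f <- tempfile(fileext = ".cfg")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  for (field in c("cutoff", "epsilon_r", "dt", "n_steps", "T0", "tau_T",
                  "P0", "tau_P", "thermostat", "barostat"))
    expect_equal(back[[field]], cfg[[field]], info = field)
})

test_that("effective time applies the 4x convention", {
  traj <- make_ff_run("v3", n_mol = 3, box = 3.2, n_steps = 400L,
                      stride = 200L)
  expect_equal(traj$effective_times_ns, 4 * traj$times_ns)
  # 5e7 steps x 25 fs x 4 = 5 us of effective time
  expect_equal(5e7 * 25e-6 * 4 / 1000, 5)
})
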