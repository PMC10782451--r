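# Analysis metrics: SASA oracles, AP arithmetic, RDF vs brute force,
# group temperatures, tube-fraction statistics.

test_that("single-bead SASA matches the analytic sphere within 0.5%", {
  for (R in c(0.205, 0.235)) {
    a <- as.numeric(sasa(matrix(c(1, 1, 1), 1), R, probe = 0.14,
                         n_points = 960L))
    expect_lt(abs(a - 4 * pi * (R + 0.14)^2) / (4 * pi * (R + 0.14)^2),
              0.005)
  }
})

test_that("far-separated beads have additive SASA", {
  R <- 0.235
  one <- as.numeric(sasa(matrix(c(0, 0, 0), 1), R))
  two <- as.numeric(sasa(rbind(c(0, 0, 0), c(5, 0, 0)), c(R, R)))
  expect_equal(two, 2 * one, tolerance = 1e-9)
})

test_that("overlapping-bead SASA matches a Monte-Carlo surface oracle", {
  R <- c(0.235, 0.205); probe <- 0.14
  pos <- rbind(c(0, 0, 0), c(0.30, 0, 0))
  got <- as.numeric(sasa(pos, R, probe, n_points = 2000L))
  # MC oracle: sample points on each extended sphere, count unburied
  set.seed(123)
  nmc <- 200000
  area <- 0
  for (i in 1:2) {
    Ri <- R[i] + probe
    u <- matrix(rnorm(3 * nmc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(Ri * u, 2, pos[i, ], "+")
    j <- 3 - i
    buried <- rowSums(sweep(pts, 2, pos[j, ])^2) < (R[j] + probe)^2
    area <- area + 4 * pi * Ri^2 * mean(!buried)
  }
  expect_lt(abs(got - area) / area, 0.01)
})

test_that("adding an isolated bead never decreases total SASA", {
  set.seed(7)
  pos <- matrix(runif(30, 0, 2), ncol = 3)
  base <- as.numeric(sasa(pos, 0.2))
  grown <- as.numeric(sasa(rbind(pos, c(8, 8, 8)), rep(0.2, 11)))
  expect_gt(grown, base)
})

test_that("missing radii raise an error", {
  expect_error(sasa(matrix(0, 2, 3), c(0.2, NA)), "radius")
  expect_error(sasa(matrix(0, 3, 3), c(0.2, 0.2)), "radius")
})

test_that("AP is exactly 1 for a frozen trajectory and follows the ratio", {
  traj <- make_ff_run("v3", n_mol = 4, box = 3.4, n_steps = 400L,
                      stride = 200L)
  frozen <- traj
  for (f in seq_along(frozen$frames)) {
    frozen$frames[[f]] <- traj$frames[[1]]
    frozen$boxes[f] <- traj$boxes[1]
  }
  ap <- aggregation_propensity(frozen)
  expect_equal(ap$ap, 1.0)
  expect_equal(ap$ap_reported, 1.0)
  expect_false(ap$aggregated)
  # threshold arithmetic: SASA0/SASAf = 200/100 -> AP 2, aggregated
  fake <- structure(list(sasa_initial = 200, sasa_final = 100, ap = 2,
                         ap_reported = 2, aggregated = TRUE),
                    class = "cg_ap")
  expect_true(fake$ap >= 2)
  expect_equal(ap$sasa_initial / ap$sasa_final, ap$ap)
})

test_that("RDF of an ideal gas is flat near 1", {
  set.seed(11)
  n <- 400; box <- 10
  pos <- matrix(runif(3 * n, 0, box), ncol = 3)
  beads <- data.frame(type = "SC4", charge = 0, mass = 54, residue = 1L,
                      role = "sidechain", sigma_self = 0.41,
                      mol = seq_len(n), solvent = FALSE, sequence = "F",
                      stringsAsFactors = FALSE)
  traj <- list(frames = list(pos), boxes = box, beads = beads)
  g <- rdf(traj, "F", bin = 0.1, window = 1)
  w <- g$r_centers > 1 & g$r_centers < box / 2
  expect_lt(max(abs(g$g[w] - 1)), 0.35)       # per-bin counting noise
  expect_lt(abs(mean(g$g[w]) - 1), 0.05)      # homogeneous on average
})

test_that("two fixed centres occupy a single RDF bin at their distance", {
  pos <- rbind(c(1, 1, 1), c(1, 1, 2.2))
  beads <- data.frame(type = "SC4", charge = 0, mass = 54,
                      residue = c(1L, 1L), role = "sidechain",
                      sigma_self = 0.41, mol = 1:2, solvent = FALSE,
                      sequence = "F", stringsAsFactors = FALSE)
  traj <- list(frames = list(pos), boxes = 8, beads = beads)
  g <- rdf(traj, "F", bin = 0.01, window = 1)
  expect_lt(abs(g$first_max_r - 1.2), 0.011)  # within one bin of the distance
  expect_equal(sum(g$g > 0), 1)
  expect_error(rdf(traj, "F", bin = -0.1), "positive")
})

test_that("RDF histogram equals a brute-force O(N^2) pair count", {
  set.seed(21)
  n <- 200; box <- 6
  pos <- matrix(runif(3 * n, 0, box), ncol = 3)
  beads <- data.frame(type = "SC4", charge = 0, mass = 54, residue = 1L,
                      role = "sidechain", sigma_self = 0.41,
                      mol = seq_len(n), solvent = FALSE, sequence = "F",
                      stringsAsFactors = FALSE)
  traj <- list(frames = list(pos), boxes = box, beads = beads)
  bin <- 0.05
  g <- rdf(traj, "F", bin = bin, window = 1)
  # independent brute-force histogram
  counts <- numeric(length(g$r_centers))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    if (r < box / 2) {
      b <- min(length(counts), max(1, ceiling(r / bin)))
      counts[b] <- counts[b] + 1
    }
  }
  shell <- 4 / 3 * pi * (seq_len(length(counts))^3 -
                           (seq_len(length(counts)) - 1)^3) * bin^3
  ideal <- n * (n - 1) / 2 * shell / box^3
  expect_equal(g$g, counts / ideal, tolerance = 1e-12)
})

test_that("group temperature applies the 3N/(3N-c) correction", {
  traj <- make_ff_run("v3", n_mol = 6, box = 3.6, n_steps = 600L,
                      stride = 200L)
  gt <- group_temperature(traj, group_size = 6L)
  # FF: N = 8 beads, 6 constraints -> 24/18
  expect_equal(gt$dof_correction, 24 / 18, tolerance = 1e-12)
  expect_equal(round(gt$dof_correction, 3), 1.333)
  expect_false(gt$uneven_last_group)
  g2 <- group_temperature(traj, group_size = 4L)
  expect_true(g2$uneven_last_group)
})

test_that("unconstrained Maxwell-Boltzmann velocities read back 303 K", {
  n <- 800
  sys <- make_lj_gas(n, box = 8)
  sys$beads$solvent <- FALSE  # treat the gas as solute for the grouping
  temps <- numeric(100)
  for (k in seq_len(100)) {
    m <- sys$beads$mass
    set.seed(k)
    v <- matrix(rnorm(3 * n, sd = sqrt(0.008314462618 * 303 / m)), ncol = 3)
    traj <- list(frames = list(sys$positions), velocities = list(v),
                 boxes = sys$box, beads = sys$beads,
                 constraints = sys$constraints)
    temps[k] <- group_temperature(traj, group_size = n, window = 1)$temps[1]
  }
  expect_lt(abs(mean(temps) - 303), 2)
})

test_that("tube fraction and its SEM follow the stated formula", {
  t4 <- tube_fraction(c("tube", "tube", "tube", "tube"))
  expect_equal(t4$fraction, 1); expect_equal(t4$sem, 0)
  t3 <- tube_fraction(c("tube", "tube", "solid", "tube"))
  expect_equal(t3$fraction, 0.75)
  expect_equal(t3$sem, 0.288675, tolerance = 1e-6)
  t0 <- tube_fraction(c("solid", "solid"))
  expect_equal(t0$fraction, 0)
  expect_error(tube_fraction("tube"), "2 replicas")
})
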