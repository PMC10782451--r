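# Shared fixtures built in code: small systems the engine tests reuse.

# uncharged LJ gas of water beads on a jittered lattice
make_lj_gas <- function(n = 100, box = 3.0, seed = 1, version = "v3") {
  wname <- if (version == "v3") "W" else "P4"
  bt <- bead_types(version)
  iw <- match(wname, bt$name)
  nper <- ceiling(n^(1 / 3))
  g <- (seq_len(nper) - 0.5) * box / nper
  pos <- as.matrix(expand.grid(g, g, g))[seq_len(n), ]
  set.seed(seed)
  pos <- pos + matrix(rnorm(3 * n, sd = 0.02), ncol = 3)
  pos <- pos - box * floor(pos / box)
  beads <- data.frame(
    type = wname, charge = 0, mass = bt$mass[iw], residue = 1L,
    role = "solvent", sigma_self = bt$sigma_self[iw], mol = seq_len(n),
    solvent = TRUE, sequence = "W", stringsAsFactors = FALSE)
  structure(list(
    beads = beads, positions = pos, velocities = NULL, box = box,
    bonds = data.frame(i = integer(0), j = integer(0), b0 = numeric(0),
                       k = numeric(0)),
    constraints = data.frame(i = integer(0), j = integer(0), d = numeric(0)),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0), ktheta = numeric(0)),
    exclusions = data.frame(i = integer(0), j = integer(0)),
    set = NULL, n_solute_molecules = 0L, version = version),
    class = "cg_system")
}

# system of n free beads at given positions (single bead type, no bonds)
make_bead_system <- function(positions, box, type = "W", charge = 0,
                             version = "v3") {
  n <- nrow(positions)
  bt <- bead_types(version)
  it <- match(type, bt$name)
  if (length(charge) == 1) charge <- rep(charge, n)
  beads <- data.frame(
    type = type, charge = charge, mass = bt$mass[it], residue = 1L,
    role = "solvent", sigma_self = bt$sigma_self[it], mol = seq_len(n),
    solvent = FALSE, sequence = "X", stringsAsFactors = FALSE)
  structure(list(
    beads = beads, positions = positions, velocities = NULL, box = box,
    bonds = data.frame(i = integer(0), j = integer(0), b0 = numeric(0),
                       k = numeric(0)),
    constraints = data.frame(i = integer(0), j = integer(0), d = numeric(0)),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0), ktheta = numeric(0)),
    exclusions = data.frame(i = integer(0), j = integer(0)),
    set = NULL, n_solute_molecules = n, version = version),
    class = "cg_system")
}

# independent brute-force connected components over a geometric graph
brute_components <- function(positions, box, cutoff) {
  n <- nrow(positions)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- positions[i, ] - positions[j, ]
      d <- d - box * round(d / box)
      if (sum(d^2) < cutoff^2 && lab[i] != lab[j]) {
        new <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# small solvated FF system ready to run (shared by engine/screen tests)
make_ff_run <- function(set_id = "v3", n_mol = 12, box = 4.2, seed = 1,
                        n_steps = 2000L, stride = NULL) {
  set <- make_parameter_set(set_id)
  mat <- interaction_matrix(set$base_version)
  cfg <- sim_config(n_steps = as.integer(n_steps),
                    stride = as.integer(if (is.null(stride))
                      max(100L, n_steps / 5) else stride))
  top <- build_topology("FF", set)
  sys <- insert_molecules(top, n_mol, box, seed = seed)
  sys <- solvate_and_neutralize(sys, seed = seed)
  sys <- minimize(sys, mat, cfg)
  run_md(sys, mat, cfg, seed = seed)
}
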