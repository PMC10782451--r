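# NPT engine front-end: configuration, pair potentials, minimization, runs.

#' Simulation configuration
#'
#' Interaction and coupling settings for the NPT engine.  Defaults follow the
#' standard coarse-grained protocol: shifted Lennard-Jones and reaction-field
#' electrostatics cut off at 1.1 nm with a dielectric constant of 15,
#' neighbour list updated every 10 steps, 25 fs time step, V-rescale
#' thermostat at 303 K (tau 1 ps) and isotropic Berendsen barostat at 1 bar
#' (tau 3 ps).  Reported "effective" times multiply simulated time by the
#' conventional factor 4 accounting for the faster coarse-grained dynamics.
#'
#' @param cutoff nonbonded cutoff, nm.
#' @param epsilon_r relative dielectric constant inside the cutoff.
#' @param nlist_update neighbour-list update interval, steps.
#' @param dt time step, fs.
#' @param n_steps default step count for [run_md()].
#' @param T0 thermostat set point, K. @param tau_T thermostat constant, ps.
#' @param P0 barostat set point, bar. @param tau_P barostat constant, ps.
#' @param compressibility isothermal compressibility, 1/bar.
#' @param constraint_tol relative constraint tolerance.
#' @param minimize_max_steps,minimize_fmax steepest-descent stopping rule
#'   (force threshold in pN).
#' @param time_scale_factor effective-time multiplier (fixed at 4).
#' @param skin neighbour-list buffer, nm.
#' @param thermostat,barostat,remove_com coupling switches.
#' @param stride frame output interval, steps.
#' @return object of class `cg_sim_config`.
#' @export
sim_config <- function(cutoff = 1.1, epsilon_r = 15, nlist_update = 10L,
                       dt = 25, n_steps = 50000L, T0 = 303, tau_T = 1,
                       P0 = 1, tau_P = 3, compressibility = 3e-4,
                       constraint_tol = 1e-4, minimize_max_steps = 5000L,
                       minimize_fmax = 2000, time_scale_factor = 4,
                       skin = 0.2, thermostat = TRUE, barostat = TRUE,
                       remove_com = TRUE, stride = 1000L) {
  stopifnot(cutoff > 0, dt > 0, epsilon_r > 0, time_scale_factor == 4)
  structure(list(cutoff = cutoff, epsilon_r = epsilon_r,
                 nlist_update = as.integer(nlist_update), dt = dt,
                 n_steps = as.integer(n_steps), T0 = T0, tau_T = tau_T,
                 P0 = P0, tau_P = tau_P, compressibility = compressibility,
                 constraint_tol = constraint_tol,
                 minimize_max_steps = as.integer(minimize_max_steps),
                 minimize_fmax = minimize_fmax,
                 time_scale_factor = time_scale_factor, skin = skin,
                 thermostat = thermostat, barostat = barostat,
                 remove_com = remove_com, stride = as.integer(stride)),
            class = "cg_sim_config")
}

#' @export
print.cg_sim_config <- function(x, ...) {
  cat("<cg_sim_config> cutoff", x$cutoff, "nm, eps_r", x$epsilon_r,
      ", dt", x$dt, "fs,", x$n_steps, "steps, T", x$T0, "K, P", x$P0,
      "bar\n")
  invisible(x)
}

# flat key = value config files using MDP-style names
.mdp_map <- c(rvdw = "cutoff", rcoulomb = "cutoff", `epsilon-r` = "epsilon_r",
              `epsilon_r` = "epsilon_r", nstlist = "nlist_update", dt = "dt",
              nsteps = "n_steps", `ref-t` = "T0", `tau-t` = "tau_T",
              `ref-p` = "P0", `tau-p` = "tau_P",
              compressibility = "compressibility")

#' Read or write a flat simulation config file
#'
#' Files use `key = value` lines with MDP-style names where an equivalent
#' exists (`rvdw`, `rcoulomb`, `epsilon-r`, `dt` in ps, `nsteps`, `tau-t`,
#' `tau-p`, `ref-t`, `ref-p`, `nstlist`, `compressibility`, `tcoupl`,
#' `pcoupl`).
#'
#' @param path file path.
#' @param config a `cg_sim_config` (for writing).
#' @return `read_sim_config` returns a `cg_sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- sub(";.*$", "", lines)
  cfg <- sim_config()
  for (ln in lines) {
    t <- trimws(ln)
    if (t == "" || !grepl("=", t)) next
    kv <- strsplit(t, "=")[[1]]
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "tcoupl") { cfg$thermostat <- tolower(val) != "no"; next }
    if (key == "pcoupl") { cfg$barostat <- tolower(val) != "no"; next }
    if (!key %in% names(.mdp_map)) next
    field <- .mdp_map[[key]]
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop("bad value for ", key, ": ", val)
    if (field == "dt") num <- num * 1000  # ps in file, fs internally
    cfg[[field]] <- if (field %in% c("nlist_update", "n_steps"))
      as.integer(num) else num
  }
  cfg
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "cg_sim_config"))
  lines <- c(
    sprintf("dt = %g", config$dt / 1000),
    sprintf("nsteps = %d", config$n_steps),
    sprintf("rvdw = %g", config$cutoff),
    sprintf("rcoulomb = %g", config$cutoff),
    sprintf("epsilon-r = %g", config$epsilon_r),
    sprintf("nstlist = %d", config$nlist_update),
    sprintf("tcoupl = %s", if (config$thermostat) "v-rescale" else "no"),
    sprintf("ref-t = %g", config$T0),
    sprintf("tau-t = %g", config$tau_T),
    sprintf("pcoupl = %s", if (config$barostat) "berendsen" else "no"),
    sprintf("ref-p = %g", config$P0),
    sprintf("tau-p = %g", config$tau_P),
    sprintf("compressibility = %g", config$compressibility)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Shifted Lennard-Jones pair energy
#'
#' V(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6) minus its value at the cutoff,
#' exactly zero at and beyond the cutoff.
#'
#' @param r separation, nm (vectorized). @param sigma nm.
#' @param epsilon kJ/mol. @param cutoff nm.
#' @return energy in kJ/mol.
#' @export
pair_energy_lj_shifted <- function(r, sigma, epsilon, cutoff = 1.1) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  raw <- function(x) 4 * epsilon * ((sigma / x)^12 - (sigma / x)^6)
  ifelse(r < cutoff, raw(r) - raw(cutoff), 0)
}

#' Reaction-field pair electrostatic energy
#'
#' Coulomb interaction screened by `epsilon_r` with a reaction-field
#' correction for a conducting continuum beyond the cutoff
#' (k_rf = 1/(2 rc^3)), potential-shifted to zero at the cutoff.
#'
#' @param r separation, nm (vectorized).
#' @param qq product of the charges, e^2.
#' @param epsilon_r dielectric constant. @param cutoff nm.
#' @return energy in kJ/mol.
#' @export
pair_energy_reaction_field <- function(r, qq, epsilon_r = 15, cutoff = 1.1) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  if (all(qq == 0)) return(rep(0, length(r)))
  krf <- 1 / (2 * cutoff^3)
  crf <- 3 / (2 * cutoff)
  ifelse(r < cutoff,
         .FELEC * qq / epsilon_r * (1 / r + krf * r^2 - crf), 0)
}

# pack a system + matrix into the argument list the C++ core expects
.pack <- function(system, matrix) {
  stopifnot(inherits(system, "cg_system"), inherits(matrix, "cg_matrix"))
  tidx <- match(system$beads$type, rownames(matrix$eps)) - 1L
  if (anyNA(tidx))
    stop("bead type(s) missing from matrix: ",
         paste(unique(system$beads$type[is.na(tidx)]), collapse = ", "))
  eng <- if (!is.null(matrix$eps_engine)) matrix$eps_engine else matrix$eps
  list(
    type = tidx, ntypes = nrow(matrix$eps),
    eps = as.numeric(eng), sig = as.numeric(matrix$sigma),
    mass = system$beads$mass, charge = system$beads$charge,
    bonded = list(
      bonds_idx = matrix(as.integer(c(system$bonds$i - 1, system$bonds$j - 1)),
                         ncol = 2),
      bonds_par = matrix(c(system$bonds$b0, system$bonds$k), ncol = 2),
      angles_idx = matrix(as.integer(c(system$angles$i - 1, system$angles$j - 1,
                                       system$angles$k - 1)), ncol = 3),
      angles_par = matrix(c(system$angles$theta0 * pi / 180,
                            system$angles$ktheta), ncol = 2),
      cons_idx = matrix(as.integer(c(system$constraints$i - 1,
                                     system$constraints$j - 1)), ncol = 2),
      cons_d = as.numeric(system$constraints$d),
      excl_idx = matrix(as.integer(c(system$exclusions$i - 1,
                                     system$exclusions$j - 1)), ncol = 2)
    )
  )
}

#' Potential energy and forces of a configuration
#'
#' One-shot evaluation of the total shifted potential and its exact negative
#' gradient; beads closer than `clash_floor` are counted and reported.
#'
#' @param system a `cg_system`. @param matrix a `cg_matrix`.
#' @param config a [sim_config()].
#' @param clash_floor hard overlap floor, nm.
#' @return list with `energy` (kJ/mol), `forces` (N x 3, kJ/mol/nm),
#'   `virial` and `n_clash`.
#' @export
compute_forces <- function(system, matrix, config = sim_config(),
                           clash_floor = 0.05) {
  p <- .pack(system, matrix)
  out <- cpp_forces(system$positions, system$box, p$mass, p$charge, p$type,
                    p$ntypes, p$eps, p$sig, p$bonded, config$cutoff,
                    config$epsilon_r, clash_floor)
  if (out$n_clash > 0)
    warning(out$n_clash, " bead pair(s) below the ", clash_floor,
            " nm overlap floor", call. = FALSE)
  out
}

#' Steepest-descent energy minimization
#'
#' Minimizes until the maximum force drops below `minimize_fmax` (pN) or
#' `minimize_max_steps` steps, keeping constrained geometries rigid.
#'
#' @inheritParams compute_forces
#' @return the system with relaxed positions; attributes `energy`, `fmax_pN`,
#'   `steps`, `converged`.
#' @export
minimize <- function(system, matrix, config = sim_config()) {
  p <- .pack(system, matrix)
  fmax_kj <- config$minimize_fmax / .PN_PER_KJMOLNM
  out <- cpp_minimize(system$positions, system$box, p$mass, p$charge, p$type,
                      p$ntypes, p$eps, p$sig, p$bonded, config$cutoff,
                      config$epsilon_r, config$minimize_max_steps, fmax_kj,
                      0.01, config$constraint_tol)
  system$positions <- out$positions
  attr(system, "energy") <- out$energy
  attr(system, "fmax_pN") <- out$fmax * .PN_PER_KJMOLNM
  attr(system, "steps") <- out$steps
  attr(system, "converged") <- out$converged
  system
}

#' Maxwell-Boltzmann velocities
#'
#' Draws velocities at temperature `T0`, removes centre-of-mass motion and
#' rescales to the target temperature exactly.
#'
#' @param system a `cg_system`. @param T0 temperature, K.
#' @param seed integer seed.
#' @return the system with a `velocities` matrix (nm/ps).
#' @export
generate_velocities <- function(system, T0 = 303, seed = 1L) {
  n <- nrow(system$beads)
  m <- system$beads$mass
  v <- with_seed(seed, function()
    matrix(rnorm(3 * n, sd = rep(sqrt(.kB * T0 / m), 3)), ncol = 3))
  v <- sweep(v, 2, colSums(v * m) / sum(m))
  ndof <- 3 * n - 3 - nrow(system$constraints)
  Tnow <- sum(m * rowSums(v^2)) / (ndof * .kB)
  system$velocities <- v * sqrt(T0 / Tnow)
  system
}

#' Run NPT (or NVE/NVT) dynamics
#'
#' Leapfrog integration with SHAKE constraints, stochastic V-rescale
#' thermostat and isotropic Berendsen barostat.  Deterministic under a fixed
#' seed.  Velocities are generated from a Maxwell-Boltzmann draw when the
#' system carries none.
#'
#' @param system a `cg_system` (ideally minimized).
#' @param matrix a `cg_matrix`. @param config a [sim_config()].
#' @param seed integer seed driving velocity generation and the thermostat.
#' @param n_steps override of `config$n_steps`.
#' @return object of class `cg_trajectory`: frame positions and velocities,
#'   box sizes, times (ns, plus effective ns at the 4x convention), an energy
#'   log and the bead metadata needed by the analysis functions.
#' @export
run_md <- function(system, matrix, config = sim_config(), seed = 1L,
                   n_steps = NULL) {
  if (is.null(system$velocities))
    system <- generate_velocities(system, config$T0, seed)
  p <- .pack(system, matrix)
  nst <- if (is.null(n_steps)) config$n_steps else as.integer(n_steps)
  cfg <- list(cutoff = config$cutoff, epsilon_r = config$epsilon_r,
              skin = config$skin, nlist_update = config$nlist_update,
              dt = config$dt / 1000, thermostat = config$thermostat,
              barostat = config$barostat, T0 = config$T0,
              tau_T = config$tau_T, P0 = config$P0, tau_P = config$tau_P,
              compressibility = config$compressibility,
              constraint_tol = config$constraint_tol,
              remove_com = config$remove_com, clash_floor = 0.0)
  stride <- min(config$stride, nst)
  out <- cpp_run_md(system$positions, system$velocities, system$box,
                    p$mass, p$charge, p$type, p$ntypes, p$eps, p$sig,
                    p$bonded, cfg, nst, as.integer(stride), as.integer(seed))
  en <- as.data.frame(out$energies)
  structure(list(
    frames = out$frames, velocities = out$velocities,
    boxes = as.numeric(out$boxes), times_ns = as.numeric(out$times) / 1000,
    effective_times_ns = as.numeric(out$times) / 1000 *
      config$time_scale_factor,
    energies = en, ndof = out$ndof,
    beads = system$beads, constraints = system$constraints,
    set = system$set, config = config, seed = seed,
    final_velocities = out$final_velocities
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nf <- length(x$frames)
  cat("<cg_trajectory>", nf, "frames,", nrow(x$beads), "beads,",
      sprintf("%.3f ns simulated (%.3f ns effective)",
              max(x$times_ns), max(x$effective_times_ns)), "\n")
  invisible(x)
}

#' Solute bead indices of a trajectory or system
#' @param x a `cg_trajectory` or `cg_system`.
#' @return integer indices of non-solvent, non-ion beads.
#' @export
solute_indices <- function(x) {
  which(!x$beads$solvent & x$beads$type != "NA" & x$beads$type != "CL")
}
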