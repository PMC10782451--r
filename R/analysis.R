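# Quantitative screening metrics: SASA, aggregation propensity, RDF,
# constraint-corrected group temperatures, tube-fraction statistics.

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the bead spheres using a deterministic
#' golden-spiral point set.  Bead radii default to half the bead's
#' self-interaction sigma; the probe default (0.14 nm) matches the standard
#' CG analysis protocol.
#'
#' @param positions N x 3 matrix, nm (solute beads only).
#' @param radii per-bead radii, nm.
#' @param probe probe radius, nm.
#' @param n_points sphere points per bead (default 960).
#' @param box cubic box edge for minimum-image treatment; 0 disables
#'   periodicity.
#' @return total area in nm^2; per-bead areas in attribute `per_bead`.
#' @export
sasa <- function(positions, radii, probe = 0.14, n_points = 960L, box = 0) {
  positions <- as.matrix(positions)
  if (length(radii) == 1) radii <- rep(radii, nrow(positions))
  if (length(radii) != nrow(positions))
    stop("need one radius per bead (", nrow(positions), "), got ",
         length(radii), call. = FALSE)
  if (anyNA(radii)) stop("missing radius for some bead(s)", call. = FALSE)
  out <- cpp_sasa(positions, radii, probe, as.integer(n_points), box)
  structure(out$total, per_bead = out$per_bead)
}

#' Aggregation propensity from a trajectory
#'
#' AP = SASA(first frame) / SASA(last frame) over the solute beads.  AP stays
#' near 1 for molecules that remain in solution and grows as aggregation
#' buries surface; systems with AP >= 2 are read as aggregated.  Reported to
#' one decimal by convention.
#'
#' @param traj a [run_md()] trajectory (or list with `frames`, `boxes`,
#'   `beads`).
#' @param radii per-solute-bead radii; defaults to `sigma_self / 2`.
#' @param probe probe radius, nm.
#' @param n_points sphere points per bead.
#' @return object of class `cg_ap` with `sasa_initial`, `sasa_final`, `ap`,
#'   `ap_reported` (1 decimal) and `aggregated` (AP >= 2).
#' @export
aggregation_propensity <- function(traj, radii = NULL, probe = 0.14,
                                   n_points = 960L) {
  if (length(traj$frames) < 2)
    stop("need at least two frames", call. = FALSE)
  sol <- solute_indices(traj)
  if (is.null(radii)) radii <- traj$beads$sigma_self[sol] / 2
  first <- traj$frames[[1]][sol, , drop = FALSE]
  last <- traj$frames[[length(traj$frames)]][sol, , drop = FALSE]
  s0 <- as.numeric(sasa(first, radii, probe, n_points, traj$boxes[1]))
  sf <- as.numeric(sasa(last, radii, probe, n_points,
                        traj$boxes[length(traj$boxes)]))
  if (sf <= 0) stop("degenerate final SASA (zero)", call. = FALSE)
  ap <- s0 / sf
  structure(list(sasa_initial = s0, sasa_final = sf, ap = ap,
                 ap_reported = round(ap, 1), aggregated = ap >= 2),
            class = "cg_ap")
}

#' @export
print.cg_ap <- function(x, ...) {
  cat(sprintf("<cg_ap> AP = %.1f (SASA %.1f -> %.1f nm^2)%s\n",
              x$ap_reported, x$sasa_initial, x$sasa_final,
              if (x$aggregated) " [aggregated]" else ""))
  invisible(x)
}

# mass-weighted side-chain centres of mass per residue of a residue type
.sidechain_coms <- function(frame, beads, residue_letter = "F", box = 0) {
  sel <- !beads$solvent & beads$role == "sidechain" &
    substr(beads$sequence, beads$residue, beads$residue) == residue_letter
  if (!any(sel)) return(matrix(0, 0, 3))
  key <- paste(beads$mol[sel], beads$residue[sel])
  pos <- frame[sel, , drop = FALSE]
  m <- beads$mass[sel]
  ks <- unique(key)
  out <- matrix(0, length(ks), 3)
  for (i in seq_along(ks)) {
    w <- key == ks[i]
    p <- pos[w, , drop = FALSE]
    # make the ring whole before averaging (minimum image about first bead)
    ref <- p[1, ]
    for (j in seq_len(nrow(p))) {
      d <- p[j, ] - ref
      if (box > 0) d <- d - box * round(d / box)
      p[j, ] <- ref + d
    }
    out[i, ] <- colSums(p * m[w]) / sum(m[w])
  }
  out
}

#' Radial distribution function of side-chain centres of mass
#'
#' Standard pair-density g(r) under cubic periodic boundaries, computed over
#' the last fraction of the trajectory (default 20%, the scaled-down analogue
#' of analysing the final microsecond).  The selection is the mass-weighted
#' centre of mass of each side chain of `residue_letter`.
#'
#' @param traj a trajectory. @param residue_letter residue to select.
#' @param bin histogram bin width, nm. @param r_max maximum distance
#'   (default half the box). @param window fraction of final frames used.
#' @return object of class `cg_rdf` with `r_centers`, `g`, `first_max_r`.
#' @export
rdf <- function(traj, residue_letter = "F", bin = 0.01, r_max = NULL,
                window = 0.2) {
  if (bin <= 0) stop("bin must be positive", call. = FALSE)
  nf <- length(traj$frames)
  use <- seq(max(1, ceiling(nf * (1 - window))), nf)
  box <- traj$boxes[use[1]]
  if (is.null(r_max)) r_max <- box / 2
  edges <- seq(0, r_max, by = bin)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin)
  counts <- numeric(length(edges) - 1)
  npairs_tot <- 0; vol_tot <- 0; nsel <- NA
  for (f in use) {
    centers <- .sidechain_coms(traj$frames[[f]], traj$beads, residue_letter,
                               traj$boxes[f])
    if (nrow(centers) < 2)
      stop("need at least two selected centres", call. = FALSE)
    nsel <- nrow(centers)
    d <- cpp_pair_dists(centers, traj$boxes[f])
    d <- d[d < r_max]
    counts <- counts + tabulate(pmin(length(counts),
                                     pmax(1L, ceiling(d / bin))),
                                nbins = length(counts))
    npairs_tot <- npairs_tot + nrow(centers) * (nrow(centers) - 1) / 2
    vol_tot <- vol_tot + traj$boxes[f]^3
  }
  r_lo <- edges[-length(edges)]; r_hi <- edges[-1]
  shell <- 4 / 3 * pi * (r_hi^3 - r_lo^3)
  vbar <- vol_tot / length(use)
  ideal <- npairs_tot * shell / vbar
  g <- ifelse(ideal > 0, counts / ideal, 0)
  rc <- (r_lo + r_hi) / 2
  structure(list(r_centers = rc, g = g,
                 first_max_r = rc[which.max(g)],
                 selection = paste0(residue_letter, " side-chain COM"),
                 n_centers = nsel, n_frames = length(use)),
            class = "cg_rdf")
}

#' @export
print.cg_rdf <- function(x, ...) {
  cat(sprintf("<cg_rdf> %s, %d centres, %d frames; global max at %.2f nm\n",
              x$selection, x$n_centers, x$n_frames, x$first_max_r))
  invisible(x)
}

#' Constraint-corrected group temperatures
#'
#' Kinetic temperatures of consecutive groups of solute molecules, with the
#' degrees of freedom reduced by the constraints each molecule carries: for a
#' molecule of N beads and c constraints the correction factor is
#' 3N/(3N - c) (24/18 = 1.333 for an 8-bead, 6-constraint dipeptide).
#'
#' @param traj a trajectory carrying frame velocities.
#' @param group_size molecules per group (default 200).
#' @param window fraction of final frames averaged (default 0.5).
#' @return object of class `cg_group_temp`: per-group mean temperatures,
#'   the per-molecule `dof_correction`, and a flag for a short last group.
#' @export
group_temperature <- function(traj, group_size = 200L, window = 0.5) {
  sol <- solute_indices(traj)
  if (length(sol) == 0) stop("no solute beads", call. = FALSE)
  beads <- traj$beads[sol, ]
  mols <- unique(beads$mol)
  nmol <- length(mols)
  ngrp <- ceiling(nmol / group_size)
  grp_of_mol <- setNames(rep(seq_len(ngrp), each = group_size)[seq_len(nmol)],
                         mols)
  uneven <- nmol %% group_size != 0 && ngrp > 1
  # constraints per molecule (solute constraints only)
  conmol <- traj$beads$mol[traj$constraints$i]
  beads_per_mol <- table(beads$mol)[as.character(mols)]
  cons_per_mol <- table(factor(conmol, levels = mols))
  N1 <- as.numeric(beads_per_mol[1]); c1 <- as.numeric(cons_per_mol[1])
  nf <- length(traj$frames)
  use <- seq(max(1, ceiling(nf * (1 - window))), nf)
  temps <- matrix(0, length(use), ngrp)
  grp_of_bead <- grp_of_mol[as.character(beads$mol)]
  for (fi in seq_along(use)) {
    v <- traj$velocities[[use[fi]]][sol, , drop = FALSE]
    ke2 <- beads$mass * rowSums(v^2)  # 2 x kinetic energy per bead
    for (g in seq_len(ngrp)) {
      w <- grp_of_bead == g
      nb <- sum(w)
      nc <- sum(cons_per_mol[unique(beads$mol[w]) |> as.character()])
      dof <- 3 * nb - nc
      temps[fi, g] <- sum(ke2[w]) / (dof * .kB)
    }
  }
  structure(list(temps = colMeans(temps), group_size = group_size,
                 n_groups = ngrp, uneven_last_group = uneven,
                 dof_correction = 3 * N1 / (3 * N1 - c1)),
            class = "cg_group_temp")
}

#' @export
print.cg_group_temp <- function(x, ...) {
  cat(sprintf(
    "<cg_group_temp> %d group(s) of %d molecules; mean T %.1f K; DOF factor %.3f\n",
    x$n_groups, x$group_size, mean(x$temps), x$dof_correction))
  if (x$uneven_last_group) cat("  note: last group is smaller\n")
  invisible(x)
}

#' Tube fraction across replica simulations
#'
#' Fraction of replicas whose final morphology is a tube, with the standard
#' error computed as sd of the replica indicators divided by sqrt(n - 1).
#'
#' @param labels character vector of per-replica morphology labels.
#' @return object of class `cg_tube_fraction` with `fraction`, `sem`,
#'   `n_replicas`.
#' @export
tube_fraction <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2) stop("need at least 2 replicas (sem undefined)", call. = FALSE)
  ind <- as.numeric(labels == "tube")
  structure(list(fraction = mean(ind), sem = sd(ind) / sqrt(n - 1),
                 n_replicas = n),
            class = "cg_tube_fraction")
}

#' @export
print.cg_tube_fraction <- function(x, ...) {
  cat(sprintf("<cg_tube_fraction> %.2f +/- %.3f (n = %d)\n",
              x$fraction, x$sem, x$n_replicas))
  invisible(x)
}
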