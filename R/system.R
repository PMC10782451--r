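# Periodic system assembly: random insertion, solvation, neutralization.

#' System specification
#'
#' Records the composition of a periodic simulation box: sequences with copy
#' counts (co-assembly ratios supported), box side, solvation/neutralization
#' switches and the insertion seed.
#'
#' @param sequences character vector of residue strings.
#' @param counts integer copy count per sequence.
#' @param box_side cubic box edge, nm.
#' @param water,neutralize logical switches.
#' @param seed integer seed for insertion and solvation.
#' @return object of class `cg_system_spec`.
#' @export
system_spec <- function(sequences, counts, box_side, water = TRUE,
                        neutralize = TRUE, seed = 1L) {
  stopifnot(length(sequences) == length(counts), box_side > 0,
            all(counts >= 0))
  structure(list(sequences = toupper(sequences), counts = as.integer(counts),
                 box_side = box_side, water = water, neutralize = neutralize,
                 seed = as.integer(seed)),
            class = "cg_system_spec")
}

#' Solute concentration of a composition
#'
#' total molecules / (Avogadro x box volume), reported in mM.
#'
#' @param counts total molecule count (or a `cg_system_spec`).
#' @param box_side box edge in nm (ignored when a spec is given).
#' @return concentration in mM.
#' @export
concentration_of <- function(counts, box_side = NULL) {
  if (inherits(counts, "cg_system_spec")) {
    box_side <- counts$box_side
    counts <- sum(counts$counts)
  }
  stopifnot(box_side > 0)
  vol_l <- box_side^3 * 1e-24
  counts / (.N_AVOGADRO * vol_l) * 1000
}

#' @export
print.cg_system_spec <- function(x, ...) {
  cat("<cg_system_spec>",
      paste(sprintf("%dx %s", x$counts, x$sequences), collapse = " + "),
      "in", x$box_side, "nm box ->",
      signif(concentration_of(x), 3), "mM\n")
  invisible(x)
}

# replicate a topology n times into global bead/bonded tables
.replicate_topology <- function(topology, n, mol_offset = 0L,
                                idx_offset = 0L) {
  m <- nrow(topology$beads)
  beads <- topology$beads[rep(seq_len(m), n), , drop = FALSE]
  beads$mol <- mol_offset + rep(seq_len(n), each = m)
  beads$solvent <- FALSE
  beads$sequence <- topology$sequence
  rownames(beads) <- NULL
  off <- idx_offset + (rep(seq_len(n), each = 1) - 1) * m
  shift2 <- function(df, cols) {
    if (nrow(df) == 0) return(df[rep(0, 0), , drop = FALSE])
    out <- df[rep(seq_len(nrow(df)), n), , drop = FALSE]
    for (cl in cols)
      out[[cl]] <- out[[cl]] + rep(off, each = nrow(df))
    rownames(out) <- NULL
    out
  }
  list(beads = beads,
       bonds = shift2(topology$bonds, c("i", "j")),
       constraints = shift2(topology$constraints, c("i", "j")),
       angles = shift2(topology$angles, c("i", "j", "k")),
       exclusions = shift2(topology$exclusions, c("i", "j")))
}

#' Insert molecules into a periodic box
#'
#' Places `count` rigid copies of the topology template at random positions
#' and orientations, rejecting placements that bring beads of different
#' molecules closer than `min_dist` (minimum image).  Deterministic under a
#' fixed seed.
#'
#' @param topology a [build_topology()] result.
#' @param count number of copies.
#' @param box_side cubic box edge, nm.
#' @param seed integer seed.
#' @param min_dist insertion cutoff in nm (default 0.21).
#' @param max_tries placement attempts per molecule before giving up.
#' @return object of class `cg_system`.
#' @export
insert_molecules <- function(topology, count, box_side, seed = 1L,
                             min_dist = 0.21, max_tries = 5000L) {
  stopifnot(inherits(topology, "cg_topology"), count >= 1, box_side > 0)
  tmpl <- topology$coords
  tmpl <- sweep(tmpl, 2, colMeans(tmpl))
  res <- cpp_insert_molecules(tmpl, as.integer(count), box_side, min_dist,
                              as.integer(seed), as.integer(max_tries))
  if (res$placed < count)
    stop("insertion failed: placed ", res$placed, " of ", count,
         " molecules in a ", box_side, " nm box at min_dist ", min_dist,
         call. = FALSE)
  rep <- .replicate_topology(topology, count)
  structure(list(beads = rep$beads, positions = res$positions,
                 velocities = NULL, box = box_side,
                 bonds = rep$bonds, constraints = rep$constraints,
                 angles = rep$angles, exclusions = rep$exclusions,
                 set = topology$set, n_solute_molecules = count,
                 version = topology$set$base_version),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  ns <- sum(!x$beads$solvent)
  cat("<cg_system>", nrow(x$beads), "beads (", ns, "solute ) in",
      x$box, "nm box, net charge", sum(x$beads$charge), "\n")
  invisible(x)
}

# reference CG water number density (one bead per 4 waters), beads/nm^3
.WATER_DENSITY <- 8.3

#' Solvate and neutralize a system
#'
#' Fills void space with coarse-grained water beads at the reference density
#' (about one bead per four real waters, 8.3 beads/nm^3), then replaces water
#' beads by counter-ions until the net system charge is zero.  Zwitterionic
#' solutes such as FF need no ions.
#'
#' @param system a [insert_molecules()] result (or NULL for water only).
#' @param box_side box edge when `system` is NULL.
#' @param water,neutralize switches.
#' @param seed integer seed for lattice jitter and ion placement.
#' @param exclusion_radius water beads closer than this to a solute bead are
#'   discarded, nm.
#' @param version force-field generation of the water bead when building a
#'   water-only box (`"v3"` uses W, the v2 generation P4).
#' @return the solvated `cg_system`.
#' @export
solvate_and_neutralize <- function(system = NULL, box_side = NULL,
                                   water = TRUE, neutralize = TRUE,
                                   seed = 1L, exclusion_radius = 0.40,
                                   version = "v3") {
  if (is.null(system)) {
    stopifnot(!is.null(box_side))
    system <- structure(list(
      beads = data.frame(type = character(0), charge = numeric(0),
                         mass = numeric(0), residue = integer(0),
                         role = character(0), sigma_self = numeric(0),
                         mol = integer(0), solvent = logical(0),
                         sequence = character(0)),
      positions = matrix(0, 0, 3), velocities = NULL, box = box_side,
      bonds = data.frame(i = integer(0), j = integer(0), b0 = numeric(0),
                         k = numeric(0)),
      constraints = data.frame(i = integer(0), j = integer(0), d = numeric(0)),
      angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                          theta0 = numeric(0), ktheta = numeric(0)),
      exclusions = data.frame(i = integer(0), j = integer(0)),
      set = NULL, n_solute_molecules = 0L, version = version),
      class = "cg_system")
  }
  stopifnot(inherits(system, "cg_system"))
  ver <- if (identical(system$version, "v3")) "v3" else "v2"
  wname <- if (ver == "v3") "W" else "P4"
  bt <- bead_types(if (ver == "v3") "v3" else "v2.1")
  L <- system$box

  if (water) {
    spacing0 <- (1 / .WATER_DENSITY)^(1 / 3)
    nper <- max(1L, ceiling(L / spacing0))
    sp <- L / nper
    g <- seq(0, L - sp, length.out = nper) + sp / 2
    grid <- as.matrix(expand.grid(x = g, y = g, z = g))
    keep <- rep(TRUE, nrow(grid))
    if (nrow(system$positions) > 0) {
      # minimum-image distance of each grid point to the nearest solute bead
      sol <- system$positions
      nmax <- 200000  # grid-point x solute-bead products per chunk
      for (start in seq(1, nrow(grid), by = max(1, floor(nmax / nrow(sol))))) {
        end <- min(nrow(grid), start + max(1, floor(nmax / nrow(sol))) - 1)
        idx <- start:end
        dmin <- rep(Inf, length(idx))
        for (k in seq_len(nrow(sol))) {
          dx <- grid[idx, 1] - sol[k, 1]; dx <- dx - L * round(dx / L)
          dy <- grid[idx, 2] - sol[k, 2]; dy <- dy - L * round(dy / L)
          dz <- grid[idx, 3] - sol[k, 3]; dz <- dz - L * round(dz / L)
          dmin <- pmin(dmin, dx * dx + dy * dy + dz * dz)
        }
        keep[idx] <- dmin >= exclusion_radius^2
      }
    }
    cand <- grid[keep, , drop = FALSE]
    target <- round(.WATER_DENSITY * L^3 * nrow(cand) / nrow(grid))
    target <- min(target, nrow(cand))
    wpos <- with_seed(seed, function() {
      sel <- sample.int(nrow(cand), target)
      jit <- matrix(rnorm(3 * target, sd = 0.05), ncol = 3)
      p <- cand[sel, , drop = FALSE] + jit
      p - L * floor(p / L)
    })
    iw <- match(wname, bt$name)
    wbeads <- data.frame(
      type = wname, charge = 0, mass = bt$mass[iw], residue = 1L,
      role = "solvent", sigma_self = bt$sigma_self[iw],
      mol = max(c(0L, system$beads$mol)) + seq_len(target),
      solvent = TRUE, sequence = "W", stringsAsFactors = FALSE
    )
    system$beads <- rbind(system$beads, wbeads)
    system$positions <- rbind(system$positions, wpos)
  }

  if (neutralize) {
    q <- round(sum(system$beads$charge))
    if (q != 0) {
      wat <- which(system$beads$solvent & system$beads$type %in% c("W", "P4"))
      if (length(wat) < abs(q))
        stop("not enough water beads to place ", abs(q), " counter-ions")
      ion <- if (q > 0) "CL" else "NA"
      ii <- match(ion, bt$name)
      pick <- with_seed(seed + 1L, function() sample(wat, abs(q)))
      system$beads$type[pick] <- ion
      system$beads$charge[pick] <- if (q > 0) -1 else 1
      system$beads$mass[pick] <- bt$mass[ii]
      system$beads$sigma_self[pick] <- bt$sigma_self[ii]
      system$beads$role[pick] <- "ion"
    }
  }
  rownames(system$beads) <- NULL
  system
}

#' Number of ions of each species in a system
#' @param system a `cg_system`.
#' @return named integer vector (NA+, CL-).
#' @export
ion_counts <- function(system) {
  c(`NA` = sum(system$beads$type == "NA"),
    CL = sum(system$beads$type == "CL"))
}
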