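# Residue -> coarse-grained topology mapping for 1-3 residue peptides.
#
# Backbone: one bead per residue; charged termini (protonated N-terminus +1,
# deprotonated C-terminus -1) use the parameter set's terminus beads, middle
# residues a neutral polar bead (P5 in the v2 generation, P2 in v3).
# Aromatic side chains are rigid bodies held by distance constraints (the F
# ring is a 3-bead constrained triangle; W a 4-bead constrained plate), so
# their geometry is maintained exactly by the constraint solver.  Only the
# backbone bond force constants (400 coil / 1250 extended) are anchored to
# published values; side-chain bond lengths and the 0.27 nm ring edges follow
# the public force-field releases.

.SUPPORTED_RESIDUES <- c("F", "W", "Y", "I", "P", "G", "H", "K", "D")

# side-chain bead names per base version; F comes from the parameter set
.side_beads <- function(res, set) {
  v2 <- set$base_version %in% c("v2.1", "v2.2")
  if (res == "F") return(set$f_ring)
  if (v2) {
    switch(res,
      W = c("SC4", "SNd", "SC4", "SC4"),
      Y = c("SC4", "SC4", "SP1"),
      I = "C1", P = "C3",
      H = c("SC4", "SP1", "SP1"),
      K = c("C3", "Qd"),
      D = "Qa",
      G = character(0))
  } else {
    arom <- isTRUE(set$aromatic_sc4)
    switch(res,
      W = if (arom) c("SC4", "TN6d", "SC4", "SC4")
          else c("TC4", "TN6d", "TC5", "TC5"),
      Y = if (arom) c("SC4", "SC4", "TN6d") else c("TC4", "TC5", "TN6d"),
      I = "SC2", P = "SC3",
      H = c("TC4", "TN6d", "TN5a"),
      K = c("SC3", "SQ4p"),
      D = "SQ5n",
      G = character(0))
  }
}

.side_charge <- function(res, nbeads) {
  q <- rep(0, nbeads)
  if (res == "K") q[nbeads] <- 1
  if (res == "D") q[nbeads] <- -1
  q
}

# embed a triangle with edge lengths d12, d13, d23 in the plane
.triangle_xy <- function(d12, d13, d23) {
  x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y3 <- sqrt(pmax(0, d13^2 - x3^2))
  rbind(c(0, 0), c(d12, 0), c(x3, y3))
}

#' Build a coarse-grained peptide topology
#'
#' Maps a 1-3 residue sequence onto beads, bonds, constraints, angles and
#' exclusions under a chosen parameter set, together with a template 3D
#' conformation whose ring geometries satisfy the constraints exactly.
#'
#' @param sequence residue string over F, W, Y, I, P, G, H, K, D.
#' @param set a [make_parameter_set()] object (or an id string).
#' @return object of class `cg_topology` with elements `beads` (data.frame:
#'   `type`, `charge`, `mass`, `residue`, `role`, `sigma_self`), `bonds`,
#'   `constraints`, `angles`, `exclusions`, `coords` (template, nm) and
#'   metadata.
#' @export
build_topology <- function(sequence, set) {
  if (is.character(set)) set <- make_parameter_set(set)
  stopifnot(inherits(set, "cg_parameter_set"))
  res <- strsplit(toupper(sequence), "")[[1]]
  if (length(res) < 1 || length(res) > 3)
    stop("sequence must have 1-3 residues", call. = FALSE)
  bad <- setdiff(res, .SUPPORTED_RESIDUES)
  if (length(bad))
    stop("unsupported residue(s) ", paste(bad, collapse = ", "),
         "; supported: ", paste(.SUPPORTED_RESIDUES, collapse = ", "),
         call. = FALSE)
  v2 <- set$base_version %in% c("v2.1", "v2.2")
  mid_bb <- if (v2) "P5" else "P2"
  bt <- bead_types(set$base_version)
  nres <- length(res)

  type <- charge <- role <- character(0)
  residue <- integer(0)
  coords <- NULL
  bonds <- cons <- angles <- NULL
  bb_idx <- integer(nres)
  sc1_idx <- rep(NA_integer_, nres)
  chg <- numeric(0)

  add_bead <- function(ty, q, resi, ro, xyz) {
    type <<- c(type, ty); chg <<- c(chg, q)
    residue <<- c(residue, resi); role <<- c(role, ro)
    coords <<- rbind(coords, xyz)
    length(type)
  }
  ring_edge_len <- function(a, b) {
    # S-S and T-T edges 0.27 nm; S-T edges 0.30 nm (mixed-size rings)
    sa <- bt$size_class[match(a, bt$name)]
    sb <- bt$size_class[match(b, bt$name)]
    if (!is.na(sa) && !is.na(sb) && sa != sb) 0.30 else 0.27
  }

  for (i in seq_len(nres)) {
    bb_x <- 0.35 * (i - 1)
    if (nres == 1) {
      bb_type <- set$termini[1]; bb_q <- 0  # single-residue zwitterion
    } else if (i == 1) {
      bb_type <- set$termini[1]; bb_q <- 1
    } else if (i == nres) {
      bb_type <- set$termini[2]; bb_q <- -1
    } else {
      bb_type <- mid_bb; bb_q <- 0
    }
    bb_idx[i] <- add_bead(bb_type, bb_q, i, "backbone", c(bb_x, 0, 0))

    sb <- .side_beads(res[i], set)
    if (length(sb) > 0) {
      qs <- .side_charge(res[i], length(sb))
      base <- c(bb_x, 0.31, 0)
      if (length(sb) %in% c(3, 4)) {
        d12 <- ring_edge_len(sb[1], sb[2])
        d13 <- if (length(sb) == 3) ring_edge_len(sb[1], sb[3]) else
          ring_edge_len(sb[1], sb[3])
        d23 <- ring_edge_len(sb[2], sb[3])
        tri <- .triangle_xy(d12, d13, d23)
        pos <- cbind(tri[, 1] + base[1], tri[, 2] + base[2], 0)
        if (length(sb) == 4) {
          # planar plate: 4th bead mirrors bead 1 across the 2-3 edge
          p4 <- pos[2, ] + pos[3, ] - pos[1, ]
          pos <- rbind(pos, p4)
        }
        idx <- integer(length(sb))
        for (k in seq_along(sb))
          idx[k] <- add_bead(sb[k], qs[k], i, "sidechain", pos[k, ])
        sc1_idx[i] <- idx[1]
        # rigid body: constrain every pair at its template distance
        for (a in seq_along(idx)) for (b in seq_along(idx)) {
          if (b <= a) next
          d <- sqrt(sum((pos[a, ] - pos[b, ])^2))
          cons <- rbind(cons, c(idx[a], idx[b], d))
        }
        bonds <- rbind(bonds, c(bb_idx[i], idx[1], 0.31, 7500))
      } else {
        idx <- integer(length(sb))
        for (k in seq_along(sb)) {
          xyz <- base + c(0, 0.30 * (k - 1), 0)
          idx[k] <- add_bead(sb[k], qs[k], i, "sidechain", xyz)
        }
        sc1_idx[i] <- idx[1]
        bonds <- rbind(bonds, c(bb_idx[i], idx[1], 0.32, 5000))
        if (length(idx) == 2)
          bonds <- rbind(bonds, c(idx[1], idx[2], 0.30, 5000))
      }
    }
  }
  # backbone bonds and angles
  if (nres >= 2) {
    for (i in seq_len(nres - 1))
      bonds <- rbind(bonds, c(bb_idx[i], bb_idx[i + 1], 0.35, set$bb_bond_k))
    for (i in seq_len(nres)) {
      j <- if (i < nres) i + 1 else i - 1
      if (!is.na(sc1_idx[i]))
        angles <- rbind(angles, c(sc1_idx[i], bb_idx[i], bb_idx[j], 100, 25))
    }
    if (nres == 3)
      angles <- rbind(angles, c(bb_idx[1], bb_idx[2], bb_idx[3], 127, 20))
  }

  bonds_df <- if (is.null(bonds)) {
    data.frame(i = integer(0), j = integer(0), b0 = numeric(0), k = numeric(0))
  } else {
    data.frame(i = bonds[, 1], j = bonds[, 2], b0 = bonds[, 3], k = bonds[, 4])
  }
  cons_df <- if (is.null(cons)) {
    data.frame(i = integer(0), j = integer(0), d = numeric(0))
  } else {
    data.frame(i = cons[, 1], j = cons[, 2], d = cons[, 3])
  }
  ang_df <- if (is.null(angles)) {
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               theta0 = numeric(0), ktheta = numeric(0))
  } else {
    data.frame(i = angles[, 1], j = angles[, 2], k = angles[, 3],
               theta0 = angles[, 4], ktheta = angles[, 5])
  }
  excl <- unique(rbind(
    as.matrix(bonds_df[, c("i", "j")]),
    as.matrix(cons_df[, c("i", "j")])
  ))
  excl_df <- data.frame(i = excl[, 1], j = excl[, 2])

  m <- match(type, bt$name)
  if (anyNA(m)) stop("internal: bead type missing from table: ",
                     paste(type[is.na(m)], collapse = ", "))
  beads <- data.frame(
    type = type, charge = chg, mass = bt$mass[m], residue = residue,
    role = role, sigma_self = bt$sigma_self[m], stringsAsFactors = FALSE
  )
  rownames(coords) <- NULL
  structure(list(sequence = paste(res, collapse = ""), set = set,
                 beads = beads, bonds = bonds_df, constraints = cons_df,
                 angles = ang_df, exclusions = excl_df, coords = coords),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology>", x$sequence, "under", x$set$id, "-",
      nrow(x$beads), "beads,", nrow(x$bonds), "bonds,",
      nrow(x$constraints), "constraints, net charge",
      sum(x$beads$charge), "\n")
  invisible(x)
}

#' Net molecular charge of a topology
#' @param topology a `cg_topology`.
#' @return integer net charge in elementary charges.
#' @export
net_charge <- function(topology) {
  stopifnot(inherits(topology, "cg_topology"))
  sum(topology$beads$charge)
}
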