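# Labelled synthetic bead-cloud fixtures for the morphology classifier.
#
# Each geometry is generated with a ground-truth label by construction
# (hollow geometries have interior voids by design), deterministic under a
# seed, with every bead its own molecule - the classifier input produced by
# dissolving real trajectories into (position, molecule) pairs.

#' Fixture specification and generation
#'
#' Supported geometries and their size parameters (nm):
#' * `tube`: open hollow cylinder (`inner_radius`, `wall`, `length`);
#' * `vesicle`: closed spherical shell (`inner_radius`, `wall`);
#' * `bilayer`: flat disc patch (`patch_radius`, `wall` thickness);
#' * `solid_sphere`: filled ball (`outer_radius`);
#' * `dispersed`: monomer lattice with spacing > the clustering cutoff.
#'
#' @param geometry one of tube, vesicle, bilayer, solid_sphere, dispersed.
#' @param inner_radius,wall,length,patch_radius,outer_radius geometry sizes.
#' @param density bead number density inside the geometry, nm^-3.
#' @param noise isotropic positional jitter sd, nm.
#' @param seed integer seed.
#' @param box cubic box edge; default fits the geometry with a margin.
#' @return list with `positions`, `mol`, `box`, `label` (the ground truth)
#'   and the spec.
#' @export
generate_fixture <- function(geometry = c("tube", "vesicle", "bilayer",
                                          "solid_sphere", "dispersed"),
                             inner_radius = 3, wall = 1, length = 8,
                             patch_radius = 4, outer_radius = 3,
                             density = 8, noise = 0.05, seed = 1L,
                             box = NULL) {
  geometry <- match.arg(geometry)
  if (geometry %in% c("tube", "vesicle") && inner_radius <= 0)
    stop("inner_radius must be positive", call. = FALSE)
  if (wall <= 0 || density <= 0) stop("invalid geometry sizes", call. = FALSE)

  pts <- with_seed(seed, function() {
    switch(geometry,
      tube = {
        ro <- inner_radius + wall
        vol <- pi * (ro^2 - inner_radius^2) * length
        n <- max(50, round(vol * density))
        r <- sqrt(runif(n, inner_radius^2, ro^2))
        th <- runif(n, 0, 2 * pi)
        z <- runif(n, -length / 2, length / 2)
        cbind(r * cos(th), r * sin(th), z)
      },
      vesicle = {
        ro <- inner_radius + wall
        vol <- 4 / 3 * pi * (ro^3 - inner_radius^3)
        n <- max(50, round(vol * density))
        r <- (runif(n, inner_radius^3, ro^3))^(1 / 3)
        u <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
        s <- sqrt(1 - u^2)
        cbind(r * s * cos(phi), r * s * sin(phi), r * u)
      },
      bilayer = {
        vol <- pi * patch_radius^2 * wall
        n <- max(50, round(vol * density))
        r <- sqrt(runif(n, 0, patch_radius^2))
        th <- runif(n, 0, 2 * pi)
        z <- runif(n, -wall / 2, wall / 2)
        cbind(r * cos(th), r * sin(th), z)
      },
      solid_sphere = {
        vol <- 4 / 3 * pi * outer_radius^3
        n <- max(50, round(vol * density))
        r <- (runif(n, 0, outer_radius^3))^(1 / 3)
        u <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
        s <- sqrt(1 - u^2)
        cbind(r * s * cos(phi), r * s * sin(phi), r * u)
      },
      dispersed = {
        g <- seq(-4.5, 4.5, by = 1.5)
        as.matrix(expand.grid(g, g, g))
      }
    )
  })
  pts <- pts + with_seed(seed + 7L, function()
    matrix(rnorm(nrow(pts) * 3, sd = noise), ncol = 3))
  # random rigid rotation so orientation is never axis-aligned by accident
  rot <- with_seed(seed + 13L, function() {
    m <- matrix(rnorm(9), 3)
    qr.Q(qr(m))
  })
  pts <- pts %*% rot
  if (is.null(box)) {
    ext <- max(apply(pts, 2, function(x) diff(range(x))))
    box <- ext + 4
  }
  pts <- sweep(pts, 2, colMeans(pts)) + box / 2
  pts <- pts - box * floor(pts / box)
  list(positions = pts, mol = seq_len(nrow(pts)), box = box,
       label = switch(geometry, tube = "tube", vesicle = "vesicle",
                      bilayer = "bilayer", solid_sphere = "solid",
                      dispersed = "solution"),
       geometry = geometry, seed = seed)
}
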