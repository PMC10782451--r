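# Fixed-column GRO coordinate files (nm; optional velocities) and a minimal
# TOP writer for the molecule/system sections.

.parse_gro_block <- function(lines, start) {
  if (start + 1 > length(lines))
    stop("truncated GRO file at line ", start, call. = FALSE)
  title <- lines[start]
  nat <- suppressWarnings(as.integer(trimws(lines[start + 1])))
  if (is.na(nat))
    stop("malformed atom count at line ", start + 1, call. = FALSE)
  if (start + 1 + nat + 1 > length(lines))
    stop("truncated GRO file: expected ", nat, " atoms from line ",
         start + 2, call. = FALSE)
  at <- lines[(start + 2):(start + 1 + nat)]
  num <- function(s, from, to) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    v
  }
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resname <- trimws(substr(at, 6, 10))
  name <- trimws(substr(at, 11, 15))
  x <- num(at, 21, 28); y <- num(at, 29, 36); z <- num(at, 37, 44)
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed coordinate at line ", start + 1 + bad[1], call. = FALSE)
  has_vel <- all(nchar(at) >= 68)
  vel <- NULL
  if (has_vel) {
    vx <- num(at, 45, 52); vy <- num(at, 53, 60); vz <- num(at, 61, 68)
    if (!anyNA(c(vx, vy, vz))) vel <- cbind(vx, vy, vz)
  }
  bl <- strsplit(trimws(lines[start + 2 + nat]), "\\s+")[[1]]
  boxv <- suppressWarnings(as.numeric(bl))
  if (anyNA(boxv) || length(boxv) < 3)
    stop("malformed box line at line ", start + 2 + nat, call. = FALSE)
  list(title = title, resid = resid, resname = resname, name = name,
       positions = cbind(x, y, z), velocities = vel, box = boxv[1],
       next_start = start + 3 + nat)
}

#' Read a GRO coordinate file
#'
#' Parses the fixed-column GRO dialect (positions in nm to three decimals,
#' optional velocities).  Multi-frame files are supported.
#'
#' @param path file path.
#' @param frames `"first"`, `"last"` or `"all"`.
#' @return a frame list (`title`, `name`, `resname`, `resid`, `positions`,
#'   `velocities`, `box`) or a list of frames when `frames = "all"`.
#' @export
read_gro <- function(path, frames = c("first", "all", "last")) {
  frames <- match.arg(frames)
  lines <- readLines(path)
  out <- list()
  start <- 1
  while (start <= length(lines) && nzchar(trimws(paste(
    lines[seq(start, min(start + 1, length(lines)))], collapse = "")))) {
    blk <- .parse_gro_block(lines, start)
    out[[length(out) + 1]] <- blk[setdiff(names(blk), "next_start")]
    start <- blk$next_start
    if (frames == "first") break
  }
  if (length(out) == 0) stop("no frames in ", path, call. = FALSE)
  switch(frames, first = out[[1]], last = out[[length(out)]], all = out)
}

#' Write a GRO coordinate file
#'
#' @param path file path.
#' @param positions N x 3 matrix, nm.
#' @param names atom (bead) names. @param resnames residue names.
#' @param resid residue numbers. @param box cubic box edge, nm.
#' @param velocities optional N x 3 matrix, nm/ps.
#' @param title header line. @param append append as an extra frame.
#' @return the path, invisibly.
#' @export
write_gro <- function(path, positions, names, box, resnames = NULL,
                      resid = NULL, velocities = NULL,
                      title = "cgpep frame", append = FALSE) {
  n <- nrow(positions)
  if (is.null(resnames)) resnames <- names
  if (is.null(resid)) resid <- seq_len(n)
  resid <- ((resid - 1) %% 99999) + 1
  atnum <- ((seq_len(n) - 1) %% 99999) + 1
  lines <- c(title, sprintf("%5d", n))
  if (is.null(velocities)) {
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    resid, substr(resnames, 1, 5), substr(names, 1, 5),
                    atnum, positions[, 1], positions[, 2], positions[, 3])
  } else {
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                    resid, substr(resnames, 1, 5), substr(names, 1, 5),
                    atnum, positions[, 1], positions[, 2], positions[, 3],
                    velocities[, 1], velocities[, 2], velocities[, 3])
  }
  lines <- c(lines, body, sprintf("%10.5f%10.5f%10.5f", box, box, box))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Write a system as GRO (+ optional TOP)
#'
#' @param system a `cg_system`.
#' @param gro_path output GRO path.
#' @param top_path optional TOP path (molecule + system sections).
#' @return `gro_path`, invisibly.
#' @export
write_system_gro <- function(system, gro_path, top_path = NULL) {
  b <- system$beads
  resname <- ifelse(b$solvent, ifelse(b$type %in% c("NA", "CL"), "ION", "W"),
                    b$sequence)
  write_gro(gro_path, system$positions, b$type, system$box,
            resnames = resname, resid = b$mol,
            velocities = system$velocities,
            title = sprintf("cgpep system, %d beads", nrow(b)))
  if (!is.null(top_path)) {
    con <- file(top_path, "w"); on.exit(close(con))
    writeLines(c("; topology written by cgpep", "", "[ system ]",
                 "cgpep system", "", "[ molecules ]"), con)
    seqs <- unique(b$sequence[!b$solvent])
    for (s in seqs)
      writeLines(sprintf("%-10s %d", s,
                         length(unique(b$mol[b$sequence == s & !b$solvent]))),
                 con)
    nw <- sum(b$solvent & !b$type %in% c("NA", "CL"))
    if (nw > 0) writeLines(sprintf("%-10s %d", "W", nw), con)
    ic <- ion_counts(system)
    for (i in seq_along(ic))
      if (ic[i] > 0)
        writeLines(sprintf("%-10s %d", names(ic)[i], ic[i]), con)
  }
  invisible(gro_path)
}

#' Write a trajectory as multi-frame GRO
#'
#' @param traj a `cg_trajectory`. @param path output path.
#' @param velocities include frame velocities.
#' @return the path, invisibly.
#' @export
write_trajectory_gro <- function(traj, path, velocities = FALSE) {
  b <- traj$beads
  resname <- ifelse(b$solvent, ifelse(b$type %in% c("NA", "CL"), "ION", "W"),
                    b$sequence)
  for (f in seq_along(traj$frames)) {
    write_gro(path, traj$frames[[f]], b$type, traj$boxes[f],
              resnames = resname, resid = b$mol,
              velocities = if (velocities) traj$velocities[[f]] else NULL,
              title = sprintf("t = %.4f ns (effective %.4f ns)",
                              traj$times_ns[f], traj$effective_times_ns[f]),
              append = f > 1)
  }
  invisible(path)
}
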