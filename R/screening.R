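# Screening orchestration: parameter sets x conditions x replicas ->
# aggregation propensities, morphologies, phase tables, tube-fraction curves.

#' Screening plan
#'
#' @param parameter_sets character vector of parameter-set ids.
#' @param conditions data.frame with columns `box_side` (nm) and
#'   `n_molecules`.
#' @param replicas replicas per (set, condition).
#' @param seeds integer seeds, at least `replicas` of them.
#' @param sequence residue string simulated (default FF).
#' @param config a [sim_config()] for the production runs.
#' @param step_budget warn when the planned total step count exceeds this.
#' @param cache_dir optional directory for resumable results.
#' @return object of class `cg_screen_plan`.
#' @export
screen_plan <- function(parameter_sets, conditions, replicas = 1L,
                        seeds = seq_len(replicas), sequence = "FF",
                        config = sim_config(), step_budget = 5e7,
                        cache_dir = NULL) {
  stopifnot(is.data.frame(conditions),
            all(c("box_side", "n_molecules") %in% names(conditions)),
            nrow(conditions) > 0, length(seeds) >= replicas)
  total <- length(parameter_sets) * nrow(conditions) * replicas *
    config$n_steps
  if (total > step_budget)
    warning("planned ", format(total, big.mark = ","),
            " integration steps exceed the step budget (",
            format(step_budget, big.mark = ","), ")", call. = FALSE)
  structure(list(parameter_sets = parameter_sets, conditions = conditions,
                 replicas = as.integer(replicas), seeds = as.integer(seeds),
                 sequence = toupper(sequence), config = config,
                 cache_dir = cache_dir),
            class = "cg_screen_plan")
}

.run_key <- function(set_id, box_side, n_mol, seed, n_steps, sequence) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(set_id, box_side, n_mol, seed, n_steps, sequence, 1L), f)
  unname(tools::md5sum(f))
}

# one screening simulation -> result row
.screen_one <- function(set_id, sequence, box_side, n_mol, seed, config) {
  set <- make_parameter_set(set_id)
  mat <- interaction_matrix(set$base_version)
  top <- build_topology(sequence, set)
  sys <- insert_molecules(top, n_mol, box_side, seed = seed)
  sys <- solvate_and_neutralize(sys, seed = seed)
  sys <- minimize(sys, mat, config)
  traj <- run_md(sys, mat, config, seed = seed)
  ap <- aggregation_propensity(traj)
  sol <- solute_indices(traj)
  lastf <- traj$frames[[length(traj$frames)]]
  morph <- classify_morphology(lastf[sol, , drop = FALSE],
                               traj$beads$mol[sol],
                               traj$boxes[length(traj$boxes)],
                               masses = traj$beads$mass[sol])
  data.frame(set_id = set$id, box_side = box_side, n_molecules = n_mol,
             concentration_mM = concentration_of(n_mol, box_side),
             seed = seed, ap = ap$ap, ap_reported = ap$ap_reported,
             morphology = morph$label,
             phase_class = phase_class(ap$ap, morph$label),
             stringsAsFactors = FALSE)
}

#' Map (AP, morphology) to a phase-diagram class
#'
#' Nonaggregated systems (AP < 2) are "solution"; aggregated systems whose
#' morphology is not compatible with hollow objects are "solid";
#' tube-compatible morphologies (bilayer, vesicle, tube) map to
#' "tube_compatible", with actual tubes promoted to "tube".
#'
#' @param ap aggregation propensity. @param morphology label.
#' @return one of solution, solid, tube_compatible, tube.
#' @export
phase_class <- function(ap, morphology) {
  stopifnot(length(ap) == length(morphology))
  out <- character(length(ap))
  for (i in seq_along(ap)) {
    out[i] <- if (ap[i] < 2) "solution"
    else if (morphology[i] == "tube") "tube"
    else if (morphology[i] %in% c("bilayer", "vesicle")) "tube_compatible"
    else "solid"
  }
  out
}

#' Run a screening plan
#'
#' One simulation per (parameter set, condition, replica seed).  Individual
#' failures are recorded and the screen continues.  With a `cache_dir`,
#' finished runs are identified by a content hash and skipped on replay.
#'
#' @param plan a [screen_plan()].
#' @param verbose print per-run progress.
#' @return object of class `cg_screen_result`: `runs` data.frame plus the
#'   plan.
#' @export
run_screen <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "cg_screen_plan"))
  cache_file <- NULL
  cache <- NULL
  if (!is.null(plan$cache_dir)) {
    dir.create(plan$cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache_file <- file.path(plan$cache_dir, "runs.csv")
    if (file.exists(cache_file))
      cache <- read.csv(cache_file, stringsAsFactors = FALSE)
  }
  rows <- list()
  n_new <- 0
  for (sid in plan$parameter_sets) {
    for (ci in seq_len(nrow(plan$conditions))) {
      bs <- plan$conditions$box_side[ci]
      nm <- plan$conditions$n_molecules[ci]
      for (r in seq_len(plan$replicas)) {
        seed <- plan$seeds[r]
        key <- .run_key(sid, bs, nm, seed, plan$config$n_steps,
                        plan$sequence)
        if (!is.null(cache) && key %in% cache$key) {
          rows[[length(rows) + 1]] <- cache[cache$key == key, , drop = FALSE]
          next
        }
        row <- tryCatch(
          .screen_one(sid, plan$sequence, bs, nm, seed, plan$config),
          error = function(e)
            data.frame(set_id = sid, box_side = bs, n_molecules = nm,
                       concentration_mM = concentration_of(nm, bs),
                       seed = seed, ap = NA_real_, ap_reported = NA_real_,
                       morphology = NA_character_,
                       phase_class = NA_character_,
                       stringsAsFactors = FALSE)
        )
        row$key <- key
        n_new <- n_new + 1
        if (verbose)
          message(sprintf("[screen] %s %gx%d seed %d: AP %.1f %s", sid, bs,
                          nm, seed, row$ap, row$morphology))
        rows[[length(rows) + 1]] <- row
        if (!is.null(cache_file)) {
          all <- do.call(rbind, rows)
          if (!is.null(cache))
            all <- rbind(cache[!cache$key %in% all$key, , drop = FALSE], all)
          write.csv(all, cache_file, row.names = FALSE)
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  structure(list(runs = runs, plan = plan, n_new_simulations = n_new),
            class = "cg_screen_result")
}

#' @export
print.cg_screen_result <- function(x, ...) {
  cat("<cg_screen_result>", nrow(x$runs), "runs (",
      x$n_new_simulations, "new )\n")
  print(head(x$runs[, c("set_id", "n_molecules", "seed", "ap_reported",
                        "morphology", "phase_class")], 10))
  invisible(x)
}

.PHASE_ORDER <- c("solution", "solid", "tube_compatible", "tube")

#' Phase table over a parameter grid
#'
#' One phase class per (ring beads x terminus bead) cell, decided by majority
#' vote across replicas/conditions; ties break toward the less ordered class
#' (solution < solid < tube_compatible < tube), conservative against false
#' tube claims.  Cells without data are `"no data"`.
#'
#' @param result a [run_screen()] result (or its `runs` data.frame).
#' @return data.frame: `ring`, `terminus`, `phase`.
#' @export
phase_table <- function(result) {
  runs <- if (inherits(result, "cg_screen_result")) result$runs else result
  split_id <- function(id) {
    m <- regmatches(id, regexec("^(.*)-(Q[1-5a-z]*)$", id))[[1]]
    if (length(m) == 3) c(m[2], m[3]) else c(id, "")
  }
  parts <- t(vapply(runs$set_id, split_id, character(2)))
  runs$ring <- parts[, 1]; runs$terminus <- parts[, 2]
  cells <- unique(runs[, c("ring", "terminus")])
  phase <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    w <- runs$ring == cells$ring[i] & runs$terminus == cells$terminus[i] &
      !is.na(runs$phase_class)
    if (!any(w)) { phase[i] <- "no data"; next }
    tb <- table(factor(runs$phase_class[w], levels = .PHASE_ORDER))
    best <- names(tb)[tb == max(tb)]
    phase[i] <- .PHASE_ORDER[min(match(best, .PHASE_ORDER))]
  }
  data.frame(ring = cells$ring, terminus = cells$terminus, phase = phase,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tube-fraction curve for one parameter set
#'
#' Per-concentration tube fraction with SEM = sd/sqrt(n - 1) over replicas,
#' plus the overall average optionally restricted to conditions with at
#' least `min_molecules` molecules.
#'
#' @param result a [run_screen()] result.
#' @param set_id parameter-set id.
#' @param min_molecules molecule-count floor for the overall average.
#' @return list with `curve` (data.frame) and `overall_fraction`.
#' @export
tube_fraction_curve <- function(result, set_id, min_molecules = 0) {
  runs <- if (inherits(result, "cg_screen_result")) result$runs else result
  runs <- runs[runs$set_id == set_id & !is.na(runs$morphology), ]
  if (nrow(runs) == 0) stop("no runs for set ", set_id, call. = FALSE)
  concs <- sort(unique(runs$n_molecules))
  rows <- lapply(concs, function(nm) {
    w <- runs$n_molecules == nm
    tf <- tube_fraction(runs$morphology[w])
    data.frame(n_molecules = nm,
               concentration_mM = runs$concentration_mM[w][1],
               fraction = tf$fraction, sem = tf$sem,
               n_replicas = tf$n_replicas)
  })
  curve <- do.call(rbind, rows)
  keep <- curve$n_molecules >= min_molecules
  list(curve = curve,
       overall_fraction = if (any(keep)) mean(curve$fraction[keep]) else NA)
}
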