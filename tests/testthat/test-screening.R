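# Screening orchestration: bookkeeping, caching, phase classes, tube curves.

.tiny_cfg <- function() sim_config(n_steps = 300L, stride = 150L)

test_that("a screen yields one row per (set, condition, seed)", {
  plan <- screen_plan(c("v3", "v3opt"),
                      data.frame(box_side = 3.4, n_molecules = 4),
                      replicas = 2, seeds = c(1, 2), config = .tiny_cfg())
  res <- run_screen(plan)
  expect_equal(nrow(res$runs), 4)
  expect_setequal(res$runs$set_id, c("v3", "v3opt"))
  expect_true(all(!is.na(res$runs$ap)))
  expect_equal(res$n_new_simulations, 4)
})

test_that("replaying a finished plan runs nothing new", {
  cache <- tempfile()
  plan <- screen_plan("v3", data.frame(box_side = 3.4, n_molecules = 4),
                      replicas = 2, seeds = c(1, 2), config = .tiny_cfg(),
                      cache_dir = cache)
  first <- run_screen(plan)
  expect_equal(first$n_new_simulations, 2)
  again <- run_screen(plan)
  expect_equal(again$n_new_simulations, 0)
  expect_equal(again$runs$ap, first$runs$ap)
})

test_that("identical plans and seeds give identical result tables", {
  plan <- screen_plan("v3", data.frame(box_side = 3.4, n_molecules = 4),
                      replicas = 1, seeds = 5, config = .tiny_cfg())
  a <- run_screen(plan); b <- run_screen(plan)
  expect_identical(a$runs[names(a$runs) != "key"],
                   b$runs[names(b$runs) != "key"])
})

test_that("phase-class mapping is exhaustive over the label set", {
  labels <- c("solution", "solid", "bilayer", "vesicle", "tube",
              "spanning_artifact")
  for (lab in labels) {
    expect_identical(phase_class(1.5, lab), "solution")  # AP < 2 wins
    high <- phase_class(3.0, lab)
    want <- if (lab == "tube") "tube"
    else if (lab %in% c("bilayer", "vesicle")) "tube_compatible"
    else "solid"
    expect_identical(high, want, info = lab)
  }
})

test_that("phase tables take majority votes with ties toward less order", {
  runs <- data.frame(
    set_id = rep("SC3/SC3-Q3", 4), box_side = 5, n_molecules = 8,
    concentration_mM = 100, seed = 1:4, ap = c(3, 3, 3, 1.2),
    ap_reported = c(3, 3, 3, 1.2),
    morphology = c("tube", "tube", "solid", "solution"),
    phase_class = c("tube", "tube", "solid", "solution"),
    stringsAsFactors = FALSE)
  tb <- phase_table(runs)
  expect_identical(tb$phase, "tube")
  expect_identical(tb$ring, "SC3/SC3")
  expect_identical(tb$terminus, "Q3")
  # 2-2 tie: the less ordered class wins
  runs$phase_class <- c("tube", "tube", "solid", "solid")
  expect_identical(phase_table(runs)$phase, "solid")
  # missing cells are reported as no data
  runs$phase_class <- NA_character_
  expect_identical(phase_table(runs)$phase, "no data")
})

test_that("tube-fraction curves aggregate replicas and apply the floor", {
  mk <- function(nm, conc, labs) data.frame(
    set_id = "v3opt", box_side = 17, n_molecules = nm,
    concentration_mM = conc, seed = seq_along(labs), ap = 3,
    ap_reported = 3, morphology = labs,
    phase_class = ifelse(labs == "tube", "tube", "solid"),
    stringsAsFactors = FALSE)
  runs <- rbind(mk(400, 133, c("tube", "tube", "tube", "tube")),
                mk(600, 200, c("tube", "tube", "solid", "solid")),
                mk(800, 267, c("solid", "solid", "solid", "solid")))
  out <- tube_fraction_curve(runs, "v3opt")
  expect_equal(out$curve$fraction, c(1, 0.5, 0))
  expect_equal(out$curve$sem, c(0, sd(c(1, 1, 0, 0)) / sqrt(3), 0))
  expect_equal(out$overall_fraction, 0.5)
  floored <- tube_fraction_curve(runs, "v3opt", min_molecules = 600)
  expect_equal(floored$overall_fraction, 0.25)
})

test_that("individual run failures are recorded and the screen continues", {
  plan <- screen_plan(c("SC99/SC9-Q9"),  # malformed id fails in the worker
                      data.frame(box_side = 3.4, n_molecules = 4),
                      replicas = 1, seeds = 1, config = .tiny_cfg())
  res <- suppressWarnings(run_screen(plan))
  expect_equal(nrow(res$runs), 1)
  expect_true(is.na(res$runs$ap))
})
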