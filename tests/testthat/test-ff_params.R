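# Force-field tables: printed anchors, symmetry, monotonicity, parameter-set
# grammar, grid enumeration, ITP round-trips.

test_that("published interaction energies are reproduced exactly", {
  m3 <- interaction_matrix("v3")
  expect_equal(get_epsilon(m3, "SC4", "SC4"), 2.35)
  expect_equal(get_epsilon(m3, "SC4", "W"), 1.80)
  expect_equal(get_epsilon(m3, "SC4", "Q5"), 1.48)
  expect_equal(get_epsilon(m3, "Q5", "Q5"), 5.79)
  expect_equal(get_epsilon(m3, "Q5", "W"), 5.64)
  expect_equal(get_epsilon(m3, "TC5", "W"), 1.36)
  expect_equal(get_epsilon(m3, "TC5", "Q5"), 0.98)
  expect_equal(get_epsilon(m3, "SC3", "Q3"), 2.16)
  expect_equal(get_epsilon(m3, "TC3", "Q3"), 1.45)
  expect_equal(get_epsilon(m3, "TC3", "W"), 1.12)
  expect_equal(get_epsilon(m3, "Q3", "W"), 4.99)
  m2 <- interaction_matrix("v2.1")
  expect_equal(get_epsilon(m2, "SC4", "P4"), 2.7)
  expect_equal(get_epsilon(m2, "SC5", "P4"), 3.1)
  expect_equal(get_epsilon(m2, "SC4", "SC4"), 3.5)
  expect_equal(get_epsilon(m2, "SC5", "SC5"), 3.5)
  expect_equal(get_epsilon(m2, "Qa", "P4"), 5.6)
  expect_equal(get_epsilon(m2, "Qd", "P4"), 5.6)
  expect_equal(get_epsilon(m2, "Qa", "Qd"), 5.6)
  expect_equal(get_epsilon(m2, "SC4", "Qa"), 2.7)
  # every printed entry is flagged as such
  for (m in list(m3, m2)) {
    pp <- m$pairs[m$pairs$provenance == "paper-printed", ]
    expect_gt(nrow(pp), 5)
  }
})

test_that("interaction matrices are symmetric and positive for every pair", {
  for (v in c("v3", "v2.1")) {
    m <- interaction_matrix(v)
    expect_identical(m$eps, t(m$eps))
    expect_identical(m$sigma, t(m$sigma))
    expect_true(all(m$eps > 0))
    expect_true(all(m$sigma > 0))
    # random lookups agree both ways
    set.seed(42)
    nm <- rownames(m$eps)
    for (k in 1:20) {
      a <- sample(nm, 1); b <- sample(nm, 1)
      expect_identical(get_epsilon(m, a, b), get_epsilon(m, b, a))
      expect_identical(get_sigma(m, a, b), get_sigma(m, b, a))
    }
  }
})

test_that("epsilon decreases from C2 to C5 against apolar partners", {
  m <- interaction_matrix("v3")
  for (partner in c("SC3", "TC4")) {
    s_row <- sapply(paste0("SC", 2:5), function(b) get_epsilon(m, b, partner))
    t_row <- sapply(paste0("TC", 2:5), function(b) get_epsilon(m, b, partner))
    expect_true(all(diff(s_row) < 0))
    expect_true(all(diff(t_row) < 0))
  }
})

test_that("unknown bead names raise a lookup error naming bead and version", {
  m <- interaction_matrix("v3")
  expect_error(get_epsilon(m, "XX9", "W"), "XX9.*v3")
})

test_that("named parameter sets carry the documented bead assignments", {
  v3 <- make_parameter_set("v3")
  expect_identical(v3$f_ring, c("SC4", "TC5", "TC5"))
  expect_identical(v3$termini, c("Q5", "Q5"))
  opt <- make_parameter_set("v3opt")
  expect_identical(opt$f_ring, c("SC4", "SC4", "SC4"))
  expect_identical(opt$termini, c("Q4", "Q4"))
  expect_true(opt$aromatic_sc4)
  c21 <- make_parameter_set("v2.1-C")
  e21 <- make_parameter_set("v2.1-E")
  expect_equal(c21$bb_bond_k, 400)
  expect_equal(e21$bb_bond_k, 1250)
  # C and E differ in nothing else
  expect_identical(c21[setdiff(names(c21), c("id", "bb_bond_k",
                                             "secondary_structure"))],
                   e21[setdiff(names(e21), c("id", "bb_bond_k",
                                             "secondary_structure"))])
  expect_identical(make_parameter_set("v2.2")$f_ring, rep("SC5", 3))
})

test_that("grid codes parse case-insensitively and reject malformed input", {
  g <- make_parameter_set("SC3/TC3-Q3")
  expect_identical(g$f_ring, c("SC3", "TC3", "TC3"))
  expect_identical(g$termini, c("Q3", "Q3"))
  expect_identical(make_parameter_set("sc3/tc3-q3")$id, g$id)
  h <- make_parameter_set("SCh4/TCh4-Q2")
  expect_identical(h$f_ring, c("SCh4", "TCh4", "TCh4"))
  expect_error(make_parameter_set("SC9/TC3-Q3"), "SC9/TC3-Q3")
  expect_error(make_parameter_set("bogus"), "bogus")
})

test_that("grid enumeration is the documented cartesian product", {
  small <- screening_grid("S", c_levels = 3:4, termini = c("Q3", "Q4"))
  expect_length(enumerate_grid(small), 4)
  full <- enumerate_grid(screening_grid())
  ids <- vapply(full, `[[`, character(1), "id")
  # independent hand enumeration of the full grid
  expected <- character(0)
  for (style in list(c("SC", "SC"), c("TC", "TC"), c("SC", "TC"),
                     c("SCh", "TCh")))
    for (cl in 2:5)
      for (q in 1:5)
        expected <- c(expected, sprintf("%s%d/%s%d-Q%d", style[1], cl,
                                        style[2], cl, q))
  expect_length(ids, 80)
  expect_setequal(ids, expected)
  expect_false(any(duplicated(ids)))
  # empty option set contract: empty list
  expect_length(enumerate_grid(screening_grid("S", 2, character(0))), 0)
})

test_that("h-variant beads scale only h-h pair epsilons", {
  m <- interaction_matrix("v3", h_factor = 1.1)
  expect_equal(get_epsilon(m, "SCh4", "SCh4"), round(2.35 * 1.1, 3))
  expect_equal(get_epsilon(m, "SCh4", "W"), get_epsilon(m, "SC4", "W"))
  expect_equal(get_epsilon(m, "SCh4", "Q5"), get_epsilon(m, "SC4", "Q5"))
})

test_that("ITP nonbonded tables round-trip in both forms", {
  m <- interaction_matrix("v2.1")
  for (form in c("sigeps", "c6c12")) {
    f <- tempfile(fileext = ".itp")
    write_itp_nonbonded(m, f, form = form)
    back <- read_itp_nonbonded(f)
    key <- function(df) paste(pmin(df$a, df$b), pmax(df$a, df$b))
    i <- match(key(m$pairs), key(back))
    expect_false(anyNA(i))
    expect_equal(back$epsilon[i], m$pairs$epsilon, tolerance = 1e-6)
    expect_equal(back$sigma[i], m$pairs$sigma, tolerance = 1e-6)
  }
})

test_that("user ITP overrides replace entries and are flagged", {
  m <- interaction_matrix("v3")
  ov <- data.frame(a = "SC4", b = "W", epsilon = 2.0, sigma = 0.45)
  m2 <- override_interactions(m, ov)
  expect_equal(get_epsilon(m2, "W", "SC4"), 2.0)
  expect_equal(get_sigma(m2, "W", "SC4"), 0.45)
  expect_identical(m2$provenance["SC4", "W"], "user")
})
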