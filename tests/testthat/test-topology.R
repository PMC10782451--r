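# Topology builder: bead mapping, charges, bonded terms, exclusions.

# hand-built mapping fixture: beads per residue = 1 backbone + side beads
.beads_per_residue <- c(F = 4, W = 5, Y = 4, I = 2, P = 2, G = 1, H = 4,
                        K = 3, D = 2)

# the sixteen peptides studied, with an independent per-sequence charge tally
.paper_peptides <- c("FF", "FW", "IF", "WF", "WW", "DFF", "FFD", "FFF",
                     "GHK", "GGG", "KFD", "KFF", "KYF", "KYW", "KYY", "PFF")
.expected_charge <- function(seq) {
  r <- strsplit(seq, "")[[1]]
  # +1 N-terminus, -1 C-terminus, +1 per K, -1 per D, H neutral
  1 - 1 + sum(r == "K") - sum(r == "D")
}

test_that("FF maps to 8 beads with the documented v3 types", {
  top <- build_topology("FF", "v3")
  expect_equal(nrow(top$beads), 8)
  expect_identical(top$beads$type[top$beads$role == "backbone"],
                   c("Q5", "Q5"))
  sc <- top$beads$type[top$beads$role == "sidechain"]
  expect_identical(sc, rep(c("SC4", "TC5", "TC5"), 2))
  expect_equal(net_charge(top), 0)
  expect_equal(nrow(top$constraints), 6)  # two rigid 3-bead rings
})

test_that("backbone bond force constant follows the secondary structure", {
  bb_k <- function(id) {
    top <- build_topology("FF", id)
    bb <- which(top$beads$role == "backbone")
    w <- top$bonds$i %in% bb & top$bonds$j %in% bb
    top$bonds$k[w]
  }
  expect_equal(bb_k("v2.1-C"), 400)
  expect_equal(bb_k("v2.1-E"), 1250)
  expect_equal(bb_k("v2.2"), 1250)  # v2.2 bonded terms equal v2.1-E
})

test_that("glycine dipeptide is two beads with set-specific termini", {
  top <- build_topology("GG", "v3opt")
  expect_equal(nrow(top$beads), 2)
  expect_identical(top$beads$type, c("Q4", "Q4"))
  expect_equal(net_charge(top), 0)
  expect_equal(nrow(top$constraints), 0)
})

test_that("bead counts match the mapping fixture for every supported residue", {
  for (r in names(.beads_per_residue)) {
    for (id in c("v3", "v2.1-E")) {
      top <- build_topology(r, id)
      expect_equal(nrow(top$beads), unname(.beads_per_residue[[r]]),
                   info = paste(r, id))
    }
  }
})

test_that("net charge equals the independent tally for all 16 peptides", {
  for (seq in .paper_peptides) {
    for (id in c("v3", "v3opt", "v2.1-E")) {
      top <- build_topology(seq, id)
      expect_equal(net_charge(top), .expected_charge(seq),
                   info = paste(seq, id))
      # builder total equals the per-bead sum by construction; check both
      expect_equal(sum(top$beads$charge), .expected_charge(seq))
    }
  }
})

test_that("every bonded index pair appears in the exclusions", {
  for (seq in c("FF", "KYW", "PFF")) {
    top <- build_topology(seq, "v3")
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    exc <- key(top$exclusions$i, top$exclusions$j)
    expect_true(all(key(top$bonds$i, top$bonds$j) %in% exc))
    expect_true(all(key(top$constraints$i, top$constraints$j) %in% exc))
  }
})

test_that("ring templates satisfy their constraints exactly", {
  for (id in c("v3", "v3opt", "v2.1-C")) {
    top <- build_topology("FF", id)
    for (p in seq_len(nrow(top$constraints))) {
      d <- sqrt(sum((top$coords[top$constraints$i[p], ] -
                     top$coords[top$constraints$j[p], ])^2))
      expect_equal(d, top$constraints$d[p], tolerance = 1e-10)
    }
  }
})

test_that("unsupported residues and bad lengths are rejected informatively", {
  expect_error(build_topology("FX", "v3"), "unsupported residue")
  expect_error(build_topology("FX", "v3"), "F, W, Y")
  expect_error(build_topology("FFFF", "v3"), "1-3 residues")
  expect_error(build_topology("", "v3"), "1-3 residues")
})

test_that("v3opt moves W and Y aromatic hydrophobic beads to SC4", {
  wy <- build_topology("WY", "v3opt")
  sc <- wy$beads$type[wy$beads$role == "sidechain"]
  expect_identical(sc[1:4], c("SC4", "TN6d", "SC4", "SC4"))  # W ring
  expect_identical(sc[5:7], c("SC4", "SC4", "TN6d"))         # Y ring
  # heteroatom beads unchanged relative to v3
  wy3 <- build_topology("WY", "v3")
  expect_equal(sum(wy3$beads$type == "TN6d"), sum(wy$beads$type == "TN6d"))
})
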