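# Two-chain toy complex: chain A residues 1..3, chain B residues 1..2,
# laid out on the x axis so every pairwise distance is known by hand.
toy_complex_atoms <- function() {
  data.frame(
    name = c("CA", "CB", "CA", "CA", "CA", "CB", "CA"),
    chain = c("A", "A", "A", "A", "B", "B", "B"),
    resno = c(1, 1, 2, 3, 1, 1, 2),
    x = c(0, 1, 4, 30, 3, 5, 10),
    y = 0, z = 0,
    stringsAsFactors = FALSE)
}

test_that("minimum atom distances match hand-computed and brute-force values", {
  pdb <- write_toy_pdb(toy_complex_atoms())
  map_a <- data.frame(pos = 1:3, resno = 1:3)
  map_b <- data.frame(pos = 1:2, resno = 1:2)
  dm <- min_atom_distances(pdb, "A", "B", map_a, map_b)
  # A:1 atoms at x 0,1; B:1 atoms at x 3,5 -> min |1-3| = 2
  expect_equal(dm$dist["1", "1"], 2)
  expect_equal(dm$dist["2", "1"], 1)   # 4 vs 3
  expect_equal(dm$dist["3", "2"], 20)  # 30 vs 10
  # full brute-force oracle over all mapped pairs
  atoms <- toy_complex_atoms()
  for (ra in 1:3) for (rb in 1:2) {
    expect_equal(dm$dist[as.character(ra), as.character(rb)],
                 bf_min_distance(atoms[atoms$chain == "A" &
                                         atoms$resno == ra, ],
                                 atoms[atoms$chain == "B" &
                                         atoms$resno == rb, ]))
  }
  # symmetry under swapping the chain arguments
  dm2 <- min_atom_distances(pdb, "B", "A", map_b, map_a)
  expect_equal(dm2$dist["1", "2"], dm$dist["2", "1"])
  expect_equal(unname(dm$dist), unname(t(dm2$dist)))
  expect_error(min_atom_distances(pdb, "A", "Z", map_a, map_b),
               "chain not found")
})

test_that("hydrogens are excluded and altloc resolves to highest occupancy", {
  atoms <- data.frame(
    name = c("CA", "H", "CA", "CA"),
    chain = c("A", "A", "B", "B"),
    resno = c(1, 1, 1, 1),
    x = c(0, 4.9, 5, 20), y = 0, z = 0,
    elesy = c("C", "H", "C", "C"),
    occ = c(1, 1, 0.7, 0.3),
    alt = c("", "", "A", "B"),
    stringsAsFactors = FALSE)
  pdb <- write_toy_pdb(atoms)
  dm <- min_atom_distances(pdb, "A", "B",
                           data.frame(pos = 1, resno = 1),
                           data.frame(pos = 1, resno = 1))
  # hydrogen at 4.9 ignored; low-occupancy altloc at 20 ignored
  expect_equal(dm$dist["1", "1"], 5)
})

test_that("unmapped residues are unresolved rather than fatal", {
  pdb <- write_toy_pdb(toy_complex_atoms())
  dm <- min_atom_distances(pdb, "A", "B",
                           data.frame(pos = c(1, 9), resno = c(1, 99)),
                           data.frame(pos = 1, resno = 1))
  expect_equal(dm$dist["1", "1"], 2)
  expect_true(is.na(dm$dist["9", "1"]))
})

test_that("precision counts TP at or below the cutoff and skips unresolved pairs", {
  dm <- base::structure(
    list(dist = matrix(c(3, 7.5, 8.0, 9, NA), 5, 1,
                       dimnames = list(as.character(1:5), "1")),
         chain_a = "A", chain_b = "B"),
    class = "ev_distmap")
  contacts <- data.frame(pos_a = 1:5, pos_b = 1)
  p <- contact_precision(contacts, dm, cutoff = 8)
  expect_equal(p$tp, 3L)   # 8.0 exactly counts as a contact
  expect_equal(p$fp, 1L)
  expect_equal(p$unresolved, 1L)
  expect_equal(p$precision, 0.75)
  expect_equal(p$tp + p$fp + p$unresolved, nrow(contacts))
  # precision is monotone non-decreasing in the cutoff
  cuts <- c(5, 8, 10, 12)
  precs <- vapply(cuts, function(cc) {
    pr <- contact_precision(contacts, dm, cc)
    pr$tp / max(1L, pr$tp + pr$fp)
  }, numeric(1))
  expect_true(all(diff(precs) >= 0))
})

test_that("precision is undefined when every contact is unresolved", {
  dm <- base::structure(
    list(dist = matrix(NA_real_, 2, 1,
                       dimnames = list(c("1", "2"), "1"))),
    class = "ev_distmap")
  p <- contact_precision(data.frame(pos_a = 1:2, pos_b = 1), dm)
  expect_false(p$defined)
  expect_equal(p$tp, 0L)
  expect_equal(p$fp, 0L)
  expect_true(is.na(p$precision))
  expect_error(contact_precision(data.frame(pos_a = integer(0),
                                            pos_b = integer(0)), dm),
               "no contacts")
})

test_that("four-fifths of near contacts give precision 0.8", {
  dm <- base::structure(
    list(dist = matrix(c(2, 4, 6, 7, 12), 5, 1,
                       dimnames = list(as.character(1:5), "1"))),
    class = "ev_distmap")
  p <- contact_precision(data.frame(pos_a = 1:5, pos_b = 1), dm, 8)
  expect_equal(p$precision, 0.8)
})

test_that("contact-map table bins distances at the 5/8/12 cutoffs", {
  dm <- base::structure(
    list(dist = matrix(c(4.2, 7, 11, 20), 4, 1,
                       dimnames = list(as.character(1:4), "5"))),
    class = "ev_distmap")
  tab <- contact_map_table(
    data.frame(pos_a = c(1:4, 9), pos_b = 5,
               block = c("inter", "inter", "intra_a", "inter", "inter"),
               score = 1),
    dmaps = dm)
  expect_equal(tab$distance_class,
               c("<=5", "<=8", "<=12", ">12", "unresolved"))
  # binning agrees with a direct comparison oracle on random distances
  set.seed(8)
  d <- runif(50, 0, 20)
  dm2 <- base::structure(
    list(dist = matrix(d, 50, 1,
                       dimnames = list(as.character(1:50), "1"))),
    class = "ev_distmap")
  tab2 <- contact_map_table(
    data.frame(pos_a = 1:50, pos_b = 1, block = "inter", score = 0),
    dm2)
  oracle <- ifelse(d <= 5, "<=5", ifelse(d <= 8, "<=8",
                                         ifelse(d <= 12, "<=12", ">12")))
  expect_equal(tab2$distance_class, oracle)
})

test_that("interface residues use a strict 6 Angstrom any-atom rule", {
  near <- write_toy_pdb(data.frame(
    name = "CA", chain = c("A", "B"), resno = c(1, 1),
    x = c(0, 5.9), y = 0, z = 0))
  iface <- interface_residues(near, "A", "B")
  expect_equal(iface$chain_a, 1)
  expect_equal(iface$chain_b, 1)
  at_cut <- write_toy_pdb(data.frame(
    name = "CA", chain = c("A", "B"), resno = c(1, 1),
    x = c(0, 6.0), y = 0, z = 0))
  iface2 <- interface_residues(at_cut, "A", "B")
  expect_length(iface2$chain_a, 0)
  expect_length(iface2$chain_b, 0)
  # brute-force oracle on a synthetic multi-residue complex
  atoms <- toy_complex_atoms()
  pdb <- write_toy_pdb(atoms)
  iface3 <- interface_residues(pdb, "A", "B", cutoff = 6)
  for (ra in 1:3) {
    d <- bf_min_distance(atoms[atoms$chain == "A" & atoms$resno == ra, ],
                         atoms[atoms$chain == "B", ])
    expect_equal(ra %in% iface3$chain_a, d < 6)
  }
})

test_that("restraint writer emits one parseable assign per contact", {
  contacts <- data.frame(res_a = c(10, 12, 30), res_b = c(25, 40, 7))
  f <- tempfile(fileext = ".tbl")
  write_haddock_restraints(contacts, "A", "B", f)
  lines <- readLines(f)
  expect_length(lines, nrow(contacts))
  expect_match(lines[1], "segid A and resid 10 and name CA")
  expect_match(lines[1], "segid B and resid 25 and name CA")
  expect_match(lines[1], "5.0 2.0 2.0$")
  back <- read_haddock_restraints(f)
  expect_equal(back$res_a, contacts$res_a)
  expect_equal(back$res_b, contacts$res_b)
  expect_equal(unique(back$segid_a), "A")
  expect_equal(unique(back$d_eff), 5.0)
  expect_equal(unique(back$lower), 2.0)
  expect_equal(unique(back$upper), 2.0)
  expect_error(write_haddock_restraints(contacts[0, ], "A", "B", f),
               "no contacts")
})
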