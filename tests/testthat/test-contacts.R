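test_that("the 4.0 A cutoff is a sharp edge", {
  a <- make_atoms(1, chain = "A")
  near <- make_atoms(1, chain = "B", x = 3.99)
  far <- make_atoms(1, chain = "B", x = 4.01)
  expect_equal(nrow(find_contacts(a, near)), 1)
  expect_equal(nrow(find_contacts(a, far)), 0)
  expect_equal(attr(find_contacts(a, near), "cutoff"), 4.0)
})

test_that("grid acceleration reproduces the all-pairs oracle exactly", {
  set.seed(31)
  a <- random_atoms(250, chain = "A"); a$resno <- 1:250
  b <- random_atoms(250, chain = "B"); b$resno <- 1:250
  g <- find_contacts(a, b, method = "grid")
  br <- find_contacts(a, b, method = "brute")
  expect_gt(nrow(g), 50)           # the fixture actually has contacts
  expect_same_contacts(g, br)
})

test_that("empty groups yield an empty table, not an error", {
  a <- make_atoms(1)
  empty <- a[0, ]
  tab <- find_contacts(a, empty)
  expect_s3_class(tab, "contact_table")
  expect_equal(nrow(tab), 0)
})

test_that("contact classification follows the distance-chemistry rules", {
  rec <- function(resid_a, atom_a, el_a, resid_b, atom_b, el_b, d) {
    data.frame(resid_a = resid_a, atom_a = atom_a, element_a = el_a,
               resid_b = resid_b, atom_b = atom_b, element_b = el_b,
               distance = d, stringsAsFactors = FALSE)
  }
  expect_equal(classify_contacts(
    rec("GLY", "O", "O", "ALA", "N", "N", 2.9)), "hbond")
  expect_equal(classify_contacts(
    rec("GLU", "OE1", "O", "LYS", "NZ", "N", 3.8)), "salt_bridge")
  expect_equal(classify_contacts(
    rec("ALA", "CB", "C", "LEU", "CD1", "C", 3.7)), "nonbonded")
  # salt bridge takes precedence over the hbond rule at short range
  expect_equal(classify_contacts(
    rec("ASP", "OD2", "O", "ARG", "NH1", "N", 3.2)), "salt_bridge")
  # N/O pair beyond 3.5 A is nonbonded
  expect_equal(classify_contacts(
    rec("GLY", "O", "O", "ALA", "N", "N", 3.8)), "nonbonded")
})

test_that("closest-per-residue-pair reduction keeps the minimum with stable ties", {
  a <- make_atoms(3, chain = "A", resno = 1, atom = c("N", "CA", "C"),
                  x = c(0, 0.5, 1.0))
  b <- make_atoms(1, chain = "B", resno = 9, x = 3.4)
  tab <- find_contacts(a, b)      # three atom contacts at 2.4/2.9/3.4
  expect_equal(nrow(tab), 3)
  red <- reduce_closest(tab)
  expect_equal(nrow(red), 1)
  expect_equal(red$atom_a, "C")
  expect_equal(red$distance, 2.4)
  expect_identical(reduce_closest(red)$distance, red$distance)  # idempotent
  # exact tie resolves lexicographically by atom names
  a2 <- make_atoms(2, chain = "A", resno = 1, atom = c("CB", "CA"),
                   x = c(0, 0), y = c(1, -1))
  b2 <- make_atoms(1, chain = "B", resno = 5, x = 0)
  red2 <- reduce_closest(find_contacts(a2, b2))
  expect_equal(red2$atom_a, "CA")
})

test_that("reduction equals a brute-force group-by-minimum on random fixtures", {
  set.seed(32)
  a <- random_atoms(120, box = 12, chain = "A"); a$resno <- rep(1:12, each = 10)
  a$atom <- paste0("C", rep(1:10, 12))
  b <- random_atoms(120, box = 12, chain = "B"); b$resno <- rep(1:12, each = 10)
  b$atom <- paste0("C", rep(1:10, 12))
  tab <- find_contacts(a, b)
  red <- reduce_closest(tab)
  oracle <- brute_reduce(tab)
  key <- function(t) paste(t$resno_a, t$resno_b)
  m <- match(key(red), key(oracle))
  expect_false(anyNA(m))
  expect_equal(red$distance, oracle$distance[m])
  expect_equal(red$atom_a, oracle$atom_a[m])
})

test_that("contact partners are distinct residues with counts", {
  toy <- build_toy_complex(placements = data.frame(
    target_resno = c(146, 146, 150), distance = c(3.0, 3.5, 3.2)))
  ag <- select_atoms(toy$model, toy$map, "mhc_heavy")
  pr <- select_atoms(toy$model, toy$map, "ab_light")
  tab <- find_contacts(ag, pr)
  p146 <- contact_partners(tab, "A", 146)
  expect_equal(nrow(p146), 2)          # two designed probe residues
  expect_true(all(p146$n_contacts >= 1))
  expect_equal(nrow(contact_partners(tab, "A", 999)), 0)
  expect_equal(nrow(contact_partners(tab[0, ], "A", 146)), 0)
})

test_that("contact map marginals equal per-residue partner counts", {
  toy <- build_toy_complex(placements = data.frame(
    target_resno = c(143, 146, 146, 151), distance = c(3.1, 3.0, 3.6, 3.3)))
  ag <- select_atoms(toy$model, toy$map, "mhc_heavy")
  pr <- select_atoms(toy$model, toy$map, "ab_light")
  red <- reduce_closest(find_contacts(ag, pr))
  m <- export_contact_map(red)
  expect_equal(sum(m), nrow(red))
  for (rn in c(143, 146, 151)) {
    row <- grep(paste0(":", rn, ":"), rownames(m))
    expect_equal(sum(m[row, ]),
                 nrow(contact_partners(red, "A", rn)))
  }
  expect_equal(dim(export_contact_map(red[0, ])), c(0, 0))
})

test_that("contacts are symmetric under group swap and monotone in cutoff", {
  set.seed(33)
  a <- random_atoms(60, box = 10, chain = "A"); a$resno <- 1:60
  b <- random_atoms(60, box = 10, chain = "B"); b$resno <- 1:60
  ab <- find_contacts(a, b)
  ba <- find_contacts(b, a)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$resno_a, ab$atom_a, ab$resno_b, ab$atom_b),
                  paste(ba$resno_b, ba$atom_b, ba$resno_a, ba$atom_a))
  key <- function(t) paste(t$resno_a, t$atom_a, t$resno_b, t$atom_b)
  for (cuts in list(c(2.5, 4.0), c(3.0, 4.5))) {
    small <- find_contacts(a, b, cutoff = cuts[1])
    large <- find_contacts(a, b, cutoff = cuts[2])
    expect_true(all(key(small) %in% key(large)))
  }
})

test_that("the contact set is invariant under rigid motion of the complex", {
  set.seed(34)
  a <- random_atoms(40, box = 9, chain = "A"); a$resno <- 1:40
  b <- random_atoms(40, box = 9, chain = "B"); b$resno <- 1:40
  t1 <- find_contacts(a, b)
  tr <- rigid_transform(random_rotation(), rnorm(3, 0, 30))
  t2 <- find_contacts(shift_atoms(a, tr), shift_atoms(b, tr))
  expect_same_contacts(t1, t2, tol = 1e-6)
})
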