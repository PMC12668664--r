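test_that("the contact-based footprint is exactly the designed epitope", {
  toy <- build_toy_complex(placements = data.frame(
    target_resno = c(143, 146, 150), distance = c(3.5, 3.0, 3.9)))
  fp <- epitope_footprint(toy$model, toy$map, binder_roles = "ab_light")
  expect_setequal(fp$resno, c(143, 146, 150))
  expect_true(all(fp$n_partners >= 1))
  # a vanishing cutoff empties the footprint
  fp0 <- epitope_footprint(toy$model, toy$map, binder_roles = "ab_light",
                           cutoff = 0.1)
  expect_equal(nrow(fp0), 0)
  expect_error(epitope_footprint(toy$model, toy$map,
                                 binder_roles = "receptor"), "no chain")
})

test_that("footprint overlap: self gives jaccard 1, disjoint gives 0", {
  toy <- build_toy_complex(placements = data.frame(
    target_resno = c(143, 146), distance = c(3.0, 3.0)))
  fp <- epitope_footprint(toy$model, toy$map, binder_roles = "ab_light")
  self <- compare_footprints(list(fp, fp))
  expect_equal(self$jaccard, 1)
  expect_setequal(self$shared, c(143, 146))
  toy2 <- build_toy_complex(placements = data.frame(
    target_resno = c(151, 153), distance = c(3.0, 3.0)))
  fp2 <- epitope_footprint(toy2$model, toy2$map, binder_roles = "ab_light")
  disjoint <- compare_footprints(list(fp, fp2))
  expect_equal(disjoint$jaccard, 0)
  expect_length(disjoint$shared, 0)
  expect_setequal(disjoint$unique_per_complex[[1]], c(143, 146))
})

test_that("multi-way overlap is order-invariant and segment restriction works", {
  mk <- function(res) {
    toy <- build_toy_complex(placements = data.frame(
      target_resno = res, distance = rep(3.2, length(res))))
    epitope_footprint(toy$model, toy$map, binder_roles = "ab_light")
  }
  fps <- list(mk(c(143, 145, 146, 150)), mk(c(145, 146, 150, 153)),
              mk(c(144, 145, 146, 150)))
  r1 <- compare_footprints(fps, restrict = c(145, 149), restrict_name = "mid")
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    r2 <- compare_footprints(fps[perm])
    expect_setequal(r2$shared, r1$shared)
    expect_equal(r2$jaccard, r1$jaccard)
  }
  expect_setequal(r1$shared, c(145, 146, 150))
  expect_setequal(r1$restricted$shared, c(145, 146))
  expect_gte(r1$jaccard, 0); expect_lte(r1$jaccard, 1)
})

test_that("explicit correspondences remap and report unmappable residues", {
  toy <- build_toy_complex(placements = data.frame(
    target_resno = c(143, 146), distance = c(3.0, 3.0)))
  fp <- epitope_footprint(toy$model, toy$map, binder_roles = "ab_light")
  # correspondence shifting 143->243 only; 146 has no image
  co <- data.frame(resno_a = 243, ins_a = "", resid_a = "ALA",
                   resno_b = 143, ins_b = "", resid_b = "ALA")
  rep <- compare_footprints(list(fp, fp), correspondences = list(NULL, co))
  expect_equal(rep$unmapped[[2]], 146)
  expect_true(243 %in% rep$sets[[2]])
})

test_that("receptor transplantation lands a rigid-motion copy on itself", {
  ref <- helix_bundle(c(200, 60), chains = c("H", "K"), backbone = TRUE)
  ref_map <- assign_roles(ref, hints = c(H = "mhc_heavy", K = "receptor"))
  set.seed(41)
  tr <- rigid_transform(random_rotation(), rnorm(3, 0, 25))
  donor <- structure_model(shift_atoms(ref$atoms, tr), id = "moved-copy")
  tp <- transplant_receptor(ref, donor, ref_map, ref_map)
  expect_lt(tp$fit_rmsd, 1e-8)
  orig <- select_atoms(ref, ref_map, "receptor", heavy_only = FALSE)
  expect_lt(max(abs(coords_of(tp$receptor_atoms) - coords_of(orig))), 1e-7)
  # transform agrees with a direct Kabsch fit on the same subsets
  ref_ca <- select_atoms(ref, ref_map, "mhc_heavy", "alpha1_alpha2")
  ref_ca <- ref_ca[ref_ca$atom == "CA", ]
  don_ca <- shift_atoms(ref_ca, tr)
  direct <- kabsch_superpose(coords_of(ref_ca), coords_of(don_ca))
  expect_equal(tp$transform$rotation, direct$transform$rotation,
               tolerance = 1e-8)
})

test_that("too few correspondences make the fit fail loudly", {
  ref <- helix_bundle(c(200, 60), chains = c("H", "K"), backbone = TRUE)
  map <- assign_roles(ref, hints = c(H = "mhc_heavy", K = "receptor"))
  short <- helix_bundle(c(20, 60), chains = c("H", "K"), backbone = TRUE)
  smap <- assign_roles(short, hints = c(H = "mhc_heavy", K = "receptor"))
  expect_error(transplant_receptor(ref, short, map, smap), "unreliable|>=")
})

test_that("clash detection follows the vdW-overlap closed form", {
  a <- make_atoms(1, chain = "A")
  far <- make_atoms(1, chain = "B", x = 20)
  expect_equal(clash_scan(a, far)$n_clashes, 0)
  near <- make_atoms(1, chain = "B", x = 2.0)   # overlap 1.7+1.7-2.0 = 1.4
  cs <- clash_scan(a, near)
  expect_equal(cs$n_clashes, 1)
  expect_equal(cs$pairs$overlap, 1.4)
  # threshold edge: two carbons at 3.0 overlap 0.4, not a clash at 0.4
  edge <- make_atoms(1, chain = "B", x = 3.0)
  expect_equal(clash_scan(a, edge)$n_clashes, 0)
  expect_equal(clash_scan(a, edge, overlap_threshold = 0.39)$n_clashes, 1)
})

test_that("an antibody superposed on itself clashes atom-for-atom", {
  toy <- build_toy_complex()
  ab <- select_atoms(toy$model, toy$map, "ab_light")
  cs <- clash_scan(ab, ab)
  self_pairs <- cs$pairs[paste(cs$pairs$resno_a, cs$pairs$atom_a) ==
                           paste(cs$pairs$resno_b, cs$pairs$atom_b), ]
  expect_equal(nrow(self_pairs), nrow(ab))   # every atom meets its own image
})

test_that("clash counts bin by segment and name the dominant cell", {
  probe <- make_atoms(6, resno = 1:6, x = seq(0, 10, by = 2))
  target <- make_atoms(6, chain = "B", resno = 1:6,
                       x = seq(0, 10, by = 2), y = 2.0)
  cs <- clash_scan(probe, target,
                   probe_segments = list(D1 = c(1, 3), D2 = c(4, 6)),
                   target_segments = list(VL = c(1, 6)))
  expect_equal(sum(cs$matrix), cs$n_clashes)
  expect_equal(unname(cs$dominant["target_segment"]), "VL")
  expect_setequal(rownames(cs$matrix), c("D1", "D2"))
})

test_that("transplant + clash is invariant under rigid motion of the donor", {
  ref <- helix_bundle(c(200, 60), chains = c("H", "K"), backbone = TRUE)
  map <- assign_roles(ref, hints = c(H = "mhc_heavy", K = "receptor"))
  # donor: same MHC, receptor shifted to overlap the reference receptor
  set.seed(42)
  for (rep in 1:3) {
    tr <- rigid_transform(random_rotation(), rnorm(3, 0, 40))
    donor <- structure_model(shift_atoms(ref$atoms, tr), id = "donor")
    tp <- transplant_receptor(ref, donor, map, map)
    cs <- clash_scan(tp$receptor_atoms,
                     select_atoms(ref, map, "receptor"))
    # the transplanted receptor meets its own original: full self-clash
    expect_equal(cs$n_clashes,
                 clash_scan(select_atoms(ref, map, "receptor"),
                            select_atoms(ref, map, "receptor"))$n_clashes)
  }
})

test_that("peptide contact profiles flag exactly the designed positions", {
  # peptide = the toy antigen numbered 1..9; probe contacts position 3 only
  toy <- build_toy_complex(n_antigen = 9, antigen_start = 1,
                           placements = data.frame(target_resno = 3,
                                                   distance = 3.0),
                           roles = c(peptide = "A", ab_light = "P"))
  prof <- peptide_contact_profile(toy$model, toy$map,
                                  binder_roles = "ab_light")
  expect_equal(prof$contacted, c(FALSE, FALSE, TRUE, rep(FALSE, 6)))
  expect_equal(prof$position[prof$contacted], 3)
  expect_equal(prof$position, 1:9)
  # no peptide role -> error
  toy2 <- build_toy_complex()
  expect_error(peptide_contact_profile(toy2$model, toy2$map), "no chain")
})
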