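test_that("principal alignment centers the molecule deterministically", {
  two <- box_structure(2, 0, 0)   # two-point degenerate case included below
  pep <- peptide_distribution(aligned = FALSE)
  al <- align_principal(pep)
  str <- attr(al, "structure")
  m <- nanofet:::atom_masses(str$element)
  com <- colSums(cbind(str$x, str$y, str$z) * m) / sum(m)
  expect_lt(sqrt(sum(com^2)) / 10, 1e-9)  # nm

  # extents sorted: x largest, z smallest
  ext <- c(diff(range(str$x)), diff(range(str$y)), diff(range(str$z)))
  expect_true(all(diff(ext) <= 1e-9))

  # idempotence: realigning changes nothing
  al2 <- align_principal(al)
  expect_equal(attr(al2, "structure")$x, str$x, tolerance = 1e-9)
  expect_equal(al2$z_nm, al$z_nm, tolerance = 1e-9)

  # pairwise distances preserved
  d0 <- dist(cbind(pep$x_nm, pep$y_nm, pep$z_nm))
  d1 <- dist(cbind(al$x_nm, al$y_nm, al$z_nm))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)

  # degenerate cases: two atoms on an axis; a single site
  al_two <- align_principal(two)
  expect_equal(mean(al_two$x), 0, tolerance = 1e-9)
  single <- make_point_charges(data.frame(x_nm = 5, y_nm = 5, z_nm = 5,
                                          charge = 1))
  al_single <- align_principal(single)
  expect_equal(c(al_single$x_nm, al_single$y_nm, al_single$z_nm),
               c(0, 0, 0), tolerance = 1e-12)
})

test_that("rotations act rigidly and flip the charge order", {
  pep <- peptide_distribution()
  vert <- orient_end_down(pep, "ASP")
  expect_lt(mean(vert$z_nm[vert$class == "ASP"]),
            mean(vert$z_nm[vert$class == "LYS"]))
  # half-turn about x inverts the z order (the A <-> C flip)
  flipped <- orient(vert, euler_deg = c(180, 0, 0))
  expect_gt(mean(flipped$z_nm[flipped$class == "ASP"]),
            mean(flipped$z_nm[flipped$class == "LYS"]))

  ident <- orient(pep, euler_deg = c(0, 0, 0))
  expect_equal(ident$x_nm, pep$x_nm)

  expect_equal(net_charge(flipped), net_charge(pep))
  d0 <- dist(cbind(pep$x_nm, pep$y_nm, pep$z_nm))
  d1 <- dist(cbind(flipped$x_nm, flipped$y_nm, flipped$z_nm))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)

  bad <- matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 1), 3)
  expect_error(orient(pep, rotation = bad), class = "nanofet_input_error")
  refl <- diag(c(-1, 1, 1))  # improper
  expect_error(orient(pep, rotation = refl), class = "nanofet_input_error")
})

test_that("distance profile removes free space below the molecule", {
  d <- make_point_charges(data.frame(x_nm = 0, y_nm = 0, z_nm = c(-2, 0, 3),
                                     charge = c(1, 1, 1)))
  prof <- distance_profile(d, t_linker_nm = 1, t_ox_nm = 2)
  expect_equal(prof$l_nm, c(3, 5, 8))
  expect_equal(min(prof$l_nm) - 1 - 2, 0)

  # translating the whole distribution in z changes nothing
  d2 <- d
  d2$z_nm <- d2$z_nm + 7
  prof2 <- distance_profile(d2, t_linker_nm = 1, t_ox_nm = 2)
  expect_equal(prof2$l_nm, prof$l_nm)

  one <- make_point_charges(data.frame(x_nm = 0, y_nm = 0, z_nm = 4,
                                       charge = -1))
  expect_equal(distance_profile(one, 1.5, 2.5)$l_nm, 4)

  empty <- make_point_charges(data.frame(x_nm = numeric(), y_nm = numeric(),
                                         z_nm = numeric(),
                                         charge = numeric()))
  expect_error(distance_profile(empty), class = "nanofet_input_error")
})

test_that("coverage counts molecules from the bounding-box footprint", {
  # 10 x 20 nm footprint = 100 x 200 Angstrom box
  box <- box_structure(100, 200, 5)
  params <- device_params(R_nm = 10, t_ox_nm = 2, L_nm = 2000)
  expect_equal(coverage(box, params), 753L)  # floor(2 pi 12 2000 / 200)

  # manual override wins over any box
  expect_equal(coverage(box, params, N_mol = 4000), 4000L)

  # doubling the footprint area halves the count (up to flooring)
  twice <- box_structure(200, 200, 5)
  expect_lte(abs(coverage(twice, params) - 753 %/% 2), 1)

  # linear in wire length and outer radius
  p2 <- device_params(R_nm = 10, t_ox_nm = 2, L_nm = 4000)
  expect_lte(abs(coverage(box, p2) - 2 * 753), 1)

  flat <- box_structure(0, 200, 5)  # zero x extent
  expect_error(coverage(flat, params), "N_mol",
               class = "nanofet_input_error")
})

test_that("single-charge mode collapses to the box center", {
  dipole <- make_point_charges(data.frame(x_nm = c(0, 0), y_nm = 0,
                                          z_nm = c(1, 3), charge = c(1, -1)))
  sc <- single_charge(dipole)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$charge, 0)
  expect_equal(sc$z_nm, 2)

  pep <- peptide_distribution()
  scp <- single_charge(pep)
  expect_equal(scp$charge, net_charge(pep))
  # center of the all-atom box, not of the charge sites
  box <- nanofet:::bounding_box_nm(pep)
  expect_equal(scp$x_nm, (box$min[1] + box$max[1]) / 2)

  one <- make_point_charges(data.frame(x_nm = 1, y_nm = 2, z_nm = 3,
                                       charge = -1))
  expect_identical(single_charge(one), one)
})
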