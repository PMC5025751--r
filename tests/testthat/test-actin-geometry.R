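# Helical lattice and bundle target-zone geometry.

test_that("subunit azimuths follow the helical twist with the (-180,180] wrap", {
  h <- helix_params()
  expect_identical(subunit_azimuth(h, 0), 0)
  # exact 13-subunit pseudo-repeat under the default twist
  expect_lt(abs(subunit_azimuth(h, 13)), 1e-6)
  expect_lt(abs(subunit_azimuth(h, 26)), 1e-6)
  # modular-arithmetic oracle over n = 1..30
  for (n in 1:30) {
    az <- (n * h$twist_deg) %% 360
    if (az > 180) az <- az - 360
    expect_equal(subunit_azimuth(h, n), az, tolerance = 1e-12)
  }
  expect_equal(subunit_azimuth(h, 15), 27.69, tolerance = 0.01)
  expect_error(subunit_azimuth(h, -1), "must be >= 0")
})

test_that("same-filament accessible sites match the known step geometry", {
  h <- helix_params()
  z <- accessible_sites_same_filament(h, accessibility_params(60, 33, 57))
  expect_equal(z$axial_nm, c(35.75, 41.25, 46.75))
  expect_false(is.unsorted(z$axial_nm))
  expect_false(anyDuplicated(z[c("filament_id", "subunit_index")]) > 0)

  # zero tolerance keeps only exact pseudo-repeat subunits
  z0 <- accessible_sites_same_filament(h, accessibility_params(0, 0, 80))
  expect_equal(z0$axial_nm, c(35.75, 71.5))

  # the half-turn region 47-57 nm faces away from the motor
  z47 <- accessible_sites_same_filament(h, accessibility_params(60, 47, 57))
  expect_equal(nrow(z47), 0L)
})

test_that("neighbour-filament sites honour the registry phase", {
  h <- helix_params()
  pl <- filament_placement("N1", c(12, 0), 0, 90)
  zn <- accessible_sites_neighbor(h, pl, accessibility_params(30, 45, 60))
  expect_equal(zn$axial_nm, c(52.25, 57.75))

  zn2 <- accessible_sites_neighbor(h, pl, accessibility_params(30, 15, 60))
  expect_equal(zn2$axial_nm, c(16.5, 22, 52.25, 57.75))

  # zero registry = same lattice as the rear head's own filament
  pl0 <- filament_placement("N1", c(12, 0), 0, 0)
  acc <- accessibility_params(60, 33, 57)
  expect_equal(accessible_sites_neighbor(h, pl0, acc)$axial_nm,
               accessible_sites_same_filament(h, acc)$axial_nm)

  # a same-position placement is rejected
  expect_error(
    accessible_sites_neighbor(h, filament_placement("X", c(0, 0)), acc),
    "neighbour")
})

test_that("bundle target map unions filaments and covers the fascin hot spots", {
  h <- helix_params()
  acc <- accessibility_params(30, 15, 60)

  # single-filament 'bundle' reduces to the same-filament computation
  b1 <- bundle_lattice(list(filament_placement("F0", c(0, 0))), helix = h)
  m1 <- bundle_target_map(b1, list("F0", 0), acc,
                          acc_same = accessibility_params(60, 33, 57))
  expect_equal(
    m1$axial_nm,
    accessible_sites_same_filament(h, accessibility_params(60, 33, 57))$axial_nm)

  # fascin preset covers each published hot spot within 2 nm
  m <- bundle_target_map(fascin_bundle(helix = h), list("F0", 0), acc)
  for (hot in c(19, 38, 52, 57)) {
    expect_lt(min(abs(m$axial_nm - hot)), 2)
  }

  # duplicated neighbour placements do not duplicate (filament, subunit) rows
  b2 <- bundle_lattice(list(
    filament_placement("F0", c(0, 0)),
    filament_placement("N1", c(12, 0), 0, 90),
    filament_placement("N2", c(12, 0), 0, 90)
  ), helix = h)
  m2 <- bundle_target_map(b2, list("F0", 0), acc)
  expect_false(anyDuplicated(m2[c("filament_id", "subunit_index")]) > 0)
  expect_equal(sum(m2$filament_id == "N1"), sum(m2$filament_id == "N2"))

  expect_error(bundle_target_map(b2, list("nope", 0), acc), "unknown filament")
})

test_that("accessible sets are monotone in tolerance and band", {
  h <- helix_params()
  base <- accessible_sites_same_filament(h, accessibility_params(40, 30, 55))
  wider_tol <- accessible_sites_same_filament(h, accessibility_params(70, 30, 55))
  wider_band <- accessible_sites_same_filament(h, accessibility_params(40, 20, 70))
  expect_true(all(base$subunit_index %in% wider_tol$subunit_index))
  expect_true(all(base$subunit_index %in% wider_band$subunit_index))
})

test_that("accessible sets are invariant under 13-subunit translation of the rear head", {
  b <- fascin_bundle()
  acc <- accessibility_params(30, 15, 60)
  m0 <- bundle_target_map(b, list("F0", 0), acc)
  m13 <- bundle_target_map(b, list("F0", 13), acc)
  expect_equal(m13$axial_nm, m0$axial_nm, tolerance = 1e-9)
  expect_equal(m13$subunit_index, m0$subunit_index + 13L)
})

test_that("accessible sets equal brute-force enumeration on random parameters", {
  set.seed(71)
  for (i in 1:100) {
    rise <- runif(1, 2, 4)
    twist <- runif(1, -179, -120)
    tol <- runif(1, 5, 90)
    bmin <- runif(1, 0, 40)
    bmax <- bmin + runif(1, 5, 40)
    phase <- runif(1, -180, 180)
    h <- helix_params(rise_nm = rise, twist_deg = twist, n_subunits = 60)
    got <- accessible_sites_neighbor(
      h, filament_placement("N", c(10, 0), 0, phase),
      accessibility_params(tol, bmin, bmax))
    want <- oracle_accessible(rise, twist, tol, bmin, bmax, phase = phase)
    expect_equal(got$subunit_index, want$subunit, info = paste("case", i))
    expect_equal(got$axial_nm, want$axial, tolerance = 1e-9)
  }
})

test_that("invalid lattice parameters are rejected", {
  expect_error(helix_params(rise_nm = 0), "rise_nm")
  expect_error(helix_params(twist_deg = 0), "twist_deg")
  expect_error(helix_params(twist_deg = 360), "twist_deg")
  expect_error(accessibility_params(200), "azim_tol_deg")
  expect_error(accessibility_params(30, 50, 40), "band_max_nm")
  expect_error(
    bundle_lattice(list(filament_placement("A", c(0, 0)),
                        filament_placement("A", c(12, 0)))),
    "unique")
})
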