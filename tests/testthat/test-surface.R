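# single pseudo-atom models for analytic SASA cases
one_atom <- function(x = 0, elem = "C", vdw = 1.70, chain = "A", resno = 1) {
  data.frame(eleno = 1, elety = elem, altloc = "", resid = "DUM",
             chain = chain, resno = resno, insert = "", x = x, y = 0, z = 0,
             o = 1, b = 0, elem = elem, vdw = vdw, kind = "other",
             stringsAsFactors = FALSE)
}

test_that("isolated atom SASA equals the analytic sphere area", {
  m <- structure_model(one_atom(), "c1")
  for (np in c(240, 960)) {
    s <- sasa(m, probe = 1.4, n_points = np)
    analytic <- 4 * pi * (1.70 + 1.4)^2        # ~120.76 A^2
    # a golden-spiral estimate is exact up to one sample point's area
    expect_equal(s$total, analytic, tolerance = 1e-9)
  }
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  for (d in c(2.0, 3.5, 5.0)) {
    at <- rbind(one_atom(0), one_atom(d))
    at$eleno <- 1:2; at$resno <- 1:2
    s <- sasa(structure_model(at, "c2"), probe = 1.4, n_points = 960)
    rho <- 1.70 + 1.4
    want <- two_sphere_area(rho, d)
    expect_equal(s$per_atom[1], want, tolerance = 0.01)
    expect_equal(s$per_atom[2], want, tolerance = 0.01)
  }
})

test_that("SASA converges with the sampling density", {
  tc <- make_toy_complex(6, 6, salt_bridges = 3.2)
  s1 <- sasa(tc$model, n_points = 960)
  s2 <- sasa(tc$model, n_points = 3840)
  expect_equal(s1$total, s2$total, tolerance = 0.01)
})

test_that("SASA is bounded by the isolated-sphere total, equal when disjoint", {
  tc <- make_toy_complex(6, 6)
  m <- tc$model
  s <- sasa(m)
  iso <- sum(4 * pi * (m$atoms$vdw + 1.4)^2)
  expect_lte(s$total, iso)
  expect_lt(s$total, iso)                      # bonded atoms overlap
  expect_equal(s$total, sum(s$per_atom), tolerance = 1e-6)
  # disjoint cloud: exact equality
  far <- structure_model({
    a <- do.call(rbind, lapply(1:4, function(i) one_atom(20 * i, resno = i)))
    a$eleno <- 1:4; a
  }, "far")
  sf <- sasa(far)
  expect_equal(sf$total, 4 * 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
})

test_that("buried surface obeys its defining identity and detects interfaces", {
  tc <- make_toy_complex(10, 10, salt_bridges = 3.2, hbonds = 2.9)
  m <- tc$model
  a <- select_atoms(m, chain = "A"); b <- select_atoms(m, chain = "B")
  rep <- buried_surface(m, a, b)
  # bsa_a + SASA(a in complex) = SASA(a alone)
  s_a <- sasa(a)
  s_ab <- sasa(m)
  in_complex_a <- sum(s_ab$per_atom[m$atoms$chain == "A"])
  expect_equal(rep$bsa_a, s_a$total - in_complex_a, tolerance = 1e-9)
  expect_gt(rep$bsa_a, 0)
  expect_equal(rep$interface_area, (rep$bsa_a + rep$bsa_b) / 2)
  expect_true(rep$fraction_of_surface_a >= 0 && rep$fraction_of_surface_a <= 1)
  # interface residues are exactly the engineered ones
  expect_setequal(rep$interface_residues_a$resno,
                  tc$manifest$interface_residues_a)
  expect_setequal(rep$interface_residues_b$resno,
                  tc$manifest$interface_residues_b)
  # per-residue delta-SASA recomputed by brute force: free minus complexed
  free_res <- sasa(a)$per_residue
  expect_equal(sum(rep$per_residue_a$dsasa), rep$bsa_a, tolerance = 1e-6)
  expect_true(all(rep$per_residue_a$dsasa <= free_res$area + 1e-9))
})

test_that("distant chains bury nothing", {
  tc <- make_toy_complex(6, 6, gap = 100)
  m <- tc$model
  rep <- buried_surface(m, select_atoms(m, chain = "A"),
                        select_atoms(m, chain = "B"))
  expect_equal(rep$bsa_a, 0, tolerance = 1e-9)
  expect_equal(rep$bsa_b, 0, tolerance = 1e-9)
  expect_equal(nrow(rep$interface_residues_a), 0)
})

test_that("interface residue sets grow monotonically as the threshold shrinks", {
  tc <- make_toy_complex(10, 10, salt_bridges = c(3.2, 3.8))
  m <- tc$model
  a <- select_atoms(m, chain = "A"); b <- select_atoms(m, chain = "B")
  thresholds <- c(20, 5, 0)
  prev <- character(0)
  for (th in thresholds) {
    ir <- interface_residues(m, a, b, delta_threshold = th)
    now <- paste(ir$residues_a$chain, ir$residues_a$resno)
    expect_true(all(prev %in% now))
    prev <- now
  }
})

test_that("overlapping partner selections are rejected", {
  tc <- make_toy_complex(6, 6)
  m <- tc$model
  a <- select_atoms(m, chain = "A")
  expect_error(buried_surface(m, a, a), "overlap")
})
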