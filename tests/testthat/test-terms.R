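# The five additive shift terms, their parameter surfaces and invariances.

test_that("backbone cosine series matches a term-by-term oracle", {
  pp <- test_params()
  tab <- pp$backbone
  oracle <- function(phi, psi) {
    v <- 0
    for (t in seq_len(nrow(tab))) {
      f1 <- switch(substr(tab$basis[t], 1, 1),
                   c = cos(tab$kphi[t] * phi * pi / 180),
                   s = sin(tab$kphi[t] * phi * pi / 180))
      f2 <- switch(substr(tab$basis[t], 2, 2),
                   c = cos(tab$kpsi[t] * psi * pi / 180),
                   s = sin(tab$kpsi[t] * psi * pi / 180))
      v <- v + tab$coeff[t] * f1 * f2
    }
    v
  }
  for (ang in list(c(-57, -47), c(-139, 135), c(60, 40), c(180, -180))) {
    expect_equal(backbone_term(ang[1], ang[2], pp, scale = c(1, 0)),
                 oracle(ang[1], ang[2]), tolerance = 1e-12)
  }
})

test_that("backbone scaling is affine and its degenerate cases behave", {
  pp <- test_params()
  raw <- backbone_term(-57, -47, pp, scale = c(1, 0))
  expect_equal(backbone_term(-57, -47, pp, scale = c(0, 8)), 8)
  expect_equal(backbone_term(12, 34, pp, scale = c(0, 8)), 8)
  expect_equal(backbone_term(-57, -47, pp, scale = c(2, 1)), 2 * raw + 1)
})

test_that("ring-current term follows the point-dipole geometry", {
  pp <- test_params()
  rg <- one_ring(c(0, 0, 0), c(0, 0, 1))
  magic <- acos(1 / sqrt(3)) * 180 / pi   # 54.7356... deg
  for (r in c(2.5, 4, 7)) {
    p <- r * c(sin(magic * pi / 180), 0, cos(magic * pi / 180))
    expect_lt(abs(ring_current_term(p, rg, pp)), 1e-9)
  }
  # axial (shielded) vs equatorial (deshielded) have opposite signs
  ax <- ring_current_term(c(0, 0, 3), rg, pp)
  eq <- ring_current_term(c(3, 0, 0), rg, pp)
  expect_lt(ax, 0)
  expect_gt(eq, 0)
  # 1/r^3 decay
  near <- ring_current_term(c(0, 0, 3), rg, pp)
  far <- ring_current_term(c(0, 0, 100), rg, pp)
  expect_lt(abs(far), 1e-4 * abs(near))
  expect_equal(far * 100^3, near * 3^3, tolerance = 1e-9)
  # hand evaluation: proton 3 A along the normal, i = 1, B = 30.42:
  # 30.42 * (1 - 3) / 27 = -2.2533... ppm
  rg1 <- one_ring(c(0, 0, 0), c(0, 0, 1))
  pp1 <- pp; pp1$ring_intensity["PHE6"] <- 1
  expect_equal(ring_current_term(c(0, 0, 3), rg1, pp1), 30.42 * (1 - 3) / 27,
               tolerance = 1e-9)
  expect_error(ring_current_term(c(0, 0, 0), rg, pp), "coincident")
})

test_that("solvent-exposed protons get the fixed water-model primary term", {
  pp <- test_params()
  hb <- tibble::tibble(acceptor_class = "NONE", r_ho = NA_real_,
                       angle_hoc = NA_real_)
  expect_identical(primary_hb_term(hb, pp), 2.07)
})

test_that("amide-amide primary term decays strictly with bond length", {
  pp <- test_params()
  r <- seq(1.8, 3.0, by = 0.1)
  hb <- tibble::tibble(acceptor_class = "BACKBONE_AMIDE", r_ho = r,
                       angle_hoc = 155)
  v <- primary_hb_term(hb, pp)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0))
})

test_that("lookup surfaces reproduce grid nodes exactly and stay bounded", {
  pp <- test_params()
  for (gname in c("CARBOXYLATE", "ALCOHOL")) {
    g <- pp$grids[[gname]]
    nodes <- expand.grid(i = seq_along(g$r), j = seq_along(g$angle))
    got <- interp_surface(g, g$r[nodes$i], g$angle[nodes$j])
    expect_equal(got, g$values[cbind(nodes$i, nodes$j)], tolerance = 1e-12)
    # between nodes: bounded by surrounding node extrema (bilinear property)
    set.seed(4)
    for (rep in 1:25) {
      i <- sample(length(g$r) - 1, 1); j <- sample(length(g$angle) - 1, 1)
      tr <- runif(1); ta <- runif(1)
      q <- interp_surface(g, g$r[i] + tr * diff(g$r[i + 0:1]),
                          g$angle[j] + ta * diff(g$angle[j + 0:1]))
      corner <- g$values[i + 0:1, j + 0:1]
      expect_gte(q, min(corner) - 1e-12)
      expect_lte(q, max(corner) + 1e-12)
    }
    # clamped out-of-range with warning
    expect_warning(v <- interp_surface(g, max(g$r) + 1, 150), "clamped")
    expect_equal(v, interp_surface(g, max(g$r), 150))
  }
})

test_that("carboxylate bonds at grid nodes evaluate to stored node values", {
  pp <- test_params()
  g <- pp$grids$CARBOXYLATE
  hb <- tibble::tibble(acceptor_class = "CARBOXYLATE",
                       r_ho = g$r[3], angle_hoc = g$angle[4])
  expect_equal(primary_hb_term(hb, pp), g$values[3, 4], tolerance = 1e-12)
  # independent re-read of the shipped table
  raw <- utils::read.table(
    system.file("extdata", "hb_carboxylate_grid_synthetic.tsv",
                package = "amideshift"),
    header = TRUE, sep = "\t", comment.char = "#")
  node <- raw[raw$r == g$r[3] & raw$angle == g$angle[4], "value"]
  expect_equal(primary_hb_term(hb, pp), node, tolerance = 1e-12)
})

test_that("secondary term is zero without a bond and decays with distance", {
  pp <- test_params()
  expect_identical(secondary_hb_term(NULL, pp), 0)
  r <- seq(1.9, 2.5, by = 0.1)
  v <- secondary_hb_term(tibble::tibble(r_ho = r, angle_hoc = 150), pp)
  expect_true(all(diff(abs(v)) < 0))
  # oracle: direct evaluation of the bundled closed form
  cf <- pp$secondary
  expect_equal(v, exp(-cf$k * r) * (cf$a * cos(150 * pi / 180)^2 + cf$b),
               tolerance = 1e-12)
})

test_that("tertiary increments follow the bundled table and stay small", {
  pp <- test_params()
  expect_identical(tertiary_term(FALSE, FALSE, pp), 0)
  expect_equal(tertiary_term(TRUE, FALSE, pp),
               unname(pp$tertiary["PRIMARY_PARTNER_BONDED"]))
  expect_equal(tertiary_term(TRUE, TRUE, pp), unname(sum(pp$tertiary)))
  # a three-amide chain produces a nonzero tertiary term smaller than the
  # primary term
  helix <- make_peptide(12)
  pr <- predict_shifts(helix, pp)
  chained <- pr[pr$tertiary > 0, ]
  expect_gt(nrow(chained), 0)
  expect_true(all(abs(chained$tertiary) < abs(chained$primary_hb)))
})

test_that("missing parameter files raise a configuration error", {
  expect_error(shift_params(dir = withr::local_tempdir()),
               "configuration error")
})
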