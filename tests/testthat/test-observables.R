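# Trans-hydrogen-bond couplings, RDC tensor fitting and Q-factors.

test_that("h3J matches its closed form and decays with bond length", {
  pp <- test_params()
  geom <- tibble::tibble(r_ho = 1.9, angle_nho = 165, angle_hoc = 155)
  cf <- pp$jcoupling
  oracle <- -cf$A * exp(-cf$k * (1.9 - cf$r0)) * cos(165 * pi / 180)^2 *
    (cf$p * cos(155 * pi / 180)^2 + cf$q)
  expect_equal(j_coupling(geom, pp), oracle, tolerance = 1e-12)
  expect_lt(j_coupling(geom, pp), 0)

  r <- seq(1.8, 2.4, by = 0.1)
  v <- j_coupling(tibble::tibble(r_ho = r, angle_nho = 165, angle_hoc = 155), pp)
  expect_true(all(diff(abs(v)) < 0))
})

test_that("opened hydrogen bonds back-calculate to ~0 Hz", {
  pp <- test_params()
  d <- make_amide_dimer(6, 150)
  g <- amide_pair_geometry(d, 12, 1)
  expect_lt(abs(j_coupling(g, pp)), 0.01)
})

test_that("couplings are defined only across amide-amide bonds", {
  pp <- test_params()
  hb <- tibble::tibble(acceptor_class = "ALCOHOL", r_ho = 1.9,
                       angle_nho = 165, angle_hoc = 150)
  expect_error(j_coupling(hb, pp), "amide-amide")
})

test_that("couplings are invariant under rigid motions", {
  pp <- test_params()
  s <- make_peptide(10)
  j1 <- couplings(s, params = pp)
  j2 <- couplings(rigid_move(s), params = pp)
  expect_equal(j2$j, j1$j, tolerance = 1e-8)
})

test_that("ensemble coupling statistics match a brute-force double loop", {
  pp <- test_params()
  s <- make_peptide(10)
  base <- couplings(s, params = pp)
  pairs <- tibble::tibble(donor = base$donor, acceptor = base$acceptor)

  # single conformer, J == experiment -> RMSD 0
  exp_tbl <- tibble::tibble(donor = base$donor, acceptor = base$acceptor,
                            j_exp = base$j)
  one <- ensemble_couplings(s, pairs, exp_tbl, pp)
  expect_equal(attr(one, "rmsd"), 0, tolerance = 1e-12)
  expect_equal(one$sd_j, rep(0, nrow(one)))

  # 20-conformer synthetic ensemble vs brute force
  set.seed(21)
  ens <- lapply(1:20, function(i)
    make_peptide(10, phi = -57 + rnorm(10, 0, 3), psi = -47 + rnorm(10, 0, 3)))
  got <- ensemble_couplings(ens, pairs, exp_tbl, pp)
  jm <- sapply(ens, function(ss) couplings(ss, pairs, pp)$j)
  bf_mean <- apply(jm, 1, mean)
  bf_sd <- sqrt(apply((jm - bf_mean)^2, 1, mean))
  expect_equal(got$mean_j, bf_mean, tolerance = 1e-12)
  expect_equal(got$sd_j, bf_sd, tolerance = 1e-12)
  expect_equal(attr(got, "rmsd"),
               sqrt(mean((bf_mean - exp_tbl$j_exp)^2)), tolerance = 1e-12)

  # two conformers symmetric about experiment: zero mean error per bond
  jm2 <- sapply(ens[1:2], function(ss) couplings(ss, pairs, pp)$j)
  sym_exp <- tibble::tibble(donor = pairs$donor, acceptor = pairs$acceptor,
                            j_exp = rowMeans(jm2))
  two <- ensemble_couplings(ens[1:2], pairs, sym_exp, pp)
  expect_equal(attr(two, "rmsd"), 0, tolerance = 1e-12)
})

test_that("alignment tensor round-trips from noiseless synthetic RDCs", {
  h <- make_peptide(12)
  rdc <- make_synthetic_rdcs(h, seed = 17)
  fit <- fit_alignment_tensor(h, rdc[, c("resno", "d")])
  expect_lt(max(abs(fit$saupe - attr(rdc, "tensor"))), 1e-8)
  expect_lt(fit$q, 1e-6)
  # Saupe matrix is symmetric traceless
  S <- saupe_matrix(fit)
  expect_equal(S, t(S))
  expect_equal(sum(diag(S)), 0, tolerance = 1e-12)
  # duplicated-conformer ensemble gives the identical tensor
  fit2 <- fit_alignment_tensor(list(h, h, h), rdc[, c("resno", "d")])
  expect_equal(fit2$saupe, fit$saupe, tolerance = 1e-12)
})

test_that("round-trip exactness holds for random full-rank geometries", {
  set.seed(33)
  for (rep in 1:5) {
    s <- make_peptide(9, phi = runif(9, -150, -50), psi = runif(9, -60, 150))
    rdc <- make_synthetic_rdcs(s)
    fit <- fit_alignment_tensor(s, rdc[, c("resno", "d")])
    expect_lt(fit$q, 1e-6)
  }
})

test_that("underdetermined and degenerate RDC fits error out", {
  h <- make_peptide(12)
  rdc <- make_synthetic_rdcs(h, seed = 1)
  expect_error(fit_alignment_tensor(h, rdc[1:4, c("resno", "d")]), ">= 5")

  # collinear N-H vectors: a flat extended strand has (anti)parallel N-H
  # bonds, whose quadratic orientation rows are rank deficient
  flat <- make_peptide(8, phi = -180, psi = 180)
  fake <- tibble::tibble(resno = 2:8, d = rnorm(7))
  expect_error(fit_alignment_tensor(flat, fake), "rank-deficient")
})

test_that("Q-factor normalization behaves at its anchors and by hand", {
  d <- c(3.2, -1.5, 0.7)
  expect_equal(q_factor(d, d), 0)
  expect_equal(q_factor(rep(0, 3), d), 1)
  calc <- c(3.0, -1.0, 1.0)
  expect_equal(q_factor(calc, d),
               sqrt(((3.0 - 3.2)^2 + (-1.0 + 1.5)^2 + (1.0 - 0.7)^2) /
                      (3.2^2 + 1.5^2 + 0.7^2)),
               tolerance = 1e-12)
  expect_error(q_factor(numeric(0), numeric(0)), "no RDC")
  expect_error(q_factor(c(1, 2), c(0, 0)), "zero")
})

test_that("ensemble Q with identical conformers equals single-structure Q", {
  h <- make_peptide(12)
  rdc <- make_synthetic_rdcs(h, seed = 5, noise_sd = 0.3)
  q1 <- fit_alignment_tensor(h, rdc[, c("resno", "d")])$q
  qE <- fit_alignment_tensor(list(h, h), rdc[, c("resno", "d")])$q
  expect_equal(qE, q1, tolerance = 1e-12)
})

test_that("tidy/glance/autoplot methods work for tensor fits", {
  h <- make_peptide(12)
  rdc <- make_synthetic_rdcs(h, seed = 2, noise_sd = 0.2)
  fit <- fit_alignment_tensor(h, rdc[, c("resno", "d")])
  td <- generics::tidy(fit)
  expect_equal(td$component, c("Sxx", "Syy", "Sxy", "Sxz", "Syz"))
  gl <- generics::glance(fit)
  expect_equal(gl$n, nrow(rdc))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("coupling and RDC tables read from CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("donor,acceptor,j_exp", "5,1,-0.45"), f)
  expect_equal(read_coupling_table(f)$j_exp, -0.45)
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("resno,d", "2,4.3"), f2)
  expect_equal(read_rdc_table(f2)$d, 4.3)
})
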