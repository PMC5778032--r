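test_that("standardization gives exact zero mean, unit sample SD", {
  s <- standardize_series(matrix(c(1, 2, 3), 1))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(as.numeric(s$z), c(-1, 0, 1))

  # constant row: flagged invalid, SD 0, zeroed
  s2 <- standardize_series(rbind(c(5, 5, 5, 5), c(1, 2, 4, 0)))
  expect_false(s2$valid[1])
  expect_equal(s2$sd[1], 0)
  expect_equal(as.numeric(s2$z[1, ]), rep(0, 4))

  set.seed(42)
  s3 <- standardize_series(matrix(rnorm(50 * 40), 50))
  expect_true(all(abs(rowMeans(s3$z)) < 1e-12))
  expect_true(all(abs(apply(s3$z, 1, sd) - 1) < 1e-12))

  expect_error(standardize_series(matrix(1, 3, 1)), "2 timepoints")
})

test_that("perfectly shared signal gives unit correlations and vIFC = STD", {
  ico <- make_icosphere(0)
  nb <- build_neighborhoods(ico, 2)
  set.seed(3)
  base <- rnorm(60, sd = 2)
  series <- matrix(base, nrow = 12, ncol = 60, byrow = TRUE)
  series <- series * seq(0.5, 6, length.out = 12)  # positive rescalings
  maps <- compute_vifc(series, nb)
  expect_equal(maps$corr_in, rep(1, 12), tolerance = 1e-12)
  expect_equal(maps$corr_out, rep(1, 12), tolerance = 1e-12)
  expect_equal(maps$vifc, maps$std, tolerance = 1e-12)
})

test_that("anticorrelated blocks flip the signed outside mean only", {
  ico <- make_icosphere(0)
  nb <- build_neighborhoods(ico, 1)
  set.seed(4)
  sig <- rnorm(80)
  series <- rbind(matrix(sig, 6, 80, byrow = TRUE),
                  matrix(-sig, 6, 80, byrow = TRUE))
  signed <- compute_vifc(series, nb)
  absolute <- compute_vifc(series, nb, mode = "absolute")
  expect_equal(absolute$corr_out, rep(1, 12), tolerance = 1e-12)
  expect_equal(absolute$corr_in, rep(1, 12), tolerance = 1e-12)
  # every vertex sees some +sig and some -sig outside; |signed out| < 1
  expect_true(all(abs(signed$corr_out) < 1))
})

test_that("independent white noise keeps neighborhood correlations small", {
  set.seed(1234)
  m <- make_icosphere(1)
  nb <- build_neighborhoods(m, 2)
  series <- matrix(rnorm(42 * 2000), 42)
  ci <- mean_corr_in(standardize_series(series), nb)
  expect_true(all(abs(ci) < 0.1))
})

test_that("fast paths match the naive double-loop oracle on small meshes", {
  for (spec in list(
    list(mesh = make_icosphere(0), n = 40, order = 1),
    list(mesh = make_icosphere(1), n = 60, order = 2))) {
    set.seed(99)
    series <- matrix(rnorm(nrow(spec$mesh$vertices) * spec$n),
                     ncol = spec$n)
    series[2, ] <- 7  # one constant vertex exercises the valid flags
    nb <- build_neighborhoods(spec$mesh, spec$order)
    for (mode in c("signed", "absolute")) {
      got <- compute_vifc(series, nb, mode = mode)
      ref <- oracle_vifc(series, nb, mode = mode)
      expect_equal(got$corr_in, ref$corr_in, tolerance = 1e-10)
      expect_equal(got$corr_out, ref$corr_out, tolerance = 1e-10)
      expect_equal(got$vifc, ref$vifc, tolerance = 1e-10)
      expect_equal(got$std, ref$std, tolerance = 1e-10)
    }
  }
})

test_that("oracle equivalence holds under a cortex mask and include_self", {
  set.seed(7)
  mesh0 <- make_icosphere(1)
  mask <- rep(TRUE, 42)
  mask[c(3, 17, 30)] <- FALSE
  mesh <- surface_mesh(mesh0$vertices, mesh0$faces, mask = mask)
  series <- matrix(rnorm(42 * 50), 42)
  nb <- build_neighborhoods(mesh, 2)
  for (mode in c("signed", "absolute")) {
    for (self in c(FALSE, TRUE)) {
      got <- compute_vifc(series, nb, mode = mode, include_self = self)
      ref <- oracle_vifc(series, nb, mask = mask, mode = mode,
                         include_self = self)
      expect_equal(got$corr_in, ref$corr_in, tolerance = 1e-10)
      expect_equal(got$corr_out, ref$corr_out, tolerance = 1e-10)
      expect_equal(got$vifc, ref$vifc, tolerance = 1e-10)
    }
  }
  expect_true(all(is.na(got$vifc[!mask])))
})

test_that("vIFC is scale-equivariant; correlations are scale-invariant", {
  set.seed(5)
  m <- make_icosphere(1)
  nb <- build_neighborhoods(m, 2)
  series <- matrix(rnorm(42 * 80), 42)
  a <- compute_vifc(series, nb)
  b <- compute_vifc(series * 3.7, nb)
  expect_equal(b$std, 3.7 * a$std, tolerance = 1e-12)
  expect_equal(b$vifc, 3.7 * a$vifc, tolerance = 1e-10)
  expect_equal(b$corr_in, a$corr_in, tolerance = 1e-12)
  expect_equal(b$corr_out, a$corr_out, tolerance = 1e-12)
})

test_that("identity vIFC = STD * Corr_in / Corr_out holds wherever defined", {
  set.seed(6)
  m <- make_icosphere(1)
  nb <- build_neighborhoods(m, 2)
  maps <- compute_vifc(matrix(rnorm(42 * 60), 42), nb)
  ok <- maps$defined
  expect_true(any(ok))
  expect_equal(maps$vifc[ok],
               (maps$std * maps$corr_in / maps$corr_out)[ok],
               tolerance = 1e-12)
})

test_that("near-zero denominators produce missing values, never infinities", {
  set.seed(8)
  m <- make_icosphere(1)
  nb <- build_neighborhoods(m, 2)
  series <- matrix(rnorm(42 * 30), 42)
  maps <- compute_vifc(series, nb, epsilon = 1)  # guard swallows everything
  expect_true(all(is.na(maps$vifc)))
  expect_equal(maps$n_undefined, 42L)
  maps2 <- compute_vifc(series, nb, epsilon = 0)
  expect_false(any(is.infinite(maps2$vifc), na.rm = TRUE))
})

test_that("degenerate inputs raise the documented errors", {
  m <- make_icosphere(0)
  nb2 <- build_neighborhoods(m, 2)
  expect_error(compute_vifc(matrix(rnorm(10 * 20), 10), nb2), "12 vertices")
  # order 3 on an icosahedron leaves no outside set
  nb3 <- build_neighborhoods(m, 3)
  expect_error(compute_vifc(matrix(rnorm(12 * 20), 12), nb3),
               "outside set is empty")
  expect_error(compute_vifc(matrix(rnorm(24), 12), nb2), "3 timepoints")
  expect_error(compute_vifc(matrix(rnorm(12 * 20), 12), nb2, epsilon = -1),
               "epsilon")
})

test_that("separation AUC has the Wilcoxon interpretation", {
  expect_equal(separation_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(separation_auc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # pairwise wins: (1>2)F (1>4)F (3>2)T (3>4)F -> 1/4
  expect_equal(separation_auc(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE)),
               0.25)
  expect_equal(separation_auc(c(1, 2, 3, 4), c(TRUE, FALSE, FALSE, TRUE)),
               0.5)
  expect_error(separation_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})
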