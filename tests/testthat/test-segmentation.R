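test_that("Otsu threshold splits two-valued and mixture images like the exhaustive scan", {
  z <- matrix(c(rep(0.2, 128), rep(0.8, 128)), 16)
  t2 <- otsu_threshold(z)
  expect_gt(t2, 0.2)
  expect_lt(t2, 0.8)

  set.seed(21)
  zm <- matrix(pmin(pmax(c(rnorm(2048, 0.15, 0.05), rnorm(2048, 0.75, 0.05)), 0), 1), 64)
  expect_lt(abs(otsu_threshold(zm) - oracle_otsu(zm)), 0.05)

  expect_error(otsu_threshold(matrix(0.5, 8, 8)),
               class = "fins_degenerate_histogram")
})

test_that("fitting term is the pointwise threshold difference", {
  z <- matrix(0, 4, 4)
  expect_equal(build_fitting_term(z, 0.3)$f, matrix(0.3, 4, 4))
  zb <- matrix(c(0, 1), 4, 4)
  expect_equal(sort(unique(as.vector(build_fitting_term(zb, 0.5)$f))),
               c(-0.5, 0.5))
  z2 <- matrix(c(0.4, 0.1, 0.9, 0.4), 2)
  f2 <- build_fitting_term(z2, 0.4)$f
  expect_equal(f2[1, 1], 0)      # zero crossing where z equals t
  expect_error(build_fitting_term(z, 0), ">")
})

test_that("initial labelling is the indicator of negative fitting values", {
  fpos <- build_fitting_term(matrix(0.1, 8, 8), 0.4)       # f = +0.3
  expect_equal(initialize_indicator(fpos)$u, matrix(0, 8, 8))
  fneg <- build_fitting_term(matrix(0.9, 8, 8), 0.4)       # f = -0.5
  expect_equal(initialize_indicator(fneg)$u, matrix(1, 8, 8))
  z <- make_two_disk_image(centers = rbind(c(32, 32)), radius = 10)
  fd <- build_fitting_term(z, 0.5)
  expect_equal(initialize_indicator(fd)$u, (z > 0.5) * 1)
  expect_equal(initialize_indicator(fd)$iterations, 0L)
})

test_that("constant-sign fitting terms give the analytic minimizers", {
  params <- fins_params()
  up <- minimize_energy(build_fitting_term(matrix(0.1, 24, 24), 0.4), params)
  expect_equal(up$u, matrix(0, 24, 24))
  expect_equal(up$final_energy, 0)
  un <- minimize_energy(build_fitting_term(matrix(0.9, 24, 24), 0.4), params,
                        init = "zero")
  expect_equal(un$u, matrix(1, 24, 24), tolerance = 1e-8)
})

test_that("solver output matches or beats the best binary candidate on a disk", {
  h <- 80; w <- 80
  disk <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w)
    if ((i - 40)^2 + (j - 40)^2 <= 20^2) disk[i, j] <- TRUE
  f <- list(f = ifelse(disk, -0.5, 0.5), threshold = 0.5)
  class(f) <- "fins_fitting"
  params <- fins_params()
  sol <- minimize_energy(f, params)
  # candidate binary solutions: empty, the disk, the full domain
  cand <- c(empty = tv_energy(matrix(0, h, w), f, params$lambda),
            disk = tv_energy(disk * 1, f, params$lambda),
            full = tv_energy(matrix(1, h, w), f, params$lambda))
  expect_equal(names(which.min(cand)), "disk")  # fidelity beats perimeter here
  expect_lte(sol$final_energy, min(cand) + 0.01 * abs(min(cand)))
  expect_equal(binarize_solution(sol, 0.5), disk)
})

test_that("energy never increases from the initialization", {
  params <- fins_params()
  for (s in 1:5) {
    fx <- generate_fixture(fixture_spec(n_nuclei = 8, height = 128, width = 128,
                                        noise_sigma = 0.03, seed = 60 + s))
    t <- otsu_threshold(fx$channels$DAPI)
    f <- build_fitting_term(fx$channels$DAPI, t)
    u0 <- initialize_indicator(f)
    e0 <- tv_energy(u0$u, f, params$lambda)
    sol <- minimize_energy(f, params)
    expect_lte(sol$final_energy, e0 + 1e-9 * abs(e0))
  }
})

test_that("the binarized segmentation does not depend on the initialization", {
  for (s in 1:4) {
    fx <- generate_fixture(fixture_spec(n_nuclei = 8, height = 128, width = 128,
                                        noise_sigma = 0.03, seed = 80 + s))
    t <- otsu_threshold(fx$channels$DAPI)
    f <- build_fitting_term(fx$channels$DAPI, t)
    a <- binarize_solution(minimize_energy(f, init = "threshold"))
    b <- binarize_solution(minimize_energy(f, init = "zero"))
    expect_identical(a, b)
  }
})

test_that("binarization level does not matter where the solution is binary", {
  # exact level-invariance is a theorem on noiseless piecewise-constant
  # fields, where the converged labelling is fully binary
  fx <- generate_fixture(fixture_spec(n_nuclei = 8, height = 128, width = 128,
                                      noise_sigma = 0, speckle_rate = 0,
                                      n_detritus = 0, profile = "hard",
                                      seed = 91))
  t <- otsu_threshold(fx$channels$DAPI)
  sol <- minimize_energy(build_fitting_term(fx$channels$DAPI, t))
  expect_lt(sol$nonbinary_fraction, 0.01)
  m1 <- binarize_solution(sol, 0.25)
  m2 <- binarize_solution(sol, 0.5)
  m3 <- binarize_solution(sol, 0.75)
  expect_identical(m1, m2)
  expect_identical(m2, m3)

  # under noise the relaxed minimiser may be fractional at interface
  # pixels; level changes may flip only those, and never the count
  fxn <- generate_fixture(fixture_spec(n_nuclei = 8, height = 128, width = 128,
                                       noise_sigma = 0.02, seed = 91))
  tn <- otsu_threshold(fxn$channels$DAPI)
  soln <- minimize_energy(build_fitting_term(fxn$channels$DAPI, tn))
  nonbin <- soln$u > 0.05 & soln$u < 0.95
  d1 <- binarize_solution(soln, 0.25); d3 <- binarize_solution(soln, 0.75)
  expect_true(all((d1 != d3) <= nonbin))
  expect_equal(label_nuclei(d1)$n, label_nuclei(d3)$n)

  expect_identical(binarize_solution(matrix(0, 4, 4)), matrix(FALSE, 4, 4))
  expect_identical(binarize_solution(matrix(1, 4, 4)), matrix(TRUE, 4, 4))
})

test_that("labelling agrees with flood-fill oracles under both connectivities", {
  empty <- label_nuclei(matrix(FALSE, 16, 16))
  expect_equal(empty$n, 0)

  z <- make_two_disk_image()
  two <- label_nuclei(z > 0.5)
  expect_equal(two$n, 2)

  corner <- matrix(FALSE, 8, 8)
  corner[2, 2] <- TRUE; corner[3, 3] <- TRUE
  expect_equal(label_nuclei(corner, connectivity = 8)$n, 1)
  expect_equal(label_nuclei(corner, connectivity = 4)$n, 2)

  set.seed(33)
  for (rep in 1:5) {
    m <- matrix(runif(400) < 0.35, 20, 20)
    expect_equal(label_nuclei(m, connectivity = 8)$n, oracle_label(m, 8)$n)
    expect_equal(label_nuclei(m, connectivity = 4)$n, oracle_label(m, 4)$n)
    # EBImage's labeller is 4-connected: independent cross-check
    expect_equal(label_nuclei(m, connectivity = 4)$n,
                 max(EBImage::bwlabel(m * 1)))
  }
})

test_that("labels are raster-ordered, disjoint, and filterable by area", {
  z <- make_two_disk_image(centers = rbind(c(40, 12), c(12, 40)), radius = 6)
  z[50, 50] <- 0.9                      # single-pixel object, last in raster order
  lab <- label_nuclei(z > 0.5)
  expect_equal(lab$n, 3)
  # raster order: the disk whose first pixel comes first scans first
  first_rows <- vapply(1:3, function(i)
    min(which(lab$label_map == i, arr.ind = TRUE)[, 1]), numeric(1))
  expect_equal(first_rows, sort(first_rows))
  expect_equal(sum(lab$sizes), sum(z > 0.5))
  expect_equal(sort(unique(as.vector(lab$label_map))), 0:3)
  filtered <- label_nuclei(z > 0.5, min_area = 5)
  expect_equal(filtered$n, 2)
  expect_equal(region_pixels(filtered, 1), which(filtered$label_map == 1))
})

test_that("segment_nuclei recovers the exact threshold set on noiseless piecewise-constant fields", {
  fx <- generate_fixture(fixture_spec(n_nuclei = 10, noise_sigma = 0,
                                      speckle_rate = 0, n_detritus = 0,
                                      profile = "hard", seed = 14))
  seg <- segment_nuclei(fx$channels$DAPI)
  expect_identical(seg$mask, unclass(fx$channels$DAPI) > seg$t_delta)
  expect_equal(seg$labels$n, fx$truth$n_nuclei)
})

test_that("TV segmentation resists noise and speckle that break plain thresholding", {
  for (s in 1:3) {
    fx <- generate_fixture(fixture_spec(n_nuclei = 10, noise_sigma = 0.03,
                                        seed = 300 + s))
    z <- fx$channels$DAPI
    t <- otsu_threshold(z)
    plain_err <- abs(label_nuclei(unclass(z) > t)$n - fx$truth$n_nuclei)
    seg <- segment_nuclei(z)
    fins_err <- abs(seg$labels$n - fx$truth$n_nuclei)
    expect_lte(fins_err, plain_err)
    expect_equal(seg$labels$n, fx$truth$n_nuclei)
  }
})
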