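test_that("monoisotopic masses match tabulated values", {
  expect_equal(monoisotopic_mz("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mz("CH4"), 16.031300, tolerance = 1e-6)
  expect_equal(monoisotopic_mz(c(C = 1, H = 4)), 16.031300, tolerance = 1e-6)
  # linearity: doubling all counts doubles the neutral mass exactly
  expect_equal(monoisotopic_mz("C24H48O4"), 2 * monoisotopic_mz("C12H24O2"))
  # protonated dodecanoic acid: neutral + proton mass
  expect_equal(monoisotopic_mz("C12H25O2", charge = 1),
               monoisotopic_mz("C12H24O2") + 1.00782503207 - 0.000548579909,
               tolerance = 1e-9)
  expect_error(monoisotopic_mz("Xx2"), "unknown element")
  expect_error(monoisotopic_mz("c12"), "parse")
})

test_that("EIC window is closed at +/- tol and zero-fills empty scans", {
  rt <- c(1, 2, 3)
  run <- new_centroid_run(tibble::tibble(
    rt_s = c(1, 1, 2), mz = c(299.97, 300.03001, 310), intensity = c(5, 7, 9)),
    scan_rt = rt)
  eic <- extract_eic(run, 300, ppm_tol = 100) # window [299.97, 300.03]
  expect_equal(eic$rt_s, rt)
  expect_equal(eic$intensity, c(5, 0, 0)) # boundary included, beyond excluded
  eic_l <- extract_eic(run, 299.985, ppm_tol = 50.1)
  expect_equal(eic_l$intensity[1], 5)

  empty <- extract_eic(run, 500, ppm_tol = 100)
  expect_equal(empty$intensity, c(0, 0, 0))
})

test_that("widening the ppm window never decreases any scan's intensity", {
  pk <- tibble::tibble(mz = c(300, 300.05), rt_center_s = c(40, 60),
                       rt_sigma_s = 4, apex_intensity = c(1e5, 5e4))
  run <- sim_ms_run(pk, rt_range = c(0, 100), mz_jitter_ppm = 30,
                    noise_floor = 100, seed = 31)
  tols <- c(10, 50, 100, 200, 400)
  eics <- lapply(tols, function(tol) extract_eic(run, 300, ppm_tol = tol))
  for (i in seq_along(tols)[-1]) {
    expect_true(all(eics[[i]]$intensity >= eics[[i - 1]]$intensity))
  }
})

test_that("disjoint windows covering all centroids conserve the TIC", {
  pk <- tibble::tibble(mz = c(200, 300, 400), rt_center_s = c(30, 50, 70),
                       rt_sigma_s = 5, apex_intensity = c(1e5, 2e5, 3e5))
  run <- sim_ms_run(pk, rt_range = c(0, 100), mz_jitter_ppm = 10,
                    noise_floor = 0, seed = 32)
  parts <- lapply(c(200, 300, 400), function(mz)
    extract_eic(run, mz, ppm_tol = 100)$intensity)
  tic <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(run), rt_s),
                          tic = sum(intensity), .groups = "drop")
  full <- tibble::tibble(rt_s = scan_times(run)) |>
    dplyr::left_join(tic, by = "rt_s") |>
    dplyr::mutate(tic = dplyr::coalesce(tic, 0))
  expect_equal(Reduce(`+`, parts), full$tic, tolerance = 1e-12)
})

test_that("jitter-free generator round-trip reproduces the Gaussian profile and area", {
  pk <- tibble::tibble(mz = 300, rt_center_s = 150, rt_sigma_s = 5,
                       apex_intensity = 1e6)
  run <- sim_ms_run(pk, rt_range = c(0, 300), scan_interval = 1,
                    mz_jitter_ppm = 0, noise_floor = 0, seed = 33)
  eic <- extract_eic(run, 300, ppm_tol = 100)
  expected <- 1e6 * exp(-(eic$rt_s - 150)^2 / (2 * 25))
  expect_equal(eic$intensity, expected, tolerance = 1e-12)

  area <- integrate_peak(eic, c(100, 200))$area
  analytic <- 1e6 * 5 * sqrt(2 * pi)
  expect_lt(abs(area - analytic) / analytic, 0.01)
})

test_that("peak integration: rectangle, linear baseline, scaling, apex", {
  eic <- structure(tibble::tibble(rt_s = 0:20, intensity = rep(100, 21)),
                   class = c("eic", class(tibble::tibble())))
  expect_equal(integrate_peak(eic, c(5, 15))$area, 1000)
  expect_equal(integrate_peak(eic, c(5, 15), baseline = "linear")$area, 0)

  tri <- structure(tibble::tibble(rt_s = 0:10,
                                  intensity = c(0:5, 4:0) * 10),
                   class = c("eic", class(tibble::tibble())))
  res <- integrate_peak(tri, c(0, 10))
  expect_equal(res$apex_rt, 5)
  scaled <- tri
  scaled$intensity <- tri$intensity * 2.5
  expect_equal(integrate_peak(scaled, c(0, 10))$area, 2.5 * res$area,
               tolerance = 1e-12)

  zero <- structure(tibble::tibble(rt_s = 0:10, intensity = rep(0, 11)),
                    class = c("eic", class(tibble::tibble())))
  expect_equal(integrate_peak(zero, c(0, 10))$area, 0)
  expect_error(integrate_peak(eic, c(15, 30)), "outside")
  expect_error(integrate_peak(eic, c(10, 5)), "start < end")
})

test_that("relative abundance handles floors and degenerate controls", {
  expect_equal(relative_abundance(1000, 100, 1)$ratio, 10)
  expect_true(relative_abundance(1000, 100, 1)$detected_above_background)
  expect_equal(relative_abundance(500, 500, 1)$ratio, 1)
  low <- relative_abundance(0.5, 100, detection_floor = 1)
  expect_false(low$detected_above_background)
  no_ctrl <- relative_abundance(1000, 0.5, detection_floor = 1)
  expect_equal(no_ctrl$ratio, Inf)
  expect_error(relative_abundance(-1, 5), ">= 0")
})

test_that("centroid runs survive a JSON-lines round trip, empty scans included", {
  pk <- tibble::tibble(mz = 300, rt_center_s = 5, rt_sigma_s = 1,
                       apex_intensity = 1e4)
  run <- sim_ms_run(pk, rt_range = c(0, 20), mz_jitter_ppm = 5,
                    noise_floor = 0, seed = 34)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_centroid_jsonl(run, path)
  back <- read_centroid_jsonl(path)
  expect_equal(scan_times(back), scan_times(run))
  expect_equal(back$mz, run$mz, tolerance = 1e-12)
  expect_equal(back$intensity, run$intensity, tolerance = 1e-12)
  # EICs from the round-tripped run are identical
  expect_equal(extract_eic(back, 300)$intensity,
               extract_eic(run, 300)$intensity, tolerance = 1e-12)
})
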