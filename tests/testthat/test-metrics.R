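test_that("DVHs are exact empirical distributions", {
  dose <- array(5, c(10, 1, 1))
  mask <- array(TRUE, c(10, 1, 1))
  h <- dvh(dose, mask, voxel_cc = 0.1)
  expect_equal(unname(v_at_dose(h, 4.9)["cc"]), 1.0)
  expect_equal(unname(v_at_dose(h, 5)["cc"]), 1.0) # closed threshold
  expect_equal(unname(v_at_dose(h, 5.1)["cc"]), 0)
  dose2 <- array(0, c(100, 1, 1)); dose2[] <- 1:100
  h2 <- dvh(dose2, array(TRUE, c(100, 1, 1)), 1)
  expect_equal(unname(v_at_dose(h2, 50)["cc"]), 51) # doses 50..100
  expect_equal(unname(v_at_dose(h2, 50.5)["cc"]), 50)
  expect_equal(unname(v_at_dose(h2, 0)["pct"]), 100)
  # masked-out voxels are ignored entirely
  m3 <- array(FALSE, c(100, 1, 1)); m3[1:10] <- TRUE
  expect_length(dvh(dose2, m3, 1)$doses, 10)
  expect_error(dvh(dose2, array(FALSE, c(100, 1, 1)), 1), "empty")
})

test_that("D-at-volume is the ceiling-order statistic", {
  dose <- array(0, c(100, 1, 1)); dose[] <- sample(1:100)
  h <- dvh(dose, array(TRUE, c(100, 1, 1)), 1)
  expect_equal(d_at_volume(h, 0.02), 99) # 2nd hottest of 1..100
  expect_equal(d_at_volume(h, 1), 1) # limit: minimum dose
  u <- dvh(array(7.5, c(13, 1, 1)), array(TRUE, c(13, 1, 1)), 1)
  expect_equal(d_at_volume(u, 0.02), 7.5)
  expect_error(d_at_volume(h, 0), "fraction")
})

test_that("coverage agrees with the PTV DVH at the prescription dose", {
  dose <- array(12, c(100, 1, 1))
  ptv <- array(TRUE, c(100, 1, 1))
  expect_equal(coverage(dose, ptv), 100) # >= convention at exactly 12
  dose[1:2] <- 11.9
  expect_equal(coverage(dose, ptv), 98)
  h <- dvh(dose, ptv, 1)
  expect_equal(coverage(dose, ptv), unname(v_at_dose(h, 12)["pct"]))
})

test_that("conformity indices follow both documented variants", {
  dim3 <- c(10, 10, 1)
  ptv <- array(FALSE, dim3); ptv[3:6, 3:6, 1] <- TRUE
  body <- array(TRUE, dim3)
  dose <- array(0, dim3); dose[ptv] <- 12
  ci <- conformity_index(dose, ptv, body)
  expect_equal(ci$ratio, 1)
  expect_equal(ci$inverse_overlap, 1)
  # PIV twice the PTV volume, fully covering it
  dose2 <- array(0, dim3); dose2[3:6, 3:10, 1] <- 12
  ci2 <- conformity_index(dose2, ptv, body)
  expect_equal(ci2$ratio, 2)
  expect_equal(ci2$inverse_overlap, 2)
  # disjoint PIV: ratio finite, inverse-overlap undefined
  dose3 <- array(0, dim3); dose3[8:9, 1:2, 1] <- 12
  ci3 <- conformity_index(dose3, ptv, body)
  expect_equal(ci3$ratio, 4 / 16)
  expect_true(is.na(ci3$inverse_overlap))
})

test_that("rescaling hits the target coverage exactly", {
  ptv <- array(TRUE, c(50, 1, 1))
  # fixed point at exactly 98%
  dose <- array(0, c(50, 1, 1)); dose[] <- c(rep(12, 49), 11)
  rs <- rescale_to_coverage(dose, ptv)
  expect_equal(rs$factor, 1)
  # uniform 6 Gy doubles
  rs2 <- rescale_to_coverage(array(6, c(50, 1, 1)), ptv)
  expect_equal(rs2$factor, 2)
  expect_equal(coverage(rs2$dose, ptv), 100)
  # random fields: the order-statistic factor agrees with bisection to 1e-9
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(30:200, 1)
    d <- array(runif(n, 2, 18), c(n, 1, 1))
    p <- array(TRUE, c(n, 1, 1))
    rs3 <- rescale_to_coverage(d, p)
    lo <- 0.1; hi <- 10
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (coverage(mid * d, p) >= 98) hi <- mid else lo <- mid
    }
    expect_equal(rs3$factor, hi, tolerance = 1e-9)
    k <- ceiling(0.98 * n)
    expect_equal(sum(rs3$dose >= 12), k) # exact by the order statistic
  }
  # declined upscale is flagged
  rs4 <- rescale_to_coverage(array(6, c(50, 1, 1)), ptv,
                             hard_check = function(s) FALSE)
  expect_false(rs4$achieved)
  expect_equal(rs4$factor, 1)
  expect_error(rescale_to_coverage(array(0, c(10, 1, 1)),
                                   array(TRUE, c(10, 1, 1))), "zero")
})

test_that("metrics are invariant under voxel reordering", {
  set.seed(13)
  n <- 64
  d <- runif(n, 0, 15)
  perm <- sample(n)
  h1 <- dvh(array(d, c(n, 1, 1)), array(TRUE, c(n, 1, 1)), 1)
  h2 <- dvh(array(d[perm], c(n, 1, 1)), array(TRUE, c(n, 1, 1)), 1)
  expect_equal(d_at_volume(h1, 0.02), d_at_volume(h2, 0.02))
  expect_equal(v_at_dose(h1, 5), v_at_dose(h2, 5))
})

test_that("plan reports cover the full metric registry with explicit NAs", {
  ph <- generate_phantom(phantom_spec(voxel_mm = 4, rng_seed = 14))
  shells <- suppressWarnings(
    build_shell_set(ph$masks$PTV, ph$masks$body, 4, c(1, 2, 3, 5, 7), 4))
  rep0 <- plan_report(array(0, ph$dim), ph, shells)
  expect_s3_class(rep0, "vs_plan_metrics")
  expect_equal(rep0$value[rep0$metric == "V12Gy"], 0)
  expect_true(all(rep0$value[grepl("^V\\d+Gy$", rep0$metric) &
                               rep0$structure == "patient"] == 0))
  expect_true(is.na(rep0$value[rep0$metric == "CI"]))
  # missing structure yields NA, never zero
  ph2 <- ph
  ph2$masks$cochlea[] <- FALSE
  rep2 <- plan_report(array(1, ph$dim), ph2, shells)
  expect_true(is.na(rep2$value[rep2$structure == "cochlea"]))
  # schema: metric/structure/value/unit columns, plan rows present
  expect_named(rep2, c("metric", "structure", "value", "unit"))
  expect_true(all(c("MU", "Nodes", "Beams", "TreatmentTime") %in% rep2$metric))
  expect_true(all(paste0("shell_", names(shells$masks)) %in%
                    rep2$structure[rep2$metric == "D2%"]))
})
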