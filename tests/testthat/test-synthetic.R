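test_that("phantom ground truth carries labels, counts and passes validation", {
  spec <- phantom_spec(
    shape = c(48, 48, 48), spacing = c(1.5, 1.5, 1.5),
    lungs = list(list(center = c(0, 0, 0), semi = c(33, 33, 33))),
    tubes = c(
      lapply(1:6, function(i) list(
        control_points = cbind(-28 + i * 8, -10, c(-15, 15)), radius = 1.4,
        identity = "artery")),
      lapply(1:6, function(i) list(
        control_points = cbind(-28 + i * 8, 10, c(-15, 15)), radius = 1.4,
        identity = "vein"))),
    seed = 9L)
  ph <- make_phantom(spec)
  labs <- vapply(ph$truth$segments, function(s) s$label, character(1))
  expect_equal(sum(labs == "artery"), 6)
  expect_equal(sum(labs == "vein"), 6)
  expect_silent(validate_vessel_graph(ph$truth))
})

test_that("phantom generation is a pure function of the spec and seed", {
  spec <- phantom_spec(
    shape = c(32, 32, 32),
    lungs = list(list(center = c(0, 0, 0), semi = c(20, 20, 20))),
    tubes = list(list(control_points = cbind(0, 0, c(-10, 10)), radius = 2,
                      identity = "artery")),
    seed = 42L)
  p1 <- make_phantom(spec)
  p2 <- make_phantom(spec)
  expect_identical(p1$volume$data, p2$volume$data)
  p3 <- make_phantom(phantom_spec(
    shape = c(32, 32, 32),
    lungs = spec$lungs, tubes = spec$tubes, seed = 43L))
  expect_false(identical(p1$volume$data, p3$volume$data))
})

test_that("a vessel tube leaving the lung raises a spec error", {
  spec <- phantom_spec(
    shape = c(32, 32, 32),
    lungs = list(list(center = c(0, 0, 0), semi = c(10, 10, 10))),
    tubes = list(list(control_points = cbind(0, 0, c(-20, 20)), radius = 2,
                      identity = "artery")),
    seed = 1L)
  expect_error(make_phantom(spec), "spec error")
})

test_that("the benchmark phantom spans all bins for both labels", {
  ph <- benchmark_bundle()
  cnt <- ph$truth_bin_counts
  expect_equal(unname(cnt["artery", c("2_4", "4_6", "6_10")]), c(4, 2, 2))
  expect_equal(unname(cnt["vein", c("2_4", "4_6", "6_10")]), c(4, 2, 2))
  expect_equal(length(ph$truth$segments), 16)
  expect_silent(validate_vessel_graph(ph$truth))
})

test_that("cohort generation is deterministic with consistent group labels", {
  sp <- cohort_spec(n_patients = 60, seed = 7L)
  t1 <- make_cohort(sp)
  t2 <- make_cohort(sp)
  expect_identical(t1, t2)
  expect_true(all(t1$mPAP > 0))
  expect_identical(t1$ph_status, t1$mPAP > 20)
  expect_error(cohort_spec(n_patients = 3), "at least 4")
})

test_that("the PH prevalence follows the binomial target", {
  tab <- make_cohort(cohort_spec(n_patients = 170, seed = 12L))
  p <- 149 / 170
  ci <- qbinom(c(0.0005, 0.9995), 170, p)
  expect_gte(sum(tab$ph_status), ci[1])
  expect_lte(sum(tab$ph_status), ci[2])
})

test_that("a zero link strength gives a null mPAP-ratio correlation", {
  tab <- make_cohort(cohort_spec(n_patients = 1000, link_scale = 0,
                                 seed = 3L))
  r <- spearman_cor(tab$mPAP, tab$ratio_av_6_10)
  expect_lt(abs(r$rho), 0.08)
})

test_that("the planted mPAP group shift is overwhelmingly detectable", {
  tab <- make_cohort(cohort_spec(n_patients = 2000, seed = 17L))
  res <- rank_tests(list(tab$mPAP[!tab$ph_status], tab$mPAP[tab$ph_status]))
  expect_lt(res$p.value, 1e-6)
})

test_that("cohort marginals sit near their target medians", {
  tab <- make_cohort(cohort_spec(n_patients = 2000, seed = 23L))
  expect_lt(abs(median(tab$mPAP[tab$ph_status]) - 38), 3)
  expect_lt(abs(median(tab$mPAP[!tab$ph_status]) - 17), 1.5)
  expect_lt(abs(median(tab$n_segments_total) - 1843), 80)
  expect_lt(abs(median(tab$DMPA[tab$ph_status]) - 32.7), 1.5)
  expect_lt(abs(median(tab$DMPA[!tab$ph_status]) - 27.4), 1.5)
  # density consistency identity
  expect_equal(tab$density_total, tab$n_segments_total / tab$lung_volume_L)
  expect_equal(tab$ratio_av_6_10,
               tab$count_artery_6_10 / tab$count_vein_6_10)
})

test_that("exactly the requested number of low-accuracy rows is planted", {
  tab <- make_cohort(cohort_spec(n_patients = 170, seed = 2L))
  expect_equal(sum(tab$av_accuracy < 0.80), 53)
  tab2 <- make_cohort(cohort_spec(n_patients = 80, n_low_accuracy = 10,
                                  seed = 2L))
  expect_equal(sum(tab2$av_accuracy < 0.80), 10)
})
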