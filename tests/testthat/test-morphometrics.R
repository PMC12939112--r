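test_that("representative diameter is twice the median radius", {
  s1 <- vessel_segment(cbind(0:5, 0, 0), rep(1.5, 6))
  expect_equal(segment_diameter(s1), 3.0)
  s2 <- vessel_segment(cbind(0:2, 0, 0), c(1.0, 1.2, 3.0))
  expect_equal(segment_diameter(s2), 2.4)
})

test_that("SOAM closed-form cases are exact", {
  straight <- vessel_segment(cbind(seq(0, 30, by = 1.7), 5, -2), rep(2, 18))
  expect_lt(abs(soam(straight)), 1e-12)
  bend <- vessel_segment(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0)), rep(2, 3))
  expect_equal(soam(bend), (pi / 2) / 10)
  # two-point segment: no interior angle
  expect_equal(soam(vessel_segment(cbind(c(0, 9), 0, 0), c(2, 2))), 0)
  expect_error(soam(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))), "duplicate")
})

test_that("SOAM of a sampled circle converges to its curvature", {
  # R = 10 mm circle sampled every 0.5 mm of arc; the chord-angle deficit is
  # one interior angle over the whole polyline, below 1% at this length
  th <- seq(0, 2 * pi, by = 0.05)
  arc <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_lt(abs(soam(arc) - 0.100) / 0.100, 0.01)
})

test_that("SOAM is rigid-motion invariant and scales as 1/c", {
  set.seed(8)
  pts <- cbind(cumsum(runif(12, 1, 3)), cumsum(rnorm(12)), cumsum(rnorm(12)))
  seg <- vessel_segment(pts, rep(2, 12))
  base <- soam(seg)
  # rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- vessel_segment(pts %*% t(R) + 5, rep(2, 12))
  expect_equal(soam(moved), base, tolerance = 1e-12)
  # uniform scaling by c scales SOAM by 1/c
  expect_equal(soam(vessel_segment(pts * 3, rep(2, 12))), base / 3,
               tolerance = 1e-12)
})

test_that("helical ground-truth SOAM matches the analytic curvature", {
  hx <- helix_centerline(R = 10, c_pitch = 4, turns = 2, step = 0.5)
  expect_lt(abs(soam(hx$points) - hx$kappa) / hx$kappa, 0.01)
})

test_that("report arithmetic: densities, ratios, differences, totals", {
  # 100 segments in a 4 L lung -> density 25 / L
  segs <- lapply(1:100, function(i)
    vessel_segment(cbind(i, 0, c(0, 10)), c(1.5, 1.5),
                   label = c("artery", "vein")[1 + i %% 2], id = i))
  rep100 <- compute_report(vessel_graph(segs), 4.0)
  expect_equal(rep100$density_total, 25.0)
  # constructed bin counts: artery (2,1,4), vein (2,1,2), lung 4 L
  mk <- function(lab, dias, off) lapply(seq_along(dias), function(i)
    vessel_segment(cbind(off + i * 20, 0, c(0, 10)), rep(dias[i] / 2, 2),
                   label = lab, id = off + i))
  g <- vessel_graph(c(mk("artery", c(2.5, 3, 4.5, 7, 7.5, 8, 9), 0),
                      mk("vein", c(2.6, 3.1, 5.5, 6.5, 9.5), 100)))
  r <- compute_report(g, 4.0)
  expect_equal(r$count_artery_2_4, 2)
  expect_equal(r$count_artery_4_6, 1)
  expect_equal(r$count_artery_6_10, 4)
  expect_equal(r$ratio_av_2_4, 1.0)
  expect_equal(r$ratio_av_4_6, 1.0)
  expect_equal(r$ratio_av_6_10, 2.0)
  expect_equal(r$density_diff_av_6_10, 0.5)
  # totals: artery + vein + unknown = total
  expect_equal(r$count_artery_all + r$count_vein_all, r$n_segments_total)
  # ratio undefined when the vein bin is empty
  g2 <- vessel_graph(mk("artery", c(7), 0))
  expect_true(is.na(compute_report(g2, 4.0)$ratio_av_6_10))
})

test_that("vessel volume approximates the analytic cylinder volume", {
  seg <- vessel_segment(cbind(0, 0, seq(0, 50, by = 2)), rep(2, 26),
                        label = "artery", id = 1L)
  r <- compute_report(vessel_graph(list(seg)), 1.0)
  expect_lt(abs(r$vessel_volume_mm3 - pi * 4 * 50) / (pi * 4 * 50), 0.05)
  expect_equal(r$normalized_vessel_volume, r$vessel_volume_mm3 * 1e-6)
})

test_that("densities scale inversely with lung volume", {
  segs <- lapply(1:10, function(i)
    vessel_segment(cbind(i * 10, 0, c(0, 10)), c(2, 2), label = "artery",
                   id = i))
  g <- vessel_graph(segs)
  r1 <- compute_report(g, 2.0)
  r2 <- compute_report(g, 4.0)
  for (col in grep("^density", names(r1), value = TRUE))
    expect_equal(r2[[col]], r1[[col]] / 2)
  expect_error(compute_report(g, 0), "positive")
})

test_that("unknown labels count toward totals but not A/V metrics", {
  segs <- list(
    vessel_segment(cbind(0, 0, c(0, 10)), c(1.5, 1.5), "artery", 1L),
    vessel_segment(cbind(20, 0, c(0, 10)), c(1.5, 1.5), "vein", 2L),
    vessel_segment(cbind(40, 0, c(0, 10)), c(1.5, 1.5), "unknown", 3L))
  r <- compute_report(vessel_graph(segs), 1.0)
  expect_equal(r$n_segments_total, 3)
  expect_equal(r$count_artery_all, 1)
  expect_equal(r$count_vein_all, 1)
  expect_equal(r$density_total, 3)
})
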