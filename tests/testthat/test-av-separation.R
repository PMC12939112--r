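test_that("subtree grouping partitions segments by connectivity", {
  s <- function(id, x) vessel_segment(cbind(x, 0, 0:3 * 5), rep(2, 4), id = id)
  g4 <- vessel_graph(list(s(1, 0), s(2, 20), s(3, 40), s(4, 60)))
  expect_equal(length(group_subtrees(g4)), 4)
  expect_equal(length(group_subtrees(vessel_graph())), 0)
  # connected pair counts as one unit
  adj <- data.frame(branch_id = c(9L, 9L), seg_id = c(1L, 2L))
  g2 <- vessel_graph(list(s(1, 0), s(2, 20)), adj)
  u <- group_subtrees(g2)
  expect_equal(length(u), 1)
  expect_setequal(u[[1]]$segment_ids, c(1L, 2L))
})

test_that("bronchus affinity is high beside a parallel bronchus, zero otherwise", {
  # artery with a parallel bronchus 7 mm away, vein far from any airway
  spec <- phantom_spec(
    shape = c(64, 64, 64), spacing = c(1.5, 1.5, 1.5),
    lungs = list(list(center = c(0, 0, 0), semi = c(42, 42, 42))),
    tubes = list(
      list(control_points = cbind(-10, 0, c(-20, 20)), radius = 2,
           identity = "artery", paired_bronchus = TRUE, bronchus_gap = 7),
      list(control_points = cbind(20, 0, c(-20, 20)), radius = 2,
           identity = "vein")),
    hu = list(parenchyma = -850, vessel = 300, airway = -1000, body = 0,
              noise_sd = 0),
    seed = 4L)
  ph <- make_phantom(spec)
  units <- group_subtrees(ph$truth)
  aff <- vapply(units, bronchus_affinity, numeric(1),
                airways = ph$airway_mask, parallel_tol = 30, dist_max = 10)
  lab1 <- ph$truth$segments[[units[[1]]$segment_ids[1]]]$label
  a_aff <- aff[if (lab1 == "artery") 1 else 2]
  v_aff <- aff[if (lab1 == "artery") 2 else 1]
  expect_gte(a_aff, 0.8)
  expect_equal(v_aff, 0)
  # empty airway mask -> all zero
  empty <- mask_volume(array(0L, c(64, 64, 64)), spacing = c(1.5, 1.5, 1.5),
                       origin = ph$airway_mask$origin)
  expect_equal(vapply(units, bronchus_affinity, numeric(1), airways = empty),
               c(0, 0))
})

test_that("a vessel perpendicular to a touching airway has zero affinity", {
  spec <- phantom_spec(
    shape = c(64, 64, 64), spacing = c(1.5, 1.5, 1.5),
    lungs = list(list(center = c(0, 0, 0), semi = c(42, 42, 42))),
    tubes = list(
      list(control_points = cbind(0, 0, c(-20, 20)), radius = 2,
           identity = "artery"),
      list(control_points = cbind(c(-20, 20), 4.5, 0), radius = 2,
           identity = "bronchus")),
    hu = list(parenchyma = -850, vessel = 300, airway = -1000, body = 0,
              noise_sd = 0),
    seed = 4L)
  ph <- make_phantom(spec)
  units <- group_subtrees(ph$truth)
  expect_equal(bronchus_affinity(units[[1]], ph$airway_mask,
                                 parallel_tol = 30, dist_max = 10), 0)
})

test_that("pairwise weights reflect intertwining and vanish at distance", {
  near <- list(
    list(points = cbind(0, 0, seq(0, 40, by = 2))),
    list(points = cbind(6, 0, seq(0, 40, by = 2))),
    list(points = cbind(100, 0, seq(0, 40, by = 2))))
  pr <- build_av_problem(near, c(0.9, 0, 0), neighbor_radius = 10)
  expect_gt(pr$W[1, 2], 0)
  expect_equal(pr$W[1, 3], 0)
  expect_equal(pr$W[2, 3], 0)
  expect_true(isSymmetric(pr$W))
})

test_that("a single unit with full bronchus affinity is labelled artery", {
  pr <- build_av_problem(list(list(points = matrix(0, 1, 3))), 1)
  sol <- solve_av(pr)
  expect_identical(sol$labels, "artery")
  expect_identical(sol$status, "optimal")
  # objective equals recomputed objective of the labeling
  expect_equal(sol$objective, av_objective(pr, sol$x))
})

test_that("two intertwined units with one-sided bronchus evidence split A/V", {
  units <- list(list(points = cbind(0, 0, seq(0, 40, by = 2))),
                list(points = cbind(6, 0, seq(0, 40, by = 2))))
  pr <- build_av_problem(units, c(0.9, 0), neighbor_radius = 10)
  sol <- solve_av(pr)
  expect_identical(sol$labels, c("artery", "vein"))
  # oracle: enumerate all 4 labelings
  best <- max(vapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                     function(x) av_objective(pr, x), numeric(1)))
  expect_equal(sol$objective, best)
})

test_that("branch-and-bound matches exhaustive enumeration exactly", {
  for (i in 1:40) {
    pr <- random_av_problem(n = sample(2:14, 1), seed = 1000 + i)
    a <- solve_av(pr)
    b <- enumerate_av(pr)
    expect_equal(a$objective, b$objective, tolerance = 1e-12)
    expect_identical(a$x, b$x)  # identical tie-break order
  }
})

test_that("with no bronchus evidence the objective is swap-symmetric and the solution deterministic", {
  pr <- random_av_problem(n = 8, seed = 77)
  pr$unary_artery <- rep(0.5, 8)  # affinity 0.5 everywhere: symmetric
  pr$unary_vein <- rep(0.5, 8)
  sol1 <- solve_av(pr)
  sol2 <- solve_av(pr)
  expect_identical(sol1$x, sol2$x)
  expect_equal(av_objective(pr, sol1$x), av_objective(pr, 1 - sol1$x))
})

test_that("oversized problems use the greedy fallback and report it", {
  pr <- random_av_problem(n = 12, seed = 5)
  sol <- solve_av(pr, exact_max_units = 8)
  expect_identical(sol$status, "fallback")
  # fallback is still a local optimum matching its recomputed objective
  expect_equal(sol$objective, av_objective(pr, sol$x))
})

test_that("label accuracy is length-weighted with optional global swap", {
  mk <- function(labels, lens) {
    segs <- lapply(seq_along(labels), function(i)
      vessel_segment(cbind(0, i * 20, c(0, lens[i])), c(2, 2),
                     label = labels[i], id = i))
    vessel_graph(segs)
  }
  truth <- mk(c("artery", "artery", "vein", "vein"), c(10, 10, 10, 10))
  expect_equal(label_accuracy(truth, truth), 1.0)
  flipped <- mk(c("vein", "vein", "artery", "artery"), c(10, 10, 10, 10))
  expect_equal(label_accuracy(flipped, truth), 0.0)
  expect_equal(label_accuracy(flipped, truth, allow_swap = TRUE), 1.0)
  part <- mk(c("artery", "artery", "vein", "artery"), c(10, 10, 10, 10))
  expect_equal(label_accuracy(part, truth), 0.75)
  # length weighting: one long wrong segment dominates
  truth_w <- mk(c("artery", "vein"), c(30, 10))
  pred_w <- mk(c("vein", "vein"), c(30, 10))
  expect_equal(label_accuracy(pred_w, truth_w), 0.25)
  # id mismatch -> error
  truth3 <- mk(c("artery", "vein", "vein"), c(10, 10, 10))
  expect_error(label_accuracy(part, truth3), "mismatch")
})
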