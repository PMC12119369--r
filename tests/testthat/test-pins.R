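test_that("lateral outlier trim drops far points and keeps tight clusters", {
  set.seed(1)
  cluster <- cbind(stats::rnorm(50, 0, 10), stats::rnorm(50, 0, 10),
                   seq(0, 1000, length.out = 50))
  # outlier at ~10 sigma laterally
  out <- rbind(cluster, c(1500, 0, 500))
  kept <- trim_lateral_outliers(out, f_lat = 2)
  expect_equal(nrow(kept), 50)
  expect_false(51 %in% attr(kept, "kept"))
  # huge f_lat keeps everything
  expect_equal(nrow(trim_lateral_outliers(out, f_lat = 100)), 51)
  # perfectly collinear points have zero lateral spread and are retained
  line <- cbind(0, 0, 1:10)
  expect_equal(nrow(trim_lateral_outliers(line, f_lat = 2)), 10)
})

test_that("endpoints of a straight vertical cloud land on the surfaces", {
  surfaces <- list(top = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                   bottom = list(point = c(0, 0, 1), normal = c(0, 0, 1)))
  set.seed(2)
  pts <- cbind(stats::rnorm(1000, 0, 0.01), stats::rnorm(1000, 0, 0.01),
               stats::runif(1000))
  ep <- estimate_endpoints(pts, surfaces, pin_params("medulla"))
  expect_equal(ep$r_top[3], 0, tolerance = 1e-12)
  expect_equal(ep$r_bottom[3], 1, tolerance = 1e-12)
  expect_equal(ep$r_top[1:2], c(0, 0), tolerance = 0.01, ignore_attr = TRUE)
  # fewer points than N_PC in the top fraction falls back to N_PC smallest t
  few <- pts[1:100, ]
  ep2 <- estimate_endpoints(few, surfaces, pin_params("medulla"))
  expect_equal(ep2$r_top[3], 0, tolerance = 1e-12)
  # a PC1 parallel to the surface cannot intersect it
  flat <- cbind(seq(0, 1, length.out = 100), stats::rnorm(100, 0, 1e-4),
                rep(0.5, 100))
  expect_error(
    estimate_endpoints(flat, surfaces, pin_params("medulla"),
                       axis = list(origin = c(0.5, 0, 0.5),
                                   direction = c(1, 0, 0))),
    class = "no_intersection")
})

test_that("curved synthetic columns yield endpoints near the planted axis ends", {
  grid <- generate_grid(1, spacing = 8000, curvature = 0.05)
  specs <- lapply(default_type_specs(nrow(grid))[1:3], function(sp) {
    sp$partner_rules <- sp$partner_rules[0, ]
    sp
  })
  vol <- generate_neurons(specs, grid, seed = 77)
  syn <- vol$synapses[vol$synapses$true_p == 0 & vol$synapses$true_q == 0, ]
  ax <- attr(grid, "axes")[[hex_key_chr(0, 0)]]
  ep <- estimate_endpoints(as.matrix(syn[, c("x", "y", "z")]),
                           attr(grid, "surfaces"), pin_params("medulla"))
  expect_lt(sqrt(sum((ep$r_top - ax[1, ])^2)), 8000 / 4)
  expect_lt(sqrt(sum((ep$r_bottom - ax[nrow(ax), ])^2)), 8000 / 4)
})

test_that("running-mean smoothing preserves endpoints and averages noise", {
  const <- matrix(rep(c(1, 2, 3), each = 10), ncol = 3)
  sm <- smooth_ordered_points(const, c(1, 2, 3), c(1, 2, 3), N_avg = 4)
  expect_true(all(abs(sweep(sm, 2, c(1, 2, 3))) < 1e-12))
  set.seed(3)
  n <- 500
  noisy <- cbind(stats::rnorm(n, 0, 1), stats::rnorm(n, 0, 1),
                 seq(0.01, 0.99, length.out = n))
  sm2 <- smooth_ordered_points(noisy, c(0, 0, 0), c(0, 0, 1), N_avg = 100)
  interior <- sm2[50:(nrow(sm2) - 50), 1:2]
  expect_lt(max(abs(interior)), 4 / sqrt(100))  # noise / sqrt(window)
  expect_equal(sm2[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(sm2[nrow(sm2), ], c(0, 0, 1), ignore_attr = TRUE)
})

test_that("shortest bounded sublist is forced on equally spaced points", {
  # 99 unit-spaced points: d_max = span / N_tang = 14 is a whole number of
  # steps, so the minimum N_tang + 1 = 8 points is achievable exactly
  l <- cbind(0, 0, 0:98)
  d_max <- 98 / 7
  o <- shortest_bounded_sublist(l, d_max)
  expect_equal(nrow(o), 8)  # N_tang + 1
  expect_equal(o[1, ], l[1, ], ignore_attr = TRUE)
  expect_equal(o[8, ], l[99, ], ignore_attr = TRUE)
  expect_true(all(sqrt(rowSums(diff(o)^2)) <= d_max + 1e-9))
  expect_error(
    shortest_bounded_sublist(rbind(c(0, 0, 0), c(0, 0, 10)), d_max = 1),
    class = "infeasible_pin")
})

test_that("shortest bounded sublist matches independent oracles on random instances", {
  set.seed(42)
  n_checked <- 0
  for (rep in 1:60) {
    n <- sample(5:20, 1)
    l <- cbind(cumsum(stats::runif(n)), stats::rnorm(n, 0, 0.3),
               stats::rnorm(n, 0, 0.3))
    d_max <- stats::runif(1, 0.5, 2.5)
    oracle_len <- oracle_shortest_sublist_len(l, d_max)
    mine <- tryCatch(shortest_bounded_sublist(l, d_max),
                     hexpin_error = function(e) NULL)
    if (is.na(oracle_len)) {
      expect_null(mine)
    } else {
      expect_equal(nrow(mine), oracle_len)
      expect_true(all(sqrt(rowSums(diff(mine)^2)) <= d_max + 1e-9))
      n_checked <- n_checked + 1
    }
    # small instances also checked against full enumeration
    if (n <= 10 && !is.na(oracle_len)) {
      expect_equal(nrow(mine), oracle_enumerate_sublist_len(l, d_max))
    }
  }
  expect_gt(n_checked, 20)
})

test_that("PCHIP resampling is uniform on lines and does not overshoot", {
  line <- cbind(seq(0, 10, length.out = 5), seq(0, 20, length.out = 5),
                seq(0, 30, length.out = 5))
  rs <- resample_pin(line, 121)
  expect_equal(nrow(rs), 121)
  gaps <- sqrt(rowSums(diff(rs)^2))
  expect_lt(diff(range(gaps)) / mean(gaps), 1e-9)
  expect_equal(rs[1, ], line[1, ], ignore_attr = TRUE)
  expect_equal(rs[121, ], line[5, ], ignore_attr = TRUE)
  # monotone helix: per-coordinate output stays within the data range
  t <- seq(0, 4 * pi, length.out = 30)
  helix <- cbind(cos(t), sin(t), t)
  rh <- resample_pin(helix, 200)
  for (j in 1:3) {
    expect_gte(min(rh[, j]), min(helix[, j]) - 1e-9)
    expect_lte(max(rh[, j]), max(helix[, j]) + 1e-9)
  }
})

test_that("built pins have the preset point counts and follow planted axes", {
  pins <- fixture_pins()
  vol <- fixture_volume()
  expect_true(all(vapply(pins, function(x) nrow(x$points), integer(1)) == 121))
  # pin stays close to the planted (curved) axis
  for (k in c("0,0", "1,-1", "-1,0")) {
    ax <- attr(vol$grid, "axes")[[k]]
    d <- hexpin:::nearest_ref_index(pins[[k]]$points, ax)$distance
    expect_lt(max(d), 8000 / 4)
  }
  # deterministic rebuild
  coords <- fixture_coords()
  ids <- vol$neurons$neuron_id[vol$neurons$type %in% columnar_type_names(vol)]
  syn <- merge(vol$synapses[vol$synapses$neuron_id %in% ids, ],
               coords[, c("neuron_id", "p", "q")], by = "neuron_id")
  chunk <- syn[syn$p == 0 & syn$q == 0, ]
  p1 <- build_pin(as.matrix(chunk[, c("x", "y", "z")]), c(0, 0),
                  attr(vol$grid, "surfaces"), pin_params("medulla"))
  p2 <- build_pin(as.matrix(chunk[, c("x", "y", "z")]), c(0, 0),
                  attr(vol$grid, "surfaces"), pin_params("medulla"))
  expect_identical(p1$points, p2$points)
})

test_that("thin-neuropil criteria reject undersized or truncated clouds", {
  grid <- generate_grid(1, spacing = 8000, depth = 30000)
  surf <- attr(grid, "surfaces")
  params <- pin_params("lobula")  # N_avg = 37
  few <- straight_column_cloud(n = 60, depth = 30000, seed = 5)$points[1:10, ]
  res <- build_pin(few, c(0, 0), surf, params)
  expect_s3_class(res, "pin_rejection")
  expect_equal(res$reason, "criterion-i")
  # a cloud far from the bottom surface fails the endpoint-proximity criterion
  cl <- straight_column_cloud(n = 400, depth = 30000, seed = 6)
  shallow <- cl$points[cl$points[, 3] < 12000, ]
  res2 <- build_pin(shallow, c(0, 0), surf, params)
  expect_s3_class(res2, "pin_rejection")
  expect_match(res2$reason, "criterion")
})

test_that("pin depth order is monotone along the planted axis", {
  pins <- fixture_pins()
  for (pin in pins[c("0,0", "1,0", "-1,1")]) {
    z <- pin$points[, 3]
    expect_true(all(diff(z) > -200))  # monotone up to small numerical ripple
    expect_gt(stats::cor(z, seq_along(z)), 0.999)
  }
})

test_that("regularization is a fixed point for translated pins and fills deletions", {
  grid <- generate_grid(2, spacing = 8000)
  axes <- attr(grid, "axes")
  pins <- structure(
    lapply(seq_len(nrow(grid)), function(i) {
      hexpin:::new_pin(grid$p[i], grid$q[i], axes[[i]])
    }),
    names = hex_key_chr(grid$p, grid$q), class = "pin_set")
  reg <- regularize_and_fill(pins, grid, max_iter = 5)
  expect_equal(attr(reg, "iterations"), 1)  # nothing to fill, stop at once
  for (k in names(pins)) {
    expect_equal(reg[[k]]$points, pins[[k]]$points, tolerance = 1e-9)
  }
  # delete the centre pin: the median of its four axial neighbours restores it
  dropped <- pins[names(pins) != "0,0"]
  filled <- regularize_and_fill(structure(dropped, class = "pin_set"), grid)
  expect_true("0,0" %in% names(filled))
  expect_equal(filled[["0,0"]]$provenance, "filled")
  d <- sqrt(rowSums((filled[["0,0"]]$points - pins[["0,0"]]$points)^2))
  expect_lt(max(d), 8000 / 10)
})

test_that("point assignment partitions synapses with correct depth endpoints", {
  pins <- fixture_pins()
  vol <- fixture_volume()
  # pin point index 0 has depth 0, last index depth 1
  pt0 <- pins[["0,0"]]$points[1, , drop = FALSE]
  ptN <- pins[["0,0"]]$points[121, , drop = FALSE]
  expect_equal(assign_points_to_pins(pt0, pins)$depth, 0)
  expect_equal(assign_points_to_pins(ptN, pins)$depth, 1)
  asg <- fixture_depth_assignments()
  expect_equal(nrow(asg), nrow(vol$synapses))    # total and single-valued
  expect_true(all(!is.na(asg$depth)))
  expect_lt(mean(abs(asg$depth - vol$synapses$true_depth)), 0.05)
})
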