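test_that("cumulative fraction curves follow rank arithmetic", {
  one <- cumulative_fraction_curve(list(c(a = 50)))
  expect_equal(one$median, 1)
  mix <- cumulative_fraction_curve(list(c(a = 60, b = 30, c = 10)))
  expect_equal(mix$median, c(0.6, 0.9, 1.0))
  # median of identical neurons equals any one curve
  same <- cumulative_fraction_curve(rep(list(c(a = 60, b = 30, c = 10)), 5))
  expect_equal(same$median, c(0.6, 0.9, 1.0))
  # shorter curves are padded with 1 beyond their last rank
  pad <- cumulative_fraction_curve(list(c(a = 1), c(a = 5, b = 5)))
  expect_equal(length(pad$median), 2)
  expect_equal(pad$median[2], 1)
  expect_warning(cumulative_fraction_curve(list(c(a = 1), c(b = 0))), "zero")
})

test_that("knee detection finds columnar knees and falls back on flat curves", {
  # columnar type: steep first rank
  curve <- c(0.95, 0.99, rep(1, 8))
  r <- knee_rank(curve)
  expect_equal(as.integer(r), 1L)
  expect_equal(attr(r, "method"), "knee")
  # linear rise to 1 at rank 10: no knee above 0.775 -> first rank >= 0.995
  lin <- seq(0.1, 1, by = 0.1)
  rl <- knee_rank(lin)
  expect_equal(as.integer(rl), 10L)
  expect_equal(attr(rl, "method"), "fallback")
  # single-column curve
  expect_equal(as.integer(knee_rank(1)), 1L)
  # knee below the 0.775 mass floor falls back to the 0.995 rank
  low <- c(0.5, 0.52, 0.54, 0.56, 0.6, 0.8, 0.97, 0.995, 1, 1)
  rlow <- knee_rank(low)
  expect_equal(attr(rlow, "method"), "fallback")
  expect_equal(as.integer(rlow), 8L)
  # curve that never reaches 0.995 ends at its maximum
  part <- c(0.3, 0.6, 0.9, 0.99)
  expect_equal(as.integer(knee_rank(part)), 4L)
})

test_that("trimming keeps tied columns and respects rank bounds", {
  counts <- c(home = 95, s1 = 3, s2 = 2)
  expect_equal(names(trim_neuron(counts, 1)), "home")
  tied <- c(a = 10, b = 10, c = 1)
  expect_equal(sort(names(trim_neuron(tied, 1))), c("a", "b"))
  # rank* at (or beyond) the occupied count discards nothing
  expect_equal(trim_neuron(counts, 3), counts)
  expect_equal(trim_neuron(counts, 10), counts)
})

test_that("coverage summaries recover planted tiling and overlap factors", {
  vol <- fixture_volume()
  asg <- merge(fixture_depth_assignments(),
               vol$neurons[, c("neuron_id", "type")], by = "neuron_id")
  cov <- do.call(rbind, lapply(split(asg, asg$type), function(d) {
    coverage_summary(d, vol$grid, type = d$type[1])
  }))
  # columnar mosaics: cell size 1, coverage factor ~1, full completeness
  for (ty in c("McA", "McB", "McC")) {
    expect_equal(cov[ty, "cell_size"], 1)
    expect_equal(cov[ty, "coverage_factor"], 1, tolerance = 0.1)
    expect_equal(cov[ty, "completeness"], 1)
  }
  # five-column planted type: coverage factor ~5
  expect_equal(cov["DmX", "coverage_factor"], 5, tolerance = 0.1 * 5)
  # one cell with all synapses in one column of the 19-column lattice
  single <- data.frame(neuron_id = 1, p = 0, q = 0)[rep(1, 40), ]
  s <- coverage_summary(single, vol$grid, type = "solo")
  expect_equal(s$cell_size, 1)
  expect_equal(s$coverage_factor, 1)
  expect_equal(s$completeness, 1 / 19, tolerance = 1e-9)
})

test_that("the double-counting identity holds exactly after trimming", {
  vol <- fixture_volume()
  asg <- merge(fixture_depth_assignments(),
               vol$neurons[, c("neuron_id", "type")], by = "neuron_id")
  for (ty in c("DmX", "WfY")) {
    d <- asg[asg$type == ty, ]
    key <- hex_key_chr(d$p, d$q)
    per_neuron <- lapply(split(key, d$neuron_id), function(k) c(table(k)))
    rs <- knee_rank(cumulative_fraction_curve(per_neuron)$median)
    trimmed <- lapply(per_neuron, trim_neuron, rank_star = rs)
    occupied <- unlist(lapply(trimmed, names), use.names = FALSE)
    mean_cells <- length(occupied) / length(unique(occupied))
    expect_equal(mean_cells * length(unique(occupied)),
                 sum(vapply(trimmed, length, integer(1))))
  }
})

test_that("hull area is reported in column units with the count fallback", {
  # the 7-column single-ring patch has hull corners at the 6 ring centres
  asg <- data.frame(neuron_id = 1,
                    p = c(0, 1, 0, -1, 0, 1, -1), q = c(0, 0, 1, 1, -1, -1, 0))
  s <- coverage_summary(asg, generate_grid(1), type = "ring")
  # hexagon of circumradius 1 has area 3*sqrt(3)/2 -> 3 column units
  expect_equal(s$column_area, 3, tolerance = 1e-9)
  s2 <- coverage_summary(asg, generate_grid(1), type = "ring",
                         area_by_count = TRUE)
  expect_equal(s2$column_area, 7)
  # collinear occupancy degenerates to the count
  line <- data.frame(neuron_id = 1, p = 0:3, q = 0)
  expect_equal(coverage_summary(line, generate_grid(3), type = "l")$column_area, 4)
})
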