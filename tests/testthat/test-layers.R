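test_that("depth histograms conserve counts and localize peaks", {
  asg <- data.frame(station = c(rep(60L, 5), rep(10L, 3)))
  d <- depth_distribution(asg, n_samp = 121)
  expect_equal(sum(d$bins), 8)
  expect_equal(which(d$bins == 5) - 1L, 60L)
  # subsampling merges adjacent station pairs: 121 -> 61 bins
  ds <- depth_distribution(asg, n_samp = 121, subsample = TRUE)
  expect_length(ds$bins, 61)
  expect_equal(sum(ds$bins), 8)
  empty <- depth_distribution(data.frame(station = integer()), n_samp = 121)
  expect_true(empty$empty)
})

test_that("planted bimodal profiles give empirical modes at planted depths", {
  vol <- fixture_volume()
  asg <- fixture_depth_assignments()
  wf <- vol$neurons$neuron_id[vol$neurons$type == "WfY"]
  pre <- asg[asg$neuron_id %in% wf & asg$prepost == "pre", ]
  d <- depth_distribution(pre, n_samp = 121, subsample = TRUE)
  pk <- find_peak_cutoffs(d, frac_peaks = 0.8)
  expect_equal(nrow(pk), 2)
  # planted WfY presynapse modes at depths 0.35 and 0.9
  expect_lt(abs(mean(c(pk$lower[1], pk$upper[1])) - 0.35), 0.1)
  expect_lt(abs(mean(c(pk$lower[2], pk$upper[2])) - 0.9), 0.1)
})

test_that("peak cut-offs follow the threshold scan rules", {
  counts <- numeric(50)
  counts[10:20] <- 7          # single rectangular peak
  pk <- find_peak_cutoffs(counts, frac_peaks = 0.9)
  expect_equal(c(pk$lower_idx, pk$upper_idx), c(10, 20))
  # two peaks separated by fewer than 3 stations merge
  counts2 <- numeric(50)
  counts2[c(10:14, 16:20)] <- 5
  pk2 <- find_peak_cutoffs(counts2, frac_peaks = 0.9)
  expect_equal(nrow(pk2), 1)
  expect_equal(c(pk2$lower_idx, pk2$upper_idx), c(10, 20))
  # well-separated peaks stay distinct
  counts3 <- numeric(50)
  counts3[c(10:15, 30:35)] <- 5
  expect_equal(nrow(find_peak_cutoffs(counts3, frac_peaks = 0.9)), 2)
  # a uniform distribution sitting entirely below the threshold has no peaks
  expect_equal(nrow(find_peak_cutoffs(rep(4, 50), frac_peaks = 0.5,
                                      syn_thre = 5)), 0)
  # invariant to uniform count rescaling
  pk_scaled <- find_peak_cutoffs(counts * 10, frac_peaks = 0.9)
  expect_equal(pk, pk_scaled)
  expect_error(find_peak_cutoffs(counts, frac_peaks = 1.2),
               class = "invalid_parameter")
})

test_that("layer schemes are built from marker cut-offs and partition depth", {
  mk_dist <- function(lo, hi) {
    counts <- numeric(61)
    counts[lo:hi] <- 10
    structure(list(bins = counts, depth = (0:60) / 60, n_samp = 61,
                   subsampled = FALSE, cell_type = "m", polarity = "pre",
                   empty = FALSE), class = "depth_distribution")
  }
  dists <- list(m1.pre = mk_dist(5, 15), m2.pre = mk_dist(30, 40))
  specs <- data.frame(cell_type = c("m1", "m2"), polarity = "pre",
                      peak = 1L, side = "upper")
  sch <- build_layer_scheme(specs, dists, layer_names = c("L1", "L2", "L3"),
                            frac_peaks = 0.8)
  expect_equal(sch$boundaries, c(14 / 60, 39 / 60))
  # one marker, one boundary -> two layers partitioning [0,1]
  sch1 <- build_layer_scheme(specs[1, ], dists, frac_peaks = 0.8)
  expect_length(sch1$layers, 2)
  expect_error(
    build_layer_scheme(data.frame(cell_type = "m1", polarity = "pre",
                                  peak = 3L, side = "upper"),
                       dists, frac_peaks = 0.8),
    class = "marker_resolution")
  # shifting a marker peak deeper never moves its boundary shallower
  sch_deep <- build_layer_scheme(specs, list(m1.pre = mk_dist(8, 18),
                                             m2.pre = mk_dist(30, 40)),
                                 layer_names = c("L1", "L2", "L3"),
                                 frac_peaks = 0.8)
  expect_gte(sch_deep$boundaries[1], sch$boundaries[1])
})

test_that("lobula-plate mode averages marker threshold pairs", {
  mk <- function(idx) {
    counts <- numeric(51)
    counts[idx] <- 10
    structure(list(bins = counts, depth = (0:50) / 50, n_samp = 51,
                   subsampled = FALSE, cell_type = "t", polarity = "pre",
                   empty = FALSE), class = "depth_distribution")
  }
  # upper cut-offs at stations 11 and 16 -> depths 0.2 and 0.3 -> mean 0.25
  dists <- list(T4a.pre = mk(5:11), T4b.pre = mk(12:16))
  specs <- data.frame(cell_type = c("T4a", "T4b"), polarity = "pre",
                      peak = 1L, side = "upper")
  sch <- build_layer_scheme(specs, dists, frac_peaks = 0.75,
                            lobula_plate_mode = TRUE)
  expect_equal(sch$boundaries, 0.25)
})

test_that("layer lookup is total, half-open and endpoint-correct", {
  sch <- structure(list(neuropil = "ME", boundaries = c(0.3, 0.7),
                        layers = c("M1", "M2", "M3")), class = "layer_scheme")
  expect_equal(assign_layer(0, sch), "M1")
  expect_equal(assign_layer(0.3, sch), "M2")  # boundary goes to deeper layer
  expect_equal(assign_layer(1, sch), "M3")
  expect_error(assign_layer(1.2, sch), class = "invalid_depth")
  # total and single-valued over a depth sweep
  sweep_d <- seq(0, 1, by = 0.01)
  lays <- assign_layer(sweep_d, sch)
  expect_true(all(lays %in% sch$layers))
  expect_length(lays, length(sweep_d))
})

test_that("synapses of a planted single-layer type land in their layer", {
  vol <- fixture_volume()
  asg <- fixture_depth_assignments()
  sch <- structure(list(neuropil = "ME", boundaries = c(0.35, 0.6),
                        layers = c("shallow", "mid", "deep")),
                   class = "layer_scheme")
  # McB presynapses are planted at depths 0.45-0.55, inside "mid"
  mcb <- vol$neurons$neuron_id[vol$neurons$type == "McB"]
  pre <- asg[asg$neuron_id %in% mcb & asg$prepost == "pre", ]
  expect_gte(mean(assign_layer(pre$depth, sch) == "mid"), 0.9)
})
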