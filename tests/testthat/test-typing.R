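test_that("connectivity features sum weights by partner type and direction", {
  labels <- data.frame(neuron_id = 1:4, type = c("N", "X", "X", "Y"))
  conn <- data.frame(pre_id = c(2, 3, 1, 1), post_id = c(1, 1, 4, 4),
                     weight = c(2, 1, 1, 1), roi = "ME")
  f <- build_conn_features(1, conn, labels)
  expect_equal(f["1", "X:in"], 3)
  expect_equal(f["1", "Y:out"], 2)
  expect_equal(sum(f), 5)
})

test_that("unclear partners are excluded and fragments fold into their type", {
  labels <- data.frame(neuron_id = 1:4,
                       type = c("N", "R7_unclear", "X", "X"),
                       instance = c("N_R", "R7_unclear_R", "X_fragment_R", "X_R"))
  conn <- data.frame(pre_id = c(2, 3, 4), post_id = c(1, 1, 1),
                     weight = c(5, 2, 3), roi = "ME")
  f <- build_conn_features(1, conn, labels)
  expect_false(any(grepl("unclear", colnames(f))))
  expect_equal(f["1", "X:in"], 5)  # fragment weight folded into X
  # region restriction drops out-of-scope connections
  conn2 <- rbind(conn, data.frame(pre_id = 4, post_id = 1, weight = 10,
                                  roi = "CB"))
  f2 <- build_conn_features(1, conn2, labels, in_regions = "ME")
  expect_equal(f2["1", "X:in"], 5)
})

test_that("clustering separates planted types and handles edge cases", {
  x <- rbind(matrix(rep(c(10, 0, 0, 1), each = 8), nrow = 8),
             matrix(rep(c(0, 10, 2, 0), each = 8), nrow = 8))
  cl <- cluster_features(x, "cosine", 2)
  expect_equal(length(unique(cl[1:8])), 1)
  expect_equal(length(unique(cl[9:16])), 1)
  expect_false(cl[1] == cl[9])
  # duplicated rows co-cluster
  dup <- x[c(1, 1, 9, 9), ]
  cld <- cluster_features(dup, "cosine", 2)
  expect_equal(unname(cld[1]), unname(cld[2]))
  expect_equal(unname(cld[3]), unname(cld[4]))
  # n_clusters = n gives singletons
  cls <- cluster_features(x + stats::rnorm(64, 0, 0.01), "euclidean", 16)
  expect_equal(sort(unique(cls)), 1:16)
  # zero rows are excluded under cosine with a warning
  expect_warning(clz <- cluster_features(rbind(x, 0), "cosine", 2),
                 "zero")
  expect_true(is.na(clz[17]))
})

test_that("cosine and L2-normalized Euclidean clustering agree on fixtures", {
  vol <- fixture_volume()
  f <- build_conn_features(vol$neurons$neuron_id, vol$connections,
                           vol$neurons[, c("neuron_id", "type")])
  f <- f[rowSums(f) > 0, ]
  k <- length(unique(vol$neurons$type))
  c1 <- cluster_features(f, "cosine", k)
  c2 <- cluster_features(f, "l2_euclidean", k)
  # identical partitions up to label permutation
  expect_equal(completeness_score(c1, c2), 1)
  expect_equal(homogeneity_score(c1, c2), 1)
})

test_that("morphology vectors have length 244 with the planted normalization", {
  pins <- fixture_pins()
  vol <- fixture_volume()
  syn <- vol$synapses[vol$synapses$neuron_id == vol$neurons$neuron_id[1], ]
  f <- build_morph_features(syn, pins)
  expect_length(f, 244)
  # block 1 sums to the presynaptic innervated-column count (= block 3 sum)
  b1 <- f[1:61]; b3 <- f[123:183]
  expect_equal(sum(b1), sum(b3))
  # scaling synapse counts leaves the normalized blocks unchanged
  f2 <- build_morph_features(syn[rep(seq_len(nrow(syn)), 3), ], pins)
  expect_equal(f2[1:61], f[1:61], tolerance = 1e-12)
  expect_equal(f2[123:183], f[123:183])
})

test_that("a single-depth single-column neuron gives unit feature entries", {
  pins <- fixture_pins()
  pt <- fixture_pins()[["0,0"]]$points[31, ]  # station 30 -> bin 16
  syn <- data.frame(x = pt[1], y = pt[2], z = pt[3], prepost = "pre",
                    confidence = 0.95)
  f <- build_morph_features(syn, pins)
  expect_equal(sum(f[1:61] != 0), 1)
  expect_equal(sum(f[1:61]), 1)       # N_pre,size = 1
  expect_equal(sum(f[123:183]), 1)    # one column at one depth bin
  expect_equal(which(f[123:183] != 0), 16)
  # below-confidence synapses are ignored
  syn$confidence <- 0.5
  expect_true(attr(build_morph_features(syn, pins), "empty"))
})

test_that("morphology clustering separates planted depth-profile types", {
  vol <- fixture_volume()
  pins <- fixture_pins()
  ids <- vol$neurons$neuron_id[vol$neurons$type %in% c("McA", "McB", "McC")]
  feats <- t(vapply(ids, function(id) {
    build_morph_features(vol$synapses[vol$synapses$neuron_id == id, ], pins)
  }, numeric(244)))
  cl <- cluster_features(feats, "euclidean", 3)
  truth <- vol$neurons$type[match(ids, vol$neurons$neuron_id)]
  expect_gte(completeness_score(truth, cl), 0.9)
  expect_gte(homogeneity_score(truth, cl), 0.9)
})

test_that("confusion categories follow the 80/10 rules", {
  # identical labelings: everything red, perfect scores
  t1 <- rep(c("a", "b"), each = 10)
  s <- confusion_summary(t1, t1)
  expect_true(all(s$category[s$matrix > 0] == "red"))
  expect_equal(s$completeness, 1)
  expect_equal(s$homogeneity, 1)
  # one type split into two pure clusters: green, completeness < 1
  s2 <- confusion_summary(rep("a", 10), rep(c(1, 2), each = 5))
  expect_true(all(s2$category[s2$matrix > 0] == "green"))
  expect_lt(s2$completeness, 1)
  expect_equal(s2$homogeneity, 1)
  # two types merged in one cluster: blue, homogeneity < 1
  s3 <- confusion_summary(rep(c("a", "b"), each = 5), rep(1, 10))
  expect_true(all(s3$category[s3$matrix > 0] == "blue"))
  expect_equal(s3$completeness, 1)
  expect_lt(s3$homogeneity, 1)
  # categories are exhaustive and exclusive on a messy labeling
  set.seed(8)
  tt <- sample(letters[1:4], 100, replace = TRUE)
  cc <- sample(1:5, 100, replace = TRUE)
  s4 <- confusion_summary(tt, cc)
  expect_true(all(s4$category[s4$matrix > 0] %in%
                    c("red", "blue", "green", "yellow", "grey")))
  expect_true(all(s4$category[s4$matrix == 0] == ""))
  # row sums equal type sizes
  expect_equal(as.vector(rowSums(s4$matrix)), as.vector(table(tt)))
})

test_that("fingerprint uniqueness counts distinct ranked top-n sets", {
  tc <- data.frame(
    type = rep(c("A", "B", "C"), each = 2),
    partner = c("X", "Y", "X", "Z", "W", "V"),
    direction = "out",
    weight = c(10, 5, 10, 5, 9, 4))
  expect_equal(top_n_fingerprint_uniqueness(tc, 2), 1.0)
  # two identical types are both non-unique
  tc2 <- data.frame(type = rep(c("A", "B", "C"), each = 1),
                    partner = c("X", "X", "Y"), direction = "out",
                    weight = c(5, 5, 5))
  expect_equal(top_n_fingerprint_uniqueness(tc2, 1), 1 / 3)
  # monotone non-decreasing in n on random tables
  set.seed(10)
  for (rep in 1:5) {
    rt <- data.frame(type = rep(letters[1:6], each = 4),
                     partner = sample(LETTERS[1:5], 24, replace = TRUE),
                     direction = sample(c("in", "out"), 24, replace = TRUE),
                     weight = sample(1:50, 24, replace = TRUE))
    props <- vapply(1:4, function(n) top_n_fingerprint_uniqueness(rt, n),
                    numeric(1))
    expect_true(all(diff(props) >= 0))
  }
})

test_that("mosaic projection preserves the lattice geometry", {
  vol <- fixture_volume()
  mca <- vol$neurons[vol$neurons$type == "McA", ]
  syn <- vol$synapses[vol$synapses$neuron_id %in% mca$neuron_id, ]
  # reference PCA on a preselected depth band of synapses, so the first two
  # axes span the retinotopic sheet rather than the depth axis of the slab
  ref <- syn[syn$z < 10000, ]
  proj <- mosaic_projection(syn, reference = ref)
  m <- merge(proj, mca, by = "neuron_id")
  truth_xy <- hexpin:::axial_to_cart(m$true_p, m$true_q, 8000)
  d2_true <- as.vector(stats::dist(truth_xy))
  d2_proj <- as.vector(stats::dist(m[, c("pc1", "pc2")]))
  expect_gt(stats::cor(d2_true, d2_proj, method = "spearman"), 0.9)
  # duplicating every synapse leaves the projection unchanged
  proj2 <- mosaic_projection(syn[rep(seq_len(nrow(syn)), 2), ], reference = ref)
  expect_equal(proj2$pc1, proj$pc1, tolerance = 1e-9)
})
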