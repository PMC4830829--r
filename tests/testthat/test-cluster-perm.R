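tf_layout <- function(nf, nt, n_pre_cols = floor(nt / 2)) {
  list(coords = data.frame(fi = rep(seq_len(nf), nt),
                           ti = rep(seq_len(nt), each = nf)),
       phase = rep(c("pre", "post"), c(nf * n_pre_cols, nf * (nt - n_pre_cols))),
       grid = list(type = "tf", dims = c(nf, nt)))
}

test_that("connected components follow the configured grid connectivity", {
  offs8 <- paindecode:::conn_offsets(8)
  # two diagonal pixels join under 8-connectivity
  labs <- paindecode:::label_components(cbind(c(1, 2), c(1, 2)), c(5, 5), offs8)
  expect_equal(labs, c(1L, 1L))
  # separated pixels stay apart
  labs2 <- paindecode:::label_components(cbind(c(1, 4), c(1, 4)), c(5, 5), offs8)
  expect_equal(labs2, c(1L, 2L))
  # 3-D: a face-diagonal pair is disconnected at 6 but connected at 26
  vox <- cbind(c(1, 2), c(1, 2), c(1, 1))
  expect_equal(paindecode:::label_components(vox, c(4, 4, 4),
                                             paindecode:::conn_offsets(6)),
               c(1L, 2L))
  expect_equal(paindecode:::label_components(vox, c(4, 4, 4),
                                             paindecode:::conn_offsets(26)),
               c(1L, 1L))
  # labels are deterministic scan order: first cluster holds the lowest index
  labs3 <- paindecode:::label_components(cbind(c(5, 1), c(5, 1)), c(6, 6), offs8)
  expect_equal(labs3, c(2L, 1L))
})

test_that("all-zero maps produce no supra-threshold features and no clusters", {
  ly <- tf_layout(6, 10)
  g <- cluster_permutation_test(matrix(0, 5, 60), ly$coords, ly$phase, ly$grid,
                                n_perm = 100, seed = 1)
  expect_length(g$clusters, 0)
  expect_length(extract_patterns(g), 0)
  expect_equal(length(g$excluded_features), 60)
})

test_that("a coherent planted block is found with a near-floor cluster p", {
  # 20 subjects share a +1 effect on a 3x3 block (plus noise so the t-test is
  # defined); with 999 sign-flip permutations the cluster p is bounded below
  # by 1/1000 and must not exceed 0.01
  set.seed(42)
  ly <- tf_layout(30, 50, 20)
  maps <- matrix(rnorm(20 * 1500, sd = 0.5), 20)
  block <- which(ly$coords$fi %in% 10:12 & ly$coords$ti %in% 10:12)
  maps[, block] <- maps[, block] + 1
  g <- cluster_permutation_test(maps, ly$coords, ly$phase, ly$grid,
                                n_perm = 999, seed = 7)
  pats <- extract_patterns(g)
  expect_gte(length(pats), 1)
  main <- pats[[which.max(vapply(pats, function(p) length(p$features), 0))]]
  expect_gte(jaccard(main$features, block), 0.8)
  expect_gte(main$cluster_p, 1 / 1000)
  expect_lte(main$cluster_p, 0.01)
  expect_equal(main$sign, 1L)
})

test_that("the permutation test is exactly reproducible for a fixed seed", {
  set.seed(1)
  ly <- tf_layout(10, 12)
  maps <- matrix(rnorm(8 * 120), 8)
  g1 <- cluster_permutation_test(maps, ly$coords, ly$phase, ly$grid,
                                 n_perm = 200, seed = 5)
  g2 <- cluster_permutation_test(maps, ly$coords, ly$phase, ly$grid,
                                 n_perm = 200, seed = 5)
  expect_identical(g1$null_max, g2$null_max)
  expect_identical(g1$tmap, g2$tmap)
  g3 <- cluster_permutation_test(maps, ly$coords, ly$phase, ly$grid,
                                 n_perm = 200, seed = 6)
  expect_false(identical(g1$null_max, g3$null_max))
})

test_that("cluster p-values decrease with observed cluster mass within a map", {
  set.seed(3)
  ly <- tf_layout(20, 30, 10)
  maps <- matrix(rnorm(12 * 600, sd = 0.6), 12)
  b1 <- which(ly$coords$fi %in% 2:3 & ly$coords$ti %in% 2:3)
  b2 <- which(ly$coords$fi %in% 10:14 & ly$coords$ti %in% 15:22)
  maps[, b1] <- maps[, b1] + 0.8
  maps[, b2] <- maps[, b2] + 0.8
  g <- cluster_permutation_test(maps, ly$coords, ly$phase, ly$grid,
                                n_perm = 300, seed = 2)
  cl <- g$clusters
  masses <- vapply(cl, `[[`, 0, "mass")
  ps <- vapply(cl, `[[`, 0, "p")
  ord <- order(masses)
  expect_true(all(diff(ps[ord]) <= 0))
})

test_that("zero-variance features are excluded from testing and clustering", {
  set.seed(4)
  ly <- tf_layout(5, 8)
  maps <- matrix(rnorm(6 * 40), 6)
  maps[, 7] <- 2                      # constant across subjects
  g <- cluster_permutation_test(maps, ly$coords, ly$phase, ly$grid,
                                n_perm = 100, seed = 1)
  expect_true(7 %in% g$excluded_features)
  expect_equal(g$tmap[7], 0)
  expect_false(any(vapply(g$clusters, function(cl) 7 %in% cl$features, TRUE)))
})

test_that("guard rails: few subjects, tiny permutation counts", {
  ly <- tf_layout(4, 4)
  maps <- matrix(rnorm(2 * 16), 2)
  expect_error(cluster_permutation_test(maps, ly$coords, ly$phase, ly$grid,
                                        n_perm = 100, seed = 1), "3 subjects")
  expect_warning(cluster_permutation_test(rbind(maps, rnorm(16), rnorm(16)),
                                          ly$coords, ly$phase, ly$grid,
                                          n_perm = 50, seed = 1), "coarse")
})

test_that("patterns inherit phase, sign and disjoint coordinates", {
  set.seed(6)
  ly <- tf_layout(24, 40, 16)           # pre: ti 1..16, post: 17..40
  maps <- matrix(rnorm(15 * 960, sd = 0.5), 15)
  # a positive post-stimulus cluster in a low-frequency band and a negative
  # pre-stimulus cluster, disjoint by construction
  post_block <- which(ly$coords$fi %in% 2:6 & ly$coords$ti %in% 20:28)
  pre_block <- which(ly$coords$fi %in% 15:18 & ly$coords$ti %in% 3:8)
  maps[, post_block] <- maps[, post_block] + 1
  maps[, pre_block] <- maps[, pre_block] - 1
  g <- cluster_permutation_test(maps, ly$coords, ly$phase, ly$grid,
                                n_perm = 300, seed = 9)
  pats <- extract_patterns(g, cluster_alpha = 0.05)
  expect_gte(length(pats), 2)
  phases <- vapply(pats, `[[`, "", "phase")
  signs <- vapply(pats, `[[`, 0L, "sign")
  expect_true(any(phases == "post" & signs == 1L))
  expect_true(any(phases == "pre" & signs == -1L))
  feats <- lapply(pats, `[[`, "features")
  for (i in seq_along(feats)) for (j in seq_len(i - 1L))
    expect_length(intersect(feats[[i]], feats[[j]]), 0)
  # every pattern's coordinates share one phase
  for (p in pats) expect_length(unique(g$phase[p$features]), 1)
})

test_that("group maps serialize to JSON with clusters and settings", {
  set.seed(5)
  ly <- tf_layout(6, 8)
  maps <- matrix(rnorm(5 * 48), 5)
  g <- cluster_permutation_test(maps, ly$coords, ly$phase, ly$grid,
                                n_perm = 120, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_group_map(g, extract_patterns(g), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_perm, 120)
  expect_equal(unname(unlist(back$grid$dims)), c(6, 8))
  expect_equal(back$tmap, g$tmap, tolerance = 1e-12)
})
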