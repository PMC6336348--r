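test_that("RIF counts are per-residue pose incidences", {
  universe <- c("A:1", "A:2", "A:3")
  sets <- list(c("A:1", "A:2"), c("A:3"), c("A:1"))
  prof <- compute_rif(sets, universe)
  expect_equal(as.integer(prof$counts), c(2L, 1L, 1L))
  expect_equal(prof$n_poses, 3L)
  expect_setequal(prof$sampled_residues, universe)
  # a residue present in every pose saturates at n_poses
  allsets <- replicate(200, c("A:1"), simplify = FALSE)
  expect_equal(unname(compute_rif(allsets, universe)$counts["A:1"]), 200L)
  expect_error(compute_rif(list(), universe), "empty")
  expect_error(compute_rif(list(c("B:9")), universe), "outside")
})

test_that("RIF counts equal the naive recount oracle on random ensembles", {
  set.seed(71)
  universe <- make_res_id("A", 1:30)
  for (rep in 1:5) {
    sets <- lapply(1:50, function(k)
      sample(universe, sample.int(10, 1)))
    prof <- compute_rif(sets, universe)
    expect_equal(prof$counts, oracle_rif_counts(sets, universe))
    # conservation: sum Ni = total (pose, residue) incidences
    expect_equal(sum(prof$counts), sum(lengths(sets)))
    # permutation invariance
    prof2 <- compute_rif(sets[sample.int(50)], universe)
    expect_equal(prof2$counts, prof$counts)
  }
})

test_that("top-k ranking orders by count with deterministic tie-breaks", {
  universe <- make_res_id("A", 1:5)
  prof <- compute_rif(list(rep("A:2", 1), c("A:2", "A:4"), c("A:2", "A:4"),
                           c("A:4", "A:1"), "A:2"), universe)
  # counts: A:1=1, A:2=4, A:4=3
  expect_equal(rank_top_k(prof, 2), c("A:2", "A:4"))
  tied <- compute_rif(list(c("A:1", "A:3")), universe)
  expect_equal(rank_top_k(tied, 1), "A:1")  # tie -> residue order
  # zero-count residues are never returned
  expect_equal(rank_top_k(tied, 10), c("A:1", "A:3"))
  # matches an independent sort-then-cut oracle at scale
  set.seed(72)
  big <- make_res_id("A", 1:100)
  sets <- lapply(1:300, function(k) sample(big, sample.int(12, 1)))
  prof2 <- compute_rif(sets, big)
  cnt <- oracle_rif_counts(sets, big)
  oracle_top <- names(sort(cnt[cnt > 0],
                           decreasing = TRUE, method = "radix"))
  # resolve oracle ties explicitly by universe position
  ord <- order(-cnt[cnt > 0], match(names(cnt[cnt > 0]), big))
  oracle_top <- names(cnt[cnt > 0])[ord][1:15]
  expect_equal(rank_top_k(prof2, 15), oracle_top)
})

test_that("patch-size filtering and the modal size follow the histogram", {
  sets <- list(make_res_id("A", 1:9), make_res_id("A", 1:8),
               make_res_id("A", 2:10), make_res_id("A", 1:12))
  kept <- filter_patch_size(sets, 9)
  expect_length(kept, 2L)
  expect_true(all(lengths(kept) == 9L))
  expect_error(filter_patch_size(sets, 1), "patch-size")
  expect_equal(patch_size_mode(sets), 9L)  # size 9 occurs twice
  expect_equal(patch_size_mode(list(1:8, 1:9)), 8L)  # tie -> smallest
  expect_equal(patch_size_mode(list(1:9, 1:9, 1:8)), 9L)
  expect_error(patch_size_mode(list()), "empty")
  # histogram oracle on an enriched synthetic ensemble
  toy <- make_toy_receptor(80, 10, seed = 73)
  ens <- sample_contact_ensemble(toy$structure, toy$annotation,
                                 synthetic_pose_model(n_poses = 500,
                                                      enrichment = 2),
                                 seed = 74)
  expect_equal(length(filter_patch_size(ens, 9)),
               sum(lengths(ens) == 9L))
  hist <- table(lengths(ens))
  expect_equal(patch_size_mode(ens),
               min(as.integer(names(hist)[hist == max(hist)])))
})

test_that("pooling and subsampling behave like uniform sampling without replacement", {
  probes <- lapply(1:13, function(i)
    lapply(1:10, function(k) make_res_id("A", i * k)))
  all130 <- pool_and_subsample(probes, n = 130, seed = 75)
  expect_length(all130, 130L)
  one <- pool_and_subsample(probes, n = 1, seed = 76)
  expect_length(one, 1L)
  expect_identical(one, pool_and_subsample(probes, n = 1, seed = 76))
  expect_error(pool_and_subsample(list(), n = 5), "no contact sets")
  # per-residue count expectations match pool proportions
  toy <- make_toy_receptor(60, 8, seed = 77)
  pool <- sample_contact_ensemble(toy$structure, toy$annotation,
                                  synthetic_pose_model(n_poses = 1000,
                                                       enrichment = 3),
                                  seed = 78)
  pool_prof <- compute_rif(pool, residue_ids(toy$structure))
  n_sub <- 200L
  sub_counts <- sapply(1:50, function(s) {
    sub <- pool_and_subsample(pool, n = n_sub, seed = 1000 + s)
    compute_rif(sub, residue_ids(toy$structure))$counts
  })
  expected <- pool_prof$counts * n_sub / 1000
  mc_se <- apply(sub_counts, 1, sd) / sqrt(50)
  dev <- abs(rowMeans(sub_counts) - expected)
  expect_true(all(dev <= 3 * pmax(mc_se, 0.5)))
})

test_that("subsampling the whole pool reproduces the pooled profile exactly", {
  toy <- make_toy_receptor(50, 8, seed = 79)
  pool <- sample_contact_ensemble(toy$structure, toy$annotation,
                                  synthetic_pose_model(n_poses = 300),
                                  seed = 80)
  sub <- pool_and_subsample(pool, n = 300, seed = 81)
  expect_equal(compute_rif(sub, residue_ids(toy$structure))$counts,
               compute_rif(pool, residue_ids(toy$structure))$counts)
})

test_that("consensus rankings saturate well below the full ensemble budget", {
  # 13 pooled probe ensembles: top-15 from 200 poses/probe vs 2000
  overlaps <- sapply(1:4, function(i) {
    toy <- make_toy_receptor(150, 15, seed = 400 + i)
    ids <- residue_ids(toy$structure)
    ens <- function(np, s0) do.call(c, lapply(1:13, function(j)
      sample_contact_ensemble(toy$structure, toy$annotation,
                              synthetic_pose_model(n_poses = np,
                                                   enrichment = 3),
                              seed = s0 + j)))
    big <- rank_top_k(compute_rif(ens(2000, 10000 * i), ids), 15)
    small <- rank_top_k(compute_rif(ens(200, 20000 * i), ids), 15)
    length(intersect(big, small))
  })
  expect_gte(mean(overlaps), 12)
})

test_that("RIF profiles round-trip through TSV", {
  toy <- make_toy_receptor(40, 6, seed = 82)
  ens <- sample_contact_ensemble(toy$structure, toy$annotation,
                                 synthetic_pose_model(n_poses = 100),
                                 seed = 83)
  prof <- compute_rif(ens, residue_ids(toy$structure),
                      receptor_id = toy$structure$id)
  f <- tempfile(fileext = ".tsv")
  write_rif_profile(prof, f, residue_table = toy$structure$residues)
  back <- read_rif_profile(f)
  expect_equal(back$counts, prof$counts)
  expect_equal(back$n_poses, prof$n_poses)
  expect_equal(back$sampled_residues, prof$sampled_residues)
  # contact sets round-trip too, including empty sets
  sets <- list(pose_1 = c("A:1", "A:2"), pose_2 = character(0),
               pose_3 = "A:5")
  f2 <- tempfile(fileext = ".tsv")
  write_contact_sets(sets, f2)
  expect_equal(read_contact_sets(f2), sets)
})
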