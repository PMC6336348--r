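test_that("toy receptors are lattice shells with contiguous interfaces", {
  toy <- make_toy_receptor(60, 9, seed = 111)
  expect_equal(n_residues(toy$structure), 60L)
  expect_length(toy$annotation$interface_residues, 9L)
  xyz <- atom_xyz(toy$structure)
  # nearest-neighbour lattice spacing is about 5 A
  d <- as.matrix(dist(xyz)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_true(all(nn > 2.5 & nn < 8))
  # the interface patch is geodesically contiguous: every interface
  # residue lies within 2 lattice spacings of another interface residue
  idx <- match(toy$annotation$interface_residues,
               residue_ids(toy$structure))
  din <- d[idx, idx]
  expect_true(all(apply(din, 1, min) <= 2 * median(nn)))
  # degenerate and invalid sizes
  full <- make_toy_receptor(10, 10, seed = 112)
  expect_setequal(full$annotation$interface_residues,
                  residue_ids(full$structure))
  expect_error(make_toy_receptor(10, 11), "interface_size")
  # pure function of the seed
  again <- make_toy_receptor(60, 9, seed = 111)
  expect_identical(atom_xyz(again$structure), xyz)
  expect_identical(again$annotation$interface_residues,
                   toy$annotation$interface_residues)
})

test_that("probe blobs are compact clouds that grow with atom count", {
  one <- make_probe_blob(1, seed = 113)
  expect_equal(nrow(one$atoms), 1L)
  rog <- function(n) mean(sapply(1:5, function(s) {
    xyz <- atom_xyz(make_probe_blob(n, seed = 113 + s))
    sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  }))
  expect_lt(rog(10), rog(80))
  expect_identical(atom_xyz(make_probe_blob(20, seed = 114)),
                   atom_xyz(make_probe_blob(20, seed = 114)))
})

test_that("ensemble centres follow the stated enrichment law", {
  # singleton patches make the centre directly observable
  toy <- make_toy_receptor(150, 15, seed = 115)
  frac_iface <- function(e, seed) {
    m <- synthetic_pose_model(n_poses = 2000, enrichment = e,
                              patch_sizes = 1L)
    ens <- sample_contact_ensemble(toy$structure, toy$annotation, m,
                                   seed = seed)
    mean(vapply(ens, function(s)
      s %in% toy$annotation$interface_residues, logical(1)))
  }
  # e = 1 reduces exactly to uniform choice over all N residues
  p1 <- frac_iface(1, 116)
  se1 <- sqrt(0.1 * 0.9 / 2000)
  expect_lt(abs(p1 - 15 / 150), 3 * se1)
  # e = 0 excludes the interface entirely
  expect_equal(frac_iface(0, 117), 0)
  # e = 3: closed-form probability 45 / (45 + 135) = 0.25
  p3 <- frac_iface(3, 118)
  se3 <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(p3 - 0.25), 3 * se3)
  # determinism and size validation
  m <- synthetic_pose_model(n_poses = 10, patch_sizes = 5:13)
  expect_identical(
    sample_contact_ensemble(toy$structure, toy$annotation, m, seed = 119),
    sample_contact_ensemble(toy$structure, toy$annotation, m, seed = 119))
  big <- synthetic_pose_model(n_poses = 5, patch_sizes = 500L)
  expect_error(sample_contact_ensemble(toy$structure, toy$annotation,
                                       big, seed = 1), "patch size")
})

test_that("patch sizes are drawn from the configured law", {
  toy <- make_toy_receptor(100, 12, seed = 120)
  ens <- sample_contact_ensemble(toy$structure, toy$annotation,
                                 synthetic_pose_model(n_poses = 2000),
                                 seed = 121)
  sz <- lengths(ens)
  expect_true(all(sz >= 5 & sz <= 13))
  # uniform 5:13 -> each size ~1/9 of poses
  frac <- as.numeric(table(factor(sz, levels = 5:13))) / 2000
  expect_true(all(abs(frac - 1 / 9) < 3 * sqrt((1 / 9) * (8 / 9) / 2000)))
})

test_that("benchmarks are reproducible and honor the size law", {
  b <- make_benchmark(3, model = synthetic_pose_model(n_poses = 50),
                      seed = 122)
  b2 <- make_benchmark(3, model = synthetic_pose_model(n_poses = 50),
                       seed = 122)
  expect_identical(lapply(b$receptors, `[[`, "contact_sets"),
                   lapply(b2$receptors, `[[`, "contact_sets"))
  expect_identical(lapply(b$receptors, function(r)
    r$annotation$interface_residues),
    lapply(b2$receptors, function(r) r$annotation$interface_residues))
  other <- make_benchmark(3, model = synthetic_pose_model(n_poses = 50),
                          seed = 123)
  expect_false(identical(
    lapply(b$receptors, function(r) r$annotation$interface_residues),
    lapply(other$receptors, function(r) r$annotation$interface_residues)))
  sizes <- sapply(make_benchmark(
    200, receptor_size_law = c(100L, 300L), interface_size = 5L,
    model = synthetic_pose_model(n_poses = 1L), seed = 124)$receptors,
    function(r) n_residues(r$structure))
  expect_gte(min(sizes), 100)
  expect_lte(max(sizes), 300)
  expect_lt(abs(mean(sizes) - 200), 3 * sd(sizes) / sqrt(200))
})

test_that("top-15 interface recall rises monotonically with enrichment", {
  recall_at <- function(e) {
    b <- make_benchmark(25, model = synthetic_pose_model(n_poses = 1000,
                                                         enrichment = e),
                        seed = 500 + 10 * e)
    mean(sapply(b$receptors, function(r) {
      prof <- compute_rif(r$contact_sets, residue_ids(r$structure))
      length(intersect(rank_top_k(prof, 15),
                       r$annotation$interface_residues)) / 15
    }))
  }
  rec <- sapply(c(1, 2, 3, 5), recall_at)
  expect_true(all(diff(rec) > 0))
})
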