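make_toy_chain <- function(resno, xyz, id = "A") {
  chain_model(id, resno, rep("ALA", length(resno)), xyz)
}

test_that("build_ensemble intersects resolved residues", {
  set.seed(2)
  xyz <- matrix(rnorm(300, sd = 8), 100, 3)
  a <- make_toy_chain(1:100, xyz)
  b <- make_toy_chain(1:100, xyz, id = "B")
  ens <- build_ensemble(list(a, b))
  expect_equal(ens$common_resnos, 1:100)

  b5 <- make_toy_chain(5:100, xyz[5:100, ], id = "B")
  ens <- build_ensemble(list(a, b5))
  expect_equal(ens$common_resnos, 5:100)

  tiny_a <- make_toy_chain(1:20, xyz[1:20, ])
  tiny_b <- make_toy_chain(15:20, xyz[15:20, ], id = "B")
  expect_error(build_ensemble(list(tiny_a, tiny_b)), "too small")
  expect_error(build_ensemble(list(a)), ">= 2 chains")
})

test_that("interlobe distance is plain Euclidean geometry", {
  ch <- make_toy_chain(c(15L, 416L), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(interlobe_distance(ch), 5)
  ch0 <- make_toy_chain(c(15L, 416L), rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(interlobe_distance(ch0), 0)
  expect_error(interlobe_distance(ch, res_a = 99L), "99")
})

test_that("openness ordering is invariant to global rigid motion", {
  sim <- make_hinge_ensemble(n_residues_fixed = 40L,
                             n_residues_mobile = 40L,
                             angles_deg = c(0, 10, 20), seed = 5)
  ens <- build_ensemble(sim$chains)
  tab <- openness_table(ens, sim$truth$reporter_a, sim$truth$reporter_b)
  moved <- sim$chains
  tr <- structure(list(rotation = oracle_rotation(c(1, 1, 0), 77),
                       translation = c(100, -50, 3), rmsd = 0),
                  class = "rigid_transform")
  moved[[2]] <- apply_transform(tr, moved[[2]])
  tab2 <- openness_table(build_ensemble(moved),
                         sim$truth$reporter_a, sim$truth$reporter_b)
  expect_equal(tab2$interlobe_A, tab$interlobe_A, tolerance = 1e-9)
  expect_equal(tab2$state, tab$state)
  expect_equal(tab$state[order(-tab$interlobe_A)],
               as.character(utils::as.roman(1:3)))
})

test_that("rmsd matrix is symmetric, zero-diagonal, monotone in angle gap", {
  sim <- make_hinge_ensemble(n_residues_fixed = 40L,
                             n_residues_mobile = 40L,
                             angles_deg = c(0, 10, 20), seed = 8)
  ens <- build_ensemble(sim$chains)
  M <- rmsd_matrix(ens, align_range = sim$truth$fixed_resnos)
  expect_equal(diag(M), setNames(rep(0, 3), ens$labels))
  expect_equal(M, t(M), tolerance = 1e-9)
  # displacement grows with angle gap: d(0,20) > d(0,10) and d(10,20)
  expect_gt(M[1, 3], M[1, 2])
  expect_gt(M[1, 3], M[2, 3])
  # identical members give zeros
  two <- build_ensemble(list(sim$chains[[1]], sim$chains[[1]]))
  expect_equal(max(abs(rmsd_matrix(two))), 0, tolerance = 1e-10)
})

test_that("ensemble PCA matches direct covariance eigendecomposition", {
  # small toy ensemble, aligned over every residue
  set.seed(21)
  base <- matrix(rnorm(36, sd = 4), 12, 3)
  chains <- lapply(1:4, function(k) {
    make_toy_chain(1:12, base + matrix(rnorm(36, sd = 0.3), 12, 3),
                   id = LETTERS[k])
  })
  ens <- build_ensemble(chains)
  pca <- ensemble_pca(ens, align_range = 1:12)
  # oracle: superpose with the package's own transform is allowed for the
  # coordinate assembly, but the decomposition is done directly
  X <- t(sapply(chains, function(ch) {
    tr <- kabsch(chains[[1]]$xyz, ch$xyz)
    as.vector(t(apply_transform(tr, ch$xyz)))
  }))
  ev_oracle <- eigen(stats::cov(X), symmetric = TRUE)$values
  k <- length(pca$eigenvalues)
  expect_equal(pca$eigenvalues, ev_oracle[seq_len(k)], tolerance = 1e-8)
  expect_equal(sum(pca$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  # modes are mutually orthogonal unit vectors
  V <- sapply(pca$modes, function(m) as.vector(t(m)))
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-8)
})

test_that("an identical-member ensemble is flagged as zero variance", {
  ch <- make_toy_chain(1:12, matrix(rnorm(36, sd = 5), 12, 3))
  ens <- build_ensemble(list(ch, ch, ch))
  expect_warning(pca <- ensemble_pca(ens, align_range = 1:12),
                 "no conformational variance")
  expect_true(pca$zero_variance)
  expect_true(all(pca$eigenvalues == 0))
})

test_that("a one-mode hinge ensemble concentrates variance on PC1", {
  sim <- make_hinge_ensemble(angles_deg = c(0, 5, 10, 15, 20, 25),
                             seed = 4)
  ens <- build_ensemble(sim$chains)
  pca <- ensemble_pca(ens, align_range = sim$truth$fixed_resnos)
  expect_gte(pca$variance_fractions[1], 0.99)
  # PC1 projection strictly monotone in the generating angle
  proj <- pca$projections[, 1]
  ord <- order(sim$truth$angles_deg)
  expect_true(all(diff(proj[ord]) > 0) || all(diff(proj[ord]) < 0))
})

test_that("hinge angle recovers a constructed rotation exactly", {
  set.seed(13)
  pair <- toy_hinge_pair(angle_deg = 23.8, axis = c(0, 1, 0))
  hg <- hinge_angle(pair$a, pair$b, pair$fixed_range, pair$mobile_range)
  expect_equal(hg$angle_deg, 23.8, tolerance = 1e-6)
  expect_equal(abs(sum(hg$axis * pair$axis)), 1, tolerance = 1e-6)

  # identical chains: zero angle (up to acos conditioning near identity)
  hg0 <- hinge_angle(pair$a, pair$a, pair$fixed_range, pair$mobile_range)
  expect_lt(hg0$angle_deg, 1e-5)

  # swapping open and closed leaves the angle unchanged
  hg_rev <- hinge_angle(pair$b, pair$a, pair$fixed_range,
                        pair$mobile_range)
  expect_equal(hg_rev$angle_deg, hg$angle_deg, tolerance = 1e-9)
})
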