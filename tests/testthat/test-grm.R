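test_that("compute_grm reproduces the standardised cross-product by hand", {
  g <- genotype_matrix(matrix(c(0, 2,
                                2, 0), nrow = 2, byrow = TRUE))
  G <- compute_grm(g)
  expect_equal(G$values, matrix(c(2, -2, -2, 2), 2,
                                dimnames = list(g$individual_ids,
                                                g$individual_ids)),
               tolerance = 1e-12)
  expect_true(all(G$n_markers_per_pair == 2))
})

test_that("centred dosages give a zero GRM and duplicated rows match diagonals", {
  # all individuals heterozygous: freq 0.5, centred dosage 0 everywhere
  g <- genotype_matrix(matrix(1, nrow = 4, ncol = 1))
  expect_true(all(compute_grm(g)$values == 0))

  set.seed(11)
  X <- matrix(rbinom(5 * 60, 2, 0.4), 5, 60)
  X <- rbind(X, X[3, ])  # individual 6 duplicates individual 3
  G <- compute_grm(genotype_matrix(X))$values
  expect_equal(G[3, 6], G[3, 3], tolerance = 1e-12)
  expect_equal(G[3, 6], G[6, 6], tolerance = 1e-12)
})

test_that("GRM is invariant to marker order and allele relabeling", {
  set.seed(21)
  for (r in 1:5) {
    X <- matrix(rbinom(8 * 40, 2, runif(40, 0.1, 0.9)), 8, 40, byrow = FALSE)
    G0 <- compute_grm(genotype_matrix(X))$values
    perm <- sample(ncol(X))
    G1 <- compute_grm(genotype_matrix(X[, perm]))$values
    expect_equal(G0, G1, tolerance = 1e-12, ignore_attr = TRUE)
    flip <- runif(ncol(X)) < 0.5
    Xf <- X
    Xf[, flip] <- 2 - Xf[, flip]
    G2 <- compute_grm(genotype_matrix(Xf))$values
    expect_equal(G0, G2, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("random-mating off-diagonals centre on zero at sampling precision", {
  G <- simulate_grm(400, 3000, seed = 5)
  off <- G$values[upper.tri(G$values)]
  expect_lt(abs(mean(off)), 3 * (1 / sqrt(3000)) / sqrt(2))
  expect_lt(abs(mean(diag(G$values)) - 1), 0.02)
})

test_that("compute_grm uses pairwise-complete markers and flags empty pairs", {
  X <- matrix(c(0, 2, NA,
                2, NA, 1,
                1, 1, 2), nrow = 3, byrow = TRUE)
  G <- compute_grm(genotype_matrix(X))
  expect_equal(G$n_markers_per_pair[1, 2], 1)  # only marker 1 shared
  # polymorphic markers but no shared non-missing marker for pair (1,2)
  Xz <- matrix(c(0, NA,
                 NA, 0,
                 2,  2), nrow = 3, byrow = TRUE)
  expect_error(compute_grm(genotype_matrix(Xz)), "zero shared")
  expect_error(compute_grm(genotype_matrix(matrix(c(0, 0, 2, 2), 2))),
               "monomorphic")
})

test_that("greedy pruning satisfies the cutoff with deterministic tie-breaks", {
  V <- diag(4)
  expect_equal(prune_related(grm(V), 0.05), paste0("ind", 1:4))

  V2 <- diag(4); V2[1, 2] <- V2[2, 1] <- 0.30
  expect_equal(prune_related(grm(V2), 0.05), paste0("ind", c(2, 3, 4)))

  # star: hub related to 3 leaves; only the hub should go
  V3 <- diag(5)
  V3[1, 2:4] <- V3[2:4, 1] <- 0.2
  expect_equal(prune_related(grm(V3), 0.05), paste0("ind", 2:5))
})

test_that("greedy pruning is a valid near-minimal cover on random small graphs", {
  set.seed(33)
  for (r in 1:20) {
    n <- sample(4:9, 1)
    adj <- matrix(FALSE, n, n)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    V <- diag(n)
    V[on] <- 0.2; V <- pmax(V, t(V))
    kept <- prune_related(grm(V), 0.05)
    kidx <- match(kept, paste0("ind", seq_len(n)))
    expect_true(all(V[kidx, kidx][upper.tri(diag(length(kidx)))] <= 0.05))
    adj[on] <- TRUE; adj <- adj | t(adj)
    mvc <- min_vertex_cover_size(adj)
    expect_lte(n - length(kept), mvc + 1)  # greedy max-degree near-minimal
  }
})

test_that("GCTA binary GRM files round-trip at float32 precision", {
  set.seed(4)
  G <- compute_grm(genotype_matrix(matrix(rbinom(3 * 50, 2, 0.3), 3, 50)))
  pre <- file.path(tempdir(), "rt3")
  write_grm_gcta(G, pre)
  G2 <- read_grm_gcta(pre)
  expect_lt(max(abs(G$values - G2$values)), 1e-6)
  expect_equal(G2$individual_ids, G$individual_ids)
  expect_equal(G2$n_markers_per_pair, G$n_markers_per_pair,
               tolerance = 1e-6, ignore_attr = TRUE)

  # n = 1 degenerate size
  g1 <- grm(matrix(1.02, 1, 1), "solo")
  pre1 <- file.path(tempdir(), "rt1")
  write_grm_gcta(g1, pre1)
  expect_equal(read_grm_gcta(pre1)$values[1, 1], 1.02, tolerance = 1e-6)

  # truncated binary -> corrupt-file error
  sz <- file.size(paste0(pre, ".grm.bin"))
  bin <- readBin(paste0(pre, ".grm.bin"), "raw", sz)
  writeBin(bin[seq_len(sz - 4)], paste0(pre, ".grm.bin"))
  expect_error(read_grm_gcta(pre), "corrupt")
})

test_that("eigendecomposition reconstructs and orders eigenvalues", {
  gI <- grm_eigen(grm(diag(4)))
  expect_equal(gI$eigen$values, rep(1, 4))

  n <- 5; sc <- 0.3
  g1 <- grm_eigen(grm(matrix(sc, n, n) + diag(1e-15, n)))
  expect_equal(g1$eigen$values[1], n * sc, tolerance = 1e-10)
  expect_true(all(abs(g1$eigen$values[-1]) < 1e-10))

  set.seed(8)
  A <- crossprod(matrix(rnorm(25), 5))
  ge <- grm_eigen(grm(A))
  rec <- ge$eigen$vectors %*% (ge$eigen$values * t(ge$eigen$vectors))
  expect_lt(max(abs(rec - A)), 1e-10)
  expect_true(all(diff(ge$eigen$values) <= 1e-12))
})

test_that("PLINK binary filesets round-trip including missing dosages", {
  set.seed(14)
  X <- matrix(rbinom(7 * 20, 2, 0.4), 7, 20)
  X[sample(length(X), 12)] <- NA
  g <- genotype_matrix(X)
  pre <- file.path(tempdir(), "plinkrt")
  write_plink(g, pre)
  g2 <- read_plink(pre)
  expect_equal(g2$values, g$values, ignore_attr = TRUE)
  expect_equal(g2$individual_ids, g$individual_ids)
  # corrupted magic number is rejected
  bed <- paste0(pre, ".bed")
  raw <- readBin(bed, "raw", file.size(bed))
  raw[1] <- as.raw(0)
  writeBin(raw, bed)
  expect_error(read_plink(pre), "magic")
})
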