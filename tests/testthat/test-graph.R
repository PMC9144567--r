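test_that("montage presets give the expected physical adjacency", {
  A <- physical_adjacency(c("F3", "F4", "C3", "C4", "O1", "O2"))
  expect_equal(dim(A), c(6L, 6L))
  expect_equal(sum(A != 0), 14)              # 7 undirected edges
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  # referential labels map to the same montage
  A2 <- physical_adjacency(c("F3-A2", "F4-A1", "C3-A2", "C4-A1",
                             "O1-A2", "O2-A1"))
  expect_equal(unname(A2), unname(A))

  expect_equal(unname(physical_adjacency(c("Fpz-Cz", "Pz-Oz"))),
               matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(physical_adjacency("Cz", edges = list())),
               matrix(0, 1, 1))
  expect_error(physical_adjacency(c("Q1", "Q2", "Q3")), "unknown montage")
  # custom edge list
  A3 <- physical_adjacency(c("Q1", "Q2", "Q3"),
                           edges = list(c("Q1", "Q3")))
  expect_equal(sum(A3), 2)
})

test_that("symmetric normalization matches hand-computed cases", {
  expect_equal(normalize_adjacency(matrix(0, 3, 3)), diag(3))
  expect_equal(normalize_adjacency(matrix(c(0, 1, 1, 0), 2)),
               matrix(0.5, 2, 2))
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(normalize_adjacency(k3), matrix(1 / 3, 3, 3))
  expect_error(normalize_adjacency(matrix(c(0, -1, -1, 0), 2)),
               "non-negative")
})

test_that("normalized adjacency is symmetric, bounded, spectral radius <= 1", {
  set.seed(30)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    A <- matrix(rbinom(n * n, 1, 0.4), n, n)
    A <- (A + t(A)) > 0; A <- A * 1; diag(A) <- 0
    An <- normalize_adjacency(A)
    expect_equal(An, t(An), tolerance = 1e-12)
    expect_true(all(An >= 0 & An <= 1))
    expect_lte(max(abs(eigen(An, only.values = TRUE)$values)), 1 + 1e-10)
  }
})

test_that("dynamic graph is row-stochastic, uniform on equal features, and matches brute force", {
  set.seed(31)
  w <- runif(5)
  expect_equal(dynamic_graph(matrix(3, 4, 5), w), matrix(0.25, 4, 4))
  for (rep in 1:10) {
    v <- sample(2:6, 1)
    X <- matrix(rnorm(v * 5, sd = 2), v, 5)
    g <- dynamic_graph(X, w)
    expect_true(all(g >= 0))
    expect_equal(rowSums(g), rep(1, v), tolerance = 1e-6)
    expect_equal(g, oracle_dynamic_graph(X, w), tolerance = 1e-10)
  }
  # clustered features with positive w concentrate mass on distant nodes
  X <- rbind(matrix(0, 3, 5), matrix(5, 2, 5))
  g <- dynamic_graph(X, rep(1, 5))
  expect_gt(sum(g[1, 4:5]), sum(g[1, 2:3]))
  expect_error(dynamic_graph(matrix(0, 3, 4), w), "length")
})

test_that("dynamic graph is permutation-equivariant", {
  set.seed(32)
  X <- matrix(rnorm(6 * 5), 6, 5)
  w <- runif(5)
  perm <- sample(6)
  g <- dynamic_graph(X, w)
  gp <- dynamic_graph(X[perm, ], w)
  expect_equal(gp, g[perm, perm], tolerance = 1e-12)
})

test_that("dynamic graph gradients match finite differences", {
  set.seed(33)
  f <- 4; v <- 5; m <- 3
  X3 <- array(rnorm(f * v * m), c(f, v, m))
  w <- runif(f, 0.2, 1)
  R <- array(rnorm(v * v * m), c(v, v, m))   # random cotangent
  loss <- function(X3, w) sum(dyngraph_forward(X3, w)$Gd * R)
  fw <- dyngraph_forward(X3, w)
  bk <- dyngraph_backward(R, fw, w)
  eps <- 1e-6
  for (i in sample(length(w), 3)) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    fd <- (loss(X3, wp) - loss(X3, wm)) / (2 * eps)
    expect_equal(bk$dw[i], fd, tolerance = 1e-4)
  }
  for (i in sample(length(X3), 5)) {
    xp <- X3; xp[i] <- xp[i] + eps
    xm <- X3; xm[i] <- xm[i] - eps
    fd <- (loss(xp, w) - loss(xm, w)) / (2 * eps)
    expect_equal(bk$dX3[i], fd, tolerance = 1e-4)
  }
})
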