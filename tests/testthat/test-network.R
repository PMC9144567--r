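test_that("static GCN matches dense per-frame recomputation and identities", {
  set.seed(40)
  c_in <- 4; tt <- 5; v <- 3; c_out <- 6
  x <- array(rnorm(c_in * tt * v), c(c_in, tt, v))
  A <- matrix(runif(v * v), v, v)
  mu <- matrix(rnorm(c_in * c_out), c_in, c_out)
  expect_equal(gcn_static(x, A, mu), oracle_gcn_static(x, A, mu),
               tolerance = 1e-6)
  # identity composition: Gm = 0, A = I, mu = I on non-negative input
  xp <- abs(x)
  expect_equal(gcn_static(xp, diag(v), diag(c_in)), xp, tolerance = 1e-12)
  # no bias: zero in, zero out
  expect_equal(gcn_static(array(0, dim(x)), A, mu), array(0, c(c_out, tt, v)))
})

test_that("dynamic GCN matches dense recomputation; uniform graph averages nodes", {
  set.seed(41)
  c_in <- 5; tt <- 4; v <- 4; c_out <- 3
  x <- array(rnorm(c_in * tt * v), c(c_in, tt, v))
  mu2 <- matrix(rnorm(c_in * c_out), c_in, c_out)
  Gd <- array(abs(rnorm(v * v * tt)), c(v, v, tt))
  for (t in seq_len(tt)) Gd[, , t] <- Gd[, , t] / rowSums(Gd[, , t])
  expect_equal(gcn_dynamic(x, Gd, mu2), oracle_gcn_dynamic(x, Gd, mu2),
               tolerance = 1e-6)
  # identity graph and identity kernel reproduce the input
  expect_equal(gcn_dynamic(x, diag(v), diag(c_in)), x, tolerance = 1e-12)
  # uniform rows: every node receives the node-mean times mu2
  gu <- matrix(1 / v, v, v)
  out <- gcn_dynamic(x, gu, mu2)
  for (t in seq_len(tt)) {
    mean_feat <- colMeans(t(x[, t, ]))           # C
    expect_equal(out[, t, 1], as.vector(t(mu2) %*% mean_feat),
                 tolerance = 1e-12)
    expect_equal(out[, t, v], out[, t, 1], tolerance = 1e-12)
  }
})

test_that("branch fusion weights the static branch by phi", {
  set.seed(42)
  stat <- array(rnorm(24), c(2, 3, 4))
  dyn <- array(rnorm(24), c(2, 3, 4))
  expect_equal(gcn_fuse(stat, dyn, 0), dyn)
  expect_equal(gcn_fuse(stat, dyn, 1), stat + dyn)
  ones <- array(1, c(2, 3, 4))
  expect_equal(gcn_fuse(ones, ones, 0.5), 1.5 * ones)
  expect_error(gcn_fuse(stat, dyn, 1.2), "0, 1")
  expect_error(gcn_fuse(stat, array(0, c(2, 3, 5)), 0.5), "equal shapes")
})

test_that("multi-scale TCN matches dense recomputation and preserves time", {
  set.seed(43)
  for (tt in c(1, 5, 25)) {
    x <- array(rnorm(8 * tt * 3), c(8, tt, 3))
    p <- mstcn_params(8, 14)
    y <- mstcn(x, p)
    expect_equal(dim(y), c(14L, tt, 3L))
    expect_equal(y, oracle_mstcn(x, p), tolerance = 1e-6)
  }
  # channel widths: six transform branches of floor(C/7), residual the rest
  p <- mstcn_params(8, 30)
  expect_equal(p$b, 4)
  expect_equal(p$rw, 30 - 24)
  expect_error(mstcn_params(8, 5), "at least 7")
})

test_that("TCN on frame-constant input: pool branch passes the constant, dilation-1 interior frames are constant", {
  set.seed(44)
  c_in <- 6; v <- 2; tt <- 5
  const <- rnorm(c_in)
  x <- array(rep(const, tt * v), c(c_in, tt, v))
  p <- mstcn_params(c_in, 21)   # b = 3
  y <- mstcn(x, p)
  expect_equal(y, oracle_mstcn(x, p), tolerance = 1e-8)
  # max-pool branch (6th block of width b): shrink-window pooling of a
  # constant is that constant
  zp <- as.vector(p$pW %*% const)
  for (t in seq_len(tt))
    expect_equal(y[15 + seq_len(3), t, 1] -
                   (p$resW %*% const)[15 + seq_len(3)], zp,
                 tolerance = 1e-8)
  # dilation-1 branch: interior frames equal (sum of taps) applied to the
  # bottlenecked constant
  s <- (p$tW[[1]][, , 1] + p$tW[[1]][, , 2] + p$tW[[1]][, , 3])
  expected <- as.vector(s %*% (p$bW[[1]] %*% const))
  for (t in 2:4)
    expect_equal(y[seq_len(3), t, 1] - (p$resW %*% const)[seq_len(3)],
                 expected, tolerance = 1e-8)
})

test_that("attention matches dense recomputation, keeps shape, and contracts", {
  set.seed(45)
  for (rep in 1:5) {
    cc <- sample(c(4, 8, 12), 1); tt <- sample(2:5, 1); v <- sample(2:6, 1)
    x <- array(rnorm(cc * tt * v, sd = 2), c(cc, tt, v))
    p <- attention_params(cc, r = 4)
    y <- attention_block(x, p)
    expect_equal(dim(y), dim(x))
    expect_equal(y, oracle_attention(x, p), tolerance = 1e-6)
    expect_true(all(abs(y) <= abs(x) + 1e-12))   # both sigmoids in (0,1)
  }
  expect_error(attention_params(3, r = 4), "exceeds")
})

test_that("channel-constant attention input yields a per-channel scalar map", {
  set.seed(46)
  cc <- 6; tt <- 4; v <- 3
  x <- array(rep(rnorm(cc), tt * v), c(cc, tt, v))
  p <- attention_params(cc, r = 2)
  y <- attention_block(x, p)
  ratio <- y / x
  for (c in seq_len(cc))
    expect_lt(diff(range(ratio[c, , ])), 1e-12)
})

test_that("classifier head is a softmax over pooled features", {
  set.seed(47)
  x <- array(rnorm(8 * 5 * 3), c(8, 5, 3, 4))
  W <- matrix(rnorm(40), 5, 8); b <- rnorm(5)
  p <- classify_head(x, W, b)
  expect_equal(colSums(p), rep(1, 4), tolerance = 1e-6)
  # zero features with a zero-initialized head: uniform 0.2
  p0 <- classify_head(array(0, c(8, 5, 3, 1)), matrix(0, 5, 8), numeric(5))
  expect_equal(as.vector(p0), rep(0.2, 5))
  # argmax of probabilities equals argmax of logits
  g <- colMeans(matrix(aperm(x, c(2, 3, 1, 4)), 15, 32)); dim(g) <- c(8, 4)
  logits <- W %*% g + b
  expect_equal(max.col(t(p)), max.col(t(logits)))
})

test_that("module stack propagates shapes; ablation removes the attention block", {
  set.seed(48)
  x <- array(rnorm(5 * 5 * 6), c(5, 5, 6, 1))   # bands x Tn x electrodes
  cfg9 <- stgcn_config(n_electrodes = 6, n_bands = 5, context_len = 5)
  m9 <- stgcn_init(cfg9, seed = 1)
  fwd <- network_forward(m9, x, training = FALSE)
  expect_equal(unname(fwd$feat_dim), c(264L, 5L, 6L, 1L))
  expect_equal(length(m9$modules), 9L)

  cfg_no <- stgcn_config(n_electrodes = 6, n_bands = 5, context_len = 5,
                         channels = c(16, 16), attention = FALSE)
  m_no <- stgcn_init(cfg_no, seed = 1)
  expect_null(m_no$modules[[1]]$att)
  fwd_no <- network_forward(m_no, x, training = FALSE)
  expect_equal(unname(fwd_no$feat_dim)[1], 16L)
})

test_that("class probabilities are invariant under electrode permutation", {
  set.seed(49)
  v <- 5
  Gp <- physical_adjacency(c("F3", "F4", "C3", "C4", "O1", "O2"))[1:v, 1:v]
  cfg <- stgcn_config(n_electrodes = v, n_bands = 4, context_len = 3,
                      channels = c(14, 14), dropout = 0)
  m <- stgcn_init(cfg, Gp = Gp, seed = 2)
  m$Gm <- matrix(rnorm(v * v, sd = 0.1), v, v)
  x <- array(rnorm(4 * 3 * v * 2), c(4, 3, v, 2))
  perm <- c(3, 5, 1, 2, 4)
  m2 <- m
  m2$Gp <- m$Gp[perm, perm]
  m2$A0 <- normalize_adjacency(m2$Gp)
  m2$Gm <- m$Gm[perm, perm]
  p1 <- softmax_probs(network_forward(m, x, FALSE)$logits)
  p2 <- softmax_probs(network_forward(m2, x[, , perm, , drop = FALSE],
                                      FALSE)$logits)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("evaluation-mode forward is deterministic; dropout only acts in training", {
  set.seed(50)
  cfg <- stgcn_config(n_electrodes = 4, n_bands = 3, context_len = 4,
                      channels = c(14, 14), dropout = 0.5)
  m <- stgcn_init(cfg, seed = 5)
  x <- array(rnorm(3 * 4 * 4 * 3), c(3, 4, 4, 3))
  f1 <- network_forward(m, x, training = FALSE)$logits
  f2 <- network_forward(m, x, training = FALSE)$logits
  expect_identical(f1, f2)
  set.seed(1); t1 <- network_forward(m, x, training = TRUE)$logits
  set.seed(2); t2 <- network_forward(m, x, training = TRUE)$logits
  expect_false(identical(t1, t2))
})

test_that("analytic gradients of the full module stack match finite differences", {
  set.seed(7)
  cfg <- stgcn_config(n_electrodes = 4, n_bands = 3, context_len = 4,
                      channels = c(14, 14), attention = TRUE, dropout = 0,
                      reduction = 2)
  m <- stgcn_init(cfg, seed = 3)
  m$config$class_weights_vec <- NULL
  x <- array(rnorm(3 * 4 * 4 * 6), c(3, 4, 4, 6))
  y <- sample(1:5, 6, replace = TRUE)
  g <- network_loss_grad(m, x, y, training = TRUE)$grads
  paths <- list(
    list("Gm"), list("head", "W"), list("head", "b"),
    list("modules", 1L, "mu"), list("modules", 1L, "mu2"),
    list("modules", 1L, "w"), list("modules", 1L, "g1"),
    list("modules", 1L, "b2"),
    list("modules", 1L, "tcn", "bW", 2L), list("modules", 1L, "tcn", "tW", 3L),
    list("modules", 1L, "tcn", "oneW"), list("modules", 1L, "tcn", "rW"),
    list("modules", 1L, "tcn", "resW"),
    list("modules", 2L, "mu"), list("modules", 2L, "w"),
    list("modules", 2L, "att", "W0"), list("modules", 2L, "att", "gamma"),
    list("modules", 2L, "att", "Wt"), list("modules", 2L, "att", "Ws"),
    list("modules", 2L, "att", "bs"))
  for (path in paths) {
    err <- fd_check(m, x, y, list(Gm = g$Gm, head = g$head,
                                  modules = g$modules), path)
    expect_lt(err, 1e-4)
  }
})

test_that("gd_agg='mean' and static_norm variants keep exact gradients", {
  set.seed(51)
  for (variant in list(list(gd = "mean", sn = "pre"),
                       list(gd = "frame", sn = "none"))) {
    cfg <- stgcn_config(n_electrodes = 3, n_bands = 3, context_len = 3,
                        channels = c(7, 7), dropout = 0, reduction = 2,
                        gd_agg = variant$gd, static_norm = variant$sn)
    m <- stgcn_init(cfg, seed = 4)
    m$config$class_weights_vec <- NULL
    x <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
    y <- sample(1:5, 4, replace = TRUE)
    g <- network_loss_grad(m, x, y, training = TRUE)$grads
    for (path in list(list("Gm"), list("modules", 1L, "w"),
                      list("modules", 2L, "mu2"))) {
      err <- fd_check(m, x, y, list(Gm = g$Gm, head = g$head,
                                    modules = g$modules), path)
      expect_lt(err, 1e-4)
    }
  }
})

test_that("a full-size forward+backward step completes quickly on one CPU", {
  set.seed(52)
  cfg <- stgcn_config(n_electrodes = 6, n_bands = 5, context_len = 5)
  m <- stgcn_init(cfg, seed = 1)
  m$config$class_weights_vec <- NULL
  x <- array(rnorm(5 * 5 * 6), c(5, 5, 6, 1))
  el <- system.time(network_loss_grad(m, x, 2L, training = TRUE))[["elapsed"]]
  expect_lt(el, 1)
})
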