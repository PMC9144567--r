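# Independent brute-force recomputations of the network blocks (plain
# per-frame loops, no shared code with the implementation) and a
# finite-difference utility. Used to oracle-check forward passes and
# analytic gradients.

# internal entry points exercised directly by the tests
network_loss_grad <- somnograph:::network_loss_grad
network_forward <- somnograph:::network_forward
softmax_probs <- somnograph:::softmax_probs
dyngraph_forward <- somnograph:::dyngraph_forward
dyngraph_backward <- somnograph:::dyngraph_backward

oracle_gcn_static <- function(x, A, mu) {
  d <- dim(x)
  out <- array(0, c(ncol(mu), d[2], d[3]))
  for (t in seq_len(d[2])) {
    xv <- t(x[, t, ])                # V x C
    m <- A %*% xv %*% mu             # V x C_out
    out[, t, ] <- t(pmax(m, 0))
  }
  out
}

oracle_gcn_dynamic <- function(x, Gd, mu2) {
  d <- dim(x)
  out <- array(0, c(ncol(mu2), d[2], d[3]))
  for (t in seq_len(d[2])) {
    g <- if (length(dim(Gd)) == 3) Gd[, , t] else Gd
    out[, t, ] <- t(g %*% t(x[, t, ]) %*% mu2)
  }
  out
}

oracle_dynamic_graph <- function(X, w) {
  v <- nrow(X)
  s <- matrix(0, v, v)
  for (i in seq_len(v)) for (j in seq_len(v))
    s[i, j] <- max(0, sum(w * abs(X[i, ] - X[j, ])))
  g <- matrix(0, v, v)
  for (i in seq_len(v)) g[i, ] <- exp(s[i, ]) / sum(exp(s[i, ]))
  g
}

oracle_tconv <- function(W, z, dil) {
  d <- dim(z)
  out <- array(0, c(dim(W)[1], d[2], d[3]))
  for (t in seq_len(d[2])) for (v in seq_len(d[3])) {
    acc <- numeric(dim(W)[1])
    for (k in 1:3) {
      tt <- t + (k - 2) * dil
      if (tt >= 1 && tt <= d[2]) acc <- acc + W[, , k] %*% z[, tt, v]
    }
    out[, t, v] <- acc
  }
  out
}

oracle_mstcn <- function(x, p) {
  d <- dim(x)
  lin3 <- function(W, x) {
    out <- array(0, c(nrow(W), d[2], d[3]))
    for (t in seq_len(d[2])) for (v in seq_len(d[3]))
      out[, t, v] <- W %*% x[, t, v]
    out
  }
  outs <- list()
  for (i in 1:4)
    outs[[i]] <- oracle_tconv(p$tW[[i]], lin3(p$bW[[i]], x), p$dilations[i])
  outs[[5]] <- lin3(p$oneW, x)
  zp <- lin3(p$pW, x)
  pool <- array(0, dim(zp))
  for (t in seq_len(d[2]))
    pool[, t, ] <- apply(zp[, max(1, t - 1):min(d[2], t + 1), , drop = FALSE],
                         c(1, 3), max)
  outs[[6]] <- pool
  outs[[7]] <- if (is.null(p$rW)) x else lin3(p$rW, x)
  y <- array(0, c(p$c_out, d[2], d[3]))
  off <- 0
  for (i in 1:7) {
    w <- dim(outs[[i]])[1]
    y[off + seq_len(w), , ] <- outs[[i]]
    off <- off + w
  }
  y + (if (is.null(p$resW)) x else lin3(p$resW, x))
}

oracle_attention <- function(x, p, bn_mean = NULL, bn_var = NULL) {
  d <- dim(x)
  tt <- d[2]; v <- d[3]
  if (is.null(bn_mean)) bn_mean <- numeric(p$cr)
  if (is.null(bn_var)) bn_var <- rep(1, p$cr)
  gt <- apply(x, c(1, 3), max)   # C x V
  gs <- apply(x, c(1, 2), max)   # C x T
  fcat <- cbind(gt, gs)          # C x (V+T)
  h1 <- p$W0 %*% fcat + p$b0
  h2 <- p$gamma * (h1 - bn_mean) / sqrt(bn_var + 1e-5) + p$beta
  h3 <- h2 / (1 + exp(-h2))
  es <- 1 / (1 + exp(-(p$Ws %*% h3[, seq_len(v), drop = FALSE] + p$bs)))
  fs <- 1 / (1 + exp(-(p$Wt %*% h3[, v + seq_len(tt), drop = FALSE] + p$bt)))
  y <- array(0, d)
  for (t in seq_len(tt)) for (vv in seq_len(v))
    y[, t, vv] <- x[, t, vv] * fs[, t] * es[, vv]
  y
}

# --- finite-difference checking over nested parameter paths ------------------

get_path <- function(obj, path) { for (k in path) obj <- obj[[k]]; obj }

set_path <- function(obj, path, value) {
  if (length(path) == 1) { obj[[path[[1]]]] <- value; return(obj) }
  obj[[path[[1]]]] <- set_path(obj[[path[[1]]]], path[-1], value)
  obj
}

# Max relative error between analytic gradient and central differences at
# `n_probe` random coordinates of the parameter at `path`.
fd_check <- function(model, x, y, grads, path, n_probe = 4, eps = 1e-6) {
  p0 <- get_path(model, path)
  g <- get_path(grads, path)
  idx <- sample(length(p0), min(n_probe, length(p0)))
  worst <- 0
  for (i in idx) {
    pp <- p0; pp[i] <- pp[i] + eps
    lp <- network_loss_grad(set_path(model, path, pp), x, y, TRUE)$loss
    pp <- p0; pp[i] <- pp[i] - eps
    lm <- network_loss_grad(set_path(model, path, pp), x, y, TRUE)$loss
    fd <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(fd - g[i]) / max(1e-8, abs(fd), abs(g[i])))
  }
  worst
}

# small labeled context set that is linearly separable in feature space:
# five class prototypes plus light noise
make_separable_contexts <- function(n = 60, v = 4, f = 5, tn = 5,
                                    noise = 0.1, seed = 99) {
  set.seed(seed)
  proto <- array(stats::rnorm(5 * v * f * tn, sd = 1.5), c(5, v, f, tn))
  y <- rep(stage_levels(), length.out = n)
  x <- array(0, c(v, f, tn, n))
  for (i in seq_len(n)) {
    k <- match(y[i], stage_levels())
    x[, , , i] <- proto[k, , , ] + stats::rnorm(v * f * tn, sd = noise)
  }
  list(x = x, y = y)
}
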