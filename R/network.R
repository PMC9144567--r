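# The spatiotemporal graph convolutional network with inter-temporal
# attention, written as explicit forward/backward passes over base-R
# arrays. Activation tensors are laid out (C, T, V, B): channels, frames,
# electrodes, batch. Channel-mixing ops reshape to a C x (T*V*B) matrix;
# graph ops permute V to the front; temporal convolutions shift along T.
# Every layer's backward pass is finite-difference checked in the tests.

cmat <- function(x) { d <- dim(x); dim(x) <- c(d[1], prod(d[-1])); x }

reshape_as <- function(x, template) { dim(x) <- dim(template); x }

# --- elementary layers -------------------------------------------------------

lin_f <- function(W, x, b = NULL) {
  d <- dim(x)
  y <- W %*% cmat(x)
  if (!is.null(b)) y <- y + b
  dim(y) <- c(nrow(W), d[-1])
  y
}

lin_b <- function(W, x, dy, bias = FALSE) {
  dym <- cmat(dy); xm <- cmat(x)
  dx <- crossprod(W, dym)
  dim(dx) <- dim(x)
  out <- list(dW = tcrossprod(dym, xm), dx = dx)
  if (bias) out$db <- .rowSums(dym, nrow(dym), ncol(dym))
  out
}

relu_f <- function(x) x * (x > 0)

sigm <- function(x) 1 / (1 + exp(-x))

bn_f <- function(x, gamma, beta, training, state, momentum = 0.1,
                 eps = 1e-5) {
  xm <- cmat(x)
  m <- ncol(xm)
  nr <- nrow(xm)
  if (training) {
    mu <- .rowMeans(xm, nr, m)
    v <- .rowMeans(xm * xm, nr, m) - mu^2
    v[v < 0] <- 0
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * invstd
  y <- gamma * xhat + beta
  dim(y) <- dim(x)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           m = m, training = training, dims = dim(x)),
       state = state)
}

bn_b <- function(dy, cache) {
  dym <- cmat(dy)
  nr <- nrow(dym); m <- cache$m
  dgamma <- .rowSums(dym * cache$xhat, nr, m)
  dbeta <- .rowSums(dym, nr, m)
  dxhat <- dym * cache$gamma
  if (cache$training) {
    dx <- (cache$invstd / m) *
      (m * dxhat - .rowSums(dxhat, nr, m) -
         cache$xhat * .rowSums(dxhat * cache$xhat, nr, m))
  } else {
    dx <- dxhat * cache$invstd
  }
  dim(dx) <- cache$dims
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Shift along the frame axis (dim 2) with zero fill: out[, t, , ] = x[, t+s, , ].
shift_t <- function(x, s, fill = 0) {
  if (s == 0) return(x)
  d <- dim(x)
  tt <- d[2]
  y <- array(fill, d)
  if (abs(s) >= tt) return(y)
  if (s >= 0) {
    y[, seq_len(tt - s), , ] <- x[, (1 + s):tt, , , drop = FALSE]
  } else {
    y[, (1 - s):tt, , ] <- x[, seq_len(tt + s), , , drop = FALSE]
  }
  y
}

# Temporal convolution, kernel 3 along T with dilation, zero ("same")
# padding. W is (C_out, C_in, 3); tap k applies to frame t + (k-2)*dil.
tap <- function(W, k) {
  Wk <- W[, , k, drop = FALSE]
  dim(Wk) <- dim(W)[1:2]
  Wk
}

tconv_f <- function(W, x, dil) {
  y <- 0
  for (k in 1:3) y <- y + lin_f(tap(W, k), shift_t(x, (k - 2) * dil))
  y
}

tconv_b <- function(W, x, dy, dil) {
  dW <- array(0, dim(W))
  dx <- array(0, dim(x))
  for (k in 1:3) {
    xs <- shift_t(x, (k - 2) * dil)
    g <- lin_b(tap(W, k), xs, dy)
    dW[, , k] <- g$dW
    dx <- dx + shift_t(g$dx, -(k - 2) * dil)
  }
  list(dW = dW, dx = dx)
}

# Max pooling over frames, window 3, stride 1, "same" extent (edge windows
# shrink rather than pad). Ties resolve to the earliest frame.
maxpool_t_f <- function(x) {
  xm1 <- shift_t(x, -1, fill = -Inf)   # value at t-1
  xp1 <- shift_t(x, 1, fill = -Inf)    # value at t+1
  y <- pmax(xm1, x, xp1)
  k <- array(1L, dim(x))               # offset +1 default (t+1)
  k[x >= xp1] <- 0L
  k[xm1 >= x & xm1 >= xp1] <- -1L
  list(y = y, cache = k)
}

maxpool_t_b <- function(dy, cache) {
  dx <- array(0, dim(dy))
  for (k in -1:1) dx <- dx + shift_t(dy * (cache == k), -k)
  dx
}

# Apply a shared V x V matrix on the electrode axis: y[c,t,v,b] =
# sum_u A[v,u] x[c,t,u,b].
gapply_f <- function(A, x) {
  d <- dim(x)
  p <- aperm(x, c(3, 1, 2, 4))
  dim(p) <- c(d[3], d[1] * d[2] * d[4])
  y <- A %*% p
  dim(y) <- c(d[3], d[1], d[2], d[4])
  aperm(y, c(2, 3, 1, 4))
}

gapply_b <- function(A, x, dy) {
  d <- dim(x)
  pm <- aperm(x, c(3, 1, 2, 4)); dim(pm) <- c(d[3], d[1] * d[2] * d[4])
  dym <- aperm(dy, c(3, 1, 2, 4)); dim(dym) <- c(d[3], d[1] * d[2] * d[4])
  dA <- dym %*% t(pm)
  dp <- t(A) %*% dym
  dim(dp) <- c(d[3], d[1], d[2], d[4])
  list(dA = dA, dx = aperm(dp, c(2, 3, 1, 4)))
}

# Apply per-frame graphs: Gd (V, V, M), x (C, T, V, B) with M = T*B.
# Work in a (C*V, M) matrix whose rows are ordered (c, v): each frame's
# V x V matmul becomes columnwise Khatri-Rao-style products built from
# row replication, avoiding per-frame loops and axis permutation.
gapply_dyn_f <- function(Gd, x) {
  d <- dim(x)
  cc <- d[1]; v <- d[3]; m <- d[2] * d[4]
  rep_c <- rep(seq_len(cc), times = v)
  rep_v <- rep(seq_len(v), each = cc)
  o <- matrix(0, cc * v, m)
  for (j in seq_len(v)) {
    xj <- matrix(x[, , j, ], cc, m)              # frame features of node j
    gj <- matrix(Gd[, j, ], v, m)                # edge weights into node j
    o <- o + xj[rep_c, , drop = FALSE] * gj[rep_v, , drop = FALSE]
  }
  dim(o) <- c(cc, v, d[2], d[4])
  aperm(o, c(1, 3, 2, 4))
}

gapply_dyn_b <- function(Gd, x, dy) {
  d <- dim(x)
  cc <- d[1]; v <- d[3]; m <- d[2] * d[4]
  rep_c <- rep(seq_len(cc), times = v)
  rep_v <- rep(seq_len(v), each = cc)
  dyr <- aperm(dy, c(1, 3, 2, 4)); dim(dyr) <- c(cc * v, m)  # rows (c, i)
  dGd <- array(0, c(v, v, m))
  dcp <- matrix(0, cc * v, m)                    # rows (c, j)
  for (j in seq_len(v)) {
    xj <- matrix(x[, , j, ], cc, m)
    # dGd[i,j,m] = sum_c dy[c,i,m] * x_j[c,m]
    pj <- dyr * xj[rep_c, , drop = FALSE]
    dGd[, j, ] <- .colSums(matrix(pj, cc, v * m), cc, v * m)
  }
  for (i in seq_len(v)) {
    gi <- matrix(Gd[i, , ], v, m)                # weights from node i
    dyi <- dyr[(i - 1) * cc + seq_len(cc), , drop = FALSE]
    dcp <- dcp + dyi[rep_c, , drop = FALSE] * gi[rep_v, , drop = FALSE]
  }
  dim(dcp) <- c(cc, v, d[2], d[4])
  list(dGd = dGd, dx = aperm(dcp, c(1, 3, 2, 4)))
}

# --- parameter initializers --------------------------------------------------

he_mat <- function(nout, nin, gain = 2) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(gain / nin)), nout, nin)
}

#' Multi-scale TCN parameters
#'
#' Allocates the seven-branch temporal block mapping `c_in` channels to
#' `c_out`: four bottlenecked dilated 3x1 convolution branches, one 1x1
#' branch, one bottlenecked 3x1 max-pool branch, and a residual branch.
#' Each transform branch gets `floor(c_out/7)` output channels; the
#' residual branch carries the remainder (via a 1x1 projection unless its
#' width equals `c_in`). A module-level residual (identity or 1x1) is
#' added on top.
#'
#' @param c_in,c_out input and output channel counts (`c_out >= 7`).
#' @param dilations four dilation factors (default 1:4).
#' @return Parameter list for [mstcn()].
#' @export
mstcn_params <- function(c_in, c_out, dilations = 1:4) {
  if (c_out < 7) stop("c_out must be at least 7 (one channel per branch)")
  if (length(dilations) != 4) stop("exactly four dilation factors required")
  b <- c_out %/% 7
  rw <- c_out - 6 * b
  list(
    bW = lapply(1:4, function(i) he_mat(b, c_in)),
    tW = lapply(1:4, function(i) array(stats::rnorm(b * b * 3,
                                                    sd = sqrt(2 / (3 * b))),
                                       c(b, b, 3))),
    oneW = he_mat(b, c_in),
    pW = he_mat(b, c_in),
    rW = if (rw == c_in) NULL else he_mat(rw, c_in),
    resW = if (c_out == c_in) NULL else he_mat(c_out, c_in),
    dilations = dilations, b = b, rw = rw, c_in = c_in, c_out = c_out
  )
}

mstcn_f <- function(x, p) {
  caches <- list()
  outs <- vector("list", 7)
  for (i in 1:4) {
    z <- lin_f(p$bW[[i]], x)
    outs[[i]] <- tconv_f(p$tW[[i]], z, p$dilations[i])
    caches[[i]] <- z
  }
  outs[[5]] <- lin_f(p$oneW, x)
  zp <- lin_f(p$pW, x)
  mp <- maxpool_t_f(zp)
  outs[[6]] <- mp$y
  outs[[7]] <- if (is.null(p$rW)) x else lin_f(p$rW, x)
  d <- dim(x)
  y <- array(0, c(p$c_out, d[2], d[3], d[4]))
  off <- 0
  for (i in 1:7) {
    w <- dim(outs[[i]])[1]
    y[off + seq_len(w), , , ] <- outs[[i]]
    off <- off + w
  }
  res <- if (is.null(p$resW)) x else lin_f(p$resW, x)
  y <- y + res
  list(y = y, cache = list(z = caches, zp = zp, mp = mp$cache, x = x))
}

mstcn_b <- function(dy, p, cache) {
  x <- cache$x
  g <- list(bW = vector("list", 4), tW = vector("list", 4))
  dx <- array(0, dim(x))
  # module-level residual
  if (is.null(p$resW)) dx <- dx + dy
  else {
    gb <- lin_b(p$resW, x, dy)
    g$resW <- gb$dW
    dx <- dx + gb$dx
  }
  widths <- c(rep(p$b, 6), p$rw)
  off <- 0
  slices <- lapply(1:7, function(i) {
    s <- dy[off + seq_len(widths[i]), , , , drop = FALSE]
    off <<- off + widths[i]
    s
  })
  for (i in 1:4) {
    tb <- tconv_b(p$tW[[i]], cache$z[[i]], slices[[i]], p$dilations[i])
    g$tW[[i]] <- tb$dW
    lb <- lin_b(p$bW[[i]], x, tb$dx)
    g$bW[[i]] <- lb$dW
    dx <- dx + lb$dx
  }
  lb <- lin_b(p$oneW, x, slices[[5]])
  g$oneW <- lb$dW
  dx <- dx + lb$dx
  dzp <- maxpool_t_b(slices[[6]], cache$mp)
  lb <- lin_b(p$pW, x, dzp)
  g$pW <- lb$dW
  dx <- dx + lb$dx
  if (is.null(p$rW)) dx <- dx + slices[[7]]
  else {
    lb <- lin_b(p$rW, x, slices[[7]])
    g$rW <- lb$dW
    dx <- dx + lb$dx
  }
  list(dx = dx, grads = g)
}

#' Inter-temporal attention parameters
#'
#' @param c channel count of the block input.
#' @param r reduction ratio of the shared bottleneck FC (hidden width
#'   `max(1, floor(c/r))`).
#' @param gate_bias initial bias of the two sigmoid score FCs. The
#'   default +2 opens the gates (sigmoid ~ 0.88) so the block starts
#'   close to an identity map — the standard open-gate initialization of
#'   gated architectures; at 0 a stack of blocks would attenuate the
#'   signal by ~4x per module at the start of training.
#' @return Parameter list for [attention_block()].
#' @export
attention_params <- function(c, r = 4, gate_bias = 2) {
  if (r > c) stop("reduction ratio exceeds the channel count")
  cr <- max(1L, c %/% r)
  list(W0 = he_mat(cr, c, gain = 1), b0 = numeric(cr),
       gamma = rep(1, cr), beta = numeric(cr),
       Wt = he_mat(c, cr, gain = 1), bt = rep(gate_bias, c),
       Ws = he_mat(c, cr, gain = 1), bs = rep(gate_bias, c),
       r = r, cr = cr, c = c)
}

# max over an axis of a (C, T, V, B) array, returning value + argmax index
max_over <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  perm <- c(axis, setdiff(1:4, axis))
  xp <- aperm(x, perm)
  dim(xp) <- c(n, prod(d[-axis]))
  best <- xp[1, ]
  idx <- rep(1L, length(best))
  for (i in seq_len(n)[-1]) {
    better <- xp[i, ] > best
    best[better] <- xp[i, better]
    idx[better] <- i
  }
  val <- array(best, d[-axis])
  list(y = val, idx = idx, dims = d, axis = axis)
}

max_over_b <- function(dy, cache) {
  d <- cache$dims
  axis <- cache$axis
  n <- d[axis]
  dxp <- matrix(0, n, prod(d[-axis]))
  dxp[cbind(cache$idx, seq_along(cache$idx))] <- as.vector(dy)
  dim(dxp) <- c(n, d[-axis])
  aperm(dxp, order(c(axis, setdiff(1:4, axis))))
}

attention_f <- function(x, p, training = FALSE, state = NULL) {
  d <- dim(x)           # (C, T, V, B)
  tt <- d[2]; v <- d[3]; b <- d[4]
  if (is.null(state)) state <- list(mean = numeric(p$cr), var = rep(1, p$cr))
  gt <- max_over(x, 2)  # electrode descriptor (C, V, B)
  gs <- max_over(x, 3)  # frame descriptor (C, T, B)
  fcat <- array(0, c(d[1], v + tt, b))
  fcat[, seq_len(v), ] <- gt$y
  fcat[, v + seq_len(tt), ] <- gs$y
  h1 <- lin_f(p$W0, fcat, p$b0)
  bn <- bn_f(h1, p$gamma, p$beta, training, state)
  sg <- sigm(bn$y)
  h3 <- bn$y * sg                               # Swish
  helec <- h3[, seq_len(v), , drop = FALSE]
  hframe <- h3[, v + seq_len(tt), , drop = FALSE]
  epre <- lin_f(p$Ws, helec, p$bs)
  fpre <- lin_f(p$Wt, hframe, p$bt)
  escore <- sigm(epre)                          # (C, V, B)
  fscore <- sigm(fpre)                          # (C, T, B)
  fx <- aperm(array(fscore, c(d[1], tt, b, v)), c(1, 2, 4, 3))
  ex <- aperm(array(escore, c(d[1], v, b, tt)), c(1, 4, 2, 3))
  y <- x * fx * ex
  list(y = y,
       cache = list(x = x, gt = gt, gs = gs, fcat = fcat, bn = bn$cache,
                    h2 = bn$y, sg = sg, helec = helec, hframe = hframe,
                    escore = escore, fscore = fscore, fx = fx, ex = ex,
                    d = d),
       state = bn$state)
}

attention_b <- function(dy, p, cache) {
  d <- cache$d
  tt <- d[2]; v <- d[3]
  dx <- dy * cache$fx * cache$ex                 # direct path
  dm_f <- dy * cache$x * cache$ex                # d wrt expanded fscore
  dm_e <- dy * cache$x * cache$fx
  dfscore <- colSums(aperm(dm_f, c(3, 1, 2, 4)))  # sum over V -> (C, T, B)
  descore <- colSums(aperm(dm_e, c(2, 1, 3, 4)))  # sum over T -> (C, V, B)
  dfpre <- dfscore * cache$fscore * (1 - cache$fscore)
  depre <- descore * cache$escore * (1 - cache$escore)
  gt_b <- lin_b(p$Wt, cache$hframe, dfpre, bias = TRUE)
  gs_b <- lin_b(p$Ws, cache$helec, depre, bias = TRUE)
  dh3 <- array(0, dim(cache$h2))
  dh3[, seq_len(v), ] <- gs_b$dx
  dh3[, v + seq_len(tt), ] <- gt_b$dx
  dh2 <- dh3 * (cache$sg + cache$h2 * cache$sg * (1 - cache$sg))
  bnb <- bn_b(dh2, cache$bn)
  w0_b <- lin_b(p$W0, cache$fcat, bnb$dx, bias = TRUE)
  dgt <- w0_b$dx[, seq_len(v), , drop = FALSE]
  dgs <- w0_b$dx[, v + seq_len(tt), , drop = FALSE]
  dx <- dx + max_over_b(dgt, cache$gt) + max_over_b(dgs, cache$gs)
  grads <- list(W0 = w0_b$dW, b0 = w0_b$db, gamma = bnb$dgamma,
                beta = bnb$dbeta, Wt = gt_b$dW, bt = gt_b$db,
                Ws = gs_b$dW, bs = gs_b$db)
  list(dx = dx, grads = grads)
}

# --- exported single-sample block wrappers -----------------------------------

as4 <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  x
}

drop4 <- function(y, had3) if (had3) array(y, dim(y)[1:3]) else y

#' Static-branch graph convolution
#'
#' Per frame t computes \eqn{\lambda((G + G_m) X_t \mu)} with
#' \eqn{\lambda} = ReLU: the montage graph (plus trainable mask) aggregates
#' electrode features, followed by a linear channel map.
#'
#' @param x array (C, T, V) or (C, T, V, B) of node features.
#' @param A static adjacency, typically
#'   `normalize_adjacency(Gp)` plus the mask `Gm` (V x V).
#' @param mu weight matrix (C_in x C_out).
#' @return Array of the same frame/electrode shape with C_out channels.
#' @export
gcn_static <- function(x, A, mu) {
  had3 <- length(dim(x)) == 3
  x <- as4(x)
  if (dim(x)[3] != nrow(A)) stop("electrode axis does not match A")
  if (dim(x)[1] != nrow(mu)) stop("channel axis does not match mu")
  drop4(relu_f(gapply_f(A, lin_f(t(mu), x))), had3)
}

#' Dynamic-branch graph convolution
#'
#' Per frame t computes \eqn{G_d X_t \mu'} with no activation; the
#' per-sample graph `Gd` replaces the fixed montage graph and its kernel
#' is not shared with the static branch.
#'
#' @param x array (C, T, V) or (C, T, V, B).
#' @param Gd dynamic graph: (V, V) shared across frames, or (V, V, T)
#'   (or (V, V, T*B)) per frame.
#' @param mu2 weight matrix (C_in x C_out).
#' @return Array with C_out channels.
#' @export
gcn_dynamic <- function(x, Gd, mu2) {
  had3 <- length(dim(x)) == 3
  x <- as4(x)
  d <- dim(x)
  m <- d[2] * d[4]
  if (length(dim(Gd)) == 2) Gd <- array(Gd, c(dim(Gd), m))
  if (dim(Gd)[3] != m) stop("Gd must supply one graph per frame")
  drop4(gapply_dyn_f(Gd, lin_f(t(mu2), x)), had3)
}

#' Fuse the static and dynamic GCN branches
#'
#' Weighted sum `dyn + phi * stat` with the balance `phi` in [0, 1]:
#' phi = 0 keeps only the adaptive branch, phi = 1 adds the full static
#' topology.
#'
#' @param stat,dyn equally shaped arrays.
#' @param phi balance scalar in [0, 1].
#' @return Array of the same shape.
#' @export
gcn_fuse <- function(stat, dyn, phi) {
  if (!isTRUE(all.equal(dim(stat), dim(dyn))))
    stop("branch outputs must have equal shapes")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  dyn + phi * stat
}

#' Multi-scale temporal convolution block
#'
#' Seven parallel branches over the frame axis (four dilated 3x1
#' convolutions behind 1x1 bottlenecks, a 1x1-only branch, a max-pool
#' branch, and a residual branch), concatenated on the channel axis, plus
#' a module-level residual. The frame extent is preserved.
#'
#' @param x array (C, T, V) or (C, T, V, B).
#' @param params from [mstcn_params()].
#' @return Array with `params$c_out` channels.
#' @export
mstcn <- function(x, params) {
  had3 <- length(dim(x)) == 3
  x <- as4(x)
  if (dim(x)[1] != params$c_in) stop("channel axis does not match params")
  drop4(mstcn_f(x, params)$y, had3)
}

#' Inter-temporal attention block
#'
#' Joint frame-by-electrode reweighting: max-pool descriptors over the
#' frame and electrode axes are concatenated, squeezed by a shared
#' bottleneck FC (Swish), split, expanded back by two independent FCs
#' (sigmoid), and combined per channel as the outer product of frame and
#' electrode scores; the input is multiplied elementwise by the resulting
#' map, so the output is bounded by the input in magnitude.
#'
#' @param x array (C, T, V) or (C, T, V, B).
#' @param params from [attention_params()].
#' @param training use batch statistics in the internal normalization
#'   (default FALSE: running statistics).
#' @return Array of the same shape as `x`.
#' @export
attention_block <- function(x, params, training = FALSE) {
  had3 <- length(dim(x)) == 3
  x <- as4(x)
  if (dim(x)[1] != params$c) stop("channel axis does not match params")
  drop4(attention_f(x, params, training)$y, had3)
}

#' Classifier head: global average pooling + linear softmax
#'
#' @param x array (C, T, V) or (C, T, V, B).
#' @param W weight matrix (n_classes x C).
#' @param b bias vector (n_classes).
#' @return Probability matrix (n_classes x B), columns summing to 1.
#' @export
classify_head <- function(x, W, b) {
  x <- as4(x)
  d <- dim(x)
  g <- colMeans(matrix(aperm(x, c(2, 3, 1, 4)), d[2] * d[3], d[1] * d[4]))
  dim(g) <- c(d[1], d[4])
  logits <- W %*% g + b
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(e, 2, colSums(e), "/")
}
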