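# Network assembly: nine (configurably fewer) ST-GCN modules, each a fused
# static/dynamic graph convolution, a multi-scale temporal block, and an
# optional inter-temporal attention block, followed by a global-average
# softmax head. stgcn() is the user-facing fitting function.

#' Network configuration
#'
#' @param n_electrodes number of electrodes V.
#' @param n_bands number of differential-entropy bands Fde (input
#'   channels).
#' @param context_len temporal context length Tn (default 5).
#' @param channels output channel plan, one entry per module (default the
#'   nine-module plan 66,66,66,132,132,132,264,264,264).
#' @param attention include the attention block after every module
#'   (default TRUE; FALSE gives the ablated GCN+TCN model).
#' @param phi static/dynamic balance in [0, 1] (default 0.5).
#' @param reduction attention reduction ratio r (default 4). The shared
#'   FC's hidden width is `floor(C/r)` (at least 1), so channel counts
#'   not divisible by r are allowed.
#' @param dropout dropout probability after each module (default 0.2).
#' @param dilations four dilation factors for the dilated TCN branches.
#' @param static_norm normalization of the static branch: `"pre"`
#'   (default; the mask is added to the degree-normalized montage graph),
#'   `"none"` (raw Gp + Gm), or `"post"` (Gp + Gm normalized together; the
#'   mask is then held fixed because the degree normalization is treated
#'   as part of graph construction, not of the differentiable path).
#' @param gd_agg dynamic graph per `"frame"` (default) or averaged per
#'   sample (`"mean"`).
#' @param n_classes number of output classes (default 5).
#' @param class_weights optional per-class loss weights (default NULL:
#'   unweighted cross-entropy; `"balanced"` computes inverse-frequency
#'   weights from the training labels).
#' @return Object of class `stgcn_config`.
#' @export
stgcn_config <- function(n_electrodes, n_bands, context_len = 5,
                         channels = c(66, 66, 66, 132, 132, 132,
                                      264, 264, 264),
                         attention = TRUE, phi = 0.5, reduction = 4,
                         dropout = 0.2, dilations = 1:4,
                         static_norm = c("pre", "none", "post"),
                         gd_agg = c("frame", "mean"), n_classes = 5,
                         class_weights = NULL) {
  static_norm <- match.arg(static_norm)
  gd_agg <- match.arg(gd_agg)
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (any(channels < 7)) stop("every channel plan entry must be >= 7")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (length(dilations) != 4) stop("exactly four dilation factors required")
  structure(list(n_electrodes = n_electrodes, n_bands = n_bands,
                 context_len = context_len, channels = channels,
                 attention = attention, phi = phi, reduction = reduction,
                 dropout = dropout, dilations = dilations,
                 static_norm = static_norm, gd_agg = gd_agg,
                 n_classes = n_classes, class_weights = class_weights),
            class = "stgcn_config")
}

init_bn_state <- function(n) list(mean = numeric(n), var = rep(1, n))

#' Initialize network parameters
#'
#' @param config an `stgcn_config`.
#' @param Gp physical adjacency (V x V); defaults to the preset matching
#'   `montage` via [physical_adjacency()].
#' @param montage electrode labels (used when `Gp` is NULL).
#' @param seed RNG seed for the weight draws.
#' @return Untrained model object of class `stgcn`.
#' @export
stgcn_init <- function(config, Gp = NULL, montage = NULL, seed = NULL) {
  stopifnot(inherits(config, "stgcn_config"))
  if (!is.null(seed)) set.seed(seed)
  v <- config$n_electrodes
  if (is.null(Gp)) {
    if (is.null(montage)) montage <- paste0("E", seq_len(v))
    Gp <- tryCatch(physical_adjacency(montage),
                   error = function(e) {
                     ring <- matrix(0, v, v)
                     if (v > 1) for (i in seq_len(v))
                       ring[i, i %% v + 1] <- ring[i %% v + 1, i] <- 1
                     ring
                   })
  }
  if (nrow(Gp) != v) stop("Gp size does not match n_electrodes")
  A0 <- switch(config$static_norm,
               pre = normalize_adjacency(Gp),
               none = Gp,
               post = Gp)
  cins <- c(config$n_bands, utils::head(config$channels, -1))
  modules <- vector("list", length(config$channels))
  bn <- vector("list", length(config$channels))
  for (i in seq_along(config$channels)) {
    ci <- cins[i]; co <- config$channels[i]
    modules[[i]] <- list(
      mu = he_mat(ci, ci, gain = 1),
      mu2 = he_mat(ci, ci, gain = 1),
      w = stats::runif(ci, 0.01, 0.1),
      g1 = rep(1, ci), b1 = numeric(ci),
      tcn = mstcn_params(ci, co, config$dilations),
      g2 = rep(1, co), b2 = numeric(co))
    if (config$attention)
      modules[[i]]$att <- attention_params(co, config$reduction)
    bn[[i]] <- list(bn1 = init_bn_state(ci), bn2 = init_bn_state(co),
                    att = init_bn_state(
                      max(1L, co %/% config$reduction)))
  }
  cl <- utils::tail(config$channels, 1)
  structure(list(config = config, Gp = Gp, A0 = A0,
                 Gm = matrix(0, v, v),
                 modules = modules,
                 head = list(W = he_mat(config$n_classes, cl, gain = 1) / 10,
                             b = numeric(config$n_classes)),
                 bn = bn, trained = FALSE, loss_trace = numeric(0),
                 levels = stage_levels()[seq_len(config$n_classes)]),
            class = "stgcn")
}

static_adjacency <- function(model) {
  if (model$config$static_norm == "post")
    normalize_adjacency(model$Gp + model$Gm)
  else model$A0 + model$Gm
}

module_f <- function(x, mp, Astat, cfg, training, bn_state,
                     drop_p = 0) {
  d <- dim(x)
  # dynamic graph from this module's input features
  x3 <- aperm(x, c(1, 3, 2, 4)); dim(x3) <- c(d[1], d[3], d[2] * d[4])
  dg <- dyngraph_forward(x3, mp$w)
  Gd <- dg$Gd
  if (cfg$gd_agg == "mean") {
    g4 <- array(Gd, c(d[3], d[3], d[2], d[4]))
    gm <- colMeans(aperm(g4, c(3, 1, 2, 4)))            # mean over T
    Gd <- array(aperm(array(gm, c(d[3], d[3], d[4], d[2])),
                      c(1, 2, 4, 3)), c(d[3], d[3], d[2] * d[4]))
  }
  c1 <- lin_f(t(mp$mu), x)
  stat_pre <- gapply_f(Astat, c1)
  stat <- relu_f(stat_pre)
  c2 <- lin_f(t(mp$mu2), x)
  dyn <- gapply_dyn_f(Gd, c2)
  fuse <- dyn + cfg$phi * stat
  bn1 <- bn_f(fuse, mp$g1, mp$b1, training, bn_state$bn1)
  tc <- mstcn_f(bn1$y, mp$tcn)
  bn2 <- bn_f(tc$y, mp$g2, mp$b2, training, bn_state$bn2)
  y <- relu_f(bn2$y)
  att <- NULL
  if (!is.null(mp$att)) {
    att <- attention_f(y, mp$att, training, bn_state$att)
    bn_state$att <- att$state
    y_att <- att$y
  } else y_att <- y
  mask <- NULL
  if (training && drop_p > 0) {
    mask <- (array(stats::runif(length(y_att)), dim(y_att)) >= drop_p) /
      (1 - drop_p)
    y_out <- y_att * mask
  } else y_out <- y_att
  bn_state$bn1 <- bn1$state
  bn_state$bn2 <- bn2$state
  list(y = y_out, state = bn_state,
       cache = list(x = x, dg = dg, Gd = Gd, c1 = c1, stat_pre = stat_pre,
                    stat = stat, c2 = c2, bn1 = bn1$cache, tc = tc$cache,
                    bn2 = bn2$cache, bn2y = bn2$y, att = att$cache,
                    mask = mask, d = d))
}

module_b <- function(dy, mp, Astat, cfg, cache, train_mask = TRUE) {
  d <- cache$d
  g <- list()
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  if (!is.null(mp$att)) {
    ab <- attention_b(dy, mp$att, cache$att)
    g$att <- ab$grads
    dy <- ab$dx
  }
  dy <- dy * (cache$bn2y > 0)
  b2 <- bn_b(dy, cache$bn2)
  g$g2 <- b2$dgamma; g$b2 <- b2$dbeta
  tb <- mstcn_b(b2$dx, mp$tcn, cache$tc)
  g$tcn <- tb$grads
  b1 <- bn_b(tb$dx, cache$bn1)
  g$g1 <- b1$dgamma; g$b1 <- b1$dbeta
  dfuse <- b1$dx
  # static branch
  dstat <- cfg$phi * dfuse * (cache$stat_pre > 0)
  gs <- gapply_b(Astat, cache$c1, dstat)
  dGm <- if (cfg$static_norm == "post") NULL else gs$dA
  lc1 <- lin_b(t(mp$mu), cache$x, gs$dx)
  g$mu <- t(lc1$dW)
  dx <- lc1$dx
  # dynamic branch
  gd_b <- gapply_dyn_b(cache$Gd, cache$c2, dfuse)
  lc2 <- lin_b(t(mp$mu2), cache$x, gd_b$dx)
  g$mu2 <- t(lc2$dW)
  dx <- dx + lc2$dx
  dGd <- gd_b$dGd
  if (cfg$gd_agg == "mean") {
    # each frame's pre-average graph receives the mean of the frame grads
    dg4 <- array(dGd, c(d[3], d[3], d[2], d[4]))
    dgm <- colMeans(aperm(dg4, c(3, 1, 2, 4)))
    dGd <- array(aperm(array(dgm, c(d[3], d[3], d[4], d[2])),
                       c(1, 2, 4, 3)), c(d[3], d[3], d[2] * d[4]))
  }
  dyg <- dyngraph_backward(dGd, cache$dg, mp$w)
  g$w <- dyg$dw
  dx3 <- dyg$dX3
  dim(dx3) <- c(d[1], d[3], d[2], d[4])
  dx <- dx + aperm(dx3, c(1, 3, 2, 4))
  list(dx = dx, grads = g, dGm = dGm)
}

network_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  Astat <- static_adjacency(model)
  caches <- vector("list", length(model$modules))
  for (i in seq_along(model$modules)) {
    mf <- module_f(x, model$modules[[i]], Astat, cfg, training,
                   model$bn[[i]], cfg$dropout)
    x <- mf$y
    caches[[i]] <- mf$cache
    if (training) model$bn[[i]] <- mf$state
  }
  d <- dim(x)
  gpool <- colMeans(matrix(aperm(x, c(2, 3, 1, 4)),
                           d[2] * d[3], d[1] * d[4]))
  dim(gpool) <- c(d[1], d[4])
  logits <- model$head$W %*% gpool + model$head$b
  list(logits = logits, caches = caches, gpool = gpool, feat_dim = d,
       model = model)
}

softmax_probs <- function(logits) {
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

# cross-entropy over a batch; y integer class indices (1-based)
ce_loss <- function(logits, y, class_weights = NULL) {
  p <- softmax_probs(logits)
  b <- ncol(logits)
  wy <- if (is.null(class_weights)) rep(1, b) else class_weights[y]
  py <- p[cbind(y, seq_len(b))]
  loss <- sum(-log(pmax(py, 1e-12)) * wy) / sum(wy)
  dlog <- p
  dlog[cbind(y, seq_len(b))] <- dlog[cbind(y, seq_len(b))] - 1
  dlog <- sweep(dlog, 2, wy / sum(wy), "*")
  list(loss = loss, p = p, dlogits = dlog)
}

network_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  Astat <- static_adjacency(model)
  d <- fwd$feat_dim
  grads <- list(head = list(W = dlogits %*% t(fwd$gpool),
                            b = rowSums(dlogits)),
                modules = vector("list", length(model$modules)),
                Gm = matrix(0, nrow(model$Gm), ncol(model$Gm)))
  dg <- t(model$head$W) %*% dlogits      # (C, B)
  dx <- aperm(array(rep(dg, each = d[2] * d[3]) / (d[2] * d[3]),
                    c(d[2], d[3], d[1], d[4])), c(3, 1, 2, 4))
  has_gm <- cfg$static_norm != "post"
  for (i in rev(seq_along(model$modules))) {
    mb <- module_b(dx, model$modules[[i]], Astat, cfg, fwd$caches[[i]])
    grads$modules[[i]] <- mb$grads
    if (has_gm && !is.null(mb$dGm)) grads$Gm <- grads$Gm + mb$dGm
    dx <- mb$dx
  }
  if (!has_gm) grads$Gm <- NULL
  grads
}

# loss + gradients of everything, for one batch (used by the trainer and
# by finite-difference tests)
network_loss_grad <- function(model, x, y, training = TRUE) {
  fwd <- network_forward(model, x, training)
  cl <- ce_loss(fwd$logits, y, model$config$class_weights_vec)
  grads <- network_backward(model, fwd, cl$dlogits)
  list(loss = cl$loss, grads = grads, model = fwd$model, p = cl$p)
}

#' Fit the sleep staging network
#'
#' The main entry point: takes feature contexts (from
#' [extract_features()] / [assemble_contexts()] or the matching array
#' layout), initializes the ST-GCN and trains it with Adam under the
#' step-decayed learning rate schedule.
#'
#' @param x a `feature_contexts` object, or an array
#'   (electrodes x bands x Tn x samples).
#' @param y stage labels (ignored when `x` is a `feature_contexts`).
#' @param config an [stgcn_config()]; a compact default is built from the
#'   data dimensions when omitted.
#' @param Gp optional physical adjacency.
#' @param montage optional electrode labels for the montage preset.
#' @param epochs,batch_size,lr,lr_steps,seed training controls; see
#'   [train_control()].
#' @param control a [train_control()] list overriding the individual
#'   arguments.
#' @param verbose print the loss every few epochs.
#' @return A fitted object of class `stgcn` with the loss trace in
#'   `$loss_trace`.
#' @seealso [predict.stgcn()], [evaluate_confusion()]
#' @export
stgcn <- function(x, y = NULL, config = NULL, Gp = NULL, montage = NULL,
                  epochs = 120, batch_size = 64, lr = 1e-3,
                  lr_steps = c(30, 60, 90), seed = 1, control = NULL,
                  verbose = FALSE) {
  if (inherits(x, "feature_contexts")) { y <- x$y; x <- x$x }
  if (length(dim(x)) != 4) stop("x must be electrodes x bands x Tn x samples")
  if (is.null(control))
    control <- train_control(epochs = epochs, batch_size = batch_size,
                             lr = lr, lr_steps = lr_steps, seed = seed)
  if (is.null(config))
    config <- stgcn_config(n_electrodes = dim(x)[1], n_bands = dim(x)[2],
                           context_len = dim(x)[3])
  model <- stgcn_init(config, Gp = Gp, montage = montage,
                      seed = control$seed)
  train_stgcn(model, x, y, control, verbose = verbose)
}

#' Training hyperparameters
#'
#' Defaults follow the staging experiment: Adam, batch size 64, 120
#' epochs, initial learning rate 0.001 divided by 10 at epochs 30, 60
#' and 90.
#'
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param lr_steps epochs at which the rate is divided by 10 (sorted,
#'   all below `epochs`... larger steps simply never trigger).
#' @param seed RNG seed governing initialization and shuffling.
#' @return List of class `train_control`.
#' @export
train_control <- function(epochs = 120, batch_size = 64, lr = 1e-3,
                          lr_steps = c(30, 60, 90), seed = 1) {
  if (is.unsorted(lr_steps)) stop("lr_steps must be ascending")
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 lr_steps = lr_steps, seed = seed),
            class = "train_control")
}

#' Learning rate at a given epoch under the step-decay schedule
#'
#' @param epoch 1-based epoch number.
#' @param control a [train_control()].
#' @return The learning rate `lr * 10^-(number of steps reached)`.
#' @export
lr_at_epoch <- function(epoch, control = train_control()) {
  control$lr * 10^(-sum(epoch >= control$lr_steps))
}
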