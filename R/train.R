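# Adam optimization over the nested parameter list, the epoch loop with
# step-decayed learning rate, subject-wise cross-validation folds, and the
# S3 methods of the fitted model.

# Recursively update params by the grads structure (grads is a sub-tree of
# params; metadata fields never appear in grads and are left untouched).
adam_walk <- function(p, g, m, v, lr, b1, b2, eps, bc1, bc2) {
  if (is.null(g)) return(list(p = p, m = m, v = v))
  if (is.list(g)) {
    if (is.null(m)) m <- vector("list", length(g))
    if (is.null(v)) v <- vector("list", length(g))
    keys <- if (!is.null(names(g))) names(g) else seq_along(g)
    for (k in keys) {
      r <- adam_walk(p[[k]], g[[k]], m[[k]], v[[k]], lr, b1, b2, eps,
                     bc1, bc2)
      p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  if (is.null(m)) { m <- g * 0; v <- g * 0 }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  list(p = p, m = m, v = v)
}

adam_step <- function(model, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  tree <- list(modules = model$modules, head = model$head, Gm = model$Gm)
  gtree <- list(modules = grads$modules, head = grads$head, Gm = grads$Gm)
  r <- adam_walk(tree, gtree, opt$m, opt$v, lr, b1, b2, eps, bc1, bc2)
  model$modules <- r$p$modules
  model$head <- r$p$head
  if (!is.null(grads$Gm)) model$Gm <- r$p$Gm
  opt$m <- r$m; opt$v <- r$v
  list(model = model, opt = opt)
}

labels_to_idx <- function(y, levels) {
  idx <- match(as.character(y), levels)
  if (anyNA(idx))
    stop("labels outside the class set: ",
         paste(unique(y[is.na(idx)]), collapse = ", "))
  idx
}

#' Train an initialized network
#'
#' Minibatch Adam with the step-decay learning-rate schedule of
#' [train_control()]. Aborts with a diagnostic if the loss diverges to
#' NaN. One global seed (in `control`) governs shuffling; initialization
#' is seeded by [stgcn_init()].
#'
#' @param model an `stgcn` model from [stgcn_init()].
#' @param x array (electrodes x bands x Tn x samples) or a
#'   `feature_contexts`.
#' @param y stage labels.
#' @param control a [train_control()].
#' @param verbose print progress.
#' @return The trained model (class `stgcn`) with `$loss_trace`.
#' @export
train_stgcn <- function(model, x, y = NULL, control = train_control(),
                        verbose = FALSE) {
  if (inherits(x, "feature_contexts")) { y <- x$y; x <- x$x }
  xi <- aperm(x, c(2, 3, 1, 4))   # -> (C = bands, T, V, B)
  yidx <- labels_to_idx(y, model$levels)
  n <- dim(xi)[4]
  if (n < 1) stop("no training samples")
  cw <- model$config$class_weights
  if (identical(cw, "balanced")) {
    freq <- tabulate(yidx, model$config$n_classes)
    w <- ifelse(freq > 0, 1 / freq, 0)
    model$config$class_weights_vec <- w / mean(w[freq > 0])
  } else if (is.numeric(cw)) {
    model$config$class_weights_vec <- cw
  } else model$config$class_weights_vec <- NULL
  set.seed(control$seed + 1L)
  opt <- list(t = 0, m = NULL, v = NULL)
  trace <- numeric(control$epochs)
  for (ep in seq_len(control$epochs)) {
    lr <- lr_at_epoch(ep, control)
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = control$batch_size)) {
      sel <- ord[start:min(start + control$batch_size - 1, n)]
      xb <- xi[, , , sel, drop = FALSE]
      lg <- network_loss_grad(model, xb, yidx[sel], training = TRUE)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      model <- lg$model          # updated BN running stats
      st <- adam_step(model, lg$grads, opt, lr)
      model <- st$model
      opt <- st$opt
      losses <- c(losses, lg$loss)
    }
    trace[ep] <- mean(losses)
    if (verbose && (ep %% 10 == 0 || ep == 1))
      message(sprintf("epoch %3d  lr %.1e  loss %.4f", ep, lr, trace[ep]))
  }
  model$loss_trace <- c(model$loss_trace, trace)
  model$trained <- TRUE
  model$control <- control
  model
}

#' Subject-wise cross-validation folds
#'
#' Each fold's test set is the recordings of exactly one subject;
#' with `k` equal to the number of subjects this is
#' leave-one-subject-out. The assignment is deterministic given the
#' subject ordering (subjects sorted, first `k` used as test subjects).
#'
#' @param subject_ids character/factor vector, one entry per sample (or
#'   per recording).
#' @param k number of folds; must not exceed the number of distinct
#'   subjects.
#' @return List of `k` lists with integer index vectors `train` and
#'   `test`.
#' @export
subject_folds <- function(subject_ids, k) {
  subjects <- sort(unique(as.character(subject_ids)))
  if (k > length(subjects))
    stop("k exceeds the number of distinct subjects (",
         length(subjects), ")")
  if (k < 1) stop("k must be positive")
  lapply(subjects[seq_len(k)], function(s) {
    test <- which(subject_ids == s)
    list(subject = s, train = setdiff(seq_along(subject_ids), test),
         test = test)
  })
}

# --- S3 methods --------------------------------------------------------------

#' Predict sleep stages
#'
#' @param object a fitted `stgcn`.
#' @param newdata a `feature_contexts` or array
#'   (electrodes x bands x Tn x samples).
#' @param type `"class"` (default) for stage labels, `"prob"` for the
#'   samples-x-classes probability matrix.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Character vector of stages, or a probability matrix.
#' @export
predict.stgcn <- function(object, newdata, type = c("class", "prob"),
                          batch_size = 256, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_contexts")) newdata <- newdata$x
  if (length(dim(newdata)) == 3) dim(newdata) <- c(dim(newdata), 1)
  xi <- aperm(newdata, c(2, 3, 1, 4))
  n <- dim(xi)[4]
  probs <- matrix(NA_real_, n, object$config$n_classes,
                  dimnames = list(NULL, object$levels))
  for (start in seq(1, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, n)
    fwd <- network_forward(object, xi[, , , sel, drop = FALSE],
                           training = FALSE)
    probs[sel, ] <- t(softmax_probs(fwd$logits))
  }
  if (type == "prob") probs
  else object$levels[max.col(probs, ties.method = "first")]
}

#' @export
print.stgcn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "ST-GCN sleep stager: %d module(s), channels [%s], %d electrodes, %d bands, Tn=%d\n",
    length(cfg$channels), paste(cfg$channels, collapse = ","),
    cfg$n_electrodes, cfg$n_bands, cfg$context_len))
  cat(sprintf("  attention: %s | phi = %g | static_norm = %s | dropout = %g\n",
              if (cfg$attention) "on" else "off", cfg$phi,
              cfg$static_norm, cfg$dropout))
  cat(sprintf("  %s, %s parameters\n",
              if (x$trained) sprintf("trained (%d epochs, final loss %.4f)",
                                     length(x$loss_trace),
                                     utils::tail(x$loss_trace, 1))
              else "untrained",
              format(length(unlist(coef(x))), big.mark = ",")))
  invisible(x)
}

#' @export
summary.stgcn <- function(object, ...) {
  print(object)
  cat("  per-module parameter counts:\n")
  for (i in seq_along(object$modules))
    cat(sprintf("    module %d: %d\n", i,
                length(unlist(object$modules[[i]][
                  !(names(object$modules[[i]]) %in% c())]))))
  invisible(object)
}

#' Model parameters
#'
#' @param object a `stgcn`.
#' @param ... unused.
#' @return Nested list of all learnable arrays (modules, mask `Gm`,
#'   classifier head).
#' @export
coef.stgcn <- function(object, ...) {
  strip_meta <- function(p) p[setdiff(names(p),
                                      c("dilations", "b", "rw", "c_in",
                                        "c_out", "r", "cr", "c"))]
  list(Gm = object$Gm,
       modules = lapply(object$modules, function(m) {
         m$tcn <- strip_meta(m$tcn)
         if (!is.null(m$att)) m$att <- strip_meta(m$att)
         m
       }),
       head = object$head)
}

#' @export
plot.stgcn <- function(x, ...) {
  if (!length(x$loss_trace)) stop("model has no loss trace (untrained)")
  graphics::plot(x$loss_trace, type = "l", xlab = "epoch",
                 ylab = "mean training loss",
                 main = "ST-GCN training loss", ...)
  invisible(x)
}

#' Residuals of a fitted stager
#'
#' Deviance-style residuals: \eqn{\sqrt{-2 \log p_{y}}} where
#' \eqn{p_{y}} is the predicted probability of the true stage, signed
#' negative for misclassified epochs.
#'
#' @param object a fitted `stgcn`.
#' @param newdata a `feature_contexts` (with labels) used for evaluation.
#' @param ... unused.
#' @return Numeric vector, one residual per context.
#' @export
residuals.stgcn <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_contexts"))
  p <- predict(object, newdata, type = "prob")
  yidx <- labels_to_idx(newdata$y, object$levels)
  py <- p[cbind(seq_len(nrow(p)), yidx)]
  hit <- max.col(p, ties.method = "first") == yidx
  sqrt(pmax(0, -2 * log(pmax(py, 1e-12)))) * ifelse(hit, 1, -1)
}
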