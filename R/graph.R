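# Electrode graphs. The static branch uses a fixed montage adjacency Gp
# (symmetrically degree-normalized) plus a freely trainable mask Gm; the
# dynamic branch scores every ordered electrode pair from the current
# feature matrix and row-normalizes with a softmax, so the graph adapts to
# each input sample.

montage_presets <- function() {
  list(
    "isruc6" = list(
      labels = c("F3", "F4", "C3", "C4", "O1", "O2"),
      edges = list(c("F3", "F4"), c("F3", "C3"), c("F4", "C4"),
                   c("C3", "C4"), c("C3", "O1"), c("C4", "O2"),
                   c("O1", "O2"))),
    "sleepedf2" = list(
      labels = c("Fpz-Cz", "Pz-Oz"),
      edges = list(c("Fpz-Cz", "Pz-Oz")))
  )
}

#' Physical electrode adjacency matrix
#'
#' Builds the 0/1 symmetric adjacency of the montage: either a named
#' preset (`"isruc6"` for the six-channel F/C/O referential montage,
#' `"sleepedf2"` for the two-derivation sleep-EDF montage) or a custom
#' undirected edge list over arbitrary labels. Referential suffixes
#' ("C3-A2" etc.) are stripped before matching preset labels.
#'
#' @param montage character vector of electrode labels.
#' @param edges optional list of length-2 character vectors (undirected
#'   edges). Required when the montage matches no preset.
#' @return N x N 0/1 matrix, symmetric with zero diagonal, dimnames =
#'   montage labels.
#' @examples
#' physical_adjacency(c("F3", "F4", "C3", "C4", "O1", "O2"))
#' @export
physical_adjacency <- function(montage, edges = NULL) {
  montage <- as.character(montage)
  n <- length(montage)
  base <- sub("-(A1|A2|M1|M2)$", "", montage)
  if (is.null(edges)) {
    for (p in montage_presets()) {
      if (all(base %in% p$labels)) { edges <- p$edges; break }
      if (all(montage %in% p$labels)) { edges <- p$edges; base <- montage; break }
    }
    if (is.null(edges) && n == 2) edges <- list(montage)
    if (is.null(edges) && n == 1) edges <- list()
    if (is.null(edges))
      stop("unknown montage and no edge list supplied")
  }
  A <- matrix(0, n, n, dimnames = list(montage, montage))
  for (e in edges) {
    i <- match(e[1], base); j <- match(e[2], base)
    if (is.na(i)) i <- match(e[1], montage)
    if (is.na(j)) j <- match(e[2], montage)
    if (is.na(i) || is.na(j)) next
    if (i != j) { A[i, j] <- 1; A[j, i] <- 1 }
  }
  A
}

#' Symmetric degree normalization with self-loops
#'
#' Returns \eqn{\tilde D^{-1/2} (A + I) \tilde D^{-1/2}} where
#' \eqn{\tilde D} is the diagonal degree matrix of \eqn{A + I}: the
#' standard GCN propagation matrix. Its spectral radius is at most 1.
#'
#' @param A square non-negative matrix.
#' @return Normalized matrix of the same shape.
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2))  # all entries 0.5
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (any(A < 0)) stop("A must be non-negative")
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  Dm <- diag(1 / sqrt(d), nrow(A))
  Dm %*% At %*% Dm
}

# --- dynamic graph -----------------------------------------------------------
#
# For node features X (V x F per frame) the ordered-pair score is
# s(i, j) = relu(w' |x_i - x_j|), and Gd(i, .) = softmax over j of s(i, .).
# Rows sum to one; identical node features give uniform rows. The forward
# over a stack of frames keeps every intermediate needed for backprop.

#' Per-sample dynamic electrode graph
#'
#' Edge score between electrodes i and j is a rectified weighted absolute
#' feature difference, row-normalized with a softmax. Identical features
#' give a uniform graph (all entries 1/N).
#'
#' @param X numeric matrix, electrodes x features (one frame).
#' @param w numeric weight vector, length = number of features.
#' @return N x N row-stochastic non-negative matrix.
#' @export
dynamic_graph <- function(X, w) {
  X <- as.matrix(X)
  if (length(w) != ncol(X))
    stop("length(w) must equal the number of node features")
  fw <- dyngraph_forward(array(t(X), c(ncol(X), nrow(X), 1)), w)
  matrix(fw$Gd, nrow(X), nrow(X))
}

# X3: array (F, V, M) of M frames; returns Gd (V, V, M) plus caches.
# Pairwise differences are kept feature-first ((F, V*V, M), ordered-pair
# index i + (j-1)V) so that the w-contraction and its backward are plain
# matrix products with no axis permutation.
dyngraph_forward <- function(X3, w) {
  f <- dim(X3)[1]; v <- dim(X3)[2]; m <- dim(X3)[3]
  ii <- rep(seq_len(v), times = v)
  jj <- rep(seq_len(v), each = v)
  Dif <- X3[, ii, , drop = FALSE] - X3[, jj, , drop = FALSE]  # (F, V*V, M)
  Dabs <- abs(Dif)
  s <- array(as.vector(w %*% matrix(Dabs, f, v * v * m)), c(v, v, m))
  relu_mask <- s > 0
  s <- s * relu_mask
  # row-wise softmax along j (dim 2), numerically stabilized
  mx <- s[, 1, , drop = FALSE]
  for (j in seq_len(v)[-1]) mx <- pmax(mx, s[, j, , drop = FALSE])
  e <- array(0, c(v, v, m))
  for (j in seq_len(v)) e[, j, ] <- exp(s[, j, , drop = FALSE] - mx)
  Z <- e[, 1, , drop = FALSE]
  for (j in seq_len(v)[-1]) Z <- Z + e[, j, , drop = FALSE]
  Gd <- array(0, c(v, v, m))
  for (j in seq_len(v)) Gd[, j, ] <- e[, j, ] / Z[, 1, ]
  list(Gd = Gd, Dabs = Dabs, Dif = Dif, relu_mask = relu_mask,
       dims = c(f = f, v = v, m = m))
}

# Backward: given dGd (V, V, M) and the forward cache, return dX3 (F, V, M)
# and dw (F).
dyngraph_backward <- function(dGd, fw, w) {
  f <- fw$dims[["f"]]; v <- fw$dims[["v"]]; m <- fw$dims[["m"]]
  Gd <- fw$Gd
  # softmax backward per row: ds = Gd * (dGd - sum_j dGd*Gd)
  rowdot <- dGd[, 1, , drop = FALSE] * Gd[, 1, , drop = FALSE]
  for (j in seq_len(v)[-1])
    rowdot <- rowdot + dGd[, j, , drop = FALSE] * Gd[, j, , drop = FALSE]
  ds <- array(0, c(v, v, m))
  for (j in seq_len(v))
    ds[, j, ] <- Gd[, j, ] * (dGd[, j, ] - rowdot[, 1, ])
  ds <- ds * fw$relu_mask
  # s[i,j,fr] = sum_f w[f] * Dabs[f, (i,j), fr]
  dsv <- as.vector(ds)
  dw <- as.vector(matrix(fw$Dabs, f, v * v * m) %*% dsv)
  dDif <- array(outer(w, dsv), dim(fw$Dif)) * sign(fw$Dif)  # (F, V*V, M)
  dX3 <- array(0, c(f, v, m))
  for (j in seq_len(v)) {
    blk <- dDif[, (j - 1) * v + seq_len(v), , drop = FALSE]
    dX3 <- dX3 + blk                     # d/dx_i of |x_i - x_j|, i varies
    acc <- blk[, 1, , drop = FALSE]      # d/dx_j: minus the block's i-sum
    for (i in seq_len(v)[-1]) acc <- acc + blk[, i, , drop = FALSE]
    dX3[, j, ] <- dX3[, j, ] - acc[, 1, ]
  }
  list(dX3 = dX3, dw = dw)
}
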