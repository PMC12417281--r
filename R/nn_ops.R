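# Minimal neural-network machinery on BLAS matrix ops with hand-derived
# backprop. Feature matrices use a flat voxel layout:
#   temporal tensors [V*T, C] with row (t-1)*V + v  (voxel-major per frame)
#   spatial tensors  [H*W, C] with row (y-1)*H + x  (column-major image)
# Every forward function returns the output plus the cache its backward needs.

.relu <- function(x) (x > 0) * x
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
.sigmoid <- function(x) 1 / (1 + exp(-x))

.initConv <- function(cin, cout, k, gain = 1) {
  sd <- gain * sqrt(2 / (cin * k))
  list(W = lapply(seq_len(k), function(j) matrix(rnorm(cin * cout, 0, sd), cin, cout)),
       b = numeric(cout))
}

.initDense <- function(cin, cout, gain = 1) {
  list(W = matrix(rnorm(cin * cout, 0, gain * sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

.addBias <- function(Y, b) Y + rep(b, each = nrow(Y))

# ---- temporal shift / 1-D dilated conv --------------------------------------

.shiftT <- function(X, o, V, Tn) {
  if (o == 0L) return(X)
  C <- ncol(X)
  if (o > 0L) rbind(X[(o * V + 1L):(Tn * V), , drop = FALSE],
                    matrix(0, o * V, C))
  else rbind(matrix(0, -o * V, C), X[seq_len((Tn + o) * V), , drop = FALSE])
}

.conv1dF <- function(X, p, dil, V, Tn) {
  offs <- dil * (seq_along(p$W) - (length(p$W) + 1L) %/% 2L)  # centred taps
  Y <- matrix(0, nrow(X), ncol(p$W[[1]]))
  for (j in seq_along(offs)) Y <- Y + .shiftT(X, offs[j], V, Tn) %*% p$W[[j]]
  list(Y = .addBias(Y, p$b), X = X, offs = offs)
}

.conv1dB <- function(dY, p, cache, V, Tn) {
  offs <- cache$offs
  dX <- matrix(0, nrow(dY), nrow(p$W[[1]]))
  gW <- vector("list", length(offs))
  for (j in seq_along(offs)) {
    gW[[j]] <- crossprod(.shiftT(cache$X, offs[j], V, Tn), dY)
    dX <- dX + .shiftT(dY, -offs[j], V, Tn) %*% t(p$W[[j]])
  }
  list(dX = dX, g = list(W = gW, b = colSums(dY)))
}

# ---- spatial shift / 3x3 conv ----------------------------------------------

.shiftS <- function(X, dx, dy, H, W) {
  if (dx == 0L && dy == 0L) return(X)
  C <- ncol(X)
  A <- array(X, c(H, W, C))
  Y <- array(0, c(H, W, C))
  xs <- seq_len(H); ys <- seq_len(W)
  okx <- xs + dx >= 1L & xs + dx <= H
  oky <- ys + dy >= 1L & ys + dy <= W
  Y[xs[okx], ys[oky], ] <- A[xs[okx] + dx, ys[oky] + dy, , drop = FALSE]
  matrix(Y, H * W, C)
}

.offs2d <- rbind(expand.grid(dx = -1:1, dy = -1:1))

.conv2dF <- function(X, p, H, W) {
  Y <- matrix(0, nrow(X), ncol(p$W[[1]]))
  for (j in seq_len(9L))
    Y <- Y + .shiftS(X, .offs2d$dx[j], .offs2d$dy[j], H, W) %*% p$W[[j]]
  list(Y = .addBias(Y, p$b), X = X)
}

.conv2dB <- function(dY, p, cache, H, W) {
  dX <- matrix(0, nrow(dY), nrow(p$W[[1]]))
  gW <- vector("list", 9L)
  for (j in seq_len(9L)) {
    gW[[j]] <- crossprod(.shiftS(cache$X, .offs2d$dx[j], .offs2d$dy[j], H, W), dY)
    dX <- dX + .shiftS(dY, -.offs2d$dx[j], -.offs2d$dy[j], H, W) %*% t(p$W[[j]])
  }
  list(dX = dX, g = list(W = gW, b = colSums(dY)))
}

.denseF <- function(X, p) list(Y = .addBias(X %*% p$W, p$b), X = X)
.denseB <- function(dY, p, cache)
  list(dX = dY %*% t(p$W), g = list(W = crossprod(cache$X, dY), b = colSums(dY)))

# ---- pooling ----------------------------------------------------------------

.pool2F <- function(X, H, W) {
  C <- ncol(X)
  A <- array(X, c(H, W, C))
  P <- (A[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
        A[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
        A[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
        A[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]) / 4
  matrix(P, H * W / 4L, C)
}

.pool2B <- function(dP, H, W) {
  C <- ncol(dP)
  D <- array(dP / 4, c(H %/% 2L, W %/% 2L, C))
  dA <- array(0, c(H, W, C))
  dA[seq(1, H, 2), seq(1, W, 2), ] <- D
  dA[seq(2, H, 2), seq(1, W, 2), ] <- D
  dA[seq(1, H, 2), seq(2, W, 2), ] <- D
  dA[seq(2, H, 2), seq(2, W, 2), ] <- D
  matrix(dA, H * W, C)
}

.up2F <- function(P, h, w) {       # nearest-neighbour x2; input is [h*w, C]
  C <- ncol(P)
  A <- array(P, c(h, w, C))
  U <- A[rep(seq_len(h), each = 2L), rep(seq_len(w), each = 2L), , drop = FALSE]
  matrix(U, 4L * h * w, C)
}

.up2B <- function(dU, h, w) {
  C <- ncol(dU)
  A <- array(dU, c(2L * h, 2L * w, C))
  D <- A[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
       A[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
       A[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE] +
       A[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE]
  matrix(D, h * w, C)
}

# ---- parameter-tree helpers and Adam ---------------------------------------

.nnMap <- function(a, f) {
  if (is.list(a)) lapply(a, .nnMap, f = f) else f(a)
}

.nnZip <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .nnZip(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

.nnZip3 <- function(a, b, c, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .nnZip3(a[[i]], b[[i]], c[[i]], f)
    out
  } else f(a, b, c)
}

.adamInit <- function(params) {
  list(m = .nnMap(params, function(x) x * 0),
       v = .nnMap(params, function(x) x * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .nnZip(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  state$v <- .nnZip(state$v, grads, function(v, g) b2 * v + (1 - b2) * g^2)
  c1 <- 1 / (1 - b1^state$t); c2 <- 1 / (1 - b2^state$t)
  params <- .nnZip3(params, state$m, state$v,
                    function(p, m, v) p - lr * (m * c1) / (sqrt(v * c2) + eps))
  list(params = params, state = state)
}

.nnFinite <- function(a) {
  ok <- TRUE
  walk <- function(x) if (is.list(x)) lapply(x, walk) else ok <<- ok && all(is.finite(x))
  walk(a)
  ok
}
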