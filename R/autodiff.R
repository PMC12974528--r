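# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The message-passing network is small enough that a tape of matrix
# operations in base R is fast and, more importantly, fully transparent:
# every backward rule below is exercised by the numeric-vs-analytic
# gradient check in the test suite. Values are plain matrices; a tape
# node records its value, its parents and a closure producing parent
# gradients from the output gradient.

adTape <- function() {
  new.env(parent = emptyenv())
}

adNode <- function(tape, value, parents = integer(0), backward = NULL) {
  # force the arguments before allocating this node's id: evaluating them
  # may append nodes, and reverse-mode needs ids in topological order
  force(value); force(parents); force(backward)
  id <- (tape$n %||% 0L) + 1L
  tape$n <- id
  if (is.null(tape$nodes)) tape$nodes <- vector("list", 64L)
  if (id > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[id]] <- list(value = value, parents = parents, backward = backward)
  id
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adValue <- function(tape, id) {
  # force `id` before touching tape$nodes: nested calls append nodes while
  # their own id argument is still an unevaluated promise
  force(id)
  tape$nodes[[id]]$value
}

adLeaf <- function(tape, value) adNode(tape, value)

adMatmul <- function(tape, a, b) {
  A <- adValue(tape, a); B <- adValue(tape, b)
  adNode(tape, A %*% B, c(a, b), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

adAdd <- function(tape, a, b) {
  adNode(tape, adValue(tape, a) + adValue(tape, b), c(a, b),
         function(g) list(g, g))
}

# Add a 1 x d bias row to every row of an n x d matrix.
adAddBias <- function(tape, a, bias) {
  A <- adValue(tape, a); Bv <- adValue(tape, bias)
  adNode(tape, sweep(A, 2, as.numeric(Bv), "+"), c(a, bias), function(g) {
    list(g, matrix(colSums(g), 1))
  })
}

adTanh <- function(tape, a) {
  y <- tanh(adValue(tape, a))
  adNode(tape, y, a, function(g) list(g * (1 - y^2)))
}

adSigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-adValue(tape, a)))
  adNode(tape, y, a, function(g) list(g * y * (1 - y)))
}

adMul <- function(tape, a, b) {
  A <- adValue(tape, a); B <- adValue(tape, b)
  adNode(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

adScale <- function(tape, a, s) {
  adNode(tape, adValue(tape, a) * s, a, function(g) list(g * s))
}

# Row gather: value = A[idx, ]; gradient scatter-adds back.
adRows <- function(tape, a, idx) {
  A <- adValue(tape, a)
  n <- nrow(A)
  adNode(tape, A[idx, , drop = FALSE], a, function(g) {
    list(scatterRows(g, idx, n))
  })
}

# Row aggregation: out[k, ] = sum of A[i, ] over i with group[i] == k.
adRowsumBy <- function(tape, a, group, ngroups) {
  A <- adValue(tape, a)
  adNode(tape, scatterRows(A, group, ngroups), a, function(g) {
    list(g[group, , drop = FALSE])
  })
}

adCbind <- function(tape, ...) {
  ids <- c(...)
  vals <- lapply(ids, adValue, tape = tape)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  adNode(tape, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

adRbind <- function(tape, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, adValue, tape = tape)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, head(ends, -1L) + 1L)
  adNode(tape, do.call(rbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# Row-wise layer normalisation without learned affine parameters.
adLayerNorm <- function(tape, a, eps = 1e-5) {
  A <- adValue(tape, a)
  d <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  y <- xc / sd_
  adNode(tape, y, a, function(g) {
    gm <- rowMeans(g)
    gy <- rowMeans(g * y)
    list((g - gm - y * gy) / sd_)
  })
}

adSum <- function(tape, a) {
  A <- adValue(tape, a)
  adNode(tape, matrix(sum(A)), a, function(g) {
    list(matrix(as.numeric(g), nrow(A), ncol(A)))
  })
}

adMean <- function(tape, a) {
  A <- adValue(tape, a)
  n <- length(A)
  adNode(tape, matrix(mean(A)), a, function(g) {
    list(matrix(as.numeric(g) / n, nrow(A), ncol(A)))
  })
}

adPick <- function(tape, a, i) {
  A <- adValue(tape, a)
  adNode(tape, matrix(A[i, 1]), a, function(g) {
    z <- matrix(0, nrow(A), ncol(A)); z[i, 1] <- as.numeric(g); list(z)
  })
}

adLogSumExp <- function(tape, a) {
  A <- as.numeric(adValue(tape, a))
  m <- max(A)
  p <- exp(A - m) / sum(exp(A - m))
  adNode(tape, matrix(m + log(sum(exp(A - m)))), a, function(g) {
    list(matrix(as.numeric(g) * p, ncol = 1))
  })
}

# Scalar arithmetic on 1x1 nodes.
adSAdd <- function(tape, a, b) adAdd(tape, a, b)

adSDiv <- function(tape, a, b) {
  A <- as.numeric(adValue(tape, a)); B <- as.numeric(adValue(tape, b))
  adNode(tape, matrix(A / B), c(a, b), function(g) {
    gg <- as.numeric(g)
    list(matrix(gg / B), matrix(-gg * A / B^2))
  })
}

adConstPlus <- function(tape, a, k) {
  adNode(tape, adValue(tape, a) + k, a, function(g) list(g))
}

# Numerically stable weighted binary cross-entropy from logits.
# loss = mean( w*y*softplus(-z) + (1-y)*softplus(z) ), w applied to positives.
adBceLogits <- function(tape, z, y, posWeight = 1) {
  Z <- as.numeric(adValue(tape, z))
  n <- length(Z)
  sp <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  val <- mean(posWeight * y * sp(-Z) + (1 - y) * sp(Z))
  sig <- 1 / (1 + exp(-Z))
  grad <- (-posWeight * y * (1 - sig) + (1 - y) * sig) / n
  adNode(tape, matrix(val), z, function(g) {
    list(matrix(as.numeric(g) * grad, ncol = 1))
  })
}

# Reverse sweep from scalar node `loss`; returns gradients for `wanted` ids.
adBackward <- function(tape, loss, wanted) {
  n <- tape$n
  grads <- vector("list", n)
  grads[[loss]] <- matrix(1)
  for (id in seq(n, 1L)) {
    nd <- tape$nodes[[id]]
    g <- grads[[id]]
    if (is.null(g) || is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  lapply(wanted, function(w) {
    g <- grads[[w]]
    if (is.null(g)) matrix(0, nrow(adValue(tape, w)), ncol(adValue(tape, w))) else g
  })
}
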