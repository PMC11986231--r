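# Reverse-mode automatic differentiation on a dynamic tape.
#
# Values are plain R arrays (feature maps in (H, W, C, N) layout, dense
# activations as N x d matrices, reductions as vectors/scalars). Each node
# records its parents and a vector-Jacobian product; ag_backward() walks the
# tape in reverse topological order. Parameters are long-lived nodes whose
# $grad field is consumed by the optimizer; all other nodes are rebuilt per
# forward pass.

.ag_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

ag_node <- function(value, parents = list(), vjp = NULL) {
  n <- new.env(parent = emptyenv())
  n$id <- .ag_counter()
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$vjp <- vjp
  n$param <- FALSE
  class(n) <- "ag_node"
  n
}

ag_param <- function(value) {
  n <- ag_node(value)
  n$param <- TRUE
  n
}

ag_const <- function(value) ag_node(value)

is_ag <- function(x) inherits(x, "ag_node")

as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

#' @noRd
ag_value <- function(x) if (is_ag(x)) x$value else x

# reshape-preserving accumulate: grads for a node keep the value's dim
.ag_acc <- function(node, g) {
  if (!is.null(dim(node$value)) && is.null(dim(g))) dim(g) <- dim(node$value)
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Run the tape backwards from a scalar node.
ag_backward <- function(root) {
  stopifnot(is_ag(root), length(root$value) == 1L)
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(top$node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = top$node, stage = 2L)
      for (p in top$node$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      order[[length(order) + 1L]] <- top$node
    }
  }
  root$grad <- 1
  for (k in rev(seq_along(order))) {
    nd <- order[[k]]
    if (is.null(nd$vjp) || is.null(nd$grad)) next
    gs <- nd$vjp(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) .ag_acc(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(root)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise arithmetic (shapes equal, or one operand scalar) -----------

.bcast_vjp <- function(a, g) {
  if (length(a$value) == 1L && length(g) > 1L) sum(g) else g
}

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(ag_value(a) + ag_value(b), list(a, b), function(g) {
    list(.bcast_vjp(a, g), .bcast_vjp(b, g))
  })
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(ag_value(a) - ag_value(b), list(a, b), function(g) {
    list(.bcast_vjp(a, g), .bcast_vjp(b, -g))
  })
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) {
    list(.bcast_vjp(a, g * bv), .bcast_vjp(b, g * av))
  })
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_node(av / bv, list(a, b), function(g) {
    list(.bcast_vjp(a, g / bv), .bcast_vjp(b, -g * av / (bv * bv)))
  })
}

ag_square <- function(a) {
  av <- a$value
  ag_node(av * av, list(a), function(g) list(2 * g * av))
}

ag_sqrt <- function(a) {
  v <- sqrt(a$value)
  ag_node(v, list(a), function(g) list(g / (2 * v)))
}

ag_log <- function(a) {
  av <- a$value
  ag_node(log(av), list(a), function(g) list(g / av))
}

ag_relu <- function(a) {
  v <- cpp_relu_forward(a$value)
  ag_node(v, list(a), function(g) list(cpp_relu_backward(g, v)))
}

ag_sigmoid <- function(a) {
  v <- stats::plogis(a$value)
  ag_node(v, list(a), function(g) list(g * v * (1 - v)))
}

# clip with straight-through-zero gradient outside the range
ag_clip <- function(a, lo, hi) {
  av <- a$value
  mask <- av >= lo & av <= hi
  ag_node(pmin(pmax(av, lo), hi), list(a), function(g) list(g * mask))
}

# ---- reductions -------------------------------------------------------------

ag_sum <- function(a) {
  ag_node(sum(a$value), list(a), function(g) {
    list(array(g, dim = dim(a$value) %||% length(a$value)))
  })
}

ag_mean <- function(a) {
  n <- length(a$value)
  ag_node(mean(a$value), list(a), function(g) {
    list(array(g / n, dim = dim(a$value) %||% length(a$value)))
  })
}

# per-sample mean over everything but the last axis: (H,W,C,N) -> length-N
ag_sw_mean <- function(a) {
  d <- dim(a$value)
  per <- prod(d[-length(d)])
  m <- matrix(a$value, per, d[length(d)])
  ag_node(colMeans(m), list(a), function(g) {
    list(array(rep(g / per, each = per), dim = d))
  })
}

ag_sw_sum <- function(a) {
  d <- dim(a$value)
  per <- prod(d[-length(d)])
  m <- matrix(a$value, per, d[length(d)])
  ag_node(colSums(m), list(a), function(g) {
    list(array(rep(g, each = per), dim = d))
  })
}

# ---- dense layers -----------------------------------------------------------

# x: N x din, W: din x dout, b: length dout
ag_linear <- function(x, W, b) {
  xv <- x$value; Wv <- W$value
  v <- xv %*% Wv
  v <- sweep(v, 2L, b$value, "+")
  ag_node(v, list(x, W, b), function(g) {
    list(g %*% t(Wv), crossprod(xv, g), colSums(g))
  })
}

ag_dropout <- function(x, rate, training = TRUE) {
  if (!training || rate <= 0) return(x)
  keep <- 1 - rate
  mask <- (array(stats::runif(length(x$value)), dim = dim(x$value)) < keep) / keep
  ag_node(x$value * mask, list(x), function(g) list(g * mask))
}

# mean softmax cross-entropy over rows; labels are 0-based integers
ag_softmax_ce <- function(logits, labels) {
  z <- logits$value
  zmax <- apply(z, 1L, max)
  ez <- exp(z - zmax)
  p <- ez / rowSums(ez)
  n <- nrow(z)
  pick <- cbind(seq_len(n), labels + 1L)
  v <- -mean(log(pmax(p[pick], 1e-12)))
  ag_node(v, list(logits), function(g) {
    d <- p
    d[pick] <- d[pick] - 1
    list(g * d / n)
  })
}

# mean binary cross-entropy from logits over all entries (stable softplus form)
ag_bce_logits <- function(z, target) {
  zv <- z$value
  tv <- ag_value(target)
  n <- length(zv)
  # log(1+exp(z)) - t*z, computed stably
  sp <- ifelse(zv > 0, zv + log1p(exp(-zv)), log1p(exp(zv)))
  v <- sum(sp - tv * zv) / n
  ag_node(v, list(z), function(g) {
    list(array(g * (stats::plogis(zv) - tv) / n, dim = dim(zv)))
  })
}

# ---- convolutional ops ------------------------------------------------------

ag_conv2d <- function(x, w, b, pad) {
  xv <- x$value; wv <- w$value
  v <- cpp_conv2d_forward(xv, wv, b$value, pad)
  ag_node(v, list(x, w, b), function(g) {
    bk <- cpp_conv2d_backward(xv, wv, g, pad)
    list(bk$gx, bk$gw, bk$gb)
  })
}

ag_maxpool2 <- function(x) {
  fw <- cpp_maxpool2_forward(x$value)
  xd <- dim(x$value)
  ag_node(fw$out, list(x), function(g) {
    list(cpp_maxpool2_backward(fw$idx, g, xd))
  })
}

# nearest-neighbour 2x upsampling
ag_upsample2 <- function(x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  v <- x$value[ri, ci, , , drop = FALSE]
  ag_node(v, list(x), function(g) {
    # sum each 2x2 block
    g1 <- g[seq(1, 2 * d[1], 2), , , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), , , , drop = FALSE]
    list(g1[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
           g1[, seq(2, 2 * d[2], 2), , , drop = FALSE])
  })
}

ag_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  v <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  ag_node(v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# global average pool: (H,W,C,N) -> N x C
ag_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- matrix(x$value, hw, d[3] * d[4])
  v <- t(matrix(colMeans(m), d[3], d[4]))  # N x C
  ag_node(v, list(x), function(g) {
    list(cpp_bcast_channel(g / hw, d[1], d[2]))
  })
}

# broadcast a (H,W,1,N) map over C channels
ag_bcast_spatial <- function(a, C) {
  ag_node(cpp_bcast_spatial(a$value, C), list(a), function(g) {
    list(cpp_reduce_spatial(g))
  })
}

# broadcast a per-sample channel vector (N x C) to (H,W,C,N)
ag_bcast_channel <- function(a, H, W) {
  ag_node(cpp_bcast_channel(a$value, H, W), list(a), function(g) {
    list(cpp_reduce_channel(g))
  })
}

# per-channel mean over (H, W, N): (H,W,C,N) -> length-C
ag_chan_mean <- function(x) {
  d <- dim(x$value)
  per <- d[1] * d[2]
  m <- matrix(x$value, per, d[3] * d[4])
  cs <- colSums(m)
  v <- rowSums(matrix(cs, d[3], d[4])) / (per * d[4])
  ag_node(v, list(x), function(g) {
    gc <- g / (per * d[4])
    list(array(rep(rep(gc, each = per), times = d[4]), dim = d))
  })
}

# broadcast a length-C vector to (H,W,C,N)
ag_bcast_cvec <- function(a, H, W, N) {
  av <- a$value
  C <- length(av)
  v <- array(rep(rep(av, each = H * W), times = N), dim = c(H, W, C, N))
  ag_node(v, list(a), function(g) {
    m <- matrix(g, H * W, C * N)
    list(rowSums(matrix(colSums(m), C, N)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
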