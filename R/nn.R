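# Layer constructors and the Adam optimizer used by every trainable module.

new_conv_layer <- function(kh, kw, cin, cout, init_sd = NULL) {
  sd <- init_sd %||% sqrt(2 / (kh * kw * cin))
  list(
    w = ag_param(array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                       dim = c(kh, kw, cin, cout))),
    b = ag_param(numeric(cout)),
    pad = if (kh == 3L) 1L else 0L
  )
}

conv_forward <- function(layer, x) ag_conv2d(x, layer$w, layer$b, layer$pad)

new_dense_layer <- function(din, dout, init_sd = NULL) {
  sd <- init_sd %||% sqrt(2 / din)
  list(
    w = ag_param(matrix(stats::rnorm(din * dout, sd = sd), din, dout)),
    b = ag_param(numeric(dout))
  )
}

dense_forward <- function(layer, x) ag_linear(x, layer$w, layer$b)

new_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  bn <- new.env(parent = emptyenv())
  bn$gamma <- ag_param(rep(1, C))
  bn$beta <- ag_param(numeric(C))
  bn$running_mean <- numeric(C)
  bn$running_var <- rep(1, C)
  bn$momentum <- momentum
  bn$eps <- eps
  bn
}

batchnorm_forward <- function(bn, x, training) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (training) {
    fw <- cpp_bn_forward(x$value, bn$gamma$value, bn$beta$value, bn$eps)
    bn$running_mean <- (1 - bn$momentum) * bn$running_mean +
      bn$momentum * fw$mean
    bn$running_var <- (1 - bn$momentum) * bn$running_var +
      bn$momentum * (1 / fw$invstd^2 - bn$eps)
    gamma_now <- bn$gamma$value
    ag_node(fw$y, list(x, bn$gamma, bn$beta), function(g) {
      bk <- cpp_bn_backward(g, fw$xhat, gamma_now, fw$invstd)
      list(bk$gx, bk$ggamma, bk$gbeta)
    })
  } else {
    xc <- ag_sub(x, ag_bcast_cvec(ag_const(bn$running_mean), H, W, N))
    inv <- 1 / sqrt(bn$running_var + bn$eps)
    xhat <- ag_mul(xc, ag_bcast_cvec(ag_const(inv), H, W, N))
    ag_add(ag_mul(xhat, ag_bcast_cvec(bn$gamma, H, W, N)),
           ag_bcast_cvec(bn$beta, H, W, N))
  }
}

# ---- Adam with decoupled L2 weight decay ------------------------------------

new_adam <- function(params, lr = 1e-3, weight_decay = 1e-5,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$wd <- weight_decay
  st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) {
    if (is.null(dim(p$value))) numeric(length(p$value))
    else array(0, dim = dim(p$value))
  })
  st$v <- st$m
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (st$wd > 0) g <- g + st$wd * p$value
    st$m[[i]] <- st$b1 * st$m[[i]] + (1 - st$b1) * g
    st$v[[i]] <- st$b2 * st$v[[i]] + (1 - st$b2) * g * g
    p$value <- p$value - st$lr * (st$m[[i]] / bc1) /
      (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  ag_zero_grads(st$params)
  invisible(st)
}

# collect every ag_param inside a nested layer structure
collect_params <- function(x) {
  out <- list()
  walk <- function(o) {
    if (is_ag(o)) {
      if (o$param) out[[length(out) + 1L]] <<- o
    } else if (is.environment(o)) {
      for (nm in ls(o)) if (is_ag(o[[nm]]) && o[[nm]]$param) out[[length(out) + 1L]] <<- o[[nm]]
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(x)
  out
}
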