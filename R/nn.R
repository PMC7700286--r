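#' @useDynLib mammodense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal convolutional-network engine.
#
# Tensors are plain R arrays with dim = c(H, W, C, N).  Each layer is a
# mutable environment exposing forward(x, train) / backward(dout) and, for
# parameterized layers, `par` and `grad` lists of equal shape.  Backprop is
# chained manually by the containers; convolution, pooling and upsampling run
# through the compiled kernels in src/nn_kernels.cpp.
# ---------------------------------------------------------------------------

as_tensor <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, gain = 2) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  sd <- sqrt(gain / (k * k * in_ch))
  e$par <- list(w = array(stats::rnorm(k * k * in_ch * out_ch, sd = sd),
                          dim = c(k, k, in_ch, out_ch)),
                b = numeric(out_ch))
  e$grad <- list(w = array(0, dim(e$par$w)), b = numeric(out_ch))
  e$forward <- function(x, train = TRUE) {
    e$x <- x
    .conv2d_fwd(x, e$par$w, e$par$b, e$stride, e$pad)
  }
  e$backward <- function(dout, need_dx = TRUE) {
    g <- .conv2d_bwd(e$x, e$par$w, dout, e$stride, e$pad, need_dx)
    e$grad$w <- e$grad$w + g$dw
    e$grad$b <- e$grad$b + g$db
    if (need_dx) g$dx else NULL
  }
  e
}

layer_dense <- function(in_dim, out_dim, gain = 2) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"
  e$par <- list(w = matrix(stats::rnorm(in_dim * out_dim,
                                        sd = sqrt(gain / in_dim)),
                           in_dim, out_dim),
                b = numeric(out_dim))
  e$grad <- list(w = matrix(0, in_dim, out_dim), b = numeric(out_dim))
  e$forward <- function(x, train = TRUE) { # x: (in_dim, N)
    e$x <- x
    sweep(crossprod(e$par$w, x), 1, e$par$b, `+`)
  }
  e$backward <- function(dout, need_dx = TRUE) {
    e$grad$w <- e$grad$w + tcrossprod(e$x, dout)
    e$grad$b <- e$grad$b + rowSums(dout)
    if (need_dx) e$par$w %*% dout else NULL
  }
  e
}

layer_act <- function(kind = c("relu", "lrelu", "sigmoid"), slope = 0.2) {
  kind <- match.arg(kind)
  e <- new.env(parent = emptyenv())
  e$type <- kind
  e$forward <- function(x, train = TRUE) {
    y <- switch(kind,
      relu = { x[x < 0] <- 0; x },
      lrelu = { neg <- x < 0; x[neg] <- slope * x[neg]; x },
      sigmoid = 1 / (1 + exp(-x)))
    e$y <- y
    y
  }
  e$backward <- function(dout, need_dx = TRUE) {
    switch(kind,
      relu = dout * (e$y > 0),
      lrelu = { neg <- e$y < 0; dout[neg] <- slope * dout[neg]; dout },
      sigmoid = dout * e$y * (1 - e$y))
  }
  e
}

layer_maxpool <- function(k, stride = k) {
  e <- new.env(parent = emptyenv())
  e$type <- "maxpool"
  e$forward <- function(x, train = TRUE) {
    e$xdim <- dim(x)
    r <- .maxpool_fwd(x, as.integer(k), as.integer(stride))
    e$idx <- r$idx
    r$out
  }
  e$backward <- function(dout, need_dx = TRUE)
    .maxpool_bwd(dout, e$idx, as.integer(e$xdim))
  e
}

layer_upsample2 <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "upsample2"
  e$forward <- function(x, train = TRUE) .upsample2_fwd(x)
  e$backward <- function(dout, need_dx = TRUE) .upsample2_bwd(dout)
  e
}

layer_flatten <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "flatten"
  e$forward <- function(x, train = TRUE) {
    e$xdim <- dim(x)
    matrix(x, prod(e$xdim[1:3]), e$xdim[4])
  }
  e$backward <- function(dout, need_dx = TRUE) array(dout, e$xdim)
  e
}

layer_dropout <- function(p = 0.5) {
  e <- new.env(parent = emptyenv())
  e$type <- "dropout"
  e$forward <- function(x, train = TRUE) {
    if (!train || p <= 0) { e$mask <- NULL; return(x) }
    e$mask <- (stats::runif(length(x)) >= p) / (1 - p)
    y <- x * e$mask
    if (!is.null(dim(x))) dim(y) <- dim(x)
    y
  }
  e$backward <- function(dout, need_dx = TRUE) {
    if (is.null(e$mask)) dout else dout * e$mask
  }
  e
}

# Two 3x3 same-padding convs with an identity skip: out = relu(x + c2(relu(c1 x)))
layer_resblock <- function(ch) {
  e <- new.env(parent = emptyenv())
  e$type <- "resblock"
  e$c1 <- layer_conv(ch, ch, 3L, 1L, 1L)
  e$a1 <- layer_act("relu")
  e$c2 <- layer_conv(ch, ch, 3L, 1L, 1L)
  e$a2 <- layer_act("relu")
  e$forward <- function(x, train = TRUE) {
    h <- e$c2$forward(e$a1$forward(e$c1$forward(x, train), train), train)
    e$a2$forward(x + h, train)
  }
  e$backward <- function(dout, need_dx = TRUE) {
    d <- e$a2$backward(dout)
    dh <- e$c1$backward(e$a1$backward(e$c2$backward(d)))
    d + dh
  }
  e
}

nn_sequential <- function(...) {
  e <- new.env(parent = emptyenv())
  e$type <- "sequential"
  e$layers <- list(...)
  if (length(e$layers) == 1L && is.list(e$layers[[1]]) &&
      !is.environment(e$layers[[1]]))
    e$layers <- e$layers[[1]]
  e$forward <- function(x, train = TRUE) {
    for (l in e$layers) x <- l$forward(x, train)
    x
  }
  e$backward <- function(dout, need_dx = TRUE) {
    n <- length(e$layers)
    for (i in seq(n, 1)) {
      last <- (i == 1L)
      dout <- e$layers[[i]]$backward(dout, need_dx = need_dx || !last)
    }
    dout
  }
  e
}

# Recursively collect every parameterized layer environment in a module tree.
collect_param_layers <- function(mod) {
  out <- list()
  walk <- function(m) {
    if (is.environment(m)) {
      if (!is.null(m$par)) out[[length(out) + 1L]] <<- m
      for (nm in c("layers", "c1", "c2"))
        if (!is.null(m[[nm]])) walk(m[[nm]])
      for (nm in setdiff(ls(m), c("par", "grad", "forward", "backward",
                                  "layers", "c1", "c2")))
        if (is.environment(m[[nm]]) || is.list(m[[nm]])) walk(m[[nm]])
    } else if (is.list(m)) {
      for (el in m) walk(el)
    }
  }
  walk(mod)
  out
}

zero_grads <- function(layers) {
  for (l in layers) for (nm in names(l$grad)) l$grad[[nm]][] <- 0
  invisible(NULL)
}

n_params <- function(mod)
  sum(vapply(collect_param_layers(mod),
             function(l) sum(vapply(l$par, length, 0L)), 0))

# Extract / restore flat parameter state (for checkpoints and smoke tests).
get_params <- function(mod)
  lapply(collect_param_layers(mod), function(l) l$par)
set_params <- function(mod, state) {
  ls <- collect_param_layers(mod)
  stopifnot(length(ls) == length(state))
  for (i in seq_along(ls)) ls[[i]]$par <- state[[i]]
  invisible(mod)
}

# ---------------------------------------------------------------------------
# Optimizers (standard update rules; state kept per parameter array)
# ---------------------------------------------------------------------------

opt_adam <- function(mod, lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$layers <- collect_param_layers(mod)
  e$m <- lapply(e$layers, function(l) lapply(l$par, function(p) p * 0))
  e$v <- e$m
  e$t <- 0L
  e$step <- function() {
    e$t <- e$t + 1L
    bc1 <- 1 - beta1^e$t; bc2 <- 1 - beta2^e$t
    for (i in seq_along(e$layers)) {
      l <- e$layers[[i]]
      for (nm in names(l$par)) {
        g <- l$grad[[nm]]
        e$m[[i]][[nm]] <- beta1 * e$m[[i]][[nm]] + (1 - beta1) * g
        e$v[[i]][[nm]] <- beta2 * e$v[[i]][[nm]] + (1 - beta2) * g * g
        l$par[[nm]] <- l$par[[nm]] -
          lr * (e$m[[i]][[nm]] / bc1) / (sqrt(e$v[[i]][[nm]] / bc2) + eps)
      }
    }
    invisible(NULL)
  }
  e
}

opt_rmsprop <- function(mod, lr = 1e-3, momentum = 0.9, rho = 0.9, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$layers <- collect_param_layers(mod)
  e$lr <- lr # mutable: training schedules may decay it
  e$s <- lapply(e$layers, function(l) lapply(l$par, function(p) p * 0))
  e$mom <- e$s
  e$step <- function() {
    for (i in seq_along(e$layers)) {
      l <- e$layers[[i]]
      for (nm in names(l$par)) {
        g <- l$grad[[nm]]
        e$s[[i]][[nm]] <- rho * e$s[[i]][[nm]] + (1 - rho) * g * g
        upd <- e$lr * g / (sqrt(e$s[[i]][[nm]]) + eps)
        e$mom[[i]][[nm]] <- momentum * e$mom[[i]][[nm]] + upd
        l$par[[nm]] <- l$par[[nm]] - e$mom[[i]][[nm]]
      }
    }
    invisible(NULL)
  }
  e
}
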