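# Compact depthwise-separable CNN (Xception-style), implemented on the
# Rcpp convolution kernels. Two scales:
#   mini — stem conv + 2 separable residual blocks; the desk-scale default.
#   full — 14 modules: a preprocessing module of 3 standard convolutions
#          plus 13 residual modules holding 33 depthwise-separable
#          convolutions (3 entry x2, 8 middle x3, exit x2, tail x1).
# Training: softmax cross-entropy, Adam, deterministic under the config
# seed (single-threaded reference implementation).

#' Classifier configuration
#'
#' @param scale `"mini"` (default; 2 separable residual blocks, accepts
#'   native image sizes) or `"full"` (the 14-module architecture with 3
#'   standard + 33 depthwise-separable convolution layers; inputs are
#'   upscaled to at least `input_size` by nearest-neighbour).
#' @param input_size Minimum spatial input (default 71 for `full`, native
#'   for `mini`).
#' @param epochs Training epochs (default 30).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return List of class `model_config`.
#' @export
model_config <- function(scale = c("mini", "full"), input_size = NULL,
                         epochs = 30, learning_rate = 1e-3,
                         batch_size = 32, seed = 1L) {
  scale <- match.arg(scale)
  if (is.null(input_size)) input_size <- if (scale == "full") 71L else NA
  structure(
    list(
      scale = scale, input_size = input_size, epochs = epochs,
      learning_rate = learning_rate, batch_size = batch_size,
      seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

# ---- architecture specs --------------------------------------------------

conv_spec <- function(out, k = 3, stride = 1, pad = 1) {
  list(type = "conv", out = out, k = k, stride = stride, pad = pad)
}
relu_spec <- function() list(type = "relu")
sep_spec <- function(filters, n_sep = 2, stride = 1,
                     skip = c("conv", "identity"), pre_relu = FALSE) {
  list(
    type = "sepblock", filters = filters, n_sep = n_sep,
    stride = stride, skip = match.arg(skip), pre_relu = pre_relu
  )
}

build_arch <- function(scale) {
  if (scale == "mini") {
    list(
      conv_spec(8), relu_spec(),
      sep_spec(16, 2, 1, "conv"),
      sep_spec(32, 2, 1, "conv"),
      list(type = "gap"), list(type = "dense", out = 2)
    )
  } else {
    c(
      list(
        conv_spec(32, 3, 2, 1), relu_spec(),
        conv_spec(64, 3, 1, 1), relu_spec(),
        sep_spec(128, 2, 2, "conv"),
        sep_spec(256, 2, 2, "conv"),
        sep_spec(728, 2, 2, "conv")
      ),
      replicate(8, sep_spec(728, 3, 1, "identity", pre_relu = TRUE),
        simplify = FALSE
      ),
      list(
        sep_spec(1024, 2, 2, "conv"),
        sep_spec(2048, 1, 1, "conv"),
        conv_spec(1536, 1, 1, 0), relu_spec(),
        list(type = "gap"), list(type = "dense", out = 2)
      )
    )
  }
}

#' Count the layers of a classifier architecture
#'
#' @param scale `"mini"` or `"full"`.
#' @return Named list: `common_conv` (standard convolution layers),
#'   `separable` (depthwise-separable convolution layers), `modules`
#'   (residual modules plus the preprocessing module).
#' @export
count_layers <- function(scale = c("mini", "full")) {
  arch <- build_arch(match.arg(scale))
  common <- sum(vapply(arch, function(l) l$type == "conv", logical(1)))
  sep <- sum(vapply(
    arch,
    function(l) if (l$type == "sepblock") l$n_sep else 0L, numeric(1)
  ))
  modules <- sum(vapply(
    arch, function(l) l$type == "sepblock",
    logical(1)
  )) + 1L
  list(common_conv = common, separable = as.integer(sep), modules = modules)
}

# ---- parameter init ------------------------------------------------------

he_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
    dim = c(k, k, cin, cout)
  )
}

init_params <- function(arch, in_ch) {
  c <- in_ch
  lapply(arch, function(l) {
    switch(l$type,
      conv = {
        p <- list(w = he_conv(l$k, c, l$out), b = rep(0, l$out))
        c <<- l$out
        p
      },
      sepblock = {
        cin <- c
        sep <- list()
        for (i in seq_len(l$n_sep)) {
          cout <- l$filters
          sep[[i]] <- list(
            dw = array(rnorm(9 * cin, sd = sqrt(2 / 9)), dim = c(3, 3, cin)),
            dwb = rep(0, cin),
            pw = he_conv(1, cin, cout),
            pwb = rep(0, cout)
          )
          cin <- cout
        }
        skip <- if (l$skip == "conv") {
          list(w = he_conv(1, c, l$filters), b = rep(0, l$filters))
        } else {
          NULL
        }
        c <<- l$filters
        list(sep = sep, skip = skip)
      },
      dense = {
        p <- list(
          w = matrix(rnorm(c * l$out, sd = sqrt(1 / c)), c, l$out),
          b = rep(0, l$out)
        )
        p
      },
      NULL
    )
  })
}

# ---- forward / backward --------------------------------------------------

relu_f <- function(x) relu_fwd(x)

sep_unit_fwd <- function(x, p, stride) {
  d <- dwconv2d_fwd(x, p$dw, p$dwb, stride, 1L)
  y <- conv2d_fwd(d, p$pw, p$pwb, 1L, 0L)
  list(y = y, d = d)
}

sep_unit_bwd <- function(x, p, cache, gy, stride) {
  bp <- conv2d_bwd(cache$d, p$pw, gy, 1L, 0L)
  bd <- dwconv2d_bwd(x, p$dw, bp$gx, stride, 1L)
  list(
    gx = bd$gx,
    gp = list(dw = bd$gw, dwb = bd$gb, pw = bp$gw, pwb = bp$gb)
  )
}

sepblock_fwd <- function(x, l, p) {
  caches <- list()
  t <- x
  for (i in seq_len(l$n_sep)) {
    stride <- if (i == l$n_sep) l$stride else 1L
    pre <- if (l$pre_relu || i > 1) relu_f(t) else t
    u <- sep_unit_fwd(pre, p$sep[[i]], stride)
    caches[[i]] <- list(input = pre, raw = t, d = u$d)
    t <- u$y
  }
  if (l$skip == "conv") {
    s <- conv2d_fwd(x, p$skip$w, p$skip$b, l$stride, 0L)
  } else {
    s <- x
  }
  y <- t + s
  list(y = relu_f(y), pre_add = y, caches = caches)
}

sepblock_bwd <- function(x, l, p, cache, gy) {
  g <- relu_bwd(gy, cache$pre_add)
  gp <- list(sep = vector("list", l$n_sep), skip = NULL)
  if (l$skip == "conv") {
    bs <- conv2d_bwd(x, p$skip$w, g, l$stride, 0L)
    gx <- bs$gx
    gp$skip <- list(w = bs$gw, b = bs$gb)
  } else {
    gx <- g
  }
  gt <- g
  for (i in rev(seq_len(l$n_sep))) {
    stride <- if (i == l$n_sep) l$stride else 1L
    cc <- cache$caches[[i]]
    bu <- sep_unit_bwd(cc$input, p$sep[[i]],
      list(d = cc$d), gt, stride)
    gp$sep[[i]] <- bu$gp
    gt <- bu$gx
    if (l$pre_relu || i > 1) gt <- relu_bwd(gt, cc$raw)
  }
  list(gx = gx + gt, gp = gp)
}

net_forward <- function(arch, params, x, train = TRUE) {
  caches <- vector("list", length(arch))
  h <- x
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    p <- params[[i]]
    if (l$type == "conv") {
      caches[[i]] <- list(x = h)
      h <- conv2d_fwd(h, p$w, p$b, l$stride, l$pad)
    } else if (l$type == "relu") {
      caches[[i]] <- list(x = h)
      h <- relu_f(h)
    } else if (l$type == "sepblock") {
      fb <- sepblock_fwd(h, l, p)
      caches[[i]] <- c(list(x = h), fb[c("pre_add", "caches")])
      h <- fb$y
    } else if (l$type == "gap") {
      d <- dim(h)
      caches[[i]] <- list(dim = d)
      dim(h) <- c(d[1] * d[2], d[3] * d[4])
      h <- matrix(colMeans(h), d[3], d[4])
    } else if (l$type == "dense") {
      caches[[i]] <- list(x = h)
      h <- crossprod(p$w, h) + p$b
    }
  }
  list(z = h, caches = caches)
}

net_backward <- function(arch, params, caches, gz) {
  grads <- vector("list", length(arch))
  g <- gz
  for (i in rev(seq_along(arch))) {
    l <- arch[[i]]
    p <- params[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(w = tcrossprod(cc$x, g), b = rowSums(g))
      g <- p$w %*% g
    } else if (l$type == "gap") {
      d <- cc$dim
      gx <- array(0, dim = d)
      per <- 1 / (d[1] * d[2])
      gfull <- array(rep(as.vector(g), each = d[1] * d[2]) * per, dim = d)
      g <- gfull
    } else if (l$type == "sepblock") {
      bb <- sepblock_bwd(cc$x, l, p, cc, g)
      grads[[i]] <- bb$gp
      g <- bb$gx
    } else if (l$type == "relu") {
      g <- relu_bwd(g, cc$x)
    } else if (l$type == "conv") {
      bc <- conv2d_bwd(cc$x, p$w, g, l$stride, l$pad)
      grads[[i]] <- list(w = bc$gw, b = bc$gb)
      g <- bc$gx
    }
  }
  grads
}

softmax_probs <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# ---- recursive parameter-tree helpers (Adam) -----------------------------

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(x, y, f), a, b)
    return(out)
  }
  if (is.null(a)) {
    return(NULL)
  }
  f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) {
    return(lapply(a, tree_zero))
  }
  if (is.null(a)) {
    return(NULL)
  }
  a * 0
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mh <- 1 - beta1^t
  vh <- 1 - beta2^t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / mh) / (sqrt(v / vh) + eps)
  })
  params <- tree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# ---- stacking and training ----------------------------------------------

#' Stack encoded images into a training tensor
#'
#' Converts a list of `image_sample` matrices (pixels 0-255) into a
#' `(H, W, 1, N)` array scaled to \[0, 1\], optionally upscaling each
#' image by nearest-neighbour to `input_size` (required by the full-scale
#' architecture).
#'
#' @param images List of integer pixel matrices of one shape.
#' @param input_size Optional minimum spatial size.
#' @return Numeric 4-d array.
#' @export
stack_images <- function(images, input_size = NA) {
  if (!is.na(input_size)) {
    images <- lapply(images, function(m) {
      resize_nn(m, max(nrow(m), input_size), max(ncol(m), input_size))
    })
  }
  d <- dim(images[[1]])
  x <- array(unlist(images, use.names = FALSE) / 255,
    dim = c(d[1], d[2], 1, length(images))
  )
  x
}

class_levels <- function() c("HVA", "LVA")

#' Train the depthwise-separable CNN
#'
#' Trains the image classifier with Adam on softmax cross-entropy.
#' Training is deterministic given `cfg$seed` (pure single-threaded
#' implementation: no backend nondeterminism).
#'
#' @param x Training tensor `(H, W, 1, N)` from [stack_images()], or a
#'   list of `image_sample` matrices.
#' @param y Character/factor labels (`"HVA"`/`"LVA"`).
#' @param x_val,y_val Optional validation set, monitored once per epoch.
#' @param cfg A [model_config()].
#' @return Object of class `emofc_cnn` with elements `arch`, `params`,
#'   `cfg`, `history` (tibble of per-epoch loss/accuracy).
#' @export
train_cnn <- function(x, y, x_val = NULL, y_val = NULL,
                      cfg = model_config()) {
  if (length(x) == 0 || length(y) == 0) {
    abort_emofc("empty training set", class = "emofc_config_error")
  }
  if (is.list(x) && !is.array(x)) x <- stack_images(x, cfg$input_size)
  y <- factor(as.character(y), levels = class_levels())
  if (anyNA(y)) {
    abort_emofc("labels must be HVA or LVA", class = "emofc_config_error")
  }
  arch <- build_arch(cfg$scale)
  n <- dim(x)[4]
  history <- list()
  with_seed(cfg$seed, {
    params <- init_params(arch, in_ch = dim(x)[3])
    state <- list(m = tree_zero(params), v = tree_zero(params))
    step <- 0
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      tot_loss <- 0
      tot_correct <- 0
      for (bi in batches) {
        xb <- x[, , , bi, drop = FALSE]
        yb <- as.integer(y[bi])
        fw <- net_forward(arch, params, xb)
        probs <- softmax_probs(fw$z)
        nb <- length(bi)
        onehot <- matrix(0, 2, nb)
        onehot[cbind(yb, seq_len(nb))] <- 1
        tot_loss <- tot_loss -
          sum(log(pmax(probs[cbind(yb, seq_len(nb))], 1e-12)))
        tot_correct <- tot_correct +
          sum(apply(probs, 2, which.max) == yb)
        gz <- (probs - onehot) / nb
        grads <- net_backward(arch, params, fw$caches, gz)
        step <- step + 1
        upd <- adam_step(params, grads, state, cfg$learning_rate, step)
        params <- upd$params
        state <- upd$state
      }
      val_acc <- NA_real_
      if (!is.null(x_val)) {
        vx <- if (is.list(x_val) && !is.array(x_val)) {
          stack_images(x_val, cfg$input_size)
        } else {
          x_val
        }
        vp <- softmax_probs(net_forward(arch, params, vx)$z)
        val_acc <- mean(class_levels()[apply(vp, 2, which.max)] ==
          as.character(y_val))
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = tot_loss / n,
        train_accuracy = tot_correct / n, val_accuracy = val_acc
      )
    }
    structure(
      list(
        arch = arch, params = params, cfg = cfg,
        history = dplyr::bind_rows(history)
      ),
      class = "emofc_cnn"
    )
  })
}

#' Predict class probabilities or labels from a trained CNN
#'
#' Softmax outputs: per-sample probabilities over the two classes sum
#' to 1.
#'
#' @param object An `emofc_cnn`.
#' @param x Image tensor or list of images.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @return Matrix `N x 2` of probabilities (columns HVA, LVA) or a factor
#'   of predicted labels.
#' @export
predict.emofc_cnn <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.list(x) && !is.array(x)) {
    x <- stack_images(x, object$cfg$input_size)
  }
  probs <- t(softmax_probs(net_forward(object$arch, object$params, x)$z))
  colnames(probs) <- class_levels()
  if (type == "prob") {
    return(probs)
  }
  factor(class_levels()[max.col(probs, ties.method = "first")],
    levels = class_levels()
  )
}

#' @export
print.emofc_cnn <- function(x, ...) {
  cl <- count_layers(x$cfg$scale)
  cat(sprintf(
    "<emofc_cnn> scale=%s (%d conv + %d separable conv, %d modules), %d epochs\n",
    x$cfg$scale, cl$common_conv, cl$separable, cl$modules,
    nrow(x$history)
  ))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf(
      "  final loss %.4f, train acc %.3f\n", last$loss,
      last$train_accuracy
    ))
  }
  invisible(x)
}

#' @describeIn train_cnn Per-epoch training history as a tibble.
#' @param x An `emofc_cnn`.
#' @param ... Unused.
#' @method tidy emofc_cnn
#' @export
tidy.emofc_cnn <- function(x, ...) x$history

#' @describeIn train_cnn One-row model summary.
#' @method glance emofc_cnn
#' @export
glance.emofc_cnn <- function(x, ...) {
  cl <- count_layers(x$cfg$scale)
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    scale = x$cfg$scale, epochs = nrow(x$history),
    common_conv_layers = cl$common_conv,
    separable_conv_layers = cl$separable, modules = cl$modules,
    final_loss = last$loss, train_accuracy = last$train_accuracy,
    val_accuracy = last$val_accuracy
  )
}
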