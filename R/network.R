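# The binding-prediction network: sigmoid(FC(f_R(f_S(f_C(X))))), where
#   f_C = ReLU(BN(Conv2d)) over the L x D sequence-and-structure plane,
#   f_S = squeeze-excitation channel recalibration x (x) sigmoid(W2 ReLU(W1 z)),
#   f_R = ResidualBlock1d(AvgPool_D(ResidualBlock2d(x))),
# with ResidualBlock(x) = ReLU(x + B3(ReLU(B2(ReLU(B1(x)))))), B_j = BN(Conv_j).
# Dropout follows each residual block. Parameters live in a flat named list;
# gradients mirror that structure, which keeps Adam and clipping generic.

#' Model configuration
#'
#' @param L site length (default 101).
#' @param D input depth: 4 one-hot sequence channels + 1 reactivity channel.
#' @param conv_kernel 2d kernel (l, d), both odd so "same" padding
#'   \code{((l-1)/2, (d-1)/2)} preserves the spatial shape.
#' @param channels feature-map count C, constant along the residual path
#'   (the identity shortcut \code{x + I(x)} requires equal widths).
#' @param se_reduction SE dimension-reduction ratio r (must divide C).
#' @param res2_kernel 2d kernel of the residual-block convolutions.
#' @param res1_kernel 1d kernel length for the post-pooling residual block.
#' @param fc_hidden hidden width of the fully connected head.
#' @param dropout dropout probabilities after the 2d and 1d residual blocks.
#' @param bn_momentum,bn_eps batch-norm running-estimate momentum and
#'   numerical-stability constant.
#' @return a \code{model_config} list.
#' @export
model_config <- function(L = 101L, D = 5L, conv_kernel = c(7L, 5L),
                         channels = 8L, se_reduction = 2L,
                         res2_kernel = c(7L, 5L), res1_kernel = 7L,
                         fc_hidden = 256L, dropout = c(0.5, 0.3),
                         bn_momentum = 0.1, bn_eps = 1e-5) {
  if (any(c(conv_kernel, res2_kernel) %% 2 == 0) || res1_kernel %% 2 == 0) {
    stop("kernel sizes must be odd for same padding")
  }
  if (channels %% se_reduction != 0) {
    stop("se_reduction must divide channels")
  }
  structure(list(L = as.integer(L), D = as.integer(D),
                 conv_kernel = as.integer(conv_kernel),
                 channels = as.integer(channels),
                 se_reduction = as.integer(se_reduction),
                 res2_kernel = as.integer(res2_kernel),
                 res1_kernel = as.integer(res1_kernel),
                 fc_hidden = as.integer(fc_hidden), dropout = dropout,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "model_config")
}

kaiming <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build a model with Kaiming-initialized weights
#'
#' Convolution and fully connected weights are drawn from
#' \code{N(0, sqrt(2/fan_in))}; batch-norm scale/shift start at 1/0, and all
#' running statistics at 0/1. Reproducible given \code{seed}.
#'
#' @param config a [model_config()].
#' @param seed RNG seed.
#' @return a model object (list with \code{params}, \code{state},
#'   \code{config}).
#' @export
build_model <- function(config = model_config(), seed = 1) {
  C <- config$channels
  l <- config$conv_kernel[1]; d <- config$conv_kernel[2]
  l2 <- config$res2_kernel[1]; d2 <- config$res2_kernel[2]
  l1 <- config$res1_kernel
  Cr <- C %/% config$se_reduction
  with_seed(seed, {
    p <- list()
    p[["conv1.W"]] <- kaiming(c(1L, l, d, C), l * d)
    p[["bn1.gamma"]] <- rep(1, C); p[["bn1.beta"]] <- rep(0, C)
    p[["se.W1"]] <- kaiming(c(Cr, C), C)
    p[["se.W2"]] <- kaiming(c(C, Cr), Cr)
    for (j in 1:3) {
      p[[paste0("res2.conv", j, ".W")]] <- kaiming(c(C, l2, d2, C),
                                                   C * l2 * d2)
      p[[paste0("res2.bn", j, ".gamma")]] <- rep(1, C)
      p[[paste0("res2.bn", j, ".beta")]] <- rep(0, C)
      p[[paste0("res1.conv", j, ".W")]] <- kaiming(c(C, l1, C), C * l1)
      p[[paste0("res1.bn", j, ".gamma")]] <- rep(1, C)
      p[[paste0("res1.bn", j, ".beta")]] <- rep(0, C)
    }
    p[["fc1.W"]] <- kaiming(c(config$fc_hidden, config$L * C), config$L * C)
    p[["fc1.b"]] <- rep(0, config$fc_hidden)
    p[["fc2.W"]] <- kaiming(c(1L, config$fc_hidden), config$fc_hidden)
    p[["fc2.b"]] <- 0
    st <- list()
    for (nm in c("bn1", paste0("res2.bn", 1:3), paste0("res1.bn", 1:3))) {
      st[[nm]] <- list(mean = rep(0, C), var = rep(1, C))
    }
    structure(list(params = p, state = st, config = config),
              class = "rbpnet_model")
  })
}

# Residual block forward shared by the 2d and 1d variants; `cf`/`cb` are the
# matching conv forward/backward functions.
res_forward <- function(x, params, prefix, model, mode, cf) {
  cfg <- model$config
  h <- x; caches <- list()
  for (j in 1:3) {
    cv <- cf(h, params[[paste0(prefix, ".conv", j, ".W")]])
    bn <- bn_forward(cv$out, params[[paste0(prefix, ".bn", j, ".gamma")]],
                     params[[paste0(prefix, ".bn", j, ".beta")]],
                     model$state[[paste0(prefix, ".bn", j)]], mode,
                     cfg$bn_momentum, cfg$bn_eps)
    model$state[[paste0(prefix, ".bn", j)]] <- bn$state
    caches[[j]] <- list(conv = cv, bn = bn$cache)
    h <- bn$out
    if (j < 3) {
      rl <- relu_forward(h)
      caches[[j]]$relu <- rl$mask
      h <- rl$out
    }
  }
  rl <- relu_forward(x + h)
  list(out = rl$out, cache = list(inner = caches, out_mask = rl$mask),
       state = model$state)
}

res_backward <- function(dout, cache, params, prefix, cb, guided = FALSE) {
  d <- relu_backward(dout, cache$out_mask, guided)
  dskip <- d
  grads <- list()
  for (j in 3:1) {
    cc <- cache$inner[[j]]
    if (j < 3) d <- relu_backward(d, cc$relu, guided)
    bb <- bn_backward(d, cc$bn, params[[paste0(prefix, ".bn", j, ".gamma")]])
    grads[[paste0(prefix, ".bn", j, ".gamma")]] <- bb$dgamma
    grads[[paste0(prefix, ".bn", j, ".beta")]] <- bb$dbeta
    cv <- cb(bb$dx, cc$conv, params[[paste0(prefix, ".conv", j, ".W")]])
    grads[[paste0(prefix, ".conv", j, ".W")]] <- cv$dW
    d <- cv$dx
  }
  list(dx = d + dskip, grads = grads)
}

#' Forward pass
#'
#' @param model model from [build_model()].
#' @param X input array, either \code{N x L x D} or a single \code{L x D}
#'   matrix.
#' @param mode \code{"eval"} (deterministic: running BN statistics, no
#'   dropout) or \code{"train"}.
#' @param keep_cache keep intermediates for [backward_pass()].
#' @return list with \code{y} (probabilities in (0,1)), the updated
#'   \code{model} (BN running stats advance in train mode) and, if requested,
#'   \code{cache}.
#' @export
forward_pass <- function(model, X, mode = c("eval", "train"),
                         keep_cache = FALSE) {
  mode <- match.arg(mode)
  cfg <- model$config
  if (length(dim(X)) == 2) X <- array(X, c(1L, dim(X)))
  stopifnot(dim(X)[2] == cfg$L, dim(X)[3] == cfg$D)
  N <- dim(X)[1]
  p <- model$params
  cache <- list(X = X, mode = mode)

  x4 <- array(X, c(N, cfg$L, cfg$D, 1L))
  cv1 <- conv2d_forward(x4, p[["conv1.W"]])
  bn1 <- bn_forward(cv1$out, p[["bn1.gamma"]], p[["bn1.beta"]],
                    model$state[["bn1"]], mode, cfg$bn_momentum, cfg$bn_eps)
  model$state[["bn1"]] <- bn1$state
  rl1 <- relu_forward(bn1$out)
  cache$conv1 <- cv1; cache$bn1 <- bn1$cache; cache$relu1 <- rl1$mask

  se <- se_forward(rl1$out, p[["se.W1"]], p[["se.W2"]])
  cache$se <- se$cache

  r2 <- res_forward(se$out, p, "res2", model, mode, conv2d_forward)
  model$state <- r2$state
  cache$res2 <- r2$cache
  dp1 <- dropout_forward(r2$out, cfg$dropout[1], mode)
  cache$drop1 <- dp1$mask

  ap <- avgpool_d_forward(dp1$out)
  cache$pool <- ap

  r1 <- res_forward(ap$out, p, "res1", model, mode, conv1d_forward)
  model$state <- r1$state
  cache$res1 <- r1$cache
  dp2 <- dropout_forward(r1$out, cfg$dropout[2], mode)
  cache$drop2 <- dp2$mask

  flat <- matrix(dp2$out, nrow = N)          # N x (L*C), length-major blocks
  f1 <- fc_forward(flat, p[["fc1.W"]], p[["fc1.b"]])
  rlf <- relu_forward(f1$out)
  f2 <- fc_forward(rlf$out, p[["fc2.W"]], p[["fc2.b"]])
  y <- as.vector(sigmoid(f2$out))
  cache$fc1 <- f1; cache$reluf <- rlf$mask; cache$fc2 <- f2; cache$y <- y
  cache$flat_dim <- dim(dp2$out)

  out <- list(y = y, model = model)
  if (keep_cache) out$cache <- cache
  out
}

#' Backward pass
#'
#' Backpropagates \code{dL/dy} (gradient w.r.t. the output probabilities)
#' through the whole graph, returning parameter gradients and the gradient
#' w.r.t. the input (used by the saliency map).
#'
#' @param model model object.
#' @param cache cache from \code{forward_pass(..., keep_cache = TRUE)}.
#' @param dy numeric vector, gradient of the objective w.r.t. y.
#' @param guided apply guided-backpropagation gating at every ReLU.
#' @return list with \code{grads} (flat named list matching
#'   \code{model$params}) and \code{dX} (N x L x D).
#' @export
backward_pass <- function(model, cache, dy, guided = FALSE) {
  p <- model$params
  cfg <- model$config
  N <- length(cache$y)
  grads <- list()

  dpre <- matrix(dy * cache$y * (1 - cache$y), ncol = 1)
  b2 <- fc_backward(dpre, cache$fc2, p[["fc2.W"]])
  grads[["fc2.W"]] <- b2$dW; grads[["fc2.b"]] <- b2$db
  dh <- relu_backward(b2$dx, cache$reluf, guided)
  b1 <- fc_backward(dh, cache$fc1, p[["fc1.W"]])
  grads[["fc1.W"]] <- b1$dW; grads[["fc1.b"]] <- b1$db

  d <- array(b1$dx, cache$flat_dim)
  d <- dropout_backward(d, cache$drop2)
  r1 <- res_backward(d, cache$res1, p, "res1", conv1d_backward, guided)
  grads <- c(grads, r1$grads)
  d <- avgpool_d_backward(r1$dx, cache$pool)
  d <- dropout_backward(d, cache$drop1)
  r2 <- res_backward(d, cache$res2, p, "res2", conv2d_backward, guided)
  grads <- c(grads, r2$grads)
  se <- se_backward(r2$dx, cache$se, p[["se.W1"]], p[["se.W2"]])
  grads[["se.W1"]] <- se$dW1; grads[["se.W2"]] <- se$dW2
  d <- relu_backward(se$dx, cache$relu1, guided)
  bb <- bn_backward(d, cache$bn1, p[["bn1.gamma"]])
  grads[["bn1.gamma"]] <- bb$dgamma; grads[["bn1.beta"]] <- bb$dbeta
  cv <- conv2d_backward(bb$dx, cache$conv1, p[["conv1.W"]])
  grads[["conv1.W"]] <- cv$dW
  dX <- array(cv$dx, c(N, cfg$L, cfg$D))
  list(grads = grads, dX = dX)
}

#' Weighted binary cross-entropy loss with L2 weight decay
#'
#' \code{Loss = -(1/N) sum(p_c t log y + (1-t) log(1-y)) + lambda sum(w^2)},
#' natural log, probabilities clipped to \code{[1e-7, 1-1e-7]}.
#'
#' @param y predicted probabilities.
#' @param t 0/1 labels.
#' @param params model parameter list (for the penalty); NULL to skip.
#' @param pos_weight positive-class weight p_c (default 2).
#' @param lambda L2 penalty weight (default 1e-6).
#' @return list with scalar \code{loss} and \code{dy}, the gradient
#'   w.r.t. \code{y}.
#' @export
bce_loss <- function(y, t, params = NULL, pos_weight = 2, lambda = 1e-6) {
  N <- length(y)
  if (N == 0) stop("empty batch")
  stopifnot(length(t) == N)
  yc <- pmin(pmax(y, 1e-7), 1 - 1e-7)
  data_loss <- -mean(pos_weight * t * log(yc) + (1 - t) * log(1 - yc))
  reg <- 0
  if (!is.null(params) && lambda > 0) {
    reg <- lambda * sum(vapply(params, function(w) sum(w^2), numeric(1)))
  }
  dy <- -(pos_weight * t / yc - (1 - t) / (1 - yc)) / N
  dy[y != yc] <- 0   # clipped probabilities are locally flat
  list(loss = data_loss + reg, dy = dy)
}

# Add the L2-penalty gradient 2*lambda*w to a gradient list.
add_l2_grad <- function(grads, params, lambda) {
  if (lambda <= 0) return(grads)
  for (nm in names(params)) grads[[nm]] <- grads[[nm]] + 2 * lambda * params[[nm]]
  grads
}

#' Predict binding probabilities for a batch of encoded sites
#' @param model trained model.
#' @param X encoded input (N x L x D or L x D).
#' @param batch_size evaluation batch size.
#' @return numeric vector of probabilities.
#' @export
predict_batch <- function(model, X, batch_size = 256L) {
  if (length(dim(X)) == 2) X <- array(X, c(1L, dim(X)))
  n <- dim(X)[1]
  y <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    y[s:e] <- forward_pass(model, X[s:e, , , drop = FALSE], "eval")$y
  }
  y
}

#' Save / load a model checkpoint
#'
#' Plain-text JSON checkpoint: parameters, BN state, configuration and an
#' optional training manifest.
#'
#' @param model model object.
#' @param path file path.
#' @param manifest optional list (seed, epochs, best AUROC, ...).
#' @export
save_model <- function(model, path, manifest = NULL) {
  obj <- list(
    format_version = 1L,
    config = unclass(model$config),
    param_dims = lapply(model$params, function(w) dim(w) %||% length(w)),
    params = lapply(model$params, as.vector),
    state = model$state,
    manifest = manifest
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config)
  params <- mapply(function(v, d) {
    if (length(d) > 1) array(v, unlist(d)) else as.numeric(v)
  }, obj$params, obj$param_dims, SIMPLIFY = FALSE)
  state <- lapply(obj$state, function(s)
    list(mean = as.numeric(s$mean), var = as.numeric(s$var)))
  structure(list(params = params, state = state, config = cfg,
                 manifest = obj$manifest),
            class = "rbpnet_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
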