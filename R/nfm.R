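#' Initialize neural factorization machine parameters
#'
#' The NFM scores an n-dimensional instance x as
#' \deqn{\hat y(x) = w_0 + \sum_i w_i x_i + p^T z_L,}
#' where the network part embeds each scalar feature i as \eqn{x_i v_i}
#' (a dense k-vector), pools all pairs through the Bi-Interaction layer
#' \eqn{f_{BI} = \sum_{i<j} (x_i v_i) \odot (x_j v_j)}, and pushes the pooled
#' vector through a stack of fully connected layers \eqn{z_l = \sigma_l(W_l
#' z_{l-1} + b_l)} to the prediction weights p.  A logistic link turns the
#' raw score into an interaction probability.
#'
#' Initialization is Xavier-uniform from `seed` for `V`, the hidden weights
#' and `p`; `w0` and `w` start at zero.
#'
#' @param n Number of input features.
#' @param k Feature-embedding dimension (default 64).
#' @param hidden Integer vector of hidden-layer widths (default one layer of
#'   64).
#' @param activation `"relu"`, `"tanh"`, or `"identity"` for the hidden
#'   stack.
#' @param dropout Dropout rate applied to the Bi-Interaction output during
#'   training (default 0.2).
#' @param seed Integer seed.
#' @param field_spec Optional named integer vector of block widths recorded
#'   alongside the parameters (see [assemble_features()]).
#' @return An object of class `nfm_params`.
#' @export
nfm_params <- function(n, k = 64, hidden = 64, activation = "relu",
                       dropout = 0.2, seed = 1, field_spec = NULL) {
  stopifnot(n >= 1, k >= 1, activation %in% c("relu", "tanh", "identity"),
            dropout >= 0, dropout < 1)
  dims <- c(k, hidden)
  params <- NULL
  local_seed(seed, {
    xav <- function(fan_in, fan_out) {
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_out, fan_in)
    }
    layers <- purrr::map(seq_along(hidden), function(l) {
      list(W = xav(dims[l], dims[l + 1]), b = double(dims[l + 1]))
    })
    params <- list(
      w0 = 0,
      w = double(n),
      V = xav(k, n),                        # n x k (fan_out rows)
      layers = layers,
      p = drop(xav(utils::tail(dims, 1), 1)),
      activation = activation,
      dropout = dropout,
      n = as.integer(n), k = as.integer(k),
      seed = as.integer(seed),
      field_spec = field_spec)
  })
  params$V <- matrix(params$V, n, k)
  structure(params, class = "nfm_params")
}

#' @export
print.nfm_params <- function(x, ...) {
  cat("<nfm_params> n =", x$n, ", k =", x$k, ", hidden:",
      paste(purrr::map_int(x$layers, ~ length(.x$b)), collapse = "-"),
      paste0("(", x$activation, ")"), "\n")
  invisible(x)
}

#' Embed the features of one instance
#'
#' Returns the set of scaled embedding vectors
#' \eqn{V_x = \{x_1 v_1, ..., x_n v_n\}} as an n x k matrix; zero-valued
#' features contribute zero rows.
#'
#' @param x Numeric instance vector of length n.
#' @param V n x k feature-embedding matrix.
#' @return n x k matrix whose i-th row is `x[i] * V[i, ]`.
#' @export
embed_features <- function(x, V) {
  V <- as.matrix(V)
  if (length(x) != nrow(V)) {
    stop("embed_features(): length(x) must equal nrow(V)", call. = FALSE)
  }
  V * x
}

#' Bi-Interaction pooling
#'
#' Pools a set of scaled embedding vectors into one k-vector:
#' \eqn{f_{BI} = \sum_{i<j} u_i \odot u_j}, computed with the O(nk) identity
#' \eqn{0.5 [ (\sum_i u_i)^{\odot 2} - \sum_i u_i^{\odot 2} ]}.
#' A single row (no pairs) pools to the zero vector.
#'
#' @param Vx n x k matrix of scaled embeddings (rows \eqn{u_i = x_i v_i}).
#' @return Numeric vector of length k.
#' @export
bi_interaction <- function(Vx) {
  Vx <- as.matrix(Vx)
  if (nrow(Vx) == 0) {
    stop("bi_interaction(): empty embedding set", call. = FALSE)
  }
  0.5 * (colSums(Vx)^2 - colSums(Vx^2))
}

# activation and its derivative as a function of the activated output
act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(a) (a > 0) * 1),
         tanh = list(f = tanh,
                     df = function(a) 1 - a^2),
         identity = list(f = identity,
                         df = function(a) a * 0 + 1))
}

# batch forward pass; X is B x n.  Returns score, probability and the caches
# needed for backprop.  `mask` (B x k or NULL) is the inverted-dropout mask
# applied to the Bi-Interaction output.
nfm_forward_batch <- function(X, params, mask = NULL) {
  act <- act_fun(params$activation)
  S <- X %*% params$V                       # B x k: sum_i x_i v_i
  Q <- (X^2) %*% (params$V^2)               # B x k: sum_i (x_i v_i)^2
  f_bi <- 0.5 * (S^2 - Q)
  z <- if (is.null(mask)) f_bi else f_bi * mask
  zs <- list(z)
  for (l in seq_along(params$layers)) {
    z <- act$f(sweep(z %*% t(params$layers[[l]]$W), 2,
                     params$layers[[l]]$b, `+`))
    if (any(!is.finite(z))) {
      stop("nfm_forward(): non-finite activation in hidden layer ", l,
           call. = FALSE)
    }
    zs[[l + 1]] <- z
  }
  score <- params$w0 + drop(X %*% params$w) + drop(z %*% params$p)
  list(score = score, probability = logistic(score),
       S = S, f_bi = f_bi, zs = zs, mask = mask)
}

#' NFM forward pass for one instance
#'
#' @param x Numeric instance vector of length n (or a B x n matrix for a
#'   batch).
#' @param params An `nfm_params` object.
#' @return List with `score` (raw \eqn{\hat y}) and `probability`
#'   (logistic of the score).
#' @export
nfm_forward <- function(x, params) {
  X <- if (is.matrix(x)) x else matrix(x, 1)
  if (ncol(X) != params$n) {
    stop("nfm_forward(): instance width ", ncol(X), " != n = ", params$n,
         call. = FALSE)
  }
  out <- nfm_forward_batch(X, params)
  list(score = unname(out$score), probability = unname(out$probability))
}

# gradients of the mean binary cross-entropy over the batch wrt all
# parameters; shares the forward cache.  l2 adds weight decay on w, V,
# hidden weights and p.
nfm_gradients <- function(X, y, params, mask = NULL, l2 = 0) {
  B <- nrow(X)
  act <- act_fun(params$activation)
  fw <- nfm_forward_batch(X, params, mask = mask)
  dscore <- (fw$probability - y) / B        # B
  g <- list(w0 = sum(dscore),
            w = drop(crossprod(X, dscore)) + l2 * params$w)
  zL <- fw$zs[[length(fw$zs)]]
  g$p <- drop(crossprod(zL, dscore)) + l2 * params$p
  dz <- outer(dscore, params$p)             # B x width(L)
  g$layers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    a <- fw$zs[[l + 1]]
    dpre <- dz * act$df(a)
    g$layers[[l]] <- list(W = crossprod(dpre, fw$zs[[l]]) +
                            l2 * params$layers[[l]]$W,
                          b = colSums(dpre))
    dz <- dpre %*% params$layers[[l]]$W
  }
  dfbi <- if (is.null(mask)) dz else dz * mask
  # f_bi = 0.5 (S^2 - Q): dV = X'(dfbi * S) - V * (X^2)' dfbi
  g$V <- crossprod(X, dfbi * fw$S) - params$V * crossprod(X^2, dfbi) +
    l2 * params$V
  g$loss <- mean(-(y * log(pmax(fw$probability, 1e-12)) +
                     (1 - y) * log(pmax(1 - fw$probability, 1e-12))))
  g
}

#' Train a neural factorization machine
#'
#' Minimizes binary cross-entropy of the logistic-linked NFM score with Adam
#' over seeded mini-batches.  Training is deterministic given the
#' configuration and seed; `epochs = 0` returns the seeded initialization
#' unchanged.  Dropout (inverted scaling) is applied to the Bi-Interaction
#' output during training only.
#'
#' @param x B x n numeric matrix of instances.
#' @param labels Binary vector of length B; both classes must be present.
#' @param k,hidden,activation,dropout,seed Passed to [nfm_params()].
#' @param epochs Training epochs (>= 0).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param l2 Weight-decay coefficient.
#' @param field_spec Optional block-width spec stored with the parameters.
#' @return A trained `nfm_params` object with a `loss` attribute (mean
#'   per-epoch training loss).
#' @export
train_nfm <- function(x, labels, k = 64, hidden = 64, activation = "relu",
                      dropout = 0.2, epochs = 20, lr = 0.01, batch_size = 256,
                      l2 = 1e-6, seed = 1, field_spec = NULL) {
  X <- as.matrix(x)
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y), epochs >= 0)
  if (length(unique(y)) < 2) {
    stop("train_nfm(): both classes must be present in the labels",
         call. = FALSE)
  }
  params <- nfm_params(ncol(X), k = k, hidden = hidden,
                       activation = activation, dropout = dropout,
                       seed = seed, field_spec = field_spec)
  if (epochs == 0) return(params)
  flat <- nfm_flatten(params)
  m <- v <- flat * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  loss_trace <- double(epochs)
  for (epoch in seq_len(epochs)) {
    perm <- NULL
    local_seed(seed_from(seed, 31L + epoch), {
      perm <- sample.int(nrow(X))
      masks <- if (dropout > 0) {
        matrix(stats::rbinom(nrow(X) * params$k, 1, 1 - dropout),
               nrow(X), params$k) / (1 - dropout)
      }
    })
    starts <- seq(1, nrow(X), by = batch_size)
    epoch_loss <- 0
    for (s in starts) {
      sel <- perm[s:min(s + batch_size - 1, nrow(X))]
      mask <- if (dropout > 0) masks[sel, , drop = FALSE]
      gr <- nfm_gradients(X[sel, , drop = FALSE], y[sel], params,
                          mask = mask, l2 = l2)
      epoch_loss <- epoch_loss + gr$loss * length(sel)
      gflat <- nfm_flatten(gr, like = params)
      t <- t + 1
      m <- b1 * m + (1 - b1) * gflat
      v <- b2 * v + (1 - b2) * gflat^2
      step <- lr * sqrt(1 - b2^t) / (1 - b1^t) * m / (sqrt(v) + eps)
      params <- nfm_unflatten(nfm_flatten(params) - step, params)
    }
    loss_trace[epoch] <- epoch_loss / nrow(X)
    if (!is.finite(loss_trace[epoch])) {
      stop("train_nfm(): training diverged at epoch ", epoch, call. = FALSE)
    }
  }
  attr(params, "loss") <- loss_trace
  params
}

# pack parameters (or a gradient list shaped like them) into one vector
nfm_flatten <- function(p, like = p) {
  c(p$w0, p$w, as.vector(p$V),
    unlist(purrr::map(seq_along(like$layers),
                      ~ c(as.vector(p$layers[[.x]]$W), p$layers[[.x]]$b))),
    p$p)
}

nfm_unflatten <- function(flat, template) {
  out <- template
  i <- 1
  take <- function(n) {
    v <- flat[i:(i + n - 1)]
    i <<- i + n
    v
  }
  out$w0 <- take(1)
  out$w <- take(length(template$w))
  out$V <- matrix(take(length(template$V)), nrow(template$V), ncol(template$V))
  for (l in seq_along(template$layers)) {
    W <- template$layers[[l]]$W
    out$layers[[l]]$W <- matrix(take(length(W)), nrow(W), ncol(W))
    out$layers[[l]]$b <- take(length(template$layers[[l]]$b))
  }
  out$p <- take(length(template$p))
  out
}

#' Serialize / load NFM parameters
#'
#' One JSON file carrying a manifest (shapes, activation, field_spec, seed)
#' and every parameter array printed with 17 significant digits, so a reload
#' reproduces the parameters exactly.
#'
#' @param params An `nfm_params` object.
#' @param path File path.
#' @return `path` (writer); an `nfm_params` object (reader).
#' @export
write_nfm <- function(params, path) {
  num <- function(x) sprintf("%.17g", x)
  obj <- list(
    manifest = list(n = params$n, k = params$k,
                    hidden = purrr::map_int(params$layers, ~ length(.x$b)),
                    activation = params$activation,
                    dropout = params$dropout,
                    seed = params$seed,
                    field_spec = as.list(params$field_spec)),
    w0 = num(params$w0), w = num(params$w), V = num(as.vector(params$V)),
    layers = purrr::map(params$layers,
                        ~ list(W = num(as.vector(.x$W)), b = num(.x$b))),
    p = num(params$p))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nfm
#' @export
read_nfm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  man <- obj$manifest
  fs <- unlist(man$field_spec)
  template <- nfm_params(man$n, k = man$k,
                         hidden = if (length(man$hidden)) man$hidden else integer(),
                         activation = man$activation, dropout = man$dropout,
                         seed = man$seed,
                         field_spec = if (length(fs)) fs)
  template$w0 <- as.double(obj$w0)
  template$w <- as.double(obj$w)
  template$V <- matrix(as.double(obj$V), man$n, man$k)
  if (length(template$layers)) {
    dims <- c(man$k, man$hidden)
    for (l in seq_along(template$layers)) {
      template$layers[[l]]$W <- matrix(as.double(obj$layers$W[[l]]),
                                       dims[l + 1], dims[l])
      template$layers[[l]]$b <- as.double(obj$layers$b[[l]])
    }
  }
  template$p <- as.double(obj$p)
  template
}
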