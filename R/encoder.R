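## The prompt-guided encoder: a small transformer-style network over the
## amino-acid vocabulary. One learned prompt vector per pretraining task is
## prepended as an extra token; all decoder heads consume the same
## per-residue representations. Forward/backward passes are written out
## explicitly so training and the finite-difference gradient checks share
## one code path.

#' Initialize a prompt-guided encoder
#'
#' The input embedding of each residue is its token embedding mixed with a
#' learned linear map of the embeddings in a small sequence window (local
#' context, so short sequence patterns are visible to the attention
#' layers), plus a fixed sinusoidal positional encoding. Transformer-style
#' attention + feed-forward blocks follow; one learned prompt vector per
#' pretraining task is prepended as an extra token.
#'
#' @param d Representation width (also the pair-projection width `dW`).
#' @param n_layers Number of attention + feed-forward blocks.
#' @param h Feed-forward hidden width.
#' @param hc Hidden width of the two-layer coordinate head.
#' @param seed Integer seed for the parameter draw.
#' @param init_sd Standard deviation of the initial parameter draw.
#' @param scale_attn Divide pair-attention logits by `dW` (see
#'   [pair_representation()]).
#' @param conv_window Half-width of the local context window in the
#'   embedding layer.
#' @param pe_scale Amplitude of the additive sinusoidal positional
#'   encoding.
#' @return A `ModelState`: nested list of parameter matrices (embedding
#'   table, task prompts, local-context maps, per-layer
#'   attention/feed-forward weights, token, coordinate and pair heads,
#'   prompt-tuning module).
#' @export
init_model <- function(d = 16L, n_layers = 2L, h = 2L * d, hc = 2L * d,
                       seed = 1L, init_sd = 0.15, scale_attn = TRUE,
                       conv_window = 2L, pe_scale = 0.1) {
  n_tok <- .MASK_ID
  with_seed(substream_seed(seed, "model-init"), {
    rmat <- function(a, b) matrix(rnorm(a * b, sd = init_sd), a, b)
    offsets <- setdiff(seq(-conv_window, conv_window), 0L)
    conv <- stats::setNames(lapply(offsets, function(o) rmat(d, d)),
                            paste0("off", ifelse(offsets < 0, "m", "p"),
                                   abs(offsets)))
    layers <- stats::setNames(
      lapply(seq_len(n_layers), function(i) list(
        Wq = rmat(d, d), Wk = rmat(d, d), Wv = rmat(d, d),
        W1 = rmat(d, h), b1 = numeric(h),
        W2 = rmat(h, d), b2 = numeric(d))),
      paste0("layer", seq_len(n_layers)))
    structure(list(
      config = list(d = d, n_layers = n_layers, h = h, hc = hc,
                    scale_attn = scale_attn, conv_window = conv_window,
                    pe_scale = pe_scale, conv_offsets = offsets),
      E = rmat(n_tok, d),
      prompts = rmat(3L, d),              # rows: MLM, CRD, PPI
      conv = conv,
      layers = layers,
      U = rmat(d, .N_AA), bu = numeric(.N_AA),
      Wc1 = rmat(d, hc), bc1 = numeric(hc),
      Wc2 = rmat(hc, 3L), bc2 = numeric(3L),
      W = rmat(d, d),                     # pair projection
      # pair-classification head: one-hidden-layer perceptron on the
      # 2d pair representation (a linear head cannot express "both
      # proteins carry the same latent pattern")
      pair_head = list(W1 = rmat(2L * d, 2L * d), b1 = numeric(2L * d),
                       w2 = rnorm(2L * d, sd = init_sd), b2 = 0),
      tuner = list(weight = rmat(d, 3L * d), bias = numeric(d))
    ), class = "ModelState")
  })
}

#' @export
print.ModelState <- function(x, ...) {
  cfg <- x$config
  cat("Prompt-guided multi-task protein encoder\n")
  cat(sprintf("  width d = %d, layers = %d, ff width = %d\n",
              cfg$d, cfg$n_layers, cfg$h))
  cat(sprintf("  parameters: %d\n", length(flatten_params(x))))
  if (!is.null(x$trace))
    cat(sprintf("  trained %d epochs; loss %.4f -> %.4f\n",
                length(x$trace), x$trace[1], x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
coef.ModelState <- function(object, ...) flatten_params(object)

# ---- forward / backward ------------------------------------------------

# rows shifted by o (row i of result is X[i + o, ], zero outside)
.shift_rows <- function(X, o) {
  L <- nrow(X)
  out <- matrix(0, L, ncol(X))
  if (o > 0 && o < L) out[1:(L - o), ] <- X[(1 + o):L, , drop = FALSE]
  if (o < 0 && -o < L) out[(1 - o):L, ] <- X[1:(L + o), , drop = FALSE]
  out
}

# fixed sinusoidal positional encoding, L x d
.pe_matrix <- function(L, d) {
  pos <- seq_len(L)
  k <- seq_len(d)
  freq <- 1 / 10000^(((k - 1) %/% 2) * 2 / d)
  M <- outer(pos, freq)
  phase <- matrix(rep(k %% 2 == 0, each = L), L, d)
  ifelse(phase, cos(M), sin(M))
}

# tokens: integer vector; prompt: length-d vector prepended as token 0.
# Returns list(H = L x d residue representations, cache for backward).
encode_forward <- function(model, tokens, prompt) {
  d <- model$config$d
  E0 <- model$E[tokens, , drop = FALSE]
  Xr <- E0
  for (i in seq_along(model$conv)) {
    o <- model$config$conv_offsets[i]
    Xr <- Xr + .shift_rows(E0, o) %*% model$conv[[i]]
  }
  if (model$config$pe_scale > 0)
    Xr <- Xr + model$config$pe_scale * .pe_matrix(length(tokens), d)
  X <- rbind(prompt, Xr)
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    Q <- X %*% ly$Wq; K <- X %*% ly$Wk; M <- X %*% ly$Wv
    S <- tcrossprod(Q, K) / sqrt(d)
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    X1 <- X + A %*% M
    Tn <- tanh(sweep(X1 %*% ly$W1, 2, ly$b1, "+"))
    X2 <- X1 + sweep(Tn %*% ly$W2, 2, ly$b2, "+")
    caches[[i]] <- list(X = X, Q = Q, K = K, M = M, A = A, X1 = X1, Tn = Tn)
    X <- X2
  }
  list(H = X[-1L, , drop = FALSE],
       cache = list(tokens = tokens, E0 = E0, layers = caches))
}

# dH: gradient w.r.t. residue representations; dprompt_out: optional
# gradient w.r.t. the prompt row of the FINAL layer output (rarely needed).
# Returns grads for layers/E plus dprompt (gradient w.r.t. the input prompt).
encode_backward <- function(model, cache, dH, dprompt_out = NULL) {
  d <- model$config$d
  if (is.null(dprompt_out)) dprompt_out <- numeric(d)
  dX <- rbind(dprompt_out, dH)
  glayers <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]; ca <- cache$layers[[i]]
    # feed-forward block
    dF <- dX
    dT <- dF %*% t(ly$W2)
    dW2 <- crossprod(ca$Tn, dF); db2 <- colSums(dF)
    dpre <- dT * (1 - ca$Tn^2)
    dW1 <- crossprod(ca$X1, dpre); db1 <- colSums(dpre)
    dX1 <- dX + dpre %*% t(ly$W1)
    # attention block
    dXin <- dX1
    dA <- dX1 %*% t(ca$M)
    dM <- crossprod(ca$A, dX1)
    dWv <- crossprod(ca$X, dM)
    dXin <- dXin + dM %*% t(ly$Wv)
    dS <- ca$A * (dA - rowSums(dA * ca$A))
    dQ <- dS %*% ca$K / sqrt(d)
    dK <- crossprod(dS, ca$Q) / sqrt(d)
    dWq <- crossprod(ca$X, dQ); dWk <- crossprod(ca$X, dK)
    dXin <- dXin + dQ %*% t(ly$Wq) + dK %*% t(ly$Wk)
    glayers[[i]] <- list(Wq = dWq, Wk = dWk, Wv = dWv,
                         W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    dX <- dXin
  }
  dprompt <- dX[1L, ]
  dXr <- dX[-1L, , drop = FALSE]
  dE0 <- dXr                                 # direct embedding path
  gconv <- vector("list", length(model$conv))
  names(gconv) <- names(model$conv)
  for (i in seq_along(model$conv)) {
    o <- model$config$conv_offsets[i]
    Es <- .shift_rows(cache$E0, o)
    gconv[[i]] <- crossprod(Es, dXr)
    dE0 <- dE0 + .shift_rows(dXr %*% t(model$conv[[i]]), -o)
  }
  dE <- matrix(0, nrow(model$E), d)
  agg <- rowsum(dE0, group = cache$tokens)
  dE[as.integer(rownames(agg)), ] <- agg
  list(layers = glayers, E = dE, conv = gconv, dprompt = dprompt)
}

# heads --------------------------------------------------------------

token_head_forward <- function(model, H, positions) {
  sweep(H[positions, , drop = FALSE] %*% model$U, 2, model$bu, "+")
}

coord_head_forward <- function(model, H) {
  Tc <- tanh(sweep(H %*% model$Wc1, 2, model$bc1, "+"))
  list(coords = sweep(Tc %*% model$Wc2, 2, model$bc2, "+"), Tc = Tc)
}

coord_head_backward <- function(model, H, Tc, dC) {
  dTc <- dC %*% t(model$Wc2)
  dWc2 <- crossprod(Tc, dC); dbc2 <- colSums(dC)
  dpre <- dTc * (1 - Tc^2)
  dWc1 <- crossprod(H, dpre); dbc1 <- colSums(dpre)
  list(dH = dpre %*% t(model$Wc1),
       Wc1 = dWc1, bc1 = dbc1, Wc2 = dWc2, bc2 = dbc2)
}

# ---- parameter plumbing ------------------------------------------------

.trainable <- function(model) {
  model[setdiff(names(model), c("config", "trace", "proteins"))]
}

flatten_params <- function(model) {
  unlist(.trainable(model), use.names = FALSE)
}

unflatten_params <- function(model, flat) {
  tr <- .trainable(model)
  rel <- utils::relist(flat, tr)
  for (nm in names(rel)) {
    model[[nm]] <- .restore_shape(model[[nm]], rel[[nm]])
  }
  model
}

.restore_shape <- function(template, values) {
  if (is.list(template)) {
    for (nm in names(template))
      template[[nm]] <- .restore_shape(template[[nm]], values[[nm]])
    template
  } else if (is.matrix(template)) {
    matrix(unlist(values, use.names = FALSE), nrow(template), ncol(template))
  } else {
    as.numeric(unlist(values, use.names = FALSE))
  }
}

# zero-filled gradient accumulator with the trainable structure
zero_grads <- function(model) {
  z <- function(x) {
    if (is.list(x)) lapply(x, z) else x * 0
  }
  z(.trainable(model))
}

grad_axpy <- function(acc, g, a = 1) {       # acc + a * g, recursively
  if (is.list(acc)) {
    for (nm in names(acc)) if (!is.null(g[[nm]]))
      acc[[nm]] <- grad_axpy(acc[[nm]], g[[nm]], a)
    acc
  } else acc + a * g
}

# Adam over the nested parameter structure (flat internally)
adam_init <- function(model) {
  n <- length(flatten_params(model))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(model, grads, state, lr = 1e-2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      mask = NULL, clip = 25) {
  g <- unlist(grads, use.names = FALSE)
  if (!is.null(mask)) g <- g * mask
  gn <- sqrt(sum(g^2))                     # global-norm gradient clipping
  if (is.finite(clip) && gn > clip) g <- g * (clip / gn)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  step <- lr * mh / (sqrt(vh) + eps)
  model <- unflatten_params(model, flatten_params(model) - step)
  list(model = model, state = state)
}

# boolean mask over the flat parameter vector selecting named top-level blocks
param_mask <- function(model, blocks) {
  tr <- .trainable(model)
  unlist(lapply(names(tr), function(nm) {
    rep(nm %in% blocks, length(unlist(tr[[nm]], use.names = FALSE)))
  }))
}
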