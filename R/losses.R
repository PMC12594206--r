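## Pretraining losses and the prompt machinery.
## Conventions: sequences are integer token vectors over the amino-acid
## vocabulary; per-residue representations are L x d matrices (rows =
## residues); all losses are sums over their batch, not means.

#' Amino-acid vocabulary
#'
#' The 20 canonical residues, plus an unknown token `X` for non-canonical
#' residues and a mask token used by the masked-residue objective.
#' @return Character vector of tokens; canonical residues first.
#' @export
aa_vocabulary <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "<mask>")
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.N_AA <- 20L
.UNK_ID <- 21L
.MASK_ID <- 22L

# sequence string -> integer tokens; non-canonical residues -> unknown
tokenize_sequence <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, .AA)
  idx[is.na(idx)] <- .UNK_ID
  idx
}

#' Mask residues for the masked-language-modelling objective
#'
#' Replaces exactly `round(rate * L)` distinct positions (sampled without
#' replacement) by the mask token and records the true residues at those
#' positions.
#'
#' @param record A `ProteinRecord` (see [gen_proteins()]) or a plain
#'   sequence string.
#' @param rate Masking fraction in `[0, 1]`.
#' @param seed Integer seed for the position draw.
#' @return An `MlmBatch`: list with `tokens` (masked integer sequence),
#'   `masked_positions` (set Y), `targets` (true token ids on Y) and
#'   `n_vocab` (canonical vocabulary size).
#' @export
mask_sequence <- function(record, rate = 0.15, seed = 0L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  seq <- if (is.list(record)) record$sequence else record
  tok <- tokenize_sequence(seq)
  L <- length(tok)
  k <- round(rate * L)
  pos <- if (k > 0) with_seed(seed, sample.int(L, k)) else integer(0)
  pos <- sort(pos)
  out <- tok
  out[pos] <- .MASK_ID
  structure(list(tokens = out, masked_positions = pos,
                 targets = tok[pos], n_vocab = .N_AA),
            class = "MlmBatch")
}

#' Masked-language-modelling loss
#'
#' Sum over masked positions of the negative log softmax probability of the
#' true residue, the softmax taken over the canonical amino-acid vocabulary.
#' With uniform scores this is exactly `log(20)` per masked residue.
#'
#' @param batch An `MlmBatch` from [mask_sequence()].
#' @param token_scores Numeric matrix of unnormalized scores, one row per
#'   masked position (in the order of `batch$masked_positions`), one column
#'   per vocabulary entry.
#' @param gradient If `TRUE`, also return the gradient w.r.t. `token_scores`.
#' @return Nonnegative loss, or `list(loss, gradient)`.
#' @export
mlm_loss <- function(batch, token_scores, gradient = FALSE) {
  Y <- batch$masked_positions
  if (length(Y) == 0L) {
    warning("no masked positions; MLM loss is 0")
    if (gradient) return(list(loss = 0, gradient = token_scores * 0))
    return(0)
  }
  S <- matrix(token_scores, nrow = length(Y))
  if (ncol(S) < max(batch$targets))
    stop("scores must cover every vocabulary token")
  # row-wise log-softmax, stabilized
  m <- apply(S, 1, max)
  Z <- S - m
  lse <- log(rowSums(exp(Z)))
  logq <- Z - lse
  loss <- -sum(logq[cbind(seq_along(Y), batch$targets)])
  if (!gradient) return(loss)
  G <- exp(logq)                       # softmax probabilities
  G[cbind(seq_along(Y), batch$targets)] <-
    G[cbind(seq_along(Y), batch$targets)] - 1
  list(loss = loss, gradient = G)
}

#' Attention-based pair representation for two proteins
#'
#' Builds the pair-aware representation of proteins m and n from their
#' per-residue representations: `Attn = sigmoid((Hm W)(Hn W)^T / dW)`,
#' then the concatenation of the row-means of `t(Attn) %*% Hm` and of
#' `Attn %*% Hn`. Swapping the two proteins swaps the two halves.
#'
#' @param Hm,Hn Per-residue representation matrices (`L_m x d`, `L_n x d`).
#' @param W Square projection matrix (`dW x dW`, here `dW = d`).
#' @param scale_by_d Divide the logits by `dW` before the sigmoid
#'   (scaled-attention convention, the default); set `FALSE` for raw logits.
#' @return Numeric vector of length `2 d`.
#' @export
pair_representation <- function(Hm, Hn, W, scale_by_d = TRUE) {
  Hm <- as.matrix(Hm); Hn <- as.matrix(Hn)
  d <- ncol(Hm)
  stopifnot(ncol(Hn) == d, nrow(W) == d, ncol(W) == d)
  Um <- Hm %*% W
  Un <- Hn %*% W
  S <- tcrossprod(Um, Un)
  if (scale_by_d) S <- S / d
  A <- 1 / (1 + exp(-S))                         # L_m x L_n, entries in (0,1)
  h1 <- colMeans(crossprod(A, Hm))               # mean over rows of t(A) Hm
  h2 <- colMeans(A %*% Hn)                       # mean over rows of A  Hn
  c(h1, h2)
}

# backward pass for pair_representation; returns gradients w.r.t. Hm, Hn, W
pair_representation_backward <- function(Hm, Hn, W, dout, scale_by_d = TRUE) {
  Hm <- as.matrix(Hm); Hn <- as.matrix(Hn)
  d <- ncol(Hm); Lm <- nrow(Hm); Ln <- nrow(Hn)
  Um <- Hm %*% W; Un <- Hn %*% W
  S <- tcrossprod(Um, Un)
  if (scale_by_d) S <- S / d
  A <- 1 / (1 + exp(-S))
  d1 <- dout[seq_len(d)]; d2 <- dout[d + seq_len(d)]
  # h1 = colMeans(t(A) Hm): G1 = t(A) Hm (Ln x d), h1 = colMeans(G1)
  dG1 <- matrix(d1 / Ln, Ln, d, byrow = TRUE)
  dA <- Hm %*% t(dG1)
  dHm <- A %*% dG1
  # h2 = colMeans(A Hn): G2 = A Hn (Lm x d)
  dG2 <- matrix(d2 / Lm, Lm, d, byrow = TRUE)
  dA <- dA + dG2 %*% t(Hn)
  dHn <- crossprod(A, dG2)
  dS <- dA * A * (1 - A)
  if (scale_by_d) dS <- dS / d
  dUm <- dS %*% Un
  dUn <- crossprod(dS, Um)
  dW <- crossprod(Hm, dUm) + crossprod(Hn, dUn)
  dHm <- dHm + dUm %*% t(W)
  dHn <- dHn + dUn %*% t(W)
  list(dHm = dHm, dHn = dHn, dW = dW)
}

#' Protein-protein-interaction loss
#'
#' Sum over a batch of pairs of the binary cross-entropy between the true
#' label and the predicted interaction probability. `k` pairs all predicted
#' at probability 0.5 give exactly `k * log(2)`.
#'
#' @param pair_probs Predicted probabilities in `(0, 1)`.
#' @param labels Binary labels (0/1), same length.
#' @param gradient If `TRUE`, also return d loss / d prob.
#' @return Nonnegative loss, or `list(loss, gradient)`.
#' @export
ppi_loss <- function(pair_probs, labels, gradient = FALSE) {
  stopifnot(length(pair_probs) == length(labels))
  p <- pmin(pmax(pair_probs, 1e-12), 1 - 1e-12)
  loss <- -sum(labels * log(p) + (1 - labels) * log1p(-p))
  if (!gradient) return(loss)
  list(loss = loss, gradient = (p - labels) / (p * (1 - p)))
}

#' Weighted multitask pretraining objective
#'
#' Combines the three task losses, each computed on the representation
#' obtained with its own prompt token prepended, with nonnegative weights.
#'
#' @param losses Named or positional numeric vector/list of the three
#'   component losses (MLM, CRD, PPI).
#' @param weights `LossWeights`: numeric length-3 vector `(alpha1, alpha2,
#'   alpha3)`, default `c(1, 1, 1)`.
#' @return The weighted sum.
#' @export
multitask_loss <- function(losses, weights = c(1, 1, 1)) {
  losses <- unlist(losses)
  stopifnot(length(losses) == 3L, length(weights) == 3L, all(weights >= 0))
  sum(weights * losses)
}

#' Combine task prompts with the prompt-tuning module
#'
#' The prompt-tuning module is a single linear layer mapping the
#' concatenation of the three learned task prompts (MLM, CRD, PPI) to one
#' d-length prompt used for downstream encoding.
#'
#' @param prompts A list or 3 x d matrix of the three prompt vectors, in
#'   the order MLM, CRD, PPI.
#' @param tuner List with `weight` (`d x 3d` matrix) and `bias` (length d).
#' @return The tuned prompt `p'`, a length-d vector.
#' @export
prompt_tune <- function(prompts, tuner) {
  P <- if (is.list(prompts)) do.call(rbind, prompts) else as.matrix(prompts)
  stopifnot(nrow(P) == 3L)
  d <- ncol(P)
  stopifnot(nrow(tuner$weight) == d, ncol(tuner$weight) == 3L * d)
  as.numeric(tuner$weight %*% c(t(P))) + tuner$bias
}
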