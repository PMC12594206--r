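## Multitask pretraining and prompt-tuned fine-tuning. Pretraining
## optimizes the encoder, the three task prompts and all decoder heads
## under the weighted sum of the masked-residue, coordinate and
## interaction losses, each computed with its own prompt token prepended.
## Fine-tuning freezes the encoder and optimizes only the prompt-tuning
## module and the pair-classification head on training edges.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# pair head forward: one-hidden-layer perceptron on the pair representation
.pair_head_fwd <- function(ph, rep) {
  hid <- tanh(as.numeric(rep %*% ph$W1) + ph$b1)
  z <- sum(ph$w2 * hid) + ph$b2
  list(p = .sigmoid(z), hid = hid)
}

# forward + backward for one labelled pair given cached encodings
.pair_step <- function(model, Hm, Hn, label) {
  sc <- !isFALSE(model$config$scale_attn)
  rep <- pair_representation(Hm, Hn, model$W, scale_by_d = sc)
  ph <- model$pair_head
  fw <- .pair_head_fwd(ph, rep)
  p <- fw$p; hid <- fw$hid
  eps <- 1e-12
  loss <- -(label * log(p + eps) + (1 - label) * log(1 - p + eps))
  dz <- p - label
  dhid <- dz * ph$w2
  dpre <- dhid * (1 - hid^2)
  drep <- as.numeric(ph$W1 %*% dpre)
  pb <- pair_representation_backward(Hm, Hn, model$W, drep, scale_by_d = sc)
  list(loss = loss, p = p, dHm = pb$dHm, dHn = pb$dHn, dW = pb$dW,
       dhead = list(W1 = outer(rep, dpre), b1 = dpre,
                    w2 = dz * hid, b2 = dz))
}

# accumulate encoder gradients (layers, conv, embedding, prompt row)
.acc_encoder <- function(acc, model, cache, dH, prompt_row = NULL) {
  eg <- encode_backward(model, cache, dH)
  acc$E <- acc$E + eg$E
  for (i in seq_along(acc$conv))
    acc$conv[[i]] <- acc$conv[[i]] + eg$conv[[i]]
  for (i in seq_along(acc$layers))
    acc$layers[[i]] <- grad_axpy(acc$layers[[i]], eg$layers[[i]])
  if (!is.null(prompt_row))
    acc$prompts[prompt_row, ] <- acc$prompts[prompt_row, ] + eg$dprompt
  attr(acc, "dprompt") <- eg$dprompt
  acc
}

.acc_pair_head <- function(acc, dhead, a = 1) {
  acc$pair_head$W1 <- acc$pair_head$W1 + a * dhead$W1
  acc$pair_head$b1 <- acc$pair_head$b1 + a * dhead$b1
  acc$pair_head$w2 <- acc$pair_head$w2 + a * dhead$w2
  acc$pair_head$b2 <- acc$pair_head$b2 + a * dhead$b2
  acc
}

# balanced sample of pair indices (half positive, half negative)
.balanced_pairs <- function(labels, k, seed) {
  with_seed(seed, {
    ipos <- which(labels == 1); ineg <- which(labels == 0)
    sample(c(sample(ipos, min(k %/% 2, length(ipos))),
             sample(ineg, min(k - k %/% 2, length(ineg)))))
  })
}

#' Multitask pretraining of the prompt-guided encoder
#'
#' Optimizes encoder parameters, task prompts and decoder heads with Adam
#' (global-norm gradient clipping) under the weighted objective
#' `alpha1 * L_MLM + alpha2 * L_CRD + alpha3 * L_PPI`, each component
#' computed on the representation obtained with its own prompt token.
#' Per epoch, the masked-residue task visits a sample of proteins in small
#' batches, the coordinate task a smaller sample, and the interaction task
#' one protein clique (so encodings are shared across that epoch's pairs).
#' Deterministic under `seed` on a single thread.
#'
#' @param dataset List with `proteins` (records carrying `sequence` and,
#'   for the coordinate task, `coords`) and optionally `network` (an
#'   `InteractionNetwork` providing interaction labels for the pair task).
#' @param weights `LossWeights` `(alpha1, alpha2, alpha3)`, default
#'   `c(1, 1, 1)`.
#' @param config Model/optimizer settings overriding the defaults:
#'   `d`, `n_layers`, `h`, `hc`, `conv_window`, `pe_scale`, `scale_attn`,
#'   `init_sd`, `epochs`, `lr`, `mask_rate`, `mlm_per_epoch`,
#'   `crd_per_epoch`, `clique_size`, `ppi_pairs_per_epoch`, `batch_size`.
#' @param seed Integer seed (parameter init, masking, batch order).
#' @return A trained `ModelState` with a per-epoch `trace` of the total
#'   weighted loss (on that epoch's samples).
#' @export
pretrain <- function(dataset, weights = c(1, 1, 1), config = list(),
                     seed = 1L) {
  cfg <- utils::modifyList(list(d = 16L, n_layers = 1L, h = 32L, hc = 32L,
                                conv_window = 2L, pe_scale = 0.1,
                                scale_attn = TRUE, init_sd = 0.15,
                                epochs = 220L, lr = 3e-3, mask_rate = 0.2,
                                mlm_per_epoch = 100L, crd_per_epoch = 12L,
                                clique_size = 32L,
                                ppi_pairs_per_epoch = 128L,
                                batch_size = 4L,
                                # two-phase schedule: feature building
                                # (masked-residue-heavy) then interaction-
                                # heavy refinement
                                phase_split = 0.55,
                                mlm_per_epoch_late = 30L,
                                ppi_cliques_late = 3L), config)
  proteins <- dataset$proteins
  if (length(proteins) == 0L) stop("dataset has no proteins")
  model <- init_model(d = cfg$d, n_layers = cfg$n_layers, h = cfg$h,
                      hc = cfg$hc, seed = seed, init_sd = cfg$init_sd,
                      scale_attn = cfg$scale_attn,
                      conv_window = cfg$conv_window, pe_scale = cfg$pe_scale)
  ids <- vapply(proteins, `[[`, "", "id")
  tokens <- stats::setNames(lapply(proteins, function(p)
    tokenize_sequence(p$sequence)), ids)
  coords <- stats::setNames(lapply(proteins, `[[`, "coords"), ids)
  pairs <- if (!is.null(dataset$network)) dataset$network$pairs else NULL
  opt <- adam_init(model)
  trace <- numeric(cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    ep_seed <- substream_seed(seed, paste0("pretrain-epoch-", ep))
    ep_loss <- 0
    late <- ep > cfg$phase_split * cfg$epochs
    n_mlm <- if (late) cfg$mlm_per_epoch_late else cfg$mlm_per_epoch
    n_cliques <- if (late) cfg$ppi_cliques_late else 1L
    # ---- masked-residue pass, prompt [MLM]
    if (weights[1] > 0 && n_mlm > 0) {
      sel <- with_seed(ep_seed, sample(ids, min(n_mlm, length(ids))))
      for (pb in split(sel, ceiling(seq_along(sel) / cfg$batch_size))) {
        acc <- zero_grads(model)
        for (id in pb) {
          mb <- mask_sequence(proteins[[match(id, ids)]],
                              rate = cfg$mask_rate,
                              seed = (ep_seed + .hash_string(id)) %%
                                2147483647)
          if (length(mb$masked_positions) == 0L) next
          fw <- encode_forward(model, mb$tokens, model$prompts[1, ])
          sc <- token_head_forward(model, fw$H, mb$masked_positions)
          ml <- mlm_loss(mb, sc, gradient = TRUE)
          ep_loss <- ep_loss + weights[1] * ml$loss
          dsc <- weights[1] * ml$gradient
          dH <- matrix(0, nrow(fw$H), cfg$d)
          dH[mb$masked_positions, ] <- dsc %*% t(model$U)
          acc$U <- acc$U +
            crossprod(fw$H[mb$masked_positions, , drop = FALSE], dsc)
          acc$bu <- acc$bu + colSums(dsc)
          acc <- .acc_encoder(acc, model, fw$cache, dH, prompt_row = 1L)
        }
        st <- adam_step(model, acc, opt, lr = cfg$lr)
        model <- st$model; opt <- st$state
      }
    }
    # ---- coordinate pass, prompt [CRD]
    has_coords <- !vapply(coords, is.null, TRUE)
    if (weights[2] > 0 && any(has_coords)) {
      sel <- with_seed(ep_seed + 1L,
                       sample(ids[has_coords],
                              min(cfg$crd_per_epoch, sum(has_coords))))
      for (pb in split(sel, ceiling(seq_along(sel) / cfg$batch_size))) {
        acc <- zero_grads(model)
        for (id in pb) {
          fw <- encode_forward(model, tokens[[id]], model$prompts[2, ])
          ch <- coord_head_forward(model, fw$H)
          cl <- crd_loss(ch$coords, coords[[id]], gradient = TRUE)
          ep_loss <- ep_loss + weights[2] * cl$loss
          hb <- coord_head_backward(model, fw$H, ch$Tc,
                                    weights[2] * cl$gradient)
          acc$Wc1 <- acc$Wc1 + hb$Wc1; acc$bc1 <- acc$bc1 + hb$bc1
          acc$Wc2 <- acc$Wc2 + hb$Wc2; acc$bc2 <- acc$bc2 + hb$bc2
          acc <- .acc_encoder(acc, model, fw$cache, hb$dH, prompt_row = 2L)
        }
        st <- adam_step(model, acc, opt, lr = cfg$lr)
        model <- st$model; opt <- st$state
      }
    }
    # ---- interaction pass, prompt [PPI]: one clique per epoch so the
    # clique's encodings are computed once and reused by all its pairs
    if (weights[3] > 0 && !is.null(pairs) && nrow(pairs) > 0) {
      for (cl in seq_len(n_cliques)) {
      clique <- with_seed(ep_seed + 2L * cl,
                          sample(ids, min(cfg$clique_size, length(ids))))
      cand <- which(pairs$a %in% clique & pairs$b %in% clique)
      if (length(cand) >= 4L && sum(pairs$label[cand] == 1) >= 2L &&
          sum(pairs$label[cand] == 0) >= 2L) {
        sub <- pairs[cand, ]
        sel <- .balanced_pairs(sub$label, cfg$ppi_pairs_per_epoch,
                               ep_seed + 3L + 7L * cl)
        used <- unique(c(sub$a[sel], sub$b[sel]))
        enc <- stats::setNames(lapply(used, function(id)
          encode_forward(model, tokens[[id]], model$prompts[3, ])), used)
        dHbuf <- stats::setNames(lapply(used, function(id)
          matrix(0, nrow(enc[[id]]$H), cfg$d)), used)
        acc <- zero_grads(model)
        for (k in sel) {
          a <- sub$a[k]; b <- sub$b[k]
          ps <- .pair_step(model, enc[[a]]$H, enc[[b]]$H, sub$label[k])
          ep_loss <- ep_loss + weights[3] * ps$loss
          acc$W <- acc$W + weights[3] * ps$dW
          acc <- .acc_pair_head(acc, ps$dhead, weights[3])
          dHbuf[[a]] <- dHbuf[[a]] + weights[3] * ps$dHm
          dHbuf[[b]] <- dHbuf[[b]] + weights[3] * ps$dHn
        }
        for (id in used)
          acc <- .acc_encoder(acc, model, enc[[id]]$cache, dHbuf[[id]],
                              prompt_row = 3L)
        st <- adam_step(model, acc, opt, lr = cfg$lr)
        model <- st$model; opt <- st$state
      }
      }
    }
    if (!is.finite(ep_loss))
      stop("training diverged: non-finite loss at epoch ", ep,
           " (reduce lr or loss weights)")
    trace[ep] <- ep_loss
  }
  model$trace <- trace
  model$proteins <- tokens
  model
}

#' Fine-tune the prompt-tuning module and pair head for PPI screening
#'
#' Freezes the encoder and its task prompts. The prompt-tuning module is
#' warm-started at the PPI prompt selection; training edges are encoded
#' with the tuned prompt `p'` once, the pair-classification head is fitted
#' on the resulting pair representations (many cheap Adam steps), and a
#' short joint phase then updates the prompt-tuning module together with
#' the head. Only training edges are ever used.
#'
#' @param model A pretrained `ModelState`.
#' @param network An `InteractionNetwork` of training edges.
#' @param proteins Optional protein records; defaults to the corpus cached
#'   by [pretrain()].
#' @param config Optimizer settings: `head_pairs`, `head_steps`,
#'   `head_batch`, `head_lr`, `joint_epochs`, `joint_pairs`,
#'   `joint_batch`, `joint_lr`.
#' @param seed Integer seed.
#' @return A `ppi_predictor`: callable via [predict.ppi_predictor()],
#'   caching tuned per-protein representations; probabilities are always
#'   in (0, 1).
#' @export
finetune <- function(model, network, proteins = NULL, config = list(),
                     seed = 1L) {
  cfg <- utils::modifyList(list(head_pairs = 4000L, head_steps = 3000L,
                                head_batch = 64L, head_lr = 5e-3,
                                joint_epochs = 3L, joint_pairs = 96L,
                                joint_batch = 16L, joint_lr = 5e-3),
                           config)
  pairs <- network$pairs
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no training edges")
  tokens <- if (!is.null(proteins))
    stats::setNames(lapply(proteins, function(p) tokenize_sequence(p$sequence)),
                    vapply(proteins, `[[`, "", "id"))
  else model$proteins
  if (is.null(tokens)) stop("no protein sequences available; pass `proteins`")
  missing <- setdiff(unique(c(pairs$a, pairs$b)), names(tokens))
  if (length(missing))
    stop("network references unknown proteins: ",
         paste(utils::head(missing, 3), collapse = ", "))
  d <- model$config$d
  sc <- !isFALSE(model$config$scale_attn)
  # warm start: select the PPI prompt exactly
  model$tuner$weight <- cbind(matrix(0, d, 2 * d), diag(d))
  model$tuner$bias <- numeric(d)

  # ---- phase 1: fit the pair head on representations under p'
  p_tuned <- prompt_tune(model$prompts, model$tuner)
  reps <- lapply(tokens, function(tok)
    encode_forward(model, tok, p_tuned)$H)
  sel <- .balanced_pairs(pairs$label, min(cfg$head_pairs, nrow(pairs)),
                         substream_seed(seed, "finetune-head-pairs"))
  feats <- t(vapply(sel, function(k)
    pair_representation(reps[[pairs$a[k]]], reps[[pairs$b[k]]], model$W,
                        scale_by_d = sc), numeric(2 * d)))
  labs <- pairs$label[sel]
  ph <- model$pair_head
  hstate <- list(m = lapply(ph, function(x) x * 0),
                 v = lapply(ph, function(x) x * 0), t = 0L)
  trace1 <- numeric(0)
  with_seed(substream_seed(seed, "finetune-head-steps"), {
    for (step in seq_len(cfg$head_steps)) {
      bi <- sample.int(nrow(feats), min(cfg$head_batch, nrow(feats)))
      gW1 <- ph$W1 * 0; gb1 <- ph$b1 * 0; gw2 <- ph$w2 * 0; gb2 <- 0
      bl <- 0
      pre <- tanh(sweep(feats[bi, , drop = FALSE] %*% ph$W1, 2, ph$b1, "+"))
      z <- as.numeric(pre %*% ph$w2) + ph$b2
      p <- .sigmoid(z)
      bl <- -sum(labs[bi] * log(p + 1e-12) +
                 (1 - labs[bi]) * log(1 - p + 1e-12))
      dz <- p - labs[bi]
      gw2 <- as.numeric(crossprod(pre, dz)); gb2 <- sum(dz)
      dpre <- (dz %o% ph$w2) * (1 - pre^2)
      gW1 <- crossprod(feats[bi, , drop = FALSE], dpre)
      gb1 <- colSums(dpre)
      g <- list(W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2)
      hstate$t <- hstate$t + 1L
      for (nm in names(ph)) {
        hstate$m[[nm]] <- 0.9 * hstate$m[[nm]] + 0.1 * g[[nm]]
        hstate$v[[nm]] <- 0.999 * hstate$v[[nm]] + 0.001 * g[[nm]]^2
        mh <- hstate$m[[nm]] / (1 - 0.9^hstate$t)
        vh <- hstate$v[[nm]] / (1 - 0.999^hstate$t)
        ph[[nm]] <- ph[[nm]] - cfg$head_lr * mh / (sqrt(vh) + 1e-8)
      }
      if (step %% 200 == 0) trace1 <- c(trace1, bl)
    }
  })
  model$pair_head <- ph

  # ---- phase 2: short joint optimization of prompt-tuning module + head
  mask <- param_mask(model, c("tuner", "pair_head"))
  opt <- adam_init(model)
  trace2 <- numeric(cfg$joint_epochs)
  for (ep in seq_len(cfg$joint_epochs)) {
    ep_seed <- substream_seed(seed, paste0("finetune-joint-", ep))
    sel <- .balanced_pairs(pairs$label, cfg$joint_pairs, ep_seed)
    ep_loss <- 0
    p_tuned <- prompt_tune(model$prompts, model$tuner)
    for (bb in split(sel, ceiling(seq_along(sel) / cfg$joint_batch))) {
      acc <- zero_grads(model)
      dprompt_tot <- numeric(d)
      enc <- list()
      for (k in bb) {
        a <- pairs$a[k]; b <- pairs$b[k]
        for (id in c(a, b)) if (is.null(enc[[id]]))
          enc[[id]] <- encode_forward(model, tokens[[id]], p_tuned)
        ps <- .pair_step(model, enc[[a]]$H, enc[[b]]$H, pairs$label[k])
        ep_loss <- ep_loss + ps$loss
        acc <- .acc_pair_head(acc, ps$dhead)
        acc <- .acc_encoder(acc, model, enc[[a]]$cache, ps$dHm)
        dprompt_tot <- dprompt_tot + attr(acc, "dprompt")
        acc <- .acc_encoder(acc, model, enc[[b]]$cache, ps$dHn)
        dprompt_tot <- dprompt_tot + attr(acc, "dprompt")
      }
      pc <- c(t(model$prompts))            # concatenated frozen prompts
      acc$tuner$weight <- acc$tuner$weight + outer(dprompt_tot, pc)
      acc$tuner$bias <- acc$tuner$bias + dprompt_tot
      st <- adam_step(model, acc, opt, lr = cfg$joint_lr, mask = mask)
      model <- st$model; opt <- st$state
      p_tuned <- prompt_tune(model$prompts, model$tuner)
    }
    if (!is.finite(ep_loss)) stop("fine-tuning diverged at epoch ", ep)
    trace2[ep] <- ep_loss
  }
  p_tuned <- prompt_tune(model$prompts, model$tuner)
  reps <- lapply(tokens, function(tok) encode_forward(model, tok, p_tuned)$H)
  out <- structure(list(model = model, tuned_prompt = p_tuned, reps = reps,
                        head_trace = trace1, joint_trace = trace2,
                        threshold = 0.5),
                   class = "ppi_predictor")
  # calibrate the decision threshold on training pairs at their natural
  # class ratio (the head is fitted on balanced batches)
  ncal <- min(6000L, nrow(pairs))
  cal <- with_seed(substream_seed(seed, "finetune-calibration"),
                   sample.int(nrow(pairs), ncal))
  pcal <- predict(out, pairs[cal, ])
  grid <- seq(0.05, 0.95, by = 0.025)
  f1s <- vapply(grid, function(th)
    evaluate_f1(as.integer(pcal > th), pairs$label[cal])$f1, 0)
  out$threshold <- grid[which.max(f1s)]
  out
}

#' Predict interaction probabilities for protein pairs
#'
#' @param object A `ppi_predictor` from [finetune()].
#' @param pairs Data frame with columns `a`, `b` (protein ids known to the
#'   predictor).
#' @param ... Unused.
#' @return Numeric probabilities in (0, 1), one per row of `pairs`.
#' @export
predict.ppi_predictor <- function(object, pairs, ...) {
  unknown <- setdiff(unique(c(pairs$a, pairs$b)), names(object$reps))
  if (length(unknown))
    stop("protein(s) not in the model vocabulary: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  m <- object$model
  sc <- !isFALSE(m$config$scale_attn)
  vapply(seq_len(nrow(pairs)), function(i) {
    rep <- pair_representation(object$reps[[pairs$a[i]]],
                               object$reps[[pairs$b[i]]], m$W,
                               scale_by_d = sc)
    .pair_head_fwd(m$pair_head, rep)$p
  }, 0)
}

#' @export
print.ppi_predictor <- function(x, ...) {
  cat(sprintf("PPI predictor: %d proteins in vocabulary, d = %d\n",
              length(x$reps), x$model$config$d))
  invisible(x)
}

#' Evaluate a predictor on labelled pairs
#'
#' @param predictor A `ppi_predictor`.
#' @param pairs Data frame `a, b, label`.
#' @param threshold Decision threshold on the probability.
#' @return An `EvalResult` (see [evaluate_f1()]).
#' @export
screen_f1 <- function(predictor, pairs, threshold = predictor$threshold) {
  p <- predict(predictor, pairs)
  evaluate_f1(as.integer(p > threshold), pairs$label)
}
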