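ns <- asNamespace("spliceppi")

test_that("masking selects the exact number of distinct positions", {
  seq100 <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  mb <- mask_sequence(seq100, rate = 0.15, seed = 1)
  expect_length(mb$masked_positions, 15)
  expect_false(anyDuplicated(mb$masked_positions) > 0)
  expect_true(all(mb$tokens[mb$masked_positions] == 22L))
  expect_identical(mb$targets,
                   ns$tokenize_sequence(seq100)[mb$masked_positions])
  expect_length(mask_sequence(seq100, rate = 0)$masked_positions, 0)
  expect_length(mask_sequence(seq100, rate = 1)$masked_positions, 100)
})

test_that("masked-residue loss matches closed forms and a hand softmax", {
  mb <- mask_sequence("ACDEFGHIKLMNPQRSTVWY", rate = 0.05, seed = 2)
  expect_length(mb$masked_positions, 1)
  expect_equal(mlm_loss(mb, matrix(0, 1, 20)), log(20), tolerance = 1e-12)
  # a huge margin on the true token drives the loss to zero
  sc <- matrix(0, 1, 20); sc[1, mb$targets] <- 1e4
  expect_lt(mlm_loss(mb, sc), 1e-10)
  # two masked tokens, scores (2,0,0,...): position 1's true token carries
  # the 2, position 2's true token a 0
  mb2 <- mask_sequence("ACDEFGHIKLMNPQRSTVWY", rate = 0.1, seed = 2)
  expect_length(mb2$masked_positions, 2)
  # row 1: softmax of a 2 among 19 zeros; row 2: uniform zeros
  S2 <- matrix(0, 2, 20)
  S2[1, mb2$targets[1]] <- 2
  row1 <- exp(2) / (exp(2) + 19)
  row2 <- 1 / 20
  expect_equal(mlm_loss(mb2, S2), -(log(row1) + log(row2)),
               tolerance = 1e-12)
  expect_warning(out <- mlm_loss(mask_sequence("ACD", 0), matrix(0, 0, 20)),
                 "no masked")
  expect_equal(out, 0)
})

test_that("Kabsch superposition removes rigid transforms and never reflects", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), sin(th[2]),
                   0, -sin(th[2]), cos(th[2])), 3, 3)
    fit <- kabsch_superpose(P %*% Rz %*% Rx + rep(rnorm(3), each = n), P)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  expect_equal(kabsch_superpose(diag(3), diag(3))$rmsd, 0)
  # degenerate: coincident points return the identity by convention
  pt <- matrix(1, 4, 3)
  deg <- kabsch_superpose(pt, matrix(2, 4, 3))
  expect_identical(deg$rotation, diag(3))
  expect_equal(deg$rmsd, 0)
  expect_error(kabsch_superpose(diag(3), matrix(0, 4, 3)), "equal row")
})

test_that("Kabsch agrees with bio3d and a grid-search oracle", {
  set.seed(17)
  P <- matrix(rnorm(18), 6, 3); Q <- matrix(rnorm(18), 6, 3)
  fit <- kabsch_superpose(P, Q)
  # independent route 1: bio3d's least-squares fit
  r_bio3d <- suppressWarnings(            # bio3d notes it fits all positions
    sqrt(mean((bio3d::fit.xyz(as.numeric(t(Q)), as.numeric(t(P))) -
               as.numeric(t(Q)))^2) * 3))
  expect_equal(fit$rmsd, r_bio3d, tolerance = 1e-6)
  # independent route 2: brute-force rotation grid (0.5 degree refinement)
  expect_lt(abs(fit$rmsd - grid_search_rmsd(P, Q)), 1e-3)
  # unit displacement of one point among non-coplanar points
  P4 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  Q4 <- P4; Q4[4, 3] <- Q4[4, 3] + 1
  expect_lt(abs(kabsch_superpose(P4, Q4)$rmsd - grid_search_rmsd(P4, Q4)),
            1e-4)
})

test_that("coordinate loss is superposition-invariant and below plain MSE", {
  Z <- ns$helix_template(12, list(rise = 1.5, radius = 2.3,
                                  turn = 100 * pi / 180))
  expect_equal(crd_loss(Z, Z), 0, tolerance = 1e-12)
  expect_lt(crd_loss(Z + 5, Z), 1e-15)              # offsets removed
  set.seed(4)
  for (i in 1:20) {
    pred <- Z + matrix(rnorm(36, sd = 2), 12, 3)
    expect_lte(crd_loss(pred, Z), mean((pred - Z)^2) + 1e-12)
  }
  # doubling a centered structure: residual known in closed form, since
  # the optimal rotation is the identity and scaling is not removed
  Zc <- sweep(Z, 2, colMeans(Z))
  expect_equal(crd_loss(2 * Zc, Zc), mean(Zc^2), tolerance = 1e-8)
  expect_error(crd_loss(Z[1:5, ], Z), "mismatch")
})

test_that("pair representation matches closed forms and swaps halves", {
  set.seed(8)
  Hm <- matrix(rnorm(12), 3, 4); Hn <- matrix(rnorm(20), 5, 4)
  # W = 0: attention is uniformly 1/2
  pr0 <- pair_representation(Hm, Hn, matrix(0, 4, 4))
  expect_equal(pr0, c(0.5 * 3 * colMeans(Hm), 0.5 * 5 * colMeans(Hn)),
               tolerance = 1e-12)
  for (i in 1:100) {
    W <- matrix(rnorm(16), 4, 4)
    A <- matrix(rnorm(sample(1:6, 1) * 4), ncol = 4)
    B <- matrix(rnorm(sample(1:6, 1) * 4), ncol = 4)
    ab <- pair_representation(A, B, W)
    ba <- pair_representation(B, A, W)
    expect_equal(ba, c(ab[5:8], ab[1:4]), tolerance = 1e-10)
  }
  # single-residue proteins, identity W, d = 2: scalar arithmetic
  hm <- matrix(c(1, 2), 1, 2); hn <- matrix(c(3, -1), 1, 2)
  a <- 1 / (1 + exp(-(1 * 3 + 2 * -1) / 2))       # sigmoid of dot/d
  expect_equal(pair_representation(hm, hn, diag(2)),
               c(a * c(1, 2), a * c(3, -1)), tolerance = 1e-12)
})

test_that("interaction and multitask losses match hand arithmetic", {
  expect_equal(ppi_loss(rep(0.5, 7), rep(1, 7)), 7 * log(2),
               tolerance = 1e-12)
  expect_lt(ppi_loss(c(1 - 1e-13, 1e-13), c(1, 0)), 1e-9)
  expect_equal(ppi_loss(c(0.9, 0.2, 0.5), c(1, 0, 1)),
               -(log(0.9) + log(0.8) + log(0.5)), tolerance = 1e-12)
  expect_equal(multitask_loss(c(0.5, 0.25, 1), c(1, 2, 3)), 4)
  expect_equal(multitask_loss(c(9, 9, 9), c(0, 0, 0)), 0)
  expect_equal(multitask_loss(c(0.7, 9, 9), c(1, 0, 0)), 0.7)
})

test_that("prompt tuning reduces to selection, zero and averaging", {
  d <- 6
  P <- matrix(rnorm(18), 3, d)
  sel <- list(weight = cbind(matrix(0, d, 2 * d), diag(d)),
              bias = numeric(d))
  expect_equal(prompt_tune(P, sel), P[3, ], tolerance = 1e-12)
  zero <- list(weight = matrix(0, d, 3 * d), bias = numeric(d))
  expect_equal(prompt_tune(P, zero), numeric(d))
  avg <- list(weight = cbind(diag(d), diag(d), diag(d)) / 3,
              bias = numeric(d))
  expect_equal(prompt_tune(P, avg), colMeans(P), tolerance = 1e-12)
})

test_that("analytic gradients of all three losses match finite differences", {
  m <- ns$init_model(d = 8, n_layers = 2, h = 8, hc = 8, seed = 3)
  tok1 <- ns$tokenize_sequence("ACDEFGHIKL")
  tok2 <- ns$tokenize_sequence("MNPQRST")
  Z <- ns$helix_template(10, list(rise = 1.5, radius = 2.3,
                                  turn = 100 * pi / 180))
  mb <- mask_sequence("ACDEFGHIKL", rate = 0.3, seed = 7)

  losses <- list(
    mlm = function(m) {
      fw <- ns$encode_forward(m, mb$tokens, m$prompts[1, ])
      mlm_loss(mb, ns$token_head_forward(m, fw$H, mb$masked_positions))
    },
    crd = function(m) {
      fw <- ns$encode_forward(m, tok1, m$prompts[2, ])
      crd_loss(ns$coord_head_forward(m, fw$H)$coords, Z)
    },
    ppi = function(m) {
      fa <- ns$encode_forward(m, tok1, m$prompts[3, ])
      fb <- ns$encode_forward(m, tok2, m$prompts[3, ])
      ns$.pair_step(m, fa$H, fb$H, 1)$loss
    })
  grads <- list(
    mlm = local({
      fw <- ns$encode_forward(m, mb$tokens, m$prompts[1, ])
      sc <- ns$token_head_forward(m, fw$H, mb$masked_positions)
      ml <- mlm_loss(mb, sc, gradient = TRUE)
      acc <- ns$zero_grads(m)
      dH <- matrix(0, nrow(fw$H), 8)
      dH[mb$masked_positions, ] <- ml$gradient %*% t(m$U)
      acc$U <- acc$U + crossprod(fw$H[mb$masked_positions, , drop = FALSE],
                                 ml$gradient)
      acc$bu <- acc$bu + colSums(ml$gradient)
      acc <- ns$.acc_encoder(acc, m, fw$cache, dH, prompt_row = 1L)
      unlist(acc, use.names = FALSE)
    }),
    crd = local({
      fw <- ns$encode_forward(m, tok1, m$prompts[2, ])
      ch <- ns$coord_head_forward(m, fw$H)
      cl <- crd_loss(ch$coords, Z, gradient = TRUE)
      hb <- ns$coord_head_backward(m, fw$H, ch$Tc, cl$gradient)
      acc <- ns$zero_grads(m)
      acc$Wc1 <- acc$Wc1 + hb$Wc1; acc$bc1 <- acc$bc1 + hb$bc1
      acc$Wc2 <- acc$Wc2 + hb$Wc2; acc$bc2 <- acc$bc2 + hb$bc2
      acc <- ns$.acc_encoder(acc, m, fw$cache, hb$dH, prompt_row = 2L)
      unlist(acc, use.names = FALSE)
    }),
    ppi = local({
      fa <- ns$encode_forward(m, tok1, m$prompts[3, ])
      fb <- ns$encode_forward(m, tok2, m$prompts[3, ])
      ps <- ns$.pair_step(m, fa$H, fb$H, 1)
      acc <- ns$zero_grads(m)
      acc$W <- acc$W + ps$dW
      acc <- ns$.acc_pair_head(acc, ps$dhead)
      acc <- ns$.acc_encoder(acc, m, fa$cache, ps$dHm, prompt_row = 3L)
      acc <- ns$.acc_encoder(acc, m, fb$cache, ps$dHn, prompt_row = 3L)
      unlist(acc, use.names = FALSE)
    }))

  flat <- ns$flatten_params(m)
  set.seed(12)
  idx <- sort(sample(length(flat), 60))
  for (task in names(losses)) {
    fn <- losses[[task]]
    fd <- vapply(idx, function(i) {
      e <- 1e-5
      fp <- flat; fp[i] <- fp[i] + e
      l1 <- fn(ns$unflatten_params(m, fp))
      fp[i] <- fp[i] - 2 * e
      l2 <- fn(ns$unflatten_params(m, fp))
      (l1 - l2) / (2 * e)
    }, 0)
    rel <- abs(fd - grads[[task]][idx]) / pmax(abs(fd), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("pretraining honors its optimizer contract", {
  cfg <- sim_config(seed = 13, n_proteins = 20, length_range = c(30L, 40L))
  pr <- gen_structures(gen_proteins(cfg), noise_sd = 0.5, config = cfg)
  nw <- gen_ppi_network(pr, cfg)
  small <- list(epochs = 1L, mlm_per_epoch = 6L, crd_per_epoch = 2L,
                clique_size = 8L, ppi_pairs_per_epoch = 8L)
  # learning rate zero leaves every parameter unchanged
  m0 <- pretrain(list(proteins = pr, network = nw),
                 config = c(small, list(lr = 0)), seed = 5)
  ref <- ns$init_model(d = 16, n_layers = 1, h = 32, hc = 32, seed = 5)
  expect_equal(ns$flatten_params(m0), ns$flatten_params(ref),
               tolerance = 1e-14)
  # identical seeds give identical training runs
  cfg2 <- c(small, list(epochs = 3L))
  m1 <- pretrain(list(proteins = pr, network = nw), config = cfg2, seed = 5)
  m2 <- pretrain(list(proteins = pr, network = nw), config = cfg2, seed = 5)
  expect_identical(m1$trace, m2$trace)
  expect_equal(ns$flatten_params(m1), ns$flatten_params(m2),
               tolerance = 0)
  expect_error(pretrain(list(proteins = list())), "no proteins")
})

test_that("fine-tuning needs edges and emits probabilities", {
  cfg <- sim_config(seed = 19, n_proteins = 16, length_range = c(30L, 40L))
  pr <- gen_structures(gen_proteins(cfg), noise_sd = 0.5, config = cfg)
  nw <- gen_ppi_network(pr, cfg)
  m <- pretrain(list(proteins = pr, network = nw),
                config = list(epochs = 2L, mlm_per_epoch = 6L,
                              crd_per_epoch = 2L, clique_size = 8L,
                              ppi_pairs_per_epoch = 8L), seed = 5)
  empty <- structure(list(proteins = nw$proteins,
                          pairs = nw$pairs[0, ]),
                     class = "InteractionNetwork")
  expect_error(finetune(m, empty), "no training edges")
  pred <- finetune(m, nw, config = list(head_steps = 50L, joint_epochs = 1L,
                                        joint_pairs = 8L), seed = 5)
  p <- predict(pred, nw$pairs[1:20, ])
  expect_true(all(p > 0 & p < 1))
  expect_error(predict(pred, data.frame(a = "nope", b = "P0001")),
               "vocabulary")
})

test_that("model checkpoints round-trip exactly", {
  m <- ns$init_model(d = 8, n_layers = 2, h = 8, hc = 8, seed = 42)
  f <- withr::local_tempfile(fileext = ".txt")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(ns$flatten_params(m), ns$flatten_params(m2), tolerance = 0)
  tok <- ns$tokenize_sequence("ACDEFGHIKLMN")
  expect_equal(ns$encode_forward(m, tok, m$prompts[1, ])$H,
               ns$encode_forward(m2, tok, m2$prompts[1, ])$H,
               tolerance = 0)
})
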