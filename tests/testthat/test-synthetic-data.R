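test_that("protein generator plants motifs, respects sizes and is seeded", {
  cfg <- sim_config(seed = 7, n_proteins = 50, motif_length = 6)
  pr <- gen_proteins(cfg)
  expect_length(pr, 50)
  # every sequence contains its assigned motif as an exact substring
  motif_of <- function(p) substr(p$sequence, p$motif_start,
                                 p$motif_start + 5)
  by_label <- split(vapply(pr, motif_of, ""), vapply(pr, `[[`, 0, "motif"))
  for (g in by_label) expect_length(unique(g), 1L)
  lens <- vapply(pr, function(p) nchar(p$sequence), 0)
  expect_true(all(lens >= cfg$length_range[1] & lens <= cfg$length_range[2]))
  # determinism and the empty limit
  expect_identical(pr, gen_proteins(cfg))
  expect_length(gen_proteins(sim_config(n_proteins = 0)), 0)
  expect_error(sim_config(motif_length = 60, length_range = c(50, 100)),
               "exceeds")
})

test_that("structure generator puts residues on the helix template", {
  cfg <- sim_config(seed = 3, n_proteins = 4)
  pr <- gen_structures(gen_proteins(cfg), noise_sd = 0, config = cfg)
  for (p in pr) expect_equal(nrow(p$coords), nchar(p$sequence))
  # consecutive C-alpha spacing matches the helix parameters exactly
  hx <- cfg$helix
  step <- sqrt(hx$rise^2 + (2 * hx$radius * sin(hx$turn / 2))^2)
  d <- sqrt(rowSums(diff(pr[[1]]$coords)^2))
  expect_true(all(abs(d - step) < 1e-6))
  # equal-length noise-free structures superpose exactly
  same_len <- which(vapply(pr, function(p) nchar(p$sequence), 0) ==
                    nchar(pr[[1]]$sequence))
  if (length(same_len) > 1)
    expect_lt(kabsch_superpose(pr[[same_len[1]]]$coords,
                               pr[[same_len[2]]]$coords)$rmsd, 1e-8)
})

test_that("network generator matches its edge model", {
  cfg <- sim_config(seed = 5, n_proteins = 30, p_in = 1, p_out = 0)
  pr <- gen_proteins(cfg)
  nw <- gen_ppi_network(pr, cfg)
  motifs <- stats::setNames(vapply(pr, `[[`, 0, "motif"),
                            vapply(pr, `[[`, "", "id"))
  same <- motifs[nw$pairs$a] == motifs[nw$pairs$b]
  # p_in = 1, p_out = 0: edges are exactly the within-motif cliques
  expect_true(all(nw$pairs$label[same] == 1))
  expect_true(all(nw$pairs$label[!same] == 0))
  expect_identical(nw, gen_ppi_network(pr, cfg))
  # p_in = p_out: positive rate within a binomial CI of the common rate
  for (s in 1:3) {
    cfg2 <- sim_config(seed = s, n_proteins = 40, p_in = 0.3, p_out = 0.3)
    nw2 <- gen_ppi_network(gen_proteins(cfg2), cfg2)
    n <- nrow(nw2$pairs)
    expect_lt(abs(mean(nw2$pairs$label) - 0.3),
              4 * sqrt(0.3 * 0.7 / n))
  }
})

test_that("junction-read generator is calibration-consistent with PSI", {
  counts <- gen_junction_reads(sprintf("e%03d", 1:50), c(g = 0.7),
                               depth = 2000, n_reps = 1, seed = 9)
  psi <- compute_psi(counts$I, counts$S, counts$lI, counts$lS)
  expect_lt(abs(mean(psi) - 0.7), 0.02)
  zero <- gen_junction_reads("e1", c(g = 0.5), depth = 0, n_reps = 2,
                             seed = 1)
  expect_true(all(zero$I == 0 & zero$S == 0))
  allin <- gen_junction_reads("e1", c(g = 1), depth = 500, n_reps = 3,
                              seed = 1)
  expect_true(all(allin$S == 0))
})

test_that("reporter worm generator recovers designed index ratios", {
  gm <- list(ctrl = c(gfp = 200, mcherry = 100),
             kd = c(gfp = 100, mcherry = 100))
  w0 <- gen_reporter_worms(gm, cv = 0, n_per_group = 5, seed = 2)
  expect_true(all(w0$gfp[w0$group == "ctrl"] == 200))
  expect_equal(nrow(w0), 10)
  ratios <- vapply(1:10, function(s) {
    w <- gen_reporter_worms(gm, cv = 0.3, n_per_group = 35, seed = s)
    sm <- splicing_index(w)$summary
    sm$mean[sm$group == "ctrl"] / sm$mean[sm$group == "kd"]
  }, 0)
  expect_lt(abs(mean(ratios) - 2) / 2, 0.05)
})

test_that("colocalization image generator hits its designed overlap", {
  full <- gen_coloc_images(64, coloc_fraction = 1, seed = 3)
  expect_identical(which(full$red > 0), which(full$green > 0))
  none <- gen_coloc_images(64, coloc_fraction = 0, seed = 3)
  expect_length(intersect(which(none$red > 0), which(none$green > 0)), 0)
  im <- gen_coloc_images(256, coloc_fraction = 0.6, seed = 3)
  expect_lt(abs(manders_coefficients(im)[["M1"]] - 0.6), 0.02)
})

test_that("chemotaxis count generator respects totals and expectations", {
  cc <- gen_chemotaxis_counts(1000, c(0.6, 0.2, 0.2), seed = 4)
  expect_equal(cc$IA + cc$T + cc$S, 1000)
  idx <- vapply(1:3, function(s)
    chemotaxis_index(gen_chemotaxis_counts(1000, c(0.6, 0.2, 0.2),
                                           seed = s)), 0)
  expect_lt(abs(mean(idx) - 0.4), 0.05)
  allin <- gen_chemotaxis_counts(50, c(1, 0, 0), seed = 4)
  expect_equal(chemotaxis_index(allin), 1)
})

test_that("a motif-aware baseline recovers the planted interaction signal", {
  # shared-6-mer nearest-neighbour rule; under p_in = 0.9 / p_out = 0.05
  # with four motif families the positive-class Bayes F1 is ~0.88, which
  # the baseline should approach
  fx <- make_ppi_fixture(seed = 21, n_proteins = 120)
  kmers <- lapply(fx$proteins, function(p) {
    L <- nchar(p$sequence)
    unique(substring(p$sequence, 1:(L - 5), 6:L))
  })
  names(kmers) <- vapply(fx$proteins, `[[`, "", "id")
  shared <- mapply(function(a, b) length(intersect(kmers[[a]], kmers[[b]])),
                   fx$network$pairs$a, fx$network$pairs$b)
  ev <- evaluate_f1(as.integer(shared >= 2), fx$network$pairs$label)
  expect_gt(ev$f1, 0.85)
})
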