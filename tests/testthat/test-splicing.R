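test_that("canonical event shapes are classified as defined", {
  # cassette exon: one ES event
  with_ex <- rbind(c(0, 100), c(200, 300), c(400, 500))
  without <- rbind(c(0, 100), c(400, 500))
  gm <- gene_model("g1", "+", list(t1 = with_ex, t2 = without))
  ev <- classify_ase_events(gm)
  expect_length(ev, 1)
  expect_identical(ev[[1]]$type, "ES")
  # two consecutive skipped exons: one MES event
  gm2 <- gene_model("g2", "+", list(
    t1 = rbind(c(0, 100), c(200, 300), c(400, 500), c(600, 700)),
    t2 = rbind(c(0, 100), c(600, 700))))
  ev2 <- classify_ase_events(gm2)
  expect_length(ev2, 1)
  expect_identical(ev2[[1]]$type, "MES")
  # retained intron: one IR event
  gm3 <- gene_model("g3", "+", list(
    t1 = rbind(c(0, 100), c(200, 300)),
    t2 = rbind(c(0, 300))))
  ev3 <- classify_ase_events(gm3)
  expect_length(ev3, 1)
  expect_identical(ev3[[1]]$type, "IR")
  # shifted donor on the plus strand: A5SS; on the minus strand: A3SS
  donor <- list(t1 = rbind(c(0, 100), c(200, 300)),
                t2 = rbind(c(0, 140), c(200, 300)))
  expect_identical(classify_ase_events(gene_model("g4", "+", donor))[[1]]$type,
                   "A5SS")
  expect_identical(classify_ase_events(gene_model("g4", "-", donor))[[1]]$type,
                   "A3SS")
  expect_error(gene_model("g5", "+", list(t1 = rbind(c(10, 5)))),
               "malformed")
  expect_error(classify_ase_events(gene_model("g6", "+",
                                              list(t1 = rbind(c(0, 10))))),
               ">= 2 transcripts")
})

test_that("classifier matches the brute-force enumeration oracle", {
  models <- gen_gene_models(n_genes = 40, n_transcripts = 3, n_exons = 6,
                            seed = 5)
  for (gm in models) {
    expect_identical(event_set_key(classify_ase_events(gm)),
                     event_set_key(oracle_ase_events(gm)))
  }
})

test_that("flipping the strand annotation swaps A5SS and A3SS only", {
  models <- gen_gene_models(n_genes = 30, n_transcripts = 3, n_exons = 6,
                            seed = 8)
  swap <- function(x) ifelse(x == "A3SS", "A5SS",
                             ifelse(x == "A5SS", "A3SS", x))
  for (gm in models) {
    t1 <- sort(vapply(classify_ase_events(gm), `[[`, "", "type"))
    t2 <- sort(vapply(classify_ase_events(flip_strand(gm)), `[[`, "",
                      "type"))
    expect_identical(sort(swap(t1)), t2)
  }
})

test_that("inclusion levels follow the length-normalized formula", {
  expect_equal(compute_psi(10, 0), 1)
  expect_equal(compute_psi(7, 7, 2, 2), 0.5)
  expect_equal(compute_psi(30, 10, 3, 1), 0.5)   # (30/3)/(30/3 + 10/1)
  expect_true(is.na(compute_psi(0, 0)))
  # monotone: increasing I raises PSI, increasing S lowers it
  psi <- compute_psi(0:50, 25, 2, 1)
  expect_true(all(diff(psi) > 0))
  psi2 <- compute_psi(25, 0:50, 2, 1)
  expect_true(all(diff(psi2[-1]) < 0))
  expect_true(all(psi >= 0 & psi <= 1, na.rm = TRUE))
  expect_error(compute_psi(-1, 5), "nonnegative")
})

test_that("differential test behaves under null, signal and degeneracy", {
  rep3 <- function(I, S) data.frame(I = I, S = S, lI = 2, lS = 1)
  same <- delta_psi_test(rep3(c(50, 60), c(50, 40)),
                         rep3(c(50, 60), c(50, 40)))
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  zero <- delta_psi_test(rep3(0, 0), rep3(10, 10))
  expect_false(zero$testable)
  expect_true(is.na(zero$p))
  # BH adjustment keeps order and never decreases a p-value
  counts <- gen_junction_reads(sprintf("e%02d", 1:40),
                               c(A = 0.5, B = 0.6), depth = 300,
                               n_reps = 3, seed = 3)
  res <- run_delta_psi(counts, "A", "B")
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
  expect_true(all(diff(res$padj[order(res$p)]) >= -1e-15))
})

test_that("significance filtering applies both thresholds strictly", {
  tab <- data.frame(event = paste0("e", 1:6),
                    delta = c(0.05, 0.2, -0.3, 0.15, 0.12, -0.09),
                    padj = c(0.001, 0.2, 0.01, 0.04, 0.051, 0.0001))
  kept <- filter_significant(tab)
  # hand application of |delta| > 0.1 AND padj < 0.05
  expect_identical(kept$event, c("e3", "e4"))
  expect_equal(nrow(filter_significant(tab[0, ])), 0)
})

test_that("set intersection logic matches per-element evaluation", {
  sets <- list(TvW = c("a", "b", "c", "d", "e"),
               NTvT = c("a", "b", "f"),
               NWvW = c("b", "g"),
               NTvW = c("c", "h"))
  out <- intersect_event_sets(
    sets, rule = "in(TvW) & in(NTvT) & !in(NWvW) & !in(NTvW)")
  # brute force over the union
  uni <- sort(unique(unlist(sets)))
  manual <- uni[vapply(uni, function(x)
    x %in% sets$TvW && x %in% sets$NTvT &&
      !(x %in% sets$NWvW) && !(x %in% sets$NTvW), TRUE)]
  expect_identical(out$selected, manual)
  expect_identical(out$selected, "a")
  # exclusive pattern counts always sum to the union size
  expect_equal(sum(out$patterns$count), length(uni))
  # disjoint sets: each pattern count equals its set size
  dis <- intersect_event_sets(list(A = c("x", "y"), B = c("z")))
  expect_setequal(dis$patterns$count, c(2, 1))
  # identical sets: a single full-intersection pattern
  ident <- intersect_event_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(nrow(ident$patterns), 1)
  expect_equal(ident$patterns$count, 2)
  expect_error(intersect_event_sets(sets, rule = "in(BAD)"), "unknown set")
  expect_error(intersect_event_sets(sets, rule = "system('ls')"),
               "may only")
})
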