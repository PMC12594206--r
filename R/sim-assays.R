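## Generators for the quantification inputs: junction reads, reporter
## worms, two-channel images, chemotaxis counts and toy gene models.

#' Simulate junction read counts for a set of splicing events
#'
#' Per event and replicate, the total read count is Poisson with the given
#' depth and the inclusion count is binomial with success probability
#' `psi * lI / (psi * lI + (1 - psi) * lS)` — the effective-length-weighted
#' inclusion probability — so the percent-spliced-in estimator of
#' [compute_psi()] is calibration-consistent by construction.
#'
#' @param events Character event ids, or `AseEvent` objects.
#' @param group_psi Named list/vector: per-group true inclusion fraction.
#' @param depth Mean total reads per event and replicate.
#' @param n_reps Replicates per group.
#' @param lI,lS Effective lengths of the inclusion and skipping forms.
#' @param seed Integer seed.
#' @return Data frame `event, replicate, group, I, S, lI, lS`.
#' @export
gen_junction_reads <- function(events, group_psi, depth = 2000,
                               n_reps = 3L, lI = 2L, lS = 1L, seed = 1L) {
  ids <- if (is.character(events)) events
         else vapply(events, function(e) e$id, "")
  psi <- unlist(group_psi)
  if (any(psi < 0 | psi > 1)) stop("group PSI values must lie in [0, 1]")
  grid <- expand.grid(event = ids, replicate = seq_len(n_reps),
                      group = names(psi), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$event, grid$group, grid$replicate), ]
  rownames(grid) <- NULL
  q <- psi[grid$group] * lI / (psi[grid$group] * lI + (1 - psi[grid$group]) * lS)
  with_seed(substream_seed(seed, "junction-reads"), {
    total <- stats::rpois(nrow(grid), depth)
    grid$I <- stats::rbinom(nrow(grid), total, q)
    grid$S <- total - grid$I
  })
  grid$lI <- lI
  grid$lS <- lS
  grid
}

#' Simulate per-worm dual-reporter fluorescence measurements
#'
#' Per-worm GFP (inclusion reporter) and mCherry (skipping reporter)
#' intensities are log-normal around the requested group means with a
#' common coefficient of variation; `cv = 0` gives the means exactly.
#'
#' @param group_means Named list: per group, a list/vector with `gfp` and
#'   `mcherry` mean intensities (arbitrary units, positive).
#' @param cv Per-worm coefficient of variation of each channel.
#' @param n_per_group Worms per group.
#' @param seed Integer seed.
#' @return Data frame `worm, group, gfp, mcherry`.
#' @export
gen_reporter_worms <- function(group_means, cv = 0.3, n_per_group = 30L,
                               seed = 1L) {
  stopifnot(cv >= 0)
  draw <- function(n, m, sdlog) {
    if (any(m <= 0)) stop("group means must be positive")
    if (sdlog == 0) rep(m, n)
    else stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(substream_seed(seed, "reporter-worms"), {
    out <- lapply(names(group_means), function(g) {
      gm <- group_means[[g]]
      data.frame(worm = sprintf("%s_w%03d", g, seq_len(n_per_group)),
                 group = g,
                 gfp = draw(n_per_group, gm[["gfp"]], sdlog),
                 mcherry = draw(n_per_group, gm[["mcherry"]], sdlog))
    })
    do.call(rbind, out)
  })
}

#' Simulate a two-channel image pair with a designed overlap fraction
#'
#' A set of red-channel (query protein) pixels is planted with positive
#' intensities; a fraction `coloc_fraction` of them, chosen independently
#' of intensity, also carries green (partner protein) signal. The remaining
#' green support is placed on non-red pixels, so `coloc_fraction = 1` gives
#' identical supports and `coloc_fraction = 0` disjoint ones. The designed
#' fraction is therefore what the Manders M1 coefficient estimates.
#'
#' @param size Image side length in pixels.
#' @param coloc_fraction Designed fraction of red pixels that are also green.
#' @param red_density Fraction of pixels carrying red signal.
#' @param seed Integer seed.
#' @return A `ChannelImagePair`: list with `red`, `green` (size x size
#'   intensity matrices) and `thresholds` (named, both 0).
#' @export
gen_coloc_images <- function(size = 256L, coloc_fraction = 0.6,
                             red_density = 0.1, seed = 1L) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1)
  n_px <- size * size
  n_red <- max(1L, round(red_density * n_px))
  with_seed(substream_seed(seed, "coloc-images"), {
    red_idx <- sample.int(n_px, n_red)
    n_white <- round(coloc_fraction * n_red)
    white_idx <- if (n_white > 0) sample(red_idx, n_white) else integer(0)
    n_green_only <- n_red - n_white
    green_only <- if (n_green_only > 0)
      sample(setdiff(seq_len(n_px), red_idx), n_green_only) else integer(0)
    red <- matrix(0, size, size)
    green <- matrix(0, size, size)
    red[red_idx] <- stats::rgamma(n_red, shape = 4, rate = 1 / 50)
    gidx <- c(white_idx, green_only)
    green[gidx] <- stats::rgamma(length(gidx), shape = 4, rate = 1 / 50)
    structure(list(red = red, green = green,
                   thresholds = c(red = 0, green = 0)),
              class = "ChannelImagePair")
  })
}

#' Simulate a chemotaxis assay count triple
#'
#' Each worm lands in the gradient (IA), trap (T) or start (S) region with
#' the given probabilities.
#'
#' @param n_worms Number of worms plated.
#' @param attraction Probability triple `(IA, T, S)`, summing to 1.
#' @param seed Integer seed.
#' @return A `ChemotaxisCounts`: list with integer `IA`, `T`, `S`.
#' @export
gen_chemotaxis_counts <- function(n_worms, attraction = c(0.6, 0.2, 0.2),
                                  seed = 1L) {
  stopifnot(length(attraction) == 3L, all(attraction >= 0),
            abs(sum(attraction) - 1) < 1e-9)
  k <- with_seed(substream_seed(seed, "chemotaxis"),
                 as.integer(stats::rmultinom(1L, n_worms, attraction)))
  structure(list(IA = k[1], T = k[2], S = k[3]), class = "ChemotaxisCounts")
}

#' Generate random toy gene models with local splicing differences
#'
#' Each gene starts from a chain of constitutive exons; additional
#' transcripts apply random local edits (skip one or more internal exons,
#' retain an intron, shift a donor or acceptor) so that the resulting
#' models exercise all five event categories.
#'
#' @param n_genes Number of genes.
#' @param n_transcripts Transcripts per gene (>= 2).
#' @param n_exons Exons in the base transcript.
#' @param seed Integer seed.
#' @return A list of `GeneModel` objects (see [gene_model()]).
#' @export
gen_gene_models <- function(n_genes = 10L, n_transcripts = 3L,
                            n_exons = 6L, seed = 1L) {
  stopifnot(n_transcripts >= 2L, n_exons >= 3L)
  with_seed(substream_seed(seed, "gene-models"), {
    lapply(seq_len(n_genes), function(g) {
      widths <- sample(80:250, n_exons, replace = TRUE)
      gaps <- sample(100:800, n_exons, replace = TRUE)
      starts <- cumsum(gaps) + cumsum(c(0L, widths[-n_exons]))
      base <- cbind(start = starts, end = starts + widths)
      txs <- list(t1 = base)
      for (k in 2:n_transcripts) {
        ex <- base
        edit <- sample(c("skip", "mes", "ir", "alt_donor", "alt_acceptor"), 1L)
        if (edit == "skip") {
          i <- sample(2:(n_exons - 1L), 1L)
          ex <- ex[-i, , drop = FALSE]
        } else if (edit == "mes") {
          i <- sample(2:(n_exons - 2L), 1L)
          ex <- ex[-c(i, i + 1L), , drop = FALSE]
        } else if (edit == "ir") {
          i <- sample(seq_len(n_exons - 1L), 1L)
          ex[i, "end"] <- ex[i + 1L, "end"]
          ex <- ex[-(i + 1L), , drop = FALSE]
        } else if (edit == "alt_donor") {
          i <- sample(seq_len(n_exons - 1L), 1L)
          ex[i, "end"] <- ex[i, "end"] + sample(c(-40L, 40L), 1L)
        } else {
          i <- sample(2:n_exons, 1L)
          ex[i, "start"] <- ex[i, "start"] + sample(c(-40L, 40L), 1L)
        }
        txs[[paste0("t", k)]] <- ex
      }
      gene_model(gene_id = sprintf("G%03d", g),
                 strand = sample(c("+", "-"), 1L),
                 transcripts = txs)
    })
  })
}
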