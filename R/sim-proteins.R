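#' Generate a synthetic protein corpus with planted interaction motifs
#'
#' Each protein is a uniform random amino-acid sequence carrying one latent
#' motif label; the motif's literal subsequence is embedded at a random
#' position, so downstream interaction signal (motif-sharing pairs interact)
#' is learnable from sequence alone.
#'
#' @param config A [sim_config()].
#' @return A list of `ProteinRecord`s: `id`, `sequence`, `motif` (label),
#'   `motif_start` (1-based), and `coords` (`NULL` until
#'   [gen_structures()]).
#' @export
gen_proteins <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$n_proteins
  if (n == 0L) return(list())
  if (config$n_motifs < 1L) stop("n_motifs must be >= 1")
  with_seed(substream_seed(config$seed, "proteins"), {
    motifs <- vapply(seq_len(config$n_motifs), function(i)
      paste(sample(.AA, config$motif_length, replace = TRUE), collapse = ""),
      character(1))
    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   n, replace = TRUE)
    labels <- sample.int(config$n_motifs, n, replace = TRUE)
    lapply(seq_len(n), function(i) {
      L <- lens[i]
      chars <- sample(.AA, L, replace = TRUE)
      pos <- sample.int(L - config$motif_length + 1L, 1L)
      chars[pos:(pos + config$motif_length - 1L)] <-
        strsplit(motifs[labels[i]], "")[[1]]
      structure(list(id = sprintf("P%04d", i),
                     sequence = paste(chars, collapse = ""),
                     motif = labels[i], motif_start = pos,
                     coords = NULL),
                class = "ProteinRecord")
    })
  })
}

# ideal alpha-helix C-alpha trace for a given length
helix_template <- function(L, helix) {
  i <- seq_len(L) - 1L
  cbind(x = helix$radius * cos(i * helix$turn),
        y = helix$radius * sin(i * helix$turn),
        z = i * helix$rise)
}

#' Attach synthetic C-alpha coordinates to a protein corpus
#'
#' Coordinates follow an ideal alpha-helix parameterization (any rigid
#' template suffices as ground truth for the coordinate-prediction loss)
#' plus isotropic Gaussian noise; one coordinate triple per residue.
#'
#' @param proteins Output of [gen_proteins()].
#' @param noise_sd Isotropic coordinate noise standard deviation (Angstrom).
#' @param config A [sim_config()] supplying the helix parameters and seed.
#' @return The records with a `coords` matrix (`L x 3`, Angstrom) filled in.
#' @export
gen_structures <- function(proteins, noise_sd = 0.5, config = sim_config()) {
  stopifnot(noise_sd >= 0)
  with_seed(substream_seed(config$seed, "structures"), {
    lapply(proteins, function(p) {
      L <- nchar(p$sequence)
      Z <- helix_template(L, config$helix)
      if (noise_sd > 0) Z <- Z + matrix(rnorm(3L * L, sd = noise_sd), L, 3L)
      p$coords <- unname(Z)
      p
    })
  })
}

#' Sample a labelled interaction network over a protein corpus
#'
#' Every unordered protein pair is sampled as interacting with probability
#' `p_in` when the two proteins share a planted motif and `p_out` otherwise.
#' Negative pairs are recorded explicitly, so evaluation never depends on a
#' sampling convention.
#'
#' @param proteins Output of [gen_proteins()] (must carry motif labels).
#' @param config A [sim_config()].
#' @return An `InteractionNetwork`: list with `proteins` (ids) and `pairs`
#'   (data.frame `a`, `b`, `label`).
#' @export
gen_ppi_network <- function(proteins, config) {
  if (length(proteins) < 2L)
    return(structure(list(proteins = vapply(proteins, `[[`, "", "id"),
                          pairs = data.frame(a = character(0),
                                             b = character(0),
                                             label = integer(0))),
                     class = "InteractionNetwork"))
  ids <- vapply(proteins, `[[`, "", "id")
  motifs <- vapply(proteins, `[[`, 0, "motif")
  idx <- utils::combn(length(ids), 2L)
  same <- motifs[idx[1, ]] == motifs[idx[2, ]]
  p <- ifelse(same, config$p_in, config$p_out)
  lab <- with_seed(substream_seed(config$seed, "network"),
                   as.integer(stats::runif(length(p)) < p))
  structure(list(proteins = ids,
                 pairs = data.frame(a = ids[idx[1, ]], b = ids[idx[2, ]],
                                    label = lab)),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d proteins, %d labelled pairs (%d positive)\n",
              length(x$proteins), nrow(x$pairs), sum(x$pairs$label)))
  invisible(x)
}
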