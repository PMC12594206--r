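## File interfaces: FASTA sequences, CA-only PDB coordinates, TSV edge
## lists and count tables, whitespace-separated image matrices, simplified
## GTF gene models, and a plain-text model checkpoint format. All writers
## produce byte-identical files for identical inputs.

#' Write protein sequences to FASTA
#' @param proteins List of `ProteinRecord`s.
#' @param path Output file.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(vapply(proteins, `[[`, "", "sequence"))
  names(seqs) <- vapply(proteins, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return List of `ProteinRecord`s (no coordinates).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  lapply(seq_along(seqs), function(i)
    structure(list(id = names(seqs)[i],
                   sequence = as.character(seqs[[i]]),
                   motif = NA_integer_, coords = NULL),
              class = "ProteinRecord"))
}

#' Write a CA-only PDB file for one protein record
#' @param record A `ProteinRecord` with `coords`.
#' @param path Output file.
#' @export
write_ca_pdb <- function(record, path) {
  if (is.null(record$coords)) stop("record has no coordinates")
  L <- nrow(record$coords)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(record$coords)),
                   resno = seq_len(L), resid = rep("ALA", L),
                   eleno = seq_len(L), elety = rep("CA", L),
                   chain = rep("A", L))
  invisible(path)
}

#' Read C-alpha coordinates from a PDB file
#' @param path PDB file.
#' @return Numeric `L x 3` coordinate matrix (Angstrom).
#' @export
read_ca_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  matrix(pdb$xyz[sel$xyz], ncol = 3L, byrow = TRUE)
}

#' Write an interaction network as a TSV edge list
#' @param network An `InteractionNetwork`.
#' @param path Output file (`proteinA proteinB label`).
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("proteinA", "proteinB",
                                                      "label"))
  invisible(path)
}

#' Read a TSV edge list into an interaction network
#' @param path TSV with columns `proteinA proteinB label`.
#' @return An `InteractionNetwork`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- c("a", "b", "label")
  structure(list(proteins = sort(unique(c(df$a, df$b))), pairs = df),
            class = "InteractionNetwork")
}

#' Write / read a junction count table
#' @param counts Data frame `event replicate group I S lI lS`.
#' @param path TSV path.
#' @export
write_junction_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_counts
#' @export
read_junction_counts <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read a two-channel image pair as whitespace-separated matrices
#' @param images A `ChannelImagePair`.
#' @param red_path,green_path Output files.
#' @export
write_image_pair <- function(images, red_path, green_path) {
  wr <- function(m, p) utils::write.table(
    format(m, digits = 10, trim = TRUE, scientific = FALSE), p,
    sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  wr(images$red, red_path); wr(images$green, green_path)
  invisible(c(red_path, green_path))
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(red_path, green_path) {
  rd <- function(p) as.matrix(utils::read.table(p, header = FALSE))
  structure(list(red = unname(rd(red_path)), green = unname(rd(green_path)),
                 thresholds = c(red = 0, green = 0)),
            class = "ChannelImagePair")
}

# ---- simplified GTF ----------------------------------------------------

#' Write gene models as simplified GTF
#'
#' Feature types `transcript` and `exon` with `gene_id`/`transcript_id`
#' attributes; coordinates converted from the internal 0-based half-open
#' convention to GTF's 1-based closed intervals.
#'
#' @param models List of `GeneModel`s.
#' @param path Output GTF file.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (gm in models) {
    for (nm in names(gm$transcripts)) {
      ex <- gm$transcripts[[nm]]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                       gm$gene_id, paste0(gm$gene_id, ".", nm))
      lines <- c(lines,
                 sprintf("chr1\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                         min(ex[, "start"]) + 1L, max(ex[, "end"]),
                         gm$strand, attrs),
                 sprintf("chr1\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                         ex[, "start"] + 1L, ex[, "end"], gm$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a simplified GTF
#'
#' @param path GTF with `exon` features carrying `gene_id` and
#'   `transcript_id` attributes (1-based closed; converted to 0-based
#'   half-open on read).
#' @return List of `GeneModel`s. Strand per gene is taken from its
#'   features.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(gene = gr$gene_id, tx = gr$transcript_id,
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  lapply(split(df, df$gene), function(g) {
    txs <- lapply(split(g, g$tx), function(t)
      cbind(start = t$start, end = t$end))
    names(txs) <- sub(paste0("^", g$gene[1], "\\."), "", names(txs))
    gene_model(g$gene[1], g$strand[1], txs)
  })
}

# ---- model checkpoints -------------------------------------------------

.flatten_named <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x))
      out <- c(out, .flatten_named(x[[nm]], paste0(prefix, nm, ".")))
    out
  } else {
    stats::setNames(list(x), sub("\\.$", "", prefix))
  }
}

#' Save / load a model checkpoint
#'
#' Plain-text single-file archive: a versioned header, the config line,
#' then one named block per parameter array (`@name nrow ncol` followed by
#' the values at full precision). Reloading reproduces the model exactly.
#'
#' @param model A `ModelState`.
#' @param path Checkpoint file.
#' @export
save_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# spliceppi-model v1", con)
  cfg <- model$config
  writeLines(sprintf("config d=%d n_layers=%d h=%d hc=%d scale_attn=%d conv_window=%d pe_scale=%.17g",
                     cfg$d, cfg$n_layers, cfg$h, cfg$hc,
                     as.integer(!isFALSE(cfg$scale_attn)),
                     cfg$conv_window, cfg$pe_scale), con)
  blocks <- .flatten_named(.trainable(model))
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    dims <- if (is.matrix(b)) dim(b) else c(length(b), 0L)
    writeLines(sprintf("@%s %d %d", nm, dims[1], dims[2]), con)
    writeLines(paste(sprintf("%.17g", as.numeric(b)), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "# spliceppi-model v1"))
    stop("not a spliceppi model checkpoint")
  cfg <- as.numeric(sub(".*=", "",
                        strsplit(sub("^config ", "", lines[2]), " ")[[1]]))
  model <- init_model(d = cfg[1], n_layers = cfg[2], h = cfg[3], hc = cfg[4],
                      scale_attn = cfg[5] == 1, conv_window = cfg[6],
                      pe_scale = cfg[7])
  i <- 3L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ")[[1]]
    nm <- sub("^@", "", hdr[1])
    nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3])
    vals <- as.numeric(strsplit(lines[i + 1L], " ")[[1]])
    obj <- if (nc > 0L) matrix(vals, nr, nc) else vals
    keys <- strsplit(nm, ".", fixed = TRUE)[[1]]
    model <- .assign_path(model, keys, obj)
    i <- i + 2L
  }
  model
}

.assign_path <- function(x, keys, value) {
  if (length(keys) == 1L) {
    x[[keys]] <- value
  } else {
    x[[keys[1]]] <- .assign_path(x[[keys[1]]], keys[-1], value)
  }
  x
}
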