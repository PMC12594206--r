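## Independent oracles used by the unit and acceptance tests. These follow
## different code paths than the implementation they check.

# Brute-force rigid superposition: two-stage grid search over Euler angles
# (coarse pass, then a 0.5-degree local refinement), evaluating the RMSD of
# every candidate rotation after centroid matching.
grid_search_rmsd <- function(P, Q, coarse = 6, fine = 0.5, span = 9) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  ss <- sum(Pc^2) + sum(Qc^2)
  M <- crossprod(Pc, Qc)                       # rmsd^2 = (ss - 2 tr(R'M))/n
  eval_grid <- function(al, be, ga) {
    g <- expand.grid(al = al, be = be, ga = ga)
    ca <- cos(g$al); sa <- sin(g$al); cb <- cos(g$be); sb <- sin(g$be)
    cc <- cos(g$ga); sc_ <- sin(g$ga)
    # R = Rz(al) Ry(be) Rz(ga), entries written out; trace against M
    tr <- (ca * cb * cc - sa * sc_) * M[1, 1] +
      (-ca * cb * sc_ - sa * cc) * M[2, 1] +
      (ca * sb) * M[3, 1] +
      (sa * cb * cc + ca * sc_) * M[1, 2] +
      (-sa * cb * sc_ + ca * cc) * M[2, 2] +
      (sa * sb) * M[3, 2] +
      (-sb * cc) * M[1, 3] +
      (sb * sc_) * M[2, 3] +
      cb * M[3, 3]
    i <- which.max(tr)
    list(best = unlist(g[i, ]), tr = tr[i])
  }
  deg <- pi / 180
  s1 <- eval_grid(seq(0, 360 - coarse, by = coarse) * deg,
                  seq(0, 180, by = coarse) * deg,
                  seq(0, 360 - coarse, by = coarse) * deg)
  b <- s1$best
  s2 <- eval_grid(b[1] + seq(-span, span, by = fine) * deg,
                  b[2] + seq(-span, span, by = fine) * deg,
                  b[3] + seq(-span, span, by = fine) * deg)
  sqrt(max(0, (ss - 2 * s2$tr) / nrow(P)))
}

# Brute-force ASE enumeration: pattern-matches each category independently
# with explicit interval predicates (no index-adjacency shortcuts).
oracle_ase_events <- function(model) {
  txs <- model$transcripts
  # next exon strictly after x by coordinate
  succ <- function(ex, i) {
    after <- which(ex[, "start"] > ex[i, "start"])
    if (!length(after)) return(NA_integer_)
    after[which.min(ex[after, "start"])]
  }
  gap_empty <- function(ex, lo, hi)
    !any(ex[, "start"] < hi & ex[, "end"] > lo)
  keys <- character(0); out <- list()
  add <- function(type, coords) {
    if (type == "alt_donor") type <- if (model$strand == "+") "A5SS" else "A3SS"
    if (type == "alt_acceptor") type <- if (model$strand == "+") "A3SS" else "A5SS"
    key <- paste(type, paste(coords, collapse = ","))
    if (!key %in% keys) {
      keys <<- c(keys, key)
      out[[length(out) + 1L]] <<- list(type = type, coords = unname(coords))
    }
  }
  for (p1 in seq_along(txs)) for (p2 in seq_along(txs)) {
    if (p1 == p2) next
    e1 <- txs[[p1]]; e2 <- txs[[p2]]
    n1 <- nrow(e1); n2 <- nrow(e2)
    # ES / MES: flanks a, b in e1 around a run of skipped exons that e2
    # bridges with one junction
    for (a in seq_len(n1)) for (b in seq_len(n1)) {
      if (e1[b, "start"] <= e1[a, "end"]) next
      inside <- which(e1[, "start"] >= e1[a, "end"] &
                      e1[, "end"] <= e1[b, "start"] &
                      seq_len(n1) != a & seq_len(n1) != b)
      if (length(inside) == 0L || length(inside) != b - a - 1L) next
      has_u <- any(e2[, "end"] == e1[a, "end"])
      has_v <- any(e2[, "start"] == e1[b, "start"])
      if (has_u && has_v && gap_empty(e2, e1[a, "end"], e1[b, "start"])) {
        sk <- e1[inside, , drop = FALSE]
        add(if (nrow(sk) == 1L) "ES" else "MES",
            c(e1[a, "end"], t(sk), e1[b, "start"]))
      }
    }
    # IR: e1 exon spanning an e2 junction exactly
    for (i in seq_len(n1)) for (u in seq_len(n2)) for (v in seq_len(n2)) {
      if (u == v || e2[u, "start"] != e1[i, "start"] ||
          e2[v, "end"] != e1[i, "end"]) next
      if (e2[u, "end"] >= e2[v, "start"]) next
      if (gap_empty(e2, e2[u, "end"], e2[v, "start"]))
        add("IR", c(e1[i, "start"], e2[u, "end"], e2[v, "start"],
                    e1[i, "end"]))
    }
    # alternative donor / acceptor
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      i2 <- succ(e1, i); j2 <- succ(e2, j)
      if (is.na(i2) || is.na(j2)) next
      if (e1[i, "start"] == e2[j, "start"] && e1[i, "end"] != e2[j, "end"] &&
          e1[i2, "start"] == e2[j2, "start"])
        add("alt_donor", c(e1[i, "start"],
                           sort(c(e1[i, "end"], e2[j, "end"])),
                           e1[i2, "start"]))
      if (e1[i, "end"] == e2[j, "end"] &&
          e1[i2, "start"] != e2[j2, "start"] &&
          e1[i2, "end"] == e2[j2, "end"])
        add("alt_acceptor", c(e1[i, "end"],
                              sort(c(e1[i2, "start"], e2[j2, "start"])),
                              e1[i2, "end"]))
    }
  }
  out
}

# canonical string form of an event set, for set comparison
event_set_key <- function(events) {
  sort(vapply(events, function(e)
    paste(e$type, paste(e$coords, collapse = ",")), ""))
}

# mirror a gene model: reflect coordinates and flip the strand annotation,
# keeping the same biology in mirrored coordinates
flip_strand <- function(model) {
  model$strand <- if (model$strand == "+") "-" else "+"
  model
}

# small helper: planted-signal corpus + its network and split
make_ppi_fixture <- function(seed, n_proteins = 200L, test_fraction = 0.2) {
  cfg <- sim_config(seed = seed, n_proteins = n_proteins)
  pr <- gen_proteins(cfg)
  pr <- gen_structures(pr, noise_sd = 0.5, config = cfg)
  nw <- gen_ppi_network(pr, cfg)
  sp <- split_network(nw, "random", test_fraction = test_fraction, seed = seed)
  train_nw <- structure(list(proteins = nw$proteins, pairs = sp$train),
                        class = "InteractionNetwork")
  list(config = cfg, proteins = pr, network = nw, split = sp,
       train_network = train_nw)
}
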