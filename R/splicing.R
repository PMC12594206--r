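## PSI / IncLevel estimation, ASE classification and set logic.
## Coordinates are 0-based half-open throughout; the GTF reader converts
## from GTF's 1-based closed intervals at parse time.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param transcripts Named list; each element a 2-column matrix or data
#'   frame of exons (`start`, `end`), 0-based half-open, sorted and
#'   non-overlapping within the transcript.
#' @return A `GeneModel`.
#' @export
gene_model <- function(gene_id, strand, transcripts) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  transcripts <- lapply(transcripts, function(ex) {
    ex <- as.matrix(ex)[, 1:2, drop = FALSE]
    colnames(ex) <- c("start", "end")
    ex[order(ex[, "start"]), , drop = FALSE]
  })
  for (nm in names(transcripts)) {
    ex <- transcripts[[nm]]
    if (any(ex[, "start"] < 0) || any(ex[, "end"] <= ex[, "start"]))
      stop("malformed intervals in transcript ", nm)
    if (nrow(ex) > 1L && any(ex[-1L, "start"] < ex[-nrow(ex), "end"]))
      stop("overlapping exons in transcript ", nm)
  }
  structure(list(gene_id = gene_id, strand = strand,
                 transcripts = transcripts),
            class = "GeneModel")
}

# ---- ASE classification ------------------------------------------------

.event_id <- function(type, coords) {
  paste0(type, ":", paste(coords, collapse = "-"))
}

.ase_event <- function(type, gene, coords) {
  structure(list(id = .event_id(type, coords), type = type,
                 gene = gene, coords = coords),
            class = "AseEvent")
}

# events detected on a single ordered transcript pair, genomic labels
# ("alt_donor"/"alt_acceptor" mapped to A5SS/A3SS by strand later)
.pair_events <- function(e1, e2, gene) {
  out <- list()
  n1 <- nrow(e1); n2 <- nrow(e2)
  # exon skipping: consecutive exons (j, j+1) in transcript 2 whose
  # junction spans >= 1 consecutive exons of transcript 1
  if (n2 >= 2L && n1 >= 3L) {
    for (j in seq_len(n2 - 1L)) {
      i <- match(e2[j, "end"], e1[, "end"])
      k <- match(e2[j + 1L, "start"], e1[, "start"])
      if (!is.na(i) && !is.na(k) && k > i + 1L) {
        skipped <- e1[(i + 1L):(k - 1L), , drop = FALSE]
        type <- if (nrow(skipped) == 1L) "ES" else "MES"
        out[[length(out) + 1L]] <- .ase_event(
          type, gene, c(e1[i, "end"], t(skipped), e1[k, "start"]))
      }
    }
  }
  # intron retention: an exon of transcript 1 spans a junction of
  # transcript 2 exactly (same outer boundaries)
  if (n2 >= 2L) {
    for (j in seq_len(n2 - 1L)) {
      i <- which(e1[, "start"] == e2[j, "start"] &
                 e1[, "end"] == e2[j + 1L, "end"])
      if (length(i) == 1L)
        out[[length(out) + 1L]] <- .ase_event(
          "IR", gene, c(e2[j, "start"], e2[j, "end"],
                        e2[j + 1L, "start"], e2[j + 1L, "end"]))
    }
  }
  # alternative donor: same exon start, different donor ends, shared
  # downstream acceptor
  if (n1 >= 2L && n2 >= 2L) {
    for (i in seq_len(n1 - 1L)) {
      for (j in seq_len(n2 - 1L)) {
        if (e1[i, "start"] == e2[j, "start"] &&
            e1[i, "end"] != e2[j, "end"] &&
            e1[i + 1L, "start"] == e2[j + 1L, "start"]) {
          ends <- sort(c(e1[i, "end"], e2[j, "end"]))
          out[[length(out) + 1L]] <- .ase_event(
            "alt_donor", gene,
            c(e1[i, "start"], ends, e1[i + 1L, "start"]))
        }
        # alternative acceptor: shared upstream donor, different acceptor
        # starts, same exon end
        if (e1[i, "end"] == e2[j, "end"] &&
            e1[i + 1L, "start"] != e2[j + 1L, "start"] &&
            e1[i + 1L, "end"] == e2[j + 1L, "end"]) {
          starts <- sort(c(e1[i + 1L, "start"], e2[j + 1L, "start"]))
          out[[length(out) + 1L]] <- .ase_event(
            "alt_acceptor", gene,
            c(e1[i, "end"], starts, e1[i + 1L, "end"]))
        }
      }
    }
  }
  out
}

#' Classify the alternative-splicing events of a gene model
#'
#' Pairwise transcript comparison detecting local structural differences:
#' one skipped internal exon gives exon skipping (ES), a run of two or more
#' consecutive skipped exons multiple exon skipping (MES), an exon spanning
#' another transcript's intron exactly intron retention (IR), and a shifted
#' splice site with the rest of the local structure shared an alternative
#' 5' or 3' splice site (A5SS/A3SS, oriented by transcription strand).
#' Events are de-duplicated across transcript pairs by type and defining
#' coordinates.
#'
#' @param model A [gene_model()] with at least two transcripts.
#' @return A list of `AseEvent`s (`id`, `type`, `gene`, `coords`).
#' @export
classify_ase_events <- function(model) {
  stopifnot(inherits(model, "GeneModel"))
  txs <- model$transcripts
  if (length(txs) < 2L) stop("need >= 2 transcripts to classify events")
  events <- list()
  for (i in seq_along(txs)) {
    for (j in seq_along(txs)) {
      if (i == j) next
      events <- c(events, .pair_events(txs[[i]], txs[[j]], model$gene_id))
    }
  }
  # genomic donor/acceptor labels -> strand-oriented A5SS/A3SS
  events <- lapply(events, function(e) {
    if (e$type == "alt_donor")
      e$type <- if (model$strand == "+") "A5SS" else "A3SS"
    else if (e$type == "alt_acceptor")
      e$type <- if (model$strand == "+") "A3SS" else "A5SS"
    e$id <- .event_id(e$type, e$coords)
    e
  })
  events[!duplicated(vapply(events, function(e)
    paste(e$type, paste(e$coords, collapse = ",")), ""))]
}

# ---- PSI ---------------------------------------------------------------

#' Percent-spliced-in (IncLevel) from junction counts
#'
#' The inclusion level is the length-normalized inclusion fraction
#' `(I/lI) / (I/lI + S/lS)`: the fraction of mRNAs corresponding to the
#' inclusion isoform, with `I`/`S` the inclusion/skipping junction reads
#' and `lI`/`lS` the effective lengths (read positions supporting each
#' form). Events with zero coverage are flagged missing (`NA`), not 0.
#'
#' @param I,S Inclusion and skipping read counts (vectors allowed).
#' @param lI,lS Effective lengths (>= 1).
#' @return Inclusion level(s) in `[0, 1]`, `NA` where `I + S = 0`.
#' @export
compute_psi <- function(I, S, lI = 1, lS = 1) {
  if (any(I < 0 | S < 0)) stop("read counts must be nonnegative")
  if (any(lI < 1 | lS < 1)) stop("effective lengths must be >= 1")
  psi <- (I / lI) / (I / lI + S / lS)
  psi[I + S == 0] <- NA_real_
  psi
}

# binomial log-likelihood with 0*log(0) = 0
.ll_binom <- function(I, T, q) {
  t1 <- ifelse(I > 0, I * log(q), 0)
  t2 <- ifelse(T - I > 0, (T - I) * log1p(-q), 0)
  t1 + t2
}

#' Differential inclusion test for one event
#'
#' Group inclusion levels come from pooled counts; the p-value is a
#' likelihood-ratio test of equal versus free inclusion probabilities
#' under a binomial model on the junction counts (whose success
#' probability is the effective-length-weighted inclusion probability, so
#' equality of the binomial rates is equality of the inclusion levels).
#'
#' @param groupA,groupB Data frames of replicate counts with columns
#'   `I`, `S`, `lI`, `lS` (effective lengths constant within an event).
#' @return List with `psi_a`, `psi_b`, `delta` (B minus A), `p`, and
#'   `testable` (`FALSE` when a group has zero coverage).
#' @export
delta_psi_test <- function(groupA, groupB) {
  stopifnot(nrow(groupA) >= 1L, nrow(groupB) >= 1L)
  IA <- sum(groupA$I); TA <- IA + sum(groupA$S)
  IB <- sum(groupB$I); TB <- IB + sum(groupB$S)
  lI <- groupA$lI[1]; lS <- groupA$lS[1]
  psi_a <- compute_psi(IA, TA - IA, lI, lS)
  psi_b <- compute_psi(IB, TB - IB, lI, lS)
  if (TA == 0 || TB == 0)
    return(list(psi_a = psi_a, psi_b = psi_b, delta = NA_real_,
                p = NA_real_, testable = FALSE))
  qa <- IA / TA; qb <- IB / TB; q0 <- (IA + IB) / (TA + TB)
  lr <- 2 * (.ll_binom(IA, TA, qa) + .ll_binom(IB, TB, qb) -
             .ll_binom(IA, TA, q0) - .ll_binom(IB, TB, q0))
  list(psi_a = psi_a, psi_b = psi_b, delta = psi_b - psi_a,
       p = stats::pchisq(max(lr, 0), df = 1L, lower.tail = FALSE),
       testable = TRUE)
}

#' Differential inclusion across a table of events
#'
#' Runs [delta_psi_test()] per event between two groups and applies
#' Benjamini-Hochberg adjustment across all testable events.
#'
#' @param counts Data frame `event, replicate, group, I, S, lI, lS`
#'   (as from [gen_junction_reads()] or [read_junction_counts()]).
#' @param group_a,group_b The two group labels to compare.
#' @return Data frame `event, psi_a, psi_b, delta, p, padj, testable`.
#' @export
run_delta_psi <- function(counts, group_a, group_b) {
  ev <- unique(counts$event)
  res <- lapply(ev, function(e) {
    sub <- counts[counts$event == e, ]
    r <- delta_psi_test(sub[sub$group == group_a, ],
                        sub[sub$group == group_b, ])
    data.frame(event = e, psi_a = r$psi_a, psi_b = r$psi_b,
               delta = r$delta, p = r$p, testable = r$testable)
  })
  res <- do.call(rbind, res)
  res$padj <- NA_real_
  res$padj[res$testable] <- stats::p.adjust(res$p[res$testable], "BH")
  res
}

#' Filter events by effect size and adjusted significance
#'
#' Retains events with `|delta IncLevel| > min_dpsi` and adjusted
#' `p < alpha` (both strict, matching the conventional reporting rule).
#'
#' @param results Data frame from [run_delta_psi()].
#' @param min_dpsi Minimum absolute IncLevel difference (default 0.1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The retained rows.
#' @export
filter_significant <- function(results, min_dpsi = 0.1, alpha = 0.05) {
  keep <- !is.na(results$delta) & !is.na(results$padj) &
    abs(results$delta) > min_dpsi & results$padj < alpha
  results[keep, , drop = FALSE]
}

# ---- set intersection logic --------------------------------------------

# validate and compile a membership rule like "in(A) & in(B) & !in(C)"
.compile_rule <- function(rule, set_names) {
  if (!grepl("^[A-Za-z0-9_.() !&|]+$", rule))
    stop("rule may only contain in(<set>), !, &, | and parentheses")
  used <- regmatches(rule, gregexpr("in\\(([A-Za-z0-9_.]+)\\)", rule))[[1]]
  used <- gsub("^in\\(|\\)$", "", used)
  bad <- setdiff(used, set_names)
  if (length(bad)) stop("unknown set(s) in rule: ", paste(bad, collapse = ", "))
  stripped <- gsub("in\\([A-Za-z0-9_.]+\\)", "TRUE", rule)
  if (!grepl("^[TRUE() !&|]*$", stripped))
    stop("rule may only combine in(<set>) terms")
  parse(text = gsub("in\\(([A-Za-z0-9_.]+)\\)", "`\\1`", rule))[[1]]
}

#' Membership patterns and rule-based selection over named event sets
#'
#' Computes all exclusive (UpSet-style) membership patterns over the named
#' sets, and optionally evaluates a selection rule such as
#' `"in(A) & in(B) & !in(C) & !in(D)"` per event. The exclusive pattern
#' counts always sum to the size of the union.
#'
#' @param sets Named list of character event-id vectors.
#' @param rule Optional selection rule string over `in(<set name>)` terms
#'   combined with `!`, `&`, `|` and parentheses.
#' @return List with `patterns` (data frame: one row per observed exclusive
#'   membership pattern with its count), `membership` (logical matrix,
#'   events x sets), and `selected` (character ids matching `rule`, or
#'   `NULL` when no rule is given).
#' @export
intersect_event_sets <- function(sets, rule = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  M <- vapply(sets, function(s) universe %in% s,
              logical(length(universe)))
  if (length(universe) == 1L) M <- matrix(M, nrow = 1L,
                                          dimnames = list(NULL, names(sets)))
  rownames(M) <- universe
  key <- apply(M, 1L, function(r)
    paste(ifelse(r, names(sets), paste0("!", names(sets))), collapse = "&"))
  tab <- table(key)
  patterns <- data.frame(pattern = names(tab), count = as.integer(tab),
                         row.names = NULL)
  selected <- NULL
  if (!is.null(rule)) {
    expr <- .compile_rule(rule, names(sets))
    env <- as.environment(
      stats::setNames(lapply(names(sets), function(nm) M[, nm]), names(sets)))
    parent.env(env) <- baseenv()
    hit <- eval(expr, env)
    selected <- universe[hit]
  }
  list(patterns = patterns, membership = M, selected = selected)
}
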