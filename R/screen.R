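## Network splitting, F1 evaluation and candidate ranking for PPI
## screening. BFS and DFS splits hold out whole proteins chosen by graph
## traversal, testing generalization to unseen (clustered vs path-like)
## regions of the interaction network.

#' Split an interaction network for training and evaluation
#'
#' BFS/DFS schemes traverse the positive-edge graph from a seeded-random
#' root (restarting in the next component if a component is exhausted) and
#' accumulate visited proteins as test proteins until the fraction of
#' labelled pairs incident to them reaches `test_fraction`; every pair
#' touching a test protein is a test pair (pairs with both endpoints in
#' the test set are also test pairs — the stricter choice, avoiding
#' leakage). The random scheme splits pairs uniformly.
#'
#' @param network An `InteractionNetwork`.
#' @param scheme `"BFS"`, `"DFS"` or `"random"`.
#' @param test_fraction Target fraction of pairs held out, in (0, 1).
#' @param seed Integer seed (root choice / pair shuffle).
#' @param root Optional traversal root protein id; by default a
#'   seeded-random protein with positive degree. A hub root in a dense
#'   graph can pull every pair into the test set (the training set is then
#'   empty, which [finetune()] refuses).
#' @return A `SplitResult`: list with `scheme`, `train`, `test` (pair data
#'   frames), `test_nodes`, `seed`.
#' @export
split_network <- function(network, scheme = c("random", "BFS", "DFS"),
                          test_fraction = 0.2, seed = 1L, root = NULL) {
  scheme <- match.arg(scheme)
  pairs <- network$pairs
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n_pairs <- nrow(pairs)
  if (n_pairs < 2L)
    stop(sprintf(paste0("network too small to split: %d labelled pair(s); ",
                        "need at least 2"), n_pairs))
  if (round(test_fraction * n_pairs) == 0L) {
    # limit: a target below half a pair rounds to an empty test set
    test_idx <- integer(0)
    test_nodes <- character(0)
  } else if (scheme == "random") {
    k <- round(test_fraction * n_pairs)
    idx <- with_seed(substream_seed(seed, "split-random"),
                     sample.int(n_pairs, k))
    test_idx <- sort(idx)
    test_nodes <- character(0)
  } else {
    pos <- pairs[pairs$label == 1, , drop = FALSE]
    if (nrow(pos) == 0L) stop("no positive edges to traverse")
    g <- igraph::graph_from_data_frame(pos[, c("a", "b")], directed = FALSE,
                                       vertices = network$proteins)
    if (is.null(root))
      root <- with_seed(substream_seed(seed, "split-root"),
                        sample(unique(c(pos$a, pos$b)), 1L))
    ord <- if (scheme == "BFS")
      igraph::bfs(g, root = root, order = TRUE, unreachable = TRUE)$order
    else
      igraph::dfs(g, root = root, order = TRUE, unreachable = TRUE)$order
    ord <- igraph::V(g)$name[ord]
    test_nodes <- character(0)
    in_test <- logical(n_pairs)
    for (v in ord) {
      test_nodes <- c(test_nodes, v)
      in_test <- in_test | pairs$a == v | pairs$b == v
      if (sum(in_test) / n_pairs >= test_fraction) break
    }
    test_idx <- which(in_test)
  }
  train <- if (length(test_idx)) pairs[-test_idx, , drop = FALSE] else pairs
  structure(list(scheme = scheme,
                 train = train,
                 test = pairs[test_idx, , drop = FALSE],
                 test_nodes = test_nodes,
                 seed = as.integer(seed)),
            class = "SplitResult")
}

#' Precision, recall and F1 for binary interaction labels
#'
#' `F1 = 2PR / (P + R)`, defined as 0 when `P + R = 0` (binary,
#' positive-class F1).
#'
#' @param predicted Predicted 0/1 labels.
#' @param truth True 0/1 labels.
#' @return An `EvalResult`: list with `precision`, `recall`, `f1`, `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
evaluate_f1 <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("precision %.4f, recall %.4f, F1 %.4f (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Rank candidate interactors of a query protein
#'
#' Candidates carrying any excluded annotation tag are removed before
#' truncation; the remainder are sorted by predicted interaction
#' probability (descending, ties broken lexicographically by identifier)
#' and at most `cap` are returned. Exclusion mirrors the manual removal of
#' biologically implausible partners (e.g. tagged `"nuclear"`) ahead of
#' shortlisting the top candidates.
#'
#' @param predictor A fitted `ppi_predictor` (see [finetune()]) or a
#'   function `(query, candidate) -> probability`.
#' @param query Query protein id.
#' @param candidates Character vector of candidate ids.
#' @param exclusion_tags Tags whose carriers are removed.
#' @param annotations Data frame `protein, tag` (one row per tag).
#' @param cap Maximum number of candidates returned (default 100).
#' @return A `CandidateRanking`: list with `query`, `ranking` (data frame
#'   `rank, candidate, score`), `excluded`, `cap`.
#' @export
rank_candidates <- function(predictor, query, candidates,
                            exclusion_tags = character(0),
                            annotations = NULL, cap = 100L) {
  if (inherits(predictor, "ppi_predictor")) {
    if (!query %in% names(predictor$reps))
      stop("query protein '", query, "' is not in the model vocabulary")
    score_fun <- function(q, c) predict(predictor,
                                        data.frame(a = q, b = c))
  } else {
    score_fun <- function(q, c) vapply(c, function(ci) predictor(q, ci), 0)
  }
  excluded <- character(0)
  if (length(exclusion_tags) && !is.null(annotations)) {
    tagged <- unique(annotations$protein[annotations$tag %in% exclusion_tags])
    excluded <- intersect(candidates, tagged)
    candidates <- setdiff(candidates, tagged)
  }
  candidates <- setdiff(candidates, query)
  scores <- as.numeric(score_fun(query, candidates))
  ord <- order(-scores, candidates)
  keep <- head(ord, cap)
  structure(list(query = query,
                 ranking = data.frame(rank = seq_along(keep),
                                      candidate = candidates[keep],
                                      score = scores[keep]),
                 excluded = excluded, cap = cap),
            class = "CandidateRanking")
}

#' Consensus over per-isoform candidate rankings
#'
#' Retains candidates present in every input ranking; orders by best
#' worst-rank (minimax), breaking ties by mean rank and then identifier.
#' This selects partners predicted to interact with all isoforms of the
#' query.
#'
#' @param rankings List of `CandidateRanking`s (or data frames with
#'   `rank`, `candidate`).
#' @return Data frame `candidate, worst_rank, mean_rank` in consensus
#'   order.
#' @export
consensus_rank <- function(rankings) {
  tabs <- lapply(rankings, function(r)
    if (inherits(r, "CandidateRanking")) r$ranking else r)
  common <- Reduce(intersect, lapply(tabs, `[[`, "candidate"))
  if (length(common) == 0L)
    return(data.frame(candidate = character(0), worst_rank = integer(0),
                      mean_rank = numeric(0)))
  ranks <- sapply(tabs, function(t) t$rank[match(common, t$candidate)])
  ranks <- matrix(ranks, nrow = length(common))
  worst <- apply(ranks, 1L, max)
  meanr <- rowMeans(ranks)
  ord <- order(worst, meanr, common)
  data.frame(candidate = common[ord], worst_rank = worst[ord],
             mean_rank = meanr[ord], row.names = NULL)
}
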