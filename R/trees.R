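# The two shipped rule trees. Each is an explicit node table (metric, test,
# branch targets) so the structure can be inspected, counted, or replaced by
# a user transcribing a different arrangement; evaluation walks the nodes.

make_rule_tree <- function(nodes) {
  structure(list(nodes = nodes), class = "rule_tree")
}

#' Shipped junction-metric rule tree (tree 1)
#'
#' A five-node tree over max JAD, canonical motif and primary
#' donor/acceptor status. It keeps a junction iff its motif is canonical
#' and it either carries at least one read with JAD at or above the
#' threshold or is both a primary donor and a primary acceptor:
#' `is_canonical & (max_jad >= jad_threshold |
#' (is_primary_donor & is_primary_acceptor))`.
#'
#' @param config A [filter_config()].
#' @return A `rule_tree` object.
#' @export
shipped_tree1 <- function(config = filter_config()) {
  make_rule_tree(list(
    list(metric = "max_jad", op = ">=", value = config$jad_threshold, yes = 2L, no = 3L),
    list(metric = "is_canonical", op = "is", value = TRUE, yes = "keep", no = "discard"),
    list(metric = "is_primary_donor", op = "is", value = TRUE, yes = 4L, no = "discard"),
    list(metric = "is_primary_acceptor", op = "is", value = TRUE, yes = 5L, no = "discard"),
    list(metric = "is_canonical", op = "is", value = TRUE, yes = "keep", no = "discard")
  ))
}

#' Shipped combined rule tree (tree 2)
#'
#' Replaces the canonical-motif test of tree 1 with splice-site sequence
#' scores: junctions passing the JAD threshold are kept unless the smaller
#' of their donor/acceptor sequence scores falls below the low-confidence
#' threshold (false-positive removal); junctions failing the JAD threshold
#' are rescued when they are primary at both sites and the smaller score
#' reaches the high-confidence threshold.
#'
#' @param config A [filter_config()].
#' @return A `rule_tree` object.
#' @export
shipped_tree2 <- function(config = filter_config()) {
  make_rule_tree(list(
    list(metric = "max_jad", op = ">=", value = config$jad_threshold, yes = 2L, no = 3L),
    list(metric = "min_seq_score", op = ">=", value = config$lr_low, yes = "keep", no = "discard"),
    list(metric = "is_primary_donor", op = "is", value = TRUE, yes = 4L, no = "discard"),
    list(metric = "is_primary_acceptor", op = "is", value = TRUE, yes = 5L, no = "discard"),
    list(metric = "min_seq_score", op = ">=", value = config$lr_high, yes = "keep", no = "discard")
  ))
}

#' Number of decision nodes in a rule tree
#' @param tree A `rule_tree`.
#' @return Integer node count (leaves are not counted).
#' @export
tree_node_count <- function(tree) {
  stopifnot(inherits(tree, "rule_tree"))
  length(tree$nodes)
}

#' Boolean rule expression of a rule tree
#'
#' Flattens the node structure into the equivalent boolean expression
#' (disjunction over root-to-keep paths), mostly useful for inspection.
#'
#' @param tree A `rule_tree`.
#' @return A single character string.
#' @export
tree_rule_expression <- function(tree) {
  paths <- list()
  walk <- function(node_id, conds) {
    node <- tree$nodes[[node_id]]
    lit <- if (node$op == "is") node$metric else {
      sprintf("%s %s %s", node$metric, node$op, format(node$value))
    }
    for (branch in c("yes", "no")) {
      cond <- if (branch == "yes") lit else sprintf("!(%s)", lit)
      nxt <- node[[branch]]
      if (identical(nxt, "keep")) {
        paths[[length(paths) + 1L]] <<- c(conds, cond)
      } else if (!identical(nxt, "discard")) {
        walk(nxt, c(conds, cond))
      }
    }
  }
  walk(1L, character())
  paste(vapply(paths, function(p) paste0("(", paste(p, collapse = " & "), ")"), ""),
        collapse = " | ")
}

# Walk one record (a named list of metric values) through the tree.
walk_rule_tree <- function(tree, metrics) {
  node_id <- 1L
  repeat {
    node <- tree$nodes[[node_id]]
    val <- metrics[[node$metric]]
    if (is.null(val) || is.na(val)) {
      stop(sprintf("metric %s is unset; score records fully before applying rule trees",
                   node$metric))
    }
    res <- switch(node$op,
                  "is" = identical(as.logical(val), node$value),
                  ">=" = val >= node$value,
                  "<" = val < node$value,
                  stop("unknown op"))
    nxt <- if (res) node$yes else node$no
    if (identical(nxt, "keep")) return(TRUE)
    if (identical(nxt, "discard")) return(FALSE)
    node_id <- nxt
  }
}

#' Apply the junction-metric rule tree (tree 1)
#'
#' @param records Junction record table with `max_jad`, `is_canonical`,
#'   `is_primary_donor` and `is_primary_acceptor` set (see
#'   [assign_primary_status()]).
#' @param config A [filter_config()].
#' @param tree Rule tree to apply; defaults to [shipped_tree1()].
#' @return Logical vector of verdicts (`TRUE` = keep).
#' @export
decision_tree_1 <- function(records, config = filter_config(),
                            tree = shipped_tree1(config)) {
  needed <- c("max_jad", "is_canonical", "is_primary_donor", "is_primary_acceptor")
  for (m in needed) {
    if (any(is.na(records[[m]]))) {
      stop(sprintf("metric %s is unset for %d junctions; score records fully before applying rule trees",
                   m, sum(is.na(records[[m]]))))
    }
  }
  vapply(seq_len(nrow(records)), function(i) {
    walk_rule_tree(tree, list(
      max_jad = records$max_jad[i],
      is_canonical = records$is_canonical[i],
      is_primary_donor = records$is_primary_donor[i],
      is_primary_acceptor = records$is_primary_acceptor[i]
    ))
  }, logical(1))
}

#' Apply the combined rule tree (tree 2)
#'
#' The two sequence scores of a junction (donor site and acceptor site) are
#' combined by their minimum before thresholding.
#'
#' @param records Junction record table with tree-1 metrics set.
#' @param donor_score,acceptor_score Per-junction sequence-model
#'   probabilities; default to the `donor_score`/`acceptor_score` columns of
#'   `records`.
#' @param config A [filter_config()].
#' @param tree Rule tree to apply; defaults to [shipped_tree2()].
#' @return Logical vector of verdicts (`TRUE` = keep).
#' @export
decision_tree_2 <- function(records,
                            donor_score = records$donor_score,
                            acceptor_score = records$acceptor_score,
                            config = filter_config(),
                            tree = shipped_tree2(config)) {
  if (any(is.na(donor_score)) || any(is.na(acceptor_score))) {
    stop("sequence scores are unset; run train_sequence_models() first")
  }
  needed <- c("max_jad", "is_primary_donor", "is_primary_acceptor")
  for (m in needed) {
    if (any(is.na(records[[m]]))) {
      stop(sprintf("metric %s is unset; score records fully before applying rule trees", m))
    }
  }
  min_score <- pmin(donor_score, acceptor_score)
  vapply(seq_len(nrow(records)), function(i) {
    walk_rule_tree(tree, list(
      max_jad = records$max_jad[i],
      is_canonical = records$is_canonical[i],
      is_primary_donor = records$is_primary_donor[i],
      is_primary_acceptor = records$is_primary_acceptor[i],
      min_seq_score = min_score[i]
    ))
  }, logical(1))
}
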