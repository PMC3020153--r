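#' Decision-tree nodes
#'
#' Constructors for the three node kinds of a decision tree: `decision_node()`
#' (a choice among alternatives, no edge probabilities), `chance_node()`
#' (probabilistic branching; edge probabilities must sum to 1) and
#' `terminal_node()` (a leaf carrying a payoff in QALYs).  Edges are built
#' with [edge()].  At most one edge of a chance node may carry the string
#' `"complement"` instead of a number; it is resolved to one minus the sum of
#' its siblings when the tree is validated.
#'
#' @param label character label for the node.
#' @param ... for `decision_node()` and `chance_node()`, one or more [edge()]
#'   objects (or a single list of them).
#' @param payoff terminal payoff in QALYs.
#' @return An object of class `ad_node`.
#' @examples
#' t1 <- terminal_node("dies", 0)
#' t2 <- terminal_node("survives", 2)
#' cn <- chance_node("outcome", edge("dies", 0.3, t1), edge("survives", 0.7, t2))
#' rollback(cn)
#' @seealso [rollback()], [enumerate_paths()], [validate_tree()]
#' @export
chance_node <- function(label, ...) {
  new_node("chance", label, gather_edges(...))
}

#' @rdname chance_node
#' @export
decision_node <- function(label, ...) {
  new_node("decision", label, gather_edges(...))
}

#' @rdname chance_node
#' @export
terminal_node <- function(label, payoff) {
  stopifnot(is.numeric(payoff), length(payoff) == 1L, is.finite(payoff))
  structure(list(kind = "terminal", label = as.character(label),
                 payoff = as.numeric(payoff), children = list()),
            class = "ad_node")
}

#' @param prob edge probability in `[0, 1]` for chance-node edges, the string
#'   `"complement"` to have it resolved from the siblings at validation time,
#'   or `NULL` for decision-node edges.
#' @param node the child `ad_node`.
#' @rdname chance_node
#' @export
edge <- function(label, prob, node) {
  if (!inherits(node, "ad_node")) stop("edge child must be an ad_node")
  if (!is.null(prob) && !identical(prob, "complement")) {
    stopifnot(is.numeric(prob), length(prob) == 1L)
    prob <- as.numeric(prob)
  }
  list(label = as.character(label), prob = prob, node = node)
}

new_node <- function(kind, label, edges) {
  if (length(edges) == 0L) stop(kind, " node '", label, "' has no children")
  structure(list(kind = kind, label = as.character(label), payoff = NULL,
                 children = edges),
            class = "ad_node")
}

gather_edges <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !is_edge(args[[1L]])) args <- args[[1L]]
  if (!all(vapply(args, is_edge, logical(1L))))
    stop("children must be edge() objects")
  args
}

is_edge <- function(x) {
  is.list(x) && all(c("label", "prob", "node") %in% names(x)) &&
    inherits(x$node, "ad_node")
}

#' Validate a decision tree
#'
#' Checks the structural invariants of a tree and resolves `"complement"`
#' edge probabilities: terminal nodes carry a payoff and no children; chance
#' node edge probabilities are each in `[0, 1]` and sum to 1 within `tol`
#' (at most one edge per chance node may be the string `"complement"`, which
#' is replaced by one minus the sum of its siblings); decision-node edges
#' carry no probabilities.
#'
#' @param node an `ad_node`.
#' @param tol tolerance for the probability-sum check (default `1e-9`).
#' @return The validated tree with all complements resolved to numbers.
#' @export
validate_tree <- function(node, tol = 1e-9) {
  if (!inherits(node, "ad_node")) stop("not an ad_node")
  switch(node$kind,
    terminal = {
      if (length(node$children)) stop("terminal node '", node$label, "' has children")
      if (is.null(node$payoff)) stop("terminal node '", node$label, "' has no payoff")
      node
    },
    chance = {
      probs <- lapply(node$children, `[[`, "prob")
      comp <- vapply(probs, function(p) identical(p, "complement"), logical(1L))
      if (sum(comp) > 1L)
        stop("chance node '", node$label, "' has more than one complement edge")
      known <- vapply(probs[!comp], function(p) {
        if (is.null(p)) stop("chance node '", node$label,
                             "' has an edge with no probability")
        p
      }, numeric(1L))
      if (any(known < 0))
        stop("negative probability at chance node '", node$label, "'")
      if (any(known > 1))
        stop("probability > 1 at chance node '", node$label, "'")
      if (any(comp)) {
        rest <- 1 - sum(known)
        if (rest < -tol)
          stop("complement edge of chance node '", node$label,
               "' would be negative")
        node$children[[which(comp)]]$prob <- max(rest, 0)
      } else if (abs(sum(known) - 1) > tol) {
        stop("probabilities at chance node '", node$label,
             "' sum to ", format(sum(known), digits = 12), ", not 1")
      }
      node$children <- lapply(node$children, function(e) {
        e$node <- validate_tree(e$node, tol); e
      })
      node
    },
    decision = {
      bad <- vapply(node$children,
                    function(e) !is.null(e$prob), logical(1L))
      if (any(bad))
        stop("decision node '", node$label, "' has edges carrying probabilities")
      node$children <- lapply(node$children, function(e) {
        e$node <- validate_tree(e$node, tol); e
      })
      node
    },
    stop("unknown node kind '", node$kind, "'"))
}

#' Expected-value rollback
#'
#' Folds a decision tree to its expected QALY value: a terminal node
#' contributes its payoff, a chance node the probability-weighted mean of its
#' children, and a decision node the maximum over its children (ties resolve
#' to the first-listed child, with a notice).  The tree is validated (and any
#' complement probabilities resolved) first.
#'
#' @inheritParams validate_tree
#' @param discount optional hook applied to every terminal payoff before
#'   aggregation; the default is the identity (no discounting).
#' @return Expected value in QALYs (a single number).
#' @export
rollback <- function(node, tol = 1e-9, discount = identity) {
  node <- validate_tree(node, tol)
  rollback_(node, discount)
}

rollback_ <- function(node, discount) {
  switch(node$kind,
    terminal = discount(node$payoff),
    chance = sum(vapply(node$children,
                        function(e) e$prob * rollback_(e$node, discount),
                        numeric(1L))),
    decision = {
      vals <- vapply(node$children,
                     function(e) rollback_(e$node, discount), numeric(1L))
      best <- which(vals == max(vals))
      if (length(best) > 1L)
        message("tie at decision node '", node$label,
                "': resolved to first-listed child '",
                node$children[[best[1L]]]$label, "'")
      vals[best[1L]]
    })
}

#' Enumerate root-to-leaf paths
#'
#' Expands a tree (with no decision nodes) into its full set of
#' root-to-leaf paths.  Used as the exhaustive counterpart of [rollback()]:
#' the probability-weighted sum of payoffs over the returned paths equals the
#' rolled-back value, and the path probabilities sum to 1.
#'
#' @inheritParams validate_tree
#' @return A data frame with columns `probability`, `payoff` and `path`
#'   (edge labels joined by `" > "`).
#' @export
enumerate_paths <- function(node, tol = 1e-9) {
  node <- validate_tree(node, tol)
  walk <- function(n, p, labels) {
    if (n$kind == "terminal")
      return(list(list(probability = p, payoff = n$payoff, labels = labels)))
    if (n$kind == "decision")
      stop("enumerate_paths requires a strategy (no decision nodes)")
    unlist(lapply(n$children, function(e)
      walk(e$node, p * e$prob, c(labels, e$label))), recursive = FALSE)
  }
  paths <- walk(node, 1, character())
  data.frame(
    probability = vapply(paths, `[[`, numeric(1L), "probability"),
    payoff = vapply(paths, `[[`, numeric(1L), "payoff"),
    path = vapply(paths, function(x) paste(x$labels, collapse = " > "),
                  character(1L)),
    stringsAsFactors = FALSE)
}

#' Strategies and recommendations
#'
#' A strategy is a fully resolved choice: a named tree containing no further
#' decision nodes.  `recommend()` rolls back each strategy and returns the
#' one maximizing expected QALYs, reporting the QALY difference
#' (first strategy minus second, conventionally Full Code minus DNI) and
#' `"indifferent"` when the absolute difference is within `tolerance`.
#'
#' @param name strategy name, e.g. `"Full Code"` or `"DNI"`.
#' @param root an `ad_node` with no decision nodes.
#' @return `strategy()` returns an `ad_strategy`; `recommend()` an
#'   `ad_recommendation` with fields `ev_by_strategy`, `delta_qaly` and
#'   `recommended`.
#' @export
strategy <- function(name, root) {
  root <- validate_tree(root)
  if (has_decision(root))
    stop("strategy '", name, "' contains a decision node; strategies must be",
         " fully resolved")
  structure(list(name = as.character(name), root = root),
            class = "ad_strategy")
}

has_decision <- function(node) {
  if (node$kind == "decision") return(TRUE)
  any(vapply(node$children, function(e) has_decision(e$node), logical(1L)))
}

#' @param strategies a list of two (or more) `ad_strategy` objects; the COPD
#'   surface expects exactly `"Full Code"` and `"DNI"`.
#' @param tolerance indifference tolerance in QALYs (default `1e-9`).
#' @rdname strategy
#' @export
recommend <- function(strategies, tolerance = 1e-9) {
  if (!length(strategies) || !all(vapply(strategies, inherits, logical(1L),
                                         "ad_strategy")))
    stop("recommend() needs a list of ad_strategy objects")
  nms <- vapply(strategies, `[[`, character(1L), "name")
  ev <- vapply(strategies, function(s) rollback(s$root), numeric(1L))
  names(ev) <- nms
  if (length(strategies) == 2L) {
    ref <- if (all(c("Full Code", "DNI") %in% nms))
      c("Full Code", "DNI") else nms
    delta <- ev[[ref[1L]]] - ev[[ref[2L]]]
  } else {
    delta <- NA_real_
  }
  recommended <- if (!is.na(delta) && abs(delta) <= tolerance) "indifferent"
                 else nms[which.max(ev)]
  structure(list(ev_by_strategy = ev, delta_qaly = unname(delta),
                 recommended = recommended, tolerance = tolerance),
            class = "ad_recommendation")
}

#' @export
print.ad_recommendation <- function(x, ...) {
  cat("Advance-directive recommendation\n")
  for (nm in names(x$ev_by_strategy))
    cat(sprintf("  EV(%s): %.4f QALYs\n", nm, x$ev_by_strategy[[nm]]))
  if (!is.na(x$delta_qaly))
    cat(sprintf("  delta QALY (Full Code - DNI): %.4f\n", x$delta_qaly))
  cat("  Recommended:", x$recommended, "\n")
  invisible(x)
}

# --- serialization ---------------------------------------------------------

node_to_list <- function(node) {
  out <- list(kind = node$kind, label = node$label)
  if (node$kind == "terminal") {
    out$payoff <- node$payoff
  } else {
    out$children <- lapply(node$children, function(e) {
      ch <- list(label = e$label)
      if (!is.null(e$prob)) ch$prob <- e$prob
      ch$node <- node_to_list(e$node)
      ch
    })
  }
  out
}

node_from_list <- function(x) {
  if (x$kind == "terminal") return(terminal_node(x$label, x$payoff))
  edges <- lapply(x$children, function(ch)
    edge(ch$label, ch$prob, node_from_list(ch$node)))
  new_node(x$kind, x$label, edges)
}

#' Read and write trees as YAML
#'
#' Trees serialize to a nested YAML document, the same dialect as the
#' parameter file; the round trip is lossless for labels, probabilities and
#' payoffs (complement markers are preserved verbatim).
#'
#' @param node an `ad_node`.
#' @param path file path.
#' @export
write_tree <- function(node, path) {
  yaml::write_yaml(node_to_list(node), path, precision = 15L)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  node_from_list(yaml::read_yaml(path))
}
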