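# Independent oracles and generators used across the suite.

# Expected value by explicit path enumeration, written independently of
# rollback(): walk every root-to-leaf path multiplying edge probabilities,
# then sum probability * payoff (decision nodes: maximum over children).
oracle_ev <- function(node) {
  if (node$kind == "terminal") return(node$payoff)
  if (node$kind == "decision")
    return(max(vapply(node$children, function(e) oracle_ev(e$node),
                      numeric(1))))
  acc <- 0
  stack <- list(list(node = node, p = 1))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- top$node
    if (n$kind == "terminal") {
      acc <- acc + top$p * n$payoff
    } else {
      for (e in n$children)
        stack[[length(stack) + 1L]] <- list(node = e$node, p = top$p * e$prob)
    }
  }
  acc
}

# random valid chance/terminal tree of at most `depth` levels
random_tree <- function(depth = 5, branch_max = 3) {
  if (depth == 0 || stats::runif(1) < 0.3)
    return(terminal_node("leaf", stats::runif(1, -5, 20)))
  k <- sample(2:branch_max, 1)
  probs <- stats::rgamma(k, 1) + 1e-3
  probs <- probs / sum(probs)
  edges <- lapply(seq_len(k), function(i)
    edge(paste0("e", i), probs[i], random_tree(depth - 1, branch_max)))
  chance_node("c", edges)
}

# jitter-free fixture and scenarios shared by the model tests
base_params <- function() generate_fixture(1, jitter = 0)
sev_scenario <- function(severity = "severe") copd_scenario(severity, 0.5)

quiet <- function(expr) suppressMessages(expr)
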