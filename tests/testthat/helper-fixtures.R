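# Shared fixtures and independent oracles for the test suite.

# the worked 2-node chain: A -(+)-> B, one gene under each node
toy_network <- function() {
  causal_network(
    "toy", "test family", c("A", "B"),
    data.frame(src = "A", tgt = "B", sign = 1),
    data.frame(node = c("A", "B"), gene = c("g1", "g2"), sign = c(1, 1)))
}

null_contrast <- function(network, sd = 0.1, seed = 1L) {
  genes <- unique(network$downstream_edges$gene)
  set.seed(seed)
  gene_contrast(genes, stats::rnorm(length(genes), 0, sd),
                rep(sd, length(genes)))
}

# independent oracle: minimize the NPA objective numerically
brute_fit <- function(network, contrast) {
  nodes <- network$backbone_nodes
  be <- network$backbone_edges
  de <- network$downstream_edges
  de <- de[de$gene %in% contrast$gene, , drop = FALSE]
  beta <- contrast$log2fc[match(de$gene, contrast$gene)]
  obj <- function(f) {
    names(f) <- nodes
    e1 <- if (nrow(be)) sum((f[be$src] - be$sign * f[be$tgt])^2) else 0
    e2 <- sum((f[de$node] - de$sign * beta)^2)
    e1 + e2
  }
  fit <- stats::optim(rep(0, length(nodes)), obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  stats::setNames(fit$par, nodes)
}

# independent oracle: BH step-up by its textbook definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  run_min <- Inf
  for (j in rev(seq_len(m))) {
    run_min <- min(run_min, p[ord[j]] * m / j)
    adj[ord[j]] <- min(run_min, 1)
  }
  adj
}

# independent oracle: exhaustive max-score connected subgraph via igraph
brute_module <- function(network, scores) {
  nodes <- network$backbone_nodes
  g <- igraph::graph_from_data_frame(
    network$backbone_edges[, c("src", "tgt")], directed = FALSE,
    vertices = data.frame(name = nodes))
  best <- NULL; best_score <- -Inf
  for (k in seq_along(nodes)) {
    for (sub in utils::combn(nodes, k, simplify = FALSE)) {
      if (!igraph::is_connected(igraph::induced_subgraph(g, sub))) next
      sc <- sum(scores[sub])
      if (sc > best_score + 1e-15 ||
          (abs(sc - best_score) <= 1e-15 && !is.null(best) &&
           paste(sort(sub), collapse = "\r") <
           paste(sort(best), collapse = "\r"))) {
        best <- sub; best_score <- sc
      }
    }
  }
  list(nodes = sort(best), score = best_score)
}

# direct DFT-definition periodogram (independent of the FFT route)
brute_periodogram <- function(y) {
  n <- length(y)
  yc <- y - mean(y)
  nk <- floor(n / 2) + 1L
  pw <- numeric(nk)
  for (k in seq_len(nk) - 1L) {
    X <- sum(yc * exp(-2i * pi * k * (seq_len(n) - 1L) / n))
    pw[k + 1L] <- Mod(X)^2 / n^2
  }
  dbl <- rep(2, nk); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nk] <- 1
  pw * dbl
}
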