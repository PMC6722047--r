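# Internal: align a contrast to a network's downstream layer and build the
# linear system of the backbone fit.
#
# The fit minimizes
#   E(f) = sum over backbone edges (x,y,s) of (f_x - s f_y)^2
#        + sum over downstream edges (x,g,s) of (f_x - s beta_g)^2
# whose normal equations are (L + W) f = S beta, with L the signed graph
# Laplacian of the backbone, W = diag(number of downstream genes per node)
# and S the signed node x gene-slot incidence of the downstream layer.
npa_prep <- function(network, contrast, quiet = FALSE) {
  stopifnot(inherits(network, "causal_network"))
  nodes <- network$backbone_nodes
  n <- length(nodes)
  de <- network$downstream_edges
  have <- de$gene %in% contrast$gene
  n_missing <- sum(!have)
  if (n_missing > 0 && !quiet)
    message(sprintf("dropping %d downstream edge(s) with genes absent from the contrast",
                    n_missing))
  support_frac <- vapply(nodes, function(x) {
    tot <- sum(de$node == x)
    if (tot == 0) 1 else sum(have[de$node == x]) / tot
  }, numeric(1))
  flagged <- nodes[support_frac < 0.5]
  de <- de[have, , drop = FALSE]
  if (nrow(de) == 0L) stop("no usable downstream edge after gene matching")
  ni <- match(de$node, nodes)
  beta <- contrast$log2fc[match(de$gene, contrast$gene)]
  se <- contrast$se[match(de$gene, contrast$gene)]
  w <- tabulate(ni, nbins = n)
  L <- matrix(0, n, n, dimnames = list(nodes, nodes))
  be <- network$backbone_edges
  if (nrow(be) > 0) {
    si <- match(be$src, nodes); ti <- match(be$tgt, nodes)
    for (k in seq_len(nrow(be))) {
      s <- be$sign[k]
      L[si[k], si[k]] <- L[si[k], si[k]] + 1
      L[ti[k], ti[k]] <- L[ti[k], ti[k]] + 1
      L[si[k], ti[k]] <- L[si[k], ti[k]] - s
      L[ti[k], si[k]] <- L[ti[k], si[k]] - s
    }
  }
  # every backbone connected component must carry downstream support,
  # otherwise the quadratic is flat along that component
  g <- igraph::graph_from_data_frame(
    be[, c("src", "tgt"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)$membership
  for (cid in unique(comp)) {
    if (sum(w[comp == cid]) == 0)
      stop("backbone component with no downstream genes (singular fit): ",
           paste(nodes[comp == cid], collapse = ", "))
  }
  # signed node x edge-slot incidence: column j maps beta of slot j onto its node
  S <- matrix(0, n, nrow(de))
  S[cbind(ni, seq_len(nrow(de)))] <- de$sign
  A <- L + diag(w, n)
  list(nodes = nodes, A = A, Ainv = solve(A), L = L, S = S, w = w,
       beta = beta, se = se, genes = de$gene, node_index = ni,
       flagged_nodes = flagged, n_missing = n_missing)
}

npa_score_from_f <- function(f, w) {
  if (sum(w) == 0) stop("no measurable downstream support (all weights zero)")
  contrib <- w * f^2 / sum(w)
  list(score = sum(contrib), contributions = contrib)
}

#' Fit differential backbone-node values from a gene contrast
#'
#' Infers one differential value per backbone node by least squares: node
#' values should follow the signed causal relations along the backbone while
#' matching the signed gene-level log2 fold-changes attached below each
#' node. The objective is
#' `sum_edges (f_x - s * f_y)^2 + sum_downstream (f_x - s * beta_g)^2`,
#' which is strictly convex whenever every backbone connected component has
#' at least one measured downstream gene; the minimizer solves a signed
#' graph-Laplacian linear system and is linear in the fold-changes.
#'
#' Downstream genes absent from the contrast are dropped with a message;
#' nodes losing more than half their gene support are flagged.
#'
#' @param network a [causal_network()].
#' @param contrast a [gene_contrast()].
#' @return a `node_values` object: list with `f` (named fitted values),
#'   `w` (genes per node), `contributions` (named, summing to the NPA
#'   score), `score`, `flagged_nodes`.
#' @export
fit_backbone <- function(network, contrast) {
  prep <- npa_prep(network, contrast)
  f <- drop(prep$Ainv %*% (prep$S %*% prep$beta))
  names(f) <- prep$nodes
  sc <- npa_score_from_f(f, prep$w)
  names(sc$contributions) <- prep$nodes
  structure(list(f = f, w = stats::setNames(prep$w, prep$nodes),
                 contributions = sc$contributions, score = sc$score,
                 flagged_nodes = prep$flagged_nodes),
            class = "node_values")
}

#' Network perturbation amplitude of fitted node values
#'
#' The NPA score is the gene-support-weighted mean square of the fitted
#' differential node values: `score = sum_x w_x f_x^2 / sum_x w_x` with
#' `w_x` the number of downstream genes of node `x`. Each node's
#' contribution `c_x = w_x f_x^2 / sum_x w_x` gives an exact additive
#' decomposition `sum_x c_x = score`.
#'
#' @param network a [causal_network()].
#' @param node_values a `node_values` object from [fit_backbone()] (or a
#'   named numeric vector of node values on the network's backbone).
#' @return list with `score` (>= 0) and named `contributions`.
#' @export
npa_score <- function(network, node_values) {
  if (inherits(node_values, "node_values")) {
    f <- node_values$f
    w <- node_values$w
  } else {
    f <- node_values[network$backbone_nodes]
    w <- stats::setNames(
      tabulate(match(network$downstream_edges$node, network$backbone_nodes),
               nbins = length(network$backbone_nodes)),
      network$backbone_nodes)
  }
  sc <- npa_score_from_f(f, w)
  names(sc$contributions) <- names(f)
  sc
}

# vectorized scoring of many beta columns through a cached prep
score_beta_matrix <- function(prep, Bmat) {
  Fmat <- prep$Ainv %*% (prep$S %*% Bmat)
  colSums(prep$w * Fmat^2) / sum(prep$w)
}

#' Confidence interval and experimental-variation p value of an NPA score
#'
#' Parametric Monte Carlo over the gene-level uncertainty: fold-changes are
#' redrawn as `Normal(beta_g, se_g^2)`, the backbone is refitted and
#' rescored, and the 2.5/97.5 percentiles of the redrawn scores form the
#' confidence interval. The experimental-variation p value compares the
#' observed score with scores of null draws `Normal(0, se_g^2)` using the
#' add-one estimator `(1 + #{null >= observed}) / (1 + n_draws)`.
#'
#' @param network a [causal_network()].
#' @param contrast a [gene_contrast()] with finite `se`.
#' @param n_draws number of Monte Carlo draws (>= 100).
#' @param seed integer seed.
#' @return list with `ci_low`, `ci_high`, `p_exp`, `score`.
#' @export
npa_uncertainty <- function(network, contrast, n_draws = 500, seed = 1L) {
  if (n_draws < 100) stop("n_draws must be at least 100")
  prep <- npa_prep(network, contrast, quiet = TRUE)
  if (!all(is.finite(prep$se))) stop("non-finite se in contrast")
  m <- length(prep$beta)
  obs <- score_beta_matrix(prep, cbind(prep$beta))
  set.seed(seed)
  Bci <- prep$beta + prep$se * matrix(stats::rnorm(m * n_draws), m, n_draws)
  ci_scores <- score_beta_matrix(prep, Bci)
  Bnull <- prep$se * matrix(stats::rnorm(m * n_draws), m, n_draws)
  null_scores <- score_beta_matrix(prep, Bnull)
  qs <- stats::quantile(ci_scores, c(0.025, 0.975), names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2],
       p_exp = (1 + sum(null_scores >= obs)) / (1 + n_draws),
       score = obs)
}

# rewire a backbone edge table: shuffle the endpoint multiset and re-pair,
# preserving the edge count and degree sequence; signs reshuffled with them.
# The rewired graph must stay a valid backbone (simple: no self-loops, no
# parallel edges), so the permutation null lives in the same model class as
# the observed network; after max_tries the parallel-edge requirement is
# relaxed (rare degree sequences admit few simple pairings).
rewire_backbone <- function(be, max_tries = 200L) {
  m <- nrow(be)
  ends <- c(be$src, be$tgt)
  for (i in seq_len(2L * max_tries)) {
    perm <- sample(ends)
    src <- perm[seq_len(m)]; tgt <- perm[m + seq_len(m)]
    if (any(src == tgt)) next
    if (i <= max_tries &&
        anyDuplicated(paste(pmin(src, tgt), pmax(src, tgt)))) next
    return(data.frame(src = src, tgt = tgt, sign = sample(be$sign)))
  }
  stop("could not rewire backbone without self-loops")
}

#' Permutation companion statistics O and K
#'
#' Two specificity checks of an NPA score. The O statistic permutes the
#' assignment of gene fold-changes to downstream gene slots (network fixed),
#' asking whether the score depends on which genes sit where. The K
#' statistic rewires the backbone (endpoint multiset shuffled and re-paired,
#' signs reshuffled; downstream layer fixed), asking whether the score
#' depends on the causal structure. Both report add-one permutation p
#' values `(1 + #{permuted >= observed}) / (1 + n_perm)`.
#'
#' @param network a [causal_network()].
#' @param contrast a [gene_contrast()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `p_O`, `p_K` (`NA` when the backbone has fewer than 2
#'   edges and cannot be rewired), `score`.
#' @export
permutation_tests <- function(network, contrast, n_perm = 500, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  prep <- npa_prep(network, contrast, quiet = TRUE)
  m <- length(prep$beta)
  obs <- score_beta_matrix(prep, cbind(prep$beta))
  set.seed(seed)
  Bperm <- vapply(seq_len(n_perm), function(i) prep$beta[sample.int(m)],
                  numeric(m))
  o_scores <- score_beta_matrix(prep, Bperm)
  p_O <- (1 + sum(o_scores >= obs)) / (1 + n_perm)
  be <- network$backbone_edges
  if (nrow(be) < 2L) {
    p_K <- NA_real_
  } else {
    b <- drop(prep$S %*% prep$beta)
    Wd <- diag(prep$w, length(prep$nodes))
    k_scores <- vapply(seq_len(n_perm), function(i) {
      ber <- rewire_backbone(be)
      # rebuild only the Laplacian; downstream layer (S, w, b) is unchanged
      Lr <- matrix(0, length(prep$nodes), length(prep$nodes))
      si <- match(ber$src, prep$nodes); ti <- match(ber$tgt, prep$nodes)
      for (k in seq_len(nrow(ber))) {
        s <- ber$sign[k]
        Lr[si[k], si[k]] <- Lr[si[k], si[k]] + 1
        Lr[ti[k], ti[k]] <- Lr[ti[k], ti[k]] + 1
        Lr[si[k], ti[k]] <- Lr[si[k], ti[k]] - s
        Lr[ti[k], si[k]] <- Lr[ti[k], si[k]] - s
      }
      f <- solve(Lr + Wd, b)
      sum(prep$w * f^2) / sum(prep$w)
    }, numeric(1))
    p_K <- (1 + sum(k_scores >= obs)) / (1 + n_perm)
  }
  list(p_O = p_O, p_K = p_K, score = obs)
}

#' Leading nodes of an NPA score
#'
#' Nodes sorted by decreasing contribution (ties broken lexicographically by
#' label); the leading nodes are the minimal prefix whose cumulative
#' contribution reaches `cum_threshold` of the score.
#'
#' @param contributions named nonnegative contributions summing to the score
#'   (from [fit_backbone()] or [npa_score()]).
#' @param cum_threshold cumulative fraction of the score to cover (default
#'   0.8).
#' @return character vector of leading node labels, ordered by contribution;
#'   empty when the score is 0.
#' @export
leading_nodes <- function(contributions, cum_threshold = 0.8) {
  score <- sum(contributions)
  if (score <= 0) return(character(0))
  ord <- order(-contributions, names(contributions))
  cum <- cumsum(contributions[ord])
  k <- which(cum >= cum_threshold * score - 1e-12)[1]
  names(contributions)[ord][seq_len(k)]
}

# exhaustive maximum-score connected-subgraph search (n <= 15)
max_connected_subgraph_exact <- function(adj, scores) {
  n <- length(scores)
  labels <- names(scores)
  best <- NULL; best_score <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    # BFS connectivity within the subset
    seen <- members[1]; frontier <- members[1]
    while (length(frontier)) {
      nb <- unique(unlist(adj[frontier]))
      nb <- setdiff(intersect(nb, members), seen)
      seen <- c(seen, nb); frontier <- nb
    }
    if (length(seen) != length(members)) next
    sc <- sum(scores[members])
    if (sc > best_score + 1e-15 ||
        (abs(sc - best_score) <= 1e-15 && !is.null(best) &&
         paste(sort(labels[members]), collapse = "\r") <
         paste(sort(labels[best]), collapse = "\r"))) {
      best <- members; best_score <- sc
    }
  }
  labels[sort(best)]
}

# greedy Prim-like growth for larger backbones: repeatedly add the
# best-scoring frontier node and keep the best cumulative prefix
max_connected_subgraph_greedy <- function(adj, scores) {
  labels <- names(scores)
  start <- order(-scores, labels)[1]
  members <- start
  cum <- scores[start]
  best_k <- 1L; best_cum <- cum
  while (length(members) < length(scores)) {
    frontier <- setdiff(unique(unlist(adj[members])), members)
    if (!length(frontier)) break
    nxt <- frontier[order(-scores[frontier], labels[frontier])][1]
    members <- c(members, nxt)
    cum <- cum + scores[nxt]
    if (cum > best_cum + 1e-15) { best_cum <- cum; best_k <- length(members) }
  }
  labels[sort(members[seq_len(best_k)])]
}

#' Extract the NPA module subgraph
#'
#' Finds the connected backbone subgraph of maximum total node score, where
#' a leading node scores its NPA contribution and every other node pays a
#' small penalty (default: the median contribution of the non-leading
#' nodes). A low-scoring node is therefore included only as a bridge whose
#' cost is outweighed by the leading nodes it connects. Exact enumeration of
#' connected subsets is used for backbones up to `exact_limit` nodes, a
#' greedy expansion above.
#'
#' @param network a [causal_network()].
#' @param contributions named contributions from [fit_backbone()].
#' @param cum_threshold leading-node threshold passed to [leading_nodes()].
#' @param penalty nonnegative penalty charged per non-leading node; default
#'   the median non-leading contribution.
#' @param exact_limit maximum backbone size for exhaustive search (default
#'   15).
#' @return list with `nodes` (module members, sorted), `edges` (induced
#'   backbone edge data frame), `score` (total module node score).
#' @export
extract_npa_module <- function(network, contributions, cum_threshold = 0.8,
                               penalty = NULL, exact_limit = 15L) {
  lead <- leading_nodes(contributions, cum_threshold)
  if (length(lead) == 0L) stop("empty leading-node set (score is 0)")
  nodes <- network$backbone_nodes
  nonlead <- setdiff(nodes, lead)
  if (is.null(penalty))
    penalty <- if (length(nonlead)) stats::median(contributions[nonlead]) else 0
  scores <- ifelse(nodes %in% lead, contributions[nodes], -penalty)
  names(scores) <- nodes
  be <- network$backbone_edges
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(be))) {
    adj[[be$src[k]]] <- c(adj[[be$src[k]]], match(be$tgt[k], nodes))
    adj[[be$tgt[k]]] <- c(adj[[be$tgt[k]]], match(be$src[k], nodes))
  }
  adj <- lapply(seq_along(nodes), function(i) unique(adj[[i]]))
  members <- if (length(nodes) <= exact_limit)
    max_connected_subgraph_exact(adj, scores)
  else
    max_connected_subgraph_greedy(adj, scores)
  keep <- be$src %in% members & be$tgt %in% members
  list(nodes = members,
       edges = be[keep, , drop = FALSE],
       score = sum(scores[members]))
}

#' Score one contrast against one causal network model
#'
#' Runs the full network-perturbation-amplitude analysis: backbone fit, NPA
#' score with additive node contributions, Monte Carlo confidence interval
#' and experimental-variation p value, O/K permutation companion statistics,
#' leading nodes and the NPA-module subgraph. A network is called
#' significantly perturbed when all three p values (experimental, O, K) are
#' below `alpha`.
#'
#' @inheritParams npa_uncertainty
#' @param n_perm permutations for the O/K statistics.
#' @param cum_threshold leading-node cumulative threshold.
#' @param alpha significance level for the three-way call (default 0.05).
#' @return an object of class `npa`: score, node values and contributions,
#'   `ci_low`/`ci_high`, `p_exp`, `p_O`, `p_K`, `leading_nodes`, `module`,
#'   `significant`, `flagged_nodes`, plus network/contrast labels.
#' @export
npa <- function(network, contrast, n_draws = 500, n_perm = 500, seed = 1L,
                cum_threshold = 0.8, alpha = 0.05) {
  nv <- fit_backbone(network, contrast)
  unc <- npa_uncertainty(network, contrast, n_draws = n_draws, seed = seed)
  pt <- permutation_tests(network, contrast, n_perm = n_perm, seed = seed + 1L)
  lead <- leading_nodes(nv$contributions, cum_threshold)
  module <- if (nv$score > 0)
    extract_npa_module(network, nv$contributions, cum_threshold) else NULL
  structure(
    list(network = network$name, family = network$family,
         meta = attr(contrast, "meta"),
         score = nv$score, f = nv$f, contributions = nv$contributions,
         ci_low = unc$ci_low, ci_high = unc$ci_high, p_exp = unc$p_exp,
         p_O = pt$p_O, p_K = pt$p_K,
         leading_nodes = lead, module = module,
         significant = isTRUE(unc$p_exp < alpha && pt$p_O < alpha &&
                                !is.na(pt$p_K) && pt$p_K < alpha),
         flagged_nodes = nv$flagged_nodes),
    class = "npa")
}

#' @export
print.npa <- function(x, ...) {
  cat(sprintf("npa: network '%s' (%s)\n", x$network, x$family))
  cat(sprintf("  score %.4g  [%.4g, %.4g]\n", x$score, x$ci_low, x$ci_high))
  cat(sprintf("  p_exp %.4g  p_O %.4g  p_K %s  -> %s\n",
              x$p_exp, x$p_O,
              if (is.na(x$p_K)) "NA" else sprintf("%.4g", x$p_K),
              if (x$significant) "significant" else "not significant"))
  cat("  leading nodes:", paste(x$leading_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.npa <- function(object, ...) {
  print(object)
  cat("  node contributions:\n")
  ord <- order(-object$contributions)
  for (i in ord)
    cat(sprintf("    %-30s f = %8.4f  c = %8.5f\n",
                names(object$f)[i], object$f[i], object$contributions[i]))
  invisible(object)
}

#' Write an NPA result as JSON
#'
#' @param result an `npa` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_npa_result <- function(result, path) {
  stopifnot(inherits(result, "npa"))
  jsonlite::write_json(
    list(network = result$network, family = result$family,
         score = result$score, ci_low = result$ci_low,
         ci_high = result$ci_high, p_exp = result$p_exp,
         p_O = result$p_O, p_K = result$p_K,
         significant = result$significant,
         leading_nodes = result$leading_nodes,
         node_values = as.list(result$f),
         contributions = as.list(result$contributions),
         flagged_nodes = result$flagged_nodes),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Aggregate NPA scores into the biological impact factor (BIF)
#'
#' Summarizes per-network NPA scores across a set of contrasts into one
#' impact number per contrast. Each network's scores are first rescaled by
#' that network's maximum across the contrast set (networks scoring zero
#' everywhere drop out), so no single network dominates; the rescaled member
#' scores are averaged within each network family; the BIF of a contrast is
#' the mean of its family aggregates; and the relative BIF expresses each
#' contrast as a percentage of the maximum contrast, which is marked `REF`.
#' Family percentage shares give each family's relative contribution to the
#' contrast's impact.
#'
#' @param scores data frame with columns `contrast`, `network`, `family`,
#'   `score` (one row per network per contrast), e.g. built from [npa()]
#'   results.
#' @return a `bif_result`: list of data frames `networks` (adds `rescaled`),
#'   `families` (`contrast`, `family`, `aggregate`, `share_pct`),
#'   `contrasts` (`contrast`, `bif`, `relative_bif_pct`, `is_ref`).
#' @export
compute_bif <- function(scores) {
  scores <- as.data.frame(scores)
  need <- c("contrast", "network", "family", "score")
  if (!all(need %in% names(scores)))
    stop("scores needs columns ", paste(need, collapse = ", "))
  if (any(scores$score < 0)) stop("NPA scores must be nonnegative")
  netmax <- tapply(scores$score, scores$network, max)
  dropped <- names(netmax)[netmax == 0]
  if (length(dropped) == length(netmax))
    stop("all scores are zero for all contrasts; BIF undefined")
  sc <- scores[!(scores$network %in% dropped), , drop = FALSE]
  sc$rescaled <- sc$score / netmax[sc$network]
  fam <- stats::aggregate(rescaled ~ contrast + family, sc, mean)
  names(fam)[names(fam) == "rescaled"] <- "aggregate"
  famtot <- tapply(fam$aggregate, fam$contrast, sum)
  fam$share_pct <- ifelse(famtot[fam$contrast] > 0,
                          100 * fam$aggregate / famtot[fam$contrast],
                          NA_real_)
  bif <- stats::aggregate(aggregate ~ contrast, fam, mean)
  names(bif)[names(bif) == "aggregate"] <- "bif"
  mx <- max(bif$bif)
  bif$relative_bif_pct <- 100 * bif$bif / mx
  ref <- order(-bif$bif, bif$contrast)[1]
  bif$is_ref <- seq_len(nrow(bif)) == ref
  structure(list(networks = sc, families = fam, contrasts = bif),
            class = "bif_result")
}

#' @export
print.bif_result <- function(x, ...) {
  cat("bif_result:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Write a BIF result as a long-format TSV
#'
#' One row per contrast x network with the rescaled score, the family share
#' and the contrast-level relative BIF (REF contrast marked).
#'
#' @param bif a `bif_result` from [compute_bif()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bif <- function(bif, path) {
  stopifnot(inherits(bif, "bif_result"))
  tb <- merge(bif$networks,
              bif$families[, c("contrast", "family", "share_pct")],
              by = c("contrast", "family"))
  tb <- merge(tb, bif$contrasts, by = "contrast")
  tb <- tb[order(tb$contrast, tb$family, tb$network),
           c("contrast", "network", "family", "score", "rescaled",
             "share_pct", "relative_bif_pct", "is_ref")]
  names(tb)[names(tb) == "share_pct"] <- "family_share_pct"
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
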