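test_that("backbone fit reproduces the 2-node closed-form solution", {
  net <- toy_network()
  ct <- gene_contrast(c("g1", "g2"), c(2, 0), c(0, 0))
  nv <- fit_backbone(net, ct)
  # minimize (fA - fB)^2 + (fA - 2)^2 + (fB - 0)^2 -> normal equations
  expect_equal(unname(nv$f), c(4 / 3, 2 / 3), tolerance = 1e-12)
  sc <- npa_score(net, nv)
  expect_equal(sc$score, 10 / 9, tolerance = 1e-12)
  expect_equal(sum(sc$contributions), sc$score, tolerance = 1e-12)
})

test_that("fit matches brute-force minimization on small random networks", {
  for (seed in 1:6) {
    topo <- c("chain", "scale-free", "random")[(seed %% 3) + 1]
    net <- gen_network(2 + (seed %% 4) + 1, topo, genes_per_node = 2,
                       sign_prob = 0.4, seed = seed)
    ct <- null_contrast(net, sd = 0.5, seed = 100 + seed)
    nv <- fit_backbone(net, ct)
    oracle <- brute_fit(net, ct)
    expect_equal(unname(nv$f), unname(oracle), tolerance = 1e-6)
  }
})

test_that("zero input gives zero fit, zero score, no leading nodes", {
  net <- gen_network(5, "chain", genes_per_node = 2, seed = 3)
  genes <- net$downstream_edges$gene
  ct <- gene_contrast(genes, rep(0, length(genes)), rep(0.1, length(genes)))
  nv <- fit_backbone(net, ct)
  expect_true(all(nv$f == 0))
  expect_equal(nv$score, 0)
  expect_equal(leading_nodes(nv$contributions), character(0))
})

test_that("fit is linear and score quadratic in the fold-changes", {
  net <- gen_network(6, "random", genes_per_node = 3, seed = 9)
  ct <- null_contrast(net, sd = 1, seed = 9)
  nv <- fit_backbone(net, ct)
  for (c0 in c(-1, 0.5, 3)) {
    ct_c <- gene_contrast(ct$gene, c0 * ct$log2fc, ct$se)
    nv_c <- fit_backbone(net, ct_c)
    expect_equal(nv_c$f, c0 * nv$f, tolerance = 1e-12)
    expect_equal(nv_c$score, c0^2 * nv$score, tolerance = 1e-10)
  }
})

test_that("contributions decompose the score exactly", {
  for (seed in c(2, 12)) {
    net <- gen_network(8, "scale-free", genes_per_node = 4, seed = seed)
    nv <- fit_backbone(net, null_contrast(net, sd = 0.7, seed = seed))
    expect_equal(sum(nv$contributions), nv$score, tolerance = 1e-12)
    expect_true(all(nv$contributions >= 0))
  }
})

test_that("a backbone component without gene support is refused by name", {
  net <- causal_network(
    "gap", "f", c("A", "B", "C"),
    data.frame(src = "A", tgt = "B", sign = 1),
    data.frame(node = c("A", "B"), gene = c("g1", "g2"), sign = c(1, 1)))
  ct <- gene_contrast(c("g1", "g2"), c(1, 1), c(0.1, 0.1))
  expect_error(fit_backbone(net, ct), "C")
})

test_that("genes missing from the contrast are dropped and nodes flagged", {
  net <- causal_network(
    "m", "f", c("A", "B"),
    data.frame(src = "A", tgt = "B", sign = 1),
    data.frame(node = c("A", "A", "A", "B"),
               gene = c("g1", "g2", "g3", "g4"),
               sign = c(1, 1, 1, 1)))
  ct <- gene_contrast(c("g1", "g4"), c(1, 1), c(0.1, 0.1))
  expect_message(nv <- fit_backbone(net, ct), "2 downstream")
  expect_equal(nv$flagged_nodes, "A")  # lost 2 of 3 genes
  expect_error(
    suppressMessages(fit_backbone(net, gene_contrast("zz", 1, 0.1))),
    "no usable")
})

test_that("degenerate uncertainty: zero se collapses the CI", {
  net <- toy_network()
  ct <- gene_contrast(c("g1", "g2"), c(2, 0), c(0, 0))
  u <- npa_uncertainty(net, ct, n_draws = 200, seed = 4)
  expect_equal(u$ci_low, u$score)
  expect_equal(u$ci_high, u$score)
  expect_equal(u$p_exp, 1 / 201)  # score > 0, every null draw scores 0
  ct0 <- gene_contrast(c("g1", "g2"), c(0, 0), c(0, 0))
  expect_equal(npa_uncertainty(net, ct0, n_draws = 200, seed = 4)$p_exp, 1)
  expect_error(npa_uncertainty(net, ct, n_draws = 50), "at least 100")
})

test_that("a strong planted perturbation is detected with high confidence", {
  net <- gen_network(10, "random", genes_per_node = 5, seed = 21)
  pl <- planted_perturbation(net, noise_sd = 0.2, seed = 21)
  ct <- gen_contrast(net, pl, seed = 21)  # planted beta = 10x se
  u <- npa_uncertainty(net, ct, n_draws = 500, seed = 22)
  expect_lt(u$p_exp, 0.01)
  expect_gt(u$ci_low, 0)
  p <- permutation_tests(net, ct, n_perm = 500, seed = 23)
  expect_lt(p$p_O, 0.05)
})

test_that("a coherent signal on a 20-node scale-free backbone passes O and K", {
  # K is powered against perturbations the causal structure itself predicts,
  # so the planted node values are propagated coherently along edge signs
  net <- gen_network(20, "scale-free", genes_per_node = 10, seed = 7)
  pl <- planted_perturbation(net, coherent = TRUE, noise_sd = 0.2)
  ct <- gen_contrast(net, pl, seed = 7)
  p <- permutation_tests(net, ct, n_perm = 500, seed = 23)
  expect_lt(p$p_O, 0.05)
  expect_lt(p$p_K, 0.05)
})

test_that("permutation-invariant input gives p_O = 1", {
  net <- causal_network(
    "c", "f", c("A", "B"),
    data.frame(src = "A", tgt = "B", sign = 1),
    data.frame(node = c("A", "A", "B", "B"),
               gene = paste0("g", 1:4), sign = rep(1, 4)))
  ct <- gene_contrast(paste0("g", 1:4), rep(1.3, 4), rep(0.1, 4))
  p <- permutation_tests(net, ct, n_perm = 100, seed = 5)
  expect_equal(p$p_O, 1)
})

test_that("p_K is not applicable for backbones with fewer than 2 edges", {
  p <- permutation_tests(toy_network(),
                         gene_contrast(c("g1", "g2"), c(2, 0), c(0.1, 0.1)),
                         n_perm = 100, seed = 6)
  expect_true(is.na(p$p_K))
  expect_false(is.na(p$p_O))
})

test_that("leading nodes are the minimal prefix covering the threshold", {
  expect_equal(leading_nodes(c(A = 0.9, B = 0.05, C = 0.05), 0.8), "A")
  # five equal contributions: 4/5 exactly meets 0.8; ties lexicographic
  eq <- setNames(rep(0.2, 5), c("E", "C", "A", "D", "B"))
  expect_equal(leading_nodes(eq, 0.8), c("A", "B", "C", "D"))
  expect_equal(leading_nodes(c(A = 0, B = 0)), character(0))
})

test_that("module extraction pays for bridges exactly when worthwhile", {
  path3 <- causal_network(
    "p3", "f", c("A", "B", "C"),
    data.frame(src = c("A", "B"), tgt = c("B", "C"), sign = c(1, 1)),
    data.frame(node = c("A", "B", "C"), gene = paste0("g", 1:3),
               sign = rep(1, 3)))
  contrib <- c(A = 1, B = 0.05, C = 1)
  m1 <- extract_npa_module(path3, contrib, penalty = 0.1)
  expect_equal(m1$nodes, c("A", "B", "C"))  # bridge worth paying
  m2 <- extract_npa_module(path3, contrib, penalty = 5)
  expect_equal(m2$nodes, "A")               # tie with {C} -> lexicographic
  single <- causal_network(
    "s1", "f", "A",
    data.frame(src = character(), tgt = character(), sign = numeric()),
    data.frame(node = "A", gene = "g1", sign = 1))
  m3 <- extract_npa_module(single, c(A = 2))
  expect_equal(m3$nodes, "A")
  expect_error(extract_npa_module(path3, c(A = 0, B = 0, C = 0)), "empty")
})

test_that("module extraction matches exhaustive enumeration on fixtures", {
  for (seed in c(4, 14, 24)) {
    net <- gen_network(8, "random", genes_per_node = 3, seed = seed)
    nv <- fit_backbone(net, null_contrast(net, sd = 1, seed = seed))
    lead <- leading_nodes(nv$contributions)
    nonlead <- setdiff(net$backbone_nodes, lead)
    pen <- median(nv$contributions[nonlead])
    scores <- ifelse(net$backbone_nodes %in% lead,
                     nv$contributions[net$backbone_nodes], -pen)
    names(scores) <- net$backbone_nodes
    got <- extract_npa_module(net, nv$contributions)
    oracle <- brute_module(net, scores)
    expect_equal(got$nodes, oracle$nodes)
    expect_equal(got$score, oracle$score, tolerance = 1e-12)
    # returned module is connected
    g <- igraph::graph_from_data_frame(
      got$edges[, c("src", "tgt")], directed = FALSE,
      vertices = data.frame(name = got$nodes))
    expect_true(igraph::is_connected(g))
  }
})

test_that("BIF rescaling, family shares and REF marking", {
  sc <- data.frame(contrast = c("c1", "c2"), network = "n1", family = "f1",
                   score = c(4, 1))
  b <- compute_bif(sc)
  expect_equal(b$contrasts$relative_bif_pct[b$contrasts$contrast == "c1"], 100)
  expect_equal(b$contrasts$relative_bif_pct[b$contrasts$contrast == "c2"], 25)
  expect_equal(sum(b$contrasts$is_ref), 1)
  expect_true(b$contrasts$is_ref[b$contrasts$contrast == "c1"])

  # two families: shares proportional to family aggregates, summing to 100
  sc2 <- data.frame(contrast = "c1",
                    network = c("n1", "n2"), family = c("f1", "f2"),
                    score = c(0.75, 0.25))
  sc2 <- rbind(sc2, data.frame(contrast = "c2", network = c("n1", "n2"),
                               family = c("f1", "f2"), score = c(1, 1)))
  b2 <- compute_bif(sc2)
  sh <- b2$families[b2$families$contrast == "c1", ]
  expect_equal(sh$share_pct[sh$family == "f1"], 75)
  expect_equal(sh$share_pct[sh$family == "f2"], 25)
  expect_equal(sum(sh$share_pct), 100)

  # an all-zero contrast gets relative BIF 0 and undefined shares
  sc3 <- rbind(sc, data.frame(contrast = "c3", network = "n1",
                              family = "f1", score = 0))
  b3 <- compute_bif(sc3)
  expect_equal(b3$contrasts$relative_bif_pct[b3$contrasts$contrast == "c3"], 0)
  expect_true(is.na(b3$families$share_pct[b3$families$contrast == "c3"]))

  expect_error(compute_bif(data.frame(contrast = "c1", network = "n",
                                      family = "f", score = 0)),
               "undefined")
})

test_that("npa wrapper assembles a full significant-call result", {
  net <- gen_network(20, "scale-free", genes_per_node = 10, seed = 7)
  pl <- planted_perturbation(net, coherent = TRUE, noise_sd = 0.2)
  ct <- gen_contrast(net, pl, seed = 7)
  r <- npa(net, ct, n_draws = 200, n_perm = 200, seed = 32)
  expect_s3_class(r, "npa")
  expect_true(r$score > 0)
  expect_true(r$ci_low <= r$score && r$score <= r$ci_high)
  expect_true(all(c(r$p_exp, r$p_O, r$p_K) >= 0 &
                    c(r$p_exp, r$p_O, r$p_K) <= 1))
  expect_true(r$significant)
  expect_equal(sum(r$contributions), r$score, tolerance = 1e-12)
  expect_true(length(r$leading_nodes) >= 1)

  jf <- tempfile(fileext = ".json")
  write_npa_result(r, jf)
  out <- jsonlite::read_json(jf)
  expect_equal(out$score, r$score)
  expect_equal(unlist(out$leading_nodes), r$leading_nodes)
})
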