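#' Generate a synthetic cilia beat movie
#'
#' Emulates a high-speed recording of beating cilia: a fraction of pixels
#' oscillates at the beat frequency with independent uniform-random phases
#' (desynchronized pixels, the regime in which the median-over-pixels step
#' matters), every pixel carries a slow sub-2.5 Hz drift mimicking mucus
#' movement above the culture, plus Gaussian sensor noise; intensities are
#' rounded and clipped to the bit depth. Deterministic given the seed.
#'
#' @param f_beat beat frequency in Hz (must be < `fps/2`).
#' @param fps frame rate in Hz (default 100, the standard recording rate).
#' @param n_frames frames per movie (default 512).
#' @param height,width frame size in pixels (defaults 480 x 640, the
#'   standard recording resolution).
#' @param amplitude beat amplitude in intensity units (default 30).
#' @param offset baseline intensity (default 128).
#' @param drift_freq mucus-drift frequency in Hz, must be < 2.5 (default
#'   1.5).
#' @param drift_amplitude drift amplitude in intensity units (default 0).
#' @param noise_sd Gaussian noise sd in intensity units (default 0).
#' @param beating_fraction fraction of pixels carrying the beat (default 1).
#' @param bit_depth 8 or 16 (default 8).
#' @param seed integer seed.
#' @return a [movie_stack()] with attribute `truth` (the generating
#'   parameters).
#' @export
gen_beat_movie <- function(f_beat, fps = 100, n_frames = 512L, height = 480L,
                           width = 640L, amplitude = 30, offset = 128,
                           drift_freq = 1.5, drift_amplitude = 0,
                           noise_sd = 0, beating_fraction = 1,
                           bit_depth = 8L, seed = 1L) {
  if (f_beat >= fps / 2) stop("f_beat must be below the Nyquist frequency fps/2")
  if (f_beat <= 0) stop("f_beat must be positive")
  if (drift_freq >= 2.5) stop("drift_freq must be below 2.5 Hz")
  if (beating_fraction < 0 || beating_fraction > 1)
    stop("beating_fraction must be in [0, 1]")
  set.seed(seed)
  npix <- height * width
  t <- seq_len(n_frames) - 1L
  phases <- stats::runif(npix, 0, 2 * pi)
  beating <- stats::runif(npix) < beating_fraction
  # frames x pixels: beat term via cos(a+b) expansion to stay vectorized
  wbeat <- 2 * pi * f_beat / fps
  beat <- outer(cos(wbeat * t), cos(phases)) -
    outer(sin(wbeat * t), sin(phases))
  beat <- amplitude * sweep(beat, 2L, as.numeric(beating), `*`)
  drift <- drift_amplitude * cos(2 * pi * drift_freq * t / fps)
  x <- offset + beat + drift
  if (noise_sd > 0)
    x <- x + stats::rnorm(length(x), sd = noise_sd)
  x <- round(x)
  maxv <- 2^bit_depth - 1
  x[x < 0] <- 0; x[x > maxv] <- maxv
  frames <- array(x, dim = c(n_frames, height, width))
  out <- movie_stack(frames, fps = fps, bit_depth = bit_depth)
  attr(out, "truth") <- list(f_beat = f_beat, fps = fps, n_frames = n_frames,
                             amplitude = amplitude, offset = offset,
                             drift_freq = drift_freq,
                             drift_amplitude = drift_amplitude,
                             noise_sd = noise_sd,
                             beating_fraction = beating_fraction, seed = seed)
  out
}

#' Generate a synthetic causal network model
#'
#' Builds a connected signed backbone of the requested topology and hangs
#' `genes_per_node` signed downstream genes below every backbone node.
#' Topologies: `chain` (path graph), `scale-free` (preferential attachment),
#' `random` (uniform random edges over a random spanning tree, edge count
#' about 1.5 per node). Edge signs are -1 with probability `sign_prob`.
#' Deterministic given the seed.
#'
#' @param n_backbone number of backbone nodes (>= 2).
#' @param topology `"chain"`, `"scale-free"` or `"random"`.
#' @param genes_per_node downstream genes per backbone node (>= 1).
#' @param sign_prob probability of a negative sign per edge (default 0.3).
#' @param name,family labels for the model.
#' @param seed integer seed.
#' @return a [causal_network()].
#' @export
gen_network <- function(n_backbone, topology = c("chain", "scale-free",
                                                 "random"),
                        genes_per_node = 3L, sign_prob = 0.3,
                        name = "synthetic", family = "synthetic",
                        seed = 1L) {
  topology <- match.arg(topology)
  if (n_backbone < 2L) stop("n_backbone must be at least 2")
  if (genes_per_node < 1L) stop("genes_per_node must be at least 1")
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_backbone))
  g <- switch(topology,
    chain = igraph::make_ring(n_backbone, circular = FALSE),
    `scale-free` = igraph::sample_pa(n_backbone, m = 1, directed = FALSE),
    random = {
      # random spanning tree guarantees connectivity, then extra edges
      perm <- sample.int(n_backbone)
      tree <- cbind(perm[1 + seq_len(n_backbone - 1L)],
                    vapply(seq_len(n_backbone - 1L),
                           function(i) perm[sample.int(i, 1L)], integer(1)))
      n_extra <- min(max(0L, round(0.5 * n_backbone)),
                     choose(n_backbone, 2) - (n_backbone - 1L))
      extra <- matrix(integer(0), ncol = 2)
      while (nrow(extra) < n_extra) {
        cand <- sample.int(n_backbone, 2L)
        extra <- rbind(extra, sort(cand))
        extra <- unique(extra)
        key <- paste(extra[, 1], extra[, 2])
        tkey <- paste(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
        extra <- extra[!key %in% tkey, , drop = FALSE]
      }
      igraph::graph_from_edgelist(rbind(tree, extra), directed = FALSE)
    })
  el <- igraph::as_edgelist(g, names = FALSE)
  be <- data.frame(src = nodes[el[, 1]], tgt = nodes[el[, 2]],
                   sign = ifelse(stats::runif(nrow(el)) < sign_prob, -1, 1))
  de <- data.frame(
    node = rep(nodes, each = genes_per_node),
    gene = sprintf("G%04d", seq_len(n_backbone * genes_per_node)),
    sign = ifelse(stats::runif(n_backbone * genes_per_node) < sign_prob,
                  -1, 1))
  causal_network(name, family, nodes, be, de)
}

#' Planted backbone perturbation
#'
#' True differential node values used to generate a synthetic contrast;
#' the generative converse of the backbone fit.
#'
#' @param network a [causal_network()].
#' @param values named numeric vector of true node values `f0` (names must
#'   be backbone nodes; unnamed nodes get 0), or `NULL` to draw them:
#'   `n_perturbed` nodes chosen at random get magnitudes uniform in
#'   `magnitude` with random signs.
#' @param n_perturbed number of perturbed nodes when drawing (default 30%
#'   of the backbone, at least 1).
#' @param magnitude range of |f0| when drawing. The default plants a fixed
#'   magnitude 2 on every perturbed node (with the default `noise_sd` this
#'   puts the planted gene-level fold-changes at 10x their standard error,
#'   a strong coherent perturbation); equal planted effect sizes keep
#'   leading-node recall well defined, since the cumulative-share
#'   definition of leading nodes necessarily drops the weakest true nodes
#'   when effect sizes are strongly heterogeneous.
#' @param noise_sd sd of the gene-level Gaussian noise added by
#'   [gen_contrast()].
#' @param coherent if `TRUE`, plant a backbone-coherent perturbation
#'   instead: every node is perturbed at magnitude `magnitude[1]` with signs
#'   propagated along a spanning tree of the backbone so that
#'   `f0_x = sign(x, y) * f0_y` holds on the tree edges. A coherent
#'   perturbation is one the causal structure itself predicts, which is what
#'   the K (structure-specificity) statistic is powered against.
#' @param seed integer seed (used when drawing values).
#' @return a `planted_perturbation`: list with named `f0`, `noise_sd`,
#'   `seed`.
#' @export
planted_perturbation <- function(network, values = NULL,
                                 n_perturbed = NULL, magnitude = c(2, 2),
                                 noise_sd = 0.2, coherent = FALSE, seed = 1L) {
  nodes <- network$backbone_nodes
  f0 <- stats::setNames(numeric(length(nodes)), nodes)
  if (coherent) {
    if (!is.null(values)) stop("give either values or coherent, not both")
    be <- network$backbone_edges
    g <- igraph::graph_from_data_frame(
      be[, c("src", "tgt")], directed = FALSE,
      vertices = data.frame(name = nodes))
    f0[] <- NA_real_
    f0[nodes[1]] <- magnitude[1]
    # BFS sign propagation; cycle inconsistencies resolved by first visit
    queue <- nodes[1]
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      nb <- rbind(be[be$src == x, c("tgt", "sign")],
                  stats::setNames(be[be$tgt == x, c("src", "sign")],
                                  c("tgt", "sign")))
      for (k in seq_len(nrow(nb))) {
        y <- nb$tgt[k]
        if (is.na(f0[y])) {
          f0[y] <- nb$sign[k] * f0[x]
          queue <- c(queue, y)
        }
      }
    }
    f0[is.na(f0)] <- 0  # disconnected nodes (none for generated networks)
  } else if (is.null(values)) {
    set.seed(seed)
    if (is.null(n_perturbed))
      n_perturbed <- max(1L, round(0.3 * length(nodes)))
    pick <- sample(nodes, n_perturbed)
    f0[pick] <- stats::runif(n_perturbed, magnitude[1], magnitude[2]) *
      sample(c(-1, 1), n_perturbed, replace = TRUE)
  } else {
    if (!all(names(values) %in% nodes))
      stop("planted values reference undeclared nodes")
    f0[names(values)] <- values
  }
  if (all(f0 == 0)) stop("at least one nonzero planted value required")
  structure(list(f0 = f0, noise_sd = noise_sd, seed = seed),
            class = "planted_perturbation")
}

#' Generate a gene contrast from a planted perturbation
#'
#' Realizes gene-level log2 fold-changes from true backbone node values
#' through the signed downstream layer: for downstream edge `(x, g, s)`,
#' `beta_g = s * f0_x + Normal(0, noise_sd^2)`, with `se_g = noise_sd`
#' reported as the (true) standard error. Deterministic given the seed.
#'
#' @param network a [causal_network()].
#' @param planted a [planted_perturbation()] (its `noise_sd` is used).
#' @param seed integer seed.
#' @return a [gene_contrast()] with attribute `truth` (the planted values).
#' @export
gen_contrast <- function(network, planted, seed = 1L) {
  stopifnot(inherits(planted, "planted_perturbation"))
  de <- network$downstream_edges
  set.seed(seed)
  beta <- de$sign * planted$f0[de$node] +
    stats::rnorm(nrow(de), sd = planted$noise_sd)
  # one record per gene: a duplicated gene keeps its first edge's draw
  keep <- !duplicated(de$gene)
  out <- gene_contrast(de$gene[keep], beta[keep],
                       rep(planted$noise_sd, sum(keep)))
  attr(out, "truth") <- planted$f0
  out
}

#' Generate a global-null paired expression matrix
#'
#' A blocked exposed/air design with no true treatment effect: per gene a
#' baseline, per run a shared additive offset (the blocking structure that
#' the paired analysis must remove), and i.i.d. Gaussian noise on every
#' sample. Used for type-I-error calibration of the paired contrast
#' pipeline. Deterministic given the seed.
#'
#' @param n_genes number of genes.
#' @param n_runs number of exposure runs (>= 2; default 9, one per
#'   independent exposure experiment).
#' @param sd residual sd on the log2 scale (default 0.25).
#' @param run_sd sd of the shared run offsets (default `sd`).
#' @param baseline_range range of gene baselines (default `c(4, 12)`).
#' @param seed integer seed.
#' @return list with `expr` (gene x sample matrix) and `design` (a
#'   [paired_design()]).
#' @export
gen_null_matrix <- function(n_genes, n_runs = 9L, sd = 0.25, run_sd = sd,
                            baseline_range = c(4, 12), seed = 1L) {
  if (n_runs < 2L) stop("n_runs must be at least 2")
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  runs <- sprintf("R%02d", seq_len(n_runs))
  design <- paired_design(data.frame(
    sample_id = c(paste0(runs, "_exposed"), paste0(runs, "_air")),
    run = rep(runs, 2L),
    arm = rep(c("exposed", "air"), each = n_runs)))
  base <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
  run_off <- stats::rnorm(n_runs, sd = run_sd)
  expr <- base +
    matrix(rep(run_off, each = n_genes), n_genes, 2L * n_runs) +
    matrix(stats::rnorm(n_genes * 2L * n_runs, sd = sd), n_genes)
  dimnames(expr) <- list(genes, c(paste0(runs, "_exposed"),
                                  paste0(runs, "_air")))
  list(expr = expr, design = design)
}

#' Generate a synthetic mediator concentration panel
#'
#' Log-normal concentrations for a paired exposed/air design with planted
#' per-analyte log2 fold-changes (applied to the exposed arm) and a shared
#' run offset on the log scale. Deterministic given the seed.
#'
#' @param n_analytes number of analytes (default 10, the size of a typical
#'   multiplexed inflammatory panel).
#' @param effect numeric vector of planted log2 fold-changes, recycled to
#'   `n_analytes`.
#' @param n_runs number of exposure runs (default 9).
#' @param cv coefficient of variation of concentrations (> 0, default 0.2);
#'   the log-scale sd is `sqrt(log(1 + cv^2))`.
#' @param baseline geometric-mean baseline concentration (default 100,
#'   arbitrary pg/mL-like units).
#' @param seed integer seed.
#' @return list with `conc` (analyte x sample matrix), `design` (a
#'   [paired_design()]) and `truth` (planted log2 fold-changes).
#' @export
gen_mediator_panel <- function(n_analytes = 10L, effect = 0, n_runs = 9L,
                               cv = 0.2, baseline = 100, seed = 1L) {
  if (n_runs < 2L) stop("n_runs must be at least 2")
  if (cv <= 0) stop("cv must be positive")
  set.seed(seed)
  effect <- rep_len(effect, n_analytes)
  analytes <- sprintf("A%02d", seq_len(n_analytes))
  runs <- sprintf("R%02d", seq_len(n_runs))
  design <- paired_design(data.frame(
    sample_id = c(paste0(runs, "_exposed"), paste0(runs, "_air")),
    run = rep(runs, 2L),
    arm = rep(c("exposed", "air"), each = n_runs)))
  sdlog <- sqrt(log(1 + cv^2))
  run_off <- stats::rnorm(n_runs, sd = sdlog)
  logc <- log(baseline) +
    matrix(rep(run_off, each = n_analytes), n_analytes, 2L * n_runs) +
    matrix(stats::rnorm(n_analytes * 2L * n_runs, sd = sdlog), n_analytes)
  logc[, seq_len(n_runs)] <- logc[, seq_len(n_runs)] + effect * log(2)
  conc <- exp(logc)
  dimnames(conc) <- list(analytes, c(paste0(runs, "_exposed"),
                                     paste0(runs, "_air")))
  list(conc = conc, design = design,
       truth = stats::setNames(effect, analytes))
}
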