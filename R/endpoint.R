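#' Paired exposed-vs-air design
#'
#' Encodes the blocking structure of an exposure experiment: each exposure
#' run contributes one exposed and one matched air-control sample, and all
#' comparisons are paired within run so that run-to-run level shifts cancel.
#'
#' @param samples data frame with columns `sample_id`, `run`, `arm`
#'   (`"exposed"`/`"air"`); extra metadata columns (`item`,
#'   `concentration`, `timepoint`, ...) are kept.
#' @return a `paired_design`: the validated data frame with attribute
#'   `runs` (run ids of complete pairs).
#' @export
paired_design <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "run", "arm")
  if (!all(need %in% names(samples)))
    stop("design needs columns ", paste(need, collapse = ", "))
  if (!all(samples$arm %in% c("exposed", "air")))
    stop("arm must be 'exposed' or 'air'")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  tab <- table(samples$run, factor(samples$arm, levels = c("air", "exposed")))
  if (any(tab > 1))
    stop("a run contributes more than one sample per arm")
  complete <- rownames(tab)[tab[, "air"] == 1 & tab[, "exposed"] == 1]
  if (length(complete) < 2L)
    stop("need at least 2 complete exposed/air pairs")
  attr(samples, "runs") <- complete
  class(samples) <- c("paired_design", "data.frame")
  samples
}

# exposed and air sample ids ordered by run, complete pairs only
paired_ids <- function(design) {
  runs <- attr(design, "runs")
  list(runs = runs,
       exposed = design$sample_id[match(paste(runs, "exposed"),
                                        paste(design$run, design$arm))],
       air = design$sample_id[match(paste(runs, "air"),
                                    paste(design$run, design$arm))])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR adjustment across genes: `fdr_i = min_{j >= rank(i)}
#' p_(j) * m / j`, capped at 1, input order preserved.
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @return vector of FDR-adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-gene paired contrast with run blocking
#'
#' For each gene, forms the within-run differences `d_r = exposed_r -
#' air_r` over complete pairs and runs a paired t test: `log2fc = mean(d)`,
#' `se = sd(d)/sqrt(n)`, two-sided p from the t distribution with `n - 1`
#' degrees of freedom, then BH-FDR adjustment across genes. Genes with zero
#' variance across pairs get `p = 1` by convention and are flagged (dropping
#' them would silently change the BH denominator).
#'
#' @param expr numeric gene x sample matrix of log2 expression; column names
#'   are sample ids.
#' @param design a [paired_design()].
#' @return a `contrast_table` data frame: `gene`, `log2fc`, `se`, `t`, `p`,
#'   `fdr`, `zero_variance` flag.
#' @export
paired_contrast <- function(expr, design) {
  stopifnot(inherits(design, "paired_design"))
  ids <- paired_ids(design)
  miss <- setdiff(c(ids$exposed, ids$air), colnames(expr))
  if (length(miss)) stop("samples absent from expression matrix: ",
                         paste(miss, collapse = ", "))
  d <- expr[, ids$exposed, drop = FALSE] - expr[, ids$air, drop = FALSE]
  n <- ncol(d)
  log2fc <- rowMeans(d)
  se <- sqrt(apply(d, 1L, stats::var) / n)
  zero <- se == 0
  tt <- ifelse(zero, NA_real_, log2fc / se)
  p <- ifelse(zero, 1, 2 * stats::pt(-abs(tt), df = n - 1))
  out <- data.frame(gene = rownames(expr), log2fc = log2fc, se = se,
                    t = tt, p = p, fdr = bh_adjust(p),
                    zero_variance = zero, row.names = NULL)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Count differentially expressed genes
#'
#' DEGs are genes with FDR below the threshold; they are split by the sign
#' of the log2 fold-change (up- vs down-regulated).
#'
#' @param table a `contrast_table` from [paired_contrast()] (any data frame
#'   with `fdr` and `log2fc` columns works).
#' @param threshold FDR cutoff, default 0.05.
#' @return named integer vector `c(n_up, n_down)`.
#' @export
count_degs <- function(table, threshold = 0.05) {
  hit <- table$fdr < threshold
  c(n_up = sum(hit & table$log2fc > 0),
    n_down = sum(hit & table$log2fc < 0))
}

#' Geometric-mean fold-changes of secreted mediators
#'
#' Concentrations are log-transformed; per analyte the fold-change is the
#' ratio of geometric means (exposed over air), with a paired t test on the
#' log concentrations (paired within exposure run). Nonpositive readings
#' are replaced by a detection floor (default half the smallest positive
#' value of that analyte) and flagged; an analyte entirely at the floor is
#' flagged as below detection.
#'
#' @param conc numeric analyte x sample matrix of concentrations; column
#'   names are sample ids.
#' @param design a [paired_design()].
#' @param floor optional fixed detection floor; default per-analyte half
#'   minimum positive value.
#' @return a `mediator_table` data frame: `analyte`, `geomean_exposed`,
#'   `geomean_air`, `fold_change`, `log2fc`, `p`, `n_floored`,
#'   `below_detection`.
#' @export
mediator_foldchanges <- function(conc, design, floor = NULL) {
  stopifnot(inherits(design, "paired_design"))
  ids <- paired_ids(design)
  used <- c(ids$exposed, ids$air)
  miss <- setdiff(used, colnames(conc))
  if (length(miss)) stop("samples absent from concentration table: ",
                         paste(miss, collapse = ", "))
  conc <- conc[, used, drop = FALSE]
  n_floored <- integer(nrow(conc))
  below <- logical(nrow(conc))
  for (i in seq_len(nrow(conc))) {
    bad <- conc[i, ] <= 0
    if (any(bad)) {
      fl <- if (!is.null(floor)) floor
            else if (any(!bad)) min(conc[i, !bad]) / 2
            else NA_real_
      if (!is.finite(fl) || fl <= 0) {
        below[i] <- TRUE
        fl <- 1e-12
      }
      conc[i, bad] <- fl
      n_floored[i] <- sum(bad)
      if (all(bad)) below[i] <- TRUE
    }
  }
  lg <- log(conc)
  n <- length(ids$runs)
  le <- lg[, ids$exposed, drop = FALSE]
  la <- lg[, ids$air, drop = FALSE]
  gm_e <- exp(rowMeans(le))
  gm_a <- exp(rowMeans(la))
  d <- le - la
  m <- rowMeans(d)
  se <- sqrt(apply(d, 1L, stats::var) / n)
  p <- ifelse(se == 0, 1, 2 * stats::pt(-abs(m / se), df = n - 1))
  out <- data.frame(analyte = rownames(conc),
                    geomean_exposed = gm_e, geomean_air = gm_a,
                    fold_change = gm_e / gm_a,
                    log2fc = log2(gm_e / gm_a),
                    p = p, n_floored = n_floored,
                    below_detection = below, row.names = NULL)
  class(out) <- c("mediator_table", "data.frame")
  out
}

#' Percent distribution of ordinal histopathology scores
#'
#' Tallies, per finding and treatment group, the percentage of samples at
#' each ordinal severity level. Levels with no samples are reported as 0%;
#' a (finding, group) combination with no samples at all is reported as a
#' row of `NA` (not applicable), not as 0%.
#'
#' @param scores data frame with columns `sample`, `group`, `finding`,
#'   `score`.
#' @param levels the declared ordinal scale (default `0:3`).
#' @return a `histo_distribution` data frame: `finding`, `group`, `n`, one
#'   `pct_<level>` column per scale level.
#' @export
histo_distribution <- function(scores, levels = 0:3) {
  scores <- as.data.frame(scores)
  need <- c("sample", "group", "finding", "score")
  if (!all(need %in% names(scores)))
    stop("scores needs columns ", paste(need, collapse = ", "))
  if (!all(scores$score %in% levels))
    stop("scores outside the declared scale: ",
         paste(unique(setdiff(scores$score, levels)), collapse = ", "))
  combos <- expand.grid(finding = unique(scores$finding),
                        group = unique(scores$group),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- scores$finding == combos$finding[i] & scores$group == combos$group[i]
    n <- sum(sel)
    pct <- if (n == 0) rep(NA_real_, length(levels))
           else 100 * vapply(levels, function(l) sum(scores$score[sel] == l),
                             numeric(1)) / n
    c(n = n, stats::setNames(pct, paste0("pct_", levels)))
  })
  out <- cbind(combos, do.call(rbind, rows))
  class(out) <- c("histo_distribution", "data.frame")
  out
}
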