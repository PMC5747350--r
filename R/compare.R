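#' Cohen's D effect size
#'
#' Absolute standardized mean difference `|mean_a - mean_b| / s_pooled` with
#' the pooled standard deviation
#' `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`. With zero
#' pooled variance the statistic is 0 for equal means and `Inf` otherwise
#' (two point masses at different locations are maximally separated).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return Non-negative effect size (possibly `Inf`).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs n >= 2")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  dm <- abs(mean(a) - mean(b))
  if (sp2 == 0) {
    return(if (dm == 0) 0 else Inf)
  }
  dm / sqrt(sp2)
}

#' Kruskal-Wallis rank test
#'
#' The standard tie-corrected rank statistic `H` with its chi-squared
#' approximation on `k - 1` degrees of freedom (delegated to
#' [stats::kruskal.test()]). The fully degenerate case (every value
#' identical) returns `H = 0`, `p = 1`.
#'
#' @param groups List of numeric samples (>= 2 groups, total n >= 3).
#' @return Named list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(!vapply(groups, length, integer(1)))) stop("empty group")
  values <- unlist(groups)
  if (length(values) < 3) stop("need total n >= 3")
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Compare parameter ensembles across cell lines
#'
#' For every free parameter shared by the ensembles: a Kruskal-Wallis test
#' across all cell lines, Benjamini-Hochberg adjustment across parameters,
#' and the maximum pairwise Cohen's D (optionally one-vs-rest). A parameter
#' is flagged divergent when `D > d_threshold` and the adjusted p-value is
#' below `p_threshold` (defaults 4 and 1e-10, the thresholds used to call
#' functional interactions different between cell lines).
#'
#' @param ensembles List of `ensemble` objects (>= 2) with shared parameter
#'   names.
#' @param d_threshold Effect-size threshold (default 4).
#' @param p_threshold Adjusted-p threshold (default 1e-10).
#' @param adjustment Multiple-testing method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @param one_vs_rest Use each line vs the pool of the others instead of the
#'   maximum pairwise D.
#' @return Data frame (class `parameter_comparison`) sorted by descending D:
#'   per-line `n`/`mean`/`sd`/`median` columns, `cohens_d`, `kw_H`, `p`,
#'   `p_adj`, `divergent`.
#' @export
compare_ensembles <- function(ensembles, d_threshold = 4, p_threshold = 1e-10,
                              adjustment = "BH", one_vs_rest = FALSE) {
  if (length(ensembles) < 2) stop("need >= 2 ensembles")
  labels <- vapply(ensembles, function(e) e$cell_line, character(1))
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  pnames <- colnames(ensembles[[1]]$parameters)
  for (e in ensembles[-1]) {
    if (!identical(colnames(e$parameters), pnames)) {
      stop("ensembles have mismatched parameter names")
    }
  }
  rows <- lapply(pnames, function(pn) {
    samples <- lapply(ensembles, function(e) e$parameters[, pn])
    kw <- kruskal_wallis(samples)
    d <- if (one_vs_rest) {
      max(vapply(seq_along(samples), function(i)
        cohens_d(samples[[i]], unlist(samples[-i])), numeric(1)))
    } else {
      pairs <- utils::combn(length(samples), 2)
      max(apply(pairs, 2, function(ij)
        cohens_d(samples[[ij[1]]], samples[[ij[2]]])))
    }
    stats <- unlist(lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      stats::setNames(c(length(s), mean(s), stats::sd(s), stats::median(s)),
                      paste0(c("n_", "mean_", "sd_", "median_"), labels[i]))
    }))
    c(list(parameter = pn), as.list(stats),
      list(cohens_d = d, kw_H = kw$H, p = kw$p))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out$p_adj <- stats::p.adjust(out$p, method = adjustment)
  out$divergent <- out$cohens_d > d_threshold & out$p_adj < p_threshold
  out <- out[order(-out$cohens_d, out$p_adj), ]
  rownames(out) <- NULL
  class(out) <- c("parameter_comparison", "data.frame")
  out
}

#' Map divergent parameters to network edges
#'
#' An interaction (edge) is divergent when any of its Hill parameters is
#' flagged; time constants and metabolic rates are reported under their own
#' names.
#'
#' @param comparison Result of [compare_ensembles()].
#' @param network The `pkn` the parameters belong to.
#' @return Data frame of edges with a `divergent` flag and the names of the
#'   flagged parameters.
#' @export
edge_divergence <- function(comparison, network) {
  rows <- lapply(network$edges, function(e) {
    if (e$mechanism == "hill_regulatory") {
      pn <- c(sprintf("k_%s_%s", e$sources$node, e$target),
              sprintf("n_%s_%s", e$sources$node, e$target))
    } else {
      pn <- stats::na.omit(c(e$rate_param, e$km_param, e$ki_param))
    }
    flagged <- comparison$parameter[comparison$divergent]
    hit <- intersect(pn, flagged)
    data.frame(edge = e$id, mechanism = e$mechanism,
               divergent = length(hit) > 0,
               parameters = paste(hit, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transfer-function curves of an ensemble
#'
#' Evaluates each ensemble member's normalized Hill transfer for a
#' regulatory edge over a uniform \[0,1\] input grid and summarizes the
#' member curves with quantile bands (0.1/0.25/0.75/0.9 by default, plus
#' the median).
#'
#' @param ensemble An `ensemble`.
#' @param network The `pkn` holding the edge.
#' @param edge Edge id (must be `hill_regulatory`).
#' @param source Source node, needed when the edge has several.
#' @param grid_size Number of grid points (default 101).
#' @param quantiles Band quantiles.
#' @return A `transfer_curve` list: `edge`, `source`, `x`, `curves`
#'   (member x grid matrix), `bands` (data frame).
#' @export
transfer_curves <- function(ensemble, network, edge, source = NULL,
                            grid_size = 101,
                            quantiles = c(0.1, 0.25, 0.75, 0.9)) {
  e <- network$edges[[edge]]
  if (is.null(e)) stop("unknown edge: ", edge)
  if (e$mechanism != "hill_regulatory") {
    stop("edge '", edge, "' is not a regulatory (Hill) edge")
  }
  if (is.null(source)) {
    if (nrow(e$sources) > 1) stop("edge has several sources; pass source")
    source <- e$sources$node[1]
  }
  kname <- sprintf("k_%s_%s", source, e$target)
  nname <- sprintf("n_%s_%s", source, e$target)
  get_par <- function(i, nm) {
    if (nm %in% colnames(ensemble$parameters)) ensemble$parameters[i, nm]
    else ensemble$par_table$value[match(nm, ensemble$par_table$name)]
  }
  x <- seq(0, 1, length.out = grid_size)
  curves <- t(vapply(seq_len(nrow(ensemble$parameters)), function(i)
    hill_transfer(x, get_par(i, kname), get_par(i, nname)),
    numeric(grid_size)))
  qs <- apply(curves, 2, stats::quantile, probs = sort(c(quantiles, 0.5)))
  bands <- data.frame(x = x, t(qs), check.names = FALSE)
  structure(list(edge = edge, source = source, x = x, curves = curves,
                 bands = bands), class = "transfer_curve")
}

#' Export transfer curves to CSV
#'
#' Writes the long-format member curves (`edge`, `source`, `member`, `x`,
#' `y`) and, optionally, the quantile bands alongside.
#'
#' @param curve A [transfer_curves()] result.
#' @param path Output CSV path for the curves.
#' @param bands_path Optional output path for the band table.
#' @return Invisibly, `path`.
#' @export
export_transfer_curves <- function(curve, path, bands_path = NULL) {
  long <- data.frame(
    edge = curve$edge, source = curve$source,
    member = rep(seq_len(nrow(curve$curves)), each = length(curve$x)),
    x = rep(curve$x, times = nrow(curve$curves)),
    y = as.vector(t(curve$curves)), stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  if (!is.null(bands_path)) {
    utils::write.csv(curve$bands, bands_path, row.names = FALSE)
  }
  invisible(path)
}
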