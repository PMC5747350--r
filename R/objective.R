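#' Objective configuration
#'
#' Settings of the adapted fitting objective: weighted mean of squared
#' residuals over measured (and pseudo) data points, plus a penalty pulling
#' the unquantified nodes (ER and medium cholesterol, LDLR, NPC1 in the
#' packaged network) toward the 0.5 reference along the untreated
#' trajectory. Differential measurements carry a higher weight and
#' pseudo-timepoints a lower one; a failed simulation contributes a large
#' finite penalty (a multiple of the all-0.5 constant predictor's loss) so
#' the search stays finite without masking failures.
#'
#' @param penalized_nodes Unmeasured nodes penalized in the untreated
#'   condition (default the four unquantified cholesterol-model nodes,
#'   intersected with the network).
#' @param lambda Penalty weight (>= 0, default 1).
#' @param reference Reference level for penalized nodes (default 0.5).
#' @param differential_weight,pseudo_weight Weights applied by
#'   [flag_differential()] / [augment_dataset()].
#' @param fail_factor Multiplier on the constant-predictor loss for failed
#'   simulations (default 10).
#' @param rtol,atol Integration tolerances used inside the objective (looser
#'   than the simulation defaults; residuals are resolved far above 1e-5).
#' @return An `objective_config` list.
#' @export
objective_config <- function(penalized_nodes = c("CholER", "CholMedia",
                                                 "LDLR", "NPC1"),
                             lambda = 1, reference = 0.5,
                             differential_weight = 2, pseudo_weight = 0.5,
                             fail_factor = 10, rtol = 1e-5, atol = 1e-7) {
  stopifnot(lambda >= 0, fail_factor > 0, pseudo_weight >= 0)
  structure(list(penalized_nodes = penalized_nodes, lambda = lambda,
                 reference = reference,
                 differential_weight = differential_weight,
                 pseudo_weight = pseudo_weight, fail_factor = fail_factor,
                 rtol = rtol, atol = atol), class = "objective_config")
}

# Precompiled closure evaluating the objective for one cell line.
# Returns a function(full_parameter_vector) -> list(loss, converged_frac).
make_objective <- function(compiled, dataset, config, x0, cell_line = NULL) {
  m <- dataset$measurements
  if (!is.null(cell_line)) {
    if (!cell_line %in% m$cell_line) {
      stop("cell line '", cell_line, "' not in dataset (has: ",
           paste(unique(m$cell_line), collapse = ", "), ")")
    }
    m <- m[m$cell_line == cell_line, , drop = FALSE]
  }
  if (length(unique(m$cell_line)) > 1) {
    stop("dataset spans multiple cell lines; pass cell_line")
  }
  if (!nrow(m)) stop("no measurements for objective")
  cond <- dataset$conditions
  cond <- cond[cond$condition %in% m$condition, , drop = FALSE]
  pen_nodes <- intersect(config$penalized_nodes, compiled$dyn_ids)
  pen_idx <- match(pen_nodes, compiled$dyn_ids)
  untreated <- cond$condition[cond$untreated]

  plans <- lapply(seq_len(nrow(cond)), function(i) {
    cd <- cond$condition[i]
    rows <- m[m$condition == cd & !is.na(m$value), , drop = FALSE]
    et <- cond$end_time[i]
    is_untreated <- length(untreated) && cd == untreated[1]
    times <- sort(unique(c(
      0, rows$time, et,
      if (is_untreated && length(pen_idx)) seq(0, et, length.out = 41L)
    )))
    list(
      u = condition_inputs(compiled, cond[i, , drop = FALSE]),
      times = times,
      ti = match(rows$time, times),
      ni = match(rows$node, compiled$dyn_ids),
      w = rows$weight, obs = rows$value,
      ssq05 = sum(rows$weight * (0.5 - rows$value)^2),
      untreated = is_untreated
    )
  })
  bad <- vapply(plans, function(p) any(is.na(p$ni)), logical(1))
  if (any(bad)) {
    nn <- unique(m$node[!m$node %in% compiled$dyn_ids])
    stop("measured node(s) not dynamic in network: ", paste(nn, collapse = ", "))
  }
  wtot <- sum(vapply(plans, function(p) sum(p$w), numeric(1)))
  if (wtot <= 0) stop("total observation weight is zero")
  xv <- align_state(x0, compiled$dyn_ids)

  function(pv) {
    ssq <- 0
    penalty <- 0
    nconv <- 0L
    for (p in plans) {
      res <- tryCatch(
        sim_network_cpp(compiled$comp, pv, p$u, xv, p$times,
                        config$rtol, config$atol, max_steps = 50000L,
                        ss_exit = 1e-9),
        error = function(e) NULL)
      if (is.null(res) || !res$ok || any(!is.finite(res$states))) {
        ssq <- ssq + config$fail_factor * p$ssq05
        next
      }
      S <- res$states
      ssq <- ssq + sum(p$w * (S[cbind(p$ti, p$ni)] - p$obs)^2)
      if (max(abs(res$final_deriv)) < 1e-3) nconv <- nconv + 1L
      if (p$untreated && length(pen_idx) && config$lambda > 0) {
        dev <- S[, pen_idx, drop = FALSE] - config$reference
        penalty <- penalty + config$lambda * mean(dev^2)
      }
    }
    list(loss = ssq / wtot + penalty,
         converged_frac = nconv / length(plans))
  }
}

#' Evaluate the fitting objective
#'
#' Loss = weighted mean of squared residuals between simulated and observed
#' values (pseudo-timepoints entering at their reduced weight) plus
#' `lambda` times the mean squared deviation of the penalized unmeasured
#' nodes from the reference level along the untreated trajectory. Failed
#' simulations contribute `fail_factor` times the all-0.5 constant
#' predictor's residual sum for that condition.
#'
#' @param params Named parameter vector or parameter table.
#' @param network A `pkn` or [compile_network()] result.
#' @param dataset A `scaled_dataset` (one cell line, or pass `cell_line`).
#' @param config An [objective_config()].
#' @param cell_line Cell line to evaluate when the dataset spans several.
#' @return Non-negative scalar loss.
#' @export
objective <- function(params, network, dataset, config = objective_config(),
                      cell_line = NULL) {
  compiled <- if (inherits(network, "pkn")) compile_network(network) else network
  x0 <- if (inherits(network, "pkn")) initial_state(network) else
    stats::setNames(rep(0.5, length(compiled$dyn_ids)), compiled$dyn_ids)
  pv <- align_params(params, compiled$par_names)
  obj <- make_objective(compiled, dataset, config, x0, cell_line)
  obj(pv)$loss
}

#' Bootstrap a dataset by resampling biological replicates
#'
#' For each (cell line, node, condition) cell, draws its replicate values
#' with replacement to the original count. Pseudo-timepoints, which derive
#' from replicate means, are regenerated from the resampled data.
#' Deterministic given `seed`; the dataset shape is preserved.
#'
#' @param dataset A `scaled_dataset`.
#' @param seed Integer seed.
#' @return A resampled `scaled_dataset`.
#' @export
bootstrap_dataset <- function(dataset, seed) {
  m <- dataset$measurements
  has_pseudo <- any(m$pseudo)
  pseudo_w <- if (has_pseudo) m$weight[m$pseudo][1] else 0.5
  m <- m[!m$pseudo, , drop = FALSE]
  if (!nrow(m)) stop("empty dataset")
  set.seed(seed)
  key <- interaction(m$cell_line, m$node, m$condition, drop = TRUE)
  for (g in split(seq_len(nrow(m)), key)) {
    if (!length(g)) next
    m$value[g] <- m$value[g][sample.int(length(g), length(g), replace = TRUE)]
  }
  dataset$measurements <- m
  if (has_pseudo) dataset <- augment_dataset(dataset, weight = pseudo_w)
  dataset
}
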