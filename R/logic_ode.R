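#' Normalized Hill transfer function
#'
#' Maps an upstream node level in \[0,1\] to its regulatory effect through
#' `f(x) = x^n * (1 + k^n) / (x^n + k^n)`. The normalization pins `f(0) = 0`
#' and `f(1) = 1` so a fully active regulator transmits its full effect; `k`
#' is the half-effect constant and `n` the steepness.
#'
#' @param x Input level(s) in \[0,1\].
#' @param k Half-effect constant, `k > 0`.
#' @param n Hill exponent, `n >= 1`.
#' @return Transfer value(s) in \[0,1\].
#' @examples
#' hill_transfer(0.5, k = 0.5, n = 2)  # 0.625
#' @export
hill_transfer <- function(x, k, n) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("hill_transfer: x must lie in [0,1]")
  }
  if (any(k <= 0)) stop("hill_transfer: k must be > 0")
  if (any(n < 1)) stop("hill_transfer: n must be >= 1")
  xn <- x^n
  kn <- k^n
  out <- xn * (1 + kn) / (xn + kn)
  out[x == 0] <- 0
  out
}

#' Default parameter vector for a network
#'
#' Builds the named, bounded, partially fixed parameter table spanning the
#' Hill constants (`k_<source>_<target>`, `n_<source>_<target>` per regulatory
#' edge source), the per-node time constants (`tau_<node>`), and the metabolic
#' rate constants named by the edge metadata (e.g. `k1`..`k8`, `kM4`, `kI`).
#' Bounds are shared across cell lines: `k` in \[0.01, 1\], `n` in \[1, 10\],
#' `tau` in \[0.01, 10\], metabolic rates in \[0, 10\] and Michaelis/inhibition
#' constants in \[0.01, 10\]. Parameters of fixed edges are pinned at their
#' declared values and excluded from optimization.
#'
#' @param network A `pkn` object.
#' @param fix_tau Fix all time constants at 1 (useful when only terminal
#'   states are fitted and transients are unconstrained).
#' @return A data frame with columns `name`, `value`, `lower`, `upper`,
#'   `fixed`.
#' @export
default_parameters <- function(network, fix_tau = FALSE) {
  rows <- list()
  add <- function(name, value, lower, upper, fixed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, value = value, lower = lower, upper = upper, fixed = fixed,
      stringsAsFactors = FALSE)
  }
  for (e in network$edges) {
    if (e$mechanism != "hill_regulatory") next
    for (i in seq_len(nrow(e$sources))) {
      src <- e$sources$node[i]
      kv <- if (e$fixed) e$fixed_k else 0.5
      nv <- if (e$fixed) e$fixed_n else 2
      add(sprintf("k_%s_%s", src, e$target), kv, 0.01, 1, e$fixed)
      add(sprintf("n_%s_%s", src, e$target), nv, 1, 10, e$fixed)
    }
  }
  for (id in dynamic_nodes(network)) {
    add(sprintf("tau_%s", id), 1, 0.01, 10, fix_tau)
  }
  seen <- character(0)
  for (e in network$edges) {
    if (e$mechanism == "hill_regulatory") next
    for (p in c(e$rate_param, e$km_param, e$ki_param)) {
      if (is.na(p) || p %in% seen) next
      seen <- c(seen, p)
      if (identical(p, e$km_param) || identical(p, e$ki_param)) {
        add(p, if (identical(p, e$km_param)) 0.5 else 1, 0.01, 10, FALSE)
      } else {
        add(p, 1, 0, 10, FALSE)
      }
    }
  }
  for (i in seq_len(nrow(network$nodes))) {
    p <- network$nodes$source_param[i]
    if (!is.na(p) && !p %in% seen) {
      seen <- c(seen, p)
      add(p, 1, 0, 10, FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$name)) {
    stop("duplicate parameter names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  }
  rownames(tab) <- NULL
  tab
}

#' Compile a network into integrator-ready index structures
#'
#' Flattens the network into the integer/real arrays consumed by the compiled
#' right-hand side: per-node dispatch (relaxation vs metabolic), Hill edge
#' terms with parameter indices, and metabolic flux descriptors with their
#' stoichiometric output coefficients. Knockdown-input edges are marked so
#' they multiply the target's activation (AND-NOT) instead of OR-combining.
#'
#' @param network A `pkn` object.
#' @return A list with the compiled structure (`comp`), the canonical
#'   parameter-name order (`par_names`), the parameter table (`par_table`),
#'   and the dynamic/input node orderings.
#' @export
compile_network <- function(network) {
  nd_tab <- network$nodes
  dyn_ids <- nd_tab$id[nd_tab$dynamic]
  inp_ids <- nd_tab$id[!nd_tab$dynamic]
  par_table <- default_parameters(network)
  pidx <- function(name) {
    i <- match(name, par_table$name)
    if (any(is.na(i))) stop("unknown parameter: ", paste(name[is.na(i)], collapse = ", "))
    i - 1L
  }
  ref <- function(id) {
    d <- match(id, dyn_ids)
    ifelse(!is.na(d), d - 1L, -match(id, inp_ids))
  }
  kd_nodes <- nd_tab$id[nd_tab$category == "knockdown_input"]
  met_cat <- nd_tab$category %in% METABOLITE_CATEGORIES

  # a dynamic node is metabolic iff it is the target of a metabolic flux edge
  met_targets <- unique(unlist(lapply(network$edges, function(e)
    if (e$mechanism != "hill_regulatory") c(e$target, e$consumes) else NULL)))
  is_met <- as.integer(dyn_ids %in% met_targets)
  # regulatory states are hard-bounded in [0,1]; metabolites only at 0
  clamp01 <- as.integer(!(dyn_ids %in% met_targets &
                          dyn_ids %in% nd_tab$id[met_cat]))

  he_node <- he_kd <- integer(0)
  ht_src <- ht_sign <- ht_k <- ht_n <- integer(0)
  he_tptr <- 0L
  fl_type <- fl_rate <- fl_km <- fl_ki <- fl_sub <- fl_has_inh <- fl_inh <- integer(0)
  fl_fptr <- 0L
  ff_src <- integer(0); ff_exp <- numeric(0)
  fl_optr <- 0L
  fo_node <- integer(0); fo_coef <- numeric(0)

  for (e in network$edges) {
    if (e$mechanism == "hill_regulatory") {
      he_node <- c(he_node, match(e$target, dyn_ids) - 1L)
      he_kd <- c(he_kd, as.integer(any(e$sources$node %in% kd_nodes)))
      for (i in seq_len(nrow(e$sources))) {
        src <- e$sources$node[i]
        ht_src <- c(ht_src, ref(src))
        ht_sign <- c(ht_sign, as.integer(e$sources$sign[i]))
        ht_k <- c(ht_k, pidx(sprintf("k_%s_%s", src, e$target)))
        ht_n <- c(ht_n, pidx(sprintf("n_%s_%s", src, e$target)))
      }
      he_tptr <- c(he_tptr, length(ht_src))
    } else {
      mm <- e$mechanism == "michaelis_menten_inhibited"
      drain <- e$target %in% e$sources$node[e$sources$sign < 0]
      fl_type <- c(fl_type, as.integer(mm))
      fl_rate <- c(fl_rate, pidx(e$rate_param))
      fl_km <- c(fl_km, if (mm) pidx(e$km_param) else 0L)
      inh <- e$sources$node[e$sources$sign < 0 & e$sources$node != e$target]
      has_inh <- mm && length(inh) == 1
      fl_ki <- c(fl_ki, if (has_inh) pidx(e$ki_param) else 0L)
      fl_sub <- c(fl_sub, if (mm) ref(e$substrate) else 0L)
      fl_has_inh <- c(fl_has_inh, as.integer(has_inh))
      fl_inh <- c(fl_inh, if (has_inh) ref(inh) else 0L)
      fac <- if (mm) {
        e$sources[e$sources$node != e$substrate & e$sources$sign > 0, , drop = FALSE]
      } else {
        e$sources
      }
      ff_src <- c(ff_src, vapply(fac$node, ref, integer(1)))
      ff_exp <- c(ff_exp, fac$exponent)
      fl_fptr <- c(fl_fptr, length(ff_src))
      if (drain) {
        fo_node <- c(fo_node, match(e$target, dyn_ids) - 1L)
        fo_coef <- c(fo_coef, -1)
      } else {
        fo_node <- c(fo_node, match(e$target, dyn_ids) - 1L)
        fo_coef <- c(fo_coef, 1)
        for (cn in e$consumes) {
          fo_node <- c(fo_node, match(cn, dyn_ids) - 1L)
          fo_coef <- c(fo_coef, -1)
        }
      }
      fl_optr <- c(fl_optr, length(fo_node))
    }
  }

  src_rate <- rep(-1L, length(dyn_ids))
  src_scale <- rep(1, length(dyn_ids))
  for (i in seq_along(dyn_ids)) {
    row <- nd_tab[match(dyn_ids[i], nd_tab$id), ]
    if (!is.na(row$source_param)) {
      src_rate[i] <- pidx(row$source_param)
      src_scale[i] <- row$source_scale
    }
  }

  comp <- list(
    nd = length(dyn_ids), ni = length(inp_ids),
    is_met = is_met, tau_idx = pidx(sprintf("tau_%s", dyn_ids)),
    clamp01 = clamp01, src_rate = src_rate, src_scale = src_scale,
    he_node = he_node, he_kd = he_kd, he_tptr = as.integer(he_tptr),
    ht_src = as.integer(ht_src), ht_sign = ht_sign, ht_k = ht_k, ht_n = ht_n,
    fl_type = fl_type, fl_rate = fl_rate, fl_km = fl_km, fl_ki = fl_ki,
    fl_sub = as.integer(fl_sub), fl_has_inh = fl_has_inh,
    fl_inh = as.integer(fl_inh), fl_fptr = as.integer(fl_fptr),
    ff_src = as.integer(ff_src), ff_exp = ff_exp,
    fl_optr = as.integer(fl_optr), fo_node = fo_node, fo_coef = fo_coef
  )
  list(comp = comp, par_names = par_table$name, par_table = par_table,
       dyn_ids = dyn_ids, input_ids = inp_ids, network_name = network$name)
}

# Align user-supplied parameters (named vector or table) to the compiled order.
align_params <- function(params, par_names) {
  if (is.data.frame(params)) {
    params <- stats::setNames(params$value, params$name)
  }
  if (any(!is.finite(params))) stop("non-finite parameter value(s)")
  miss <- setdiff(par_names, names(params))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  unname(params[par_names])
}

# Clamped input levels for a condition (named vector/list or roster row).
condition_inputs <- function(compiled, condition = NULL) {
  u <- stats::setNames(rep(0, length(compiled$input_ids)), compiled$input_ids)
  if (!is.null(condition)) {
    if (is.data.frame(condition)) {
      condition <- unlist(condition[1, intersect(names(condition),
                                                 compiled$input_ids),
                                    drop = FALSE])
    }
    condition <- condition[names(condition) %in% compiled$input_ids]
    if (any(condition < 0 | condition > 1)) {
      stop("condition input levels must lie in [0,1]")
    }
    u[names(condition)] <- as.numeric(condition)
  }
  u
}

#' Initial state of a network
#'
#' Default starting level is the node's declared `initial_level` (0.5 for most
#' nodes, 0 for intracellular drug nodes, which are absent before treatment).
#'
#' @param network A `pkn` object.
#' @return Named numeric vector over dynamic nodes.
#' @export
initial_state <- function(network) {
  dyn <- network$nodes$dynamic
  stats::setNames(network$nodes$initial_level[dyn], network$nodes$id[dyn])
}

#' Build the derivative function of a compiled network
#'
#' Returns `f(x, condition)` evaluating the hybrid right-hand side at a state
#' vector: relaxation dynamics `tau * (B - x)` for Hill-regulated nodes and the
#' explicit metabolic rate laws (zero-order source, mass-action condensation
#' and synthesis, Michaelis-Menten flux under competitive inhibition, linear
#' drains) for the metabolite nodes.
#'
#' @param network A `pkn` object (or the result of [compile_network()]).
#' @param params Named parameter vector or parameter table; an error names any
#'   missing parameter.
#' @return Function `(x, condition = NULL) -> named derivative vector`.
#' @export
build_rhs <- function(network, params) {
  compiled <- if (inherits(network, "pkn")) compile_network(network) else network
  pv <- align_params(params, compiled$par_names)
  function(x, condition = NULL) {
    u <- condition_inputs(compiled, condition)
    xv <- align_state(x, compiled$dyn_ids)
    stats::setNames(rhs_network_cpp(compiled$comp, pv, u, xv), compiled$dyn_ids)
  }
}

align_state <- function(x, dyn_ids) {
  if (!is.null(names(x))) {
    miss <- setdiff(dyn_ids, names(x))
    if (length(miss)) stop("state lacks node(s): ", paste(miss, collapse = ", "))
    x <- x[dyn_ids]
  } else if (length(x) != length(dyn_ids)) {
    stop("state length ", length(x), " != ", length(dyn_ids), " dynamic nodes")
  }
  as.numeric(x)
}

#' Simulate a network condition to quasi-steady state
#'
#' Integrates the hybrid ODE system from the default initial levels with
#' clamped inputs set by the condition. Two integration routes are available:
#' the package's adaptive embedded Runge-Kutta 5(4) core (`dopri`, default)
#' and `deSolve::lsoda` (`lsoda`), a stiff-capable cross-check sharing the
#' same compiled right-hand side. State-bound guards keep regulatory states in
#' \[0,1\] and metabolite states non-negative.
#'
#' @param network A `pkn` object or a [compile_network()] result.
#' @param params Named parameter vector or parameter table.
#' @param condition Named input levels (or roster row); unlisted inputs are 0.
#' @param end_time Simulation horizon in model time units (default 100, the
#'   48-h-class horizon; 150 is used for 72-h-class siRNA conditions).
#' @param times Optional explicit output grid (overrides `end_time`).
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param ss_tol Steady-state residual tolerance on `max |dx/dt|` at the
#'   final time.
#' @param method `"dopri"` or `"lsoda"`.
#' @param x0 Optional named initial state overriding the defaults.
#' @return A `sim_result` list: `times`, `states` (time x node matrix),
#'   `terminal`, `converged`, `max_residual`.
#' @export
simulate_network <- function(network, params, condition = NULL, end_time = 100,
                             times = NULL, rtol = 1e-6, atol = 1e-8,
                             ss_tol = 1e-6, method = c("dopri", "lsoda"),
                             x0 = NULL) {
  method <- match.arg(method)
  compiled <- if (inherits(network, "pkn")) compile_network(network) else network
  pv <- align_params(params, compiled$par_names)
  u <- condition_inputs(compiled, condition)
  if (is.data.frame(condition) && "end_time" %in% names(condition) &&
      missing(end_time)) {
    end_time <- condition$end_time[1]
  }
  if (is.null(times)) {
    stopifnot(end_time > 0)
    times <- seq(0, end_time, length.out = 41L)
  }
  if (is.null(x0)) {
    x0 <- if (inherits(network, "pkn")) initial_state(network) else
      stop("x0 required when simulating from a compiled network")
  }
  xv <- align_state(x0, compiled$dyn_ids)

  if (method == "dopri") {
    res <- sim_network_cpp(compiled$comp, pv, u, xv, times, rtol, atol,
                           max_steps = 200000L)
    if (!res$ok) stop("integration failure (step limit or non-finite state)")
    states <- res$states
    final_deriv <- res$final_deriv
  } else {
    fn <- function(t, y, parms) {
      list(rhs_network_cpp(compiled$comp, pv, u, y))
    }
    sol <- deSolve::lsoda(y = xv, times = times, func = fn, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) stop("lsoda integration failure")
    states <- unname(sol[, -1, drop = FALSE])
    final_deriv <- rhs_network_cpp(compiled$comp, pv, u,
                                   states[nrow(states), ])
  }
  if (any(!is.finite(states))) stop("non-finite state in simulation output")
  dimnames(states) <- list(NULL, compiled$dyn_ids)
  structure(list(
    times = times, states = states,
    terminal = stats::setNames(states[nrow(states), ], compiled$dyn_ids),
    converged = max(abs(final_deriv)) < ss_tol,
    max_residual = max(abs(final_deriv)), method = method
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation over [%g, %g], %d nodes; converged: %s (max |dx/dt| = %.3g)\n",
              min(x$times), max(x$times), ncol(x$states),
              x$converged, x$max_residual))
  invisible(x)
}

#' Cholesterol flux summaries from terminal states
#'
#' Computes, per condition, the cholesterol uptake flux
#' `k6 * CholMedia * LDLR * NPC1`, the synthesis flux `k5 * Mevalonate`, and
#' the uptake fraction `uptake / (uptake + synthesis)`. A zero total flux
#' yields an undefined-fraction flag rather than an error.
#'
#' @param terminal_states Named numeric vector (single condition) or a matrix
#'   / data frame with one row per condition and node columns.
#' @param params Named parameter vector or table providing `k5` and `k6`.
#' @return Data frame with columns `condition`, `uptake`, `synthesis`,
#'   `fraction`, `fraction_defined`.
#' @export
flux_summaries <- function(terminal_states, params) {
  if (is.data.frame(params)) params <- stats::setNames(params$value, params$name)
  if (is.numeric(terminal_states) && is.null(dim(terminal_states))) {
    terminal_states <- matrix(terminal_states, nrow = 1,
                              dimnames = list("condition",
                                              names(terminal_states)))
  }
  ts <- as.matrix(terminal_states)
  need <- c("CholMedia", "LDLR", "NPC1", "Mevalonate")
  miss <- setdiff(need, colnames(ts))
  if (length(miss)) stop("terminal states lack node(s): ",
                         paste(miss, collapse = ", "))
  uptake <- params[["k6"]] * ts[, "CholMedia"] * ts[, "LDLR"] * ts[, "NPC1"]
  synthesis <- params[["k5"]] * ts[, "Mevalonate"]
  total <- uptake + synthesis
  frac <- ifelse(total > 0, uptake / total, NA_real_)
  data.frame(
    condition = if (is.null(rownames(ts))) as.character(seq_len(nrow(ts))) else
      rownames(ts),
    uptake = unname(uptake), synthesis = unname(synthesis),
    fraction = unname(frac), fraction_defined = unname(total > 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Relative change of a flux between two conditions
#'
#' @param flux Data frame from [flux_summaries()].
#' @param treated,control Condition names.
#' @param quantity Column to compare (default `uptake`).
#' @return Relative change `(treated - control) / control`.
#' @export
relative_flux_change <- function(flux, treated, control, quantity = "uptake") {
  a <- flux[[quantity]][match(treated, flux$condition)]
  b <- flux[[quantity]][match(control, flux$condition)]
  if (anyNA(c(a, b))) stop("condition not found in flux table")
  if (b == 0) stop("control flux is zero; relative change undefined")
  (a - b) / b
}
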