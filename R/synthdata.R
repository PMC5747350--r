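#' Draw a convergent ground-truth parameter set
#'
#' Samples the free parameters uniformly within their shared bounds (fixed
#' parameters keep their values) and accepts the draw only if the untreated
#' condition integrates to a quasi-steady state; otherwise it resamples, up
#' to `max_tries` times. Deterministic given `seed`.
#'
#' @param network A `pkn` object.
#' @param seed Integer seed.
#' @param conditions Condition roster supplying the untreated condition
#'   (defaults to all inputs at zero).
#' @param par_table Parameter table with bounds (default
#'   [default_parameters()]).
#' @param ss_tol Quasi-steady-state residual tolerance for acceptance.
#' @param max_tries Retry limit (default 100).
#' @param sampler `uniform` draws every free parameter uniformly within its
#'   bounds; `log_uniform` draws the positive rate/time constants
#'   log-uniformly over the central decade of their bounds (Hill parameters
#'   stay uniform), which favors balanced metabolic fluxes on larger
#'   networks.
#' @param min_peak Informativeness filter: every measured node must reach at
#'   least this level somewhere in the design.
#' @param min_spread,spread_frac At least `spread_frac` of the measured
#'   nodes must move by `min_spread` across the design.
#' @return A `ground_truth` list: `params` (named vector), `par_table`,
#'   `seed`.
#' @export
generate_ground_truth <- function(network, seed, conditions = NULL,
                                  par_table = NULL, ss_tol = 1e-3,
                                  max_tries = 100,
                                  sampler = c("uniform", "log_uniform"),
                                  min_peak = 0.15, min_spread = 0.1,
                                  spread_frac = 0.5) {
  sampler <- match.arg(sampler)
  compiled <- compile_network(network)
  if (is.null(par_table)) par_table <- compiled$par_table
  stopifnot(identical(par_table$name, compiled$par_names))
  free <- !par_table$fixed
  meas <- measured_nodes(network)
  set.seed(seed)
  x0 <- initial_state(network)
  is_hill <- grepl("^[kn]_", par_table$name)
  for (i in seq_len(max_tries)) {
    pv <- par_table$value
    if (sampler == "uniform") {
      pv[free] <- stats::runif(sum(free), par_table$lower[free],
                               par_table$upper[free])
    } else {
      for (ix in which(free)) {
        lo <- par_table$lower[ix]
        hi <- par_table$upper[ix]
        pv[ix] <- if (is_hill[ix]) stats::runif(1, lo, hi) else
          exp(stats::runif(1, log(max(lo, 0.1)), log(min(hi, 2))))
      }
    }
    names(pv) <- par_table$name
    ok <- TRUE
    if (is.null(conditions)) {
      sim <- tryCatch(simulate_network(compiled, pv, NULL, end_time = 100,
                                       ss_tol = ss_tol, x0 = x0),
                      error = function(e) NULL)
      ok <- !is.null(sim) && sim$converged
    } else {
      # accept only draws for which every roster condition integrates, the
      # untreated condition converges, measured states stay on the [0,1]
      # data scale, and the emitted data are informative: every measured
      # node must reach a visible level somewhere in the design and the
      # design must move a reasonable share of nodes (emulating scaled
      # perturbation-response data rather than an all-zero table)
      terms <- matrix(NA_real_, nrow(conditions), length(meas),
                      dimnames = list(conditions$condition, meas))
      for (j in seq_len(nrow(conditions))) {
        sim <- tryCatch(
          simulate_network(compiled, pv, conditions[j, , drop = FALSE],
                           end_time = conditions$end_time[j],
                           ss_tol = ss_tol, x0 = x0),
          error = function(e) NULL)
        if (is.null(sim) ||
            (conditions$untreated[j] && !sim$converged) ||
            any(sim$terminal[meas] > 1 + 1e-9)) {
          ok <- FALSE
          break
        }
        terms[j, ] <- sim$terminal[meas]
      }
      if (ok) {
        peak <- apply(terms, 2, max)
        spread <- apply(terms, 2, function(v) diff(range(v)))
        ok <- all(peak >= min_peak) && mean(spread >= min_spread) >= spread_frac
      }
    }
    if (ok) {
      return(structure(list(params = pv, par_table = par_table, seed = seed),
                       class = "ground_truth"))
    }
  }
  stop("no convergent parameter draw in ", max_tries, " tries")
}

#' Simulate a synthetic perturbation-response dataset
#'
#' Simulates every roster condition to its terminal state under the
#' ground-truth parameters and emits replicate measurements with
#' multiplicative log-normal noise at the configured coefficient of
#' variation (the mean-preserving parameterization, matching the error
#' structure of MS intensities). Technical replicates, generated for
#' metabolite-class analytes, add a smaller nested noise (CV/4). The
#' modeling dataset carries the noisy states directly (clipped to \[0,1\];
#' synthetic states are already on the model scale), while the accompanying
#' raw table multiplies them by class-specific amplitudes so the
#' class-scaling rules can be exercised on it.
#'
#' @param network A `pkn` object.
#' @param ground_truth A [generate_ground_truth()] result (or named
#'   parameter vector).
#' @param conditions Condition roster (default [default_conditions()] /
#'   [toy_conditions()] by network name).
#' @param cv Biological-replicate coefficient of variation (default 0.20,
#'   the replicate-CV level of the underlying study design).
#' @param bio_replicates Biological replicates per condition (default 3).
#' @param tech_replicates Technical replicates for metabolite-class analytes
#'   (default 2).
#' @param seed Measurement seed.
#' @param cell_line Cell-line label stored in the tables.
#' @param amplitudes Named raw-signal amplitudes per analyte class.
#' @return A `synth_dataset` list: `dataset` (a `scaled_dataset`), `raw`
#'   (raw-signal table for [scale_signals()]), `truth_states` (condition x
#'   node matrix), `ground_truth`, `seed`.
#' @export
simulate_dataset <- function(network, ground_truth, conditions = NULL,
                             cv = 0.20, bio_replicates = 3,
                             tech_replicates = 2, seed = 1,
                             cell_line = "cellline1",
                             amplitudes = c(protein = 1e5,
                                            endogenous_metabolite = 1e4,
                                            drug_or_drug_metabolite = 1e3)) {
  stopifnot(cv >= 0, bio_replicates >= 1)
  if (is.null(conditions)) {
    conditions <- if (network$name == "toy") toy_conditions() else
      default_conditions()
  }
  params <- if (inherits(ground_truth, "ground_truth")) ground_truth$params
            else ground_truth
  compiled <- compile_network(network)
  x0 <- initial_state(network)
  meas <- measured_nodes(network)
  cls <- analyte_class(network, meas)

  states <- matrix(NA_real_, nrow(conditions), length(compiled$dyn_ids),
                   dimnames = list(conditions$condition, compiled$dyn_ids))
  for (i in seq_len(nrow(conditions))) {
    sim <- tryCatch(
      simulate_network(compiled, params, conditions[i, , drop = FALSE],
                       end_time = conditions$end_time[i], x0 = x0),
      error = function(e) stop("simulation failed for condition '",
                               conditions$condition[i], "': ",
                               conditionMessage(e)))
    states[i, ] <- sim$terminal
  }

  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  sdlog_tech <- sqrt(log(1 + (cv / 4)^2))
  grid <- expand.grid(replicate = seq_len(bio_replicates), node = meas,
                      condition = conditions$condition,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- states[cbind(grid$condition, grid$node)]
  bio <- if (cv > 0) {
    mu * stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else mu
  meas_tab <- data.frame(
    cell_line = cell_line, node = grid$node, condition = grid$condition,
    replicate = grid$replicate,
    time = conditions$end_time[match(grid$condition, conditions$condition)],
    value = pmin(pmax(bio, 0), 1), weight = 1, differential = FALSE,
    pseudo = FALSE, stringsAsFactors = FALSE)

  ntech <- ifelse(cls[grid$node] == "protein", 1L, as.integer(tech_replicates))
  ridx <- rep(seq_len(nrow(grid)), ntech)
  tech_rep <- sequence(ntech)
  tech <- bio[ridx]
  multi <- ntech[ridx] > 1
  if (cv > 0 && any(multi)) {
    tech[multi] <- tech[multi] * stats::rlnorm(sum(multi),
                                               meanlog = -sdlog_tech^2 / 2,
                                               sdlog = sdlog_tech)
  }
  raw <- data.frame(
    analyte = grid$node[ridx], class = unname(cls[grid$node[ridx]]),
    cell_line = cell_line, condition = grid$condition[ridx],
    bio_rep = grid$replicate[ridx], tech_rep = tech_rep,
    signal = pmax(tech, 0) * amplitudes[cls[grid$node[ridx]]],
    stringsAsFactors = FALSE)
  rownames(raw) <- NULL

  ds <- scaled_dataset(meas_tab, conditions)
  structure(list(dataset = ds, raw = raw, truth_states = states,
                 ground_truth = ground_truth, seed = seed),
            class = "synth_dataset")
}

# Map node categories to raw-measurement analyte classes.
analyte_class <- function(network, nodes) {
  cat <- network$nodes$category[match(nodes, network$nodes$id)]
  stats::setNames(ifelse(cat %in% c("protein", "activity"), "protein",
                  ifelse(cat == "drug_intracellular",
                         "drug_or_drug_metabolite", "endogenous_metabolite")),
                  nodes)
}

#' Planted-divergence scenario across cell lines
#'
#' Constructs per-cell-line ground truths that are identical except for the
#' designated parameter shifts, then simulates a dataset per line - the
#' known-answer input for divergence-detection power experiments (mirroring
#' the cross-cell-line comparison of functional interactions).
#'
#' @param network A `pkn` object.
#' @param base_truth A [generate_ground_truth()] result.
#' @param shifts Data frame with columns `parameter`, `line` (2..n_lines)
#'   and `shift` (added to the base value; must stay within bounds). Zero
#'   rows plant nothing.
#' @param n_lines Number of cell lines (default 4).
#' @param conditions,cv,bio_replicates,tech_replicates,seed Passed to
#'   [simulate_dataset()]; per-line measurement seeds derive from `seed`.
#' @return List with `truths` (per line) and `datasets` (per line).
#' @export
make_divergence_scenario <- function(network, base_truth, shifts = NULL,
                                     n_lines = 4, conditions = NULL,
                                     cv = 0.20, bio_replicates = 3,
                                     tech_replicates = 2, seed = 1) {
  tab <- base_truth$par_table
  lines <- paste0("cellline", seq_len(n_lines))
  truths <- lapply(seq_len(n_lines), function(i) {
    pv <- base_truth$params
    if (!is.null(shifts) && nrow(shifts)) {
      for (j in which(shifts$line == i)) {
        pn <- shifts$parameter[j]
        ix <- match(pn, tab$name)
        if (is.na(ix)) stop("unknown parameter in shifts: ", pn)
        val <- pv[[pn]] + shifts$shift[j]
        if (val < tab$lower[ix] || val > tab$upper[ix]) {
          stop("shift pushes '", pn, "' out of bounds")
        }
        pv[[pn]] <- val
      }
    }
    structure(list(params = pv, par_table = tab, seed = base_truth$seed),
              class = "ground_truth")
  })
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_lines)
  datasets <- lapply(seq_len(n_lines), function(i) {
    simulate_dataset(network, truths[[i]], conditions = conditions, cv = cv,
                     bio_replicates = bio_replicates,
                     tech_replicates = tech_replicates, seed = seeds[i],
                     cell_line = lines[i])
  })
  names(truths) <- names(datasets) <- lines
  list(truths = truths, datasets = datasets)
}

#' Sample a parameter ensemble around a ground truth
#'
#' Draws `n` parameter sets from independent normal distributions centered
#' on the ground-truth values (free parameters only), clipped to the shared
#' bounds - a cheap stand-in for a fitted ensemble with a known dispersion,
#' used in divergence-detection calibration.
#'
#' @param truth A `ground_truth` (or named parameter vector plus
#'   `par_table`).
#' @param n Ensemble size.
#' @param sd Standard deviation of the draws (scalar or named per
#'   parameter).
#' @param seed Integer seed.
#' @param cell_line Label for the resulting ensemble.
#' @param par_table Required when `truth` is a bare vector.
#' @return An `ensemble` object (without fit results).
#' @export
sample_parameter_ensemble <- function(truth, n = 100, sd = 0.02, seed = 1,
                                      cell_line = "cellline1",
                                      par_table = NULL) {
  if (inherits(truth, "ground_truth")) {
    par_table <- truth$par_table
    pv <- truth$params
  } else {
    if (is.null(par_table)) stop("par_table required for bare truth vector")
    pv <- truth
  }
  free <- par_table$name[!par_table$fixed]
  sdv <- if (length(sd) == 1) stats::setNames(rep(sd, length(free)), free) else
    sd[free]
  set.seed(seed)
  params <- sapply(free, function(pn) {
    ix <- match(pn, par_table$name)
    pmin(pmax(stats::rnorm(n, pv[[pn]], sdv[[pn]]), par_table$lower[ix]),
         par_table$upper[ix])
  })
  structure(list(cell_line = cell_line, fits = list(), parameters = params,
                 par_table = par_table, seeds = seed, base_seed = seed),
            class = "ensemble")
}

#' Generate a synthetic identification table
#'
#' Seeded toy target/decoy identification records in the shape consumed by
#' the MS post-processing statistics: per-run m-scores with controllable
#' pass rates, log-normal intensities, retention times, proteotypic flags
#' and condition/replicate labels.
#'
#' @param seed Integer seed.
#' @param n_target,n_decoy Numbers of target and decoy precursors.
#' @param n_runs Number of runs/files.
#' @param target_pass_prob Probability a target precursor passes the
#'   confidence threshold in a given run.
#' @param decoy_pass_prob Same for decoys.
#' @param m_threshold The m-score threshold the pass probabilities refer to.
#' @param n_conditions Conditions cycled across runs.
#' @return Data frame with one row per (precursor, run).
#' @export
generate_id_table <- function(seed, n_target = 100, n_decoy = 5, n_runs = 6,
                              target_pass_prob = 0.8, decoy_pass_prob = 0.05,
                              m_threshold = 1e-5, n_conditions = 2) {
  stopifnot(n_target >= 0, n_decoy >= 0, n_runs >= 1)
  set.seed(seed)
  prec <- data.frame(
    precursor = c(sprintf("pep%04d", seq_len(n_target)),
                  sprintf("DECOY_pep%04d", seq_len(n_decoy))),
    protein = c(sprintf("prot%03d", 1 + (seq_len(n_target) - 1) %/% 10),
                sprintf("DECOY_prot%03d", 1 + (seq_len(n_decoy) - 1) %/% 10)),
    is_decoy = rep(c(FALSE, TRUE), c(n_target, n_decoy)),
    proteotypic = c(stats::runif(n_target) < 0.8, rep(FALSE, n_decoy)),
    base_intensity = stats::rlnorm(n_target + n_decoy, 10, 1),
    rt = stats::runif(n_target + n_decoy, 0, 3600),
    pass_prob = rep(c(target_pass_prob, decoy_pass_prob),
                    c(n_target, n_decoy)),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(n_runs), function(r) {
    pass <- stats::runif(nrow(prec)) < prec$pass_prob
    m <- ifelse(pass,
                m_threshold * stats::runif(nrow(prec)),
                exp(stats::runif(nrow(prec), log(m_threshold * 10), log(1))))
    data.frame(
      precursor = prec$precursor, protein = prec$protein,
      is_decoy = prec$is_decoy, proteotypic = prec$proteotypic,
      m_score = pmin(m, 1), run = sprintf("run%02d", r),
      condition = sprintf("cond%d", 1 + (r - 1) %% n_conditions),
      bio_rep = 1 + (r - 1) %/% n_conditions,
      intensity = prec$base_intensity *
        stats::rlnorm(nrow(prec), -0.02, 0.2),
      rt = pmin(pmax(prec$rt + stats::rnorm(nrow(prec), 0, 15), 0), 3600),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
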