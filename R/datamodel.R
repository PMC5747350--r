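#' Construct a scaled measurement dataset
#'
#' The container behind MIDAS-backed modeling data: replicate-level scaled
#' values in \[0,1\] per (cell line, measured node, condition), with per-row
#' weights, differential flags and pseudo-timepoint markers, plus the
#' condition roster (input levels and simulation horizon per condition).
#'
#' @param measurements Data frame with columns `cell_line`, `node`,
#'   `condition`, `replicate`, `time`, `value`, `weight`, `differential`,
#'   `pseudo`.
#' @param conditions Condition roster: `condition`, `end_time`, `untreated`
#'   flag and one column per clamped input node.
#' @return An object of class `scaled_dataset`.
#' @export
scaled_dataset <- function(measurements, conditions) {
  need <- c("cell_line", "node", "condition", "replicate", "time", "value",
            "weight", "differential", "pseudo")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("measurements lack column(s): ",
                         paste(miss, collapse = ", "))
  ok <- is.na(measurements$value) |
    (measurements$value >= 0 & measurements$value <= 1)
  if (!all(ok)) stop("scaled values must lie in [0,1]")
  if (any(measurements$weight < 0)) stop("weights must be >= 0")
  if (!all(c("condition", "end_time") %in% names(conditions))) {
    stop("conditions must have 'condition' and 'end_time' columns")
  }
  unknown <- setdiff(unique(measurements$condition), conditions$condition)
  if (length(unknown)) stop("measurement condition(s) not in roster: ",
                            paste(unknown, collapse = ", "))
  structure(list(measurements = measurements, conditions = conditions),
            class = "scaled_dataset")
}

#' @export
print.scaled_dataset <- function(x, ...) {
  m <- x$measurements
  cat(sprintf(
    "Scaled dataset: %d data points (%d pseudo), %d nodes, %d conditions, %d cell line(s)\n",
    nrow(m), sum(m$pseudo), length(unique(m$node)),
    length(unique(m$condition)), length(unique(m$cell_line))))
  invisible(x)
}

#' Number of data points in a dataset
#' @param dataset A `scaled_dataset`.
#' @param include_pseudo Count pseudo-timepoints too (default `FALSE`).
#' @return Integer count.
#' @export
n_datapoints <- function(dataset, include_pseudo = FALSE) {
  m <- dataset$measurements
  if (include_pseudo) nrow(m) else sum(!m$pseudo)
}

#' Scale raw signals to the unit interval by analyte class
#'
#' Applies the class-specific scaling rules over the total observed range
#' across all cell lines and conditions, preserving inter-cell-line
#' differences: proteins are min-max scaled over the global range; drugs and
#' drug metabolites are min-max scaled (removing the signal offset);
#' endogenous metabolites are scaled between 0 and the global maximum (so
#' small steady-state variation is not inflated). Outputs are clipped to
#' \[0,1\]. A constant analyte under a min-max rule is flagged and assigned
#' 0.5 with zero weight. Technical replicates, where present, are averaged
#' into their biological replicate after scaling.
#'
#' @param raw Data frame with columns `analyte`, `class` (one of `protein`,
#'   `endogenous_metabolite`, `drug_or_drug_metabolite`), `cell_line`,
#'   `condition`, `bio_rep`, optional `tech_rep`, `signal` (non-negative).
#' @param conditions Condition roster for the resulting dataset; a minimal
#'   roster is derived from the data when omitted.
#' @return A `scaled_dataset`; degenerate analytes are listed in
#'   `attr(, "degenerate")`.
#' @export
scale_signals <- function(raw, conditions = NULL) {
  need <- c("analyte", "class", "cell_line", "condition", "bio_rep", "signal")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("raw table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(raw$signal < 0)) stop("signals must be non-negative")
  bad <- setdiff(unique(raw$class),
                 c("protein", "endogenous_metabolite", "drug_or_drug_metabolite"))
  if (length(bad)) stop("unknown analyte class(es): ", paste(bad, collapse = ", "))

  raw$scaled <- NA_real_
  raw$w <- 1
  degenerate <- character(0)
  for (a in unique(raw$analyte)) {
    idx <- raw$analyte == a
    x <- raw$signal[idx]
    cls <- raw$class[idx][1]
    if (cls == "endogenous_metabolite") {
      hi <- max(x)
      if (hi <= 0) {
        raw$scaled[idx] <- 0.5; raw$w[idx] <- 0
        degenerate <- c(degenerate, a)
        next
      }
      raw$scaled[idx] <- x / hi
    } else {
      lo <- min(x); hi <- max(x)
      if (hi == lo) {
        raw$scaled[idx] <- 0.5; raw$w[idx] <- 0
        degenerate <- c(degenerate, a)
        next
      }
      raw$scaled[idx] <- (x - lo) / (hi - lo)
    }
  }
  raw$scaled <- pmin(pmax(raw$scaled, 0), 1)

  # collapse technical replicates into biological replicates
  key <- interaction(raw$analyte, raw$cell_line, raw$condition, raw$bio_rep,
                     drop = TRUE)
  agg <- data.frame(
    cell_line = tapply(raw$cell_line, key, `[`, 1),
    node = tapply(raw$analyte, key, `[`, 1),
    condition = tapply(raw$condition, key, `[`, 1),
    replicate = tapply(raw$bio_rep, key, `[`, 1),
    value = as.numeric(tapply(raw$scaled, key, mean)),
    weight = as.numeric(tapply(raw$w, key, min)),
    stringsAsFactors = FALSE
  )
  rownames(agg) <- NULL
  if (is.null(conditions)) {
    conditions <- data.frame(condition = sort(unique(agg$condition)),
                             end_time = 100,
                             untreated = sort(unique(agg$condition)) == "untreated",
                             stringsAsFactors = FALSE)
  }
  agg$time <- conditions$end_time[match(agg$condition, conditions$condition)]
  agg$differential <- FALSE
  agg$pseudo <- FALSE
  ds <- scaled_dataset(agg[, c("cell_line", "node", "condition", "replicate",
                               "time", "value", "weight", "differential",
                               "pseudo")], conditions)
  attr(ds, "degenerate") <- degenerate
  ds
}

#' Write a dataset in MIDAS format
#'
#' Columns use the MIDAS prefixes: `ID:` identifiers (cell line, condition,
#' replicate), `TR:` treatment/input levels, `DA:ALL` acquisition time and
#' `DV:<node>` data values, one row per (cell line, condition, replicate).
#' Pseudo-timepoints are a derived augmentation and are not serialized.
#'
#' @param dataset A `scaled_dataset`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_midas <- function(dataset, path) {
  m <- dataset$measurements[!dataset$measurements$pseudo, , drop = FALSE]
  cond <- dataset$conditions
  input_cols <- setdiff(names(cond), c("condition", "end_time", "untreated",
                                       "class"))
  nodes <- sort(unique(m$node))
  key <- interaction(m$cell_line, m$condition, m$replicate, drop = TRUE)
  rows <- lapply(split(m, key), function(g) {
    ci <- match(g$condition[1], cond$condition)
    vals <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
    vals[g$node] <- g$value
    cbind(
      data.frame(`ID:CellLine` = g$cell_line[1], `ID:Condition` = g$condition[1],
                 `ID:BioRep` = g$replicate[1], check.names = FALSE),
      stats::setNames(as.data.frame(as.list(
        vapply(input_cols, function(ic) as.numeric(cond[[ic]][ci]),
               numeric(1)))), paste0("TR:", input_cols)),
      data.frame(`DA:ALL` = g$time[1], check.names = FALSE),
      stats::setNames(as.data.frame(as.list(vals)), paste0("DV:", nodes))
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$`ID:CellLine`, out$`ID:Condition`, out$`ID:BioRep`), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from MIDAS format
#'
#' Inverse of [write_midas()]: reconstructs the measurement table and the
#' condition roster (input levels from `TR:` columns, horizon from `DA:ALL`).
#' Weights and differential flags are re-derivable via [flag_differential()]
#' and [augment_dataset()] and default to 1 / `FALSE` on read.
#'
#' @param path MIDAS CSV path.
#' @param untreated Name of the untreated reference condition (default
#'   `"untreated"` when present).
#' @return A `scaled_dataset`.
#' @export
read_midas <- function(path, untreated = "untreated") {
  tab <- utils::read.csv(path, check.names = FALSE)
  cn <- names(tab)
  dv <- grep("^DV:", cn, value = TRUE)
  tr <- grep("^TR:", cn, value = TRUE)
  da <- grep("^DA:", cn, value = TRUE)
  if (!length(dv)) stop("MIDAS parse error: no DV: columns in ", path)
  if (!length(da)) stop("MIDAS parse error: no DA: columns in ", path)
  if (!length(tr)) stop("MIDAS parse error: no TR: columns in ", path)
  cell <- if ("ID:CellLine" %in% cn) tab$`ID:CellLine` else "cellline1"
  condid <- if ("ID:Condition" %in% cn) tab$`ID:Condition` else
    apply(tab[, tr, drop = FALSE], 1, paste, collapse = "_")
  rep_ <- if ("ID:BioRep" %in% cn) tab$`ID:BioRep` else
    stats::ave(seq_len(nrow(tab)), cell, condid, FUN = seq_along)

  rows <- lapply(seq_len(nrow(tab)), function(i) {
    vals <- as.numeric(tab[i, dv])
    keep <- !is.na(vals)
    if (!any(keep)) return(NULL)
    data.frame(cell_line = cell[i], node = sub("^DV:", "", dv)[keep],
               condition = condid[i], replicate = rep_[i],
               time = as.numeric(tab[i, da[1]]), value = vals[keep],
               weight = 1, differential = FALSE, pseudo = FALSE,
               stringsAsFactors = FALSE)
  })
  meas <- do.call(rbind, rows)

  uc <- !duplicated(condid)
  conditions <- cbind(
    data.frame(condition = condid[uc],
               end_time = as.numeric(tab[uc, da[1]]),
               untreated = condid[uc] == untreated, stringsAsFactors = FALSE),
    stats::setNames(tab[uc, tr, drop = FALSE], sub("^TR:", "", tr))
  )
  rownames(conditions) <- NULL
  scaled_dataset(meas, conditions)
}

#' Pseudo-timepoints between baseline and final level
#'
#' Interpolates three anchor levels at 0.5, 0.8 and 0.9 of the total
#' difference between the baseline and the final (terminal) level. Attached
#' between the last measured time point and the baseline, these
#' reduced-weight points penalize biologically unexpected oscillatory
#' trajectories during fitting.
#'
#' @param baseline,final Levels in \[0,1\].
#' @param fractions Interpolation fractions (default `c(0.5, 0.8, 0.9)`).
#' @param weight Weight the pseudo-points carry (must stay below the
#'   measured-data weight; default 0.5).
#' @return Numeric vector of levels with a `"weight"` attribute.
#' @export
augment_pseudo_timepoints <- function(baseline, final,
                                      fractions = c(0.5, 0.8, 0.9),
                                      weight = 0.5) {
  stopifnot(baseline >= 0, baseline <= 1, final >= 0, final <= 1)
  structure(baseline + fractions * (final - baseline), weight = weight)
}

#' Flag differentially abundant (node, condition) cells and raise their weight
#'
#' Measured nodes whose condition mean deviates from the untreated mean by
#' more than `threshold` scaled units are flagged differential and their
#' measurements get the higher weight.
#'
#' @param dataset A `scaled_dataset`.
#' @param threshold Absolute deviation on the \[0,1\] scale (default 0.1).
#' @param weight Weight assigned to differential measurements (default 2).
#' @return The dataset with updated `differential` and `weight` columns.
#' @export
flag_differential <- function(dataset, threshold = 0.1, weight = 2) {
  m <- dataset$measurements
  untreated <- dataset$conditions$condition[dataset$conditions$untreated][1]
  if (is.na(untreated)) stop("no untreated condition in roster")
  base <- m[m$condition == untreated & !m$pseudo, ]
  bmean <- tapply(base$value, interaction(base$cell_line, base$node, drop = TRUE),
                  mean)
  key <- interaction(m$cell_line, m$node, m$condition, drop = TRUE)
  cmean <- stats::ave(m$value, key, FUN = mean)
  b <- bmean[paste(m$cell_line, m$node, sep = ".")]
  diffs <- !is.na(b) & abs(cmean - b) > threshold & !m$pseudo &
    m$condition != untreated
  m$differential <- as.logical(diffs)
  m$weight[diffs & m$weight > 0] <- weight
  dataset$measurements <- m
  dataset
}

#' Augment a dataset with pseudo-timepoints
#'
#' For every measured (cell line, node, condition) cell, adds the three
#' pseudo-timepoints of [augment_pseudo_timepoints()] at interior grid times
#' (fractions 1/4, 1/2 and 3/4 of the condition horizon), interpolating from
#' the untreated baseline mean toward the condition mean.
#'
#' @param dataset A `scaled_dataset`.
#' @param weight Pseudo-point weight (default 0.5, below the measured-data
#'   weight).
#' @param time_fractions Horizon fractions at which the points are placed.
#' @return The dataset with pseudo rows appended.
#' @export
augment_dataset <- function(dataset, weight = 0.5,
                            time_fractions = c(0.25, 0.5, 0.75)) {
  m <- dataset$measurements[!dataset$measurements$pseudo, , drop = FALSE]
  cond <- dataset$conditions
  untreated <- cond$condition[cond$untreated][1]
  if (is.na(untreated)) stop("no untreated condition in roster")
  base <- m[m$condition == untreated, ]
  bmean <- tapply(base$value, interaction(base$cell_line, base$node, drop = TRUE),
                  mean)
  key <- interaction(m$cell_line, m$node, m$condition, drop = TRUE)
  cells <- m[!duplicated(key), c("cell_line", "node", "condition")]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells$cell_line[i]; nd <- cells$node[i]; cd <- cells$condition[i]
    b <- bmean[paste(cl, nd, sep = ".")]
    if (is.na(b)) return(NULL)
    fm <- mean(m$value[m$cell_line == cl & m$node == nd & m$condition == cd])
    lv <- augment_pseudo_timepoints(b, fm, weight = weight)
    et <- cond$end_time[match(cd, cond$condition)]
    data.frame(cell_line = cl, node = nd, condition = cd, replicate = NA,
               time = time_fractions * et, value = as.numeric(lv),
               weight = weight, differential = FALSE, pseudo = TRUE,
               stringsAsFactors = FALSE)
  })
  dataset$measurements <- rbind(m, do.call(rbind, rows))
  dataset
}
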