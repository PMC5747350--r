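#' @useDynLib cholode, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Node categories whose levels are clamped experimental inputs (never integrated).
INPUT_CATEGORIES <- c("stimulus", "knockdown_input", "drug_extracellular")

# Categories counted as metabolite species and eligible as mass-action targets.
METABOLITE_CATEGORIES <- c(
  "metabolite_intracellular", "metabolite_extracellular", "drug_intracellular"
)

NODE_CATEGORIES <- c(
  "protein", "activity", "metabolite_intracellular", "metabolite_extracellular",
  "drug_extracellular", "drug_intracellular", "stimulus", "knockdown_input"
)

EDGE_MECHANISMS <- c(
  "hill_regulatory", "mass_action", "michaelis_menten_inhibited", "uptake_product"
)

#' Construct a network node table
#'
#' Builds the node table of a prior-knowledge network. Each node carries a
#' category (protein, enzymatic activity, intra-/extracellular metabolite or
#' drug, stimulus, or knockdown input), a measured flag, an initial level on
#' the \[0,1\] scale and a dynamic flag. Input-category nodes (stimulus,
#' knockdown, extracellular drug) are clamped at their condition value and are
#' never integrated.
#'
#' @param id Character vector of unique node identifiers.
#' @param label Display names (defaults to `id`).
#' @param category One of the declared node categories, recycled.
#' @param species Metabolite species name shared by compartmental duplicates
#'   (e.g. ER and medium cholesterol); `NA` for non-metabolites.
#' @param measured Logical, was this node experimentally quantified.
#' @param initial_level Starting level in \[0,1\] (default 0.5).
#' @param dynamic Logical, is this node integrated (defaults to `TRUE` except
#'   for input categories).
#' @param source_param Name of a zero-order source-rate constant feeding this
#'   node (e.g. the acetyl-CoA supply), or `NA`.
#' @param source_scale Multiplier on the source constant (the acetyl-CoA
#'   supply enters as 0.5 times its rate constant).
#' @return A `data.frame` with one row per node.
#' @export
network_nodes <- function(id, label = id, category = "protein", species = NA_character_,
                          measured = FALSE, initial_level = 0.5,
                          dynamic = !(category %in% INPUT_CATEGORIES),
                          source_param = NA_character_, source_scale = 1) {
  n <- length(id)
  data.frame(
    id = as.character(id), label = rep_len(as.character(label), n),
    category = rep_len(as.character(category), n),
    species = rep_len(as.character(species), n),
    measured = rep_len(as.logical(measured), n),
    initial_level = rep_len(as.numeric(initial_level), n),
    dynamic = rep_len(as.logical(dynamic), n),
    source_param = rep_len(as.character(source_param), n),
    source_scale = rep_len(as.numeric(source_scale), n),
    stringsAsFactors = FALSE
  )
}

#' Construct a network edge
#'
#' An edge combines one or more signed sources conjunctively (an AND
#' hyperedge) onto a single target. The mechanism decides how the edge enters
#' the compiled ODE system: `hill_regulatory` edges contribute a normalized
#' Hill term to the target's input logic; `mass_action`, `uptake_product` and
#' `michaelis_menten_inhibited` edges contribute explicit metabolic fluxes.
#'
#' @param id Unique edge identifier.
#' @param sources Data frame with columns `node`, `sign` (+1/-1) and
#'   optionally `exponent` (mass-action stoichiometry, default 1), or a
#'   character vector of node ids (all activating, exponent 1).
#' @param target Target node id.
#' @param mechanism One of `hill_regulatory`, `mass_action`,
#'   `michaelis_menten_inhibited`, `uptake_product`.
#' @param fixed Logical; fixed edges keep their parameters out of optimization.
#' @param rate_param,km_param,ki_param Names of the rate, Michaelis and
#'   inhibition constants for metabolic mechanisms.
#' @param substrate Substrate node id for the Michaelis-Menten mechanism.
#' @param consumes Character vector of source node ids depleted by the flux.
#' @param fixed_k,fixed_n Values at which the Hill parameters of a fixed
#'   regulatory edge are pinned.
#' @return An object of class `pkn_edge`.
#' @export
network_edge <- function(id, sources, target, mechanism = "hill_regulatory",
                         fixed = FALSE, rate_param = NA_character_,
                         km_param = NA_character_, ki_param = NA_character_,
                         substrate = NA_character_, consumes = character(0),
                         fixed_k = 0.5, fixed_n = 2) {
  if (is.character(sources)) {
    sources <- data.frame(node = sources, sign = 1, exponent = 1,
                          stringsAsFactors = FALSE)
  }
  if (is.null(sources$exponent)) sources$exponent <- 1
  stopifnot(all(c("node", "sign") %in% names(sources)))
  structure(list(
    id = as.character(id), sources = sources, target = as.character(target),
    mechanism = as.character(mechanism), fixed = isTRUE(fixed),
    rate_param = rate_param, km_param = km_param, ki_param = ki_param,
    substrate = substrate, consumes = as.character(consumes),
    fixed_k = as.numeric(fixed_k), fixed_n = as.numeric(fixed_n)
  ), class = "pkn_edge")
}

#' Assemble a prior-knowledge network
#'
#' @param nodes Node table from [network_nodes()] (rows may be concatenated
#'   with `rbind`).
#' @param edges List of [network_edge()] objects.
#' @param name Network name.
#' @param check If `TRUE` (default), stop when [validate_network()] reports
#'   violations.
#' @return An object of class `pkn`.
#' @export
pkn <- function(nodes, edges, name = "network", check = TRUE) {
  names(edges) <- vapply(edges, `[[`, character(1), "id")
  net <- structure(list(name = name, nodes = nodes, edges = edges),
                   class = "pkn")
  if (check) {
    report <- validate_network(net)
    if (nrow(report) > 0) {
      stop("invalid network '", name, "':\n",
           paste(sprintf("- [%s] %s", report$rule, report$detail), collapse = "\n"))
    }
  }
  net
}

#' @export
print.pkn <- function(x, ...) {
  cts <- pkn_counts(x)
  cat(sprintf(
    "Prior-knowledge network '%s': %d nodes, %d edges\n  %d proteins, %d metabolite species, %d measured nodes, %d inputs\n",
    x$name, nrow(x$nodes), cts[["edges"]], cts[["proteins"]],
    cts[["metabolite_species"]], cts[["measured"]], length(input_nodes(x))
  ))
  invisible(x)
}

#' Node id accessors
#'
#' `input_nodes()` returns clamped input nodes, `dynamic_nodes()` the
#' integrated nodes, and `measured_nodes()` the experimentally quantified ones.
#'
#' @param network A `pkn` object.
#' @return Character vector of node ids.
#' @export
input_nodes <- function(network) network$nodes$id[!network$nodes$dynamic]

#' @rdname input_nodes
#' @export
dynamic_nodes <- function(network) network$nodes$id[network$nodes$dynamic]

#' @rdname input_nodes
#' @export
measured_nodes <- function(network) network$nodes$id[network$nodes$measured]

#' Summary counts of a network
#'
#' Counts edges, protein-category nodes, distinct metabolite species
#' (compartmental duplicates such as ER and medium cholesterol count once;
#' extracellular drug doses are inputs, not species) and measured nodes.
#'
#' @param network A `pkn` object.
#' @return Named integer vector.
#' @export
pkn_counts <- function(network) {
  nd <- network$nodes
  met <- nd$category %in% METABOLITE_CATEGORIES
  c(
    edges = length(network$edges),
    proteins = sum(nd$category == "protein"),
    metabolite_species = length(unique(nd$species[met & !is.na(nd$species)])),
    measured = sum(nd$measured)
  )
}

#' Validate a prior-knowledge network
#'
#' Checks identifier uniqueness, level ranges, category rules (inputs are
#' non-dynamic, measured implies dynamic, metabolic edges target metabolite
#' nodes, regulatory edges target dynamic non-input nodes), dangling edge
#' references, duplicated edges and reachability (every dynamic node must be
#' reachable from an input or from a node with a zero-order source term).
#'
#' @param network A `pkn` object.
#' @return A data frame with columns `rule` and `detail`; zero rows means the
#'   network is valid.
#' @export
validate_network <- function(network) {
  nd <- network$nodes
  ed <- network$edges
  bad <- list()
  flag <- function(rule, detail) bad[[length(bad) + 1L]] <<- data.frame(
    rule = rule, detail = detail, stringsAsFactors = FALSE)

  if (anyDuplicated(nd$id)) {
    flag("node_id_unique", paste("duplicated node id:",
         paste(unique(nd$id[duplicated(nd$id)]), collapse = ", ")))
  }
  off <- nd$id[!is.na(nd$initial_level) &
               (nd$initial_level < 0 | nd$initial_level > 1)]
  if (length(off)) flag("initial_level_range",
                        paste("initial level outside [0,1]:", paste(off, collapse = ", ")))
  unknown <- nd$id[!nd$category %in% NODE_CATEGORIES]
  if (length(unknown)) flag("node_category",
                            paste("unknown category for:", paste(unknown, collapse = ", ")))
  dyn_inputs <- nd$id[nd$category %in% INPUT_CATEGORIES & nd$dynamic]
  if (length(dyn_inputs)) flag("input_not_dynamic",
                               paste("input-category node marked dynamic:",
                                     paste(dyn_inputs, collapse = ", ")))
  meas_static <- nd$id[nd$measured & !nd$dynamic]
  if (length(meas_static)) flag("measured_implies_dynamic",
                                paste("measured but not dynamic:",
                                      paste(meas_static, collapse = ", ")))

  ids <- vapply(ed, `[[`, character(1), "id")
  if (anyDuplicated(ids)) flag("edge_id_unique",
                               paste("duplicated edge id:",
                                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (e in ed) {
    refs <- c(e$sources$node, e$target)
    miss <- setdiff(refs, nd$id)
    if (length(miss)) flag("edge_reference",
                           sprintf("edge '%s' references unknown node(s): %s",
                                   e$id, paste(miss, collapse = ", ")))
    if (!e$mechanism %in% EDGE_MECHANISMS) {
      flag("edge_mechanism", sprintf("edge '%s' has unknown mechanism '%s'",
                                     e$id, e$mechanism))
      next
    }
    tgt <- nd[match(e$target, nd$id), ]
    if (nrow(tgt) == 1 && !is.na(tgt$id)) {
      if (e$mechanism %in% c("mass_action", "michaelis_menten_inhibited",
                             "uptake_product") &&
          !tgt$category %in% METABOLITE_CATEGORIES) {
        flag("metabolic_target", sprintf(
          "edge '%s' (%s) targets non-metabolite node '%s'",
          e$id, e$mechanism, e$target))
      }
      if (e$mechanism == "hill_regulatory" &&
          (!tgt$dynamic || tgt$category %in% INPUT_CATEGORIES)) {
        flag("regulatory_target", sprintf(
          "edge '%s' targets non-dynamic or input node '%s'", e$id, e$target))
      }
    }
  }

  # reachability from inputs and source-fed nodes via edge adjacency
  seeds <- union(nd$id[!nd$dynamic], nd$id[!is.na(nd$source_param)])
  reach <- seeds
  repeat {
    grow <- unlist(lapply(ed, function(e)
      if (any(e$sources$node %in% reach)) e$target else NULL))
    new <- setdiff(grow, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  orphan <- setdiff(nd$id[nd$dynamic], reach)
  if (length(orphan)) flag("reachability",
                           paste("dynamic node(s) unreachable from inputs/sources:",
                                 paste(orphan, collapse = ", ")))

  if (length(bad)) do.call(rbind, bad) else
    data.frame(rule = character(0), detail = character(0))
}

canonical_edge_key <- function(e) {
  s <- e$sources[order(e$sources$node), , drop = FALSE]
  paste0(paste(sprintf("%s:%d", s$node, as.integer(s$sign)), collapse = ";"),
         ">", e$target)
}

#' Read a prior-knowledge network from SIF and metadata files
#'
#' The SIF dialect is tab-separated `source relation target` with relation
#' codes `1` (activation) and `-1` (inhibition). AND hyperedges are encoded
#' through auxiliary gate rows named `and<k>`: each source connects into the
#' gate with its own sign and the gate connects into the target with
#' relation 1. The metadata table (CSV, one `record` column distinguishing
#' `node` and `edge` rows) supplies categories, measured flags, mechanisms,
#' stoichiometry and parameter naming; the SIF topology and the metadata edge
#' set are cross-checked.
#'
#' @param network_path Path to the SIF file.
#' @param metadata_path Path to the metadata CSV.
#' @param name Network name (defaults to the SIF file name).
#' @param check Validate on construction (default `TRUE`).
#' @return A `pkn` object.
#' @export
read_network <- function(network_path, metadata_path,
                         name = sub("[.]sif$", "", basename(network_path)),
                         check = TRUE) {
  if (!file.exists(network_path)) stop("SIF file not found: ", network_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)

  lines <- readLines(network_path)
  lines <- lines[nzchar(trimws(lines))]
  sif <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      stop(sprintf("parse error in '%s' line %d: expected 3 tab-separated fields, got %d",
                   network_path, i, length(parts)))
    }
    if (!parts[2] %in% c("1", "-1")) {
      stop(sprintf("parse error in '%s' line %d: unknown relation code '%s'",
                   network_path, i, parts[2]))
    }
    sif[[i]] <- data.frame(source = parts[1], sign = as.integer(parts[2]),
                           target = parts[3], stringsAsFactors = FALSE)
  }
  sif <- if (length(sif)) do.call(rbind, sif) else
    data.frame(source = character(0), sign = integer(0), target = character(0))

  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!"record" %in% names(meta)) stop("metadata lacks a 'record' column")
  nmeta <- meta[meta$record == "node", , drop = FALSE]
  emeta <- meta[meta$record == "edge", , drop = FALSE]

  nodes <- network_nodes(
    id = nmeta$id, label = nmeta$label, category = nmeta$category,
    species = nmeta$species, measured = as.logical(nmeta$measured),
    initial_level = as.numeric(nmeta$initial_level),
    dynamic = as.logical(nmeta$dynamic), source_param = nmeta$source_param,
    source_scale = as.numeric(nmeta$source_scale)
  )
  nodes$species[nodes$species == ""] <- NA_character_
  nodes$source_param[nodes$source_param == ""] <- NA_character_

  blank_na <- function(x) {
    x <- as.character(x); x[!nzchar(x)] <- NA_character_; x
  }
  edges <- lapply(seq_len(nrow(emeta)), function(i) {
    r <- emeta[i, ]
    src <- do.call(rbind, lapply(strsplit(r$sources, ";", fixed = TRUE)[[1]],
      function(tok) {
        f <- strsplit(tok, ":", fixed = TRUE)[[1]]
        data.frame(node = f[1], sign = as.numeric(f[2]),
                   exponent = if (length(f) >= 3) as.numeric(f[3]) else 1,
                   stringsAsFactors = FALSE)
      }))
    consumes <- if (is.na(r$consumes) || !nzchar(r$consumes)) character(0) else
      strsplit(r$consumes, ";", fixed = TRUE)[[1]]
    network_edge(
      id = r$id, sources = src, target = r$target, mechanism = r$mechanism,
      fixed = as.logical(r$fixed), rate_param = blank_na(r$rate_param),
      km_param = blank_na(r$km_param), ki_param = blank_na(r$ki_param),
      substrate = blank_na(r$substrate), consumes = consumes,
      fixed_k = as.numeric(r$fixed_k), fixed_n = as.numeric(r$fixed_n)
    )
  })

  # consistency: SIF nodes (ignoring gates) must be known to the metadata
  gate <- grepl("^and[0-9]+$", c(sif$source, sif$target))
  sif_nodes <- setdiff(unique(c(sif$source, sif$target)[!gate]), nodes$id)
  if (length(sif_nodes)) {
    stop("consistency error: SIF node(s) absent from metadata: ",
         paste(sif_nodes, collapse = ", "))
  }
  # and the SIF edge set must match the metadata edge set
  sif_keys <- sif_edge_keys(sif)
  meta_keys <- vapply(edges, canonical_edge_key, character(1))
  if (!setequal(sif_keys, meta_keys)) {
    only_sif <- setdiff(sif_keys, meta_keys)
    only_meta <- setdiff(meta_keys, sif_keys)
    stop("consistency error: SIF and metadata edge sets differ",
         if (length(only_sif)) paste0("; only in SIF: ",
                                      paste(only_sif, collapse = " | ")) else "",
         if (length(only_meta)) paste0("; only in metadata: ",
                                       paste(only_meta, collapse = " | ")) else "")
  }

  pkn(nodes, edges, name = name, check = check)
}

# Collapse gate rows of a parsed SIF into canonical source-set>target keys.
sif_edge_keys <- function(sif) {
  is_gate_tgt <- grepl("^and[0-9]+$", sif$target)
  gates <- unique(sif$target[is_gate_tgt])
  keys <- character(0)
  for (g in gates) {
    src <- sif[sif$target == g, , drop = FALSE]
    out <- sif[sif$source == g, , drop = FALSE]
    if (nrow(out) != 1) stop("consistency error: gate '", g,
                             "' must feed exactly one target")
    src <- src[order(src$source), , drop = FALSE]
    keys <- c(keys, paste0(paste(sprintf("%s:%d", src$source, src$sign),
                                 collapse = ";"), ">", out$target))
  }
  plain <- sif[!is_gate_tgt & !grepl("^and[0-9]+$", sif$source), , drop = FALSE]
  c(keys, sprintf("%s:%d>%s", plain$source, plain$sign, plain$target))
}

#' Write a prior-knowledge network to SIF and metadata files
#'
#' Inverse of [read_network()]: multi-source edges are written through
#' auxiliary `and<k>` gate rows; all node and edge attributes go to the
#' metadata CSV. Output is deterministic (stable ordering), and
#' `read_network()` on the written pair reconstructs the network structure.
#'
#' @param network A `pkn` object.
#' @param network_path,metadata_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(network, network_path, metadata_path) {
  rows <- character(0)
  gate_i <- 0L
  for (e in network$edges) {
    s <- e$sources
    if (nrow(s) == 1) {
      rows <- c(rows, sprintf("%s\t%d\t%s", s$node, as.integer(s$sign), e$target))
    } else {
      gate_i <- gate_i + 1L
      g <- sprintf("and%d", gate_i)
      rows <- c(rows,
                sprintf("%s\t%d\t%s", s$node, as.integer(s$sign), g),
                sprintf("%s\t1\t%s", g, e$target))
    }
  }
  writeLines(rows, network_path)

  nd <- network$nodes
  na_col <- rep(NA, nrow(nd))
  node_rec <- data.frame(
    record = rep("node", nrow(nd)), id = nd$id, label = nd$label,
    category = nd$category,
    species = nd$species, measured = nd$measured,
    initial_level = nd$initial_level, dynamic = nd$dynamic,
    source_param = nd$source_param, source_scale = nd$source_scale,
    sources = na_col, target = na_col, mechanism = na_col, fixed = na_col,
    rate_param = na_col, km_param = na_col, ki_param = na_col,
    substrate = na_col, consumes = na_col, fixed_k = na_col,
    fixed_n = na_col, stringsAsFactors = FALSE
  )
  edge_rec <- do.call(rbind, lapply(network$edges, function(e) {
    s <- e$sources
    data.frame(
      record = "edge", id = e$id, label = NA, category = NA, species = NA,
      measured = NA, initial_level = NA, dynamic = NA, source_param = NA,
      source_scale = NA,
      sources = paste(sprintf("%s:%g:%g", s$node, s$sign, s$exponent),
                      collapse = ";"),
      target = e$target, mechanism = e$mechanism, fixed = e$fixed,
      rate_param = e$rate_param, km_param = e$km_param, ki_param = e$ki_param,
      substrate = e$substrate,
      consumes = if (length(e$consumes)) paste(e$consumes, collapse = ";") else NA,
      fixed_k = e$fixed_k, fixed_n = e$fixed_n, stringsAsFactors = FALSE
    )
  }))
  meta <- rbind(node_rec, edge_rec)
  utils::write.csv(meta, metadata_path, row.names = FALSE, na = "")
  invisible(c(network_path, metadata_path))
}
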