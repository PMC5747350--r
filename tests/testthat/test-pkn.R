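test_that("SIF + metadata parsing builds small networks and rejects bad input", {
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "net.sif")
  meta <- file.path(dir, "net.csv")
  nodes <- network_nodes(c("A", "B", "C"), category = c("stimulus", "protein",
                                                        "stimulus"),
                         initial_level = c(0, 0.5, 0))
  edges <- list(
    network_edge("A_B", data.frame(node = "A", sign = 1, exponent = 1), "B"),
    network_edge("C_B", data.frame(node = "C", sign = -1, exponent = 1), "B"))
  write_network(pkn(nodes, edges, "tiny"), sif, meta)

  net <- read_network(sif, meta)
  expect_equal(nrow(net$nodes), 3)
  expect_length(net$edges, 2)
  signs <- vapply(net$edges, function(e) e$sources$sign[1], numeric(1))
  expect_setequal(signs, c(1, -1))

  # malformed relation code -> parse error with line number
  writeLines(c("A\t1\tB", "C\t2\tB"), sif)
  expect_error(read_network(sif, meta), "line 2")
  # node missing from metadata -> consistency error
  writeLines(c("A\t1\tB", "Z\t-1\tB"), sif)
  expect_error(read_network(sif, meta), "consistency")
})

test_that("write/read round trip is structurally lossless and byte-stable", {
  dir <- withr::local_tempdir()
  for (net in list(chol_net(), toy_net())) {
    sif <- file.path(dir, paste0(net$name, ".sif"))
    meta <- file.path(dir, paste0(net$name, ".csv"))
    write_network(net, sif, meta)
    back <- read_network(sif, meta, name = net$name)
    expect_identical(names(back$edges), names(net$edges))
    expect_identical(vapply(back$edges, cholode:::canonical_edge_key,
                            character(1)),
                     vapply(net$edges, cholode:::canonical_edge_key,
                            character(1)))
    expect_equal(back$nodes[order(back$nodes$id), ],
                 net$nodes[order(net$nodes$id), ], ignore_attr = TRUE)
    # determinism: writing twice yields identical bytes
    sif2 <- file.path(dir, "again.sif")
    meta2 <- file.path(dir, "again.csv")
    write_network(net, sif2, meta2)
    expect_identical(readLines(sif), readLines(sif2))
    expect_identical(readLines(meta), readLines(meta2))
  }
})

test_that("packaged fixture files reproduce the in-code cholesterol network", {
  files <- cholesterol_pkn_files()
  net <- read_network(files["sif"], files["metadata"],
                      name = "cholesterol_regulation")
  ref <- chol_net()
  expect_identical(pkn_counts(net), pkn_counts(ref))
  expect_identical(names(net$edges), names(ref$edges))
  expect_equal(net$nodes[order(net$nodes$id), ],
               ref$nodes[order(ref$nodes$id), ], ignore_attr = TRUE)
})

test_that("the cholesterol fixture matches its structural constraints", {
  net <- chol_net()
  cts <- pkn_counts(net)
  expect_identical(unname(cts["edges"]), 44L)
  expect_identical(unname(cts["proteins"]), 21L)
  expect_identical(unname(cts["metabolite_species"]), 11L)
  expect_identical(unname(cts["measured"]), 25L)
  expect_identical(nrow(validate_network(net)), 0L)

  nd <- net$nodes
  for (id in c("CholER", "CholMedia", "LDLR", "NPC1")) {
    expect_false(nd$measured[nd$id == id], label = paste(id, "unmeasured"))
  }
  # fixed SREBP->SREBP1/2 edges and the hypothetical SREBP1 -| SREBP feedback
  expect_true(net$edges[["SREBP_SREBP1"]]$fixed)
  expect_true(net$edges[["SREBP_SREBP2"]]$fixed)
  srcs <- net$edges[["sterol_SREBP"]]$sources
  expect_true("SREBP1" %in% srcs$node && all(srcs$sign == -1))
  expect_true(all(c("ACAT2act", "HMGCS1act") %in% nd$id))
  # intra/extracellular duplicates share a species
  expect_identical(nd$species[nd$id == "CholER"],
                   nd$species[nd$id == "CholMedia"])
})

test_that("validate_network reports duplicates, dangling refs, category violations", {
  nodes <- network_nodes(c("A", "B", "M"),
                         category = c("stimulus", "protein",
                                      "metabolite_intracellular"),
                         initial_level = c(0, 0.5, 0.5))
  e1 <- network_edge("e1", data.frame(node = "A", sign = 1, exponent = 1), "B")
  net <- pkn(nodes, list(e1), check = FALSE)

  dup <- net
  dup$edges <- c(dup$edges, list(e1))
  expect_true("edge_id_unique" %in% validate_network(dup)$rule)

  dangling <- net
  dangling$edges <- list(network_edge(
    "e2", data.frame(node = "ZZZ", sign = 1, exponent = 1), "B"))
  expect_true("edge_reference" %in% validate_network(dangling)$rule)

  # mass-action edge targeting a protein node is a category violation
  badmech <- net
  badmech$edges <- c(badmech$edges, list(network_edge(
    "e3", data.frame(node = "M", sign = 1, exponent = 1), "B",
    mechanism = "mass_action", rate_param = "kx")))
  expect_true("metabolic_target" %in% validate_network(badmech)$rule)
})

test_that("the 23-condition roster matches the study design", {
  conds <- default_conditions()
  expect_identical(nrow(conds), 23L)
  expect_identical(sum(conds$untreated), 1L)
  expect_identical(sum(conds$class == "sirna72"), 11L)
  expect_true(all(conds$end_time[conds$class == "sirna72"] == 150))
  expect_true(all(conds$end_time[conds$class == "drug48"] == 100))
  inputs <- setdiff(names(conds), c("condition", "class", "end_time",
                                    "untreated"))
  expect_setequal(inputs, input_nodes(chol_net()))
  lv <- as.matrix(conds[, inputs])
  expect_true(all(lv >= 0 & lv <= 1))
})

test_that("empty networks round-trip", {
  dir <- withr::local_tempdir()
  empty <- pkn(network_nodes(character(0)), list(), "empty", check = FALSE)
  sif <- file.path(dir, "e.sif"); meta <- file.path(dir, "e.csv")
  write_network(empty, sif, meta)
  back <- read_network(sif, meta, check = FALSE)
  expect_identical(nrow(back$nodes), 0L)
  expect_length(back$edges, 0)
})
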