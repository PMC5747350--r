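raw_row <- function(analyte, class, signal, condition = "untreated",
                    cell_line = "L1", bio_rep = 1) {
  data.frame(analyte = analyte, class = class, cell_line = cell_line,
              condition = condition, bio_rep = bio_rep, tech_rep = 1,
              signal = signal, stringsAsFactors = FALSE)
}

test_that("class-specific scaling rules match the stated arithmetic", {
  raw <- rbind(
    raw_row("drugA", "drug_or_drug_metabolite", c(5, 10, 25),
            condition = c("untreated", "c1", "c2"), bio_rep = 1),
    raw_row("metB", "endogenous_metabolite", c(0, 5, 10),
            condition = c("untreated", "c1", "c2"), bio_rep = 1),
    raw_row("protC", "protein", c(100, 300, 500),
            condition = c("untreated", "c1", "c2"), bio_rep = 1),
    raw_row("flat", "drug_or_drug_metabolite", c(7, 7, 7),
            condition = c("untreated", "c1", "c2"), bio_rep = 1))
  ds <- scale_signals(raw)
  m <- ds$measurements
  val <- function(a) m$value[m$node == a][order(m$condition[m$node == a])]
  # min-max rule for drugs: {5,10,25} -> {0, 0.25, 1}
  expect_equal(sort(m$value[m$node == "drugA"]), c(0, 0.25, 1))
  # 0-to-max rule for endogenous metabolites: {0,5,10} -> {0, 0.5, 1}
  expect_equal(sort(m$value[m$node == "metB"]), c(0, 0.5, 1))
  # proteins: global min-max
  expect_equal(sort(m$value[m$node == "protC"]), c(0, 0.5, 1))
  # constant analyte: flagged, 0.5 with zero weight
  expect_true(all(m$value[m$node == "flat"] == 0.5))
  expect_true(all(m$weight[m$node == "flat"] == 0))
  expect_identical(attr(ds, "degenerate"), "flat")
})

test_that("scaling preserves order within each analyte and global protein range", {
  set.seed(8)
  raw <- do.call(rbind, lapply(c("L1", "L2"), function(cl)
    raw_row("p1", "protein", runif(5, 10, 100),
            condition = paste0("c", 1:5), cell_line = cl)))
  raw$condition[1] <- "untreated"
  ds <- scale_signals(raw)
  m <- ds$measurements
  m <- m[order(m$cell_line, m$condition), ]
  raw <- raw[order(raw$cell_line, raw$condition), ]
  expect_identical(order(m$value), order(raw$signal))
  expect_true(min(m$value) == 0 && max(m$value) == 1)
  # metabolite rule is idempotent when the maximum is already 1
  raw2 <- raw_row("m", "endogenous_metabolite", c(0.2, 0.7, 1),
                  condition = c("untreated", "c1", "c2"))
  expect_equal(sort(scale_signals(raw2)$measurements$value), c(0.2, 0.7, 1))
})

test_that("MIDAS write/read round-trips values, conditions and replicates", {
  sd <- simulate_dataset(toy_net(), toy_truth(), cv = 0.1,
                         bio_replicates = 3, seed = 21)
  ds <- sd$dataset
  path <- withr::local_tempfile(fileext = ".csv")
  write_midas(ds, path)
  back <- read_midas(path)

  key <- function(m) {
    m <- m[order(m$cell_line, m$condition, m$node, m$replicate), ]
    m[, c("cell_line", "condition", "node", "replicate", "value")]
  }
  expect_equal(key(back$measurements), key(ds$measurements),
               ignore_attr = TRUE)
  expect_setequal(back$conditions$condition, ds$conditions$condition)
  # input levels survive the round trip
  ic <- c("S", "D")
  orig <- ds$conditions[order(ds$conditions$condition), c("condition", ic)]
  got <- back$conditions[order(back$conditions$condition), c("condition", ic)]
  expect_equal(got, orig, ignore_attr = TRUE)
  expect_identical(back$conditions$untreated,
                   back$conditions$condition == "untreated")
})

test_that("MIDAS parsing errors on missing prefix classes and counts points", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(`TR:S` = c(0, 1), `DA:ALL` = c(10, 10),
                       check.names = FALSE), path, row.names = FALSE)
  expect_error(read_midas(path), "no DV:")

  write.csv(data.frame(`ID:Condition` = c("untreated", "c1"),
                       `TR:S` = c(0, 1), `DA:ALL` = c(10, 10),
                       `DV:A` = c(0.1, 0.2), `DV:B` = c(0.3, 0.4),
                       check.names = FALSE), path, row.names = FALSE)
  ds <- read_midas(path)
  expect_identical(n_datapoints(ds), 4L)  # 2 conditions x 2 nodes
})

test_that("pseudo-timepoints interpolate at 0.5/0.8/0.9 of the difference", {
  expect_equal(as.numeric(augment_pseudo_timepoints(0.2, 0.8)),
               c(0.5, 0.68, 0.74))
  expect_equal(as.numeric(augment_pseudo_timepoints(0.4, 0.4)),
               c(0.4, 0.4, 0.4))
  expect_equal(as.numeric(augment_pseudo_timepoints(1, 0)), c(0.5, 0.2, 0.1))
  expect_equal(attr(augment_pseudo_timepoints(0, 1, weight = 0.25), "weight"),
               0.25)
  # pseudo levels always lie between baseline and final
  set.seed(4)
  for (i in 1:25) {
    b <- runif(1); f <- runif(1)
    lv <- as.numeric(augment_pseudo_timepoints(b, f))
    expect_true(all(lv >= min(b, f) & lv <= max(b, f)))
  }
})

test_that("dataset augmentation adds reduced-weight interior points", {
  sd <- simulate_dataset(toy_net(), toy_truth(), cv = 0, bio_replicates = 1,
                         seed = 3)
  aug <- augment_dataset(sd$dataset, weight = 0.5)
  m <- aug$measurements
  ps <- m[m$pseudo, ]
  n_cells <- length(unique(paste(m$node[!m$pseudo], m$condition[!m$pseudo])))
  expect_identical(nrow(ps), 3L * n_cells)
  expect_true(all(ps$weight == 0.5))
  expect_true(all(ps$time > 0 & ps$time < 100))
  # interior levels lie between the untreated baseline and the final level
  base <- m[!m$pseudo & m$condition == "untreated", ]
  for (i in seq_len(nrow(ps))) {
    b <- base$value[base$node == ps$node[i]]
    f <- m$value[!m$pseudo & m$node == ps$node[i] &
                 m$condition == ps$condition[i]]
    expect_true(ps$value[i] >= min(b, f) - 1e-12 &&
                ps$value[i] <= max(b, f) + 1e-12)
  }
})

test_that("differential flagging raises weights beyond the threshold", {
  sd <- simulate_dataset(toy_net(), toy_truth(), cv = 0, bio_replicates = 2,
                         seed = 5)
  fl <- flag_differential(sd$dataset, threshold = 0.1, weight = 2)
  m <- fl$measurements
  expect_true(all(m$weight[m$differential] == 2))
  expect_true(all(m$weight[!m$differential] == 1))
  expect_false(any(m$differential[m$condition == "untreated"]))
  st <- sd$truth_states
  moved <- abs(st[, colnames(st) %in% unique(m$node)] -
               rep(st["untreated", colnames(st) %in% unique(m$node)],
                   each = nrow(st))) > 0.1
  # every truly moved (node, condition) cell is flagged at zero noise
  for (cd in rownames(st)) {
    if (cd == "untreated") next
    for (nd in unique(m$node)) {
      expect_identical(
        unique(m$differential[m$condition == cd & m$node == nd]),
        abs(st[cd, nd] - st["untreated", nd]) > 0.1)
    }
  }
})
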