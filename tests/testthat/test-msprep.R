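test_that("decoy FDR estimator reproduces the printed worked examples", {
  expect_identical(round(estimate_fdr(24266, 111, 0.6)$fdr, 6), 0.002745)
  expect_identical(round(estimate_fdr(2209, 88, 0.45)$fdr, 4), 0.0179)
  expect_identical(estimate_fdr(500, 0, 0.6)$fdr, 0)
  # linear in fft and in decoys
  expect_equal(estimate_fdr(100, 10, 0.8)$fdr,
               2 * estimate_fdr(100, 10, 0.4)$fdr)
  expect_equal(estimate_fdr(100, 10, 0.5)$fdr,
               2 * estimate_fdr(100, 5, 0.5)$fdr)
  expect_error(estimate_fdr(0, 5, 0.6), "n_targets")
  expect_error(estimate_fdr(100, 5, 1.5), "fft")
})

make_records <- function(m_scores, runs, precursors, conditions = NULL,
                         bio_reps = NULL) {
  data.frame(precursor = precursors, run = runs, m_score = m_scores,
             condition = if (is.null(conditions)) "c1" else conditions,
             bio_rep = if (is.null(bio_reps)) 1 else bio_reps,
             stringsAsFactors = FALSE)
}

test_that("presence filters are inclusive at the boundary and match enumeration", {
  # 10 files; precursor A passes in 2, B in 1
  rec <- rbind(
    make_records(rep(1e-6, 2), c("r1", "r2"), "A"),
    make_records(rep(1e-6, 1), "r1", "B"),
    make_records(rep(0.5, 10), paste0("r", 1:10), "pad"))
  expect_identical(filter_by_presence(rec, 1e-5, "fraction_of_files", q = 0.2),
                   "A")
  expect_error(filter_by_presence(rec, 1e-5, q = 0), "q must")
  expect_error(filter_by_presence(rec, 1e-2, "replicates_in_condition", r = 0),
               "r must")

  # 5 precursors x 6 runs with random m-scores vs exhaustive enumeration
  set.seed(12)
  grid <- expand.grid(precursor = paste0("p", 1:5), run = paste0("r", 1:6),
                      stringsAsFactors = FALSE)
  grid$m_score <- 10^runif(nrow(grid), -8, 0)
  grid$condition <- rep(c("c1", "c2"), each = 3)[match(grid$run,
                                                       paste0("r", 1:6))]
  grid$bio_rep <- rep(c(1, 2, 3), 2)[match(grid$run, paste0("r", 1:6))]
  thr <- 1e-3
  manual_frac <- sort(unique(grid$precursor[vapply(
    grid$precursor, function(p)
      sum(grid$m_score[grid$precursor == p] <= thr) >= 0.2 * 6, logical(1))]))
  expect_identical(filter_by_presence(grid, thr, "fraction_of_files", q = 0.2),
                   manual_frac)
  manual_rep <- sort(unique(unlist(lapply(unique(grid$precursor), function(p) {
    for (cd in c("c1", "c2")) {
      ok <- grid$m_score <= thr & grid$precursor == p & grid$condition == cd
      if (length(unique(grid$bio_rep[ok])) >= 2) return(p)
    }
    NULL
  }))))
  expect_identical(
    filter_by_presence(grid, thr, "replicates_in_condition", r = 2),
    manual_rep)

  # monotonicity: a laxer threshold or smaller q never loses survivors
  s1 <- filter_by_presence(grid, thr, "fraction_of_files", q = 0.5)
  s2 <- filter_by_presence(grid, thr * 10, "fraction_of_files", q = 0.5)
  s3 <- filter_by_presence(grid, thr, "fraction_of_files", q = 0.2)
  expect_true(all(s1 %in% s2))
  expect_true(all(s1 %in% s3))
})

test_that("quantification peptides are proteotypic top-7 by total signal", {
  rec <- data.frame(
    protein = rep("P1", 10), peptide = sprintf("pep%02d", 1:10),
    proteotypic = TRUE, intensity = seq(1000, 100, length.out = 10))
  out <- select_quant_peptides(rec)
  expect_identical(nrow(out), 7L)
  expect_setequal(out$peptide, sprintf("pep%02d", 1:7))

  small <- data.frame(protein = "P2", peptide = paste0("q", 1:3),
                      proteotypic = TRUE, intensity = 1:3)
  expect_identical(nrow(select_quant_peptides(small)), 3L)

  shared <- rbind(small, data.frame(protein = "P2", peptide = "shared",
                                    proteotypic = FALSE, intensity = 1e9))
  expect_false("shared" %in% select_quant_peptides(shared)$peptide)

  # deterministic lexicographic tie-break
  tied <- data.frame(protein = "P3", peptide = c("b", "a", "c"),
                     proteotypic = TRUE, intensity = c(5, 5, 5))
  out <- select_quant_peptides(tied, top_k = 2)
  expect_setequal(out$peptide, c("a", "b"))
})

test_that("total-intensity normalization preserves magnitude and handles windows", {
  rec <- data.frame(run = rep(c("r1", "r2"), each = 2),
                    intensity = c(10, 10, 20, 20), rt = c(100, 700, 100, 700))
  out <- total_intensity_normalize(rec, "global")
  # totals T and 2T: run2 halved relative to run1 after mean-total rescale
  expect_equal(out$intensity, c(15, 15, 15, 15))
  expect_equal(sum(out$intensity), 2 * mean(c(20, 40)))

  one <- data.frame(run = "r1", intensity = c(3, 7), rt = c(10, 20))
  expect_equal(total_intensity_normalize(one, "global")$intensity, c(3, 7))

  # windowed mode with a window spanning everything equals global mode
  g <- total_intensity_normalize(rec, "global")
  w <- total_intensity_normalize(rec, "rt_windowed", window = 1e6)
  expect_equal(w$intensity, g$intensity)

  wn <- total_intensity_normalize(rec, "rt_windowed", window = 600)
  expect_equal(wn$intensity, c(15, 15, 15, 15))

  bad <- data.frame(run = c("r1", "r2"), intensity = c(5, 0), rt = c(1, 1))
  expect_error(total_intensity_normalize(bad, "rt_windowed"), "zero total")
})

test_that("dual-control differential calls follow the decision rule", {
  expect_true(differential_call(0.6, 0.7, 5e-4, fdr_threshold = 1e-3))
  expect_false(differential_call(0.6, 0.3, 5e-4, fdr_threshold = 1e-3))
  expect_false(differential_call(0.49, NA, 1e-6))
  expect_true(differential_call(-0.8, -0.9, 1e-4))
  expect_false(differential_call(0.8, 0.9, 0.02))
  expect_identical(differential_call(c(0.6, 0.6), c(0.7, 0.2), c(1e-4, 1e-4)),
                   c(TRUE, FALSE))
})

test_that("nested CV and nested ANOVA match hand computation", {
  expect_identical(nested_cv(c(5, 5, 5), 1:3), 0)
  expect_equal(nested_cv(c(90, 100, 110), 1:3), 0.1)
  expect_equal(nested_cv(c(89, 91, 99, 101, 109, 111),
                         rep(1:3, each = 2)), 0.1)
  expect_error(nested_cv(c(1, 2), c(1, 1)), "replicates")

  # balanced 2 treatments x 3 bio x 2 tech against explicit sums of squares
  set.seed(21)
  d <- expand.grid(tech = 1:2, bio = 1:3, trt = c("a", "b"))
  d$y <- rnorm(nrow(d)) + ifelse(d$trt == "b", 1, 0) + rep(rnorm(6), each = 2)
  res <- nested_anova(d$y, d$trt, d$bio)
  grand <- mean(d$y)
  trt_means <- tapply(d$y, d$trt, mean)
  bio_means <- tapply(d$y, interaction(d$trt, d$bio), mean)
  ss_trt <- 6 * sum((trt_means - grand)^2)
  ss_bio <- 2 * sum((bio_means - rep(trt_means, 3))^2)
  f_manual <- (ss_trt / 1) / (ss_bio / 4)
  expect_equal(res$F, f_manual, tolerance = 1e-10)
  expect_equal(res$p, pf(f_manual, 1, 4, lower.tail = FALSE))
  expect_identical(nested_anova(rep(1, 12), d$trt, d$bio)$p, 1)
})

test_that("nested ANOVA p-values are uniform under the null", {
  set.seed(77)
  d <- expand.grid(tech = 1:2, bio = 1:3, trt = c("a", "b"))
  ps <- vapply(1:2000, function(i) {
    y <- rnorm(12) + rep(rnorm(6, sd = 0.7), each = 2)
    nested_anova(y, d$trt, d$bio)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("exact-mass annotation applies cutoff, tolerance and uniqueness", {
  ref <- reference_masses()
  hit <- annotate_ions(data.frame(mass = 480.0317, intensity = 1e4), ref)
  expect_identical(hit$metabolite, "T0901317")
  expect_identical(hit$adduct, "[M-H]-")
  expect_lt(abs(hit$mass_error), 0.001)

  expect_identical(nrow(annotate_ions(
    data.frame(mass = 480.0317, intensity = 1000), ref)), 0L)
  expect_identical(nrow(annotate_ions(
    data.frame(mass = 480.0317 + 0.002, intensity = 1e4), ref)), 0L)
  expect_error(annotate_ions(480.0317, ref[0, ]), "empty reference")

  # symmetric under reference reordering; unique per ion and metabolite
  set.seed(5)
  ions <- data.frame(mass = c(480.0317, 480.0320, 539.2346, 147.0663),
                     intensity = c(1e4, 5e3, 2e3, 1e5))
  a1 <- annotate_ions(ions, ref)
  a2 <- annotate_ions(ions, ref[sample(nrow(ref)), ])
  expect_equal(a1, a2)
  expect_false(anyDuplicated(a1$metabolite) > 0)
  expect_false(anyDuplicated(a1$ion_mass) > 0)
  # the closest of the two T0901317-compatible ions wins the metabolite
  expect_identical(a1$ion_mass[a1$metabolite == "T0901317"], 480.0317)

  # excluded salt adducts are dropped in the final step
  salt <- annotate_ions(data.frame(mass = 480.0317, intensity = 1e4), ref,
                        adducts = c("H/Na" = -1.007276466),
                        excluded_adducts = "H/Na")
  expect_identical(nrow(salt), 0L)
})

test_that("synthetic identification tables have the declared structure", {
  tab <- generate_id_table(3, n_target = 100, n_decoy = 5, n_runs = 6)
  expect_identical(nrow(tab), 105L * 6L)
  expect_identical(sum(tab$is_decoy) , 5L * 6L)
  expect_identical(generate_id_table(3), tab)
  expect_false(identical(generate_id_table(4), tab))
  expect_true(all(tab$m_score > 0 & tab$m_score <= 1))
  expect_true(all(tab$intensity >= 0))
  # estimate_fdr on its own counts: 0.6 * 5 / 100
  n_t <- length(unique(tab$precursor[!tab$is_decoy]))
  n_d <- length(unique(tab$precursor[tab$is_decoy]))
  expect_equal(estimate_fdr(n_t, n_d, 0.6)$fdr, 0.03)
})
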