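#' Decoy-based FDR estimate
#'
#' False discovery rate from target/decoy counts corrected by the estimated
#' fraction of false targets (FFT, also called the pi0 value):
#' `FDR = FFT * n_decoys / n_targets`.
#'
#' @param n_targets Number of targets passing the filter (>= 1).
#' @param n_decoys Number of decoys passing the same filter (>= 0).
#' @param fft Fraction of false targets in (0, 1].
#' @param level Identification level label (`precursor`, `peptide`,
#'   `protein`, ...).
#' @return An `fdr_estimate` list: `level`, `n_targets`, `n_decoys`, `fft`,
#'   `fdr` (full precision).
#' @examples
#' estimate_fdr(24266, 111, 0.6)$fdr   # 0.002745 at 6 decimals
#' estimate_fdr(2209, 88, 0.45)$fdr    # 0.0179 at 4 decimals
#' @export
estimate_fdr <- function(n_targets, n_decoys, fft, level = "peptide") {
  if (n_targets < 1) stop("n_targets must be >= 1")
  if (n_decoys < 0) stop("n_decoys must be >= 0")
  if (fft <= 0 || fft > 1) stop("fft must lie in (0, 1]")
  structure(list(level = level, n_targets = n_targets, n_decoys = n_decoys,
                 fft = fft, fdr = fft * n_decoys / n_targets),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("%s-level FDR: %.6g (FFT %.2f x %d decoys / %d targets)\n",
              x$level, x$fdr, x$fft, x$n_decoys, x$n_targets))
  invisible(x)
}

#' Presence filter on identification records
#'
#' A precursor survives if it passes the m-score confidence threshold either
#' in at least a fraction `q` of all files (`fraction_of_files`; the
#' proteomics rule: 1e-5 in at least 20% of files) or in at least `r`
#' biological replicates of at least one condition
#' (`replicates_in_condition`; the phosphoproteomics rule: 0.01 in 3
#' replicates of one condition). Boundaries are inclusive.
#'
#' @param records Data frame with columns `precursor`, `m_score`, `run` and,
#'   for the replicate rule, `condition` and `bio_rep`.
#' @param m_threshold m-score threshold (records pass at `m_score <=`
#'   threshold; smaller is more confident).
#' @param rule `fraction_of_files` or `replicates_in_condition`.
#' @param q Fraction of files, in (0, 1].
#' @param r Replicate count, >= 1.
#' @return Sorted character vector of surviving precursor ids.
#' @export
filter_by_presence <- function(records, m_threshold,
                               rule = c("fraction_of_files",
                                        "replicates_in_condition"),
                               q = 0.2, r = 3) {
  rule <- match.arg(rule)
  pass <- records[records$m_score <= m_threshold, , drop = FALSE]
  if (rule == "fraction_of_files") {
    if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
    n_files <- length(unique(records$run))
    hits <- tapply(pass$run, pass$precursor,
                   function(x) length(unique(x)))
    sort(names(hits)[hits >= q * n_files - 1e-9])
  } else {
    if (r < 1) stop("r must be >= 1")
    if (!all(c("condition", "bio_rep") %in% names(records))) {
      stop("replicate rule needs 'condition' and 'bio_rep' columns")
    }
    key <- paste(pass$precursor, pass$condition, sep = "\r")
    hits <- tapply(pass$bio_rep, key, function(x) length(unique(x)))
    ok <- unique(vapply(strsplit(names(hits)[hits >= r], "\r", fixed = TRUE),
                        `[`, character(1), 1))
    sort(ok)
  }
}

#' Select quantification peptides: proteotypic, top-k by signal
#'
#' Removes non-proteotypic (shared) peptides regardless of signal, then
#' keeps per protein the `top_k` peptides with the highest total signal
#' (default 7). Ties are broken by lexicographic peptide id for
#' determinism.
#'
#' @param records Data frame with columns `protein`, `proteotypic`,
#'   `intensity` and `peptide` (falls back to `precursor`).
#' @param top_k Peptides retained per protein (default 7).
#' @return The surviving rows of `records`.
#' @export
select_quant_peptides <- function(records, top_k = 7) {
  pep_col <- if ("peptide" %in% names(records)) "peptide" else "precursor"
  rec <- records[records$proteotypic, , drop = FALSE]
  if (!nrow(rec)) return(rec)
  key <- paste(rec$protein, rec[[pep_col]], sep = "\r")
  tot <- tapply(rec$intensity, key, sum)
  parts <- strsplit(names(tot), "\r", fixed = TRUE)
  tab <- data.frame(protein = vapply(parts, `[`, character(1), 1),
                    peptide = vapply(parts, `[`, character(1), 2),
                    total = as.numeric(tot), stringsAsFactors = FALSE)
  tab <- tab[order(tab$protein, -tab$total, tab$peptide), ]
  keep <- unlist(lapply(split(tab$peptide, tab$protein), utils::head, top_k))
  rec[rec[[pep_col]] %in% keep, , drop = FALSE]
}

#' Total-intensity normalization
#'
#' Divides each intensity by its run's total intensity - globally, or
#' within tiled retention-time windows (default width 600 s, the
#' 10-minute local normalization) - and rescales by the cross-run mean
#' total so overall magnitudes are preserved. A single run is left
#' unchanged (up to that global constant).
#'
#' @param records Data frame with columns `run`, `intensity` and, for the
#'   windowed mode, `rt` (seconds).
#' @param mode `global` or `rt_windowed`.
#' @param window Window width in seconds (default 600).
#' @return `records` with normalized `intensity`.
#' @export
total_intensity_normalize <- function(records, mode = c("global",
                                                        "rt_windowed"),
                                      window = 600) {
  mode <- match.arg(mode)
  if (mode == "global") {
    tot <- tapply(records$intensity, records$run, sum)
    if (any(tot == 0)) {
      stop("zero total intensity in run ", names(tot)[tot == 0][1])
    }
    records$intensity <- records$intensity /
      as.numeric(tot[records$run]) * mean(tot)
  } else {
    if (!"rt" %in% names(records)) stop("rt column required for windowed mode")
    win <- floor(records$rt / window)
    key <- paste(records$run, win, sep = "\r")
    tot <- tapply(records$intensity, key, sum)
    if (any(tot == 0)) {
      bad <- strsplit(names(tot)[tot == 0][1], "\r", fixed = TRUE)[[1]]
      stop("zero total intensity in run ", bad[1], ", rt window ", bad[2])
    }
    wmean <- tapply(as.numeric(tot),
                    vapply(strsplit(names(tot), "\r", fixed = TRUE),
                           `[`, character(1), 2), mean)
    records$intensity <- records$intensity / as.numeric(tot[key]) *
      as.numeric(wmean[as.character(win)])
  }
  records
}

#' Dual-control differential-abundance decision
#'
#' An analyte is called significantly changed when the FDR is below the
#' threshold and the absolute log2 fold change exceeds the threshold against
#' the untreated reference and, where a vehicle control applies (DMSO or
#' ethanol), against the vehicle as well.
#'
#' @param log2fc_vs_untreated Log2 fold change against untreated.
#' @param log2fc_vs_vehicle Log2 fold change against the vehicle control, or
#'   `NA`/`NULL` when no vehicle applies.
#' @param fdr FDR of the comparison.
#' @param fc_threshold Fold-change threshold (default 0.5; the call requires
#'   a strictly larger magnitude).
#' @param fdr_threshold FDR threshold (0.01 for metabolites, 0.001 for
#'   proteins in the underlying design; default 0.01).
#' @return Logical vector of significance calls.
#' @export
differential_call <- function(log2fc_vs_untreated, log2fc_vs_vehicle = NULL,
                              fdr, fc_threshold = 0.5, fdr_threshold = 0.01) {
  if (is.null(log2fc_vs_vehicle)) {
    log2fc_vs_vehicle <- rep(NA_real_, length(log2fc_vs_untreated))
  }
  ok <- fdr < fdr_threshold & abs(log2fc_vs_untreated) > fc_threshold
  veh <- is.na(log2fc_vs_vehicle) | abs(log2fc_vs_vehicle) > fc_threshold
  as.logical(ok & veh)
}

#' Coefficient of variation over biological replicates
#'
#' SD/mean of the biological-replicate means (technical replicates are
#' averaged into their biological replicate first).
#'
#' @param values Numeric measurements.
#' @param bio Biological-replicate labels.
#' @param tech Optional technical-replicate labels (unused beyond grouping;
#'   averaging happens per `bio` level).
#' @return The coefficient of variation.
#' @export
nested_cv <- function(values, bio, tech = NULL) {
  if (length(unique(bio)) < 2) stop("need >= 2 biological replicates")
  means <- tapply(values, bio, mean)
  m <- mean(means)
  if (m == 0) stop("zero mean; CV undefined")
  stats::sd(means) / m
}

#' Two-level nested ANOVA
#'
#' Tests a treatment effect with biological replicates nested in treatment
#' and technical replicates nested in biological replicates. The treatment
#' mean square is tested against the among-biological-replicate
#' (within-treatment) mean square: `F = MS_treatment / MS_bio(treatment)`
#' on (t - 1, sum(b_i) - t) degrees of freedom, fitted via [stats::aov()].
#'
#' @param values Numeric measurements.
#' @param treatment Treatment labels (>= 2 levels).
#' @param bio Biological-replicate labels within treatment.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
nested_anova <- function(values, treatment, bio) {
  treatment <- factor(treatment)
  if (nlevels(treatment) < 2) stop("need >= 2 treatment levels")
  bio_f <- interaction(treatment, bio, drop = TRUE)
  if (nlevels(bio_f) <= nlevels(treatment)) {
    stop("need >= 2 biological replicates in some treatment")
  }
  if (length(unique(values)) == 1) {
    return(list(F = 0, p = 1,
                df1 = nlevels(treatment) - 1,
                df2 = nlevels(bio_f) - nlevels(treatment)))
  }
  fit <- stats::aov(values ~ treatment + bio_f)
  tab <- stats::anova(fit)
  ms_t <- tab["treatment", "Mean Sq"]
  ms_b <- tab["bio_f", "Mean Sq"]
  df1 <- tab["treatment", "Df"]
  df2 <- tab["bio_f", "Df"]
  f <- ms_t / ms_b
  list(F = unname(f), p = unname(stats::pf(f, df1, df2, lower.tail = FALSE)),
       df1 = df1, df2 = df2)
}

# Negative-mode adduct mass shifts (Da): proton loss and fluoride attachment
# (electron mass included so [M-H]- ion masses match printed values).
NEGATIVE_ADDUCTS <- c("[M-H]-" = -1.007276466, "[M+F]-" = 18.998952)

#' Exact-mass metabolite annotation of ions
#'
#' Matches observed (negative-mode) ion masses against a reference list of
#' neutral monoisotopic masses under the configured adducts, within a mass
#' tolerance, ignoring ions below the intensity cutoff. Candidates then pass
#' the three-step filter: per ion only the top-scoring metabolite is
#' retained, per metabolite only the top-scoring annotation is retained, and
#' annotations with excluded (salt-type) adducts are removed. The default
#' annotation score is the negative absolute mass error (closest match
#' wins); ties break lexicographically.
#'
#' @param ions Data frame with columns `mass` (Da) and `intensity`, or a
#'   numeric mass vector (intensities then default above the cutoff).
#' @param reference Data frame with columns `metabolite` and
#'   `monoisotopic_mass` (neutral, Da).
#' @param tolerance Mass tolerance in Da (default 0.001).
#' @param intensity_cutoff Minimum intensity (default 1500 counts).
#' @param adducts Named vector of adduct mass shifts (default `[M-H]-` and
#'   `[M+F]-`).
#' @param excluded_adducts Adduct names removed in the final filter step
#'   (salt adducts such as NaCl, H/Na, H/K when supplied).
#' @return Data frame with one annotation per surviving ion: `ion_mass`,
#'   `intensity`, `metabolite`, `adduct`, `mass_error`, `score`.
#' @export
annotate_ions <- function(ions, reference, tolerance = 0.001,
                          intensity_cutoff = 1500,
                          adducts = NEGATIVE_ADDUCTS,
                          excluded_adducts = c("NaCl", "H/Na", "H/K")) {
  if (is.numeric(ions) && is.null(dim(ions))) {
    ions <- data.frame(mass = ions, intensity = intensity_cutoff + 1)
  }
  if (!nrow(reference)) stop("empty reference list")
  if (any(ions$mass <= 0) || any(reference$monoisotopic_mass <= 0)) {
    stop("masses must be positive")
  }
  cand <- list()
  for (i in seq_len(nrow(ions))) {
    if (ions$intensity[i] < intensity_cutoff) next
    for (a in names(adducts)) {
      expected <- reference$monoisotopic_mass + adducts[[a]]
      err <- ions$mass[i] - expected
      hit <- which(abs(err) <= tolerance)
      for (j in hit) {
        cand[[length(cand) + 1L]] <- data.frame(
          ion = i, ion_mass = ions$mass[i], intensity = ions$intensity[i],
          metabolite = reference$metabolite[j], adduct = a,
          mass_error = err[j], score = -abs(err[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(ion_mass = numeric(0), intensity = numeric(0),
                      metabolite = character(0), adduct = character(0),
                      mass_error = numeric(0), score = numeric(0))
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$ion, -cand$score, cand$metabolite, cand$adduct), ]
  # step 1: per ion, keep the top-scoring metabolite
  cand <- cand[!duplicated(cand$ion), , drop = FALSE]
  # step 2: per metabolite, keep the top-scoring annotation
  cand <- cand[order(cand$metabolite, -cand$score, cand$ion), ]
  cand <- cand[!duplicated(cand$metabolite), , drop = FALSE]
  # step 3: drop excluded (salt) adducts
  cand <- cand[!cand$adduct %in% excluded_adducts, , drop = FALSE]
  cand <- cand[order(cand$ion), setdiff(names(cand), "ion"), drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Packaged reference monoisotopic masses
#'
#' The small packaged reference list for exact-mass annotation: the study
#' drugs and drug metabolites (stored as neutral masses recovering the
#' printed negative-ion masses under proton loss) plus a few endogenous
#' metabolites.
#'
#' @return Data frame with `metabolite` and `monoisotopic_mass`.
#' @export
reference_masses <- function() {
  utils::read.csv(system.file("extdata", "reference_masses.csv",
                              package = "cholode", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
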