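# Single-cell measurement statistics: SRM-style relative-abundance tables
# (eggs x proteins) and immunofluorescence/FRET per-cell tables.
#
# The abundance side mirrors a targeted-proteomics workflow: light/heavy
# peptide ratios per sample, a per-sample correction factor derived from a
# reference set of non-cycling peptides, per-batch coefficients of variation
# with bootstrap intervals, and BH-adjusted pairwise Pearson correlations.
# The imaging side covers total-protein-mass normalization, DNA-content (2N)
# gating, FRET-timecourse activity scoring, and extreme-group comparisons.

#' Construct an abundance table
#'
#' Wraps a samples x proteins matrix of relative abundances (light/heavy
#' ratios) into a [SummarizedExperiment::SummarizedExperiment] with proteins
#' as rows and samples as columns, carrying sample annotations (batch,
#' timepoint) and protein annotations (reference-set membership, cell-cycle
#' regulation).
#'
#' @param values Samples x proteins numeric matrix (all positive); column
#'   names are protein names, row names sample ids.
#' @param sample_meta Data.frame with one row per sample; typically columns
#'   `batch` and `timepoint`.
#' @param protein_meta Data.frame with one row per protein; typically logical
#'   columns `is_reference` (member of the correction set) and
#'   `is_cell_cycle_regulated`.
#' @return A `SummarizedExperiment` with assay `"abundance"`.
#' @export
abundance_table <- function(values, sample_meta = NULL, protein_meta = NULL) {
  values <- as.matrix(values)
  if (any(values <= 0) || any(!is.finite(values)))
    stop("abundance values must be positive and finite", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("protein_", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(sample_meta))
    sample_meta <- data.frame(row.names = rownames(values))
  if (is.null(protein_meta))
    protein_meta <- data.frame(is_reference = rep(TRUE, ncol(values)),
                               row.names = colnames(values))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = t(values)),
    colData = S4Vectors::DataFrame(sample_meta, row.names = rownames(values)),
    rowData = S4Vectors::DataFrame(protein_meta, row.names = colnames(values)))
}

# samples x proteins matrix out of the SE (inverse of the constructor layout)
abundance_values <- function(se) t(SummarizedExperiment::assay(se, "abundance"))

#' Per-sample correction factors from reference peptides
#'
#' Each reference peptide is first normalized by its median across samples;
#' the per-sample correction factor is the median of these normalized values
#' over the reference set, and every abundance in the sample is divided by it.
#' This removes a common multiplicative calibration error per sample (typical
#' factors fall between 0.9 and 1.1 for a ~10% calibration error).  The
#' per-peptide reference medians act as the anchor of the normalization; they
#' are returned so a second pass can reuse them, in which case the correction
#' is exactly idempotent (all second-pass factors are 1: dividing a sample by
#' a scalar divides its median normalized reference value by the same
#' scalar).  Recomputing the medians from already-corrected data instead
#' shifts the anchor slightly and gives second-pass factors near, but not
#' exactly, 1.
#'
#' @param se An [abundance_table()]; reference proteins are those with
#'   `rowData(se)$is_reference == TRUE` (all proteins if the column is
#'   absent).
#' @param reference_medians Optional named per-reference-peptide medians from
#'   a previous pass (or an external standard); computed from `se` when
#'   `NULL`.
#' @return A list with `factors` (named per-sample vector), `corrected`
#'   (the `SummarizedExperiment` with the corrected assay), and
#'   `reference_medians`.
#' @export
correction_factors <- function(se, reference_medians = NULL) {
  v <- abundance_values(se)
  if (nrow(v) < 2L) stop("need at least 2 samples", call. = FALSE)
  rd <- SummarizedExperiment::rowData(se)
  ref <- if ("is_reference" %in% names(rd)) which(rd$is_reference)
         else seq_len(ncol(v))
  if (length(ref) == 0L) stop("reference set is empty", call. = FALSE)
  if (is.null(reference_medians)) {
    reference_medians <- apply(v[, ref, drop = FALSE], 2L, stats::median)
  } else if (length(reference_medians) != length(ref)) {
    stop("'reference_medians' must have one entry per reference peptide",
         call. = FALSE)
  }
  norm_ref <- sweep(v[, ref, drop = FALSE], 2L, reference_medians, "/")
  factors <- apply(norm_ref, 1L, stats::median)
  corrected <- v / factors
  out <- se
  SummarizedExperiment::assay(out, "abundance") <- t(corrected)
  list(factors = factors, corrected = out,
       reference_medians = reference_medians)
}

#' Per-protein, per-group coefficients of variation
#'
#' CV = sample standard deviation (n - 1 denominator) over mean, per protein
#' within each group of samples (e.g. each batch of eggs collected together).
#' Optionally adds bootstrap percentile confidence intervals.
#'
#' @param se An [abundance_table()].
#' @param grouping Name of the `colData` column defining groups (default
#'   `"batch"`), or a vector of group labels with one entry per sample.
#' @param n_boot Bootstrap resamples for the CI (default 0 = no CI).
#' @return Data.frame with columns `protein`, `group`, `n`, `cv` (and
#'   `ci_lo`, `ci_hi` when `n_boot > 0`).  Groups with fewer than 2 samples
#'   are dropped with a warning.
#' @export
batch_cv <- function(se, grouping = "batch", n_boot = 0L) {
  v <- abundance_values(se)
  groups <- if (length(grouping) == 1L && is.character(grouping)) {
    cd <- SummarizedExperiment::colData(se)
    if (!grouping %in% names(cd))
      stop("no colData column '", grouping, "'", call. = FALSE)
    cd[[grouping]]
  } else grouping
  groups <- as.character(groups)
  small <- names(which(table(groups) < 2L))
  if (length(small)) {
    warning("dropping groups with fewer than 2 samples: ",
            paste(small, collapse = ", "))
  }
  keep <- setdiff(unique(groups), small)
  rows <- list()
  for (g in keep)
    for (p in colnames(v)) {
      x <- v[groups == g, p]
      row <- data.frame(protein = p, group = g, n = length(x),
                        cv = stats::sd(x) / mean(x))
      if (n_boot > 0L) {
        ci <- bootstrap_cv(x, n_boot = n_boot)
        row$ci_lo <- ci[[1L]]
        row$ci_hi <- ci[[2L]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap confidence interval for a coefficient of variation
#'
#' Percentile interval (2.5th-97.5th by default) of the CV over resamples
#' drawn with replacement.
#'
#' @param x Numeric vector (n >= 3).
#' @param n_boot Number of resamples (default 2000).
#' @param probs Interval probabilities (default `c(0.025, 0.975)`).
#' @return Named numeric vector of the interval endpoints.
#' @export
bootstrap_cv <- function(x, n_boot = 2000L, probs = c(0.025, 0.975)) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  m <- matrix(sample(x, n * n_boot, replace = TRUE), nrow = n)
  cvs <- matrixStats_colSds(m) / colMeans(m)
  stats::quantile(cvs, probs, names = TRUE)
}

# column sds without an extra dependency
matrixStats_colSds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt((colSums(m^2) - n * mu^2) / (n - 1))
}

#' Pairwise Pearson correlations with BH adjustment
#'
#' Pearson correlation with a two-sided t-test p-value (df = n - 2) for every
#' unordered protein pair, adjusted over the m = P(P-1)/2 unique pairs by the
#' Benjamini-Hochberg step-up procedure.  Pairs involving a zero-variance
#' protein are reported with `NA` and excluded from the adjustment.
#'
#' @param se An [abundance_table()] (typically correction-applied first; pass
#'   the `corrected` element of [correction_factors()]).
#' @param alpha Significance level for the mask (default 0.05).
#' @return Data.frame with columns `protein_1`, `protein_2`, `r`, `p`,
#'   `p_adj`, `significant`.
#' @export
pairwise_correlations <- function(se, alpha = 0.05) {
  v <- abundance_values(se)
  if (nrow(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  prots <- colnames(v)
  sds <- apply(v, 2L, stats::sd)
  pairs <- utils::combn(prots, 2L)
  n <- nrow(v)
  res <- data.frame(protein_1 = pairs[1L, ], protein_2 = pairs[2L, ],
                    r = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    if (sds[a] == 0 || sds[b] == 0) next
    r <- stats::cor(v[, a], v[, b])
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    res$r[i] <- r
    res$p[i] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  ok <- !is.na(res$p)
  res$p_adj <- NA_real_
  res$p_adj[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Compare technical and biological variation per protein
#'
#' Pairs a technical CV report (replicate aliquots of a pooled lysate, which
#' collapses biological variability) with a biological CV report, returns the
#' biological/technical ratio per protein, and flags proteins whose
#' biological CV is indistinguishable from the technical floor (overlapping
#' bootstrap intervals).
#'
#' @param tech_cvs,bio_cvs Data.frames with columns `protein`, `cv`, `ci_lo`,
#'   `ci_hi` (one row per protein; aggregate multi-batch reports first).
#' @return Data.frame with columns `protein`, `cv_tech`, `cv_bio`, `ratio`,
#'   `at_technical_floor`.
#' @export
technical_vs_biological <- function(tech_cvs, bio_cvs) {
  need <- c("protein", "cv", "ci_lo", "ci_hi")
  if (!all(need %in% names(tech_cvs)) || !all(need %in% names(bio_cvs)))
    stop("reports need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!setequal(tech_cvs$protein, bio_cvs$protein))
    stop("protein sets of the two reports do not match", call. = FALSE)
  tech <- tech_cvs[match(bio_cvs$protein, tech_cvs$protein), ]
  data.frame(protein = bio_cvs$protein,
             cv_tech = tech$cv, cv_bio = bio_cvs$cv,
             ratio = bio_cvs$cv / tech$cv,
             at_technical_floor = bio_cvs$ci_lo <= tech$ci_hi)
}

#' Gate cells to the 2N (G0/G1) DNA-content mode
#'
#' Locates the 2N mode as the lowest prominent peak of a kernel-density
#' estimate of the integrated DNA stain and keeps cells whose DNA content
#' falls within `mode * [1 - width, 1 + width]`.  Optionally also drops cells
#' beyond a central radius from the image center (to avoid illumination
#' fall-off toward the corners).
#'
#' @param cells Data.frame with a `dna` column (and `x`, `y` when
#'   `radius_limit` is used).
#' @param width Half-width of the gate as a fraction of the mode
#'   (default 0.25).
#' @param radius_limit Optional radius (same units as `x`, `y`).
#' @param image_center Optional `c(x, y)` center; defaults to the midrange of
#'   the observed positions.
#' @param prominence Minimum peak height relative to the tallest density peak
#'   for a mode to count (default 0.2).
#' @return The gated data.frame, with attributes `dna_mode` and
#'   `kept_fraction`.
#' @export
gate_g1 <- function(cells, width = 0.25, radius_limit = NULL,
                    image_center = NULL, prominence = 0.2) {
  if (!"dna" %in% names(cells)) stop("'cells' needs a 'dna' column",
                                     call. = FALSE)
  kept <- cells
  if (!is.null(radius_limit)) {
    if (!all(c("x", "y") %in% names(kept)))
      stop("radius filtering needs 'x' and 'y' columns", call. = FALSE)
    if (is.null(image_center))
      image_center <- c(mean(range(kept$x)), mean(range(kept$y)))
    r <- sqrt((kept$x - image_center[1L])^2 + (kept$y - image_center[2L])^2)
    kept <- kept[r <= radius_limit, , drop = FALSE]
  }
  dna <- kept$dna
  if (length(unique(dna)) == 1L) {
    mode2n <- dna[1L]
  } else {
    d <- stats::density(dna)
    peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
    peaks <- peaks[d$y[peaks] >= prominence * max(d$y)]
    if (length(peaks) == 0L)
      stop("no discernible 2N peak in the DNA histogram; density summary: ",
           paste(signif(stats::quantile(dna), 3), collapse = " / "),
           call. = FALSE)
    mode2n <- d$x[min(peaks)]  # lowest prominent mode = 2N
  }
  gated <- kept[kept$dna >= mode2n * (1 - width) &
                  kept$dna <= mode2n * (1 + width), , drop = FALSE]
  attr(gated, "dna_mode") <- mode2n
  attr(gated, "kept_fraction") <- nrow(gated) / nrow(cells)
  gated
}

#' Normalize antibody intensities by total protein mass
#'
#' Per-cell relative concentration = antibody intensity / total-protein-mass
#' stain intensity; a common multiplicative volume factor cancels exactly.
#'
#' @param cells Data.frame with a `mass_stain` column and one intensity
#'   column per target.
#' @param targets Character vector of intensity column names.
#' @return The data.frame with an added `<target>_conc` column per target.
#' @export
normalize_by_mass <- function(cells, targets) {
  if (!"mass_stain" %in% names(cells))
    stop("'cells' needs a 'mass_stain' column", call. = FALSE)
  if (any(cells$mass_stain <= 0))
    stop("mass-stain intensities must be positive", call. = FALSE)
  for (tg in targets) {
    if (!tg %in% names(cells)) stop("no column '", tg, "'", call. = FALSE)
    cells[[paste0(tg, "_conc")]] <- cells[[tg]] / cells$mass_stain
  }
  cells
}

#' Integrated activity of a FRET timecourse
#'
#' Trapezoidal area under the FRET/CFP ratio from the stimulus time to the
#' end of the trace (no baseline subtraction unless requested).
#'
#' @param time,ratio Numeric vectors of time points and FRET ratios.
#' @param stim_time Stimulus-addition time; integration starts here.
#' @param baseline_subtract If `TRUE`, the mean pre-stimulus ratio is
#'   subtracted before integrating (off by default).
#' @return The area under the curve.
#' @export
integrated_activity <- function(time, ratio, stim_time,
                                baseline_subtract = FALSE) {
  if (length(time) != length(ratio))
    stop("'time' and 'ratio' must have equal length", call. = FALSE)
  post <- time >= stim_time
  if (sum(post) < 2L)
    stop("trace does not cover a post-stimulus window of positive length",
         call. = FALSE)
  y <- ratio
  if (baseline_subtract) {
    pre <- time < stim_time
    if (any(pre)) y <- y - mean(ratio[pre])
  }
  pracma::trapz(time[post], y[post])
}

#' Threshold separating active from inactive cells
#'
#' Smooths the (bimodal) distribution of integrated-activity scores with a
#' Gaussian kernel (Silverman bandwidth) and places the threshold at the
#' density minimum between the two most prominent modes.  Fails if the
#' smoothed distribution is unimodal.
#'
#' @param scores Numeric vector of integrated-activity scores.
#' @return The threshold value.
#' @export
activity_threshold <- function(scores) {
  d <- stats::density(scores, bw = "nrd0")
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (length(peaks) < 2L)
    stop("activity-score distribution is unimodal; cannot place a threshold",
         call. = FALSE)
  top2 <- peaks[order(d$y[peaks], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(d$y[lo:hi]) - 1L
  d$x[valley]
}

#' Compare concentrations between extreme activity groups
#'
#' Splits cells into the top and bottom `fraction` (default 15%) by their
#' integrated-activity score and compares a concentration between the two
#' groups: medians, quartiles, notch half-widths `1.58 * IQR / sqrt(n)`
#' (approximate 95% CI of the median), and a two-sided Wilcoxon rank-sum
#' p-value.
#'
#' @param scores Integrated-activity scores, one per cell.
#' @param concentration Matched concentration values.
#' @param fraction Tail fraction per group (default 0.15).
#' @return List with `summary` (data.frame, one row per group) and `p_value`.
#' @export
compare_extremes <- function(scores, concentration, fraction = 0.15) {
  n <- length(scores)
  if (length(concentration) != n)
    stop("'scores' and 'concentration' must have equal length", call. = FALSE)
  k <- floor(fraction * n)
  if (k < 1L || n < 2 / fraction)
    stop("too few cells for a ", fraction * 100, "% split", call. = FALSE)
  ord <- order(scores)
  bottom <- concentration[ord[seq_len(k)]]
  top <- concentration[ord[seq(n - k + 1L, n)]]
  summ <- do.call(rbind, lapply(list(top = top, bottom = bottom), function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(x), q1 = q[1L], median = q[2L], q3 = q[3L],
               notch = 1.58 * (q[3L] - q[1L]) / sqrt(length(x)))
  }))
  summ <- cbind(group = rownames(summ), summ)
  rownames(summ) <- NULL
  list(summary = summ,
       p_value = stats::wilcox.test(top, bottom)$p.value)
}
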