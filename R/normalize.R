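#' Peptide iTRAQ ratios against the reference channel
#'
#' For each qualified peptide the iTRAQ ratio of channel X is the reporter
#' intensity of X divided by the reference channel's intensity (114 by
#' default), i.e. r_X = x_X / x_ref, with r_ref = 1.
#'
#' @param psm a PSM data frame with positive intensities (qualified
#'   peptides).
#' @param reference_channel channel tag of the denominator.
#' @return A numeric matrix, one row per record, columns named by channel
#'   tag.
#' @export
peptide_ratios <- function(psm, reference_channel = "114") {
  tags <- itraq_channels()
  if (!reference_channel %in% tags)
    stop("unknown reference channel: ", reference_channel)
  ints <- as.matrix(psm[intensity_cols()])
  colnames(ints) <- tags
  ref <- ints[, reference_channel]
  if (any(ref <= 0)) stop("reference channel has non-positive intensities")
  ints / ref
}

#' Per-channel normalization factors
#'
#' Container for the multiplicative factors N_X that rescale each
#' channel's reporter intensities (`x_norm = x_raw * N_X`).
#'
#' @param factors named numeric vector of 4 positive factors, names
#'   `"114"..."117"`.
#' @param method_id which fitting rule produced them (1, 2, 3 or 4).
#' @param reference_channel the reference channel tag.
#' @return An object of class `normalization_factors`.
#' @export
normalization_factors <- function(factors, method_id, reference_channel) {
  tags <- itraq_channels()
  stopifnot(setequal(names(factors), tags))
  factors <- factors[tags]
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("normalization factors must be positive and finite")
  structure(list(factors = factors, method_id = method_id,
                 reference_channel = reference_channel),
            class = "normalization_factors")
}

#' @export
print.normalization_factors <- function(x, ...) {
  cat("Normalization factors (method ", x$method_id, ", reference ",
      x$reference_channel, ")\n", sep = "")
  print(round(x$factors, 6))
  invisible(x)
}

#' Method 1: equal summation of peptide iTRAQ signals
#'
#' Each channel is rescaled so its total summed signal over all qualified
#' peptides equals the reference channel's raw total:
#' N_X = sum(x_ref) / sum(x_X).
#'
#' @inheritParams peptide_ratios
#' @return A [normalization_factors()] object.
#' @export
fit_method1 <- function(psm, reference_channel = "114") {
  if (nrow(psm) == 0L) stop("no qualified peptides")
  ints <- as.matrix(psm[intensity_cols()])
  totals <- colSums(ints)
  names(totals) <- itraq_channels()
  if (any(totals <= 0)) stop("a channel has zero total signal")
  normalization_factors(totals[reference_channel] / totals, 1L,
                        reference_channel)
}

#' Method 2: median log2 peptide iTRAQ ratio to zero
#'
#' The factor for channel X is chosen so that, after normalization, the
#' median over qualified peptides of log2(x_X / x_ref) is exactly zero:
#' N_X = 2^(-median_i log2 r_X,i).  The reference channel's factor is 1 by
#' construction.  This is the median-centering normalization usually
#' preferred for isobaric-tag data.
#'
#' @inheritParams peptide_ratios
#' @return A [normalization_factors()] object.
#' @export
fit_method2 <- function(psm, reference_channel = "114") {
  if (nrow(psm) == 0L) stop("no qualified peptides")
  lr <- log2(peptide_ratios(psm, reference_channel))
  med <- apply(lr, 2L, stats::median)
  normalization_factors(2^(-med), 2L, reference_channel)
}

#' Methods 3 and 4: trend-line normalization
#'
#' Method 3 fits, per channel, a least-squares line through the origin of
#' the raw signal x_X against the reference signal x_ref; the factor is
#' the reciprocal slope.  Method 4 fits a unit-slope line (an offset) on
#' the log2 signals, log2 x_X = log2 x_ref + b, and converts the offset
#' back to a multiplicative factor 2^(-b).  These are declared
#' interpretations of the one-line "trend line" descriptions in common
#' use; see the package vignette.
#'
#' @inheritParams peptide_ratios
#' @param method 3 or 4.
#' @return A [normalization_factors()] object.
#' @export
fit_trend <- function(psm, method = 3, reference_channel = "114") {
  method <- as.integer(method)
  stopifnot(method %in% c(3L, 4L))
  if (nrow(psm) < 2L) stop("need at least 2 qualified peptides")
  ints <- as.matrix(psm[intensity_cols()])
  colnames(ints) <- itraq_channels()
  ref <- ints[, reference_channel]
  if (any(ref <= 0)) stop("reference channel has non-positive intensities")
  if (stats::var(ref) == 0 && method == 3L)
    stop("degenerate (constant) reference signals")
  fac <- if (method == 3L) {
    slopes <- colSums(ints * ref) / sum(ref^2)
    1 / slopes
  } else {
    if (any(ints <= 0)) stop("log-trend fit needs positive intensities")
    offsets <- colMeans(log2(ints) - log2(ref))
    2^(-offsets)
  }
  names(fac) <- itraq_channels()
  normalization_factors(fac, method, reference_channel)
}

#' @rdname fit_trend
#' @export
fit_method3 <- function(psm, reference_channel = "114")
  fit_trend(psm, 3, reference_channel)

#' @rdname fit_trend
#' @export
fit_method4 <- function(psm, reference_channel = "114")
  fit_trend(psm, 4, reference_channel)

#' Method 7: median log2 protein abundance ratio to zero
#'
#' Operates after rollup, on protein-level log2 ratios of one comparison:
#' returns the additive shift s = -median(log2 ratios) that centers the
#' comparison's median at zero.
#'
#' @param protein_log_ratios numeric vector of per-protein log2 abundance
#'   ratios for one comparison.
#' @return The additive shift (log2 scale).
#' @export
fit_method7 <- function(protein_log_ratios) {
  protein_log_ratios <- protein_log_ratios[is.finite(protein_log_ratios)]
  if (length(protein_log_ratios) == 0L) stop("no protein ratios")
  -stats::median(protein_log_ratios)
}

#' Apply normalization factors to a PSM table
#'
#' Multiplies each channel's intensities by its factor; record order and
#' count are preserved.
#'
#' @param psm a PSM data frame.
#' @param factors a [normalization_factors()] object.
#' @return The PSM data frame with normalized intensities.
#' @export
apply_factors <- function(psm, factors) {
  stopifnot(inherits(factors, "normalization_factors"))
  cols <- intensity_cols()
  for (k in seq_along(cols))
    psm[[cols[k]]] <- psm[[cols[k]]] * factors$factors[[k]]
  psm
}

#' Fit and apply a normalization method
#'
#' Convenience wrapper dispatching on method id 1, 2, 3 or 4 (method 7 is
#' protein-level; see [fit_method7()]).
#'
#' @inheritParams peptide_ratios
#' @param method method id.
#' @return List with `psm` (normalized table) and `factors`.
#' @export
normalize_psm <- function(psm, method = 2, reference_channel = "114") {
  method <- as.integer(method)
  factors <- switch(as.character(method),
    "1" = fit_method1(psm, reference_channel),
    "2" = fit_method2(psm, reference_channel),
    "3" = fit_trend(psm, 3, reference_channel),
    "4" = fit_trend(psm, 4, reference_channel),
    stop("unknown peptide-level normalization method: ", method)
  )
  list(psm = apply_factors(psm, factors), factors = factors)
}

#' Evaluate a normalization by the mean S value
#'
#' Under a paired design each protein yields two treatment/control ratios
#' (T1/C1 and T2/C2 for biological duplicates; T1a/C1a and T1b/C1b for
#' technical duplicates) and hence one S value, the half-difference of
#' their log2s.  A good normalization drives the mean S toward zero.  This
#' reproduces the method-comparison table workflow: normalize, roll up,
#' compute S per protein, then summarize.
#'
#' @param quant a protein quantitation table from [rollup()], computed on
#'   normalized peptides.
#' @param sd_type `"sample"` (n-1) or `"population"` (n) standard
#'   deviation over proteins.
#' @return A list with `mean_S` and `sd_S` (log2 scale) and `n_proteins`.
#' @export
evaluate_normalization <- function(quant, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (nrow(quant) < 2L) stop("need at least 2 quantified proteins")
  s <- s_value(quant$`T1/C1`, quant$`T2/C2`)
  list(mean_S = mean(s), sd_S = sd_vec(s, sd_type), n_proteins = length(s))
}

#' Duplicate-channel reproducibility
#'
#' Squared Pearson correlation of raw reporter intensities between two
#' channels across qualified peptides; used to check that technical
#' duplicate channels agree.
#'
#' @param psm a PSM data frame of qualified peptides.
#' @param channel_a,channel_b channel tags.
#' @return R-squared.
#' @export
evaluate_reproducibility <- function(psm, channel_a, channel_b) {
  if (nrow(psm) < 2L) stop("need at least 2 qualified peptides")
  a <- psm[[paste0("i", channel_a)]]
  b <- psm[[paste0("i", channel_b)]]
  if (is.null(a) || is.null(b)) stop("unknown channel tag")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("constant channel: correlation undefined")
  stats::cor(a, b)^2
}

# standard deviation with selectable divisor
sd_vec <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values for a standard deviation")
  if (sd_type == "sample") stats::sd(x)
  else sqrt(sum((x - mean(x))^2) / n)
}
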