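#' Per-protein R value (mean log2 treatment/control ratio)
#'
#' The R value of a protein is the average of the log2 of its four
#' treatment/control abundance ratios,
#' R = (log2 T1/C1 + log2 T2/C2 + log2 T2/C1 + log2 T1/C2) / 4,
#' and 2^R is the linear fold change.
#'
#' All ratio arguments are vectorized over proteins.
#'
#' @param t1c1,t2c2,t2c1,t1c2 positive abundance ratios.
#' @return R (log2 scale).
#' @examples
#' r_value(2, 2, 2, 2)  # 1: a clean 2-fold protein
#' @export
r_value <- function(t1c1, t2c2, t2c1, t1c2) {
  check_pos_ratio(t1c1, t2c2, t2c1, t1c2)
  (log2(t1c1) + log2(t2c2) + log2(t2c1) + log2(t1c2)) / 4
}

#' Per-protein ratio dispersion sigma_R
#'
#' sigma_R = (1/2) * sqrt(log2^2(C2/C1) + log2^2(T2/T1)), the spread of a
#' protein's four treatment/control log2 ratios driven by disagreement
#' between same-group samples.  Because the four log2 T/C ratios satisfy
#' log2(T1/C1) + log2(T2/C2) = log2(T2/C1) + log2(T1/C2), this closed
#' form equals the population standard deviation (divisor 4) of the four
#' log2 ratios; the equivalence is exercised in the test suite against a
#' brute-force oracle.
#'
#' @param c2c1,t2t1 positive same-group abundance ratios C2/C1 and T2/T1.
#' @return sigma_R (log2 scale, non-negative).
#' @export
sigma_r <- function(c2c1, t2t1) {
  check_pos_ratio(c2c1, t2t1)
  0.5 * sqrt(log2(c2c1)^2 + log2(t2t1)^2)
}

#' Per-protein error statistic S
#'
#' Exchanging sample C2 with T2 in the R-value equation turns the four
#' treatment/control ratios into T1/C1, C2/T2, C2/C1 and T1/T2, whose
#' mean log2 simplifies to
#' S = (log2(T1/C1) - log2(T2/C2)) / 2.
#' Under no measurement error and no biological variation the two paired
#' ratios agree and S = 0, so the spread of S across proteins measures
#' the error of the abundance ratios.  For technical-duplicate designs
#' the same formula applies to T1a/C1a and T1b/C1b.  The simplification
#' is verified in the test suite against the literal exchanged four-term
#' formula.
#'
#' @param ratio1 first paired treatment/control ratio (T1/C1).
#' @param ratio2 second paired treatment/control ratio (T2/C2).
#' @return S (log2 scale); antisymmetric in its arguments.
#' @export
s_value <- function(ratio1, ratio2) {
  check_pos_ratio(ratio1, ratio2)
  (log2(ratio1) - log2(ratio2)) / 2
}

#' Per-protein differential statistics from a quantitation table
#'
#' Computes R, sigma_R and S for every protein in a [rollup()] table.
#'
#' @param quant a [rollup()] table.
#' @return Data frame with `protein_id`, `R`, `sigma_R`, `S`.
#' @export
differential_stats <- function(quant) {
  data.frame(
    protein_id = quant$protein_id,
    R = r_value(quant$`T1/C1`, quant$`T2/C2`, quant$`T2/C1`, quant$`T1/C2`),
    sigma_R = sigma_r(quant$`C2/C1`, quant$`T2/T1`),
    S = s_value(quant$`T1/C1`, quant$`T2/C2`),
    stringsAsFactors = FALSE
  )
}

#' Derive study-level differential-expression cut-offs
#'
#' Errors in the R value (measurement error plus animal-to-animal
#' variation) are estimated by the distribution of S values across
#' proteins.  Assuming normal errors, |S| beyond z = 1.96 standard
#' deviations is significant at P < 0.05, so the cut-offs are placed at
#' M_R +/- z * sigma_S, where M_R is the median R value.
#'
#' If the S-value standard deviation of a technical-duplicate experiment
#' is supplied, the biological component is also computed via
#' [decompose_variance()].
#'
#' @param R_values per-protein R values.
#' @param S_values per-protein S values (signed; at least 2).
#' @param z normal quantile for significance (1.96 for P < 0.05).
#' @param sigma_S_technical optional sigma_S(t) from a technical-duplicate
#'   experiment.
#' @param sd_type standard-deviation convention for sigma_S over proteins:
#'   `"sample"` (n-1, default) or `"population"` (n).
#' @return An object of class `cutoff_model`: list with `M_R`, `sigma_S`,
#'   `upper_cutoff`, `lower_cutoff`, `z`, `sigma_S_technical`,
#'   `sigma_S_biological` (the latter two `NA` when not derivable).
#' @examples
#' set.seed(1)
#' S <- rnorm(1000, 0, 0.4)
#' derive_cutoffs(rnorm(1000, 0, 0.4), S)
#' @export
derive_cutoffs <- function(R_values, S_values, z = 1.96,
                           sigma_S_technical = NULL,
                           sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  R_values <- R_values[is.finite(R_values)]
  S_values <- S_values[is.finite(S_values)]
  if (length(S_values) < 2L) stop("need at least 2 S values")
  if (length(R_values) < 1L) stop("need at least 1 R value")
  sigma_S <- sd_vec(S_values, sd_type)
  M_R <- stats::median(R_values)
  sig_t <- if (is.null(sigma_S_technical)) NA_real_ else sigma_S_technical
  sig_b <- if (is.na(sig_t)) NA_real_ else decompose_variance(sigma_S, sig_t)
  structure(
    list(M_R = M_R, sigma_S = sigma_S, z = z,
         upper_cutoff = M_R + z * sigma_S,
         lower_cutoff = M_R - z * sigma_S,
         sigma_S_technical = sig_t, sigma_S_biological = sig_b,
         n_proteins = length(S_values), sd_type = sd_type),
    class = "cutoff_model"
  )
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat("Differential-expression cut-off model\n")
  cat(sprintf("  M_R      = %.4f   sigma_S = %.4f (%s sd, n = %d)\n",
              x$M_R, x$sigma_S, x$sd_type, x$n_proteins))
  cat(sprintf("  cut-offs = %.4f / %.4f  (z = %.2f)\n",
              x$upper_cutoff, x$lower_cutoff, x$z))
  if (!is.na(x$sigma_S_technical))
    cat(sprintf("  sigma_S(t) = %.4f   sigma_S(b) = %.4f\n",
                x$sigma_S_technical, x$sigma_S_biological))
  invisible(x)
}

#' Split total S-value variation into technical and biological parts
#'
#' The S-value spread of a biological-duplicate experiment carries both
#' measurement error and animal-to-animal variation; a technical-duplicate
#' experiment carries measurement error only.  Assuming independence the
#' components add in quadrature, so
#' sigma_S(b) = sqrt(sigma_S^2 - sigma_S(t)^2).
#'
#' @param sigma_S total S-value standard deviation.
#' @param sigma_S_technical technical-only standard deviation; must not
#'   exceed `sigma_S`.
#' @return sigma_S(b), the biological component.
#' @examples
#' decompose_variance(0.5, 0.3)  # 0.4
#' @export
decompose_variance <- function(sigma_S, sigma_S_technical) {
  if (sigma_S_technical < 0 || sigma_S < 0)
    stop("standard deviations must be non-negative")
  if (sigma_S_technical > sigma_S)
    stop("technical component exceeds total: negative biological variance")
  sqrt(sigma_S^2 - sigma_S_technical^2)
}

#' Classify proteins against the cut-off model
#'
#' Up-regulated when R is strictly greater than the upper cut-off,
#' down-regulated when strictly smaller than the lower cut-off, otherwise
#' unchanged.  Values exactly on a cut-off are unchanged (strict
#' inequalities).
#'
#' @param R per-protein R values.
#' @param cutoffs a [derive_cutoffs()] model.
#' @return Character vector: `"up"`, `"down"` or `"unchanged"`.
#' @export
classify <- function(R, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_model"))
  ifelse(R > cutoffs$upper_cutoff, "up",
         ifelse(R < cutoffs$lower_cutoff, "down", "unchanged"))
}

check_pos_ratio <- function(...) {
  for (v in list(...)) {
    if (any(!is.finite(v)) || any(v <= 0))
      stop("abundance ratios must be positive and finite")
  }
  invisible(TRUE)
}
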