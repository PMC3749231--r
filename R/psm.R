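#' Read a PSM table
#'
#' Reads the flat tab-separated peptide-spectrum-match (PSM) table the
#' pipeline consumes.  One row per identified spectrum, with the four
#' reporter-ion intensities and identification metadata.  The header must
#' contain exactly the documented columns:
#' `spectrum_id`, `peptide`, `ion_score`, `identity_threshold`,
#' `is_decoy` (0/1), `itraq_labeled` (0/1), `is_unique` (0/1),
#' `accessions` (semicolon-separated `ACC|species` pairs, species
#' `human` or `mouse`), `i114`, `i115`, `i116`, `i117`.
#'
#' Empty intensity cells are read as 0 -- parsing never filters; the
#' dynamic-range rule is applied later by [qualify_peptides()].
#'
#' @param path path to a TSV file with the header above.
#' @return A data frame of PSM records (class `psm_table`).
#' @seealso [write_psm_table()], [qualify_peptides()]
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  req <- psm_columns()
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L)
    stop("PSM table header lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[req]
  num_cols <- c("ion_score", "identity_threshold", intensity_cols())
  for (cc in num_cols) {
    raw <- tab[[cc]]
    raw[raw == ""] <- "0"
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      stop("malformed value in column '", cc, "' at data line ", bad,
           ": '", raw[bad], "'")
    }
    tab[[cc]] <- val
  }
  for (cc in c("is_decoy", "itraq_labeled", "is_unique")) {
    val <- tab[[cc]]
    if (!all(val %in% c("0", "1"))) {
      bad <- which(!val %in% c("0", "1"))[1]
      stop("column '", cc, "' must be 0/1; bad value at data line ", bad)
    }
    tab[[cc]] <- val == "1"
  }
  validate_psm_table(tab)
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]; intensities are written in full double
#' precision so a round trip is lossless to ~1e-15 relative.
#'
#' @param psm a PSM data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psm, path) {
  psm <- validate_psm_table(psm)
  out <- psm
  for (cc in c("is_decoy", "itraq_labeled", "is_unique"))
    out[[cc]] <- as.integer(out[[cc]])
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

psm_columns <- function() {
  c("spectrum_id", "peptide", "ion_score", "identity_threshold",
    "is_decoy", "itraq_labeled", "is_unique", "accessions",
    intensity_cols())
}

# minimal structural checks shared by readers and the simulator
validate_psm_table <- function(psm) {
  stopifnot(is.data.frame(psm))
  missing_cols <- setdiff(psm_columns(), names(psm))
  if (length(missing_cols) > 0L)
    stop("PSM table lacks column(s): ", paste(missing_cols, collapse = ", "))
  ints <- as.matrix(psm[intensity_cols()])
  if (any(!is.finite(ints)) || any(ints < 0))
    stop("reporter intensities must be finite and non-negative")
  if (any(!is.finite(psm$ion_score)) || any(!is.finite(psm$identity_threshold)))
    stop("ion_score and identity_threshold must be finite")
  if (any(!psm$is_decoy & (is.na(psm$accessions) | psm$accessions == "")))
    stop("non-decoy records must carry at least one accession")
  class(psm) <- unique(c("psm_table", class(psm)))
  psm
}

#' Parse an accession string into accession/species pairs
#'
#' Accessions are stored as `"ACC1|human;ACC2|mouse"`.
#' @param x character vector of accession strings.
#' @return A list of data frames with columns `accession`, `species`.
#' @keywords internal
parse_accessions <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(pairs) {
    parts <- strsplit(pairs, "|", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("malformed accession entry: ", pairs[bad][1])
    acc <- vapply(parts, `[`, "", 1L)
    sp <- vapply(parts, `[`, "", 2L)
    unknown <- setdiff(sp, c("human", "mouse"))
    if (length(unknown) > 0L)
      stop("unknown species tag: ", unknown[1])
    data.frame(accession = acc, species = sp, stringsAsFactors = FALSE)
  })
}

#' Select qualified peptides for quantitation
#'
#' A PSM is qualified for quantitation when it satisfies all four
#' criteria:
#'
#' 1. the peptide is labeled with iTRAQ tags;
#' 2. the identification is confident: ion score strictly greater than the
#'    identity-threshold score (Mascot identity score at P < 0.05);
#' 3. the peptide is unique (non-degenerate protein assignment);
#' 4. the reporter intensities are within the dynamic range: every channel
#'    strictly positive and the mean of the four channels at least
#'    `min_mean_intensity` ion counts (default 30).
#'
#' Decoy PSMs are never retained.  A record failing several criteria is
#' counted once, under the first failing criterion in the order 1 to 4.
#'
#' @param psm a PSM data frame (see [read_psm_table()]).
#' @param min_mean_intensity minimum mean reporter intensity (ion counts).
#' @param require_positive require every channel > 0 (criterion 4 first
#'   clause); kept switchable for diagnostics.
#' @return A `qualification_report`: list with `qualified` (the retained
#'   rows), `n_input`, `n_qualified`, `n_failed_per_criterion` (length-4
#'   named integer), `n_decoy_removed` and `labeled_fraction` (percent).
#' @examples
#' psm <- simulate_psm(simulation_config(n_proteins = 20, seed = 1))$psm
#' qc <- qualify_peptides(psm)
#' qc$n_qualified
#' @export
qualify_peptides <- function(psm, min_mean_intensity = 30,
                             require_positive = TRUE) {
  psm <- validate_psm_table(psm)
  if (nrow(psm) == 0L) stop("no PSM records to qualify")
  target <- psm[!psm$is_decoy, , drop = FALSE]
  n_decoy <- nrow(psm) - nrow(target)

  ints <- as.matrix(target[intensity_cols()])
  fail1 <- !target$itraq_labeled
  fail2 <- !(target$ion_score > target$identity_threshold)
  fail3 <- !target$is_unique
  fail4 <- (if (require_positive) apply(ints <= 0, 1L, any) else FALSE) |
    rowMeans(ints) < min_mean_intensity

  # first-failing-criterion attribution
  first_fail <- rep(0L, nrow(target))
  first_fail[fail4] <- 4L
  first_fail[fail3] <- 3L
  first_fail[fail2] <- 2L
  first_fail[fail1] <- 1L
  keep <- first_fail == 0L

  structure(
    list(
      qualified = target[keep, , drop = FALSE],
      n_input = nrow(psm),
      n_decoy_removed = n_decoy,
      n_qualified = sum(keep),
      n_failed_per_criterion = c(
        labeled = sum(first_fail == 1L),
        confident = sum(first_fail == 2L),
        unique = sum(first_fail == 3L),
        dynamic_range = sum(first_fail == 4L)
      ),
      labeled_fraction = labeling_rate(target)
    ),
    class = "qualification_report"
  )
}

#' @export
print.qualification_report <- function(x, ...) {
  cat("Peptide qualification\n")
  cat("  input PSMs:          ", x$n_input, "\n")
  cat("  decoys removed:      ", x$n_decoy_removed, "\n")
  cat("  qualified:           ", x$n_qualified, "\n")
  cat("  failed (1 labeled / 2 confident / 3 unique / 4 range): ",
      paste(x$n_failed_per_criterion, collapse = " / "), "\n")
  cat(sprintf("  iTRAQ-labeled: %.2f%%\n", x$labeled_fraction))
  invisible(x)
}

#' Decoy-based false discovery rate
#'
#' FDR = D / R x 100%, with D and R the numbers of matches above the
#' identity threshold in the decoy and real database searches.
#'
#' @param n_decoy_above_threshold D.
#' @param n_real_above_threshold R (> 0).
#' @return The FDR as a percentage.
#' @examples
#' compute_fdr(5, 100)  # 5%
#' @export
compute_fdr <- function(n_decoy_above_threshold, n_real_above_threshold) {
  stopifnot(n_decoy_above_threshold >= 0)
  if (n_real_above_threshold <= 0)
    stop("number of real matches must be positive")
  100 * n_decoy_above_threshold / n_real_above_threshold
}

#' Percentage of iTRAQ-labeled peptides
#'
#' @param psm a PSM data frame; decoys should already be excluded.
#' @return Percent of records with `itraq_labeled` set.
#' @export
labeling_rate <- function(psm) {
  if (nrow(psm) == 0L) stop("no PSM records")
  100 * sum(psm$itraq_labeled) / nrow(psm)
}
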