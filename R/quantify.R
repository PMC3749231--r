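#' Roll peptide intensities up to protein-level quantitation
#'
#' Protein quantitation uses the sum of intensities: the reporter-ion
#' intensities of all qualified peptides assigned to a protein are summed
#' per channel, and each protein abundance ratio is the quotient of two
#' channel sums.  Summation weights high-intensity peptides more, which is
#' robust to low-signal outliers.  Six ratios are reported per protein:
#' T1/C1, T2/C2, T2/C1, T1/C2 (the treatment/control set used by the R
#' statistic) plus the same-group ratios C2/C1 and T2/T1 used for
#' diagnostics and for the per-protein ratio dispersion.
#'
#' The protein grouping key is the record's full accession string; the
#' upstream search engine has already resolved degeneracy (only unique
#' peptides are qualified), so no re-grouping is attempted.
#'
#' @param qualified a PSM data frame of qualified peptides (all
#'   intensities positive), e.g. `qualify_peptides(...)$qualified`.
#' @param design a [channel_design()].
#' @return A data frame (class `protein_quant`) with one row per protein:
#'   `protein_id` (first human accession if any, else first accession),
#'   `accessions`, `species_class`, `n_unique_peptides`, the four channel
#'   sums `sum_114` ... `sum_117`, and the six ratio columns named as
#'   above.
#' @examples
#' sim <- simulate_psm(simulation_config(n_proteins = 10, seed = 1))
#' q <- qualify_peptides(sim$psm)$qualified
#' rollup(normalize_psm(q)$psm, design_biological())
#' @export
rollup <- function(qualified, design) {
  stopifnot(inherits(design, "channel_design"))
  if (nrow(qualified) == 0L) stop("no qualified peptides to roll up")
  ints <- as.matrix(qualified[intensity_cols()])
  if (any(ints <= 0))
    stop("rollup expects qualified peptides with positive intensities")

  key <- qualified$accessions
  groups <- split(seq_len(nrow(qualified)), key)
  acc_info <- parse_accessions(names(groups))

  sums <- t(vapply(groups, function(idx)
    colSums(ints[idx, , drop = FALSE]), numeric(4L)))
  colnames(sums) <- paste0("sum_", itraq_channels())

  species <- vapply(acc_info, function(a) infer_species(a$species), "")
  protein_id <- vapply(acc_info, function(a) {
    hum <- a$accession[a$species == "human"]
    if (length(hum) > 0L) hum[1] else a$accession[1]
  }, "")

  out <- data.frame(
    protein_id = protein_id,
    accessions = names(groups),
    species_class = species,
    n_unique_peptides = vapply(groups, length, 1L),
    sums,
    stringsAsFactors = FALSE,
    check.names = FALSE,
    row.names = NULL
  )
  cmp <- design_comparisons(design)
  for (lab in names(cmp)) {
    num <- out[[paste0("sum_", cmp[[lab]][1])]]
    den <- out[[paste0("sum_", cmp[[lab]][2])]]
    out[[lab]] <- num / den
  }
  out <- out[order(out$protein_id), , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("protein_quant", class(out))
  out
}

#' Classify a protein's species of origin in a xenograft sample
#'
#' Xenograft tumors mix human tumor cells with mouse host cells.  A
#' protein is classified from the species tags of all peptides assigned
#' to it:
#'
#' 1. peptides matched only human proteins: `human_only` (retained);
#' 2. peptides matched only mouse proteins: `mouse_only` (excluded from
#'    the human differential proteome);
#' 3. peptides matched both (sequence conserved between the species):
#'    `shared` (retained, flagged `+` in reports).
#'
#' @param species character vector of species tags (`"human"`/`"mouse"`)
#'   over the protein's peptide set.
#' @return One of `"human_only"`, `"mouse_only"`, `"shared"`.
#' @export
infer_species <- function(species) {
  if (length(species) == 0L) stop("empty species set")
  unknown <- setdiff(species, c("human", "mouse"))
  if (length(unknown) > 0L) stop("unknown species tag: ", unknown[1])
  has_h <- "human" %in% species
  has_m <- "mouse" %in% species
  if (has_h && has_m) "shared" else if (has_h) "human_only" else "mouse_only"
}

#' Restrict a protein table to the human proteome
#'
#' Applies the three-case xenograft rule: keep `human_only` and `shared`
#' proteins, drop `mouse_only`.
#'
#' @param quant a [rollup()] table.
#' @return The filtered table; `shared` rows keep their class for the
#'   `+` report flag.
#' @export
filter_human <- function(quant) {
  quant[quant$species_class != "mouse_only", , drop = FALSE]
}

#' Write the protein quantitation report
#'
#' One row per protein with the four treatment/control log2 ratios, the R
#' value and its dispersion, the linear fold change 2^R, and the species
#' flag (`+` marks proteins whose peptides also matched mouse proteins).
#'
#' @param quant a [rollup()] table.
#' @param stats optional per-protein statistics from
#'   [differential_stats()]; if omitted they are computed here.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path, stats = NULL) {
  if (is.null(stats)) stats <- differential_stats(quant)
  stopifnot(identical(quant$protein_id, stats$protein_id))
  out <- data.frame(
    accession = quant$protein_id,
    gene = if (is.null(quant$gene)) "" else quant$gene,
    description = if (is.null(quant$description)) "" else quant$description,
    n_unique_peptides = quant$n_unique_peptides,
    log2_T1C1 = log2(quant$`T1/C1`),
    log2_T2C2 = log2(quant$`T2/C2`),
    log2_T2C1 = log2(quant$`T2/C1`),
    log2_T1C2 = log2(quant$`T1/C2`),
    R = stats$R,
    sigma_R = stats$sigma_R,
    TC_ratio = 2^stats$R,
    species_flag = ifelse(quant$species_class == "shared", "+", ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of identified proteins that were quantified
#'
#' A protein counts as identified when any PSM (qualified or not) maps to
#' it, and quantified when at least one of its peptides is qualified.
#'
#' @param psm the full PSM table (decoys are ignored).
#' @param qualified the qualified subset.
#' @return Percentage of identified proteins with >= 1 qualified peptide.
#' @export
quantified_protein_rate <- function(psm, qualified) {
  ident <- unique(psm$accessions[!psm$is_decoy])
  if (length(ident) == 0L) stop("no identified proteins")
  100 * sum(ident %in% unique(qualified$accessions)) / length(ident)
}
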