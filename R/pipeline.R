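#' End-to-end pipeline configuration
#'
#' @param input path to a PSM TSV ([read_psm_table()] schema) or a PSM
#'   data frame.
#' @param out_dir directory for the report bundle (created if needed);
#'   `NULL` to skip writing files.
#' @param design a [channel_design()], or `"biological"` / `"technical"`
#'   for the standard layouts.
#' @param method peptide-level normalization method id (1, 2, 3 or 4).
#' @param z cut-off quantile (1.96 for P < 0.05).
#' @param sd_type sd convention for sigma_S (`"sample"` or
#'   `"population"`).
#' @param sigma_S_technical optional technical sigma_S(t) for the
#'   variance decomposition.
#' @param min_mean_intensity dynamic-range threshold (ion counts).
#' @param human_only_report restrict the differential table to the human
#'   proteome by the xenograft three-case rule (default `TRUE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir = NULL, design = "biological",
                            method = 2, z = 1.96,
                            sd_type = c("sample", "population"),
                            sigma_S_technical = NULL,
                            min_mean_intensity = 30,
                            human_only_report = TRUE) {
  if (is.character(design))
    design <- switch(match.arg(design, c("biological", "technical")),
                     biological = design_biological(),
                     technical = design_technical())
  stopifnot(inherits(design, "channel_design"))
  structure(
    list(input = input, out_dir = out_dir, design = design,
         method = as.integer(method), z = z,
         sd_type = match.arg(sd_type),
         sigma_S_technical = sigma_S_technical,
         min_mean_intensity = min_mean_intensity,
         human_only_report = human_only_report),
    class = "pipeline_config"
  )
}

#' Run the full quantitation pipeline
#'
#' Chains qualification, normalization, protein rollup, differential
#' statistics, cut-off derivation and classification, and (for xenograft
#' data) restriction of the differential table to human proteins.  When
#' `out_dir` is set, writes `qc_report.tsv`, `psm_norm.tsv`,
#' `proteins.tsv`, `differential.tsv` and `cutoffs.json`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return A list of class `pipeline_result` with `qc`
#'   (qualification report), `factors`, `quant`, `stats`, `cutoffs`,
#'   `differential` (the classified, species-filtered table) and `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[itraq4] ", ...)

  psm <- if (is.character(config$input)) {
    say("reading ", config$input)
    read_psm_table(config$input)
  } else validate_psm_table(config$input)
  say("stage qc: ", nrow(psm), " PSMs")
  qc <- qualify_peptides(psm, config$min_mean_intensity)
  if (qc$n_qualified == 0L)
    stop("qc left no qualified peptides (failures per criterion: ",
         paste(qc$n_failed_per_criterion, collapse = "/"), ")")
  say("stage qc: ", qc$n_qualified, " qualified of ", qc$n_input)

  norm <- normalize_psm(qc$qualified, config$method,
                        config$design$reference_channel)
  say("stage normalize: method ", config$method)

  quant <- rollup(norm$psm, config$design)
  say("stage quantify: ", nrow(quant), " proteins")

  stats <- differential_stats(quant)
  cutoffs <- derive_cutoffs(stats$R, stats$S, z = config$z,
                            sigma_S_technical = config$sigma_S_technical,
                            sd_type = config$sd_type)
  stats$classification <- classify(stats$R, cutoffs)
  say(sprintf("stage select: cut-offs %.4f / %.4f; %d up, %d down",
              cutoffs$upper_cutoff, cutoffs$lower_cutoff,
              sum(stats$classification == "up"),
              sum(stats$classification == "down")))

  differential <- cbind(
    quant[c("protein_id", "accessions", "species_class",
            "n_unique_peptides")],
    stats[c("R", "sigma_R", "S", "classification")]
  )
  differential$TC_ratio <- 2^differential$R
  differential$species_flag <-
    ifelse(differential$species_class == "shared", "+", "")
  if (config$human_only_report)
    differential <- filter_human(differential)

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    utils::write.table(
      data.frame(metric = c("n_input", "n_decoy_removed", "n_qualified",
                            names(qc$n_failed_per_criterion),
                            "labeled_fraction"),
                 value = c(qc$n_input, qc$n_decoy_removed, qc$n_qualified,
                           unname(qc$n_failed_per_criterion),
                           qc$labeled_fraction)),
      p("qc_report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_psm_table(norm$psm, p("psm_norm.tsv"))
    write_quant_table(quant, p("proteins.tsv"),
                      stats[c("protein_id", "R", "sigma_R", "S")])
    utils::write.table(
      format(differential, digits = 17, trim = TRUE, scientific = FALSE),
      p("differential.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(M_R = cutoffs$M_R, sigma_S = cutoffs$sigma_S, z = cutoffs$z,
           upper_cutoff = cutoffs$upper_cutoff,
           lower_cutoff = cutoffs$lower_cutoff,
           sigma_S_technical = cutoffs$sigma_S_technical,
           sigma_S_biological = cutoffs$sigma_S_biological,
           n_up = sum(stats$classification == "up"),
           n_down = sum(stats$classification == "down")),
      p("cutoffs.json"), auto_unbox = TRUE, digits = NA, na = "null")
    files <- vapply(c("qc_report.tsv", "psm_norm.tsv", "proteins.tsv",
                      "differential.tsv", "cutoffs.json"), p, "")
  }

  structure(
    list(qc = qc, factors = norm$factors, quant = quant, stats = stats,
         cutoffs = cutoffs, differential = differential, files = files),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("iTRAQ 4-plex pipeline result\n")
  cat("  qualified peptides: ", x$qc$n_qualified, "\n")
  cat("  quantified proteins:", nrow(x$quant), "\n")
  print(x$cutoffs)
  cat("  differential table: ", nrow(x$differential), " proteins (",
      sum(x$differential$classification == "up"), " up, ",
      sum(x$differential$classification == "down"), " down)\n", sep = "")
  invisible(x)
}

#' Union of two differential tables
#'
#' Merges two differential-protein tables by accession, keeping the first
#' table's row when a protein appears in both (e.g. the union of
#' small-scale and large-scale experiment results).  Merging a table with
#' itself is the identity.
#'
#' @param a,b data frames with a `protein_id` column.
#' @return The merged table.
#' @export
merge_differential <- function(a, b) {
  stopifnot("protein_id" %in% names(a), "protein_id" %in% names(b))
  out <- rbind(a, b[!b$protein_id %in% a$protein_id, , drop = FALSE])
  row.names(out) <- NULL
  out
}
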