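#' Describe a 4-plex iTRAQ channel layout
#'
#' A channel design maps the four iTRAQ reporter channels (m/z 114, 115,
#' 116, 117) to biological samples, their group (control or treatment) and
#' the kind of replication the design carries.  Two layouts cover the usual
#' experiments:
#'
#' * **biological duplicates** -- two control tumors and two treated tumors
#'   from four animals (C1/C2/T1/T2);
#' * **technical duplicates** -- one control and one treated tumor, each
#'   split in two and labeled twice (C1a/C1b/T1a/T1b).
#'
#' @param sample_id character vector of 4 sample names, in channel order
#'   114, 115, 116, 117.
#' @param group character vector of 4 values in `"control"`/`"treatment"`;
#'   exactly two of each.
#' @param replicate_kind `"technical"` or `"biological"`.
#' @param reference_channel the channel tag all peptide iTRAQ ratios are
#'   taken against (default `"114"`).
#' @return An object of class `channel_design`: a list with a `channels`
#'   data frame (columns `tag`, `sample_id`, `group`) plus
#'   `replicate_kind` and `reference_channel`.
#' @examples
#' channel_design(c("C1", "C2", "T1", "T2"),
#'                c("control", "control", "treatment", "treatment"),
#'                "biological")
#' @export
channel_design <- function(sample_id, group,
                           replicate_kind = c("biological", "technical"),
                           reference_channel = "114") {
  replicate_kind <- match.arg(replicate_kind)
  tags <- itraq_channels()
  if (length(sample_id) != 4L || anyDuplicated(sample_id))
    stop("'sample_id' must be 4 distinct sample names")
  group <- match.arg(group, c("control", "treatment"), several.ok = TRUE)
  if (length(group) != 4L || sum(group == "control") != 2L)
    stop("'group' must contain exactly 2 control and 2 treatment channels")
  if (!reference_channel %in% tags)
    stop("'reference_channel' must be one of ", paste(tags, collapse = ", "))
  structure(
    list(
      channels = data.frame(tag = tags, sample_id = as.character(sample_id),
                            group = group, stringsAsFactors = FALSE),
      replicate_kind = replicate_kind,
      reference_channel = reference_channel
    ),
    class = "channel_design"
  )
}

#' @export
print.channel_design <- function(x, ...) {
  cat("iTRAQ 4-plex channel design (", x$replicate_kind,
      " duplicates, reference ", x$reference_channel, ")\n", sep = "")
  print(x$channels, row.names = FALSE)
  invisible(x)
}

#' The four iTRAQ 4-plex reporter channel tags
#' @return `c("114", "115", "116", "117")`
#' @keywords internal
itraq_channels <- function() c("114", "115", "116", "117")

# intensity column names in the PSM table, in channel order
intensity_cols <- function() paste0("i", itraq_channels())

#' Standard biological-duplicate design (C1, C2, T1, T2)
#'
#' Channels 114/115 carry the two control tumors, 116/117 the two treated
#' tumors, each from a different animal.
#' @inheritParams channel_design
#' @return A [channel_design()].
#' @export
design_biological <- function(reference_channel = "114") {
  channel_design(c("C1", "C2", "T1", "T2"),
                 c("control", "control", "treatment", "treatment"),
                 "biological", reference_channel)
}

#' Standard technical-duplicate design (C1a, C1b, T1a, T1b)
#'
#' One control tumor split across channels 114/115 and one treated tumor
#' split across 116/117; the split halves share all biology and differ only
#' in measurement.
#' @inheritParams channel_design
#' @return A [channel_design()].
#' @export
design_technical <- function(reference_channel = "114") {
  channel_design(c("C1a", "C1b", "T1a", "T1b"),
                 c("control", "control", "treatment", "treatment"),
                 "technical", reference_channel)
}

# The six comparisons the pipeline reports, as (numerator, denominator)
# channel tags.  Controls and treatments are ordered by channel; the first
# control pairs with the first treatment (T1/C1 is 116/114 etc.).
design_comparisons <- function(design) {
  ch <- design$channels
  ctrl <- ch$tag[ch$group == "control"]
  trt  <- ch$tag[ch$group == "treatment"]
  list(
    "T1/C1" = c(trt[1], ctrl[1]),
    "T2/C2" = c(trt[2], ctrl[2]),
    "T2/C1" = c(trt[2], ctrl[1]),
    "T1/C2" = c(trt[1], ctrl[2]),
    "C2/C1" = c(ctrl[2], ctrl[1]),
    "T2/T1" = c(trt[2], trt[1])
  )
}
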