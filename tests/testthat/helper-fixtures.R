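# Build small PSM tables in code.  Defaults give a fully qualified record;
# override individual fields to violate one criterion at a time.
make_psm <- function(n = 1, i114 = 100, i115 = 100, i116 = 100, i117 = 100,
                     ion_score = 50, identity_threshold = 30,
                     is_decoy = FALSE, itraq_labeled = TRUE,
                     is_unique = TRUE, accessions = "HP00001|human",
                     peptide = "PEPTIDEK", spectrum_id = NULL) {
  if (n == 0) return(make_psm(1)[0, ])
  df <- data.frame(
    spectrum_id = if (is.null(spectrum_id)) sprintf("S%03d", seq_len(n))
                  else spectrum_id,
    peptide = peptide, ion_score = ion_score,
    identity_threshold = identity_threshold,
    is_decoy = is_decoy, itraq_labeled = itraq_labeled,
    is_unique = is_unique, accessions = accessions,
    i114 = i114, i115 = i115, i116 = i116, i117 = i117,
    stringsAsFactors = FALSE
  )
  df
}

# PSM table where every channel of record k is base[k] * bias per channel;
# used for exact normalization arithmetic.
make_biased_psm <- function(base, bias = c(1, 1, 1, 1)) {
  make_psm(n = length(base),
           i114 = base * bias[1], i115 = base * bias[2],
           i116 = base * bias[3], i117 = base * bias[4],
           accessions = sprintf("HP%05d|human", seq_along(base)))
}

write_psm_fixture <- function(psm, path = tempfile(fileext = ".tsv")) {
  itraq4::write_psm_table(psm, path)
  path
}
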