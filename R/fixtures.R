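# Access to the packaged intron catalog: 161 streptophyte mitochondrial
# group II intron insertion sites with clade occurrence and family ids,
# reconstructed from the published per-family distribution descriptions
# (per-row provenance recorded: text / inferred / schematic).

#' Load the packaged intron catalog
#'
#' Columns: `label`, `clade_occurrence` (8-character 0/1 string ordered
#' LIV, MOS, HOR, LYC, FER, GYM, ANG, SAL), `family_id`, `provenance`.
#'
#' @return data.frame of 161 insertion sites.
#' @export
intron_catalog <- function() {
  path <- system.file("extdata", "intron_catalog.tsv", package = "intronfam")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(nchar(df$clade_occurrence) == 8))
  df
}

#' Presence/absence matrix from the catalog
#'
#' @param catalog catalog data.frame (defaults to the packaged one).
#' @param embryophyte_only keep only introns present in at least one of the
#'   seven embryophyte clades, and drop the algae column's influence on row
#'   filtering only (the SAL column itself is retained).
#' @return integer matrix with clade columns.
#' @export
catalog_matrix <- function(catalog = intron_catalog(),
                           embryophyte_only = FALSE) {
  m <- t(vapply(strsplit(catalog$clade_occurrence, ""),
                function(x) as.integer(x), integer(8)))
  dimnames(m) <- list(catalog$label, CLADE_CODES)
  if (embryophyte_only) {
    emb <- rowSums(m[, setdiff(CLADE_CODES, "SAL"), drop = FALSE]) > 0
    m <- m[emb, , drop = FALSE]
  }
  m
}
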