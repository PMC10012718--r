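# Detection of degenerate "fossil" intron copies in intergenic spacers and
# pseudogenes, and the fraction of a mitogenome they occupy.

#' Scan intergenic spacers and pseudogenes for intron fossils
#'
#' Every query intron is searched (both strands, sensitive settings) against
#' all spacer and pseudogene features of the genome. Overlapping hits from
#' paralogous queries are collapsed to the best-scoring source; hits shorter
#' than `min_length` are discarded (domain V alone must not count as a
#' fossil).
#'
#' @param queries named character vector of intron sequences (names are
#'   intron labels or family ids).
#' @param bundle a [genome_bundle()]; spacers are derived from the gene
#'   annotation when not annotated explicitly.
#' @param scheme a [scoring_scheme()].
#' @param evalue_max expectation cutoff.
#' @param min_length minimum fossil hit length (nt, on the genome).
#' @return data.frame of fossil hits: `source`, `genome`, `start`, `end`
#'   (0-based half-open genomic), `strand`, `context` (`spacer` or
#'   `pseudogene`), `bits`, `evalue`, `identity`,
#'   `termini_5`, `termini_3` (alignment reaches the source intron's ends).
#' @export
scan_intergenic <- function(queries, bundle, scheme = scoring_scheme(),
                            evalue_max = 1e-5, min_length = 100) {
  if (nrow(bundle$features) == 0L)
    stop("unannotated genome: provide gene features so spacers can be derived",
         call. = FALSE)
  sp <- bundle$features[bundle$features$type == "spacer", , drop = FALSE]
  if (nrow(sp) == 0L) sp <- derive_spacers(bundle)
  ps <- bundle$features[bundle$features$type == "pseudogene", , drop = FALSE]
  targets <- rbind(
    if (nrow(sp) > 0) data.frame(context = "spacer", start = sp$start,
                                 end = sp$end, stringsAsFactors = FALSE),
    if (nrow(ps) > 0) data.frame(context = "pseudogene", start = ps$start,
                                 end = ps$end, stringsAsFactors = FALSE))
  hits <- list()
  for (qi in seq_along(queries)) {
    qname <- names(queries)[qi]
    qlen <- nchar(queries[[qi]])
    for (ti in seq_len(nrow(targets))) {
      tseq <- substr(bundle$sequence, targets$start[ti] + 1L, targets$end[ti])
      if (nchar(tseq) < 7) next
      h <- seeded_local_search(queries[[qi]], tseq, scheme,
                               evalue_max = evalue_max, query_id = qname,
                               subject_id = targets$context[ti])
      if (nrow(h) == 0L) next
      for (r in seq_len(nrow(h))) {
        # genomic coordinates of the best HSP span
        hsp1 <- strsplit(strsplit(h$hsps[r], ";")[[1]][1], "[:-]")[[1]]
        qs <- as.integer(hsp1[1]); qe <- as.integer(hsp1[2])
        ss <- as.integer(hsp1[3]); se <- as.integer(hsp1[4])
        gstart <- targets$start[ti] + ss - 1L
        gend <- targets$start[ti] + se
        if (gend - gstart < min_length) next
        hits[[length(hits) + 1L]] <- data.frame(
          source = qname, genome = bundle$id, start = gstart, end = gend,
          strand = h$strand[r], context = targets$context[ti],
          bits = h$bits[r], evalue = h$evalue[r], identity = h$identity[r],
          termini_5 = qs <= 5L, termini_3 = qe >= qlen - 4L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(source = character(0), genome = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), context = character(0),
                      bits = numeric(0), evalue = numeric(0),
                      identity = numeric(0), termini_5 = logical(0),
                      termini_3 = logical(0)))
  res <- do.call(rbind, hits)
  # collapse overlapping hits from paralogous queries: keep best bits
  res <- res[order(-res$bits), , drop = FALSE]
  ir <- IRanges::IRanges(res$start + 1L, res$end)
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1]) {
    ov <- IRanges::overlapsAny(ir[i], ir[which(keep[seq_len(i - 1)])])
    if (ov) keep[i] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a fossil hit and assign its label
#'
#' A hit in an intergenic spacer or pseudogene context is a fossil (it does
#' not splice); termini completeness records whether the alignment reaches
#' the first and last 5 nt of the source intron. Intergenic fossils are
#' labeled by their source family (`F02g2f` style); in-pseudogene fossils get
#' the gene-anchored intron label with the `f` suffix (`rps8i52g2f` style).
#'
#' @param hit one row of the [scan_intergenic()] result.
#' @param family_id family of the source intron (used for intergenic
#'   labels); `NA` for solitary sources.
#' @param source_label intron label of the source (used for pseudogene
#'   context).
#' @return list with `splicing_status`, `label`, `termini_complete`.
#' @export
classify_fossil <- function(hit, family_id = NA_character_,
                            source_label = hit$source) {
  status <- "fossil"
  label <- if (hit$context == "pseudogene") {
    paste0(site_key(source_label), "f")
  } else if (!is.na(family_id) && nzchar(family_id) && family_id != "S") {
    paste0(family_id, "g2f")
  } else {
    paste0(site_key(source_label), "f")
  }
  list(splicing_status = status, label = label,
       termini_complete = c(five = isTRUE(hit$termini_5),
                            three = isTRUE(hit$termini_3)))
}

#' Fraction of the genome covered by fossil hits
#'
#' Overlapping hit intervals are merged before counting, so shared bases are
#' counted once.
#'
#' @param bundle a [genome_bundle()].
#' @param fossil_hits data.frame from [scan_intergenic()].
#' @return percentage of genome length (0-100).
#' @export
fossil_fraction <- function(bundle, fossil_hits) {
  glen <- nchar(bundle$sequence)
  if (nrow(fossil_hits) == 0L) return(0)
  merged <- IRanges::reduce(IRanges::IRanges(fossil_hits$start + 1L,
                                             fossil_hits$end))
  100 * sum(IRanges::width(merged)) / glen
}
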