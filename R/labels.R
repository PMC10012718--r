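#' @useDynLib intronfam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Clade codes used throughout: seven embryophyte clades plus the streptophyte
# algae. "ALG" is accepted as a synonym for "SAL" (some cladogram displays use
# ALG for the algal outgroup).
CLADE_CODES <- c("LIV", "MOS", "HOR", "LYC", "FER", "GYM", "ANG", "SAL")

#' Normalize a clade code
#'
#' Maps the synonym `ALG` (algal outgroup) to `SAL` and validates against the
#' eight recognized clade codes.
#'
#' @param clade character vector of clade codes.
#' @return character vector of canonical codes.
#' @export
normalize_clade <- function(clade) {
  out <- ifelse(toupper(clade) == "ALG", "SAL", toupper(clade))
  bad <- setdiff(unique(out), CLADE_CODES)
  if (length(bad) > 0)
    stop("unknown clade code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out
}

#' Construct a group II intron label
#'
#' Builds an intron label of the form `geneiPOSg2` (optionally suffixed `f`
#' for fossil copies), naming the insertion site by the host gene and the
#' nucleotide position in the reference homologue after which the intron
#' inserts. Internal introns of twintrons prepend the host intron's label and
#' use the `ii` dialect, e.g. `atp1i1050g2ii1536g2`.
#'
#' @param gene gene symbol (e.g. `"cox2"`); for internal twintron introns the
#'   gene of the parent label is used and this argument must agree with it.
#' @param ref_position 1-based insertion position in the reference coding
#'   sequence.
#' @param intron_class `"g1"` or `"g2"`.
#' @param fossil logical; append `"f"` for a degenerate fossil copy.
#' @param twintron_parent optional parent `intron_label` for an internal
#'   twintron intron.
#' @return an object of class `intron_label`.
#' @examples
#' format(intron_label("cox2", 373, "g2"))
#' @export
intron_label <- function(gene, ref_position, intron_class = "g2",
                         fossil = FALSE, twintron_parent = NULL) {
  if (!is.character(gene) || length(gene) != 1L || !nzchar(gene))
    stop("gene must be a nonempty string", call. = FALSE)
  ref_position <- as.integer(ref_position)
  if (is.na(ref_position) || ref_position < 1L)
    stop("ref_position must be >= 1", call. = FALSE)
  if (!intron_class %in% c("g1", "g2"))
    stop("invalid intron class token: ", intron_class, call. = FALSE)
  if (!is.null(twintron_parent) && !inherits(twintron_parent, "intron_label"))
    stop("twintron_parent must be an intron_label", call. = FALSE)
  structure(list(gene = gene, ref_position = ref_position,
                 intron_class = intron_class, fossil = isTRUE(fossil),
                 twintron_parent = twintron_parent),
            class = "intron_label")
}

#' Format an intron label as a string
#'
#' @param x an `intron_label`.
#' @param ... unused.
#' @return the label string.
#' @export
format.intron_label <- function(x, ...) {
  base <- paste0(x$gene, "i", x$ref_position, x$intron_class,
                 if (x$fossil) "f" else "")
  if (!is.null(x$twintron_parent)) {
    parent <- format(x$twintron_parent)
    paste0(parent, "ii", x$ref_position, x$intron_class, if (x$fossil) "f" else "")
  } else base
}

#' @export
print.intron_label <- function(x, ...) {
  cat("<intron_label> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format_intron_label <- function(gene, ref_position, intron_class = "g2",
                                fossil = FALSE, twintron_parent = NULL) {
  format(intron_label(gene, ref_position, intron_class, fossil, twintron_parent))
}

#' Parse an intron label string
#'
#' Inverse of [format_intron_label()]. Accepts the plain dialect
#' `geneiPOS(g1|g2)[f]` and the internal-twintron dialect where the parent
#' label is prefixed and the internal position follows `ii`.
#'
#' @param label label string.
#' @return an `intron_label`.
#' @examples
#' parse_intron_label("rps8i52g2f")
#' parse_intron_label("atp1i1050g2ii1536g2")
#' @export
parse_intron_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  tw <- regmatches(label, regexec("^(.*g[12])ii([0-9]+)(g[12])(f?)$", label))[[1]]
  if (length(tw) == 5L) {
    parent <- parse_intron_label(tw[2])
    if (parent$fossil)
      stop("malformed intron label '", label, "': fossil parent in twintron dialect",
           call. = FALSE)
    return(intron_label(parent$gene, as.integer(tw[3]), tw[4],
                        fossil = nzchar(tw[5]), twintron_parent = parent))
  }
  m <- regmatches(label, regexec("^([A-Za-z][A-Za-z0-9-]*?)i([0-9]+)(g[12])(f?)$",
                                 label))[[1]]
  if (length(m) != 5L) {
    tok <- sub("^[A-Za-z][A-Za-z0-9-]*?i", "", label)
    stop("malformed intron label '", label, "' (offending token: '", tok, "')",
         call. = FALSE)
  }
  intron_label(m[2], as.integer(m[3]), m[4], fossil = nzchar(m[5]))
}

#' Insertion-site identity key of a label
#'
#' Two intron records belong to the same insertion site iff their gene,
#' reference position (and twintron parentage) match exactly; the site key is
#' the canonical non-fossil label string.
#'
#' @param label an `intron_label` or label string.
#' @return site key string.
#' @export
site_key <- function(label) {
  if (is.character(label)) label <- parse_intron_label(label)
  x <- label
  x$fossil <- FALSE
  format(x)
}

#' Map an upstream exon back to the reference insertion position
#'
#' Globally aligns the exon sequence immediately 5' of an intron to the
#' reference homologue's coding sequence and returns the 1-based reference
#' coordinate of the last reference nucleotide homologous to the final exon
#' base, i.e. the position "behind which" the intron inserts in the reference
#' numbering.
#'
#' @param host_exon_upstream nucleotide sequence of the upstream exon (5'->3').
#' @param reference_cds reference coding sequence.
#' @param scheme scoring scheme, see [scoring_scheme()].
#' @param min_identity minimum global identity for the mapping to be trusted.
#' @return integer reference position.
#' @export
reference_insertion_position <- function(host_exon_upstream, reference_cds,
                                         scheme = scoring_scheme(),
                                         min_identity = 0.5) {
  if (!nzchar(host_exon_upstream))
    stop("unmappable insertion: empty upstream exon", call. = FALSE)
  aln <- global_align(host_exon_upstream, reference_cds, scheme)
  if (aln$identity < min_identity)
    stop("unmappable insertion: no significant exon/reference alignment ",
         sprintf("(identity %.2f < %.2f)", aln$identity, min_identity),
         call. = FALSE)
  qlen <- nchar(host_exon_upstream)
  # reference column aligned to (or last before) the final exon base
  cols <- which(aln$a_idx == qlen)
  if (length(cols) == 0L)
    stop("unmappable insertion: exon end unaligned", call. = FALSE)
  ref_at_or_before <- aln$b_idx[seq_len(cols[1])]
  pos <- max(ref_at_or_before, 0L)
  if (pos < 1L)
    stop("unmappable insertion: exon end maps before reference start", call. = FALSE)
  as.integer(pos)
}

#' Assemble a validated table of intron records
#'
#' The record table is the working currency of the pipeline: one row per
#' intron copy with its parsed label, taxon and clade, genomic location
#' (0-based half-open, strand of the genome; the stored sequence is always the
#' intron 5'->3'), and termini/splicing status.
#'
#' @param label character vector of intron labels.
#' @param taxon species identifiers.
#' @param clade clade codes (see [normalize_clade()]).
#' @param genome genome identifiers.
#' @param start,end 0-based half-open interval on the genome.
#' @param strand `"+"` or `"-"`.
#' @param sequence intron sequences (T is normalized to U).
#' @param splicing_status `"functional"`, `"fossil"` or `"unknown"`.
#' @return a `data.frame` of class `intron_records`.
#' @export
intron_records <- function(label, taxon, clade, genome = taxon,
                           start = 0L, end = nchar(sequence), strand = "+",
                           sequence, splicing_status = "unknown") {
  n <- length(label)
  df <- data.frame(label = label, taxon = taxon,
                   clade = normalize_clade(clade), genome = genome,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, sequence = normalize_rna(sequence),
                   splicing_status = splicing_status,
                   stringsAsFactors = FALSE)
  parsed <- lapply(df$label, parse_intron_label)
  df$gene <- vapply(parsed, function(p) p$gene, character(1))
  df$ref_position <- vapply(parsed, function(p) p$ref_position, integer(1))
  df$site <- vapply(df$label, site_key, character(1))
  fossil <- vapply(parsed, function(p) p$fossil, logical(1))
  df$splicing_status[fossil] <- "fossil"
  if (any(df$end <= df$start))
    stop("interval end must exceed start", call. = FALSE)
  if (any(nchar(df$sequence) != df$end - df$start))
    stop("sequence length must equal interval length", call. = FALSE)
  tm <- t(vapply(df$sequence, check_termini, logical(2)))
  df$five_ok <- tm[, 1]; df$three_ok <- tm[, 2]
  class(df) <- c("intron_records", "data.frame")
  df
}

#' Normalize nucleotide text to the internal RNA alphabet
#'
#' Uppercases and converts T to U. Readers accept DNA entries; motifs and all
#' internal logic use ACGU.
#'
#' @param x character vector of sequences.
#' @return normalized sequences.
#' @export
normalize_rna <- function(x) {
  chartr("acgtuT", "ACGUUU", x)
}

#' Reverse complement in the internal RNA alphabet
#' @param x character vector of ACGU sequences.
#' @return reverse complements.
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
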