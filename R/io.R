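# Readers and writers for the standard formats the pipeline consumes:
# FASTA (via Biostrings), GFF3 or a simple feature TSV, Newick clade trees
# (via ape), and the binary presence/absence matrix.

#' Read a FASTA file
#'
#' Order-preserving; the id is the header up to the first whitespace and the
#' remainder becomes the description. Sequences are normalized to the
#' internal RNA alphabet (T -> U). Duplicate ids are an error.
#'
#' @param path FASTA file.
#' @return named character vector of sequences with a `description`
#'   attribute.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA file: ", path)
    out <- character(0)
    attr(out, "description") <- character(0)
    return(out)
  }
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
  out <- normalize_rna(as.character(ss))
  names(out) <- ids
  attr(out, "description") <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param records named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    cat(">", names(records)[i], "\n", sep = "", file = con)
    s <- records[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    for (st in starts) cat(substr(s, st, st + width - 1), "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Read genome feature annotations
#'
#' Accepts GFF3 (1-based inclusive coordinates, converted to the internal
#' 0-based half-open convention) or a simple TSV dialect with columns
#' `genome`, `type`, `start`, `end`, `strand`, `attributes` already in the
#' internal convention. Feature types used by the pipeline: `gene`, `exon`,
#' `intron`, `pseudogene`, `spacer`.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param genome_lengths optional named vector to validate coordinates
#'   against.
#' @return data.frame with columns `genome`, `type`, `start`, `end`,
#'   `strand`, `attributes` (0-based half-open).
#' @export
read_annotations <- function(path, dialect = c("gff3", "tsv"),
                             genome_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0L)
      return(data.frame(genome = character(0), type = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), attributes = character(0)))
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) != 9))
      stop("malformed GFF3: expected 9 tab-separated columns", call. = FALSE)
    df <- data.frame(genome = vapply(parts, `[`, "", 1),
                     type = vapply(parts, `[`, "", 3),
                     start = as.integer(vapply(parts, `[`, "", 4)) - 1L,
                     end = as.integer(vapply(parts, `[`, "", 5)),
                     strand = vapply(parts, `[`, "", 7),
                     attributes = vapply(parts, `[`, "", 9),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome", "type", "start", "end", "strand", "attributes")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      stop("feature TSV lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    df <- df[need]
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  }
  if (any(is.na(df$start)) || any(is.na(df$end)) || any(df$end <= df$start))
    stop("invalid feature coordinates", call. = FALSE)
  if (!is.null(genome_lengths)) {
    for (g in unique(df$genome)) {
      if (!g %in% names(genome_lengths)) next
      if (any(df$end[df$genome == g] > genome_lengths[[g]]))
        stop("feature beyond genome end in ", g, call. = FALSE)
    }
  }
  df
}

#' Bundle a genome sequence with its features
#'
#' @param id genome identifier.
#' @param sequence genome sequence.
#' @param features feature data.frame as from [read_annotations()].
#' @return an object of class `genome_bundle`.
#' @export
genome_bundle <- function(id, sequence, features) {
  sequence <- normalize_rna(sequence)
  if (nrow(features) > 0 && any(features$end > nchar(sequence)))
    stop("feature beyond genome end", call. = FALSE)
  structure(list(id = id, sequence = sequence, features = features),
            class = "genome_bundle")
}

#' Derive intergenic spacers as the complement of gene features
#'
#' @param bundle a [genome_bundle()].
#' @param min_length drop spacers shorter than this.
#' @return data.frame of spacer intervals (0-based half-open).
#' @export
derive_spacers <- function(bundle, min_length = 1) {
  genes <- bundle$features[bundle$features$type %in% c("gene", "pseudogene"), ,
                           drop = FALSE]
  glen <- nchar(bundle$sequence)
  if (nrow(genes) == 0L) {
    iv <- data.frame(start = 0L, end = glen)
  } else {
    ir <- IRanges::reduce(IRanges::IRanges(genes$start + 1L, genes$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = glen)
    iv <- data.frame(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps))
  }
  iv <- iv[iv$end - iv$start >= min_length, , drop = FALSE]
  if (nrow(iv) == 0L)
    return(data.frame(genome = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), attributes = character(0)))
  data.frame(genome = bundle$id, type = "spacer", start = iv$start,
             end = iv$end, strand = "+",
             attributes = sprintf("ID=spacer%02d", seq_len(nrow(iv))),
             stringsAsFactors = FALSE)
}

#' Read a rooted clade topology from Newick
#'
#' Leaf labels must be clade codes (`ALG` is normalized to `SAL`).
#'
#' @param path Newick file or a literal Newick string.
#' @return an `ape` `phylo` object with normalized tip labels.
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  tr$tip.label <- normalize_clade(tr$tip.label)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaves in topology", call. = FALSE)
  tr
}

#' Read a binary presence/absence matrix (TSV)
#'
#' Rows are intron labels, columns clade codes, cells 0/1.
#'
#' @param path TSV file with a leading label column.
#' @return integer matrix with intron rownames and clade colnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  if (any(is.na(m)) || !all(m %in% c(0L, 1L)))
    stop("presence/absence cells must be 0 or 1", call. = FALSE)
  rownames(m) <- labs
  colnames(m) <- normalize_clade(colnames(m))
  if (any(rowSums(m) == 0))
    stop("matrix rows with no presence: ",
         paste(labs[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  m
}

#' Write a run manifest
#'
#' Every analysis driver writes a small JSON manifest recording the
#' configuration, seed and package version so that outputs are auditable.
#'
#' @param path output JSON path.
#' @param config named list of parameters.
#' @param seed integer seed used.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NA_integer_) {
  manifest <- list(package = "intronfam",
                   version = as.character(utils::packageVersion("intronfam")),
                   seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
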