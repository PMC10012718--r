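# Intron-borne maturase annotation: ORF discovery (with a frameshift-tolerant
# mode), grading of reverse transcriptase / X / endonuclease domain
# conservation against a motif table, and protein similarity clustering.

GENETIC_CODE_STOP <- c("UAA", "UAG", "UGA")

translate_rna <- function(seq) {
  s <- chartr("U", "T", normalize_rna(seq))
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1, n)),
                                     if.fuzzy.codon = "X"))
}

#' Find candidate maturase ORFs in an intron
#'
#' Scans the intron's sense strand in all three frames for ATG-initiated
#' open reading frames of at least `min_aa` codons (standard genetic code).
#' In frameshift-tolerant mode, chains of two or more sub-ORFs (each at
#' least `min_sub_aa` codons, not necessarily ATG-initiated after the first)
#' in different frames with collinear, nearby coordinates are additionally
#' reported as a single candidate - decayed maturases frequently survive
#' only as frameshifted reading-frame fragments.
#'
#' @param intron_seq intron sequence (5'->3').
#' @param min_aa minimum ORF length in amino acids.
#' @param frameshift_tolerant also report frameshifted sub-ORF chains.
#' @param min_sub_aa minimum sub-ORF length for chain parts.
#' @param max_chain_gap maximum nucleotide gap/overlap between chained
#'   sub-ORFs.
#' @return data.frame ranked by total protein length: `start`, `end`
#'   (0-based half-open nucleotide coords within the intron), `frame`
#'   (`"chain"` for multi-part candidates), `n_parts`, `protein`.
#' @export
find_maturase_orf <- function(intron_seq, min_aa = 200,
                              frameshift_tolerant = FALSE, min_sub_aa = 60,
                              max_chain_gap = 250) {
  s <- normalize_rna(intron_seq)
  n <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      frame = character(0), n_parts = integer(0),
                      protein = character(0), stringsAsFactors = FALSE)
  if (n < 3 * min_sub_aa) return(empty)
  subs <- list()  # all maximal ORF stretches per frame (stop-to-stop)
  for (f in 0:2) {
    fs <- substr(s, f + 1, n)
    aa <- translate_rna(fs)
    if (!nzchar(aa)) next
    # maximal stop-free stretches
    parts <- gregexpr("[^*]+", aa)[[1]]
    if (parts[1] == -1) next
    lens <- attr(parts, "match.length")
    for (k in seq_along(parts)) {
      aa_start <- parts[k]; aa_len <- lens[k]
      pep <- substr(aa, aa_start, aa_start + aa_len - 1)
      # ATG-anchored ORF within the stretch
      mpos <- regexpr("M", pep)
      orf_pep <- if (mpos > 0) substr(pep, mpos, nchar(pep)) else ""
      subs[[length(subs) + 1L]] <- data.frame(
        frame = f, aa_start = aa_start, aa_len = aa_len,
        nt_start = f + (aa_start - 1L) * 3L,
        nt_end = f + (aa_start - 1L + aa_len) * 3L,
        pep = pep, orf_pep = orf_pep,
        m_offset = if (mpos > 0) as.integer(mpos) - 1L else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(subs) == 0L) return(empty)
  subs <- do.call(rbind, subs)
  out <- list()
  # single-frame ATG-initiated ORFs
  single <- subs[!is.na(subs$m_offset) &
                 nchar(subs$orf_pep) >= min_aa, , drop = FALSE]
  for (k in seq_len(nrow(single))) {
    st <- single$nt_start[k] + 3L * single$m_offset[k]
    out[[length(out) + 1L]] <- data.frame(
      start = st, end = single$nt_end[k], frame = as.character(single$frame[k]),
      n_parts = 1L, protein = single$orf_pep[k], stringsAsFactors = FALSE)
  }
  if (frameshift_tolerant) {
    cand <- subs[nchar(subs$pep) >= min_sub_aa, , drop = FALSE]
    cand <- cand[order(cand$nt_start), , drop = FALSE]
    if (nrow(cand) >= 2) {
      # greedy collinear chaining of nearby sub-ORFs in different frames
      used <- rep(FALSE, nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (used[i]) next
        chain <- i
        repeat {
          last <- chain[length(chain)]
          nxt <- which(!used & seq_len(nrow(cand)) > last &
                       cand$nt_start > cand$nt_end[last] - max_chain_gap &
                       cand$nt_start < cand$nt_end[last] + max_chain_gap &
                       cand$frame != cand$frame[last])
          if (length(nxt) == 0) break
          chain <- c(chain, nxt[1]); used[nxt[1]] <- TRUE
        }
        if (length(chain) >= 2) {
          prot <- paste(cand$pep[chain], collapse = "")
          if (nchar(prot) >= min_aa) {
            first <- chain[1]
            st <- if (!is.na(cand$m_offset[first]))
              cand$nt_start[first] + 3L * cand$m_offset[first] else cand$nt_start[first]
            pfirst <- if (!is.na(cand$m_offset[first])) cand$orf_pep[first] else cand$pep[first]
            prot <- paste(c(pfirst, cand$pep[chain[-1]]), collapse = "")
            out[[length(out) + 1L]] <- data.frame(
              start = st, end = cand$nt_end[chain[length(chain)]],
              frame = "chain", n_parts = length(chain), protein = prot,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[nchar(res$protein) >= min_aa, , drop = FALSE]
  res <- res[order(-nchar(res$protein), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Default maturase domain motif set
#'
#' Reads the packaged motif table: short peptide signatures per maturase
#' subdomain (reverse transcriptase core around the YADD catalytic motif,
#' the maturase-specific X domain, and the DNA endonuclease En domain). The
#' table is data, not code: simulator-truth motif sets are supplied the same
#' way in tests, and users can substitute curated sets.
#'
#' @return data.frame with columns `domain` (`RT`, `X`, `En`), `order`
#'   and `motif` (peptide, exact match with up to one mismatch).
#' @export
default_motif_set <- function() {
  path <- system.file("extdata", "maturase_motifs.tsv", package = "intronfam")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# fuzzy fixed-peptide search: position of first occurrence with <= max_mm
# mismatches, or -1
find_motif <- function(protein, motif, max_mm = 1) {
  n <- nchar(protein); m <- nchar(motif)
  if (n < m) return(-1L)
  pv <- strsplit(protein, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  for (i in 1:(n - m + 1)) {
    if (sum(pv[i:(i + m - 1)] != mv) <= max_mm) return(i)
  }
  -1L
}

#' Grade maturase domain conservation
#'
#' Maps motif evidence to the conservation states used for display symbols:
#' * `intact`: all queried motifs of the domain group found, in order;
#' * `partial` (reported as `rt_x = intact, en = absent`): RT and X motifs
#'   present, En motifs absent;
#' * `traces`: at least one motif found, or at least `traces_min_frac` of the
#'   expected ORF length is recognizable;
#' * `absent`: otherwise.
#'
#' @param protein protein sequence (possibly from a frameshift chain);
#'   `NULL`/empty means no ORF.
#' @param motif_set motif table, see [default_motif_set()].
#' @param expected_aa expected length of a complete maturase.
#' @param traces_min_frac length fraction that counts as traces.
#' @return list with `rt_x` in `intact`/`partial`/`traces`/`absent` and `en`
#'   in `intact`/`traces`/`absent`.
#' @export
grade_domains <- function(protein, motif_set = default_motif_set(),
                          expected_aa = 450, traces_min_frac = 0.3) {
  if (is.null(motif_set) || nrow(motif_set) == 0L)
    stop("empty motif set", call. = FALSE)
  if (is.null(protein) || !nzchar(protein))
    return(list(rt_x = "absent", en = "absent"))
  motif_set <- motif_set[order(motif_set$order), , drop = FALSE]
  pos <- vapply(motif_set$motif, function(m) find_motif(protein, m), integer(1))
  found <- pos > 0
  in_order <- function(p) all(diff(p[p > 0]) > 0) # found subset ascending
  rtx_rows <- motif_set$domain %in% c("RT", "X")
  en_rows <- motif_set$domain == "En"
  rtx_all <- all(found[rtx_rows]) && in_order(pos[rtx_rows])
  en_all <- any(en_rows) && all(found[en_rows]) && in_order(pos[en_rows])
  # traces: a strict motif hit, or (for decayed copies) a length-plausible
  # remnant that still carries a relaxed (2-mismatch) motif match
  relaxed <- vapply(motif_set$motif, function(mm)
    find_motif(protein, mm, max_mm = 2), integer(1)) > 0
  long_enough <- nchar(protein) >= traces_min_frac * expected_aa
  rt_x <- if (rtx_all) "intact"
          else if (any(found[rtx_rows]) ||
                   (long_enough && any(relaxed[rtx_rows]))) "traces"
          else "absent"
  en <- if (en_all) "intact"
        else if (any(found[en_rows])) "traces"
        else "absent"
  list(rt_x = rt_x, en = en)
}

#' Cluster maturase proteins by local similarity
#'
#' All-vs-all local protein alignment (BLOSUM-style scheme); pairs meeting
#' both the identity and the coverage threshold are linked and clusters are
#' the connected components (single linkage), deterministically ordered.
#'
#' @param proteins named character vector of protein sequences (names are
#'   site labels).
#' @param scheme a [protein_scheme()].
#' @param identity_threshold minimum identity of the best local alignment.
#' @param coverage_threshold minimum aligned fraction of the shorter
#'   protein.
#' @return data.frame: `site`, `cluster` (integer, 1-based, ordered by
#'   descending cluster size then smallest member).
#' @export
cluster_maturases <- function(proteins, scheme = protein_scheme(),
                              identity_threshold = 0.35,
                              coverage_threshold = 0.5) {
  n <- length(proteins)
  if (n == 0L) return(data.frame(site = character(0), cluster = integer(0)))
  nm <- names(proteins)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, n, name = nm)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- smith_waterman(proteins[[i]], proteins[[j]], scheme)
    shorter <- min(nchar(proteins[[i]]), nchar(proteins[[j]]))
    cov <- if (shorter > 0) r$columns / shorter else 0
    if (r$identity >= identity_threshold && cov >= coverage_threshold)
      g <- igraph::add_edges(g, c(nm[i], nm[j]))
  }
  comp <- igraph::components(g)
  groups <- split(nm, comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, `[`, "", 1))
  groups <- groups[ord]
  out <- do.call(rbind, lapply(seq_along(groups), function(k)
    data.frame(site = groups[[k]], cluster = k, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
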