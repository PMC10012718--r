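# Structural screens for group II intron hallmarks: the 34-nt catalytic
# domain V hairpin and the conserved 5'/3' splice-boundary motifs.

# Domain V layout (5'->3'): 9-nt stem strand | 2-nt bulge | 5-nt stem strand |
# 4-nt loop | 5-nt stem strand | 9-nt stem strand. The arithmetic identity
# 2*9 + 2 + 2*5 + 4 == 34 is asserted at load time.
DOMAINV_LAYOUT <- c(stem1 = 9L, bulge = 2L, stem2 = 5L, loop = 4L)
DOMAINV_LEN <- 2L * DOMAINV_LAYOUT[["stem1"]] + DOMAINV_LAYOUT[["bulge"]] +
  2L * DOMAINV_LAYOUT[["stem2"]] + DOMAINV_LAYOUT[["loop"]]
stopifnot(DOMAINV_LEN == 34L)

# Watson-Crick plus G.U wobble
is_paired <- function(x, y) {
  (x == "A" & y == "U") | (x == "U" & y == "A") |
  (x == "G" & y == "C") | (x == "C" & y == "G") |
  (x == "G" & y == "U") | (x == "U" & y == "G")
}

#' Scan a sequence for domain V candidates
#'
#' Slides a 34-nt window and tests the canonical domain V layout: a 9-bp
#' outer stem, a 2-nt bulge on the 5' side, a 5-bp inner stem and a 4-nt
#' terminal tetraloop (most often GNRA). Pairing allows Watson-Crick and G.U;
#' up to `max_mismatch_stem1`/`max_mismatch_stem2` unpaired positions are
#' tolerated per stem.
#'
#' @param seq nucleotide sequence (length >= 34).
#' @param max_mismatch_stem1,max_mismatch_stem2 per-stem mismatch tolerance.
#' @param require_gnra only report candidates whose tetraloop matches GNRA.
#' @return data.frame of candidates sorted by (mismatches, position):
#'   `position` (0-based window offset), `mm_stem1`, `mm_stem2`, `loop`,
#'   `gnra`, `score` (total paired positions).
#' @export
find_domainV <- function(seq, max_mismatch_stem1 = 1, max_mismatch_stem2 = 1,
                         require_gnra = FALSE) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  empty <- data.frame(position = integer(0), mm_stem1 = integer(0),
                      mm_stem2 = integer(0), loop = character(0),
                      gnra = logical(0), score = integer(0))
  if (n < DOMAINV_LEN) return(empty)
  ch <- strsplit(s, "")[[1]]
  starts <- seq_len(n - DOMAINV_LEN + 1L)
  res <- lapply(starts, function(st) {
    w <- ch[st:(st + DOMAINV_LEN - 1L)]
    # layout offsets within the window (1-based)
    s1a <- w[1:9]; s1b <- rev(w[26:34])
    s2a <- w[12:16]; s2b <- rev(w[21:25])
    loop <- w[17:20]
    mm1 <- sum(!is_paired(s1a, s1b))
    mm2 <- sum(!is_paired(s2a, s2b))
    if (mm1 > max_mismatch_stem1 || mm2 > max_mismatch_stem2) return(NULL)
    gnra <- loop[1] == "G" && loop[3] %in% c("A", "G") && loop[4] == "A"
    if (require_gnra && !gnra) return(NULL)
    data.frame(position = st - 1L, mm_stem1 = mm1, mm_stem2 = mm2,
               loop = paste(loop, collapse = ""), gnra = gnra,
               score = (9L - mm1) + (5L - mm2), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  res[order(res$mm_stem1 + res$mm_stem2, res$position), , drop = FALSE]
}

#' Build a zero-mismatch domain V window from stem/loop parts
#'
#' Convenience for constructing valid domain V sequences (simulator and
#' tests): given the 5' strand of each stem, the bulge and the loop, the 3'
#' strands are generated as reverse complements.
#'
#' @param stem1 9-nt 5' strand of the outer stem.
#' @param bulge 2-nt bulge.
#' @param stem2 5-nt 5' strand of the inner stem.
#' @param loop 4-nt terminal loop.
#' @return a 34-nt sequence satisfying the layout with zero mismatches.
#' @export
make_domainV <- function(stem1 = "GGGAGGUCC", bulge = "AC", stem2 = "GCGUC",
                         loop = "GAAA") {
  stopifnot(nchar(stem1) == 9, nchar(bulge) == 2, nchar(stem2) == 5,
            nchar(loop) == 4)
  paste0(normalize_rna(stem1), normalize_rna(bulge), normalize_rna(stem2),
         normalize_rna(loop), rna_revcomp(normalize_rna(stem2)),
         rna_revcomp(normalize_rna(stem1)))
}

#' Check the conserved splice-boundary motifs
#'
#' The 5' boundary is scored against the GUGCG consensus allowing one
#' mismatch; the 3' boundary requires the terminal dinucleotide A followed by
#' a pyrimidine (AY).
#'
#' @param seq intron sequence (5'->3').
#' @return logical vector `c(five_prime_ok, three_prime_ok)`.
#' @export
check_termini <- function(seq) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  if (n < 7) return(c(five_prime_ok = FALSE, three_prime_ok = FALSE))
  head5 <- strsplit(substr(s, 1, 5), "")[[1]]
  five <- sum(head5 != strsplit("GUGCG", "")[[1]]) <= 1
  last2 <- strsplit(substr(s, n - 1, n), "")[[1]]
  three <- last2[1] == "A" && last2[2] %in% c("C", "U")
  c(five_prime_ok = five, three_prime_ok = three)
}

terminus_score <- function(seq) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  if (n < 7) return(-Inf)
  head5 <- strsplit(substr(s, 1, 5), "")[[1]]
  last2 <- strsplit(substr(s, n - 1, n), "")[[1]]
  (5 - sum(head5 != strsplit("GUGCG", "")[[1]])) +
    (last2[1] == "A") + (last2[2] %in% c("C", "U"))
}

#' Correct an annotated intron boundary against the motif consensus
#'
#' Re-anchors an intron annotation by sliding each boundary within
#' `search_radius` and keeping the offsets that maximize the splice-motif
#' score plus exon reading-frame continuity (combined exon length divisible
#' by three scores a bonus). The annotation is unchanged when no shift
#' improves the score; if no candidate within the radius has acceptable
#' termini the boundary is flagged unverifiable.
#'
#' @param genome_seq host genome (or gene region) sequence.
#' @param start,end 0-based half-open annotated intron interval.
#' @param search_radius maximum shift per boundary.
#' @param exon5_start,exon3_end 0-based bounds of the flanking exons, used
#'   for the reading-frame term; defaults assume the full flanks.
#' @return list with `start`, `end`, `shift5`, `shift3`, `score`,
#'   `status` (`"unchanged"`, `"corrected"` or `"unverifiable"`).
#' @export
correct_boundaries <- function(genome_seq, start, end, search_radius = 10,
                               exon5_start = 0L, exon3_end = nchar(genome_seq)) {
  s <- normalize_rna(genome_seq)
  n <- nchar(s)
  cand <- expand.grid(d5 = -search_radius:search_radius,
                      d3 = -search_radius:search_radius)
  cand$start <- start + cand$d5
  cand$end <- end + cand$d3
  cand <- cand[cand$start >= exon5_start & cand$end <= exon3_end &
               cand$end - cand$start >= 7, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(list(start = start, end = end, shift5 = 0L, shift3 = 0L,
                score = -Inf, status = "unverifiable"))
  cand$motif <- vapply(seq_len(nrow(cand)), function(i)
    terminus_score(substr(s, cand$start[i] + 1L, cand$end[i])), numeric(1))
  # frame continuity: the spliced exon length should be a codon multiple
  exon_len <- (cand$start - exon5_start) + (exon3_end - cand$end)
  cand$frame <- as.numeric(exon_len %% 3 == 0)
  cand$score <- cand$motif + cand$frame
  # prefer the unshifted annotation on ties, then the smallest total shift
  cand$pref <- abs(cand$d5) + abs(cand$d3)
  cand <- cand[order(-cand$score, cand$pref), , drop = FALSE]
  best <- cand[1, ]
  base <- cand[cand$d5 == 0 & cand$d3 == 0, , drop = FALSE]
  base_score <- if (nrow(base) > 0) base$score[1] else -Inf
  if (best$motif < 5)  # no tolerable boundary motif pair anywhere in radius
    return(list(start = start, end = end, shift5 = 0L, shift3 = 0L,
                score = base_score, status = "unverifiable"))
  if (best$score <= base_score)
    return(list(start = start, end = end, shift5 = 0L, shift3 = 0L,
                score = base_score, status = "unchanged"))
  list(start = as.integer(best$start), end = as.integer(best$end),
       shift5 = as.integer(best$d5), shift3 = as.integer(best$d3),
       score = best$score, status = "corrected")
}
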