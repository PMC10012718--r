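# Pairwise similarity engine: scoring scheme with Karlin-Altschul statistics,
# exact affine-gap local/global alignment, and the sensitive word-seeded
# search used for the all-vs-all intron comparisons and fossil scans.

NT_ALPHA <- c("A", "C", "G", "U")
AA_ALPHA <- strsplit("ARNDCQEGHILKMFPSTWYVBJZX*", "")[[1]]

encode_nt <- function(x) {
  v <- match(strsplit(x, "")[[1]], NT_ALPHA) - 1L
  v[is.na(v)] <- 0L  # ambiguity codes scored as A; rare in practice
  v
}

encode_aa <- function(x) {
  v <- match(strsplit(x, "")[[1]], AA_ALPHA) - 1L
  v[is.na(v)] <- match("X", AA_ALPHA) - 1L
  v
}

#' Nucleotide scoring scheme with Karlin-Altschul parameters
#'
#' The default parameters are the sensitive search settings used throughout
#' the pipeline: match +2, mismatch -3, gap open 5, gap extend 2 (a gap of
#' length k costs open + k * extend), word size 7 and an expectation cutoff of
#' 1e-5. `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`; `K` uses the documented
#' continuous-walk approximation `K = H / lambda` with `H` the relative
#' entropy of the induced target frequencies (see the methods vignette; a
#' constant offset in K shifts all bit scores equally and does not affect any
#' comparative decision).
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (positive number, subtracted).
#' @param gap_open gap opening penalty (positive).
#' @param gap_extend gap extension penalty per residue (positive).
#' @param base_frequencies background base frequencies (A, C, G, U).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = 3, gap_open = 5,
                           gap_extend = 2,
                           base_frequencies = rep(0.25, 4)) {
  stopifnot(match > 0, mismatch > 0, gap_open > 0, gap_extend > 0,
            length(base_frequencies) == 4,
            abs(sum(base_frequencies) - 1) < 1e-8)
  submat <- matrix(-mismatch, 4, 4, dimnames = list(NT_ALPHA, NT_ALPHA))
  diag(submat) <- match
  ka <- karlin_altschul_params(submat, base_frequencies)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, base_frequencies = base_frequencies,
                 submat = submat, lambda = ka$lambda, K = ka$K,
                 alphabet = "nt"),
            class = "scoring_scheme")
}

#' Protein scoring scheme (BLOSUM-style)
#'
#' Wraps a substitution matrix from Biostrings (BLOSUM62 by default) for the
#' maturase protein comparisons. Karlin-Altschul parameters are computed from
#' the matrix under uniform residue frequencies over the 20 standard amino
#' acids.
#'
#' @param matrix_name name of a matrix shipped with Biostrings.
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return an object of class `scoring_scheme`.
#' @export
protein_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  data_env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = data_env)
  bl <- get(matrix_name, envir = data_env)
  submat <- matrix(-4, length(AA_ALPHA), length(AA_ALPHA),
                   dimnames = list(AA_ALPHA, AA_ALPHA))
  common <- intersect(rownames(bl), AA_ALPHA)
  submat[common, common] <- bl[common, common]
  std <- AA_ALPHA[1:20]
  p <- rep(1 / 20, 20)
  ka <- tryCatch(karlin_altschul_params(submat[std, std], p),
                 error = function(e) list(lambda = 0.267, K = 0.041))
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 base_frequencies = p, submat = submat,
                 lambda = ka$lambda, K = ka$K, alphabet = "aa"),
            class = "scoring_scheme")
}

#' Karlin-Altschul parameters for an ungapped scoring system
#'
#' `lambda` is found by bisection (to 1e-9) as the unique positive root of
#' `sum_ij p_i p_j exp(lambda s_ij) = 1`, which exists iff the expected pair
#' score is negative and some score is positive. `K` is approximated as
#' `H / lambda`, the continuous-walk (high-resolution) limit of the ungapped
#' Karlin-Altschul constant, where `H = lambda * sum_ij q_ij s_ij` is the
#' relative entropy with target frequencies
#' `q_ij = p_i p_j exp(lambda s_ij)`.
#'
#' @param submat substitution matrix.
#' @param p background letter frequencies (one per row/column of `submat`).
#' @return list with `lambda`, `K` and `H`.
#' @export
karlin_altschul_params <- function(submat, p) {
  stopifnot(nrow(submat) == length(p), ncol(submat) == length(p))
  pij <- outer(p, p)
  expected <- sum(pij * submat)
  if (expected >= 0)
    stop("no positive lambda: expected pair score is nonnegative", call. = FALSE)
  if (max(submat) <= 0)
    stop("no positive lambda: no positive score", call. = FALSE)
  f <- function(l) sum(pij * exp(l * submat)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 1e-12
  # bisection to 1e-9
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  qij <- pij * exp(lambda * submat)
  H <- lambda * sum(qij * submat)
  # crude surrogate for the ungapped K constant: H/lambda truncated at 1.
  # Any constant here shifts all bit scores equally (by -log2 K), so family
  # decisions, rankings and threshold comparisons are unaffected; lambda,
  # which scales scores, is computed exactly.
  list(lambda = lambda, K = min(1, H / lambda), H = H)
}

bit_score <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

evalue_from_bits <- function(bits, m, n) {
  m * n * 2^(-bits)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact affine-gap local alignment; serves as the oracle that the seeded
#' heuristic can never exceed. Traceback ties resolve diagonal > up > left.
#'
#' @param a,b nucleotide (or, with a protein scheme, amino acid) sequences.
#' @param scheme a [scoring_scheme()].
#' @return list with `score`, 1-based endpoints `a_start`/`a_end`/
#'   `b_start`/`b_end`, `matches`, `columns`, `identity` and per-column index
#'   vectors `a_idx`/`b_idx` (0 marks a gap).
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty", call. = FALSE)
  enc <- if (scheme$alphabet == "aa") encode_aa else encode_nt
  if (scheme$alphabet == "nt") { a <- normalize_rna(a); b <- normalize_rna(b) }
  r <- sw_align_c(enc(a), enc(b), scheme$submat, scheme$gap_open,
                  scheme$gap_extend, TRUE)
  r$identity <- if (r$columns > 0) r$matches / r$columns else 0
  r
}

#' Global alignment (Needleman-Wunsch, affine gaps) with percent identity
#'
#' Identity is matches divided by alignment columns after trimming terminal
#' gap runs, so a short sequence globally aligned into a longer one is scored
#' on the aligned core only.
#'
#' @inheritParams smith_waterman
#' @return list with `score`, `matches`, `columns` (post-trim), `identity`
#'   and per-column index vectors `a_idx`/`b_idx`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty", call. = FALSE)
  enc <- if (scheme$alphabet == "aa") encode_aa else encode_nt
  if (scheme$alphabet == "nt") { a <- normalize_rna(a); b <- normalize_rna(b) }
  r <- nw_align_c(enc(a), enc(b), scheme$submat, scheme$gap_open,
                  scheme$gap_extend)
  # trim terminal gap runs (columns where either index is 0 at the ends)
  gap <- r$a_idx == 0 | r$b_idx == 0
  keep <- rep(TRUE, length(gap))
  i <- 1L
  while (i <= length(gap) && gap[i]) { keep[i] <- FALSE; i <- i + 1L }
  i <- length(gap)
  while (i >= 1L && gap[i]) { keep[i] <- FALSE; i <- i - 1L }
  cols <- sum(keep)
  r$columns_full <- length(gap)
  r$columns <- cols
  r$a_idx_full <- r$a_idx; r$b_idx_full <- r$b_idx
  r$a_idx <- r$a_idx[keep]; r$b_idx <- r$b_idx[keep]
  r$identity <- if (cols > 0) r$matches / cols else 0
  r
}

#' Mask low-complexity tracts
#'
#' Slides a window over the sequence and lower-cases every position covered
#' by a window whose Shannon entropy (base 2, over the four nucleotides)
#' falls below the threshold. Masked positions are excluded from seeding but
#' scored normally during extension.
#'
#' @param seq nucleotide sequence.
#' @param window window length.
#' @param entropy_threshold minimum entropy (bits) for a window to stay
#'   unmasked.
#' @return the sequence with masked tracts in lower case.
#' @export
mask_low_complexity <- function(seq, window = 16, entropy_threshold = 1.0) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  if (n < window) return(s)
  ch <- strsplit(s, "")[[1]]
  code <- match(ch, NT_ALPHA)
  counts <- integer(4)
  masked <- logical(n)
  for (k in seq_len(window - 1)) if (!is.na(code[k])) counts[code[k]] <- counts[code[k]] + 1L
  for (i in window:n) {
    if (!is.na(code[i])) counts[code[i]] <- counts[code[i]] + 1L
    p <- counts / sum(counts)
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
    if (ent < entropy_threshold) masked[(i - window + 1):i] <- TRUE
    j <- i - window + 1
    if (!is.na(code[j])) counts[code[j]] <- counts[code[j]] - 1L
  }
  ch[masked] <- tolower(ch[masked])
  paste(ch, collapse = "")
}

#' Sensitive seeded local search of a query against a subject
#'
#' Reimplements a word-seeded local similarity search: exact word matches
#' (default word size 7) are clustered by diagonal, each cluster is extended
#' by optimal affine-gap local alignment within a padded window, and the
#' resulting HSPs are scored with Karlin-Altschul statistics. Both subject
#' strands are searched; the query is never reverse-complemented. Hits with
#' an E-value above `evalue_max` are dropped; survivors are sorted by bit
#' score (descending), ties by query id, subject id, position.
#'
#' Lower-case (masked, see [mask_low_complexity()]) positions never seed but
#' are scored normally during extension.
#'
#' @param query,subject nucleotide sequences (may carry lower-case masking).
#' @param scheme a [scoring_scheme()].
#' @param word_size exact-match seed length.
#' @param evalue_max expectation cutoff.
#' @param query_id,subject_id identifiers carried into the hit table.
#' @param both_strands search the subject's reverse complement as well.
#' @param pad half-width of the extension window around a seed cluster.
#' @return a `data.frame` of hits: `query`, `subject`, `strand`, `raw`,
#'   `bits`, `evalue`, `identity`, `qcov`, `n_hsps`, `hsps` (encoded as
#'   `qstart-qend:sstart-send` separated by `;`; subject coordinates are on
#'   the forward strand of the subject).
#' @export
seeded_local_search <- function(query, subject, scheme = scoring_scheme(),
                                word_size = 7, evalue_max = 1e-5,
                                query_id = "query", subject_id = "subject",
                                both_strands = TRUE, pad = 400) {
  qmasked <- grepl("[acgut]", query)
  q <- normalize_rna(query)
  if (nchar(q) < word_size) {
    warning("query shorter than word size; returning no hits")
    return(empty_hits())
  }
  qseed <- encode_seed(query)
  qenc <- encode_nt(q)
  strands <- if (both_strands) c("+", "-") else "+"
  hsps_all <- list()
  for (st in strands) {
    subj <- if (st == "+") subject else rna_revcomp(normalize_rna(subject))
    s <- normalize_rna(subj)
    if (nchar(s) < word_size) next
    sseed <- if (st == "+") encode_seed(subject) else encode_nt(s)
    senc <- encode_nt(s)
    # raw score below which no HSP can reach the E-value cutoff
    min_raw <- (log2(nchar(q) * nchar(s) / evalue_max) * log(2) +
                  log(scheme$K)) / scheme$lambda
    min_raw <- max(min_raw, 4)
    hs <- seeded_search_c(qenc, qseed, senc, sseed, scheme$submat,
                          scheme$gap_open, scheme$gap_extend,
                          as.integer(word_size), 16L, 100L, as.integer(pad), 4L,
                          min_raw)
    slen <- nchar(s)
    for (h in hs) {
      if (st == "-") {
        tmp <- h
        h$s_start <- slen - tmp$s_end + 1L
        h$s_end <- slen - tmp$s_start + 1L
      }
      h$strand <- st
      hsps_all[[length(hsps_all) + 1L]] <- h
    }
  }
  if (length(hsps_all) == 0L) return(empty_hits())
  hsp_df <- do.call(rbind, lapply(hsps_all, function(h)
    data.frame(strand = h$strand, score = h$score, q_start = h$q_start,
               q_end = h$q_end, s_start = h$s_start, s_end = h$s_end,
               matches = h$matches, columns = h$columns)))
  m <- nchar(q); n <- nchar(normalize_rna(subject))
  out <- lapply(split(hsp_df, hsp_df$strand), function(d) {
    d <- d[order(-d$score, d$q_start), , drop = FALSE]
    # drop HSPs nested in a better one on both axes
    keep <- rep(TRUE, nrow(d))
    if (nrow(d) > 1) for (i in 2:nrow(d)) for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      if (d$q_start[i] >= d$q_start[j] - 10 && d$q_end[i] <= d$q_end[j] + 10 &&
          d$s_start[i] >= d$s_start[j] - 10 && d$s_end[i] <= d$s_end[j] + 10) {
        keep[i] <- FALSE; break
      }
    }
    d <- d[keep, , drop = FALSE]
    best <- d[1, ]
    bits <- bit_score(best$score, scheme)
    ev <- evalue_from_bits(bits, m, n)
    qcov_iv <- IRanges::reduce(IRanges::IRanges(d$q_start, d$q_end))
    qcov <- sum(IRanges::width(qcov_iv)) / m
    # count non-overlapping (on the query) HSP regions
    n_regions <- length(qcov_iv)
    data.frame(query = query_id, subject = subject_id, strand = best$strand,
               raw = best$score, bits = bits, evalue = ev,
               identity = best$matches / best$columns, qcov = qcov,
               n_hsps = n_regions,
               hsps = paste(sprintf("%d-%d:%d-%d", d$q_start, d$q_end,
                                    d$s_start, d$s_end), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[res$evalue <= evalue_max, , drop = FALSE]
  res <- res[order(-res$bits, res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

encode_seed <- function(x) {
  # masked (lower-case) positions become -1 so they never form seed words
  ch <- strsplit(x, "")[[1]]
  lower <- ch %in% c("a", "c", "g", "t", "u")
  v <- match(strsplit(normalize_rna(x), "")[[1]], NT_ALPHA) - 1L
  v[is.na(v)] <- 0L
  v[lower] <- -1L
  v
}

empty_hits <- function() {
  data.frame(query = character(0), subject = character(0),
             strand = character(0), raw = numeric(0), bits = numeric(0),
             evalue = numeric(0), identity = numeric(0), qcov = numeric(0),
             n_hsps = integer(0), hsps = character(0), stringsAsFactors = FALSE)
}
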