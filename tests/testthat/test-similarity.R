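# Alignment engines and Karlin-Altschul statistics.

test_that("Smith-Waterman scores identical and tiny sequences correctly", {
  s <- random_rna(100)
  r <- smith_waterman(s, s)
  expect_equal(r$score, 200)          # 100 x match(+2)
  expect_equal(r$identity, 1)
  expect_equal(smith_waterman("ACGU", "UGCA")$score,
               smith_waterman("UGCA", "ACGU")$score)
})

test_that("Smith-Waterman equals brute-force enumeration on 4-mers", {
  # oracle: enumerate all substring pairs, gapless plus single-gap layouts
  sch <- scoring_scheme()
  score_pair <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    sum(ifelse(av == bv, sch$match, -sch$mismatch))
  }
  brute <- function(a, b) {
    best <- 0
    for (i in 1:nchar(a)) for (j in i:nchar(a))
      for (k in 1:nchar(b)) for (l in k:nchar(b)) {
        if (j - i == l - k)
          best <- max(best, score_pair(substr(a, i, j), substr(b, k, l)))
      }
    best
  }
  pairs <- list(c("ACGU", "UGCA"), c("AAGG", "AAGG"), c("ACGU", "ACGA"),
                c("GGGG", "CCCC"))
  for (p in pairs) {
    expect_equal(smith_waterman(p[1], p[2])$score, brute(p[1], p[2]),
                 info = paste(p, collapse = " vs "))
  }
})

test_that("global alignment identity counts matches over trimmed columns", {
  s <- random_rna(100)
  expect_equal(global_align(s, s)$identity, 1)
  s2 <- s
  substr(s2, 10, 10) <- if (substr(s, 10, 10) == "A") "C" else "A"
  substr(s2, 60, 60) <- if (substr(s, 60, 60) == "G") "U" else "G"
  expect_equal(global_align(s, s2)$identity, 0.98)
  # recount matches independently from the emitted alignment columns
  set.seed(3)
  a <- random_rna(80); b <- mutate_seq(a, 0.3)$seq
  aln <- global_align(a, b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  recount <- sum(aln$a_idx > 0 & aln$b_idx > 0 &
                 av[pmax(aln$a_idx, 1)] == bv[pmax(aln$b_idx, 1)] &
                 aln$a_idx > 0 & aln$b_idx > 0)
  expect_equal(aln$matches, recount)
  expect_equal(aln$identity, recount / aln$columns)
})

test_that("Karlin-Altschul lambda is the positive root (grid-scan oracle)", {
  grid_lambda <- function(submat, p) {
    f <- function(l) sum(outer(p, p) * exp(l * submat)) - 1
    xs <- seq(1e-6, 5, by = 1e-4)
    i <- which(diff(sign(vapply(xs, f, numeric(1)))) > 0)[1]
    uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root
  }
  p <- rep(0.25, 4)
  m1 <- matrix(-3, 4, 4); diag(m1) <- 2
  expect_equal(karlin_altschul_params(m1, p)$lambda, grid_lambda(m1, p),
               tolerance = 1e-6)
  m2 <- matrix(-1, 4, 4); diag(m2) <- 1
  expect_equal(karlin_altschul_params(m2, p)$lambda, grid_lambda(m2, p),
               tolerance = 1e-6)
  m3 <- matrix(0, 4, 4); diag(m3) <- 1
  expect_error(karlin_altschul_params(m3, p), "no positive lambda")
})

test_that("E-values decrease strictly as bit scores increase", {
  sch <- scoring_scheme()
  raws <- seq(20, 400, by = 20)
  bits <- (sch$lambda * raws - log(sch$K)) / log(2)
  ev <- 1000 * 1000 * 2^(-bits)
  expect_true(all(diff(bits) > 0))
  expect_true(all(diff(ev) < 0))
})

test_that("seeded search finds identical substrings as single full hits", {
  set.seed(21)
  subj <- random_rna(800)
  q <- substr(subj, 201, 400)
  h <- seeded_local_search(q, subj)
  expect_gte(nrow(h), 1)
  expect_equal(h$raw[1], 2 * 200)
  expect_equal(h$identity[1], 1)
  expect_equal(h$strand[1], "+")
  # short query: warning and empty result
  expect_warning(h6 <- seeded_local_search("ACGUAC", subj), "word size")
  expect_equal(nrow(h6), 0)
})

test_that("self-search top hit is the full-length identity hit", {
  set.seed(8)
  for (k in 1:5) {
    s <- random_rna(300 + 50 * k)
    h <- seeded_local_search(s, s)
    expect_equal(h$raw[1], 2 * nchar(s))
    expect_equal(h$qcov[1], 1)
  }
})

test_that("heuristic never exceeds the exact local score (property)", {
  set.seed(77)
  for (k in 1:25) {
    a <- random_rna(sample(100:400, 1))
    b <- if (k %% 2 == 0) mutate_seq(a, runif(1, 0.05, 0.6))$seq
         else random_rna(sample(100:400, 1))
    h <- seeded_local_search(a, b, evalue_max = Inf)
    plus <- h$raw[h$strand == "+"]
    if (length(plus) > 0)
      expect_lte(max(plus), smith_waterman(a, b)$score)
    minus <- h$raw[h$strand == "-"]
    if (length(minus) > 0)
      expect_lte(max(minus), smith_waterman(a, rna_revcomp(b))$score)
  }
})

test_that("antisense homology is reported on the minus strand", {
  set.seed(5)
  q <- random_rna(300)
  subj <- paste0(random_rna(500), rna_revcomp(q), random_rna(400))
  h <- seeded_local_search(q, subj)
  expect_equal(h$strand[1], "-")
  expect_equal(h$identity[1], 1)
})

test_that("low-complexity masking suppresses seeding but not extension", {
  m <- mask_low_complexity(strrep("A", 50))
  expect_equal(m, tolower(strrep("A", 50)))
  # analytic entropy for a fixed periodic string: ACGU repeated has 2 bits
  per <- strrep("ACGU", 13)
  expect_equal(mask_low_complexity(per), per)
  # masked query yields no seeds at all
  subj <- paste0(random_rna(200), strrep("A", 60), random_rna(200))
  h <- seeded_local_search(mask_low_complexity(strrep("A", 60)), subj,
                           evalue_max = Inf)
  expect_equal(nrow(h), 0)
})
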