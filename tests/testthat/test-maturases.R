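# Maturase ORF discovery, domain grading and protein clustering.

sim_intron_with_orf <- function(seed = 11) {
  set.seed(seed)
  p <- simulation_params(tree = "(A:0,B:0);", seed = seed)
  intronfam:::make_intron_seq(p, TRUE, default_motif_set())
}

test_that("planted maturase ORFs are recovered at their coordinates", {
  intr <- sim_intron_with_orf()
  orfs <- find_maturase_orf(intr$seq)
  expect_gte(nrow(orfs), 1)
  expect_equal(orfs$start[1], intr$orf_start)
  expect_equal(orfs$end[1], intr$orf_start + intr$orf_len - 3L)
  # no long ATG-initiated stretch in plain random sequence
  set.seed(12)
  expect_equal(nrow(find_maturase_orf(random_rna(900))), 0)
})

test_that("a single frameshift is recovered as a two-part chain", {
  intr <- sim_intron_with_orf()
  set.seed(14)
  dg <- degrade_orf(intr$seq, intr$orf_start, intr$orf_len,
                    event = "frameshift", at_frac = 0.5)
  chains <- find_maturase_orf(dg$seq, frameshift_tolerant = TRUE)
  chain <- chains[chains$frame == "chain", ]
  expect_gte(nrow(chain), 1)
  expect_equal(chain$n_parts[1], 2L)
  expect_equal(chain$start[1], intr$orf_start)
})

test_that("domain grading follows the motif-evidence rules", {
  motifs <- default_motif_set()
  intr <- sim_intron_with_orf()
  prot <- find_maturase_orf(intr$seq)$protein[1]
  g <- grade_domains(prot, motifs)
  expect_equal(g$rt_x, "intact")
  expect_equal(g$en, "intact")
  # truncation before the endonuclease motifs: partial (RT+X intact, En absent)
  gp <- grade_domains(substr(prot, 1, floor(0.72 * nchar(prot))), motifs)
  expect_equal(gp$rt_x, "intact")
  expect_equal(gp$en, "absent")
  # random protein: nothing recognizable
  set.seed(15)
  rnd <- paste(sample(setdiff(intronfam:::AA_LETTERS, "M"), 300, TRUE),
               collapse = "")
  gr <- grade_domains(rnd, motifs)
  expect_equal(gr$rt_x, "absent")
  expect_equal(gr$en, "absent")
  expect_error(grade_domains(prot, motifs[0, ]), "empty motif set")
})

test_that("grading is monotone under C-terminal truncation", {
  motifs <- default_motif_set()
  intr <- sim_intron_with_orf()
  prot <- find_maturase_orf(intr$seq)$protein[1]
  rank <- c(absent = 0, traces = 1, partial = 2, intact = 3)
  last <- Inf
  for (frac in c(1, 0.9, 0.7, 0.5, 0.3, 0.15, 0.05)) {
    g <- grade_domains(substr(prot, 1, floor(frac * nchar(prot))), motifs)
    cur <- rank[[g$rt_x]]
    expect_lte(cur, last)
    last <- cur
  }
})

test_that("protein clustering is single linkage over identity and coverage", {
  intr <- sim_intron_with_orf()
  p1 <- find_maturase_orf(intr$seq)$protein[1]
  set.seed(16)
  mutate_prot <- function(p, rate) {
    v <- strsplit(p, "")[[1]]
    hit <- runif(length(v)) < rate
    v[hit] <- sample(setdiff(intronfam:::AA_LETTERS, "M"), sum(hit), TRUE)
    paste(v, collapse = "")
  }
  p2 <- mutate_prot(p1, 0.10)
  p3 <- paste(sample(setdiff(intronfam:::AA_LETTERS, "M"), 280, TRUE),
              collapse = "")
  cl <- cluster_maturases(c(sA = p1, sB = p2, sC = p3))
  expect_equal(cl$cluster[cl$site == "sA"], cl$cluster[cl$site == "sB"])
  expect_false(cl$cluster[cl$site == "sC"] == cl$cluster[cl$site == "sA"])
  # cluster count is non-increasing as the identity threshold is lowered
  n_strict <- max(cluster_maturases(c(sA = p1, sB = p2, sC = p3),
                                    identity_threshold = 0.9)$cluster)
  n_loose <- max(cluster_maturases(c(sA = p1, sB = p2, sC = p3),
                                   identity_threshold = 0.2)$cluster)
  expect_lte(n_loose, n_strict)
})

test_that("protein alignment agrees with an independent aligner on identity", {
  skip_if_not_installed("Biostrings")
  intr <- sim_intron_with_orf()
  p1 <- find_maturase_orf(intr$seq)$protein[1]
  set.seed(17)
  v <- strsplit(p1, "")[[1]]
  hit <- runif(length(v)) < 0.15
  v[hit] <- sample(setdiff(intronfam:::AA_LETTERS, "M"), sum(hit), TRUE)
  p2 <- paste(v, collapse = "")
  sch <- protein_scheme()
  mine <- smith_waterman(p1, p2, sch)
  ref <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = "BLOSUM62", gapOpening = sch$gap_open,
    gapExtension = sch$gap_extend, type = "local")
  expect_equal(mine$score, Biostrings::score(ref))
})

test_that("simulated decay events yield the recorded truth grades", {
  motifs <- default_motif_set()
  intr <- sim_intron_with_orf()
  set.seed(18)
  # premature stop before the En motifs: truth says partial; grader agrees
  dg <- degrade_orf(intr$seq, intr$orf_start, intr$orf_len,
                    event = "stop", at_frac = 0.75)
  expect_equal(dg$grade, "partial")
  orfs <- find_maturase_orf(dg$seq)
  g <- grade_domains(orfs$protein[1], motifs)
  expect_equal(g$rt_x, "intact")
  expect_equal(g$en, "absent")
  # zero events leave the grade intact; full deletion is absent
  expect_equal(degrade_orf(intr$seq, NA_integer_, 0L)$grade, "absent")
})
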