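# Simulator: determinism, null evolution, substitution models, replay and
# truth consistency.

test_that("null evolution reproduces the root genome at every tip", {
  p <- simulation_params(tree = "((LIV:0,MOS:0):0,(HOR:0,LYC:0):0):0;",
                        retro_rate = 0, loss_prob = 0, maturase_decay = 0,
                        fossil_prob = 0, seed = 61)
  sim <- simulate_introns(p)
  seqs <- vapply(sim$genomes, function(g) g$sequence, character(1))
  expect_equal(length(unique(seqs)), 1L)
  expect_equal(nrow(sim$truth$events), 0L)
  # founders only, present everywhere
  expect_equal(sort(unique(sim$records$site)),
               sort(vapply(sim$truth$founders, function(f) f$site,
                           character(1))))
})

test_that("a fixed seed gives byte-identical simulations", {
  a <- small_sim(62)
  b <- small_sim(62)
  expect_identical(vapply(a$genomes, function(g) g$sequence, character(1)),
                   vapply(b$genomes, function(g) g$sequence, character(1)))
  expect_identical(a$truth$events, b$truth$events)
  expect_error(simulation_params(tree = "(A,B);", seed = 1),
               "branch lengths")
  expect_error(simulation_params(tree = "(A:1,B:1);"), "seed")
})

test_that("JC69 substitution counts match the closed form within 3 SE", {
  set.seed(63)
  s <- random_rna(10000)
  d <- 0.1
  p_expected <- 3 / 4 * (1 - exp(-4 * d / 3))
  obs <- mutate_seq(s, d)
  phat <- length(obs$positions) / nchar(s)
  se <- sqrt(p_expected * (1 - p_expected) / nchar(s))
  expect_lt(abs(phat - p_expected), 3 * se)
  expect_identical(mutate_seq(s, 0)$seq, s)
})

test_that("K2P with kappa 1 matches the JC69 substitution fraction", {
  set.seed(64)
  s <- random_rna(20000)
  d <- 0.15
  p_expected <- 3 / 4 * (1 - exp(-4 * d / 3))
  k2p <- mutate_seq(s, d, model = "K2P", kappa = 1)
  phat <- length(k2p$positions) / nchar(s)
  se <- sqrt(p_expected * (1 - p_expected) / nchar(s))
  expect_lt(abs(phat - p_expected), 3 * se)
  # transitions enriched at high kappa
  k2p9 <- mutate_seq(s, d, model = "K2P", kappa = 9)
  sv <- strsplit(s, "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "U", U = "C")
  is_ts <- ts_map[sv[k2p9$positions]] == k2p9$bases
  expect_gt(mean(is_ts), 0.6)
})

test_that("replaying the event log reproduces tip genomes byte-for-byte", {
  sim <- small_sim(65, loss_prob = 0.15, fossil_prob = 0.5)
  rebuilt <- replay_truth(sim)
  emitted <- vapply(sim$genomes, function(g) g$sequence, character(1))
  expect_identical(rebuilt[names(emitted)], emitted)
})

test_that("the truth matrix from events equals the matrix from genomes", {
  sim <- small_sim(66, loss_prob = 0.2)
  m_rec <- build_matrix(sim$records,
                        clades = sort(unique(sim$records$clade)))
  m_ev <- truth_matrix_from_events(sim)
  common <- intersect(rownames(m_rec), rownames(m_ev))
  expect_setequal(rownames(m_rec), rownames(m_ev))
  expect_equal(m_rec[common, colnames(m_ev)], m_ev[common, ])
})

test_that("emitted intron records carry the simulated hallmarks", {
  sim <- small_sim(67)
  expect_true(all(sim$records$end - sim$records$start ==
                  nchar(sim$records$sequence)))
  # founders were built with proper termini; most records retain them
  expect_gt(mean(sim$records$five_ok), 0.7)
  # most introns retain a recognizable domain V layout after divergence
  idx <- seq_len(min(10, nrow(sim$records)))
  with_dv <- vapply(sim$records$sequence[idx], function(s)
    nrow(find_domainV(s, max_mismatch_stem1 = 2,
                      max_mismatch_stem2 = 2)) > 0, logical(1))
  expect_gt(mean(with_dv), 0.5)
})
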