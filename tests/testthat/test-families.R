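# MDO cutoffs, family graph rules, gating, clustering and refinement.

make_records <- function(seqs, sites, taxa) {
  intron_records(label = sites, taxon = taxa,
                 clade = rep(c("LIV", "MOS", "HOR", "LYC", "FER", "GYM",
                               "ANG", "SAL"), length.out = length(sites)),
                 sequence = seqs)
}

test_that("all-vs-all scores every unordered pair once", {
  set.seed(31)
  s <- random_rna(400)
  recs <- make_records(c(s, s, s), rep("cox1i100g2", 3),
                       c("ta", "tb", "tc"))
  h <- all_vs_all(recs)
  expect_equal(nrow(h), 3)                     # 3 unordered pairs
  expect_true(all(h$identity == 1))
  expect_true(all(h$qcov == 1))
  expect_warning(h1 <- all_vs_all(recs[1, ]), "fewer than two")
  expect_equal(nrow(h1), 0)
})

test_that("MDO cutoffs are the minimum orthologue-pair bit score", {
  # three orthologues at one site with different divergences
  set.seed(32)
  base <- random_rna(500)
  recs <- make_records(c(base, mutate_seq(base, 0.05)$seq,
                         mutate_seq(base, 0.4)$seq),
                       rep("nad5i230g2", 3), c("ta", "tb", "tc"))
  h <- all_vs_all(recs)
  cut <- compute_mdo_cutoffs(h, recs)
  same <- h[h$query_site == h$subject_site, ]
  expect_equal(cut$mdo_bitscore, min(same$bits))
  expect_equal(cut$n_ortholog_pairs + cut$n_missing, 3L)
  # single-member sites get the infinite sentinel, never an error
  solo <- make_records(random_rna(300), "cobi100g2", "tx")
  both <- rbind(recs, solo)
  h2 <- all_vs_all(both)
  cut2 <- compute_mdo_cutoffs(h2, both)
  expect_true(is.infinite(cut2$mdo_bitscore[cut2$site == "cobi100g2"]))
})

test_that("edges follow the one-sided cutoff rule with significance gate", {
  cutoffs <- data.frame(site = c("A", "B"), mdo_bitscore = c(95, 200),
                        n_ortholog_pairs = 1L, n_missing = 0L,
                        n_members = 2L)
  hit <- function(bits) data.frame(
    query = "a1", subject = "b1", strand = "+", raw = bits, bits = bits,
    evalue = 1e-10, identity = 0.8, qcov = 0.5, n_hsps = 1L, hsps = "1-10:1-10",
    query_site = "A", subject_site = "B", query_taxon = "ta",
    subject_taxon = "tb", stringsAsFactors = FALSE)
  g150 <- build_family_graph(hit(150), cutoffs)
  expect_equal(igraph::ecount(g150), 1)        # exceeds A's cutoff only
  g80 <- build_family_graph(hit(80), cutoffs)
  expect_equal(igraph::ecount(g80), 0)
  g2s <- build_family_graph(hit(150), cutoffs, two_sided = TRUE)
  expect_equal(igraph::ecount(g2s), 0)
  # significance gate dominates
  h <- hit(150); h$evalue <- 1
  expect_equal(igraph::ecount(build_family_graph(h, cutoffs)), 0)
})

test_that("low-score edges need multiple regions or coverage to survive", {
  cutoffs <- data.frame(site = c("A", "B"), mdo_bitscore = c(50, 50),
                        n_ortholog_pairs = 1L, n_missing = 0L, n_members = 2L)
  base <- data.frame(query = "a1", subject = "b1", strand = "+",
                     raw = 150, bits = 150, evalue = 1e-12, identity = 0.8,
                     qcov = 0.1, n_hsps = 1L, hsps = "1-30:1-30",
                     query_site = "A", subject_site = "B",
                     query_taxon = "ta", subject_taxon = "tb",
                     stringsAsFactors = FALSE)
  g1 <- gate_low_score_edges(build_family_graph(base, cutoffs))
  expect_equal(igraph::ecount(g1), 0)
  expect_length(attr(g1, "gated_edges"), 1)
  multi <- base; multi$n_hsps <- 2L
  expect_equal(igraph::ecount(gate_low_score_edges(
    build_family_graph(multi, cutoffs))), 1)
  cov <- base; cov$qcov <- 0.4
  expect_equal(igraph::ecount(gate_low_score_edges(
    build_family_graph(cov, cutoffs))), 1)
  high <- base; high$bits <- 250; high$raw <- 250
  expect_equal(igraph::ecount(gate_low_score_edges(
    build_family_graph(high, cutoffs))), 1)
})

test_that("families are connected components with canonical numbering", {
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 6, name = c("c1", "a1", "b1", "d1", "e1", "f1"))
  g <- igraph::add_edges(g, c("a1", "b1", "b1", "c1", "d1", "e1"),
                         bits = 300, n_hsps = 1, qcov = 0.9, rule = "mdo")
  fam <- cluster_families(g)
  # chain a1-b1-c1 is one family (single linkage), numbered before the pair
  expect_equal(fam$family[fam$site %in% c("a1", "b1", "c1")],
               rep("F01", 3))
  expect_equal(fam$family[fam$site %in% c("d1", "e1")], rep("F02", 2))
  expect_equal(fam$family[fam$site == "f1"], "S")
  # order independence: same result from a permuted vertex order
  perm <- igraph::make_empty_graph(directed = FALSE)
  perm <- igraph::add_vertices(perm, 6, name = c("f1", "e1", "d1", "c1", "b1", "a1"))
  perm <- igraph::add_edges(perm, c("b1", "a1", "c1", "b1", "e1", "d1"),
                            bits = 300, n_hsps = 1, qcov = 0.9, rule = "mdo")
  expect_equal(cluster_families(perm), fam)
})

test_that("positional orthologues are rescued or flagged, never moved", {
  sites <- c("cox1i10g2", "nad1i20g2", "cobi30g2")
  assignments <- data.frame(site = sites,
                            family = c("F01", "F01", "F02"),
                            family_size = c(2L, 2L, 2L), rule = "mdo",
                            stringsAsFactors = FALSE)
  recs <- make_records(c(random_rna(300), random_rna(300), random_rna(300)),
                       sites, c("ta", "tb", "tc"))
  # no hits at all: distant orthologue stays by position
  none <- all_vs_all(recs)[0, ]
  ref <- refine_positional_orthologs(assignments, recs, none)
  expect_equal(ref$rule[ref$site == "cox1i10g2"], "positional_rescue")
  # strong hit to another family: flagged as conflict, family unchanged
  conflict <- data.frame(query = "cox1i10g2.ta", subject = "cobi30g2.tc",
                         strand = "+", raw = 300, bits = 300, evalue = 1e-30,
                         identity = 0.9, qcov = 0.8, n_hsps = 1L,
                         hsps = "1-100:1-100", query_site = "cox1i10g2",
                         subject_site = "cobi30g2", query_taxon = "ta",
                         subject_taxon = "tc", stringsAsFactors = FALSE)
  ref2 <- refine_positional_orthologs(assignments, recs, conflict)
  expect_equal(ref2$rule[ref2$site == "cox1i10g2"], "conflicting_positional")
  expect_equal(ref2$family[ref2$site == "cox1i10g2"], "F01")
  expect_equal(ref2$best_other_family[ref2$site == "cox1i10g2"], "F02")
})

test_that("maturase clusters extend families into superfamilies", {
  asg <- data.frame(site = c("a1", "a2", "b1", "b2", "c1", "d1"),
                    family = c("F01", "F01", "F02", "F02", "S", "S"),
                    family_size = c(2L, 2L, 2L, 2L, 1L, 1L),
                    rule = c(rep("mdo", 4), "none", "none"),
                    stringsAsFactors = FALSE)
  # cluster spanning two families plus a solitary
  sf <- assemble_superfamilies(asg, data.frame(site = c("a1", "b1", "c1"),
                                               cluster = 1))
  expect_equal(unique(sf$superfamily[sf$family %in% c("F01", "F02")]),
               "SF01-02")
  expect_equal(sf$rule[sf$site == "c1"], "maturase_link")
  # no overlap: unchanged
  un <- assemble_superfamilies(asg, data.frame(site = character(0),
                                               cluster = integer(0)))
  expect_equal(un$family, asg$family[order(asg$family, asg$site)])
  # solitary-only cluster becomes a maturase-based family after the cores
  mf <- assemble_superfamilies(asg, data.frame(site = c("c1", "d1"),
                                               cluster = 1))
  expect_equal(unique(mf$family[mf$site %in% c("c1", "d1")]), "mF03")
})

test_that("a repeat-driven spurious link is removed by masking plus gating", {
  set.seed(41)
  repeat_tract <- strrep("AAAU", 20)
  a <- paste0(random_rna(150), repeat_tract, random_rna(150))
  b <- paste0(random_rna(150), repeat_tract, random_rna(150))
  recs <- make_records(c(a, b), c("cox1i10g2", "nad1i20g2"), c("ta", "tb"))
  h <- all_vs_all(recs, mask = TRUE)
  cut <- compute_mdo_cutoffs(h, recs)
  g <- gate_low_score_edges(build_family_graph(h, cut))
  fam <- cluster_families(g)
  expect_true(all(fam$family == "S"))
})
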