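# Presence/absence analytics: matrix building, Euler counts, weighted
# Sankoff parsimony, topology comparison and weight selection.

test_that("matrix building excludes fossils and validates clades", {
  recs <- intron_records(
    label = c("cox1i100g2", "cox1i100g2", "nad5i20g2f"),
    taxon = c("t1", "t2", "t3"), clade = c("MOS", "MOS", "LYC"),
    sequence = c(random_rna(60), random_rna(60), random_rna(60)))
  m <- build_matrix(recs)
  expect_equal(sum(m["cox1i100g2", ]), 1L)     # two records, one clade
  expect_equal(m["cox1i100g2", "MOS"], 1L)
  expect_false("nad5i20g2" %in% rownames(m)[rowSums(m) > 0])
  expect_length(attr(m, "excluded"), 1)
  expect_error(intron_records(label = "cox1i100g2", taxon = "t",
                              clade = "XXX", sequence = random_rna(10)),
               "unknown clade")
})

test_that("Euler region counts enumerate exactly and conserve totals", {
  m <- matrix(c(1, 0, 1,
                0, 1, 1,
                0, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("i1", "i2", "i3"), c("LIV", "MOS", "HOR")))
  ec <- euler_counts(m, list(A = "LIV", B = c("MOS", "HOR")))
  expect_equal(ec$count[ec$region == "A"], 0L)       # i1 is in both
  expect_equal(ec$count[ec$region == "B"], 2L)
  expect_equal(ec$count[ec$region == "A&B"], 1L)
  expect_equal(sum(ec$count), nrow(m))
  # identical sets: intersection only
  ec2 <- euler_counts(m, list(A = "LIV", B = "LIV"))
  expect_equal(ec2$count[ec2$region == "A&B"], 1L)
  expect_equal(ec2$count[ec2$region %in% c("A", "B")], c(0L, 0L))
  expect_error(euler_counts(m, list(a = "LIV", b = "LIV", c = "LIV",
                                    d = "LIV", e = "LIV")), "at most 4")
})

test_that("forced optima come out exactly", {
  nle <- preset_topology("NLE_HT")
  all_present <- matrix(1L, 1, 8,
                        dimnames = list("x", c("LIV", "MOS", "HOR", "LYC",
                                               "FER", "GYM", "ANG", "SAL")))
  r <- sankoff_gainloss(all_present, nle)
  expect_equal(r$totals$gains, 1L)   # one root-stem gain
  expect_equal(r$totals$losses, 0L)
  one <- all_present; one[1, ] <- 0L; one[1, "MOS"] <- 1L
  r1 <- sankoff_gainloss(one, nle)
  expect_equal(r1$totals$gains, 1L)
  expect_equal(r1$totals$losses, 0L)
  expect_equal(r1$events$branch, "MOS")
  expect_error(sankoff_gainloss(one, nle, w_gain = 0), "positive")
})

test_that("the textbook 4-leaf case prefers one gain plus two losses", {
  phy <- read_newick("((LIV,MOS),(HOR,LYC));")
  m <- matrix(c(1L, 0L, 1L, 0L), 1, 4,
              dimnames = list("x", c("LIV", "MOS", "HOR", "LYC")))
  r <- sankoff_gainloss(m, phy, 4, 1)
  expect_equal(r$totals$gains, 1L)
  expect_equal(r$totals$losses, 2L)
  expect_equal(r$totals$cost, 6)
  expect_equal(brute_gainloss_cost(phy, c(1L, 0L, 1L, 0L), 4, 1), 6)
})

test_that("weighted cost equals the exhaustive oracle (random instances)", {
  set.seed(99)
  for (k in 1:120) {
    nt <- sample(3:8, 1)
    phy <- ape::rtree(nt)
    phy$tip.label <- paste0("t", seq_len(nt))
    states <- sample(0:1, nt, TRUE)
    if (all(states == 0)) states[sample.int(nt, 1)] <- 1L
    w <- sample(c(1, 2, 4, 8), 1)
    m <- matrix(states, 1, nt, dimnames = list("x", phy$tip.label))
    r <- sankoff_gainloss(m, phy, w, 1)
    expect_equal(r$totals$cost,
                 brute_gainloss_cost(phy, states, w, 1),
                 info = sprintf("instance %d", k))
  }
})

test_that("totals decompose per intron and respect weight monotonicity", {
  set.seed(100)
  nle <- preset_topology("NLE_HT")
  m <- matrix(sample(0:1, 20 * 8, TRUE, prob = c(0.6, 0.4)), 20, 8,
              dimnames = list(sprintf("i%02d", 1:20), nle$tip.label))
  m[rowSums(m) == 0, 1] <- 1L
  r <- sankoff_gainloss(m, nle, 4, 1)
  expect_equal(r$totals$gains, sum(r$per_intron$gains))
  expect_equal(r$totals$losses, sum(r$per_intron$losses))
  gains_by_w <- vapply(c(1, 2, 4, 8), function(w)
    sankoff_gainloss(m, nle, w, 1)$totals$gains, numeric(1))
  expect_true(all(diff(gains_by_w) <= 0))
})

test_that("topology comparison reports totals and differences", {
  nle <- preset_topology("NLE_HT"); bry <- preset_topology("BRY_SET")
  m <- catalog_matrix(embryophyte_only = TRUE)[1:10, ]
  same <- compare_topologies(m, nle, nle)
  expect_equal(same$gains[3], 0)
  expect_equal(same$cost[3], 0)
  cmp <- compare_topologies(m, nle, bry)
  expect_equal(cmp$steps, cmp$gains + cmp$losses)
  # toy matrix verified against the exhaustive oracle on both topologies
  toy <- matrix(c(1, 0, 1, 0, 0, 0, 0, 0,
                  1, 1, 0, 0, 0, 0, 0, 1,
                  0, 0, 1, 1, 1, 0, 0, 0), 3, 8, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), nle$tip.label))
  for (topo in list(nle, bry)) {
    r <- sankoff_gainloss(toy, topo, 4, 1)
    oracle <- sum(vapply(1:3, function(i)
      brute_gainloss_cost(topo, toy[i, topo$tip.label], 4, 1), numeric(1)))
    expect_equal(r$totals$cost, oracle)
  }
})

test_that("weight selection follows the lowest-eligible-gains rule", {
  nle <- preset_topology("NLE_HT")
  # no homoplasy: every weighting yields one gain per intron
  clean <- matrix(0L, 3, 8, dimnames = list(c("a", "b", "c"), nle$tip.label))
  clean[1, c("LIV", "MOS")] <- 1L
  clean[2, "HOR"] <- 1L
  clean[3, c("GYM", "ANG")] <- 1L
  sel <- select_weight(clean, nle)
  expect_true(sel$indifferent)
  expect_equal(unname(sel$chosen["w_gain"]), 8)
  expect_equal(nrow(sel$table), 4)
  # a disjunct pattern inflates gains at 1:1; selection avoids the excess
  hom <- matrix(0L, 1, 8, dimnames = list("z", nle$tip.label))
  hom[1, c("LIV", "ANG")] <- 1L
  sel2 <- select_weight(hom, nle, target_gains = 1)
  tab <- sel2$table
  expect_gt(tab$gains[tab$w_gain == 1], tab$gains[tab$w_gain == 8])
  expect_equal(unname(sel2$chosen["w_gain"]), 8)
  # single-intron matrix: table still has all four candidate rows
  expect_equal(nrow(select_weight(hom, nle)$table), 4)
})
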