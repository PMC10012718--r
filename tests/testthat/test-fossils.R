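# Fossil intron detection in intergenic spacers and genome-fraction
# accounting.

make_fossil_genome <- function(seed = 51, divergence = 0.15,
                               antisense = FALSE) {
  set.seed(seed)
  intron <- paste0("GUGCG", random_rna(650), make_domainV(), "AC")
  fossil <- mutate_seq(intron, divergence)$seq
  if (antisense) fossil <- rna_revcomp(fossil)
  spacer1 <- random_rna(400)
  spacer2 <- paste0(random_rna(200), fossil, random_rna(300))
  gene1 <- random_rna(900)
  gene2 <- random_rna(900)
  seq <- paste0(spacer1, gene1, spacer2, gene2)
  feats <- data.frame(
    genome = "toy", type = "gene",
    start = c(400L, 400L + 900L + nchar(spacer2)),
    end = c(1300L, 400L + 900L + nchar(spacer2) + 900L),
    strand = "+", attributes = c("ID=g1", "ID=g2"), stringsAsFactors = FALSE)
  list(bundle = genome_bundle("toy", seq, feats), intron = intron,
       fossil_start = 400L + 900L + 200L,
       fossil_end = 400L + 900L + 200L + nchar(fossil))
}

test_that("a planted degenerate copy is recovered with its source", {
  fx <- make_fossil_genome()
  hits <- scan_intergenic(c(nad5i700g2 = fx$intron), fx$bundle)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$source, "nad5i700g2")
  expect_equal(hits$context, "spacer")
  expect_equal(hits$strand, "+")
  expect_lte(hits$evalue, 1e-5)
  # recovered interval overlaps the planted one substantially
  ov <- min(hits$end, fx$fossil_end) - max(hits$start, fx$fossil_start)
  expect_gte(ov / (fx$fossil_end - fx$fossil_start), 0.9)
})

test_that("genomes without fossils yield empty results", {
  set.seed(52)
  seq <- paste0(random_rna(300), random_rna(800), random_rna(300))
  feats <- data.frame(genome = "g", type = "gene", start = 300L,
                      end = 1100L, strand = "+", attributes = "ID=g1")
  b <- genome_bundle("g", seq, feats)
  expect_equal(nrow(scan_intergenic(c(x1i10g2 = random_rna(500)), b)), 0)
  # unannotated genome: explicit error
  b0 <- genome_bundle("g", seq, feats[0, ])
  expect_error(scan_intergenic(c(x1i10g2 = random_rna(500)), b0),
               "unannotated")
})

test_that("antisense fossils are found on the minus strand", {
  fx <- make_fossil_genome(seed = 53, antisense = TRUE)
  hits <- scan_intergenic(c(cobi300g2 = fx$intron), fx$bundle)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
})

test_that("fossil classification assigns status, termini and labels", {
  fx <- make_fossil_genome(seed = 54, divergence = 0.08)
  hits <- scan_intergenic(c(rps8i52g2 = fx$intron), fx$bundle)
  expect_true(hits$termini_5[1] && hits$termini_3[1])
  cls <- classify_fossil(hits[1, ], family_id = "F02")
  expect_equal(cls$splicing_status, "fossil")
  expect_equal(cls$label, "F02g2f")
  hits$context <- "pseudogene"
  cls2 <- classify_fossil(hits[1, ], family_id = "F02")
  expect_equal(cls2$label, "rps8i52g2f")
  # fossil preserving only the intron interior: termini incomplete when
  # queried with the full source intron
  set.seed(57)
  partial <- substr(fx$intron, 150, 450)
  spacer <- paste0(random_rna(200), mutate_seq(partial, 0.05)$seq,
                   random_rna(200))
  seq2 <- paste0(spacer, random_rna(900))
  b2 <- genome_bundle("p", seq2, data.frame(
    genome = "p", type = "gene", start = nchar(spacer),
    end = nchar(spacer) + 900L, strand = "+", attributes = "ID=g1"))
  h3 <- scan_intergenic(c(rps8i52g2 = fx$intron), b2)
  expect_gte(nrow(h3), 1)
  cls3 <- classify_fossil(h3[1, ], family_id = "F02")
  expect_false(any(cls3$termini_complete))
})

test_that("fossil fraction merges overlaps and matches planted truth", {
  # arithmetic: two disjoint 500-nt fossils in a 25 kb genome are 4 percent
  b <- genome_bundle("g", strrep("A", 25000),
                     data.frame(genome = "g", type = "gene", start = 0L,
                                end = 100L, strand = "+", attributes = "x"))
  fh <- data.frame(source = c("a", "b"), genome = "g",
                   start = c(1000L, 3000L), end = c(1500L, 3500L),
                   strand = "+", context = "spacer", bits = 100,
                   evalue = 1e-10, identity = 0.9,
                   termini_5 = TRUE, termini_3 = TRUE)
  expect_equal(fossil_fraction(b, fh), 4.0)
  # overlapping hits are counted once
  fh2 <- fh
  fh2$start <- c(100L, 200L); fh2$end <- c(300L, 400L)
  expect_equal(fossil_fraction(b, fh2), 100 * 300 / 25000)
  # planted fraction recovered within half a percentage point
  fx <- make_fossil_genome(seed = 55, divergence = 0.18)
  hits <- scan_intergenic(c(q1i10g2 = fx$intron), fx$bundle)
  truth <- 100 * (fx$fossil_end - fx$fossil_start) /
    nchar(fx$bundle$sequence)
  expect_lt(abs(fossil_fraction(fx$bundle, hits) - truth), 0.5)
})

test_that("fossil hits never overlap annotated functional introns", {
  fx <- make_fossil_genome(seed = 56)
  # annotate a functional intron copy inside gene 1 and add it as a feature
  b <- fx$bundle
  b$features <- rbind(b$features, data.frame(
    genome = "toy", type = "intron", start = 500L, end = 700L, strand = "+",
    attributes = "ID=i1"))
  hits <- scan_intergenic(c(q1i10g2 = fx$intron), b)
  if (nrow(hits) > 0) {
    expect_true(all(hits$end <= 500 | hits$start >= 700 |
                    hits$context != "intron"))
  }
})
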