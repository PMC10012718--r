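# Intron nomenclature: label grammar, round trips, insertion-site identity,
# and mapping exons back to reference coordinates.

test_that("labels format and parse per the site nomenclature", {
  expect_equal(format_intron_label("cox2", 373, "g2"), "cox2i373g2")
  expect_equal(format_intron_label("rps8", 52, "g2", fossil = TRUE),
               "rps8i52g2f")
  tw <- intron_label("atp1", 1536, "g2",
                     twintron_parent = intron_label("atp1", 1050, "g2"))
  expect_equal(format(tw), "atp1i1050g2ii1536g2")

  p <- parse_intron_label("rps10i235g2")
  expect_equal(p$gene, "rps10")
  expect_equal(p$ref_position, 235L)
  expect_equal(p$intron_class, "g2")
  expect_false(p$fossil)

  pf <- parse_intron_label("rps8i52g2f")
  expect_true(pf$fossil)

  ptw <- parse_intron_label("cox1i1116g1ii207g2")
  expect_equal(ptw$twintron_parent$intron_class, "g1")
  expect_equal(ptw$ref_position, 207L)
  expect_equal(ptw$gene, "cox1")

  expect_error(parse_intron_label("cox2iXg2"), "malformed")
  expect_error(intron_label("cox2", 373, "g3"), "invalid")
  expect_error(intron_label("cox2", 0, "g2"), ">= 1")
})

test_that("round trip parse(format(x)) == x on random labels", {
  set.seed(42)
  genes <- c("cox1", "nad4L", "trnS-GCU", "ccmFC", "rrnL", "atp9")
  for (k in 1:50) {
    x <- intron_label(sample(genes, 1), sample.int(3000, 1),
                      sample(c("g1", "g2"), 1), fossil = runif(1) < 0.3)
    if (runif(1) < 0.3 && !x$fossil)
      x <- intron_label(x$gene, sample.int(3000, 1), "g2",
                        twintron_parent = x)
    expect_equal(parse_intron_label(format(x)), x)
  }
})

test_that("the full packaged catalog parses and re-formats identically", {
  labs <- intron_catalog()$label
  expect_length(labs, 161)
  rt <- vapply(labs, function(l) format(parse_intron_label(l)), character(1))
  expect_equal(unname(rt), labs)
})

test_that("site identity is exact on (gene, position); neighbours differ", {
  expect_identical(site_key("cox2i97g2"), "cox2i97g2")
  expect_false(site_key("cox2i97g2") == site_key("cox2i98g2"))
  expect_identical(site_key("rps8i52g2f"), "rps8i52g2")  # fossil joins its site
})

test_that("reference insertion position maps through a global alignment", {
  set.seed(9)
  ref <- random_rna(600)
  expect_equal(reference_insertion_position(substr(ref, 1, 373), ref), 373L)
  # internal deletion in the host exon must not shift the reference position
  ex <- paste0(substr(ref, 1, 100), substr(ref, 121, 373))
  expect_equal(reference_insertion_position(ex, ref), 373L)
  # independent oracle: walk the alignment columns explicitly
  aln <- global_align(ex, ref)
  cols <- which(aln$a_idx == nchar(ex))
  expect_equal(max(aln$b_idx[seq_len(cols[1])]), 373L)
  expect_error(reference_insertion_position("", ref), "empty")
  expect_error(reference_insertion_position(random_rna(200), ref),
               "unmappable")
})
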