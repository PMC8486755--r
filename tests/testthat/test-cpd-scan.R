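test_that("site_to_column follows the human row's non-gap count", {
  aln <- make_alignment(c(human = "MARK", sp = "MARK"))
  expect_equal(site_to_column(aln, 3), 3)
  aln <- make_alignment(c(human = "M-AK", sp = "MTAK"))
  expect_equal(site_to_column(aln, 2), 3)
  expect_error(site_to_column(aln, 4), "only 3 residues")
})

test_that("site_to_column agrees with a brute-force scan on gapped rows", {
  set.seed(42)
  for (rep in 1:25) {
    n <- 30
    chars <- sample(c(AMINO_ACIDS, "-"), n, replace = TRUE,
                    prob = c(rep(1, 20), 8))
    if (!any(chars != "-")) next
    human <- paste(chars, collapse = "")
    aln <- make_alignment(c(human = human, sp = paste(rep("A", n),
                                                      collapse = "")))
    # brute force: walk the row counting residues
    count <- 0
    expected <- integer(0)
    for (i in seq_len(n)) if (chars[i] != "-") {
      count <- count + 1
      expected[count] <- i
    }
    for (pos in seq_len(count))
      expect_equal(site_to_column(aln, pos), expected[pos])
  }
})

test_that("column profiles count covered species only", {
  aln <- make_alignment(c(human = "E", a = "E", b = "E"))
  p <- column_profile(aln, 1)
  expect_equal(as.numeric(p$frequencies["E"]), 1.0)

  aln <- make_alignment(c(human = "E", a = "E", b = "-", c = "X"))
  p <- column_profile(aln, 1)
  expect_equal(p$coverage, 2)
  expect_equal(p$n_excluded, 2)
  expect_equal(as.numeric(p$frequencies["E"]), 1.0)
  expect_equal(sum(p$frequencies), 1.0)
  expect_error(column_profile(aln, 2), "outside")
})

test_that("a planted minor allele is recovered at its exact frequency", {
  b <- simulate_bundle(tempfile(), seed = 5)
  tr <- b$truth$cpds[[1]]
  aln <- b$alignment
  col <- site_to_column(aln, tr$site)
  p <- column_profile(aln, col)
  expect_equal(as.integer(p$counts[tr$pathogenic_aa]), length(tr$species))
  expect_equal(as.numeric(p$frequencies[tr$pathogenic_aa]),
               length(tr$species) / p$coverage)
})

test_that("find_cpd_species returns exactly the planted carriers", {
  taxon <- c(a1 = "mites", a2 = "mites", a3 = "mites", a4 = "mites",
             b1 = "fish", human = "primates")
  aln <- make_alignment(
    c(human = "ME", a1 = "MK", a2 = "MK", a3 = "MK", a4 = "MK", b1 = "M-"),
    taxon = taxon)
  mut <- list(gene = "ND1", protein_position = 2, ref_aa = "E", alt_aa = "K")
  hit <- find_cpd_species(aln, mut)
  expect_setequal(hit$species_with_cpd, c("a1", "a2", "a3", "a4"))
  expect_equal(as.integer(hit$clade_breakdown["mites"]), 4)
  expect_equal(hit$n_excluded, 1)  # the gapped species is never a carrier
  expect_false(hit$flagged)

  none <- find_cpd_species(aln, list(gene = "ND1", protein_position = 2,
                                     ref_aa = "E", alt_aa = "W"))
  expect_length(none$species_with_cpd, 0)

  expect_warning(
    flagged <- find_cpd_species(aln, list(gene = "ND1", protein_position = 2,
                                          ref_aa = "Q", alt_aa = "K")),
    "flagged")
  expect_true(flagged$flagged)
})

test_that("scan results are invariant under all-gap column insertion", {
  aln <- make_alignment(c(human = "MEK", a = "MKK", b = "MEK"))
  mut <- list(protein_position = 2, ref_aa = "E", alt_aa = "K")
  before <- find_cpd_species(aln, mut)
  gapped <- make_alignment(c(human = "M--E-K", a = "M--K-K", b = "M--E-K"))
  after <- find_cpd_species(gapped, mut)
  expect_identical(before$species_with_cpd, after$species_with_cpd)
  expect_equal(column_profile(aln, before$column)$counts,
               column_profile(gapped, after$column)$counts)
})
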