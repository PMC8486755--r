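make_masking_fixture <- function(contact_states) {
  # human + two CPD carriers (s1, s2) + two background species
  # contact_states: states of s1 and s2 at the contact site (column 3)
  rows <- c(human = paste0("ME", "A", "Q"),
            s1 = paste0("MK", contact_states[1], "Q"),
            s2 = paste0("MK", contact_states[2], "Q"),
            b1 = "MEAQ", b2 = "MEAQ")
  aln <- make_alignment(rows)
  hit <- find_cpd_species(aln, list(gene = "ND1", protein_position = 2,
                                    ref_aa = "E", alt_aa = "K"))
  contacts <- data.frame(site_i = 2, site_j = 3, distance = 5.0,
                         seq_separation = 1)
  classify_contact_states(aln, hit, contacts)
}

test_that("contact-state categories follow the all/some/none rule", {
  expect_equal(make_masking_fixture(c("V", "C"))[[1]]$category, "all")
  expect_equal(make_masking_fixture(c("V", "A"))[[1]]$category, "some")
  expect_equal(make_masking_fixture(c("A", "A"))[[1]]$category, "none")
  # missing data does not veto "all"; it is excluded and counted
  cand <- make_masking_fixture(c("V", "-"))[[1]]
  expect_equal(cand$category, "all")
  expect_equal(cand$n_missing, 1)
  both_missing <- make_masking_fixture(c("-", "X"))[[1]]
  expect_equal(both_missing$category, "unassessable")
})

test_that("contact sites outside the alignment are flagged unmappable", {
  aln <- make_alignment(c(human = "MEK", s1 = "MKK"))
  hit <- find_cpd_species(aln, list(protein_position = 2, ref_aa = "E",
                                    alt_aa = "K"))
  contacts <- data.frame(site_i = 2, site_j = 9, distance = 5,
                         seq_separation = 7)
  cand <- classify_contact_states(aln, hit, contacts)
  expect_true(cand[[1]]$unmappable)
  expect_equal(cand[[1]]$category, "unmappable")
})

test_that("masking summary reproduces (n_contacts, n_some, n_all) tallies", {
  # 5 contacts: 3 "all", 1 "some", 1 "none" -> (5, 4, 3)
  rows <- c(human = "MEAAAAA",
            s1 = "MKVVVCA", s2 = "MKVVVAA",
            b1 = "MEAAAAA")
  aln <- make_alignment(rows)
  hit <- find_cpd_species(aln, list(protein_position = 2, ref_aa = "E",
                                    alt_aa = "K"))
  contacts <- data.frame(site_i = 2, site_j = 3:7,
                         distance = c(4, 5, 6, 7, 7.5),
                         seq_separation = 1:5)
  cands <- classify_contact_states(aln, hit, contacts)
  rep <- masking_report(cands)
  expect_equal(rep$n_contacts, 5)
  expect_equal(rep$n_some, 4)
  expect_equal(rep$n_all, 3)
  expect_equal(rep$sites_all, "3,4,5")
  expect_true(rep$n_all <= rep$n_some && rep$n_some <= rep$n_contacts)

  empty <- masking_report(structure(list(), class = "masking_candidates"))
  expect_equal(c(empty$n_contacts, empty$n_some, empty$n_all), c(0, 0, 0))
})

test_that("clade restriction limits which CPD species are inspected", {
  taxon <- c(human = "primates", s1 = "primates", s2 = "fish")
  aln <- make_alignment(c(human = "MEA", s1 = "MKV", s2 = "MKA"),
                        taxon = taxon)
  hit <- find_cpd_species(aln, list(protein_position = 2, ref_aa = "E",
                                    alt_aa = "K"))
  contacts <- data.frame(site_i = 2, site_j = 3, distance = 5,
                         seq_separation = 1)
  unrestricted <- classify_contact_states(aln, hit, contacts)
  expect_equal(unrestricted[[1]]$category, "some")
  primates_only <- classify_contact_states(aln, hit, contacts,
                                           restrict_species = "s1")
  expect_equal(primates_only[[1]]$category, "all")
})

test_that("co-occurrence counts species jointly covered at both sites", {
  rows <- c(human = "AT", g = "AT", o = "AT", f = "TT", s = "TT",
            x = "AA", gap = "A-")
  aln <- make_alignment(rows)
  tab <- cooccurrence_table(aln, 1, 2)
  expect_equal(sum(tab), 6)  # gapped species excluded everywhere
  expect_equal(as.integer(tab["A", "T"]), 3)
  expect_equal(as.integer(tab["T", "T"]), 2)
  expect_equal(as.integer(tab["A", "A"]), 1)
  expect_equal(attr(tab, "n_excluded"), 1)

  uni <- make_alignment(c(human = "AA", b = "AA", c = "AA"))
  t1 <- cooccurrence_table(uni, 1, 2)
  expect_equal(as.integer(t1["A", "A"]), 3)
  expect_equal(length(t1), 1)

  # focus bucketing
  rows2 <- c(human = "AT", b = "GT", c = "AC")
  aln2 <- make_alignment(rows2)
  t2 <- cooccurrence_table(aln2, 1, 2, focus_states = c("A", "T"))
  expect_equal(as.integer(t2["other", "T"]), 1)
  expect_equal(as.integer(t2["A", "other"]), 1)
})
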