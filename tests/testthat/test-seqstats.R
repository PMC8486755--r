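test_that("NG86 handles the canonical one-codon cases", {
  same <- ng86_dnds("TTTAAA", "TTTAAA")
  expect_equal(same$Sd, 0)
  expect_equal(same$Nd, 0)
  expect_true(is.na(same$ratio))

  syn <- ng86_dnds("TTT", "TTC")  # Phe -> Phe in every supported table
  expect_equal(syn$Nd, 0)
  expect_equal(syn$Sd, 1)
  expect_equal(syn$dN, 0)
  expect_equal(syn$ratio, 0)

  non <- ng86_dnds("TTT", "TTA")  # Phe -> Leu
  expect_equal(non$Nd, 1)
  expect_equal(non$Sd, 0)
  expect_equal(non$dS, 0)
  expect_true(is.na(non$ratio))

  expect_error(ng86_dnds("TTTA", "TTTA"), "multiple of 3")
  expect_error(ng86_dnds("TTTAAA", "TTT"), "differ in length")
})

test_that("NG86 site counts match neighbour enumeration in all tables", {
  set.seed(1234)
  for (tab in c("vertebrate.mito", "invertebrate.mito", "standard")) {
    code <- genetic_code(tab)
    for (rep in 1:60) {
      a <- paste(replicate(4, random_codon(code)), collapse = "")
      b <- paste(replicate(4, random_codon(code)), collapse = "")
      res <- ng86_dnds(a, b, table = tab)
      ora <- function(s) sum(vapply(
        substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)),
        oracle_syn_sites, 0, code = code))
      expect_equal(res$S, (ora(a) + ora(b)) / 2, tolerance = 1e-12)
      expect_equal(res$N + res$S, 3 * res$n_codons)
    }
  }
})

test_that("single-difference codon pairs are classified by translation", {
  # every single-nt neighbour pair: Sd/Nd must match the aa comparison
  code <- genetic_code("vertebrate.mito")
  codons <- names(code)[code != "*"]
  nt <- c("T", "C", "A", "G")
  set.seed(9)
  for (a in sample(codons, 25)) {
    for (pos in 1:3) for (b in nt) {
      if (b == substr(a, pos, pos)) next
      nb <- a
      substr(nb, pos, pos) <- b
      if (code[[nb]] == "*") next
      res <- ng86_dnds(a, nb)
      if (code[[a]] == code[[nb]]) {
        expect_equal(c(res$Sd, res$Nd), c(1, 0))
      } else {
        expect_equal(c(res$Sd, res$Nd), c(0, 1))
      }
    }
  }
})

test_that("NG86 is symmetric in its two sequences", {
  set.seed(55)
  code <- genetic_code("vertebrate.mito")
  for (rep in 1:20) {
    a <- paste(replicate(6, random_codon(code)), collapse = "")
    b <- paste(replicate(6, random_codon(code)), collapse = "")
    r1 <- ng86_dnds(a, b)
    r2 <- ng86_dnds(b, a)
    expect_equal(unclass(r1), unclass(r2))
  }
})

test_that("gapped and ambiguous codons are skipped pairwise", {
  r <- ng86_dnds("TTT---AAA", "TTCNNNAAA")
  expect_equal(r$n_codons, 2)
  expect_equal(r$Sd, 1)
})

test_that("hypergeometric probability equals subset enumeration", {
  # closed-form check on all instances with N <= 12
  for (N in 2:12) for (K in 0:N) for (k in 0:N) {
    got <- conserved_contact_probability(k, K, N)
    want <- if (k > K) 0 else {
      # enumerate k-subsets of 1..N; favourable = all within 1..K
      subsets <- utils::combn(N, max(k, 1))
      if (k == 0) 1 else mean(apply(subsets <= K, 2, all))
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_equal(conserved_contact_probability(3, 10, 10), 1.0)
  expect_error(conserved_contact_probability(13, 5, 12), "exceeds")
  expect_error(conserved_contact_probability(2, 6, 5), "<=")
})

test_that("conservation probability is monotone in k and K", {
  N <- 100
  for (K in c(30, 60, 90)) {
    p <- vapply(0:10, conserved_contact_probability,
                0, n_identical_sites = K, protein_length = N)
    expect_true(all(diff(p) <= 0))
  }
  for (k in c(3, 7)) {
    p <- vapply(seq(k, N), function(K)
      conserved_contact_probability(k, K, N), 0)
    expect_true(all(diff(p) >= 0))
  }
  # the binomial approximation is exposed and close for small k/N
  expect_equal(conserved_contact_probability(7, 103, 174, "binomial"),
               (103 / 174)^7)
})

test_that("Miyata matrix reproduces published entries and axioms", {
  m <- miyata_matrix()
  expect_equal(round(m["P", "A"], 2), 0.06)
  expect_equal(round(m["L", "I"], 2), 0.14)
  expect_equal(round(m["K", "R"], 2), 0.40)
  expect_equal(round(m["C", "P"], 2), 1.33)
  expect_equal(round(m["C", "A"], 2), 1.39)
  expect_true(all(diag(m) == 0))
  expect_true(isSymmetric(m))
  expect_true(all(m[upper.tri(m)] > 0))
})

test_that("Miyata ranking is a bijection onto 1..19 for every reference", {
  for (ref in rownames(miyata_matrix())) {
    ranks <- vapply(setdiff(rownames(miyata_matrix()), ref),
                    function(q) miyata_rank(ref, q), 0L)
    expect_setequal(ranks, 1:19)
  }
  m <- miyata_matrix()
  nearest <- names(which.min(m["A", setdiff(colnames(m), "A")]))
  expect_equal(miyata_rank("A", nearest), 1L)
  expect_error(miyata_rank("A", "B"), "non-standard")
  expect_error(miyata_rank("A", "A"), "differ")
})
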