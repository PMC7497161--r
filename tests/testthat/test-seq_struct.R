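test_that("identical sequences align gap-free at 100% identity", {
  a <- protein_sequence("x", "MKVLDESAR")
  r <- global_align(a, a)
  expect_equal(r$identity_pct, 100)
  expect_false(grepl("-", r$aligned_a))
  expect_identical(r$aligned_a, r$aligned_b)
})

test_that("alignment scores equal brute-force enumeration on short pairs", {
  mat <- blosum62()
  r <- global_align("HEAGAWGH", "PAWHEA")
  expect_equal(r$score,
               oracle_best_alignment_score("HEAGAWGH", "PAWHEA", mat, 10, 0.5))

  withr::with_seed(101, {
    for (k in 1:8) {
      la <- sample(1:5, 1); lb <- sample(1:5, 1)
      a <- paste(sample(aa_alphabet(), la, TRUE), collapse = "")
      b <- paste(sample(aa_alphabet(), lb, TRUE), collapse = "")
      expect_equal(global_align(a, b)$score,
                   oracle_best_alignment_score(a, b, mat, 10, 0.5),
                   info = paste(a, b))
    }
  })
})

test_that("alignment is symmetric up to sequence swap", {
  r1 <- global_align("MKVLDE", "MKIDE")
  r2 <- global_align("MKIDE", "MKVLDE")
  expect_equal(r1$score, r2$score)
  expect_identical(r1$aligned_a, r2$aligned_b)
  expect_identical(r1$aligned_b, r2$aligned_a)
  expect_equal(r1$identity_pct, r2$identity_pct)
})

test_that("percent identity counts gap columns in the denominator", {
  r <- structure(list(aligned_a = "AB-", aligned_b = "ABC"),
                 class = "alignment_result")
  expect_equal(percent_identity(r), 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(percent_identity(r, denominator = "ungapped"), 100)
  all_id <- structure(list(aligned_a = "ACDE", aligned_b = "ACDE"),
                      class = "alignment_result")
  expect_equal(percent_identity(all_id), 100)
})

test_that("invalid residues are rejected", {
  expect_error(protein_sequence("bad", "MKXB"), "invalid")
  expect_error(protein_sequence("empty", ""), "nonempty")
})

test_that("active-site selection respects the distance cutoff", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  # reference residue 100 at origin; residue 101 at 5 A; residue 150 at 15 A
  write_synthetic_pdb(tmp, resnos = c(100L, 101L, 150L),
                      distances_A = c(0, 5, 15))
  pdb <- bio3d::read.pdb(tmp)
  sel <- select_active_site(pdb, list(chain = "A", resno = 100L),
                            cutoff_nm = 1.0, stretch_len = 3L)
  expect_setequal(sel$seeds, c(100L, 101L))
  expect_false(any(sel$stretches$start <= 150 & sel$stretches$end >= 150))

  # cutoff 0 keeps only the reference residue's own stretch
  sel0 <- select_active_site(pdb, list(chain = "A", resno = 100L),
                             cutoff_nm = 0, stretch_len = 3L)
  expect_identical(sel0$seeds, 100L)

  expect_error(select_active_site(pdb, list(chain = "B", resno = 100L)),
               "not found")
})

test_that("active-site selection is monotone in the cutoff", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  withr::with_seed(5, {
    resnos <- 200:230
    dists <- sort(stats::runif(31, 0, 20))
  })
  write_synthetic_pdb(tmp, resnos = resnos, distances_A = dists)
  pdb <- bio3d::read.pdb(tmp)
  ref <- list(chain = "A", resno = 200L)
  prev <- integer()
  for (cut in c(0.2, 0.5, 1.0, 1.5, 2.0)) {
    sel <- select_active_site(pdb, ref, cutoff_nm = cut, stretch_len = 5L)
    expect_true(all(prev %in% sel$seeds))
    prev <- sel$seeds
  }
})

test_that("candidate nomination keeps only prime-side differences", {
  # identical sequences give no candidates
  a <- protein_sequence("a", "MKVLDESGHA", numbering_offset = 221L)
  r_id <- global_align(a, a)
  sel <- structure(list(
    stretches = data.frame(start = c(221L, 227L), end = c(225L, 230L)),
    seeds = c(222L, 228L),
    rule = list()), class = "active_site_selection")
  classes <- c("221-225" = "prime", "227-230" = "nonprime")
  expect_equal(nrow(candidate_mutations(r_id, sel, classes)), 0L)

  # one difference inside the prime stretch (pos 223, V->I), one inside the
  # nonprime stretch (pos 228, G->A): only the prime one is nominated
  b <- protein_sequence("b", "MKILDESAHA", numbering_offset = 221L)
  r <- global_align(a, b)
  cand <- candidate_mutations(r, sel, classes)
  expect_equal(cand$position, 223L)
  expect_equal(cand$from_aa, "V")
  expect_equal(cand$to_aa, "I")

  expect_error(candidate_mutations(r, sel, c("221-225" = "prime")),
               "unclassified")
})

test_that("FASTA sequences round-trip through the reader", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P00001 test protein", "MKVLDE", ">P00002", "AC"), tmp)
  seqs <- read_protein_fasta(tmp, numbering_offset = 10L)
  expect_named(seqs, c("P00001", "P00002"))
  expect_equal(seqs$P00001$residues, "MKVLDE")
  expect_equal(seqs$P00001$numbering_offset, 10L)
})
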