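sc <- scoring_scheme()

test_that("substitution extraction maps mismatches to reference coordinates", {
  id <- strrep("A", 50)
  aln <- global_align(id, id, sc)
  expect_equal(nrow(extract_substitutions(aln)), 0L)

  # mismatch A->D at reference position 128 of a 150-residue protein
  set.seed(3)
  ref <- random_protein(150)
  substr(ref, 128, 128) <- "A"
  other <- ref
  substr(other, 128, 128) <- "D"
  recs <- extract_substitutions(global_align(ref, other, sc),
                                strain_id = "JZ043")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$reference_position, 128)
  expect_equal(recs$from_residue, "A")
  expect_equal(recs$to_residue, "D")
  expect_equal(recs$classification, "non_conservative")
})

test_that("insertions in the subject are logged, not recorded as substitutions", {
  aln <- alignment("ref", "s", 0, 1, 6, 1, 7, "ACD-EFG", "ACDKEFG")
  recs <- extract_substitutions(aln)
  expect_equal(nrow(recs), 0L)
  expect_equal(attr(recs, "n_insertions"), 1L)
  aln2 <- alignment("ref", "s", 0, 1, 7, 1, 6, "ACDKEFG", "ACD-EFG")
  expect_equal(attr(extract_substitutions(aln2), "n_deletions"), 1L)
})

test_that("classification follows the substitution-matrix sign and is symmetric", {
  expect_equal(classify_substitution("A", "D"), "non_conservative")
  expect_equal(classify_substitution("I", "V"), "conservative")
  expect_equal(classify_substitution("K", "R"), "conservative")
  expect_error(classify_substitution("A", "A"), "identical")
  expect_error(classify_substitution("A", "B"), "invalid residue")
  aas <- rownames(sc$matrix)[1:20]
  pairs <- t(combn(aas, 2))
  expect_equal(classify_substitution(pairs[, 1], pairs[, 2]),
               classify_substitution(pairs[, 2], pairs[, 1]))
})

test_that("group comparison finds exactly the group-discriminating substitutions", {
  set.seed(41)
  ref <- random_protein(200)
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  pos_a <- which(chars == "A")[1]
  pos_i <- which(chars == "I")[1]
  pos_g <- which(chars == "G")[1]
  neg_chars <- chars
  neg_chars[c(pos_a, pos_i, pos_g)] <- c("D", "V", "W")
  neg <- paste(neg_chars, collapse = "")
  # a private substitution in only one negative strain must be excluded
  neg2_chars <- neg_chars
  pos_priv <- which(neg2_chars == "L")[1]
  neg2_chars[pos_priv] <- "F"
  seqs <- c(P1 = ref, P2 = ref, N1 = neg,
            N2 = paste(neg2_chars, collapse = ""))
  groups <- list(oxalate_positive = c("P1", "P2"),
                 oxalate_negative = c("N1", "N2"))
  cmp <- compare_groups(seqs, groups, "P1", sc)
  expect_setequal(unique(cmp$records$reference_position),
                  c(pos_a, pos_i, pos_g))
  expect_false(pos_priv %in% cmp$records$reference_position)
  expect_equal(cmp$summary$n_conservative, 1L)
  expect_equal(cmp$summary$n_non_conservative, 2L)
  expect_equal(cmp$summary$per_pair_counts[["A>D"]], 1L)

  # negatives identical to the reference: nothing discriminates
  same <- compare_groups(c(P1 = ref, P2 = ref, N1 = ref),
                         list(oxalate_positive = c("P1", "P2"),
                              oxalate_negative = "N1"), "P1", sc)
  expect_equal(nrow(same$records), 0L)
  expect_equal(same$summary$n_conservative + same$summary$n_non_conservative, 0L)
})

test_that("group comparison is invariant to relabeling within groups", {
  set.seed(42)
  ref <- random_protein(120)
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  p <- which(chars == "A")[1]
  chars[p] <- "D"
  neg <- paste(chars, collapse = "")
  seqs <- c(R = ref, P2 = ref, N1 = neg, N2 = neg)
  g1 <- list(oxalate_positive = c("R", "P2"), oxalate_negative = c("N1", "N2"))
  g2 <- list(oxalate_positive = c("R", "P2"), oxalate_negative = c("N2", "N1"))
  a <- compare_groups(seqs, g1, "R", sc)
  b <- compare_groups(seqs, g2, "R", sc)
  expect_equal(a$summary, b$summary)
  expect_setequal(a$records$reference_position, b$records$reference_position)
})

test_that("group comparison validates its inputs", {
  seqs <- c(A = "MKLV", B = "MKLV")
  expect_error(compare_groups(seqs, list(oxalate_positive = "A",
                                         oxalate_negative = character()),
                              "A"), "non-empty")
  expect_error(compare_groups(seqs, list(oxalate_positive = "A",
                                         oxalate_negative = "B"), "B"),
               "positive group")
  expect_error(compare_groups(seqs, list(oxalate_positive = "A",
                                         oxalate_negative = c("B", "C")), "A"),
               "C")
})

test_that("aligned FASTA import round-trips gapped rows", {
  path <- tempfile(fileext = ".afa")
  writeLines(c(">s1", "MK-LV", ">s2 extra", "MKALV"), path)
  rows <- read_aligned_fasta(path)
  expect_equal(rows, c(s1 = "MK-LV", s2 = "MKALV"))
  writeLines(c(">s1", "MK-LV", ">s2", "MKALVX"), path)
  expect_error(read_aligned_fasta(path), "gapped length")
})
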