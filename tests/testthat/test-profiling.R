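cat3 <- toy_catalogue()

test_that("no hits gives an all-zero matrix of full cohort dimensions", {
  cohort <- toy_cohort(c("S1", "S2", "S3"))
  no_hits <- toy_hits("S1", "4.1.1.8", "p1")[0, ]
  m <- copy_number_matrix(no_hits, cohort, cat3)
  expect_equal(dim(m), c(3L, 3L))
  expect_true(all(m == 0L))
  expect_equal(rownames(m), c("S1", "S2", "S3"))
  expect_equal(colnames(m), cat3$class_id)
})

test_that("copy number counts distinct proteins, not hit records", {
  cohort <- toy_cohort("S1")
  # one protein hit by two reference variants of the same class = one copy
  hits <- rbind(toy_hits("S1", "4.1.1.8", "p1", "r1a"),
                toy_hits("S1", "4.1.1.8", "p1", "r1b"))
  m <- copy_number_matrix(hits, cohort, cat3)
  expect_equal(unname(m["S1", "4.1.1.8"]), 1L)
  # two distinct proteins = two copies
  hits2 <- rbind(hits, toy_hits("S1", "4.1.1.8", "p2"))
  expect_equal(unname(copy_number_matrix(hits2, cohort, cat3)["S1", "4.1.1.8"]), 2L)
})

test_that("matrix construction rejects unknown strains and classes", {
  cohort <- toy_cohort("S1")
  expect_error(copy_number_matrix(toy_hits("S9", "4.1.1.8", "p1"), cohort, cat3),
               "unknown strain")
  expect_error(copy_number_matrix(toy_hits("S1", "9.9.9.9", "p1"), cohort, cat3),
               "unknown class")
})

test_that("matrix construction is invariant to hit order", {
  cohort <- toy_cohort(c("S1", "S2"))
  hits <- rbind(toy_hits("S1", "4.1.1.8", "p1"),
                toy_hits("S1", "OxlT", "p2"),
                toy_hits("S2", "2.8.3.16", "p7"))
  set.seed(8)
  perm <- hits[sample(nrow(hits)), ]
  expect_equal(copy_number_matrix(hits, cohort, cat3),
               copy_number_matrix(perm, cohort, cat3))
})

test_that("presence view is exactly copy number >= 1", {
  sim <- small_sim()
  m <- sim$manifest$copy_number
  expect_identical(trait_presence(m), unclass(m) >= 1L)
})

test_that("genus percentages are per-genus presence fractions", {
  cohort <- toy_cohort(c("S1", "S2", "S3", "S4", "S5"),
                       genus = c("Pseudomonas", rep("Bacillus", 4)))
  hits <- rbind(toy_hits("S1", "4.1.1.8", "p1"),
                toy_hits("S2", "4.1.1.8", "p1"))
  m <- copy_number_matrix(hits, cohort, cat3)
  gp <- genus_percentages(m, cohort)
  expect_equal(sum(gp$n_strains), 5L)
  expect_equal(gp[gp$genus == "Pseudomonas", "4.1.1.8"], 100)
  expect_equal(gp[gp$genus == "Bacillus", "4.1.1.8"], 25)
  expect_equal(gp[gp$genus == "Bacillus", "OxlT"], 0)
})

test_that("strains without genus metadata fall back to Unassigned", {
  cohort <- toy_cohort(c("S1", "S2"), genus = c("Pseudomonas", NA))
  m <- copy_number_matrix(toy_hits("S1", "OxlT", "p1"), cohort, cat3)
  expect_warning(gp <- genus_percentages(m, cohort), "Unassigned")
  expect_true("Unassigned" %in% gp$genus)
})

test_that("presence column sums equal genus-weighted percentages", {
  sim <- small_sim()
  m <- sim$manifest$copy_number
  gp <- genus_percentages(m, sim$cohort)
  classes <- colnames(m)
  implied <- colSums(as.matrix(gp[, classes]) * gp$n_strains / 100)
  expect_equal(unname(implied), unname(colSums(trait_presence(m))),
               tolerance = 1e-9)
})

test_that("prevalence clustering is the exact 1-D k-means optimum", {
  mk_matrix <- function(prev, n = 20L) {
    m <- vapply(prev, function(p) as.integer(seq_len(n) <= round(p * n)),
                integer(n))
    colnames(m) <- paste0("c", seq_along(prev))
    rownames(m) <- paste0("s", seq_len(n))
    class(m) <- c("trait_matrix", class(m))
    m
  }
  m <- mk_matrix(c(1.0, 0.95, 0.5, 0.05))
  cl <- presence_clusters(m, k = 3)
  expect_equal(cl$cluster, c(1L, 1L, 2L, 3L))
  expect_equal(presence_clusters(m, k = 1)$cluster, rep(1L, 4))
  expect_error(presence_clusters(m, k = 5), "between 1 and")
  # ties broken deterministically by column order
  tie <- mk_matrix(c(0.5, 0.5, 0.5))
  expect_equal(presence_clusters(tie, k = 2),
               presence_clusters(tie, k = 2))
  # optimality against exhaustive partition enumeration
  set.seed(12)
  for (i in 1:20) {
    prev <- runif(sample(4:9, 1))
    k <- sample(1:3, 1)
    m2 <- mk_matrix(round(prev, 2), n = 100L)
    got <- presence_clusters(m2, k)
    expect_equal(kmeans1d_group_sse(got$prevalence, got$cluster),
                 oracle_kmeans1d_sse(got$prevalence, k), tolerance = 1e-9)
  }
})

test_that("trait matrix and iTOL exports are well-formed", {
  sim <- small_sim()
  m <- sim$manifest$copy_number
  tsv <- tempfile(fileext = ".tsv")
  write_trait_matrix(m, tsv)
  back <- read.delim(tsv, check.names = FALSE)
  expect_equal(back$strain_id, rownames(m))
  expect_equal(as.matrix(back[, -1]), unclass(m), ignore_attr = TRUE)
  itol <- tempfile(fileext = ".txt")
  write_itol_binary(m, itol)
  lines <- readLines(itol)
  expect_equal(lines[1], "DATASET_BINARY")
  expect_equal(sum(grepl("^SYN", lines)), nrow(m))
})
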