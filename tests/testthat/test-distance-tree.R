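test_that("sketching is deterministic and canonicalises reverse complements", {
  seqs <- c("ACGTACGGTTAGCAGTACCGATTTGCAG")
  a <- sketch_genome(sequences = seqs, k = 5, s = 100, strain_id = "g1")
  b <- sketch_genome(sequences = seqs, k = 5, s = 100, strain_id = "g1")
  expect_identical(a$hashes, b$hashes)
  expect_true(all(diff(a$hashes) > 0))
  # a sequence and its reverse complement share every canonical k-mer
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
  expect_identical(sketch_genome(sequences = rc, k = 5, s = 100)$hashes,
                   a$hashes)
})

test_that("the palindromic 4-mer genome has a single canonical k-mer", {
  s <- sketch_genome(sequences = "ACGT", k = 4, s = 10)
  expect_equal(length(s$hashes), 1L)
  expect_equal(s$genome_kmer_count, 1)
})

test_that("sketch size caps at the distinct canonical k-mer count", {
  s <- sketch_genome(sequences = "ACGTACGTAAACCC", k = 3, s = 1000)
  expect_equal(length(s$hashes), s$genome_kmer_count)
  expect_lt(s$genome_kmer_count, 1000)
})

test_that("genomes shorter than k give an empty sketch with a warning", {
  expect_warning(s <- sketch_genome(sequences = "ACG", k = 21, s = 10), "k")
  expect_length(s$hashes, 0L)
  full <- sketch_genome(sequences = strrep("ACGT", 30), k = 21, s = 10)
  expect_equal(mash_distance(s, full), 1.0)
})

test_that("k-mers containing ambiguous bases are skipped", {
  a <- sketch_genome(sequences = "ACGTTGCA", k = 4, s = 100)
  b <- sketch_genome(sequences = "ACGTTGCANNNNGGGG", k = 4, s = 100)
  expect_true(all(a$hashes %in% b$hashes))
  expect_equal(b$genome_kmer_count, a$genome_kmer_count + 1)  # + GGGG/CCCC
})

test_that("mash distance follows the closed form on controlled sketches", {
  fake <- function(h, k = 21, s = 10)
    structure(list(strain_id = "f", k = k, sketch_size = s,
                   hashes = as.numeric(h), genome_kmer_count = length(h)),
              class = "sketch")
  a <- fake(1:10)
  expect_equal(mash_distance(a, a), 0)
  # bottom-10 of the union 1..15 is 1..10, of which 1..5 are shared: j = 0.5
  b <- fake(c(1:5, 11:15))
  expect_equal(mash_distance(a, b), -(1 / 21) * log(2 * 0.5 / 1.5),
               tolerance = 1e-12)
  expect_equal(mash_distance(a, b), 0.0193079, tolerance = 1e-5)
  # disjoint sketches cap at 1.0
  expect_equal(mash_distance(a, fake(101:110)), 1.0)
  expect_error(mash_distance(a, fake(1:10, k = 17)), "different k")
})

test_that("mash distance is symmetric and decreasing in sketch overlap", {
  fake <- function(h) structure(list(strain_id = "f", k = 21, sketch_size = 20,
                                     hashes = as.numeric(sort(h)),
                                     genome_kmer_count = length(h)),
                                class = "sketch")
  a <- fake(1:20)
  prev <- Inf
  for (shared in c(1, 5, 10, 15, 20)) {  # growing overlap -> shrinking d
    b <- fake(c(seq_len(shared), 100 + seq_len(20 - shared)))
    d <- mash_distance(a, b)
    expect_equal(d, mash_distance(b, a))
    expect_lt(d, prev)
    prev <- d
  }
})

test_that("neighbor joining recovers the known additive quartet", {
  m <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(m)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(m), colnames(m)],
               m, ignore_attr = TRUE)
  # internal edge 2, leaf edges 1
  expect_setequal(round(tr$edge.length, 9), c(1, 1, 1, 1, 2))
})

test_that("neighbor joining validates its input", {
  m <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(m), "at least 3")
  m3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(m3), "asymmetric")
})

test_that("neighbor joining reproduces path lengths of random additive matrices", {
  set.seed(404)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    m <- as.matrix(ape::cophenetic.phylo(tr0))
    tr <- neighbor_joining(m)
    back <- as.matrix(ape::cophenetic.phylo(tr))[rownames(m), colnames(m)]
    expect_equal(back, m, tolerance = 1e-9, ignore_attr = TRUE)
    # label order must not matter beyond relabeling
    perm <- sample(n)
    trp <- neighbor_joining(m[perm, perm])
    backp <- as.matrix(ape::cophenetic.phylo(trp))[rownames(m), colnames(m)]
    expect_equal(backp, m, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("newick export round-trips topology, lengths and quoted labels", {
  m <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(m)
  txt <- write_newick(tr)
  expect_match(txt, "^\\(.*\\);$")
  back <- ape::read.tree(text = txt)
  expect_setequal(back$tip.label, c("A", "B", "C"))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)

  tr$tip.label[1] <- "Pseudomonas sp. JZ024"
  txt2 <- write_newick(tr)
  expect_match(txt2, "'Pseudomonas sp. JZ024'", fixed = TRUE)
  back2 <- ape::read.tree(text = txt2)
  # ape keeps the quote characters on quoted labels; the text survives
  expect_true("Pseudomonas sp. JZ024" %in% gsub("'", "", back2$tip.label))

  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_equal(readLines(path), txt2)
})

test_that("phylip export carries labels and a parseable square matrix", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  path <- tempfile()
  write_phylip(m, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 2L)
  expect_match(lines[2], "^A\\s")
})
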