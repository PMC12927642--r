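test_that("mutate_protein hits its identity target within tolerance", {
  set.seed(10)
  ref <- random_protein(200)
  expect_identical(mutate_protein(ref, 100), ref)
  mut <- mutate_protein(ref, 50, seed = 11)
  ident <- 100 * mean(strsplit(ref, "")[[1]] == strsplit(mut, "")[[1]])
  expect_gte(ident, 48); expect_lte(ident, 52)
  expect_equal(nchar(mut), nchar(ref))
  expect_identical(mutate_protein(ref, 50, seed = 11),
                   mutate_protein(ref, 50, seed = 11))
  expect_error(mutate_protein("MKLVA", 97), "unattainable")
  expect_error(mutate_protein(ref, 0), "target_identity")
})

test_that("cohort config validates probabilities and requires a seed", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(seed = 1, presence_prob = c(OxlT = 1.5)),
               "\\[0, 1\\]")
  expect_error(cohort_config(seed = 1, identity_range = c(-5, 90)),
               "identity_range")
  cfg <- cohort_config(seed = 1)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(sum(cfg$genera), 30L)
})

test_that("generated cohorts have the configured shape and are loadable", {
  sim <- small_sim()
  expect_length(sim$cohort, 10L)
  expect_equal(nrow(sim$metadata), 10L)
  expect_equal(nrow(sim$manifest$toolkit_calls), 10L)
  expect_equal(dim(sim$manifest$copy_number), c(10L, 20L))
  # every strain carries its decoys on top of planted homologs
  n_planted <- table(sim$manifest$plantings$strain_id)
  for (p in sim$cohort) {
    expected <- 5L + if (p$strain_id %in% names(n_planted))
      n_planted[[p$strain_id]] else 0L
    expect_length(p$proteins, expected)
  }
  dir <- tempfile()
  generate_cohort(small_config(), dir = dir)
  expect_length(list.files(file.path(dir, "proteomes")), 10L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  cohort <- read_cohort(file.path(dir, "proteomes"),
                        file.path(dir, "metadata.tsv"))
  expect_equal(vapply(cohort, `[[`, "", "strain_id"),
               vapply(sim$cohort, `[[`, "", "strain_id"))
  expect_identical(cohort[[3]]$proteins, sim$cohort[[3]]$proteins)
})

test_that("identical config and seed give identical cohorts", {
  a <- generate_cohort(small_config(seed = 500L))
  b <- generate_cohort(small_config(seed = 500L))
  expect_identical(a$cohort[[1]]$proteins, b$cohort[[1]]$proteins)
  expect_identical(a$manifest$copy_number, b$manifest$copy_number)
  expect_identical(a$metadata, b$metadata)
  c2 <- generate_cohort(small_config(seed = 501L))
  expect_false(identical(a$cohort[[1]]$proteins, c2$cohort[[1]]$proteins))
})

test_that("the manifest's toolkit intent is derivable from its copy numbers", {
  sim <- small_sim()
  expect_equal(sim$manifest$toolkit_calls,
               classify_cohort(sim$manifest$copy_number))
})

test_that("planted substitutions separate the phenotype groups by construction", {
  sim <- small_sim()
  man <- sim$manifest
  expect_length(man$groups$oxalate_negative, 2L)
  expect_true(all(man$groups$oxalate_negative %in%
                    sim$metadata$strain_id[sim$metadata$genus == "Pseudomonas"]))
  ref_strain <- man$reference_strain
  gcl_of <- function(s) {
    pl <- man$plantings
    pid <- pl$protein_id[pl$strain_id == s & pl$class_id == man$gcl_class][1]
    sim$cohort[[s]]$proteins[[pid]]
  }
  ref_seq <- gcl_of(ref_strain)
  for (s in man$groups$oxalate_positive)
    expect_identical(gcl_of(s), ref_seq)
  for (s in man$groups$oxalate_negative) {
    neg <- strsplit(gcl_of(s), "")[[1]]
    refc <- strsplit(ref_seq, "")[[1]]
    expect_equal(which(neg != refc), sort(man$substitutions$reference_position))
  }
})

test_that("a homolog planted below the coverage threshold stays absent", {
  set.seed(606)
  cat20 <- load_catalogue(default_catalogue())
  refdb <- load_reference_db(default_reference_fasta(), cat20)
  ref <- refdb$sequences[["ref_2.8.3.16_1"]]
  L <- nchar(ref)
  flen <- round(0.55 * L)  # 55% coverage: under the 60% floor
  frag <- mutate_protein(substr(ref, 1, flen), 90)
  p <- proteome("SX", c(low_cov = frag, decoy = random_protein(150)))
  hits <- search_proteome(refdb, p)
  expect_false(any(hits$class_id == "2.8.3.16"))
})

test_that("simulated genomes diverge with their mutation rate", {
  cfg <- small_config()
  g <- generate_genomes(cfg)
  expect_length(g$genomes, 10L)
  expect_equal(unique(nchar(g$genomes)), cfg$genome_length)
  # rate-0 strains are identical to each other (same untouched ancestor)
  zero <- names(g$rates)[g$rates == 0]
  expect_gt(length(zero), 1)
  expect_identical(unname(g$genomes[zero[1]]), unname(g$genomes[zero[2]]))
  expect_equal(g$divergence[zero[1], zero[2]], 0)
  # realised divergence from a rate-0 strain grows with the rate
  rates <- sort(unique(g$rates))
  div <- vapply(rates, function(r) {
    s <- names(g$rates)[g$rates == r][1]
    g$divergence[zero[1], s]
  }, 0)
  expect_true(all(diff(div) > 0) || rates[1] == 0 && all(diff(div[-1]) > 0))
  expect_identical(generate_genomes(cfg)$genomes, g$genomes)
})
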