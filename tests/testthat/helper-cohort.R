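# Shared simulated cohorts, generated once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

# full-size planted-truth cohort at the generator's default study
# conditions (30 strains, 5 genera, 50 decoys/strain)
big_sim <- function() {
  if (is.null(.sim_cache$big)) {
    .sim_cache$big <- generate_cohort(cohort_config(seed = 424242L))
  }
  .sim_cache$big
}

big_screen <- function() {
  if (is.null(.sim_cache$big_hits)) {
    sim <- big_sim()
    cat20 <- load_catalogue(default_catalogue())
    refdb <- load_reference_db(default_reference_fasta(), cat20)
    .sim_cache$big_hits <- list(
      hits = search_cohort(refdb, sim$cohort),
      catalogue = cat20, refdb = refdb)
  }
  .sim_cache$big_hits
}

# small fast cohort for structural tests
small_config <- function(seed = 77L, ...) {
  cohort_config(seed = seed,
                genera = c(Pseudomonas = 6L, Bacillus = 4L),
                phylum_of = c(Pseudomonas = "Pseudomonadota",
                              Bacillus = "Bacillota"),
                decoys_per_strain = 5L, ...)
}

small_sim <- function() {
  if (is.null(.sim_cache$small)) .sim_cache$small <- generate_cohort(small_config())
  .sim_cache$small
}

# minimal hand-built fixtures for profiling/toolkit unit tests
toy_catalogue <- function() {
  path <- withr_local_tempfile()
  writeLines(c("class_id\tdisplay_name\tpathway_roles\treference_ids",
               "4.1.1.8\tOxc\tbiomineralization\tr1",
               "2.8.3.16\tFrc\tbiomineralization\tr2",
               "OxlT\tantiporter\tbiomineralization\tr3"), path)
  load_catalogue(path)
}

withr_local_tempfile <- function() tempfile(fileext = ".tsv")

toy_cohort <- function(strains, genus = NULL) {
  out <- lapply(seq_along(strains), function(i)
    proteome(strains[i], setNames(character(), character()),
             genus = if (is.null(genus)) "G" else genus[i]))
  setNames(out, strains)
}

toy_hits <- function(strain_id, class_id, protein_id,
                     reference_id = paste0("r_", class_id)) {
  data.frame(class_id = class_id, strain_id = strain_id,
             reference_id = reference_id, protein_id = protein_id,
             raw_score = 100, bitscore = 50, evalue = 1e-10,
             percent_identity = 90, query_coverage = 95,
             align_length = 100L, query_start = 1L, query_end = 100L,
             subject_start = 1L, subject_end = 100L,
             stringsAsFactors = FALSE)
}
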