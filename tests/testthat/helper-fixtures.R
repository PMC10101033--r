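# shared fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

# the bundled 20-species community and the full pipeline run over it
get_table1_community <- function() {
  if (is.null(.fixture_env$comm)) {
    .fixture_env$comm <- generate_community(table1_like_spec(), seed = 42L)
  }
  .fixture_env$comm
}

get_pipeline_result <- function() {
  if (is.null(.fixture_env$res)) {
    comm <- get_table1_community()
    .fixture_env$res <- run_pipeline(comm$genomes, comm$taxonomy, seed = 7L)
  }
  .fixture_env$res
}

# random IUPAC primer / plain subject pair for matcher oracle checks
random_primer <- function(len) {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  # weight plain bases so matches actually occur
  paste(sample(codes, len, replace = TRUE,
               prob = c(rep(0.2, 4), rep(0.016, 10), 0.04)),
        collapse = "")
}

random_subject <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# expand one IUPAC string into a concrete realization
realize_iupac <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) sample(iupac_expand(ch), 1), character(1)),
        collapse = "")
}

# minimal taxonomy row builder
tax_row <- function(genome_id, species = "Genus species", strain = NA,
                    superkingdom = "Bacteria", phylum = "Firmicutes") {
  tibble::tibble(
    genome_id = genome_id, superkingdom = superkingdom, phylum = phylum,
    class = "Classia", order = "Orderales", family = "Familyaceae",
    genus = strsplit(species, " ")[[1]][1], species = species,
    strain = ifelse(is.na(strain), species, strain)
  )
}
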