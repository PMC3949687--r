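# Fixtures and the assembled annotated cohort, loaded once per run.
fx <- load_fixture_tables()
cohort <- fixture_cohort(fx)
cohort_diagnoses <- diagnose_cohort(cohort$patients, cohort$variants,
                                    cohort$pedigrees)

# A small hand-built trio for segregation tests: proband het for two
# variants, configurable parental carriers.
make_trio <- function(geno_father, geno_mother, geno_child = c("het", "het"),
                      keys = c("GENEA:c.1A>G", "GENEB:c.2C>T")) {
  members <- tibble::tibble(
    family_id = "F", individual_id = c("fa", "mo", "ch"),
    father_id = c(NA, NA, "fa"), mother_id = c(NA, NA, "mo"),
    sex = c(1L, 2L, 1L), affected = c(FALSE, FALSE, TRUE))
  genotypes <- tibble::tibble(
    individual_id = rep(c("fa", "mo", "ch"), each = 2),
    variant_key = rep(keys, 3),
    genotype = c(geno_father, geno_mother, geno_child))
  ush_pedigree(members, genotypes)
}
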