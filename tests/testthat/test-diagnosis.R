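test_that("segregation traces a het pair through the published family", {
  ped <- fx$pedigrees[["4"]]
  keys <- c(variant_key("MYO7A", "c.2311G>T"),
            variant_key("PCDH15", "c.158-1G>A"))
  seg <- check_segregation(keys, ped)
  expect_equal(seg$phase, "trans")
  expect_true(seg$consistent)
  expect_error(check_segregation(c(keys[1], "USH1C:c.1A>G"), ped), "absent")
})

test_that("phase calls distinguish trans, cis and undetermined", {
  # both variants from the father only -> cis
  cis <- make_trio(geno_father = c("het", "het"), geno_mother = c("ref", "ref"))
  expect_equal(check_segregation(c("GENEA:c.1A>G", "GENEB:c.2C>T"), cis)$phase,
               "cis")
  # one from each parent -> trans, order-invariant
  tr <- make_trio(geno_father = c("het", "ref"), geno_mother = c("ref", "het"))
  expect_equal(check_segregation(c("GENEA:c.1A>G", "GENEB:c.2C>T"), tr)$phase,
               "trans")
  expect_equal(check_segregation(c("GENEB:c.2C>T", "GENEA:c.1A>G"), tr)$phase,
               "trans")
  # a variant carried by both parents is uninformative
  amb <- make_trio(geno_father = c("het", "het"), geno_mother = c("het", "ref"))
  expect_equal(check_segregation(c("GENEA:c.1A>G", "GENEB:c.2C>T"), amb)$phase,
               "undetermined")
})

test_that("Mendelian impossibilities mark the family inconsistent", {
  # child homozygous for a variant absent in both parents
  bad <- make_trio(geno_father = c("ref", "ref"), geno_mother = c("ref", "ref"),
                   geno_child = c("hom", "ref"))
  seg <- check_segregation(c("GENEA:c.1A>G", "GENEB:c.2C>T"), bad)
  expect_false(seg$consistent)
  # het child with one carrier parent is fine
  ok <- make_trio(geno_father = c("het", "ref"), geno_mother = c("ref", "het"))
  expect_true(check_segregation(c("GENEA:c.1A>G", "GENEB:c.2C>T"), ok)$consistent)
})

test_that("the decision ladder reproduces the published case calls", {
  d <- cohort_diagnoses
  row <- function(id) d[d$patient_id == id, ]
  # homozygous nonsense -> biallelic
  expect_equal(row(6)$category, "solved_biallelic")
  expect_equal(row(6)$genes, "MYO7A")
  expect_equal(row(6)$n_causal_alleles, 2L)
  # compound het without family data -> biallelic, phase assumed
  expect_equal(row(11)$category, "solved_biallelic")
  expect_equal(row(11)$segregation_status, "assumed")
  # one het in each of two genes, trans by pedigree -> digenic
  expect_equal(row(4)$category, "digenic")
  expect_equal(row(4)$genes, "MYO7A/PCDH15")
  expect_equal(row(4)$segregation_status, "confirmed_trans")
  # homozygous nonsense plus damaging missense in another USH1 gene
  expect_equal(row(15)$category, "solved_biallelic")
  expect_equal(row(15)$genes, "CDH23")
  expect_equal(row(15)$modifier_candidates[[1]],
               variant_key("USH1C", "c.2437T>G"))
  # single reported variant of uncertain tier is still monoallelic
  expect_equal(row(10)$category, "monoallelic")
  # nothing reported -> unsolved
  expect_equal(row(14)$category, "unsolved")
})

test_that("cohort category counts match the published totals", {
  tab <- table(cohort_diagnoses$category)
  expect_equal(as.integer(tab[c("solved_biallelic", "digenic", "monoallelic",
                                "unsolved")]), c(12L, 1L, 3L, 1L))
  # patients with two pathogenic mutations: biallelic plus digenic
  expect_equal(sum(cohort_diagnoses$n_causal_alleles == 2), 13)
  expect_setequal(
    cohort_diagnoses$patient_id[cohort_diagnoses$n_modifiers > 0],
    c(3, 5, 8, 15))
})

test_that("diagnosis is invariant to variant-row ordering", {
  set.seed(3)
  for (i in 1:5) {
    shuffled <- cohort$variants[sample(nrow(cohort$variants)), ]
    d2 <- diagnose_cohort(cohort$patients, shuffled, cohort$pedigrees)
    expect_equal(d2$category, cohort_diagnoses$category)
    expect_equal(d2$genes, cohort_diagnoses$genes)
    expect_equal(d2$n_modifiers, cohort_diagnoses$n_modifiers)
  }
})

test_that("a cis digenic pair is downgraded, not called digenic", {
  pv <- annotate_variants(tibble::tibble(
    gene = c("MYO7A", "PCDH15"),
    hgvs_c = c("c.1477C>T", "c.1006C>T"),
    hgvs_p = c("p.Gln493X", "p.Arg336X"),
    zygosity = "het"))
  pv$key <- variant_key(pv$gene, pv$hgvs_c)
  ped <- make_trio(geno_father = c("het", "het"), geno_mother = c("ref", "ref"),
                   keys = pv$key)
  d <- diagnose_patient("p1", pv, ped)
  expect_equal(d$category, "monoallelic")
  # same pair without the pedigree is digenic with assumed phase
  d2 <- diagnose_patient("p1", pv)
  expect_equal(d2$category, "digenic")
  expect_equal(d2$segregation_status, "assumed")
})

test_that("Sanger fallback flags monoallelic and unsolved patients", {
  expect_setequal(sanger_fallback_list(cohort_diagnoses), c(10, 12, 13, 14))
  # restricted to platform-detectable variants, the two rescued cases appear
  tab1 <- annotate_variants(fx$variants, catalog = fx$catalog)
  tab1$key <- variant_key(tab1$gene, tab1$hgvs_c)
  undetectable <- tab1$key[!is.na(tab1$detectability)]
  mps_only <- cohort$variants[!cohort$variants$key %in% undetectable, ]
  d_mps <- diagnose_cohort(cohort$patients, mps_only, cohort$pedigrees)
  flagged <- sanger_fallback_list(d_mps)
  expect_true(all(c(8, 9, 14) %in% flagged))
  expect_equal(d_mps$category[d_mps$patient_id %in% c(8, 9)],
               rep("monoallelic", 2))
  # an all-solved cohort yields an empty list
  solved <- cohort_diagnoses[cohort_diagnoses$category == "solved_biallelic", ]
  expect_length(sanger_fallback_list(solved), 0)
})
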