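test_that("consequence classification follows the HGVS grammar", {
  cases <- tibble::tribble(
    ~hgvs_c,            ~hgvs_p,              ~expected,
    "c.1477C>T",        "p.Gln493X",          "nonsense",
    "c.5821-2A>G",      "?",                  "splice",
    "c.158-1G>A",       "?",                  "splice",
    "c.1623dup",        "p.Lys542GlnfsX5",    "frameshift",
    "c.4482_4483insTG", "p.Trp1495CysfsX55",  "frameshift",
    "c.6205_6206delAT", "p.Ile2069ProfsX6",   "frameshift",
    "c.3567delG",       "p.Arg1189ArgfsX5",   "frameshift",
    "c.2074G>A",        "p.Val692Met",        "missense",
    "c.6321G>A",        "p.Trp2107X",         "nonsense",
    "c.100+5G>A",       "?",                  "other",
    "c.300_302delAAG",  "p.Lys101del",        "other",
    "c.200A>G",         "p.Lys67Lys",         "other")
  expect_equal(classify_consequence(cases$hgvs_c, cases$hgvs_p),
               cases$expected)
})

test_that("unparseable coding changes raise naming the token", {
  expect_error(classify_consequence("c.12_13inv", "?"), "c.12_13INV")
  expect_error(classify_consequence("g.1477C>T", "?"), "unparseable")
})

test_that("three-source rarity filter admits only sub-threshold frequencies", {
  pol <- rarity_policy()
  expect_true(rarity_filter(0, 0, 0, policy = pol))
  expect_true(rarity_filter(NA, NA, 0.0026, policy = pol))
  expect_false(rarity_filter(0.02, NA, NA, policy = pol))
  expect_false(rarity_filter(NA, NA, 0.01, policy = pol))  # strict <
  expect_true(all(rarity_filter(c(0.001, 0.009), c(0, 0), c(NA, 0.0026))))
  expect_error(rarity_filter(-0.1), "non-negative")
  # in-house frequency from carrier alleles over the 384-allele panel
  expect_equal(inhouse_frequency(1), 1 / 384, tolerance = 1e-12)
})

test_that("rarity filter is monotone in the frequency cutoff", {
  set.seed(7)
  f1 <- runif(100, 0, 0.05); f2 <- runif(100, 0, 0.05)
  f3 <- sample(c(runif(50, 0, 0.05), rep(NA, 50)))
  cuts <- sort(runif(8, 0.001, 0.05))
  prev <- rep(FALSE, 100)
  for (cut in cuts) {
    cur <- rarity_filter(f1, f2, f3, policy = rarity_policy(cut))
    expect_true(all(prev <= cur))  # raising the cutoff never removes a pass
    prev <- cur
  }
})

test_that("pathogenicity tiering follows the truncating/missense rule", {
  pol <- missense_policy()
  expect_equal(tier_pathogenicity("nonsense"), "pathogenic")
  expect_equal(tier_pathogenicity("frameshift"), "pathogenic")
  expect_equal(tier_pathogenicity("splice"), "pathogenic")
  # SIFT 0.09 alone is tolerated but PolyPhen 0.982 rescues
  expect_equal(tier_pathogenicity("missense", 0.09, 0.982, pol),
               "probable_pathogenic")
  expect_equal(tier_pathogenicity("missense", 0.8, 0.1, pol), "uncertain")
  expect_equal(tier_pathogenicity("missense", NA, NA, pol), "uncertain")
  expect_equal(tier_pathogenicity("other"), "uncertain")
})

test_that("a missense change is never tiered pathogenic", {
  set.seed(11)
  s <- runif(500); p <- runif(500)
  expect_false(any(tier_pathogenicity(rep("missense", 500), s, p) == "pathogenic"))
})

test_that("novelty is absence from the previously-reported catalog", {
  expect_false(mark_novel("CDH23", "c.6319C>T", fx$catalog))   # prior report
  expect_true(mark_novel("MYO7A", "c.4482_4483insTG", fx$catalog))
  expect_true(all(mark_novel(fx$variants$gene, fx$variants$hgvs_c, NULL)))
})

test_that("the annotation chain reproduces the published variant table", {
  ann <- annotate_variants(fx$variants, catalog = fx$catalog)
  label <- c(Frameshift = "frameshift", Nonsense = "nonsense",
             Missense = "missense", Splicing = "splice")
  expect_equal(ann$consequence, unname(label[fx$variants$mutation_type]))
  expect_true(all(ann$rarity_pass))
  expect_equal(sum(ann$tier == "pathogenic"), 15)
  expect_equal(sum(ann$tier == "probable_pathogenic"), 4)
  expect_equal(sum(ann$novel), 14)
  # the four second-gene missense candidates are all predictor-damaging
  mods <- annotate_variants(
    tibble::tibble(gene = fx$modifiers$modifier_gene,
                   hgvs_c = fx$modifiers$hgvs_c,
                   hgvs_p = fx$modifiers$hgvs_p,
                   freq_inhouse = fx$modifiers$freq_inhouse,
                   sift = fx$modifiers$sift,
                   polyphen = fx$modifiers$polyphen))
  expect_true(all(mods$damaging_missense))
  # the common Pro240Leu fails rarity (0.26 in controls) yet stays damaging
  expect_equal(mods$tier[mods$hgvs_c == "c.C719T"], "excluded")
})
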