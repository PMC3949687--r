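#' Construct a pedigree with per-variant genotypes
#'
#' @param members Tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` (`"0"` or `NA` for founders), `sex`
#'   (1 = male, 2 = female), `affected` (logical).
#' @param genotypes Tibble with columns `individual_id`, `variant_key`,
#'   `genotype` in `{"ref", "het", "hom"}`.
#' @return An object of class `ush_pedigree`.
#' @export
ush_pedigree <- function(members, genotypes) {
  members <- tibble::as_tibble(members)
  genotypes <- tibble::as_tibble(genotypes)
  members$father_id[members$father_id %in% c("0", "")] <- NA_character_
  members$mother_id[members$mother_id %in% c("0", "")] <- NA_character_
  ids <- members$individual_id
  refs <- c(members$father_id, members$mother_id)
  if (!all(refs[!is.na(refs)] %in% ids))
    stop("pedigree parent references must resolve or be founders")
  if (!any(members$affected))
    stop("pedigree must contain an affected proband")
  if (!all(genotypes$genotype %in% c("ref", "het", "hom")))
    stop("genotypes must be ref/het/hom")
  structure(list(members = members, genotypes = genotypes),
            class = "ush_pedigree")
}

#' @export
print.ush_pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x$members), "members,",
      sum(x$members$affected), "affected,",
      length(unique(x$genotypes$variant_key)), "genotyped variants\n")
  invisible(x)
}

ped_genotype <- function(ped, individual, key) {
  g <- ped$genotypes$genotype[ped$genotypes$individual_id == individual &
                                ped$genotypes$variant_key == key]
  if (length(g) == 0) NA_character_ else g[1]
}

ped_proband <- function(ped) {
  m <- ped$members
  cand <- m$individual_id[m$affected & !is.na(m$father_id) & !is.na(m$mother_id)]
  if (length(cand) == 0) cand <- m$individual_id[m$affected]
  cand[1]
}

# Mendelian consistency of all genotyped members with known parents.
ped_consistent <- function(ped) {
  m <- ped$members
  for (i in seq_len(nrow(m))) {
    fa <- m$father_id[i]; mo <- m$mother_id[i]
    if (is.na(fa) || is.na(mo)) next
    keys <- unique(ped$genotypes$variant_key[
      ped$genotypes$individual_id == m$individual_id[i]])
    for (k in keys) {
      gc <- ped_genotype(ped, m$individual_id[i], k)
      gf <- ped_genotype(ped, fa, k)
      gm <- ped_genotype(ped, mo, k)
      if (is.na(gc) || is.na(gf) || is.na(gm)) next
      carrier_f <- gf %in% c("het", "hom")
      carrier_m <- gm %in% c("het", "hom")
      if (gc == "hom" && !(carrier_f && carrier_m)) return(FALSE)
      if (gc == "het" && !(carrier_f || carrier_m)) return(FALSE)
      if (gc == "ref" && (gf == "hom" || gm == "hom")) return(FALSE)
    }
  }
  TRUE
}

#' Segregation analysis of a heterozygous variant pair
#'
#' Traces two heterozygous proband variants through the family: phase is
#' `trans` iff exactly one variant is carried by the mother and the other
#' by the father, `cis` iff both trace to a single parent, and
#' `undetermined` when a parent is unavailable or carriers are
#' ambiguous (e.g. a variant carried by both parents). Mendelian
#' consistency of every genotyped family member is checked alongside.
#'
#' @param variant_keys Character vector of two variant keys, both
#'   heterozygous in the proband.
#' @param ped An [ush_pedigree()].
#' @param proband Proband id; defaults to the first affected member with
#'   both parents in the pedigree.
#' @return A list with `variant_pair`, `phase`
#'   (`trans`/`cis`/`undetermined`) and `consistent` (logical).
#' @export
check_segregation <- function(variant_keys, ped, proband = NULL) {
  stopifnot(length(variant_keys) == 2)
  if (is.null(proband)) proband <- ped_proband(ped)
  m <- ped$members
  fa <- m$father_id[m$individual_id == proband]
  mo <- m$mother_id[m$individual_id == proband]
  for (k in variant_keys)
    if (!k %in% ped$genotypes$variant_key)
      stop("variant absent from pedigree genotype map: ", k)

  consistent <- ped_consistent(ped)
  phase <- "undetermined"
  if (length(fa) == 1 && length(mo) == 1 && !is.na(fa) && !is.na(mo)) {
    gf <- vapply(variant_keys, function(k) ped_genotype(ped, fa, k), character(1))
    gm <- vapply(variant_keys, function(k) ped_genotype(ped, mo, k), character(1))
    from_f <- !is.na(gf) & gf %in% c("het", "hom")
    from_m <- !is.na(gm) & gm %in% c("het", "hom")
    if (!any(is.na(gf)) && !any(is.na(gm))) {
      if ((from_m[1] && !from_f[1] && from_f[2] && !from_m[2]) ||
          (from_f[1] && !from_m[1] && from_m[2] && !from_f[2])) {
        phase <- "trans"
      } else if ((all(from_f) && !any(from_m)) ||
                 (all(from_m) && !any(from_f))) {
        phase <- "cis"
      }
    }
  }
  list(variant_pair = variant_keys, phase = phase, consistent = consistent)
}

# Variants that can support a causal (biallelic/digenic/monoallelic) call.
causal_set <- function(pv) {
  pv[pv$rarity_pass & pv$selected &
       pv$tier %in% c("pathogenic", "probable_pathogenic"), , drop = FALSE]
}

# Reported variants: everything the screening algorithm retains, i.e.
# rare variants of a selected consequence class (tier may be uncertain).
reported_set <- function(pv) {
  pv[pv$rarity_pass & pv$selected, , drop = FALSE]
}

diagnose_one <- function(patient_id, pv, ped = NULL,
                         modifier_genes = ush1_genes()) {
  pv <- pv[order(pv$key), , drop = FALSE]
  causal <- causal_set(pv)
  reported <- reported_set(pv)
  category <- "unsolved"
  genes <- character(0)
  causal_keys <- character(0)
  segregation <- "not_tested"
  n_alleles <- 0L

  seg_phase <- function(keys) {
    if (is.null(ped)) return(NULL)
    ok <- all(keys %in% ped$genotypes$variant_key)
    if (!ok) return(NULL)
    check_segregation(keys, ped)
  }

  # (1) biallelic: a gene with a hom causal variant or >= 2 het causal
  # variants (trans or undetermined phase)
  if (nrow(causal) > 0) {
    for (g in unique(causal$gene)) {
      cg <- causal[causal$gene == g, , drop = FALSE]
      if (any(cg$zygosity == "hom")) {
        hom <- cg[cg$zygosity == "hom", , drop = FALSE][1, ]
        category <- "solved_biallelic"; genes <- g
        causal_keys <- hom$key; n_alleles <- 2L
        segregation <- "not_tested"
        break
      }
      hets <- cg[cg$zygosity == "het", , drop = FALSE]
      if (nrow(hets) >= 2) {
        seg <- seg_phase(hets$key[1:2])
        if (!is.null(seg) && seg$phase == "cis") next
        category <- "solved_biallelic"; genes <- g
        causal_keys <- hets$key[1:2]; n_alleles <- 2L
        segregation <- if (is.null(seg)) "assumed"
          else if (!seg$consistent) "inconsistent"
          else if (seg$phase == "trans") "confirmed_trans" else "assumed"
        break
      }
    }
  }

  # (2) digenic: exactly one causal het in each of two distinct genes
  if (category == "unsolved" && nrow(causal) == 2 &&
      all(causal$zygosity == "het") &&
      length(unique(causal$gene)) == 2) {
    seg <- seg_phase(causal$key)
    if (!is.null(seg) && seg$phase == "cis") {
      # same haplotype: two independent monoallelic findings
      category <- "monoallelic"; genes <- unique(causal$gene)
      causal_keys <- causal$key; n_alleles <- 1L
      segregation <- "not_tested"
    } else {
      category <- "digenic"; genes <- causal$gene
      causal_keys <- causal$key; n_alleles <- 2L
      segregation <- if (is.null(seg)) "assumed"
        else if (!seg$consistent) "inconsistent"
        else if (seg$phase == "trans") "confirmed_trans" else "assumed"
    }
  }

  # (3) monoallelic: exactly one reported het variant overall (a reported
  # variant of uncertain tier still makes its carrier a mutation carrier)
  if (category == "unsolved") {
    if (nrow(causal) == 1 && causal$zygosity[1] == "het") {
      category <- "monoallelic"; genes <- causal$gene
      causal_keys <- causal$key; n_alleles <- 1L
    } else if (nrow(causal) == 0 && nrow(reported) == 1 &&
               reported$zygosity[1] == "het") {
      category <- "monoallelic"; genes <- reported$gene
      causal_keys <- reported$key; n_alleles <- 1L
    }
  }

  # modifier candidates: for biallelic patients, additional rare damaging
  # missense variants in a different gene of the modifier set (rarity is
  # reported but does not gate candidacy)
  modifiers <- pv[0, , drop = FALSE]
  if (category == "solved_biallelic") {
    modifiers <- pv[pv$damaging_missense & !pv$gene %in% genes &
                      pv$gene %in% modifier_genes &
                      !pv$key %in% causal_keys, , drop = FALSE]
  }

  tibble::tibble(
    patient_id = patient_id,
    category = category,
    genes = paste(genes, collapse = "/"),
    causal_variants = list(causal_keys),
    n_causal_alleles = n_alleles,
    segregation_status = segregation,
    modifier_candidates = list(modifiers$key),
    n_modifiers = nrow(modifiers),
    n_reported_variants = nrow(reported))
}

#' Diagnose a single patient
#'
#' Applies the decision ladder to a patient's filtered, annotated
#' variants: (1) a gene with a homozygous causal variant, or two
#' heterozygous ones in trans or with undetermined phase, is called
#' `solved_biallelic`; (2) otherwise exactly one causal heterozygous
#' variant in each of two genes — in trans when a pedigree is available —
#' is `digenic` (a cis pair is downgraded to monoallelic findings);
#' (3) otherwise a single reported heterozygous variant is `monoallelic`;
#' (4) otherwise `unsolved`. Causal means tier pathogenic or
#' probable_pathogenic after rarity filtering. Independently, biallelic
#' patients collect rare damaging missense variants in a different gene
#' of `modifier_genes` as disease-modifier candidates.
#'
#' @param patient_id Identifier.
#' @param variants Annotated variant tibble for this patient (from
#'   [annotate_variants()], with `zygosity` and `key` columns).
#' @param ped Optional [ush_pedigree()] for segregation.
#' @param modifier_genes Genes searched for modifier candidates; defaults
#'   to the USH1 genes.
#' @return One-row tibble: `category`, `genes`, `causal_variants`
#'   (list-column of keys), `n_causal_alleles`, `segregation_status`,
#'   `modifier_candidates`, `n_modifiers`, `n_reported_variants`.
#' @export
diagnose_patient <- function(patient_id, variants, ped = NULL,
                             modifier_genes = ush1_genes()) {
  v <- tibble::as_tibble(variants)
  if (nrow(v) > 0 && !"key" %in% names(v))
    v$key <- variant_key(v$gene, v$hgvs_c)
  diagnose_one(patient_id, v, ped, modifier_genes)
}

#' Diagnose every patient in a cohort
#'
#' @param patients Tibble with a `patient_id` column (patients with no
#'   surviving variants are still diagnosed, as `unsolved`).
#' @param variants Annotated long variant table with `patient_id`.
#' @param pedigrees Named list of [ush_pedigree()] objects keyed by
#'   patient id.
#' @param modifier_genes Passed to [diagnose_patient()].
#' @return Tibble with one diagnostic row per patient, in input order.
#' @export
diagnose_cohort <- function(patients, variants, pedigrees = list(),
                            modifier_genes = ush1_genes()) {
  v <- tibble::as_tibble(variants)
  if (nrow(v) > 0 && !"key" %in% names(v))
    v$key <- variant_key(v$gene, v$hgvs_c)
  purrr::map_dfr(patients$patient_id, function(pid) {
    pv <- v[v$patient_id == pid, , drop = FALSE]
    ped <- pedigrees[[as.character(pid)]]
    diagnose_one(pid, pv, ped, modifier_genes)
  })
}

#' Patients needing orthogonal Sanger confirmation
#'
#' The screening algorithm fully re-sequences, by capillary Sanger
#' chemistry, every patient left with one heterozygous causative variant
#' or none at all, to verify the panel result and rescue variants the
#' platform cannot see.
#'
#' @param diagnoses Tibble from [diagnose_cohort()].
#' @return Vector of patient ids with category monoallelic or unsolved.
#' @export
sanger_fallback_list <- function(diagnoses) {
  diagnoses$patient_id[diagnoses$category %in% c("monoallelic", "unsolved")]
}
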