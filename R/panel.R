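#' The nine screened Usher genes with their RefSeq transcripts
#'
#' The five USH1 genes (MYO7A, USH1C, CDH23, PCDH15, USH1G), the three
#' USH2 genes (USH2A, GPR98, DFNB31) and the USH3 gene (CLRN1), each with
#' the transcript accession used for HGVS coding-DNA notation.
#'
#' @return A tibble with columns `gene`, `refseq` and `type`
#'   (`"USH1"`, `"USH2"` or `"USH3"`).
#' @export
usher_panel_genes <- function() {
  tibble::tibble(
    gene   = c("MYO7A", "USH1C", "CDH23", "PCDH15", "USH1G",
               "USH2A", "GPR98", "DFNB31", "CLRN1"),
    refseq = c("NM_000260.3", "NM_153676.3", "NM_022124.5", "NM_033056.3",
               "NM_173477.2", "NM_206933.2", "NM_032119.3", "NM_015404.3",
               "NM_174878.2"),
    type   = c(rep("USH1", 5), rep("USH2", 3), "USH3"))
}

#' Genes of the USH1 subtype
#'
#' Convenience accessor: the five USH1 genes, the default gene set in
#' which disease-modifier candidates are sought.
#'
#' @return Character vector of gene symbols.
#' @export
ush1_genes <- function() {
  p <- usher_panel_genes()
  p$gene[p$type == "USH1"]
}

#' Construct a gene-panel description
#'
#' @param genes Tibble with at least a `gene` column of unique symbols
#'   (default [usher_panel_genes()]).
#' @param covered_fraction Proportion of target exons the amplicon design
#'   covers, in `[0, 1]`. The study design achieved 0.97.
#' @return An object of class `ush_panel`.
#' @export
ush_panel <- function(genes = usher_panel_genes(), covered_fraction = 0.97) {
  stopifnot(is.data.frame(genes), "gene" %in% names(genes))
  if (anyDuplicated(genes$gene))
    stop("panel gene symbols must be unique")
  if (!is.numeric(covered_fraction) || length(covered_fraction) != 1 ||
      is.na(covered_fraction) || covered_fraction < 0 || covered_fraction > 1)
    stop("covered_fraction must be a single value in [0, 1]")
  structure(list(genes = tibble::as_tibble(genes),
                 covered_fraction = covered_fraction),
            class = "ush_panel")
}

#' @export
print.ush_panel <- function(x, ...) {
  cat("Usher gene panel:", nrow(x$genes), "genes,",
      sprintf("%.1f%%", 100 * x$covered_fraction), "of target exons covered\n")
  cat(paste(x$genes$gene, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize an HGVS coding-DNA string
#'
#' Canonicalizes case and whitespace so that equivalent spellings compare
#' equal: bases upper-case, the `c.` prefix and the `del`/`dup`/`ins`
#' keywords lower-case, all whitespace removed. ANNOVAR-style
#' substitutions (`c.C719T`) are rewritten to HGVS (`c.719C>T`).
#'
#' @param x Character vector of coding-DNA change strings.
#' @return Character vector of normalized strings.
#' @export
normalize_hgvs_c <- function(x) {
  x <- gsub("[[:space:]]+", "", as.character(x))
  if (any(!nzchar(x) | is.na(x)))
    stop("hgvs_c must be non-empty")
  body <- toupper(sub("^[Cc]\\.", "", x))
  body <- gsub("DELINS", "delins", body, fixed = TRUE)
  body <- gsub("DEL", "del", body, fixed = TRUE)
  body <- gsub("DUP", "dup", body, fixed = TRUE)
  body <- gsub("INS", "ins", body, fixed = TRUE)
  # ANNOVAR-style c.C719T -> c.719C>T
  annovar <- grepl("^[ACGT][0-9]+[ACGT]$", body)
  body[annovar] <- sub("^([ACGT])([0-9]+)([ACGT])$", "\\2\\1>\\3", body[annovar])
  paste0("c.", body)
}

#' Canonical identity key for a variant
#'
#' Two calls denote the same variant iff they share a gene symbol and a
#' normalized coding-DNA change; keys are case- and
#' whitespace-insensitive.
#'
#' @param gene Gene symbol(s).
#' @param hgvs_c Coding-DNA change string(s).
#' @return Character vector of keys, `GENE:c.change`.
#' @export
variant_key <- function(gene, hgvs_c) {
  paste0(toupper(trimws(gene)), ":", normalize_hgvs_c(hgvs_c))
}

fixture_path <- function(file, dir = NULL) {
  if (is.null(dir)) dir <- system.file("extdata", package = "usherpanel")
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop("fixture table missing: ", file)
  path
}

read_fixture_tsv <- function(file, dir = NULL) {
  path <- fixture_path(file, dir)
  out <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("NA", "")),
    error = function(e) stop("corrupt fixture table ", file, ": ",
                             conditionMessage(e)))
  if (nrow(readr::problems(out)) > 0)
    stop("corrupt fixture table ", file)
  out
}

#' Load the packaged study fixtures
#'
#' Reads the packaged transcriptions of the study's printed tables: the
#' 19 probable pathogenic variants, the 17 patients and their alleles,
#' the four second-gene (modifier-candidate) missense variants, the
#' previously-reported-variant catalog, and the Case #4 family (pedigree
#' plus per-member genotypes). Basic integrity is checked on load and a
#' failure names the offending table.
#'
#' Case #10's allele is printed only as a protein change
#' (PCDH15 p.Arg962Cys); its coding change in the allele fixture is
#' reconstructed from codon arithmetic and the variant is absent from the
#' 19-variant table, so it annotates to tier `uncertain`.
#'
#' @param dir Directory holding the fixture files; defaults to the
#'   package's `extdata`.
#' @return A list with tibbles `variants` (19 rows), `patients` (17),
#'   `patient_variants` (long allele table), `modifiers` (4), `catalog`,
#'   and `pedigrees` (named list of [ush_pedigree()] objects, here the
#'   Case #4 family).
#' @export
load_fixture_tables <- function(dir = NULL) {
  variants <- read_fixture_tsv("table1_variants.tsv", dir)
  if (nrow(variants) != 19 ||
      length(unique(variant_key(variants$gene, variants$hgvs_c))) != 19)
    stop("corrupt fixture table table1_variants.tsv: expected 19 distinct variants")

  patients <- read_fixture_tsv("table2_patients.tsv", dir)
  if (nrow(patients) != 17 || anyDuplicated(patients$patient_id))
    stop("corrupt fixture table table2_patients.tsv: expected 17 patients")
  patients$onset_night_blindness <-
    suppressWarnings(as.integer(patients$onset_night_blindness))

  alleles <- read_fixture_tsv("table2_alleles.tsv", dir)
  if (!all(alleles$patient_id %in% patients$patient_id))
    stop("corrupt fixture table table2_alleles.tsv: unknown patient id")
  if (!all(alleles$zygosity %in% c("het", "hom")))
    stop("corrupt fixture table table2_alleles.tsv: bad zygosity")

  modifiers <- read_fixture_tsv("table3_modifiers.tsv", dir)
  if (!setequal(modifiers$patient_id, c(3L, 5L, 8L, 15L)))
    stop("corrupt fixture table table3_modifiers.tsv: expected cases 3, 5, 8, 15")

  catalog <- read_fixture_tsv("known_variants.tsv", dir)

  ped <- read_ped(fixture_path("family_case4.ped", dir),
                  genotypes = fixture_path("family_case4_genotypes.tsv", dir))
  if (nrow(ped$members) != 5)
    stop("corrupt fixture table family_case4.ped: expected 5 members")

  list(variants = variants, patients = patients, patient_variants = alleles,
       modifiers = modifiers, catalog = catalog,
       pedigrees = list("4" = ped))
}

#' Assemble the annotated fixture cohort
#'
#' Joins the packaged tables into the form the diagnosis stage consumes:
#' one row per observed variant per patient carrying zygosity, frequency
#' and predictor annotations (second-gene modifier-candidate variants
#' included), run through the full annotation chain against the
#' previously-reported catalog.
#'
#' @param fx Fixture list from [load_fixture_tables()]; loaded if `NULL`.
#' @return A list: `patients`, annotated long table `variants`, and
#'   `pedigrees`.
#' @export
fixture_cohort <- function(fx = NULL) {
  if (is.null(fx)) fx <- load_fixture_tables()
  tab1 <- fx$variants
  tab1$key <- variant_key(tab1$gene, tab1$hgvs_c)

  pv <- fx$patient_variants
  pv$key <- variant_key(pv$gene, pv$hgvs_c)
  pv <- dplyr::left_join(
    pv, tab1[, c("key", "freq_inhouse", "sift", "polyphen", "detectability")],
    by = "key")

  mods <- fx$modifiers
  mod_rows <- tibble::tibble(
    patient_id = mods$patient_id,
    gene = mods$modifier_gene,
    hgvs_c = mods$hgvs_c,
    hgvs_p = mods$hgvs_p,
    zygosity = mods$zygosity,
    key = variant_key(mods$modifier_gene, mods$hgvs_c),
    freq_inhouse = mods$freq_inhouse,
    sift = mods$sift,
    polyphen = mods$polyphen,
    detectability = NA_character_)

  all_pv <- dplyr::bind_rows(pv, mod_rows)
  all_pv$freq_1000g <- NA_real_
  all_pv$freq_exome <- NA_real_
  ann <- annotate_variants(all_pv, catalog = fx$catalog)
  list(patients = fx$patients, variants = ann, pedigrees = fx$pedigrees)
}
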