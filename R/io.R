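#' Read a variant call table
#'
#' Two dialects are supported. `tsv`: a tab-delimited table with header,
#' requiring at least `gene` and `hgvs_c` (plus `patient_id` when
#' multi-patient) and carrying optional `depth`, `mean_base_quality`,
#' `alt_fraction`, frequency and predictor-score columns; malformed
#' lines are reported with their line numbers. `vcf`: a minimal VCF 4.2
#' file (read via Bioconductor's VariantAnnotation) whose INFO field
#' carries `GENE`/`HGVSC`/`HGVSP` and whose FORMAT carries `DP` and
#' allele depths `AD`; the alternate-allele fraction is taken from a
#' FORMAT `AF` when present and otherwise derived from the allele
#' depths.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param patient_id Patient id to assign when the table does not name
#'   one (for VCF, defaults to the sample name).
#' @return Tibble of variant calls; zero rows for a header-only file.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               patient_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           na = c("NA", ""))
    prob <- readr::problems(out)
    if (nrow(prob) > 0)
      stop("malformed TSV at line(s) ",
           paste(unique(prob$row), collapse = ", "), " of ", path)
    missing <- setdiff(c("gene", "hgvs_c"), names(out))
    if (length(missing))
      stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
    if (!"patient_id" %in% names(out) && !is.null(patient_id))
      out$patient_id <- patient_id
    return(out)
  }
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  n <- nrow(info)
  if (n == 0) return(tibble::tibble())
  samples <- colnames(vcf)
  dp <- VariantAnnotation::geno(vcf)$DP
  ad <- VariantAnnotation::geno(vcf)$AD
  af <- if ("AF" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$AF else NULL
  bq <- if ("BQ" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$BQ else NULL
  unlist1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)[1]
  purrr::map_dfr(samples, function(s) {
    frac <- vapply(seq_len(n), function(i) {
      if (!is.null(af)) return(as.numeric(af[i, s][[1]])[1])
      pair <- as.numeric(ad[i, s][[1]])
      if (length(pair) < 2 || sum(pair) == 0) return(NA_real_)
      pair[2] / sum(pair)
    }, numeric(1))
    tibble::tibble(
      patient_id = if (!is.null(patient_id)) patient_id else s,
      gene = vapply(seq_len(n), function(i) unlist1(info$GENE[i]), character(1)),
      hgvs_c = vapply(seq_len(n), function(i) unlist1(info$HGVSC[i]), character(1)),
      hgvs_p = if ("HGVSP" %in% names(info))
        vapply(seq_len(n), function(i) unlist1(info$HGVSP[i]), character(1))
        else NA_character_,
      depth = as.integer(dp[, s]),
      mean_base_quality = if (!is.null(bq)) as.numeric(bq[, s]) else NA_real_,
      alt_fraction = frac)
  })
}

#' Write variant calls as a minimal VCF 4.2 file
#'
#' Records live in transcript space: identity is gene + HGVS (carried in
#' INFO as `GENE`/`HGVSC`/`HGVSP`), the 1-based POS is the coding
#' position extracted from the HGVS string, and REF/ALT hold the
#' substituted bases (symbolic `N`/`<INDEL>` for length changes). FORMAT
#' carries `DP`, `AD` (ref,alt derived from depth and fraction), `AF`
#' and `BQ`.
#'
#' @param calls Tibble of calls for one sample, with `gene`, `hgvs_c`,
#'   `depth`, `alt_fraction`, optionally `hgvs_p`, `mean_base_quality`.
#' @param path Output path.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path, sample = "SAMPLE") {
  calls <- tibble::as_tibble(calls)
  genes <- unique(calls$gene)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", sort(genes), ">"),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS coding change\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"HGVS protein change\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    "##FORMAT=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- vapply(seq_len(nrow(calls)), function(i) {
    p <- parse_hgvs_c(calls$hgvs_c[i])
    ref <- if (p$kind == "substitution") p$ref else "N"
    alt <- if (p$kind == "substitution") p$alt else "<INDEL>"
    depth <- calls$depth[i]
    af <- calls$alt_fraction[i]
    alt_reads <- as.integer(round(depth * af))
    hp <- if ("hgvs_p" %in% names(calls) && !is.na(calls$hgvs_p[i]))
      calls$hgvs_p[i] else "."
    bq <- if ("mean_base_quality" %in% names(calls))
      calls$mean_base_quality[i] else NA
    paste(calls$gene[i], max(p$position, 1L), calls$hgvs_c[i], ref, alt,
          ".", "PASS",
          paste0("GENE=", calls$gene[i], ";HGVSC=", calls$hgvs_c[i],
                 ";HGVSP=", hp),
          "DP:AD:AF:BQ",
          paste(depth, paste0(depth - alt_reads, ",", alt_reads),
                signif(af, 6), ifelse(is.na(bq), ".", bq), sep = ":"),
          sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a pedigree from a standard 6-column PED file
#'
#' Columns: family id, individual id, father id, mother id, sex (1 =
#' male, 2 = female), phenotype (2 = affected). A companion genotype
#' table (TSV: `individual_id`, `gene`, `hgvs_c`, `genotype` in
#' ref/het/hom) supplies per-variant genotypes.
#'
#' @param path PED file path.
#' @param genotypes Path to the genotype TSV, or a tibble, or `NULL`.
#' @return An [ush_pedigree()].
#' @export
read_ped <- function(path, genotypes = NULL) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "individual_id",
                                         "father_id", "mother_id", "sex",
                                         "phenotype"))
  members <- tibble::tibble(
    family_id = as.character(ped$family_id),
    individual_id = as.character(ped$individual_id),
    father_id = as.character(ped$father_id),
    mother_id = as.character(ped$mother_id),
    sex = as.integer(ped$sex),
    affected = ped$phenotype == 2)
  geno <- tibble::tibble(individual_id = character(0),
                         variant_key = character(0), genotype = character(0))
  if (!is.null(genotypes)) {
    g <- if (is.character(genotypes))
      readr::read_tsv(genotypes, show_col_types = FALSE, progress = FALSE)
      else tibble::as_tibble(genotypes)
    geno <- tibble::tibble(
      individual_id = as.character(g$individual_id),
      variant_key = if ("variant_key" %in% names(g)) g$variant_key
        else variant_key(g$gene, g$hgvs_c),
      genotype = g$genotype)
  }
  ush_pedigree(members, geno)
}

#' Run the full diagnostic pipeline
#'
#' Executes filter, annotate, diagnose and report on a cohort call
#' table, writing each stage's output plus a rejection log (every removed
#' variant with its first failing predicate, in the fixed order depth,
#' quality, zygosity band, consequence class, rarity) and a JSON/text
#' report to `out_dir`. Deterministic given its inputs: rerunning on the
#' same inputs reproduces byte-identical artifacts.
#'
#' @param calls Cohort variant call table (one row per call per
#'   patient).
#' @param patients Tibble with `patient_id` (and onset column for the
#'   modifier comparison); defaults to the distinct patients in `calls`.
#' @param pedigrees Named list of [ush_pedigree()] keyed by patient id.
#' @param catalog Previously-reported catalog for novelty flagging.
#' @param thresholds,rarity,missense Stage policies.
#' @param modifier_genes Genes searched for modifier candidates.
#' @param out_dir Output directory, created if needed; `NULL` writes
#'   nothing.
#' @return List with `filtered`, `rejections`, `annotated`, `diagnoses`,
#'   `summary`, invisibly.
#' @export
run_pipeline <- function(calls, patients = NULL, pedigrees = list(),
                         catalog = NULL,
                         thresholds = filter_thresholds(),
                         rarity = rarity_policy(),
                         missense = missense_policy(),
                         modifier_genes = ush1_genes(),
                         out_dir = NULL) {
  calls <- tibble::as_tibble(calls)
  if (is.null(patients))
    patients <- tibble::tibble(patient_id = unique(calls$patient_id))

  filtered <- apply_qc_filters(calls, thresholds)
  rejections <- qc_rejections(filtered)

  annotated <- annotate_variants(filtered, rarity = rarity,
                                 missense = missense, catalog = catalog)
  annotated$key <- variant_key(annotated$gene, annotated$hgvs_c)
  # common damaging missense variants stay visible to the diagnosis stage:
  # they can never be causal (tier excluded) but remain modifier candidates
  keep_ann <- annotated$selected &
    (annotated$rarity_pass | annotated$damaging_missense)
  removed <- annotated[!keep_ann, , drop = FALSE]
  if (nrow(removed) > 0 || nrow(rejections) > 0) {
    removed$reason <- ifelse(!removed$selected, "consequence_class", "rarity")
    rejections <- dplyr::bind_rows(rejections, removed)
  }
  retained <- annotated[keep_ann, , drop = FALSE]

  diagnoses <- diagnose_cohort(patients, retained, pedigrees, modifier_genes)
  # the cohort's distinct-variant tally covers primary disease alleles;
  # modifier-candidate attachments are reported per patient, not here
  causal_keys <- unique(unlist(diagnoses$causal_variants))
  distinct_variants <- retained[retained$key %in% causal_keys &
                                  !duplicated(retained$key), , drop = FALSE]
  summary <- summarize_cohort(diagnoses, distinct_variants)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage <- function(df, file) {
      flat <- df
      for (cl in names(flat))
        if (is.list(flat[[cl]]))
          flat[[cl]] <- vapply(flat[[cl]], paste, character(1), collapse = ";")
      readr::write_tsv(flat, file.path(out_dir, file))
    }
    write_stage(filtered, "filtered_variants.tsv")
    write_stage(rejections, "rejection_log.tsv")
    write_stage(annotated, "annotated_variants.tsv")
    write_stage(diagnoses, "diagnoses.tsv")
    jsonlite::write_json(unclass(summary),
                         file.path(out_dir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    con <- file(file.path(out_dir, "cohort_report.txt"), open = "wt")
    sink(con); print(summary); sink(); close(con)
    writeLines(c(
      sprintf("min_depth\t%s", thresholds$min_depth),
      sprintf("min_mean_base_quality\t%s", thresholds$min_mean_base_quality),
      sprintf("het_band\t%s-%s", thresholds$het_band[1], thresholds$het_band[2]),
      sprintf("hom_band\t%s-%s", thresholds$hom_band[1], thresholds$hom_band[2]),
      sprintf("max_frequency\t%s", rarity$max_frequency),
      sprintf("sift_damaging_max\t%s", missense$sift_damaging_max),
      sprintf("polyphen_damaging_min\t%s", missense$polyphen_damaging_min)),
      file.path(out_dir, "pipeline_settings.tsv"))
  }
  invisible(list(filtered = filtered, rejections = rejections,
                 annotated = annotated, diagnoses = diagnoses,
                 summary = summary))
}
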