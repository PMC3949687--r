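#' Round-half-away-from-zero percentage rendering
#'
#' Renders a fraction as a percentage with one decimal, rounding halves
#' away from zero (so 7/17 prints 41.2, 16/17 prints 94.1), matching the
#' reporting convention of clinical yield tables.
#'
#' @param x Fractions in `[0, 1]`.
#' @param digits Decimal places.
#' @return Numeric percentages.
#' @export
percent_1dp <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * 100 * scale + 0.5) / scale
}

#' Cohort-level diagnostic summary
#'
#' Aggregates per-patient diagnoses into the headline numbers of a panel
#' screen: diagnostic yield (patients carrying at least one reported
#' variant), per-gene biallelic frequencies, the count of patients with
#' two pathogenic mutations (biallelic plus digenic), digenic and
#' modifier-candidate patients, and — when the cohort's distinct variant
#' table is supplied — the number of distinct tiered variants, how many
#' are novel, and how many are detectable by the sequencing platform
#' (no detectability flag).
#'
#' @param diagnoses Tibble from [diagnose_cohort()].
#' @param variants Optional annotated distinct-variant table with
#'   `tier`, `novel` and `detectability` columns.
#' @return An object of class `ush_cohort_summary` (a list).
#' @export
summarize_cohort <- function(diagnoses, variants = NULL) {
  if (nrow(diagnoses) == 0) stop("empty cohort")
  n <- nrow(diagnoses)
  carriers <- sum(diagnoses$n_reported_variants > 0)
  biallelic <- diagnoses[diagnoses$category == "solved_biallelic", , drop = FALSE]
  per_gene <- table(biallelic$genes)
  per_gene <- per_gene[order(-as.integer(per_gene), names(per_gene))]

  out <- list(
    n_patients = n,
    n_with_any_mutation = carriers,
    yield_fraction = carriers / n,
    yield_percent = percent_1dp(carriers / n),
    per_gene_biallelic_counts = setNames(as.integer(per_gene), names(per_gene)),
    per_gene_biallelic_percent = setNames(
      percent_1dp(as.integer(per_gene) / n), names(per_gene)),
    n_solved_biallelic = nrow(biallelic),
    n_digenic = sum(diagnoses$category == "digenic"),
    n_monoallelic = sum(diagnoses$category == "monoallelic"),
    n_unsolved = sum(diagnoses$category == "unsolved"),
    n_two_mutation = sum(diagnoses$n_causal_alleles == 2),
    n_modifier_patients = sum(diagnoses$n_modifiers > 0))

  if (!is.null(variants)) {
    v <- tibble::as_tibble(variants)
    if (!"key" %in% names(v)) v$key <- variant_key(v$gene, v$hgvs_c)
    tiered <- v[v$tier %in% c("pathogenic", "probable_pathogenic"), , drop = FALSE]
    tiered <- tiered[!duplicated(tiered$key), , drop = FALSE]
    out$n_distinct_variants <- nrow(tiered)
    out$n_novel <- sum(tiered$novel)
    if ("detectability" %in% names(tiered))
      out$n_detected_by_mps <- sum(is.na(tiered$detectability))
  }
  structure(out, class = "ush_cohort_summary")
}

#' @export
print.ush_cohort_summary <- function(x, ...) {
  cat("Cohort diagnostic summary\n")
  cat(sprintf("  patients screened          %d\n", x$n_patients))
  cat(sprintf("  with >= 1 mutation         %d (%.1f%%)\n",
              x$n_with_any_mutation, x$yield_percent))
  cat(sprintf("  two pathogenic mutations   %d\n", x$n_two_mutation))
  cat(sprintf("  biallelic / digenic / monoallelic / unsolved   %d / %d / %d / %d\n",
              x$n_solved_biallelic, x$n_digenic, x$n_monoallelic, x$n_unsolved))
  cat(sprintf("  modifier-candidate carriers %d\n", x$n_modifier_patients))
  if (length(x$per_gene_biallelic_counts)) {
    cat("  biallelic frequency by gene:\n")
    for (g in names(x$per_gene_biallelic_counts))
      cat(sprintf("    %-8s %d/%d (%.1f%%)\n", g,
                  x$per_gene_biallelic_counts[[g]], x$n_patients,
                  x$per_gene_biallelic_percent[[g]]))
  }
  if (!is.null(x$n_distinct_variants))
    cat(sprintf("  distinct variants %d (novel %d, platform-detectable %d)\n",
                x$n_distinct_variants, x$n_novel,
                if (is.null(x$n_detected_by_mps)) NA else x$n_detected_by_mps))
  invisible(x)
}

#' Welch's unequal-variance two-sample t test
#'
#' Implemented from the formulas: `t = (m1 - m2) / sqrt(s1^2/n1 +
#' s2^2/n2)`, with Welch–Satterthwaite degrees of freedom and a
#' two-sided p from the t distribution.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p.value`, `estimate` (the two
#'   means).
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group must have at least two values")
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df),
       estimate = c(mean_x = mean(x), mean_y = mean(y)))
}

#' Exact two-sample permutation test on the difference of means
#'
#' Enumerates every assignment of the pooled values into groups of the
#' observed sizes and reports the fraction whose absolute mean difference
#' is at least the observed one (two-sided). The p-value is therefore
#' bounded below by 1 / choose(n, n1).
#'
#' @param x,y Numeric vectors.
#' @param max_assignments Safety cap on the enumeration size.
#' @return List with `p.value`, `n_assignments`, `observed`.
#' @export
permutation_test_mean <- function(x, y, max_assignments = 2e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  if (nx < 1 || n - nx < 1) stop("both groups must be non-empty")
  if (choose(n, nx) > max_assignments)
    stop("too many assignments for exact enumeration")
  obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(n, nx)
  total <- sum(pooled)
  diffs <- apply(idx, 2, function(i) {
    sx <- sum(pooled[i])
    abs(sx / nx - (total - sx) / (n - nx))
  })
  list(p.value = mean(diffs >= obs - 1e-12),
       n_assignments = ncol(idx),
       observed = obs)
}

#' Compare retinitis pigmentosa onset between modifier carriers and
#' other two-mutation patients
#'
#' Groups the cohort into biallelic patients carrying a modifier
#' candidate versus two-mutation patients without one (biallelic only by
#' default; set `include_digenic = TRUE` to add digenic patients to the
#' comparison group), dropping patients whose onset of night blindness is
#' unknown. Both a Welch unequal-variance t test (from the formulas) and
#' an exact permutation test over all group assignments are reported.
#'
#' @param patients Tibble with `patient_id` and `onset_night_blindness`.
#' @param diagnoses Tibble from [diagnose_cohort()].
#' @param include_digenic Should digenic patients enter the comparison
#'   group? Default `FALSE`.
#' @return List with `groups` (tibble of patient, group, onset), `welch`
#'   and `permutation`.
#' @export
compare_onset_by_modifier <- function(patients, diagnoses,
                                      include_digenic = FALSE) {
  d <- dplyr::left_join(diagnoses,
                        patients[, c("patient_id", "onset_night_blindness")],
                        by = "patient_id")
  comp_cats <- if (include_digenic) c("solved_biallelic", "digenic")
    else "solved_biallelic"
  grp <- dplyr::case_when(
    d$category == "solved_biallelic" & d$n_modifiers > 0 ~ "modifier",
    d$category %in% comp_cats & d$n_modifiers == 0 ~ "no_modifier",
    TRUE ~ NA_character_)
  keep <- !is.na(grp) & !is.na(d$onset_night_blindness)
  groups <- tibble::tibble(patient_id = d$patient_id[keep],
                           group = grp[keep],
                           onset = d$onset_night_blindness[keep])
  x <- groups$onset[groups$group == "modifier"]
  y <- groups$onset[groups$group == "no_modifier"]
  if (length(x) == 0 || length(y) == 0)
    stop("both onset groups must be non-empty")
  welch <- if (length(x) >= 2 && length(y) >= 2) welch_t_test(x, y) else NULL
  list(groups = groups,
       welch = welch,
       permutation = permutation_test_mean(x, y))
}
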