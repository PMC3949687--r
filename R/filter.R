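#' QC thresholds for amplicon variant calls
#'
#' Defaults reproduce the study's filter chain for semiconductor amplicon
#' sequencing: minimum mean base quality 25 (Phred), minimum depth 10,
#' heterozygous allele-fraction band 40--60% and homozygous band
#' 80--100%, all bounds inclusive.
#'
#' @param min_mean_base_quality Minimum per-variant mean base quality.
#' @param min_depth Minimum read depth (>= 1).
#' @param het_band,hom_band Length-2 numeric allele-fraction intervals;
#'   must not overlap.
#' @return An object of class `ush_thresholds`.
#' @export
filter_thresholds <- function(min_mean_base_quality = 25, min_depth = 10,
                              het_band = c(0.40, 0.60),
                              hom_band = c(0.80, 1.00)) {
  stopifnot(length(het_band) == 2, length(hom_band) == 2,
            het_band[1] <= het_band[2], hom_band[1] <= hom_band[2])
  if (min_depth < 1) stop("min_depth must be >= 1")
  if (het_band[2] >= hom_band[1] && hom_band[2] >= het_band[1] &&
      max(het_band[1], hom_band[1]) <= min(het_band[2], hom_band[2]))
    stop("het_band and hom_band must not overlap")
  structure(list(min_mean_base_quality = min_mean_base_quality,
                 min_depth = min_depth,
                 het_band = as.numeric(het_band),
                 hom_band = as.numeric(hom_band)),
            class = "ush_thresholds")
}

#' Assign zygosity from the alternate-allele fraction
#'
#' A fraction inside the heterozygous band (inclusive) is called `het`,
#' inside the homozygous band `hom`, anything else `rejected`. For every
#' fraction in `[0, 1]` exactly one of the three labels is returned.
#'
#' @param alt_fraction Numeric vector of alternate-allele fractions in
#'   `[0, 1]`.
#' @param thresholds A [filter_thresholds()] object.
#' @return Character vector over `{"het", "hom", "rejected"}`.
#' @export
assign_zygosity <- function(alt_fraction, thresholds = filter_thresholds()) {
  if (any(is.na(alt_fraction)) ||
      any(alt_fraction < 0 | alt_fraction > 1))
    stop("alt_fraction must lie in [0, 1]")
  hb <- thresholds$het_band
  mb <- thresholds$hom_band
  out <- rep("rejected", length(alt_fraction))
  out[alt_fraction >= hb[1] & alt_fraction <= hb[2]] <- "het"
  out[alt_fraction >= mb[1] & alt_fraction <= mb[2]] <- "hom"
  out
}

#' Apply the QC filter chain to variant calls
#'
#' A call survives iff depth >= `min_depth`, mean base quality >=
#' `min_mean_base_quality`, and its allele fraction falls in the het or
#' hom band. Input order is preserved; each surviving call carries its
#' zygosity. Rejected calls are recorded (with the first failing
#' predicate, in the fixed order depth, quality, zygosity band) in the
#' `"rejected"` attribute of the result, retrievable with
#' [qc_rejections()].
#'
#' Calls with missing depth/quality/fraction measurements — e.g.
#' transcriptions of published variant tables, which are post-QC — pass
#' the corresponding predicate untested; such calls must then supply a
#' `zygosity` column.
#'
#' @param calls Tibble of variant calls; columns `depth`,
#'   `mean_base_quality`, `alt_fraction` are used when present.
#' @param thresholds A [filter_thresholds()] object.
#' @return The surviving rows with a `zygosity` column, `"rejected"`
#'   attribute attached.
#' @export
apply_qc_filters <- function(calls, thresholds = filter_thresholds()) {
  calls <- tibble::as_tibble(calls)
  n <- nrow(calls)
  depth <- if ("depth" %in% names(calls)) calls$depth else rep(NA_real_, n)
  qual <- if ("mean_base_quality" %in% names(calls))
    calls$mean_base_quality else rep(NA_real_, n)
  af <- if ("alt_fraction" %in% names(calls))
    calls$alt_fraction else rep(NA_real_, n)
  given <- if ("zygosity" %in% names(calls))
    calls$zygosity else rep(NA_character_, n)

  zyg <- rep(NA_character_, n)
  ok_af <- !is.na(af)
  if (any(ok_af)) zyg[ok_af] <- assign_zygosity(af[ok_af], thresholds)
  zyg[!ok_af] <- ifelse(is.na(given[!ok_af]), "rejected", given[!ok_af])

  reason <- rep(NA_character_, n)
  fail_depth <- !is.na(depth) & depth < thresholds$min_depth
  fail_qual <- !is.na(qual) & qual < thresholds$min_mean_base_quality
  fail_band <- zyg == "rejected"
  reason[fail_band] <- "zygosity_band"
  reason[fail_qual] <- "quality"
  reason[fail_depth] <- "depth"

  keep <- is.na(reason)
  kept <- calls[keep, , drop = FALSE]
  kept$zygosity <- zyg[keep]
  rejected <- calls[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  attr(kept, "rejected") <- rejected
  kept
}

#' Rejected calls from a QC-filtered table
#'
#' @param filtered Result of [apply_qc_filters()].
#' @return Tibble of rejected calls with a `reason` column.
#' @export
qc_rejections <- function(filtered) {
  rej <- attr(filtered, "rejected")
  if (is.null(rej)) tibble::tibble() else tibble::as_tibble(rej)
}
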