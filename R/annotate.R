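#' Rarity policy for the three-source frequency filter
#'
#' A candidate must be rare — frequency below `max_frequency` — in each
#' of the 1000 Genomes database, the 5400-exome variant set and the
#' in-house control panel (384 alleles by default). Sources without a
#' known frequency do not veto (novel variants are absent from all
#' catalogs).
#'
#' @param max_frequency Maximum allele frequency, strict; default 0.01.
#' @param inhouse_alleles Denominator of the in-house control panel.
#' @return An object of class `ush_rarity_policy`.
#' @export
rarity_policy <- function(max_frequency = 0.01, inhouse_alleles = 384L) {
  if (!(max_frequency > 0 && max_frequency < 1))
    stop("max_frequency must lie in (0, 1)")
  structure(list(max_frequency = max_frequency,
                 inhouse_alleles = as.integer(inhouse_alleles)),
            class = "ush_rarity_policy")
}

#' Missense deleteriousness policy
#'
#' A missense change is treated as damaging when SIFT calls it
#' intolerant (score <= `sift_damaging_max`) OR PolyPhen-2 calls it
#' damaging (score >= `polyphen_damaging_min`). The disjunction with
#' defaults 0.05 / 0.5 reproduces every published probable-pathogenic
#' missense call in the study, including SIFT scores of 0.09 and 0.19
#' rescued by high PolyPhen scores.
#'
#' @param sift_damaging_max SIFT threshold (low = damaging).
#' @param polyphen_damaging_min PolyPhen-2 threshold (high = damaging).
#' @return An object of class `ush_missense_policy`.
#' @export
missense_policy <- function(sift_damaging_max = 0.05,
                            polyphen_damaging_min = 0.5) {
  stopifnot(sift_damaging_max >= 0, sift_damaging_max <= 1,
            polyphen_damaging_min >= 0, polyphen_damaging_min <= 1)
  structure(list(sift_damaging_max = sift_damaging_max,
                 polyphen_damaging_min = polyphen_damaging_min),
            class = "ush_missense_policy")
}

# Parse one normalized coding-DNA change. Supported grammar:
# substitutions c.N(+/-k)X>Y, deletions/duplications c.N(_M)del/dup(SEQ),
# insertions c.N_MinsSEQ. Anything else raises naming the token.
parse_hgvs_c <- function(hgvs_c) {
  x <- normalize_hgvs_c(hgvs_c)
  body <- sub("^c\\.", "", x)

  m <- regmatches(body, regexec("^(-?[0-9]+)([+-][0-9]+)?([ACGT])>([ACGT])$", body))[[1]]
  if (length(m)) {
    return(list(kind = "substitution",
                position = as.integer(m[2]),
                offset = if (nzchar(m[3])) as.integer(m[3]) else 0L,
                ref = m[4], alt = m[5], length_change = 0L))
  }
  m <- regmatches(body, regexec("^([0-9]+)(?:_([0-9]+))?(del|dup)([ACGT]*)$", body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    len <- if (nzchar(m[5])) nchar(m[5]) else end - start + 1L
    sign <- if (m[4] == "del") -1L else 1L
    return(list(kind = m[4], position = start, offset = 0L,
                ref = NA_character_, alt = NA_character_,
                length_change = sign * len))
  }
  m <- regmatches(body, regexec("^([0-9]+)_([0-9]+)ins([ACGT]+)$", body))[[1]]
  if (length(m)) {
    return(list(kind = "ins", position = as.integer(m[2]), offset = 0L,
                ref = NA_character_, alt = NA_character_,
                length_change = nchar(m[4])))
  }
  stop("unparseable HGVS coding change: ", x)
}

classify_consequence_one <- function(hgvs_c, hgvs_p = NA, location = NA) {
  p <- parse_hgvs_c(hgvs_c)
  prot <- if (is.null(hgvs_p) || is.na(hgvs_p)) "" else gsub("[[:space:]]+", "", hgvs_p)
  if (prot %in% c("?", "-", "p.?")) prot <- ""

  if (p$kind == "substitution" && p$offset != 0L) {
    if (abs(p$offset) <= 2L) return("splice")
    return("other")
  }
  if (grepl("fs", prot, ignore.case = TRUE)) return("frameshift")
  if (p$kind %in% c("del", "dup", "ins")) {
    if (p$length_change %% 3L != 0L) return("frameshift")
    return("other")
  }
  # exonic substitution from here on
  if (grepl("(X|Ter|\\*)$", prot)) return("nonsense")
  m <- regmatches(prot, regexec("^p\\.([A-Z][a-z]{2})[0-9]+([A-Z][a-z]{2})$", prot))[[1]]
  if (length(m)) {
    if (m[2] == m[3]) return("other")  # synonymous
    return("missense")
  }
  "other"
}

#' Classify the molecular consequence of a variant
#'
#' Deterministic classification from HGVS strings: `splice` for intronic
#' substitutions within +/-2 of an exon boundary (the canonical splice
#' dinucleotides); `frameshift` for protein changes containing `fs` or
#' length-changing del/dup/ins whose length is not a multiple of three;
#' `nonsense` for substitutions whose protein change ends in a stop
#' (X/Ter/*); `missense` for single-residue substitutions; `other`
#' otherwise. Unparseable coding changes raise an error naming the
#' offending token rather than guessing.
#'
#' @param hgvs_c Coding-DNA change(s).
#' @param hgvs_p Protein change(s); `"?"`, `"-"` or `NA` mean unknown.
#' @param location Optional exon/intron label (carried, not used).
#' @return Character vector over
#'   `{"missense", "nonsense", "frameshift", "splice", "other"}`.
#' @export
classify_consequence <- function(hgvs_c, hgvs_p = NA, location = NA) {
  n <- length(hgvs_c)
  hgvs_p <- rep_len(hgvs_p, n)
  location <- rep_len(location, n)
  vapply(seq_len(n), function(i)
    classify_consequence_one(hgvs_c[i], hgvs_p[i], location[i]),
    character(1))
}

#' Three-source rarity filter
#'
#' Passes iff every known source frequency is below the policy cutoff
#' (default < 1%); unknown frequencies pass.
#'
#' @param freq_1000g,freq_exome,freq_inhouse Numeric allele frequencies
#'   in `[0, 1]`, `NA` for unknown. Recycled to a common length.
#' @param policy A [rarity_policy()].
#' @return Logical vector, `TRUE` = pass.
#' @export
rarity_filter <- function(freq_1000g = NA, freq_exome = NA, freq_inhouse = NA,
                          policy = rarity_policy()) {
  n <- max(length(freq_1000g), length(freq_exome), length(freq_inhouse))
  f <- cbind(rep_len(as.numeric(freq_1000g), n),
             rep_len(as.numeric(freq_exome), n),
             rep_len(as.numeric(freq_inhouse), n))
  if (any(f < 0, na.rm = TRUE)) stop("allele frequencies must be non-negative")
  if (any(f > 1, na.rm = TRUE)) stop("allele frequencies must be <= 1")
  apply(f, 1, function(r) all(is.na(r) | r < policy$max_frequency))
}

#' In-house control frequency from carrier-allele counts
#'
#' @param carrier_alleles Count of alternate alleles observed in the
#'   control panel.
#' @param policy A [rarity_policy()] supplying the allele denominator.
#' @return Allele frequency.
#' @export
inhouse_frequency <- function(carrier_alleles, policy = rarity_policy()) {
  if (any(carrier_alleles < 0)) stop("carrier_alleles must be non-negative")
  carrier_alleles / policy$inhouse_alleles
}

#' Is a missense change damaging under the predictor policy?
#'
#' @param sift,polyphen Predictor scores in `[0, 1]`, `NA` if absent.
#' @param policy A [missense_policy()].
#' @return Logical vector; `NA` scores contribute `FALSE` to their
#'   predicate, so a variant with no scores is not damaging.
#' @export
is_damaging_missense <- function(sift, polyphen, policy = missense_policy()) {
  n <- max(length(sift), length(polyphen))
  sift <- rep_len(as.numeric(sift), n)
  polyphen <- rep_len(as.numeric(polyphen), n)
  s <- !is.na(sift) & sift <= policy$sift_damaging_max
  p <- !is.na(polyphen) & polyphen >= policy$polyphen_damaging_min
  s | p
}

#' Pathogenicity tier of a rare variant
#'
#' Truncating and canonical splice-site changes (nonsense, frameshift,
#' splice) are classified `pathogenic` outright; missense changes are
#' `probable_pathogenic` when the predictor policy calls them damaging
#' and `uncertain` otherwise; everything else is `uncertain`. A missense
#' change is never tiered `pathogenic`. Assumes the rarity filter has
#' already been applied.
#'
#' @param consequence Character vector of consequence classes.
#' @param sift,polyphen Predictor scores (used for missense only).
#' @param policy A [missense_policy()].
#' @return Character vector over
#'   `{"pathogenic", "probable_pathogenic", "uncertain"}`.
#' @export
tier_pathogenicity <- function(consequence, sift = NA, polyphen = NA,
                               policy = missense_policy()) {
  n <- length(consequence)
  damaging <- is_damaging_missense(rep_len(sift, n), rep_len(polyphen, n), policy)
  out <- rep("uncertain", n)
  out[consequence %in% c("nonsense", "frameshift", "splice")] <- "pathogenic"
  mis <- consequence == "missense"
  out[mis & damaging] <- "probable_pathogenic"
  out
}

#' Flag variants absent from the previously-reported catalog
#'
#' @param gene,hgvs_c Variant identity.
#' @param catalog Tibble of previously reported variants with columns
#'   `gene` and `hgvs_c`; an empty or `NULL` catalog makes everything
#'   novel.
#' @return Logical vector, `TRUE` = novel.
#' @export
mark_novel <- function(gene, hgvs_c, catalog = NULL) {
  keys <- variant_key(gene, hgvs_c)
  if (is.null(catalog) || nrow(catalog) == 0)
    return(rep(TRUE, length(keys)))
  !keys %in% variant_key(catalog$gene, catalog$hgvs_c)
}

#' Run the full annotation chain on a variant table
#'
#' Adds, in order: `consequence` (from HGVS), `rarity_pass` (three-source
#' frequency filter), `selected` (consequence is one of the classes the
#' screening algorithm retains: missense/nonsense/frameshift/splice),
#' `tier` (pathogenicity tier, `excluded` when the rarity filter fails),
#' `damaging_missense` (predictor call, rarity-independent — used for
#' modifier candidacy), and `novel` (absence from the catalog).
#'
#' @param variants Tibble with columns `gene`, `hgvs_c`; optional
#'   `hgvs_p`, `freq_1000g`, `freq_exome`, `freq_inhouse`, `sift`,
#'   `polyphen`.
#' @param rarity A [rarity_policy()].
#' @param missense A [missense_policy()].
#' @param catalog Previously-reported catalog for [mark_novel()].
#' @return The input with annotation columns appended.
#' @export
annotate_variants <- function(variants, rarity = rarity_policy(),
                              missense = missense_policy(), catalog = NULL) {
  v <- tibble::as_tibble(variants)
  n <- nrow(v)
  col <- function(name) if (name %in% names(v)) v[[name]] else rep(NA_real_, n)
  v$consequence <- classify_consequence(
    v$hgvs_c, if ("hgvs_p" %in% names(v)) v$hgvs_p else NA)
  v$rarity_pass <- rarity_filter(col("freq_1000g"), col("freq_exome"),
                                 col("freq_inhouse"), rarity)
  v$selected <- v$consequence %in% c("missense", "nonsense", "frameshift", "splice")
  tier <- tier_pathogenicity(v$consequence, col("sift"), col("polyphen"), missense)
  tier[!v$rarity_pass] <- "excluded"
  v$tier <- tier
  v$damaging_missense <- v$consequence == "missense" &
    is_damaging_missense(col("sift"), col("polyphen"), missense)
  v$novel <- mark_novel(v$gene, v$hgvs_c, catalog)
  v
}
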