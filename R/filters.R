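# variant_filters: the filtering ladder that turns raw consensus calls into
# the unique-mutation set used for every burden and spectrum statistic.
# Order: clonal collapse -> SNVs over clonal MNVs -> SNVs near indel
# boundaries -> intra-cohort contamination -> VAF gate. Contamination runs
# before the VAF gate so germline copies (VAF > 30%) are still visible when
# matching; each removed variant is attributed to exactly one (the first
# triggering) filter.

#' Filtering configuration
#'
#' @param vaf_max Inclusive VAF gate for mutation analysis (default 0.01;
#'   0.02 and 0.05 are explored alternatives).
#' @param clonal_mnv_vaf_min An MNV is "clonal" when its post-collapse VAF is
#'   at or above this (default 0.01); SNVs inside such spans are removed.
#' @param indel_exclusion_window_bp SNVs within this many bp (inclusive) of an
#'   indel boundary are removed (default 10).
#' @param contamination_low_vaf,contamination_germline_vaf A call is an
#'   intra-cohort contaminant when its VAF is strictly below
#'   `contamination_low_vaf` while the identical variant appears with VAF
#'   strictly above `contamination_germline_vaf` in at least one other sample.
#' @param shared_mutation_mode Alternative cross-tissue rule: additionally
#'   remove variants present in both tissues of the same individual (requires
#'   `tissue` and `individual` columns). Off by default.
#' @return A `filter_config` list.
#' @export
filter_config <- function(vaf_max = 0.01,
                          clonal_mnv_vaf_min = 0.01,
                          indel_exclusion_window_bp = 10L,
                          contamination_low_vaf = 0.01,
                          contamination_germline_vaf = 0.30,
                          shared_mutation_mode = FALSE) {
  stopifnot(vaf_max > 0, vaf_max <= 1, indel_exclusion_window_bp >= 0)
  structure(
    list(
      vaf_max = vaf_max,
      clonal_mnv_vaf_min = clonal_mnv_vaf_min,
      indel_exclusion_window_bp = as.integer(indel_exclusion_window_bp),
      contamination_low_vaf = contamination_low_vaf,
      contamination_germline_vaf = contamination_germline_vaf,
      shared_mutation_mode = isTRUE(shared_mutation_mode)
    ),
    class = "filter_config"
  )
}

#' Collapse clonally expanded calls into unique mutations
#'
#' Identical mutations (same sample, chrom, pos, ref, alt) appearing in more
#' than one molecule of the same sample are taken to derive from clonal
#' expansion and counted once, with `alt_count` summed over the merged rows.
#'
#' @param variants Variant tibble (may span samples; collapse is per sample).
#' @return Collapsed variant tibble; the fraction of unique mutations
#'   supported by a single molecule is available via [summarize_clonality()].
#' @export
collapse_clonal <- function(variants) {
  variants %>%
    group_by(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      across(dplyr::any_of(c("tissue", "vtype", "sv_len")), first),
      alt_count = sum(.data$alt_count),
      site_depth = first(.data$site_depth),
      .groups = "drop"
    ) %>%
    mutate(vaf = .data$alt_count / .data$site_depth) %>%
    arrange(.data$sample_id, .data$chrom, .data$pos)
}

#' Clonality summary of a unique-mutation set
#'
#' @param variants Collapsed variant tibble.
#' @return Tibble with single-count fractions for SNVs and non-SNVs.
#' @export
summarize_clonality <- function(variants) {
  variants %>%
    mutate(group = if_else(.data$vtype == "SNV", "SNV", "non-SNV")) %>%
    group_by(.data$group) %>%
    summarise(
      n_unique = n(),
      n_single_count = sum(.data$alt_count == 1L),
      single_count_fraction = mean(.data$alt_count == 1L),
      .groups = "drop"
    )
}

#' Gate calls by variant allele frequency
#'
#' Retains calls with `vaf <= vaf_max` (inclusive), the rare-mutation gate
#' that removes inherited polymorphisms and early-developmental mutations.
#'
#' @param variants Variant tibble.
#' @param vaf_max Inclusive upper VAF bound (default 0.01).
#' @return Retained rows.
#' @export
apply_vaf_gate <- function(variants, vaf_max = 0.01) {
  filter(variants, .data$vaf <= vaf_max)
}

#' Remove SNVs overlapping clonal MNV spans
#'
#' A no-call at one position of a clonal or germline MNV can surface as a
#' spurious partial SNV call. SNVs whose position falls within the reference
#' span `[pos, pos + nchar(ref) - 1]` of a same-sample MNV with VAF at or
#' above `clonal_mnv_vaf_min` are therefore removed.
#'
#' @param variants Variant tibble (SNVs and MNVs together).
#' @param clonal_mnv_vaf_min Clonality threshold on the MNV VAF (default 0.01).
#' @return `variants` without the offending SNVs.
#' @export
exclude_snv_over_clonal_mnv <- function(variants, clonal_mnv_vaf_min = 0.01) {
  spans <- variants %>%
    filter(.data$vtype == "MNV", .data$vaf >= clonal_mnv_vaf_min) %>%
    mutate(span_start = .data$pos, span_end = .data$pos + nchar(.data$ref) - 1L) %>%
    select("sample_id", "chrom", "span_start", "span_end")
  if (nrow(spans) == 0) return(variants)
  snvs <- filter(variants, .data$vtype == "SNV")
  hit <- snvs %>%
    inner_join(spans, by = c("sample_id", "chrom"),
               relationship = "many-to-many") %>%
    filter(.data$pos >= .data$span_start, .data$pos <= .data$span_end) %>%
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt)
  anti_join(variants, mutate(hit, vtype = "SNV"),
            by = c("sample_id", "chrom", "pos", "ref", "alt", "vtype"))
}

# reference-coordinate boundaries of an indel: {pos, pos + |net|} for
# deletions (and net-loss complex variants), {pos, pos + 1} for insertions
indel_boundaries <- function(variants) {
  ind <- variants %>%
    mutate(net = variant_net_length(.data$ref, .data$alt, .data$sv_len)) %>%
    filter(.data$vtype %in% c("insertion", "deletion", "complex"),
           !is.na(.data$net))
  if (nrow(ind) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  boundary = integer()))
  }
  ind %>%
    mutate(b2 = if_else(.data$net < 0, .data$pos + abs(.data$net), .data$pos + 1L)) %>%
    select("sample_id", "chrom", b1 = "pos", "b2") %>%
    tidyr::pivot_longer(c("b1", "b2"), values_to = "boundary") %>%
    distinct(.data$sample_id, .data$chrom, .data$boundary)
}

#' Remove SNVs near indel boundaries
#'
#' Clusters of SNV calls near indel boundaries are realignment artifacts;
#' any SNV whose position lies within `window_bp` (inclusive) of a
#' same-sample indel boundary is removed. Boundaries are the two reference
#' coordinates `{pos, pos + |net length|}` for deletions and `{pos, pos + 1}`
#' for insertions.
#'
#' @param variants Variant tibble.
#' @param window_bp Inclusive exclusion window in bp (default 10).
#' @return `variants` without the proximal SNVs.
#' @export
exclude_snv_near_indels <- function(variants, window_bp = 10L) {
  bounds <- indel_boundaries(variants)
  if (nrow(bounds) == 0) return(variants)
  snvs <- filter(variants, .data$vtype == "SNV")
  hit <- snvs %>%
    inner_join(bounds, by = c("sample_id", "chrom"),
               relationship = "many-to-many") %>%
    filter(abs(.data$pos - .data$boundary) <= window_bp) %>%
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt)
  anti_join(variants, mutate(hit, vtype = "SNV"),
            by = c("sample_id", "chrom", "pos", "ref", "alt", "vtype"))
}

#' Remove intra-cohort contamination
#'
#' A call is flagged as contamination when its VAF is strictly below
#' `low_vaf` in its own sample while the identical variant (chrom, pos, ref,
#' alt) appears at a likely germline frequency (VAF strictly above
#' `germline_vaf`) in at least one other sample. The germline copy itself is
#' untouched.
#'
#' @param variants Cohort-wide variant tibble (>= 2 samples).
#' @param low_vaf,germline_vaf Thresholds (defaults 0.01 and 0.30).
#' @return List with `retained` and `removed` tibbles.
#' @export
remove_intra_cohort_contamination <- function(variants, low_vaf = 0.01,
                                              germline_vaf = 0.30) {
  if (n_distinct(variants$sample_id) < 2) {
    warn("single-sample cohort: contamination filter is a no-op")
    return(list(retained = variants, removed = variants[0, ]))
  }
  germ_keys <- variants %>%
    filter(.data$vaf > germline_vaf) %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
             germ_sample = .data$sample_id)
  flagged <- variants %>%
    filter(.data$vaf < low_vaf) %>%
    inner_join(germ_keys, by = c("chrom", "pos", "ref", "alt"),
               relationship = "many-to-many") %>%
    filter(.data$germ_sample != .data$sample_id) %>%
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt)
  removed <- semi_join(variants, flagged,
                       by = c("sample_id", "chrom", "pos", "ref", "alt"))
  retained <- anti_join(variants, flagged,
                        by = c("sample_id", "chrom", "pos", "ref", "alt"))
  list(retained = retained, removed = removed)
}

#' Run the full filtering ladder
#'
#' Applies, in order: clonal collapse, SNV-over-clonal-MNV exclusion,
#' indel-proximal SNV exclusion, intra-cohort contamination removal, and the
#' VAF gate. Every input call is accounted for: collapsed into a retained
#' unique mutation or attributed to exactly one removal step. The VAF gate is
#' deliberately last so that germline-frequency copies are still present for
#' contamination matching; the eccDNA analysis consumes the pre-gate set
#' (`pre_vaf_gate`), since no VAF filter applies to large insertions there.
#'
#' @param variants Raw cohort variant tibble.
#' @param config A [filter_config()].
#' @return A `filter_result` list: `variants` (retained unique mutations),
#'   `pre_vaf_gate` (unique mutations before the VAF gate), `report`
#'   (per-step removal counts), `clonality`, and `removed` (per-step rows).
#'   [tidy()] returns the retained tibble, [glance()] the report as one row.
#' @export
run_filter_ladder <- function(variants, config = filter_config()) {
  n_input <- nrow(variants)
  collapsed <- collapse_clonal(variants)

  after_mnv <- exclude_snv_over_clonal_mnv(collapsed, config$clonal_mnv_vaf_min)
  removed_mnv <- anti_join(
    collapsed, after_mnv,
    by = c("sample_id", "chrom", "pos", "ref", "alt")
  )
  after_indel <- exclude_snv_near_indels(after_mnv,
                                         config$indel_exclusion_window_bp)
  removed_indel <- anti_join(
    after_mnv, after_indel,
    by = c("sample_id", "chrom", "pos", "ref", "alt")
  )
  cont <- remove_intra_cohort_contamination(
    after_indel, config$contamination_low_vaf, config$contamination_germline_vaf
  )
  pre_gate <- cont$retained
  retained <- apply_vaf_gate(pre_gate, config$vaf_max)
  removed_gate <- anti_join(
    pre_gate, retained,
    by = c("sample_id", "chrom", "pos", "ref", "alt")
  )
  if (config$shared_mutation_mode) {
    if (!all(c("tissue", "individual") %in% names(retained))) {
      warn("shared_mutation_mode needs 'tissue' and 'individual' columns; skipped")
    } else {
      shared <- retained %>%
        distinct(.data$individual, .data$tissue, .data$chrom, .data$pos,
                 .data$ref, .data$alt) %>%
        count(.data$individual, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
        filter(.data$n > 1)
      retained <- anti_join(
        retained, shared,
        by = c("individual", "chrom", "pos", "ref", "alt")
      )
    }
  }

  # clonality describes the retained rare-mutation set: artifact and
  # contaminant calls would otherwise dilute the single-count fractions
  clonality <- summarize_clonality(retained)

  report <- tibble(
    n_input_calls = n_input,
    n_unique_after_collapse = nrow(collapsed),
    removed_clonal_collapse = n_input - nrow(collapsed),
    removed_snv_over_clonal_mnv = nrow(removed_mnv),
    removed_snv_near_indel = nrow(removed_indel),
    removed_contamination = nrow(cont$removed),
    removed_vaf_gate = nrow(removed_gate),
    n_retained = nrow(retained)
  )
  per_sample <- retained %>%
    mutate(class = variant_class(
      .data$vtype, variant_net_length(.data$ref, .data$alt, .data$sv_len)
    )) %>%
    count(.data$sample_id, .data$class, name = "n_unique")

  structure(
    list(
      variants = retained,
      pre_vaf_gate = pre_gate,
      report = report,
      per_sample = per_sample,
      clonality = clonality,
      removed = list(
        snv_over_clonal_mnv = removed_mnv,
        snv_near_indel = removed_indel,
        contamination = cont$removed,
        vaf_gate = removed_gate
      ),
      config = config
    ),
    class = "filter_result"
  )
}

#' @exportS3Method generics::tidy
tidy.filter_result <- function(x, ...) x$variants

#' @exportS3Method generics::glance
glance.filter_result <- function(x, ...) x$report

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result>\n")
  cat("  input calls:          ", x$report$n_input_calls, "\n")
  cat("  unique after collapse:", x$report$n_unique_after_collapse, "\n")
  cat("  removed (SNV over clonal MNV):", x$report$removed_snv_over_clonal_mnv, "\n")
  cat("  removed (SNV near indel):     ", x$report$removed_snv_near_indel, "\n")
  cat("  removed (contamination):      ", x$report$removed_contamination, "\n")
  cat("  removed (VAF gate):           ", x$report$removed_vaf_gate, "\n")
  cat("  retained unique mutations:    ", x$report$n_retained, "\n")
  invisible(x)
}
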