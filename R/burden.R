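# burden: mutation-frequency arithmetic. The per-sample MF of a variant class
# is the number of unique (post-ladder) mutations of that class divided by
# the sample's total duplex bases; substitution subtypes are normalized by
# the duplex depth at reference C/G or T/A positions; C>T calls are further
# split by CpG (NCG trinucleotide) context.

#' Mutation frequency per duplex base
#'
#' @param unique_count Number of unique mutations.
#' @param duplex_bases Total informative duplex bases (> 0).
#' @return Rate per bp (double).
#' @export
mutation_frequency <- function(unique_count, duplex_bases) {
  if (any(duplex_bases <= 0)) abort("duplex_bases must be > 0")
  unique_count / duplex_bases
}

#' Format a rate at two significant figures in scientific notation
#'
#' Display convention for mutation frequencies, e.g. `7.6E-09`; zero renders
#' as `"0"`.
#'
#' @param x Numeric vector of rates.
#' @return Character vector.
#' @export
format_mf <- function(x) {
  out <- toupper(formatC(signif(x, 2), format = "e", digits = 1))
  out[x == 0] <- "0"
  out
}

#' Per-sample mutation burden by variant class
#'
#' Counts unique mutations in the four broad classes (SNV, MNV, indel, SV —
#' indels are net length changes of at most 1000 bp, SVs are larger changes
#' plus all inversions) and divides by each sample's duplex bases. Pooled
#' rows (`sample_id == "total"`) divide summed counts by summed bases; the
#' mean of per-sample MFs generally differs from the pooled MF, so both are
#' reported (see [burden_summary()]).
#'
#' @param variants Unique-mutation tibble (post filter ladder).
#' @param totals Per-sample duplex totals, from [depth_totals()] or a tibble
#'   with `sample_id` and `total_duplex_bases` columns.
#' @return Tibble with one row per sample x class plus pooled `total` rows:
#'   `sample_id`, `class`, `n`, `duplex_bases`, `mf`, `mf_display`.
#' @export
compute_burden <- function(variants, totals) {
  classes <- c("SNV", "MNV", "indel", "SV")
  counts <- variants %>%
    mutate(class = variant_class(
      .data$vtype, variant_net_length(.data$ref, .data$alt, .data$sv_len)
    )) %>%
    count(.data$sample_id, .data$class)
  grid <- tidyr::expand_grid(
    sample_id = totals$sample_id,
    class = factor(classes, levels = classes)
  ) %>%
    mutate(class = as.character(.data$class))
  per_sample <- grid %>%
    left_join(counts, by = c("sample_id", "class")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L)) %>%
    left_join(select(totals, "sample_id", duplex_bases = "total_duplex_bases"),
              by = "sample_id")
  pooled <- per_sample %>%
    group_by(.data$class) %>%
    summarise(n = sum(.data$n), duplex_bases = sum(.data$duplex_bases),
              .groups = "drop") %>%
    mutate(sample_id = "total")
  bind_rows(per_sample, pooled) %>%
    mutate(
      mf = mutation_frequency(.data$n, .data$duplex_bases),
      mf_display = format_mf(.data$mf),
      class = factor(.data$class, levels = classes)
    ) %>%
    arrange(.data$sample_id != "total", .data$sample_id, .data$class) %>%
    mutate(class = as.character(.data$class))
}

#' Pooled and mean-of-samples burden summaries per class
#'
#' @param burden Output of [compute_burden()].
#' @return Tibble per class with pooled MF, mean and SD of per-sample MFs.
#' @export
burden_summary <- function(burden) {
  per_sample <- filter(burden, .data$sample_id != "total")
  pooled <- filter(burden, .data$sample_id == "total") %>%
    select("class", pooled_mf = "mf", n_total = "n")
  per_sample %>%
    group_by(.data$class) %>%
    summarise(mean_mf = mean(.data$mf), sd_mf = sd(.data$mf), .groups = "drop") %>%
    left_join(pooled, by = "class")
}

#' Pyrimidine-collapsed substitution class of SNVs
#'
#' Substitutions at purine reference bases (G, A) are complemented so that
#' every SNV falls in one of the six classes of [sbs6_classes()].
#'
#' @param ref,alt Single-base reference and alternate alleles.
#' @return Character vector of classes.
#' @export
pyrimidine_class <- function(ref, alt) {
  flip <- ref %in% c("G", "A")
  r <- if_else(flip, unname(DNA_COMPLEMENT[ref]), ref)
  a <- if_else(flip, unname(DNA_COMPLEMENT[alt]), alt)
  paste0(r, ">", a)
}

#' Depth-normalized substitution subtype rates
#'
#' Counts unique SNVs in each pyrimidine-collapsed class and divides C-class
#' counts (C>A, C>G, C>T) by the duplex depth at reference C/G positions and
#' T-class counts by the depth at T/A positions.
#'
#' @param snvs Unique SNV tibble.
#' @param totals Per-sample depth totals from [depth_totals()]. Pool samples
#'   beforehand (sum the columns) for cohort-level rates.
#' @return Tibble per sample x class: `n`, `denominator`, `rate`.
#' @export
subtype_rates <- function(snvs, totals) {
  stopifnot(all(c("depth_at_CG", "depth_at_TA") %in% names(totals)))
  counts <- snvs %>%
    filter(.data$vtype == "SNV") %>%
    mutate(class = pyrimidine_class(.data$ref, .data$alt)) %>%
    count(.data$sample_id, .data$class)
  grid <- tidyr::expand_grid(sample_id = totals$sample_id,
                             class = sbs6_classes())
  out <- grid %>%
    left_join(counts, by = c("sample_id", "class")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L)) %>%
    left_join(select(totals, "sample_id", "depth_at_CG", "depth_at_TA"),
              by = "sample_id") %>%
    mutate(
      denominator = if_else(startsWith(.data$class, "C"),
                            .data$depth_at_CG, .data$depth_at_TA),
      rate = .data$n / .data$denominator
    ) %>%
    select("sample_id", "class", "n", "denominator", "rate")
  if (any(out$denominator == 0 & out$n > 0)) {
    abort("nonzero subtype count with zero depth at the relevant reference base")
  }
  out
}

#' Fraction of C>T mutations at CpG sites
#'
#' A C>T (pyrimidine-collapsed) mutation is at a CpG when its reference
#' context is C followed by G — equivalently, an NCG trinucleotide — or the
#' reverse complement for G>A calls. Calls whose context falls off the panel
#' edge are skipped with a warning.
#'
#' @param snvs Unique SNV tibble.
#' @param panel Panel tibble.
#' @return One-row tibble: `n_ct`, `n_ct_cpg`, `cpg_fraction` (`NA` when
#'   there are no C>T calls).
#' @export
cpg_fraction <- function(snvs, panel) {
  pp <- select(panel_positions(panel), "contig", "pos", "is_cpg", "prev", "nxt")
  ct <- snvs %>%
    filter(.data$vtype == "SNV") %>%
    mutate(class = pyrimidine_class(.data$ref, .data$alt)) %>%
    filter(.data$class == "C>T") %>%
    left_join(pp, by = c(chrom = "contig", pos = "pos"))
  edge <- is.na(ct$prev) | is.na(ct$nxt)
  if (any(edge)) {
    warn(paste0(sum(edge), " C>T call(s) at panel edges skipped (no context)"))
    ct <- ct[!edge, ]
  }
  tibble(
    n_ct = nrow(ct),
    n_ct_cpg = sum(ct$is_cpg),
    cpg_fraction = if (nrow(ct) == 0) NA_real_ else mean(ct$is_cpg)
  )
}

#' Locus-specific mutation frequencies and their fold-range
#'
#' Rates are per-locus unique-mutation counts over per-locus duplex bases
#' (strictly in-locus positions), pooled across samples. The fold-range is
#' max/min over loci with a nonzero rate; zero-count and zero-depth loci are
#' excluded from the fold-range and flagged.
#'
#' @param variants Unique-mutation tibble (typically SNVs only).
#' @param depth Depth tibble.
#' @param panel Panel tibble.
#' @return List with `per_locus` tibble (`locus_id`, `n`, `locus_bases`,
#'   `mf`, `in_fold_range`) and scalar `fold_range`.
#' @export
per_locus_mf <- function(variants, depth, panel) {
  pp <- select(panel_positions(panel), "contig", "pos", "locus_id")
  counts <- variants %>%
    inner_join(pp, by = c(chrom = "contig", pos = "pos")) %>%
    count(.data$locus_id)
  bases <- depth_by_locus(depth, panel) %>%
    group_by(.data$locus_id) %>%
    summarise(locus_bases = sum(.data$locus_bases), .groups = "drop")
  per_locus <- bases %>%
    left_join(counts, by = "locus_id") %>%
    mutate(
      n = tidyr::replace_na(.data$n, 0L),
      mf = if_else(.data$locus_bases > 0, .data$n / .data$locus_bases, NA_real_),
      in_fold_range = .data$n > 0 & .data$locus_bases > 0
    )
  usable <- filter(per_locus, .data$in_fold_range)
  fold <- if (nrow(usable) == 0) NA_real_ else max(usable$mf) / min(usable$mf)
  list(per_locus = per_locus, fold_range = fold)
}

#' Pearson correlation between paired mutation frequencies
#'
#' Standard product-moment correlation with a two-sided t-test, for e.g.
#' per-individual sperm vs blood MFs or per-locus rates across tissues.
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @return One-row tibble: `estimate`, `p_value`, `n` (`NA` estimate when
#'   either vector has zero variance).
#' @export
cross_tissue_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(estimate = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
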