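# eccdna_caller: D-A junction detection among apparent large insertions,
# physical fragment-length inference from consensus read-pair geometry,
# circle vs tandem-duplication discrimination, the binomial subset test, and
# candidate microDNA calling. A D-A junction joins the end (D) to the
# beginning (A) of a reference allele ABCD and arises from either excision
# and circularization of the allele or a chromosomal tandem duplication; the
# two are separated by fragment-length geometry (circle fragments can never
# exceed the allele length, TD fragments follow the library insert-size
# distribution and may contain duplicated/flanking sequence).

safe_max <- function(x) if (length(x) == 0) NA_integer_ else max(x)

insertion_allele <- function(ref, alt) {
  # anchor-base convention: alt = anchor + inserted sequence
  substring(alt, nchar(ref) + 1L)
}

#' Detect D-A junctions among apparent insertions
#'
#' For each insertion call with an inserted allele of at least 20 bp, the
#' inserted sequence is searched against the call's own contig allowing
#' `floor(allele_length * mismatch_per_bp)` mismatches (1 per 50 bp by
#' default, floor taken as the stricter reading). The call supports a D-A
#' junction when a match starts exactly 1 bp downstream of the variant
#' position, i.e. at `pos + 1` under the anchor-base convention — the unique
#' placement making the inserted allele a copy of the downstream reference.
#'
#' @param variants Variant tibble (non-insertions and inserted alleles
#'   shorter than 20 bp pass through with `has_da_junction = NA`).
#' @param panel Panel tibble supplying contig sequences.
#' @param mismatch_per_bp Allowed mismatch density (default 1/50).
#' @return `variants` with `allele_length`, `has_da_junction`,
#'   `match_position` columns added.
#' @export
detect_da_junction <- function(variants, panel, mismatch_per_bp = 1 / 50) {
  contig_seq <- panel %>%
    group_by(.data$contig) %>%
    summarise(seq = first(.data$sequence), offset = first(.data$start),
              .groups = "drop")
  seqs <- setNames(
    as.list(Biostrings::DNAStringSet(contig_seq$seq)), contig_seq$contig
  )
  offsets <- setNames(contig_seq$offset, contig_seq$contig)
  x <- variants %>%
    mutate(
      allele_length = if_else(
        .data$vtype %in% c("insertion", "complex") & !grepl("^<", .data$alt),
        nchar(insertion_allele(.data$ref, .data$alt)),
        NA_integer_
      ),
      has_da_junction = NA,
      match_position = NA_integer_
    )
  todo <- which(!is.na(x$allele_length) & x$allele_length >= 20 &
                  x$chrom %in% names(seqs))
  for (i in todo) {
    ins <- insertion_allele(x$ref[i], x$alt[i])
    L <- nchar(ins)
    subject <- seqs[[x$chrom[i]]]
    max_mm <- floor(L * mismatch_per_bp)
    m <- Biostrings::matchPattern(ins, subject, max.mismatch = max_mm)
    starts <- BiocGenerics::start(m) + offsets[x$chrom[i]]
    x$has_da_junction[i] <- (x$pos[i] + 1L) %in% starts
    x$match_position[i] <- if (x$has_da_junction[i]) {
      x$pos[i] + 1L
    } else if (length(starts) > 0) {
      starts[1]
    } else {
      NA_integer_
    }
  }
  x
}

#' Infer physical fragment lengths from read-pair geometry
#'
#' Concordant pairs: the computed insert size plus any 5' soft-clipped bases.
#' Discordant split pairs: a pseudo-pair is formed from the primary alignment
#' of one read and the supplementary alignment of the other; the fragment
#' length is the difference between the right-most end of the reverse-aligned
#' member and the left-most start of the forward-aligned member (inclusive),
#' plus both members' 5' soft-clips, which align at the other end of the
#' allele and so extend the physical fragment. 3' soft-clips are adapter
#' read-through (present only on fragments shorter than ~142 bp) and are
#' ignored. Discordant rows without any supplementary alignment are
#' ambiguous: their fragment length is `NA` and they are reported.
#'
#' @param geometry Geometry tibble (see [read_alignment_geometry()]).
#' @return `geometry` with a `fragment_length` column.
#' @export
infer_fragment_length <- function(geometry) {
  g <- geometry
  n <- nrow(g)
  frag <- rep(NA_integer_, n)
  conc <- g$geometry == "concordant"
  frag[conc] <- g$insert_size[conc] +
    tidyr::replace_na(g$r1_clip5[conc], 0L) +
    tidyr::replace_na(g$r2_clip5[conc], 0L)
  disc <- which(!conc)
  for (i in disc) {
    if (!is.na(g$r2_sup_start[i])) {
      m1 <- list(start = g$r1_start[i], end = g$r1_end[i],
                 strand = g$r1_strand[i], clip5 = g$r1_clip5[i])
      m2 <- list(start = g$r2_sup_start[i], end = g$r2_sup_end[i],
                 strand = g$r2_sup_strand[i], clip5 = g$r2_sup_clip5[i])
    } else if (!is.na(g$r1_sup_start[i])) {
      m1 <- list(start = g$r2_start[i], end = g$r2_end[i],
                 strand = g$r2_strand[i], clip5 = g$r2_clip5[i])
      m2 <- list(start = g$r1_sup_start[i], end = g$r1_sup_end[i],
                 strand = g$r1_sup_strand[i], clip5 = g$r1_sup_clip5[i])
    } else {
      next # no supplementary: ambiguous, skipped
    }
    fwd <- if (m1$strand == "fwd") m1 else m2
    rev <- if (m1$strand == "rev") m1 else m2
    if (fwd$strand != "fwd" || rev$strand != "rev") next
    frag[i] <- (rev$end - fwd$start + 1L) +
      tidyr::replace_na(fwd$clip5, 0L) + tidyr::replace_na(rev$clip5, 0L)
  }
  n_skip <- sum(!conc & is.na(frag))
  if (n_skip > 0) {
    inform(paste0(n_skip, " discordant pair(s) without usable supplementary ",
                  "alignment: fragment length ambiguous, skipped"))
  }
  mutate(g, fragment_length = frag)
}

#' Classify junction calls as circle-consistent or tandem duplication
#'
#' A junction call is a tandem duplication as soon as one supporting fragment
#' contains duplicated or flanking sequence (fragment longer than the
#' allele); it is circle-consistent when all fragments are no longer than the
#' allele (a circle can only be cut into pieces of itself); junction-positive
#' calls without any usable fragment are ambiguous.
#'
#' @param junctions Junction tibble (insertion calls with `allele_length`,
#'   `has_da_junction`), keyed by `sample_id`, `chrom`, `pos`.
#' @param fragments Geometry tibble with `fragment_length` (from
#'   [infer_fragment_length()]).
#' @return `junctions` with `n_fragments`, `max_fragment`,
#'   `any_duplicated_flanking` and `classification` columns.
#' @export
classify_circle_vs_td <- function(junctions, fragments) {
  frag_sum <- fragments %>%
    filter(!is.na(.data$fragment_length)) %>%
    group_by(.data$sample_id, .data$chrom, .data$pos) %>%
    summarise(
      n_fragments = n(),
      max_fragment = safe_max(.data$fragment_length),
      .groups = "drop"
    )
  junctions %>%
    left_join(frag_sum, by = c("sample_id", "chrom", "pos")) %>%
    mutate(
      n_fragments = tidyr::replace_na(.data$n_fragments, 0L),
      any_duplicated_flanking = .data$n_fragments > 0 &
        .data$max_fragment > .data$allele_length,
      classification = case_when(
        !.data$has_da_junction ~ NA_character_,
        .data$n_fragments == 0 ~ "ambiguous",
        .data$any_duplicated_flanking ~ "tandem_duplication",
        TRUE ~ "circle_consistent"
      )
    )
}

#' One-sided binomial test on the below-median fragment subset
#'
#' Under the null that all D-A junctions arise from chromosomal tandem
#' duplications, fragment lengths mirror the library insert-size
#' distribution, so about half the fragments supporting alleles at or below
#' the median insert size should be shorter than that median. The test
#' reports the exact one-sided upper tail `P(X >= k | n, 1/2)` for `k`
#' fragments below the median out of `n`.
#'
#' @param fragment_lengths Fragment lengths (bp) for the subset of junction
#'   calls with allele length at or below the median insert size.
#' @param median_insert Median library insert size (bp).
#' @return One-row tibble: `k_below`, `n`, `p_value` (`NA` on empty input).
#' @export
binomial_subset_test <- function(fragment_lengths, median_insert) {
  fl <- fragment_lengths[!is.na(fragment_lengths)]
  n <- length(fl)
  if (n == 0) {
    return(tibble(k_below = NA_integer_, n = 0L, p_value = NA_real_))
  }
  k <- sum(fl < median_insert)
  tibble(
    k_below = k, n = n,
    p_value = pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  )
}

#' Call candidate microDNAs
#'
#' Candidates are junction-positive events with allele length strictly
#' greater than 125 bp; no VAF filter applies to the analysis of large
#' insertions, but a gated count is reported alongside when `vaf_max` is
#' supplied (for consistency with the mutation-frequency tables).
#'
#' @param junctions Classified junction tibble.
#' @param totals Per-sample duplex totals (for candidate frequencies).
#' @param min_allele Strict lower bound on candidate allele length
#'   (default 125).
#' @param vaf_max Optional VAF gate for the secondary count.
#' @return List with `candidates` tibble and `per_sample` frequency tibble.
#' @export
call_candidate_microdnas <- function(junctions, totals, min_allele = 125L,
                                     vaf_max = NULL) {
  candidates <- junctions %>%
    filter(.data$has_da_junction %in% TRUE,
           .data$allele_length > min_allele)
  per_sample <- totals %>%
    select("sample_id", duplex_bases = "total_duplex_bases") %>%
    left_join(count(candidates, .data$sample_id, name = "n_candidates"),
              by = "sample_id") %>%
    mutate(
      n_candidates = tidyr::replace_na(.data$n_candidates, 0L),
      frequency = .data$n_candidates / .data$duplex_bases
    )
  if (!is.null(vaf_max)) {
    gated <- filter(candidates, .data$vaf <= vaf_max)
    per_sample <- per_sample %>%
      left_join(count(gated, .data$sample_id, name = "n_candidates_vaf_gated"),
                by = "sample_id") %>%
      mutate(
        n_candidates_vaf_gated =
          tidyr::replace_na(.data$n_candidates_vaf_gated, 0L),
        frequency_vaf_gated = .data$n_candidates_vaf_gated / .data$duplex_bases
      )
  }
  list(candidates = candidates, per_sample = per_sample)
}

#' Full putative-circle analysis of a cohort
#'
#' Runs, over the pre-VAF-gate unique mutation set: D-A junction detection on
#' apparent insertions (>= 20 bp), fragment-length inference, circle vs
#' tandem-duplication classification, the below-median binomial subset test,
#' and candidate microDNA calling with per-sample frequencies.
#'
#' @param variants Unique-mutation tibble (no VAF gate applied).
#' @param geometry Alignment-geometry tibble for junction-supporting pairs.
#' @param panel Panel tibble.
#' @param totals Per-sample duplex totals.
#' @param median_insert Median library insert size in bp; `NULL` computes it
#'   from `library_inserts` when supplied, else defaults to 233.
#' @param library_inserts Optional vector of whole-library insert sizes from
#'   which the median is taken (junction-supporting pairs alone are a biased
#'   sample of the library, so they are never used for this).
#' @param min_allele Candidate allele-length cutoff (strict, default 125).
#' @param vaf_max Optional VAF gate for the secondary candidate count.
#' @return A `circle_analysis` object; [tidy()] returns the classified
#'   junction table, [glance()] a one-row summary.
#' @export
analyze_circles <- function(variants, geometry, panel, totals,
                            median_insert = NULL, library_inserts = NULL,
                            min_allele = 125L, vaf_max = NULL) {
  if (is.null(median_insert)) {
    median_insert <- if (!is.null(library_inserts)) {
      as.integer(median(library_inserts))
    } else {
      233L
    }
  }
  detected <- detect_da_junction(variants, panel)
  insertions <- detected %>%
    filter(!is.na(.data$allele_length), .data$allele_length > 20)
  fragments <- infer_fragment_length(geometry)
  classified <- classify_circle_vs_td(insertions, fragments)

  subset_calls <- classified %>%
    filter(.data$has_da_junction %in% TRUE,
           .data$allele_length <= median_insert)
  # one representative (the longest, i.e. most TD-informative) fragment per
  # event: the test counts events, not read pairs
  subset_frags <- fragments %>%
    semi_join(subset_calls, by = c("sample_id", "chrom", "pos")) %>%
    filter(!is.na(.data$fragment_length)) %>%
    group_by(.data$sample_id, .data$chrom, .data$pos) %>%
    summarise(fragment_length = safe_max(.data$fragment_length), .groups = "drop")
  binom <- binomial_subset_test(subset_frags$fragment_length, median_insert)
  micro <- call_candidate_microdnas(classified, totals, min_allele, vaf_max)

  structure(
    list(
      junctions = classified,
      fragments = fragments,
      n_insertions_gt20 = nrow(insertions),
      n_with_junction = sum(insertions$has_da_junction, na.rm = TRUE),
      median_insert = median_insert,
      subset = subset_calls,
      binomial = binom,
      candidates = micro$candidates,
      per_sample = micro$per_sample
    ),
    class = "circle_analysis"
  )
}

#' @exportS3Method generics::tidy
tidy.circle_analysis <- function(x, ...) x$junctions

#' @exportS3Method generics::glance
glance.circle_analysis <- function(x, ...) {
  tibble(
    n_insertions_gt20 = x$n_insertions_gt20,
    n_with_junction = x$n_with_junction,
    junction_fraction = ifelse(x$n_insertions_gt20 > 0,
                               x$n_with_junction / x$n_insertions_gt20, NA_real_),
    median_insert = x$median_insert,
    k_below = x$binomial$k_below,
    n_subset_fragments = x$binomial$n,
    binomial_p = x$binomial$p_value,
    n_candidates = nrow(x$candidates),
    mean_candidates_per_sample = mean(x$per_sample$n_candidates),
    mean_candidate_frequency = mean(x$per_sample$frequency)
  )
}

#' @export
print.circle_analysis <- function(x, ...) {
  g <- glance(x)
  cat("<circle_analysis>\n")
  cat(sprintf("  insertions > 20 bp: %d (%.0f%% with D-A junction)\n",
              g$n_insertions_gt20, 100 * g$junction_fraction))
  cat(sprintf("  below-median subset: %s of %s fragments below %d bp (binomial p = %.3g)\n",
              g$k_below, g$n_subset_fragments, g$median_insert, g$binomial_p))
  cat(sprintf("  candidate microDNAs: %d (mean %.1f per sample, mean frequency %.2g)\n",
              g$n_candidates, g$mean_candidates_per_sample,
              g$mean_candidate_frequency))
  invisible(x)
}

#' Plot the allele-length distribution of junction calls
#'
#' Histogram of insertion allele lengths coloured by D-A junction status,
#' with the median insert size marked.
#'
#' @param object A `circle_analysis`.
#' @param binwidth Histogram bin width in bp.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.circle_analysis <- function(object, binwidth = 20, ...) {
  df <- object$junctions
  ggplot2::ggplot(df, ggplot2::aes(.data$allele_length,
                                   fill = .data$has_da_junction)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$median_insert, linetype = 2) +
    ggplot2::labs(x = "allele length (bp)", y = "insertion calls",
                  fill = "D-A junction") +
    ggplot2::theme_minimal()
}
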