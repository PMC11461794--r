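# spectra_stats: 6- and 96-class substitution spectra, the likelihood-ratio
# (G) test for comparing mutant spectra between groups, cosine similarity to
# reference signatures, and the indel/MNV/SV size-and-type tabulation.

#' Build a pyrimidine-collapsed substitution spectrum
#'
#' For `sbs96`, the flanking bases on either side of the mutated base are
#' taken from the panel sequence; substitutions at purine reference bases are
#' reverse-complemented into pyrimidine classes with complemented context
#' (e.g. G>A with 5' T and 3' A becomes T[C>T]A). Calls without full context
#' (at a locus edge) are skipped with a warning.
#'
#' @param snvs Unique SNV tibble.
#' @param panel Panel tibble (needed for `sbs96`).
#' @param kind `"sbs6"` or `"sbs96"`.
#' @return An `sbs_spectrum` tibble: `context`, `count`, `proportion`, with
#'   the kind stored as an attribute.
#' @export
build_sbs_spectrum <- function(snvs, panel = NULL, kind = c("sbs6", "sbs96")) {
  kind <- match.arg(kind)
  snvs <- filter(snvs, .data$vtype == "SNV")
  if (kind == "sbs6") {
    counts <- snvs %>%
      mutate(context = pyrimidine_class(.data$ref, .data$alt)) %>%
      count(.data$context)
    levels <- sbs6_classes()
  } else {
    if (is.null(panel)) abort("sbs96 spectra need the panel for flanking context")
    pp <- select(panel_positions(panel), "contig", "pos", "prev", "nxt")
    ctx <- snvs %>%
      left_join(pp, by = c(chrom = "contig", pos = "pos"))
    edge <- is.na(ctx$prev) | is.na(ctx$nxt)
    if (any(edge)) {
      warn(paste0(sum(edge), " SNV(s) without full trinucleotide context skipped"))
      ctx <- ctx[!edge, ]
    }
    flip <- ctx$ref %in% c("G", "A")
    p5 <- if_else(flip, unname(DNA_COMPLEMENT[ctx$nxt]), ctx$prev)
    p3 <- if_else(flip, unname(DNA_COMPLEMENT[ctx$prev]), ctx$nxt)
    cls <- pyrimidine_class(ctx$ref, ctx$alt)
    counts <- count(tibble(context = paste0(p5, "[", cls, "]", p3)), .data$context)
    levels <- sbs96_contexts()
  }
  out <- tibble(context = levels) %>%
    left_join(counts, by = "context") %>%
    mutate(
      count = tidyr::replace_na(.data$n, 0L),
      proportion = if (sum(.data$count) > 0) .data$count / sum(.data$count) else 0
    ) %>%
    select("context", "count", "proportion")
  structure(out, kind = kind, class = c("sbs_spectrum", class(out)))
}

spectrum_counts <- function(x) {
  if (inherits(x, "sbs_spectrum") ||
      (is.data.frame(x) && all(c("context", "count") %in% names(x)))) {
    setNames(x$count, x$context)
  } else if (is.numeric(x)) {
    x
  } else {
    abort("expected an sbs_spectrum, a context/count data frame, or a numeric vector")
  }
}

#' Likelihood-ratio test for homogeneity of two mutant spectra
#'
#' The likelihood-ratio statistic for comparing multinomial mutant spectra:
#' observed class counts of the two groups are stacked into a 2 x k table and
#' `G = 2 * sum(O * log(O / E))` computed with expectations from the row and
#' column margins (zero cells contribute nothing). Under homogeneity G is
#' asymptotically chi-square with k - 1 degrees of freedom; because several
#' germline comparisons involve small counts, a Monte Carlo p-value
#' (multinomial resampling under the pooled proportions) is also available.
#'
#' @param a,b Count vectors over the same category space (spectra from
#'   [build_sbs_spectrum()], context/count data frames, or numeric vectors).
#' @param monte_carlo If `TRUE`, add a resampling p-value.
#' @param n_rep Monte Carlo replicates (default 10000).
#' @return An `lr_spectrum_test` object; [tidy()]/[glance()] return one-row
#'   tibbles with `statistic`, `df`, `p_value` (and `p_monte_carlo`).
#' @export
lr_spectrum_test <- function(a, b, monte_carlo = FALSE, n_rep = 10000L) {
  ca <- spectrum_counts(a)
  cb <- spectrum_counts(b)
  if (length(ca) != length(cb)) abort("spectra have different category spaces")
  if (sum(ca) == 0 || sum(cb) == 0) abort("both spectra need a positive total")
  O <- rbind(as.numeric(ca), as.numeric(cb))
  G <- g_statistic(O)
  df <- ncol(O) - 1L
  p <- pchisq(G, df = df, lower.tail = FALSE)
  p_mc <- NA_real_
  if (monte_carlo) {
    pooled <- colSums(O) / sum(O)
    na <- sum(O[1, ]); nb <- sum(O[2, ])
    sim_a <- rmultinom(n_rep, na, pooled)
    sim_b <- rmultinom(n_rep, nb, pooled)
    g_sim <- g_statistic_batch(sim_a, sim_b)
    p_mc <- (1 + sum(g_sim >= G)) / (n_rep + 1)
  }
  structure(
    list(statistic = G, df = df, p_value = p, p_monte_carlo = p_mc,
         observed = O),
    class = "lr_spectrum_test"
  )
}

g_statistic <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  terms <- O * log(O / E)
  2 * sum(terms[O > 0])
}

# vectorized G over paired columns of two k x B count matrices
g_statistic_batch <- function(A, B) {
  na <- colSums(A); nb <- colSums(B)
  tot <- A + B
  n <- na + nb
  g <- numeric(ncol(A))
  for (row in list(list(A, na), list(B, nb))) {
    O <- row[[1]]
    E <- sweep(tot, 2, row[[2]] / n, "*")
    term <- O * log(O / E)
    term[O == 0] <- 0
    g <- g + colSums(term)
  }
  2 * g
}

#' @exportS3Method generics::tidy
tidy.lr_spectrum_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         p_monte_carlo = x$p_monte_carlo)
}

#' @exportS3Method generics::glance
glance.lr_spectrum_test <- function(x, ...) tidy(x)

#' @export
print.lr_spectrum_test <- function(x, ...) {
  cat("Likelihood-ratio spectrum homogeneity test\n")
  cat(sprintf("  G = %.4g, df = %d, p = %.3g\n", x$statistic, x$df, x$p_value))
  if (!is.na(x$p_monte_carlo)) {
    cat(sprintf("  Monte Carlo p = %.3g\n", x$p_monte_carlo))
  }
  invisible(x)
}

#' Cosine similarity between two nonnegative spectra
#'
#' `u . v / (||u|| ||v||)`, in [0, 1] for nonnegative vectors; used to compare
#' trinucleotide spectra with each other and with reference signature columns.
#'
#' @param u,v Equal-length numeric vectors with nonzero norm.
#' @return Scalar similarity.
#' @export
cosine_similarity <- function(u, v) {
  u <- spectrum_counts(u); v <- spectrum_counts(v)
  if (length(u) != length(v)) abort("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Tabulate indels, MNVs and SVs by size and type
#'
#' Small events are binned as insertions/deletions of 1-2 bp or 3-20 bp plus
#' MNVs (the five-category small-event spectrum). Events with a net allele
#' length change beyond 20 bp — indels and SVs together, since the 1000 bp
#' indel/SV boundary is an arbitrary variant-calling parameter — are divided
#' into deletions, insertions/duplications, and inversions. Identity for
#' complex variants follows the sign of the net change in allele length,
#' which also defines the indel length.
#'
#' @param variants Unique non-SNV mutation tibble.
#' @param duplex_bases Optional denominator; when given, large-event
#'   frequencies are added.
#' @return An `indel_sv_spectrum` list with tibbles `small` (category,
#'   count) and `large` (type, count, and `frequency` when `duplex_bases`
#'   given).
#' @export
classify_indels_svs <- function(variants, duplex_bases = NULL) {
  x <- variants %>%
    filter(.data$vtype != "SNV") %>%
    mutate(net = variant_net_length(.data$ref, .data$alt, .data$sv_len))
  if (any(x$vtype == "inversion" & is.na(x$net))) {
    inform("inversion(s) with undefined length counted without a length")
  }
  small_levels <- c("Ins 1-2", "Ins 3-20", "Del 1-2", "Del 3-20", "MNV")
  small <- x %>%
    filter(.data$vtype == "MNV" |
             (!is.na(.data$net) & abs(.data$net) >= 1 & abs(.data$net) <= 20 &
                .data$vtype != "inversion")) %>%
    mutate(category = case_when(
      .data$vtype == "MNV" ~ "MNV",
      .data$net > 0 & .data$net <= 2 ~ "Ins 1-2",
      .data$net > 2 ~ "Ins 3-20",
      .data$net >= -2 ~ "Del 1-2",
      TRUE ~ "Del 3-20"
    )) %>%
    count(.data$category, name = "count")
  small <- tibble(category = small_levels) %>%
    left_join(small, by = "category") %>%
    mutate(count = tidyr::replace_na(.data$count, 0L))

  large <- x %>%
    filter(.data$vtype == "inversion" |
             (!is.na(.data$net) & abs(.data$net) > 20)) %>%
    mutate(type = case_when(
      .data$vtype == "inversion" ~ "inversion",
      .data$net < 0 ~ "deletion",
      TRUE ~ "insertion/duplication"
    )) %>%
    count(.data$type, name = "count")
  large <- tibble(type = c("deletion", "insertion/duplication", "inversion")) %>%
    left_join(large, by = "type") %>%
    mutate(count = tidyr::replace_na(.data$count, 0L))
  if (!is.null(duplex_bases)) {
    large <- mutate(large, frequency = .data$count / duplex_bases)
  }
  # deletion length summary for events beyond 20 bp (net loss)
  del_len <- x %>%
    filter(!is.na(.data$net), .data$net < -20, .data$vtype != "inversion") %>%
    pull(.data$net) %>%
    abs()
  structure(
    list(
      small = small, large = large,
      deletion_length = tibble(
        n = length(del_len),
        median_bp = if (length(del_len)) median(del_len) else NA_real_,
        max_bp = if (length(del_len)) max(del_len) else NA_real_
      )
    ),
    class = "indel_sv_spectrum"
  )
}

#' @exportS3Method generics::tidy
tidy.indel_sv_spectrum <- function(x, ...) {
  bind_rows(
    mutate(rename(x$small, group = "category"), table = "small"),
    mutate(rename(x$large, group = "type"), table = "large")
  )
}

#' @export
print.indel_sv_spectrum <- function(x, ...) {
  cat("<indel_sv_spectrum>\nsmall events:\n")
  print(as.data.frame(x$small), row.names = FALSE)
  cat("events > 20 bp:\n")
  print(as.data.frame(x$large), row.names = FALSE)
  invisible(x)
}

#' Plot a substitution spectrum
#'
#' Bar chart of class proportions; SBS96 spectra are faceted by substitution
#' class in the conventional layout.
#'
#' @param object An `sbs_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sbs_spectrum <- function(object, ...) {
  kind <- attr(object, "kind")
  df <- as_tibble(object)
  if (identical(kind, "sbs6")) {
    ggplot2::ggplot(df, ggplot2::aes(.data$context, .data$proportion,
                                     fill = .data$context)) +
      ggplot2::geom_col(show.legend = FALSE) +
      ggplot2::labs(x = NULL, y = "proportion of SNVs") +
      ggplot2::theme_minimal()
  } else {
    df$sub <- stringr::str_match(df$context, "\\[(.*)\\]")[, 2]
    ggplot2::ggplot(df, ggplot2::aes(.data$context, .data$proportion,
                                     fill = .data$sub)) +
      ggplot2::geom_col(show.legend = FALSE) +
      ggplot2::facet_grid(. ~ sub, scales = "free_x") +
      ggplot2::labs(x = NULL, y = "proportion of SNVs") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_blank())
  }
}
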