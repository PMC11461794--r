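# report_cli: orchestration of simulate -> filter -> burden -> spectra ->
# eccdna into one deterministic, seeded pipeline with a written report
# bundle. The function surface (rather than a shell binary) is the package's
# command interface; scripts/acceptance.R shows the end-to-end invocation.

#' Published reference-cohort counts
#'
#' Per-participant duplex-sequencing yields and unique mutation counts
#' (SNV/MNV/indel/SV after the filtering ladder at the 1% VAF gate) for a
#' published reference cohort of six young men with matched blood and sperm
#' samples. Shipped as a plain-text fixture; pure division reproduces the
#' published per-sample and pooled mutation frequencies.
#'
#' @return Tibble with columns `tissue`, `participant`, `duplex_bases`,
#'   `n_snv`, `n_mnv`, `n_indel`, `n_sv`.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "reference_cohort_counts.tsv",
                      package = "duplexmut", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ciiiiii", progress = FALSE)
}

#' Burden table from per-sample counts and duplex yields
#'
#' Computes per-sample and pooled mutation frequencies directly from a count
#' table (as from [reference_cohort_counts()]), without variant-level data.
#' Pooling is per tissue when a `tissue` column is present.
#'
#' @param counts Tibble with `duplex_bases` and `n_snv`, `n_mnv`, `n_indel`,
#'   `n_sv` columns, plus `sample_id` or `tissue`/`participant`.
#' @return Burden tibble in the [compute_burden()] layout, with a `tissue`
#'   column when pooling per tissue.
#' @export
burden_from_counts <- function(counts) {
  x <- as_tibble(counts)
  if (!"sample_id" %in% names(x)) {
    x$sample_id <- paste0(x$tissue, x$participant)
  }
  long <- x %>%
    tidyr::pivot_longer(
      dplyr::all_of(c("n_snv", "n_mnv", "n_indel", "n_sv")),
      names_to = "class", values_to = "n"
    ) %>%
    mutate(class = dplyr::recode(.data$class, n_snv = "SNV", n_mnv = "MNV",
                                 n_indel = "indel", n_sv = "SV"))
  group_cols <- intersect("tissue", names(long))
  pooled <- long %>%
    group_by(across(dplyr::all_of(c(group_cols, "class")))) %>%
    summarise(n = sum(.data$n), duplex_bases = sum(.data$duplex_bases),
              .groups = "drop") %>%
    mutate(sample_id = "total")
  bind_rows(
    select(long, dplyr::all_of(c(group_cols, "sample_id", "class",
                                 "n", "duplex_bases"))),
    pooled
  ) %>%
    mutate(mf = mutation_frequency(.data$n, .data$duplex_bases),
           mf_display = format_mf(.data$mf))
}

#' Pipeline configuration
#'
#' All thresholds are surfaced here; nothing downstream hides a constant.
#'
#' @param output_dir Directory for the report bundle.
#' @param seed Master seed for the simulated cohort.
#' @param blood,sperm Tissue generator configs ([cohort_config()]).
#' @param filters Filter thresholds ([filter_config()]).
#' @param signatures Optional path to a reference signature TSV (cosine
#'   similarities are added to the stats).
#' @param comparison_spectrum Optional path to a TSV with `context`, `count`
#'   columns: an external six-class spectrum to test the sperm spectrum
#'   against.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir = tempfile("duplexmut_report_"),
                            seed = 1L,
                            blood = cohort_config("blood"),
                            sperm = cohort_config("sperm"),
                            filters = filter_config(),
                            signatures = NULL,
                            comparison_spectrum = NULL) {
  for (p in c(signatures, comparison_spectrum)) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("no such file: ", p))
  }
  structure(
    list(output_dir = output_dir, seed = as.integer(seed), blood = blood,
         sperm = sperm, filters = filters, signatures = signatures,
         comparison_spectrum = comparison_spectrum),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Recognised top-level keys: `seed`, `output_dir`, `signatures`,
#' `comparison_spectrum`, and `blood`/`sperm`/`filters` blocks whose entries
#' override the corresponding [cohort_config()]/[filter_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    output_dir = y$output_dir %||% tempfile("duplexmut_report_"),
    seed = y$seed %||% 1L,
    signatures = y$signatures,
    comparison_spectrum = y$comparison_spectrum
  )
  args$blood <- do.call(cohort_config, c(list(tissue = "blood"), y$blood))
  args$sperm <- do.call(cohort_config, c(list(tissue = "sperm"), y$sperm))
  args$filters <- do.call(filter_config, y$filters %||% list())
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Simulates matched blood and sperm cohorts, runs the filtering ladder per
#' tissue, computes burden tables, subtype rates, CpG fractions, per-locus
#' frequencies, SBS6/SBS96 spectra with the likelihood-ratio comparison and
#' cosine similarity, and the putative-circle analysis; writes a report
#' bundle (TSV tables, a stats JSON and a log) to `config$output_dir`.
#' Deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate and final object
#'   (`study`, per-tissue `filtered`, `burden`, `spectra`, `stats`,
#'   `circles`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "pipeline.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  logf("pipeline start, seed %d", config$seed)

  study <- simulate_study(seed = config$seed, blood = config$blood,
                          sperm = config$sperm)
  totals <- depth_totals(study$depth, study$panel)

  tissues <- c("blood", "sperm")
  filtered <- purrr::map(setNames(tissues, tissues), function(tis) {
    res <- run_filter_ladder(filter(study$variants, .data$tissue == tis),
                             config$filters)
    logf("%s: %d calls -> %d unique mutations (removals: MNV %d, indel %d, contamination %d, VAF %d)",
         tis, res$report$n_input_calls, res$report$n_retained,
         res$report$removed_snv_over_clonal_mnv,
         res$report$removed_snv_near_indel,
         res$report$removed_contamination, res$report$removed_vaf_gate)
    res
  })

  burden <- purrr::imap_dfr(filtered, function(res, tis) {
    ids <- unique(study$depth$sample_id[study$depth$tissue == tis])
    mutate(
      compute_burden(res$variants, filter(totals, .data$sample_id %in% ids)),
      tissue = tis, .before = 1
    )
  })
  readr::write_tsv(burden, file.path(config$output_dir, "burden.tsv"),
                   progress = FALSE)

  pooled_totals <- purrr::imap_dfr(
    setNames(tissues, tissues),
    function(tis, nm) {
      ids <- unique(study$depth$sample_id[study$depth$tissue == tis])
      filter(totals, .data$sample_id %in% ids) %>%
        summarise(sample_id = nm,
                  total_duplex_bases = sum(.data$total_duplex_bases),
                  depth_at_CG = sum(.data$depth_at_CG),
                  depth_at_TA = sum(.data$depth_at_TA))
    }
  )
  subtypes <- subtype_rates(
    bind_rows(
      mutate(filtered$blood$variants, sample_id = "blood"),
      mutate(filtered$sperm$variants, sample_id = "sperm")
    ),
    pooled_totals
  )
  readr::write_tsv(subtypes, file.path(config$output_dir, "subtype_rates.tsv"),
                   progress = FALSE)

  spectra <- purrr::map(filtered, function(res) {
    list(
      sbs6 = build_sbs_spectrum(res$variants, study$panel, "sbs6"),
      sbs96 = build_sbs_spectrum(res$variants, study$panel, "sbs96")
    )
  })
  purrr::iwalk(spectra, function(sp, tis) {
    readr::write_tsv(as_tibble(sp$sbs96),
                     file.path(config$output_dir, paste0("sbs96_", tis, ".tsv")),
                     progress = FALSE)
  })

  lr_tissue <- lr_spectrum_test(spectra$blood$sbs6, spectra$sperm$sbs6)
  cpg <- purrr::map(filtered, ~ cpg_fraction(.x$variants, study$panel))
  locus <- purrr::imap(filtered, function(res, tis) {
    per_locus_mf(
      filter(res$variants, .data$vtype == "SNV"),
      filter(study$depth, .data$tissue == tis),
      study$panel
    )
  })
  snv_mf_by_sample <- burden %>%
    filter(.data$class == "SNV", .data$sample_id != "total") %>%
    arrange(.data$tissue, .data$sample_id)
  mf_b <- filter(snv_mf_by_sample, .data$tissue == "blood")$mf
  mf_s <- filter(snv_mf_by_sample, .data$tissue == "sperm")$mf
  corr <- if (length(mf_b) == length(mf_s) && length(mf_b) >= 3) {
    cross_tissue_correlation(mf_b, mf_s)
  } else {
    tibble(estimate = NA_real_, p_value = NA_real_, n = length(mf_b))
  }
  indel_sv <- purrr::imap(filtered, function(res, tis) {
    classify_indels_svs(
      res$variants,
      sum(pooled_totals$total_duplex_bases[pooled_totals$sample_id == tis])
    )
  })

  circles <- purrr::imap(filtered, function(res, tis) {
    ids <- unique(study$depth$sample_id[study$depth$tissue == tis])
    analyze_circles(
      res$pre_vaf_gate,
      filter(study$geometry, .data$tissue == tis),
      study$panel,
      filter(totals, .data$sample_id %in% ids),
      median_insert = config[[tis]]$median_insert_size,
      vaf_max = config$filters$vaf_max
    )
  })

  stats <- list(
    seed = config$seed,
    filter_report = purrr::map(filtered, ~ as.list(glance(.x))),
    clonality = purrr::map(filtered, ~ as.data.frame(.x$clonality)),
    burden_summary = purrr::map(
      setNames(tissues, tissues),
      ~ as.data.frame(burden_summary(filter(burden, .data$tissue == .x)))
    ),
    spectrum_lr_test = as.list(tidy(lr_tissue)),
    spectrum_cosine_blood_sperm = cosine_similarity(
      spectra$blood$sbs96$count, spectra$sperm$sbs96$count
    ),
    cpg_ct_fraction = purrr::map(cpg, as.list),
    locus_fold_range = purrr::map(locus, "fold_range"),
    snv_mf_cross_tissue_correlation = as.list(corr),
    circle_summary = purrr::map(circles, ~ as.list(glance(.x)))
  )
  if (!is.null(config$signatures)) {
    sig <- read_signature_matrix(config$signatures)
    stats$signature_cosines <- purrr::map(spectra, function(sp) {
      vapply(sig[, -1, drop = FALSE],
             function(col) cosine_similarity(sp$sbs96$count, col), numeric(1))
    })
  }
  if (!is.null(config$comparison_spectrum)) {
    cmp <- readr::read_tsv(config$comparison_spectrum, show_col_types = FALSE,
                           progress = FALSE)
    stats$comparison_lr_test <- as.list(tidy(
      lr_spectrum_test(spectra$sperm$sbs6, cmp)
    ))
  }
  jsonlite::write_json(stats, file.path(config$output_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline done")

  invisible(list(
    config = config, study = study, totals = totals, filtered = filtered,
    burden = burden, subtypes = subtypes, spectra = spectra,
    lr_tissue = lr_tissue, cpg = cpg, locus = locus, correlation = corr,
    indel_sv = indel_sv, circles = circles, stats = stats
  ))
}
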