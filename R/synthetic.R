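# synthetic_cohort: generator for panels, per-sample variant tables, depth
# profiles, junction-read geometries and ground-truth labels. Defaults encode
# the study conditions of the blood/sperm duplex-sequencing cohort the
# pipeline targets: six samples per tissue, ~1.25e9 duplex bases per sample
# over a 20 x 2.4 kb panel, class-specific mutation frequencies, a 233 bp
# median library insert, and (in sperm) a population of small DNA circles
# with a multimodal length distribution.

#' Generate a random DNA sequence with controlled GC content
#'
#' Homopolymer runs longer than `max_homopolymer` are broken by resampling,
#' mimicking panel design that avoids long homopolymers.
#'
#' @param n Sequence length.
#' @param gc_fraction Target GC fraction, in (0, 1).
#' @param max_homopolymer Longest allowed single-base run.
#' @return A character scalar of length-`n` DNA.
#' @keywords internal
random_dna <- function(n, gc_fraction = 0.42, max_homopolymer = 8L) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  b <- sample(names(p), n, replace = TRUE, prob = p)
  repeat {
    r <- rle(b)
    long <- which(r$lengths > max_homopolymer)
    if (length(long) == 0) break
    ends <- cumsum(r$lengths)
    for (i in long) {
      at <- ends[i] - r$lengths[i] + seq(max_homopolymer + 1L, r$lengths[i])
      b[at] <- vapply(
        b[at],
        function(x) sample(setdiff(names(p), x), 1),
        character(1)
      )
    }
  }
  paste(b, collapse = "")
}

#' Generate a synthetic targeted panel
#'
#' Each locus becomes its own contig (`locus01`, `locus02`, ...) of random
#' sequence at the requested GC fraction with homopolymers capped at 8 bp.
#' With the default 20 loci, genic/intergenic/mixed labels are assigned
#' 10/6/4; other locus counts recycle that proportion.
#'
#' @param n_loci Number of loci (default 20).
#' @param locus_len Locus length in bp (default 2400, i.e. a 48 kb panel).
#' @param gc_fraction Target GC fraction (default 0.42, genome-like).
#' @param seed Integer seed; fixed seeds give byte-identical panels.
#' @return Panel tibble (see [read_panel_bed()] for columns).
#' @export
generate_panel <- function(n_loci = 20L, locus_len = 2400L,
                           gc_fraction = 0.42, seed = 1L) {
  if (n_loci < 1) abort("n_loci must be >= 1")
  if (gc_fraction <= 0 || gc_fraction >= 1) abort("gc_fraction must be in (0, 1)")
  cls <- if (n_loci == 20L) {
    c(rep("genic", 10), rep("intergenic", 6), rep("mixed", 4))
  } else {
    rep_len(c("genic", "intergenic", "mixed"), n_loci)
  }
  withr::with_seed(seed, {
    tibble(
      locus_id = sprintf("locus%02d", seq_len(n_loci)),
      contig = sprintf("locus%02d", seq_len(n_loci)),
      start = 0L,
      end = as.integer(locus_len),
      cls = cls,
      sequence = purrr::map_chr(seq_len(n_loci),
                                ~ random_dna(locus_len, gc_fraction))
    )
  })
}

#' Generator configuration for one tissue cohort
#'
#' Defaults are tissue-specific and encode the study conditions the pipeline
#' is built around: pooled class mutation frequencies (per duplex base),
#' six-class substitution weights, the fraction of C>T at CpG sites, circle
#' and tandem-duplication loads, and the 233 bp median library insert size.
#' Sperm defaults carry ~51 DNA circles per sample (length mixture centred at
#' 180/370/560 bp), one tandem duplication and two junction-negative large
#' insertions; blood carries none.
#'
#' @param tissue `"sperm"` or `"blood"`.
#' @param n_samples Samples in the cohort (default 6).
#' @param duplex_bases_per_sample Target informative duplex bases per sample.
#' @param snv_mf,mnv_mf,indel_mf,sv_mf Class mutation rates per duplex base.
#'   `indel_mf` covers ordinary (non-junction) indels; circles and TDs are
#'   added on top via `circle_count`/`td_count` and, being mostly sub-kb
#'   insertions, land in the indel class of burden tables.
#' @param locus_weights Optional relative per-locus SNV rate multipliers
#'   (recycled over loci); `NULL` means uniform. Lets fixtures implant a
#'   known fold-spread in locus-specific mutation frequency.
#' @param sbs6_weights Probability vector over [sbs6_classes()].
#' @param cpg_ct_fraction Fraction of C>T placed at CpG (NCG) sites.
#' @param germline_het_rate Per-position heterozygosity for germline variants
#'   (VAF ~ 50%).
#' @param clonal_fraction_snv,clonal_fraction_other Fraction of somatic
#'   SNV / non-SNV events emitted as clonal expansions (k >= 2 molecules).
#' @param circle_count Mean DNA circles per sample (Poisson).
#' @param circle_length_modes,circle_length_sd,circle_length_weights Gaussian
#'   mixture for circle allele lengths (bp), floored at 130 bp.
#' @param td_count Tandem duplications per sample (exact).
#' @param nonjunction_insertion_count Junction-negative insertions of
#'   21-125 bp per sample (exact).
#' @param sv_type_weights Probabilities for SV types
#'   (deletion, duplication, inversion).
#' @param median_insert_size Median library insert size in bp.
#' @param contaminant_pairs Cross-sample contaminant copies implanted across
#'   the cohort (low-VAF copies of another sample's germline variant).
#' @param contaminant_hotspot How many of those land in the first sample.
#' @param mnv_partial_snv_count Per sample: clonal MNVs each paired with a
#'   spurious partial SNV inside the MNV span.
#' @param indel_proximal_snv_count Per sample: indels each paired with a
#'   spurious SNV within 10 bp of an indel boundary.
#' @param clonal_as_rows If `TRUE`, clonal events are emitted as k duplicate
#'   rows (exercising deduplication); default is one row with `alt_count = k`.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(tissue = c("sperm", "blood"),
                          n_samples = 6L,
                          duplex_bases_per_sample = 1.25e9,
                          snv_mf = NULL, mnv_mf = NULL,
                          indel_mf = NULL, sv_mf = NULL,
                          sbs6_weights = NULL,
                          cpg_ct_fraction = NULL,
                          germline_het_rate = 1e-3,
                          clonal_fraction_snv = 0.04,
                          clonal_fraction_other = 0.30,
                          circle_count = NULL,
                          circle_length_modes = c(180, 370, 560),
                          circle_length_sd = 25,
                          circle_length_weights = c(0.5, 0.3, 0.2),
                          td_count = NULL,
                          nonjunction_insertion_count = NULL,
                          sv_type_weights = NULL,
                          locus_weights = NULL,
                          median_insert_size = 233L,
                          contaminant_pairs = NULL,
                          contaminant_hotspot = NULL,
                          mnv_partial_snv_count = 1L,
                          indel_proximal_snv_count = 1L,
                          clonal_as_rows = FALSE) {
  tissue <- match.arg(tissue)
  sperm <- tissue == "sperm"
  cfg <- list(
    tissue = tissue,
    n_samples = as.integer(n_samples),
    duplex_bases_per_sample = duplex_bases_per_sample,
    snv_mf = snv_mf %||% if (sperm) 2.5e-8 else 1.2e-7,
    mnv_mf = mnv_mf %||% if (sperm) 4.0e-10 else 1.3e-9,
    indel_mf = indel_mf %||% if (sperm) 3.3e-8 else 7.6e-9,
    sv_mf = sv_mf %||% if (sperm) 9.1e-9 else 3.8e-10,
    sbs6_weights = sbs6_weights %||%
      if (sperm) c(0.07, 0.07, 0.46, 0.07, 0.26, 0.07)
      else c(0.14, 0.07, 0.53, 0.07, 0.12, 0.07),
    cpg_ct_fraction = cpg_ct_fraction %||% if (sperm) 0.36 else 0.35,
    germline_het_rate = germline_het_rate,
    clonal_fraction_snv = clonal_fraction_snv,
    clonal_fraction_other = clonal_fraction_other,
    circle_count = circle_count %||% if (sperm) 51 else 0,
    circle_length_modes = circle_length_modes,
    circle_length_sd = circle_length_sd,
    circle_length_weights = circle_length_weights,
    td_count = td_count %||% if (sperm) 1L else 0L,
    nonjunction_insertion_count =
      nonjunction_insertion_count %||% if (sperm) 2L else 1L,
    sv_type_weights = sv_type_weights %||%
      if (sperm) c(deletion = 5, duplication = 40, inversion = 23) / 68
      else c(deletion = 0, duplication = 0, inversion = 1),
    locus_weights = locus_weights,
    median_insert_size = as.integer(median_insert_size),
    contaminant_pairs = contaminant_pairs %||% if (sperm) 21L else 5L,
    contaminant_hotspot = contaminant_hotspot %||% if (sperm) 16L else 0L,
    mnv_partial_snv_count = as.integer(mnv_partial_snv_count),
    indel_proximal_snv_count = as.integer(indel_proximal_snv_count),
    clonal_as_rows = isTRUE(clonal_as_rows)
  )
  stopifnot(
    cfg$duplex_bases_per_sample > 0,
    all(unlist(cfg[c("snv_mf", "mnv_mf", "indel_mf", "sv_mf")]) >= 0),
    abs(sum(cfg$sbs6_weights) - 1) < 1e-8
  )
  structure(cfg, class = "cohort_config")
}

# picks a base different from `ref`
other_base <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
         character(1), USE.NAMES = FALSE)
}

# alt base for a pyrimidine-collapsed class given the actual reference base
alt_for_class <- function(ref, cls) {
  to <- substr(cls, 3, 3)
  if_else(ref %in% c("C", "T"), to, unname(DNA_COMPLEMENT[to]))
}

#' Simulate one sample's variant table, depth profile and geometry
#'
#' Workhorse behind [simulate_cohort()]; exposed for targeted fixtures.
#' Events implanted (each labelled in the returned truth table): germline
#' variants at VAF ~ 50%, singleton and clonal somatic SNVs/MNVs/indels/SVs at
#' the configured rates, spurious partial SNVs inside clonal MNV spans,
#' spurious SNVs within 10 bp of indel boundaries, DNA circles and tandem
#' duplications (both emitted as insertions whose alternate allele copies the
#' downstream reference, hence carrying a D-A junction), and junction-negative
#' random-sequence insertions.
#'
#' @param config A [cohort_config()].
#' @param panel Panel tibble.
#' @param sample_id Sample name.
#' @param seed Integer seed for this sample.
#' @param pp Optional precomputed [panel_positions()] table.
#' @return List with tibbles `variants`, `depth`, `geometry`, `truth`.
#' @export
simulate_sample <- function(config, panel, sample_id, seed, pp = NULL) {
  if (config$duplex_bases_per_sample <= 0) abort("duplex_bases_per_sample must be > 0")
  if (nrow(panel) == 0) abort("panel is empty")
  pp <- pp %||% panel_positions(panel)
  withr::with_seed(seed, simulate_sample_impl(config, panel, sample_id, pp))
}

simulate_sample_impl <- function(config, panel, sample_id, pp) {
  npos <- nrow(pp)
  mean_depth <- config$duplex_bases_per_sample / npos
  depth_vec <- pmax(1L, as.integer(round(rnorm(npos, mean_depth, 0.03 * mean_depth))))
  total_bases <- sum(as.numeric(depth_vec))
  locus_end <- setNames(
    panel$start + nchar(panel$sequence), panel$contig
  )
  locus_start <- setNames(panel$start + 1L, panel$contig)
  seq_of <- setNames(panel$sequence, panel$contig)
  ref_at <- function(contig, pos) {
    off <- pos - (locus_start[contig] - 1L)
    substr(seq_of[contig], off, off)
  }
  seq_at <- function(contig, from, to) {
    o1 <- from - (locus_start[contig] - 1L)
    o2 <- to - (locus_start[contig] - 1L)
    substr(seq_of[contig], o1, o2)
  }
  depth_at <- function(idx) depth_vec[idx]

  rows <- list()
  truth <- list()
  geometry <- list()
  add <- function(chrom, pos, ref, alt, vtype, alt_count, site_depth, sv_len,
                  label, allele_length = NA_integer_) {
    k <- length(rows) + 1L
    rows[[k]] <<- tibble(
      sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
      ref = ref, alt = alt, vtype = vtype,
      alt_count = as.integer(alt_count), site_depth = as.integer(site_depth),
      sv_len = as.integer(sv_len)
    )
    truth[[k]] <<- tibble(
      sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
      ref = ref, alt = alt, vtype = vtype, label = label,
      alt_count = as.integer(alt_count),
      allele_length = as.integer(allele_length)
    )
  }

  # optional per-locus rate multipliers for SNV placement
  w_pos <- if (is.null(config$locus_weights)) {
    rep(1, npos)
  } else {
    lw <- rep_len(config$locus_weights, length(unique(pp$locus_id)))
    lw[match(pp$locus_id, unique(pp$locus_id))]
  }
  idx_C <- which(pp$pyr == "C")
  idx_T <- which(pp$pyr == "T")
  idx_cpg <- which(pp$is_cpg)
  idx_c_noncpg <- setdiff(idx_C, idx_cpg)

  pick1 <- function(idx) {
    if (length(idx) == 1) idx else sample(idx, 1, prob = w_pos[idx])
  }
  pick_snv_site <- function(cls) {
    if (startsWith(cls, "C")) {
      if (cls == "C>T" && runif(1) < config$cpg_ct_fraction) {
        pick1(idx_cpg)
      } else if (cls == "C>T") {
        pick1(idx_c_noncpg)
      } else {
        pick1(idx_C)
      }
    } else {
      pick1(idx_T)
    }
  }

  emit_snv <- function(i, alt_count, label, cls = NULL) {
    ref <- pp$ref[i]
    alt <- if (is.null(cls)) other_base(ref) else alt_for_class(ref, cls)
    dp <- depth_at(i)
    if (config$clonal_as_rows && label == "clonal_somatic") {
      for (j in seq_len(alt_count)) {
        add(pp$contig[i], pp$pos[i], ref, alt, "SNV", 1L, dp,
            NA_integer_, label)
      }
    } else {
      add(pp$contig[i], pp$pos[i], ref, alt, "SNV", alt_count, dp,
          NA_integer_, label)
    }
  }

  # --- germline heterozygous variants (VAF ~ 0.5) -------------------------
  n_germ <- rbinom(1, npos, config$germline_het_rate)
  for (i in sample.int(npos, n_germ)) {
    dp <- depth_at(i)
    ac <- max(1L, rbinom(1, dp, 0.5))
    add(pp$contig[i], pp$pos[i], pp$ref[i], other_base(pp$ref[i]),
        "SNV", ac, dp, NA_integer_, "germline")
  }

  # --- somatic SNVs -------------------------------------------------------
  n_snv <- rpois(1, config$snv_mf * total_bases)
  if (n_snv > 0) {
    classes <- sample(sbs6_classes(), n_snv, replace = TRUE,
                      prob = config$sbs6_weights)
    clonal <- runif(n_snv) < config$clonal_fraction_snv
    for (j in seq_len(n_snv)) {
      i <- pick_snv_site(classes[j])
      if (clonal[j]) {
        emit_snv(i, sample(2:5, 1), "clonal_somatic", classes[j])
      } else {
        emit_snv(i, 1L, "singleton", classes[j])
      }
    }
  }

  # --- somatic MNVs -------------------------------------------------------
  n_mnv <- rpois(1, config$mnv_mf * total_bases)
  for (j in seq_len(n_mnv)) {
    len <- sample(c(2L, 3L), 1, prob = c(0.8, 0.2))
    i <- sample.int(npos - len, 1)
    if (pp$pos[i] + len - 1L > locus_end[pp$contig[i]]) next
    ref <- seq_at(pp$contig[i], pp$pos[i], pp$pos[i] + len - 1L)
    alt <- paste(other_base(strsplit(ref, "")[[1]]), collapse = "")
    ac <- if (runif(1) < config$clonal_fraction_other) sample(2:4, 1) else 1L
    add(pp$contig[i], pp$pos[i], ref, alt, "MNV", ac, depth_at(i),
        NA_integer_, if (ac > 1) "clonal_somatic" else "singleton")
  }

  # --- ordinary small indels (plus a few complex variants) ----------------
  emit_indel <- function(label = NULL) {
    is_del <- runif(1) < 0.5
    len <- if (is_del) {
      bin <- sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
      switch(bin, sample(1:2, 1), sample(3:20, 1),
             min(2512L, 21L + as.integer(round(stats::rlnorm(1, log(60), 0.8)))))
    } else {
      if (runif(1) < 0.6) sample(1:2, 1) else sample(3:20, 1)
    }
    i <- sample.int(npos - (len + 25L), 1)
    contig <- pp$contig[i]
    if (pp$pos[i] + len + 1L > locus_end[contig]) return(NULL)
    anchor <- pp$ref[i]
    complex_var <- runif(1) < 0.05
    if (is_del) {
      ref <- seq_at(contig, pp$pos[i], pp$pos[i] + len)
      alt <- if (complex_var) paste0(anchor, random_dna(1, 0.5)) else anchor
      if (complex_var) ref <- seq_at(contig, pp$pos[i], pp$pos[i] + len + 1L)
      vt <- if (complex_var) "complex" else "deletion"
    } else {
      ref <- anchor
      alt <- paste0(anchor, random_dna(len, 0.5))
      vt <- "insertion"
    }
    ac <- if (runif(1) < config$clonal_fraction_other) sample(2:4, 1) else 1L
    lab <- label %||% if (ac > 1) "clonal_somatic" else "singleton"
    add(contig, pp$pos[i], ref, alt, vt, ac, depth_at(i), NA_integer_, lab)
    list(contig = contig, pos = pp$pos[i], len = len, is_del = is_del)
  }
  n_indel <- rpois(1, config$indel_mf * total_bases)
  for (j in seq_len(n_indel)) emit_indel()

  # --- SVs (symbolic alleles with SVLEN) ----------------------------------
  n_sv <- rpois(1, config$sv_mf * total_bases)
  for (j in seq_len(n_sv)) {
    type <- sample(names(config$sv_type_weights), 1,
                   prob = config$sv_type_weights)
    i <- sample.int(npos, 1)
    ac <- if (runif(1) < config$clonal_fraction_other) sample(2:3, 1) else 1L
    sv_len <- switch(type,
      deletion = -sample(1001:2512, 1),
      duplication = sample(1001:3000, 1),
      inversion = sample(200:2400, 1)
    )
    alt <- switch(type, deletion = "<DEL>", duplication = "<DUP>",
                  inversion = "<INV>")
    vt <- switch(type, deletion = "deletion", duplication = "insertion",
                 inversion = "inversion")
    add(pp$contig[i], pp$pos[i], pp$ref[i], alt, vt, ac, depth_at(i),
        sv_len, if (ac > 1) "clonal_somatic" else "singleton")
  }

  # --- clonal MNV with a spurious partial SNV -----------------------------
  for (j in seq_len(config$mnv_partial_snv_count)) {
    len <- 3L
    i <- sample.int(npos - len, 1)
    contig <- pp$contig[i]
    if (pp$pos[i] + len - 1L > locus_end[contig]) next
    ref <- seq_at(contig, pp$pos[i], pp$pos[i] + len - 1L)
    alt <- paste(other_base(strsplit(ref, "")[[1]]), collapse = "")
    dp <- depth_at(i)
    add(contig, pp$pos[i], ref, alt, "MNV", max(2L, as.integer(0.02 * dp)),
        dp, NA_integer_, "clonal_mnv")
    off <- sample.int(len, 1) - 1L
    add(contig, pp$pos[i] + off, ref_at(contig, pp$pos[i] + off),
        substr(alt, off + 1L, off + 1L), "SNV", 1L, depth_at(i + off),
        NA_integer_, "mnv_partial_snv")
  }

  # --- indel with a spurious proximal SNV ---------------------------------
  for (j in seq_len(config$indel_proximal_snv_count)) {
    ind <- emit_indel(label = "indel_with_proximal_snv")
    if (is.null(ind)) next
    boundary <- if (ind$is_del) ind$pos + ind$len else ind$pos + 1L
    off <- sample.int(10L, 1)
    p <- min(boundary + off, locus_end[ind$contig])
    i <- which(pp$contig == ind$contig & pp$pos == p)[1]
    add(ind$contig, p, pp$ref[i], other_base(pp$ref[i]), "SNV", 1L,
        depth_at(i), NA_integer_, "indel_proximal_snv")
  }

  # --- D-A junction events: circles, tandem duplications ------------------
  emit_junction_event <- function(L, label) {
    # anchor such that the downstream copy [pos+1, pos+L] stays in the locus;
    # on small fixture panels the allele is clipped to the longest that fits
    L <- min(L, max(locus_end - locus_start) - 1L)
    ok <- which(pp$pos + L <= locus_end[pp$contig] &
                  pp$pos >= locus_start[pp$contig])
    if (length(ok) == 0) return(invisible(NULL))
    i <- ok[sample.int(length(ok), 1)]
    contig <- pp$contig[i]
    anchor <- pp$ref[i]
    insert_seq <- seq_at(contig, pp$pos[i] + 1L, pp$pos[i] + L)
    dp <- depth_at(i)
    u <- runif(1)
    ac <- if (label == "circle" && u < 0.06) {
      max(2L, as.integer(0.015 * dp)) # a few circles above the 1% VAF gate
    } else if (label == "circle") {
      if (u < 0.76) 1L else sample(2:3, 1)
    } else {
      sample(1:2, 1)
    }
    add(contig, pp$pos[i], anchor, paste0(anchor, insert_seq), "insertion",
        ac, dp, NA_integer_, label, allele_length = L)
    # geometry records a representative subset of supporting read pairs
    geometry[[length(geometry) + 1L]] <<- generate_junction_reads(
      chrom = contig, pos = pp$pos[i], allele_length = L,
      kind = if (label == "circle") "circle" else "td",
      n_fragments = min(ac, 25L), config = config, sample_id = sample_id
    )
  }
  n_circ <- rpois(1, config$circle_count)
  if (n_circ > 0) {
    comp <- sample(seq_along(config$circle_length_modes), n_circ,
                   replace = TRUE, prob = config$circle_length_weights)
    Ls <- pmax(130L, as.integer(round(rnorm(
      n_circ, config$circle_length_modes[comp], config$circle_length_sd
    ))))
    for (L in Ls) emit_junction_event(L, "circle")
  }
  for (j in seq_len(config$td_count)) {
    emit_junction_event(sample(60:100, 1), "tandem_duplication")
  }

  # --- junction-negative large insertions ---------------------------------
  for (j in seq_len(config$nonjunction_insertion_count)) {
    L <- sample(21:125, 1)
    i <- sample.int(npos, 1)
    add(pp$contig[i], pp$pos[i], pp$ref[i],
        paste0(pp$ref[i], random_dna(L, 0.5)), "insertion", 1L,
        depth_at(i), NA_integer_, "nonjunction_insertion",
        allele_length = L)
  }

  empty_variants <- tibble(
    sample_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), vtype = character(0),
    alt_count = integer(0), site_depth = integer(0), sv_len = integer(0)
  )
  variants <- bind_rows(empty_variants, bind_rows(rows))
  truth_tbl <- bind_rows(
    mutate(select(empty_variants, -"site_depth"),
           label = character(0), allele_length = integer(0)),
    bind_rows(truth)
  )
  # rare position collisions between independently placed events: keep first
  # (duplicate rows are intentional when clonal events are emitted as rows)
  dup <- duplicated(variants[, c("chrom", "pos", "ref", "alt")])
  keep <- !dup | (config$clonal_as_rows & variants$alt_count == 1L)
  variants <- variants[keep, ]
  truth_tbl <- truth_tbl[keep, ]

  depth <- tibble(
    sample_id = sample_id, contig = pp$contig, pos = pp$pos, depth = depth_vec
  )
  geom <- bind_rows(geometry)
  if (nrow(geom) == 0) {
    chr_cols <- c("sample_id", "chrom", "geometry", "r1_strand",
                  "r1_sup_strand", "r2_strand", "r2_sup_strand")
    geom <- as_tibble(setNames(
      lapply(GEOMETRY_COLUMNS,
             function(x) if (x %in% chr_cols) character(0) else integer(0)),
      GEOMETRY_COLUMNS
    ))
  }
  list(
    variants = validate_variants(variants, source = sample_id),
    depth = depth,
    geometry = geom,
    truth = truth_tbl
  )
}

#' Generate junction-supporting read-pair geometry for one event
#'
#' Fragment lengths follow the event type: circle fragments are bounded above
#' by the allele length (a circle can only yield pieces of itself), while
#' tandem-duplication fragments are drawn from the library insert-size
#' distribution independent of allele length, so fragments longer than the
#' allele necessarily contain duplicated and/or flanking sequence. Most pairs
#' are emitted as discordant split alignments (primary + supplementary
#' spanning the D-A junction); a minority align concordantly and carry an
#' insert size. Fragments shorter than 142 bp receive an extra 3' soft-clip
#' mimicking adapter read-through (ignored by fragment-length inference).
#'
#' @param chrom,pos Anchor of the insertion call.
#' @param allele_length Length of the circularized/duplicated allele (>= 20).
#' @param kind `"circle"` or `"td"`.
#' @param n_fragments Number of supporting read pairs.
#' @param config A [cohort_config()] (for the insert-size distribution).
#' @param sample_id Sample name carried into the output.
#' @return Geometry tibble (one row per read pair; see
#'   [read_alignment_geometry()]).
#' @export
generate_junction_reads <- function(chrom, pos, allele_length, kind,
                                    n_fragments, config, sample_id = "s1") {
  if (allele_length < 20) abort("allele_length must be >= 20")
  L <- as.integer(allele_length)
  a <- pos + 1L          # first base of the allele copy (A)
  d <- pos + L           # last base of the allele copy (D)
  med <- config$median_insert_size
  out <- vector("list", n_fragments)
  for (f in seq_len(n_fragments)) {
    F_len <- if (kind == "circle") {
      min(L, max(50L, as.integer(round(rnorm(1, min(med, L * 0.9), 40)))))
    } else {
      max(50L, as.integer(round(rnorm(1, med, 40))))
    }
    concordant <- runif(1) < 0.15
    adapter <- if (F_len < 142L) 10L else 0L
    if (concordant) {
      c1 <- min(30L, F_len - 2L)
      out[[f]] <- tibble(
        sample_id = sample_id, chrom = chrom, pos = pos,
        geometry = "concordant",
        r1_start = a, r1_end = a + max(1L, F_len - c1) - 1L,
        r1_strand = "fwd", r1_clip5 = c1, r1_clip3 = adapter,
        r1_sup_start = NA_integer_, r1_sup_end = NA_integer_,
        r1_sup_strand = NA_character_, r1_sup_clip5 = NA_integer_,
        r2_start = a, r2_end = a + max(1L, F_len - c1) - 1L,
        r2_strand = "rev", r2_clip5 = 0L, r2_clip3 = adapter,
        r2_sup_start = NA_integer_, r2_sup_end = NA_integer_,
        r2_sup_strand = NA_character_, r2_sup_clip5 = NA_integer_,
        insert_size = F_len - c1
      )
    } else {
      # fragment wraps the D-A junction: s bases of the D side, F-s of the
      # A side. Read 1 (fwd) primary covers the D side and split-aligns its
      # junction-crossing tail; read 2 (rev) is the mirror image.
      s <- max(1L, min(as.integer(round(F_len / 2)), L - 1L, F_len - 1L))
      out[[f]] <- tibble(
        sample_id = sample_id, chrom = chrom, pos = pos,
        geometry = "discordant_split",
        r1_start = d - s + 1L, r1_end = d,
        r1_strand = "fwd", r1_clip5 = 0L, r1_clip3 = (F_len - s) + adapter,
        r1_sup_start = a, r1_sup_end = a + (F_len - s) - 1L,
        r1_sup_strand = "fwd", r1_sup_clip5 = s,
        r2_start = a, r2_end = a + (F_len - s) - 1L,
        r2_strand = "rev", r2_clip5 = 0L, r2_clip3 = s + adapter,
        r2_sup_start = d - s + 1L, r2_sup_end = d,
        r2_sup_strand = "rev", r2_sup_clip5 = F_len - s,
        insert_size = NA_integer_
      )
    }
  }
  bind_rows(out)
}

#' Simulate a full tissue cohort
#'
#' Generates every sample of one tissue from a single seed, then implants
#' cross-sample contaminant pairs: low-VAF copies (VAF ~ 0.5%) of germline
#' variants taken from another sample. Per-sample streams are keyed by
#' `(seed, sample index)` so each sample is independently reproducible.
#'
#' @param config A [cohort_config()].
#' @param panel Panel tibble; generated with [generate_panel()] if `NULL`.
#' @param seed Integer master seed.
#' @return List with `variants`, `depth`, `geometry`, `truth`, `panel`, and
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), panel = NULL, seed = 1L) {
  panel <- panel %||% generate_panel(seed = seed)
  pp <- panel_positions(panel)
  ids <- sprintf("%s%d", config$tissue, seq_len(config$n_samples))
  sims <- purrr::map2(ids, seq_along(ids), function(id, i) {
    simulate_sample(config, panel, id,
                    seed = (seed * 1009 + i * 9973) %% 2147483647L, pp = pp)
  })
  variants <- bind_rows(purrr::map(sims, "variants"))
  depth <- bind_rows(purrr::map(sims, "depth"))
  geometry <- bind_rows(purrr::map(sims, "geometry"))
  truth <- bind_rows(purrr::map(sims, "truth"))

  n_cont <- config$contaminant_pairs
  if (n_cont > 0 && config$n_samples >= 2) {
    res <- withr::with_seed(
      (seed * 31 + 17) %% 2147483647L,
      implant_contaminants(variants, truth, config, ids, n_cont)
    )
    variants <- res$variants
    truth <- res$truth
  }
  list(variants = variants, depth = depth, geometry = geometry,
       truth = truth, panel = panel, config = config)
}

implant_contaminants <- function(variants, truth, config, ids, n_cont) {
  germ <- truth %>% filter(.data$label == "germline")
  # the hotspot sample receives exactly its share; the remainder is spread
  # over the other samples
  others <- if (config$contaminant_hotspot > 0 && length(ids) > 1) ids[-1] else ids
  recipients <- c(
    rep(ids[1], config$contaminant_hotspot),
    others[sample.int(length(others), max(0, n_cont - config$contaminant_hotspot),
                      replace = TRUE)]
  )[seq_len(n_cont)]
  added_v <- list()
  added_t <- list()
  used <- paste(variants$sample_id, variants$chrom, variants$pos,
                variants$ref, variants$alt)
  for (j in seq_along(recipients)) {
    rec <- recipients[j]
    pool <- germ %>% filter(.data$sample_id != rec)
    if (nrow(pool) == 0) next
    don <- NULL
    for (try in seq_len(20)) { # redraw on key collisions within the recipient
      cand <- pool[sample.int(nrow(pool), 1), ]
      key <- paste(rec, cand$chrom, cand$pos, cand$ref, cand$alt)
      if (!key %in% used) {
        don <- cand
        used <- c(used, key)
        break
      }
    }
    if (is.null(don)) next
    dp_here <- variants$site_depth[
      variants$sample_id == rec & variants$chrom == don$chrom
    ]
    dp <- if (length(dp_here) > 0) dp_here[1] else 20000L
    ac <- max(1L, as.integer(round(0.005 * dp)))
    added_v[[length(added_v) + 1L]] <- tibble(
      sample_id = rec, chrom = don$chrom, pos = don$pos, ref = don$ref,
      alt = don$alt, vtype = "SNV", alt_count = ac, site_depth = dp,
      sv_len = NA_integer_, vaf = ac / dp
    )
    added_t[[length(added_t) + 1L]] <- tibble(
      sample_id = rec, chrom = don$chrom, pos = don$pos, ref = don$ref,
      alt = don$alt, vtype = "SNV", label = "contaminant_pair",
      alt_count = ac, allele_length = NA_integer_
    )
  }
  list(
    variants = bind_rows(variants, bind_rows(added_v)),
    truth = bind_rows(truth, bind_rows(added_t))
  )
}

#' Simulate the full two-tissue study
#'
#' Convenience wrapper producing matched blood and sperm cohorts over a shared
#' panel, with tissue recorded on every variant row.
#'
#' @param seed Integer master seed.
#' @param blood,sperm Tissue configs (defaults are the study conditions).
#' @param panel Optional shared panel.
#' @return List with combined `variants` (with a `tissue` column), `depth`,
#'   `geometry`, `truth`, `panel`, and per-tissue configs.
#' @export
simulate_study <- function(seed = 1L,
                           blood = cohort_config("blood"),
                           sperm = cohort_config("sperm"),
                           panel = NULL) {
  panel <- panel %||% generate_panel(seed = seed)
  b <- simulate_cohort(blood, panel, seed = seed)
  s <- simulate_cohort(sperm, panel, seed = (seed + 104729) %% 2147483647L)
  tag <- function(x, tis) mutate(x, tissue = tis, .after = "sample_id")
  list(
    variants = bind_rows(tag(b$variants, "blood"), tag(s$variants, "sperm")),
    depth = bind_rows(tag(b$depth, "blood"), tag(s$depth, "sperm")),
    geometry = bind_rows(tag(b$geometry, "blood"), tag(s$geometry, "sperm")),
    truth = bind_rows(tag(b$truth, "blood"), tag(s$truth, "sperm")),
    panel = panel,
    config = list(blood = blood, sperm = sperm)
  )
}
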