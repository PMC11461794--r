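# io_layer: readers/writers for variant tables, depth profiles, panel
# definitions, signature matrices and alignment-geometry records. All readers
# return validated tibbles; coordinates are 1-based inside the pipeline and
# converted from BED's 0-based half-open convention only at this boundary.

VARIANT_COLUMNS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "vtype",
  "alt_count", "site_depth", "sv_len", "vaf"
)

VTYPES <- c("SNV", "MNV", "insertion", "deletion", "inversion", "complex")

#' Infer the fine-grained variant type from allele strings
#'
#' Equal-length ref/alt of length 1 are SNVs, longer equal-length pairs MNVs.
#' Anchored length changes (alt extends ref, or ref extends alt) are
#' insertions/deletions; symbolic `<INV>` alleles are inversions; anything
#' else is complex.
#'
#' @param ref,alt Allele strings.
#' @param sv_len Optional signed SVLEN (used only for symbolic alleles).
#' @return Character vector of variant types.
#' @export
infer_vtype <- function(ref, alt, sv_len = NA_integer_) {
  dplyr::case_when(
    alt == "<INV>" ~ "inversion",
    grepl("^<DUP", alt) ~ "insertion",
    grepl("^<DEL", alt) ~ "deletion",
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    nchar(ref) == nchar(alt) ~ "MNV",
    nchar(alt) > nchar(ref) & startsWith(alt, ref) ~ "insertion",
    nchar(ref) > nchar(alt) & startsWith(ref, alt) ~ "deletion",
    TRUE ~ "complex"
  )
}

validate_variants <- function(x, source = "variant table") {
  x <- as_tibble(x)
  missing_cols <- setdiff(
    c("sample_id", "chrom", "pos", "ref", "alt", "alt_count", "site_depth"),
    names(x)
  )
  if (length(missing_cols) > 0) {
    abort(paste0(
      source, ": missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"sv_len" %in% names(x)) x$sv_len <- NA_integer_
  x$pos <- suppressWarnings(as.integer(x$pos))
  x$alt_count <- suppressWarnings(as.integer(x$alt_count))
  x$site_depth <- suppressWarnings(as.integer(x$site_depth))
  x$sv_len <- suppressWarnings(as.integer(x$sv_len))

  line_of <- function(i) paste0("line ", i + 1L) # +1 for the header line
  bad <- which(is.na(x$pos) | x$pos < 1L)
  if (length(bad) > 0) {
    abort(paste0(
      source, ": malformed coordinate at ",
      paste(line_of(head(bad, 5)), collapse = ", ")
    ))
  }
  bad <- which(is.na(x$alt_count) | x$alt_count < 1L)
  if (length(bad) > 0) {
    abort(paste0(
      source, ": alt_count must be >= 1 at ",
      paste(line_of(head(bad, 5)), collapse = ", ")
    ))
  }
  bad <- which(is.na(x$site_depth) | x$alt_count > x$site_depth)
  if (length(bad) > 0) {
    abort(paste0(
      source, ": alt_count exceeds site_depth at ",
      paste(line_of(head(bad, 5)), collapse = ", ")
    ))
  }
  if (!"vtype" %in% names(x) || all(is.na(x$vtype))) {
    x$vtype <- infer_vtype(x$ref, x$alt, x$sv_len)
  } else {
    x$vtype <- if_else(is.na(x$vtype), infer_vtype(x$ref, x$alt, x$sv_len), x$vtype)
    bad_type <- which(!x$vtype %in% VTYPES)
    if (length(bad_type) > 0) {
      abort(paste0(
        source, ": unknown vtype at ",
        paste(line_of(head(bad_type, 5)), collapse = ", ")
      ))
    }
  }
  # VAF is computed once here and carried through all downstream stages.
  x$vaf <- x$alt_count / x$site_depth
  select(x, dplyr::all_of(VARIANT_COLUMNS))
}

#' Read a consensus variant-call table
#'
#' The native dialect is a TSV with columns `sample_id`, `chrom`, `pos`
#' (1-based; the anchor base before inserted/deleted sequence), `ref`, `alt`,
#' optional `vtype`, `alt_count` (distinct duplex molecules supporting the
#' alternate allele), `site_depth` (duplex molecules at the position) and
#' optional `sv_len` (signed SVLEN-style length for SV-class calls). A minimal
#' VCF 4.x reader (INFO keys `SVLEN`/`SVTYPE`; per-sample `AD`/`DP`) is
#' provided for interchange. Variant allele frequency (`vaf`) is computed as
#' `alt_count / site_depth` at parse time.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (native) or `"vcf"`.
#' @return Tibble of validated variant calls; rows failing validation raise an
#'   error naming the offending line.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "tsv") {
    raw <- readr::read_tsv(
      path,
      col_types = readr::cols(
        sample_id = readr::col_character(),
        chrom = readr::col_character(),
        ref = readr::col_character(),
        alt = readr::col_character(),
        .default = readr::col_guess()
      ),
      progress = FALSE, show_col_types = FALSE
    )
    return(validate_variants(raw, source = path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sv_len <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
  ad <- vcfR::extract.gt(v, "AD")
  dp <- suppressWarnings(apply(vcfR::extract.gt(v, "DP"), 2, as.integer))
  samples <- colnames(ad)
  rows <- purrr::map(samples, function(s) {
    alt_count <- suppressWarnings(
      as.integer(vapply(strsplit(ad[, s], ","), function(z) z[2], character(1)))
    )
    tibble(
      sample_id = s,
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT,
      alt_count = alt_count,
      site_depth = as.integer(dp[, s]),
      sv_len = sv_len
    )
  })
  out <- bind_rows(rows) %>% filter(!is.na(.data$alt_count), .data$alt_count > 0)
  validate_variants(out, source = path)
}

#' Write a variant table in the native TSV dialect
#'
#' @param variants Variant tibble (as returned by [read_variant_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- select(
    as_tibble(variants),
    dplyr::all_of(setdiff(VARIANT_COLUMNS, "vaf"))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# panel ----------------------------------------------------------------------

#' Read a panel definition from BED + FASTA
#'
#' The BED file (0-based half-open, per the BED standard) defines the targeted
#' loci; the FASTA provides the contig sequences from which each locus
#' sequence is extracted. The BED name column encodes the locus label and its
#' genic class as `<locus_id>_<class>` with class one of `genic`,
#' `intergenic`, `mixed` (e.g. `locus01_genic`).
#'
#' @param path BED file path.
#' @param fasta FASTA file path.
#' @return Panel tibble with columns `locus_id`, `contig`, `start`, `end`
#'   (0-based half-open), `cls`, `sequence`.
#' @export
read_panel_bed <- function(path, fasta) {
  gr <- rtracklayer::import(path, format = "BED")
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  contig <- as.character(GenomeInfoDb_seqnames(gr))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  nm <- gr$name %||% paste0("locus", seq_along(gr), "_mixed")
  missing <- setdiff(unique(contig), names(seqs))
  if (length(missing) > 0) {
    abort(paste0("panel BED names contig(s) absent from FASTA: ",
                 paste(missing, collapse = ", ")))
  }
  too_long <- end0 > Biostrings::width(seqs)[match(contig, names(seqs))]
  if (any(too_long)) {
    abort(paste0("panel interval(s) extend beyond contig end: ",
                 paste(nm[too_long], collapse = ", ")))
  }
  cls <- sub("^.*_", "", nm)
  if (!all(cls %in% c("genic", "intergenic", "mixed"))) {
    warn("panel BED name column lacks a _genic/_intergenic/_mixed suffix; using 'mixed'")
    cls[!cls %in% c("genic", "intergenic", "mixed")] <- "mixed"
  }
  panel <- tibble(
    locus_id = sub("_(genic|intergenic|mixed)$", "", nm),
    contig = contig,
    start = start0,
    end = end0,
    cls = cls,
    sequence = unname(as.character(Biostrings::subseq(
      seqs[contig],
      start = start0 + 1L, end = end0
    )))
  )
  ov <- panel %>%
    group_by(.data$contig) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(overlaps = .data$start < dplyr::lag(.data$end, default = -1L)) %>%
    ungroup()
  if (any(ov$overlaps)) warn("panel contains overlapping intervals; accepted as-is")
  panel
}

# rtracklayer loads GenomeInfoDb; accessed indirectly to keep Imports small
GenomeInfoDb_seqnames <- function(gr) {
  getExportedValue("GenomeInfoDb", "seqnames")(gr)
}

#' Write a panel definition as BED + FASTA
#'
#' Inverse of [read_panel_bed()]; the FASTA contains one record per panel
#' contig.
#'
#' @param panel Panel tibble.
#' @param bed_path,fasta_path Output paths.
#' @return `bed_path`, invisibly.
#' @export
write_panel <- function(panel, bed_path, fasta_path) {
  bed <- tibble(
    chrom = panel$contig,
    start = panel$start,
    end = panel$end,
    name = paste0(panel$locus_id, "_", panel$cls),
    score = 0L,
    strand = "+"
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  # synthetic panels have one contig per locus; general panels may share one
  contig_seq <- panel %>%
    group_by(.data$contig) %>%
    summarise(seq = first(.data$sequence), .groups = "drop")
  seqs <- Biostrings::DNAStringSet(setNames(contig_seq$seq, contig_seq$contig))
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(bed_path)
}

#' Per-position reference table for a panel
#'
#' Expands a panel into one row per targeted position with the reference base,
#' its pyrimidine representation, the immediate 5'/3' neighbours (within the
#' locus; `NA` at edges) and a CpG flag (reference C followed by G, or G
#' preceded by C).
#'
#' @param panel Panel tibble.
#' @return Tibble with columns `locus_id`, `contig`, `pos` (1-based genomic),
#'   `ref`, `pyr`, `prev`, `nxt`, `is_cpg`.
#' @export
panel_positions <- function(panel) {
  purrr::pmap_dfr(
    panel[, c("locus_id", "contig", "start", "end", "sequence")],
    function(locus_id, contig, start, end, sequence) {
      b <- strsplit(sequence, "")[[1]]
      n <- length(b)
      prev <- c(NA_character_, b[-n])
      nxt <- c(b[-1], NA_character_)
      tibble(
        locus_id = locus_id,
        contig = contig,
        pos = start + seq_len(n),
        ref = b,
        pyr = if_else(b %in% c("C", "G"), "C", "T"),
        prev = prev,
        nxt = nxt,
        is_cpg = (b == "C" & !is.na(nxt) & nxt == "G") |
          (b == "G" & !is.na(prev) & prev == "C")
      )
    }
  )
}

# depth ----------------------------------------------------------------------

#' Read a per-position duplex depth profile
#'
#' TSV with columns `sample_id`, `contig`, `pos` (1-based), `depth`. All
#' positions must fall inside the panel.
#'
#' @param path Depth TSV path.
#' @param panel Panel tibble.
#' @return Depth tibble (`sample_id`, `contig`, `pos`, `depth`).
#' @export
read_depth_profile <- function(path, panel) {
  d <- readr::read_tsv(path, col_types = "ccii", progress = FALSE, show_col_types = FALSE)
  if (nrow(d) == 0) abort(paste0(path, ": no depth records"))
  pp <- panel_positions(panel)
  off <- anti_join(d, pp, by = c("contig", "pos"))
  if (nrow(off) > 0) {
    abort(paste0(
      path, ": ", nrow(off), " depth record(s) outside the panel, e.g. ",
      paste(head(paste0(off$contig, ":", off$pos), 5), collapse = ", ")
    ))
  }
  if (any(d$depth < 0)) abort(paste0(path, ": negative depth"))
  d
}

#' Write a depth profile TSV
#'
#' @param depth Depth tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_profile <- function(depth, path) {
  readr::write_tsv(depth, path, progress = FALSE)
  invisible(path)
}

#' Per-sample duplex depth totals split by reference base
#'
#' Sums per-position duplex depth into the denominators used throughout:
#' total duplex bases, depth at reference C/G positions and depth at reference
#' T/A positions. Because panel sequences are pure ACGT, the two strata always
#' add up to the total.
#'
#' @param depth Depth tibble.
#' @param panel Panel tibble.
#' @return Tibble with `sample_id`, `total_duplex_bases`, `depth_at_CG`,
#'   `depth_at_TA`.
#' @export
depth_totals <- function(depth, panel) {
  pp <- select(panel_positions(panel), "contig", "pos", "pyr")
  depth %>%
    inner_join(pp, by = c("contig", "pos")) %>%
    group_by(.data$sample_id) %>%
    summarise(
      total_duplex_bases = sum(as.numeric(.data$depth)),
      depth_at_CG = sum(as.numeric(.data$depth)[.data$pyr == "C"]),
      depth_at_TA = sum(as.numeric(.data$depth)[.data$pyr == "T"]),
      .groups = "drop"
    )
}

#' Per-locus duplex depth totals
#'
#' @param depth Depth tibble.
#' @param panel Panel tibble.
#' @return Tibble with `sample_id`, `locus_id`, `locus_bases`.
#' @export
depth_by_locus <- function(depth, panel) {
  pp <- select(panel_positions(panel), "contig", "pos", "locus_id")
  depth %>%
    inner_join(pp, by = c("contig", "pos")) %>%
    group_by(.data$sample_id, .data$locus_id) %>%
    summarise(locus_bases = sum(as.numeric(.data$depth)), .groups = "drop")
}

# signatures -----------------------------------------------------------------

#' Read a reference signature matrix (SBS96 TSV)
#'
#' Expects the conventional layout: a `Type` column of 96 context labels in
#' `A[C>A]A` style, plus one numeric column per signature; each signature
#' column must sum to 1 (within 1e-9). Rows are reordered to the canonical
#' [sbs96_contexts()] ordering.
#'
#' @param path TSV path.
#' @return Tibble with a `context` column followed by one column per
#'   signature.
#' @export
read_signature_matrix <- function(path) {
  m <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  type_col <- intersect(c("Type", "MutationType", "context"), names(m))[1]
  if (is.na(type_col)) abort(paste0(path, ": no Type/MutationType column"))
  m <- rename(m, context = dplyr::all_of(type_col))
  want <- sbs96_contexts()
  if (!setequal(m$context, want) || nrow(m) != 96) {
    abort(paste0(path, ": signature matrix must have exactly the 96 SBS contexts"))
  }
  m <- m[match(want, m$context), ]
  sums <- colSums(m[, -1, drop = FALSE])
  if (any(abs(sums - 1) > 1e-9)) {
    abort(paste0(
      path, ": signature column(s) do not sum to 1: ",
      paste(names(sums)[abs(sums - 1) > 1e-9], collapse = ", ")
    ))
  }
  m
}

# alignment geometry ---------------------------------------------------------

GEOMETRY_COLUMNS <- c(
  "sample_id", "chrom", "pos", "geometry",
  "r1_start", "r1_end", "r1_strand", "r1_clip5", "r1_clip3",
  "r1_sup_start", "r1_sup_end", "r1_sup_strand", "r1_sup_clip5",
  "r2_start", "r2_end", "r2_strand", "r2_clip5", "r2_clip3",
  "r2_sup_start", "r2_sup_end", "r2_sup_strand", "r2_sup_clip5",
  "insert_size"
)

#' Read alignment-geometry records for junction-supporting read pairs
#'
#' One row per duplex consensus read pair supporting a putative junction call
#' (keyed by `sample_id`, `chrom`, `pos` of the insertion call). Each read
#' carries its primary alignment interval, strand (`fwd`/`rev`), 5'/3'
#' soft-clip lengths and, when split-aligned, a supplementary alignment with
#' its own 5' clip. Concordant pairs (`geometry == "concordant"`) carry the
#' computed `insert_size`.
#'
#' @param path TSV path.
#' @return Geometry tibble.
#' @export
read_alignment_geometry <- function(path) {
  g <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(c(
    "sample_id", "chrom", "pos", "geometry", "r1_start", "r1_end", "r1_strand"
  ), names(g))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing geometry column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(GEOMETRY_COLUMNS, names(g))) g[[col]] <- NA
  bad <- which(g$r1_end < g$r1_start)
  if (length(bad) > 0) abort(paste0(path, ": aligned_end < aligned_start at row ", bad[1]))
  conc <- g$geometry == "concordant"
  if (any(conc & is.na(g$insert_size))) {
    abort(paste0(path, ": concordant pair without insert_size"))
  }
  select(g, dplyr::all_of(GEOMETRY_COLUMNS))
}

#' Write alignment-geometry records
#'
#' @param geometry Geometry tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_geometry <- function(geometry, path) {
  readr::write_tsv(geometry, path, progress = FALSE)
  invisible(path)
}
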