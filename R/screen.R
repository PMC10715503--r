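# Per-case second-hit screening: combine rare SV clusters, rare small
# variants, trio phasing, ROH containment and parental mosaicism evidence
# into a ranked candidate table.

#' Screening parameters
#'
#' @param sv_max_freq Maximum cohort frequency for candidate SV clusters
#'   (default 0.01, strict inequality).
#' @param window_bp Padding around the first-hit gene body within which
#'   candidates are considered ("within approximately 1 kb of the gene" is
#'   fixed at exactly 1000 bp by default; the boundary is inclusive).
#' @param weights Small-variant evidence weights ([evidence_weights()]).
#' @param mosaic_min_pct,mosaic_max_pct Range of estimated parental cell
#'   fractions flagged as possible mosaicism (defaults 10-90%; outside this
#'   range depth is consistent with absence or constitutive heterozygosity).
#' @return Named list of parameters.
#' @export
screen_params <- function(sv_max_freq = 0.01, window_bp = 1000,
                          weights = evidence_weights(),
                          mosaic_min_pct = 10, mosaic_max_pct = 90) {
  stopifnot(sv_max_freq > 0, sv_max_freq <= 1, window_bp >= 0)
  list(sv_max_freq = sv_max_freq, window_bp = window_bp, weights = weights,
       mosaic_min_pct = mosaic_min_pct, mosaic_max_pct = mosaic_max_pct)
}

#' Does an SV cluster fall in a gene's screening window?
#'
#' True iff the cluster's representative interval intersects the gene body
#' padded by `window_bp` on both sides (inclusive boundary: an SV ending
#' exactly `window_bp` before the gene start is in).
#'
#' @param clusters Cluster tibble (`chrom`, `start`, `end`).
#' @param gene One-row gene record (`chrom`, `start`, `end`).
#' @param window_bp Padding in bp (default 1000).
#' @return Logical vector over clusters.
#' @export
sv_window_overlap <- function(clusters, gene, window_bp = 1000) {
  interval_intersects(clusters$chrom, clusters$start, clusters$end,
                      gene$chrom, max(1, gene$start - window_bp),
                      gene$end + window_bp)
}

# origin of an SV cluster from its carrier set (presence/absence of the
# parents among carriers)
cluster_origin <- function(carriers, mother_id, father_id) {
  if (is.na(mother_id) || is.na(father_id)) return("UNKNOWN_NO_TRIO")
  m <- mother_id %in% carriers
  f <- father_id %in% carriers
  if (m && !f) "MATERNAL" else if (f && !m) "PATERNAL"
  else if (!m && !f) "DE_NOVO" else "AMBIGUOUS"
}

variant_origin <- function(gt, variant_id, proband, mother_id, father_id) {
  if (is.na(mother_id) || is.na(father_id)) return("UNKNOWN_NO_TRIO")
  inherited_from(gt[variant_id, proband], gt[variant_id, mother_id],
                 gt[variant_id, father_id])
}

#' Screen one case for candidate second hits
#'
#' Implements the per-case screen anchored on the first-hit gene:
#' \enumerate{
#'   \item candidate SVs: rare clusters (cohort frequency below
#'     `params$sv_max_freq`) whose representative interval falls within
#'     `window_bp` of the gene and whose carriers include the proband;
#'   \item candidate small variants: rare variants in the same window
#'     carried by the proband, excluding the first-hit variant itself;
#'   \item phasing: every candidate is phased against the first hit by trio
#'     inheritance when a trio and a first-hit variant exist;
#'   \item homozygous path: proband-homozygous rare variants lying inside a
#'     detected ROH are emitted with zygosity path `HOMOZYGOUS_IN_ROH`
#'     (promoted even when a heterozygous first hit was recorded - the
#'     recorded first hit can be misleading in consanguineous cases);
#'   \item ranking: trans/homozygous-in-ROH candidates first, then unknown
#'     phase, then cis (cis candidates are flagged, never dropped - phase
#'     can be wrong under ambiguity), with ties broken by descending
#'     evidence score and then genomic position.
#' }
#' SVs and small variants are screened in that priority order but both are
#' always reported.
#'
#' @param case One-row case record (`case_id`, `sample_id`,
#'   `first_hit_gene`, `first_hit_kind`, `first_hit_id`).
#' @param genes Gene tibble ([read_gene_bed()]); must contain the first-hit
#'   gene, else a hard error names it.
#' @param clusters SV cluster tibble with `cohort_frequency`.
#' @param variants,gt Small-variant table and genotype matrix.
#' @param pedigree Pedigree tibble ([read_ped()]).
#' @param depth Optional depth table for parental mosaic estimation.
#' @param roh_regions Optional precomputed ROH tibble for the proband
#'   (`chrom`, `start`, `end`); computed from the genotypes when `NULL`.
#' @param params [screen_params()].
#' @return Ranked candidate tibble: `case_id`, `rank`, `candidate_id`,
#'   `candidate_type`, `chrom`, `start`, `end`, `svtype`, `zygosity_path`,
#'   `phase`, `origin`, `first_hit_origin`, `rank_score`, `in_roh`,
#'   `mosaic_mother_pct`, `mosaic_father_pct`, `notes`.
#' @export
screen_case <- function(case, genes, clusters, variants, gt, pedigree,
                        depth = NULL, roh_regions = NULL,
                        params = screen_params()) {
  gene <- dplyr::filter(genes, .data$symbol == case$first_hit_gene)
  if (nrow(gene) != 1) {
    stop("first-hit gene not found in annotation: ", case$first_hit_gene,
         call. = FALSE)
  }
  prob <- case$sample_id
  ped_row <- dplyr::filter(pedigree, .data$sample_id == prob)
  mother_id <- if (nrow(ped_row)) ped_row$mother_id[1] else NA_character_
  father_id <- if (nrow(ped_row)) ped_row$father_id[1] else NA_character_
  has_trio <- !is.na(mother_id) && !is.na(father_id)
  w_start <- max(1, gene$start - params$window_bp)
  w_end <- gene$end + params$window_bp

  first_hit_origin <- if (has_trio &&
                          identical(case$first_hit_kind, "small_variant") &&
                          !is.na(case$first_hit_id) &&
                          case$first_hit_id %in% rownames(gt) &&
                          gt[case$first_hit_id, prob] > 0L) {
    variant_origin(gt, case$first_hit_id, prob, mother_id, father_id)
  } else {
    NA_character_
  }

  ## step 1: rare SV clusters in the window carried by the proband
  sv_cand <- rare_clusters(clusters, params$sv_max_freq)
  sv_cand <- sv_cand[sv_window_overlap(sv_cand, gene, params$window_bp), ]
  sv_cand <- dplyr::filter(sv_cand,
                           purrr::map_lgl(.data$carriers, ~ prob %in% .x))
  sv_rows <- purrr::map(seq_len(nrow(sv_cand)), function(i) {
    cl <- sv_cand[i, ]
    origin <- if (has_trio) {
      cluster_origin(cl$carriers[[1]], mother_id, father_id)
    } else "UNKNOWN_NO_TRIO"
    phase <- if (!is.na(first_hit_origin)) {
      phase_pair(first_hit_origin, origin)
    } else if (!has_trio) "NOT_APPLICABLE" else "UNKNOWN"
    mm <- mf <- NA_real_
    notes <- character()
    if (!is.null(depth) && cl$svtype == "DEL" && has_trio) {
      em <- estimate_mosaic(depth, mother_id, cl)
      ef <- estimate_mosaic(depth, father_id, cl)
      mm <- em$fraction_pct; mf <- ef$fraction_pct
      for (nm in c("mother", "father")) {
        v <- if (nm == "mother") mm else mf
        if (!is.na(v) && v >= params$mosaic_min_pct && v <= params$mosaic_max_pct) {
          notes <- c(notes, sprintf("possible %s mosaicism (%.0f%% of cells)", nm, v))
        }
      }
    }
    tibble::tibble(
      candidate_id = cl$cluster_id, candidate_type = "sv_cluster",
      chrom = cl$chrom, start = cl$start, end = cl$end, svtype = cl$svtype,
      zygosity_path = "COMPOUND_HET", phase = phase, origin = origin,
      rank_score = 0, in_roh = FALSE,
      mosaic_mother_pct = mm, mosaic_father_pct = mf,
      notes = paste(notes, collapse = "; "))
  }) |> purrr::list_rbind()

  ## steps 2+4: rare small variants in the window (first hit excluded)
  v_window <- variants |>
    dplyr::filter(.data$chrom == gene$chrom, .data$pos >= w_start,
                  .data$pos <= w_end)
  v_rare <- filter_rare_small(v_window, gt, prob, params$weights)
  if (!is.na(case$first_hit_id)) {
    v_rare <- dplyr::filter(v_rare, .data$variant_id != case$first_hit_id)
  }
  # ROH detection is only needed once a candidate variant exists; most
  # cases have none, so it is computed lazily
  if (is.null(roh_regions) && nrow(v_rare) > 0) {
    roh_regions <- roh_for_sample(variants, gt, prob)
  }
  snv_rows <- purrr::map(seq_len(nrow(v_rare)), function(i) {
    v <- v_rare[i, ]
    g <- gt[v$variant_id, prob]
    roh_hit <- containing_roh(roh_regions,
                              list(chrom = v$chrom, start = v$pos, end = v$pos))
    hom_in_roh <- g == 2L && nrow(roh_hit) == 1
    origin <- if (has_trio && g == 1L) {
      variant_origin(gt, v$variant_id, prob, mother_id, father_id)
    } else NA_character_
    phase <- if (hom_in_roh) {
      "NOT_APPLICABLE"
    } else if (!has_trio) {
      "NOT_APPLICABLE"
    } else if (!is.na(first_hit_origin) && !is.na(origin)) {
      phase_pair(first_hit_origin, origin)
    } else "UNKNOWN"
    notes <- character()
    if (g == 2L) notes <- c(notes, "homozygous in proband")
    if (hom_in_roh) {
      notes <- c(notes, sprintf("inside %.1f Mb ROH (%s:%d-%d)",
                                (roh_hit$end - roh_hit$start) / 1e6,
                                roh_hit$chrom, roh_hit$start, roh_hit$end))
    }
    if (!is.na(v$ag) || !is.na(v$al) || !is.na(v$dg) || !is.na(v$dl)) {
      mx <- max(c(v$ag, v$al, v$dg, v$dl), na.rm = TRUE)
      notes <- c(notes, sprintf("splice delta max %.2f", mx))
    }
    tibble::tibble(
      candidate_id = v$variant_id, candidate_type = "small_variant",
      chrom = v$chrom, start = v$pos, end = v$pos, svtype = NA_character_,
      zygosity_path = if (hom_in_roh) "HOMOZYGOUS_IN_ROH" else "COMPOUND_HET",
      phase = phase,
      origin = if (is.na(origin)) NA_character_ else origin,
      rank_score = v$rank_score, in_roh = nrow(roh_hit) == 1,
      mosaic_mother_pct = NA_real_, mosaic_father_pct = NA_real_,
      notes = paste(notes, collapse = "; "))
  }) |> purrr::list_rbind()

  cand <- dplyr::bind_rows(sv_rows, snv_rows)
  if (is.null(cand) || nrow(cand) == 0) {
    return(tibble::tibble(
      case_id = character(), rank = integer(), candidate_id = character(),
      candidate_type = character(), chrom = character(), start = integer(),
      end = integer(), svtype = character(), zygosity_path = character(),
      phase = character(), origin = character(),
      first_hit_origin = character(), rank_score = double(),
      in_roh = logical(), mosaic_mother_pct = double(),
      mosaic_father_pct = double(), notes = character()))
  }
  tier <- dplyr::case_when(
    cand$zygosity_path == "HOMOZYGOUS_IN_ROH" ~ 1L,
    cand$phase == "TRANS" ~ 1L,
    cand$phase == "CIS" ~ 3L,
    TRUE ~ 2L)
  cand |>
    dplyr::mutate(case_id = case$case_id,
                  first_hit_origin = first_hit_origin,
                  .tier = tier) |>
    dplyr::arrange(.data$.tier, dplyr::desc(.data$rank_score), .data$chrom,
                   .data$start, .data$candidate_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("case_id", "rank", "candidate_id", "candidate_type",
                  "chrom", "start", "end", "svtype", "zygosity_path",
                  "phase", "origin", "first_hit_origin", "rank_score",
                  "in_roh", "mosaic_mother_pct", "mosaic_father_pct",
                  "notes")
}

#' Screen every analysable case of a cohort
#'
#' Runs [screen_case()] for each correctly recruited case with a first-hit
#' gene; ROH detection runs on a proband's marker genotypes whenever that
#' case yields candidate variants.
#'
#' @param cases Case manifest tibble.
#' @param genes,clusters,variants,gt,pedigree,depth,params As in
#'   [screen_case()].
#' @return An object of class `secondhit_screen` with elements
#'   `candidates` (all candidate rows), `cases` (the screened subset) and
#'   `params`. Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and `print()`.
#' @export
screen_cohort <- function(cases, genes, clusters, variants, gt, pedigree,
                          depth = NULL, params = screen_params()) {
  todo <- dplyr::filter(cases, .data$recruitment_status == "correctly_recruited",
                        !is.na(.data$first_hit_gene))
  cand <- purrr::map(seq_len(nrow(todo)), function(i) {
    screen_case(todo[i, ], genes, clusters, variants, gt, pedigree, depth,
                params = params)
  }) |> purrr::list_rbind()
  structure(list(candidates = cand, cases = todo, params = params),
            class = "secondhit_screen")
}

#' @export
print.secondhit_screen <- function(x, ...) {
  cat("Second-hit screen:", nrow(x$cases), "cases,",
      nrow(x$candidates), "candidates in",
      dplyr::n_distinct(x$candidates$case_id), "cases\n")
  invisible(x)
}
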