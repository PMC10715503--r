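# Cross-caller, cross-sample SV aggregation: calls tibbles have columns
# sample_id, caller, svtype, chrom, start, end, ins_length, genotype, qual.

#' Default SV matching parameters
#'
#' @param ro_threshold Minimum reciprocal overlap for non-insertion SVs
#'   (default 0.8, i.e. "80% overlap", so that slight differences in
#'   breakpoint calling of the same variant are tolerated).
#' @param ins_tol_bp Maximum breakpoint distance for two insertions to match
#'   (default 50 bp). Reciprocal overlap is undefined for point insertions,
#'   so insertions match on breakpoint proximity and length similarity
#'   instead.
#' @param ins_len_tol Maximum relative length difference for insertions
#'   (default 0.2: the shorter length must be at least 80% of the longer).
#' @return A named list of parameters.
#' @export
sv_match_params <- function(ro_threshold = 0.8, ins_tol_bp = 50, ins_len_tol = 0.2) {
  stopifnot(ro_threshold >= 0, ro_threshold <= 1, ins_tol_bp >= 0,
            ins_len_tol >= 0, ins_len_tol <= 1)
  list(ro_threshold = ro_threshold, ins_tol_bp = ins_tol_bp,
       ins_len_tol = ins_len_tol)
}

#' Do two SV calls describe the same variant?
#'
#' Non-insertion calls match when they share `svtype` and achieve at least
#' `ro_threshold` reciprocal overlap. Insertions match when their
#' breakpoints lie within `ins_tol_bp` and their inserted lengths agree to
#' within `ins_len_tol` (ratio of shorter to longer >= 1 - tol). Mixed
#' INS/non-INS comparisons are `FALSE`, never an error. Vectorised over
#' rows of equal-length call tibbles.
#'
#' @param a,b Data frames of SV calls (recycled rowwise if one has one row).
#' @param params Matching parameters from [sv_match_params()].
#' @return Logical vector.
#' @export
calls_match <- function(a, b, params = sv_match_params()) {
  same_type <- a$svtype == b$svtype & a$chrom == b$chrom
  is_ins <- a$svtype == "INS" | b$svtype == "INS"
  out <- logical(max(nrow(a), nrow(b)))
  non_ins <- same_type & !is_ins
  if (any(non_ins)) {
    ro <- reciprocal_overlap(a$chrom, a$start, a$end, b$chrom, b$start, b$end)
    out[non_ins] <- ro[non_ins] >= params$ro_threshold
  }
  both_ins <- same_type & a$svtype == "INS" & b$svtype == "INS"
  if (any(both_ins)) {
    bp_ok <- abs(a$start - b$start) <= params$ins_tol_bp
    len_ratio <- pmin(a$ins_length, b$ins_length) / pmax(a$ins_length, b$ins_length)
    out[both_ins] <- (bp_ok & len_ratio >= 1 - params$ins_len_tol)[both_ins]
  }
  out
}

# lower median: ties toward the smaller coordinate
median_lo <- function(x) sort(x)[floor((length(x) + 1) / 2)]

#' Cluster SV calls across samples and callers
#'
#' Partitions calls into single-linkage connected components under
#' [calls_match()]: two calls land in the same cluster when they are
#' connected by a chain of pairwise matches, so the same true variant
#' reported by different callers (or in different samples) with jittered
#' breakpoints aggregates into one cluster. Candidate pairs are found with
#' an interval-overlap index ([IRanges::findOverlaps()]) and components are
#' taken with [igraph::components()].
#'
#' @param calls SV call tibble (see [read_sv_vcf()]).
#' @param params Matching parameters from [sv_match_params()].
#' @return Tibble of clusters ordered by (chrom, start, svtype):
#'   `cluster_id`, `chrom`, `start`, `end` (representative interval:
#'   per-coordinate lower median of members), `svtype`, `ins_length`
#'   (median, insertions only), `n_carriers`, `carriers` (list column of
#'   sample ids), `members` (list column of member call rows).
#' @export
cluster_sv_calls <- function(calls, params = sv_match_params()) {
  empty <- tibble::tibble(
    cluster_id = character(), chrom = character(), start = integer(),
    end = integer(), svtype = character(), ins_length = integer(),
    n_carriers = integer(), carriers = list(), members = list())
  if (nrow(calls) == 0) return(empty)
  n <- nrow(calls)
  edge_parts <- list()
  for (idx in split(seq_len(n), paste(calls$chrom, calls$svtype))) {
    sub <- calls[idx, , drop = FALSE]
    maxgap <- if (sub$svtype[1] == "INS") params$ins_tol_bp else -1L
    ir <- IRanges::IRanges(start = sub$start, end = sub$end)
    hits <- IRanges::findOverlaps(ir, maxgap = maxgap, drop.self = TRUE,
                                  drop.redundant = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (!length(qi)) next
    ok <- calls_match(sub[qi, , drop = FALSE], sub[si, , drop = FALSE], params)
    if (any(ok)) {
      edge_parts[[length(edge_parts) + 1L]] <- rbind(idx[qi[ok]], idx[si[ok]])
    }
  }
  edges <- if (length(edge_parts)) as.vector(do.call(cbind, edge_parts)) else integer()
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- calls |>
    dplyr::mutate(.comp = comp) |>
    dplyr::group_by(.data$.comp) |>
    dplyr::summarise(
      # members must be captured before the coordinate columns are
      # overwritten by their summaries
      members = list(dplyr::pick(dplyr::everything())),
      n_carriers = dplyr::n_distinct(.data$sample_id),
      carriers = list(sort(unique(.data$sample_id))),
      chrom = .data$chrom[1],
      start = median_lo(.data$start),
      end = median_lo(.data$end),
      svtype = .data$svtype[1],
      ins_length = if (.data$svtype[1] == "INS") {
        median_lo(.data$ins_length)
      } else NA_integer_,
      .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "svtype", "ins_length",
                  "n_carriers", "carriers", "members", ".comp") |>
    dplyr::select(-".comp") |>
    dplyr::arrange(.data$chrom, .data$start, .data$svtype)
  dplyr::mutate(clusters,
                cluster_id = sprintf("SVC%05d", dplyr::row_number()),
                .before = 1)
}

#' Cohort carrier frequency of SV clusters
#'
#' Frequency is the fraction of *participants* carrying the cluster
#' (heterozygous and homozygous carriers each count once), not an allele
#' frequency.
#'
#' @param clusters Cluster tibble from [cluster_sv_calls()].
#' @param n_participants Total participants in the cohort; must be >= the
#'   largest carrier count and > 0.
#' @return `clusters` with a `cohort_frequency` column.
#' @export
cohort_frequency <- function(clusters, n_participants) {
  if (length(n_participants) != 1 || n_participants <= 0) {
    stop("n_participants must be a single positive count", call. = FALSE)
  }
  if (any(clusters$n_carriers > n_participants)) {
    stop("n_participants is smaller than a cluster's carrier count", call. = FALSE)
  }
  dplyr::mutate(clusters, cohort_frequency = .data$n_carriers / n_participants)
}

#' Keep rare SV clusters
#'
#' Strict inequality: a cluster is kept iff its cohort frequency is
#' *below* `max_freq` (default 1%); a cluster at exactly the threshold is
#' dropped. Input order is preserved.
#'
#' @param clusters Cluster tibble with `cohort_frequency`.
#' @param max_freq Rarity threshold (default 0.01).
#' @return The rare subset.
#' @export
rare_clusters <- function(clusters, max_freq = 0.01) {
  dplyr::filter(clusters, .data$cohort_frequency < max_freq)
}

#' Write a cluster table to TSV
#'
#' Emits the flat columns plus a comma-separated carrier list.
#' @param clusters Cluster tibble (frequency column optional).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path) {
  flat <- clusters |>
    dplyr::mutate(carriers = purrr::map_chr(.data$carriers, paste, collapse = ",")) |>
    dplyr::select(dplyr::any_of(c("cluster_id", "chrom", "start", "end", "svtype",
                                  "ins_length", "n_carriers", "cohort_frequency",
                                  "carriers")))
  readr::write_tsv(flat, path)
  invisible(path)
}
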