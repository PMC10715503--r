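# Synthetic cohort generator. Produces, from one seed, a complete trio
# cohort (SV calls per caller, small-variant genotypes, pedigree, gene
# models, depth summaries) with planted second-hit truth, so that the whole
# screen is testable end-to-end without access-controlled data.

PLANTED_KINDS <- c("second_hit_SV", "second_hit_intronic_SNV",
                   "homozygous_in_ROH", "mosaic_parent_SV")

mk_empty_sv_calls <- function() {
  tibble::tibble(sample_id = character(), caller = character(),
                 svtype = character(), chrom = character(), start = integer(),
                 end = integer(), ins_length = integer(),
                 genotype = character(), qual = double())
}

#' Configuration for the synthetic cohort
#'
#' Defaults describe the study conditions the generator emulates: trio
#' families recruited with one known heterozygous first-hit variant, two SV
#' callers reporting the same true SV with independently jittered
#' breakpoints, a background SV frequency spectrum spanning common (>1%)
#' and rare (<1%) clusters, planted compound-heterozygous second hits
#' genuinely in trans, one mosaic parental deletion, and
#' consanguinity-style runs of homozygosity.
#'
#' @param n_families Number of trio families (default 200).
#' @param n_background_sv_clusters Background SV clusters segregating in
#'   the cohort (default 30).
#' @param background_freq_spectrum Carrier fractions for background
#'   clusters, recycled across clusters; the default mixes common and rare.
#' @param breakpoint_jitter_sd SD (bp) of the rounded-Normal breakpoint
#'   jitter applied independently per caller (default 20).
#' @param caller_dropout_prob Probability that one caller misses a true
#'   call (default 0.05). For true variants at least one caller always
#'   reports each carrier: a variant missed by every caller would simply
#'   not be in the callset, which is a different (unmodelled) failure mode.
#' @param n_planted_cases Families carrying a planted second hit (default 10).
#' @param planted_kinds Character vector of length `n_planted_cases` over
#'   `second_hit_SV`, `second_hit_intronic_SNV`, `homozygous_in_ROH`,
#'   `mosaic_parent_SV`.
#' @param roh_length_mb Length of planted ROH blocks (default 10 Mb,
#'   within the 9-20 Mb scale typical of consanguinity-related findings).
#' @param mosaic_fraction True cell fraction of the mosaic parental
#'   deletion (default 0.44).
#' @param mean_depth Mean sequencing depth emulated in depth summaries
#'   (default 60x).
#' @param genotype_error_rate Heterozygote contamination rate inside ROH
#'   blocks (default 0.005).
#' @param marker_spacing_bp Spacing of common marker sites used for ROH
#'   detection (default 25 kb).
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(n_families = 200,
                       n_background_sv_clusters = 30,
                       background_freq_spectrum = c(0.05, 0.03, 0.02, 0.012,
                                                    0.008, 0.005, 0.003,
                                                    0.002, 0.001, 0.0005),
                       breakpoint_jitter_sd = 20,
                       caller_dropout_prob = 0.05,
                       n_planted_cases = 10,
                       planted_kinds = c(rep("second_hit_SV", 4),
                                         rep("second_hit_intronic_SNV", 3),
                                         rep("homozygous_in_ROH", 2),
                                         "mosaic_parent_SV"),
                       roh_length_mb = 10,
                       mosaic_fraction = 0.44,
                       mean_depth = 60,
                       genotype_error_rate = 0.005,
                       marker_spacing_bp = 25e3,
                       seed = 1) {
  stopifnot(n_families >= 1, n_background_sv_clusters >= 0,
            all(background_freq_spectrum > 0 & background_freq_spectrum < 1),
            breakpoint_jitter_sd >= 0,
            caller_dropout_prob >= 0, caller_dropout_prob <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            mosaic_fraction >= 0, mosaic_fraction <= 1,
            mean_depth > 0, roh_length_mb > 0)
  if (n_planted_cases > n_families) {
    stop("n_planted_cases exceeds n_families", call. = FALSE)
  }
  if (length(planted_kinds) != n_planted_cases) {
    stop("planted_kinds must have length n_planted_cases", call. = FALSE)
  }
  if (!all(planted_kinds %in% PLANTED_KINDS)) {
    stop("unknown planted kind(s): ",
         paste(setdiff(planted_kinds, PLANTED_KINDS), collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_families = as.integer(n_families),
    n_background_sv_clusters = as.integer(n_background_sv_clusters),
    background_freq_spectrum = background_freq_spectrum,
    breakpoint_jitter_sd = breakpoint_jitter_sd,
    caller_dropout_prob = caller_dropout_prob,
    n_planted_cases = as.integer(n_planted_cases),
    planted_kinds = planted_kinds,
    roh_length_mb = roh_length_mb,
    mosaic_fraction = mosaic_fraction,
    mean_depth = mean_depth,
    genotype_error_rate = genotype_error_rate,
    marker_spacing_bp = marker_spacing_bp,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Two synthetic 250 Mb chromosomes; genes on a fixed grid so they never
# overlap.
sim_chroms <- function() c(chr1 = 250e6, chr2 = 250e6)

sim_genes <- function(n_per_chrom = 20) {
  chroms <- names(sim_chroms())
  rows <- purrr::map(seq_along(chroms), function(ci) {
    purrr::map(seq_len(n_per_chrom), function(k) {
      base <- 5e6 + (k - 1) * 12e6
      start <- as.integer(base + round(stats::runif(1, 0, 1e6)))
      len <- as.integer(round(stats::runif(1, 60e3, 180e3)))
      n_ex <- sample(10:30, 1)
      segw <- len %/% n_ex
      ex_size <- sample(100:300, n_ex, replace = TRUE)
      ex_start <- start + (seq_len(n_ex) - 1L) * segw
      exons <- tibble::tibble(start = as.integer(ex_start),
                              end = as.integer(ex_start + ex_size - 1L))
      tibble::tibble(
        gene_id = NA_character_, symbol = NA_character_, chrom = chroms[ci],
        start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1), exons = list(exons))
    }) |> purrr::list_rbind()
  })
  genes <- purrr::list_rbind(rows)
  genes$symbol <- sprintf("GENE%03d", seq_len(nrow(genes)))
  genes$gene_id <- genes$symbol
  genes
}

#' Jitter an SV call's breakpoints
#'
#' Start and end are shifted independently by rounded Normal(0, sd) noise,
#' emulating caller-to-caller breakpoint discrepancies for the same true
#' variant. Coordinate ordering is repaired (swap if inverted) and the
#' start clamped to >= 1; insertions keep their point-like locus (only the
#' breakpoint moves). SV type is preserved.
#'
#' @param sv One-row data frame (or list) with `svtype`, `chrom`, `start`,
#'   `end` (and `ins_length` for insertions).
#' @param sd Jitter standard deviation in bp, >= 0.
#' @return The jittered call as a one-row tibble.
#' @export
jitter_call <- function(sv, sd) {
  stopifnot(sd >= 0)
  out <- tibble::as_tibble(sv[c("svtype", "chrom", "start", "end",
                                intersect("ins_length", names(sv)))])
  if (sv$svtype == "INS") {
    s <- as.integer(sv$start + round(stats::rnorm(1, 0, sd)))
    out$start <- max(1L, s)
    out$end <- out$start
  } else {
    s <- as.integer(sv$start + round(stats::rnorm(1, 0, sd)))
    e <- as.integer(sv$end + round(stats::rnorm(1, 0, sd)))
    if (s > e) { tmp <- s; s <- e; e <- tmp }
    out$start <- max(1L, s)
    out$end <- max(out$start, e)
  }
  out
}

# calls for one true SV across its carriers and both callers; at least one
# caller reports each carrier (vectorised over carriers x callers)
emit_sv_calls <- function(sv, carriers, genotypes, cfg) {
  k <- length(carriers)
  keep <- matrix(stats::runif(2 * k) >= cfg$caller_dropout_prob, nrow = k)
  both_dropped <- !keep[, 1] & !keep[, 2]
  if (any(both_dropped)) {
    rescue <- sample(c(1L, 2L), sum(both_dropped), replace = TRUE)
    keep[cbind(which(both_dropped), rescue)] <- TRUE
  }
  carrier_idx <- rep(seq_len(k), 2)[as.vector(keep)]
  caller <- rep(c("callerA", "callerB"), each = k)[as.vector(keep)]
  n <- length(carrier_idx)
  sd <- cfg$breakpoint_jitter_sd
  if (sv$svtype == "INS") {
    start <- pmax(1L, as.integer(sv$start + round(stats::rnorm(n, 0, sd))))
    end <- start
    ins_length <- pmax(1L, as.integer(sv$ins_length +
                                        round(stats::rnorm(n, 0, sd))))
  } else {
    s <- as.integer(sv$start + round(stats::rnorm(n, 0, sd)))
    e <- as.integer(sv$end + round(stats::rnorm(n, 0, sd)))
    start <- pmax(1L, pmin(s, e))
    end <- pmax(start, pmax(s, e))
    ins_length <- rep(NA_integer_, n)
  }
  tibble::tibble(
    sample_id = carriers[carrier_idx], caller = caller,
    svtype = sv$svtype, chrom = sv$chrom, start = start, end = end,
    ins_length = ins_length, genotype = genotypes[carrier_idx],
    qual = round(stats::runif(n, 30, 99)))
}

#' Per-region mean depth under a mosaic heterozygous deletion
#'
#' Draws the mean depth of a region of `region_bp` bases as a scaled
#' Poisson total: `Poisson(mean_depth * region_bp * (1 - f/2)) / region_bp`
#' for a heterozygous deletion present in a cell fraction `f` (`f = 0`
#' outside deletions, `f = 1` for a constitutive het deletion).
#'
#' @param f True cell fraction in \[0, 1\].
#' @param mean_depth Diploid mean depth.
#' @param region_bp Region length in bp.
#' @param n Number of independent draws.
#' @return Numeric vector of mean depths.
#' @export
simulate_region_depth <- function(f, mean_depth, region_bp, n = 1) {
  stopifnot(f >= 0, f <= 1, mean_depth > 0, region_bp >= 1)
  stats::rpois(n, mean_depth * region_bp * (1 - f / 2)) / region_bp
}

#' Simulate one chromosome of marker genotypes with an ROH block
#'
#' Marker sites at regular spacing carry Hardy-Weinberg genotypes outside
#' the block; inside the block the sample is homozygous apart from
#' heterozygote contamination at `het_error`.
#'
#' @param block_start,block_end ROH block coordinates (bp); use `NULL` for
#'   no block.
#' @param chrom_length Chromosome length (default 250 Mb).
#' @param spacing_bp Marker spacing (default 25 kb).
#' @param het_error Heterozygote contamination rate inside the block.
#' @return Tibble with `pos`, `gt` (allele counts) sorted by position.
#' @export
simulate_roh_sites <- function(block_start, block_end, chrom_length = 250e6,
                               spacing_bp = 25e3, het_error = 0.005) {
  pos <- as.integer(seq(spacing_bp / 2, chrom_length, by = spacing_bp))
  maf <- stats::runif(length(pos), 0.1, 0.5)
  gt <- stats::rbinom(length(pos), 1, maf) + stats::rbinom(length(pos), 1, maf)
  if (!is.null(block_start)) {
    inside <- pos >= block_start & pos <= block_end
    hom_allele <- stats::rbinom(sum(inside), 1, maf[inside])
    gt[inside] <- 2L * hom_allele
    err <- stats::runif(sum(inside)) < het_error
    gt[inside][err] <- 1L
  }
  tibble::tibble(pos = pos, gt = as.integer(gt))
}

#' Simulate a synthetic trio cohort with planted second hits
#'
#' Generates, deterministically from `config$seed`: trio pedigrees; common
#' marker genotypes (Mendelian within each trio) with consanguinity-style
#' ROH blocks for the planted homozygous cases; per-family novel first-hit
#' variants; planted second hits genuinely in trans (the two variants of a
#' pair always descend from different parents); background SV clusters
#' realised at their configured carrier fractions; two callers reporting
#' each true SV with independent breakpoint jitter and dropout; one mosaic
#' parental deletion reflected in the depth table but genotyped
#' heterozygous; and a truth table describing every planted case.
#'
#' @param config A [sim_config()].
#' @return A list of class `secondhit_cohort`: `config`, `genes`,
#'   `pedigree`, `sv_calls`, `variants`, `gt`, `depth`, `cases`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sim_chroms()
  genes <- sim_genes()
  nf <- config$n_families
  fams <- sprintf("F%03d", seq_len(nf))
  proband <- paste0(fams, "_P"); mother <- paste0(fams, "_M")
  father <- paste0(fams, "_F")
  samples <- as.vector(rbind(proband, mother, father))
  pedigree <- tibble::tibble(
    sample_id = c(proband, mother, father),
    family_id = rep(fams, 3),
    father_id = c(father, rep(NA_character_, 2 * nf)),
    mother_id = c(mother, rep(NA_character_, 2 * nf)),
    sex = c(sample(1:2, nf, replace = TRUE), rep(2L, nf), rep(1L, nf)),
    affected = c(rep(2L, nf), rep(1L, 2 * nf)))

  ## ---- planted case plan ----------------------------------------------
  planted_fam_idx <- seq_len(config$n_planted_cases)
  planted_genes <- sample(nrow(genes), config$n_planted_cases)
  plan <- tibble::tibble(
    fam_idx = planted_fam_idx, kind = config$planted_kinds,
    gene_row = planted_genes)
  # transmitting parent of the first hit; the second hit comes from the
  # other parent (trans by construction). Mosaic deletions are paternal,
  # so the mosaic case's first hit is maternal.
  plan$first_parent <- sample(c("M", "F"), nrow(plan), replace = TRUE)
  plan$first_parent[plan$kind == "mosaic_parent_SV"] <- "M"
  # one ROH case is recruited on the ROH alone, without a first-hit variant
  roh_rows <- which(plan$kind == "homozygous_in_ROH")
  plan$roh_only <- FALSE
  if (length(roh_rows)) plan$roh_only[roh_rows[1]] <- TRUE

  ## ---- marker genotypes (Mendelian trios, ROH blocks) ------------------
  marker_pos <- purrr::imap(chroms, function(len, ch) {
    tibble::tibble(chrom = ch,
                   pos = as.integer(seq(config$marker_spacing_bp / 2, len,
                                        by = config$marker_spacing_bp)))
  }) |> purrr::list_rbind()
  ns <- nrow(marker_pos)
  maf <- stats::runif(ns, 0.1, 0.5)
  draw <- function() matrix(stats::rbinom(ns * nf, 1, maf), nrow = ns)
  m1 <- draw(); m2 <- draw(); f1 <- draw(); f2 <- draw()
  c_m <- m1; sw <- which(stats::runif(ns * nf) < 0.5); c_m[sw] <- m2[sw]
  c_f <- f1; sw <- which(stats::runif(ns * nf) < 0.5); c_f[sw] <- f2[sw]

  roh_truth <- list()
  for (r in seq_len(nrow(plan))) {
    if (plan$kind[r] != "homozygous_in_ROH") next
    g <- genes[plan$gene_row[r], ]
    centre <- (g$start + g$end) / 2
    half <- config$roh_length_mb * 1e6 / 2
    b_start <- max(1, round(centre - half))
    b_end <- min(chroms[[g$chrom]], round(centre + half))
    j <- plan$fam_idx[r]
    idx <- which(marker_pos$chrom == g$chrom & marker_pos$pos >= b_start &
                   marker_pos$pos <= b_end)
    h <- stats::rbinom(length(idx), 1, maf[idx])
    m1[idx, j] <- h; f1[idx, j] <- h
    c_m[idx, j] <- h; c_f[idx, j] <- h
    err <- which(stats::runif(length(idx)) < config$genotype_error_rate)
    if (length(err)) {
      # heterozygote contamination: flip one child allele at error sites
      c_m[idx[err], j] <- 1L - c_m[idx[err], j]
    }
    roh_truth[[length(roh_truth) + 1]] <- tibble::tibble(
      fam_idx = j, roh_chrom = g$chrom, roh_start = as.integer(b_start),
      roh_end = as.integer(b_end))
  }
  roh_truth <- if (length(roh_truth)) purrr::list_rbind(roh_truth) else
    tibble::tibble(fam_idx = integer(), roh_chrom = character(),
                   roh_start = integer(), roh_end = integer())

  marker_gt <- matrix(0L, nrow = ns, ncol = 3 * nf)
  colnames(marker_gt) <- samples
  marker_gt[, proband] <- c_m + c_f
  marker_gt[, mother] <- m1 + m2
  marker_gt[, father] <- f1 + f2

  marker_variants <- tibble::tibble(
    chrom = marker_pos$chrom, pos = marker_pos$pos,
    ref = "A", alt = "G",
    af_1000g = round(maf, 4),
    af_gnomad = round(pmin(0.999, pmax(0.001, maf + stats::rnorm(ns, 0, 0.01))), 4),
    cadd_phred = NA_real_, ag = NA_real_, al = NA_real_, dg = NA_real_,
    dl = NA_real_)

  ## ---- per-family first hits and planted small variants ----------------
  gene_for_fam <- integer(nf)
  gene_for_fam[plan$fam_idx] <- plan$gene_row
  unplanted <- setdiff(seq_len(nf), plan$fam_idx)
  gene_for_fam[unplanted] <- sample(nrow(genes), length(unplanted), replace = TRUE)

  used_pos <- new.env(parent = emptyenv())
  fresh_pos <- function(chrom, pos0) {
    p <- as.integer(pos0)
    repeat {
      key <- paste0(chrom, ":", p)
      if (is.null(used_pos[[key]])) { used_pos[[key]] <- TRUE; return(p) }
      p <- p + 1L
    }
  }
  # marker positions are never reused for planted variants
  for (k in paste0(marker_pos$chrom, ":", marker_pos$pos)) used_pos[[k]] <- TRUE

  extra_var <- list(); extra_gt <- list()
  add_variant <- function(chrom, pos, carriers_gt, cadd = NA_real_,
                          ag = NA_real_, al = NA_real_, dg = NA_real_,
                          dl = NA_real_) {
    pos <- fresh_pos(chrom, pos)
    row <- integer(3 * nf)
    names(row) <- samples
    row[names(carriers_gt)] <- carriers_gt
    extra_var[[length(extra_var) + 1L]] <<- tibble::tibble(
      chrom = chrom, pos = pos, ref = "C", alt = "T",
      af_1000g = NA_real_, af_gnomad = NA_real_, cadd_phred = cadd,
      ag = ag, al = al, dg = dg, dl = dl)
    extra_gt[[length(extra_gt) + 1L]] <<- row
    paste(chrom, pos, "C", "T", sep = ":")
  }

  plan$first_hit_id <- NA_character_
  first_hit_kind <- rep("small_variant", nf)
  first_hit_id <- rep(NA_character_, nf)
  for (j in seq_len(nf)) {
    r <- match(j, plan$fam_idx)
    if (!is.na(r) && plan$roh_only[r]) {
      first_hit_kind[j] <- "ROH_only"
      next
    }
    g <- genes[gene_for_fam[j], ]
    ex <- g$exons[[1]]
    parent <- if (!is.na(r)) plan$first_parent[r] else sample(c("M", "F"), 1)
    carrier <- if (parent == "M") mother[j] else father[j]
    gt_set <- stats::setNames(c(1L, 1L), c(proband[j], carrier))
    vid <- add_variant(g$chrom, ex$start[2] + 5L, gt_set,
                       cadd = round(stats::runif(1, 15, 35), 2))
    first_hit_id[j] <- vid
    if (!is.na(r)) plan$first_hit_id[r] <- vid
  }

  plan$second_hit_id <- NA_character_
  plan$second_chrom <- NA_character_
  plan$second_start <- NA_integer_
  plan$second_end <- NA_integer_
  sv_call_parts <- list()
  depth_parts <- list()

  add_depth_trio <- function(j, sv, f_proband, f_mother, f_father) {
    L <- sv$end - sv$start + 1L
    guard <- 1000L
    regions <- tibble::tibble(
      start = c(sv$start, sv$start - guard - L, sv$end + guard + 1L),
      end = c(sv$end, sv$start - guard - 1L, sv$end + guard + L),
      in_sv = c(TRUE, FALSE, FALSE))
    members <- c(proband[j], mother[j], father[j])
    fr <- c(f_proband, f_mother, f_father)
    rows <- purrr::map(seq_along(members), function(i) {
      tibble::tibble(
        sample_id = members[i], chrom = sv$chrom,
        start = as.integer(regions$start), end = as.integer(regions$end),
        mean_depth = purrr::map2_dbl(regions$in_sv, regions$end - regions$start + 1,
          function(is_in, w) {
            simulate_region_depth(if (is_in) fr[i] else 0, config$mean_depth, w)
          }))
    })
    depth_parts[[length(depth_parts) + 1L]] <<- purrr::list_rbind(rows)
  }

  for (r in seq_len(nrow(plan))) {
    j <- plan$fam_idx[r]
    g <- genes[plan$gene_row[r], ]
    other_parent <- if (plan$first_parent[r] == "M") "F" else "M"
    other_sample <- if (other_parent == "M") mother[j] else father[j]
    kind <- plan$kind[r]
    if (kind %in% c("second_hit_SV", "mosaic_parent_SV")) {
      ex <- g$exons[[1]]
      k <- sample(2:(nrow(ex) - 1), 1)
      sv_start <- as.integer(ex$start[k] - round(stats::runif(1, 200, 2000)))
      sv_len <- as.integer(round(stats::runif(1, 5e3, 30e3)))
      sv <- tibble::tibble(svtype = "DEL", chrom = g$chrom, start = sv_start,
                           end = sv_start + sv_len - 1L, ins_length = NA_integer_)
      carrier_parent <- if (kind == "mosaic_parent_SV") father[j] else other_sample
      sv_call_parts[[length(sv_call_parts) + 1L]] <- emit_sv_calls(
        sv, c(proband[j], carrier_parent), c("het", "het"), config)
      plan$second_chrom[r] <- sv$chrom
      plan$second_start[r] <- sv$start
      plan$second_end[r] <- sv$end
      if (kind == "mosaic_parent_SV") {
        add_depth_trio(j, sv, f_proband = 1, f_mother = 0,
                       f_father = config$mosaic_fraction)
      } else {
        add_depth_trio(j, sv,
                       f_proband = 1,
                       f_mother = if (other_parent == "M") 1 else 0,
                       f_father = if (other_parent == "F") 1 else 0)
      }
    } else if (kind == "second_hit_intronic_SNV") {
      ex <- g$exons[[1]]
      pos <- as.integer((ex$end[1] + ex$start[2]) %/% 2)
      gt_set <- stats::setNames(c(1L, 1L), c(proband[j], other_sample))
      vid <- add_variant(g$chrom, pos, gt_set,
                         cadd = round(stats::runif(1, 0.5, 25), 2),
                         ag = round(stats::runif(1, 0.02, 0.99), 2))
      plan$second_hit_id[r] <- vid
      plan$second_chrom[r] <- g$chrom
      plan$second_start[r] <- pos
      plan$second_end[r] <- pos
    } else if (kind == "homozygous_in_ROH") {
      ex <- g$exons[[1]]
      pos <- ex$start[3] + 7L
      gt_set <- stats::setNames(c(2L, 1L, 1L),
                                c(proband[j], mother[j], father[j]))
      vid <- add_variant(g$chrom, pos, gt_set,
                         cadd = round(stats::runif(1, 10, 35), 2))
      plan$second_hit_id[r] <- vid
      plan$second_chrom[r] <- g$chrom
      plan$second_start[r] <- pos
      plan$second_end[r] <- pos
    }
  }

  ## ---- background SV clusters ------------------------------------------
  bg_freqs <- rep_len(config$background_freq_spectrum,
                      config$n_background_sv_clusters)
  bg_truth <- list()
  for (b in seq_len(config$n_background_sv_clusters)) {
    ch <- sample(names(chroms), 1)
    svtype <- sample(c("DEL", "DUP", "INS"), 1, prob = c(0.45, 0.45, 0.1))
    st <- as.integer(round(stats::runif(1, 1e6, chroms[[ch]] - 1e6)))
    if (svtype == "INS") {
      sv <- tibble::tibble(svtype = svtype, chrom = ch, start = st, end = st,
                           ins_length = as.integer(round(stats::runif(1, 300, 3000))))
    } else {
      len <- as.integer(round(10^stats::runif(1, 3.3, 5)))
      sv <- tibble::tibble(svtype = svtype, chrom = ch, start = st,
                           end = st + len - 1L, ins_length = NA_integer_)
    }
    p <- bg_freqs[b]
    m_car <- stats::runif(nf) < p
    f_car <- stats::runif(nf) < p
    c_car <- (m_car & stats::runif(nf) < 0.5) | (f_car & stats::runif(nf) < 0.5)
    carriers <- c(mother[m_car], father[f_car], proband[c_car])
    if (length(carriers) == 0) next
    sv_call_parts[[length(sv_call_parts) + 1L]] <- emit_sv_calls(
      sv, carriers, rep("het", length(carriers)), config)
    bg_truth[[length(bg_truth) + 1L]] <- dplyr::bind_cols(
      sv, tibble::tibble(configured_freq = p, n_carriers = length(carriers)))
  }
  bg_truth <- if (length(bg_truth)) purrr::list_rbind(bg_truth) else NULL

  sv_calls <- if (length(sv_call_parts)) purrr::list_rbind(sv_call_parts) else
    mk_empty_sv_calls()
  sv_calls <- dplyr::arrange(sv_calls, .data$chrom, .data$start, .data$svtype,
                             .data$caller, .data$sample_id)

  ## ---- assemble variant table + genotype matrix ------------------------
  extra_variants <- purrr::list_rbind(extra_var)
  extra_mat <- do.call(rbind, extra_gt)
  variants <- dplyr::bind_rows(marker_variants, extra_variants)
  gt <- rbind(marker_gt, extra_mat)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  gt <- gt[ord, , drop = FALSE]
  variants <- dplyr::mutate(
    variants,
    variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
    .before = 1)
  rownames(gt) <- variants$variant_id
  variants$af_cohort <- round(rowSums(gt, na.rm = TRUE) / (2 * ncol(gt)), 5)

  depth <- if (length(depth_parts)) purrr::list_rbind(depth_parts) else
    tibble::tibble(sample_id = character(), chrom = character(),
                   start = integer(), end = integer(), mean_depth = double())

  ## ---- cases and truth --------------------------------------------------
  cases <- tibble::tibble(
    case_id = fams, sample_id = proband,
    referral_condition = "simulated recessive disorder",
    recruitment_status = "correctly_recruited",
    first_hit_gene = genes$symbol[gene_for_fam],
    first_hit_kind = first_hit_kind,
    first_hit_id = first_hit_id,
    solved = "unsolved")

  truth <- plan |>
    dplyr::left_join(roh_truth, by = "fam_idx") |>
    dplyr::mutate(
      case_id = fams[.data$fam_idx],
      gene = genes$symbol[.data$gene_row],
      second_hit_type = ifelse(.data$kind %in% c("second_hit_SV", "mosaic_parent_SV"),
                               "sv", "snv"),
      true_path = ifelse(.data$kind == "homozygous_in_ROH",
                         "HOMOZYGOUS_IN_ROH", "COMPOUND_HET"),
      true_phase = ifelse(.data$kind == "homozygous_in_ROH", NA_character_,
                          "TRANS"),
      true_mosaic_fraction = ifelse(.data$kind == "mosaic_parent_SV",
                                    config$mosaic_fraction, NA_real_)) |>
    dplyr::select("case_id", "kind", "gene", "first_hit_id",
                  "second_hit_type", "second_hit_id", "second_chrom",
                  "second_start", "second_end", "true_path", "true_phase",
                  "true_mosaic_fraction", "roh_chrom", "roh_start", "roh_end")

  structure(list(
    config = config, genes = genes, pedigree = pedigree, sv_calls = sv_calls,
    variants = variants, gt = gt, depth = depth, cases = cases,
    truth = truth, background_sv = bg_truth
  ), class = "secondhit_cohort")
}

#' @export
print.secondhit_cohort <- function(x, ...) {
  cat("Synthetic second-hit cohort\n")
  cat("  families:        ", x$config$n_families, " (",
      nrow(x$pedigree), " samples)\n", sep = "")
  cat("  planted cases:   ", nrow(x$truth), "\n", sep = "")
  cat("  SV calls:        ", nrow(x$sv_calls), "\n", sep = "")
  cat("  small variants:  ", nrow(x$variants), "\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk in its exchange formats
#'
#' Emits exactly the formats the readers in this package consume: one SV
#' VCF per caller, a multi-sample small-variant VCF, a PED pedigree, a
#' BED12 gene file, depth / annotation / case-manifest / truth TSVs.
#' Deterministic cohort in, byte-identical files out.
#'
#' @param cohort A `secondhit_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "secondhit_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  for (cl in unique(cohort$sv_calls$caller)) {
    calls <- dplyr::filter(cohort$sv_calls, .data$caller == cl)
    write_sv_vcf(calls, p(paste0("sv_", cl, ".vcf")),
                 samples = cohort$pedigree$sample_id |> sort())
  }
  write_small_vcf(cohort$variants, cohort$gt, p("small_variants.vcf"))
  readr::write_tsv(
    dplyr::select(cohort$variants, "chrom", "pos", "ref", "alt", "af_1000g",
                  "af_gnomad", "cadd_phred", "ag", "al", "dg", "dl"),
    p("annotations.tsv"), na = "")
  write_ped(cohort$pedigree, p("cohort.ped"))
  write_gene_bed(cohort$genes, p("genes.bed"))
  readr::write_tsv(cohort$depth, p("depth.tsv"), na = "")
  readr::write_tsv(cohort$cases, p("cases.tsv"), na = "")
  readr::write_tsv(cohort$truth, p("truth.tsv"), na = "")
  invisible(dir)
}
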