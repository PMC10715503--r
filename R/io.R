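# File I/O. Internal coordinates are 1-based inclusive (VCF-native);
# BED converts at the boundary. VCF reading goes through vcfR; the VCF
# writers emit minimal spec-conformant VCF 4.2 text.

info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  m
}

#' Read a structural-variant VCF into a call table
#'
#' One call row is emitted per sample with a non-reference genotype per
#' record. Records without an `SVTYPE` INFO key are rejected with a
#' warning; a record whose `END` precedes `POS` is a hard error naming the
#' record. Insertions (`SVTYPE=INS`) are modelled as point-like loci
#' (`end = start`) with the inserted length taken from `SVLEN`; deletions,
#' duplications and inversions take their span from `END` (or from
#' `|SVLEN|` when `END` is absent). Translocations/breakends are not
#' supported.
#'
#' @param path VCF file (text or bgzipped).
#' @param caller Caller label for the calls; defaults to the `##source=`
#'   header line when present, else `NA`.
#' @return Tibble of calls: `sample_id`, `caller`, `svtype`, `chrom`,
#'   `start`, `end`, `ins_length`, `genotype` (`"het"`/`"hom"`), `qual`.
#' @export
read_sv_vcf <- function(path, caller = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(caller)) {
    src <- grep("^##source=", v@meta, value = TRUE)
    caller <- if (length(src)) sub("^##source=", "", src[1]) else NA_character_
  }
  fix <- v@fix
  empty <- tibble::tibble(
    sample_id = character(), caller = character(), svtype = character(),
    chrom = character(), start = integer(), end = integer(),
    ins_length = integer(), genotype = character(), qual = double())
  if (nrow(fix) == 0) return(empty)
  svtype <- info_field(fix[, "INFO"], "SVTYPE")
  bad <- is.na(svtype)
  if (any(bad)) {
    warning(sum(bad), " record(s) without SVTYPE rejected (first at ",
            fix[which(bad)[1], "CHROM"], ":", fix[which(bad)[1], "POS"], ")",
            call. = FALSE)
  }
  pos <- as.integer(fix[, "POS"])
  end <- suppressWarnings(as.integer(info_field(fix[, "INFO"], "END")))
  svlen <- suppressWarnings(as.integer(info_field(fix[, "INFO"], "SVLEN")))
  bad_end <- !is.na(end) & end < pos
  if (any(bad_end)) {
    i <- which(bad_end)[1]
    stop("malformed record (END < POS) at ", fix[i, "CHROM"], ":", fix[i, "POS"],
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  rows <- purrr::map(which(!bad), function(i) {
    st <- svtype[i]
    if (st == "INS") {
      s <- pos[i]; e <- pos[i]
      il <- abs(svlen[i])
    } else {
      s <- pos[i]
      e <- if (!is.na(end[i])) end[i] else pos[i] + abs(svlen[i])
      il <- NA_integer_
    }
    code <- gt_code(gt[i, ])
    carrier <- which(!is.na(code) & code > 0L)
    if (length(carrier) == 0) return(NULL)
    q <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    tibble::tibble(
      sample_id = samples[carrier], caller = caller, svtype = unname(st),
      chrom = unname(fix[i, "CHROM"]), start = unname(s), end = unname(e),
      ins_length = unname(il),
      genotype = unname(ifelse(code[carrier] == 1L, "het", "hom")),
      qual = unname(ifelse(is.na(q), 0, q))
    )
  })
  out <- purrr::list_rbind(rows)
  if (is.null(out) || nrow(out) == 0) empty else out
}

#' Write SV calls as a VCF
#'
#' Calls sharing (`svtype`, `chrom`, `start`, `end`, `ins_length`, `qual`)
#' are merged into one multi-sample record. The caller label is recorded in
#' a `##source=` header line so a round trip through [read_sv_vcf()]
#' reproduces the call table.
#'
#' @param calls SV call tibble (single caller).
#' @param path Output path.
#' @param samples Sample columns to emit; defaults to the samples present
#'   in `calls`.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, samples = NULL) {
  caller <- unique(calls$caller)
  if (length(caller) > 1) stop("write_sv_vcf() writes one caller per file", call. = FALSE)
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (length(caller) == 1 && !is.na(caller)) paste0("##source=", caller),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of inserted sequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  recs <- calls |>
    dplyr::group_by(.data$svtype, .data$chrom, .data$start, .data$end,
                    .data$ins_length, .data$qual) |>
    dplyr::summarise(gt_by_sample = list(stats::setNames(.data$genotype, .data$sample_id)),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start, .data$svtype)
  lines <- purrr::pmap_chr(recs, function(svtype, chrom, start, end, ins_length,
                                          qual, gt_by_sample) {
    info <- if (svtype == "INS") {
      paste0("SVTYPE=INS;SVLEN=", ins_length)
    } else {
      paste0("SVTYPE=", svtype, ";END=", end)
    }
    gts <- rep("0/0", length(samples))
    names(gts) <- samples
    gts[names(gt_by_sample)] <- ifelse(gt_by_sample == "hom", "1/1", "0/1")
    paste(c(chrom, start, ".", "N", paste0("<", svtype, ">"),
            format(qual, trim = TRUE), "PASS", info, "GT", gts), collapse = "\t")
  })
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a multi-sample small-variant VCF
#'
#' Multi-allelic records are split into bi-allelic variants on read: each
#' ALT allele becomes its own variant and each sample's genotype is recoded
#' as the count of that allele. Coordinates stay 1-based.
#'
#' @param path VCF file.
#' @return A list with `variants` (tibble: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`) and `gt` (integer allele-count matrix, variants x
#'   samples, `NA` for missing).
#' @export
read_small_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_chr)
  out_var <- list(); out_gt <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    g <- gsub("\\|", "/", gt_chr[i, ])
    alleles <- strsplit(g, "/", fixed = TRUE)
    for (ai in seq_along(alts)) {
      counts <- vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
        sum(a == as.character(ai))
      }, integer(1))
      out_var[[length(out_var) + 1L]] <- tibble::tibble(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[ai])
      out_gt[[length(out_gt) + 1L]] <- counts
    }
  }
  variants <- purrr::list_rbind(out_var)
  variants <- dplyr::mutate(
    variants,
    variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
    .before = 1)
  gt <- do.call(rbind, out_gt)
  dimnames(gt) <- list(variants$variant_id, samples)
  list(variants = variants, gt = gt)
}

#' Write a bi-allelic small-variant table + genotype matrix as VCF
#'
#' @param variants Variant tibble (`variant_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param gt Allele-count matrix (variants x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_small_vcf <- function(variants, gt, path) {
  samples <- colnames(gt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
  gt_str[is.na(gt_str)] <- "./."
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt_str[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 6-column pedigree (PED) file
#'
#' Standard tab-separated PED: family, individual, father, mother, sex,
#' affected status; `0` marks a missing parent and is returned as `NA`.
#'
#' @param path PED file.
#' @return Tibble: `sample_id`, `family_id`, `father_id`, `mother_id`,
#'   `sex`, `affected`. Parent ids must resolve within the pedigree or be
#'   absent.
#' @export
read_ped <- function(path) {
  ped <- readr::read_tsv(path, col_names = c("family_id", "sample_id",
                                             "father_id", "mother_id",
                                             "sex", "affected"),
                         col_types = "ccccii", progress = FALSE)
  ped <- dplyr::mutate(
    ped,
    father_id = dplyr::na_if(.data$father_id, "0"),
    mother_id = dplyr::na_if(.data$mother_id, "0"))
  parents <- stats::na.omit(c(ped$father_id, ped$mother_id))
  missing <- setdiff(parents, ped$sample_id)
  if (length(missing)) {
    stop("pedigree parent id(s) not present as individuals: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::select(ped, "sample_id", "family_id", "father_id", "mother_id",
                "sex", "affected")
}

#' Write a pedigree tibble as a PED file
#' @param ped Pedigree tibble (see [read_ped()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- tibble::tibble(
    family_id = ped$family_id, sample_id = ped$sample_id,
    father_id = dplyr::coalesce(ped$father_id, "0"),
    mother_id = dplyr::coalesce(ped$mother_id, "0"),
    sex = ped$sex, affected = ped$affected)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read (and back on write, so a
#' read/write round trip is byte-preserving for files this package
#' writes). Blocks become exons.
#'
#' @param path BED12 file.
#' @return Gene tibble: `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`, `exons` (list column of tibbles with `start`, `end`).
#' @export
read_gene_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
                  "thickStart", "thickEnd", "itemRgb", "blockCount",
                  "blockSizes", "blockStarts"),
    col_types = "ciiciciicicc", progress = FALSE)
  exons <- purrr::pmap(bed, function(chromStart, blockSizes, blockStarts, ...) {
    sizes <- as.integer(strsplit(blockSizes, ",")[[1]])
    offs <- as.integer(strsplit(blockStarts, ",")[[1]])
    tibble::tibble(start = chromStart + offs + 1L,
                   end = chromStart + offs + sizes)
  })
  tibble::tibble(
    gene_id = bed$name, symbol = bed$name, chrom = bed$chrom,
    start = bed$chromStart + 1L, end = bed$chromEnd, strand = bed$strand,
    exons = exons)
}

#' Write gene models as BED12
#' @param genes Gene tibble (see [read_gene_bed()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  lines <- purrr::pmap_chr(
    dplyr::select(genes, "chrom", "start", "end", "symbol", "strand", "exons"),
    function(chrom, start, end, symbol, strand, exons) {
      sizes <- exons$end - exons$start + 1L
      offs <- exons$start - start
      paste(chrom, start - 1L, end, symbol, 0L, strand, start - 1L, end, "0",
            nrow(exons), paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(offs, collapse = ","), ","), sep = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-region mean-depth table
#'
#' @param path TSV with header `sample_id`, `chrom`, `start`, `end`,
#'   `mean_depth`.
#' @return Tibble with those columns.
#' @export
read_depth_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", chrom = "c", start = "i", end = "i", mean_depth = "d"),
    progress = FALSE)
}

#' Read a variant annotation table
#'
#' Precomputed evidence annotations keyed by (`chrom`, `pos`, `ref`,
#' `alt`): population AFs, PHRED-scaled CADD, and splice delta scores
#' (acceptor/donor gain/loss). Empty cells mean "absent" and read as `NA`.
#' The package consumes these scores; it never runs the underlying models.
#'
#' @param path TSV with header `chrom`, `pos`, `ref`, `alt`, `af_1000g`,
#'   `af_gnomad`, `cadd_phred`, `ag`, `al`, `dg`, `dl`.
#' @return Tibble with those columns.
#' @export
read_annotation_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", af_1000g = "d",
    af_gnomad = "d", cadd_phred = "d", ag = "d", al = "d", dg = "d", dl = "d"),
    progress = FALSE)
}

#' Join annotation evidence onto a variant table
#'
#' @param variants Variant tibble from [read_small_vcf()].
#' @param annot Annotation tibble from [read_annotation_tsv()].
#' @return `variants` with the annotation columns joined by
#'   (`chrom`, `pos`, `ref`, `alt`).
#' @export
annotate_variants <- function(variants, annot) {
  dplyr::left_join(variants, annot, by = c("chrom", "pos", "ref", "alt"))
}

#' Read a case manifest
#'
#' One row per recruited case. Required columns: `case_id`, `sample_id`
#' (proband), `referral_condition`, `recruitment_status` (one of
#' `correctly_recruited`, `excluded_misrecruited`, `excluded_data_quality`,
#' `no_first_hit_info`), `first_hit_gene`, `first_hit_kind` (one of
#' `small_variant`, `sv`, `ROH_only`, `none`, or empty), `first_hit_id`
#' (variant id / cluster id, or empty), `solved` (`previously_solved`,
#' `newly_solved`, `unsolved`). First-hit fields must be empty exactly for
#' `no_first_hit_info` cases.
#'
#' @param path TSV file.
#' @return Validated tibble.
#' @export
read_case_manifest <- function(path) {
  cases <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("case_id", "sample_id", "referral_condition", "recruitment_status",
            "first_hit_gene", "first_hit_kind", "first_hit_id", "solved")
  miss <- setdiff(need, names(cases))
  if (length(miss)) stop("case manifest missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ok_status <- c("correctly_recruited", "excluded_misrecruited",
                 "excluded_data_quality", "no_first_hit_info")
  if (!all(cases$recruitment_status %in% ok_status)) {
    stop("invalid recruitment_status value(s)", call. = FALSE)
  }
  if (!all(cases$solved %in% c("previously_solved", "newly_solved", "unsolved"))) {
    stop("invalid solved value(s)", call. = FALSE)
  }
  no_info <- cases$recruitment_status == "no_first_hit_info"
  has_hit <- !is.na(cases$first_hit_kind) & cases$first_hit_kind != ""
  if (any(no_info & has_hit) || any(!no_info & !has_hit)) {
    stop("first-hit fields must be empty exactly for no_first_hit_info cases",
         call. = FALSE)
  }
  cases
}

#' Confirm that a case's first-hit small variant is carried by the proband
#'
#' @param case One-row case record (list or tibble row) with `sample_id`,
#'   `first_hit_kind`, `first_hit_id`.
#' @param variants,gt Variant tibble and genotype matrix.
#' @return `TRUE` when the proband genotype at the first-hit variant is
#'   non-reference, `FALSE` when it is reference or the variant is missing
#'   from the table, and `NA` (not applicable) for sentinel first hits
#'   (`ROH_only` / `none`) - never an error for those.
#' @export
confirm_first_hit <- function(case, variants, gt) {
  if (is.na(case$first_hit_kind) || case$first_hit_kind %in% c("ROH_only", "none")) {
    return(NA)
  }
  if (case$first_hit_kind != "small_variant") {
    stop("confirm_first_hit() checks small-variant first hits only", call. = FALSE)
  }
  if (!case$first_hit_id %in% rownames(gt) || !case$sample_id %in% colnames(gt)) {
    return(FALSE)
  }
  g <- gt[case$first_hit_id, case$sample_id]
  !is.na(g) && g > 0L
}
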