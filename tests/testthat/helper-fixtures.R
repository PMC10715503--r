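# Shared fixtures and independent oracles.

mk_call <- function(sample_id = "S1", caller = "callerA", svtype = "DEL",
                    chrom = "chr1", start = 1000L, end = 2000L,
                    ins_length = NA_integer_, genotype = "het", qual = 50) {
  tibble::tibble(sample_id = sample_id, caller = caller, svtype = svtype,
                 chrom = chrom, start = as.integer(start),
                 end = as.integer(end), ins_length = as.integer(ins_length),
                 genotype = genotype, qual = qual)
}

# brute-force transitive closure over the pairwise calls_match relation:
# the independent oracle for cluster_sv_calls. O(n^2) pair test + BFS.
brute_force_components <- function(calls, params = sv_match_params()) {
  n <- nrow(calls)
  if (n == 0) return(integer())
  pair <- expand.grid(i = seq_len(n), j = seq_len(n))
  ok <- calls_match(calls[pair$i, ], calls[pair$j, ], params)
  adj <- matrix(ok, n, n)
  diag(adj) <- FALSE
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# canonical form of a clustering: sorted list of sorted member row-keys
clustering_signature <- function(groups, calls) {
  key <- paste(calls$sample_id, calls$caller, calls$svtype, calls$chrom,
               calls$start, calls$end, calls$ins_length)
  sig <- vapply(split(key, groups), function(k) paste(sort(k), collapse = "|"),
                character(1))
  sort(unname(sig))
}

random_calls <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  svtype <- sample(c("DEL", "DUP", "INV", "INS"), n, replace = TRUE,
                   prob = c(0.4, 0.25, 0.15, 0.2))
  start <- as.integer(sample(1e4:5e4, n, replace = TRUE))
  len <- as.integer(round(10^runif(n, 1.5, 3.5)))
  tibble::tibble(
    sample_id = sprintf("S%d", sample(1:8, n, replace = TRUE)),
    caller = sample(c("callerA", "callerB"), n, replace = TRUE),
    svtype = svtype,
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start,
    end = ifelse(svtype == "INS", start, start + len),
    ins_length = ifelse(svtype == "INS",
                        as.integer(sample(100:2000, n, replace = TRUE)),
                        NA_integer_),
    genotype = sample(c("het", "hom"), n, replace = TRUE, prob = c(0.9, 0.1)),
    qual = round(runif(n, 30, 99)))
}

# one moderate cohort shared across screen tests (built once per run)
.test_cache <- new.env(parent = emptyenv())

test_cohort <- function() {
  if (is.null(.test_cache$cohort)) {
    cfg <- sim_config(
      n_families = 120, n_planted_cases = 6,
      planted_kinds = c("second_hit_SV", "second_hit_SV",
                        "second_hit_intronic_SNV", "second_hit_intronic_SNV",
                        "homozygous_in_ROH", "mosaic_parent_SV"),
      seed = 42)
    co <- simulate_cohort(cfg)
    clusters <- cohort_frequency(cluster_sv_calls(co$sv_calls),
                                 n_participants = nrow(co$pedigree))
    .test_cache$cohort <- list(cohort = co, clusters = clusters)
  }
  .test_cache$cohort
}

# does a candidate row match a truth row?
candidate_matches_truth <- function(cand, tr) {
  if (tr$second_hit_type == "snv") {
    return(identical(cand$candidate_id, tr$second_hit_id))
  }
  cand$candidate_type == "sv_cluster" &&
    reciprocal_overlap(cand$chrom, cand$start, cand$end,
                       tr$second_chrom, tr$second_start, tr$second_end) >= 0.8
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "secondhit", mustWork = FALSE)
}
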