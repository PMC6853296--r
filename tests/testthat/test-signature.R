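# terminal/flanking composition, cleavage-site inference, profiles

test_that("end_composition counts positions from either end", {
  comp5 <- end_composition(c("ACG", "AAT"), end = 5, n_positions = 3)
  expect_identical(comp5$fractions["A", 1], 1)
  expect_identical(comp5$fractions["C", 2], 0.5)
  comp3 <- end_composition(c("ACG", "AAT"), end = 3, n_positions = 3)
  expect_identical(comp3$fractions["G", 1], 0.5)
  expect_identical(comp3$fractions["U", 1], 0.5)  # T reported as U

  # shorter reads only contribute to covered positions
  mix <- end_composition(c("AC", "AAAA"), end = 5, n_positions = 4)
  expect_identical(mix$n_per_position, c(2L, 2L, 1L, 1L))

  empty <- end_composition(character(0))
  expect_identical(empty$n_reads, 0L)
  expect_true(all(is.na(empty$fractions)))

  # probability columns sum to 1 wherever covered
  comp <- end_composition(clean_assignments()$seq, 5)
  sums <- colSums(comp$fractions)
  expect_true(all(abs(sums[comp$n_per_position > 0] - 1) < 1e-9))
})

test_that("flanking_context indexes the reference around the fragment", {
  refs <- structure(list(
    categories = list(
      spike_in = Biostrings::DNAStringSet(),
      cyto_tRNA = Biostrings::DNAStringSet(),
      rRNA = Biostrings::DNAStringSet(),
      mito = Biostrings::DNAStringSet(),
      mRNA = Biostrings::DNAStringSet(c(m1 = "GGCAGTCCAG")),
      genome = Biostrings::DNAStringSet()
    ), trna_annotation = data.frame(), adapter = cp_default_adapter()
  ), class = "cp_refs")
  aln <- data.frame(read_id = "r1", seq = "AGTCC", category = "mRNA",
                    ref_id = "m1", start = 3L, end = 8L, strand = "+",
                    n_mismatch = 0L, stringsAsFactors = FALSE)
  ctx <- flanking_context(aln, refs, k = 4)
  expect_identical(ctx$fractions["C", "-1"], 1)  # index 2 = C
  expect_identical(ctx$fractions["A", "+1"], 1)  # index 8 = A
  # -4 would be index -1: fragment near the edge misses it
  expect_identical(ctx$n_per_position[1], 0L)

  # fragment at index 0: no upstream contribution at all
  edge <- aln
  edge$start <- 0L; edge$end <- 5L; edge$seq <- "GGCAG"
  ctx_edge <- flanking_context(edge, refs, k = 4)
  expect_true(all(ctx_edge$n_per_position[1:4] == 0L))

  # antisense fragment: flanks are reverse-complemented
  rc <- data.frame(read_id = "r2", seq = oracle_revcomp("AGTCC"),
                   category = "mRNA", ref_id = "m1", start = 3L, end = 8L,
                   strand = "-", n_mismatch = 0L, stringsAsFactors = FALSE)
  ctx_rc <- flanking_context(rc, refs, k = 1)
  # biological -1 of the antisense fragment = complement of index 8 (A)
  expect_identical(ctx_rc$fractions["U", "-1"], 1)
  expect_identical(ctx_rc$fractions["G", "+1"], 1)  # complement of C at 2
})

test_that("flanking context matches brute-force re-extraction", {
  aln <- noisy_assignments()
  refs <- toy_refs()
  seqs <- ref_seq_list()
  fb <- cpseq:::flank_bases(aln, refs, k = 2)
  a <- fb$aln
  set.seed(404)
  for (i in sample(nrow(a), 50)) {
    s <- seqs[[a$ref_id[i]]]
    if (a$strand[i] == "+") {
      exp_up <- ifelse(a$start[i] >= 1, substr(s, a$start[i], a$start[i]),
                       NA)
      exp_down <- ifelse(a$end[i] < nchar(s),
                         substr(s, a$end[i] + 1, a$end[i] + 1), NA)
    } else {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      exp_up <- if (a$end[i] < nchar(s))
        unname(comp[substr(s, a$end[i] + 1, a$end[i] + 1)]) else NA
      exp_down <- if (a$start[i] >= 1)
        unname(comp[substr(s, a$start[i], a$start[i])]) else NA
    }
    expect_identical(unname(fb$upstream[i, "-1"]), as.character(exp_up))
    expect_identical(unname(fb$downstream[i, "+1"]), as.character(exp_down))
  }
})

test_that("C|A signature saturates at p = 1 and grows with p", {
  refs <- toy_refs()
  frac_at <- function(p) {
    lib <- simulate_library(refs, simulator_config(
      seed = 31, n_reads = 1500, p_ca_cleavage = p, error_rate = 0))
    pre <- preprocess_reads(lib$reads)
    aln <- map_sequential(pre$reads, refs)
    internal <- aln$category %in% c("rRNA", "mito", "mRNA", "genome")
    ca_boundary_fraction(aln[internal, , drop = FALSE], refs)
  }
  f0 <- frac_at(0); f05 <- frac_at(0.5); f1 <- frac_at(1)
  expect_identical(f1$five_prime, 1)
  expect_identical(f1$three_prime, 1)
  expect_identical(f1$both, 1)
  expect_lt(f0$both, f05$both)
  expect_lt(f05$both, f1$both)

  empty <- ca_boundary_fraction(
    data.frame(read_id = character(0), seq = character(0),
               category = character(0), ref_id = character(0),
               start = integer(0), end = integer(0),
               strand = character(0), n_mismatch = integer(0),
               stringsAsFactors = FALSE), refs)
  expect_true(is.na(empty$both))
})

test_that("cleavage sites are inferred from half ends and starts", {
  calls <- data.frame(
    read_id = c("a", "b", "c"),
    ref_id = "tRNA-X",
    fragment_class = c("FIVE_HALF", "THREE_HALF", "FIVE_HALF"),
    np_start = c(1L, 35L, 1L),
    np_end = c(34L, 75L, 30L),
    stringsAsFactors = FALSE
  )
  prof <- infer_cleavage_sites(calls, data.frame())
  b34 <- prof[prof$boundary_np == 34, ]
  expect_identical(b34$n_from_five_half, 1L)
  expect_identical(b34$n_from_three_half, 1L)
  expect_true(b34$concordant)
  b30 <- prof[prof$boundary_np == 30, ]
  expect_false(b30$concordant)

  only5 <- infer_cleavage_sites(calls[calls$fragment_class == "FIVE_HALF", ,
                                      drop = FALSE], data.frame())
  expect_false(any(only5$concordant))

  modal <- modal_cleavage_boundary(prof)
  expect_identical(modal$boundary_np, 34L)
})

test_that("alignment profiles conserve coverage and rank intervals", {
  aln <- data.frame(
    read_id = c("a", "b"), seq = strrep("A", 20), category = "mRNA",
    ref_id = "m1", start = 5L, end = 25L, strand = "+", n_mismatch = 0L,
    stringsAsFactors = FALSE)
  prof <- alignment_profile(aln, "m1", 40)
  expect_identical(prof$coverage[6:25], rep(2L, 20))
  expect_identical(sum(prof$coverage), 40L)
  expect_identical(prof$top_intervals,
                   data.frame(start = 5L, end = 25L, count = 2L,
                              stringsAsFactors = FALSE))

  none <- alignment_profile(aln[0, ], "m1", 40)
  expect_true(all(none$coverage == 0L))

  # conservation on simulated data: sum(coverage) = sum of lengths
  sim <- clean_assignments()
  rid <- names(sort(table(sim$ref_id[sim$category == "mRNA"]),
                    decreasing = TRUE))[1]
  L <- nchar(ref_seq_list()[[rid]])
  p <- alignment_profile(sim, rid, L)
  on_ref <- sim[!is.na(sim$ref_id) & sim$ref_id == rid, ]
  expect_identical(sum(p$coverage), sum(on_ref$end - on_ref$start))
  expect_identical(sum(p$start_counts), nrow(on_ref))

  # a dominant site is recovered as the top interval
  dom <- data.frame(
    read_id = sprintf("d%d", 1:10), seq = strrep("A", 20),
    category = "mRNA", ref_id = "m1",
    start = c(rep(7L, 9), 2L), end = c(rep(27L, 9), 22L), strand = "+",
    n_mismatch = 0L, stringsAsFactors = FALSE)
  expect_identical(alignment_profile(dom, "m1", 40)$top_intervals[1, ],
                   data.frame(start = 7L, end = 27L, count = 9L,
                              stringsAsFactors = FALSE))
})

test_that("length distributions bin by category", {
  aln <- data.frame(
    read_id = c("a", "b", "c"),
    seq = c(strrep("A", 20), strrep("A", 20), strrep("A", 45)),
    category = c("mRNA", "mRNA", "rRNA"), stringsAsFactors = FALSE)
  h <- length_distribution(aln)
  expect_identical(h["mRNA", "20"], 2L)
  expect_identical(h["rRNA", "45"], 1L)
  expect_identical(sum(h), 3L)
  lib <- clean_library()
  h2 <- length_distribution(clean_assignments())
  expect_identical(sum(h2), nrow(lib$reads))
})
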