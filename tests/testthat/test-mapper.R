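# bounded-Hamming hits and sequential category assignment

test_that("hamming_hits finds exact and near placements", {
  refs <- c(refA = "GGCAGTCCAGTTACGCTGGAGTC", refB = "TTTTTTTTTTTTTTTTTT")
  hit <- hamming_hits("AGTCCAGTT", refs, k = 0, strands = "+")
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$ref_id, "refA")
  expect_identical(hit$start, 3L)
  expect_identical(hit$end, 12L)
  expect_identical(hit$n_mismatch, 0L)

  # one substitution found at k = 1, not at k = 0
  expect_identical(nrow(hamming_hits("AGTCGAGTT", refs, k = 0,
                                     strands = "+")), 0L)
  h1 <- hamming_hits("AGTCGAGTT", refs, k = 1, strands = "+")
  expect_identical(h1$n_mismatch, 1L)

  # antisense placement
  rc <- oracle_revcomp("AGTCCAGTT")
  hm <- hamming_hits(rc, refs, k = 0)
  expect_identical(hm$strand, "-")
  expect_identical(hm$start, 3L)
})

test_that("spike-in read hits the spike-in reference exactly once at 0", {
  refs <- toy_refs()
  spike <- cp_spike_in_sequence()
  hits <- hamming_hits(spike,
                       as.character(refs$categories$spike_in),
                       k = 1, strands = "+")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 0L)
  expect_identical(hits$n_mismatch, 0L)
})

test_that("hamming_hits equals the brute-force scan on random reads", {
  refs <- ref_seq_list()
  set.seed(301)
  reads <- c(random_dna(30, 25),
             # reads sampled from the references, some mutated
             vapply(1:30, function(i) {
               rid <- sample(names(refs), 1)
               L <- nchar(refs[[rid]])
               w <- sample(20:min(45, L), 1)
               s0 <- sample(0:(L - w), 1)
               x <- substr(refs[[rid]], s0 + 1, s0 + w)
               if (i %% 2 == 0) {
                 p <- sample(w, 1)
                 substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                   substr(x, p, p)), 1)
               }
               x
             }, ""))
  for (k in 0:1) {
    for (read in reads[seq(1, length(reads), by = 3)]) {
      got <- hamming_hits(read, refs, k = k)
      exp <- oracle_hamming(read, refs, k = k)
      rownames(got) <- rownames(exp) <- NULL
      expect_identical(got, exp)
    }
  }
})

test_that("sequential priority overrides mismatch count", {
  trna_seq <- paste0(paste(rep("ACGT", 18), collapse = ""), "CCCA")  # 76 nt
  read <- substr(trna_seq, 11, 40)
  read_mut <- read
  substr(read_mut, 5, 5) <- "T"
  stopifnot(substr(read, 5, 5) != "T")
  # an mRNA carrying the mutated read exactly
  mrna_seq <- paste0(strrep("GATTC", 40), read_mut, strrep("CTGAA", 40))
  refs <- structure(list(
    categories = list(
      spike_in = Biostrings::DNAStringSet(c(spike = cp_spike_in_sequence())),
      cyto_tRNA = Biostrings::DNAStringSet(c(tX = trna_seq)),
      rRNA = Biostrings::DNAStringSet(),
      mito = Biostrings::DNAStringSet(),
      mRNA = Biostrings::DNAStringSet(c(mX = mrna_seq)),
      genome = Biostrings::DNAStringSet()
    ),
    trna_annotation = data.frame(),
    adapter = cp_default_adapter()
  ), class = "cp_refs")

  reads <- data.frame(read_id = c("exact_both", "mut"),
                      seq = c(read, read_mut), stringsAsFactors = FALSE)
  suppressWarnings(aln <- map_sequential(reads, refs, max_mismatch = 1))
  # exact in tRNA and 1-mm in mRNA -> tRNA; exact in mRNA but 1-mm in
  # tRNA -> still tRNA (priority precedes mismatch count)
  expect_identical(aln$category, c("cyto_tRNA", "cyto_tRNA"))
  expect_identical(aln$n_mismatch, c(0L, 1L))
})

test_that("map_sequential matches the sequential brute-force oracle", {
  aln <- noisy_assignments()
  refs <- toy_refs()
  set.seed(303)
  pick <- sample(nrow(aln), 40)
  for (i in pick) {
    exp <- oracle_category(aln$seq[i], refs, k = 1)
    expect_identical(aln$category[i], exp$category)
    if (exp$category != "unmapped") {
      expect_identical(aln$ref_id[i], exp$ref_id)
      expect_identical(aln$start[i], exp$start)
      expect_identical(aln$strand[i], exp$strand)
      expect_identical(aln$n_mismatch[i], exp$n_mismatch)
    }
  }
})

test_that("assignment recovers the generator's truth and partitions reads", {
  lib <- clean_library()
  aln <- clean_assignments()
  truth <- lib$truth[match(aln$read_id, lib$truth$read_id), ]

  # partition: every read appears exactly once
  expect_identical(sort(aln$read_id), sort(lib$reads$read_id))
  expect_identical(sum(table(aln$category)), nrow(aln))

  expect_gte(mean(aln$category == truth$source_category), 0.99)
  spike <- truth$is_spike_in
  expect_true(all(aln$category[spike] == "spike_in"))
})

test_that("antisense policy: sense-only categories reject reversed reads", {
  refs <- toy_refs()
  trna <- as.character(refs$categories$cyto_tRNA[[1]])
  fwd <- substr(trna, 6, 35)
  rev_read <- oracle_revcomp(fwd)
  aln <- map_sequential(
    data.frame(read_id = c("f", "r"), seq = c(fwd, rev_read),
               stringsAsFactors = FALSE), refs)
  expect_identical(aln$category[1], "cyto_tRNA")
  expect_false(aln$category[2] == "cyto_tRNA")

  mrna <- as.character(refs$categories$mRNA[[1]])
  mr <- oracle_revcomp(substr(mrna, 51, 85))
  aln2 <- map_sequential(
    data.frame(read_id = "m", seq = mr, stringsAsFactors = FALSE), refs)
  expect_identical(aln2$category, "mRNA")
  expect_identical(aln2$strand, "-")
  expect_identical(aln2$start, 50L)
})

test_that("raising max_mismatch never unmaps reads", {
  lib <- noisy_library()
  pre <- preprocess_reads(lib$reads)
  a0 <- map_sequential(pre$reads, toy_refs(), max_mismatch = 0)
  a1 <- noisy_assignments()
  expect_gte(sum(a1$category != "unmapped"), sum(a0$category != "unmapped"))
})

test_that("category_proportions normalizes over mapped non-spike reads", {
  aln <- data.frame(
    read_id = letters[1:6],
    seq = strrep("A", 25),
    category = c("cyto_tRNA", "cyto_tRNA", "cyto_tRNA", "mRNA",
                 "spike_in", "unmapped"),
    stringsAsFactors = FALSE
  )
  props <- category_proportions(aln)
  expect_identical(props$fraction[props$category == "cyto_tRNA"], 0.75)
  expect_identical(props$fraction[props$category == "mRNA"], 0.25)

  only <- category_proportions(aln[aln$category == "mRNA", , drop = FALSE])
  expect_identical(only$fraction, 1)

  expect_warning(
    empty <- category_proportions(aln[aln$category == "unmapped", ,
                                      drop = FALSE]),
    "no mapped")
  expect_identical(nrow(empty), 0L)
})

test_that("simulator category weights are recovered at scale", {
  w <- c(cyto_tRNA = 0.4, rRNA = 0.3, mRNA = 0.2, genome = 0.1)
  lib <- simulate_library(toy_refs(), simulator_config(
    seed = 15, n_reads = 20000, category_weights = w, error_rate = 0))
  pre <- preprocess_reads(lib$reads)
  aln <- map_sequential(pre$reads, toy_refs())
  props <- category_proportions(aln)
  for (cat_ in names(w)) {
    got <- props$fraction[props$category == cat_]
    ci <- qbinom(c(0.005, 0.995), 20000, w[[cat_]]) / 20000
    expect_gte(got, ci[1] - 0.01)
    expect_lte(got, ci[2] + 0.01)
  }
})
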