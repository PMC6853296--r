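# simulator and toy reference generator

test_that("toy references satisfy their construction contracts", {
  refs <- toy_refs()

  spike <- as.character(refs$categories$spike_in[[1]])
  expect_identical(spike, "CAGTGGTGGGCCAGATGTAAACATTAGATTGTTCTTG")
  expect_identical(nchar(spike), 37L)

  trnas <- as.character(refs$categories$cyto_tRNA)
  ann <- refs$trna_annotation
  expect_true(all(substr(trnas, nchar(trnas) - 2, nchar(trnas)) == "CCA"))
  expect_true(all(ann$loop_end - ann$loop_start + 1L == 7L))
  # one His-like record with a -1 G, one base longer than the others
  his <- ann[ann$has_minus1, ]
  expect_identical(nrow(his), 1L)
  expect_identical(substr(trnas[[his$ref_id]], 1, 1), "G")
  expect_identical(nchar(trnas[[his$ref_id]]), 77L)
  expect_true(all(nchar(trnas[!ann$has_minus1]) == 76L))

  # substrates carry at least one C|A junction pair inside the window
  for (cat_ in c("rRNA", "mito", "mRNA", "genome")) {
    for (s in as.character(refs$categories[[cat_]])) {
      expect_true(grepl("CA", s, fixed = TRUE))
    }
  }

  # adapter 5-mer blocks are absent from every reference, so trimming
  # cannot fire inside a substrate sequence
  blocks <- cpseq:::adapter_blocks(refs$adapter)
  for (s in ref_seq_list(refs)) {
    expect_false(any(vapply(blocks, grepl, TRUE, x = s, fixed = TRUE)))
  }
})

test_that("reference building and simulation are byte-deterministic", {
  r1 <- build_toy_references(seed = 99)
  r2 <- build_toy_references(seed = 99)
  expect_identical(lapply(r1$categories, as.character),
                   lapply(r2$categories, as.character))

  cfg <- simulator_config(seed = 5, n_reads = 300)
  l1 <- simulate_library(r1, cfg)
  l2 <- simulate_library(r2, cfg)
  f1 <- tempfile(fileext = ".fastq"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fastq"); t2 <- tempfile(fileext = ".tsv")
  write_library(l1, f1, t1)
  write_library(l2, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("zero reads and invalid configurations are handled", {
  refs <- toy_refs()
  lib <- simulate_library(refs, simulator_config(seed = 1, n_reads = 0))
  expect_identical(nrow(lib$reads), 0L)
  expect_identical(nrow(lib$truth), 0L)

  expect_error(simulator_config(reduction_factor = 0), "reduction_factor")
  expect_error(simulator_config(p_ca_cleavage = 1.5))
  expect_error(simulator_config(fragment_len_range = c(30, 20)))
  expect_error(build_toy_references(n_trna = 0), "counts")
})

test_that("truth table is faithful: boundaries, lengths, flanking bases", {
  lib <- clean_library()
  truth <- lib$truth
  seqs <- ref_seq_list()
  expect_identical(nrow(truth), nrow(lib$reads))
  expect_identical(anyDuplicated(truth$read_id), 0L)

  len <- truth$end - truth$start
  expect_true(all(len >= 20 & len <= 45))

  # re-extract flanking bases straight from the references
  rs <- seqs[truth$source_reference_id]
  up <- ifelse(truth$start > 0, substr(rs, truth$start, truth$start), NA)
  down <- ifelse(truth$end < nchar(rs),
                 substr(rs, truth$end + 1, truth$end + 1), NA)
  expect_identical(unname(up), truth$upstream_base)
  expect_identical(unname(down), truth$downstream_base)

  # error_rate = 0: every read is insert + adapter, insert matches the
  # reference slice except for the His U-1 substitution
  insert <- substr(lib$reads$seq, 1, nchar(lib$reads$seq) -
                     nchar(lib$config$adapter))
  ref_slice <- substr(rs, truth$start + 1, truth$end)
  plain <- is.na(truth$his_variant) | truth$his_variant != "U_minus1"
  expect_identical(insert[plain], unname(ref_slice[plain]))
  u1 <- !plain
  expect_true(all(substr(insert[u1], 1, 1) == "T"))
  expect_identical(substr(insert[u1], 2, nchar(insert[u1])),
                   unname(substr(ref_slice[u1], 2, nchar(ref_slice[u1]))))
})

test_that("pure C|A cleavage yields C|A boundaries for internal fragments", {
  truth <- clean_library()$truth
  internal <- !truth$is_spike_in &
    !is.na(truth$upstream_base) & !is.na(truth$downstream_base) &
    truth$source_category != "cyto_tRNA"
  expect_gt(sum(internal), 500)
  expect_true(all(truth$upstream_base[internal] == "C"))
  expect_true(all(truth$downstream_base[internal] == "A"))
  seqs <- ref_seq_list()
  first <- substr(seqs[truth$source_reference_id[internal]],
                  truth$start[internal] + 1, truth$start[internal] + 1)
  expect_true(all(first == "A"))
})

test_that("spike-in doping follows the configured fraction", {
  lib <- simulate_library(toy_refs(),
                          simulator_config(seed = 3, n_reads = 10000,
                                           spike_in_fraction = 0.05))
  n_spike <- sum(lib$truth$is_spike_in)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(n_spike, ci[1])
  expect_lte(n_spike, ci[2])
  expect_true(all(lib$truth$intended_fragment_class[lib$truth$is_spike_in]
                  %in% NA))
})

test_that("aging pair scales substrates but not the spike-in", {
  refs <- toy_refs()
  cfg <- simulator_config(seed = 21, n_reads = 30000, reduction_factor = 4,
                          error_rate = 0)
  pair <- simulate_aging_pair(refs, cfg)
  t1 <- pair$cond1$truth
  t2 <- pair$cond2$truth

  expect_gt(sum(t2$is_spike_in), 0)
  # spike-normalized substrate ratio recovers 1/reduction_factor
  r1 <- sum(!t1$is_spike_in) / sum(t1$is_spike_in)
  r2 <- sum(!t2$is_spike_in) / sum(t2$is_spike_in)
  expect_equal(r2 / r1, 0.25, tolerance = 0.15)

  # the mRNA table is exchangeable across conditions
  m <- pair$mrna
  agg <- tapply(m$count, list(m$substrate_id, m$condition), mean)
  expect_equal(unname(agg[, 1]), unname(agg[, 2]),
               tolerance = 0.4)

  # identity case: reduction_factor = 1 leaves the ratio at 1
  pair1 <- simulate_aging_pair(refs, simulator_config(
    seed = 22, n_reads = 20000, reduction_factor = 1, error_rate = 0))
  s1 <- pair1$cond1$truth; s2 <- pair1$cond2$truth
  q1 <- sum(!s1$is_spike_in) / sum(s1$is_spike_in)
  q2 <- sum(!s2$is_spike_in) / sum(s2$is_spike_in)
  expect_equal(q2 / q1, 1, tolerance = 0.15)
})
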