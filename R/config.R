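#' Default 3'-adapter sequence
#'
#' The library's 3'-adapter is configurable everywhere; this 20-nt default
#' (the common small-RNA 3'-adapter prefix) is shared by the simulator and
#' the trimmer so that simulated libraries round-trip bit-exactly.
#'
#' @return A 20-character DNA string.
#' @export
cp_default_adapter <- function() "TGGAATTCTCGGGTGCCAAG"

#' The 37-nt synthetic spike-in cP-RNA sequence (DNA alphabet)
#'
#' A synthetic cP-RNA of known sequence is doped into each library before
#' ligation; its read count is the normalization denominator across samples.
#'
#' @return A 37-character DNA string.
#' @export
cp_spike_in_sequence <- function() "CAGTGGTGGGCCAGATGTAAACATTAGATTGTTCTTG"

#' Category priority order for sequential mapping
#'
#' Reads are assigned to the first category in this order that yields at
#' least one placement within the mismatch budget.
#'
#' @return Character vector of category names.
#' @export
cp_categories <- function() {
  c("spike_in", "cyto_tRNA", "rRNA", "mito", "mRNA", "genome")
}

# Categories for which antisense placements are accepted. Mature tRNA, rRNA
# and the spike-in are single-stranded entities; only sense hits make sense.
cp_antisense_categories <- function() c("mito", "mRNA", "genome")

#' Simulator configuration
#'
#' Bundles the generative parameters of the cP-RNA biogenesis simulator.
#' Defaults state the world the analysis assumes: cleavage boundaries fall
#' at C|A dinucleotides with high probability (the terminal biases seen in
#' real libraries correspond to roughly 0.8), fragments span 20--45 nt, a
#' small spike-in dose, and a 4-fold cP-RNA reduction in the second
#' condition of an aging pair.
#'
#' @param seed Integer seed; identical configurations are byte-reproducible.
#' @param n_reads Number of reads to emit.
#' @param p_ca_cleavage Probability that each cleavage boundary is placed at
#'   a C|A dinucleotide; the remainder is uniform over other junctions.
#' @param fragment_len_range Integer `c(min, max)` fragment length in nt.
#' @param error_rate Per-base substitution probability applied to the final
#'   read (insert plus adapter).
#' @param spike_in_fraction Fraction of reads drawn from the spike-in.
#' @param category_weights Named sampling weights over substrate categories
#'   (normalized internally).
#' @param trna_class_weights Named weights over intended tRNA fragment
#'   classes (`FIVE_HALF`, `THREE_HALF`, `FIVE_TRF`, `THREE_TRF`, `I_TRF`).
#' @param his_variant_weights Named weights over tRNA-His 5'-variants
#'   (`G_minus1`, `U_minus1`, `G1`) for 5'-anchored His reads.
#' @param reduction_factor Multiplicative cP-RNA abundance reduction for
#'   condition 2 of [simulate_aging_pair()] (spike-in unaffected).
#' @param adapter 3'-adapter appended to every read.
#'
#' @return A list of class `cp_simulator_config`.
#' @export
simulator_config <- function(seed = 1L,
                             n_reads = 10000L,
                             p_ca_cleavage = 0.8,
                             fragment_len_range = c(20L, 45L),
                             error_rate = 0.001,
                             spike_in_fraction = 0.02,
                             category_weights = c(cyto_tRNA = 0.35,
                                                  rRNA = 0.20,
                                                  mito = 0.05,
                                                  mRNA = 0.20,
                                                  genome = 0.20),
                             trna_class_weights = c(FIVE_HALF = 0.60,
                                                    THREE_HALF = 0.25,
                                                    FIVE_TRF = 0.05,
                                                    THREE_TRF = 0.05,
                                                    I_TRF = 0.05),
                             his_variant_weights = c(G_minus1 = 0.6,
                                                     U_minus1 = 0.2,
                                                     G1 = 0.2),
                             reduction_factor = 4,
                             adapter = cp_default_adapter()) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    is.numeric(n_reads), length(n_reads) == 1L, n_reads >= 0,
    is.numeric(p_ca_cleavage), p_ca_cleavage >= 0, p_ca_cleavage <= 1,
    length(fragment_len_range) == 2L,
    fragment_len_range[1] >= 1, fragment_len_range[1] <= fragment_len_range[2],
    error_rate >= 0, error_rate <= 1,
    spike_in_fraction >= 0, spike_in_fraction <= 1,
    all(category_weights >= 0), sum(category_weights) > 0,
    all(trna_class_weights >= 0), sum(trna_class_weights) > 0,
    all(his_variant_weights >= 0), sum(his_variant_weights) > 0,
    nchar(adapter) > 0
  )
  if (reduction_factor <= 0) {
    stop("`reduction_factor` must be > 0", call. = FALSE)
  }
  missing_cat <- setdiff(names(category_weights), cp_categories())
  if (length(missing_cat)) {
    stop("unknown category in `category_weights`: ",
         paste(missing_cat, collapse = ", "), call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_reads = as.integer(n_reads),
    p_ca_cleavage = p_ca_cleavage,
    fragment_len_range = as.integer(fragment_len_range),
    error_rate = error_rate,
    spike_in_fraction = spike_in_fraction,
    category_weights = category_weights / sum(category_weights),
    trna_class_weights = trna_class_weights / sum(trna_class_weights),
    his_variant_weights = his_variant_weights / sum(his_variant_weights),
    reduction_factor = reduction_factor,
    adapter = toupper(adapter)
  )
  structure(cfg, class = "cp_simulator_config")
}

#' Pipeline configuration
#'
#' Parameters of the read-extraction and mapping stages.
#'
#' @param adapter_seq 3'-adapter sequence searched at read 3' ends.
#' @param min_len,max_len Inclusive length window applied after trimming
#'   (default 20--45 nt, the gel-purified size window).
#' @param max_mismatch Mismatch budget of the sequential mapper (default 1).
#' @param min_adapter_overlap Minimum adapter prefix overlap for trimming.
#' @param keep_untrimmed Keep reads in which no adapter was found? A genuine
#'   cP read must have ligated an adapter, so the default drops them.
#'
#' @return A list of class `cp_pipeline_config`.
#' @export
pipeline_config <- function(adapter_seq = cp_default_adapter(),
                            min_len = 20L,
                            max_len = 45L,
                            max_mismatch = 1L,
                            min_adapter_overlap = 5L,
                            keep_untrimmed = FALSE) {
  stopifnot(
    nchar(adapter_seq) > 0,
    min_len <= max_len, min_len >= 1,
    max_mismatch >= 0,
    min_adapter_overlap >= 1
  )
  structure(list(
    adapter_seq = toupper(adapter_seq),
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    max_mismatch = as.integer(max_mismatch),
    min_adapter_overlap = as.integer(min_adapter_overlap),
    keep_untrimmed = isTRUE(keep_untrimmed)
  ), class = "cp_pipeline_config")
}

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
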