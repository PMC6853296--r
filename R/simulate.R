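# ---------------------------------------------------------------------------
# Ground-truthed cP-RNA-seq read simulator.
#
# The generative model: an endoribonuclease cleaves substrate RNAs with a
# strong preference for C|A dinucleotide junctions (probability
# p_ca_cleavage per boundary; the remainder uniform over other junctions),
# leaving 2',3'-cyclic phosphates. Gel selection keeps 20-45 nt fragments; a
# synthetic spike-in of known sequence is doped in unfragmented; the
# 3'-adapter is ligated to every molecule. tRNA substrates are cleaved in
# the anticodon loop (halves) or yield tRFs; 3'-halves end predominantly at
# C75 (the C75|A76 cleavage), giving the 3'-CC subtype.
# ---------------------------------------------------------------------------

# Uniform draw from a:b that is safe when a == b (unlike sample(a:b, 1)).
sample_range <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

# Draw m boundary positions from the dinucleotide model: with probability p
# a C|A junction, otherwise uniform over the other junctions.
draw_boundaries <- function(m, p, ca, other) {
  if (m == 0L) return(integer(0))
  if (!length(ca) && !length(other)) return(rep(NA_integer_, m))
  use_ca <- if (length(ca)) runif(m) < p else rep(FALSE, m)
  if (!length(other)) use_ca <- rep(TRUE, m)
  out <- integer(m)
  out[use_ca] <- ca[sample.int(length(ca), sum(use_ca), replace = TRUE)]
  out[!use_ca] <- other[sample.int(length(other), sum(!use_ca),
                                   replace = TRUE)]
  out
}

# Fragment boundaries for m reads from a generic substrate (mRNA/rRNA/
# mito/genome). Boundaries are interior junctions (1..L-1), so generic
# fragments never touch the reference edge. Returns a list(start, end) of
# 0-based half-open coordinates, with NA rows for draws that never landed
# inside the length window.
draw_generic_fragments <- function(seq, m, p, len_range, max_iter = 1000L) {
  L <- nchar(seq)
  s <- rep(NA_integer_, m); e <- rep(NA_integer_, m)
  if (L - 1L < 1L || L < len_range[1]) return(list(start = s, end = e))
  ca <- ca_junctions(seq)
  other <- setdiff(seq_len(L - 1L), ca)
  todo <- seq_len(m)
  for (iter in seq_len(max_iter)) {
    if (!length(todo)) break
    b1 <- draw_boundaries(length(todo), p, ca, other)
    b2 <- draw_boundaries(length(todo), p, ca, other)
    lo <- pmin(b1, b2); hi <- pmax(b1, b2)
    ok <- !is.na(lo) & (hi - lo) >= len_range[1] & (hi - lo) <= len_range[2]
    s[todo[ok]] <- lo[ok]
    e[todo[ok]] <- hi[ok]
    todo <- todo[!ok]
  }
  list(start = s, end = e)
}

# Anticodon-loop cut boundaries for one tRNA record: boundary b means the
# 5'-part ends at index b-1 (np 32..38) and the 3'-part starts at index b.
loop_cut_boundaries <- function(seq, off) {
  b <- (off + 32L):(off + 38L)
  chars <- strsplit(seq, "")[[1]]
  is_ca <- chars[b] == "C" & chars[b + 1L] == "A"  # b is 0-based
  list(ca = b[is_ca], other = b[!is_ca])
}

# tRNA fragment coordinates for m reads of one record, honoring intended
# fragment classes and His -1 variants. Returns data.frame(start, end,
# class, his_variant, force_first_base).
draw_trna_fragments <- function(seq, ann_row, m, cfg) {
  off <- ann_row$np1_index
  np2idx <- function(np) off + np - 1L  # 0-based index of np (np >= 1)
  cls <- sample(names(cfg$trna_class_weights), m, replace = TRUE,
                prob = cfg$trna_class_weights)
  cuts <- loop_cut_boundaries(seq, off)
  p <- cfg$p_ca_cleavage
  start <- integer(m); end <- integer(m)
  his_variant <- rep(NA_character_, m)
  force_first <- rep(NA_character_, m)

  # 5'-anchored reads start at np 1; for the His record a -1 variant is
  # drawn (G-1 and U-1 start one base earlier; U-1 reads carry a U that the
  # G-1 reference does not).
  draw_5p_start <- function(k) {
    if (!isTRUE(ann_row$has_minus1)) {
      list(start = rep(0L, k), variant = rep(NA_character_, k),
           force = rep(NA_character_, k))
    } else {
      v <- sample(names(cfg$his_variant_weights), k, replace = TRUE,
                  prob = cfg$his_variant_weights)
      list(start = ifelse(v == "G1", 1L, 0L),
           variant = v,
           force = ifelse(v == "U_minus1", "T", NA_character_))
    }
  }

  for (class_ in unique(cls)) {
    i <- which(cls == class_)
    k <- length(i)
    if (class_ %in% c("FIVE_HALF", "FIVE_TRF")) {
      sp <- draw_5p_start(k)
      start[i] <- sp$start
      his_variant[i] <- sp$variant
      force_first[i] <- sp$force
      end[i] <- if (class_ == "FIVE_HALF") {
        draw_boundaries(k, p, cuts$ca, cuts$other)
      } else {
        np2idx(sample(20:31, k, replace = TRUE)) + 1L
      }
    } else if (class_ == "THREE_HALF") {
      start[i] <- draw_boundaries(k, p, cuts$ca, cuts$other)
      # 3' boundary: C75|A76 cleavage (3'-CC-half) with probability p,
      # otherwise uniform over the Di/C/CCA ends.
      use_cc <- runif(k) < p
      alt <- sample(c(73L, 74L, 76L), k, replace = TRUE)
      end_np <- ifelse(use_cc, 75L, alt)
      end[i] <- np2idx(end_np) + 1L
    } else if (class_ == "THREE_TRF") {
      e_np <- sample(73:76, k, replace = TRUE)
      # start at np >= 40: np 39 (= loop_end + 1) belongs to the 3'-half rule
      s_np <- vapply(e_np, function(en) {
        sample_range(40L, en - cfg$fragment_len_range[1] + 1L)
      }, 1L)
      start[i] <- np2idx(s_np)
      end[i] <- np2idx(e_np) + 1L
    } else {  # I_TRF
      s_np <- sample(2:53, k, replace = TRUE)
      len <- vapply(s_np, function(sn) {
        sample_range(cfg$fragment_len_range[1],
                     min(cfg$fragment_len_range[2], 72L - sn + 1L))
      }, 1L)
      start[i] <- np2idx(s_np)
      end[i] <- np2idx(s_np + len - 1L) + 1L
    }
  }
  data.frame(start = start, end = end, class = cls,
             his_variant = his_variant, force_first = force_first,
             stringsAsFactors = FALSE)
}

# Substitute bases at the given per-base error rate; substituted bases are
# drawn uniformly from the three alternatives.
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  flat_read <- rep(seq_along(seqs), lens)
  flat_pos <- sequence(lens)
  hit <- runif(length(flat_read)) < error_rate
  if (!any(hit)) return(seqs)
  idx_read <- flat_read[hit]
  idx_pos <- flat_pos[hit]
  for (j in seq_along(idx_read)) {
    r <- idx_read[j]; p <- idx_pos[j]
    old <- substr(seqs[r], p, p)
    new <- sample(setdiff(DNA_BASES, old), 1L)
    substr(seqs[r], p, p) <- new
  }
  seqs
}

#' Simulate one cP-RNA-seq library with ground truth
#'
#' Draws `cfg$n_reads` reads: a `spike_in_fraction` of them are the intact
#' 37-nt spike-in; the rest are substrate fragments whose boundaries follow
#' the C|A dinucleotide cleavage model at `p_ca_cleavage`, restricted to the
#' 20--45 nt window. tRNA reads follow the anticodon-loop half/tRF model
#' (see package vignette). The 3'-adapter is appended to every read and
#' per-base substitution errors are injected at `error_rate`.
#'
#' @param refs A `cp_refs` bundle from [build_toy_references()] or
#'   [read_reference_bundle()].
#' @param cfg A [simulator_config()].
#'
#' @return A list of class `cp_library`: `reads` (data frame `read_id`,
#'   `seq`, `qual`), `truth` (one row per read: `read_id`,
#'   `source_category`, `source_reference_id`, `start`, `end` 0-based
#'   half-open on the source reference, `upstream_base`, `downstream_base`
#'   reference bases flanking the fragment or NA at an edge,
#'   `intended_fragment_class`, `his_variant`, `is_spike_in`), and `config`.
#' @export
simulate_library <- function(refs, cfg) {
  stopifnot(inherits(refs, "cp_refs"), inherits(cfg, "cp_simulator_config"))
  with_rng(cfg$seed, simulate_library_impl(refs, cfg))
}

simulate_library_impl <- function(refs, cfg) {
  n <- cfg$n_reads
  empty <- data.frame(
    read_id = character(0), source_category = character(0),
    source_reference_id = character(0), start = integer(0), end = integer(0),
    upstream_base = character(0), downstream_base = character(0),
    intended_fragment_class = character(0), his_variant = character(0),
    is_spike_in = logical(0), stringsAsFactors = FALSE
  )
  if (n == 0L) {
    return(structure(list(
      reads = data.frame(read_id = character(0), seq = character(0),
                         qual = character(0), stringsAsFactors = FALSE),
      truth = empty, config = cfg), class = "cp_library"))
  }

  sub_w <- cfg$category_weights
  probs <- c(spike_in = cfg$spike_in_fraction,
             sub_w * (1 - cfg$spike_in_fraction))
  cats <- sample(names(probs), n, replace = TRUE, prob = probs)

  ref_id <- character(n); start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n)
  frag_class <- rep(NA_character_, n); his_variant <- rep(NA_character_, n)
  insert <- character(n)

  is_spike <- cats == "spike_in"
  if (any(is_spike)) {
    ref_id[is_spike] <- names(refs$categories$spike_in)[1]
    start[is_spike] <- 0L
    end[is_spike] <- nchar(cp_spike_in_sequence())
    insert[is_spike] <- cp_spike_in_sequence()
  }

  for (cat_ in setdiff(unique(cats), "spike_in")) {
    seqs <- ref_chars(refs, cat_)
    in_cat <- which(cats == cat_)
    pick <- sample.int(length(seqs), length(in_cat), replace = TRUE)
    for (r in unique(pick)) {
      i <- in_cat[pick == r]
      seq <- seqs[[r]]
      rid <- names(seqs)[r]
      if (cat_ == "cyto_tRNA") {
        ann_row <- refs$trna_annotation[refs$trna_annotation$ref_id == rid, ]
        fr <- draw_trna_fragments(seq, ann_row, length(i), cfg)
        start[i] <- fr$start; end[i] <- fr$end
        frag_class[i] <- fr$class; his_variant[i] <- fr$his_variant
        ins <- substr(rep(seq, length(i)), fr$start + 1L, fr$end)
        forced <- !is.na(fr$force_first)
        substr(ins[forced], 1L, 1L) <- fr$force_first[forced]
        insert[i] <- ins
      } else {
        fr <- draw_generic_fragments(seq, length(i), cfg$p_ca_cleavage,
                                     cfg$fragment_len_range)
        start[i] <- fr$start; end[i] <- fr$end
        ok <- !is.na(fr$start)
        insert[i[ok]] <- substr(rep(seq, sum(ok)),
                                fr$start[ok] + 1L, fr$end[ok])
      }
      ref_id[i] <- rid
    }
  }

  dropped <- is.na(start)
  if (any(dropped)) {
    warning(sum(dropped), " read(s) dropped: no fragment inside the length",
            " window for their substrate")
    keep <- !dropped
    cats <- cats[keep]; ref_id <- ref_id[keep]; start <- start[keep]
    end <- end[keep]; frag_class <- frag_class[keep]
    his_variant <- his_variant[keep]; insert <- insert[keep]
    is_spike <- is_spike[keep]
  }

  n_out <- length(insert)
  read_id <- sprintf("read%07d", seq_len(n_out))

  # flanking reference bases (NA at reference edges)
  all_seqs <- unlist(lapply(cp_categories(),
                            function(cat_) ref_chars(refs, cat_)))
  ref_seq <- all_seqs[ref_id]
  ref_len <- nchar(ref_seq)
  upstream <- ifelse(start > 0L, substr(ref_seq, start, start), NA_character_)
  downstream <- ifelse(end < ref_len, substr(ref_seq, end + 1L, end + 1L),
                       NA_character_)

  reads <- inject_errors(paste0(insert, cfg$adapter), cfg$error_rate)

  structure(list(
    reads = data.frame(read_id = read_id, seq = reads,
                       qual = strrep("I", nchar(reads)),
                       stringsAsFactors = FALSE),
    truth = data.frame(
      read_id = read_id, source_category = cats,
      source_reference_id = ref_id, start = start, end = end,
      upstream_base = upstream, downstream_base = downstream,
      intended_fragment_class = frag_class, his_variant = his_variant,
      is_spike_in = is_spike, stringsAsFactors = FALSE
    ),
    config = cfg
  ), class = "cp_library")
}

#' @export
print.cp_library <- function(x, ...) {
  cat(sprintf("cp_library: %d reads (%d spike-in), seed %d\n",
              nrow(x$reads), sum(x$truth$is_spike_in), x$config$seed))
  invisible(x)
}

#' Write a simulated library to FASTQ plus a truth table
#'
#' The truth table is TSV with a `# seed:` header line recording the
#' generator seed; coordinates stay 0-based half-open (this is a
#' machine-facing ground-truth artifact, not a report).
#'
#' @param lib A `cp_library`.
#' @param fastq_path Output FASTQ path (gzip if ending in `.gz`).
#' @param truth_path Output TSV path.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_library <- function(lib, fastq_path, truth_path) {
  write_fastq(lib$reads, fastq_path)
  con <- file(truth_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", lib$config$seed), con)
  write.table(lib$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fastq_path, truth_path))
}

#' Read a truth table written by [write_library()]
#' @param path TSV path.
#' @return The truth data frame.
#' @export
read_truth_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             na.strings = "NA")
}

#' Simulate a two-condition (aging) pair of libraries
#'
#' Condition 1 follows `cfg` exactly. In condition 2 the expected substrate
#' read yield is scaled by `1/cfg$reduction_factor` while the expected
#' spike-in yield is unchanged — the sequenced pool mirrors a genuine drop
#' in cP-RNA abundance against a fixed spike-in dose. A substrate mRNA
#' expression table (identical in expectation across conditions, Poisson
#' replicate noise) is emitted alongside, standing in for an external
#' mRNA-seq quantification.
#'
#' @param refs A `cp_refs` bundle.
#' @param cfg A [simulator_config()]; `seed` drives both libraries (they use
#'   derived seeds) and the mRNA table.
#' @param n_mrna_replicates mRNA-seq replicates per condition (default 3).
#'
#' @return A list of class `cp_aging_pair`: `cond1`, `cond2`
#'   (`cp_library`), and `mrna` (data frame `sample_id`, `condition`,
#'   `substrate_id`, `length_nt`, `count`, `rpkm`).
#' @export
simulate_aging_pair <- function(refs, cfg, n_mrna_replicates = 3L) {
  stopifnot(inherits(refs, "cp_refs"), inherits(cfg, "cp_simulator_config"))
  if (cfg$reduction_factor <= 0) {
    stop("`reduction_factor` must be > 0", call. = FALSE)
  }
  r <- cfg$reduction_factor
  n <- cfg$n_reads
  f <- cfg$spike_in_fraction

  cfg1 <- cfg
  cfg1$seed <- (cfg$seed * 2L + 1L) %% .Machine$integer.max
  lib1 <- simulate_library(refs, cfg1)

  # condition 2: same expected spike yield, substrate yield scaled by 1/r
  n_spike2 <- n * f
  n_sub2 <- n * (1 - f) / r
  cfg2 <- cfg
  cfg2$seed <- (cfg$seed * 2L + 2L) %% .Machine$integer.max
  cfg2$n_reads <- as.integer(round(n_spike2 + n_sub2))
  cfg2$spike_in_fraction <- if (cfg2$n_reads > 0) n_spike2 /
    (n_spike2 + n_sub2) else 0
  lib2 <- simulate_library(refs, cfg2)

  mrna_ids <- names(refs$categories$mRNA)
  mrna_len <- nchar(ref_chars(refs, "mRNA"))
  mrna <- with_rng(cfg$seed * 2L + 3L, {
    lambda <- rlnorm(length(mrna_ids), meanlog = log(500), sdlog = 1)
    rows <- list()
    for (cond in 1:2) {
      for (rep_ in seq_len(n_mrna_replicates)) {
        counts <- rpois(length(mrna_ids), lambda)
        total <- sum(counts)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("mrna_c%d_r%d", cond, rep_),
          condition = cond,
          substrate_id = mrna_ids,
          length_nt = as.integer(mrna_len),
          count = counts,
          rpkm = if (total > 0) counts * 1e9 / (mrna_len * total) else 0,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
  structure(list(cond1 = lib1, cond2 = lib2, mrna = mrna),
            class = "cp_aging_pair")
}
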