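# ---------------------------------------------------------------------------
# Terminal and flanking nucleotide composition, cleavage-site inference and
# per-substrate alignment profiles: the analyses that expose the C|A
# cleavage signature (fragments start with A after an upstream C, and end
# with C before a downstream A).
# ---------------------------------------------------------------------------

RNA_ROWS <- c("A", "C", "G", "U")

# Tabulate A/C/G/U fractions of a character matrix column.
base_fractions <- function(bases) {
  bases[bases == "T"] <- "U"
  tab <- table(factor(bases, levels = RNA_ROWS))
  n <- sum(tab)
  list(frac = if (n > 0) as.numeric(tab) / n else rep(NA_real_, 4L), n = n)
}

new_composition <- function(mat, n_per_pos, n_reads) {
  structure(list(fractions = mat, n_per_position = n_per_pos,
                 n_reads = n_reads),
            class = "cp_composition")
}

#' @export
print.cp_composition <- function(x, ...) {
  cat(sprintf("cp_composition over %d reads\n", x$n_reads))
  print(round(x$fractions, 3))
  invisible(x)
}

#' Per-position nucleotide composition from a read end
#'
#' Position `p` tabulates the `p`-th base counted from the chosen end, over
#' every read of length at least `p` (shorter reads contribute only to the
#' positions they cover). Output uses the RNA alphabet (T reported as U).
#'
#' @param seqs Character vector of read or fragment sequences.
#' @param end Which end to count from: `5` or `3`.
#' @param n_positions Number of positions (default 30).
#'
#' @return A `cp_composition`: `fractions` is a 4 x `n_positions` matrix
#'   (rows A/C/G/U, columns positions 1..n from the chosen end; columns sum
#'   to 1 where covered), `n_per_position` the per-column denominators.
#' @export
end_composition <- function(seqs, end = 5L, n_positions = 30L) {
  stopifnot(end %in% c(5L, 3L), n_positions >= 1)
  mat <- matrix(NA_real_, nrow = 4L, ncol = n_positions,
                dimnames = list(RNA_ROWS, seq_len(n_positions)))
  n_per <- integer(n_positions)
  if (length(seqs)) {
    lens <- nchar(seqs)
    for (p in seq_len(n_positions)) {
      cover <- lens >= p
      if (!any(cover)) next
      at <- if (end == 5L) p else lens[cover] - p + 1L
      bases <- substr(seqs[cover], at, at)
      bf <- base_fractions(bases)
      mat[, p] <- bf$frac
      n_per[p] <- bf$n
    }
  }
  new_composition(mat, n_per, length(seqs))
}

# Reference sequences of a bundle as one named character vector.
all_ref_chars <- function(refs) {
  unlist(lapply(cp_categories(), function(cat_) ref_chars(refs, cat_)))
}

# Flanking reference bases of aligned fragments, strand-aware and
# fragment-oriented: `upstream` lists the k bases 5' of the fragment in
# fragment orientation (labels -k..-1, -1 adjacent), `downstream` the k
# bases 3' of it (+1..+k). Positions beyond the reference edge are NA.
flank_bases <- function(assignments, refs, k = 4L) {
  aln <- assignments[assignments$category != "unmapped" &
                       !is.na(assignments$start), , drop = FALSE]
  n <- nrow(aln)
  up <- matrix(NA_character_, n, k,
               dimnames = list(NULL, as.character(-k:-1)))
  down <- matrix(NA_character_, n, k,
                 dimnames = list(NULL, paste0("+", 1:k)))
  if (!n) return(list(upstream = up, downstream = down, aln = aln))
  seqs <- all_ref_chars(refs)
  ref_seq <- seqs[aln$ref_id]
  ref_len <- nchar(ref_seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (j in seq_len(k)) {
    # plus strand: upstream label -j is reference index start - j (0-based)
    pos_up <- ifelse(aln$strand == "+", aln$start - j + 1L,
                     aln$end + j)              # 1-based reference position
    pos_down <- ifelse(aln$strand == "+", aln$end + j, aln$start - j + 1L)
    ok_up <- pos_up >= 1L & pos_up <= ref_len
    ok_down <- pos_down >= 1L & pos_down <= ref_len
    b_up <- ifelse(ok_up, substr(ref_seq, pos_up, pos_up), NA_character_)
    b_down <- ifelse(ok_down, substr(ref_seq, pos_down, pos_down),
                     NA_character_)
    minus <- aln$strand == "-"
    b_up[minus] <- unname(comp[b_up[minus]])
    b_down[minus] <- unname(comp[b_down[minus]])
    up[, k - j + 1L] <- b_up
    down[, j] <- b_down
  }
  list(upstream = up, downstream = down, aln = aln)
}

#' Flanking reference-context composition of aligned fragments
#'
#' Retrieves the `k` reference bases upstream (-k..-1) and downstream
#' (+1..+k) of every mapped fragment (strand-aware: for antisense
#' placements the flanks are reverse-complemented so that -1 is always the
#' base immediately 5' of the fragment in its own orientation) and
#' tabulates their composition. Fragments at a reference edge contribute
#' only the positions that exist.
#'
#' @param assignments A `cp_assignments` data frame.
#' @param refs A `cp_refs` bundle.
#' @param k Flank width in nt (default 4).
#'
#' @return A `cp_composition` with columns `-k..-1, +1..+k`.
#' @export
flanking_context <- function(assignments, refs, k = 4L) {
  fb <- flank_bases(assignments, refs, k)
  cols <- cbind(fb$upstream, fb$downstream)
  mat <- matrix(NA_real_, 4L, ncol(cols),
                dimnames = list(RNA_ROWS, colnames(cols)))
  n_per <- integer(ncol(cols))
  for (j in seq_len(ncol(cols))) {
    bases <- cols[, j]
    bases <- bases[!is.na(bases)]
    bf <- base_fractions(bases)
    mat[, j] <- bf$frac
    n_per[j] <- bf$n
  }
  new_composition(mat, n_per, nrow(fb$aln))
}

#' Fraction of fragments with the C|A boundary signature
#'
#' A 5' boundary carries the signature when the upstream reference base is
#' C and the fragment's first base is A; a 3' boundary when the fragment's
#' last base is C and the downstream reference base is A. Fragments whose
#' relevant flank lies outside the reference (edge fragments) are excluded
#' from that boundary's denominator.
#'
#' @param assignments A `cp_assignments` data frame.
#' @param refs A `cp_refs` bundle.
#'
#' @return List `five_prime`, `three_prime`, `both` (fractions, NA when no
#'   eligible fragment), and the denominators `n_five`, `n_three`,
#'   `n_both`.
#' @export
ca_boundary_fraction <- function(assignments, refs) {
  fb <- flank_bases(assignments, refs, k = 1L)
  aln <- fb$aln
  if (!nrow(aln)) {
    return(list(five_prime = NA_real_, three_prime = NA_real_,
                both = NA_real_, n_five = 0L, n_three = 0L, n_both = 0L))
  }
  first <- substr(aln$seq, 1L, 1L)
  last <- substr(aln$seq, nchar(aln$seq), nchar(aln$seq))
  up <- fb$upstream[, 1L]
  down <- fb$downstream[, 1L]
  ok5 <- !is.na(up)
  ok3 <- !is.na(down)
  five_ca <- up == "C" & first == "A"
  three_ca <- last == "C" & down == "A"
  both_ok <- ok5 & ok3
  list(
    five_prime = if (any(ok5)) mean(five_ca[ok5]) else NA_real_,
    three_prime = if (any(ok3)) mean(three_ca[ok3]) else NA_real_,
    both = if (any(both_ok)) mean(five_ca[both_ok] & three_ca[both_ok])
      else NA_real_,
    n_five = sum(ok5), n_three = sum(ok3), n_both = sum(both_ok)
  )
}

#' Infer anticodon-loop cleavage sites from half calls
#'
#' A 5'-half ending at reference index `i` (0-based) votes for the
#' inter-nucleotide boundary between `i` and `i+1`; a 3'-half starting at
#' index `j` votes for the boundary between `j-1` and `j`. A boundary
#' supported by both counters is "concordant" — the paired-arrowhead
#' pattern expected when both products of one endonucleolytic cut are
#' captured. Boundaries are reported in np coordinates (np of the base 5'
#' of the cut).
#'
#' @param calls A `cp_fragment_calls` data frame.
#' @param annotation tRNA annotation data frame.
#'
#' @return Data frame of class `cp_cleavage_profile`: `ref_id`,
#'   `boundary_np`, `n_from_five_half`, `n_from_three_half`, `concordant`.
#' @export
infer_cleavage_sites <- function(calls, annotation) {
  halves <- calls[calls$fragment_class %in% c("FIVE_HALF", "THREE_HALF"), ,
                  drop = FALSE]
  out <- list()
  for (rid in unique(halves$ref_id)) {
    h <- halves[halves$ref_id == rid, , drop = FALSE]
    b5 <- h$np_end[h$fragment_class == "FIVE_HALF"]       # cut after np_end
    b3 <- h$np_start[h$fragment_class == "THREE_HALF"] - 1L
    tab5 <- table(b5)
    tab3 <- table(b3)
    bs <- sort(unique(c(as.integer(names(tab5)), as.integer(names(tab3)))))
    if (!length(bs)) next
    n5 <- as.integer(tab5[as.character(bs)])
    n3 <- as.integer(tab3[as.character(bs)])
    n5[is.na(n5)] <- 0L
    n3[is.na(n3)] <- 0L
    out[[rid]] <- data.frame(ref_id = rid, boundary_np = bs,
                             n_from_five_half = n5, n_from_three_half = n3,
                             concordant = n5 > 0L & n3 > 0L,
                             stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(ref_id = character(0), boundary_np = integer(0),
               n_from_five_half = integer(0), n_from_three_half = integer(0),
               concordant = logical(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("cp_cleavage_profile", "data.frame")
  res
}

#' Modal cleavage boundary per tRNA
#'
#' The boundary with the highest combined (5'-half + 3'-half) support;
#' ties break toward the smallest np.
#'
#' @param profile A `cp_cleavage_profile`.
#' @return Data frame `ref_id`, `boundary_np`, `n_support`, `concordant`.
#' @export
modal_cleavage_boundary <- function(profile) {
  out <- lapply(split(profile, profile$ref_id), function(p) {
    tot <- p$n_from_five_half + p$n_from_three_half
    i <- which(tot == max(tot))[1L]
    data.frame(ref_id = p$ref_id[1L], boundary_np = p$boundary_np[i],
               n_support = tot[i], concordant = p$concordant[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-position alignment profile of one reference
#'
#' Read-start counts, read-end counts and coverage along a reference, plus
#' the most frequent identical (start, end) intervals — the data behind a
#' per-substrate alignment panel.
#'
#' @param assignments A `cp_assignments` data frame (any categories; rows
#'   not on `ref_id` are ignored).
#' @param ref_id Reference to profile.
#' @param ref_length Reference length in nt.
#' @param n_top Number of top intervals to report.
#'
#' @return List of class `cp_profile`: `ref_id`, `start_counts`,
#'   `end_counts` (length `ref_length`, 0-based position `i` stored at
#'   `i+1`; end counts index the last covered base), `coverage`, and
#'   `top_intervals` (data frame `start`, `end`, `count`).
#' @export
alignment_profile <- function(assignments, ref_id, ref_length,
                              n_top = 10L) {
  aln <- assignments[!is.na(assignments$ref_id) &
                       assignments$ref_id == ref_id, , drop = FALSE]
  start_counts <- integer(ref_length)
  end_counts <- integer(ref_length)
  coverage <- integer(ref_length)
  top <- data.frame(start = integer(0), end = integer(0), count = integer(0),
                    stringsAsFactors = FALSE)
  if (nrow(aln)) {
    st <- table(aln$start)
    en <- table(aln$end - 1L)
    start_counts[as.integer(names(st)) + 1L] <- as.integer(st)
    end_counts[as.integer(names(en)) + 1L] <- as.integer(en)
    delta <- integer(ref_length + 1L)
    for (i in seq_len(nrow(aln))) {
      delta[aln$start[i] + 1L] <- delta[aln$start[i] + 1L] + 1L
      delta[aln$end[i] + 1L] <- delta[aln$end[i] + 1L] - 1L
    }
    coverage <- cumsum(delta)[seq_len(ref_length)]
    key <- paste(aln$start, aln$end, sep = ":")
    tab <- sort(table(key), decreasing = TRUE)
    tab <- head(tab, n_top)
    parts <- strsplit(names(tab), ":", fixed = TRUE)
    top <- data.frame(
      start = vapply(parts, function(p) as.integer(p[1]), 1L),
      end = vapply(parts, function(p) as.integer(p[2]), 1L),
      count = as.integer(tab), stringsAsFactors = FALSE
    )
  }
  structure(list(ref_id = ref_id, start_counts = start_counts,
                 end_counts = end_counts, coverage = coverage,
                 top_intervals = top),
            class = "cp_profile")
}

#' Read-length histogram per category
#'
#' @param assignments A `cp_assignments` data frame.
#' @param min_len,max_len Histogram support (defaults 20 and 45 nt).
#' @return Matrix of counts, rows = categories (including `unmapped`),
#'   columns = lengths `min_len..max_len` (lengths outside the window are
#'   clamped into the terminal bins).
#' @export
length_distribution <- function(assignments, min_len = 20L, max_len = 45L) {
  lens <- pmin(pmax(nchar(assignments$seq), min_len), max_len)
  cats <- factor(assignments$category,
                 levels = c(cp_categories(), "unmapped"))
  table(cats, factor(lens, levels = min_len:max_len))
}
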