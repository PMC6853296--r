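# ---------------------------------------------------------------------------
# tRNA fragment taxonomy.
#
# Reads mapped to a mature cytoplasmic tRNA are classified by where they
# start and end in canonical tRNA numbering (np): np 1 is the first body
# base, np -1 the extra 5' base unique to tRNA-His, np 32-38 the anticodon
# loop, np 73 the discriminator, np 74-76 the post-transcriptional CCA.
# Classes, in precedence order:
#   FIVE_HALF : starts at np 1 (np -1 for His) and ends inside the loop
#   THREE_HALF: starts inside the loop (or at loop_end + 1) and reaches
#               np >= 73
#   FIVE_TRF  : starts at np 1 and ends before the loop
#   THREE_TRF : reaches np >= 73 and starts after the loop
#   I_TRF     : everything else
# 3'-halves are subtyped by their last base: np 76 -> CCA, 75 -> CC,
# 74 -> C, 73 -> Di (ends at the discriminator).
# ---------------------------------------------------------------------------

#' Classify tRNA-mapped reads into the fragment taxonomy
#'
#' Applies the precedence-ordered half/tRF rules (see Details) to every
#' alignment in the `cyto_tRNA` category, subtypes 3'-halves by their
#' 3'-terminal np, and calls the -1 variant (`G_minus1`, `U_minus1`, `G1`)
#' for 5'-anchored reads on records carrying a -1 nucleotide (tRNA-His).
#' The -1 variant is read from the read's own first base, so a U-1 read
#' aligned (with one mismatch) to a G-1 reference is still called
#' `U_minus1`.
#'
#' @param assignments A `cp_assignments` data frame ([map_sequential()]).
#' @param annotation tRNA annotation data frame (`ref_id`, `isoacceptor`,
#'   `loop_start`, `loop_end` 0-based inclusive, `has_minus1`,
#'   `minus1_base`, `np1_index`), e.g. `refs$trna_annotation`.
#'
#' @return Data frame of class `cp_fragment_calls`, one row per tRNA-mapped
#'   read: `read_id`, `ref_id`, `isoacceptor`, `fragment_class`,
#'   `three_half_subtype` (`none` unless `THREE_HALf`), `his_variant`
#'   (`none` for non-His records), `start`, `end`, `np_start`, `np_end`.
#' @export
classify_fragments <- function(assignments, annotation) {
  stopifnot(is.data.frame(annotation),
            all(c("ref_id", "isoacceptor", "loop_start", "loop_end",
                  "has_minus1", "np1_index") %in% names(annotation)))
  aln <- assignments[assignments$category == "cyto_tRNA", , drop = FALSE]
  if (!nrow(aln)) {
    out <- data.frame(read_id = character(0), ref_id = character(0),
                      isoacceptor = character(0),
                      fragment_class = character(0),
                      three_half_subtype = character(0),
                      his_variant = character(0),
                      start = integer(0), end = integer(0),
                      np_start = integer(0), np_end = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("cp_fragment_calls", "data.frame")
    return(out)
  }
  idx <- match(aln$ref_id, annotation$ref_id)
  if (anyNA(idx)) {
    stop("tRNA alignment to a reference absent from the annotation: ",
         paste(unique(aln$ref_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  ann <- annotation[idx, , drop = FALSE]
  off <- ann$np1_index                     # 0-based index of np 1
  np_start <- ifelse(ann$has_minus1 & aln$start == 0L, -1L,
                     aln$start - off + 1L)
  np_end <- (aln$end - 1L) - off + 1L      # np of the last aligned base
  loop_lo <- ann$loop_start - off + 1L     # np of loop start (32)
  loop_hi <- ann$loop_end - off + 1L       # np of loop end (38)

  starts_5p <- np_start == 1L | np_start == -1L
  end_in_loop <- np_end >= loop_lo & np_end <= loop_hi
  start_in_loop <- np_start >= loop_lo & np_start <= loop_hi + 1L
  reaches_3p <- np_end >= 73L

  fragment_class <- ifelse(
    starts_5p & end_in_loop, "FIVE_HALF", ifelse(
      start_in_loop & reaches_3p, "THREE_HALF", ifelse(
        starts_5p & np_end < loop_lo, "FIVE_TRF", ifelse(
          reaches_3p & np_start > loop_hi, "THREE_TRF", "I_TRF"))))

  subtype <- rep("none", nrow(aln))
  is_3h <- fragment_class == "THREE_HALF"
  subtype[is_3h] <- c(`73` = "DI", `74` = "C", `75` = "CC",
                      `76` = "CCA")[as.character(np_end[is_3h])]

  his_variant <- rep("none", nrow(aln))
  his <- which(ann$has_minus1)
  if (length(his)) {
    first_base <- substr(aln$seq[his], 1L, 1L)
    his_variant[his] <- ifelse(
      np_start[his] == -1L & first_base == "G", "G_minus1", ifelse(
        np_start[his] == -1L & first_base %in% c("T", "U"), "U_minus1",
        ifelse(np_start[his] == 1L, "G1", "none")))
  }

  out <- data.frame(
    read_id = aln$read_id, ref_id = aln$ref_id,
    isoacceptor = ann$isoacceptor,
    fragment_class = fragment_class,
    three_half_subtype = subtype,
    his_variant = his_variant,
    start = aln$start, end = aln$end,
    np_start = np_start, np_end = np_end,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("cp_fragment_calls", "data.frame")
  out
}

#' Subtype of a single 3'-half by its 3'-terminal np
#'
#' @param np_end np of the read's last base (must be >= 73).
#' @return `"CCA"`, `"CC"`, `"C"` or `"DI"`.
#' @export
subtype_three_half <- function(np_end) {
  if (any(np_end < 73L | np_end > 76L)) {
    stop("not a 3'-half: 3' end must lie at np 73..76", call. = FALSE)
  }
  unname(c(`73` = "DI", `74` = "C", `75` = "CC",
           `76` = "CCA")[as.character(np_end)])
}

#' Per-class and per-subtype summaries of fragment calls
#'
#' @param calls A `cp_fragment_calls` data frame.
#' @return List with `classes` (data frame `fragment_class`, `n`,
#'   `fraction`) and `three_half_subtypes` (fractions over 3'-halves).
#' @export
fragment_class_summary <- function(calls) {
  tab <- table(factor(calls$fragment_class,
                      levels = c("FIVE_HALF", "THREE_HALF", "FIVE_TRF",
                                 "THREE_TRF", "I_TRF")))
  classes <- data.frame(fragment_class = names(tab), n = as.integer(tab),
                        fraction = if (sum(tab) > 0)
                          as.numeric(tab) / sum(tab) else rep(NA_real_,
                                                              length(tab)),
                        stringsAsFactors = FALSE)
  th <- calls$three_half_subtype[calls$fragment_class == "THREE_HALF"]
  tab3 <- table(factor(th, levels = c("CCA", "CC", "C", "DI")))
  subtypes <- data.frame(subtype = names(tab3), n = as.integer(tab3),
                         fraction = if (sum(tab3) > 0)
                           as.numeric(tab3) / sum(tab3) else
                             rep(NA_real_, length(tab3)),
                         stringsAsFactors = FALSE)
  list(classes = classes, three_half_subtypes = subtypes)
}

#' Isoacceptor proportions among 5'-halves
#'
#' @param calls A `cp_fragment_calls` data frame.
#' @return Data frame `isoacceptor`, `n`, `fraction`, sorted descending.
#' @export
isoacceptor_proportions <- function(calls) {
  fh <- calls[calls$fragment_class == "FIVE_HALF", , drop = FALSE]
  if (!nrow(fh)) {
    stop("no 5'-half calls", call. = FALSE)
  }
  tab <- table(fh$isoacceptor)
  out <- data.frame(isoacceptor = names(tab), n = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
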