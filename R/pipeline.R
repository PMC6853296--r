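# ---------------------------------------------------------------------------
# End-to-end pipeline: trim -> select -> map -> classify -> signature ->
# quantify, with TSV/SAM/BED/bedGraph products and a reproducibility
# manifest.
# ---------------------------------------------------------------------------

#' Run the full cP-RNA-seq analysis on one library
#'
#' Executes adapter trimming, length selection, sequential mapping, tRNA
#' fragment classification, the cleavage-signature analyses and spike-in
#' quantification, writing every product into `out_dir`. The stage
#' bookkeeping satisfies the conservation identity: input reads =
#' trim/length-discarded + unmapped + sum of category counts.
#'
#' @param fastq Input FASTQ path, or a data frame of reads (`read_id`,
#'   `seq`).
#' @param refs A `cp_refs` bundle or a directory readable by
#'   [read_reference_bundle()].
#' @param out_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @param sample_id Sample label used in reports.
#'
#' @return A list of class `cp_run`: `preprocessed`, `assignments`,
#'   `fragment_calls`, `category_proportions`, `norm_expr`, `stage_counts`,
#'   `out_dir`.
#' @export
run_pipeline <- function(fastq, refs, out_dir,
                         config = pipeline_config(),
                         sample_id = "sample1") {
  if (is.character(refs)) refs <- read_reference_bundle(refs)
  stopifnot(inherits(refs, "cp_refs"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- if (is.data.frame(fastq)) fastq else read_fastq(fastq)
  input_paths <- if (is.character(fastq)) fastq else character(0)

  pre <- preprocess_reads(reads, config)
  aln <- map_sequential(pre$reads, refs, config$max_mismatch)
  calls <- classify_fragments(aln, refs$trna_annotation)
  props <- category_proportions(aln)
  norm <- quantify_library(aln, refs, sample_id)

  comp5 <- end_composition(aln$seq[aln$category != "unmapped"], 5L)
  comp3 <- end_composition(aln$seq[aln$category != "unmapped"], 3L)
  flank <- flanking_context(aln, refs)
  cleave <- infer_cleavage_sites(calls, refs$trna_annotation)

  cat_tab <- table(factor(aln$category,
                          levels = c(cp_categories(), "unmapped")))
  stage_counts <- c(
    n_input = nrow(reads),
    n_adapter_found = pre$summary$n_adapter_found,
    n_length_selected = pre$summary$n_length_selected,
    n_discarded_preprocess = nrow(reads) - nrow(pre$reads),
    setNames(as.integer(cat_tab), paste0("n_", names(cat_tab)))
  )

  p <- function(f) file.path(out_dir, f)
  write_fastq(cbind(pre$reads,
                    qual = strrep("I", nchar(pre$reads$seq))),
              p("extracted.fastq"))
  write_tsv_report(pre$summary, p("preprocess_summary.tsv"))
  write_sam(aln, refs, p("alignments.sam"))
  write_bed(aln, p("alignments.bed"))
  write_tsv_report(props, p("category_proportions.tsv"))
  write_tsv_report(as.data.frame(calls), p("fragment_calls.tsv"))
  summ <- fragment_class_summary(calls)
  write_tsv_report(summ$classes, p("fragment_class_summary.tsv"))
  write_tsv_report(summ$three_half_subtypes, p("three_half_subtypes.tsv"))
  write_tsv_report(as.data.frame(cleave), p("cleavage_profile.tsv"))
  write_composition_tsv(comp5, p("composition_5p.tsv"))
  write_composition_tsv(comp3, p("composition_3p.tsv"))
  write_composition_tsv(flank, p("composition_flanking.tsv"))
  write_tsv_report(as.data.frame(norm), p("normalized_expression.tsv"))

  for (cat_ in c("mRNA", "rRNA")) {
    seqs <- ref_chars(refs, cat_)
    if (!length(seqs)) next
    counts <- table(aln$ref_id[aln$category == cat_])
    if (!length(counts)) next
    top_ref <- names(counts)[which.max(counts)]
    prof <- alignment_profile(aln, top_ref, nchar(seqs[[top_ref]]))
    write_bedgraph(prof, p(sprintf("profile_%s.bedgraph", top_ref)))
    write_tsv_report(prof$top_intervals,
                     p(sprintf("top_intervals_%s.tsv", top_ref)))
  }

  write_run_manifest(p("manifest.json"), config, stage_counts,
                     inputs = input_paths)

  structure(list(
    preprocessed = pre, assignments = aln, fragment_calls = calls,
    category_proportions = props, norm_expr = norm,
    stage_counts = stage_counts, out_dir = out_dir
  ), class = "cp_run")
}

#' Write a composition matrix as TSV
#'
#' Positions as rows, A/C/G/U fractions and the per-position denominator
#' as columns.
#'
#' @param comp A `cp_composition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(comp, path) {
  df <- data.frame(position = colnames(comp$fractions),
                   t(comp$fractions),
                   n = comp$n_per_position,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-condition differential comparison from mapped libraries
#'
#' Quantifies each condition's libraries with spike-in normalization and
#' builds the fold-change table against an external mRNA expression table.
#'
#' @param assignments_cond1,assignments_cond2 Lists of `cp_assignments`
#'   (one per replicate).
#' @param refs A `cp_refs` bundle.
#' @param mrna Data frame `sample_id`, `condition`, `substrate_id`,
#'   `rpkm` (e.g. the `mrna` element of [simulate_aging_pair()]).
#' @param min_count Passed to [fold_change_table()].
#' @return A `cp_fold_changes` object.
#' @export
differential_analysis <- function(assignments_cond1, assignments_cond2,
                                  refs, mrna, min_count = 10) {
  quant <- function(alns, cond) {
    do.call(rbind, lapply(seq_along(alns), function(i) {
      quantify_library(alns[[i]], refs,
                       sample_id = sprintf("cp_c%d_r%d", cond, i))
    }))
  }
  cp1 <- quant(assignments_cond1, 1L)
  cp2 <- quant(assignments_cond2, 2L)
  fold_change_table(cp1, cp2,
                    mrna[mrna$condition == 1, , drop = FALSE],
                    mrna[mrna$condition == 2, , drop = FALSE],
                    min_count = min_count)
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()] and
#' [simulator_config()] under top-level `pipeline:` and `simulator:`
#' sections.
#'
#' @param path YAML path.
#' @return List with `pipeline` ([pipeline_config()]) and `simulator`
#'   ([simulator_config()]) entries.
#' @export
load_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  pl <- do.call(pipeline_config, raw$pipeline %||% list())
  sim_args <- raw$simulator %||% list()
  for (nm in c("category_weights", "trna_class_weights",
               "his_variant_weights")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  sim <- do.call(simulator_config, sim_args)
  list(pipeline = pl, simulator = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
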