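# Pipeline orchestration: the four analysis steps (preprocess, classify,
# extract-rt, date, tree) as independently runnable stages over a shared
# result directory, with element-wise parallelism and a deterministic merge
# so output bytes do not depend on the worker count.

STEP_NAMES <- c("preprocess", "classify", "extract-rt", "date", "tree", "all")

#' Run the LTR retrotransposon pipeline
#'
#' Steps, in order:
#' * `preprocess` — read the element input (predictor report, or FASTA with
#'   internal LTR-pair scanning), scan all elements for protein-domain hits
#'   against the reference library, and write the normalized report, a
#'   feature table and the hit table.
#' * `classify` — apply the classification decision tree and (optionally)
#'   the 80/80/80 rescue; write the classification table, one FASTA + TSV
#'   per category found, and the no-class list.
#' * `extract-rt` — extract and translate RT domains of autonomous elements
#'   (200-aa filter); write the RT FASTA and the rejection table.
#' * `date` — date every element from its 5'/3'-LTR divergence; write the
#'   insertion-time table and age histograms (per lineage and per
#'   superfamily/category).
#' * `tree` — align the RT domains and build the neighbor-joining tree;
#'   write the MSA FASTA and the newick tree.
#' * `all` — the above in sequence.
#'
#' Each later step reads the files written by earlier steps from
#' `result_dir`; invoking it without them is an error naming the missing
#' step. Element-level work is distributed across `workers` (forked) and
#' merged in input order, so outputs are byte-identical for any worker
#' count.
#'
#' @param step one of `r paste(STEP_NAMES, collapse = ", ")`.
#' @param config an `ltr_config` or the path to a configuration file.
#' @param workers number of parallel workers for element-level work.
#' @return Invisibly, a named list of the files written by the step(s).
#' @export
ltr_run <- function(step = "all", config = default_config(), workers = 1L) {
  if (!is.character(step) || length(step) != 1L || !step %in% STEP_NAMES)
    stop(usage_error("unknown step '", paste(step, collapse = ","),
                     "'; expected one of ", paste(STEP_NAMES, collapse = ", ")))
  cfg <- if (is.character(config)) parse_config(config) else config
  if (!inherits(cfg, "ltr_config")) cfg <- validate_config(cfg)
  dir.create(cfg$result_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$rng_seed)
  steps <- if (step == "all") STEP_NAMES[STEP_NAMES != "all"] else step
  outputs <- list()
  for (s in steps) {
    outputs <- c(outputs, switch(s,
      "preprocess" = step_preprocess(cfg, workers),
      "classify" = step_classify(cfg, workers),
      "extract-rt" = step_extract_rt(cfg),
      "date" = step_date(cfg),
      "tree" = step_tree(cfg)))
  }
  if (isTRUE(cfg$clean_mode) && step == "all") {
    unlink(file.path(cfg$result_dir, "normalized_report.txt"))
  }
  write_manifest(cfg, step, workers, outputs)
  invisible(outputs)
}

usage_error <- function(...) {
  structure(class = c("ltr_usage_error", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1)))
}

rpath <- function(cfg, name) file.path(cfg$result_dir, name)

require_outputs <- function(cfg, files, from_step) {
  missing <- files[!file.exists(vapply(files, rpath, character(1),
                                       cfg = cfg))]
  if (length(missing) > 0L)
    stop("missing prerequisite output(s) ", paste(missing, collapse = ", "),
         "; run step '", from_step, "' first")
}

log_msg <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

load_elements <- function(cfg) {
  if (cfg$input_mode == "report") {
    if (!nzchar(cfg$predictor_report))
      stop("input_mode=report but predictor_report is not set")
    parse_predictor_report(cfg$predictor_report)
  } else {
    if (!nzchar(cfg$input_fasta))
      stop("input_mode=fasta but input_fasta is not set")
    seqs <- read_fasta(cfg$input_fasta, strict = cfg$strict_alphabet)
    lapply(seqs, function(s) {
      loc <- locate_ltr_pair(s$seq)
      predictor_record(
        s$id, s$seq,
        ltr5_seq = substr(s$seq, loc$ltr5[1] + 1L, loc$ltr5[2]),
        ltr3_seq = substr(s$seq, loc$ltr3[1] + 1L, loc$ltr3[2]),
        ltr_identity = loc$identity_pct, source_tag = "internal-scan")
    })
  }
}

apply_elementwise <- function(x, f, workers) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(x, f, mc.cores = workers, mc.preschedule = TRUE)
  } else lapply(x, f)
}

step_preprocess <- function(cfg, workers = 1L) {
  elements <- load_elements(cfg)
  if (!nzchar(cfg$domain_library))
    stop("domain_library is not set in the configuration")
  library <- load_reference_library(cfg$domain_library)
  log_msg(cfg, "preprocess: ", length(elements), " elements, ",
          length(library), " reference domains")
  hit_rows <- apply_elementwise(elements, function(el) {
    hits <- scan_domains(el, library, cfg)
    if (length(hits) == 0L) return(NULL)
    do.call(rbind, lapply(hits, function(h)
      data.frame(element_id = h$element_id, domain_kind = h$domain_kind,
                 superfamily_code = h$superfamily_code, lineage = h$lineage,
                 family = h$family, ref_id = h$ref_id, score = h$score,
                 evalue = h$evalue, frame = h$frame,
                 nt_start = h$element_nt_start, nt_end = h$element_nt_end,
                 aa_identity_pct = h$aa_alignment$identity_pct,
                 stringsAsFactors = FALSE)))
  }, workers)
  hits <- do.call(rbind, hit_rows)
  if (is.null(hits)) hits <- empty_hits_frame()
  features <- do.call(rbind, lapply(elements, function(el)
    data.frame(element_id = el$element_id, length = el$element_length,
               ltr_identity = el$ltr_identity,
               ltr5_len = nchar(el$ltr5_seq), ltr3_len = nchar(el$ltr3_seq),
               source = el$source_tag, stringsAsFactors = FALSE)))
  out <- list(
    normalized_report = rpath(cfg, "normalized_report.txt"),
    features = rpath(cfg, "preprocess_features.tsv"),
    hits = rpath(cfg, "domain_hits.tsv"))
  emit_predictor_report(elements, out$normalized_report)
  write_tabular(features, out$features)
  write_tabular(hits, out$hits)
  out
}

empty_hits_frame <- function() {
  data.frame(element_id = character(), domain_kind = character(),
             superfamily_code = character(), lineage = character(),
             family = character(), ref_id = character(), score = numeric(),
             evalue = numeric(), frame = integer(), nt_start = integer(),
             nt_end = integer(), aa_identity_pct = numeric(),
             stringsAsFactors = FALSE)
}

hits_frame_to_best <- function(hits_df) {
  if (nrow(hits_df) == 0L) return(list())
  hits <- lapply(seq_len(nrow(hits_df)), function(i) {
    r <- hits_df[i, ]
    structure(list(element_id = r$element_id, domain_kind = r$domain_kind,
                   superfamily_code = r$superfamily_code,
                   lineage = r$lineage, family = r$family, ref_id = r$ref_id,
                   score = r$score, evalue = r$evalue, frame = r$frame,
                   element_nt_start = r$nt_start, element_nt_end = r$nt_end),
              class = "domain_hit")
  })
  best_hit_per_domain(hits)
}

step_classify <- function(cfg, workers = 1L) {
  require_outputs(cfg, c("normalized_report.txt", "domain_hits.tsv"),
                  "preprocess")
  elements <- parse_predictor_report(rpath(cfg, "normalized_report.txt"))
  hits_df <- read_tabular(rpath(cfg, "domain_hits.tsv"))
  results <- lapply(elements, function(el) {
    best <- hits_frame_to_best(hits_df[hits_df$element_id == el$element_id,
                                       , drop = FALSE])
    classify_element(el, best, cfg)
  })
  seqs <- stats::setNames(
    vapply(elements, `[[`, character(1), "full_seq"),
    vapply(elements, `[[`, character(1), "element_id"))
  results <- reclassify_80_80_80(results, seqs, cfg)
  tab <- do.call(rbind, lapply(results, function(r) {
    rc <- r$reclassified_from
    data.frame(element_id = r$element_id, category = r$category,
               lineage = r$lineage, rule_fired = r$evidence$rule_fired,
               domains_present = paste(r$evidence$domains_present,
                                       collapse = ","),
               reclassified = !is.null(rc),
               donor_element_id = if (is.null(rc)) "" else rc$donor_element_id,
               donor_identity_pct = if (is.null(rc)) NA_real_
                                    else rc$identity_pct,
               donor_coverage_pct = if (is.null(rc)) NA_real_
                                    else rc$coverage_pct,
               donor_aligned_bp = if (is.null(rc)) NA_integer_
                                  else as.integer(rc$aligned_bp),
               stringsAsFactors = FALSE)
  }))
  out <- list(classification = rpath(cfg, "classification.tsv"))
  write_tabular(tab, out$classification)
  # one FASTA + TSV per category found, including the unclassified
  for (category in intersect(CATEGORIES, unique(tab$category))) {
    ids <- tab$element_id[tab$category == category]
    fasta <- rpath(cfg, paste0(category, "_elements.fasta"))
    tsv <- rpath(cfg, paste0(category, "_elements.tsv"))
    write_fasta(seqs[ids], fasta)
    write_tabular(tab[tab$category == category, , drop = FALSE], tsv)
    out[[paste0(category, "_fasta")]] <- fasta
    out[[paste0(category, "_tsv")]] <- tsv
    log_msg(cfg, "classify: ", category, " n=", length(ids))
  }
  out$no_class <- rpath(cfg, "no_class_elements.txt")
  writeLines(tab$element_id[tab$category == "NO_CLASS"], out$no_class)
  out
}

step_extract_rt <- function(cfg) {
  require_outputs(cfg, c("normalized_report.txt", "domain_hits.tsv"),
                  "preprocess")
  require_outputs(cfg, "classification.tsv", "classify")
  elements <- parse_predictor_report(rpath(cfg, "normalized_report.txt"))
  hits_df <- read_tabular(rpath(cfg, "domain_hits.tsv"))
  cls <- read_tabular(rpath(cfg, "classification.tsv"))
  rt_recs <- list()
  rejected <- list()
  for (el in elements) {
    row <- cls[cls$element_id == el$element_id, , drop = FALSE]
    if (nrow(row) == 0L || !row$category[1] %in% c("GYPSY", "COPIA")) next
    best <- hits_frame_to_best(hits_df[hits_df$element_id == el$element_id,
                                       , drop = FALSE])
    res <- extract_rt(el, best$RT, cfg, mode = "element")
    if (res$accepted) {
      label <- paste(el$element_id, row$category[1], row$lineage[1],
                     sep = "#")
      rt_recs[[length(rt_recs) + 1L]] <-
        list(id = label, description = "", seq = res$aa_seq)
    } else {
      rejected[[length(rejected) + 1L]] <-
        data.frame(element_id = el$element_id, reason = res$reason,
                   stringsAsFactors = FALSE)
    }
  }
  out <- list(rt_fasta = rpath(cfg, "rt_domains.fasta"),
              rt_rejected = rpath(cfg, "rt_rejected.tsv"))
  if (length(rt_recs) > 0L) write_fasta(rt_recs, out$rt_fasta)
  else suppressWarnings(write_fasta(list(), out$rt_fasta))
  rej <- if (length(rejected) > 0L) do.call(rbind, rejected)
         else data.frame(element_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  write_tabular(rej, out$rt_rejected)
  log_msg(cfg, "extract-rt: ", length(rt_recs), " RT domains kept, ",
          nrow(rej), " rejected")
  out
}

step_date <- function(cfg) {
  require_outputs(cfg, "normalized_report.txt", "preprocess")
  require_outputs(cfg, "classification.tsv", "classify")
  elements <- parse_predictor_report(rpath(cfg, "normalized_report.txt"))
  cls <- read_tabular(rpath(cfg, "classification.tsv"))
  ord <- match(vapply(elements, `[[`, character(1), "element_id"),
               cls$element_id)
  results <- lapply(ord, function(i)
    classification_result(cls$element_id[i], cls$category[i],
                          cls$lineage[i], list(rule_fired = cls$rule_fired[i],
                                               domains_present = character(),
                                               labels_seen = character())))
  est <- date_elements(elements, results, cfg)
  hist_lineage <- bin_by_age(est, cfg$bin_width_my)
  sf <- cls$category[ord]
  est_sf <- est
  est_sf$lineage_or_category <- sf
  hist_superfamily <- bin_by_age(est_sf, cfg$bin_width_my)
  out <- list(insertion_times = rpath(cfg, "insertion_times.tsv"),
              histogram_lineage = rpath(cfg, "age_histogram_lineage.tsv"),
              histogram_superfamily =
                rpath(cfg, "age_histogram_superfamily.tsv"))
  write_tabular(est, out$insertion_times)
  write_tabular(hist_lineage, out$histogram_lineage)
  write_tabular(hist_superfamily, out$histogram_superfamily)
  log_msg(cfg, "date: ", sum(!est$saturated), " elements dated, ",
          sum(est$saturated), " saturated")
  out
}

step_tree <- function(cfg) {
  require_outputs(cfg, "rt_domains.fasta", "extract-rt")
  rt <- read_fasta(rpath(cfg, "rt_domains.fasta"), alphabet = "protein")
  if (length(rt) < 3L)
    stop("need at least 3 RT domains for a tree; found ", length(rt))
  seqs <- stats::setNames(vapply(rt, `[[`, character(1), "seq"),
                          vapply(rt, `[[`, character(1), "id"))
  msa <- progressive_msa(seqs)
  D <- distance_matrix(msa)
  tree <- nj_tree(D)
  out <- list(msa = rpath(cfg, "rt_msa.fasta"),
              tree = rpath(cfg, "rt_tree.newick"))
  rows <- apply(msa, 1L, paste, collapse = "")
  write_fasta(stats::setNames(rows, rownames(msa)), out$msa)
  write_newick(tree, out$tree)
  log_msg(cfg, "tree: ", length(seqs), " leaves")
  out
}

write_manifest <- function(cfg, step, workers, outputs) {
  inputs <- c(cfg$input_fasta, cfg$predictor_report, cfg$domain_library)
  inputs <- inputs[nzchar(inputs) & file.exists(inputs)]
  digests <- if (length(inputs) > 0L) tools::md5sum(inputs) else character()
  lines <- c(
    paste0("tool: ltrcraft ",
           as.character(utils::packageVersion("ltrcraft"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("step: ", step),
    paste0("workers: ", workers),
    paste0("seed: ", cfg$rng_seed),
    "config:",
    paste0("  ", names(cfg), " = ",
           vapply(cfg, function(v) paste(format(v), collapse = ","),
                  character(1))),
    "input_digests:",
    if (length(digests) > 0L) paste0("  ", names(digests), " ", digests)
    else "  (none)",
    "outputs:",
    paste0("  ", unlist(outputs)))
  writeLines(lines, rpath(cfg, "run_manifest.txt"))
  invisible(NULL)
}
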