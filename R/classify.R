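# Superfamily/lineage classification decision tree and the 80/80/80
# reclassification of leftover elements.

#' Classify one element from its best domain hits
#'
#' Decision tree, applied in order and total over every combination of
#' domain presence, superfamily labels and element length:
#'
#' 1. If the enzymatic (pol) domains RT/INT/RNaseH present carry both RLC
#'    and RLG labels, the element is a putative chimera: `NO_CLASS`.
#' 2. If at least one of RT/INT/RNaseH is present with a single superfamily
#'    label, the element is putatively autonomous: `GYPSY` (RLG) or `COPIA`
#'    (RLC), with a lineage from [assign_lineage()].
#' 3. If no domain at all is present, the element is non-autonomous: `TRIM`
#'    when shorter than the TRIM/LARD cutoff (2000 bp by default), `LARD`
#'    when at least that long.
#' 4. If the domain set is only GAG, or exactly GAG + AP, the element is a
#'    non-autonomous `TR_GAG`.
#' 5. Anything else (e.g. ENV-only, AP-only, or pol domains without an
#'    RLC/RLG label) is `NO_CLASS`.
#'
#' Non-autonomous categories never carry a lineage. GAG/AP/ENV labels do not
#' participate in the superfamily vote (evidence only).
#'
#' @param element a `predictor_record`.
#' @param best_hits named list from [best_hit_per_domain()].
#' @param cfg an `ltr_config`; `trim_lard_cutoff_bp` is used.
#' @return A `classification_result`: `element_id`, `category`, `lineage`
#'   (`"NONE"` unless GYPSY/COPIA), and an `evidence` record of the rule
#'   fired, domains present and superfamily labels seen.
#' @export
classify_element <- function(element, best_hits, cfg = default_config()) {
  present <- names(best_hits)
  pol <- intersect(present, c("RT", "INT", "RNASEH"))
  pol_codes <- unique(vapply(best_hits[pol], `[[`, character(1),
                             "superfamily_code"))
  pol_codes <- setdiff(pol_codes, "NONE")
  labels_seen <- if (length(present) > 0L)
    vapply(best_hits, `[[`, character(1), "superfamily_code") else character()
  len <- element$element_length
  evid <- function(rule) list(rule_fired = rule,
                              domains_present = sort(present),
                              labels_seen = labels_seen)

  if (length(pol) > 0L && all(c("RLC", "RLG") %in% pol_codes)) {
    return(classification_result(element$element_id, "NO_CLASS", "NONE",
                                 evid("chimeric-both-superfamilies")))
  }
  if (length(pol) > 0L && length(pol_codes) == 1L) {
    category <- if (pol_codes == "RLG") "GYPSY" else "COPIA"
    return(classification_result(element$element_id, category,
                                 assign_lineage(best_hits),
                                 evid("autonomous-pol-domain")))
  }
  if (length(present) == 0L) {
    category <- if (len < cfg$trim_lard_cutoff_bp) "TRIM" else "LARD"
    return(classification_result(element$element_id, category, "NONE",
                                 evid("non-autonomous-no-domains")))
  }
  if (setequal(present, "GAG") || setequal(present, c("GAG", "AP"))) {
    return(classification_result(element$element_id, "TR_GAG", "NONE",
                                 evid("non-autonomous-gag")))
  }
  classification_result(element$element_id, "NO_CLASS", "NONE",
                        evid("unclassified-domain-set"))
}

#' Construct a classification result
#'
#' Mostly used internally by [classify_element()]; exposed for building
#' donor sets programmatically. Lineage is forced to `"NONE"` for
#' non-autonomous categories.
#'
#' @param element_id element identifier.
#' @param category one of GYPSY, COPIA, TRIM, LARD, TR_GAG, NO_CLASS.
#' @param lineage lineage string or `"NONE"`.
#' @param evidence evidence record (list).
#' @param reclassified_from optional 80/80/80 provenance record.
#' @return A `classification_result` list.
#' @export
classification_result <- function(element_id, category, lineage,
                                  evidence = list(rule_fired = "manual",
                                                  domains_present = character(),
                                                  labels_seen = character()),
                                  reclassified_from = NULL) {
  stopifnot(category %in% CATEGORIES)
  if (!category %in% c("GYPSY", "COPIA")) lineage <- "NONE"
  structure(list(element_id = element_id, category = category,
                 lineage = lineage, evidence = evidence,
                 reclassified_from = reclassified_from),
            class = "classification_result")
}

#' Assign a lineage to an autonomous element
#'
#' The lineage of the best RT hit, when an RT hit exists (RT is the most
#' conserved and reliable label); otherwise the majority lineage among the
#' INT/RNaseH hits, with ties resolved in favour of the highest-scoring hit.
#'
#' @param best_hits named list from [best_hit_per_domain()].
#' @return Lineage string, or `"NONE"` when no pol hit carries one.
#' @export
assign_lineage <- function(best_hits) {
  if (!is.null(best_hits$RT) && best_hits$RT$lineage != "NONE")
    return(unname(best_hits$RT$lineage))
  voters <- best_hits[intersect(names(best_hits), c("INT", "RNASEH"))]
  voters <- voters[vapply(voters, function(h) h$lineage != "NONE", logical(1))]
  if (length(voters) == 0L) return("NONE")
  lin <- vapply(voters, `[[`, character(1), "lineage")
  sc <- vapply(voters, `[[`, numeric(1), "score")
  counts <- table(lin)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  # tie: lineage of the highest-scoring voter among the tied lineages
  cand <- order(-sc, lin, method = "radix")
  for (i in cand) if (lin[i] %in% top) return(unname(lin[i]))
  "NONE"
}

#' Rescue unclassified elements with the 80/80/80 rule
#'
#' Each `NO_CLASS` element is locally aligned against every classified
#' element. If the best match covers at least 80% of the unclassified
#' element, at 80% or more nucleotide identity, over at least 80 aligned
#' bases, the element inherits the donor's category and lineage; the donor,
#' identity, coverage and aligned length are recorded in
#' `reclassified_from`. Coverage is measured on the unclassified element.
#' Donor ties are broken by alignment score, then donor id, so the result
#' does not depend on donor order; a second pass changes nothing.
#'
#' @param results list of `classification_result`s (one per element).
#' @param seqs named character vector of element sequences (id -> sequence).
#' @param cfg an `ltr_config`; skipped unless `apply_808080` is `TRUE`.
#' @param min_identity,min_cov_pct,min_aligned_bp the three thresholds.
#' @param scheme nucleotide scoring scheme for the similarity search.
#' @return The updated list of `classification_result`s, same order.
#' @export
reclassify_80_80_80 <- function(results, seqs, cfg = default_config(),
                                min_identity = 80, min_cov_pct = 80,
                                min_aligned_bp = 80,
                                scheme = scoring_scheme("nucleotide")) {
  if (!isTRUE(cfg$apply_808080)) return(results)
  cats <- vapply(results, `[[`, character(1), "category")
  # donors are directly classified elements only; elements rescued by this
  # rule do not donate, which keeps reclassification idempotent
  rescued <- vapply(results, function(r) !is.null(r$reclassified_from),
                    logical(1))
  donors <- results[cats != "NO_CLASS" & !rescued]
  if (length(donors) == 0L) {
    if (any(cats == "NO_CLASS"))
      warning("no classified elements available as 80/80/80 donors")
    return(results)
  }
  donor_ids <- vapply(donors, `[[`, character(1), "element_id")
  donors <- donors[order(donor_ids, method = "radix")]
  donor_ids <- sort(donor_ids, method = "radix")
  for (i in which(cats == "NO_CLASS")) {
    q_id <- results[[i]]$element_id
    q <- seqs[[q_id]]
    best <- NULL
    for (j in seq_along(donors)) {
      alns <- local_align(q, seqs[[donor_ids[j]]], scheme = scheme,
                          max_hits = 1L)
      if (length(alns) == 0L) next
      aln <- alns[[1]]
      aligned_bp <- aln$q_end - aln$q_start
      cov <- 100 * aligned_bp / nchar(q)
      if (aln$identity_pct >= min_identity && cov >= min_cov_pct &&
          aligned_bp >= min_aligned_bp) {
        if (is.null(best) || aln$score > best$score)
          best <- list(score = aln$score, donor = donors[[j]],
                       identity = aln$identity_pct, coverage = cov,
                       aligned_bp = aligned_bp)
      }
    }
    if (!is.null(best)) {
      results[[i]] <- classification_result(
        q_id, best$donor$category, best$donor$lineage,
        results[[i]]$evidence,
        reclassified_from = list(
          from_category = "NO_CLASS",
          donor_element_id = best$donor$element_id,
          identity_pct = best$identity,
          coverage_pct = best$coverage,
          aligned_bp = best$aligned_bp))
    }
  }
  results
}
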