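# Synthetic LTR retrotransposons with known category, lineage and insertion
# age, plus matching reference domain libraries, so every pipeline stage can
# be tested against ground truth without external data.

GYPSY_LINEAGES <- c("TAT", "Athila", "Galadriel", "Reina", "CRM", "Del")
COPIA_LINEAGES <- c("Tork", "Retrofit", "Oryco", "SIRE", "Bianca")

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a synthetic reference domain library
#'
#' One random protein per domain kind (GAG, AP, RT, RNASEH, INT; ENV for
#' designated lineages) and per lineage, 150-400 aa (RT at least 220 aa so
#' full-length embedded copies pass the 200-aa extraction filter).
#' Independent random proteins are far below 40% mutual identity, giving
#' unambiguous lineage labels. Deterministic given `seed`.
#'
#' @param lineages named character vector mapping lineage to superfamily code
#'   (e.g. `c(Del = "RLG", Tork = "RLC")`).
#' @param seed RNG seed.
#' @param env_lineages lineages that additionally carry an ENV reference.
#' @param path optional FASTA output path.
#' @return List of `reference_domain` records (as from
#'   [load_reference_library()]); written to `path` when given.
#' @export
make_reference_library <- function(lineages, seed = 1L,
                                   env_lineages = character(), path = NULL) {
  stopifnot(!is.null(names(lineages)), all(lineages %in% c("RLC", "RLG")))
  set.seed(seed)
  refs <- list()
  for (lin in names(lineages)) {
    code <- lineages[[lin]]
    kinds <- c("GAG", "AP", "RT", "RNASEH", "INT")
    if (lin %in% env_lineages) kinds <- c(kinds, "ENV")
    for (kind in kinds) {
      len <- if (kind == "RT") sample(220:400, 1L) else sample(150:400, 1L)
      aa <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      header <- paste(kind, code, lin, paste0(lin, "fam1"), sep = "_")
      refs[[length(refs) + 1L]] <- structure(
        list(ref_id = header, domain_kind = kind, superfamily_code = code,
             lineage = lin, family = paste0(lin, "fam1"), aa_seq = aa),
        class = "reference_domain")
    }
  }
  if (!is.null(path)) {
    recs <- lapply(refs, function(r)
      list(id = r$ref_id, description = "", seq = r$aa_seq))
    write_fasta(recs, path)
  }
  refs
}

#' Specification of one synthetic element
#'
#' @param category target category: GYPSY, COPIA, TRIM, LARD, TR_GAG, or
#'   CHIMERA (mixed-superfamily pol domains; true class NO_CLASS).
#' @param lineage lineage for autonomous categories (must exist in the
#'   reference library with the matching superfamily code).
#' @param age_my insertion age in million years (>= 0).
#' @param ltr_len ancestral LTR length in bp (>= 50).
#' @param internal_domains ordered domain kinds embedded in the internal
#'   region; defaults per category (Gypsy pol order GAG,AP,RT,RNASEH,INT;
#'   Copia GAG,AP,INT,RT,RNASEH; TR_GAG GAG(,AP); none for TRIM/LARD).
#' @param internal_len internal-region length for domain-free categories.
#' @param substitution_rate per-site substitution rate per year.
#' @param kappa expected transition:transversion count ratio among
#'   substitutions (default 2).
#' @param rng_seed per-element RNG seed.
#' @return An `element_spec` list.
#' @export
element_spec <- function(category, lineage = "NONE", age_my = 1,
                         ltr_len = 300L, internal_domains = NULL,
                         internal_len = 1000L, substitution_rate = 1.3e-8,
                         kappa = 2, rng_seed = 1L) {
  stopifnot(category %in% c(CATEGORIES[CATEGORIES != "NO_CLASS"], "CHIMERA"))
  if (age_my < 0) stop("age_my must be >= 0")
  if (ltr_len < 50L) stop("ltr_len must be >= 50")
  if (is.null(internal_domains)) {
    internal_domains <- switch(category,
      GYPSY = c("GAG", "AP", "RT", "RNASEH", "INT"),
      COPIA = c("GAG", "AP", "INT", "RT", "RNASEH"),
      CHIMERA = c("RT", "INT"),
      TR_GAG = "GAG",
      character())
  }
  if (category %in% c("TRIM", "LARD") && length(internal_domains) > 0L)
    stop("TRIM/LARD specs must not embed domains")
  if (category == "TR_GAG" &&
      !(setequal(internal_domains, "GAG") ||
        setequal(internal_domains, c("GAG", "AP"))))
    stop("TR_GAG specs embed only GAG or GAG+AP")
  structure(list(category = category, lineage = lineage, age_my = age_my,
                 ltr_len = as.integer(ltr_len),
                 internal_domains = internal_domains,
                 internal_len = as.integer(internal_len),
                 substitution_rate = substitution_rate, kappa = kappa,
                 rng_seed = as.integer(rng_seed)), class = "element_spec")
}

# Deterministic back-translation: one fixed codon per amino acid
#' @noRd
BACKTRANSLATION <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT", X = "NNN")

back_translate <- function(aa) {
  codons <- BACKTRANSLATION[strsplit(aa, "")[[1]]]
  if (anyNA(codons)) stop("cannot back-translate residue(s) in: ", aa)
  paste(codons, collapse = "")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Mutate a nucleotide string with i.i.d. per-site substitution probability p
# and transition:transversion count ratio kappa.
mutate_seq <- function(seq, p, kappa = 2) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit) == 0L) return(seq)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  p_ts <- kappa / (kappa + 1)
  for (i in hit) {
    base <- chars[i]
    if (!base %in% c("A", "C", "G", "T")) next
    chars[i] <- if (stats::runif(1) < p_ts) transitions[[base]]
                else sample(transversions[[base]], 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate one LTR retrotransposon with known truth
#'
#' Builds an ancestral LTR (random sequence with TG...CA termini) and an
#' internal region; for coding categories the internal region embeds the
#' back-translated reference domain proteins of the requested lineage, in
#' order and in frame, separated by short random spacers. The LTR is copied
#' to both ends and each copy is then mutated independently with per-site
#' substitution probability `rate * T` years, so the expected pairwise LTR
#' divergence is `K* = 2 * rate * T` (multiple hits are not tracked; at
#' desk-scale divergences the K2P correction absorbs the difference).
#'
#' @param spec an [element_spec()].
#' @param library reference domain library the embedded proteins are drawn
#'   from (from [make_reference_library()]).
#' @param element_id id for the generated element.
#' @return List with `record` (a `predictor_record`) and `truth`
#'   (element_id, true category — NO_CLASS for CHIMERA specs — lineage,
#'   age_my, expected divergence).
#' @export
simulate_element <- function(spec, library, element_id = "elem1") {
  set.seed(spec$rng_seed)
  ltr <- random_nt(spec$ltr_len)
  substr(ltr, 1L, 2L) <- "TG"
  substr(ltr, spec$ltr_len - 1L, spec$ltr_len) <- "CA"

  internal <- build_internal(spec, library)
  total_len <- 2L * spec$ltr_len + nchar(internal)
  if (spec$category == "TRIM" && total_len >= 2000L)
    stop("inconsistent spec: TRIM element would be ", total_len, " bp")
  if (spec$category == "LARD" && total_len < 2000L)
    stop("inconsistent spec: LARD element would be ", total_len, " bp")

  t_years <- spec$age_my * 1e6
  p <- spec$substitution_rate * t_years
  ltr5 <- mutate_seq(ltr, p, spec$kappa)
  ltr3 <- mutate_seq(ltr, p, spec$kappa)
  full <- paste0(ltr5, internal, ltr3)
  ident <- 100 * mean(strsplit(ltr5, "")[[1]] == strsplit(ltr3, "")[[1]])
  rec <- predictor_record(element_id, full, ltr5, ltr3,
                          ltr_identity = ident, source_tag = "report")
  truth <- list(element_id = element_id,
                category = if (spec$category == "CHIMERA") "NO_CLASS"
                           else spec$category,
                lineage = if (spec$category %in% c("GYPSY", "COPIA"))
                            spec$lineage else "NONE",
                age_my = spec$age_my,
                expected_K = 2 * spec$substitution_rate * t_years,
                element_length = total_len)
  list(record = rec, truth = truth)
}

build_internal <- function(spec, library) {
  if (length(spec$internal_domains) == 0L)
    return(random_nt(spec$internal_len))
  lineage_of <- vapply(library, `[[`, character(1), "lineage")
  kind_of <- vapply(library, `[[`, character(1), "domain_kind")
  code_of <- vapply(library, `[[`, character(1), "superfamily_code")
  pick <- function(kind, lineage) {
    sel <- which(kind_of == kind & lineage_of == lineage)
    if (length(sel) == 0L)
      stop("reference library has no ", kind, " for lineage ", lineage)
    library[[sel[1L]]]
  }
  if (spec$category == "CHIMERA") {
    # one pol domain from each superfamily
    rlg <- unique(lineage_of[code_of == "RLG"])
    rlc <- unique(lineage_of[code_of == "RLC"])
    if (length(rlg) == 0L || length(rlc) == 0L)
      stop("CHIMERA specs need both superfamilies in the library")
    doms <- list(pick("RT", rlg[1L]), pick("INT", rlc[1L]))
  } else {
    lin <- if (spec$category %in% c("GYPSY", "COPIA")) spec$lineage
           else lineage_of[[1L]]   # TR_GAG: any GAG will do
    doms <- lapply(spec$internal_domains, pick, lineage = lin)
  }
  spacer <- function() random_nt(3L * sample(5:15, 1L))  # in-frame spacers
  parts <- character(0)
  for (d in doms) parts <- c(parts, spacer(), back_translate(d$aa_seq))
  paste(c(parts, spacer()), collapse = "")
}

#' Simulate a dataset of elements with ground truth
#'
#' @param mixture named integer vector of element counts per category
#'   (names from GYPSY, COPIA, TRIM, LARD, TR_GAG, CHIMERA).
#' @param ages ages in MY, recycled across elements.
#' @param seed master seed; per-element seeds are derived from it.
#' @param library optional reference library; a default two-superfamily
#'   library (Del, CRM = RLG; Tork, SIRE = RLC, SIRE carrying ENV) is
#'   generated from `seed` when omitted.
#' @param dir optional directory: writes `elements.fasta`,
#'   `predictor_report.txt`, `truth.tsv` and `reference_domains.fasta`.
#' @param ... further arguments passed to [element_spec()] (e.g. `ltr_len`).
#' @return List with `records`, `truth` (data frame), `library` and, when
#'   `dir` is given, `paths`.
#' @export
simulate_dataset <- function(mixture, ages = 1, seed = 1L, library = NULL,
                             dir = NULL, ...) {
  stopifnot(!is.null(names(mixture)), all(mixture >= 0))
  if (is.null(library)) {
    library <- make_reference_library(
      c(Del = "RLG", CRM = "RLG", Tork = "RLC", SIRE = "RLC"),
      seed = seed, env_lineages = "SIRE")
  }
  lineage_of <- vapply(library, `[[`, character(1), "lineage")
  code_of <- vapply(library, `[[`, character(1), "superfamily_code")
  rlg <- unique(lineage_of[code_of == "RLG"])
  rlc <- unique(lineage_of[code_of == "RLC"])
  cats <- rep(names(mixture), times = mixture)
  n <- length(cats)
  ages <- rep_len(ages, n)
  records <- vector("list", n)
  truth <- vector("list", n)
  extra <- list(...)
  for (i in seq_len(n)) {
    cat_i <- cats[i]
    lin <- switch(cat_i,
      GYPSY = rlg[1L + (i %% length(rlg))],
      COPIA = rlc[1L + (i %% length(rlc))],
      "NONE")
    args <- c(list(category = cat_i, lineage = lin, age_my = ages[i],
                   rng_seed = (seed * 1000L + i) %% .Machine$integer.max),
              extra)
    if (cat_i == "LARD" && is.null(extra$internal_len))
      args$internal_len <- 1800L
    sim <- simulate_element(do.call(element_spec, args), library,
                            element_id = sprintf("synth%03d_%s", i, cat_i))
    records[[i]] <- sim$record
    truth[[i]] <- as.data.frame(sim$truth, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  out <- list(records = records, truth = truth, library = library)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      elements = file.path(dir, "elements.fasta"),
      report = file.path(dir, "predictor_report.txt"),
      truth = file.path(dir, "truth.tsv"),
      library = file.path(dir, "reference_domains.fasta"))
    write_fasta(lapply(records, function(r)
      list(id = r$element_id, description = "", seq = r$full_seq)),
      paths$elements)
    emit_predictor_report(records, paths$report)
    write_tabular(truth, paths$truth)
    write_fasta(lapply(library, function(r)
      list(id = r$ref_id, description = "", seq = r$aa_seq)), paths$library)
    out$paths <- paths
  }
  out
}

#' Write predictor records in the report dialect
#'
#' Inverse of [parse_predictor_report()]: blank-line separated blocks of
#' `KEY: value` lines.
#'
#' @param records list of `predictor_record`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
emit_predictor_report <- function(records, path) {
  if (length(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  blocks <- vapply(records, function(r) {
    paste(c(paste0("ELEMENT_ID: ", r$element_id),
            paste0("LENGTH: ", r$element_length),
            paste0("LTR_IDENTITY: ", format(r$ltr_identity, digits = 10)),
            paste0("LTR5_SEQ: ", r$ltr5_seq),
            paste0("LTR3_SEQ: ", r$ltr3_seq),
            paste0("FULL_SEQ: ", r$full_seq)), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
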