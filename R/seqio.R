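# File formats: FASTA, predictor reports, key=value configs, TSV tables, newick.

DOMAIN_KINDS <- c("GAG", "AP", "RT", "RNASEH", "INT", "ENV")
SUPERFAMILY_CODES <- c("RLC", "RLG", "NONE")
CATEGORIES <- c("GYPSY", "COPIA", "TRIM", "LARD", "TR_GAG", "NO_CLASS")

#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA into a list of sequence records. For
#' nucleotide input, lower-case and IUPAC ambiguity characters are mapped to
#' `N` by default (repeat libraries are frequently soft-masked); with
#' `strict = TRUE` any character outside `A,C,G,T,N` is an error. Protein
#' input maps unknown residues to `X` under the same switch.
#'
#' @param path path to a FASTA file (first non-empty line must start with `>`).
#' @param alphabet `"dna"` or `"protein"`.
#' @param strict reject out-of-alphabet characters instead of masking them.
#' @return A list of records, each a list with `id`, `description`, `seq`.
#'   Order follows the file; ids must be unique.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein"), strict = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L || !startsWith(first[[1L]], ">"))
    stop("not a FASTA file (no '>' header): ", path)
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0L)) {
    bad <- names(set)[Biostrings::width(set) == 0L]
    stop("empty FASTA record(s): ", paste(bad, collapse = ", "))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA ids: ", paste(dups, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- vapply(seqs, clean_sequence, character(1), alphabet = alphabet,
                 strict = strict, USE.NAMES = FALSE)
  mapply(function(i, d, s) list(id = i, description = d, seq = s),
         ids, desc, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

clean_sequence <- function(seq, alphabet = "dna", strict = FALSE) {
  if (alphabet == "dna") {
    ok <- "ACGTN"
    mask <- "N"
  } else {
    ok <- "ACDEFGHIKLMNPQRSTVWYX*"
    mask <- "X"
  }
  bad <- gsub(sprintf("[%s]", gsub("\\*", "\\\\*", ok)), "", seq)
  if (nchar(bad) > 0L) {
    if (strict)
      stop("sequence contains characters outside alphabet: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    pat <- sprintf("[^%s]", gsub("\\*", "\\\\*", ok))
    seq <- gsub(pat, mask, seq)
  }
  seq
}

#' Write sequence records to FASTA
#'
#' @param records list of records as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path output path.
#' @param line_width wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  if (is.character(records)) {
    if (is.null(names(records))) stop("character input must be named by id")
    records <- mapply(function(i, s) list(id = i, description = "", seq = s),
                      names(records), unname(records),
                      SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  if (length(records) == 0L) {
    warning("writing empty FASTA file: ", path)
    file.create(path)
    return(invisible(path))
  }
  ids <- vapply(records, `[[`, character(1), "id")
  if (any(grepl("\\s", ids)))
    stop("FASTA ids must not contain whitespace: ",
         paste(ids[grepl("\\s", ids)], collapse = ", "))
  desc <- vapply(records, function(r) r$description %||% "", character(1))
  seqs <- vapply(records, `[[`, character(1), "seq")
  headers <- ifelse(nzchar(desc), paste(ids, desc), ids)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Parse a structural-predictor report
#'
#' Reads the plain-text predictor report dialect (v1): records are blank-line
#' separated blocks of `KEY: value` lines with keys `ELEMENT_ID`, `LENGTH`,
#' `LTR_IDENTITY`, `LTR5_SEQ`, `LTR3_SEQ`, `FULL_SEQ`. Per-record invariants
#' are enforced: the stated length must equal the full sequence length, the
#' LTR identity must lie in `[0, 100]`, and the 5'/3' LTR sequences must be
#' the prefix/suffix of the full sequence.
#'
#' @param path path to a report file.
#' @return A list of predictor records (lists with `element_id`, `full_seq`,
#'   `ltr5_seq`, `ltr3_seq`, `ltr_identity`, `element_length`, `source_tag`).
#' @export
parse_predictor_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  blank <- !nzchar(trimws(lines))
  if (all(blank)) return(list())
  grp <- cumsum(blank)[!blank]
  blocks <- split(lines[!blank], grp)
  recs <- lapply(blocks, parse_report_block)
  ids <- vapply(recs, `[[`, character(1), "element_id")
  if (anyDuplicated(ids))
    stop("MalformedRecord: duplicate element ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(recs) <- NULL
  recs
}

parse_report_block <- function(block) {
  kv <- regmatches(block, regexec("^([A-Z0-9_]+):\\s*(.*)$", block))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("MalformedRecord: unparsable report line: ", block[bad][[1L]])
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- vapply(kv, `[[`, character(1), 3L)
  need <- c("ELEMENT_ID", "LENGTH", "LTR_IDENTITY", "LTR5_SEQ", "LTR3_SEQ",
            "FULL_SEQ")
  missing <- setdiff(need, keys)
  if (length(missing) > 0L)
    stop("MalformedRecord: missing keys: ", paste(missing, collapse = ", "))
  v <- stats::setNames(vals, keys)
  rec <- predictor_record(
    element_id = v[["ELEMENT_ID"]],
    full_seq = clean_sequence(toupper(v[["FULL_SEQ"]])),
    ltr5_seq = clean_sequence(toupper(v[["LTR5_SEQ"]])),
    ltr3_seq = clean_sequence(toupper(v[["LTR3_SEQ"]])),
    ltr_identity = as.numeric(v[["LTR_IDENTITY"]]),
    element_length = as.integer(v[["LENGTH"]]),
    source_tag = "report")
  rec
}

#' Construct a validated predictor record
#'
#' @param element_id unique element identifier.
#' @param full_seq element nucleotide sequence.
#' @param ltr5_seq,ltr3_seq 5' and 3' LTR sequences (terminal substrings of
#'   `full_seq`).
#' @param ltr_identity percent identity of the two LTRs, in `[0, 100]`.
#' @param element_length stated element length; must equal `nchar(full_seq)`.
#' @param source_tag provenance: `"report"`, `"fasta"` or `"internal-scan"`.
#' @return A `predictor_record` list.
#' @export
predictor_record <- function(element_id, full_seq, ltr5_seq, ltr3_seq,
                             ltr_identity, element_length = nchar(full_seq),
                             source_tag = "fasta") {
  if (!nzchar(element_id)) stop("MalformedRecord: empty element id")
  if (is.na(element_length) || element_length != nchar(full_seq))
    stop("MalformedRecord: LENGTH does not match sequence length for ",
         element_id)
  if (is.na(ltr_identity) || ltr_identity < 0 || ltr_identity > 100)
    stop("MalformedRecord: LTR identity outside [0, 100] for ", element_id)
  if (!startsWith(full_seq, ltr5_seq))
    stop("MalformedRecord: 5' LTR is not a prefix of the element for ",
         element_id)
  if (!endsWith(full_seq, ltr3_seq))
    stop("MalformedRecord: 3' LTR is not a suffix of the element for ",
         element_id)
  if (!source_tag %in% c("report", "fasta", "internal-scan"))
    stop("MalformedRecord: unknown source tag ", source_tag)
  structure(list(element_id = element_id, full_seq = full_seq,
                 ltr5_seq = ltr5_seq, ltr3_seq = ltr3_seq,
                 ltr_identity = ltr_identity,
                 element_length = as.integer(element_length),
                 source_tag = source_tag),
            class = "predictor_record")
}

#' Default pipeline configuration
#'
#' Thresholds follow the pipeline defaults: translated-search e-value cutoff
#' 1e-4, TRIM/LARD length boundary 2000 bp, RT length filters of 200 aa
#' (element mode) and 150 aa (genome mode), LTR substitution rate
#' 1.3e-8 substitutions/site/year and 0.5-MY age bins.
#'
#' @param ... named overrides of any configuration field.
#' @return An `ltr_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input_mode = "report",          # "report" or "fasta"
    input_fasta = "",
    predictor_report = "",
    domain_library = "",
    result_dir = "ltrcraft_results",
    verbose = FALSE,
    clean_mode = FALSE,
    evalue_cutoff = 1e-4,
    trim_lard_cutoff_bp = 2000,
    rt_min_aa_element = 200,
    rt_min_aa_genome = 150,
    substitution_rate = 1.3e-8,
    apply_808080 = TRUE,
    bin_width_my = 0.5,
    strict_alphabet = FALSE,
    rng_seed = 1L)
  over <- list(...)
  if (length(over) > 0L) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_pos <- c("evalue_cutoff", "trim_lard_cutoff_bp", "rt_min_aa_element",
               "rt_min_aa_genome", "substitution_rate", "bin_width_my")
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || is.na(cfg[[k]]) || cfg[[k]] <= 0)
      stop("configuration key ", k, " must be a positive number")
  }
  if (!cfg$input_mode %in% c("report", "fasta"))
    stop("input_mode must be 'report' or 'fasta'")
  structure(cfg, class = "ltr_config")
}

#' Parse a configuration file
#'
#' `key=value` lines, `#` comments; unset keys take the defaults of
#' [default_config()]. Unknown keys are an error (they are more often typos
#' than extensions).
#'
#' @param path configuration file path.
#' @return An `ltr_config` list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  if (length(lines) == 0L) return(cfg)
  m <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("unparsable configuration line: ", lines[bad][[1L]])
  keys <- vapply(m, `[[`, character(1), 2L)
  vals <- trimws(vapply(m, `[[`, character(1), 3L))
  unknown <- setdiff(keys, names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (i in seq_along(keys)) {
    cfg[[keys[i]]] <- coerce_config_value(keys[i], vals[i], cfg[[keys[i]]])
  }
  validate_config(cfg)
}

coerce_config_value <- function(key, val, template) {
  if (is.logical(template)) {
    out <- toupper(val) %in% c("TRUE", "T", "YES", "1")
    if (!toupper(val) %in% c("TRUE", "T", "YES", "1", "FALSE", "F", "NO", "0"))
      stop("configuration key ", key, ": cannot parse '", val, "' as logical")
    return(out)
  }
  if (is.numeric(template)) {
    out <- suppressWarnings(as.numeric(val))
    if (is.na(out))
      stop("configuration key ", key, ": cannot parse '", val, "' as number")
    return(out)
  }
  val
}

#' Write a data frame as a TSV table with header
#'
#' @param rows a data frame (possibly with zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tabular <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "")
}

#' Write a phylogenetic tree in newick format
#'
#' Accepts an `ape` `phylo` object or a ready newick string. Leaf labels
#' containing newick metacharacters (`(),:;` or whitespace) are rewritten
#' with `_` so the output re-parses.
#'
#' @param tree a `phylo` object or a newick string ending in `;`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "phylo")) {
    tree$tip.label <- sanitize_newick_label(tree$tip.label)
    ape::write.tree(tree, file = path)
  } else if (is.character(tree) && length(tree) == 1L) {
    if (!grepl(";\\s*$", tree)) stop("newick string must end with ';'")
    writeLines(tree, path)
  } else stop("tree must be a phylo object or a newick string")
  invisible(path)
}

sanitize_newick_label <- function(x) gsub("[(),:;'\"\\s\\[\\]]", "_", x, perl = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
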