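# Built-in compound knowledge base (68 raspberry (poly)phenols and related
# metabolites; 49 negative-mode, 19 positive-mode records), plus the
# neutral-loss dictionary and diagnostic aglycone/marker ions used by the
# annotation engine.
#
# The knowledge base stores each record's composition exactly as tabulated in
# its ionization convention: anthocyanins are stored as flavylium cation
# formulas ("M+"), everything else as neutral formulas with "M-H"/"M-2H"/
# "M-3H"/"M+H" adducts. Records whose printed exact mass or ppm error cannot
# be reproduced from the printed formula carry a `discrepancy` flag ("mass",
# "delta" or "mass;delta"); these are documented transcription/typesetting
# inconsistencies of the source tables, frozen as fixtures.

.kb_env <- new.env(parent = emptyenv())

#' Neutral-loss dictionary for polyphenol fragmentation
#'
#' The recurring neutral losses of polyphenol MS2 chemistry: glycosidic units
#' (hexose 162, deoxyhexose 146, aldopentose 132, deoxyhexose-hexoside 308,
#' sophorose 324), galloyl/HHDP units of ellagitannins, and small-molecule
#' losses (H2O, CO2, methyl, methoxy, acetyl, retro-cyclization).
#'
#' @return data.frame with columns `name`, `formula`, `exact` (Da),
#'   `nominal` (integer Da) and `moiety`.
#' @export
neutral_loss_rules <- function() {
  r <- data.frame(
    name = c("hexose", "deoxyhexose", "aldopentose", "deoxyhexose-hexoside",
             "sophorose", "CO2", "H2O", "methyl", "acetyl", "methoxy",
             "galloyl-hexose", "HHDP", "retro-cyclization"),
    formula = c("C6H10O5", "C6H10O4", "C5H8O4", "C12H20O9",
                "C12H20O10", "CO2", "H2O", "CH3", "C2H3O", "CH3O",
                "C13H16O10", "C14H6O8", "C4H6O4"),
    moiety = c("hexose unit", "deoxyhexose unit", "aldopentose unit",
               "deoxyhexose-hexoside (e.g. rutinose)", "sophorose",
               "carbon dioxide", "water", "methyl group", "acetyl moiety",
               "methoxy group", "galloyl-hexose unit",
               "hexahydroxydiphenoyl (HHDP) unit",
               "retro-cyclization of the flavonoid C ring"),
    stringsAsFactors = FALSE)
  r$exact <- vapply(r$formula, monoisotopic_mass, numeric(1))
  r$nominal <- round(r$exact)
  r[, c("name", "formula", "exact", "nominal", "moiety")]
}

#' Diagnostic ions for polyphenol class calls
#'
#' Aglycone and marker ions whose presence in an MS2 spectrum identifies a
#' compound class (or a specific aglycone) even without a precursor match:
#' ellagic acid for ellagitannins, [Y0]-/[Y0-H].- aglycones for flavonol
#' glycosides, flavylium aglycone cations for anthocyanins, (epi)catechin
#' ions for flavanols.
#'
#' @return data.frame with columns `name`, `mz`, `signifies` (class or
#'   aglycone) and `polarity`.
#' @export
diagnostic_ions <- function() {
  neg <- function(f) ion_mz(f, "M-H")
  data.frame(
    name = c("ellagic acid", "galloyl-hexose anion", "gallic acid",
             "quercetin [Y0]-", "quercetin [Y0-H].-",
             "kaempferol [Y0]-", "kaempferol [Y0-H].-",
             "(epi)catechin [M-H]-", "(epi)catechin dimer [M-H]-",
             "(epi)catechin quinone methide",
             "flavanol heterocyclic-ring fission",
             "retrocyclization A-ring 151", "retrocyclization 179",
             "cyanidin aglycone", "pelargonidin aglycone",
             "delphinidin aglycone", "peonidin aglycone",
             "myricetin [M+H]+"),
    mz = c(neg("C14H6O8"), neg("C13H16O10"), neg("C7H6O5"),
           neg("C15H10O7"), neg("C15H10O7") - 1.00782503207,
           neg("C15H10O6"), neg("C15H10O6") - 1.00782503207,
           neg("C15H14O6"), neg("C30H26O12"),
           neg("C15H12O6"),
           neg("C6H6O3"),
           neg("C7H4O4"), neg("C8H4O5"),
           monoisotopic_mass("C15H11O6"), monoisotopic_mass("C15H11O5"),
           monoisotopic_mass("C15H11O7"), monoisotopic_mass("C16H13O6"),
           ion_mz("C15H10O8", "M+H")),
    signifies = c("ellagitannin/ellagic-acid derivative",
                  "ellagitannin (galloyl-hexose)", "galloyl unit",
                  "flavonol (quercetin)", "flavonol (quercetin)",
                  "flavonol (kaempferol)", "flavonol (kaempferol)",
                  "flavanol", "flavanol (procyanidin)",
                  "flavanol (procyanidin)", "flavanol",
                  "flavonoid retrocyclization", "flavonoid retrocyclization",
                  "anthocyanin (cyanidin)", "anthocyanin (pelargonidin)",
                  "anthocyanin (delphinidin)", "anthocyanin (peonidin)",
                  "flavonol (myricetin)"),
    polarity = c(rep("negative", 13), rep("positive", 5)),
    stringsAsFactors = FALSE)
}

#' Match a mass difference against the neutral-loss dictionary
#'
#' @param delta non-negative mass difference, Da.
#' @param tolerance match window, Da (default 0.05 for high-resolution data).
#' @param nominal when `TRUE`, match on integer nominal masses with a +-0.5 Da
#'   window instead (rule-authoring mode).
#' @return One row of [neutral_loss_rules()] (nearest rule, ties by smallest
#'   absolute deviation), or `NULL` when no rule lies within the window.
#' @examples
#' match_loss(341.1245 - 179.0710)$name # hexose
#' @export
match_loss <- function(delta, tolerance = 0.05, nominal = FALSE) {
  stopifnot(delta >= 0)
  rules <- neutral_loss_rules()
  ref <- if (nominal) rules$nominal else rules$exact
  tol <- if (nominal) 0.5 else tolerance
  dev <- abs(delta - ref)
  i <- which.min(dev)
  if (dev[i] > tol) return(NULL)
  rules[i, , drop = FALSE]
}

parse_fragment_field <- function(s) {
  if (is.na(s) || s == "") {
    return(data.frame(mz = numeric(0), base = logical(0), charge = integer(0)))
  }
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  base <- grepl("!", toks, fixed = TRUE)
  dbl <- grepl("^2", toks, fixed = TRUE)
  mz <- as.numeric(gsub("!", "", gsub("^2", "", toks, fixed = TRUE), fixed = TRUE))
  data.frame(mz = mz, base = base, charge = ifelse(dbl, 2L, 1L))
}

format_fragment_field <- function(fr) {
  if (nrow(fr) == 0L) return("")
  paste0(sprintf("%.4f", fr$mz),
         ifelse(fr$charge == 2L, "^2", ""),
         ifelse(fr$base, "!", ""),
         collapse = ";")
}

#' Load the compound knowledge base
#'
#' Reads the built-in knowledge base (68 records encoding the annotated
#' raspberry metabolome: peak id, name, class, composition, ion species,
#' retention time, observed m/z, MS2 fragment list with base-peak flag,
#' annotation level, standard availability and per-cultivar presence), or a
#' user file in the same tab-separated schema. Each record is validated on
#' load: the theoretical m/z is recomputed from the formula and the observed
#' m/z must lie within 5 ppm of it unless the record carries a documented
#' `"mass"` discrepancy flag, and a non-empty fragment list must flag exactly
#' one base peak.
#'
#' @param path path to a knowledge-base TSV; `NULL` (default) loads the
#'   built-in base.
#' @return A data.frame of class `"compound_kb"`, one row per record, with a
#'   list-column `fragments` (data.frames with `mz`, `base`, `charge`),
#'   logical presence columns `GA`, `T`, `G`, `J`, and a computed
#'   `theoretical_mz` column.
#' @export
load_knowledge_base <- function(path = NULL) {
  builtin <- is.null(path)
  if (builtin && !is.null(.kb_env$kb)) return(.kb_env$kb)
  if (builtin)
    path <- system.file("extdata", "kb_rubus.tsv", package = "rubusmet",
                        mustWork = TRUE)
  kb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(exact_printed = "character",
                                         delta_printed = "character"))
  required <- c("peak", "name", "class", "formula", "adduct", "rt", "tof_mz",
                "exact_printed", "delta_printed", "fragments", "level",
                "standard", "GA", "T", "G", "J", "discrepancy")
  missing <- setdiff(required, names(kb))
  if (length(missing))
    stop("knowledge base schema violation: missing column(s) ",
         paste(missing, collapse = ", "))
  kb$fragments <- lapply(kb$fragments, parse_fragment_field)
  for (cv in c("GA", "T", "G", "J")) kb[[cv]] <- kb[[cv]] == 1
  kb$standard <- as.logical(kb$standard)
  kb$polarity <- ifelse(kb$adduct %in% c("M+H", "M+"), "positive", "negative")
  kb$charge <- vapply(kb$adduct, function(a) ion_species(a)$charge, integer(1))
  kb$theoretical_mz <- mapply(function(f, a) ion_mz(f, a),
                              kb$formula, kb$adduct)
  # reference m/z used for precursor matching: the recomputed theoretical
  # value, except for records whose printed formula is the corrupted field
  # ("mass" discrepancy), where the tabulated exact mass is the usable
  # reference for the real compound
  kb$reference_mz <- ifelse(grepl("mass", kb$discrepancy),
                            as.numeric(kb$exact_printed), kb$theoretical_mz)
  validate_kb(kb)
  class(kb) <- c("compound_kb", "data.frame")
  if (builtin) .kb_env$kb <- kb
  kb
}

validate_kb <- function(kb) {
  for (i in seq_len(nrow(kb))) {
    r <- kb[i, ]
    id <- r$peak
    if (!r$level %in% c("I", "II", "III", "IV"))
      stop("record ", id, ": invalid annotation level '", r$level, "'")
    if (r$level == "I" && !r$standard)
      stop("record ", id, ": level I requires an available standard")
    mass_flagged <- grepl("mass", r$discrepancy)
    if (!mass_flagged && abs(ppm_error(r$tof_mz, r$theoretical_mz)) >= 5)
      stop("record ", id, ": observed m/z deviates >= 5 ppm from formula ",
           "and is not on the discrepancy list")
    fr <- r$fragments[[1]]
    if (nrow(fr) > 0L && sum(fr$base) != 1L)
      stop("record ", id, ": fragment list must flag exactly one base peak")
  }
  invisible(TRUE)
}

#' Serialize a knowledge base back to its TSV schema
#'
#' Round-trip stable with [load_knowledge_base()] (numeric fragment m/z are
#' written at 4 decimals, as tabulated).
#'
#' @param kb a `"compound_kb"` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  out <- kb[, c("peak", "name", "class", "formula", "adduct", "rt", "tof_mz",
                "exact_printed", "delta_printed")]
  out$fragments <- vapply(kb$fragments, format_fragment_field, character(1))
  out$level <- kb$level
  out$standard <- kb$standard
  for (cv in c("GA", "T", "G", "J")) out[[cv]] <- as.integer(kb[[cv]])
  out$discrepancy <- kb$discrepancy
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
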