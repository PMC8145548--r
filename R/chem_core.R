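# Molecular-formula parsing and high-resolution mass/charge arithmetic.
#
# Conventions used throughout the package:
#  * deprotonated ions [M-nH]^n-  : m/z = (M_mono - n * m_proton) / n
#  * protonated ions  [M+H]^+    : m/z =  M_mono + m_proton
#  * intact cations   [M]^+      : m/z =  plain monoisotopic sum of the
#    cation formula (flavylium convention for anthocyanins; no electron
#    correction, matching how exact masses of native cations are tabulated
#    in the polyphenol literature).

# Frozen physical constants: IUPAC monoisotopic masses of the lightest
# (and heavier) isotopes, conventional standard atomic weights, isotope
# abundances, proton and electron masses.
.rubusmet_constants <- local({
  mono <- c(C = 12.0, H = 1.00782503207, O = 15.99491461956,
            N = 14.0030740048, S = 31.97207100, P = 30.97376163)
  weight <- c(C = 12.011, H = 1.008, O = 15.999,
              N = 14.007, S = 32.06, P = 30.973761998)
  # per element: data.frame(shift = integer nominal mass shift, mass, abundance)
  isotopes <- list(
    C = data.frame(shift = 0:1, mass = c(12.0, 13.00335483507),
                   abundance = c(0.9893, 0.0107)),
    H = data.frame(shift = 0:1, mass = c(1.00782503207, 2.01410177785),
                   abundance = c(0.999885, 0.000115)),
    O = data.frame(shift = 0:2, mass = c(15.99491461956, 16.99913175650, 17.99915961286),
                   abundance = c(0.99757, 0.00038, 0.00205)),
    N = data.frame(shift = 0:1, mass = c(14.0030740048, 15.0001088989),
                   abundance = c(0.99636, 0.00364)),
    S = data.frame(shift = c(0L, 1L, 2L, 4L),
                   mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
                   abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
    P = data.frame(shift = 0L, mass = 30.97376163, abundance = 1.0)
  )
  list(mono = mono, weight = weight, isotopes = isotopes,
       proton = 1.0072765, electron = 0.00054857990907,
       c13_c12 = 13.00335483507 - 12.0)
})

#' Physical constants used for mass arithmetic
#'
#' Returns the frozen table of monoisotopic isotope masses, standard atomic
#' weights, natural isotope abundances, and the proton/electron masses that
#' underlie all exact-mass computations in the package.
#'
#' @return A list with elements `mono` (named vector of lightest-isotope
#'   masses, Da), `weight` (standard atomic weights), `isotopes` (per-element
#'   isotope tables), `proton`, `electron` and `c13_c12` (the 13C-12C mass
#'   difference, 1.0033548 Da).
#' @export
mass_constants <- function() .rubusmet_constants

#' Parse a molecular formula string
#'
#' Parses element-count strings such as `"C27H22O18"` into a named integer
#' vector of element counts. Supported elements are C, H, O, N, S and P;
#' parentheses and isotope labels are not part of the grammar (formulas in
#' this workflow always come from the compound knowledge base).
#'
#' @param text a formula string, e.g. `"C14H6O8"`.
#' @return A named integer vector of class `"mol_formula"`, elements in Hill
#'   order (C, H, then alphabetical).
#' @examples
#' parse_formula("C14H6O8")
#' @export
parse_formula <- function(text) {
  if (inherits(text, "mol_formula")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (txt == "" || !grepl("^([A-Z][a-z]?[0-9]*)+$", txt))
    stop("malformed formula string: '", text, "'")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", txt)[[1]]
  tokens <- regmatches(txt, list(m))[[1]]
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% names(.rubusmet_constants$mono))
      stop("unknown element symbol '", el, "' in formula '", text, "'")
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (n == "") 1L else as.integer(n)
    counts[el] <- if (is.na(counts[el])) n else counts[el] + n
  }
  if (all(counts == 0L)) stop("formula has no atoms: '", text, "'")
  new_mol_formula(counts)
}

new_mol_formula <- function(counts) {
  counts <- counts[counts > 0L]
  # Hill order: C, H, then remaining elements alphabetically
  els <- names(counts)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  structure(as.integer(counts[ord]), names = ord, class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula>", format(x), "\n")
  invisible(x)
}

#' Serialize a parsed formula back to a Hill-order string
#' @param f a `mol_formula` or formula string.
#' @return Canonical Hill-order formula string.
#' @export
formula_string <- function(f) format(parse_formula_like(f))

parse_formula_like <- function(f) {
  if (inherits(f, "mol_formula")) f else parse_formula(f)
}

#' Combine two formulas (atom-wise sum)
#' @param f1,f2 formulas (strings or `mol_formula`).
#' @return The union `mol_formula`.
#' @export
formula_add <- function(f1, f2) {
  a <- parse_formula_like(f1); b <- parse_formula_like(f2)
  els <- union(names(a), names(b))
  counts <- vapply(els, function(e) {
    sum(a[e], b[e], na.rm = TRUE)
  }, numeric(1))
  new_mol_formula(stats::setNames(as.integer(counts), els))
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the lightest-isotope mass.
#'
#' @param f formula string or `mol_formula`. An empty/zero formula is allowed
#'   and gives mass 0.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C7H6O5") # gallic acid, 170.0215
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f) && length(f) == 1L && trimws(f) == "") return(0)
  f <- parse_formula_like(f)
  sum(unclass(f) * .rubusmet_constants$mono[names(f)])
}

#' Average (molecular-weight) mass of a formula
#'
#' Sum of count times conventional standard atomic weight; this is the "MW"
#' quoted for large ellagitannins (e.g. 1569 Da for C68H48O44).
#'
#' @inheritParams monoisotopic_mass
#' @return Mass in Da.
#' @export
average_mass <- function(f) {
  if (is.character(f) && length(f) == 1L && trimws(f) == "") return(0)
  f <- parse_formula_like(f)
  sum(unclass(f) * .rubusmet_constants$weight[names(f)])
}

#' Construct an ion-species descriptor
#'
#' The three ion kinds this workflow needs: deprotonated `[M-nH]^n-` (negative
#' ESI, n = 1..3), protonated `[M+H]^+`, and the intact flavylium cation
#' `[M]^+` whose formula is itself the cation composition.
#'
#' @param adduct one of `"M-H"`, `"M-2H"`, `"M-3H"`, `"M+H"`, `"M+"`.
#' @return A list of class `"ion_species"` with fields `kind`
#'   (`"deprotonated"`, `"protonated"`, `"cation"`), `charge` (z >= 1),
#'   `polarity` (`"negative"`/`"positive"`), and `adduct`.
#' @examples
#' ion_species("M-2H")
#' @export
ion_species <- function(adduct = c("M-H", "M-2H", "M-3H", "M+H", "M+")) {
  if (inherits(adduct, "ion_species")) return(adduct)
  adduct <- match.arg(adduct)
  out <- switch(adduct,
    "M-H"  = list(kind = "deprotonated", charge = 1L, polarity = "negative"),
    "M-2H" = list(kind = "deprotonated", charge = 2L, polarity = "negative"),
    "M-3H" = list(kind = "deprotonated", charge = 3L, polarity = "negative"),
    "M+H"  = list(kind = "protonated",   charge = 1L, polarity = "positive"),
    "M+"   = list(kind = "cation",       charge = 1L, polarity = "positive"))
  out$adduct <- adduct
  structure(out, class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  lab <- switch(x$kind,
    deprotonated = sprintf("[M-%sH]%s-", if (x$charge > 1L) x$charge else "",
                           if (x$charge > 1L) x$charge else ""),
    protonated = "[M+H]+", cation = "[M]+")
  cat("<ion>", lab, x$polarity, "\n")
  invisible(x)
}

#' Theoretical m/z of a formula under an ion species
#'
#' @param f formula (string or `mol_formula`); for `"M+"` this is the cation
#'   composition itself.
#' @param ion an [ion_species()] or adduct string.
#' @return m/z in Da.
#' @examples
#' ion_mz("C16H18O9", "M-H")      # chlorogenic acid, 353.0878
#' ion_mz("C27H31O16", "M+")      # cyanidin-3-O-sophoroside cation, 611.16121
#' @export
ion_mz <- function(f, ion) {
  ion <- ion_species(ion)
  m <- monoisotopic_mass(f)
  p <- .rubusmet_constants$proton
  mz <- switch(ion$kind,
    deprotonated = (m - ion$charge * p) / ion$charge,
    protonated   = m + p,
    cation       = m)
  if (mz <= 0) stop("non-positive m/z for formula ", formula_string(f))
  mz
}

#' Neutral (or cation) monoisotopic mass from an observed m/z
#'
#' Exact inverse of [ion_mz()]: charge deconvolution for multiply deprotonated
#' ions, proton removal for `[M+H]+`, identity for intact cations.
#'
#' @param mz observed m/z (> 0).
#' @param ion an [ion_species()] or adduct string.
#' @return Reconstructed monoisotopic mass in Da.
#' @examples
#' neutral_mass_from_mz(551.0433, "M-2H") # sanguiin H-2, MW-class 1104
#' @export
neutral_mass_from_mz <- function(mz, ion) {
  stopifnot(mz > 0)
  ion <- ion_species(ion)
  p <- .rubusmet_constants$proton
  switch(ion$kind,
    deprotonated = ion$charge * mz + ion$charge * p,
    protonated   = mz - p,
    cation       = mz)
}

#' Relative mass error in parts per million
#'
#' @param observed observed m/z.
#' @param reference theoretical m/z (> 0).
#' @return `(observed - reference) / reference * 1e6`.
#' @export
ppm_error <- function(observed, reference) {
  stopifnot(all(reference > 0))
  (observed - reference) / reference * 1e6
}

#' Theoretical isotope pattern of an ion
#'
#' Aggregated (nominal-resolution) isotope distribution obtained by iterative
#' per-element convolution of natural-abundance isotope distributions, pruned
#' at a relative-abundance floor. Fine structure within a nominal peak is not
#' resolved; each A+k peak is placed at `(ion mass + k * 1.0033548) / z`.
#'
#' @param f formula (string or `mol_formula`).
#' @param ion optional [ion_species()]; when `NULL` the neutral pattern on the
#'   mass axis is returned (z = 1).
#' @param n_peaks number of peaks to retain (>= 2).
#' @param floor relative-abundance pruning floor (fraction of base peak).
#' @return A data.frame of class `"isotope_pattern"` with columns `mz` and
#'   `abundance` (base peak = 1), ordered by increasing mass.
#' @examples
#' isotope_pattern("C6H12O6", "M-H")
#' @export
isotope_pattern <- function(f, ion = NULL, n_peaks = 4L, floor = 1e-5) {
  stopifnot(n_peaks >= 2L)
  f <- parse_formula_like(f)
  dist <- c(1.0)  # probability over shift index, starting at shift 0
  for (el in names(f)) {
    iso <- .rubusmet_constants$isotopes[[el]]
    atom <- numeric(max(iso$shift) + 1L)
    atom[iso$shift + 1L] <- iso$abundance
    n <- unclass(f)[[el]]
    # repeated convolution; counts here are small (<= a few hundred atoms)
    for (i in seq_len(n)) {
      dist <- convolve_trunc(dist, atom, 2L * n_peaks)
    }
  }
  ab <- dist / max(dist)
  z <- 1L
  if (!is.null(ion)) {
    ion <- ion_species(ion)
    z <- ion$charge
    m0 <- ion_mz(f, ion) * z  # total ion mass
  } else {
    m0 <- monoisotopic_mass(f)
  }
  k <- seq_along(ab) - 1L
  keep <- ab >= floor
  keep[1] <- TRUE
  out <- data.frame(mz = (m0 + k * .rubusmet_constants$c13_c12) / z,
                    abundance = ab)[keep, , drop = FALSE]
  out <- utils::head(out, n_peaks)
  rownames(out) <- NULL
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

convolve_trunc <- function(a, b, nmax) {
  n <- min(length(a) + length(b) - 1L, nmax)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Infer charge state from isotope-peak spacing
#'
#' The 13C isotope spacing of a z-charged ion is 1.0033548/z; the nearest
#' integer z is accepted when `|1.0033548/spacing - z| <= tol`.
#'
#' @param isotope_spacing observed spacing between the first two isotope
#'   peaks, Da (> 0).
#' @param max_z maximum charge considered (default 3, the highest state seen
#'   for large ellagitannins in negative ESI).
#' @param tol acceptance tolerance on the implied charge (default 0.1).
#' @return Integer charge, or `NA_integer_` when undetermined.
#' @examples
#' infer_charge(0.5017) # 2
#' @export
infer_charge <- function(isotope_spacing, max_z = 3L, tol = 0.1) {
  stopifnot(isotope_spacing > 0)
  zhat <- .rubusmet_constants$c13_c12 / isotope_spacing
  z <- round(zhat)
  if (z < 1L || z > max_z || abs(zhat - z) > tol) return(NA_integer_)
  as.integer(z)
}
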