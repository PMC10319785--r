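#' Supported elements and their atomic properties
#'
#' The default configuration supports the 13 elements commonly found in
#' ion-mobility CCS training collections: C, H, O, N, P, S, F, Cl, Br, I,
#' Co, As and Se. For each element the table carries the standard atomic
#' mass (Da), the covalent radius and the van der Waals radius (both
#' Angstrom). The covalent radii follow Cordero et al. (2008); the van der
#' Waals radii follow Bondi (1964) with conventional fill-ins where Bondi
#' gives no value (Co).
#'
#' @format A data.frame with one row per element and columns
#'   \code{element}, \code{mass}, \code{covalent_radius}, \code{vdw_radius}.
#' @export
element_table <- function() {
  data.frame(
    element = c("C", "H", "O", "N", "P", "S", "F",
                "Cl", "Br", "I", "Co", "As", "Se"),
    mass = c(12.011, 1.008, 15.999, 14.007, 30.974, 32.06, 18.998,
             35.45, 79.904, 126.904, 58.933, 74.922, 78.971),
    covalent_radius = c(0.76, 0.31, 0.66, 0.71, 1.07, 1.05, 0.57,
                        1.02, 1.20, 1.39, 1.26, 1.19, 1.20),
    vdw_radius = c(1.70, 1.20, 1.52, 1.55, 1.80, 1.80, 1.47,
                   1.75, 1.85, 1.98, 2.00, 1.85, 1.90),
    stringsAsFactors = FALSE
  )
}

#' Default element vocabulary
#'
#' Ordered element symbols used for the one-hot symbol block of the node
#' attribute matrix. The order is fixed so that feature columns are stable
#' across checkpoints.
#' @export
default_elements <- function() element_table()$element

.element_property <- function(elements, column, table = element_table()) {
  idx <- match(elements, table$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop(errorCondition(
      sprintf("unsupported element(s): %s", paste(bad, collapse = ", ")),
      class = c("graphccs_unsupported_element", "graphccs_error")
    ))
  }
  table[[column]][idx]
}

# ---- Adducts ---------------------------------------------------------------

.ADDUCTS <- c("[M+H]+", "[M+Na]+", "[M-H]-")
.ADDUCT_MASS_SHIFT <- c(`[M+H]+` = 1.00728, `[M+Na]+` = 22.98922,
                        `[M-H]-` = -1.00728)

#' Supported adduct ion types
#'
#' The three electrospray adducts supported by the model: protonated
#' \code{[M+H]+}, sodiated \code{[M+Na]+} and deprotonated \code{[M-H]-}.
#' @return Character vector of the three adduct labels.
#' @export
supported_adducts <- function() .ADDUCTS

#' One-hot encoding of an adduct type
#'
#' \code{[M+H]+}, \code{[M+Na]+} and \code{[M-H]-} are encoded as
#' \code{c(1,0,0)}, \code{c(0,1,0)} and \code{c(0,0,1)} respectively.
#'
#' @param adduct Adduct label, one of \code{supported_adducts()}. A few
#'   common spelling variants (unicode minus, spaces) are normalised.
#' @return Numeric 3-vector one-hot code.
#' @export
adduct_code <- function(adduct) {
  adduct <- normalize_adduct(adduct)
  code <- numeric(3)
  code[match(adduct, .ADDUCTS)] <- 1
  code
}

#' Normalise an adduct label
#'
#' Maps spelling variants (unicode minus sign, embedded spaces) onto the
#' canonical labels and errors on anything outside the supported three.
#' @param adduct Character vector of adduct labels.
#' @return Canonical labels.
#' @export
normalize_adduct <- function(adduct) {
  x <- gsub("−|–", "-", adduct)
  x <- gsub(" ", "", x)
  ok <- x %in% .ADDUCTS
  if (!all(ok)) {
    stop(errorCondition(
      sprintf("unknown adduct type(s): %s (supported: %s)",
              paste(unique(adduct[!ok]), collapse = ", "),
              paste(.ADDUCTS, collapse = ", ")),
      class = c("graphccs_unknown_adduct", "graphccs_error")
    ))
  }
  x
}

#' Mass shift of an adduct ion
#'
#' @param adduct Adduct label(s).
#' @return Mass shift in Da added to the neutral monoisotopic-style mass to
#'   obtain m/z for these singly charged adducts (+1.00728 for \code{[M+H]+},
#'   +22.98922 for \code{[M+Na]+}, -1.00728 for \code{[M-H]-}).
#' @export
adduct_mass_shift <- function(adduct) {
  unname(.ADDUCT_MASS_SHIFT[normalize_adduct(adduct)])
}
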