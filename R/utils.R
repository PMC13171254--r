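# shared numeric helpers and element tables

#' Squared cross-distances between two coordinate sets
#'
#' @param a,b matrices (n x 3, m x 3), nm.
#' @return n x m matrix of squared distances.
#' @keywords internal
crossdist2 <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# atomic masses, amu
.element_masses <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007,
                     O = 15.999, S = 32.06, P = 30.974, F = 18.998)

#' Atomic masses for a vector of element symbols
#'
#' Unknown elements fall back to carbon; this only affects mass weighting
#' of pseudo-atoms in coarse models.
#' @param elements character vector of element symbols.
#' @return numeric vector, amu.
#' @export
element_masses <- function(elements) {
  m <- .element_masses[toupper(elements)]
  m[is.na(m)] <- .element_masses[["C"]]
  unname(m)
}

# Bondi van der Waals radii, nm
.bondi_radii <- c(H = 0.120, D = 0.120, C = 0.170, N = 0.155, O = 0.152,
                  F = 0.147, P = 0.180, S = 0.180, CL = 0.175, BR = 0.185,
                  I = 0.198)

#' Van der Waals radii (Bondi) for element symbols
#'
#' @param elements character vector of element symbols.
#' @param default radius used for elements missing from the table; `NA`
#'   raises an error listing the unknown elements.
#' @return numeric vector, nm.
#' @export
vdw_radii <- function(elements, default = 0.170) {
  r <- .bondi_radii[toupper(elements)]
  if (anyNA(r)) {
    if (is.na(default)) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(elements[is.na(r)]), collapse = ", "))
    }
    r[is.na(r)] <- default
  }
  unname(r)
}
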