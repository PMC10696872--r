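#' @include AllClasses.R
NULL

#' Mouse vertebral formula
#'
#' Named integer vector of vertebra counts per region: 7 cervical (Ce),
#' 13 thoracic (T), 6 lumbar (L), 4 sacral (S); caudal (Ca) vertebrae are
#' open-ended and handled implicitly.  Other species or strains can
#' supply their own counts to the functions that accept a \code{formula}
#' argument.
#'
#' @export
mouseVertebralFormula <- c(Ce = 7L, T = 13L, L = 6L, S = 4L)

#' Convert between vertebra labels and anatomical ordinals
#'
#' Ordinals number vertebrae from anterior to posterior: Ce1 = 1, ...,
#' Ce7 = 7, T1 = 8, ..., T13 = 20, L1 = 21, ..., L6 = 26, S1 = 27, ...,
#' S4 = 30, Ca1 = 31 and onward.  Labels like "L6" parse case-sensitively.
#'
#' @param label character vector of labels such as "T6" or "Ca3".
#' @param ordinal integer vector of anatomical ordinals (>= 1).
#' @param formula named region counts, see \code{\link{mouseVertebralFormula}}.
#' @return \code{vertebraOrdinal}: integer ordinals; \code{vertebraLabel}:
#'   character labels.
#' @examples
#' vertebraOrdinal(c("Ce1", "L6", "Ca2"))
#' vertebraLabel(c(1L, 26L, 32L))
#' @export
vertebraOrdinal <- function(label, formula = mouseVertebralFormula) {
  m <- regmatches(label, regexec("^(Ce|T|L|S|Ca)([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("unparseable vertebra label(s): ",
         paste(label[bad], collapse = ", "))
  region <- vapply(m, `[`, "", 2L)
  num <- as.integer(vapply(m, `[`, "", 3L))
  offsets <- c(0L, cumsum(formula))
  names(offsets) <- c(names(formula), "Ca")
  nmax <- c(formula, Ca = NA_integer_)[region]
  if (any(num < 1L) || any(!is.na(nmax) & num > nmax))
    stop("vertebra number out of range for its region: ",
         paste(label[num < 1L | (!is.na(nmax) & num > nmax)], collapse = ", "))
  as.integer(offsets[region] + num)
}

#' @rdname vertebraOrdinal
#' @export
vertebraLabel <- function(ordinal, formula = mouseVertebralFormula) {
  ordinal <- as.integer(ordinal)
  if (anyNA(ordinal) || any(ordinal < 1L))
    stop("ordinals must be positive integers; the vertebral formula is ",
         "exhausted anterior to Ce1")
  bounds <- cumsum(formula)
  total <- bounds[length(bounds)]
  out <- character(length(ordinal))
  for (i in seq_along(ordinal)) {
    k <- ordinal[i]
    if (k > total) {
      out[i] <- paste0("Ca", k - total)
    } else {
      r <- which(k <= bounds)[1L]
      prev <- if (r == 1L) 0L else bounds[r - 1L]
      out[i] <- paste0(names(formula)[r], k - prev)
    }
  }
  out
}
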