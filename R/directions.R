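#' Create a direction specification
#'
#' Build a [DirectionSpec-class] from an explicit vector or from an
#' anatomical label (see [directionFromLabel()]). Non-unit vectors are
#' normalized.
#'
#' @param label character(1) short direction name, e.g. \code{"SA"}.
#' @param vector numeric(3) direction in LPS patient coordinates, or
#'   \code{NULL} to parse \code{label} as an anatomical axis combination.
#' @param routeClass character(1) route-of-spread class used for study
#'   pooling (e.g. \code{"intraosseous"}, \code{"extraosseous"}).
#' @return a [DirectionSpec-class].
#' @examples
#' DirectionSpec("SA", routeClass = "intraosseous")          # parsed label
#' DirectionSpec("oblique", vector = c(1, 1, 0))             # explicit vector
#' @export
DirectionSpec <- function(label, vector = NULL, routeClass = "unspecified") {
  if (is.null(vector))
    return(directionFromLabel(label, routeClass = routeClass))
  vector <- as.numeric(vector)
  nv <- vnorm(vector)
  if (!is.finite(nv) || nv < 1e-12)
    ctvStop("ctv_label_parse", "direction vector must be nonzero and finite")
  new("DirectionSpec", label = as.character(label), vector = vector / nv,
      routeClass = as.character(routeClass))
}

#' @rdname ctvMargins-accessors
#' @export
setMethod("directionLabel", "DirectionSpec", function(object) object@label)

#' @rdname ctvMargins-accessors
#' @export
setMethod("directionVector", "DirectionSpec", function(object) object@vector)

#' @rdname ctvMargins-accessors
#' @export
setMethod("routeClass", "DirectionSpec", function(object) object@routeClass)

setMethod("show", "DirectionSpec", function(object) {
  cat(sprintf("DirectionSpec \"%s\" [%s]: (%.4f, %.4f, %.4f) LPS\n",
              object@label, object@routeClass, object@vector[1],
              object@vector[2], object@vector[3]))
})

# LPS axis conventions: +x Left, +y Posterior, +z Superior.
.axisVectors <- list(
  R = c(-1, 0, 0), L = c(1, 0, 0),
  A = c(0, -1, 0), P = c(0, 1, 0),
  S = c(0, 0, 1), I = c(0, 0, -1)
)
.opposites <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")

#' Parse an anatomical direction label
#'
#' Converts a label built from the tokens R, L, A, P, S, I (anatomical
#' right/left/anterior/posterior/superior/inferior), optionally hyphenated,
#' into a unit vector in LPS patient coordinates (+x Left, +y Posterior,
#' +z Superior). Compound labels such as \code{"SA"} (superior-anterior) are
#' the normalized sum of their components.
#'
#' @param label character(1), e.g. \code{"L"}, \code{"SA"}, \code{"S-A"}.
#' @param routeClass character(1) route-of-spread class.
#' @return a [DirectionSpec-class] with the parsed unit vector.
#' @examples
#' directionVector(directionFromLabel("L"))   # (1, 0, 0)
#' directionVector(directionFromLabel("SA"))  # (0, -1, 1) / sqrt(2)
#' @export
directionFromLabel <- function(label, routeClass = "unspecified") {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    ctvStop("ctv_label_parse", "label must be a single non-empty string")
  tokens <- strsplit(gsub("-", "", label, fixed = TRUE), "")[[1]]
  unknown <- setdiff(tokens, names(.axisVectors))
  if (length(unknown))
    ctvStop("ctv_label_parse",
            sprintf("unknown direction token(s) in \"%s\": %s", label,
                    paste(unknown, collapse = ", ")))
  for (tok in tokens)
    if (.opposites[[tok]] %in% tokens)
      ctvStop("ctv_label_contradiction",
              sprintf("label \"%s\" combines opposing tokens %s and %s",
                      label, tok, .opposites[[tok]]))
  v <- Reduce(`+`, .axisVectors[tokens])
  new("DirectionSpec", label = label, vector = v / vnorm(v),
      routeClass = as.character(routeClass))
}
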