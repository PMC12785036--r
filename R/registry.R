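#' The sixteen-superfamily Wicker class registry
#'
#' The default registry holds the sixteen TE superfamilies the classifier
#' distinguishes, in a fixed order, together with the roll-up from each
#' superfamily to its Wicker order (LTR, LINE, SINE, TIR, Crypton, Helitron,
#' Maverick). Class order matters: it fixes label indices during training,
#' the column order of probability outputs, and the argmax tie-break
#' (first class in registry order wins).
#'
#' @param classes Character vector of unique superfamily names.
#' @param orders Named character vector mapping each superfamily to its order.
#'   Must cover every entry of `classes`.
#' @return An object of class `te_registry`: a list with elements `classes`
#'   (character) and `orders` (named character).
#' @examples
#' reg <- default_registry()
#' reg$classes
#' superfamily_order(reg, "Gypsy")   # "LTR"
#' @export
te_registry <- function(classes, orders) {
  if (anyDuplicated(classes)) {
    stop("registry class names must be unique")
  }
  missing <- setdiff(classes, names(orders))
  if (length(missing) > 0) {
    stop("no order mapping for superfamily: ", paste(missing, collapse = ", "))
  }
  structure(
    list(classes = as.character(classes),
         orders = orders[classes]),
    class = "te_registry"
  )
}

#' @rdname te_registry
#' @export
default_registry <- function() {
  classes <- c("Copia", "Crypton", "ERV", "Gypsy", "hAT", "Helitron",
               "Jockey", "L1/L2", "Maverick", "Merlin", "P", "Pao",
               "RTE", "SINE", "TcMar", "Transib")
  orders <- c(
    Copia = "LTR", Gypsy = "LTR", Pao = "LTR", ERV = "LTR",
    "L1/L2" = "LINE", RTE = "LINE", Jockey = "LINE",
    SINE = "SINE",
    TcMar = "TIR", hAT = "TIR", Merlin = "TIR", Transib = "TIR", P = "TIR",
    Crypton = "Crypton", Helitron = "Helitron", Maverick = "Maverick"
  )
  te_registry(classes, orders)
}

#' Roll a predicted superfamily up to its Wicker order
#'
#' @param registry A `te_registry`.
#' @param superfamily Character vector of superfamily names.
#' @return Character vector of order names.
#' @export
superfamily_order <- function(registry, superfamily) {
  stopifnot(inherits(registry, "te_registry"))
  unknown <- setdiff(unique(superfamily), registry$classes)
  if (length(unknown) > 0) {
    stop("superfamily not in registry: ", paste(unknown, collapse = ", "))
  }
  unname(registry$orders[superfamily])
}

#' @export
print.te_registry <- function(x, ...) {
  cat("TE class registry:", length(x$classes), "superfamilies\n")
  for (ord in unique(unname(x$orders))) {
    cat(sprintf("  %-9s %s\n", ord,
                paste(x$classes[x$orders == ord], collapse = ", ")))
  }
  invisible(x)
}
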