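# Compound registry for brGDGT proxy work.
#
# Canonical compound ids use the Unicode prime (′) for 6-methyl isomers,
# e.g. "IIa′". ASCII apostrophes are accepted on input and normalized.

.PRIME <- "′"

.build_registry <- function() {
  p <- .PRIME
  ids <- c(
    "Ia", "Ib", "Ic",
    "IIa", paste0("IIa", p), "IIb", paste0("IIb", p),
    "IIc", paste0("IIc", p),
    "IIIa", paste0("IIIa", p), "IIIb", paste0("IIIb", p),
    "IIIc", paste0("IIIc", p),
    "Cren", "C46-GTGT"
  )
  data.frame(
    id = ids,
    methylation_class = c(rep("tetra", 3), rep("penta", 6), rep("hexa", 6),
                          "n/a", "n/a"),
    ring_count = c(0, 1, 2, 0, 0, 1, 1, 2, 2, 0, 0, 1, 1, 2, 2, NA, NA),
    isomer_position = c(rep("n/a", 3),
                        rep(c("5-methyl", "6-methyl"), 6),
                        "n/a", "n/a"),
    # SIM target ions (Da): one m/z per ring count within a methylation series;
    # 5- and 6-methyl isomers share their m/z and are resolved chromatographically.
    sim_mz = c(1022.0, 1020.0, 1018.0,
               1036.0, 1036.0, 1034.0, 1034.0, 1032.0, 1032.0,
               1050.0, 1050.0, 1048.0, 1048.0, 1046.0, 1046.0,
               1292.3, 743.6),
    stringsAsFactors = FALSE
  )
}

.REGISTRY <- .build_registry()

#' Compound registry
#'
#' The closed set of compounds handled by the package: the 15 common brGDGT
#' structures (tetra-, penta- and hexamethylated; 0-2 cyclopentane rings;
#' 5- vs 6-methyl positional isomers marked with a prime), the isoprenoid
#' GDGT crenarchaeol (`Cren`, the BIT denominator term) and the `C46-GTGT`
#' internal quantification standard, together with the selected-ion-monitoring
#' m/z each compound is detected at.
#'
#' @return A data frame with columns `id`, `methylation_class`
#'   (`tetra`/`penta`/`hexa` or `n/a`), `ring_count` (0-2 or `NA`),
#'   `isomer_position` (`5-methyl`/`6-methyl`/`n/a`) and `sim_mz` (Da).
#' @examples
#' gdgt_compounds()
#' @export
gdgt_compounds <- function() .REGISTRY

#' Canonical brGDGT compound ids
#'
#' @param series optionally restrict to one methylation series
#'   (`"tetra"`, `"penta"`, `"hexa"`).
#' @return Character vector of the 15 brGDGT ids (crenarchaeol and the
#'   internal standard excluded).
#' @export
brgdgt_ids <- function(series = NULL) {
  r <- .REGISTRY[.REGISTRY$methylation_class != "n/a", ]
  if (!is.null(series)) {
    series <- match.arg(series, c("tetra", "penta", "hexa"))
    r <- r[r$methylation_class == series, ]
  }
  r$id
}

# The five acyclic compounds entering IMBT.
.acyclic5 <- function() {
  p <- .PRIME
  c("IIIa", paste0("IIIa", p), "IIa", paste0("IIa", p), "Ia")
}

.six_methyl_ids <- function() {
  r <- .REGISTRY
  r$id[r$isomer_position == "6-methyl"]
}

.penta_hexa_ids <- function() {
  r <- .REGISTRY
  r$id[r$methylation_class %in% c("penta", "hexa")]
}

#' Normalize compound ids to their canonical form
#'
#' Accepts ASCII apostrophes (`'`), typographic apostrophes and the prime
#' mark for 6-methyl isomers, plus common spellings of crenarchaeol and the
#' internal standard; emits canonical ids (prime mark, `Cren`, `C46-GTGT`).
#'
#' @param x character vector of compound names.
#' @param strict if `TRUE` (default) unknown names are an error listing the
#'   accepted ids; if `FALSE` they map to `NA`.
#' @return Character vector of canonical ids (or `NA` where unmatched and
#'   `strict = FALSE`).
#' @examples
#' canonical_compound(c("IIa'", "crenarchaeol", "Ia"))
#' @export
canonical_compound <- function(x, strict = TRUE) {
  y <- trimws(as.character(x))
  # unify prime-like marks: ASCII apostrophe, right single quote, acute accent
  y <- gsub("['’´`]", .PRIME, y)
  low <- tolower(y)
  y[low %in% c("cren", "crenarchaeol")] <- "Cren"
  y[low %in% c("c46", "c46-gtgt", "c46 gtgt", "c46gtgt", "is",
               "internal standard")] <- "C46-GTGT"
  ok <- y %in% .REGISTRY$id
  if (strict && any(!ok)) {
    stop("unknown compound id(s): ",
         paste(sQuote(unique(x[!ok])), collapse = ", "),
         "\n  accepted ids: ", paste(.REGISTRY$id, collapse = ", "),
         call. = FALSE)
  }
  y[!ok] <- NA_character_
  y
}
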