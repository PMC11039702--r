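# The brGDGT proxy index suite.
#
# All indexes are ratios of per-compound signals, so they can be computed
# from peak areas, concentrations or fractional abundances interchangeably.
# Every compute_* function accepts a gdgt_table, a plain data frame/matrix
# with compound-identifiable columns, or a single named numeric vector, and
# returns a numeric vector (one value per sample) with two logical
# attributes:
#   "undefined"  TRUE where the formula hit a zero numerator/denominator
#                (the value is NA unless the epsilon zero-policy is chosen);
#   "incomplete" TRUE (per sample, constant here) when a compound the
#                formula references is absent from the detected set and was
#                treated as zero.
# Logs are base 10 throughout, the convention of the CBT index family and
# the one under which the shipped DOU calibration's coefficients apply.

.signal_matrix <- function(x, ids) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- as.data.frame(as.list(x), check.names = FALSE)
  }
  if (is.matrix(x)) x <- as.data.frame(x, check.names = FALSE)
  nm <- names(x)
  cand <- canonical_compound(nm, strict = FALSE)
  nm[!is.na(cand)] <- cand[!is.na(cand)]
  names(x) <- nm
  m <- matrix(0, nrow = nrow(x), ncol = length(ids),
              dimnames = list(NULL, ids))
  present <- ids %in% nm
  for (cc in ids[present]) m[, cc] <- as.numeric(x[[cc]])
  if (any(m < 0, na.rm = TRUE)) stop("negative signals", call. = FALSE)
  attr(m, "present") <- stats::setNames(present, ids)
  # total brGDGT signal, used by the epsilon floor
  br <- intersect(brgdgt_ids(), nm)
  attr(m, "total_br") <- if (length(br) > 0) {
    rowSums(as.matrix(as.data.frame(x)[br]), na.rm = TRUE)
  } else {
    rowSums(m)
  }
  m
}

.flagged <- function(value, undefined, incomplete) {
  attr(value, "undefined") <- undefined
  attr(value, "incomplete") <- rep(incomplete, length(value))
  value
}

.neg_log10_ratio <- function(num, den, total, zero_policy, epsilon) {
  undef <- den == 0 | (num == 0 & zero_policy == "undefined")
  if (zero_policy == "epsilon") num <- pmax(num, epsilon * total)
  v <- ifelse(den > 0 & num > 0, -log10(num / den), NA_real_)
  list(value = v, undefined = undef & is.na(v) | den == 0)
}

#' IMBT: isomerization and methylation index of branched tetraethers
#'
#' `IMBT = -log10[(IIIa′ + IIa′) / (IIIa + IIIa′ + IIa + IIa′ + Ia)]`,
#' computed over the five acyclic brGDGTs. Lower values indicate a higher
#' share of 6-methyl penta- and hexamethylated compounds, the composition
#' characteristic of low diffusive oxygen uptake; IMBT is >= 0 whenever
#' defined, and is the predictor of the [DOU transfer
#' function][fit_dou_calibration].
#'
#' @param x signals: a `gdgt_table`, data frame, matrix or named numeric
#'   vector (see package conventions in [compute_indices()]).
#' @param zero_policy what to do when the 6-methyl numerator is zero:
#'   `"undefined"` (default) yields a flagged `NA`; `"epsilon"` floors the
#'   numerator at `epsilon` times the total brGDGT signal so a finite value
#'   is returned.
#' @param epsilon numerator floor, as a fraction of total brGDGT signal
#'   (default `1e-3`).
#' @return Numeric vector with `"undefined"` and `"incomplete"` attributes.
#' @examples
#' compute_imbt(c(IIIa = 0.2, `IIIa'` = 0.2, IIa = 0.2, `IIa'` = 0.2,
#'                Ia = 0.2))  # -log10(0.4)
#' @export
compute_imbt <- function(x, zero_policy = c("undefined", "epsilon"),
                         epsilon = 1e-3) {
  zero_policy <- match.arg(zero_policy)
  ids <- .acyclic5()
  m <- .signal_matrix(x, ids)
  p <- .PRIME
  num <- m[, paste0("IIIa", p)] + m[, paste0("IIa", p)]
  den <- rowSums(m)
  r <- .neg_log10_ratio(num, den, attr(m, "total_br"), zero_policy, epsilon)
  .flagged(r$value, r$undefined, !all(attr(m, "present")))
}

#' BIT: branched and isoprenoid tetraether index
#'
#' `BIT = (Ia + IIa + IIIa + IIa′ + IIIa′) / (Ia + IIa + IIIa + IIa′ +
#' IIIa′ + Cren)`. A terrestrial-input proxy: below about 0.15 in open
#' marine sediments, approaching 1 in soils. Crenarchaeol must be on the
#' same signal scale as the brGDGTs (true for areas, concentrations, and
#' the output of [fractional_abundances()], which scales crenarchaeol by
#' the same total).
#'
#' @inheritParams compute_imbt
#' @return Numeric vector in `[0, 1]` with flag attributes.
#' @export
compute_bit <- function(x) {
  p <- .PRIME
  ids <- c("Ia", "IIa", "IIIa", paste0("IIa", p), paste0("IIIa", p), "Cren")
  m <- .signal_matrix(x, ids)
  num <- rowSums(m[, 1:5, drop = FALSE])
  den <- num + m[, "Cren"]
  v <- ifelse(den > 0, num / den, NA_real_)
  .flagged(v, den == 0, !all(attr(m, "present")))
}

#' IR: 6-methyl isomer ratio
#'
#' Sum of all 6-methyl penta- and hexamethylated brGDGTs over the sum of
#' all penta- and hexamethylated brGDGTs (both isomer series, all ring
#' classes). Ranges 0 (all 5-methyl) to 1 (all 6-methyl). With the 11
#' compounds typically detected in deep-sea sediments (IIIb/IIIc series
#' absent) it reduces to the available a/b/c terms, and the `"incomplete"`
#' flag is set.
#'
#' @inheritParams compute_imbt
#' @return Numeric vector in `[0, 1]` with flag attributes.
#' @export
compute_ir <- function(x) {
  ids <- .penta_hexa_ids()
  m <- .signal_matrix(x, ids)
  num <- rowSums(m[, intersect(.six_methyl_ids(), ids), drop = FALSE])
  den <- rowSums(m)
  v <- ifelse(den > 0, num / den, NA_real_)
  .flagged(v, den == 0, !all(attr(m, "present")))
}

#' MBT'5ME: methylation index of 5-methyl branched tetraethers
#'
#' `MBT'5ME = (Ia + Ib + Ic) / (Ia + Ib + Ic + IIa + IIb + IIc + IIIa)`,
#' computed on 5-methyl compounds only; conventionally calibrated to
#' temperature.
#'
#' @inheritParams compute_imbt
#' @return Numeric vector in `[0, 1]` with flag attributes.
#' @export
compute_mbt5me <- function(x) {
  ids <- c("Ia", "Ib", "Ic", "IIa", "IIb", "IIc", "IIIa")
  m <- .signal_matrix(x, ids)
  num <- rowSums(m[, c("Ia", "Ib", "Ic"), drop = FALSE])
  den <- rowSums(m)
  v <- ifelse(den > 0, num / den, NA_real_)
  .flagged(v, den == 0, !all(attr(m, "present")))
}

#' CBT5ME: cyclization index of 5-methyl branched tetraethers
#'
#' `CBT5ME = -log10[(Ib + IIb) / (Ia + IIa)]`, conventionally calibrated to
#' pH. Any real value; undefined on a zero numerator (under the default
#' zero policy) or denominator.
#'
#' @inheritParams compute_imbt
#' @return Numeric vector with flag attributes.
#' @export
compute_cbt5me <- function(x, zero_policy = c("undefined", "epsilon"),
                           epsilon = 1e-3) {
  zero_policy <- match.arg(zero_policy)
  ids <- c("Ia", "Ib", "IIa", "IIb")
  m <- .signal_matrix(x, ids)
  num <- m[, "Ib"] + m[, "IIb"]
  den <- m[, "Ia"] + m[, "IIa"]
  r <- .neg_log10_ratio(num, den, attr(m, "total_br"), zero_policy, epsilon)
  .flagged(r$value, r$undefined, !all(attr(m, "present")))
}

#' Sigma-IIIa / Sigma-IIa ratio
#'
#' `(IIIa + IIIa′) / (IIa + IIa′)`: hexa- over pentamethylated acyclic
#' brGDGTs, 5- and 6-methyl isomers combined (7-methyl isomers excluded).
#' A source proxy: < 0.59 in soils, 0.59-0.92 in marine sediments with
#' terrestrial influence, > 0.92 in marine sediments without.
#'
#' @inheritParams compute_imbt
#' @return Non-negative numeric vector with flag attributes.
#' @export
compute_siiia_siia <- function(x) {
  p <- .PRIME
  ids <- c("IIIa", paste0("IIIa", p), "IIa", paste0("IIa", p))
  m <- .signal_matrix(x, ids)
  num <- m[, "IIIa"] + m[, paste0("IIIa", p)]
  den <- m[, "IIa"] + m[, paste0("IIa", p)]
  v <- ifelse(den > 0, num / den, NA_real_)
  .flagged(v, den == 0, !all(attr(m, "present")))
}

#' Ternary coordinates: tetra / penta / hexa fractions
#'
#' Sums the tetra- (I series), penta- (II series) and hexamethylated
#' (III series) brGDGTs — both isomer series, all ring classes — and
#' renormalizes to sum 1, giving the coordinates of the standard
#' methylation ternary diagram used for source classification.
#'
#' @inheritParams compute_imbt
#' @return Numeric matrix with columns `tetra`, `penta`, `hexa`; each row
#'   sums to 1 (NA rows where the total signal is zero).
#' @export
ternary_coordinates <- function(x) {
  ids <- brgdgt_ids()
  m <- .signal_matrix(x, ids)
  out <- cbind(
    tetra = rowSums(m[, brgdgt_ids("tetra"), drop = FALSE]),
    penta = rowSums(m[, brgdgt_ids("penta"), drop = FALSE]),
    hexa  = rowSums(m[, brgdgt_ids("hexa"), drop = FALSE])
  )
  tot <- rowSums(out)
  out <- out / ifelse(tot > 0, tot, NA_real_)
  attr(out, "incomplete") <- rep(!all(attr(m, "present")), nrow(out))
  out
}

# --- extensible index registry ------------------------------------------

.index_env <- new.env(parent = emptyenv())

#' Register a user-defined index
#'
#' Indexes whose formulas are not built in (e.g. DC′ or CBT′ variants from
#' the wider literature) can be registered with a citation and are then
#' evaluated by [compute_indices()] alongside the built-in suite.
#'
#' @param name index name (column name in [compute_indices()] output).
#' @param fun function taking the signal table and returning one numeric
#'   value per sample.
#' @param citation optional character string recording the formula source.
#' @return `name`, invisibly.
#' @export
register_index <- function(name, fun, citation = NULL) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, list(fun = fun, citation = citation), envir = .index_env)
  invisible(name)
}

#' List / remove registered user indexes
#' @rdname register_index
#' @export
registered_indices <- function() ls(.index_env)

#' @rdname register_index
#' @export
unregister_index <- function(name) {
  if (exists(name, envir = .index_env)) rm(list = name, envir = .index_env)
  invisible(name)
}

#' Compute the full proxy index suite
#'
#' Evaluates IMBT, BIT, Sigma-IIIa/Sigma-IIa, IR, MBT'5ME, CBT5ME and the
#' ternary coordinates for every sample, plus any user-registered indexes.
#' Per-index defined-ness is reported in companion logical columns
#' (`<index>_ok`); compounds absent from the detected set are treated as
#' zero and recorded in the `"incomplete"` attribute (named logical vector
#' per index).
#'
#' @inheritParams compute_imbt
#' @return A data frame with one row per sample: any `sample_id` column of
#'   the input, the index columns, `tetra`/`penta`/`hexa`, and `<index>_ok`
#'   flags.
#' @export
compute_indices <- function(x, zero_policy = c("undefined", "epsilon"),
                            epsilon = 1e-3) {
  zero_policy <- match.arg(zero_policy)
  vals <- list(
    imbt = compute_imbt(x, zero_policy, epsilon),
    bit = compute_bit(x),
    siiia_siia = compute_siiia_siia(x),
    ir = compute_ir(x),
    mbt5me = compute_mbt5me(x),
    cbt5me = compute_cbt5me(x, zero_policy, epsilon)
  )
  tern <- ternary_coordinates(x)
  out <- data.frame(row.names = seq_len(length(vals$imbt)))
  if (is.data.frame(x) && "sample_id" %in% names(x)) {
    out$sample_id <- x$sample_id
  }
  incomplete <- logical(0)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    out[[nm]] <- as.numeric(v)
    out[[paste0(nm, "_ok")]] <- !(is.na(v) & attr(v, "undefined"))
    incomplete[nm] <- attr(v, "incomplete")[1]
  }
  out$tetra <- tern[, "tetra"]
  out$penta <- tern[, "penta"]
  out$hexa <- tern[, "hexa"]
  for (nm in registered_indices()) {
    out[[nm]] <- as.numeric(.index_env[[nm]]$fun(x))
  }
  attr(out, "incomplete") <- incomplete
  out
}
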