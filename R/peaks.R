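# Peak-table ingestion, internal-standard quantification and fractional
# abundances.
#
# A peak table is a data frame with one row per sediment horizon. Compound
# columns carry canonical registry ids; everything else (station, depths,
# dry weight, internal-standard mass, TOC, environmental covariates) is kept
# as metadata. The set of compound columns present in the file is the
# "detected set": a column missing from the file means the compound was not
# reported (absent), which is distinct from a detected zero area.

.meta_known <- c("sample_id", "station", "water_depth",
                 "sediment_depth_top", "sediment_depth_bottom",
                 "dry_weight", "is_mass", "toc")

.new_gdgt_table <- function(df, compounds, role) {
  attr(df, "compounds") <- compounds
  attr(df, "role") <- role
  class(df) <- c("gdgt_table", "data.frame")
  df
}

#' Compound columns of a GDGT table
#' @param x a table produced by [read_peak_table()], [quantify()] or
#'   [fractional_abundances()].
#' @return Character vector of canonical compound ids present in `x`.
#' @export
compounds <- function(x) attr(x, "compounds")

#' @export
print.gdgt_table <- function(x, ...) {
  role <- attr(x, "role")
  cat(sprintf("GDGT %s table: %d sample(s), %d compound(s)\n",
              role, nrow(x), length(attr(x, "compounds"))))
  cat("compounds:", paste(attr(x, "compounds"), collapse = ", "), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read an HPLC-MS peak-area table
#'
#' Reads a delimited text file (CSV or TSV; lines starting with `#` are
#' treated as comments) with one row per sample horizon. Columns whose names
#' resolve to registry compound ids (ASCII apostrophes accepted for 6-methyl
#' isomers) become peak-area columns; all other columns are preserved as
#' metadata/covariates. Compound columns missing from the file are recorded
#' as absent — not as zero.
#'
#' @param path path to the delimited file.
#' @param mapping optional named character vector mapping canonical compound
#'   ids to column names in the file (e.g. `c("IIa′" = "IIa_6me")`), for
#'   files whose headers are not registry ids. May also name metadata fields
#'   (e.g. `c(sample_id = "core_slice")`).
#' @param delim field delimiter; guessed from the file extension by default
#'   (`","` for `.csv`, tab otherwise).
#' @return A `gdgt_table` of peak areas with attributes `compounds` (the
#'   detected set) and `role = "area"`.
#' @seealso [quantify()], [fractional_abundances()], [write_gdgt_table()]
#' @export
read_peak_table <- function(path, mapping = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = delim, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", quote = "\"")
  if (!is.null(mapping)) {
    if (is.null(names(mapping)) || any(names(mapping) == "")) {
      stop("'mapping' must be a named character vector (canonical id = column name)",
           call. = FALSE)
    }
    miss <- setdiff(unname(mapping), names(df))
    if (length(miss) > 0) {
      stop("mapped column(s) not in file: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    idx <- match(unname(mapping), names(df))
    key <- names(mapping)
    comp_key <- !(key %in% .meta_known)
    key[comp_key] <- canonical_compound(key[comp_key])
    names(df)[idx] <- key
  }
  # resolve remaining compound-looking columns; unknown names stay metadata
  nm <- names(df)
  cand <- canonical_compound(nm, strict = FALSE)
  is_comp <- !is.na(cand)
  names(df)[is_comp] <- cand[is_comp]
  comp_cols <- names(df)[is_comp]
  if (anyDuplicated(comp_cols)) {
    stop("duplicate compound columns after normalization: ",
         paste(unique(comp_cols[duplicated(comp_cols)]), collapse = ", "),
         call. = FALSE)
  }
  for (cc in comp_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (anyNA(v) && !anyNA(df[[cc]])) {
        stop("compound column ", sQuote(cc), " is not numeric", call. = FALSE)
      }
      df[[cc]] <- v
    }
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative peak area in column %s, row %d",
                   sQuote(cc), bad[1]), call. = FALSE)
    }
  }
  if (length(comp_cols) == 0) {
    stop("no compound columns found; accepted ids: ",
         paste(gdgt_compounds()$id, collapse = ", "), call. = FALSE)
  }
  if (!("sample_id" %in% names(df))) {
    df$sample_id <- sprintf("S%03d", seq_len(nrow(df)))
  }
  # order: metadata first, compounds in registry order
  comp_cols <- intersect(gdgt_compounds()$id, comp_cols)
  meta <- setdiff(names(df), comp_cols)
  df <- df[c(meta, comp_cols)]
  .new_gdgt_table(df, comp_cols, "area")
}

#' Write a GDGT table to CSV
#'
#' Writes a `gdgt_table` as comma-separated text with a `#`-prefixed metadata
#' header recording the table role and detected compound set, in a form that
#' [read_peak_table()] reads back.
#'
#' @param x a `gdgt_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gdgt_table <- function(x, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# brgdgt %s table; compounds: %s",
                     attr(x, "role") %||% "data",
                     paste(attr(x, "compounds"), collapse = ", ")), con)
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify peak areas against the internal standard
#'
#' Converts peak areas to concentrations in ng per g dry sediment using the
#' C46-GTGT internal standard:
#' `conc = (area / area_IS) * is_mass / dry_weight / rf`, with a default
#' 1:1 MS response (`rf = 1`) between analytes and the standard. When a
#' positive TOC content (% by mass) is available, TOC-normalized
#' concentrations in ug per g TOC are attached
#' (`ug/gTOC = (ng/g dws) / (10 * TOC%)`).
#'
#' @param x a `gdgt_table` of peak areas containing a `C46-GTGT` column and
#'   `is_mass` (ng of standard added) and `dry_weight` (g) metadata columns.
#' @param response_factors optional named numeric vector of per-compound
#'   response factors relative to the standard (default 1 for all).
#' @return A `gdgt_table` of concentrations (ng per g dry sediment,
#'   `role = "concentration"`); the internal standard column is dropped.
#'   When TOC is available the TOC-normalized table (ug per g TOC) is stored
#'   in the `"toc_normalized"` attribute.
#' @examples
#' tab <- data.frame(sample_id = "s1", is_mass = 100, dry_weight = 2,
#'                   Ia = 500, IIa = 250, `C46-GTGT` = 500,
#'                   check.names = FALSE)
#' f <- tempfile(fileext = ".csv"); write.csv(tab, f, row.names = FALSE)
#' quantify(read_peak_table(f))  # Ia: 50 ng/g dws
#' @export
quantify <- function(x, response_factors = NULL) {
  comp <- attr(x, "compounds")
  if (!("C46-GTGT" %in% comp)) {
    stop("quantification impossible: no C46-GTGT internal-standard column",
         call. = FALSE)
  }
  for (req in c("is_mass", "dry_weight")) {
    if (!(req %in% names(x))) {
      stop("quantification requires metadata column ", sQuote(req),
           call. = FALSE)
    }
  }
  area_is <- x[["C46-GTGT"]]
  if (any(!is.na(area_is) & area_is <= 0)) {
    stop("quantification impossible: zero or negative internal-standard area",
         call. = FALSE)
  }
  if (any(!is.na(x$dry_weight) & x$dry_weight <= 0)) {
    stop("dry_weight must be > 0", call. = FALSE)
  }
  if (any(!is.na(x$is_mass) & x$is_mass <= 0)) {
    stop("is_mass must be > 0", call. = FALSE)
  }
  targets <- setdiff(comp, "C46-GTGT")
  rf <- stats::setNames(rep(1, length(targets)), targets)
  if (!is.null(response_factors)) {
    nm <- canonical_compound(names(response_factors))
    rf[nm[nm %in% targets]] <- response_factors[nm %in% targets]
    if (any(rf <= 0)) stop("response factors must be > 0", call. = FALSE)
  }
  out <- as.data.frame(x)
  out[["C46-GTGT"]] <- NULL
  for (cc in targets) {
    out[[cc]] <- (x[[cc]] / area_is) * x$is_mass / x$dry_weight / rf[[cc]]
  }
  res <- .new_gdgt_table(out, targets, "concentration")
  if ("toc" %in% names(x)) {
    toc <- x$toc
    ok <- !is.na(toc) & toc > 0
    tn <- out[targets]
    for (cc in targets) {
      tn[[cc]] <- ifelse(ok, out[[cc]] / (10 * toc), NA_real_)
    }
    attr(res, "toc_normalized") <- tn  # ug per g TOC
  }
  res
}

#' Fractional abundances over the detected brGDGT set
#'
#' Normalizes per-compound signals (areas or concentrations — the result is
#' identical under a common response factor) to fractions over the brGDGT
#' compounds detected in the table. Crenarchaeol and the internal standard
#' are excluded from the normalization but crenarchaeol is carried through
#' unscaled so the BIT index can still be computed downstream. Compounds not
#' reported in the table (e.g. the IIIb/IIIc series in low-abundance
#' settings) are absent from the detected set and treated as exact zeros by
#' index formulas, which flag the input as incomplete.
#'
#' @param x a `gdgt_table` (areas or concentrations), or a data frame /
#'   matrix / named numeric vector with compound-identifiable columns.
#' @return A `gdgt_table` of fractions (`role = "fraction"`); each row sums
#'   to 1 over the detected brGDGT set.
#' @export
fractional_abundances <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- as.data.frame(as.list(x), check.names = FALSE)
  }
  if (is.matrix(x)) x <- as.data.frame(x, check.names = FALSE)
  comp <- attr(x, "compounds")
  if (is.null(comp)) {
    cand <- canonical_compound(names(x), strict = FALSE)
    names(x)[!is.na(cand)] <- cand[!is.na(cand)]
    comp <- names(x)[!is.na(cand)]
  }
  br <- intersect(brgdgt_ids(), comp)
  if (length(br) == 0) stop("no brGDGT compound columns found", call. = FALSE)
  m <- as.matrix(as.data.frame(x)[br])
  if (any(m < 0, na.rm = TRUE)) stop("negative signals", call. = FALSE)
  tot <- rowSums(m, na.rm = TRUE)
  if (any(tot <= 0)) {
    stop("empty composition: all-zero brGDGT signal in row(s) ",
         paste(which(tot <= 0), collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(x)
  for (cc in br) out[[cc]] <- m[, cc] / tot
  # crenarchaeol is excluded from the normalization but scaled by the same
  # total, keeping it on the scale the BIT formula expects
  if ("Cren" %in% comp) out[["Cren"]] <- out[["Cren"]] / tot
  kept <- intersect(c(br, "Cren"), comp)
  out <- out[c(setdiff(names(out), c(comp)), kept)]
  .new_gdgt_table(out, kept, "fraction")
}
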