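compound_fields <- c("name", "charge_type", "pka", "solubility_ph74",
                     "papp_caco2_ph65", "vss_per_kg", "cl_per_kg",
                     "ppb_percent_bound", "mol_weight")

charge_types <- c("neutral", "monoacid", "monobase")

#' Construct a single compound input record
#'
#' One drug's physicochemical / pharmacokinetic input record: the quantities
#' a simulation needs and nothing more.  Optional fields (`pka` for neutral
#' compounds, `ppb_percent_bound`) are `NA` when absent; an absent plasma
#' protein binding disables free-level outputs for the compound rather than
#' implying 0% bound.
#'
#' @param name Compound name.
#' @param charge_type One of `"neutral"`, `"monoacid"`, `"monobase"`.
#' @param pka Acid dissociation constant (required unless neutral).
#' @param solubility_ph74 Aqueous solubility at pH 7.4 and room temperature (M).
#' @param papp_caco2_ph65 Apparent Caco-2 permeability, apical to basolateral,
#'   at pH 6.5 (cm s^-1).
#' @param vss_per_kg Volume of distribution at steady state (L kg^-1).
#' @param cl_per_kg Plasma clearance (mL min^-1 kg^-1).
#' @param ppb_percent_bound Plasma protein binding (% bound), or `NA`.
#' @param mol_weight Molecular weight (g mol^-1).
#'
#' @return An object of class `compound` (a named list).
#' @export
#' @examples
#' compound("diazepam", "neutral", NA, 1.57e-4, 6.03e-5, 1.00, 0.38,
#'          98.61, 284.74)
compound <- function(name, charge_type, pka = NA_real_,
                     solubility_ph74, papp_caco2_ph65, vss_per_kg,
                     cl_per_kg, ppb_percent_bound = NA_real_, mol_weight) {
  x <- list(
    name = as.character(name),
    charge_type = as.character(charge_type),
    pka = as.numeric(pka),
    solubility_ph74 = as.numeric(solubility_ph74),
    papp_caco2_ph65 = as.numeric(papp_caco2_ph65),
    vss_per_kg = as.numeric(vss_per_kg),
    cl_per_kg = as.numeric(cl_per_kg),
    ppb_percent_bound = as.numeric(ppb_percent_bound),
    mol_weight = as.numeric(mol_weight)
  )
  class(x) <- "compound"
  validate_compound(x)
}

validate_compound <- function(x) {
  nm <- if (nzchar(x$name)) x$name else "<unnamed>"
  fail <- function(msg) stop(sprintf("compound '%s': %s", nm, msg),
                             call. = FALSE)
  if (!x$charge_type %in% charge_types)
    fail(sprintf("unsupported charge type '%s' (must be %s)", x$charge_type,
                 paste(charge_types, collapse = "/")))
  if (x$charge_type == "neutral") {
    if (!is.na(x$pka)) fail("pKa must be absent for a neutral compound")
  } else {
    if (is.na(x$pka)) fail("pKa is required for an ionisable compound")
  }
  need_pos <- c("solubility_ph74", "papp_caco2_ph65", "vss_per_kg",
                "mol_weight")
  for (f in need_pos) {
    v <- x[[f]]
    if (length(v) != 1L || is.na(v) || !is.finite(v) || v <= 0)
      fail(sprintf("'%s' must be a single positive number", f))
  }
  if (is.na(x$cl_per_kg) || x$cl_per_kg < 0)
    fail("'cl_per_kg' must be >= 0")
  if (!is.na(x$ppb_percent_bound) &&
      (x$ppb_percent_bound < 0 || x$ppb_percent_bound >= 100))
    fail("'ppb_percent_bound' must lie in [0, 100)")
  x
}

#' @export
print.compound <- function(x, ...) {
  pka <- if (is.na(x$pka)) "-" else format(x$pka)
  ppb <- if (is.na(x$ppb_percent_bound)) "n/a" else
    paste0(format(x$ppb_percent_bound), "% bound")
  cat(sprintf("<compound> %s (%s, pKa %s)\n", x$name, x$charge_type, pka))
  cat(sprintf("  S(pH7.4) %.3g M | Papp(Caco-2) %.3g cm/s | MW %.5g g/mol\n",
              x$solubility_ph74, x$papp_caco2_ph65, x$mol_weight))
  cat(sprintf("  Vss %.3g L/kg | Cl %.3g mL/min/kg | PPB %s\n",
              x$vss_per_kg, x$cl_per_kg, ppb))
  invisible(x)
}

#' Read a compound table from CSV
#'
#' Expects a comma-separated, period-decimal, UTF-8 file with a header row
#' naming the fields of [compound()]; scientific notation is accepted and
#' lines starting with `#` are ignored.  Missing optional values (`pka`,
#' `ppb_percent_bound`) are stored as `NA`, never as zero.  A missing
#' mandatory column raises a schema error naming the column; a non-numeric
#' or out-of-range value raises a row-level validation error naming the
#' compound.
#'
#' @param path Path to the CSV file.
#' @return A list of `compound` objects (class `compound_set`).
#' @seealso [example_compounds()] for the packaged 15-drug table.
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) stop("compound file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(compound_fields, names(df))
  if (length(missing_cols) > 0)
    stop("compound table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    num <- function(field) {
      v <- trimws(row[[field]])
      if (is.na(v) || v == "") return(NA_real_)
      x <- suppressWarnings(as.numeric(v))
      if (is.na(x))
        stop(sprintf("compound table row %d ('%s'): non-numeric value '%s' in '%s'",
                     i, row$name, v, field), call. = FALSE)
      x
    }
    out[[i]] <- compound(
      name = row$name,
      charge_type = tolower(trimws(row$charge_type)),
      pka = num("pka"),
      solubility_ph74 = num("solubility_ph74"),
      papp_caco2_ph65 = num("papp_caco2_ph65"),
      vss_per_kg = num("vss_per_kg"),
      cl_per_kg = num("cl_per_kg"),
      ppb_percent_bound = num("ppb_percent_bound"),
      mol_weight = num("mol_weight")
    )
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  class(out) <- "compound_set"
  out
}

#' Write a compound table to CSV
#'
#' Inverse of [read_compounds()]: numeric fields are written with full
#' precision (17 significant digits) so that a read/write round trip is
#' exact.
#'
#' @param compounds A list of `compound` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  df <- as.data.frame(compounds)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  num_cols <- setdiff(compound_fields, c("name", "charge_type"))
  for (cc in num_cols) df[[cc]] <- fmt(df[[cc]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
as.data.frame.compound_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(cp) {
    data.frame(cp[compound_fields], stringsAsFactors = FALSE)
  })) -> df
  rownames(df) <- NULL
  df
}

#' The packaged 15-drug input table
#'
#' Returns the bundled table of 15 marketed oral drugs (6 monoacids, 6
#' monobases, 2 neutrals and diazepam/nifedipine among them) with measured
#' pKa, pH 7.4 solubility, Caco-2 permeability, Vss, Cl and (where
#' available) plasma protein binding, plus monograph molecular weights.
#'
#' @param path_only If `TRUE`, return the file path instead of reading it.
#' @return A `compound_set`, or the fixture path.
#' @export
#' @examples
#' drugs <- example_compounds()
#' length(drugs)      # 15
#' drugs[["diazepam"]]
example_compounds <- function(path_only = FALSE) {
  p <- system.file("extdata", "oral_drugs_15.csv", package = "dqihld",
                   mustWork = TRUE)
  if (path_only) return(p)
  read_compounds(p)
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d compounds: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}
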