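#' Built-in modification catalog
#'
#' A small catalog of modification masses in the style of UNIMOD, covering
#' the modifications most relevant to phosphoproteome open searches:
#' enzymatic phosphorylation, common sample-preparation artefacts, the
#' C13 isotope spacing, and the phosphate-containing metabolite-derived
#' modifications (glycerophosphoryl-Lys, glycerylphosphorylethanolamine-Glu,
#' FMN-His).
#'
#' @details Masses are monoisotopic and signed; losses are negative.
#' `specificity` is a comma-separated set of one-letter residue codes and/or
#' the terminal flags `peptide-Nterm`, `protein-Nterm`, `Cterm`, `any`.
#' `origin` classifies each entry as `biological`, `artefactual` or
#' `unknown`; artefactual entries are those introduced during benchwork or
#' fragmentation (e.g. ammonia loss from peptide-N-terminal
#' carbamidomethyl-Cys) rather than present in the living sample.
#'
#' @return A tibble with columns `name`, `mono_mass` (Da), `specificity`,
#'   `origin`.
#' @export
#' @examples
#' default_catalog()
default_catalog <- function() {
  tibble::tribble(
    ~name,                  ~mono_mass,  ~specificity,      ~origin,
    "phospho",               79.966331,  "S,T,Y",           "biological",
    "carbamidomethyl",       57.021464,  "C",               "artefactual",
    "oxidation",             15.994915,  "M",               "biological",
    "acetyl_protein_nterm",  42.010565,  "protein-Nterm",   "biological",
    "deamidation",            0.984016,  "N,Q",             "biological",
    "ammonia_loss",         -17.026549,  "peptide-Nterm",   "artefactual",
    "carbamylation",         43.005814,  "peptide-Nterm,K", "artefactual",
    "met_loss",            -131.040485,  "protein-Nterm",   "biological",
    "c13",                    1.003355,  "any",             "biological",
    "phosphoglyceryl",      167.982375,  "K",               "biological",
    "glyceryl_pe",          197.045309,  "E",               "biological",
    "fmn",                  454.088965,  "H",               "biological"
  )
}

#' Read a modification catalog from a delimited file
#'
#' @param path Path to a tab-delimited file with columns `name`, `mono_mass`,
#'   `specificity`, `origin`.
#' @return A tibble with the same columns as [default_catalog()].
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  cat_df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  if (nrow(cat_df) == 0) stop("catalog file is empty: ", path)
  required <- c("name", "mono_mass", "specificity", "origin")
  missing <- setdiff(required, names(cat_df))
  if (length(missing) > 0)
    stop("catalog is missing required column(s): ",
         paste(missing, collapse = ", "))
  mass <- suppressWarnings(as.numeric(cat_df$mono_mass))
  if (anyNA(mass))
    stop("non-numeric mono_mass in catalog row(s): ",
         paste(which(is.na(mass)), collapse = ", "))
  out <- tibble::tibble(
    name = cat_df$name,
    mono_mass = mass,
    specificity = cat_df$specificity,
    origin = cat_df$origin
  )
  validate_catalog(out)
  out
}

#' Write a modification catalog to a tab-delimited file
#'
#' @param catalog A catalog tibble as from [default_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  readr::write_tsv(catalog, path, progress = FALSE)
  invisible(path)
}

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  required <- c("name", "mono_mass", "specificity", "origin")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0)
    stop("catalog is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!all(is.finite(catalog$mono_mass)))
    stop("catalog mono_mass must be finite")
  if (any(is.na(catalog$specificity) | catalog$specificity == ""))
    stop("catalog specificity must be non-empty")
  if (anyDuplicated(catalog$name))
    stop("catalog names must be unique")
  invisible(catalog)
}

# Split a specificity string into residue letters / terminal flags.
specificity_tokens <- function(spec) {
  strsplit(spec, ",", fixed = TRUE)[[1]] |> trimws()
}

# Residue letters (subset of the 20-letter alphabet) named in a specificity.
specificity_residues <- function(spec) {
  tok <- specificity_tokens(spec)
  tok[tok %in% strsplit(AA_ALPHABET, "")[[1]]]
}

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"
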