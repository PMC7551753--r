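#' Canonical physiological-variable (PV) catalog
#'
#' The 17 bedside and laboratory variables used throughout the package, in
#' canonical order. This order is the deterministic tie-break used when two
#' PVs obtain exactly equal importance scores, and the column order of all
#' feature matrices.
#'
#' @return Character vector of 17 PV abbreviations.
#' @seealso [pv_physiology()] for the plausible-physiology table behind the
#'   synthetic generator and the default cleaning ranges.
#' @export
#' @examples
#' pv_catalog()
pv_catalog <- function() {
  c("SpO2", "CRR", "FiO2", "GCST", "GCSE", "GCSM", "GCSV", "PH", "Wt",
    "TEMP", "SBP", "RR", "MBP", "Ht", "HR", "Glu", "DBP")
}

#' Canonical disease-code catalog
#'
#' Codes `D1`..`D24` for the 24 grouped ICU discharge diagnoses (CCS-style
#' phenotype groups) the classifiers are trained on. Diseases are not
#' mutually exclusive: a stay may carry several labels.
#'
#' @return Character vector of 24 disease codes.
#' @export
disease_catalog <- function() paste0("D", 1:24)

#' Human-readable disease descriptions
#'
#' @return A data.frame with columns `code` and `name`.
#' @export
disease_descriptions <- function() {
  data.frame(
    code = disease_catalog(),
    name = c(
      "Acute and unspecified renal failure",
      "Acute cerebrovascular disease",
      "Acute myocardial infarction",
      "Cardiac dysrhythmias",
      "Chronic kidney disease",
      "Congestive heart failure; non-hypertensive",
      "Chronic obstructive pulmonary disease and bronchiectasis",
      "Complications of surgical procedures or medical care",
      "Conduction disorder",
      "Coronary atherosclerosis and other heart diseases",
      "Diabetes mellitus with complications",
      "Diabetes mellitus without complications",
      "Disorders of lipid metabolism",
      "Essential hypertension",
      "Hypertension with complications and secondary hypertension",
      "Fluid and electrolyte disorders",
      "Gastrointestinal hemorrhage",
      "Other liver diseases",
      "Other lower respiratory diseases",
      "Other upper respiratory diseases",
      "Pleurisy; pneumothorax; pulmonary collapse",
      "Pneumonia",
      "Respiratory failure; insufficiency; arrest (adult)",
      "Septicemia"
    ),
    stringsAsFactors = FALSE
  )
}

#' Plausible-physiology table for the 17 PVs
#'
#' Per-PV marginal mean and spread used by the synthetic cohort generator,
#' together with the canonical measurement unit and a plausible value range
#' `[lo, hi]` used as the default outlier filter during cleaning. CRR
#' (capillary refill rate) is categorical and encoded 0 = normal,
#' 1 = abnormal; the Glasgow coma scale components stay on their native
#' numeric scales. Values are typical adult-ICU figures; they are
#' configuration, not estimates from any particular database, and can be
#' overridden wherever the table is consumed.
#'
#' @return A data.frame with columns `pv`, `mean`, `sd`, `unit`, `lo`, `hi`,
#'   `binary`.
#' @export
pv_physiology <- function() {
  tab <- data.frame(
    pv   = pv_catalog(),
    mean = c(97,    0.15, 0.50, 12,   3.4, 5.2, 3.8, 7.38, 81,
             36.9,  120,  19,   80,   170, 85,  130, 60),
    sd   = c(2.5,   NA,   0.15, 3.5,  1.0, 1.2, 1.5, 0.07, 23,
             0.7,   20,   6,    15,   11,  15,  45,  12),
    unit = c("%",   "cat", "frac", "points", "points", "points", "points",
             "pH",  "kg", "C", "mmHg", "insp/min", "mmHg", "cm", "bpm",
             "mg/dL", "mmHg"),
    lo   = c(0,     0,    0.21, 3,    1,   1,   1,   6.3,  20,
             25,    30,   0,    20,   120, 0,   20,  10),
    hi   = c(100,   1,    1,    15,   4,   6,   5,   8.0,  300,
             45,    300,  70,   200,  230, 300, 1000, 200),
    binary = FALSE,
    stringsAsFactors = FALSE
  )
  tab$binary[tab$pv == "CRR"] <- TRUE
  tab
}

#' Default cleaning range table
#'
#' The per-PV plausible ranges and canonical units consumed by
#' [clean_events()]. A value falling outside `[lo, hi]` *after* unit
#' conversion is treated as an outlier and dropped.
#'
#' @param physiology a physiology table as returned by [pv_physiology()].
#' @return data.frame with columns `pv`, `lo`, `hi`, `unit`.
#' @export
default_range_table <- function(physiology = pv_physiology()) {
  physiology[, c("pv", "lo", "hi", "unit")]
}

# alias map for PV labels seen in external tables
.pv_aliases <- c(
  "Weight" = "Wt", "weight" = "Wt", "Height" = "Ht", "height" = "Ht",
  "Temp" = "TEMP", "Temperature" = "TEMP", "pH" = "PH", "Glucose" = "Glu",
  "SpO2" = "SpO2"
)

#' Normalize PV labels to canonical abbreviations
#'
#' Maps common long or alternate spellings (e.g. `"Weight"`, `"pH"`) onto
#' the canonical abbreviations of [pv_catalog()]. Unknown labels are
#' returned unchanged so callers can decide whether they are errors.
#'
#' @param x character vector of PV labels.
#' @return character vector of canonical abbreviations.
#' @export
pv_normalize <- function(x) {
  hit <- match(x, names(.pv_aliases))
  out <- ifelse(is.na(hit), x, unname(.pv_aliases[hit]))
  out
}

#' Published example PV importance rankings
#'
#' Full 17-deep PV importance orderings for four conditions — conduction
#' disorder (D9), coronary atherosclerosis and other heart diseases (D10),
#' diabetes mellitus with complications (D11) and diabetes mellitus without
#' complications (D12) — as reported by the ICU study this method is built
#' around. They ship with the package as a plain-text fixture so that the
#' disease-comparison operation can be exercised against real published
#' orderings (no AUC-drop scores were published, so `delta` is `NA`).
#'
#' @return Named list of [as_importance_ranking()] objects keyed by disease
#'   code.
#' @export
example_rankings <- function() {
  path <- system.file("extdata", "example_rankings.csv", package = "pvrank")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(setdiff(names(tab), "rank"), function(code) {
    as_importance_ranking(pv_normalize(tab[[code]]), disease = code)
  })
  names(out) <- setdiff(names(tab), "rank")
  out
}
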