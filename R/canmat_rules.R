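# CANMAT drug-tier knowledge: antidepressant catalog, monotherapy lines,
# superior-efficacy set, adjunctive lines. All concordance logic reads these
# tables; no drug name is hard-coded anywhere else in the package.

.lines <- c("first", "second", "third")

#' Path to the drug catalog shipped with the package
#'
#' The catalog lists every generic drug name the package knows about, its
#' pharmacological class and whether it is an antidepressant. It covers the
#' antidepressants available on the Chinese market plus the adjunctive agents
#' named in the CANMAT 2016 recommendations. The file is plain TSV and is
#' intended to be copied and edited for other formularies.
#'
#' @return File path of the default `drug_catalog.tsv`.
#' @export
canmat_catalog_file <- function() {
  system.file("extdata", "drug_catalog.tsv", package = "adconcord",
              mustWork = TRUE)
}

#' Path to the CANMAT tier table shipped with the package
#'
#' Transcription of the CANMAT 2016 stepwise pharmacotherapy recommendations:
#' monotherapy lines 1-3 with the superior-efficacy flag, and adjunctive
#' (augmentation) lines 1-3. Buspirone is deliberately absent from the
#' adjunct list (it was dropped in the 2016 revision). Editable TSV.
#'
#' @return File path of the default `canmat_tiers.tsv`.
#' @export
canmat_tier_file <- function() {
  system.file("extdata", "canmat_tiers.tsv", package = "adconcord",
              mustWork = TRUE)
}

#' Load a drug catalog
#'
#' @param path TSV file with columns `drug_id`, `ad_class`,
#'   `is_antidepressant` (0/1). Defaults to the shipped catalog.
#' @return A `data.table` of class `adc_catalog` with one row per drug.
#' @export
load_drug_catalog <- function(path = canmat_catalog_file()) {
  cat_dt <- tryCatch(
    fread(path, sep = "\t", colClasses = list(character = c("drug_id", "ad_class"))),
    error = function(e) stop("malformed drug catalog '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("drug_id", "ad_class", "is_antidepressant")
  if (!all(need %in% names(cat_dt)))
    stop("drug catalog must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(cat_dt) == 0L) stop("drug catalog is empty", call. = FALSE)
  if (anyDuplicated(cat_dt$drug_id))
    stop("duplicate drug_id in catalog: ",
         paste(unique(cat_dt$drug_id[duplicated(cat_dt$drug_id)]), collapse = ", "),
         call. = FALSE)
  classes <- c("SSRI", "SNRI", "TCA", "NaSSA", "other_AD",
               "antipsychotic", "mood_stabilizer", "other_adjunct")
  bad <- setdiff(unique(cat_dt$ad_class), classes)
  if (length(bad))
    stop("unknown ad_class value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cat_dt[, is_antidepressant := as.logical(is_antidepressant)]
  setkey(cat_dt, drug_id)
  setattr(cat_dt, "class", c("adc_catalog", class(cat_dt)))
  cat_dt[]
}

#' Is a drug an antidepressant?
#'
#' @param catalog An `adc_catalog`.
#' @param drug Character vector of drug ids.
#' @return Logical vector; error if any drug is not in the catalog.
#' @export
is_antidepressant <- function(catalog, drug) {
  miss <- setdiff(drug, catalog$drug_id)
  if (length(miss))
    stop("drug(s) not in catalog: ", paste(miss, collapse = ", "), call. = FALSE)
  catalog[J(drug), is_antidepressant]
}

#' Load a CANMAT tier table
#'
#' Reads a drug -> line-of-treatment table covering monotherapy and adjunctive
#' roles and validates it against a drug catalog. Concordance semantics are
#' attached here as well: which monotherapy lines a switch may target and
#' which adjunct lines count as "in the recommendation list".
#'
#' The default switch-eligible set follows the guideline wording literally
#' (superior-efficacy first-line drugs, plus any second- or third-line drug);
#' `switch_allow_any_first_line = TRUE` broadens it so that any first-line
#' drug is an acceptable switch target.
#'
#' @param path TSV with columns `drug_id`, `role` (`monotherapy`|`adjunct`),
#'   `line` (1|2|3), `superior_efficacy` (0|1). Defaults to the shipped table.
#' @param catalog An `adc_catalog`; every drug in the file must resolve.
#' @param switch_allow_any_first_line Logical; see above.
#' @param adjunct_eligible_lines Character subset of
#'   `c("first","second","third")` counted as recommended adjuncts.
#' @return A list of class `canmat_tiers` with elements `monotherapy_line`
#'   (named character vector drug -> line), `superior_efficacy` (character
#'   vector), `adjunct_line` (named character vector), the two eligibility
#'   settings, and `catalog`.
#' @export
load_tier_table <- function(path = canmat_tier_file(),
                            catalog = load_drug_catalog(),
                            switch_allow_any_first_line = FALSE,
                            adjunct_eligible_lines = c("first", "second", "third")) {
  tt <- tryCatch(
    fread(path, sep = "\t", colClasses = list(character = c("drug_id", "role"))),
    error = function(e) stop("malformed tier table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("drug_id", "role", "line", "superior_efficacy")
  if (!all(need %in% names(tt)))
    stop("tier table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tt) == 0L) stop("tier table is empty", call. = FALSE)
  bad_role <- setdiff(unique(tt$role), c("monotherapy", "adjunct"))
  if (length(bad_role))
    stop("unknown role(s) in tier table: ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  if (!all(tt$line %in% 1:3)) {
    i <- which(!(tt$line %in% 1:3))[1L]
    stop("tier table line ", i, ": line must be 1, 2 or 3", call. = FALSE)
  }
  miss <- setdiff(tt$drug_id, catalog$drug_id)
  if (length(miss))
    stop("tier table references drug(s) not in catalog: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tt[, .(drug_id, role)]))
    stop("duplicate (drug_id, role) rows in tier table", call. = FALSE)

  mono <- tt[role == "monotherapy"]
  if (any(!is_antidepressant(catalog, mono$drug_id)))
    stop("monotherapy lines may contain only antidepressants; offending: ",
         paste(mono$drug_id[!is_antidepressant(catalog, mono$drug_id)],
               collapse = ", "), call. = FALSE)
  adj <- tt[role == "adjunct"]
  sup <- mono[superior_efficacy == 1, drug_id]

  adjunct_eligible_lines <- match.arg(adjunct_eligible_lines, .lines,
                                      several.ok = TRUE)
  out <- structure(list(
    monotherapy_line = stats::setNames(.lines[mono$line], mono$drug_id),
    superior_efficacy = sup,
    adjunct_line = stats::setNames(.lines[adj$line], adj$drug_id),
    switch_allow_any_first_line = isTRUE(switch_allow_any_first_line),
    adjunct_eligible_lines = adjunct_eligible_lines,
    catalog = catalog
  ), class = "canmat_tiers")
  out
}

#' Write a tier table back to file
#'
#' Inverse of [load_tier_table()]; reloading the written file yields an
#' identical table.
#'
#' @param tiers A `canmat_tiers` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tier_table <- function(tiers, path) {
  stopifnot(inherits(tiers, "canmat_tiers"))
  mono <- data.table(
    drug_id = names(tiers$monotherapy_line),
    role = "monotherapy",
    line = match(unname(tiers$monotherapy_line), .lines),
    superior_efficacy = as.integer(names(tiers$monotherapy_line) %in%
                                     tiers$superior_efficacy)
  )
  adj <- data.table(
    drug_id = names(tiers$adjunct_line),
    role = "adjunct",
    line = match(unname(tiers$adjunct_line), .lines),
    superior_efficacy = 0L
  )
  fwrite(rbind(mono, adj), path, sep = "\t")
  invisible(path)
}

.tier_lookup <- function(map, catalog, drug) {
  miss <- setdiff(drug, catalog$drug_id)
  if (length(miss))
    stop("drug(s) not in catalog: ", paste(miss, collapse = ", "), call. = FALSE)
  out <- unname(map[drug])
  out[is.na(out)] <- "unlisted"
  out
}

#' Monotherapy line of treatment for a drug
#'
#' @param tiers A `canmat_tiers` object.
#' @param drug Character vector of drug ids (must exist in the catalog).
#' @return Character vector in `c("first","second","third","unlisted")`.
#' @export
monotherapy_status <- function(tiers, drug) {
  .tier_lookup(tiers$monotherapy_line, tiers$catalog, drug)
}

#' Adjunctive (augmentation) line of treatment for a drug
#'
#' @inheritParams monotherapy_status
#' @return Character vector in `c("first","second","third","unlisted")`.
#' @export
adjunct_status <- function(tiers, drug) {
  .tier_lookup(tiers$adjunct_line, tiers$catalog, drug)
}

#' Is a drug an acceptable switch target under the algorithm?
#'
#' Concordant switch targets are antidepressants with evidence of superior
#' efficacy, or second-/third-line antidepressants; optionally any first-line
#' drug when the table was loaded with `switch_allow_any_first_line = TRUE`.
#'
#' @inheritParams monotherapy_status
#' @return Logical vector.
#' @export
switch_eligible <- function(tiers, drug) {
  st <- monotherapy_status(tiers, drug)
  ok <- st %in% c("second", "third") | drug %in% tiers$superior_efficacy
  if (tiers$switch_allow_any_first_line) ok <- ok | st == "first"
  ok
}

#' Is a drug an acceptable adjunct under the algorithm?
#'
#' @inheritParams monotherapy_status
#' @return Logical vector.
#' @export
adjunct_eligible <- function(tiers, drug) {
  adjunct_status(tiers, drug) %in% tiers$adjunct_eligible_lines
}
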