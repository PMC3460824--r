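#' IUCN Red List categories handled by the package
#'
#' Ordered from least to most threatened; `DD` (data deficient) must be
#' resolved with [apply_dd_scenario()] before probabilities are assigned.
#' @return Character vector `c("LC","NT","VU","EN","CR")`.
#' @export
iucn_categories <- function() c("LC", "NT", "VU", "EN", "CR")

#' Construct a category-to-extinction-probability model
#'
#' Probabilities must lie in \[0, 1\] and are expected to be non-decreasing
#' from LC to CR; a violation is allowed but warned about.
#'
#' @param name Model name.
#' @param LC,NT,VU,EN,CR Extinction probabilities per category.
#' @return An object of class `extinction_model`: a named numeric vector
#'   with a `name` attribute.
#' @export
extinction_model <- function(name, LC, NT, VU, EN, CR) {
  p <- c(LC = LC, NT = NT, VU = VU, EN = EN, CR = CR)
  if (any(p < 0 | p > 1))
    stop("extinction probabilities must be in [0, 1]", call. = FALSE)
  if (is.unsorted(p))
    warning("probabilities are not monotone over LC <= NT <= VU <= EN <= CR",
            call. = FALSE)
  structure(p, name = name, class = "extinction_model")
}

#' The IUCN50 extinction-probability model
#'
#' Red List categories mapped to 50-year extinction probabilities:
#' LC = 0.00005, NT = 0.004, VU = 0.05, EN = 0.42, CR = 0.97.
#'
#' @return An `extinction_model`.
#' @examples
#' iucn50()
#' @export
iucn50 <- function() {
  extinction_model("IUCN50",
                   LC = 0.00005, NT = 0.004, VU = 0.05, EN = 0.42, CR = 0.97)
}

#' @export
print.extinction_model <- function(x, ...) {
  cat("Extinction-probability model:", attr(x, "name"), "\n")
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

#' Read an extinction model from JSON
#'
#' Expects an object `{"name": ..., "LC": ..., ..., "CR": ...}`.
#' @param file JSON path.
#' @return An `extinction_model`.
#' @export
read_extinction_model <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  extinction_model(j$name, LC = j$LC, NT = j$NT, VU = j$VU, EN = j$EN, CR = j$CR)
}

#' Validate a species-to-category risk assessment
#'
#' @param risk Named character vector or factor: species -> category in
#'   LC, NT, VU, EN, CR, DD.
#' @return Named character vector.
#' @export
validate_risk <- function(risk) {
  risk <- stats::setNames(as.character(risk), trimws(names(risk)))
  if (is.null(names(risk)) || any(!nzchar(names(risk))))
    stop("risk assessment must be named by species", call. = FALSE)
  if (anyDuplicated(names(risk)))
    stop("duplicate species in risk assessment", call. = FALSE)
  bad <- setdiff(unique(risk), c(iucn_categories(), "DD"))
  if (length(bad))
    stop("unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  risk
}

#' Read a risk assessment from CSV
#'
#' Columns `species` and `category`; categories LC/NT/VU/EN/CR/DD.
#' @param file CSV path.
#' @return Named character vector of categories.
#' @export
read_risk <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("species", "category") %in% names(df)))
    stop("risk CSV needs columns 'species' and 'category'", call. = FALSE)
  validate_risk(stats::setNames(trimws(df$category), df$species))
}

#' Resolve data-deficient species under a scenario
#'
#' Data-deficient (DD) species are either removed (`"exclude"`), recoded as
#' least concern (`"as_LC"`) or recoded as critically endangered
#' (`"as_CR"`) — the two extreme assumptions bracketing their true status.
#'
#' @param risk Named category vector (may contain DD).
#' @param scenario One of `"exclude"`, `"as_LC"`, `"as_CR"`.
#' @return Named category vector without DD entries.
#' @export
apply_dd_scenario <- function(risk, scenario = c("exclude", "as_LC", "as_CR")) {
  scenario <- match.arg(scenario)
  risk <- validate_risk(risk)
  dd <- risk == "DD"
  switch(scenario,
         exclude = risk[!dd],
         as_LC = replace(risk, dd, "LC"),
         as_CR = replace(risk, dd, "CR"))
}

#' Map species to extinction probabilities
#'
#' @param risk Named category vector without DD (see [apply_dd_scenario()]).
#' @param model An `extinction_model`; default [iucn50()].
#' @return Named numeric vector of extinction probabilities.
#' @examples
#' extinction_probabilities(c(sp1 = "CR", sp2 = "LC"))
#' @export
extinction_probabilities <- function(risk, model = iucn50()) {
  risk <- validate_risk(risk)
  if (any(risk == "DD"))
    stop("DD categories present; resolve them with apply_dd_scenario() first",
         call. = FALSE)
  stats::setNames(as.numeric(unclass(model)[risk]), names(risk))
}

#' Ordinal midranks of extinction-risk categories
#'
#' Categories are ordered LC < NT < VU < EN < CR and rank-transformed with
#' midranks (ties within a category receive the block's average rank), the
#' standard treatment for Spearman correlations over heavily tied levels.
#'
#' @param risk Named category vector without DD.
#' @return Named numeric vector of midranks.
#' @export
risk_rank <- function(risk) {
  risk <- validate_risk(risk)
  if (any(risk == "DD"))
    stop("DD categories present; resolve them with apply_dd_scenario() first",
         call. = FALSE)
  ord <- match(risk, iucn_categories())
  stats::setNames(rank(ord, ties.method = "average"), names(risk))
}
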