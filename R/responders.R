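#' Default checkpoint-inhibitor response rates per TCGA gastric subtype
#'
#' Observed response fractions to PD-1 blockade in metastatic gastric
#' cancer: all MSI and EBV cases responded, versus 5% of CIN and 12% of GS
#' cases. These are configuration defaults, not constants.
#'
#' @return Named numeric vector over EBV, MSI, GS, CIN.
#' @export
default_response_rates <- function() {
  c(EBV = 1.0, MSI = 1.0, GS = 0.12, CIN = 0.05)
}

# round half away from zero at integer precision; a 9-decimal pre-round
# keeps binary artifacts (0.1 * 0.35 * 100 = 3.4999999999999996) on the
# half-way boundary they represent
round_half_up <- function(x) sign(x) * floor(round(abs(x), 9) + 0.5)

#' Expected checkpoint-inhibitor responder fraction of a group
#'
#' The estimated responder fraction of a patient group is the sum over
#' subtypes of (fraction of the group in that subtype) x (response rate of
#' that subtype).
#'
#' @param subtype_fractions Named nonnegative numeric over subtypes, summing
#'   to 1 (within 1e-9). Missing subtypes count as fraction 0.
#' @param rates Named response-rate vector in [0, 1]
#'   (default [default_response_rates()]).
#' @param group Group label carried into the result.
#' @return Object of class `"responder_estimate"`: `group`, `therapy`,
#'   `estimated_fraction`, `rounded_percent`, and `provenance` (the
#'   fraction x rate terms summed).
#' @export
checkpoint_responder_rate <- function(subtype_fractions,
                                      rates = default_response_rates(),
                                      group = "group") {
  if (any(subtype_fractions < 0)) stop("fractions must be nonnegative")
  if (abs(sum(subtype_fractions) - 1) > 1e-9)
    stop("subtype fractions must sum to 1")
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  unknown <- setdiff(names(subtype_fractions), names(rates))
  if (length(unknown)) stop("no response rate for: ",
                            paste(unknown, collapse = ", "))
  terms <- subtype_fractions * rates[names(subtype_fractions)]
  frac <- sum(terms)
  prov <- data.frame(subtype = names(subtype_fractions),
                     fraction = unname(subtype_fractions),
                     rate = unname(rates[names(subtype_fractions)]),
                     term = unname(terms), stringsAsFactors = FALSE)
  structure(list(group = group, therapy = "checkpoint_inhibitor",
                 estimated_fraction = frac,
                 rounded_percent = round_half_up(100 * frac),
                 provenance = prov),
            class = "responder_estimate")
}

#' Expected mTOR-inhibitor responder fraction of a group
#'
#' Product of the group's driver-gene (PIK3CA) mutation frequency and the
#' response rate of driver-mutant tumors to PI3K/AKT/mTOR pathway
#' inhibitors (default 0.35).
#'
#' @param driver_mutation_fraction Mutation frequency in [0, 1].
#' @param pathway_response_rate Response rate in [0, 1] (default 0.35).
#' @param group Group label carried into the result.
#' @param driver Driver gene name (default "PIK3CA").
#' @return A `"responder_estimate"` (see [checkpoint_responder_rate()]).
#' @examples
#' mtor_responder_rate(7 / 27)$rounded_percent  # 9
#' @export
mtor_responder_rate <- function(driver_mutation_fraction,
                                pathway_response_rate = 0.35,
                                group = "group", driver = "PIK3CA") {
  if (driver_mutation_fraction < 0 || driver_mutation_fraction > 1)
    stop("driver_mutation_fraction must lie in [0, 1]")
  if (pathway_response_rate < 0 || pathway_response_rate > 1)
    stop("pathway_response_rate must lie in [0, 1]")
  frac <- driver_mutation_fraction * pathway_response_rate
  prov <- data.frame(driver = driver,
                     mutation_fraction = driver_mutation_fraction,
                     response_rate = pathway_response_rate,
                     term = frac, stringsAsFactors = FALSE)
  structure(list(group = group, therapy = "mtor_inhibitor",
                 estimated_fraction = frac,
                 rounded_percent = round_half_up(100 * frac),
                 provenance = prov),
            class = "responder_estimate")
}

#' @export
print.responder_estimate <- function(x, ...) {
  cat(sprintf("%s / %s: estimated responder fraction %.4f (~%d%%)\n",
              x$group, x$therapy, x$estimated_fraction, x$rounded_percent))
  invisible(x)
}

#' Responder report over several patient groups
#'
#' One row per group and therapy. Groups supply either a subtype-fraction
#' vector (checkpoint estimate) or a driver mutation frequency (mTOR
#' estimate), or both. When `driver_in_responsive_subtypes = TRUE` (the
#' situation where every driver-mutant tumor falls in a subtype with
#' response rate 1), the report notes that the mTOR responders are a subset
#' of the checkpoint responders.
#'
#' @param groups Named list; each element a list with optional fields
#'   `subtype_fractions` and `driver_fraction`.
#' @param rates Checkpoint response rates (default
#'   [default_response_rates()]).
#' @param pathway_response_rate mTOR pathway response rate (default 0.35).
#' @param driver_in_responsive_subtypes Logical containment flag
#'   (default `FALSE`).
#' @return `data.frame`: `group`, `therapy`, `estimated_fraction`,
#'   `rounded_percent`; attribute `containment_note` when applicable.
#' @export
summarize_groups <- function(groups, rates = default_response_rates(),
                             pathway_response_rate = 0.35,
                             driver_in_responsive_subtypes = FALSE) {
  rows <- list()
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (!is.null(g$subtype_fractions)) {
      est <- checkpoint_responder_rate(g$subtype_fractions, rates, group = nm)
      rows[[length(rows) + 1L]] <- data.frame(
        group = nm, therapy = est$therapy,
        estimated_fraction = est$estimated_fraction,
        rounded_percent = est$rounded_percent, stringsAsFactors = FALSE)
    }
    if (!is.null(g$driver_fraction)) {
      est <- mtor_responder_rate(g$driver_fraction, pathway_response_rate,
                                 group = nm)
      rows[[length(rows) + 1L]] <- data.frame(
        group = nm, therapy = est$therapy,
        estimated_fraction = est$estimated_fraction,
        rounded_percent = est$rounded_percent, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (driver_in_responsive_subtypes)
    attr(out, "containment_note") <-
      paste("All driver-mutant tumors fall in fully responsive subtypes:",
            "estimated mTOR-inhibitor responders are a subset of the",
            "estimated checkpoint-inhibitor responders.")
  out
}
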