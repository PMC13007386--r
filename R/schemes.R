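# The four RSA condition schemes. Each scheme carves the trials into four
# conditions chosen so that one task feature (the scheme's own information
# type) varies over conditions together with one nuisance feature, giving a
# 4x4 RDM in which the feature of interest corresponds to a binary partition
# of the conditions.

INFO_TYPES <- c("across", "within", "rule", "response")

#' Condition labels and feature partitions for an RSA scheme
#'
#' Each of the four information types has its own regressor scheme with four
#' condition labels:
#' \describe{
#'   \item{across}{hemifield x rule: `left-r1, left-r2, right-r1, right-r2`}
#'   \item{within}{eccentricity x rule: `inner-r1, inner-r2, outer-r1, outer-r2`}
#'   \item{rule}{the four cue colours `c1..c4` (two per rule)}
#'   \item{response}{two response-group conditions plus one cue colour from
#'     each rule: `resp-inner, resp-outer, colour-a, colour-b`}
#' }
#' For every scheme, `factors` maps each information type that is decodable
#' within the scheme to the level of that feature in each condition (NA where
#' a condition has no level on that feature).
#'
#' @param scheme One of `"across"`, `"within"`, `"rule"`, `"response"`.
#' @param colour_rule_map Cue-colour to rule map (used by the rule scheme).
#' @return List with `scheme`, `conditions` (character 4-vector) and
#'   `factors` (named list of character 4-vectors).
#' @export
rsa_scheme <- function(scheme = INFO_TYPES,
                       colour_rule_map = default_colour_rule_map()) {
  scheme <- match.arg(scheme)
  switch(scheme,
    across = list(
      scheme = "across",
      conditions = c("left-r1", "left-r2", "right-r1", "right-r2"),
      factors = list(
        across = c("left", "left", "right", "right"),
        rule = c("1", "2", "1", "2"))),
    within = list(
      scheme = "within",
      conditions = c("inner-r1", "inner-r2", "outer-r1", "outer-r2"),
      factors = list(
        within = c("inner", "inner", "outer", "outer"),
        rule = c("1", "2", "1", "2"))),
    rule = {
      cols <- names(colour_rule_map)
      list(
        scheme = "rule",
        conditions = cols,
        factors = list(rule = unname(colour_rule_map[cols])))
    },
    response = list(
      scheme = "response",
      conditions = c("resp-inner", "resp-outer", "colour-a", "colour-b"),
      factors = list(
        response = c("inner", "outer", NA, NA)))
  )
}

#' Assign each trial to its condition under an RSA scheme
#'
#' Trials that cannot be assigned (omitted or incorrect trials, which are
#' excluded from all estimation) get NA.
#'
#' @param trials A `trial_table`.
#' @param scheme Scheme name, see [rsa_scheme()].
#' @param colour_rule_map Cue-colour to rule map.
#' @param response_colours For the response scheme: the two designated cue
#'   colours (one per rule) that form the `colour-a`/`colour-b` conditions;
#'   remaining trials fall into their response-group condition.
#' @return Factor of length `nrow(trials)` with the scheme's 4 condition
#'   levels (NA for excluded trials).
#' @export
scheme_conditions <- function(trials, scheme,
                              colour_rule_map = default_colour_rule_map(),
                              response_colours = NULL) {
  sch <- rsa_scheme(scheme, colour_rule_map)
  keep <- !trials$omitted & trials$correct
  lab <- rep(NA_character_, nrow(trials))
  if (scheme == "across") {
    lab[keep] <- paste0(trials$hemifield[keep], "-r", trials$rule[keep])
  } else if (scheme == "within") {
    lab[keep] <- paste0(trials$eccentricity[keep], "-r", trials$rule[keep])
  } else if (scheme == "rule") {
    lab[keep] <- trials$cue_colour[keep]
  } else {
    if (is.null(response_colours)) {
      # default: first colour of each rule in map order
      rules <- unique(unname(colour_rule_map))
      response_colours <- vapply(rules[1:2], function(r)
        names(colour_rule_map)[colour_rule_map == r][1], character(1))
    }
    if (length(response_colours) != 2L ||
        colour_rule_map[response_colours[1]] == colour_rule_map[response_colours[2]])
      stop("response_colours must name two cue colours from different rules")
    k <- keep
    lab[k] <- paste0("resp-", trials$response_group[k])
    ca <- k & trials$cue_colour == response_colours[1]
    cb <- k & trials$cue_colour == response_colours[2]
    lab[ca] <- "colour-a"
    lab[cb] <- "colour-b"
  }
  factor(lab, levels = sch$conditions)
}

# Binary partition of a scheme's four conditions by one information type:
# returns a logical "same level" 4x4 matrix used by model RDMs, or the level
# vector itself.
scheme_levels <- function(scheme, info_type,
                          colour_rule_map = default_colour_rule_map()) {
  sch <- rsa_scheme(scheme, colour_rule_map)
  lev <- sch$factors[[info_type]]
  if (is.null(lev))
    stop("information type '", info_type, "' is not defined for scheme '",
         scheme, "'")
  lev
}
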