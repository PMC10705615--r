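#' Recognised production species groups
#'
#' The five species groups covered by the assessment: goats, sheep, alpacas,
#' waterfowl and cattle. Waterfowl is a single group (ducks and geese share
#' the same mutilation rules).
#'
#' @return Character vector of species identifiers.
#' @export
#' @examples
#' species_levels()
species_levels <- function() {
  c("alpaca", "goat", "sheep", "cattle", "waterfowl")
}

#' The four scored welfare domains and their provisions
#'
#' The Five Domains hierarchy used throughout: four scored domains
#' (nutrition, physical environment, health, behavioural interactions),
#' each owning its provisions. The fifth domain, mental state, carries no
#' indicators of its own; its score is derived as the median of the four
#' scored domains.
#'
#' @return Named list mapping domain id to a character vector of provision
#'   ids, in canonical order (2 + 3 + 4 + 3 = 12 provisions).
#' @export
#' @examples
#' domain_provisions()
domain_provisions <- function() {
  list(
    nutrition = c("appropriate_feed", "appropriate_water"),
    physical_environment = c("environmental_comfort", "resting_comfort",
                             "ease_of_movement"),
    health = c("absence_of_injuries", "absence_of_disease", "mutilations",
               "fitness"),
    behavioural_interactions = c("environmental_enrichment",
                                 "social_behaviour",
                                 "human_animal_relationship")
  )
}

#' All provision identifiers
#'
#' @return Character vector of the 12 canonical provision ids, in the order
#'   of [domain_provisions()].
#' @export
provision_levels <- function() {
  unname(unlist(domain_provisions()))
}

#' Risk category labels
#'
#' @return Character vector of the five welfare risk band labels, worst
#'   first.
#' @export
category_labels <- function() {
  paste("Probability for", c("very poor", "poor", "acceptable", "good",
                             "excellent"), "animal welfare")
}

# internal: domain owning a provision
provision_domain <- function(provision) {
  dp <- domain_provisions()
  for (d in names(dp)) if (provision %in% dp[[d]]) return(d)
  stop("unknown provision id: ", provision, call. = FALSE)
}
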