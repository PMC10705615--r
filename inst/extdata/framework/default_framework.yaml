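# Default Five Domains framework configuration.
#
# Paper-exact parts: the appropriate-feed decision tree (all species) and
# the per-species mutilation rules. Everything else is ILLUSTRATIVE:
# the remaining provisions carry placeholder trees (monotone, two or three
# single measures, leaves on the usual grid of fives) so the assessment is
# runnable end-to-end, and the capacities are ranking-built defaults
# (interaction 0.3), NOT the expert-elicited weights. Replace trees and
# capacities with your own elicited configuration for real assessments.

domains:
  nutrition: [appropriate_feed, appropriate_water]
  physical_environment: [environmental_comfort, resting_comfort, ease_of_movement]
  health: [absence_of_injuries, absence_of_disease, mutilations, fitness]
  behavioural_interactions: [environmental_enrichment, social_behaviour, human_animal_relationship]

questions:
  ad_libitum_roughage: "Is ad libitum access to roughage required?"
  appropriate_feed_quantity: "Is an appropriate quantity of (additional) feed required?"
  bcs_management: "Is the Body Condition Score of the animals regularly monitored and are the workers knowledgeable in assessing it?"
  water_quality: "Is water of appropriate quality required?"
  unlimited_water_quantity: "Is an unlimited quantity of water required?"
  unrestricted_water_access: "Is unrestricted access to water required?"
  appropriate_shelter_climate: "Is proper shelter with appropriate climate (temperature, ventilation) required?"
  noise_protection: "Are animals protected from loud noises?"
  appropriate_bedding: "Are appropriate bedding and flooring required?"
  appropriate_resting_area: "Is an appropriate resting area required?"
  no_tethering_or_isolation: "Is keeping animals tethered or individually prohibited?"
  minimum_space_requirements: "Are minimum space requirements defined?"
  daily_injury_checks: "Are daily injury checks of the herd required?"
  lameness_management: "Is proper management of lameness required?"
  regular_veterinary_checks: "Are regular veterinary checks required?"
  preventative_healthcare: "Are preventative measures (parasite control, vaccinations) and appropriate healthcare required?"
  year_round_outdoor_access: "Is year-round outdoor access (an outdoor run) required?"
  pasture_access: "Is access to pasture required?"
  enrichment_provided: "Is environmental enrichment required?"
  structured_living_area: "Is an appropriately structured living area required?"
  stable_groups: "Are animals required to be kept in stable, age-appropriate groups?"
  no_early_weaning: "Is early separation of young from their mothers prohibited?"
  positive_handling: "Is positive handling (including during shearing) required?"
  habituation_to_procedures: "Is habituation to routine husbandry procedures required?"

trees:
  # --- reference tree (paper-exact), shared by all species ---
  - provision: appropriate_feed
    species: all
    questions: [ad_libitum_roughage, appropriate_feed_quantity, bcs_management]
    leaves: {"yyy": 100, "yyn": 65, "yny": 55, "ynn": 35, "nyy": 45, "nyn": 25, "nny": 35, "nnn": 5}
    monotone: true

  # --- illustrative placeholder trees (leaf scores are NOT elicited) ---
  - provision: appropriate_water
    species: all
    questions: [water_quality, unlimited_water_quantity, unrestricted_water_access]
    leaves: {"yyy": 100, "yyn": 65, "yny": 55, "ynn": 30, "nyy": 45, "nyn": 25, "nny": 30, "nnn": 5}
    monotone: true
  - provision: environmental_comfort
    species: all
    questions: [appropriate_shelter_climate, noise_protection]
    leaves: {"yy": 100, "yn": 65, "ny": 35, "nn": 5}
    monotone: true
  - provision: resting_comfort
    species: all
    questions: [appropriate_bedding, appropriate_resting_area]
    leaves: {"yy": 100, "yn": 65, "ny": 35, "nn": 5}
    monotone: true
  - provision: ease_of_movement
    species: all
    questions: [no_tethering_or_isolation, minimum_space_requirements]
    leaves: {"yy": 100, "yn": 65, "ny": 35, "nn": 5}
    monotone: true
  - provision: absence_of_injuries
    species: all
    questions: [daily_injury_checks, lameness_management]
    leaves: {"yy": 100, "yn": 65, "ny": 35, "nn": 5}
    monotone: true
  - provision: absence_of_disease
    species: all
    questions: [regular_veterinary_checks, preventative_healthcare]
    leaves: {"yy": 100, "yn": 65, "ny": 35, "nn": 5}
    monotone: true
  - provision: fitness
    species: all
    questions: [year_round_outdoor_access, pasture_access]
    leaves: {"yy": 100, "yn": 65, "ny": 35, "nn": 5}
    monotone: true
  - provision: environmental_enrichment
    species: all
    questions: [enrichment_provided, structured_living_area]
    leaves: {"yy": 100, "yn": 65, "ny": 35, "nn": 5}
    monotone: true
  - provision: social_behaviour
    species: all
    questions: [stable_groups, no_early_weaning]
    leaves: {"yy": 100, "yn": 65, "ny": 35, "nn": 5}
    monotone: true
  - provision: human_animal_relationship
    species: all
    questions: [positive_handling, habituation_to_procedures]
    leaves: {"yy": 100, "yn": 65, "ny": 35, "nn": 5}
    monotone: true

  # --- mutilation rules (items are paper-exact; graded partial scores are
  #     configuration defaults reproducing the observed score vocabulary) ---
  - provision: mutilations
    species: [alpaca]
    type: mutilation_rule
    items: {castration: graded}
  - provision: mutilations
    species: [goat, cattle]
    type: mutilation_rule
    items: {dehorning: graded, tail_docking: graded, castration: graded}
  - provision: mutilations
    species: [sheep]
    type: mutilation_rule
    items: {dehorning: graded, tail_docking: graded, castration: graded, mulesing: prohibition_only}
  - provision: mutilations
    species: [waterfowl]
    type: mutilation_rule
    items: {live_plucking: prohibition_only, force_feeding: prohibition_only, flight_restraint: prohibition_only}

# Illustrative ranking-built capacities (interaction 0.3): the published
# domain scores are NOT reproducible from these defaults; the elicited
# capacities are user-suppliable configuration.
capacities:
  nutrition:
    ranking: [appropriate_feed, appropriate_water]
    interaction: 0.3
  physical_environment:
    ranking: [ease_of_movement, resting_comfort, environmental_comfort]
    interaction: 0.3
  health:
    ranking: [mutilations, absence_of_disease, absence_of_injuries, fitness]
    interaction: 0.3
  behavioural_interactions:
    ranking: [social_behaviour, human_animal_relationship, environmental_enrichment]
    interaction: 0.3

bands:
  - {lower: 0, upper: 19, label: "Probability for very poor animal welfare"}
  - {lower: 20, upper: 39, label: "Probability for poor animal welfare"}
  - {lower: 40, upper: 59, label: "Probability for acceptable animal welfare"}
  - {lower: 60, upper: 79, label: "Probability for good animal welfare"}
  - {lower: 80, upper: 100, label: "Probability for excellent animal welfare"}
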