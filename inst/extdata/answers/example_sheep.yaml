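# Example answer file: a fictitious wool standard assessed against the
# default framework (sheep). Every value is a yes/no answer to one
# single-measure question about the standard's obligatory requirements.
standard: "example-wool-standard"
species: sheep
answers:
  appropriate_feed:
    ad_libitum_roughage: no
    appropriate_feed_quantity: yes
    bcs_management: yes
  appropriate_water:
    water_quality: yes
    unlimited_water_quantity: yes
    unrestricted_water_access: no
  environmental_comfort:
    appropriate_shelter_climate: yes
    noise_protection: no
  resting_comfort:
    appropriate_bedding: yes
    appropriate_resting_area: no
  ease_of_movement:
    no_tethering_or_isolation: yes
    minimum_space_requirements: yes
  absence_of_injuries:
    daily_injury_checks: yes
    lameness_management: yes
  absence_of_disease:
    regular_veterinary_checks: no
    preventative_healthcare: yes
  fitness:
    year_round_outdoor_access: no
    pasture_access: yes
  environmental_enrichment:
    enrichment_provided: no
    structured_living_area: no
  social_behaviour:
    stable_groups: no
    no_early_weaning: yes
  human_animal_relationship:
    positive_handling: yes
    habituation_to_procedures: no
mutilations:
  dehorning: prohibited
  tail_docking: allowed_full_pain_relief
  castration: allowed_partial_pain_relief
  mulesing: prohibited
  other_mutilations_allowed: no
meta:
  note: "Fictitious standard for demonstration; standards in the packaged results are anonymised by number."
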