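# Reference decision tree for the appropriate feed provision.
# Shared by all five species; three single measures, eight leaf scores.
provision: appropriate_feed
species: all
questions:
  - ad_libitum_roughage
  - appropriate_feed_quantity
  - bcs_management
leaves:
  "yyy": 100
  "yyn": 65
  "yny": 55
  "ynn": 35
  "nyy": 45
  "nyn": 25
  "nny": 35
  "nnn": 5
monotone: true
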