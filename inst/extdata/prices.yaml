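# Unit prices for the societal cost model, euro at 2013 year-end prices
# (1 EUR = 8.94 SEK). Participant time valued at gross hourly wages of
# women with the same educational level; the default carries the cohort
# mean wage for both strata.
assessment_cost: 6.4
wage_by_education:
  university: 29.61
  other: 29.61
aid_unit_price: 0.134
laundry_load_price: 2.21
currency: "EUR (2013 year-end)"
sek_per_eur: 8.94
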