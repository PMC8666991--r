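# Average medication cost per recorded use-interval (investigator forms at
# 3, 6, 9 and 12 months), pounds sterling, by category.
# calibrated: false -- the source analysis does not publish its category
# averages; these are placeholder values of realistic magnitude and should
# be replaced with study-specific averages of the most commonly occurring
# medications within each category.
category,avg_cost
oral_opioid,26.00
oral_nsaid,9.50
topical_nsaid,12.00
antidepressant_neuropathic,18.50
simple_analgesic,5.50
other_medication,15.00
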