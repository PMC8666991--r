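# Unit costs of healthcare resource use, UK pounds sterling at 2015 prices,
# derived from established national costing sources (NHS reference costs and
# PSSRU unit costs). The two free-text "other" questionnaire slots per
# setting share that setting's "other" rate.
item,unit_cost,unit_description
hospital_outpatient,114.50,Per hospital outpatient clinic visit
a_and_e,140.59,Per accident & emergency attendance
other_outpatient_1,115.88,Per other outpatient visit
other_outpatient_2,115.88,Per other outpatient visit
gp_practice,44.00,Per GP patient contact at surgery (11.7 mins)
gp_home,88.92,Per GP home visit (11.4 mins plus 12 mins travel)
nurse_practice,11.11,Per 15.5 min nurse appointment (at 43 pounds per hour)
other_primary_1,33.30,Per other primary care visit
other_primary_2,33.30,Per other primary care visit
physiotherapist,38.00,Per physiotherapist hour
occupational_therapist,44.00,Per occupational therapist hour
other_community_1,66.57,Per other community care visit
other_community_2,66.57,Per other community care visit
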