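# Genotype effect profiles: multiplicative mutant/wild-type scalings applied
# by generate_cohort() to the planted wild-type parameters, one profile per
# age group. The structural scalings are transcribed from the percent group
# differences measured in the Lmna G609G progeria mouse cohorts that this
# pipeline quantifies (a scaling s plants a 100*(s-1) percent difference).
# Calcium scalings are 1: matrix mineralization does not differ by genotype.
# The empty-lacuna scaling is illustrative only; the increase is established
# but its magnitude is not published as a number.
"8W":
  growth_plate: 0.82        # -18% unmineralized resting+proliferative zone
  bvtv_primary: 0.77        # -23% primary-spongiosa BV/TV
  bvtv_secondary: 0.64      # -36% secondary-spongiosa BV/TV
  tbth_primary: 1.00        # primary Tb.Th unchanged
  tbth_secondary: 0.79      # -21% secondary Tb.Th
  bvtv_epiphysis: 1.00
  tbth_epiphysis: 1.00
  ca_cortex: 1.00
  ca_epiphysis: 1.00
  ca_metaphysis: 1.00
  empty_fraction: 2.00      # illustrative; direction only
"15W":
  growth_plate: 0.75        # -25%
  bvtv_primary: 0.62        # -38%
  bvtv_secondary: 0.51      # -49% (below significance at n = 7/7)
  tbth_primary: 1.00
  tbth_secondary: 0.76      # -24%
  bvtv_epiphysis: 1.00
  tbth_epiphysis: 1.00
  ca_cortex: 1.00
  ca_epiphysis: 1.00
  ca_metaphysis: 1.00
  empty_fraction: 2.00
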