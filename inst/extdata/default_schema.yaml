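# Default invasiveness scoring schema shipped with invacast.
#
# Synthetic default: 21 criteria in the four attribute groups used by
# biodiversity-focused invasiveness ranking systems (ecological impact,
# invasive characteristics, dispersal ability, feasibility of control),
# with group maxima 40 / 25 / 25 / 10 summing to 100. Prompts and point
# values are editable; the scoring engine only requires the structure.
name: default invasiveness ranking schema
prescreen_note: >
  Record here the outcome of any climate-match pre-screen between the
  species' known range and the assessment area.
criteria:
  - id: EI1
    prompt: Impact on ecosystem processes (fire, hydrology, nutrient cycling)
    group: ecological impact
    max_points: 10
    levels: {none: 0, minor: 3, moderate: 7, severe: 10}
  - id: EI2
    prompt: Impact on natural community structure
    group: ecological impact
    max_points: 10
    levels: {none: 0, minor: 3, moderate: 7, severe: 10}
  - id: EI3
    prompt: Impact on natural community composition
    group: ecological impact
    max_points: 10
    levels: {none: 0, minor: 3, moderate: 7, severe: 10}
  - id: EI4
    prompt: Impact on higher trophic levels and rare taxa
    group: ecological impact
    max_points: 10
    levels: {none: 0, minor: 3, moderate: 7, severe: 10}
  - id: IC1
    prompt: Mode and vigour of reproduction
    group: invasive characteristics
    max_points: 4
    levels: {low: 0, moderate: 2, high: 4}
  - id: IC2
    prompt: Propagule production per plant
    group: invasive characteristics
    max_points: 4
    levels: {low: 0, moderate: 2, high: 4}
  - id: IC3
    prompt: Seed bank longevity
    group: invasive characteristics
    max_points: 4
    levels: {short: 0, intermediate: 2, long: 4}
  - id: IC4
    prompt: Growth rate and competitive ability
    group: invasive characteristics
    max_points: 4
    levels: {low: 0, moderate: 2, high: 4}
  - id: IC5
    prompt: Tolerance of broad environmental conditions
    group: invasive characteristics
    max_points: 3
    levels: {narrow: 0, intermediate: 2, broad: 3}
  - id: IC6
    prompt: Benefits from disturbance
    group: invasive characteristics
    max_points: 3
    levels: {'no': 0, somewhat: 2, strongly: 3}
  - id: IC7
    prompt: Documented invasiveness elsewhere
    group: invasive characteristics
    max_points: 3
    levels: {'no': 0, regional: 2, widespread: 3}
  - id: DA1
    prompt: Long-distance dispersal by wind or water
    group: dispersal ability
    max_points: 5
    levels: {'no': 0, occasional: 3, frequent: 5}
  - id: DA2
    prompt: Dispersal by animals
    group: dispersal ability
    max_points: 4
    levels: {'no': 0, occasional: 2, frequent: 4}
  - id: DA3
    prompt: Spread by human activity and transport corridors
    group: dispersal ability
    max_points: 4
    levels: {'no': 0, occasional: 2, frequent: 4}
  - id: DA4
    prompt: Vegetative fragment dispersal and establishment
    group: dispersal ability
    max_points: 4
    levels: {'no': 0, occasional: 2, frequent: 4}
  - id: DA5
    prompt: Availability of invasion pathways into the assessment area
    group: dispersal ability
    max_points: 4
    levels: {few: 0, some: 2, many: 4}
  - id: DA6
    prompt: Rate of historical range expansion
    group: dispersal ability
    max_points: 4
    levels: {slow: 0, moderate: 2, rapid: 4}
  - id: FC1
    prompt: Effectiveness of available control methods (reversed)
    group: feasibility of control
    max_points: 3
    levels: {effective: 0, partial: 2, ineffective: 3}
  - id: FC2
    prompt: Likelihood of reinvasion after control
    group: feasibility of control
    max_points: 3
    levels: {low: 0, moderate: 2, high: 3}
  - id: FC3
    prompt: Detectability at low abundance (reversed)
    group: feasibility of control
    max_points: 2
    levels: {easy: 0, moderate: 1, difficult: 2}
  - id: FC4
    prompt: Non-target damage expected from control
    group: feasibility of control
    max_points: 2
    levels: {low: 0, moderate: 1, high: 2}
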