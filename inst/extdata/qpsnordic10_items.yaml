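# Default 10-item demand-control set (QPSNordic-guided): 4 psychological
# demand items and 6 decision-latitude (job control) items, all on 1-5
# frequency scales.
#
# adverse_high = true  : larger raw values mean more adverse exposure
# adverse_high = false : larger raw values mean LESS adverse exposure; the
#                        item is aligned by reflection before dichotomization
#
# Orientations for the control items are documented coding assumptions:
# frequent opportunity to decide, use and develop skills is protective
# (adverse_high: false), while frequent monotonous work is itself adverse.
name: qpsnordic10
items:
  - item_id: quantitative_demands
    label: "Quantitative demands (too much to do)"
    dimension: demand
    scale_min: 1
    scale_max: 5
    adverse_high: true
  - item_id: conflicting_ways
    label: "Conflicting ways of doing things"
    dimension: demand
    scale_min: 1
    scale_max: 5
    adverse_high: true
  - item_id: insufficient_resources
    label: "Insufficient resources to complete tasks"
    dimension: demand
    scale_min: 1
    scale_max: 5
    adverse_high: true
  - item_id: contradictory_requests
    label: "Contradictory requests from superiors"
    dimension: demand
    scale_min: 1
    scale_max: 5
    adverse_high: true
  - item_id: decide_how
    label: "Decide how to go about the work"
    dimension: control
    scale_min: 1
    scale_max: 5
    adverse_high: false
  - item_id: decide_pace
    label: "Decide the pace of work"
    dimension: control
    scale_min: 1
    scale_max: 5
    adverse_high: false
  - item_id: important_decisions
    label: "Take part in important decisions"
    dimension: control
    scale_min: 1
    scale_max: 5
    adverse_high: false
  - item_id: use_skills
    label: "Use acquired skills and knowledge"
    dimension: control
    scale_min: 1
    scale_max: 5
    adverse_high: false
  - item_id: develop_skills
    label: "Opportunity to develop skills"
    dimension: control
    scale_min: 1
    scale_max: 5
    adverse_high: false
  - item_id: monotonous_work
    label: "Monotonous, repetitive work"
    dimension: control
    scale_min: 1
    scale_max: 5
    adverse_high: true
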