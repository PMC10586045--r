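# Default hourly fall-risk concept network.
# Three-layer tree: binary target at the root, latent construct-summary
# nodes (none/one/multi active findings) below it, observable feature nodes
# at the leaves. Single-feature constructs attach directly to the target.
# The first state of every feature node is its reference (low-risk) state;
# `active_states` overrides which states count as active findings when the
# summary columns are derived, and `risk_category` links a node to the
# intervention risk-factor categories used by the CDS rules.
nodes:
  - name: fall_next_hour
    states: ["no", "yes"]
    construct: target
  - name: admin_summary
    states: [none, one, multi]
    construct: demographics_admin
    role: summary
  - name: med_summary
    states: [none, one, multi]
    construct: medication
    role: summary
  - name: assess_summary
    states: [none, one, multi]
    construct: nursing_assessment_diagnosis
    role: summary
  - name: age_band
    states: [a18_49, a50_69, a70_plus]
    construct: demographics_admin
    risk_category: mobility
    active_states: [a70_plus]
  - name: prior_fall
    states: ["no", "yes"]
    construct: demographics_admin
    risk_category: mobility
  - name: kpcs_transfer
    states: [independent, assisted, dependent]
    construct: kpcs
    risk_category: mobility
    active_states: [assisted, dependent]
  - name: kpcs_ambulation
    states: [independent, assisted, dependent]
    construct: kpcs
    risk_category: mobility
    active_states: [assisted, dependent]
  - name: kpcs_consciousness
    states: [alert, confused]
    construct: kpcs
    risk_category: cognition
  - name: sedative
    states: ["no", "yes"]
    construct: medication
    risk_category: medications
  - name: diuretic
    states: ["no", "yes"]
    construct: medication
    risk_category: medications
  - name: other_highrisk_med
    states: ["no", "yes"]
    construct: medication
    risk_category: medications
  - name: impaired_mobility
    states: ["no", "yes"]
    construct: nursing_assessment_diagnosis
    risk_category: mobility
  - name: confusion_dx
    states: ["no", "yes"]
    construct: nursing_assessment_diagnosis
    risk_category: cognition
  - name: toileting_urgency
    states: ["no", "yes"]
    construct: nursing_assessment_diagnosis
    risk_category: toileting
  - name: sensory_deficit
    states: ["no", "yes"]
    construct: nursing_assessment_diagnosis
    risk_category: sensory
  - name: sleep_disturbance
    states: ["no", "yes"]
    construct: nursing_assessment_diagnosis
    risk_category: sleep
  - name: fall_precaution_active
    states: ["no", "yes"]
    construct: nursing_intervention
  - name: heuristic_band
    states: [low, med, high]
    construct: heuristic_tool
    active_states: [med, high]
edges:
  - [fall_next_hour, admin_summary]
  - [fall_next_hour, med_summary]
  - [fall_next_hour, assess_summary]
  - [fall_next_hour, fall_precaution_active]
  - [fall_next_hour, heuristic_band]
  - [admin_summary, age_band]
  - [admin_summary, prior_fall]
  - [admin_summary, kpcs_transfer]
  - [admin_summary, kpcs_ambulation]
  - [admin_summary, kpcs_consciousness]
  - [med_summary, sedative]
  - [med_summary, diuretic]
  - [med_summary, other_highrisk_med]
  - [assess_summary, impaired_mobility]
  - [assess_summary, confusion_dx]
  - [assess_summary, toileting_urgency]
  - [assess_summary, sensory_deficit]
  - [assess_summary, sleep_disturbance]
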