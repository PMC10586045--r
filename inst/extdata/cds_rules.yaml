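# Tailored-recommendation rules linking predicted risk-factor categories and
# medication classes to catalog intervention statements. The cognition and
# diuretic+sedative rules encode the two worked clinical examples; the
# remaining rules are illustrative defaults, one per risk category. The
# universal block is always recommended regardless of predicted risk.
universal: [UNI01, UNI02, ENM01]
rules:
  - id: cognition_supervision
    risk_categories: [cognition]
    recommended: [RTC01, RTC02, ALM01]
    priority: 10
  - id: diuretic_sedative
    med_classes: [diuretic, sedative]
    recommended: [RTC03, RTC04, RTC05, EDU01, EDU02]
    priority: 20
  - id: toileting_schedule
    risk_categories: [toileting]
    recommended: [RTC06]
    priority: 30
  - id: mobility_assist
    risk_categories: [mobility]
    recommended: [RTC07]
    priority: 30
  - id: sensory_aids
    risk_categories: [sensory]
    recommended: [RTC08, EDU02]
    priority: 30
  - id: sleep_protocol
    risk_categories: [sleep]
    recommended: [RTC09, ENM02]
    priority: 30
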