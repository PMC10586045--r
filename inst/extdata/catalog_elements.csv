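"care_element","category","n_statements"
"pathophysiological","assessment_diagnosis_outcome",19
"therapeutics","assessment_diagnosis_outcome",7
"cognitive_factors","assessment_diagnosis_outcome",10
"risk_behaviors","assessment_diagnosis_outcome",3
"communication_ability","assessment_diagnosis_outcome",1
"situational_factors","assessment_diagnosis_outcome",1
"physical_environment","assessment_diagnosis_outcome",1
"universal_care","intervention",13
"environmental_management","intervention",11
"risk_targeted_care","intervention",19
"education_provision","intervention",6
"information_sharing","intervention",5
"alarm_monitoring","intervention",2
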